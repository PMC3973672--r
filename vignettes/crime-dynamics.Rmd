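---
title: "Compartmental dynamics of crime, incarceration and recidivism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartmental dynamics of crime, incarceration and recidivism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crimedyn)
```

## The models

`crimedyn` implements a hierarchy of deterministic compartmental models in
which criminal activity spreads through a fixed population of size $N$ the
way an infection does: by contact. The population is partitioned into
compartments — law-abiding ($X$), criminally active ($C$, possibly split by
offense stage), incarcerated ($I$), and recently released ($R$) — and flows
between them are first-order in the source compartment, except for the
contagion terms discussed below. Three families are provided:

* **3D** ($X, C, I$): onset at rate $\beta$ by contact (plus an optional
  autonomous rate $\varepsilon$), desistance $\delta$, incarceration
  $\sigma$, and release split into an assimilating stream $\rho_x$ (back to
  $X$) and a recidivating stream $\rho_c$ (straight back to $C$).
* **5D** ($X, C_1, I, R, C_2$): first-time offenders $C_1$ desist
  ($\delta_1$) or are incarcerated ($\sigma_1$); prison releases at rate
  $\rho$ into a reentry compartment $R$, from which people either achieve
  redemption ($\phi$, back to $X$) or recidivate into $C_2$ — by propensity
  ($\nu_p$) or by contact with the criminally active ($\nu_c$). Recidivists
  desist back to $R$ ($\delta_2$) or return to prison ($\sigma_2$).
* **9D** ($X, C_1, I_1, R_1, C_2, I_2, R_2, C_3, I_3$): the same structure
  unrolled over three incarceration spells, with per-stage rates
  ($\delta_k, \sigma_k, \rho_k$) and per-reentry recidivism/redemption
  pairs ($\nu_{p,j}, \nu_{c,j}, \phi_j$). Setting $\rho_3 = 0$ is the
  strict three-strike regime: the third incarceration is absorbing.
  With $\rho_3 > 0$ ("leakage" from life sentences) released lifers
  re-enter the second reentry stage, and fourth-or-higher incarcerations
  return to $I_3$.

The **no-parole** system is the 3D family with both release rates zero:
prison is absorbing and the non-incarcerated population $X + C$ can only
shrink (`no_parole_lyapunov()` verifies $\dot V = -\sigma C \le 0$ for
$V = X + C$ numerically).

All vector fields conserve $N$ exactly (their components sum to zero
algebraically) and preserve nonnegativity.

## The contagion incidence

Every recruitment-by-contact flow uses a single shared form, the
street-prevalence incidence
$$\beta \, X \, \frac{C_{\text{active}}}{S}, \qquad
  S = N - I_{\text{total}},$$
where $S$ is the street (non-incarcerated) population. The per-capita risk
of being drawn into crime is proportional to the *prevalence* of active
criminals among the people one actually encounters — the incarcerated are
removed from the mixing pool. This choice is load-bearing: it is the one
incidence form under which

* the tipping points carry no factor of $N$, and
* the street noncriminal fraction at the endemic equilibrium is exactly
  $1/R_0$ (the SIS prevalence law), which the test suite verifies to
  $10^{-10}$ across random parameter sweeps.

The same helper drives the recidivism contagion terms
$\nu_c R \, C_{\text{active}}/S$, with $C_{\text{active}}$ the *total*
criminally active street population ($C_1 + C_2$ in the 5D model,
$C_1+C_2+C_3$ in the 9D model): recently released individuals are recruited
back by the whole criminal milieu, not only by fellow recidivists.

## Tipping points

Each family has a closed-form basic reproduction ratio returned with its
input/output term decomposition (`r0_3d()`, `r0_5d()`, `r0_9d()`):

$$R_0^{(3)} = \frac{\beta}{\delta + \sigma w}, \qquad
  w = \frac{\rho_x}{\rho_x + \rho_c},$$

$$R_0^{(5)} = \frac{\beta}{\delta_1+\sigma_1}
  \left(1 + \frac{\sigma_1 \nu}{(\delta_2+\sigma_2)\,\phi}\right),
  \qquad \nu = \nu_c + \nu_p,$$

$$R_0^{(9)} = \frac{\beta}{\delta_1+\sigma_1}
  \left(1 + \frac{\sigma_1\nu_1}{D_1}
          + \frac{\sigma_1\nu_1}{D_1}\,
            \frac{\sigma_2\nu_2}{(\delta_3+\sigma_3)\,\phi_2}\right),
  \qquad D_1 = \sigma_2\nu_1 + \phi_1(\delta_2+\sigma_2).$$

Structural facts the tests pin down: the incarceration rate in the 3D
denominator is attenuated by the non-recidivism release fraction $w$; the
$\nu_c, \nu_p$ pairs enter only through their sums; every $R_0$ is
independent of the release rates (prison term length has no effect on the
threshold) and of $\varepsilon$. When both release rates are zero nobody
ever recidivates, so $w = 1$ and the no-parole threshold is
$\beta/(\delta+\sigma)$.

The asymmetry between the 5D second-term denominator
$(\delta_2+\sigma_2)\phi$ and the 9D stage-2 denominator $D_1$ is real, not
a typo: in the 5D model a re-incarcerated recidivist is released back into
the *same* reentry compartment and can recidivate again (only redemption
$\phi$ permanently removes them), whereas in the 9D model re-incarceration
advances them to stage 3. Both forms were derived twice independently —
from the Lyapunov feasibility chain and from the endemic equilibrium
elimination — and agree.

### Sensitivities

All partials of $R_0^{(5)}$ are analytic, each cross-checked against a
central finite difference (`sensitivity_suite()`, agreement $10^{-6}$
relative). The headline sign result:
$$\frac{\partial R_0}{\partial \sigma_1}
  = \frac{\beta}{(\delta_1+\sigma_1)^2}
    \left(\frac{\nu\,\delta_1}{(\delta_2+\sigma_2)\phi} - 1\right),$$
so incarcerating first-time offenders faster reduces long-run crime only
while $\nu\,\delta_1 < (\delta_2+\sigma_2)\,\phi$ — recidivism small
relative to rehabilitation and redemption. Enforcement against recidivists
($\sigma_2$), desistance ($\delta_1, \delta_2$) and redemption ($\phi$)
lower $R_0$ unconditionally; $\beta$ scales it linearly.

## Equilibria

With contagion-only onset ($\varepsilon = 0$) and non-contagious recidivism
($\nu_c = 0$), the positive endemic equilibrium is closed-form: the reentry
chain gives each compartment as a linear multiple of $C_1$, the prevalence
law fixes $X$, and the total fixes the scale (`endemic_3d/5d/9d()`). Below
threshold the functions return `NULL` — "no endemic state exists" is
distinct from a degenerate state. Residuals of the closed forms, plugged
back into the full vector fields, stay below $10^{-10} N$.

`numeric_equilibrium()` covers the general regime ($\varepsilon \ge 0$,
$\nu_c \ge 0$). It root-finds on the *reduced* system in the
active-criminal occupancies only: at equilibrium the incarcerated
compartments are linear in the $C$'s ($I = \sigma C/\rho$), hence the
street total is known, and the reentry compartments follow from their
balance equations. The 3D case is a bracketed scalar problem solved with
`uniroot` (the bracket endpoints have opposite signs by construction); the
5D/9D cases use Newton iteration (`pracma::fsolve`) from ten dispersed
starts, accepting only nonnegative solutions with residual below
$10^{-9} N$, and rejecting the trivial crime-free root when
$\varepsilon = 0$. Uniqueness is spot-checked by requiring agreement across
dispersed starts.

"Street" prevalence always uses the non-incarcerated denominator
($X + C_1 + R + C_2$ in the 5D model).

## Lyapunov certificates

`find_certificate_2d/5d/9d()` construct linear functions
$V = \sum_i w_i x_i$ of the non-$X$ compartments whose derivative along
trajectories is negative on the positive orthant, certifying *global*
convergence to the crime-free state. The bilinear contagion terms are
bounded by their worst case over the simplex ($X/S \le 1$,
$C_{\text{active}}/S \le 1$); collecting the per-compartment bracket
coefficients yields a chain of open interval conditions on the weights
whose solvability is algebraically equivalent to $R_0 < 1$ — strict, so at
$R_0 = 1$ the search honestly reports infeasible.

Construction is deterministic: the weight of $C_1$ (or $C$) is normalized
to 1 and each remaining weight is taken at the midpoint of its feasible
interval, walking the chain in dependency order (5D: $w_I, w_R, w_{C_2}$;
9D: $w_{R_2}$ first — its interval is what couples the stage-2/3 chain back
to the $C_1$ bracket — then $w_{I_3}, w_{C_3}, w_{I_2}, w_{I_1}, w_{R_1},
w_{C_2}$). Half-infinite intervals take `lower + lower` (or 1). Every
certificate records its minimal bracket slack, and `verify_certificate()`
checks $\dot V < 0$ on the *exact* field (not the bound) at states sampled
uniformly on the simplex with a fixed seed.

## Phase-plane classification

For the planar reduction of the 3D family (`isoclines_2d()`,
`classify_planar()`): the $\dot I = 0$ isocline is the line
$I = \sigma C/(\rho_x+\rho_c)$; clearing the street denominator makes the
$\dot C = 0$ isocline a quadratic curve whose C-axis roots are $0$ and
$N(1 - (\delta+\sigma)/\beta)$ when $\varepsilon = 0$. The three-case
classification follows the sign of the second root and the slope comparison
at the origin (which is exactly $R_0 \lessgtr 1$): `case1` (second root
nonnegative) and `case2` (negative root but $R_0 > 1$) flow to the endemic
state; `case3` ($R_0 < 1$) makes the crime-free origin globally stable.
Roots within $10^{-9}N$ of zero are reported as boundary (`"at"`). For
$\varepsilon > 0$ the curve's value at $C = 0$ drops below the origin, the
roots take opposite signs, and exactly one equilibrium lies in the closed
quadrant — low-crime or high-crime by the same threshold. "Globally
stable" is spot-checked, not proven: reference orbits must land within
$10^{-4}N$ of the predicted attractor.

## What the random-parameter generator emulates — and what it does not

`sample_params()` draws every rate log-uniformly on $[10^{-2}, 10]$ with
$N$ fixed. Three decades per rate straddle the tipping point from both
sides, put the small-recidivism condition both ways, and mix fast
enforcement with slow social processes. This emulates *parameter*
diversity, not realism: the models themselves assume a homogeneous,
well-mixed, closed population with constant rates, so passing tests say the
implementation honors the mathematics, not that any particular community
behaves this way. No empirical calibration is attempted anywhere in the
package.

### Scope of the two-sided threshold law

One scoping decision deserves emphasis. The recidivism contagion term
$\nu_c R C/S$ is bilinear, so it contributes to the worst-case (global
Lyapunov) threshold — which is why $\nu = \nu_c + \nu_p$ appears in
$R_0$ — but vanishes from the linearization at the crime-free state. For
$\nu_c \gg \nu_p$ there is consequently a wedge where $R_0 > 1$ yet the
crime-free state remains locally attracting (a backward-bifurcation
geometry), and a small perturbation returns to it. Numerically, with all
rates sampled log-uniformly, about 7–9% of 5D/9D draws land in this wedge.
The randomized two-sided agreement experiment (`threshold_agreement()`)
therefore runs the 5D/9D families with $\nu_c = 0$, where the dichotomy
"crime-free iff $R_0 < 1$" is exact; a separate property keeps $\nu_c > 0$
and asserts the one-sided guarantee that $R_0 < 1$ forces crime-free
convergence, which the Lyapunov certificate proves and simulations confirm
without exception. The same caveat applies to the $1/R_0$ prevalence law,
which fails under contagious recidivism; `endemic_5d/9d()` refuse
$\nu_c > 0$ and route callers to the numeric solver.

## Numerical choices

* **Integration**: `deSolve::lsodar` with `rtol = 1e-10`,
  `atol = 1e-10 N`, stopping early when
  $\max_i |\dot x_i| < 10^{-10} N$ (configurable). Conservation drift
  over the test horizons stays below $10^{-6}N$ and excursions below
  $-10^{-9}N$ are treated as zero by clipping states passed to the field.
* **Classification**: an endpoint is stationary if
  $\max_i |\dot x_i| < 10^{-7} N$; matching a reference equilibrium uses
  $10^{-3}N$; a horizon hit without stationarity or a match is flagged
  `undetermined`, never guessed.
* **Horizons**: $10^5$ time units for threshold experiments (near the
  exclusion band $|R_0 - 1| < 0.05$ convergence is slow);
  $\max(10^6, 10^3/\varepsilon)$ for three-strike absorption with
  autonomous onset, because a crime career started at rate $\varepsilon$
  reaches the third strike only with modest probability, making the
  effective absorption rate a fraction of $\varepsilon$.
* **Problem sizes**: the randomized suites use 200 parameter sets per
  family for threshold agreement, 100 for the prevalence and certificate
  laws, 1000 Monte-Carlo states per certificate — sizes at which every law
  tested is exercised across its qualitative regimes while the whole suite
  runs in about a minute.
* **Diminishing returns** (prison-term sweep): the equilibrium prison
  population is $I^* = N A L/(B + AL)$ in the term length $L = 1/\rho$
  (with $A, B$ positive constants), so gains per added year of term always
  shrink; the flag tests concavity on the $L$ scale. (Gains per *log-step*
  of $\rho$ are not monotone — they peak at $\rho = A/B$ — so that scale
  is not used.)
* **No-parole sweep defaults**: $N = 120$ with
  $\delta + \sigma = 0.5$, so $R_0 = 2\beta$ and the threshold sits at
  $\beta = 0.5$.

## Known limitations

* The models are deterministic mean-field ODEs: no stochasticity, age,
  space, crime-type or justice-stage structure (arrest, conviction,
  sentencing are collapsed into single rates).
* Closed-form equilibria require $\varepsilon = 0$ and $\nu_c = 0$; under
  contagious recidivism only the numeric path and the one-sided stability
  guarantee apply.
* Lyapunov certificates are only sought for $\varepsilon = 0$ (with
  autonomous onset there is no crime-free equilibrium to certify).
* Degenerate corners where an entire outflow channel vanishes (for
  example $\phi = 0$ with $\nu > 0$, which drives $R_0 \to \infty$, or an
  absorbing reentry compartment) raise informative errors rather than
  returning fabricated states.

## A worked policy example

```{r example}
p <- params_5d(beta = 1, delta1 = 0.3, sigma1 = 0.4, rho = 1,
               nu_p = 0.2, nu_c = 0, delta2 = 0.2, sigma2 = 0.5,
               phi = 0.3, N = 120)
r0_5d(p)

endemic_5d(p)

sw <- prison_term_sweep(p, rho_grid = c(10, 1, 0.1))
sw$grid[, c("rho", "X", "C1", "I", "R", "C2", "street_noncriminal")]

dr0_dsigma1(p)
```

Longer prison terms move people into prison without touching either the
tipping point or the street prevalence of crime; whether tougher
enforcement on first offenders helps at all depends on the recidivism
condition above.
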