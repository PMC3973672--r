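#' Random admissible parameter sets for property experiments
#'
#' Samples every rate log-uniformly on `[1e-2, 1e1]` (spanning slow social
#' processes to fast enforcement, and putting the small-recidivism condition
#' on both sides), with `N` fixed. Intended as the fixture generator for the
#' randomized threshold, prevalence and certificate experiments.
#'
#' @param model `"3d"`, `"5d"` or `"9d"`.
#' @param n number of parameter sets.
#' @param seed RNG seed.
#' @param eps autonomous onset rate (default 0: contagion-only variants).
#' @param nu_c_zero set all recidivism contagion coefficients to zero (the
#'   regime in which the closed-form equilibria and the exact tipping-point
#'   law are established).
#' @param N total population for every set.
#' @param range log-uniform range for each rate.
#' @return List of parameter objects.
#' @export
sample_params <- function(model, n, seed = 1L, eps = 0, nu_c_zero = FALSE,
                          N = 100, range = c(1e-2, 1e1)) {
  model <- match.arg(model, c("3d", "5d", "9d"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lu <- function(k) exp(stats::runif(k, log(range[1]), log(range[2])))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    out[[i]] <- switch(model,
      "3d" = params_3d(beta = lu(1), delta = lu(1), sigma = lu(1),
                       rho_x = lu(1), rho_c = lu(1), eps = eps, N = N),
      "5d" = {
        nc <- if (nu_c_zero) 0 else lu(1)
        params_5d(beta = lu(1), delta1 = lu(1), sigma1 = lu(1), rho = lu(1),
                  nu_p = lu(1), nu_c = nc, delta2 = lu(1), sigma2 = lu(1),
                  phi = lu(1), eps = eps, N = N)
      },
      "9d" = {
        nc1 <- if (nu_c_zero) 0 else lu(1)
        nc2 <- if (nu_c_zero) 0 else lu(1)
        params_9d(beta = lu(1), delta1 = lu(1), sigma1 = lu(1), rho1 = lu(1),
                  nu_p1 = lu(1), nu_c1 = nc1, phi1 = lu(1),
                  delta2 = lu(1), sigma2 = lu(1), rho2 = lu(1),
                  nu_p2 = lu(1), nu_c2 = nc2, phi2 = lu(1),
                  delta3 = lu(1), sigma3 = lu(1), rho3 = lu(1),
                  eps = eps, N = N)
      })
  }
  out
}

#' Randomized threshold-versus-simulation agreement experiment
#'
#' For each sampled parameter set (outside an exclusion band around
#' `R0 = 1`, where convergence is arbitrarily slow), integrates from a
#' 1%-criminally-active perturbation of the crime-free state and records
#' whether the long-run outcome (crime-free versus endemic) matches the
#' analytic classification `R0 < 1` versus `R0 > 1`.
#'
#' @param model model family.
#' @param n number of parameter sets to sample (sets inside the band are
#'   dropped, so fewer rows may be returned).
#' @param seed sampler seed.
#' @param band half-width of the `|R0 - 1|` exclusion band.
#' @param horizon integration horizon.
#' @param nu_c_zero,eps passed to [sample_params()].
#' @return Data frame: `r0`, `predicted`, `simulated`, `agree` per set.
#' @export
threshold_agreement <- function(model, n = 200, seed = 1L, band = 0.05,
                                horizon = 1e5, nu_c_zero = FALSE, eps = 0) {
  sets <- sample_params(model, n, seed = seed, eps = eps,
                        nu_c_zero = nu_c_zero)
  rows <- lapply(sets, function(p) {
    r0 <- crime_r0(p)$r0
    if (abs(r0 - 1) < band) return(NULL)
    traj <- integrate_model(model, p, perturbed_start(model, p$N),
                            horizon = horizon)
    fs <- final_state(traj)
    act <- sum(fs[active_idx(model)]) / street_population(fs, model)
    sim <- if (eps == 0) {
      if (act < 1e-4) "crime_free" else "endemic"
    } else {
      # low/high-crime split: compare to the midpoint of the two regimes
      if (act < 0.5 * max(1 - 1 / r0, 0.02)) "crime_free" else "endemic"
    }
    pred <- if (r0 < 1) "crime_free" else "endemic"
    data.frame(r0 = r0, predicted = pred, simulated = sim,
               agree = identical(sim, pred))
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Prison-term-length sweep (release-rate invariance law)
#'
#' Computes the endemic equilibrium across a grid of release rates `rho`
#' (term length `1/rho`). The tipping point and the street prevalences are
#' invariant along the grid, while the individual equilibrium compartments
#' shift: as terms lengthen (`rho` decreases) the prison population grows and
#' every street compartment shrinks, with diminishing returns per log-step.
#'
#' @param params a [params_5d()] with `eps = 0`; `nu_c = 0` uses the closed
#'   form, otherwise the numeric path.
#' @param rho_grid release-rate grid (any order; stored as given).
#' @return `"sweep_result"`: data frame of equilibria plus monotonicity and
#'   diminishing-returns flags (evaluated in decreasing-`rho` order).
#' @export
prison_term_sweep <- function(params, rho_grid = 10^seq(1, -1, length.out = 9)) {
  stopifnot(inherits(params, "params_5d"))
  rows <- lapply(rho_grid, function(r) {
    p <- params; p$rho <- r
    eq <- if (p$eps == 0 && p$nu_c == 0) endemic_5d(p)
          else numeric_equilibrium("5d", p)
    if (is.null(eq)) stop("prison_term_sweep needs an above-threshold parameter set")
    data.frame(rho = r, t(eq$state), r0 = crime_r0(p)$r0,
               street_noncriminal = eq$street_noncriminal_prevalence)
  })
  df <- do.call(rbind, rows)
  o <- order(df$rho, decreasing = TRUE)   # rho decreasing = terms lengthening
  d <- df[o, ]
  mono <- list(
    I_increasing = all(diff(d$I) > 0),
    X_decreasing = all(diff(d$X) < 0),
    C1_decreasing = all(diff(d$C1) < 0),
    R_decreasing = all(diff(d$R) < 0),
    C2_decreasing = all(diff(d$C2) <= 1e-12 * params$N),
    r0_constant = diff(range(df$r0)) < 1e-12 * max(df$r0),
    prevalence_constant = diff(range(df$street_noncriminal)) < 1e-10)
  # diminishing returns on the term-length scale: I* is concave in L = 1/rho,
  # so the secant slope dI/dL shrinks as terms lengthen
  L <- 1 / d$rho
  slopes <- diff(d$I) / diff(L)
  diminishing <- all(diff(slopes) < 1e-9 * params$N)
  structure(list(grid = df, monotone = mono,
                 diminishing_returns = diminishing),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  print(x$grid, digits = 4)
  cat("monotone flags:", paste(names(which(unlist(x$monotone))), collapse = ", "),
      "\n")
  invisible(x)
}

#' No-parole sweep of the contagion rate across the tipping point
#'
#' Reproduces the dramatic regime change in the long-run street and prison
#' populations as `R0` crosses 1 in the no-release system: above threshold
#' the entire population ends up incarcerated; below threshold the community
#' splits between the law-abiding and the incarcerated, with the prison share
#' shrinking as `R0` falls.
#'
#' @param params [params_3d()] template with zero release rates, `eps = 0`.
#' @param beta_grid contagion-rate grid to sweep.
#' @param init_frac initially criminally active fraction.
#' @param horizon integration horizon.
#' @return `"sweep_result"` with per-beta `r0` and final compartments.
#' @export
no_parole_r0_sweep <- function(params, beta_grid, init_frac = 0.05,
                               horizon = 1e5) {
  stopifnot(inherits(params, "params_3d"))
  if (params$rho_x != 0 || params$rho_c != 0)
    stop("no_parole_r0_sweep requires zero release rates")
  rows <- lapply(beta_grid, function(b) {
    p <- params; p$beta <- b
    traj <- integrate_model("no_parole", p,
                            perturbed_start("no_parole", p$N, init_frac),
                            horizon = horizon)
    fs <- final_state(traj)
    data.frame(beta = b, r0 = r0_3d(p)$r0, X = fs[["X"]], C = fs[["C"]],
               I = fs[["I"]])
  })
  df <- do.call(rbind, rows)
  structure(list(grid = df, monotone = list(), diminishing_returns = NA),
            class = "sweep_result")
}

#' Three-strike policy experiment
#'
#' Long-run outcomes of the strict three-strike regime (`rho3 = 0`:
#' mandatory life sentence at the third conviction). With contagion-only
#' onset (`eps = 0`): above threshold every orbit is absorbed into prison;
#' below threshold active crime dies out and the population splits between
#' the never-criminal, the redeemed and the lifers, in proportions that
#' depend on the initial condition. Any positive autonomous onset
#' (`eps > 0`) makes lifetime incarceration the only long-run outcome
#' regardless of `R0`.
#'
#' @param params a [params_9d()] with `rho3 = 0`.
#' @param init_fracs initially criminally active fractions, one run each.
#' @param horizon integration horizon; `eps > 0` absorption is slow (time
#'   scale `1/eps`), so long horizons are used there.
#' @param tol classification tolerance relative to N.
#' @return Data frame: one row per start with final compartments and label.
#' @export
three_strike_experiment <- function(params, init_fracs = c(0.05, 0.3),
                                    horizon = NULL, tol = 1e-3) {
  stopifnot(inherits(params, "params_9d"))
  if (params$rho3 != 0)
    stop("three-strike regime requires rho3 = 0 (no release from the third incarceration)")
  # with eps > 0 absorption into I3 is slow: a career started at rate eps
  # only ends in the third strike with modest probability, so the effective
  # absorption rate is a fraction of eps
  if (is.null(horizon))
    horizon <- if (params$eps > 0) max(1e6, 1e3 / params$eps) else 1e5
  N <- params$N
  rows <- lapply(init_fracs, function(f) {
    traj <- integrate_model("9d", params, perturbed_start("9d", N, f),
                            horizon = horizon)
    fs <- final_state(traj)
    act <- sum(fs[active_idx("9d")])
    noninc <- street_population(fs, "9d")
    label <- if (noninc < tol * N) "all_incarcerated"
             else if (params$eps == 0 && act < tol * N) "crime_free"
             else "undetermined"
    cbind(data.frame(init_frac = f, label = label, active = act,
                     street = noninc), t(fs))
  })
  do.call(rbind, rows)
}
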