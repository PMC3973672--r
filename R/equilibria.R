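#' Endemic (high-crime) equilibria of the contagion-only models
#'
#' Closed forms for the unique positive steady state when onset is purely
#' contagion driven (`eps = 0`) and — for the 5D/9D families — recidivism has
#' no contagion component (`nu_c = 0`). At that equilibrium the street
#' noncriminal prevalence obeys the SIS-like law
#' \deqn{X^*/\mathrm{street}^* = 1/R_0,}
#' so the criminally active street fraction is `1 - 1/R0`. Below threshold
#' (`R0 <= 1`) no positive equilibrium exists and the functions return `NULL`
#' so callers can distinguish "none exists" from a degenerate state.
#'
#' @param params parameter object with `eps = 0` (and `nu_c = 0` where
#'   required; the 1/R0 law fails when recidivism is itself contagious, in
#'   which case use [numeric_equilibrium()]).
#' @return An object of class `"equilibrium_solution"` (fields `state`,
#'   `kind`, `residual`, `street_noncriminal_prevalence`), or `NULL` when
#'   `R0 <= 1`.
#' @export
endemic_3d <- function(params) {
  stopifnot(inherits(params, "params_3d"))
  if (params$eps > 0)
    stop("closed-form endemic equilibrium requires eps = 0; use numeric_equilibrium()")
  r0 <- r0_3d(params)$r0
  if (r0 <= 1) return(NULL)
  rel <- params$rho_x + params$rho_c
  if (rel == 0)
    stop("no positive endemic state without release: prison is absorbing")
  # street composition: X = street/R0, C = street (1 - 1/R0); I from dI = 0.
  c_per_street <- 1 - 1 / r0
  i_per_street <- params$sigma * c_per_street / rel
  street <- params$N / (1 + i_per_street)
  state <- c(X = street / r0, C = street * c_per_street,
             I = street * i_per_street)
  equilibrium_solution(state, "3d", params, kind = "endemic")
}

#' @rdname endemic_3d
#' @export
endemic_5d <- function(params) {
  stopifnot(inherits(params, "params_5d"))
  if (params$eps > 0)
    stop("closed-form endemic equilibrium requires eps = 0; use numeric_equilibrium()")
  if (params$nu_c > 0)
    stop("closed form requires nu_c = 0 (1/R0 law fails under contagious recidivism); use numeric_equilibrium()")
  r0 <- r0_5d(params)$r0
  if (r0 <= 1) return(NULL)
  if (params$rho == 0)
    stop("no positive endemic state without release: prison is absorbing")
  # per unit of C1: linear chain ratios from the equilibrium balance
  k2 <- if (params$nu_p == 0) 0 else
    params$nu_p * params$sigma1 /
      ((params$delta2 + params$sigma2) * params$phi)
  r_ <- if (params$phi == 0) 0 else params$sigma1 / params$phi
  i_ <- (params$sigma1 + params$sigma2 * k2) / params$rho
  if (params$nu_p > 0 && params$phi == 0)
    stop("threshold undefined at phi = 0 with recidivism; no endemic closed form")
  x_ <- (1 + r_ + k2) / (r0 - 1)
  scale <- params$N / (x_ + 1 + i_ + r_ + k2)
  state <- c(X = x_, C1 = 1, I = i_, R = r_, C2 = k2) * scale
  equilibrium_solution(state, "5d", params, kind = "endemic")
}

#' @rdname endemic_3d
#' @export
endemic_9d <- function(params) {
  stopifnot(inherits(params, "params_9d"))
  if (params$eps > 0)
    stop("closed-form endemic equilibrium requires eps = 0; use numeric_equilibrium()")
  if (params$nu_c1 > 0 || params$nu_c2 > 0)
    stop("closed form requires nu_c1 = nu_c2 = 0; use numeric_equilibrium()")
  r0 <- r0_9d(params)$r0
  if (r0 <= 1) return(NULL)
  if (params$rho1 == 0)
    stop("no positive endemic state without release from first incarceration")
  d2 <- params$delta2 + params$sigma2
  d3 <- params$delta3 + params$sigma3
  k2 <- if (params$nu_p1 == 0) 0 else
    params$nu_p1 * params$sigma1 /
      (params$sigma2 * params$nu_p1 + params$phi1 * d2)
  k3 <- if (params$nu_p2 == 0 || k2 == 0) 0 else
    params$nu_p2 * params$sigma2 * k2 / (d3 * params$phi2)
  if (k3 > 0 && params$rho3 == 0)
    stop("strict three-strike regime (rho3 = 0) admits no endemic state; third incarceration is absorbing")
  r1 <- (params$sigma1 + params$delta2 * k2) / (params$nu_p1 + params$phi1)
  r2 <- if (params$nu_p2 + params$phi2 == 0) 0 else
    (params$sigma2 * k2 + (params$delta3 + params$sigma3) * k3) /
      (params$nu_p2 + params$phi2)
  i1 <- params$sigma1 / params$rho1
  i2 <- if (k2 == 0) 0 else params$sigma2 * k2 / params$rho2
  i3 <- if (k3 == 0) 0 else params$sigma3 * k3 / params$rho3
  x_ <- (1 + r1 + k2 + r2 + k3) / (r0 - 1)
  scale <- params$N / (x_ + 1 + i1 + r1 + k2 + i2 + r2 + k3 + i3)
  state <- c(X = x_, C1 = 1, I1 = i1, R1 = r1, C2 = k2,
             I2 = i2, R2 = r2, C3 = k3, I3 = i3) * scale
  equilibrium_solution(state, "9d", params, kind = "endemic")
}

equilibrium_solution <- function(state, model, params, kind) {
  rhs <- rhs_for(model)
  res <- max(abs(rhs(pmax(state, 0), params)))
  structure(list(state = state, model = model, kind = kind, residual = res,
                 street_noncriminal_prevalence =
                   street_noncriminal_prevalence(state, model)),
            class = "equilibrium_solution")
}

#' @export
print.equilibrium_solution <- function(x, ...) {
  cat(sprintf("<equilibrium: %s (%s)>  residual %.3g, street noncriminal %.4f\n",
              x$kind, x$model, x$residual, x$street_noncriminal_prevalence))
  print(round(x$state, 6))
  invisible(x)
}

#' Numeric equilibrium for any parameter regime
#'
#' Finds the unique nonnegative equilibrium of the chosen family by Newton
#' root-finding on the *reduced* system obtained from the linear equilibrium
#' relations: all incarcerated and reentry compartments are expressed in the
#' active-criminal occupancies, leaving a system in `C` (3D), `(C1, C2)` (5D)
#' or `(C1, C2, C3)` (9D). Valid for `eps >= 0` and `nu_c >= 0`. For `eps > 0`
#' the solution is classified `low_crime` (`R0 < 1`) or `high_crime`
#' (`R0 > 1`); for `eps = 0` above threshold it is the endemic state.
#'
#' @param model `"3d"`, `"5d"` or `"9d"`.
#' @param params matching parameter object; release rates must be positive.
#' @param guess optional initial guess for the active compartments (fractions
#'   of N); dispersed restarts are tried on failure.
#' @param tol residual tolerance relative to N.
#' @return An `"equilibrium_solution"`; `NULL` for `eps = 0` below threshold.
#' @export
numeric_equilibrium <- function(model, params, guess = NULL, tol = 1e-9) {
  model <- match.arg(model, c("3d", "5d", "9d"))
  r0 <- crime_r0(params)$r0
  if (params$eps == 0 && r0 <= 1) return(NULL)
  N <- params$N
  fn <- reduced_system(model, params)
  if (model == "3d") {
    # scalar problem with a guaranteed bracket: f(0+) > 0 (autonomous onset,
    # or growth when r0 > 1) and f at the X = 0 boundary <= 0
    hi <- N / (1 + params$sigma / (params$rho_x + params$rho_c))
    lo <- if (params$eps > 0) 0 else 1e-12 * N
    root <- stats::uniroot(function(z) fn(z), c(lo, hi * (1 - 1e-12)),
                           tol = 1e-15 * N, extendInt = "no")$root
    state <- reduced_to_state(model, params, root)
    eq <- equilibrium_solution(pmax(state, 0), model, params,
                               kind = equilibrium_kind(params, r0))
    if (eq$residual >= tol * N)
      stop(sprintf("numeric_equilibrium: bracketed root residual %.3g exceeds tolerance",
                   eq$residual))
    return(eq)
  }
  k <- switch(model, "5d" = 2L, "9d" = 3L)
  starts <- list()
  if (!is.null(guess)) starts <- c(starts, list(as.numeric(guess)))
  base <- c(0.3, 0.05, 0.6, 0.01, 0.15, 0.45, 0.75, 0.002, 0.9, 1e-4)
  for (b in base) starts <- c(starts, list(rep(b * N, k)))
  for (s in starts) {
    sol <- try(pracma::fsolve(fn, s, tol = 1e-13), silent = TRUE)
    if (inherits(sol, "try-error")) next
    x <- sol$x
    if (any(!is.finite(x)) || any(x < -1e-9 * N)) next
    # for eps = 0 the crime-free state is always a root; we want the positive one
    if (params$eps == 0 && sum(x) < 1e-7 * N) next
    state <- reduced_to_state(model, params, pmax(x, 0))
    if (is.null(state) || any(state < -1e-8 * N)) next
    eq <- equilibrium_solution(pmax(state, 0), model, params,
                               kind = equilibrium_kind(params, r0))
    if (eq$residual < tol * N) return(eq)
  }
  stop(sprintf(
    "numeric_equilibrium: no converged nonnegative root after %d starts (model %s, r0 = %.3g)",
    length(starts), model, r0))
}

equilibrium_kind <- function(params, r0) {
  if (params$eps > 0) {
    if (r0 < 1) "low_crime" else "high_crime"
  } else "endemic"
}

# residual functions in the active-criminal unknowns; incarcerated and
# reentry compartments eliminated through the linear balance equations
# (street total is N minus incarcerated, known once the C's are fixed).
reduced_system <- function(model, params) {
  N <- params$N
  if (model == "3d") {
    rel <- params$rho_x + params$rho_c
    if (rel <= 0) stop("numeric_equilibrium requires a positive release rate")
    function(z) {
      C <- z[1]
      I <- params$sigma * C / rel
      X <- N - C - I
      street <- N - I
      inc <- incidence(params$beta, X, C, street) + params$eps * X
      inc - (params$delta + params$sigma) * C + params$rho_c * I
    }
  } else if (model == "5d") {
    if (params$rho <= 0) stop("numeric_equilibrium requires rho > 0")
    if (params$nu_p + params$nu_c + params$phi <= 0)
      stop("reentry compartment is absorbing (nu and phi all zero): no equilibrium")
    function(z) {
      s <- reduced_to_state("5d", params, z, clip = FALSE)
      active <- s[["C1"]] + s[["C2"]]
      street <- params$N - s[["I"]]
      g <- (if (street > 0) params$nu_c * active / street else 0) + params$nu_p
      onset <- incidence(params$beta, s[["X"]], active, street) +
        params$eps * s[["X"]]
      c(onset - (params$delta1 + params$sigma1) * s[["C1"]],
        g * s[["R"]] - (params$delta2 + params$sigma2) * s[["C2"]])
    }
  } else {
    if (params$rho1 <= 0 || params$rho2 <= 0 || params$rho3 <= 0)
      stop("numeric_equilibrium for the 9D family requires all release rates positive")
    if (params$nu_p1 + params$nu_c1 + params$phi1 <= 0 ||
        params$nu_p2 + params$nu_c2 + params$phi2 <= 0)
      stop("a reentry compartment is absorbing: no equilibrium")
    function(z) {
      s <- reduced_to_state("9d", params, z, clip = FALSE)
      active <- s[["C1"]] + s[["C2"]] + s[["C3"]]
      street <- params$N - s[["I1"]] - s[["I2"]] - s[["I3"]]
      g1 <- (if (street > 0) params$nu_c1 * active / street else 0) + params$nu_p1
      g2 <- (if (street > 0) params$nu_c2 * active / street else 0) + params$nu_p2
      onset <- incidence(params$beta, s[["X"]], active, street) +
        params$eps * s[["X"]]
      c(onset - (params$delta1 + params$sigma1) * s[["C1"]],
        g1 * s[["R1"]] - (params$delta2 + params$sigma2) * s[["C2"]],
        g2 * s[["R2"]] - (params$delta3 + params$sigma3) * s[["C3"]])
    }
  }
}

# expand the reduced unknowns (active compartments) to a full state using the
# linear balance relations for incarceration (dI = 0) and reentry (dR = 0);
# with clip = TRUE a state with meaningfully negative X is rejected (NULL).
reduced_to_state <- function(model, params, z, clip = TRUE) {
  N <- params$N
  if (model == "3d") {
    C <- z[1]
    I <- params$sigma * C / (params$rho_x + params$rho_c)
    X <- N - C - I
    if (clip && X < -1e-8 * N) return(NULL)
    c(X = X, C = C, I = I)
  } else if (model == "5d") {
    C1 <- z[1]; C2 <- z[2]
    I <- (params$sigma1 * C1 + params$sigma2 * C2) / params$rho
    street <- N - I
    active <- C1 + C2
    g <- (if (street > 0) params$nu_c * active / street else 0) + params$nu_p
    R <- (params$rho * I + params$delta2 * C2) / (g + params$phi)
    X <- street - C1 - R - C2
    if (clip && X < -1e-8 * N) return(NULL)
    c(X = X, C1 = C1, I = I, R = R, C2 = C2)
  } else {
    C1 <- z[1]; C2 <- z[2]; C3 <- z[3]
    I1 <- params$sigma1 * C1 / params$rho1
    I2 <- params$sigma2 * C2 / params$rho2
    I3 <- params$sigma3 * C3 / params$rho3
    street <- N - I1 - I2 - I3
    active <- C1 + C2 + C3
    g1 <- (if (street > 0) params$nu_c1 * active / street else 0) + params$nu_p1
    g2 <- (if (street > 0) params$nu_c2 * active / street else 0) + params$nu_p2
    R1 <- (params$rho1 * I1 + params$delta2 * C2) / (g1 + params$phi1)
    R2 <- (params$rho2 * I2 + params$delta3 * C3 + params$rho3 * I3) /
      (g2 + params$phi2)
    X <- street - C1 - R1 - C2 - R2 - C3
    if (clip && X < -1e-8 * N) return(NULL)
    c(X = X, C1 = C1, I1 = I1, R1 = R1, C2 = C2, I2 = I2, R2 = R2,
      C3 = C3, I3 = I3)
  }
}
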