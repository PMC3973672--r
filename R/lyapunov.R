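#' Constructive linear Lyapunov certificates for the crime-free equilibrium
#'
#' For each contagion-only model (`eps = 0`) these functions attempt to build
#' a linear function `V = sum(w_i * x_i)` of the non-X compartments, with all
#' weights positive, whose derivative along trajectories is negative on the
#' positive orthant — certifying *global* convergence to the crime-free
#' state. Feasibility of the weight inequalities is exactly equivalent to
#' `R0 < 1` (strict; at `R0 = 1` the open feasibility intervals are empty and
#' the search reports infeasible).
#'
#' The construction normalizes the first active-criminal weight to 1 and picks
#' every remaining weight at the midpoint of its feasible interval, walking
#' the inequality chain in dependency order, so certificates are deterministic
#' and carry strictly positive slack. The bilinear contagion terms are bounded
#' by their worst case over the state simplex (`X/street <= 1`,
#' `active/street <= 1`), which is what brings `nu_c` into the 5D/9D
#' feasibility conditions.
#'
#' @param params parameter object with `eps = 0`.
#' @return An object of class `"lyapunov_certificate"`: named positive
#'   `coefficients`, logical `feasible`, `slack` (minimal margin of the
#'   bracket inequalities, relative), and the `r0` used.
#' @export
find_certificate_2d <- function(params) {
  stopifnot(inherits(params, "params_3d"))
  if (params$eps > 0) stop("Lyapunov certificates require eps = 0")
  r0 <- r0_3d(params)$r0
  if (r0 >= 1) return(infeasible_certificate(c("C", "I"), r0))
  # V = C + a I; brackets: [beta - (delta+sigma) + a sigma] C
  #                        [rho_c - a (rho_x + rho_c)] I
  lo <- 1 - nonrecidivism_fraction(params)
  hi <- if (params$sigma > 0)
    (params$delta + params$sigma - params$beta) / params$sigma else Inf
  a <- pick_in(lo, hi)
  coefs <- c(C = 1, I = a)
  brackets <- c(
    C = -(params$beta - (params$delta + params$sigma) + a * params$sigma),
    I = if (params$rho_x + params$rho_c > 0)
      -(params$rho_c - a * (params$rho_x + params$rho_c)) else NA_real_)
  certificate(coefs, brackets, r0)
}

#' @rdname find_certificate_2d
#' @export
find_certificate_5d <- function(params) {
  stopifnot(inherits(params, "params_5d"))
  if (params$eps > 0) stop("Lyapunov certificates require eps = 0")
  r0 <- r0_5d(params)$r0
  nm <- c("C1", "I", "R", "C2")
  if (r0 >= 1) return(infeasible_certificate(nm, r0))
  b <- params$beta; d1 <- params$delta1; s1 <- params$sigma1
  d2 <- params$delta2; s2 <- params$sigma2; phi <- params$phi
  nu <- params$nu_c + params$nu_p
  # V = C1 + wI I + wR R + wC2 C2 (weight of C1 normalized to 1).
  # Bracket chain (worst case over the simplex):
  #   C1: beta - (d1+s1) + wI s1 < 0
  #   I : rho (wR - wI) < 0
  #   R : (wC2 - wR) nu - wR phi < 0
  #   C2: beta + wI s2 + wR d2 - wC2 (d2+s2) < 0
  wI_lo <- if (nu == 0) 0 else b * nu / (phi * (d2 + s2))
  wI_hi <- if (s1 > 0) (d1 + s1 - b) / s1 else Inf
  wI <- pick_in(wI_lo, wI_hi)
  wR_lo <- if (nu == 0) 0 else
    nu * (b + wI * s2) / (nu * s2 + phi * (d2 + s2))
  wR <- pick_in(wR_lo, wI)
  wC2_lo <- (b + wI * s2 + wR * d2) / (d2 + s2)
  wC2_hi <- if (nu == 0) Inf else wR * (nu + phi) / nu
  wC2 <- pick_in(wC2_lo, wC2_hi)
  coefs <- c(C1 = 1, I = wI, R = wR, C2 = wC2)
  brackets <- c(
    C1 = -(b - (d1 + s1) + wI * s1),
    I  = -(params$rho * (wR - wI)),
    R  = -((wC2 - wR) * nu - wR * phi),
    C2 = -(b + wI * s2 + wR * d2 - wC2 * (d2 + s2)))
  if (params$rho == 0) brackets[["I"]] <- NA_real_
  if (nu == 0 && phi == 0) brackets[["R"]] <- NA_real_
  certificate(coefs, brackets, r0)
}

#' @rdname find_certificate_2d
#' @export
find_certificate_9d <- function(params) {
  stopifnot(inherits(params, "params_9d"))
  if (params$eps > 0) stop("Lyapunov certificates require eps = 0")
  r0 <- r0_9d(params)$r0
  nm <- c("C1", "I1", "R1", "C2", "I2", "R2", "C3", "I3")
  if (r0 >= 1) return(infeasible_certificate(nm, r0))
  b <- params$beta
  d1 <- params$delta1; s1 <- params$sigma1
  d2 <- params$delta2; s2 <- params$sigma2
  d3 <- params$delta3; s3 <- params$sigma3
  f1 <- params$phi1; f2 <- params$phi2
  nu1 <- params$nu_c1 + params$nu_p1
  nu2 <- params$nu_c2 + params$nu_p2
  # V = C1 + w2 I1 + w3 R1 + w4 C2 + w5 I2 + w6 R2 + w7 C3 + w8 I3.
  # Brackets: C1: b - (d1+s1) + w2 s1 < 0
  #           I1: rho1 (w3 - w2) < 0
  #           R1: (w4 - w3) nu1 - w3 f1 < 0
  #           C2: b + w3 d2 - w4 (d2+s2) + w5 s2 < 0
  #           I2: rho2 (w6 - w5) < 0
  #           R2: (w7 - w6) nu2 - w6 f2 < 0
  #           C3: b + w6 d3 - w7 (d3+s3) + w8 s3 < 0
  #           I3: rho3 (w6 - w8) < 0
  w2_hi <- if (s1 > 0) (d1 + s1 - b) / s1 else Inf
  D1 <- s2 * nu1 + f1 * (d2 + s2)
  # upper bound on w6 so that an admissible w3 < w2 < w2_hi still exists
  w6_hi <- if (nu1 > 0 && s2 > 0) (w2_hi * D1 / nu1 - b) / s2 else Inf
  w6_lo <- if (nu2 == 0) 0 else b * nu2 / ((d3 + s3) * f2)
  w6 <- pick_in(w6_lo, w6_hi)
  w8_hi <- if (nu2 > 0 && s3 > 0)
    (w6 * (nu2 + f2) * (d3 + s3) / nu2 - b - w6 * d3) / s3 else Inf
  w8 <- pick_in(w6, w8_hi)
  w7_lo <- (b + w6 * d3 + w8 * s3) / (d3 + s3)
  w7_hi <- if (nu2 > 0) w6 * (nu2 + f2) / nu2 else Inf
  w7 <- pick_in(w7_lo, w7_hi)
  w5 <- pick_in(w6, w6_hi)
  w3_lo <- if (nu1 == 0) 0 else nu1 * (b + w5 * s2) / D1
  w2 <- pick_in(w3_lo, w2_hi)
  w3 <- pick_in(w3_lo, w2)
  w4_lo <- (b + w3 * d2 + w5 * s2) / (d2 + s2)
  w4_hi <- if (nu1 > 0) w3 * (nu1 + f1) / nu1 else Inf
  w4 <- pick_in(w4_lo, w4_hi)
  coefs <- c(C1 = 1, I1 = w2, R1 = w3, C2 = w4, I2 = w5, R2 = w6,
             C3 = w7, I3 = w8)
  brackets <- c(
    C1 = -(b - (d1 + s1) + w2 * s1),
    I1 = -(params$rho1 * (w3 - w2)),
    R1 = -((w4 - w3) * nu1 - w3 * f1),
    C2 = -(b + w3 * d2 - w4 * (d2 + s2) + w5 * s2),
    I2 = -(params$rho2 * (w6 - w5)),
    R2 = -((w7 - w6) * nu2 - w6 * f2),
    C3 = -(b + w6 * d3 - w7 * (d3 + s3) + w8 * s3),
    I3 = -(params$rho3 * (w6 - w8)))
  if (params$rho1 == 0) brackets[["I1"]] <- NA_real_
  if (params$rho2 == 0) brackets[["I2"]] <- NA_real_
  if (params$rho3 == 0) brackets[["I3"]] <- NA_real_
  if (nu1 == 0 && f1 == 0) brackets[["R1"]] <- NA_real_
  if (nu2 == 0 && f2 == 0) brackets[["R2"]] <- NA_real_
  certificate(coefs, brackets, r0)
}

# midpoint of a (possibly half-infinite) open interval, deterministic
pick_in <- function(lo, hi) {
  if (!(lo < hi)) stop(sprintf("empty feasibility interval [%g, %g]", lo, hi))
  if (is.finite(hi)) (lo + hi) / 2 else if (lo > 0) 2 * lo else 1
}

certificate <- function(coefs, brackets, r0) {
  ok <- all(coefs > 0) && all(brackets > 0, na.rm = TRUE)
  structure(list(coefficients = coefs, feasible = ok,
                 slack = min(brackets, na.rm = TRUE), r0 = r0),
            class = "lyapunov_certificate")
}

infeasible_certificate <- function(names, r0) {
  structure(list(coefficients = stats::setNames(rep(NA_real_, length(names)),
                                                names),
                 feasible = FALSE, slack = -Inf, r0 = r0),
            class = "lyapunov_certificate")
}

#' @export
print.lyapunov_certificate <- function(x, ...) {
  cat(sprintf("<lyapunov certificate>  feasible: %s (r0 = %.4g, slack %.3g)\n",
              x$feasible, x$r0, x$slack))
  if (x$feasible) print(round(x$coefficients, 6))
  invisible(x)
}

#' Generic certificate search
#' @inheritParams find_certificate_2d
#' @export
find_certificate <- function(params) {
  if (inherits(params, "params_3d")) find_certificate_2d(params)
  else if (inherits(params, "params_5d")) find_certificate_5d(params)
  else if (inherits(params, "params_9d")) find_certificate_9d(params)
  else stop("not a crime_params object")
}

#' Monte-Carlo verification that a certificate's V-dot is negative
#'
#' Samples states uniformly on the simplex `{state >= 0, sum = N}` (the X
#' component free like the rest), excludes the crime-free state itself, and
#' evaluates the exact derivative of `V` along the vector field (not the
#' worst-case bound used in the construction).
#'
#' @param cert a feasible `"lyapunov_certificate"`.
#' @param params the parameters it was built for.
#' @param n number of sampled states.
#' @param seed RNG seed for reproducible sampling.
#' @return Maximum observed V-dot (certificates should give a negative value).
#' @export
verify_certificate <- function(cert, params, n = 1000, seed = 1L) {
  stopifnot(inherits(cert, "lyapunov_certificate"), cert$feasible)
  model <- if (inherits(params, "params_3d")) "3d"
           else if (inherits(params, "params_5d")) "5d" else "9d"
  rhs <- rhs_for(if (model == "3d" && params$rho_x + params$rho_c == 0)
                   "no_parole" else model)
  k <- length(compartments(model))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  e <- matrix(stats::rexp(n * k), nrow = n)
  states <- e / rowSums(e) * params$N
  vmax <- -Inf
  for (i in seq_len(n)) {
    d <- rhs(states[i, ], params)
    vdot <- sum(cert$coefficients * d[-1])
    if (vdot > vmax) vmax <- vdot
  }
  vmax
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Monotone decline of V = X + C in the no-parole system
#'
#' For the system with all release rates zero the function `V = X + C` (the
#' entire non-incarcerated population) is non-increasing along every
#' trajectory regardless of the tipping point, because `dV = -sigma C <= 0`.
#' This verifies the decline numerically along an integrated orbit and
#' reports the limit value.
#'
#' @param params a [params_3d()] with both release rates zero (`eps >= 0`).
#' @param init optional initial state; defaults to a 10% criminally active
#'   population.
#' @param horizon integration horizon (time units).
#' @return List with the trajectory of `V`, logical `nonincreasing`,
#'   `v_limit`, and the final state.
#' @export
no_parole_lyapunov <- function(params, init = NULL, horizon = 1e4) {
  stopifnot(inherits(params, "params_3d"))
  if (params$rho_x != 0 || params$rho_c != 0)
    stop("no-parole analysis requires both release rates to be zero")
  N <- params$N
  if (is.null(init)) init <- c(X = 0.9 * N, C = 0.1 * N, I = 0)
  traj <- integrate_model("no_parole", params, init, horizon = horizon)
  v <- traj$states[, "X"] + traj$states[, "C"]
  list(v = v, times = traj$times,
       nonincreasing = all(diff(v) <= 1e-9 * N),
       v_limit = v[length(v)],
       final_state = traj$states[nrow(traj$states), ])
}
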