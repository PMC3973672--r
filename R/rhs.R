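#' Contagion incidence shared by every model in the hierarchy
#'
#' All recruitment-by-contact flows use the same street-population-normalized
#' incidence `rate * source * active / street`: the per-capita risk for a
#' susceptible individual is proportional to the *prevalence* of active
#' criminals among the non-incarcerated, not to their absolute number. This
#' single definition is what makes the closed-form tipping points free of N
#' and the endemic street prevalence exactly 1/R0. When the street population
#' is (numerically) empty the incidence is zero.
#'
#' @param rate contact rate coefficient (1/time).
#' @param source occupancy of the compartment being recruited out of.
#' @param active total criminally active street population.
#' @param street total non-incarcerated population.
#' @return Flow in persons/time.
#' @keywords internal
incidence <- function(rate, source, active, street) {
  if (street <= 0) return(0)
  rate * source * active / street
}

#' Right-hand sides of the model ODE systems
#'
#' Exact vector fields for each family. Components always sum to zero
#' (conservation of N) and the crime-free state `(N, 0, ..., 0)` is a fixed
#' point whenever `eps = 0`.
#'
#' @param state nonnegative state vector in the fixed compartment order (see
#'   [compartments()]).
#' @param params matching parameter object.
#' @return Named derivative vector (persons/time).
#' @seealso [params_3d()], [integrate_model()]
#' @export
rhs_3d <- function(state, params) {
  stopifnot(inherits(params, "params_3d"))
  s <- as_state(state, "3d")
  X <- s[["X"]]; C <- s[["C"]]; I <- s[["I"]]
  street <- X + C
  new_crime <- incidence(params$beta, X, C, street) + params$eps * X
  dX <- params$delta * C - new_crime + params$rho_x * I
  dC <- new_crime - (params$delta + params$sigma) * C + params$rho_c * I
  dI <- params$sigma * C - (params$rho_x + params$rho_c) * I
  c(X = dX, C = dC, I = dI)
}

#' @rdname rhs_3d
#' @details `rhs_reduced_2d` is the planar reduction of the 3D system with
#'   `X = N - C - I` substituted; `state` is `(C, I)` and the result is the
#'   `(dC, dI)` pair of [rhs_3d()].
#' @export
rhs_reduced_2d <- function(state, params) {
  stopifnot(inherits(params, "params_3d"))
  if (length(state) != 2) stop("reduced planar state must be (C, I)")
  C <- state[[1]]; I <- state[[2]]
  if (C < 0 || I < 0) stop("state components must be nonnegative")
  if (C + I > params$N * (1 + 1e-12)) stop("C + I must not exceed N")
  X <- max(params$N - C - I, 0)
  d <- rhs_3d(c(X, C, I), params)
  c(C = unname(d[["C"]]), I = unname(d[["I"]]))
}

#' @rdname rhs_3d
#' @export
rhs_5d <- function(state, params) {
  stopifnot(inherits(params, "params_5d"))
  s <- as_state(state, "5d")
  X <- s[["X"]]; C1 <- s[["C1"]]; I <- s[["I"]]; R <- s[["R"]]; C2 <- s[["C2"]]
  street <- X + C1 + R + C2
  active <- C1 + C2
  onset <- incidence(params$beta, X, active, street) + params$eps * X
  recid <- incidence(params$nu_c, R, active, street) + params$nu_p * R
  dX  <- -onset + params$delta1 * C1 + params$phi * R
  dC1 <- onset - (params$delta1 + params$sigma1) * C1
  dI  <- params$sigma1 * C1 + params$sigma2 * C2 - params$rho * I
  dR  <- params$rho * I - recid - params$phi * R + params$delta2 * C2
  dC2 <- recid - (params$delta2 + params$sigma2) * C2
  c(X = dX, C1 = dC1, I = dI, R = dR, C2 = dC2)
}

#' @rdname rhs_3d
#' @details `rhs_no_parole` is the limiting system in which nobody is ever
#'   released (`rho_x = rho_c = 0`): prison is absorbing and `dI >= 0` always.
#'   It accepts a `params_3d` whose release rates must both be zero.
#' @export
rhs_no_parole <- function(state, params) {
  stopifnot(inherits(params, "params_3d"))
  if (params$rho_x != 0 || params$rho_c != 0)
    stop("no-parole dynamics require both release rates to be zero")
  rhs_3d(state, params)
}

#' @rdname rhs_3d
#' @export
rhs_9d <- function(state, params) {
  stopifnot(inherits(params, "params_9d"))
  s <- as_state(state, "9d")
  X <- s[["X"]]; C1 <- s[["C1"]]; I1 <- s[["I1"]]; R1 <- s[["R1"]]
  C2 <- s[["C2"]]; I2 <- s[["I2"]]; R2 <- s[["R2"]]
  C3 <- s[["C3"]]; I3 <- s[["I3"]]
  street <- X + C1 + R1 + C2 + R2 + C3
  active <- C1 + C2 + C3
  onset  <- incidence(params$beta, X, active, street) + params$eps * X
  recid1 <- incidence(params$nu_c1, R1, active, street) + params$nu_p1 * R1
  recid2 <- incidence(params$nu_c2, R2, active, street) + params$nu_p2 * R2
  dX  <- -onset + params$delta1 * C1 + params$phi1 * R1 + params$phi2 * R2
  dC1 <- onset - (params$delta1 + params$sigma1) * C1
  dI1 <- params$sigma1 * C1 - params$rho1 * I1
  dR1 <- params$rho1 * I1 - recid1 - params$phi1 * R1 + params$delta2 * C2
  dC2 <- recid1 - (params$delta2 + params$sigma2) * C2
  dI2 <- params$sigma2 * C2 - params$rho2 * I2
  dR2 <- params$rho2 * I2 - recid2 - params$phi2 * R2 + params$delta3 * C3 +
    params$rho3 * I3
  dC3 <- recid2 - (params$delta3 + params$sigma3) * C3
  dI3 <- params$sigma3 * C3 - params$rho3 * I3
  c(X = dX, C1 = dC1, I1 = dI1, R1 = dR1, C2 = dC2,
    I2 = dI2, R2 = dR2, C3 = dC3, I3 = dI3)
}

#' Dispatch an RHS by model family string
#' @keywords internal
rhs_for <- function(model) {
  switch(model,
         "3d" = rhs_3d, "no_parole" = rhs_no_parole,
         "5d" = rhs_5d, "9d" = rhs_9d,
         stop("unknown model family: ", model))
}

model_of <- function(params, no_parole = FALSE) {
  if (inherits(params, "params_3d")) {
    if (no_parole || (params$rho_x == 0 && params$rho_c == 0)) "no_parole" else "3d"
  } else if (inherits(params, "params_5d")) "5d"
  else if (inherits(params, "params_9d")) "9d"
  else stop("not a crime_params object")
}
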