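#' Parameter sets for the crime-contagion model hierarchy
#'
#' Constructors for the three model families. All rates are nonnegative and
#' carry units of 1/time; `N` is the (conserved) total population in persons.
#' The odd-numbered, contagion-only variants of each family are selected by
#' `eps = 0`; `eps > 0` adds an autonomous (propensity-driven) onset flow and
#' removes the crime-free equilibrium.
#'
#' @param beta contagion onset rate: per-capita rate at which contact with the
#'   criminally active recruits non-criminals into crime.
#' @param delta desistance rate, criminally active back to non-criminal.
#' @param sigma incarceration rate of the criminally active.
#' @param rho_x release rate from prison into law-abiding life.
#' @param rho_c release rate from prison straight back into active crime.
#' @param eps autonomous onset rate (individual propensity, no contagion).
#' @param N total population size (persons, constant); must be positive.
#' @return An object of class `c("params_3d", "crime_params")`: a validated
#'   named list of rates.
#' @examples
#' p <- params_3d(beta = 2, delta = 0.5, sigma = 0.5, rho_x = 1, rho_c = 0.5)
#' r0_3d(p)$r0
#' @export
params_3d <- function(beta, delta, sigma, rho_x, rho_c, eps = 0, N = 1) {
  p <- list(beta = beta, delta = delta, sigma = sigma,
            rho_x = rho_x, rho_c = rho_c, eps = eps, N = N)
  validate_params(p, "params_3d")
}

#' @rdname params_3d
#' @param delta1,sigma1 desistance / incarceration rates for first-time
#'   offenders (compartment C1).
#' @param rho release rate from prison; `1/rho` is the mean term length.
#' @param nu_p recidivism propensity: rate at which the recently released
#'   return to crime on their own.
#' @param nu_c recidivism contagion coefficient: return to crime driven by
#'   contact with the criminally active.
#' @param delta2,sigma2 desistance / re-incarceration rates for recidivists
#'   (compartment C2).
#' @param phi redemption rate: recently released who rejoin the never-criminal
#'   pool ("going straight").
#' @export
params_5d <- function(beta, delta1, sigma1, rho, nu_p, nu_c = 0,
                      delta2, sigma2, phi, eps = 0, N = 1) {
  p <- list(beta = beta, eps = eps, delta1 = delta1, sigma1 = sigma1,
            rho = rho, nu_p = nu_p, nu_c = nu_c, delta2 = delta2,
            sigma2 = sigma2, phi = phi, N = N)
  validate_params(p, "params_5d")
}

#' @rdname params_3d
#' @param delta2,sigma2,rho2 stage-2 desistance, incarceration, release rates.
#' @param delta3,sigma3,rho3 stage-3 rates; `rho3 = 0` is the strict
#'   three-strike regime (third incarceration is for life), `rho3 > 0` allows
#'   leakage from life sentences (released lifers re-enter reentry stage 2).
#' @param nu_p1,nu_c1,phi1 first-reentry recidivism propensity/contagion and
#'   redemption rates (compartment R1).
#' @param nu_p2,nu_c2,phi2 second-reentry analogues (compartment R2).
#' @export
params_9d <- function(beta, delta1, sigma1, rho1,
                      nu_p1, nu_c1 = 0, phi1,
                      delta2, sigma2, rho2,
                      nu_p2, nu_c2 = 0, phi2,
                      delta3, sigma3, rho3,
                      eps = 0, N = 1) {
  p <- list(beta = beta, eps = eps,
            delta1 = delta1, sigma1 = sigma1, rho1 = rho1,
            nu_p1 = nu_p1, nu_c1 = nu_c1, phi1 = phi1,
            delta2 = delta2, sigma2 = sigma2, rho2 = rho2,
            nu_p2 = nu_p2, nu_c2 = nu_c2, phi2 = phi2,
            delta3 = delta3, sigma3 = sigma3, rho3 = rho3,
            N = N)
  validate_params(p, "params_9d")
}

validate_params <- function(p, cls) {
  vals <- unlist(p)
  if (any(!is.finite(vals))) stop("all parameters must be finite numbers")
  if (any(vals < 0)) stop("all parameters must be nonnegative")
  if (p$N <= 0) stop("total population N must be strictly positive")
  structure(p, class = c(cls, "crime_params"))
}

#' @export
print.crime_params <- function(x, ...) {
  cat(sprintf("<%s>  N = %g\n", class(x)[1], x$N))
  r <- unlist(x[setdiff(names(x), "N")])
  print(r)
  invisible(x)
}

#' Compartment names for each model family
#'
#' State ordering is fixed: 3D `(X, C, I)`; 5D `(X, C1, I, R, C2)`;
#' 9D `(X, C1, I1, R1, C2, I2, R2, C3, I3)`. The no-parole system reuses the
#' 3D names. Serialization always uses these names, never bare positions.
#'
#' @param model one of `"3d"`, `"5d"`, `"9d"`, `"no_parole"`.
#' @return Character vector of compartment names.
#' @export
compartments <- function(model) {
  switch(match.arg(model, c("3d", "5d", "9d", "no_parole")),
         "3d"  = c("X", "C", "I"),
         "no_parole" = c("X", "C", "I"),
         "5d"  = c("X", "C1", "I", "R", "C2"),
         "9d"  = c("X", "C1", "I1", "R1", "C2", "I2", "R2", "C3", "I3"))
}

#' Indices of incarcerated compartments for a model family
#' @keywords internal
incarcerated_idx <- function(model) {
  switch(model,
         "3d" = 3L, "no_parole" = 3L, "5d" = 3L,
         "9d" = c(3L, 6L, 9L))
}

#' Indices of criminally active (street) compartments
#' @keywords internal
active_idx <- function(model) {
  switch(model,
         "3d" = 2L, "no_parole" = 2L, "5d" = c(2L, 5L),
         "9d" = c(2L, 5L, 8L))
}

as_state <- function(state, model) {
  nm <- compartments(model)
  if (length(state) != length(nm))
    stop(sprintf("state for model '%s' must have %d components", model, length(nm)))
  if (any(!is.finite(state))) stop("state components must be finite")
  if (any(state < 0)) stop("state components must be nonnegative")
  stats::setNames(as.numeric(state), nm)
}

#' Street (non-incarcerated) population of a state
#' @param state named or positional state vector.
#' @param model model family string.
#' @return Total persons not incarcerated.
#' @export
street_population <- function(state, model) {
  sum(state[-incarcerated_idx(model)])
}

#' Fraction of the street population that is not criminally active
#' @inheritParams street_population
#' @return `X / (N - incarcerated)`, a dimensionless prevalence in `[0, 1]`.
#' @export
street_noncriminal_prevalence <- function(state, model) {
  s <- street_population(state, model)
  if (s <= 0) return(NA_real_)
  unname(state[1] / s)
}
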