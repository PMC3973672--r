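#' Integrate a model trajectory
#'
#' Adaptive, stiff-capable integration (deSolve's `lsodar`) of any model
#' family, with an optional event stop once the vector field is numerically
#' stationary (`max |rhs| < stop_tol * N`). Conservation of N is a property
#' of the vector fields; the integrator is run tightly enough that drift
#' stays below `1e-6 * N` over the default horizons.
#'
#' @param model `"3d"`, `"5d"`, `"9d"` or `"no_parole"`.
#' @param params matching parameter object.
#' @param init initial state (named or in fixed compartment order), summing
#'   to `N`.
#' @param horizon final time (time units).
#' @param n_out number of output rows on the uniform time grid.
#' @param stop_tol stationarity stop tolerance, relative to N; `NULL`
#'   disables early stopping.
#' @param rtol,atol integrator tolerances.
#' @return An object of class `"trajectory"`: list with `times`, `states`
#'   (matrix with named columns), `model`, `params`, and `stopped_early`.
#' @export
integrate_model <- function(model, params, init, horizon = 1e4,
                            n_out = 201, stop_tol = 1e-10,
                            rtol = 1e-10, atol = NULL) {
  model <- match.arg(model, c("3d", "5d", "9d", "no_parole"))
  rhs <- rhs_for(model)
  y0 <- as_state(init, model)
  N <- params$N
  if (abs(sum(y0) - N) > 1e-6 * N)
    stop("initial state must sum to the total population N")
  if (is.null(atol)) atol <- 1e-10 * N
  f <- function(t, y, p) list(rhs(pmax(y, 0), params))
  times <- seq(0, horizon, length.out = n_out)
  args <- list(y = y0, times = times, func = f, parms = NULL,
               method = "lsodar", rtol = rtol, atol = atol)
  if (!is.null(stop_tol)) {
    args$rootfunc <- function(t, y, p)
      max(abs(rhs(pmax(y, 0), params))) - stop_tol * N
  }
  sol <- do.call(deSolve::ode, args)
  if (!is.null(attr(sol, "istate")) && attr(sol, "istate")[1] < 0)
    stop("integrator failure (istate = ", attr(sol, "istate")[1], ")")
  states <- unname(sol[, -1, drop = FALSE])
  colnames(states) <- compartments(model)
  structure(list(times = sol[, 1], states = states, model = model,
                 params = params,
                 stopped_early = nrow(sol) < n_out),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %s>  t in [0, %g], %d rows%s\n", x$model,
              max(x$times), length(x$times),
              if (x$stopped_early) " (stationary stop)" else ""))
  print(round(utils::tail(x$states, 1), 4))
  invisible(x)
}

#' Final state of a trajectory
#' @param traj a `"trajectory"`.
#' @return Named state vector at the last time point.
#' @export
final_state <- function(traj) traj$states[nrow(traj$states), ]

#' Classify the long-run outcome of a trajectory
#'
#' Compares the final state against the model's analytic references: the
#' crime-free state, the computed endemic (or low/high-crime) equilibrium,
#' and the everyone-incarcerated state. A trajectory that hits the horizon
#' without reaching quasi-stationarity and without matching any reference is
#' labelled `"undetermined"` rather than guessed.
#'
#' @param traj a [integrate_model()] trajectory.
#' @param params the parameters used (defaults to those in the trajectory).
#' @param tol match tolerance relative to N for the reference comparison.
#' @param stationary_tol `max |rhs| < stationary_tol * N` declares the
#'   endpoint stationary.
#' @return An object of class `"outcome_classification"`: `label` (one of
#'   `crime_free`, `low_crime`, `high_crime`, `all_incarcerated`,
#'   `undetermined`), `final_state`, `time_to_tolerance`, `tolerance`.
#' @export
classify_outcome <- function(traj, params = traj$params, tol = 1e-4,
                             stationary_tol = 1e-7) {
  model <- traj$model
  fs <- final_state(traj)
  N <- params$N
  rhs <- rhs_for(model)
  stationary <- max(abs(rhs(pmax(fs, 0), params))) < stationary_tol * N
  t_end <- max(traj$times)
  lab <- NULL
  noninc <- street_population(fs, model)
  act <- sum(fs[active_idx(model)])
  if (noninc < tol * N) {
    lab <- "all_incarcerated"
  } else if (stationary || traj$stopped_early) {
    if (params$eps == 0 && act < tol * N) {
      lab <- "crime_free"
    } else {
      eq <- long_run_reference(model, params)
      if (!is.null(eq) && max(abs(fs - eq$state)) < max(tol, 1e-3) * N) {
        lab <- eq$kind
        if (lab == "endemic") lab <- "high_crime"
      }
    }
  }
  if (is.null(lab)) lab <- "undetermined"
  structure(list(label = lab, final_state = fs,
                 time_to_tolerance = if (traj$stopped_early) t_end else NA_real_,
                 tolerance = tol, stationary = stationary),
            class = "outcome_classification")
}

long_run_reference <- function(model, params) {
  if (model == "no_parole") return(NULL)
  out <- tryCatch({
    if (params$eps == 0) {
      switch(model, "3d" = endemic_3d(params), "5d" = endemic_5d(params),
             "9d" = endemic_9d(params))
    } else numeric_equilibrium(model, params)
  }, error = function(e) NULL)
  if (is.null(out)) out <- tryCatch(numeric_equilibrium(model, params),
                                    error = function(e) NULL)
  out
}

#' @export
print.outcome_classification <- function(x, ...) {
  cat(sprintf("<outcome: %s>%s\n", x$label,
              if (!is.na(x$time_to_tolerance))
                sprintf("  (stationary by t = %g)", x$time_to_tolerance) else ""))
  invisible(x)
}

#' Default perturbed crime-free initial condition
#'
#' The standard start for threshold experiments: a fraction `frac` of the
#' population criminally active (first-time offenders), the rest law-abiding.
#'
#' @param model model family string.
#' @param N total population.
#' @param frac initially criminally active fraction.
#' @return Named state vector.
#' @export
perturbed_start <- function(model, N, frac = 0.01) {
  nm <- compartments(model)
  s <- stats::setNames(rep(0, length(nm)), nm)
  s[1] <- (1 - frac) * N
  s[2] <- frac * N
  s
}
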