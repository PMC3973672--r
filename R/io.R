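#' Read and validate an experiment configuration
#'
#' Configs are JSON (schema `crimedyn-config/1`) naming the model family,
#' semantic parameter names, an optional initial condition, horizon and seed:
#' ```json
#' {
#'   "schema": "crimedyn-config/1",
#'   "model": "5d",
#'   "params": {"beta": 1, "delta1": 0.3, "sigma1": 0.4, "rho": 1,
#'              "nu_p": 0.2, "nu_c": 0, "delta2": 0.2, "sigma2": 0.5,
#'              "phi": 0.3, "eps": 0, "N": 120},
#'   "init": {"X": 118.8, "C1": 1.2, "I": 0, "R": 0, "C2": 0},
#'   "horizon": 10000,
#'   "seed": 1
#' }
#' ```
#'
#' @param path path to the JSON config file.
#' @return List with `model`, a constructed parameter object, `init` state,
#'   `horizon` and `seed`.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$model)) stop("config must name a model family")
  model <- match.arg(cfg$model, c("3d", "5d", "9d", "no_parole"))
  pl <- as.list(cfg$params)
  ctor <- switch(model, "3d" = params_3d, "no_parole" = params_3d,
                 "5d" = params_5d, "9d" = params_9d)
  params <- do.call(ctor, pl)
  if (model == "no_parole" && (params$rho_x != 0 || params$rho_c != 0))
    stop("no_parole config must set rho_x = rho_c = 0")
  init <- if (!is.null(cfg$init)) {
    v <- unlist(cfg$init)
    as_state(v[compartments(model)], model)
  } else perturbed_start(model, params$N)
  list(model = model, params = params, init = init,
       horizon = if (is.null(cfg$horizon)) 1e4 else cfg$horizon,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}

#' Write a trajectory as RFC-4180 CSV (time column plus named compartments)
#' @param traj a `"trajectory"`.
#' @param path output file.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time = traj$times, traj$states, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Structured run summary
#'
#' Collects the threshold report (with its input/output term decomposition),
#' equilibrium, Lyapunov certificate and outcome classification for one model
#' and parameter set, for serialization to JSON.
#'
#' @param model model family string.
#' @param params parameter object.
#' @param traj optional trajectory to classify.
#' @return A plain list ready for [jsonlite::write_json()].
#' @export
run_summary <- function(model, params, traj = NULL) {
  fam <- if (model == "no_parole") "3d" else model
  thr <- crime_r0(params)
  eq <- tryCatch({
    if (model == "no_parole") NULL
    else if (params$eps == 0) {
      e <- switch(fam, "3d" = endemic_3d(params), "5d" = endemic_5d(params),
                  "9d" = endemic_9d(params))
      e
    } else numeric_equilibrium(fam, params)
  }, error = function(e) NULL)
  cert <- if (params$eps == 0)
    tryCatch(find_certificate(params), error = function(e) NULL) else NULL
  out <- list(
    model = model,
    params = params[setdiff(names(params), "")],
    r0 = thr$r0, r0_terms = as.list(thr$terms), regime = thr$regime,
    equilibrium = if (!is.null(eq)) list(kind = eq$kind,
                                         state = as.list(eq$state),
                                         residual = eq$residual,
                                         street_noncriminal_prevalence =
                                           eq$street_noncriminal_prevalence),
    certificate = if (!is.null(cert)) list(feasible = cert$feasible,
                                           coefficients =
                                             as.list(cert$coefficients),
                                           slack = cert$slack))
  if (!is.null(traj)) {
    cls <- classify_outcome(traj, params)
    out$classification <- list(label = cls$label,
                               final_state = as.list(cls$final_state),
                               stationary = cls$stationary)
  }
  out
}

#' @rdname run_summary
#' @param summary list from `run_summary()`.
#' @param path output JSON path.
#' @export
write_summary_json <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
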