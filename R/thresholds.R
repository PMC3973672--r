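#' Basic reproduction ratios (tipping points)
#'
#' Closed-form input/output expressions for the threshold separating global
#' convergence to the crime-free (or low-crime) state from convergence to the
#' endemic high-crime state. Each R0 is a sum of per-generation recruitment
#' terms; the report carries the term decomposition and a regime label.
#'
#' For the 3D family
#' \deqn{R_0 = \beta / (\delta + \sigma w), \quad w = \rho_x/(\rho_x+\rho_c),}
#' where `w` is the non-recidivist release fraction (the incarceration rate is
#' attenuated because a fraction `1 - w` of the released return directly to
#' crime). When both release rates are zero (no parole) nobody incarcerated
#' ever returns, so `w = 1` and the threshold is `beta / (delta + sigma)`.
#'
#' For the 5D family, with onset `nu = nu_c + nu_p`,
#' \deqn{R_0 = \frac{\beta}{\delta_1+\sigma_1}\Big(1 +
#'       \frac{\sigma_1 \nu}{(\delta_2+\sigma_2)\,\phi}\Big),}
#' the two summands being the X-to-C1 and X-to-C2 input/output ratios. R0 is
#' independent of the release rate `rho` and of `eps`.
#'
#' For the 9D family, with `nu_j = nu_c_j + nu_p_j` and
#' `D1 = sigma2 nu_1 + phi1 (delta2 + sigma2)`,
#' \deqn{R_0 = \frac{\beta}{\delta_1+\sigma_1}\Big(1 +
#'       \frac{\sigma_1\nu_1}{D_1} +
#'       \frac{\sigma_1\nu_1}{D_1}\frac{\sigma_2\nu_2}
#'            {(\delta_3+\sigma_3)\,\phi_2}\Big),}
#' three terms for the recruitment paths into C1, C2 and C3. Independent of
#' all three release rates.
#'
#' @param params parameter object of the matching family.
#' @param band half-width of the tolerance band within which `r0` is reported
#'   as exactly "at" the threshold.
#' @return An object of class `"threshold_report"`: list with `r0`, named
#'   `terms` summing to `r0`, `regime` (`"below"`, `"above"` or `"at"`) and
#'   `band`.
#' @export
r0_3d <- function(params, band = 1e-9) {
  stopifnot(inherits(params, "params_3d"))
  w <- nonrecidivism_fraction(params)
  denom <- params$delta + params$sigma * w
  if (denom <= 0)
    stop("threshold undefined: delta + sigma * w must be positive")
  threshold_report(c(onset = params$beta / denom), band)
}

# fraction of releases that assimilate rather than return to crime;
# with no release at all nobody ever recidivates, hence 1.
nonrecidivism_fraction <- function(params) {
  tot <- params$rho_x + params$rho_c
  if (tot == 0) 1 else params$rho_x / tot
}

#' @rdname r0_3d
#' @export
r0_5d <- function(params, band = 1e-9) {
  stopifnot(inherits(params, "params_5d"))
  nu <- params$nu_c + params$nu_p
  out1 <- params$delta1 + params$sigma1
  if (out1 <= 0) stop("threshold undefined: delta1 + sigma1 must be positive")
  t1 <- params$beta / out1
  if (nu == 0) {
    t2 <- 0
  } else {
    d2 <- (params$delta2 + params$sigma2) * params$phi
    if (d2 <= 0)
      stop("threshold undefined: (delta2 + sigma2) * phi must be positive when recidivism is possible")
    t2 <- t1 * params$sigma1 * nu / d2
  }
  threshold_report(c(first_offense = t1, recidivism = t2), band)
}

#' @rdname r0_3d
#' @export
r0_9d <- function(params, band = 1e-9) {
  stopifnot(inherits(params, "params_9d"))
  nu1 <- params$nu_c1 + params$nu_p1
  nu2 <- params$nu_c2 + params$nu_p2
  out1 <- params$delta1 + params$sigma1
  if (out1 <= 0) stop("threshold undefined: delta1 + sigma1 must be positive")
  t1 <- params$beta / out1
  if (nu1 == 0) {
    t2 <- 0; t3 <- 0
  } else {
    D1 <- params$sigma2 * nu1 + params$phi1 * (params$delta2 + params$sigma2)
    if (D1 <= 0)
      stop("threshold undefined: stage-2 outflow must be positive when stage-1 recidivism is possible")
    t2 <- t1 * params$sigma1 * nu1 / D1
    if (nu2 == 0) {
      t3 <- 0
    } else {
      D2 <- (params$delta3 + params$sigma3) * params$phi2
      if (D2 <= 0)
        stop("threshold undefined: (delta3 + sigma3) * phi2 must be positive when stage-2 recidivism is possible")
      t3 <- t2 * params$sigma2 * nu2 / D2
    }
  }
  threshold_report(c(first_offense = t1, second_stage = t2, third_stage = t3),
                   band)
}

threshold_report <- function(terms, band) {
  r0 <- sum(terms)
  regime <- if (abs(r0 - 1) < band) "at" else if (r0 < 1) "below" else "above"
  structure(list(r0 = r0, terms = terms, regime = regime, band = band),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf("R0 = %.6g  [%s threshold]\n", x$r0, x$regime))
  for (nm in names(x$terms))
    cat(sprintf("  %-14s %.6g\n", nm, x$terms[[nm]]))
  invisible(x)
}

#' Generic R0 dispatcher
#' @inheritParams r0_3d
#' @export
crime_r0 <- function(params, band = 1e-9) {
  if (inherits(params, "params_3d")) r0_3d(params, band)
  else if (inherits(params, "params_5d")) r0_5d(params, band)
  else if (inherits(params, "params_9d")) r0_9d(params, band)
  else stop("not a crime_params object")
}

#' Sensitivity of the 5D tipping point to model parameters
#'
#' Analytic partial derivatives of the 5D R0, each cross-checked against a
#' central finite difference. The sign of `dR0/dsigma1` is the headline
#' policy result: incarcerating first-time offenders faster lowers long-run
#' crime only while recidivism is small relative to rehabilitation and
#' redemption, i.e. while
#' \deqn{\nu\,\delta_1 < (\delta_2+\sigma_2)\,\phi,}
#' with `nu = nu_c + nu_p`. Once that condition is violated, increasing
#' `sigma1` *raises* R0. Enforcement against recidivists (`sigma2`),
#' desistance (`delta1`, `delta2`) and redemption (`phi`) always lower R0.
#'
#' @param params a [params_5d()] object.
#' @param h finite-difference step (absolute, central difference).
#' @return `dr0_dsigma1`: an object of class `"sensitivity_report"` with the
#'   analytic partial, the finite-difference check, the sign classification
#'   and whether the small-recidivism condition holds.
#' @export
dr0_dsigma1 <- function(params, h = 1e-6) {
  stopifnot(inherits(params, "params_5d"))
  nu <- params$nu_c + params$nu_p
  out1 <- params$delta1 + params$sigma1
  reh <- (params$delta2 + params$sigma2) * params$phi
  # d/dsigma1 [ beta/(d1+s1) + beta*s1*nu/((d1+s1)*reh) ]
  analytic <- params$beta / out1^2 * (if (nu == 0) -1 else nu * params$delta1 / reh - 1)
  fd <- fd_partial(params, "sigma1", h)
  sensitivity_report("sigma1", analytic, fd,
                     condition_holds = (nu * params$delta1 < reh))
}

fd_partial <- function(params, name, h = 1e-6) {
  up <- params; dn <- params
  up[[name]] <- params[[name]] + h
  dn[[name]] <- max(params[[name]] - h, 0)
  (r0_5d(up)$r0 - r0_5d(dn)$r0) / (up[[name]] - dn[[name]])
}

sensitivity_report <- function(parameter, analytic, fd, condition_holds = NA) {
  structure(list(parameter = parameter, analytic = analytic,
                 finite_difference = fd,
                 sign = sign(analytic), condition_holds = condition_holds),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("dR0/d%s = %.6g (finite difference %.6g)\n",
              x$parameter, x$analytic, x$finite_difference))
  invisible(x)
}

#' @rdname dr0_dsigma1
#' @details `sensitivity_suite` returns the full set of analytic partials
#'   (w.r.t. `sigma1`, `sigma2`, `delta1`, `delta2`, `phi`, `beta` and the
#'   combined recidivism onset `nu`), each with its finite-difference check.
#' @export
sensitivity_suite <- function(params, h = 1e-6) {
  stopifnot(inherits(params, "params_5d"))
  b <- params$beta; d1 <- params$delta1; s1 <- params$sigma1
  d2 <- params$delta2; s2 <- params$sigma2; phi <- params$phi
  nu <- params$nu_c + params$nu_p
  out1 <- d1 + s1
  reh <- (d2 + s2) * phi
  second <- if (nu == 0) 0 else b * s1 * nu / (out1 * reh)
  partials <- list(
    sigma1 = dr0_dsigma1(params, h)$analytic,
    sigma2 = if (nu == 0) 0 else -b * s1 * nu / (out1 * (d2 + s2)^2 * phi),
    delta1 = -b / out1^2 * (1 + if (nu == 0) 0 else nu * s1 / reh),
    delta2 = if (nu == 0) 0 else -b * s1 * nu / (out1 * (d2 + s2)^2 * phi),
    phi    = if (nu == 0) 0 else -b * s1 * nu / (out1 * reh * phi),
    beta   = r0_5d(params)$r0 / b,
    nu     = if (s1 == 0) 0 else b * s1 / (out1 * reh)
  )
  if (b == 0) partials$beta <- 1 / out1 * (1 + if (nu == 0) 0 else nu * s1 / reh)
  reports <- lapply(names(partials), function(nm) {
    fd <- if (nm == "nu") {
      up <- params; dn <- params
      up$nu_p <- params$nu_p + h; dn$nu_p <- max(params$nu_p - h, 0)
      (r0_5d(up)$r0 - r0_5d(dn)$r0) / (up$nu_p - dn$nu_p)
    } else fd_partial(params, nm, h)
    sensitivity_report(nm, partials[[nm]], fd)
  })
  stats::setNames(reports, names(partials))
}
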