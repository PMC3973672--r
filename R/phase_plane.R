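#' Isoclines of the planar (C, I) reduction
#'
#' For the 3D family reduced to the `(C, I)` plane (with `X = N - C - I`,
#' street population `N - I`), the `dI = 0` isocline is the line
#' `I = sigma/(rho_x + rho_c) * C` through the origin, and the `dC = 0`
#' isocline — after clearing the street denominator — is the quadratic curve
#' \deqn{\beta C (N - C - I) + \epsilon (N - C - I)(N - I)
#'       - (\delta+\sigma) C (N - I) + \rho_c I (N - I) = 0.}
#' On the C-axis (`I = 0`) it reduces to
#' `-beta C^2 + N (beta - delta - sigma - eps) C + eps N^2 = 0`, a concave
#' (in the polynomial sense, leading coefficient `-beta`) parabola with roots
#' at `C = 0` and `C = N (1 - (delta+sigma)/beta)` when `eps = 0`. For
#' `eps > 0` the curve no longer passes through the origin: its I-intercept
#' `-eps N / (rho_c - eps)` is negative, so the curve crosses the vertical
#' axis below the origin and the crime-free state ceases to be an
#' equilibrium.
#'
#' @param params a [params_3d()].
#' @return List: `line_slope` (dI=0 line), `quad_roots` (C-axis roots of the
#'   dC=0 curve, sorted), `I_intercept` (value of I on the curve at C = 0),
#'   `slope_at_origin` (of the dC=0 curve, `eps = 0` only, else `NA`).
#' @export
isoclines_2d <- function(params) {
  stopifnot(inherits(params, "params_3d"))
  b <- params$beta; ds <- params$delta + params$sigma
  e <- params$eps; N <- params$N
  rel <- params$rho_x + params$rho_c
  line_slope <- if (rel > 0) params$sigma / rel else Inf
  # roots on the C-axis: -b C^2 + N (b - ds - e) C + e N^2 = 0
  if (b > 0) {
    disc <- (N * (b - ds - e))^2 + 4 * b * e * N^2
    r1 <- (N * (b - ds - e) - sqrt(disc)) / (2 * b)
    r2 <- (N * (b - ds - e) + sqrt(disc)) / (2 * b)
    quad_roots <- sort(c(r1, r2))
  } else {
    quad_roots <- if (e > 0) c(NA_real_, NA_real_) else c(0, 0)
  }
  I_int <- if (e == 0) 0 else if (params$rho_c != e)
    -e * N / (params$rho_c - e) else -Inf
  slope0 <- if (e == 0 && params$rho_c > 0) (ds - b) / params$rho_c
            else if (e == 0) Inf else NA_real_
  list(line_slope = line_slope, quad_roots = quad_roots,
       I_intercept = I_int, slope_at_origin = slope0)
}

#' Three-case geometric classification of the planar system
#'
#' Classifies the relative arrangement of the two isoclines, which determines
#' the global phase portrait of the planar reduction:
#' * `case1` — both C-axis intercepts of the `dC = 0` curve nonnegative
#'   (`beta >= delta + sigma`): the origin is unstable and all orbits go to
#'   the endemic equilibrium.
#' * `case2` — second intercept negative but the `dC = 0` curve is flatter
#'   than the `dI = 0` line at the origin (`R0 > 1`): endemic equilibrium
#'   again globally stable.
#' * `case3` — second intercept negative and the curve steeper than the line
#'   (`R0 < 1`): the crime-free origin is the only nonnegative steady state
#'   and is globally stable.
#' For `eps > 0` the same three arrangements apply to the bifurcated system:
#' the unique positive equilibrium is a high-crime state in cases 1-2 and a
#' low-crime state in case 3.
#'
#' @param params a [params_3d()].
#' @param check_orbit also integrate one reference orbit and verify it lands
#'   on the predicted attractor.
#' @param boundary_tol roots within `boundary_tol * N` of zero are reported
#'   as boundary cases (`"at"`).
#' @return An object of class `"phase_portrait"`: `case_label`, `isoclines`,
#'   `equilibria` (list of [equilibrium_solution] objects), `r0`, and the
#'   orbit check result.
#' @export
classify_planar <- function(params, check_orbit = TRUE, boundary_tol = 1e-9) {
  stopifnot(inherits(params, "params_3d"))
  iso <- isoclines_2d(params)
  r0 <- r0_3d(params)$r0
  N <- params$N
  # "second" intercept = the non-origin root for eps = 0 (may be negative);
  # for eps > 0 the roots have opposite signs and the positive one plays
  # that role
  root2 <- if (params$eps == 0)
    iso$quad_roots[which.max(abs(iso$quad_roots))] else max(iso$quad_roots)
  if (is.finite(root2) && abs(root2) < boundary_tol * N) {
    case <- "at"
  } else if (root2 > 0 && params$beta >= params$delta + params$sigma) {
    case <- "case1"
  } else if (r0 > 1) {
    case <- "case2"
  } else if (r0 < 1) {
    case <- "case3"
  } else {
    case <- "at"
  }
  eqs <- list()
  if (params$eps == 0) {
    cf <- equilibrium_solution(c(X = N, C = 0, I = 0), "3d", params,
                               kind = "crime_free")
    eqs <- c(eqs, list(cf))
    en <- endemic_3d(params)
    if (!is.null(en)) eqs <- c(eqs, list(en))
  } else {
    eqs <- list(numeric_equilibrium("3d", params))
  }
  orbit <- NULL
  if (check_orbit) {
    traj <- integrate_model("3d", params, perturbed_start("3d", N, 0.05),
                            horizon = 1e5)
    target <- eqs[[length(eqs)]]$state
    if (params$eps == 0 && case == "case3") target <- c(X = N, C = 0, I = 0)
    orbit <- list(final = final_state(traj),
                  reaches_attractor =
                    max(abs(final_state(traj) - target)) < 1e-4 * N)
  }
  structure(list(case_label = case, isoclines = iso, equilibria = eqs,
                 r0 = r0, orbit = orbit),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("<phase portrait: %s>  r0 = %.4g, %d equilibria\n",
              x$case_label, x$r0, length(x$equilibria)))
  invisible(x)
}

#' Phase-portrait dichotomy of the no-parole system
#'
#' With no release from prison the planar `(X, C)` dynamics (prison
#' absorbing) have two regimes: above threshold every orbit is absorbed into
#' prison (`all_in_prison`, the street population vanishes); below threshold
#' there is a continuum of crime-free equilibria `(X, 0, I)` and the final
#' split between X and I depends on the initial condition
#' (`multi_crime_free`).
#'
#' @param params [params_3d()] with zero release rates and `eps = 0`.
#' @param n_starts number of initial criminally active fractions simulated.
#' @param horizon integration horizon.
#' @return A `"phase_portrait"` with `case_label` in
#'   `{all_in_prison, multi_crime_free}` and the per-start final states.
#' @export
classify_no_parole <- function(params, n_starts = 5, horizon = 1e5) {
  stopifnot(inherits(params, "params_3d"))
  if (params$rho_x != 0 || params$rho_c != 0)
    stop("classify_no_parole requires both release rates zero")
  if (params$eps > 0)
    stop("the dichotomy applies to eps = 0; with eps > 0 everyone is eventually incarcerated")
  N <- params$N
  r0 <- r0_3d(params)$r0
  fracs <- seq(0.05, 0.6, length.out = n_starts)
  finals <- t(vapply(fracs, function(f) {
    traj <- integrate_model("no_parole", params,
                            perturbed_start("no_parole", N, f),
                            horizon = horizon)
    final_state(traj)
  }, numeric(3)))
  colnames(finals) <- compartments("no_parole")
  case <- if (r0 > 1) "all_in_prison" else "multi_crime_free"
  structure(list(case_label = case, r0 = r0,
                 start_fractions = fracs, final_states = finals),
            class = "phase_portrait")
}

#' Quick base-graphics phase-plane sketch (not part of the tested contract)
#'
#' Draws the vector field of the planar reduction with both isoclines.
#'
#' @param params a [params_3d()].
#' @param file optional PNG path; `NULL` draws on the active device.
#' @param grid_n arrows per axis.
#' @export
plot_phase_plane <- function(params, file = NULL, grid_n = 15) {
  if (!is.null(file)) {
    grDevices::png(file, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  N <- params$N
  cs <- seq(0, N, length.out = grid_n)
  is <- seq(0, N, length.out = grid_n)
  plot(NULL, xlim = c(0, N), ylim = c(0, N), xlab = "C (criminally active)",
       ylab = "I (incarcerated)", main = sprintf("R0 = %.3g", r0_3d(params)$r0))
  for (C in cs) for (I in is) {
    if (C + I > N) next
    d <- rhs_reduced_2d(c(C, I), params)
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) next
    graphics::arrows(C, I, C + 0.03 * N * d[1] / nrm, I + 0.03 * N * d[2] / nrm,
                     length = 0.03, col = "grey40")
  }
  iso <- isoclines_2d(params)
  if (is.finite(iso$line_slope))
    graphics::abline(0, iso$line_slope, col = "blue", lwd = 2)
  cc <- seq(0, N, length.out = 200)
  ii <- vapply(cc, function(C) {
    f <- function(I) rhs_reduced_2d(c(C, min(I, N - C)), params)[1]
    out <- try(stats::uniroot(f, c(0, N - C))$root, silent = TRUE)
    if (inherits(out, "try-error")) NA_real_ else out
  }, numeric(1))
  graphics::lines(cc, ii, col = "red", lwd = 2)
  invisible(NULL)
}
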