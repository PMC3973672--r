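test_that("a trajectory started at the endemic equilibrium stays there", {
  p <- p5_above()
  eq <- endemic_5d(p)
  traj <- integrate_model("5d", p, eq$state, horizon = 1e3, stop_tol = NULL)
  expect_lt(max(abs(t(traj$states) - eq$state)), 1e-6 * p$N)
})

test_that("outcome classification matches the analytic references", {
  # contagion-only below threshold: crime-free
  t1 <- integrate_model("5d", p5_below(), perturbed_start("5d", 120),
                        horizon = 1e4)
  expect_identical(classify_outcome(t1)$label, "crime_free")
  # eps > 0 above threshold: high-crime equilibrium from the numeric solver
  p_hi <- p5_above(eps = 0.01, nu_c = 0.1)
  t2 <- integrate_model("5d", p_hi, perturbed_start("5d", 120), horizon = 1e4)
  cls2 <- classify_outcome(t2)
  expect_identical(cls2$label, "high_crime")
  expect_equal(unname(cls2$final_state),
               unname(numeric_equilibrium("5d", p_hi)$state),
               tolerance = 1e-3)
  # no-parole with autonomous onset: everyone ends up incarcerated
  t3 <- integrate_model("no_parole", p_no_parole(beta = 0.25, eps = 1e-3),
                        perturbed_start("no_parole", 120), horizon = 1e5)
  expect_identical(classify_outcome(t3)$label, "all_incarcerated")
  # a run stopped short of stationarity is flagged, not guessed
  t4 <- integrate_model("5d", p5_above(), perturbed_start("5d", 120),
                        horizon = 1, stop_tol = NULL)
  expect_identical(classify_outcome(t4)$label, "undetermined")
})

test_that("prison term sweep: invariant prevalence, monotone compartments", {
  p <- p5_above()
  sw <- prison_term_sweep(p, rho_grid = 10^seq(1, -1, length.out = 9))
  expect_true(all(unlist(sw$monotone)))
  expect_true(sw$diminishing_returns)
  # grid density does not change pointwise values
  sw2 <- prison_term_sweep(p, rho_grid = c(10, 1, 0.1))
  common <- match(sw2$grid$rho, sw$grid$rho)
  expect_equal(sw$grid$I[common], sw2$grid$I)
})

test_that("no-parole beta sweep shows the regime change at the threshold, N = 120", {
  p <- p_no_parole(beta = 1, delta = 0.3, sigma = 0.2, N = 120)  # d+s = 0.5
  sw <- no_parole_r0_sweep(p, beta_grid = c(1.5, 1.0, 0.75, 0.4, 0.25, 0.1),
                           init_frac = 0.05)
  g <- sw$grid
  above <- g[g$r0 > 1, ]; below <- g[g$r0 < 1, ]
  expect_gt(nrow(above), 0); expect_gt(nrow(below), 1)
  # everyone incarcerated above threshold
  expect_true(all(abs(above$I - 120) < 1e-3 * 120))
  # below: community splits between X and I, no active criminals
  expect_true(all(below$C < 1e-6 * 120))
  expect_true(all(below$X > 0))
  # prison share shrinks with r0 on the sub-threshold branch
  o <- order(below$r0)
  expect_true(all(diff(below$I[o]) > 0))
})

test_that("three-strike limits in all three regimes", {
  p_hi <- p9_base(beta = 2, rho3 = 0)
  hi <- three_strike_experiment(p_hi)
  expect_true(all(hi$label == "all_incarcerated"))
  p_lo <- p9_base(beta = 0.25, rho3 = 0)
  lo <- three_strike_experiment(p_lo)
  expect_true(all(lo$label == "crime_free"))
  # split among X (incl. redeemed) and lifers depends on the start
  expect_gt(abs(diff(lo$I3)), 0.5)
  expect_true(all(lo$active < 1e-3 * 100))
  p_eps <- p9_base(beta = 0.25, rho3 = 0, eps = 1e-4)
  ep <- three_strike_experiment(p_eps, init_fracs = 0.05)
  expect_identical(ep$label, "all_incarcerated")
})

test_that("configs round-trip and runs are deterministic", {
  cfg <- list(schema = "crimedyn-config/1", model = "5d",
              params = list(beta = 1, delta1 = 0.3, sigma1 = 0.4, rho = 1,
                            nu_p = 0.2, nu_c = 0, delta2 = 0.2, sigma2 = 0.5,
                            phi = 0.3, eps = 0, N = 120),
              horizon = 1000, seed = 4)
  tmp <- withr::local_tempdir()
  cfg_path <- file.path(tmp, "cfg.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE)
  parsed <- read_config(cfg_path)
  expect_s3_class(parsed$params, "params_5d")
  expect_equal(parsed$horizon, 1000)
  expect_equal(unname(parsed$init), c(118.8, 1.2, 0, 0, 0))

  run_once <- function(out) {
    set.seed(parsed$seed)
    traj <- integrate_model(parsed$model, parsed$params, parsed$init,
                            horizon = parsed$horizon)
    write_trajectory_csv(traj, file.path(out, "trajectory.csv"))
    write_summary_json(run_summary(parsed$model, parsed$params, traj),
                       file.path(out, "summary.json"))
  }
  d1 <- file.path(tmp, "a"); d2 <- file.path(tmp, "b")
  dir.create(d1); dir.create(d2)
  run_once(d1); run_once(d2)
  expect_identical(readLines(file.path(d1, "trajectory.csv")),
                   readLines(file.path(d2, "trajectory.csv")))
  expect_identical(readLines(file.path(d1, "summary.json")),
                   readLines(file.path(d2, "summary.json")))
  smry <- jsonlite::read_json(file.path(d1, "summary.json"))
  expect_equal(smry$r0, r0_5d(parsed$params)$r0, tolerance = 1e-12)
  expect_identical(smry$classification$label, "high_crime")
})

test_that("the command-line interface produces trajectory and summary files", {
  cli <- system.file("cli", "crimedyn.R", package = "crimedyn")
  expect_true(nzchar(cli))
  tmp <- withr::local_tempdir()
  cfg_path <- file.path(tmp, "cfg.json")
  jsonlite::write_json(
    list(model = "3d",
         params = list(beta = 2, delta = 0.5, sigma = 0.5, rho_x = 1,
                       rho_c = 0.5, eps = 0, N = 100),
         horizon = 500, seed = 1),
    cfg_path, auto_unbox = TRUE)
  out <- file.path(tmp, "out")
  status <- system2("Rscript", c(cli, "simulate", "--config",
                                 shQuote(cfg_path), "--out", shQuote(out)),
                    stdout = TRUE, stderr = TRUE,
                    env = paste0("R_LIBS=",
                                 paste(.libPaths(), collapse = ":")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "trajectory.csv")))
  smry <- jsonlite::read_json(file.path(out, "summary.json"))
  expect_equal(smry$r0, 2.4, tolerance = 1e-9)
})
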