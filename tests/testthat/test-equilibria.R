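test_that("below threshold no endemic state exists; above it the 1/r0 law holds", {
  expect_null(endemic_3d(p3_below()))
  expect_null(endemic_5d(p5_below()))
  expect_null(endemic_9d(p9_base(beta = 0.2)))
  for (fam in list(list("3d", endemic_3d), list("5d", endemic_5d),
                   list("9d", endemic_9d))) {
    model <- fam[[1]]; f <- fam[[2]]
    sets <- sample_params(model, 30, seed = 17, nu_c_zero = TRUE)
    n_pos <- 0
    for (p in sets) {
      r0 <- crime_r0(p)$r0
      if (r0 <= 1) { expect_null(f(p)); next }
      eq <- f(p)
      expect_s3_class(eq, "equilibrium_solution")
      expect_equal(eq$street_noncriminal_prevalence, 1 / r0,
                   tolerance = 1e-10)
      expect_lt(eq$residual, 1e-10 * p$N)
      expect_gte(min(eq$state), 0)
      expect_equal(sum(eq$state), p$N, tolerance = 1e-12)
      n_pos <- n_pos + 1
    }
    expect_gt(n_pos, 5)
  }
})

test_that("specific prevalence values follow from r0", {
  # r0 = 2 -> half of the street population law-abiding
  p <- params_3d(beta = 2, delta = 0.6, sigma = 0.8, rho_x = 1, rho_c = 1)
  expect_equal(r0_3d(p)$r0, 2)
  expect_equal(endemic_3d(p)$street_noncriminal_prevalence, 0.5)
  # 5D: engineered r0 = 2 via the two-term formula
  p5 <- params_5d(beta = 1, delta1 = 0.3, sigma1 = 0.4, rho = 1, nu_p = 0.2,
                  nu_c = 0, delta2 = 0.2, sigma2 = 0.5, phi = 0.3, N = 120)
  eq5 <- endemic_5d(p5)
  expect_equal(eq5$street_noncriminal_prevalence, 1 / r0_5d(p5)$r0,
               tolerance = 1e-12)
  # no recidivism propensity: C2 empties and the chain truncates
  p50 <- p5; p50$nu_p <- 0
  eq50 <- endemic_5d(p50)
  expect_equal(unname(eq50$state[["C2"]]), 0)
  # 9D: zero later-stage propensities leave stages 2-3 empty
  p9 <- p9_base(beta = 1.5)
  p90 <- p9; p90$nu_p1 <- 0
  eq90 <- endemic_9d(p90)
  expect_equal(unname(eq90$state[c("C2", "I2", "R2", "C3", "I3")]),
               rep(0, 5))
})

test_that("numeric equilibria match closed forms and are unique across starts", {
  p5 <- p5_above()
  eq <- endemic_5d(p5)
  num <- numeric_equilibrium("5d", p5)
  expect_equal(num$state, eq$state, tolerance = 1e-8)
  # dispersed restarts land on the same nonnegative equilibrium
  p5e <- p5_above(eps = 0.02, nu_c = 0.1)
  sols <- lapply(c(0.01, 0.1, 0.3, 0.5, 0.7, 0.9, 0.05, 0.25, 0.6, 0.85),
                 function(g) numeric_equilibrium("5d", p5e,
                                                 guess = rep(g * 120, 2)))
  for (s in sols[-1])
    expect_equal(s$state, sols[[1]]$state, tolerance = 1e-6)
  expect_identical(sols[[1]]$kind, "high_crime")
  # eps > 0 keeps every criminal compartment strictly positive
  expect_gt(min(sols[[1]]$state[c("C1", "C2")]), 0)
  # 9D numeric agrees with its closed form too
  p9 <- p9_base(beta = 1.5)
  expect_equal(numeric_equilibrium("9d", p9)$state, endemic_9d(p9)$state,
               tolerance = 1e-7)
})

test_that("as eps -> 0+ the low-crime equilibrium collapses to crime-free", {
  base <- p5_below()
  act_prev <- NA
  for (e in c(1e-2, 1e-4, 1e-6)) {
    p <- base; p$eps <- e
    eq <- numeric_equilibrium("5d", p)
    expect_identical(eq$kind, "low_crime")
    act <- sum(eq$state[c("C1", "C2")])
    if (!is.na(act_prev)) expect_lt(act, act_prev)
    act_prev <- act
  }
  expect_lt(act_prev, 1e-4 * base$N)
})

test_that("release rate moves compartments but not prevalence or r0", {
  p <- p5_above()
  prev <- c(); r0s <- c(); Is <- c()
  for (r in c(10, 1, 0.1)) {
    pp <- p; pp$rho <- r
    eq <- endemic_5d(pp)
    prev <- c(prev, eq$street_noncriminal_prevalence)
    r0s <- c(r0s, r0_5d(pp)$r0)
    Is <- c(Is, eq$state[["I"]])
  }
  expect_lt(diff(range(prev)), 1e-10)
  expect_lt(diff(range(r0s)), 1e-12)
  expect_gt(min(diff(Is)), 0)   # compartments themselves do change
})

test_that("guidance errors route users to the numeric path", {
  expect_error(endemic_3d(p5_above()), "params_3d")
  p <- p3_above(); p$eps <- 0.1
  expect_error(endemic_3d(p), "numeric_equilibrium")
  expect_error(endemic_5d(p5_above(nu_c = 0.2)), "numeric_equilibrium")
  expect_error(endemic_9d(p9_base(nu_c1 = 0.2)), "numeric_equilibrium")
})
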