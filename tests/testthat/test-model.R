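test_that("linear predictor composes fixed, random and year effects", {
  trees <- toy_trees(3, regime = "logged")
  expect_equal(linear_predictor(trees, c(intercept = 0)), rep(0, 3))
  # an elasticity of 2.4: one unit of log diameter adds 2.4
  b <- c(intercept = 0.5, log_dbh = 2.4, logged = -1)
  t1 <- trees; t2 <- trees; t2$dbh_cm <- t2$dbh_cm * exp(1)
  expect_equal(linear_predictor(t2, b) - linear_predictor(t1, b),
               rep(2.4, 3))
  # regime indicators pick up the plot's disturbance class
  tp <- toy_trees(2, regime = "protected")
  expect_equal(linear_predictor(tp, c(logged = 5)), rep(0, 2))
  tl <- toy_trees(2, regime = "logged")
  expect_equal(linear_predictor(tl, c(logged = 5)), rep(5, 2))
  # random and year effects shift additively
  expect_equal(linear_predictor(tp, c(intercept = 1), a = c(0.3, -0.3),
                                gamma = 0.1),
               c(1.4, 0.8))
  expect_error(linear_predictor(tp, c(warp_drive = 1)), "unknown")
})

test_that("maturation probability is a probit in log diameter", {
  m <- maturation_model(mu_log_dbh = log(20), sigma_log_dbh = 0.5)
  expect_equal(maturation_probability(20, m), 0.5)
  expect_equal(maturation_probability(40, m), pnorm(log(2) / 0.5))
  expect_equal(maturation_probability(40, m), 0.9172, tolerance = 1e-4)
  expect_gt(maturation_probability(1e6, m), 1 - 1e-10)
  d <- seq(10, 120, by = 1)
  expect_true(all(diff(maturation_probability(d, m)) >= 0))
  expect_error(maturation_model(sigma_log_dbh = 0), "positive")
})

test_that("trap intensity is linear and additive in fecundity", {
  s <- single_tree_setup()
  S <- shadow_matrix(s$trees, s$traps, s$u)
  expect_equal(trap_intensity(S, 1000), 1000 * s$S)
  expect_equal(trap_intensity(S, 1000), 0.79577, tolerance = 1e-4)
  expect_equal(trap_intensity(S, 0), 0)
  expect_equal(trap_intensity(S, 2000), 2 * trap_intensity(S, 1000))
  # additivity over disjoint tree subsets
  trees <- toy_trees(4)
  traps <- toy_traps(3)
  f <- c(10, 20, 30, 40)
  lam_all <- trap_intensity(shadow_matrix(trees, traps, 80), f)
  lam_a <- trap_intensity(shadow_matrix(trees[1:2, ], traps, 80), f[1:2])
  lam_b <- trap_intensity(shadow_matrix(trees[3:4, ], traps, 80), f[3:4])
  expect_equal(lam_all, lam_a + lam_b)
  expect_error(trap_intensity(S, -1), "non-negative")
})

test_that("Poisson trap likelihood has the textbook form and edge cases", {
  expect_equal(log_likelihood_counts(2, 1, 0.79577),
               2 * log(0.79577) - 0.79577 - log(2))
  expect_equal(log_likelihood_counts(2, 1, 0.79577), -1.9458,
               tolerance = 1e-4)
  expect_equal(log_likelihood_counts(0, 1, 0), 0)     # certain event
  expect_equal(log_likelihood_counts(3, 1, 0), -Inf)  # impossible data
  # single-observation likelihood peaks at lambda = y / A
  ll <- function(lam) log_likelihood_counts(6, 2, lam)
  expect_gt(ll(3), ll(2.9))
  expect_gt(ll(3), ll(3.1))
  # additive over observations
  expect_equal(log_likelihood_counts(c(1, 4), c(1, 2), c(0.5, 1.2)),
               log_likelihood_counts(1, 1, 0.5) +
                 log_likelihood_counts(4, 2, 1.2))
})

test_that("joint prior is flat in u inside bounds and proper outside", {
  pr <- prior_spec()
  base <- function(u) log_prior(c(0, 0), u, 0.1, 0.1, 0.1, pr)
  expect_identical(base(pr$u_max * 1.01), -Inf)
  expect_identical(base(pr$u_min * 0.5), -Inf)
  expect_equal(base(100), base(2000))  # flat within bounds
  expect_identical(log_prior(0, 100, -0.1, 0.1, 0.1, pr), -Inf)
  # beta prior is a proper normal: further from zero is less likely
  expect_gt(log_prior(0, 100, .1, .1, .1, pr),
            log_prior(30, 100, .1, .1, .1, pr))
})
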