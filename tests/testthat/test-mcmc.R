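small_sim <- function(seed = 5) {
  set.seed(seed)
  simulate_dataset(regimes = "protected", n_plots_per_regime = 1)
}

test_that("chains are deterministic given the seed", {
  sim <- small_sim()
  cfg <- sampler_config(n_iter = 300, burn_in = 100, thin = 2,
                        rng_seed = 42)
  f1 <- run_chain(sim$trees, sim$traps, sim$counts, config = cfg)
  f2 <- run_chain(sim$trees, sim$traps, sim$counts, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$lambda_mean, f2$lambda_mean)
})

test_that("chain output is invariant to input row order", {
  sim <- small_sim()
  cfg <- sampler_config(n_iter = 300, burn_in = 100, thin = 2,
                        rng_seed = 7)
  f1 <- run_chain(sim$trees, sim$traps, sim$counts, config = cfg)
  set.seed(99)
  perm_t <- sample(nrow(sim$trees))
  perm_c <- sample(nrow(sim$counts))
  f2 <- run_chain(sim$trees[perm_t, ], sim$traps, sim$counts[perm_c, ],
                  config = cfg)
  expect_identical(f1$draws, f2$draws)
})

test_that("species with no seeds anywhere are refused by name", {
  sim <- small_sim()
  sim$counts$count <- 0L
  expect_error(run_chain(sim$trees, sim$traps, sim$counts),
               "SP1.*unidentifiable")
})

test_that("flat-prior single-tree toy matches the analytic Gamma posterior", {
  # one tree, one trap, fixed kernel, flat prior on psi and rho pinned at
  # 1: y ~ Pois(A S f) with flat prior gives f | y ~ Gamma(y+1, A S),
  # so E[f | y] = (y+1) / (A S)
  s <- single_tree_setup(y = 3)
  fit <- run_chain(s$trees, s$traps, s$counts,
                   model = model_spec(psi_prior = "flat"),
                   fixed = list(u = s$u, rho = 1L),
                   config = sampler_config(n_iter = 22000, burn_in = 2000,
                                           thin = 1, rng_seed = 11,
                                           step_psi = 0.8))
  expect_equal(mean(fit$f_mean), (3 + 1) / (1 * s$S), tolerance = 0.05)
})

test_that("u-only posterior agrees with dense-grid quadrature", {
  sim <- small_sim(5)
  d <- seedshadow:::prep_fit_data(sim$trees, sim$traps, sim$counts)
  f_true <- sim$f[match(d$trees$tree_id, rownames(sim$f)), , drop = FALSE]
  fit <- run_chain(sim$trees, sim$traps, sim$counts,
                   fixed = list(f = f_true),
                   config = sampler_config(n_iter = 7000, burn_in = 1000,
                                           thin = 1, rng_seed = 3))
  # independent oracle: hand-coded kernel on a dense u grid
  D <- sqrt(outer(d$traps$x_m, d$trees$x_m, "-")^2 +
              outer(d$traps$y_m, d$trees$y_m, "-")^2)
  grid <- seq(u_from_mean(1), u_from_mean(150), length.out = 3000)
  lp <- vapply(grid, function(u) {
    lam <- (1 / (pi * u * (1 + D^2 / u)^2)) %*% f_true
    sum(d$Y * log(d$A * lam)) - sum(d$A * lam)
  }, 0)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  grid_mean <- sum(w * grid)
  grid_sd <- sqrt(sum(w * (grid - grid_mean)^2))
  u_draws <- fit$draws[, "u_protected"]
  expect_equal(mean(u_draws), grid_mean, tolerance = 0.05 * grid_sd / grid_mean * 5)
  expect_equal(sd(u_draws), grid_sd, tolerance = 0.15)
})

test_that("Metropolis acceptance lands in a healthy band after adaptation", {
  sim <- small_sim(3)
  fit <- run_chain(sim$trees, sim$traps, sim$counts,
                   config = sampler_config(n_iter = 1500, burn_in = 700,
                                           thin = 2, rng_seed = 5))
  expect_gt(fit$acceptance$psi, 0.1)
  expect_lt(fit$acceptance$psi, 0.6)
  expect_true(all(fit$acceptance$u > 0.1 & fit$acceptance$u < 0.6))
})

test_that("fit metrics reduce to their textbook forms", {
  fake <- structure(list(
    draws = matrix(0, 100, 1), deviance = rep(12.5, 100),
    Y = matrix(c(0L, 2L), 1, 2), A = 1,
    lambda_mean = matrix(c(1, 1), 1, 2)),
    class = "seedshadow_samples")
  # RMSPE for y = (0, 2) against predictions (1, 1)
  fake$deviance <- rep(-2 * sum(dpois(fake$Y, fake$lambda_mean, log = TRUE)),
                       100)
  m <- fit_metrics(fake)
  expect_equal(m$RMSPE, 1)
  # degenerate posterior: every draw equals the posterior mean -> p_D = 0
  expect_equal(m$p_D, 0, tolerance = 1e-12)
  expect_equal(m$DIC, m$mean_deviance)
  # perfect predictions give zero error
  fake2 <- fake
  fake2$lambda_mean <- matrix(c(1e-12, 2), 1, 2)
  expect_equal(fit_metrics(fake2)$RMSPE, 0, tolerance = 1e-6)
  expect_error(fit_metrics(structure(list(draws = matrix(0, 10, 1)),
                                     class = "seedshadow_samples")),
               "100")
})

test_that("convergence diagnostics flag what they should", {
  set.seed(13)
  good <- matrix(rnorm(4000), 2000, 2,
                 dimnames = list(NULL, c("th1", "th2")))
  cs <- convergence_summary(good)
  expect_true(all(abs(cs$rhat - 1) < 0.05))
  expect_false(any(cs$flagged))
  expect_true(all(cs$ess > 500))
  # two chains with disjoint means must be flagged
  c1 <- matrix(rnorm(500), ncol = 1, dimnames = list(NULL, "th"))
  c2 <- c1 + 50
  cs2 <- convergence_summary(list(c1, c2))
  expect_gt(cs2$rhat, 1.1)
  expect_true(cs2$flagged)
  # constant chain: undefined R-hat, zero ESS, no crash
  cs3 <- convergence_summary(matrix(1, 200, 1,
                                    dimnames = list(NULL, "const")))
  expect_true(is.na(cs3$rhat))
  expect_equal(cs3$ess, 0)
  expect_true(cs3$flagged)
  expect_error(convergence_summary(matrix(rnorm(4), 2, 2)), "few")
})

test_that("posterior-mean fecundity under a flat prior is data-driven", {
  # doubling the count roughly doubles the posterior-mean fecundity
  s2 <- single_tree_setup(y = 2)
  s8 <- single_tree_setup(y = 8)
  cfg <- sampler_config(n_iter = 8000, burn_in = 1000, thin = 1,
                        rng_seed = 2, step_psi = 0.8)
  f2 <- run_chain(s2$trees, s2$traps, s2$counts,
                  model = model_spec(psi_prior = "flat"),
                  fixed = list(u = s2$u, rho = 1L), config = cfg)
  f8 <- run_chain(s8$trees, s8$traps, s8$counts,
                  model = model_spec(psi_prior = "flat"),
                  fixed = list(u = s8$u, rho = 1L), config = cfg)
  expect_equal(mean(f8$f_mean) / mean(f2$f_mean), 3, tolerance = 0.1)
})
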