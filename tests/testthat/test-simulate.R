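test_that("stand generator matches its point-process specification", {
  set.seed(7)
  n <- replicate(400, nrow(generate_stand(stand_config())$trees))
  expect_equal(mean(n), 155, tolerance = 2 / 155)  # Poisson(155) mean
  set.seed(8)
  stand <- generate_stand(stand_config())
  expect_true(all(stand$trees$dbh_cm >= 10))
  expect_true(all(stand$trees$x_m >= 0 & stand$trees$x_m <= 100))
  # deterministic per seed
  set.seed(9); s1 <- generate_stand(stand_config())
  set.seed(9); s2 <- generate_stand(stand_config())
  expect_identical(s1, s2)
})

test_that("trap layout reconstructs the three-transect design", {
  traps <- layout_traps(100)
  expect_equal(nrow(traps), 21)
  expect_equal(sort(unique(traps$x_m)), c(25, 50, 75))
  border <- pmin(traps$x_m, traps$y_m, 100 - traps$x_m, 100 - traps$y_m)
  expect_gte(min(border), 20)
  # 10 m between successive traps along a transect
  y1 <- sort(traps$y_m[traps$x_m == 25])
  expect_equal(diff(y1), rep(10, 6))
  expect_equal(traps$area_m2, rep(1, 21))
  expect_error(layout_traps(39), "40 m")
})

test_that("seed rain is conditionally Poisson around the analytic intensity", {
  s <- single_tree_setup()
  states <- data.frame(tree_id = s$trees$tree_id, a_i = 0, rho = 1L)
  # psi = 1000 exactly: intercept log(1000), no other effects, no year noise
  truth <- ground_truth(mean_disp_m = c(protected = mean_distance(100)),
                        beta = c(intercept = log(1000)),
                        sigma_a = 0, sigma_g = 0)
  set.seed(21)
  rain <- simulate_seed_rain(s$trees, states, s$traps, truth, years = 1e5)
  expect_equal(unique(as.vector(rain$lambda)), 1000 * s$S,
               tolerance = 1e-12)
  expect_equal(mean(rain$counts$count), 1000 * s$S, tolerance = 0.02)
  # all trees immature means zero everywhere
  states0 <- transform(states, rho = 0L)
  rain0 <- simulate_seed_rain(s$trees, states0, s$traps, truth, years = 3)
  expect_true(all(rain0$counts$count == 0))
})

test_that("year effects overdisperse counts while conditional draws stay Poisson", {
  s <- single_tree_setup()
  states <- data.frame(tree_id = s$trees$tree_id, a_i = 0, rho = 1L)
  base <- c(intercept = log(4000))  # lambda*A approx 3.2: informative scale
  set.seed(31)
  noisy <- simulate_seed_rain(s$trees, states, s$traps,
                              ground_truth(mean_disp_m = c(protected = mean_distance(100)),
                                           beta = base, sigma_a = 0,
                                           sigma_g = 0.5),
                              years = 400)
  set.seed(31)
  quiet <- simulate_seed_rain(s$trees, states, s$traps,
                              ground_truth(mean_disp_m = c(protected = mean_distance(100)),
                                           beta = base, sigma_a = 0,
                                           sigma_g = 0),
                              years = 400)
  vm <- function(x) var(x) / mean(x)
  expect_gt(vm(noisy$counts$count), 1.3)
  expect_lt(abs(vm(quiet$counts$count) - 1), 0.35)
})

test_that("per-seed transport reproduces the analytic seed shadow", {
  # two-route check: simulate individual seeds with the radial sampler and
  # a uniform angle, bin them into a 1 m^2 trap, and compare with the
  # kernel density at the trap centre
  u <- 100; n_seed <- 2e6
  set.seed(41)
  r <- sample_distance(n_seed, u)
  th <- runif(n_seed, 0, 2 * pi)
  x <- r * cos(th); y <- r * sin(th)
  in_trap <- abs(x - 10) <= 0.5 & abs(y) <= 0.5
  p_hat <- mean(in_trap)
  p_analytic <- kernel_density(10, u) * 1   # density x trap area
  se <- sqrt(p_analytic / n_seed)
  expect_lt(abs(p_hat - p_analytic), 4 * se)
})

test_that("fixture suite is schema-valid and byte-stable", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  make_fixture_suite(dir1, seed = 1)
  make_fixture_suite(dir2, seed = 1)
  files <- list.files(dir1)
  expect_true(all(c("small_trees.csv", "small_seed_counts.csv",
                    "full_trees.csv", "full_truth.json") %in% files))
  for (f in files) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), info = f)
  }
  trees <- read_tree_census(file.path(dir1, "small_trees.csv"))
  traps <- read_traps(file.path(dir1, "small_traps.csv"))
  counts <- read_seed_counts(file.path(dir1, "small_seed_counts.csv"), traps)
  traits <- read_traits(file.path(dir1, "small_traits.csv"))
  rep <- validate_dataset(trees, traps, counts, traits)
  expect_length(rep$errors, 0)
})
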