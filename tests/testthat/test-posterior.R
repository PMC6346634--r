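fake_samples <- function(disp_draws, species = "SP1",
                         regimes = names(disp_draws)) {
  draws <- do.call(cbind, c(
    lapply(disp_draws, function(x) x),
    list(beta_log_dbh = rnorm(length(disp_draws[[1]]), 2, 0.1))))
  colnames(draws) <- c(paste0("disp_", regimes), "beta_log_dbh")
  structure(list(draws = draws, species = species, regimes = regimes),
            class = "seedshadow_samples")
}

test_that("posterior summaries follow the pinned percentile convention", {
  # degenerate posterior: all u draws equal
  s <- fake_samples(list(protected = rep(mean_distance(100), 200)))
  out <- summarize_posterior(s)$dispersal
  expect_equal(out$mean_m, 15.70796, tolerance = 1e-6)
  expect_equal(out$ci_lo_m, out$ci_hi_m)
  # two-point posterior on u in {100, 400}
  s2 <- fake_samples(list(protected =
    mean_distance(rep(c(100, 400), 100))))
  out2 <- summarize_posterior(s2)$dispersal
  expect_equal(out2$mean_m, (15.70796 + 31.41593) / 2, tolerance = 1e-5)
  # linear-interpolation percentile: 2.5th of 1..1000 is 25.975
  s3 <- fake_samples(list(protected = as.numeric(1:1000)))
  out3 <- summarize_posterior(s3)$dispersal
  expect_equal(out3$ci_lo_m, 25.975)
  expect_equal(out3$ci_hi_m, 975.025)
})

test_that("interval overlap classification follows the closed-interval rule", {
  est <- data.frame(
    species = rep(c("A", "B", "C"), each = 3),
    regime = rep(c("logged", "protected", "hunted_logged"), 3),
    mean_m = c(20.1, 10.3, 21.0,   35.9, 45.7, 52.0,   30, 30, 30),
    ci_lo_m = c(18.7, 9.9, 19.8,   27.9, 41.9, 50.9,   25, 25, 25),
    ci_hi_m = c(21.6, 10.8, 22.3,  42.1, 49.4, 54.3,   35, 35, 35),
    stringsAsFactors = FALSE)
  cl <- classify_overlap(est)
  # species A: both disturbed CIs clear the protected CI, higher means
  expect_true(cl$affected[cl$species == "A"])
  expect_equal(cl$logged[cl$species == "A"], "higher")
  expect_equal(cl$hunted_logged[cl$species == "A"], "higher")
  # species B: logged touches protected (42.1 vs 41.9) so logging has no
  # effect, but hunted+logged still separates
  expect_equal(cl$logged[cl$species == "B"], "none")
  expect_equal(cl$hunted_logged[cl$species == "B"], "higher")
  # identical intervals across regimes: unaffected
  expect_false(cl$affected[cl$species == "C"])

  # invariant to uniform unit rescaling
  est10 <- est
  est10[c("mean_m", "ci_lo_m", "ci_hi_m")] <-
    est[c("mean_m", "ci_lo_m", "ci_hi_m")] * 10
  expect_equal(classify_overlap(est10)[c("affected", "logged")],
               cl[c("affected", "logged")])

  bad <- est; bad$ci_lo_m[1] <- 99
  expect_error(classify_overlap(bad), "malformed")
})

test_that("affected counts aggregate by dispersal vector", {
  cl <- data.frame(species = c("A", "B", "C"),
                   affected = c(TRUE, FALSE, TRUE),
                   logged = c("higher", "none", "none"),
                   hunted_logged = c("none", "none", "lower"),
                   stringsAsFactors = FALSE)
  traits <- data.frame(species = c("A", "B", "C"),
                       vector = c("animal", "animal", "abiotic"))
  ca <- count_affected(cl, traits)
  expect_equal(ca$total_affected, 2)
  expect_equal(ca$by_vector$affected[ca$by_vector$vector == "animal"], 1)
  expect_equal(ca$by_vector$n[ca$by_vector$vector == "animal"], 2)
  expect_error(count_affected(cl, traits[1:2, ]), "missing")
  # empty input gives zeros
  ca0 <- count_affected(cl[0, ], traits)
  expect_equal(ca0$total_affected, 0)
  expect_equal(sum(ca0$by_vector$affected), 0)
})

test_that("group means are plain arithmetic on the estimate table", {
  est <- data.frame(species = rep(c("A", "B"), each = 3),
                    regime = rep(c("logged", "protected", "hunted_logged"), 2),
                    mean_m = c(10, 20, 30, 40, 50, 66),
                    ci_lo_m = 0, ci_hi_m = 100,
                    vector = rep(c("animal", "abiotic"), each = 3),
                    stringsAsFactors = FALSE)
  gv <- group_mean_dispersal(est, "vector")
  expect_equal(unname(gv["animal"]), 20)
  expect_equal(unname(gv["abiotic"]), 52)
  gr <- group_mean_dispersal(est, "regime")
  expect_equal(unname(gr["logged"]), 25)
  # single-cell group is that cell's value
  g1 <- group_mean_dispersal(est[1, ], "regime")
  expect_equal(unname(g1["logged"]), 10)
  # overall mean equals the group-size-weighted mean of group means
  overall <- mean(est$mean_m)
  sizes <- table(est$vector)[names(gv)]
  expect_equal(sum(gv * as.numeric(sizes)) / sum(sizes), overall,
               tolerance = 0.01)
  expect_error(group_mean_dispersal(est[0, ], "regime"), "no groups")
})

test_that("effect signs respect strict CI exclusion of zero", {
  eff <- data.frame(
    species = c("Albizia gummifera", "Grossera macrantha", "X"),
    covariate = c("diameter", "logging", "diameter"),
    posterior_mean = c(2.4, -1.5, 0.3),
    ci_lo = c(0.9, -3.0, -0.2),
    ci_hi = c(3.8, -0.1, 0.8),
    stringsAsFactors = FALSE)
  es <- effect_sign_table(eff)
  expect_equal(es$signs$sign, c("positive", "negative", "null"))
  expect_equal(es$counts$positive[es$counts$covariate == "diameter"], 1)
  expect_equal(es$counts$null[es$counts$covariate == "diameter"], 1)
})

test_that("packaged reference tables are complete and well-formed", {
  tab <- reference_dispersal_table()
  expect_equal(nrow(tab), 33 * 3)
  expect_equal(length(unique(tab$species)), 33)
  expect_true(all(tab$ci_lo_m <= tab$mean_m & tab$mean_m <= tab$ci_hi_m))
  expect_equal(as.vector(table(reference_traits()$vector)[c("abiotic", "animal", "both")]),
               c(7, 18, 8))
  eff <- reference_effects_table()
  expect_equal(nrow(eff), 33 * 3)
  expect_true(all(eff$ci_lo <= eff$posterior_mean &
                    eff$posterior_mean <= eff$ci_hi))
})
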