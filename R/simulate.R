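#' Stand configuration for the simulator
#'
#' Emulates the field design: square 1-ha plots, a homogeneous Poisson
#' point process of stems at 155 trees/ha (the census median), diameters
#' from a lognormal truncated at the 10 cm census threshold, one
#' disturbance regime per plot. The default mixture gives the focal
#' species `SP1` a 5/155 share of stems -- the per-species density
#' implied by a 155-stem census spread over 33 focal species -- with the
#' remainder lumped into a matrix species `OTH` that contributes no
#' seeds of the focal type. Defaults are the study conditions; they are
#' not tuning knobs.
#'
#' @param plot_side_m plot side length, metres (square plots)
#' @param density_per_ha expected stem density (trees per hectare)
#' @param dbh_meanlog,dbh_sdlog lognormal diameter distribution (log cm)
#' @param dbh_min_cm truncation threshold (census minimum), cm
#' @param species named vector of species mixture proportions
#' @param regime disturbance regime label for the plot
#' @export
stand_config <- function(plot_side_m = 100, density_per_ha = 155,
                         dbh_meanlog = log(20), dbh_sdlog = 0.5,
                         dbh_min_cm = 10, species = c(SP1 = 5, OTH = 150),
                         regime = "protected") {
  stopifnot(plot_side_m > 0, density_per_ha > 0, dbh_sdlog > 0,
            dbh_min_cm > 0, all(species > 0),
            regime %in% REGIME_LEVELS)
  list(plot_side_m = plot_side_m, density_per_ha = density_per_ha,
       dbh_meanlog = dbh_meanlog, dbh_sdlog = dbh_sdlog,
       dbh_min_cm = dbh_min_cm,
       species = species / sum(species), regime = regime)
}

#' Ground-truth parameters for forward simulation
#'
#' The data-generating parameter set retained alongside simulated data so
#' that recovery tests can compare posteriors against truth. Dispersal is
#' given as the kernel mean distance per regime; fecundity truth is
#' `f_it = rho_i * exp(x_i' beta + a_i + gamma_tg)` with
#' `a_i ~ N(0, sigma_a^2)` and `gamma_tg ~ N(0, sigma_g^2)`.
#'
#' The default intercept is calibrated once so that, under the default
#' stand mixture and trap layout, a plot traps on the order of a hundred
#' focal-species seeds over three years, matching the reported
#' per-species-per-plot seed totals (median 96).
#'
#' @param mean_disp_m named per-regime mean dispersal distances, m
#' @param beta named fixed-effect vector (see [fecundity_design()])
#' @param sigma_a SD of per-tree random intercepts
#' @param sigma_g SD of year-by-regime effects
#' @param maturation a [maturation_model()] governing true `rho`
#' @export
ground_truth <- function(mean_disp_m = c(protected = 30, logged = 30,
                                         hunted_logged = 30),
                         beta = c(intercept = 2.6, log_dbh = 2,
                                  logged = 0, hunted_logged = 0),
                         sigma_a = 0.3, sigma_g = 0.2,
                         maturation = maturation_model()) {
  stopifnot(all(mean_disp_m > 0), sigma_a >= 0, sigma_g >= 0)
  if (is.null(names(mean_disp_m))) names(mean_disp_m) <- REGIME_LEVELS
  list(mean_disp_m = mean_disp_m, u = u_from_mean(mean_disp_m),
       beta = beta, sigma_a = sigma_a, sigma_g = sigma_g,
       maturation = maturation)
}

#' Simulate a mapped stand
#'
#' Stem count is Poisson(density x area); locations are uniform in the
#' plot (homogeneous Poisson process); diameters are drawn from the
#' truncated lognormal by inverse-CDF sampling. True per-tree states
#' (random intercept `a_i`, maturation `rho_i`) are drawn from the
#' ground-truth model. Uses R's global RNG: set a seed for
#' reproducibility.
#'
#' @param cfg a [stand_config()]
#' @param truth a [ground_truth()]
#' @param plot_id plot identifier for the generated records
#' @return list with `trees` (census data frame) and `states` (data frame
#'   `tree_id`, `a_i`, `rho`)
#' @export
generate_stand <- function(cfg = stand_config(), truth = ground_truth(),
                           plot_id = "P1") {
  area_ha <- (cfg$plot_side_m / 100)^2
  n <- stats::rpois(1, cfg$density_per_ha * area_ha)
  p_min <- stats::plnorm(cfg$dbh_min_cm, cfg$dbh_meanlog, cfg$dbh_sdlog)
  q <- stats::runif(n, p_min, 1)
  trees <- data.frame(
    plot_id = rep(plot_id, n),
    tree_id = sprintf("%s_T%03d", plot_id, seq_len(n)),
    species = if (n) sample(names(cfg$species), n, replace = TRUE,
                            prob = cfg$species) else character(),
    x_m = stats::runif(n, 0, cfg$plot_side_m),
    y_m = stats::runif(n, 0, cfg$plot_side_m),
    dbh_cm = stats::qlnorm(q, cfg$dbh_meanlog, cfg$dbh_sdlog),
    regime = rep(cfg$regime, n),
    stringsAsFactors = FALSE)
  states <- data.frame(
    tree_id = trees$tree_id,
    a_i = stats::rnorm(n, 0, truth$sigma_a),
    rho = stats::rbinom(n, 1,
                        maturation_probability(trees$dbh_cm,
                                               truth$maturation)),
    stringsAsFactors = FALSE)
  list(trees = trees, states = states)
}

#' Seed-trap layout
#'
#' Reconstruction of the field design: three transects across the plot
#' (at 25, 50 and 75 m for a 100 m side), traps of 1 m^2 every 10 m along
#' each transect, all traps at least 20 m from every plot border --
#' 21 traps on a 1-ha plot.
#'
#' @param plot_side_m plot side length, metres (at least 40)
#' @param plot_id plot identifier
#' @param area_m2 trap area
#' @param season_fraction fraction of the fruiting season deployed
#' @return trap data frame (see [read_traps()])
#' @export
layout_traps <- function(plot_side_m = 100, plot_id = "P1",
                         area_m2 = 1, season_fraction = 1) {
  if (plot_side_m < 40) {
    stop("plot side must be at least 40 m to keep traps 20 m from borders",
         call. = FALSE)
  }
  tx <- pmin(pmax(plot_side_m * c(0.25, 0.5, 0.75), 20), plot_side_m - 20)
  ty <- seq(20, plot_side_m - 20, by = 10)
  grid <- expand.grid(y_m = ty, x_m = tx)[, c("x_m", "y_m")]
  data.frame(plot_id = plot_id,
             trap_id = sprintf("%s_S%02d", plot_id, seq_len(nrow(grid))),
             x_m = grid$x_m, y_m = grid$y_m,
             area_m2 = area_m2, season_fraction = season_fraction,
             stringsAsFactors = FALSE)
}

#' Simulate seed rain into traps
#'
#' Forward simulation of the observation model: for each year, draw the
#' year-by-regime effect `gamma_tg`, compute tree fecundities
#' `f_it = rho_i * exp(eta_it)`, accumulate expected trap densities
#' through the 2Dt seed shadow, and draw conditionally Poisson counts
#' `y ~ Poisson(A * lambda)`. Only censused stems of the focal species
#' act as sources (matrix trees of other species contribute nothing),
#' and trees contribute only to traps of their own plot. Uses R's
#' global RNG.
#'
#' @param trees,states a stand from [generate_stand()] (trees may span
#'   several plots; `states` rows match `trees` by `tree_id`)
#' @param traps trap data frame (same plots as `trees`)
#' @param truth a [ground_truth()]
#' @param years number of years (or an integer vector of year labels)
#' @param species species label for the emitted count records
#' @return list: `counts` (seed-count records with `effort_A`), `f`
#'   (tree x year fecundities), `gamma` (year x regime effects),
#'   `lambda` (trap x year expected densities)
#' @export
simulate_seed_rain <- function(trees, states, traps, truth = ground_truth(),
                               years = 3, species = "SP1") {
  if (length(years) == 1) years <- seq_len(years)
  n_yr <- length(years)
  stopifnot(n_yr >= 1)
  if (!is.null(trees$species) && species %in% trees$species) {
    trees <- trees[trees$species == species, , drop = FALSE]
  }
  states <- states[match(trees$tree_id, states$tree_id), , drop = FALSE]
  regimes <- unique(as.character(trees$regime))
  gamma <- matrix(stats::rnorm(n_yr * length(regimes), 0, truth$sigma_g),
                  n_yr, length(regimes), dimnames = list(years, regimes))
  eta0 <- linear_predictor(trees, truth$beta, a = states$a_i)
  f <- matrix(0, nrow(trees), n_yr,
              dimnames = list(trees$tree_id, years))
  for (t in seq_len(n_yr)) {
    f[, t] <- states$rho *
      exp(eta0 + gamma[t, as.character(trees$regime)])
  }
  lambda <- matrix(0, nrow(traps), n_yr,
                   dimnames = list(traps$trap_id, years))
  for (p in unique(traps$plot_id)) {
    ti <- trees$plot_id == p
    si <- traps$plot_id == p
    if (!any(ti)) next
    u_p <- truth$u[[as.character(trees$regime[ti][1])]]
    S <- shadow_matrix(trees[ti, ], traps[si, ], u_p)
    lambda[si, ] <- trap_intensity(S, f[ti, , drop = FALSE])
  }
  A <- traps$area_m2 * traps$season_fraction
  counts <- expand.grid(trap_row = seq_len(nrow(traps)),
                        year = years, KEEP.OUT.ATTRS = FALSE)
  counts <- data.frame(
    plot_id = traps$plot_id[counts$trap_row],
    trap_id = traps$trap_id[counts$trap_row],
    species = species,
    year = counts$year,
    count = stats::rpois(nrow(counts),
                         A[counts$trap_row] *
                           lambda[cbind(counts$trap_row,
                                        match(counts$year, years))]),
    effort_A = A[counts$trap_row],
    stringsAsFactors = FALSE)
  list(counts = counts, f = f, gamma = gamma, lambda = lambda)
}

#' Simulate a complete multi-plot data set
#'
#' Convenience wrapper generating stands, trap layouts and seed rain for
#' several plots per regime under a single ground truth, with all plot
#' pieces bound into the four analysis tables.
#'
#' @param regimes regimes to simulate
#' @param n_plots_per_regime plots per regime
#' @param years number of years of trapping
#' @param cfg base [stand_config()] (regime is overridden per plot)
#' @param truth a [ground_truth()]
#' @param species species label
#' @return list: `trees`, `traps`, `counts`, `states`, `truth`, `gamma`,
#'   `f`, `lambda`
#' @export
simulate_dataset <- function(regimes = REGIME_LEVELS,
                             n_plots_per_regime = 2, years = 3,
                             cfg = stand_config(),
                             truth = ground_truth(), species = "SP1") {
  trees <- list(); traps <- list(); states <- list()
  k <- 0
  for (g in regimes) {
    cfg_g <- cfg
    cfg_g$regime <- g
    for (j in seq_len(n_plots_per_regime)) {
      k <- k + 1
      pid <- sprintf("P%02d", k)
      stand <- generate_stand(cfg_g, truth, plot_id = pid)
      trees[[k]] <- stand$trees
      states[[k]] <- stand$states
      traps[[k]] <- layout_traps(cfg$plot_side_m, plot_id = pid)
    }
  }
  trees <- do.call(rbind, trees)
  traps <- do.call(rbind, traps)
  states <- do.call(rbind, states)
  rain <- simulate_seed_rain(trees, states, traps, truth, years, species)
  c(list(trees = trees, traps = traps, counts = rain$counts,
         states = states, truth = truth),
    rain[c("gamma", "f", "lambda")])
}

#' Write a self-contained fixture data set to disk
#'
#' Emits the four CSV schemas plus the ground truth as JSON for a small
#' (one species, one plot) and a full (three regimes, two plots each)
#' synthetic data set. Regenerating with the same seed is byte-identical.
#'
#' @param out_dir writable directory (created if needed)
#' @param seed RNG seed
#' @return invisible character vector of written paths
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  emit <- function(prefix, sim) {
    p <- character()
    for (nm in c("trees", "traps", "states")) {
      fp <- file.path(out_dir, paste0(prefix, "_", nm, ".csv"))
      write_records(sim[[nm]], fp)
      p <- c(p, fp)
    }
    fp <- file.path(out_dir, paste0(prefix, "_seed_counts.csv"))
    write_records(sim$counts[c("plot_id", "trap_id", "species",
                               "year", "count")], fp)
    p <- c(p, fp)
    fp <- file.path(out_dir, paste0(prefix, "_traits.csv"))
    write_records(data.frame(species = unique(sim$counts$species),
                             vector = "animal"), fp)
    p <- c(p, fp)
    fp <- file.path(out_dir, paste0(prefix, "_truth.json"))
    tr <- sim$truth
    tr$maturation <- unclass(tr$maturation)
    jsonlite::write_json(tr, fp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    c(p, fp)
  }
  set.seed(seed)
  small <- simulate_dataset(regimes = "protected", n_plots_per_regime = 1)
  paths <- c(paths, emit("small", small))
  set.seed(seed + 1)
  full <- simulate_dataset()
  paths <- c(paths, emit("full", full))
  invisible(paths)
}
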