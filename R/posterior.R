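#' Posterior summaries: dispersal and covariate-effect tables
#'
#' Collapses retained draws into the two reporting tables of the
#' analysis. Mean dispersal distance per regime is summarised by mapping
#' every retained draw of the kernel scale `u` through [mean_distance()]
#' and taking the posterior mean and 2.5/97.5 percentiles (linear
#' interpolation between order statistics, R quantile type 7 -- the
#' convention is pinned for reproducibility). Covariate effects on log
#' conditional fecundity are summarised on the coefficient scale.
#'
#' @param samples a `seedshadow_samples` object with at least 100
#'   retained draws
#' @return list with `dispersal` (species, regime, `mean_m`, `ci_lo_m`,
#'   `ci_hi_m`) and `effects` (species, covariate in diameter / logging /
#'   hunting_logging, `posterior_mean`, `ci_lo`, `ci_hi`)
#' @export
summarize_posterior <- function(samples) {
  if (nrow(samples$draws) < 100) {
    stop("posterior summaries need at least 100 retained draws",
         call. = FALSE)
  }
  qi <- function(x) stats::quantile(x, c(0.025, 0.975), type = 7,
                                    names = FALSE)
  disp <- do.call(rbind, lapply(samples$regimes, function(g) {
    x <- samples$draws[, paste0("disp_", g)]
    q <- qi(x)
    data.frame(species = samples$species, regime = g,
               mean_m = mean(x), ci_lo_m = q[1], ci_hi_m = q[2],
               stringsAsFactors = FALSE)
  }))
  cov_map <- c(log_dbh = "diameter", logged = "logging",
               hunted_logged = "hunting_logging")
  eff <- do.call(rbind, lapply(names(cov_map), function(cn) {
    col <- paste0("beta_", cn)
    if (!col %in% colnames(samples$draws)) return(NULL)
    x <- samples$draws[, col]
    q <- qi(x)
    data.frame(species = samples$species,
               covariate = unname(cov_map[cn]),
               posterior_mean = mean(x), ci_lo = q[1], ci_hi = q[2],
               stringsAsFactors = FALSE)
  }))
  list(dispersal = disp, effects = eff)
}

check_intervals <- function(df, lo = "ci_lo_m", hi = "ci_hi_m",
                            mid = "mean_m") {
  if (any(df[[lo]] > df[[mid]] | df[[mid]] > df[[hi]])) {
    stop("malformed credible interval: need ci_lo <= mean <= ci_hi",
         call. = FALSE)
  }
  invisible(df)
}

intervals_overlap <- function(lo_a, hi_a, lo_b, hi_b) {
  pmax(lo_a, lo_b) <= pmin(hi_a, hi_b)
}

#' Classify disturbance effects by credible-interval overlap
#'
#' A species counts as affected by disturbance when the 95 % CI of its
#' mean dispersal distance in a disturbed regime (logged, or hunted and
#' logged) fails to intersect its protected-regime CI. Intervals are
#' closed and compared at the supplied precision, so estimates printed
#' to 0.1 m that touch (e.g. 42.1 vs 41.9) overlap while a 0.1 m gap
#' does not. Non-overlap with the higher disturbed mean is classified
#' `"higher"`, otherwise `"lower"`; overlap gives `"none"`.
#'
#' @param estimates dispersal-estimate table: columns `species`,
#'   `regime`, `mean_m`, `ci_lo_m`, `ci_hi_m`, with one protected row
#'   per species and one row per disturbed regime
#' @return data frame: `species`, `affected`, and one direction column
#'   per disturbed regime (`logged`, `hunted_logged`)
#' @export
classify_overlap <- function(estimates) {
  check_intervals(estimates)
  species <- unique(estimates$species)
  disturbed <- c("logged", "hunted_logged")
  out <- data.frame(species = species, affected = FALSE,
                    logged = "none", hunted_logged = "none",
                    stringsAsFactors = FALSE)
  for (r in seq_along(species)) {
    rows <- estimates[estimates$species == species[r], ]
    prot <- rows[rows$regime == "protected", ]
    if (nrow(prot) != 1) {
      stop("need exactly one protected row per species; missing for ",
           species[r], call. = FALSE)
    }
    for (g in disturbed) {
      dg <- rows[rows$regime == g, ]
      if (nrow(dg) != 1) next
      if (!intervals_overlap(dg$ci_lo_m, dg$ci_hi_m,
                             prot$ci_lo_m, prot$ci_hi_m)) {
        out$affected[r] <- TRUE
        out[r, g] <- if (dg$mean_m > prot$mean_m) "higher" else "lower"
      }
    }
  }
  out
}

#' Count disturbance-affected species by dispersal vector
#'
#' @param classifications output of [classify_overlap()]
#' @param traits trait table (`species`, `vector`)
#' @return list: `total_affected`, `total_species`, and `by_vector`, a
#'   data frame of affected / total counts per dispersal vector
#' @export
count_affected <- function(classifications, traits) {
  idx <- match(classifications$species, traits$species)
  if (anyNA(idx)) {
    stop("species missing from trait table: ",
         paste(classifications$species[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  vec <- factor(traits$vector[idx], levels = VECTOR_LEVELS)
  by_vector <- data.frame(
    vector = VECTOR_LEVELS,
    affected = as.integer(tapply(classifications$affected, vec, sum,
                                 default = 0L)),
    n = as.integer(table(vec)),
    stringsAsFactors = FALSE)
  list(total_affected = sum(classifications$affected),
       total_species = nrow(classifications),
       by_vector = by_vector)
}

#' Group-level mean dispersal distance
#'
#' Clusters the per-species-and-regime dispersal estimates either by
#' dispersal vector (averaging each vector group's species across all
#' three regimes) or by disturbance regime (averaging all species within
#' a regime). Plain arithmetic means of the tabulated `mean_m` values,
#' reported to 0.1 m.
#'
#' @param estimates dispersal-estimate table (as in [classify_overlap()])
#' @param by `"vector"` or `"regime"`
#' @param traits trait table, required for `by = "vector"` unless
#'   `estimates` already has a `vector` column
#' @return named numeric vector of group means (m), rounded to 0.1
#' @export
group_mean_dispersal <- function(estimates, by = c("vector", "regime"),
                                 traits = NULL) {
  by <- match.arg(by)
  if (by == "vector") {
    if (!"vector" %in% names(estimates)) {
      if (is.null(traits)) {
        stop("traits needed to group by dispersal vector", call. = FALSE)
      }
      estimates$vector <- traits$vector[match(estimates$species,
                                              traits$species)]
    }
    g <- factor(estimates$vector, levels = VECTOR_LEVELS)
  } else {
    g <- factor(estimates$regime, levels = REGIME_LEVELS)
  }
  if (anyNA(g)) stop("unassignable group label", call. = FALSE)
  m <- tapply(estimates$mean_m, g, mean)
  m <- m[!is.na(m)]
  if (!length(m)) stop("no groups to average", call. = FALSE)
  round(m, 1)
}

#' Sign classification of covariate effects
#'
#' A species' covariate effect is `"positive"` when its 95 % CI lies
#' entirely above zero, `"negative"` when entirely below, `"null"` when
#' the CI straddles (or touches) zero.
#'
#' @param effects effect table: `species`, `covariate`,
#'   `posterior_mean`, `ci_lo`, `ci_hi`
#' @return list: `signs` (per species x covariate) and `counts`
#'   (per-covariate totals of positive / negative / null)
#' @export
effect_sign_table <- function(effects) {
  check_intervals(effects, "ci_lo", "ci_hi", "posterior_mean")
  sign <- ifelse(effects$ci_lo > 0, "positive",
                 ifelse(effects$ci_hi < 0, "negative", "null"))
  signs <- data.frame(species = effects$species,
                      covariate = effects$covariate, sign = sign,
                      stringsAsFactors = FALSE)
  tab <- table(factor(signs$covariate,
                      levels = unique(effects$covariate)),
               factor(signs$sign,
                      levels = c("positive", "negative", "null")))
  counts <- as.data.frame.matrix(tab)
  counts <- cbind(covariate = rownames(counts), counts,
                  stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  list(signs = signs, counts = counts)
}

#' Packaged reference estimate tables
#'
#' Published per-species posterior summaries from a three-year seed-rain
#' study of 33 common tree species in protected, logged, and hunted and
#' logged Afrotropical forest plots, transcribed at their printed
#' precision (0.1). They are the standard input for the
#' posterior-analysis stage: `reference_dispersal_table()` returns mean
#' dispersal distance with 95 % CI per species and regime (plus the
#' species' dispersal vector); `reference_effects_table()` returns the
#' covariate effects of diameter, logging, and hunting and logging on
#' log conditional fecundity.
#'
#' @return data frame (long format, one row per species x regime or
#'   species x covariate)
#' @export
reference_dispersal_table <- function() {
  path <- system.file("extdata", "dispersal_estimates.csv",
                      package = "seedshadow", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname reference_dispersal_table
#' @export
reference_effects_table <- function() {
  path <- system.file("extdata", "fecundity_effects.csv",
                      package = "seedshadow", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname reference_dispersal_table
#' @export
reference_traits <- function() {
  tab <- reference_dispersal_table()
  unique(tab[c("species", "vector")])
}
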