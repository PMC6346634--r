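#' Read and validate plot data files
#'
#' The analysis connects four plain CSV tables (comma-separated, UTF-8,
#' header row, '.' decimal): a tree census, seed-trap locations with
#' sampling effort, per-trap per-year seed counts, and a species trait
#' table giving the dispersal vector. Coordinates are metres with the
#' origin at the plot's south-west corner; plots are axis-aligned squares
#' (100 m side by default). All readers enforce the schema and the census
#' invariants and preserve row order.
#'
#' @param path path to a CSV file
#' @return `read_tree_census`: data frame with columns `plot_id`,
#'   `tree_id`, `species`, `x_m`, `y_m`, `dbh_cm`, `regime`. `regime` is a
#'   factor with levels `protected`, `logged`, `hunted_logged` (protected
#'   is the reference level throughout).
#' @name io_formats
NULL

REGIME_LEVELS <- c("protected", "logged", "hunted_logged")
VECTOR_LEVELS <- c("animal", "abiotic", "both")

#' @rdname io_formats
#' @export
read_tree_census <- function(path) {
  df <- read_table_checked(path, c("plot_id", "tree_id", "species",
                                   "x_m", "y_m", "dbh_cm", "regime"))
  bad <- which(!is.finite(df$dbh_cm) | df$dbh_cm < 10)
  if (length(bad)) {
    stop("tree census rows below the 10 cm DBH census threshold: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(df$regime), REGIME_LEVELS)
  if (length(unknown)) {
    stop("unknown disturbance regime(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  mixed <- tapply(df$regime, df$plot_id, function(r) length(unique(r)))
  if (any(mixed > 1)) {
    stop("regime must be constant within a plot; violated by plot(s): ",
         paste(names(mixed)[mixed > 1], collapse = ", "), call. = FALSE)
  }
  df$regime <- factor(df$regime, levels = REGIME_LEVELS)
  df
}

#' @rdname io_formats
#' @return `read_traps`: data frame with columns `plot_id`, `trap_id`,
#'   `x_m`, `y_m`, `area_m2`, `season_fraction`.
#' @export
read_traps <- function(path) {
  df <- read_table_checked(path, c("plot_id", "trap_id", "x_m", "y_m",
                                   "area_m2", "season_fraction"))
  if (any(df$area_m2 <= 0)) {
    stop("trap area_m2 must be positive", call. = FALSE)
  }
  if (any(df$season_fraction < 0 | df$season_fraction > 1)) {
    stop("season_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(df$area_m2 * df$season_fraction <= 0)) {
    stop("sampling effort A = area_m2 * season_fraction must be positive",
         call. = FALSE)
  }
  df
}

#' @rdname io_formats
#' @param traps data frame of traps as returned by [read_traps()]; the
#'   per-record sampling effort `effort_A = area_m2 * season_fraction`
#'   (m^2 yr) is computed from it
#' @return `read_seed_counts`: data frame with columns `plot_id`,
#'   `trap_id`, `species`, `year`, `count`, `effort_A`.
#' @export
read_seed_counts <- function(path, traps) {
  df <- read_table_checked(path, c("plot_id", "trap_id", "species",
                                   "year", "count"))
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    stop("seed counts must be non-negative integers", call. = FALSE)
  }
  key <- paste(df$trap_id, df$species, df$year, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (trap_id, species, year) rows in seed counts",
         call. = FALSE)
  }
  idx <- match(df$trap_id, traps$trap_id)
  if (anyNA(idx)) {
    stop("seed counts reference unknown trap_id(s): ",
         paste(unique(df$trap_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  df$effort_A <- traps$area_m2[idx] * traps$season_fraction[idx]
  df
}

#' @rdname io_formats
#' @return `read_traits`: data frame with columns `species`, `vector`
#'   (`animal`, `abiotic` or `both`).
#' @export
read_traits <- function(path) {
  df <- read_table_checked(path, c("species", "vector"))
  unknown <- setdiff(unique(df$vector), VECTOR_LEVELS)
  if (length(unknown)) {
    stop("unknown dispersal vector(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(df$species)) {
    stop("each species must appear exactly once in the trait table",
         call. = FALSE)
  }
  df
}

#' @rdname io_formats
#' @param x record data frame to write
#' @export
write_records <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_table_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[required]
}

#' Cross-validate a census / trap / seed-count / trait data set
#'
#' Pure consistency check run before fitting. Errors are cross-reference
#' failures (counts naming unknown traps or plots, species missing from the
#' trait table). Warnings flag conditions that degrade, but do not
#' invalidate, inference: species whose total seed count is zero (their
#' fecundity is unidentifiable) and traps closer than 20 m to a plot
#' border (the sampling design keeps all traps at least 20 m inside).
#'
#' @param trees,traps,counts data frames as returned by the readers
#' @param traits optional trait table; cross-checked when supplied
#' @param plot_side_m plot side length (m) used for the border check
#' @return object of class `seedshadow_validation`: list with character
#'   vectors `errors` and `warnings`; `ok` is `TRUE` when both are empty.
#'   Never raises on warnings.
#' @export
validate_dataset <- function(trees, traps, counts, traits = NULL,
                             plot_side_m = 100) {
  errors <- character()
  warnings <- character()

  bad_trap <- setdiff(unique(counts$trap_id), traps$trap_id)
  if (length(bad_trap)) {
    errors <- c(errors, paste0("counts reference unknown trap_id(s): ",
                               paste(bad_trap, collapse = ", ")))
  }
  bad_plot <- setdiff(unique(traps$plot_id), unique(trees$plot_id))
  if (length(bad_plot)) {
    errors <- c(errors, paste0("traps in plot(s) with no censused trees: ",
                               paste(bad_plot, collapse = ", ")))
  }
  if (!is.null(traits)) {
    missing_tr <- setdiff(unique(counts$species), traits$species)
    if (length(missing_tr)) {
      errors <- c(errors, paste0("species missing from trait table: ",
                                 paste(missing_tr, collapse = ", ")))
    }
  }

  totals <- tapply(counts$count, counts$species, sum)
  zero_sp <- names(totals)[totals == 0]
  if (length(zero_sp)) {
    warnings <- c(warnings,
                  paste0("species with zero total seeds (fecundity ",
                         "unidentifiable): ", paste(zero_sp, collapse = ", ")))
  }
  border <- pmin(traps$x_m, traps$y_m,
                 plot_side_m - traps$x_m, plot_side_m - traps$y_m)
  near <- traps$trap_id[border < 20]
  if (length(near)) {
    warnings <- c(warnings,
                  paste0("trap(s) within 20 m of a plot border: ",
                         paste(near, collapse = ", ")))
  }

  structure(list(errors = errors, warnings = warnings,
                 ok = !length(errors) && !length(warnings)),
            class = "seedshadow_validation")
}

#' @export
print.seedshadow_validation <- function(x, ...) {
  if (x$ok) {
    cat("dataset validation: OK\n")
  } else {
    for (e in x$errors) cat("ERROR:", e, "\n")
    for (w in x$warnings) cat("warning:", w, "\n")
  }
  invisible(x)
}

#' Read an analysis configuration file
#'
#' YAML file with keys mirroring the arguments of [sampler_config()],
#' [model_spec()] and [stand_config()] under top-level sections `sampler`,
#' `model` and `stand`; absent keys fall back to the function defaults.
#'
#' @param path YAML file path
#' @return list with elements `sampler`, `model`, `stand`
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sampler <- do.call(sampler_config, cfg$sampler %||% list())
  model <- do.call(model_spec, cfg$model %||% list())
  stand <- do.call(stand_config, cfg$stand %||% list())
  list(sampler = sampler, model = model, stand = stand)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
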