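# Small in-code fixtures shared across test files.

toy_trees <- function(n = 3, plot_id = "P1", regime = "protected") {
  data.frame(plot_id = plot_id,
             tree_id = sprintf("%s_T%03d", plot_id, seq_len(n)),
             species = "SP1",
             x_m = seq(20, 80, length.out = n),
             y_m = rep(50, n),
             dbh_cm = seq(15, 45, length.out = n),
             regime = regime,
             stringsAsFactors = FALSE)
}

toy_traps <- function(n = 2, plot_id = "P1") {
  data.frame(plot_id = plot_id,
             trap_id = sprintf("%s_S%02d", plot_id, seq_len(n)),
             x_m = seq(30, 70, length.out = n),
             y_m = rep(40, n),
             area_m2 = 1, season_fraction = 1,
             stringsAsFactors = FALSE)
}

toy_counts <- function(traps, years = 1:2, species = "SP1", count = 1) {
  g <- expand.grid(trap_id = traps$trap_id, year = years,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  data.frame(plot_id = traps$plot_id[match(g$trap_id, traps$trap_id)],
             trap_id = g$trap_id, species = species, year = g$year,
             count = count, stringsAsFactors = FALSE)
}

# one tree at a known distance from one trap: the analytic toy used for
# likelihood and posterior checks (S = kernel_density(10, 100))
single_tree_setup <- function(y = 2, u = 100, r = 10) {
  trees <- data.frame(plot_id = "P1", tree_id = "P1_T001", species = "SP1",
                      x_m = 50, y_m = 50, dbh_cm = 30,
                      regime = "protected", stringsAsFactors = FALSE)
  traps <- data.frame(plot_id = "P1", trap_id = "P1_S01",
                      x_m = 50 + r, y_m = 50, area_m2 = 1,
                      season_fraction = 1, stringsAsFactors = FALSE)
  counts <- data.frame(plot_id = "P1", trap_id = "P1_S01", species = "SP1",
                       year = 1, count = y, effort_A = 1,
                       stringsAsFactors = FALSE)
  list(trees = trees, traps = traps, counts = counts, u = u,
       S = 1 / (pi * u * (1 + r^2 / u)^2))
}
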