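#!/usr/bin/env Rscript
# Generate the synthetic study data: mapped stands under three disturbance
# regimes (two 1-ha plots each), the 21-trap layout, and three years of
# conditionally Poisson seed rain under the default ground truth
# (mean dispersal 30 m in every regime, diameter elasticity 2, individual
# SD 0.3, year SD 0.2). Writes the four CSV schemas plus the ground truth
# and a validation report under results/data/.

suppressPackageStartupMessages(library(seedshadow))

out <- "results/data"
paths <- make_fixture_suite(out, seed = 1)
cat("wrote", length(paths), "files to", out, "\n")

trees <- read_tree_census(file.path(out, "full_trees.csv"))
traps <- read_traps(file.path(out, "full_traps.csv"))
counts <- read_seed_counts(file.path(out, "full_seed_counts.csv"), traps)
traits <- read_traits(file.path(out, "full_traits.csv"))

cat(sprintf("census: %d trees on %d plots (%.0f per ha median target 155)\n",
            nrow(trees), length(unique(trees$plot_id)),
            nrow(trees) / length(unique(trees$plot_id))))
cat(sprintf("seed rain: %d trap-years, %d seeds total\n",
            nrow(counts), sum(counts$count)))

rep <- validate_dataset(trees, traps, counts, traits)
print(rep)
stopifnot(length(rep$errors) == 0)
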