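#!/usr/bin/env Rscript
# Simulate the synthetic study cohort used by the downstream analysis
# scripts: a drift-structured wine reference panel of near-clonal lineages,
# mosaic spontaneous-ferment query genomes (some carrying introgressed
# windows from a divergent unsampled donor), local window trees, and a
# read-depth profile set.  Everything is written as plain-text fixtures
# with truth tables under results/fixtures/.

library(feralyeast)

outdir <- "results/fixtures"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

model <- panel_model(n_clades = 2, F_drift = 0.2, lineages_per_clade = 3,
                     members_per_lineage = 2, clone_mutation_rate = 1e-3,
                     n_sites = 6000,
                     contigs = c(chrI = 300000, chrII = 300000))
panel <- simulate_panel(model, seed = 1001)
windows <- build_windows(model$contigs, 25000, 25000,
                         sites = panel$gm$sites)
mosaic <- simulate_mosaic(panel,
                          mosaic_spec(n_isolates = 6, switch_prob = 0.4,
                                      introgression_fraction = 0.15,
                                      introgression_block_len = 3),
                          windows, seed = 1002)

tree_windows <- data.frame(chrom = "chrI",
                           start = 0:39 * 10000, end = 1:40 * 10000)
set.seed(1003)
intro <- rep(FALSE, 40); intro[c(8:12, 25:28)] <- TRUE
trees <- simulate_local_trees(tree_windows, intro,
                              test_haps = sprintf("q%d", 1:4),
                              noise = 0.05, seed = 1003)

set.seed(1004)
depth <- simulate_depth(default_site_counts(8000),
                        aneuploidies = data.frame(chrom = c("chrVI", "chrIX"),
                                                  shift = c(0.5, 1)))
mask <- repeat_mask(c("chrI", "chrII"), c(120000, 40000), c(130000, 52000))

paths <- emit_fixtures(outdir, panel = panel, mosaic = mosaic,
                       trees = trees, mask = mask, depth = depth)
utils::write.table(tree_windows, file.path(outdir, "tree_windows.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

cat("cohort simulated:\n")
cat(sprintf("  panel: %d isolates in %d lineages over %d clades\n",
            nrow(panel$truth), length(unique(panel$truth$lineage)),
            length(unique(panel$truth$clade))))
cat(sprintf("  mosaics: %d isolates, %d windows each, %.0f%% introgressed\n",
            length(mosaic$mosaic_samples), nrow(windows),
            100 * mean(mosaic$truth$introgressed)))
cat(sprintf("  local trees: %d windows (%d introgressed)\n",
            nrow(tree_windows), sum(intro)))
cat("  fixtures:", normalizePath(outdir), "\n")
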