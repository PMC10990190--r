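#!/usr/bin/env Rscript
# Genotype quality control of the simulated cohort VCF: per-genotype
# GQ <= 20 / DP <= 6 missingness, removal of sites with > 80% missing
# genotypes, sample-level depth and genotyping-rate gates, and the
# per-isolate heterozygosity screen used to select painting queries.

library(feralyeast)

fx <- "results/fixtures"
gm <- load_genotypes(file.path(fx, "genotypes.vcf"), gq_min = 20, dp_min = 6)
cat(sprintf("loaded: %d samples x %d biallelic sites\n",
            length(gm$samples), nrow(gm$sites)))

gm <- filter_sites(gm, max_missing = 0.8)
gm <- filter_samples(gm, min_mean_dp = 6, min_genotyped_fraction = 0.8)
cat(sprintf("after filtering: %d samples x %d sites\n",
            length(gm$samples), nrow(gm$sites)))

het <- data.frame(sample = gm$samples,
                  heterozygosity = vapply(gm$samples, function(s)
                    heterozygosity(gm, s), 0))
het$painting_eligible <- het$heterozygosity < 0.005
utils::write.table(het, "results/heterozygosity.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_genotypes_vcf(gm, "results/genotypes_filtered.vcf")
cat(sprintf("heterozygosity: median %.2e; %d/%d isolates pass the <0.5%% screen\n",
            median(het$heterozygosity), sum(het$painting_eligible), nrow(het)))
cat("written: results/heterozygosity.tsv, results/genotypes_filtered.vcf\n")
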