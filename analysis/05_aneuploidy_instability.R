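#!/usr/bin/env Rscript
# Aneuploidy calling and genome-instability analysis on a simulated isolate
# cohort: per-chromosome Wilcoxon tests with rank-biserial >= 0.5 calls,
# Hodges-Lehmann location shifts normalized by the 2N median, the
# instability regression (polysome shift ~ mean background polysome
# shift), the admixed-vs-feral comparison, and a normalized sliding-window
# depth track for one high-copy isolate.

library(feralyeast)

set.seed(4001)
sc <- default_site_counts(8000)
chroms <- names(sc)
w <- aneuploidy_selection_weights(sc)

# cohort: each isolate has a latent instability level that drives both
# how many chromosomes are polysomic and their copy number, so polysome
# shifts are correlated within an isolate; admixed isolates draw higher
# instability than feral ones, mirroring the hypothesis under test
make_iso <- function(id, instability) {
  n_poly <- 2 + rpois(1, instability)
  poly <- sample(chroms, min(n_poly, 6), prob = w)
  shifts <- 0.5 * pmax(1, rpois(length(poly), 1 + 1.5 * instability))
  simulate_depth(sc, aneuploidies = data.frame(chrom = poly, shift = shifts),
                 isolate = id)
}
cohort <- c(lapply(1:12, function(i) make_iso(sprintf("ADM%02d", i),
                                              rgamma(1, 2, 1.2))),
            lapply(1:16, function(i) make_iso(sprintf("FER%02d", i),
                                              rgamma(1, 2, 2.5))))
group <- c(rep("admixed", 12), rep("feral", 16))
names(group) <- vapply(cohort, `[[`, "", "isolate")

cohort <- Filter(coverage_gate, cohort)
calls <- do.call(rbind, lapply(cohort, call_aneuploidies))
utils::write.table(calls, "results/aneuploidy_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
n_aneu <- tapply(calls$direction != "NONE", calls$isolate, sum)
cat(sprintf("cohort: %d isolates pass the 20X gate; %.1f%% carry >=1 aneuploidy\n",
            length(cohort), 100 * mean(n_aneu > 0)))
gains <- sum(calls$direction == "GAIN"); losses <- sum(calls$direction == "LOSS")
cat(sprintf("calls: %d gains, %d losses (%.1f%% gains)\n", gains, losses,
            100 * gains / (gains + losses)))

rec <- instability_records(calls, group = group)
utils::write.table(rec, "results/instability_records.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
fit <- suppressWarnings(instability_regression(rec))
utils::write.table(fit, "results/instability_regression.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
pooled <- fit[fit$stratum == "pooled", ]
cat(sprintf("instability regression (pooled): slope %.2f, r^2 %.2f over %d polysomes\n",
            pooled$slope, pooled$r_squared, pooled$n))

cmp <- compare_groups(rec, "admixed", "feral")
cat(sprintf("admixed > feral polysome copy number: one-sided p = %.4f (%s test, n = %d vs %d)\n",
            cmp$p_value, cmp$method, cmp$n_a, cmp$n_b))

high <- names(sort(tapply(rec$shift, rec$isolate, mean), decreasing = TRUE))[1]
prof <- cohort[[which(vapply(cohort, `[[`, "", "isolate") == high)]]
trk <- normalized_depth_track(prof, calls[calls$isolate == high, ],
                              window = 10000, step = 2000)
utils::write.table(trk, "results/normalized_depth_track.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat(sprintf("normalized 10kb/2kb depth track written for isolate %s\n", high))
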