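# Independent brute-force oracles.  These deliberately avoid the package's
# computation paths: statistics are evaluated by exhaustive enumeration so
# the frequency-based implementations can be checked against them.

# Mean pairwise difference per site between all haplotype pairs drawn
# within one population.  haps: haplotype x site 0/1 matrix.
oracle_pi <- function(haps, n_accessible = ncol(haps)) {
  n <- nrow(haps)
  tot <- 0; pairs <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(haps[i, ] != haps[j, ])
    pairs <- pairs + 1
  }
  tot / pairs / n_accessible
}

# Mean pairwise difference per site across all between-population
# haplotype pairs.
oracle_dxy <- function(haps_a, haps_b, n_accessible = ncol(haps_a)) {
  tot <- 0; pairs <- 0
  for (i in seq_len(nrow(haps_a))) for (j in seq_len(nrow(haps_b))) {
    tot <- tot + sum(haps_a[i, ] != haps_b[j, ])
    pairs <- pairs + 1
  }
  tot / pairs / n_accessible
}

# Exhaustive Hodges-Lehmann: literal median of all pairwise differences.
oracle_hl <- function(x, y) median(as.vector(outer(x, y, `-`)))

# Exhaustive rank-biserial: directional pair counting with ties at 1/2.
oracle_rank_biserial <- function(x, y) {
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  2 * sum(cmp) / (length(x) * length(y)) - 1
}

# Hand-enumerable fd: evaluate numerator and denominator sums site by site
# from a table of derived allele frequencies (already polarized).
oracle_fd <- function(p1, p2, p3, po) {
  s <- sum((1 - p1) * p2 * p3 * (1 - po) - p1 * (1 - p2) * p3 * (1 - po))
  pd <- pmax(p2, p3)
  sd_ <- sum((1 - p1) * pd * pd * (1 - po) - p1 * (1 - pd) * pd * (1 - po))
  if (sd_ == 0) return(NA_real_)
  if (s <= 0) return(0)
  s / sd_
}

# Build a geno_matrix from a haplotype list: one diploid sample per pair of
# rows (hap1 + hap2), sites placed 1 bp apart on one contig.
gm_from_haps <- function(hap_pairs, contig_len = NULL) {
  dosage <- do.call(rbind, lapply(hap_pairs, function(hp) hp[[1]] + hp[[2]]))
  S <- ncol(dosage)
  if (is.null(contig_len)) contig_len <- S + 10
  samples <- sprintf("S%02d", seq_len(nrow(dosage)))
  geno_matrix(dosage,
              data.frame(chrom = "chr1", pos = seq_len(S) - 1L,
                         ref = "A", alt = "T", site_dp = NA_integer_),
              samples, c(chr1 = contig_len))
}

# Convenience: homozygous diploids from a 0/1 haplotype matrix (rows).
gm_from_hap_matrix <- function(haps, contig_len = NULL) {
  gm_from_haps(lapply(seq_len(nrow(haps)), function(i)
    list(haps[i, ], haps[i, ])), contig_len)
}
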