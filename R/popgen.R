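# Windowed population-genetic statistics on dosage genotypes.
#
# All estimators are frequency-based (unbiased per-site forms) and agree
# with exhaustive haplotype-pair enumeration on complete data; the test
# suite pins that equivalence.

# Within-population alternate-allele frequency and haplotype counts for a
# set of site indices.  Returns list(p, n_hap) over the selected sites.
.pop_freq <- function(gm, members, site_idx) {
  rows <- match(members, gm$samples)
  if (anyNA(rows)) stop("unknown sample(s): ",
                        paste(members[is.na(rows)], collapse = ", "))
  d <- gm$dosage[rows, site_idx, drop = FALSE]
  n_hap <- 2 * colSums(!is.na(d))
  ac <- colSums(d, na.rm = TRUE)
  p <- ifelse(n_hap > 0, ac / n_hap, NA_real_)
  list(p = p, n_hap = n_hap)
}

.window_stat <- function(value, n_sites, mode = NULL) {
  out <- list(value = value, n_sites = n_sites)
  if (!is.null(mode)) out$mode <- mode
  out
}

#' Nei's nucleotide diversity (pi) in a window
#'
#' Per-site unbiased diversity \eqn{2 p (1-p) n/(n-1)} with \eqn{p} the
#' within-population alternate-allele frequency and \eqn{n} the non-missing
#' haplotype count, summed over variant sites and averaged per accessible
#' site.  When \code{n_accessible} is not supplied the denominator is the
#' number of usable variant sites (per-variant-site mode, flagged in the
#' result), since invariant genotyped sites are usually not represented in a
#' variants-only matrix.
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param members sample ids of the population (one sample = one diploid)
#' @param site_idx site row indices of the window
#' @param n_accessible optional count of accessible (variant + invariant)
#'   sites in the window, used as the averaging denominator
#' @return list with \code{value}, \code{n_sites}, \code{mode}
#' @export
nucleotide_diversity <- function(gm, members, site_idx, n_accessible = NULL) {
  f <- .pop_freq(gm, members, site_idx)
  use <- f$n_hap >= 2
  if (!any(use)) return(.window_stat(NA_real_, 0L, "undefined"))
  p <- f$p[use]; n <- f$n_hap[use]
  per_site <- 2 * p * (1 - p) * n / (n - 1)
  denom <- if (is.null(n_accessible)) sum(use) else n_accessible
  .window_stat(sum(per_site) / denom, sum(use),
               if (is.null(n_accessible)) "variant_sites" else "accessible_sites")
}

#' Nei's absolute divergence d_XY between two populations in a window
#'
#' Mean over sites of \eqn{p_A (1-p_B) + p_B (1-p_A)}, averaged per
#' accessible site (see \code{\link{nucleotide_diversity}} for the
#' denominator convention).
#'
#' @inheritParams nucleotide_diversity
#' @param members_a,members_b sample ids of the two populations
#' @return list with \code{value}, \code{n_sites}, \code{mode}
#' @export
dxy <- function(gm, members_a, members_b, site_idx, n_accessible = NULL) {
  fa <- .pop_freq(gm, members_a, site_idx)
  fb <- .pop_freq(gm, members_b, site_idx)
  use <- fa$n_hap >= 1 & fb$n_hap >= 1
  if (!any(use)) return(.window_stat(NA_real_, 0L, "undefined"))
  pa <- fa$p[use]; pb <- fb$p[use]
  per_site <- pa * (1 - pb) + pb * (1 - pa)
  denom <- if (is.null(n_accessible)) sum(use) else n_accessible
  .window_stat(sum(per_site) / denom, sum(use),
               if (is.null(n_accessible)) "variant_sites" else "accessible_sites")
}

#' Nei's ancestral distance d_a between two populations in a window
#'
#' \eqn{d_a = d_{XY} - (\pi_A + \pi_B)/2}: between-population divergence
#' with the mean within-population diversity removed, approximating the
#' distance between the ancestral nodes.  May be negative; reported as-is.
#'
#' @inheritParams dxy
#' @return list with \code{value}, \code{n_sites}
#' @export
nei_da <- function(gm, members_a, members_b, site_idx, n_accessible = NULL) {
  d <- dxy(gm, members_a, members_b, site_idx, n_accessible)
  pa <- nucleotide_diversity(gm, members_a, site_idx, n_accessible)
  pb <- nucleotide_diversity(gm, members_b, site_idx, n_accessible)
  if (is.na(d$value) || is.na(pa$value) || is.na(pb$value))
    return(.window_stat(NA_real_, 0L))
  .window_stat(d$value - (pa$value + pb$value) / 2, d$n_sites)
}

#' Pairwise identity by state on the dosage scale
#'
#' Per-site IBS is \eqn{1 - |g_A - g_B| / 2}; the value is the mean over
#' sites where both genotypes are non-missing.  The missing fraction (sites
#' with either genotype missing over all requested sites) is reported so
#' callers can discard poorly covered windows.
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param sample_a,sample_b sample ids
#' @param site_idx site row indices (defaults to all sites)
#' @return list(ibs, n_sites, missing_fraction); \code{ibs} is \code{NA}
#'   with \code{missing_fraction = 1} when no site is co-genotyped
#' @export
ibs <- function(gm, sample_a, sample_b, site_idx = seq_len(nrow(gm$sites))) {
  ga <- gm$dosage[match(sample_a, gm$samples), site_idx]
  gb <- gm$dosage[match(sample_b, gm$samples), site_idx]
  ok <- !is.na(ga) & !is.na(gb)
  n <- sum(ok)
  miss <- if (length(site_idx)) 1 - n / length(site_idx) else 1
  if (n == 0) return(list(ibs = NA_real_, n_sites = 0L, missing_fraction = 1))
  list(ibs = mean(1 - abs(ga[ok] - gb[ok]) / 2), n_sites = n,
       missing_fraction = miss)
}

#' Pairwise IBS matrix over a sample panel
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param samples sample ids (default all)
#' @param site_idx site row indices (default all)
#' @return symmetric matrix of pairwise IBS with unit diagonal
#' @export
ibs_matrix <- function(gm, samples = gm$samples,
                       site_idx = seq_len(nrow(gm$sites))) {
  n <- length(samples)
  m <- diag(1, n)
  dimnames(m) <- list(samples, samples)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- ibs(gm, samples[i], samples[j], site_idx)$ibs
  }
  m
}

#' Pairwise coancestry coefficient
#'
#' Method-of-moments allele-sharing estimator: the correlation of
#' panel-frequency-centred dosages over sites polymorphic in the panel,
#' \deqn{f_{AB} = \frac{\sum_s (g_A - 2\bar p)(g_B - 2\bar p)}
#'   {\sqrt{\sum_s (g_A - 2\bar p)^2 \sum_s (g_B - 2\bar p)^2}}.}
#' Because the centring frequencies are estimated from the panel itself,
#' the raw correlation of an average pair is biased to \eqn{-1/(n-1)} for a
#' panel of \eqn{n} samples; the estimate is rescaled by that expectation
#' so a sample against itself scores exactly 1 and pairs of independent
#' draws from the panel-wide frequencies concentrate near 0.
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param sample_a,sample_b sample ids
#' @return coancestry estimate, or error when the matrix is monomorphic
#' @export
coancestry <- function(gm, sample_a, sample_b) {
  p <- .pop_freq(gm, gm$samples, seq_len(nrow(gm$sites)))$p
  ga <- gm$dosage[match(sample_a, gm$samples), ]
  gb <- gm$dosage[match(sample_b, gm$samples), ]
  ok <- !is.na(ga) & !is.na(gb) & !is.na(p) & p > 0 & p < 1
  if (!any(ok)) stop("no polymorphic co-genotyped sites for coancestry")
  ca <- ga[ok] - 2 * p[ok]
  cb <- gb[ok] - 2 * p[ok]
  den <- sqrt(sum(ca^2) * sum(cb^2))
  if (den == 0) stop("degenerate coancestry: zero variance after centring")
  f_raw <- sum(ca * cb) / den
  m <- -1 / (length(gm$samples) - 1)   # expected value for an average pair
  (f_raw - m) / (1 - m)
}

#' Windowed fd introgression statistic
#'
#' ABBA-BABA-derived estimator of the fraction of a window affected by
#' introgression from a donor.  Sites are polarized on the outgroup major
#' allele (derived = outgroup minor allele; sites with outgroup frequency
#' exactly 0.5 are uninformative and skipped).  With derived frequencies
#' \eqn{p_1, p_2, p_3, p_O},
#' \deqn{S = \sum_s (1-p_1) p_2 p_3 (1-p_O) - p_1 (1-p_2) p_3 (1-p_O)}
#' and the denominator substitutes \eqn{p_D = \max(p_2, p_3)} for both
#' \eqn{p_2} and \eqn{p_3}.  Windows with \eqn{S \le 0} return 0 when
#' \code{clamp = TRUE} (the published recommendation) or \code{NA}
#' otherwise; windows with a zero denominator are undefined.
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param p1,p2,p3,outgroup disjoint sample-id vectors: recipient sister
#'   (P1), recipient (P2), donor (P3) and outgroup populations
#' @param site_idx site row indices of the window
#' @param clamp clamp non-positive numerators to 0 instead of \code{NA}
#' @return list(value, n_sites)
#' @export
fd_window <- function(gm, p1, p2, p3, outgroup, site_idx, clamp = TRUE) {
  pops <- list(p1, p2, p3, outgroup)
  all_m <- unlist(pops)
  if (anyDuplicated(all_m)) stop("fd populations must be disjoint")
  f <- lapply(pops, function(m) .pop_freq(gm, m, site_idx))
  ok <- Reduce(`&`, lapply(f, function(x) x$n_hap >= 1))
  q1 <- f[[1]]$p[ok]; q2 <- f[[2]]$p[ok]; q3 <- f[[3]]$p[ok]; qo <- f[[4]]$p[ok]
  informative <- qo != 0.5
  q1 <- q1[informative]; q2 <- q2[informative]; q3 <- q3[informative]
  qo <- qo[informative]
  if (!length(q1)) return(.window_stat(NA_real_, 0L))
  # polarize: derived allele is the outgroup minor allele
  flip <- qo > 0.5
  q1[flip] <- 1 - q1[flip]; q2[flip] <- 1 - q2[flip]
  q3[flip] <- 1 - q3[flip]; qo[flip] <- 1 - qo[flip]
  s_num <- sum((1 - q1) * q2 * q3 * (1 - qo) - q1 * (1 - q2) * q3 * (1 - qo))
  pd <- pmax(q2, q3)
  s_den <- sum((1 - q1) * pd * pd * (1 - qo) - q1 * (1 - pd) * pd * (1 - qo))
  n_inf <- length(q1)
  if (s_den == 0) return(.window_stat(NA_real_, n_inf))
  if (s_num <= 0) return(.window_stat(if (clamp) 0 else NA_real_, n_inf))
  .window_stat(s_num / s_den, n_inf)
}

#' Compute a window statistic across a window set
#'
#' @param windows a \code{window_set} from \code{\link{build_windows}}
#' @param fun function(site_idx) returning list(value, n_sites)
#' @return data.frame: chrom, start, end, value, n_sites
#' @export
windowed_stat <- function(windows, fun) {
  vals <- lapply(seq_len(nrow(windows)), function(i) fun(window_sites(windows, i)))
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             value = vapply(vals, function(x) as.numeric(x$value)[1], 0),
             n_sites = vapply(vals, function(x) as.integer(x$n_sites)[1], 0L),
             stringsAsFactors = FALSE)
}
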