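# Genotype container, VCF I/O and QC filters.
#
# Coordinates are 0-based half-open internally; VCF POS (1-based) is
# converted on read and back on write.  Only biallelic records are kept:
# every downstream statistic is defined on bialleles.

#' Construct a genotype matrix object
#'
#' Container for diploid dosage genotypes at biallelic sites, with optional
#' per-genotype GQ and DP.  Dosage is the alternate-allele count (0, 1, 2)
#' with \code{NA} for missing.
#'
#' @param dosage integer matrix, samples in rows, sites in columns
#' @param sites data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt} and optionally \code{site_dp}
#' @param samples character vector of sample identifiers (row names)
#' @param contigs named numeric vector of contig lengths
#' @param gq,dp optional integer matrices of the same shape as \code{dosage}
#' @param n_dropped_multiallelic count of multiallelic records dropped on read
#' @return an object of class \code{geno_matrix}
#' @export
geno_matrix <- function(dosage, sites, samples, contigs,
                        gq = NULL, dp = NULL, n_dropped_multiallelic = 0L) {
  dosage <- as.matrix(dosage)
  stopifnot(nrow(dosage) == length(samples), ncol(dosage) == nrow(sites))
  if (!is.null(gq)) stopifnot(all(dim(gq) == dim(dosage)))
  if (!is.null(dp)) stopifnot(all(dim(dp) == dim(dosage)))
  ord <- order(match(sites$chrom, names(contigs)), sites$pos)
  if (is.unsorted(ord)) {
    sites <- sites[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
    if (!is.null(gq)) gq <- gq[, ord, drop = FALSE]
    if (!is.null(dp)) dp <- dp[, ord, drop = FALSE]
  }
  rownames(dosage) <- samples
  structure(list(dosage = dosage, gq = gq, dp = dp,
                 sites = sites, samples = samples, contigs = contigs,
                 n_dropped_multiallelic = as.integer(n_dropped_multiallelic)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites on %d contig(s)\n",
              length(x$samples), nrow(x$sites), length(x$contigs)))
  cat(sprintf("  missing genotypes: %.1f%%; multiallelic records dropped: %d\n",
              100 * mean(is.na(x$dosage)), x$n_dropped_multiallelic))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(length(x$samples), nrow(x$sites))

#' Load diploid genotypes from a VCF
#'
#' Reads a (possibly bgzipped) VCF, keeps biallelic SNP records only, and
#' applies the per-genotype quality rule: genotypes with
#' \code{GQ <= gq_min} or \code{DP <= dp_min} are set to missing.  The
#' thresholds are inclusive by design, matching the filtering wording they
#' implement ("GQ <= 20 or DP <= 6" missing).
#'
#' @param vcf_path path to a VCF file
#' @param gq_min genotypes with GQ at or below this are set missing (NULL to
#'   skip; skipped automatically when the VCF lacks FORMAT/GQ)
#' @param dp_min genotypes with DP at or below this are set missing (NULL to
#'   skip; skipped automatically when the VCF lacks FORMAT/DP)
#' @return a \code{\link{geno_matrix}}
#' @export
load_genotypes <- function(vcf_path, gq_min = 20, dp_min = 6) {
  if (!file.exists(vcf_path)) stop("cannot read VCF: ", vcf_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  if (ncol(v@gt) < 2L) stop("VCF contains no sample genotypes")
  bi <- vcfR::is.biallelic(v)
  n_drop <- sum(!bi)
  if (n_drop > 0) {
    message(n_drop, " multiallelic record(s) dropped")
    v <- v[bi, ]
  }
  fix <- vcfR::getFIX(v)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt),
                dimnames = dimnames(gt))
  gtc <- gsub("\\|", "/", gt)
  dos[gtc %in% c("0/0")] <- 0L
  dos[gtc %in% c("0/1", "1/0")] <- 1L
  dos[gtc %in% c("1/1")] <- 2L
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  gq <- dp <- NULL
  if ("GQ" %in% fmt_keys)
    gq <- vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE)
  if ("DP" %in% fmt_keys)
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
  if (!is.null(gq_min) && !is.null(gq)) dos[!is.na(gq) & gq <= gq_min] <- NA_integer_
  if (!is.null(dp_min) && !is.null(dp)) dos[!is.na(dp) & dp <= dp_min] <- NA_integer_
  site_dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]) - 1L,
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      site_dp = if (length(site_dp)) site_dp else NA_integer_,
                      stringsAsFactors = FALSE)
  contigs <- .vcf_contigs(v, sites)
  geno_matrix(t(dos), sites, colnames(gt), contigs,
              gq = if (is.null(gq)) NULL else t(gq),
              dp = if (is.null(dp)) NULL else t(dp),
              n_dropped_multiallelic = n_drop)
}

.vcf_contigs <- function(v, sites) {
  meta <- v@meta
  ln <- grep("^##contig=", meta, value = TRUE)
  if (length(ln)) {
    ids <- sub(".*ID=([^,>]+).*", "\\1", ln)
    lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", ln)))
    if (!anyNA(lens)) return(stats::setNames(lens, ids))
  }
  tapply(sites$pos + 1L, sites$chrom, max)[unique(sites$chrom)]
}

#' Remove sites with excess missingness
#'
#' Drops sites where strictly more than \code{max_missing} of sample
#' genotypes are missing.  A site at exactly the threshold is retained
#' (the rule removes sites with "more than 80\%" missing).
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param max_missing maximum tolerated missing fraction per site
#' @return a filtered \code{geno_matrix}; sample set unchanged
#' @export
filter_sites <- function(gm, max_missing = 0.8) {
  stopifnot(inherits(gm, "geno_matrix"), nrow(gm$sites) > 0)
  miss <- colMeans(is.na(gm$dosage))
  keep <- miss <= max_missing
  if (!any(keep)) warning("all sites removed by missingness filter")
  .subset_gm(gm, sample_keep = NULL, site_keep = keep)
}

#' Remove samples with low depth or genotyping rate
#'
#' Retains samples with mean genotype DP at or above \code{min_mean_dp} and
#' non-missing genotype fraction strictly above
#' \code{min_genotyped_fraction} (a sample genotyped at exactly 80\% is
#' removed, per the strict ">80\% of the genome genotyped" rule).
#'
#' @param gm a \code{\link{geno_matrix}} carrying per-genotype DP
#' @param min_mean_dp minimum mean depth across genotyped sites
#' @param min_genotyped_fraction genotyping-rate threshold (strict)
#' @return a filtered \code{geno_matrix}; site set unchanged
#' @export
filter_samples <- function(gm, min_mean_dp = 6, min_genotyped_fraction = 0.8) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (is.null(gm$dp)) stop("per-genotype DP required for sample filtering")
  mean_dp <- rowMeans(gm$dp, na.rm = TRUE)
  genof <- rowMeans(!is.na(gm$dosage))
  keep <- !is.na(mean_dp) & mean_dp >= min_mean_dp & genof > min_genotyped_fraction
  .subset_gm(gm, sample_keep = keep, site_keep = NULL)
}

.subset_gm <- function(gm, sample_keep = NULL, site_keep = NULL) {
  if (is.null(sample_keep)) sample_keep <- rep(TRUE, length(gm$samples))
  if (is.null(site_keep)) site_keep <- rep(TRUE, nrow(gm$sites))
  geno_matrix(gm$dosage[sample_keep, site_keep, drop = FALSE],
              gm$sites[site_keep, , drop = FALSE],
              gm$samples[sample_keep], gm$contigs,
              gq = if (is.null(gm$gq)) NULL else gm$gq[sample_keep, site_keep, drop = FALSE],
              dp = if (is.null(gm$dp)) NULL else gm$dp[sample_keep, site_keep, drop = FALSE],
              n_dropped_multiallelic = gm$n_dropped_multiallelic)
}

#' Per-isolate heterozygosity
#'
#' Fraction of non-missing genotypes that are heterozygous (dosage 1).
#' Used to screen query isolates before identity-by-state painting, which
#' assumes near-homozygous genomes.
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param sample sample identifier
#' @return heterozygous fraction in [0, 1]
#' @export
heterozygosity <- function(gm, sample) {
  stopifnot(sample %in% gm$samples)
  g <- gm$dosage[match(sample, gm$samples), ]
  n <- sum(!is.na(g))
  if (n == 0) stop("no non-missing genotypes for sample ", sample)
  sum(g == 1L, na.rm = TRUE) / n
}

# ---- repeat mask -----------------------------------------------------------

#' Read a repeat mask from BED
#'
#' BED intervals are 0-based half-open, matching the internal coordinate
#' convention, so columns 1-3 are used as-is.  Overlapping or adjacent
#' intervals are merged per contig.
#'
#' @param path BED file (chrom, start, end, ...)
#' @return a \code{repeat_mask}: named list of two-column matrices
#' @export
read_repeat_mask <- function(path) {
  b <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  repeat_mask(b[[1]], b[[2]], b[[3]])
}

#' Build a repeat mask from vectors
#' @param chrom,start,end interval coordinates (0-based half-open)
#' @return a \code{repeat_mask} object
#' @export
repeat_mask <- function(chrom, start, end) {
  stopifnot(length(start) == length(end), all(end > start))
  chrom <- rep(chrom, length.out = length(start))
  out <- lapply(split(data.frame(start, end), chrom), function(d) {
    d <- d[order(d$start), , drop = FALSE]
    s <- d$start; e <- d$end
    ms <- s[1]; me <- e[1]; rs <- c(); re <- c()
    for (i in seq_along(s)[-1]) {
      if (s[i] <= me) me <- max(me, e[i])
      else { rs <- c(rs, ms); re <- c(re, me); ms <- s[i]; me <- e[i] }
    }
    cbind(start = c(rs, ms), end = c(re, me))
  })
  structure(out, class = "repeat_mask")
}

# TRUE where position falls inside a masked interval of its contig.
.masked <- function(mask, chrom, pos) {
  if (is.null(mask)) return(rep(FALSE, length(pos)))
  out <- rep(FALSE, length(pos))
  for (ctg in unique(chrom)) {
    iv <- mask[[ctg]]
    if (is.null(iv)) next
    idx <- which(chrom == ctg)
    p <- pos[idx]
    j <- findInterval(p, iv[, "start"])
    out[idx] <- j > 0 & p < iv[, "end"][pmax(j, 1L)]
  }
  out
}

# ---- windows ---------------------------------------------------------------

#' Tile or slide genomic windows across contigs
#'
#' Window starts are \code{0, step, 2*step, ...} with \code{s < L - size +
#' step} for contig length \code{L}; a contig shorter than \code{size}
#' yields a single window covering it.  The final window may be shorter than
#' \code{size}; it is kept but flagged \code{partial} so callers can drop
#' it.  Sites inside masked intervals are excluded from every window's site
#' list.
#'
#' @param contigs named vector of contig lengths
#' @param size window length in bp
#' @param step step in bp (equal to \code{size} for tiled windows)
#' @param mask optional \code{\link{repeat_mask}}
#' @param sites optional site table (\code{chrom}, \code{pos}) to assign
#' @return a \code{window_set}: data.frame (chrom, start, end, partial) with
#'   a \code{site_idx} list attribute mapping windows to site row indices
#' @export
build_windows <- function(contigs, size, step = size, mask = NULL, sites = NULL) {
  if (size <= 0 || step <= 0) stop("size and step must be positive")
  if (step > size) stop("step must not exceed window size")
  res <- lapply(names(contigs), function(ctg) {
    len <- contigs[[ctg]]
    lim <- len - size + step          # starts are s = k*step with s < lim
    starts <- if (lim <= 0) 0 else step * (0:((ceiling(lim) - 1) %/% step))
    data.frame(chrom = ctg, start = starts,
               end = pmin(starts + size, len), stringsAsFactors = FALSE)
  })
  w <- do.call(rbind, res)
  w$partial <- (w$end - w$start) < size
  site_idx <- rep(list(integer(0)), nrow(w))
  if (!is.null(sites) && nrow(sites) > 0) {
    keep <- !.masked(mask, sites$chrom, sites$pos)
    for (i in seq_len(nrow(w))) {
      site_idx[[i]] <- which(keep & sites$chrom == w$chrom[i] &
                               sites$pos >= w$start[i] & sites$pos < w$end[i])
    }
  }
  attr(w, "site_idx") <- site_idx
  attr(w, "size") <- size
  attr(w, "step") <- step
  class(w) <- c("window_set", "data.frame")
  w
}

#' Site indices of one window
#' @param windows a \code{window_set}
#' @param i window row index
#' @return integer vector of site row indices
#' @export
window_sites <- function(windows, i) attr(windows, "site_idx")[[i]]

# ---- VCF writing -----------------------------------------------------------

#' Write a genotype matrix to VCF
#'
#' Emits a minimal VCFv4.2 with GT:GQ:DP genotypes (GQ/DP filled with 99/30
#' placeholders when absent) so a round trip through
#' \code{\link{load_genotypes}} reproduces the dosage matrix.
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param path output path (plain text)
#' @export
write_genotypes_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", names(gm$contigs),
                       as.integer(gm$contigs)),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$samples), collapse = "\t")), con)
  gt_str <- matrix("./.", nrow(gm$dosage), ncol(gm$dosage))
  gt_str[gm$dosage == 0L] <- "0/0"
  gt_str[gm$dosage == 1L] <- "0/1"
  gt_str[gm$dosage == 2L] <- "1/1"
  gq <- if (is.null(gm$gq)) matrix(99L, nrow(gt_str), ncol(gt_str)) else gm$gq
  dp <- if (is.null(gm$dp)) matrix(30L, nrow(gt_str), ncol(gt_str)) else gm$dp
  cells <- matrix(paste(gt_str, gq, dp, sep = ":"), nrow(gt_str))
  body <- vapply(seq_len(nrow(gm$sites)), function(j) {
    paste(c(gm$sites$chrom[j], gm$sites$pos[j] + 1L, ".",
            gm$sites$ref[j], gm$sites$alt[j], ".", "PASS", ".",
            "GT:GQ:DP", cells[, j]), collapse = "\t")
  }, character(1))
  writeLines(body, con)
}
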