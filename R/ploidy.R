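# Read-depth aneuploidy detection and genome-instability statistics.
#
# The per-chromosome test compares per-site depth on the test chromosome
# against the pooled depth of all other chromosomes (Mann-Whitney), with
# the rank-biserial correlation as effect size and the Hodges-Lehmann
# location shift (median of all pairwise differences) as the copy-number
# proxy.  The Hodges-Lehmann estimate is computed exactly by order-statistic
# selection over the pairwise-difference distribution; no pair matrix is
# ever materialized for large inputs.

#' Construct a depth profile
#'
#' @param isolate isolate id
#' @param depths named list of non-negative integer vectors, one per
#'   chromosome (per-site read depth)
#' @param lengths optional named chromosome lengths (bp); defaults assume
#'   1 bp per site
#' @param positions optional named list of 0-based site positions aligned
#'   with \code{depths} (required for bp-windowed tracks; evenly spaced
#'   positions are synthesized otherwise)
#' @return a \code{depth_profile}
#' @export
depth_profile <- function(isolate, depths, lengths = NULL, positions = NULL) {
  stopifnot(is.list(depths), length(depths) >= 1, !is.null(names(depths)))
  if (any(vapply(depths, length, 0L) == 0)) stop("empty chromosome vector")
  if (is.null(lengths))
    lengths <- vapply(depths, length, 0L)
  if (is.null(positions))
    positions <- lapply(names(depths), function(ctg) {
      n <- length(depths[[ctg]])
      as.integer(floor(seq(0, lengths[[ctg]] - 1, length.out = n)))
    })
  names(positions) <- names(depths)
  structure(list(isolate = isolate, depths = depths,
                 lengths = lengths, positions = positions),
            class = "depth_profile")
}

#' Read a depth profile from a per-site TSV (chrom, pos, depth)
#' @param path TSV with columns chrom, pos (0-based), depth
#' @param isolate isolate id recorded on the profile
#' @return a \code{depth_profile}
#' @export
read_depth_tsv <- function(path, isolate = basename(path)) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  sp <- split(d, d$chrom)
  depth_profile(isolate,
                depths = lapply(sp, function(x) as.integer(x$depth[order(x$pos)])),
                positions = lapply(sp, function(x) sort(as.integer(x$pos))))
}

#' Coverage gate for instability analyses
#'
#' @param profile a \code{\link{depth_profile}}
#' @param min_mean minimum genome-wide mean depth (inclusive)
#' @return TRUE when mean depth is at or above \code{min_mean}
#' @export
coverage_gate <- function(profile, min_mean = 20) {
  mean(unlist(profile$depths)) >= min_mean
}

#' Rank-biserial correlation for two samples
#'
#' \eqn{r = 2W/(n_1 n_2) - 1} where W counts pairs with x above y (ties
#' half-weighted): +1 when every x exceeds every y, so positive values mean
#' the test group is deeper than the background.
#'
#' @param x,y numeric vectors
#' @return rank-biserial correlation in [-1, 1]
#' @export
rank_biserial <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2   # pairs x > y, ties as 1/2
  2 * w / (n1 * n2) - 1
}

#' Hodges-Lehmann location shift between two samples
#'
#' The median of all \eqn{n_1 n_2} pairwise differences \eqn{x_i - y_j},
#' computed exactly.  Integer-valued inputs use bisection on the pair-count
#' function (O((n1+n2) log range) per probe); real-valued inputs fall back
#' to the explicit difference matrix when \eqn{n_1 n_2 \le} \code{max_pairs}
#' and to bisection with a numeric tolerance otherwise.
#'
#' @param x,y numeric vectors
#' @param max_pairs explicit-enumeration ceiling for non-integer input
#' @return the location shift (x relative to y)
#' @export
hl_shift <- function(x, y, max_pairs = 1e7) {
  n1 <- length(x); n2 <- length(y)
  stopifnot(n1 > 0, n2 > 0)
  npairs <- as.double(n1) * n2
  integerish <- all(x == round(x)) && all(y == round(y))
  if (!integerish && npairs <= max_pairs)
    return(stats::median(as.vector(outer(x, y, `-`))))
  xs <- sort(x); ys <- sort(y)
  # pairs with x_i - y_j <= t
  count_leq <- function(t) sum(findInterval(t + ys, xs))
  kth <- function(k) {
    lo <- min(xs) - max(ys); hi <- max(xs) - min(ys)
    if (integerish) {
      lo <- floor(lo); hi <- ceiling(hi)
      while (lo < hi) {
        mid <- floor((lo + hi) / 2)
        if (count_leq(mid) >= k) hi <- mid else lo <- mid + 1
      }
      lo
    } else {
      for (it in 1:200) {
        mid <- (lo + hi) / 2
        if (count_leq(mid) >= k) hi <- mid else lo <- mid
        if (hi - lo < 1e-12 * max(1, abs(hi))) break
      }
      hi
    }
  }
  k1 <- floor((npairs + 1) / 2); k2 <- ceiling((npairs + 1) / 2)
  (kth(k1) + kth(k2)) / 2
}

#' Test one chromosome's depth distribution against the background
#'
#' Two-sided Mann-Whitney of the chromosome's per-site depth against the
#' pooled depth of all other chromosomes, with rank-biserial effect size
#' (positive = deeper than background) and the Hodges-Lehmann location
#' shift.  Optionally subsamples each group to \code{max_sites_per_group}
#' sites for speed; the rank-biserial estimate is stable under such caps.
#'
#' @param profile a \code{\link{depth_profile}}
#' @param chrom chromosome to test
#' @param max_sites_per_group optional per-group subsampling cap (uses the
#'   current RNG stream; seed upstream for reproducibility)
#' @return list(rank_biserial, hl_shift_raw, p_value, n_chrom, n_background,
#'   degenerate)
#' @export
test_chromosome <- function(profile, chrom, max_sites_per_group = Inf) {
  stopifnot(chrom %in% names(profile$depths))
  if (length(profile$depths) < 2) stop("need at least 2 chromosomes")
  x <- profile$depths[[chrom]]
  y <- unlist(profile$depths[setdiff(names(profile$depths), chrom)],
              use.names = FALSE)
  if (is.finite(max_sites_per_group)) {
    if (length(x) > max_sites_per_group)
      x <- x[sort(sample.int(length(x), max_sites_per_group))]
    if (length(y) > max_sites_per_group)
      y <- y[sort(sample.int(length(y), max_sites_per_group))]
  }
  if (length(unique(c(x, y))) == 1)
    return(list(rank_biserial = 0, hl_shift_raw = 0, p_value = 1,
                n_chrom = length(x), n_background = length(y),
                degenerate = TRUE))
  rb <- rank_biserial(x, y)
  hl <- hl_shift(x, y)
  p <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                           correct = TRUE)$p.value)
  list(rank_biserial = rb, hl_shift_raw = hl, p_value = p,
       n_chrom = length(x), n_background = length(y), degenerate = FALSE)
}

#' Call whole-chromosome aneuploidies from a depth profile
#'
#' One test per chromosome (\code{\link{test_chromosome}}); a chromosome is
#' called GAIN when its rank-biserial effect is at or above
#' \code{effect_threshold} with a positive shift, LOSS at or below the
#' negated threshold with a negative shift, otherwise NONE.  Location
#' shifts are normalized by the median depth of chromosomes called NONE
#' (the inferred 2N set); when every chromosome is called, the genome-wide
#' median is used and flagged.
#'
#' @param profile a \code{\link{depth_profile}}
#' @param effect_threshold rank-biserial magnitude for a call ("large"
#'   effect)
#' @param max_sites_per_group optional subsampling cap per test
#' @return data.frame: isolate, chrom, rank_biserial, hl_shift_raw,
#'   hl_shift_norm, p_value, direction, with attribute \code{diploid_median}
#'   and \code{norm_fallback}
#' @export
call_aneuploidies <- function(profile, effect_threshold = 0.5,
                              max_sites_per_group = Inf) {
  chroms <- names(profile$depths)
  if (length(chroms) < 2) stop("aneuploidy calling needs >= 2 chromosomes")
  tests <- lapply(chroms, function(ctg)
    test_chromosome(profile, ctg, max_sites_per_group))
  rb <- vapply(tests, `[[`, 0, "rank_biserial")
  hl <- vapply(tests, `[[`, 0, "hl_shift_raw")
  pv <- vapply(tests, `[[`, 0, "p_value")
  direction <- ifelse(rb >= effect_threshold & hl > 0, "GAIN",
                      ifelse(rb <= -effect_threshold & hl < 0, "LOSS", "NONE"))
  none <- direction == "NONE"
  fallback <- !any(none)
  med2n <- if (fallback) stats::median(unlist(profile$depths))
           else stats::median(unlist(profile$depths[chroms[none]]))
  out <- data.frame(isolate = profile$isolate, chrom = chroms,
                    rank_biserial = rb, hl_shift_raw = hl,
                    hl_shift_norm = hl / med2n, p_value = pv,
                    direction = direction, stringsAsFactors = FALSE)
  attr(out, "diploid_median") <- med2n
  attr(out, "norm_fallback") <- fallback
  out
}

#' Build instability records from aneuploidy calls
#'
#' One record per polysome (chromosome called GAIN or LOSS): its normalized
#' location shift paired with the mean normalized shift of the isolate's
#' \emph{other} polysomes.  Isolates with a single polysome contribute no
#' record (no background).
#'
#' @param calls data.frame of \code{\link{call_aneuploidies}} outputs,
#'   possibly row-bound across isolates
#' @param group optional named vector mapping isolate to group label
#'   (e.g. admixed / feral)
#' @return data.frame: isolate, chrom, shift, mean_background_shift, group
#' @export
instability_records <- function(calls, group = NULL) {
  poly <- calls[calls$direction != "NONE", , drop = FALSE]
  out <- do.call(rbind, lapply(split(poly, poly$isolate), function(d) {
    if (nrow(d) < 2) return(NULL)
    data.frame(isolate = d$isolate, chrom = d$chrom, shift = d$hl_shift_norm,
               mean_background_shift = vapply(seq_len(nrow(d)), function(i)
                 mean(d$hl_shift_norm[-i]), 0),
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(isolate = character(), chrom = character(),
                      shift = numeric(), mean_background_shift = numeric())
  rownames(out) <- NULL
  out$group <- if (is.null(group)) NA_character_ else unname(group[out$isolate])
  out
}

#' Genome-instability regression
#'
#' Gaussian identity-link fit of polysome location shift on the mean shift
#' of the isolate's other polysomes, per chromosome stratum and pooled.
#' Strata with fewer than 3 records are skipped with a warning.
#'
#' @param records output of \code{\link{instability_records}}
#' @return data.frame: stratum ("pooled" or chromosome), n, slope,
#'   intercept, r_squared
#' @export
instability_regression <- function(records) {
  fit_one <- function(d, label) {
    if (nrow(d) < 3) {
      warning("stratum ", label, " has < 3 records; skipped")
      return(NULL)
    }
    if (stats::var(d$mean_background_shift) == 0) {
      warning("stratum ", label, ": zero predictor variance; slope undefined")
      return(data.frame(stratum = label, n = nrow(d), slope = NA_real_,
                        intercept = NA_real_, r_squared = NA_real_))
    }
    fit <- stats::lm(shift ~ mean_background_shift, data = d)
    data.frame(stratum = label, n = nrow(d),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r_squared = summary(fit)$r.squared,
               stringsAsFactors = FALSE)
  }
  out <- rbind(fit_one(records, "pooled"),
               do.call(rbind, lapply(split(records, records$chrom),
                                     function(d) fit_one(d, d$chrom[1]))))
  rownames(out) <- NULL
  out
}

#' Compare instability between two isolate groups
#'
#' One-sided Mann-Whitney on the per-isolate mean normalized polysome
#' shift, testing whether a random observation from group A tends to exceed
#' one from group B.  Exact when the combined sample size is at most 50,
#' otherwise the normal approximation with continuity correction.
#'
#' @param records output of \code{\link{instability_records}} with a
#'   \code{group} column
#' @param group_a,group_b group labels (alternative: A greater)
#' @return list(p_value, method, n_a, n_b, stat_a, stat_b)
#' @export
compare_groups <- function(records, group_a, group_b) {
  per_iso <- tapply(records$shift, records$isolate, mean)
  grp <- tapply(records$group, records$isolate, function(g) g[1])
  a <- per_iso[grp == group_a]
  b <- per_iso[grp == group_b]
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  exact <- (length(a) + length(b)) <= 50
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "greater",
                                            exact = exact, correct = TRUE))
  list(p_value = ht$p.value,
       method = if (exact) "exact" else "normal approximation",
       n_a = length(a), n_b = length(b),
       stat_a = mean(a), stat_b = mean(b))
}

#' Normalized sliding-window depth track
#'
#' Median depth in bp windows (default 10 kb sliding by 2 kb) divided by
#' the 2N median defined by chromosomes called NONE in \code{calls}; when
#' no chromosome is 2N the genome-wide median is used and flagged.  A clean
#' k-copy chromosome tracks \eqn{1 + 0.5 (k - 2)}.
#'
#' @param profile a \code{\link{depth_profile}} with site positions
#' @param calls output of \code{\link{call_aneuploidies}} for the profile
#'   (NULL to normalize by the genome-wide median)
#' @param window,step window and step in bp
#' @return data.frame: chrom, start, end, norm_depth, n_sites; attribute
#'   \code{norm_fallback}
#' @export
normalized_depth_track <- function(profile, calls = NULL,
                                   window = 10000, step = 2000) {
  fallback <- TRUE
  med2n <- stats::median(unlist(profile$depths))
  if (!is.null(calls)) {
    none <- calls$chrom[calls$direction == "NONE"]
    if (length(none)) {
      med2n <- stats::median(unlist(profile$depths[none]))
      fallback <- FALSE
    }
  }
  out <- do.call(rbind, lapply(names(profile$depths), function(ctg) {
    pos <- profile$positions[[ctg]]
    dep <- profile$depths[[ctg]]
    len <- profile$lengths[[ctg]]
    lim <- len - window + step
    starts <- if (lim <= 0) 0 else step * (0:((ceiling(lim) - 1) %/% step))
    md <- vapply(starts, function(s) {
      sel <- pos >= s & pos < s + window
      if (!any(sel)) NA_real_ else stats::median(dep[sel])
    }, 0)
    ns <- vapply(starts, function(s) sum(pos >= s & pos < s + window), 0L)
    data.frame(chrom = ctg, start = starts,
               end = pmin(starts + window, len),
               norm_depth = md / med2n, n_sites = ns,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "norm_fallback") <- fallback
  out
}
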