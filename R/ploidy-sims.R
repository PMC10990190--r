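# Simulation designs for the aneuploidy framework: whole-chromosome
# gain/loss power, segmental-duplication robustness, and the effect of
# co-occurring high-copy polysomes on the Hodges-Lehmann copy-number proxy.
#
# Per-site depth is drawn Normal(mean, sd), multiplied by (1 + shift) on
# affected chromosomes, rounded and floored at zero.  A shift of 0.5 is a
# 3N chromosome, 3 is 8N, k/2 is a k-copy gain over 2N.

#' Background aneuploidy selection weights
#'
#' Empirically, chromosome gain frequency is negatively correlated with
#' chromosome length, with the shortest chromosomes (1, 3, 6, 9) gained
#' most often.  The simulation designs therefore select background
#' aneuploid chromosomes with probability proportional to the inverse of
#' chromosome size (site count), emulating that rate structure; pass a
#' uniform \code{select_weights} vector for unweighted selection.
#'
#' @param site_counts named per-chromosome site counts
#' @return named weight vector proportional to 1 / site count
#' @export
aneuploidy_selection_weights <- function(site_counts) {
  w <- 1 / site_counts
  w / sum(w)
}

#' Simulate a read-depth profile
#'
#' @param site_counts named integer vector: simulated sites per chromosome
#'   (see \code{\link{default_site_counts}})
#' @param mean,sd Normal depth model for the 2N baseline
#' @param aneuploidies optional data.frame (chrom, shift): whole-chromosome
#'   depth shifts as fractions of 2N (0.5 = 3N, -0.5 = 1N, -1 = 0N)
#' @param segmental optional data.frame (chrom, fraction, scale): a
#'   contiguous |fraction| of the chromosome's sites multiplied by
#'   \code{scale}
#' @param isolate isolate id on the returned profile
#' @return a \code{\link{depth_profile}}; depths are integers >= 0
#' @export
simulate_depth <- function(site_counts, mean = 30, sd = 10,
                           aneuploidies = NULL, segmental = NULL,
                           isolate = "sim") {
  stopifnot(length(site_counts) >= 2, !is.null(names(site_counts)))
  if (!is.null(aneuploidies) && nrow(aneuploidies)) {
    if (any(!aneuploidies$chrom %in% names(site_counts)))
      stop("aneuploidy on unknown chromosome")
    if (any(aneuploidies$shift < -1)) stop("shift below -1 (0N) is impossible")
  }
  depths <- lapply(names(site_counts), function(ctg) {
    n <- site_counts[[ctg]]
    base <- stats::rnorm(n, mean, sd)
    shift <- 0
    if (!is.null(aneuploidies) && ctg %in% aneuploidies$chrom)
      shift <- aneuploidies$shift[match(ctg, aneuploidies$chrom)]
    d <- base * (1 + shift)
    if (!is.null(segmental) && ctg %in% segmental$chrom) {
      seg <- segmental[match(ctg, segmental$chrom), ]
      n_seg <- round(abs(seg$fraction) * n)
      if (n_seg > 0) d[seq_len(n_seg)] <- d[seq_len(n_seg)] * seg$scale
    }
    pmax(0L, as.integer(round(d)))
  })
  names(depths) <- names(site_counts)
  depth_profile(isolate, depths)
}

#' Whole-chromosome gain/loss power grid
#'
#' For every combination of depth scaling (default -1 to 1 by 0.1, i.e. 0N
#' to 4N) and number of background 3N aneuploidies (0-5), simulates depth
#' profiles, runs the per-chromosome test on the focal chromosome and
#' records the rank-biserial effect size.  Background aneuploid chromosomes
#' are selected per replicate from the non-focal chromosomes with
#' probabilities \code{select_weights}
#' (\code{\link{aneuploidy_selection_weights}} by default).
#'
#' @param seed RNG seed (one stream for the whole grid)
#' @param scale_grid focal-chromosome scaling factors
#' @param n_background_grid counts of co-occurring background 3N chromosomes
#' @param site_counts per-chromosome site counts
#' @param focal_chrom chromosome receiving the scaling (default chrVI,
#'   mirroring the original design)
#' @param n_reps replicates (seeds) per cell
#' @param bg_mean,bg_sd 2N depth model
#' @param select_weights optional per-chromosome selection weights for
#'   background aneuploidies
#' @param effect_threshold rank-biserial call threshold recorded as
#'   \code{called}
#' @return data.frame: scale, n_background, rep, rank_biserial, called
#' @export
simulate_power_grid <- function(seed, scale_grid = seq(-1, 1, by = 0.1),
                                n_background_grid = 0:5,
                                site_counts = default_site_counts(),
                                focal_chrom = "chrVI", n_reps = 20,
                                bg_mean = 30, bg_sd = 10,
                                select_weights =
                                  aneuploidy_selection_weights(site_counts),
                                effect_threshold = 0.5) {
  set.seed(seed)
  others <- setdiff(names(site_counts), focal_chrom)
  grid <- expand.grid(scale = scale_grid, n_background = n_background_grid,
                      rep = seq_len(n_reps))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    bg <- if (g$n_background > 0)
      sample(others, g$n_background, prob = select_weights[others]) else character()
    an <- data.frame(chrom = c(focal_chrom, bg),
                     shift = c(g$scale, rep(0.5, length(bg))))
    prof <- simulate_depth(site_counts, bg_mean, bg_sd, aneuploidies = an)
    tt <- test_chromosome(prof, focal_chrom)
    data.frame(scale = g$scale, n_background = g$n_background, rep = g$rep,
               rank_biserial = tt$rank_biserial,
               called = abs(tt$rank_biserial) >= effect_threshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Segmental-duplication robustness grid
#'
#' A signed fraction of the focal chromosome (default -0.5 to 0.5) is
#' scaled: positive fractions put that share of sites at 3N (x1.5),
#' negative fractions at 1N (x0.5).  Whole-chromosome calls on such
#' segmental events are false positives for the aneuploidy rule, so the
#' recorded call rate measures robustness.
#'
#' @inheritParams simulate_power_grid
#' @param fraction_grid signed segment fractions
#' @return data.frame: fraction, rep, rank_biserial, called
#' @export
simulate_segmental_grid <- function(seed,
                                    fraction_grid = seq(-0.5, 0.5, by = 0.1),
                                    site_counts = default_site_counts(),
                                    focal_chrom = "chrVI", n_reps = 20,
                                    bg_mean = 30, bg_sd = 10,
                                    effect_threshold = 0.5) {
  stopifnot(all(abs(fraction_grid) <= 0.5))
  set.seed(seed)
  grid <- expand.grid(fraction = fraction_grid, rep = seq_len(n_reps))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    seg <- if (g$fraction == 0) NULL else
      data.frame(chrom = focal_chrom, fraction = abs(g$fraction),
                 scale = if (g$fraction > 0) 1.5 else 0.5)
    prof <- simulate_depth(site_counts, bg_mean, bg_sd, segmental = seg)
    tt <- test_chromosome(prof, focal_chrom)
    data.frame(fraction = g$fraction, rep = g$rep,
               rank_biserial = tt$rank_biserial,
               called = abs(tt$rank_biserial) >= effect_threshold)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Co-occurring-polysome copy-number bias grid
#'
#' Background polysomes with normalized location shift 0 (2N), 1 (4N),
#' 2 (6N) or 3 (8N) are simulated for 0-5 co-occurring chromosomes; a
#' single randomly selected distinct foreground chromosome carries a true
#' normalized shift of 0-5 by 0.5 (a 2N-12N range).  The foreground shift
#' is re-estimated with the Hodges-Lehmann statistic normalized by the
#' median of chromosomes called 2N, and the relative underestimation
#' (true - estimated)/true is recorded for true > 0.
#'
#' Within each replicate one simulated layout is shared across all grid
#' cells (common random numbers): the same baseline depth draws, the same
#' foreground chromosome and the same nested background selection, with
#' only the scaling factors changing cell to cell.  This isolates the
#' effect of the grid variables from between-cell sampling noise, so the
#' monotone response of the underestimation to polysome count and copy
#' number is visible at modest replicate counts.
#'
#' @inheritParams simulate_power_grid
#' @param n_cooccurring_grid background polysome counts
#' @param background_shift_grid background normalized shifts
#' @param foreground_grid true foreground normalized shifts
#' @return data.frame: n_cooccurring, background_shift, true_shift, rep,
#'   estimated_shift, underestimation (fraction; NA when true = 0)
#' @export
simulate_cooccurrence <- function(seed, n_cooccurring_grid = 0:5,
                                  background_shift_grid = c(0, 1, 2, 3),
                                  foreground_grid = seq(0, 5, by = 0.5),
                                  site_counts = default_site_counts(),
                                  n_reps = 20, bg_mean = 30, bg_sd = 10,
                                  select_weights =
                                    aneuploidy_selection_weights(site_counts),
                                  effect_threshold = 0.5) {
  set.seed(seed)
  chroms <- names(site_counts)
  max_co <- max(n_cooccurring_grid)
  grid <- expand.grid(n_cooccurring = n_cooccurring_grid,
                      background_shift = background_shift_grid,
                      true_shift = foreground_grid)
  res <- vector("list", n_reps * nrow(grid))
  k <- 0
  for (r in seq_len(n_reps)) {
    base <- lapply(site_counts, function(n) stats::rnorm(n, bg_mean, bg_sd))
    fg <- sample(chroms, 1)
    bg_pool <- if (max_co > 0)
      sample(setdiff(chroms, fg), max_co,
             prob = select_weights[setdiff(chroms, fg)]) else character()
    for (i in seq_len(nrow(grid))) {
      g <- grid[i, ]
      bg <- utils::head(bg_pool, g$n_cooccurring)
      shift_of <- stats::setNames(rep(0, length(chroms)), chroms)
      shift_of[bg] <- g$background_shift
      shift_of[fg] <- g$true_shift
      depths <- lapply(chroms, function(ctg)
        pmax(0L, as.integer(round(base[[ctg]] * (1 + shift_of[[ctg]])))))
      names(depths) <- chroms
      prof <- depth_profile("sim", depths)
      calls <- call_aneuploidies(prof, effect_threshold)
      est <- calls$hl_shift_norm[calls$chrom == fg]
      k <- k + 1
      res[[k]] <- data.frame(n_cooccurring = g$n_cooccurring,
                             background_shift = g$background_shift,
                             true_shift = g$true_shift, rep = r,
                             estimated_shift = est,
                             underestimation = if (g$true_shift > 0)
                               (g$true_shift - est) / g$true_shift
                             else NA_real_)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
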