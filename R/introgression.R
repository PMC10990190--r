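# Local-tree subtree incongruence, windowed admixture allele frequency and
# fixed-admixture-block selection.  Trees are windowed maximum-likelihood
# phylogenies supplied as input (newick, haplotype-labelled leaves).

#' Classify one haplotype's local topology as introgressed or not
#'
#' The window tree is pruned to the test haplotype, the candidate source
#' population, the Mediterranean Oak (MO) anchor and the wine reference
#' panel (WRP); unrooted trees are first rooted on the designated outgroup
#' leaves.  The call is:
#' \itemize{
#'   \item \code{INCONGRUENT} when the clade spanned by test + source
#'     excludes every MO/WRP leaf \emph{and} test + MO + WRP is not a clade
#'     (the haplotype has moved into the source lineage);
#'   \item \code{CONGRUENT} when test + MO + WRP form a clade excluding the
#'     source (the species-tree arrangement);
#'   \item \code{UNRESOLVED} otherwise (including failed rooting).
#' }
#' Zero-length internal branches are not collapsed.
#'
#' @param tree an \code{ape::phylo} with haplotype-labelled tips
#' @param test_hap tip label of the haplotype under test
#' @param source,mo,wrp tip-label sets of the candidate source population,
#'   MO anchor and wine panel (at least one of each must be in the tree)
#' @param outgroup tip labels used to root an unrooted tree
#' @return character: one of INCONGRUENT / CONGRUENT / UNRESOLVED
#' @export
classify_local_topology <- function(tree, test_hap, source, mo, wrp,
                                    outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!test_hap %in% tips) stop("test haplotype absent from tree: ", test_hap)
  source <- intersect(source, tips)
  mo <- intersect(mo, tips)
  wrp <- intersect(wrp, tips)
  if (!length(source) || !length(mo) || !length(wrp))
    stop("tree must contain at least one source, MO and WRP leaf")
  og <- intersect(outgroup, tips)
  if (!ape::is.rooted(tree) || length(og)) {
    if (!length(og)) stop("unrooted tree and no outgroup leaves present")
    tree <- tryCatch(
      ape::root(tree, outgroup = og, resolve.root = TRUE),
      error = function(e) NULL)
    if (is.null(tree)) return("UNRESOLVED")
  }
  keep <- unique(c(test_hap, source, mo, wrp))
  sub <- tryCatch(ape::keep.tip(tree, c(keep, og)), error = function(e) NULL)
  if (is.null(sub)) return("UNRESOLVED")
  if (length(og)) {
    # re-root the pruned tree on the outgroup, then remove it
    sub <- tryCatch(ape::root(sub, outgroup = intersect(og, sub$tip.label),
                              resolve.root = TRUE), error = function(e) NULL)
    if (is.null(sub)) return("UNRESOLVED")
    sub <- tryCatch(ape::drop.tip(sub, intersect(og, sub$tip.label)),
                    error = function(e) NULL)
    if (is.null(sub) || !test_hap %in% sub$tip.label) return("UNRESOLVED")
  }
  mono_src <- ape::is.monophyletic(sub, c(test_hap, source))
  mono_home <- ape::is.monophyletic(sub, c(test_hap, mo, wrp))
  if (mono_src && !mono_home) return("INCONGRUENT")
  if (mono_home) return("CONGRUENT")
  "UNRESOLVED"
}

#' Scan window trees for admixture and build the allele-frequency track
#'
#' Every haplotype of \code{population} is classified per window by
#' \code{\link{classify_local_topology}}; the window's admixture allele
#' frequency is the fraction of \emph{resolved} population haplotypes
#' called INCONGRUENT.  Haplotypes missing from a window's tree, and
#' UNRESOLVED calls, are excluded from the denominator; a window with no
#' resolved call has \code{NA} frequency (blank).
#'
#' @param trees list of \code{ape::phylo}, one per window, aligned with
#'   \code{windows}
#' @param windows data.frame (chrom, start, end) describing the tiling
#' @param population tip labels of the haplotypes whose admixture frequency
#'   is tracked
#' @param source,mo,wrp,outgroup as in \code{\link{classify_local_topology}}
#' @return list: \code{calls} (long data.frame window x haplotype x call)
#'   and \code{af_track} (chrom, start, end, af, n_resolved, admixed)
#' @export
scan_windows <- function(trees, windows, population, source, mo, wrp,
                         outgroup = NULL) {
  if (!length(population)) stop("empty population")
  stopifnot(length(trees) == nrow(windows))
  calls <- do.call(rbind, lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    data.frame(window = i,
               haplotype = population,
               call = vapply(population, function(h) {
                 if (is.null(tr) || !h %in% tr$tip.label) return("MISSING")
                 tryCatch(
                   classify_local_topology(tr, h, source, mo, wrp, outgroup),
                   error = function(e) "UNRESOLVED")
               }, ""), row.names = NULL, stringsAsFactors = FALSE)
  }))
  af <- vapply(seq_len(nrow(windows)), function(i) {
    cc <- calls$call[calls$window == i]
    res <- cc[cc %in% c("INCONGRUENT", "CONGRUENT")]
    if (!length(res)) return(NA_real_)
    mean(res == "INCONGRUENT")
  }, 0)
  n_res <- vapply(seq_len(nrow(windows)), function(i) {
    sum(calls$call[calls$window == i] %in% c("INCONGRUENT", "CONGRUENT"))
  }, 0L)
  track <- data.frame(windows[, c("chrom", "start", "end")], af = af,
                      n_resolved = n_res,
                      admixed = !is.na(af) & af > 0)
  list(calls = calls, af_track = track)
}

#' Select fixed admixture blocks and trim breakpoint windows
#'
#' Maximal runs of consecutive windows with admixture allele frequency
#' exactly 1 and length at least \code{min_run} are emitted with the first
#' and last \code{trim} windows discarded, since breakpoint windows may mix
#' both ancestries.
#'
#' @param af_track data.frame (chrom, start, end, af) over a tiled window
#'   set, in genomic order
#' @param min_run minimum run length (windows) before trimming
#' @param trim windows removed from each end of a run
#' @return data.frame of blocks: chrom, start, end, n_windows (after
#'   trimming), first_window, last_window (row indices into af_track)
#' @export
fixed_blocks <- function(af_track, min_run = 3, trim = 1) {
  if (min_run <= 2 * trim)
    stop("min_run must exceed 2 * trim or every block would be trimmed away")
  fixed <- !is.na(af_track$af) & af_track$af >= 1 - 1e-12
  blocks <- list()
  r <- rle(fixed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_run) next
    i0 <- starts[k]; i1 <- ends[k]
    # a run must sit on one chromosome with consecutive tiles
    chroms <- af_track$chrom[i0:i1]
    if (length(unique(chroms)) > 1) {
      for (ctg in unique(chroms)) {
        idx <- (i0:i1)[chroms == ctg]
        if (length(idx) >= min_run)
          blocks[[length(blocks) + 1]] <- c(min(idx), max(idx))
      }
    } else blocks[[length(blocks) + 1]] <- c(i0, i1)
  }
  if (!length(blocks))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_windows = integer(),
                      first_window = integer(), last_window = integer()))
  out <- do.call(rbind, lapply(blocks, function(b) {
    i0 <- b[1] + trim; i1 <- b[2] - trim
    data.frame(chrom = af_track$chrom[i0], start = af_track$start[i0],
               end = af_track$end[i1], n_windows = i1 - i0 + 1L,
               first_window = i0, last_window = i1,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Combine fd and topology evidence for admixed windows
#'
#' A window is admixed when flagged by either line of evidence: fd at or
#' above \code{fd_threshold}, or admixture allele frequency above zero.
#'
#' @param fd_track data.frame (chrom, start, end, value) of windowed fd
#' @param af_track data.frame (chrom, start, end, af) from
#'   \code{\link{scan_windows}}
#' @param fd_threshold fd cutoff; when \code{NULL}, the 99th percentile of
#'   the non-missing fd values of \code{fd_control} is used
#' @param fd_control optional control fd track (non-admixed isolates) from
#'   which the default threshold is derived
#' @return input windows with logical columns fd_hit, topo_hit, admixed
#' @export
combined_evidence <- function(fd_track, af_track, fd_threshold = NULL,
                              fd_control = NULL) {
  if (nrow(fd_track) != nrow(af_track) ||
      any(fd_track$start != af_track$start) ||
      any(fd_track$chrom != af_track$chrom))
    stop("fd and topology tracks are on different windowings")
  if (is.null(fd_threshold)) {
    if (is.null(fd_control))
      stop("supply fd_threshold or a control fd track to derive it")
    fd_threshold <- stats::quantile(fd_control$value, 0.99, na.rm = TRUE,
                                    names = FALSE)
  }
  fd_hit <- !is.na(fd_track$value) & fd_track$value >= fd_threshold
  topo_hit <- !is.na(af_track$af) & af_track$af > 0
  data.frame(fd_track[, c("chrom", "start", "end")],
             fd = fd_track$value, af = af_track$af,
             fd_hit = fd_hit, topo_hit = topo_hit,
             admixed = fd_hit | topo_hit)
}
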