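# Lineage collapsing of the reference panel and window-wise chromosome
# painting of query isolates.

#' Collapse a reference panel into near-clonal lineages
#'
#' Average-linkage hierarchical clustering on dissimilarity 1 - IBS,
#' descended from the root: a dendrogram node is retained as a single
#' lineage only when (a) the permutation Z-score of its between-subcluster
#' mean dissimilarity, against a null of random panel groupings of the same
#' sizes, is below \code{z_cutoff}, and (b) the minimum pairwise IBS inside
#' the node is at least \code{ibs_cutoff}.  Nodes failing either rule are
#' split and their children tested; unclustered isolates become singleton
#' (unique-isolate) lineages.
#'
#' @param ibs_mat square symmetric pairwise IBS matrix, unit diagonal,
#'   with sample names on the dimnames
#' @param z_cutoff permutation Z-score below which a merge is kept
#' @param ibs_cutoff minimum within-lineage pairwise IBS
#' @param n_perm permutation draws for the null (warns below 100)
#' @return data.frame with columns \code{sample}, \code{lineage}
#' @export
cluster_lineages <- function(ibs_mat, z_cutoff = 3, ibs_cutoff = 0.99,
                             n_perm = 1000) {
  stopifnot(is.matrix(ibs_mat), nrow(ibs_mat) == ncol(ibs_mat))
  if (n_perm < 100) warning("n_perm < 100: permutation null will be coarse")
  samples <- rownames(ibs_mat)
  d <- 1 - ibs_mat
  n <- nrow(d)
  if (n == 1)
    return(data.frame(sample = samples, lineage = "L1",
                      stringsAsFactors = FALSE))
  hc <- stats::hclust(stats::as.dist(d), method = "average")

  node_members <- function(k) { # k: row of hc$merge, negatives are leaves
    if (k < 0) return(-k)
    unlist(lapply(hc$merge[k, ], node_members))
  }
  # Z-score of the observed between-subcluster mean dissimilarity against
  # random splits of the whole panel into groups of the same sizes.
  merge_z <- function(left, right) {
    obs <- mean(d[left, right])
    sizes <- c(length(left), length(right))
    null <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, sum(sizes))
      mean(d[idx[seq_len(sizes[1])], idx[-seq_len(sizes[1])]])
    }, 0)
    s <- stats::sd(null)
    if (s == 0 || is.na(s)) return(if (obs > mean(null)) Inf else -Inf)
    (obs - mean(null)) / s
  }
  groups <- list()
  descend <- function(k) {
    if (k < 0) { groups[[length(groups) + 1]] <<- -k; return(invisible()) }
    mem <- node_members(k)
    left <- node_members(hc$merge[k, 1])
    right <- node_members(hc$merge[k, 2])
    min_ibs <- min(ibs_mat[mem, mem])
    if (min_ibs >= ibs_cutoff && merge_z(left, right) < z_cutoff) {
      groups[[length(groups) + 1]] <<- mem
    } else {
      descend(hc$merge[k, 1]); descend(hc$merge[k, 2])
    }
  }
  descend(nrow(hc$merge))
  # stable lineage numbering by first member order
  groups <- groups[order(vapply(groups, min, 0))]
  out <- data.frame(sample = samples, lineage = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(groups))
    out$lineage[groups[[i]]] <- sprintf("L%02d", i)
  out
}

#' Assign windows of a query isolate to clades by minimum Nei's d_a
#'
#' Per window, the query (treated as a one-diploid population) is compared
#' to every clade by \code{\link{nei_da}} and assigned to the closest one.
#' Ties break lexicographically on the clade name and are flagged.
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param query query sample id; must not appear in any clade
#' @param clades named list of sample-id vectors
#' @param windows a \code{window_set}
#' @return list: \code{painting} data.frame (chrom, start, end, clade, da,
#'   n_sites, tied) and \code{proportions} (assigned windows per clade /
#'   assignable windows)
#' @export
assign_clade_da <- function(gm, query, clades, windows) {
  stopifnot(length(clades) >= 1, !is.null(names(clades)))
  if (query %in% unlist(clades)) stop("query must be excluded from clades")
  cn <- sort(names(clades))
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- window_sites(windows, i)
    das <- vapply(cn, function(cl)
      nei_da(gm, query, clades[[cl]], idx)$value, 0)
    if (all(is.na(das)))
      return(data.frame(clade = "UNASSIGNED", da = NA_real_,
                        n_sites = length(idx), tied = FALSE))
    best <- min(das, na.rm = TRUE)
    hits <- cn[which(!is.na(das) & das == best)]
    data.frame(clade = hits[1], da = best, n_sites = length(idx),
               tied = length(hits) > 1)
  })
  pt <- cbind(windows[, c("chrom", "start", "end")], do.call(rbind, rows))
  assigned <- pt$clade != "UNASSIGNED"
  props <- if (any(assigned)) {
    tab <- table(factor(pt$clade[assigned], levels = cn))
    as.numeric(tab) / sum(assigned)
  } else rep(NA_real_, length(cn))
  list(painting = pt, proportions = stats::setNames(props, cn))
}

#' Identity-by-state chromosome painting against panel lineages
#'
#' Per window, each lineage is scored by the maximum IBS between the query
#' and any lineage member over the window's sites; the window is assigned
#' to the best-scoring lineage when that score reaches \code{min_ibs},
#' otherwise left \code{UNASSIGNED} (divergent, unsampled ancestry).
#' Windows where the query's missing fraction exceeds \code{max_missing}
#' are \code{TOO_MISSING}.  The query should be screened for near-zero
#' heterozygosity first (see \code{\link{heterozygosity}}).
#'
#' @param gm a \code{\link{geno_matrix}}
#' @param query query sample id
#' @param lineages data.frame (sample, lineage) as returned by
#'   \code{\link{cluster_lineages}}
#' @param windows a \code{window_set}
#' @param min_ibs minimum IBS for a putative match
#' @param max_missing maximum query missing fraction per window
#' @return data.frame painting: query, chrom, start, end, lineage, ibs,
#'   n_sites, status (ASSIGNED / UNASSIGNED / TOO_MISSING), tied
#' @export
paint_ibs <- function(gm, query, lineages, windows, min_ibs = 0.98,
                      max_missing = 0.2) {
  if (nrow(lineages) == 0) stop("empty lineage table")
  lin_ids <- sort(unique(lineages$lineage))
  qrow <- match(query, gm$samples)
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    idx <- window_sites(windows, i)
    if (length(idx) == 0)
      return(data.frame(lineage = "TOO_MISSING", ibs = NA_real_,
                        n_sites = 0L, status = "TOO_MISSING", tied = FALSE))
    qmiss <- mean(is.na(gm$dosage[qrow, idx]))
    if (qmiss > max_missing)
      return(data.frame(lineage = "TOO_MISSING", ibs = NA_real_,
                        n_sites = length(idx), status = "TOO_MISSING",
                        tied = FALSE))
    scores <- vapply(lin_ids, function(l) {
      mem <- lineages$sample[lineages$lineage == l]
      if (!length(mem)) return(NA_real_)
      max(vapply(mem, function(m) {
        v <- ibs(gm, query, m, idx)
        if (is.na(v$ibs)) -Inf else v$ibs
      }, 0))
    }, 0)
    if (all(is.na(scores) | scores == -Inf))
      return(data.frame(lineage = "UNASSIGNED", ibs = NA_real_,
                        n_sites = length(idx), status = "UNASSIGNED",
                        tied = FALSE))
    best <- max(scores, na.rm = TRUE)
    hits <- lin_ids[which(!is.na(scores) & scores == best)]
    if (best >= min_ibs)
      data.frame(lineage = hits[1], ibs = best, n_sites = length(idx),
                 status = "ASSIGNED", tied = length(hits) > 1)
    else
      data.frame(lineage = "UNASSIGNED", ibs = best, n_sites = length(idx),
                 status = "UNASSIGNED", tied = FALSE)
  })
  cbind(query = query, windows[, c("chrom", "start", "end")],
        do.call(rbind, rows))
}

#' Summarize lineage and category contributions of a painting
#'
#' @param painting output of \code{\link{paint_ibs}}
#' @param categories optional named character vector mapping lineage id to
#'   category (e.g. starter / non-starter / mixed)
#' @return list: \code{lineage_proportions}, \code{category_proportions}
#'   (each over assigned windows, summing to 1), \code{n_distinct_lineages},
#'   \code{n_assigned}, \code{n_windows}
#' @export
contribution_summary <- function(painting, categories = NULL) {
  assigned <- painting$status == "ASSIGNED"
  n_assigned <- sum(assigned)
  if (n_assigned == 0) {
    return(list(lineage_proportions = NULL, category_proportions = NULL,
                n_distinct_lineages = 0L, n_assigned = 0L,
                n_windows = nrow(painting)))
  }
  tab <- table(painting$lineage[assigned])
  lp <- as.numeric(tab) / n_assigned
  names(lp) <- names(tab)
  cp <- NULL
  if (!is.null(categories)) {
    cat_of <- categories[names(lp)]
    cat_of[is.na(cat_of)] <- "unknown"
    cp <- tapply(lp, cat_of, sum)
  }
  list(lineage_proportions = lp, category_proportions = cp,
       n_distinct_lineages = length(tab), n_assigned = n_assigned,
       n_windows = nrow(painting))
}
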