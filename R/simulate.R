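# Synthetic-data generators with truth tables.  These emulate the
# statistical structure the analyses assume: a drift-structured reference
# panel of near-clonal lineages, mosaic recombinant query genomes with
# optional introgressed windows from a divergent unsampled donor, local
# window trees under congruent vs introgressed topologies, and Normal
# read-depth profiles.  All generators are deterministic given their seed.

#' Panel model specification
#'
#' @param n_clades number of clades
#' @param F_drift per-clade Balding-Nichols drift parameter in (0, 1)
#'   (recycled across clades)
#' @param lineages_per_clade,members_per_lineage panel shape
#' @param clone_mutation_rate per-site probability that a lineage member
#'   differs from its founder
#' @param n_sites number of biallelic sites
#' @param contigs named contig lengths (sites are spread proportionally)
#' @return a list of class \code{panel_model}
#' @export
panel_model <- function(n_clades = 3, F_drift = 0.2, lineages_per_clade = 3,
                        members_per_lineage = 3, clone_mutation_rate = 0.001,
                        n_sites = 5000,
                        contigs = c(chrI = 250000, chrII = 250000)) {
  stopifnot(n_clades >= 1, all(F_drift > 0), all(F_drift < 1),
            lineages_per_clade >= 1, members_per_lineage >= 1,
            clone_mutation_rate >= 0, n_sites >= 1)
  structure(list(n_clades = n_clades,
                 F_drift = rep(F_drift, length.out = n_clades),
                 lineages_per_clade = lineages_per_clade,
                 members_per_lineage = members_per_lineage,
                 clone_mutation_rate = clone_mutation_rate,
                 n_sites = n_sites, contigs = contigs),
            class = "panel_model")
}

# sorted site table spread across contigs proportionally to length
.sim_sites <- function(contigs, n_sites) {
  n_per <- round(n_sites * contigs / sum(contigs))
  n_per[length(n_per)] <- n_sites - sum(n_per[-length(n_per)])
  do.call(rbind, lapply(seq_along(contigs), function(i) {
    pos <- sort(sample.int(contigs[[i]], n_per[[i]])) - 1L
    data.frame(chrom = names(contigs)[i], pos = pos,
               ref = "A", alt = "T", site_dp = NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate a drift-structured reference panel
#'
#' Ancestral allele frequencies are Uniform(0.05, 0.95); each clade's
#' frequencies are Balding-Nichols draws
#' \eqn{Beta(p (1-F)/F, (1-p)(1-F)/F)}.  Lineage founders are homozygous
#' diploids (one haplotype drawn from the clade frequencies and doubled,
#' matching the near-homozygous genomes the painting analysis assumes);
#' members are founder clones with \code{clone_mutation_rate} per-site
#' homozygous flips.
#'
#' @param model a \code{\link{panel_model}}
#' @param seed RNG seed
#' @return list: \code{gm} (a \code{\link{geno_matrix}}), \code{truth}
#'   (sample, clade, lineage), \code{founder_haps} (lineage x site 0/1
#'   matrix), \code{clade_freqs}, \code{sites}
#' @export
simulate_panel <- function(model, seed) {
  stopifnot(inherits(model, "panel_model"))
  set.seed(seed)
  sites <- .sim_sites(model$contigs, model$n_sites)
  S <- nrow(sites)
  p_anc <- stats::runif(S, 0.05, 0.95)
  clade_freqs <- vapply(seq_len(model$n_clades), function(c) {
    f <- model$F_drift[c]
    stats::rbeta(S, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }, numeric(S))
  n_lin <- model$n_clades * model$lineages_per_clade
  founder_haps <- matrix(0L, n_lin, S)
  truth <- NULL
  dosage <- NULL
  samples <- character(0)
  li <- 0
  for (cl in seq_len(model$n_clades)) {
    for (ln in seq_len(model$lineages_per_clade)) {
      li <- li + 1
      hap <- stats::rbinom(S, 1, clade_freqs[, cl])
      founder_haps[li, ] <- hap
      lin_id <- sprintf("C%d_L%d", cl, ln)
      for (mb in seq_len(model$members_per_lineage)) {
        g <- 2L * hap
        if (model$clone_mutation_rate > 0) {
          flip <- stats::runif(S) < model$clone_mutation_rate
          g[flip] <- 2L - g[flip]
        }
        sid <- sprintf("%s_M%d", lin_id, mb)
        samples <- c(samples, sid)
        dosage <- rbind(dosage, g)
        truth <- rbind(truth, data.frame(sample = sid,
                                         clade = sprintf("C%d", cl),
                                         lineage = lin_id,
                                         stringsAsFactors = FALSE))
      }
    }
  }
  rownames(founder_haps) <- unique(truth$lineage)
  gm <- geno_matrix(dosage, sites, samples, model$contigs,
                    gq = matrix(99L, nrow(dosage), ncol(dosage)),
                    dp = matrix(30L, nrow(dosage), ncol(dosage)))
  list(gm = gm, truth = truth, founder_haps = founder_haps,
       clade_freqs = clade_freqs, sites = sites)
}

#' Mosaic specification
#'
#' @param n_isolates number of mosaic query isolates
#' @param switch_prob per-window probability that the donor lineage changes
#' @param donor_weights optional per-lineage sampling weights
#' @param introgression_fraction fraction of windows overwritten with
#'   genotypes from a divergent unsampled donor (0 for none)
#' @param introgression_block_len length of each introgressed block, in
#'   windows
#' @param donor_F drift parameter of the divergent donor population
#' @param heterozygosity per-site probability of injecting a heterozygous
#'   genotype on top of the mosaic (0 keeps isolates fully homozygous)
#' @return a list of class \code{mosaic_spec}
#' @export
mosaic_spec <- function(n_isolates = 5, switch_prob = 0.3,
                        donor_weights = NULL, introgression_fraction = 0,
                        introgression_block_len = 3, donor_F = 0.8,
                        heterozygosity = 0) {
  stopifnot(n_isolates >= 1, switch_prob >= 0, switch_prob <= 1,
            introgression_fraction >= 0, introgression_fraction <= 1,
            introgression_block_len >= 1,
            heterozygosity >= 0, heterozygosity <= 1)
  structure(as.list(environment()), class = "mosaic_spec")
}

#' Simulate mosaic recombinant genomes from panel lineage haplotypes
#'
#' Each isolate's donor lineage follows a Markov chain over windows
#' (switching with \code{switch_prob}); window genotypes copy the donor
#' founder haplotype (homozygous).  When introgression is requested,
#' blocks of consecutive windows are overwritten with haplotypes from a
#' divergent donor population simulated at drift \code{donor_F}, and those
#' windows are flagged in the truth table.
#'
#' @param panel output of \code{\link{simulate_panel}}
#' @param spec a \code{\link{mosaic_spec}}
#' @param windows a \code{window_set} built over the panel's contigs/sites
#' @param seed RNG seed
#' @return list: \code{gm} (panel + mosaics), \code{truth} (isolate,
#'   window, donor_lineage, introgressed), \code{mosaic_samples}
#' @export
simulate_mosaic <- function(panel, spec, windows, seed) {
  stopifnot(inherits(spec, "mosaic_spec"))
  set.seed(seed)
  lin_ids <- rownames(panel$founder_haps)
  if (length(lin_ids) < 2) stop("need at least 2 panel lineages")
  S <- ncol(panel$founder_haps)
  W <- nrow(windows)
  # divergent unsampled donor haplotype (fresh drift from the ancestral
  # frequencies at high F: far from every panel lineage)
  p_anc <- stats::runif(S, 0.05, 0.95)
  f <- spec$donor_F
  donor_freq <- stats::rbeta(S, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  donor_hap <- stats::rbinom(S, 1, donor_freq)
  n_intro_windows <- round(spec$introgression_fraction * W)
  dosage <- NULL; samples <- character(0); truth <- NULL
  for (i in seq_len(spec$n_isolates)) {
    sid <- sprintf("MOS%02d", i)
    donors <- character(W)
    donors[1] <- sample(lin_ids, 1, prob = spec$donor_weights)
    for (w in seq_len(W)[-1]) {
      donors[w] <- if (stats::runif(1) < spec$switch_prob)
        sample(lin_ids, 1, prob = spec$donor_weights) else donors[w - 1]
    }
    intro <- rep(FALSE, W)
    if (n_intro_windows > 0) {
      n_blocks <- max(1, round(n_intro_windows / spec$introgression_block_len))
      starts <- sample(seq_len(max(1, W - spec$introgression_block_len + 1)),
                       n_blocks)
      for (s in starts)
        intro[s:min(W, s + spec$introgression_block_len - 1)] <- TRUE
    }
    g <- integer(S)
    for (w in seq_len(W)) {
      idx <- window_sites(windows, w)
      if (!length(idx)) next
      hap <- if (intro[w]) donor_hap[idx]
             else panel$founder_haps[donors[w], idx]
      g[idx] <- 2L * hap
    }
    if (spec$heterozygosity > 0) {
      het <- stats::runif(S) < spec$heterozygosity
      g[het] <- 1L
    }
    samples <- c(samples, sid)
    dosage <- rbind(dosage, g)
    truth <- rbind(truth, data.frame(isolate = sid, window = seq_len(W),
                                     chrom = windows$chrom,
                                     start = windows$start,
                                     end = windows$end,
                                     donor_lineage = ifelse(intro, "DIVERGENT",
                                                            donors),
                                     introgressed = intro,
                                     stringsAsFactors = FALSE))
  }
  gm <- geno_matrix(rbind(panel$gm$dosage, dosage), panel$gm$sites,
                    c(panel$gm$samples, samples), panel$gm$contigs,
                    gq = matrix(99L, nrow(panel$gm$dosage) + length(samples),
                                S),
                    dp = matrix(30L, nrow(panel$gm$dosage) + length(samples),
                                S))
  list(gm = gm, truth = truth, mosaic_samples = samples)
}

# ---- local trees -----------------------------------------------------------

.tip_clade <- function(tips) {
  if (length(tips) == 1) tips else paste0("(", paste(tips, collapse = ","), ")")
}

#' Simulate local window trees under congruent or introgressed topologies
#'
#' Null (congruent) windows place every test haplotype inside the
#' WRP clade, sister to MO: \code{(out,(src,(mo,(wrp,test))))}.
#' Introgressed windows move the listed carrier haplotypes into the source
#' clade.  With probability \code{noise} a tree is scrambled (a source and
#' a WRP leaf exchanged around the test haplotype) so neither monophyly
#' condition holds, yielding UNRESOLVED calls.  Branch lengths are
#' \code{1 + Exp(1)} noise; topology is what matters downstream.
#'
#' @param windows data.frame of windows (chrom, start, end)
#' @param introgressed logical per window
#' @param test_haps tip labels of the test haplotypes (all carriers in
#'   introgressed windows)
#' @param source,mo,wrp,outgroup tip-label sets for the fixed populations
#' @param noise per-tree probability of an unresolvable scramble
#' @param seed RNG seed
#' @return list: \code{trees} (list of \code{ape::phylo}), \code{truth}
#'   (window, introgressed, scrambled)
#' @export
simulate_local_trees <- function(windows, introgressed, test_haps,
                                 source = c("SRC1", "SRC2"),
                                 mo = c("MO1", "MO2"),
                                 wrp = c("WRP1", "WRP2"),
                                 outgroup = c("OUT1", "OUT2"),
                                 noise = 0, seed = 1) {
  stopifnot(nrow(windows) == length(introgressed))
  set.seed(seed)
  scrambled <- stats::runif(nrow(windows)) < noise
  trees <- lapply(seq_len(nrow(windows)), function(i) {
    if (scrambled[i]) {
      # neither test+source nor test+mo+wrp monophyletic for any test hap
      nwk <- sprintf("(%s,((%s,%s),(%s,%s)));",
                     .tip_clade(outgroup), .tip_clade(test_haps), mo[1],
                     source[1],
                     .tip_clade(c(tail(mo, -1), wrp, tail(source, -1))))
    } else if (introgressed[i]) {
      nwk <- sprintf("(%s,((%s,%s),(%s,%s)));",
                     .tip_clade(outgroup),
                     .tip_clade(source), .tip_clade(test_haps),
                     .tip_clade(mo), .tip_clade(wrp))
    } else {
      nwk <- sprintf("(%s,(%s,(%s,%s)));",
                     .tip_clade(outgroup), .tip_clade(source),
                     .tip_clade(mo), .tip_clade(c(wrp, test_haps)))
    }
    tr <- ape::read.tree(text = nwk)
    tr$edge.length <- 1 + stats::rexp(nrow(tr$edge))
    tr
  })
  list(trees = trees,
       truth = data.frame(window = seq_len(nrow(windows)),
                          introgressed = introgressed,
                          scrambled = scrambled))
}

# ---- sequence fixtures for the k-mer classifier ----------------------------

#' Simulate toy species references and reads
#'
#' Random genomes per species (independent sequences are effectively
#' unrelated, so most k-mers are species-unique) and error-free reads drawn
#' from one or more of them in given proportions.
#'
#' @param species character vector of species labels
#' @param genome_len genome length per species (bp)
#' @param read_len,coverage read layout for \code{\link{sim_reads}}
#' @param seed RNG seed
#' @return list: \code{genomes} (named character), \code{species}
#' @export
sim_species_genomes <- function(species, genome_len = 4000, seed = 1) {
  set.seed(seed)
  genomes <- vapply(species, function(s)
    paste(sample(c("A", "C", "G", "T"), genome_len, replace = TRUE),
          collapse = ""), "")
  list(genomes = genomes, species = species)
}

#' Draw error-free reads from a genome mixture
#'
#' @param genomes named character vector of genome sequences
#' @param proportions named mixture weights (summing to 1)
#' @param n_reads total reads
#' @param read_len read length
#' @param seed RNG seed
#' @return character vector of read sequences (random strand)
#' @export
sim_reads <- function(genomes, proportions, n_reads = 2000, read_len = 100,
                      seed = 1) {
  set.seed(seed)
  src <- sample(names(proportions), n_reads, replace = TRUE,
                prob = proportions)
  vapply(src, function(s) {
    g <- genomes[[s]]
    start <- sample.int(nchar(g) - read_len + 1, 1)
    r <- substr(g, start, start + read_len - 1)
    if (stats::runif(1) < 0.5)
      r <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(r)))
    r
  }, "", USE.NAMES = FALSE)
}

# ---- fixture emission ------------------------------------------------------

#' Write a full synthetic fixture set to disk
#'
#' Emits plain-text inputs that parse back through the package readers:
#' VCF (panel + mosaics), BED repeat mask, newick trees plus a window index
#' TSV, toy FASTA references and FASTQ reads, a per-site depth TSV and the
#' truth tables.  Deterministic given the generator seeds.
#'
#' @param outdir output directory (created if absent)
#' @param panel,mosaic,trees outputs of the corresponding simulators
#' @param mask optional \code{repeat_mask}
#' @param depth optional \code{\link{depth_profile}}
#' @param genomes optional named genome sequences (FASTA per species)
#' @param reads optional character vector of read sequences (FASTQ)
#' @return invisibly, the named list of written paths
#' @export
emit_fixtures <- function(outdir, panel = NULL, mosaic = NULL, trees = NULL,
                          mask = NULL, depth = NULL, genomes = NULL,
                          reads = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  gm <- if (!is.null(mosaic)) mosaic$gm else if (!is.null(panel)) panel$gm
  if (!is.null(gm)) {
    paths$vcf <- file.path(outdir, "genotypes.vcf")
    write_genotypes_vcf(gm, paths$vcf)
  }
  if (!is.null(panel)) {
    paths$panel_truth <- file.path(outdir, "panel_truth.tsv")
    utils::write.table(panel$truth, paths$panel_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(mosaic)) {
    paths$mosaic_truth <- file.path(outdir, "mosaic_truth.tsv")
    utils::write.table(mosaic$truth, paths$mosaic_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(mask)) {
    paths$mask <- file.path(outdir, "repeats.bed")
    bed <- do.call(rbind, lapply(names(mask), function(ctg)
      data.frame(chrom = ctg, start = mask[[ctg]][, "start"],
                 end = mask[[ctg]][, "end"])))
    utils::write.table(bed, paths$mask, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(trees)) {
    tdir <- file.path(outdir, "trees")
    dir.create(tdir, showWarnings = FALSE)
    idx <- data.frame(window = seq_along(trees$trees),
                      path = file.path("trees",
                                       sprintf("window_%04d.nwk",
                                               seq_along(trees$trees))))
    for (i in seq_along(trees$trees))
      ape::write.tree(trees$trees[[i]], file.path(outdir, idx$path[i]))
    paths$tree_index <- file.path(outdir, "tree_index.tsv")
    utils::write.table(idx, paths$tree_index, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths$tree_truth <- file.path(outdir, "tree_truth.tsv")
    utils::write.table(trees$truth, paths$tree_truth, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(depth)) {
    paths$depth <- file.path(outdir, "depth.tsv")
    dd <- do.call(rbind, lapply(names(depth$depths), function(ctg)
      data.frame(chrom = ctg, pos = depth$positions[[ctg]],
                 depth = depth$depths[[ctg]])))
    utils::write.table(dd, paths$depth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(genomes)) {
    paths$fasta <- vapply(names(genomes), function(s) {
      f <- file.path(outdir, paste0(s, ".fasta"))
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(stats::setNames(genomes[[s]], s)), f)
      f
    }, "")
  }
  if (!is.null(reads)) {
    paths$fastq <- file.path(outdir, "reads.fastq")
    rs <- Biostrings::DNAStringSet(reads)
    names(rs) <- sprintf("read_%05d", seq_along(reads))
    Biostrings::writeXStringSet(rs, paths$fastq, format = "fastq")
  }
  invisible(paths)
}

#' Read window trees back from an emitted index
#' @param outdir fixture directory containing \code{tree_index.tsv}
#' @return list of \code{ape::phylo}
#' @export
read_tree_index <- function(outdir) {
  idx <- utils::read.table(file.path(outdir, "tree_index.tsv"), header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  lapply(idx$path, function(p) ape::read.tree(file.path(outdir, p)))
}
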