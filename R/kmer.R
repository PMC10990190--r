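# Exact canonical k-mer species classification against per-species unique
# marker databases (sensu stricto Saccharomyces).

# Canonical k-mers of a character vector of sequences: lexicographic
# minimum of each k-mer and its reverse complement (A < C < G < T);
# windows containing non-ACGT characters are dropped.
.canonical_kmers <- function(seqs, k) {
  seqs <- toupper(as.character(seqs))
  kmers <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    starts <- seq_len(L - k + 1)
    substring(s, starts, starts + k - 1)
  }), use.names = FALSE)
  if (!length(kmers)) return(character(0))
  kmers <- kmers[grepl("^[ACGT]+$", kmers)]
  if (!length(kmers)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  ifelse(kmers <= rc, kmers, rc)
}

#' Build per-species unique canonical k-mer databases
#'
#' Extracts canonical k-mers from each species' reference FASTA and removes
#' any k-mer present in more than one species, leaving pairwise-disjoint
#' unique marker sets.
#'
#' @param references named character vector: species label to FASTA path
#' @param k k-mer length (odd recommended so no k-mer is its own reverse
#'   complement)
#' @return a \code{kmer_db}: list(k, species, unique_sets)
#' @export
build_db <- function(references, k = 31) {
  stopifnot(length(references) >= 1, !is.null(names(references)))
  per_species <- lapply(references, function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (any(Biostrings::width(seqs) < k))
      warning("sequence(s) shorter than k in ", path, " contribute nothing")
    unique(.canonical_kmers(seqs, k))
  })
  all_km <- unlist(per_species, use.names = FALSE)
  shared <- unique(all_km[duplicated(all_km)])
  unique_sets <- lapply(per_species, function(s) setdiff(s, shared))
  structure(list(k = k, species = names(references),
                 unique_sets = unique_sets), class = "kmer_db")
}

#' Profile a read set as a canonical k-mer count table
#'
#' Counts canonical k-mers across FASTQ read files and retains those seen
#' at least \code{min_count} times (the "more than 4 observations" rule
#' with the default of 5).
#'
#' @param fastq_paths one or more FASTQ paths (optionally gzipped)
#' @param k k-mer length
#' @param min_count minimum observation count to retain (inclusive)
#' @return named integer vector of retained canonical k-mer counts
#' @export
profile_sample <- function(fastq_paths, k = 31, min_count = 5) {
  reads <- do.call(c, lapply(fastq_paths, function(p)
    Biostrings::readDNAStringSet(p, format = "fastq")))
  if (!length(reads)) {
    warning("no reads in input")
    return(stats::setNames(integer(0), character(0)))
  }
  km <- .canonical_kmers(as.character(reads), k)
  tab <- table(km)
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  counts[counts >= min_count]
}

#' Classify a k-mer profile against the species databases
#'
#' Matches the profile's canonical k-mers against each species' unique
#' marker set.  Proportions are over distinct matched k-mers by default;
#' \code{weighted = TRUE} weights by observation counts instead.
#'
#' @param profile output of \code{\link{profile_sample}}
#' @param db a \code{kmer_db} from \code{\link{build_db}} (same k)
#' @param weighted weight matches by k-mer counts rather than distinct
#'   k-mers
#' @return list: sample-level \code{total_matched}, \code{total_kmers},
#'   \code{matched_counts}, \code{proportions} (per species, over matched
#'   k-mers), \code{classified} (FALSE when nothing matched)
#' @export
classify <- function(profile, db, weighted = FALSE) {
  stopifnot(inherits(db, "kmer_db"))
  kms <- names(profile)
  matched <- vapply(db$unique_sets, function(s) {
    hit <- kms %in% s
    if (weighted) sum(profile[hit]) else sum(hit)
  }, 0)
  total <- sum(matched)
  props <- if (total > 0) matched / total else rep(NA_real_, length(matched))
  names(props) <- db$species
  list(total_matched = total, total_kmers = length(kms),
       matched_counts = stats::setNames(matched, db$species),
       proportions = props, classified = total > 0)
}
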