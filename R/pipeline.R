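# End-to-end orchestration: a serializable run configuration and a driver
# that chains the modules in analysis order (simulate -> QC -> painting ->
# introgression scan -> aneuploidy -> report).  The numbered scripts under
# analysis/ are thin wrappers over these functions.

#' Default run configuration
#'
#' All thresholds default to the study's stated parameters: GQ <= 20 /
#' DP <= 6 genotype missingness, >80\% site missingness removal, 0.98
#' minimum painting IBS, 25 kb painting windows, rank-biserial 0.5 call
#' threshold, >=3 consecutive fixed windows with 1 trimmed at each end,
#' canonical 31-mers kept above 4 observations.
#'
#' @param ... overrides of the default fields
#' @return a named list of class \code{run_config}
#' @export
run_config <- function(...) {
  cfg <- list(seed = 1,
              gq_min = 20, dp_min = 6, max_missing = 0.8,
              min_mean_dp = 6, min_genotyped_fraction = 0.8,
              het_screen = 0.005,
              window_size = 25000, window_step = 25000,
              min_ibs = 0.98, max_window_missing = 0.2,
              z_cutoff = 3, ibs_cutoff = 0.99, n_perm = 1000,
              effect_threshold = 0.5, min_run = 3, trim = 1,
              kmer_k = 31, kmer_min_count = 5,
              depth_mean = 30, depth_sd = 10,
              outdir = tempfile("feralyeast_run_"))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  .validate_config(cfg)
  structure(cfg, class = c("run_config", "list"))
}

.validate_config <- function(cfg) {
  stopifnot(cfg$min_ibs > 0, cfg$min_ibs <= 1,
            cfg$max_missing >= 0, cfg$max_missing <= 1,
            cfg$window_step <= cfg$window_size,
            cfg$min_run > 2 * cfg$trim,
            cfg$kmer_min_count >= 1, cfg$effect_threshold > 0)
  invisible(cfg)
}

#' Load a run configuration from YAML
#' @param path YAML file of config fields (missing fields take defaults)
#' @return a \code{run_config}
#' @export
load_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' Run the synthetic end-to-end pipeline
#'
#' Simulates a reference panel and mosaic queries, applies genotype QC,
#' collapses the panel into lineages, paints each mosaic, scans simulated
#' local trees for introgression, calls aneuploidies on simulated depth
#' profiles, and writes every table plus a JSON summary under
#' \code{cfg$outdir}.  The config (with the seed) is echoed into the output
#' directory so a run is reproducible from its artifacts alone.
#'
#' @param cfg a \code{\link{run_config}}
#' @return invisibly, a list with the main in-memory results and
#'   \code{paths} of everything written
#' @export
run_pipeline <- function(cfg = run_config()) {
  .validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(cfg), file.path(cfg$outdir, "config.yaml"))
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, 10)

  # --- simulate and QC
  model <- panel_model(n_clades = 2, lineages_per_clade = 3,
                       members_per_lineage = 2, n_sites = 4000,
                       clone_mutation_rate = 1e-3,
                       contigs = c(chrI = 250000, chrII = 250000))
  panel <- simulate_panel(model, seeds[1])
  windows <- build_windows(model$contigs, cfg$window_size, cfg$window_step,
                           sites = panel$gm$sites)
  mosaic <- simulate_mosaic(panel, mosaic_spec(n_isolates = 3,
                                               switch_prob = 0.4),
                            windows, seeds[2])
  fx <- emit_fixtures(cfg$outdir, panel = panel, mosaic = mosaic)
  gm <- load_genotypes(fx$vcf, cfg$gq_min, cfg$dp_min)
  gm <- filter_sites(gm, cfg$max_missing)
  gm <- filter_samples(gm, cfg$min_mean_dp, cfg$min_genotyped_fraction)

  # --- lineages and painting
  panel_ids <- panel$gm$samples
  im <- ibs_matrix(gm, panel_ids)
  lineages <- cluster_lineages(im, cfg$z_cutoff, cfg$ibs_cutoff, cfg$n_perm)
  windows_f <- build_windows(model$contigs, cfg$window_size, cfg$window_step,
                             sites = gm$sites)
  paintings <- do.call(rbind, lapply(mosaic$mosaic_samples, function(q) {
    if (heterozygosity(gm, q) >= cfg$het_screen) return(NULL)
    paint_ibs(gm, q, lineages, windows_f, cfg$min_ibs,
              cfg$max_window_missing)
  }))
  utils::write.table(paintings, file.path(cfg$outdir, "painting.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- introgression scan on simulated local trees
  tw <- data.frame(chrom = "chrI", start = seq(0, 39) * 10000,
                   end = seq(1, 40) * 10000)
  intro_truth <- rep(FALSE, nrow(tw)); intro_truth[10:14] <- TRUE
  lt <- simulate_local_trees(tw, intro_truth,
                             test_haps = c("Q_1", "Q_2"), noise = 0.05,
                             seed = seeds[3])
  scan <- scan_windows(lt$trees, tw, population = c("Q_1", "Q_2"),
                       source = c("SRC1", "SRC2"), mo = c("MO1", "MO2"),
                       wrp = c("WRP1", "WRP2"),
                       outgroup = c("OUT1", "OUT2"))
  blocks <- fixed_blocks(scan$af_track, cfg$min_run, cfg$trim)
  utils::write.table(scan$af_track, file.path(cfg$outdir, "af_track.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(blocks, file.path(cfg$outdir, "admixture_blocks.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)

  # --- aneuploidy on a simulated depth profile
  set.seed(seeds[4])
  prof <- simulate_depth(default_site_counts(4000), cfg$depth_mean,
                         cfg$depth_sd,
                         aneuploidies = data.frame(chrom = "chrVI",
                                                   shift = 0.5))
  calls <- if (coverage_gate(prof)) call_aneuploidies(prof,
                                                      cfg$effect_threshold)
           else NULL
  if (!is.null(calls))
    utils::write.table(calls, file.path(cfg$outdir, "aneuploidy_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  # --- report
  report <- list(
    config = unclass(cfg),
    n_panel = length(panel_ids),
    n_lineages = length(unique(lineages$lineage)),
    n_queries = length(unique(paintings$query)),
    painting_assigned_fraction = mean(paintings$status == "ASSIGNED"),
    admixed_windows = sum(scan$af_track$admixed, na.rm = TRUE),
    fixed_blocks = nrow(blocks),
    aneuploid_chroms = if (is.null(calls)) 0L
                       else sum(calls$direction != "NONE"))
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(gm = gm, lineages = lineages, paintings = paintings,
                 scan = scan, blocks = blocks, calls = calls,
                 report = report, outdir = cfg$outdir))
}
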