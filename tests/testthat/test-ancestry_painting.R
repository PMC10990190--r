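# Lineage clustering recovery, d_a clade assignment, IBS painting accuracy
# and the contribution summary.

test_that("cluster_lineages separates duplicates from distant isolates", {
  m <- diag(1, 3)
  m[1, 2] <- m[2, 1] <- 1          # exact duplicates
  m[1, 3] <- m[3, 1] <- 0.9
  m[2, 3] <- m[3, 2] <- 0.9
  dimnames(m) <- list(c("a", "b", "c"), c("a", "b", "c"))
  set.seed(1)
  lin <- cluster_lineages(m, n_perm = 200)
  expect_equal(lin$lineage[1], lin$lineage[2])
  expect_false(lin$lineage[3] == lin$lineage[1])
})

test_that("uniformly dissimilar panels split into singleton lineages", {
  n <- 6
  m <- matrix(0.90, n, n); diag(m) <- 1
  dimnames(m) <- list(letters[1:n], letters[1:n])
  set.seed(2)
  lin <- cluster_lineages(m, n_perm = 200)
  expect_equal(length(unique(lin$lineage)), n)
})

test_that("three clone groups are recovered exactly, also from genotypes", {
  # constructed matrix: within-group IBS >= 0.995, between <= 0.95
  set.seed(3)
  groups <- rep(1:3, each = 4)
  n <- length(groups)
  m <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    m[i, j] <- if (i == j) 1 else if (groups[i] == groups[j])
      runif(1, 0.995, 0.999) else runif(1, 0.93, 0.95)
  }
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  dimnames(m) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  lin <- cluster_lineages(m, n_perm = 500)
  expect_equal(length(unique(lin$lineage)), 3)
  expect_true(all(tapply(lin$lineage, groups, function(x)
    length(unique(x))) == 1))

  # round trip from a simulated panel: true lineage partition recovered
  model <- panel_model(n_clades = 3, lineages_per_clade = 1,
                       members_per_lineage = 4,
                       clone_mutation_rate = 5e-4, n_sites = 10000)
  panel <- simulate_panel(model, seed = 11)
  im <- ibs_matrix(panel$gm)
  set.seed(4)
  lin2 <- cluster_lineages(im, n_perm = 500)
  cross <- table(lin2$lineage, panel$truth$lineage)
  expect_equal(length(unique(lin2$lineage)), 3)
  expect_true(all(rowSums(cross > 0) == 1))
})

test_that("d_a clade assignment recovers mosaic proportions and ties break
           lexicographically", {
  model <- panel_model(n_clades = 2, F_drift = 0.3, lineages_per_clade = 2,
                       members_per_lineage = 2, clone_mutation_rate = 0,
                       n_sites = 4000,
                       contigs = c(chrI = 250000, chrII = 250000))
  panel <- simulate_panel(model, seed = 21)
  windows <- build_windows(model$contigs, 25000, 25000,
                           sites = panel$gm$sites)
  # mosaic: copy clade A founder for 60% of windows, clade B for 40%
  W <- nrow(windows)
  take_a <- seq_len(W) <= round(0.6 * W)
  g <- integer(model$n_sites)
  for (w in seq_len(W)) {
    idx <- window_sites(windows, w)
    hap <- panel$founder_haps[if (take_a[w]) "C1_L1" else "C2_L1", idx]
    g[idx] <- 2L * hap
  }
  gm <- geno_matrix(rbind(panel$gm$dosage, Q = g), panel$gm$sites,
                    c(panel$gm$samples, "Q"), panel$gm$contigs)
  clades <- split(panel$truth$sample, panel$truth$clade)
  res <- assign_clade_da(gm, "Q", clades, windows)
  expect_equal(unname(res$proportions["C1"]), mean(take_a), tolerance = 0.05)
  expect_equal(unname(res$proportions["C2"]), 1 - mean(take_a),
               tolerance = 0.05)
  expect_equal(sum(res$proportions), 1)
  # member clone of one clade paints fully to it
  res2 <- assign_clade_da(gm, panel$truth$sample[1],
                          lapply(clades, setdiff, panel$truth$sample[1]),
                          windows)
  expect_equal(unname(res2$proportions["C1"]), 1)
  expect_error(assign_clade_da(gm, panel$truth$sample[1], clades, windows),
               "excluded")

  # equidistant clades tie-break to the lexicographically first, flagged
  haps <- rbind(X1 = rep(0L, 40), X2 = rep(0L, 40),
                Q2 = c(rep(1L, 4), rep(0L, 36)))
  gm3 <- gm_from_hap_matrix(haps, contig_len = 50)
  w3 <- build_windows(c(chr1 = 50), 50, 50, sites = gm3$sites)
  res3 <- assign_clade_da(gm3, gm3$samples[3],
                          list(B = gm3$samples[2], A = gm3$samples[1]), w3)
  expect_equal(res3$painting$clade, "A")
  expect_true(res3$painting$tied)
})

test_that("IBS painting assigns true donors and respects cutoffs", {
  model <- panel_model(n_clades = 2, lineages_per_clade = 3,
                       members_per_lineage = 2, clone_mutation_rate = 1e-3,
                       n_sites = 6000,
                       contigs = c(chrI = 300000, chrII = 300000))
  panel <- simulate_panel(model, seed = 31)
  windows <- build_windows(model$contigs, 25000, 25000,
                           sites = panel$gm$sites)
  mosaic <- simulate_mosaic(panel, mosaic_spec(n_isolates = 4,
                                               switch_prob = 0.5),
                            windows, seed = 32)
  gm <- mosaic$gm
  lineages <- panel$truth[, c("sample", "lineage")]
  acc <- vapply(mosaic$mosaic_samples, function(q) {
    pt <- paint_ibs(gm, q, lineages, windows)
    truth <- mosaic$truth[mosaic$truth$isolate == q, ]
    ok <- pt$status == "ASSIGNED"
    mean(pt$lineage[ok] == truth$donor_lineage[ok])
  }, 0)
  expect_true(all(acc >= 0.95))

  # query identical to a panel member: own lineage at IBS 1 everywhere
  q0 <- panel$truth$sample[1]
  pt0 <- paint_ibs(gm, q0, lineages, windows)
  expect_true(all(pt0$status == "ASSIGNED"))
  expect_true(all(pt0$ibs == 1))
  expect_true(all(pt0$lineage == panel$truth$lineage[1]))

  # raising min_ibs never increases assigned windows (monotonicity)
  q <- mosaic$mosaic_samples[1]
  n_assigned <- vapply(c(0.90, 0.95, 0.98, 0.995, 1.0), function(cut)
    sum(paint_ibs(gm, q, lineages, windows, min_ibs = cut)$status ==
          "ASSIGNED"), 0L)
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("windows from a divergent unsampled donor stay unassigned", {
  model <- panel_model(n_clades = 2, lineages_per_clade = 2,
                       members_per_lineage = 2, clone_mutation_rate = 0,
                       n_sites = 6000,
                       contigs = c(chrI = 300000, chrII = 300000))
  panel <- simulate_panel(model, seed = 41)
  windows <- build_windows(model$contigs, 25000, 25000,
                           sites = panel$gm$sites)
  mosaic <- simulate_mosaic(panel,
                            mosaic_spec(n_isolates = 3, switch_prob = 0.3,
                                        introgression_fraction = 0.3,
                                        introgression_block_len = 2),
                            windows, seed = 42)
  for (q in mosaic$mosaic_samples) {
    pt <- paint_ibs(mosaic$gm, q, panel$truth[, c("sample", "lineage")],
                    windows)
    truth <- mosaic$truth[mosaic$truth$isolate == q, ]
    expect_true(all(pt$status[truth$introgressed] == "UNASSIGNED"))
    frac_unassigned <- mean(pt$status == "UNASSIGNED")
    expect_equal(frac_unassigned, mean(truth$introgressed), tolerance = 0.1)
  }
})

test_that("painting flags windows with too-missing queries", {
  model <- panel_model(n_clades = 1, lineages_per_clade = 2,
                       members_per_lineage = 2, n_sites = 2000,
                       contigs = c(chrI = 100000))
  panel <- simulate_panel(model, seed = 51)
  windows <- build_windows(model$contigs, 25000, 25000,
                           sites = panel$gm$sites)
  gm <- panel$gm
  qrow <- 1
  idx1 <- window_sites(windows, 1)
  gm$dosage[qrow, idx1[seq_len(ceiling(0.5 * length(idx1)))]] <- NA
  pt <- paint_ibs(gm, gm$samples[qrow], panel$truth[, c("sample", "lineage")],
                  windows, max_missing = 0.2)
  expect_equal(pt$status[1], "TOO_MISSING")
  expect_true(all(pt$status[-1] == "ASSIGNED"))
})

test_that("contribution summary aggregates lineages and categories", {
  painting <- data.frame(query = "Q", chrom = "c", start = 0, end = 1,
                         lineage = c("L1", "L1", "L2", "UNASSIGNED"),
                         ibs = c(1, 1, 0.99, 0.9), n_sites = 10,
                         status = c("ASSIGNED", "ASSIGNED", "ASSIGNED",
                                    "UNASSIGNED"))
  cs <- contribution_summary(painting,
                             categories = c(L1 = "starter",
                                            L2 = "non-starter"))
  expect_equal(unname(cs$lineage_proportions["L1"]), 2 / 3)
  expect_equal(sum(cs$lineage_proportions), 1)
  expect_equal(unname(cs$category_proportions["starter"]), 2 / 3)
  expect_equal(cs$n_distinct_lineages, 2L)
  none <- contribution_summary(painting[4, ])
  expect_equal(none$n_distinct_lineages, 0L)
})
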