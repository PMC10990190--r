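# Aneuploidy statistics against exhaustive pairwise oracles, calling rules,
# normalization, instability regression and the group comparison.

test_that("rank-biserial and Hodges-Lehmann match exhaustive oracles", {
  set.seed(9)
  for (rep in 1:5) {
    x <- sample(0:80, 200, replace = TRUE)
    y <- sample(0:60, 150, replace = TRUE)
    expect_equal(rank_biserial(x, y), oracle_rank_biserial(x, y),
                 tolerance = 1e-9)
    expect_equal(hl_shift(x, y), oracle_hl(x, y), tolerance = 1e-9)
  }
  # spec-scale instance: 500 x 500 sites
  x <- sample(0:100, 500, replace = TRUE)
  y <- sample(0:100, 500, replace = TRUE)
  expect_equal(hl_shift(x, y), oracle_hl(x, y), tolerance = 1e-9)
  expect_equal(rank_biserial(x, y), oracle_rank_biserial(x, y),
               tolerance = 1e-9)
  # non-integer path
  xr <- rnorm(120); yr <- rnorm(80, 0.3)
  expect_equal(hl_shift(xr, yr), oracle_hl(xr, yr), tolerance = 1e-9)
  # half the sites shifted +30: exact brute-force agreement
  base <- sample(10:50, 200, replace = TRUE)
  shifted <- c(base[1:100] + 30, base[101:200])
  expect_equal(hl_shift(shifted, base), oracle_hl(shifted, base),
               tolerance = 1e-9)
})

test_that("rank-biserial is antisymmetric, bounded, and stable under caps", {
  set.seed(10)
  x <- rnorm(5000, 45, 15); y <- rnorm(5000, 30, 10)
  expect_equal(rank_biserial(x, y), -rank_biserial(y, x))
  expect_lte(abs(rank_biserial(x, y)), 1)
  prof <- simulate_depth(c(a = 20000, b = 20000, c = 20000), 30, 10,
                         aneuploidies = data.frame(chrom = "a", shift = 0.5))
  full <- test_chromosome(prof, "a")
  set.seed(11)
  capped <- test_chromosome(prof, "a", max_sites_per_group = 10000)
  expect_lt(abs(full$rank_biserial - capped$rank_biserial), 0.02)
  expect_lt(abs(full$hl_shift_raw - capped$hl_shift_raw) /
              max(1, abs(full$hl_shift_raw)), 0.005)
})

test_that("test_chromosome handles separation, null and degenerate input", {
  prof <- depth_profile("iso", list(a = rep(45L, 300), b = rep(30L, 500)))
  tt <- test_chromosome(prof, "a")
  expect_equal(tt$rank_biserial, 1)
  expect_equal(tt$hl_shift_raw, 15)
  set.seed(12)
  prof2 <- depth_profile("iso", list(a = rpois(10000, 30),
                                     b = rpois(10000, 30)))
  expect_lt(abs(test_chromosome(prof2, "a")$rank_biserial), 0.05)
  prof3 <- depth_profile("iso", list(a = rep(30L, 50), b = rep(30L, 50)))
  t3 <- test_chromosome(prof3, "a")
  expect_true(t3$degenerate)
  expect_equal(t3$rank_biserial, 0)
  expect_error(test_chromosome(depth_profile("iso", list(a = 1:5)), "a"),
               "2 chromosomes")
})

test_that("coverage gate is inclusive at the threshold", {
  expect_false(coverage_gate(depth_profile("i", list(a = rep(19L, 10),
                                                     b = rep(20L, 10)))))
  expect_true(coverage_gate(depth_profile("i", list(a = rep(20L, 10),
                                                    b = rep(20L, 10)))))
})

test_that("aneuploidy calls find gains and losses with normalized shifts", {
  set.seed(13)
  sc <- default_site_counts(6000)
  prof <- simulate_depth(sc, 30, 10,
                         aneuploidies = data.frame(
                           chrom = c("chrVI", "chrII"),
                           shift = c(0.5, -0.5)))
  calls <- call_aneuploidies(prof)
  expect_equal(calls$direction[calls$chrom == "chrVI"], "GAIN")
  expect_equal(calls$direction[calls$chrom == "chrII"], "LOSS")
  expect_true(all(calls$direction[!calls$chrom %in% c("chrVI", "chrII")] ==
                    "NONE"))
  expect_equal(calls$hl_shift_norm[calls$chrom == "chrVI"], 0.5,
               tolerance = 0.1)
  expect_equal(calls$hl_shift_norm[calls$chrom == "chrII"], -0.5,
               tolerance = 0.1)
  expect_false(attr(calls, "norm_fallback"))
  # all-zero chromosome vs strictly positive background: separation to -1
  prof0 <- simulate_depth(c(a = 500, b = 500, c = 500), 30, 5,
                          aneuploidies = data.frame(chrom = "a", shift = -1))
  c0 <- call_aneuploidies(prof0)
  expect_equal(c0$rank_biserial[c0$chrom == "a"], -1)
  expect_equal(c0$direction[c0$chrom == "a"], "LOSS")
})

test_that("instability records exclude single-polysome isolates and the
           regression recovers a simulated slope", {
  set.seed(14)
  # synthetic records: shift = 0.9 * background + noise
  n <- 200
  bg <- runif(n, 0.5, 3)
  rec <- data.frame(isolate = sprintf("i%03d", seq_len(n)),
                    chrom = sample(c("c1", "c2", "c3"), n, TRUE),
                    shift = 0.9 * bg + rnorm(n, 0, 0.2),
                    mean_background_shift = bg,
                    group = "feral")
  fit <- instability_regression(rec)
  pooled <- fit[fit$stratum == "pooled", ]
  expect_equal(pooled$slope, 0.9, tolerance = 0.1)
  expect_gt(pooled$r_squared, 0.5)
  # exact line
  rec2 <- data.frame(isolate = sprintf("i%d", 1:10), chrom = "c1",
                     shift = 2 * (1:10), mean_background_shift = 1:10,
                     group = NA)
  f2 <- suppressWarnings(instability_regression(rec2))
  expect_equal(f2$slope[f2$stratum == "pooled"], 2)
  expect_equal(f2$r_squared[f2$stratum == "pooled"], 1)
  # single-polysome isolates contribute no record
  calls <- data.frame(isolate = c("a", "a", "b"),
                      chrom = c("c1", "c2", "c1"),
                      rank_biserial = c(0.9, 0.8, 0.9),
                      hl_shift_raw = c(15, 16, 15),
                      hl_shift_norm = c(0.5, 0.55, 0.5),
                      p_value = 0, direction = "GAIN")
  rr <- instability_records(calls)
  expect_equal(unique(rr$isolate), "a")
  expect_equal(rr$mean_background_shift, c(0.55, 0.5))
})

test_that("group comparison is one-sided with an exact small-sample path", {
  rec <- function(iso, shift, grp)
    data.frame(isolate = iso, chrom = "c1", shift = shift,
               mean_background_shift = 0, group = grp)
  a <- do.call(rbind, lapply(1:5, function(i) rec(paste0("a", i), 10 + i,
                                                  "admixed")))
  b <- do.call(rbind, lapply(1:5, function(i) rec(paste0("b", i), i,
                                                  "feral")))
  res <- compare_groups(rbind(a, b), "admixed", "feral")
  expect_equal(res$method, "exact")
  expect_lte(res$p_value, 1 / choose(10, 5) + 1e-12)
  res_rev <- compare_groups(rbind(a, b), "feral", "admixed")
  expect_gt(res_rev$p_value, 0.99)
  # identical groups: p near 0.5, permutation-oracle agreement at larger n
  set.seed(15)
  big_a <- do.call(rbind, lapply(1:40, function(i)
    rec(paste0("A", i), rexp(1, 1) + 0.3, "admixed")))
  big_b <- do.call(rbind, lapply(1:60, function(i)
    rec(paste0("B", i), rexp(1, 1), "feral")))
  res_big <- compare_groups(rbind(big_a, big_b), "admixed", "feral")
  expect_equal(res_big$method, "normal approximation")
  av <- tapply(big_a$shift, big_a$isolate, mean)
  bv <- tapply(big_b$shift, big_b$isolate, mean)
  pooled <- c(av, bv)
  stat <- function(ix) mean(rank(pooled)[ix])
  obs <- stat(seq_along(av))
  perm <- replicate(20000, stat(sample(length(pooled), length(av))))
  p_perm <- mean(perm >= obs - 1e-12)
  expect_equal(res_big$p_value, p_perm, tolerance = 0.02)
})

test_that("normalized depth track sits at copy-number gridlines", {
  set.seed(16)
  prof <- simulate_depth(c(chrA = 3000, chrB = 3000, chrC = 1000), 30, 10,
                         aneuploidies = data.frame(chrom = "chrC",
                                                   shift = 0.5))
  calls <- call_aneuploidies(prof)
  trk <- normalized_depth_track(prof, calls, window = 100, step = 50)
  expect_equal(median(trk$norm_depth[trk$chrom == "chrA"]), 1,
               tolerance = 0.05)
  expect_equal(median(trk$norm_depth[trk$chrom == "chrC"]), 1.5,
               tolerance = 0.08)
  # segmental 3N over 40% of one chromosome: bimodal track
  prof2 <- simulate_depth(c(chrA = 4000, chrB = 4000), 30, 10,
                          segmental = data.frame(chrom = "chrA",
                                                 fraction = 0.4,
                                                 scale = 1.5))
  trk2 <- normalized_depth_track(prof2, NULL, window = 100, step = 100)
  va <- trk2$norm_depth[trk2$chrom == "chrA"]
  # ~40% of windows near the 3N gridline, the rest near 2N
  expect_gt(mean(va > 1.25), 0.3)
  expect_lt(mean(va > 1.25), 0.5)
  expect_gt(mean(va <= 1.25), 0.5)
})
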