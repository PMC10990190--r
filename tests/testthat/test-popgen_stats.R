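# Windowed statistics against exhaustive enumeration oracles, plus the fd
# estimator's clamping, polarization and null behaviour.

test_that("pi matches the exhaustive haplotype-pair oracle", {
  # frozen small case: 4 haplotypes, counts (2,2) at one site of 50
  haps <- rbind(c(1, rep(0, 49)), c(1, rep(0, 49)),
                c(0, rep(0, 49)), c(0, rep(0, 49)))
  gm <- gm_from_haps(list(list(haps[1, ], haps[2, ]),
                          list(haps[3, ], haps[4, ])))
  got <- nucleotide_diversity(gm, gm$samples, seq_len(50), n_accessible = 50)
  expect_equal(got$value, oracle_pi(haps, 50), tolerance = 1e-12)
  expect_equal(got$value, 2 / 150)   # mean pairwise diff 4/6 over 50 sites

  # randomized windows up to 6 haplotypes x 20 sites
  set.seed(42)
  for (rep in 1:20) {
    n_hap <- 2 * sample(1:3, 1) + 2   # 4 or 6 or 8 haplotypes, even
    n_sites <- sample(5:20, 1)
    haps <- matrix(rbinom(n_hap * n_sites, 1, runif(1, 0.2, 0.8)),
                   nrow = n_hap)
    pairs <- lapply(seq(1, n_hap, by = 2), function(i)
      list(haps[i, ], haps[i + 1, ]))
    gm <- gm_from_haps(pairs)
    got <- nucleotide_diversity(gm, gm$samples, seq_len(n_sites),
                                n_accessible = n_sites)
    expect_equal(got$value, oracle_pi(haps, n_sites), tolerance = 1e-12)
  }
})

test_that("dxy matches the between-population enumeration oracle", {
  set.seed(43)
  for (rep in 1:20) {
    n_sites <- sample(5:20, 1)
    ha <- matrix(rbinom(4 * n_sites, 1, 0.5), nrow = 4)
    hb <- matrix(rbinom(6 * n_sites, 1, 0.3), nrow = 6)
    gm <- gm_from_haps(c(lapply(c(1, 3), function(i) list(ha[i, ], ha[i + 1, ])),
                         lapply(c(1, 3, 5), function(i) list(hb[i, ], hb[i + 1, ]))))
    pa <- gm$samples[1:2]; pb <- gm$samples[3:5]
    got <- dxy(gm, pa, pb, seq_len(n_sites), n_accessible = n_sites)
    expect_equal(got$value, oracle_dxy(ha, hb, n_sites), tolerance = 1e-12)
  }
  # fixed differences: two monomorphic pops differing at 2 of 100 sites
  ha <- matrix(0, 2, 100); hb <- matrix(0, 2, 100); hb[, 1:2] <- 1
  gm <- gm_from_hap_matrix(rbind(ha, hb))
  expect_equal(dxy(gm, gm$samples[1:2], gm$samples[3:4], 1:100,
                   n_accessible = 100)$value, 0.02)
})

test_that("d_a subtracts mean within-population diversity (self-comparison closed form)", {
  set.seed(44)
  ha <- matrix(rbinom(4 * 30, 1, 0.5), nrow = 4)
  hb <- matrix(rbinom(4 * 30, 1, 0.4), nrow = 4)
  gm <- gm_from_haps(c(lapply(c(1, 3), function(i) list(ha[i, ], ha[i + 1, ])),
                       lapply(c(1, 3), function(i) list(hb[i, ], hb[i + 1, ]))))
  pa <- gm$samples[1:2]; pb <- gm$samples[3:4]
  da <- nei_da(gm, pa, pb, 1:30, n_accessible = 30)$value
  oracle <- oracle_dxy(ha, hb, 30) - (oracle_pi(ha, 30) + oracle_pi(hb, 30)) / 2
  expect_equal(da, oracle, tolerance = 1e-12)
  # self-comparison: d_XY carries no finite-sample correction while pi
  # does, so d_a(A, A) = -pi_A / n_hap rather than exactly 0
  pi_a <- nucleotide_diversity(gm, pa, 1:30, n_accessible = 30)$value
  expect_equal(nei_da(gm, pa, pa, 1:30, n_accessible = 30)$value,
               -pi_a / 4, tolerance = 1e-12)
  # fixed-different monomorphic pops: d_a = d_XY
  h1 <- matrix(0, 2, 100); h2 <- matrix(0, 2, 100); h2[, 1:2] <- 1
  gm2 <- gm_from_hap_matrix(rbind(h1, h2))
  expect_equal(nei_da(gm2, gm2$samples[1:2], gm2$samples[3:4], 1:100,
                      n_accessible = 100)$value, 0.02)
})

test_that("IBS is the dosage-scale allele-sharing mean and is symmetric", {
  dosage <- rbind(A = c(0L, 1L, 2L, 0L, NA),
                  B = c(0L, 2L, 0L, 1L, 2L))
  gm <- geno_matrix(dosage,
                    data.frame(chrom = "c", pos = 0:4, ref = "A", alt = "T",
                               site_dp = NA_integer_),
                    c("A", "B"), c(c = 10))
  got <- ibs(gm, "A", "B", 1:5)
  expect_equal(got$ibs, mean(c(1, 0.5, 0, 0.5)))
  expect_equal(got$missing_fraction, 0.2)
  expect_equal(ibs(gm, "B", "A", 1:5)$ibs, got$ibs)
  expect_equal(ibs(gm, "A", "A", 1:4)$ibs, 1)
  # single site 0/0 vs 0/1
  expect_equal(ibs(gm, "A", "B", 4)$ibs, 0.5)
})

test_that("coancestry is 1 on self, ~0 on panel draws, high on clones", {
  set.seed(45)
  p <- runif(10000, 0.1, 0.9)
  dosage <- t(vapply(1:12, function(i) rbinom(length(p), 2, p),
                     integer(length(p))))
  gm <- geno_matrix(dosage,
                    data.frame(chrom = "c", pos = seq_along(p) - 1L,
                               ref = "A", alt = "T",
                               site_dp = NA_integer_),
                    sprintf("S%d", 1:12), c(c = length(p) + 1))
  expect_equal(coancestry(gm, "S1", "S1"), 1, tolerance = 1e-9)
  offdiag <- vapply(2:6, function(i) coancestry(gm, "S1", gm$samples[i]), 0)
  expect_true(all(abs(offdiag) < 0.05))
  # clone pair with 1% of sites mutated
  clone <- dosage[1, ]
  flip <- sample(length(p), round(0.01 * length(p)))
  clone[flip] <- 2L - clone[flip]
  gm2 <- geno_matrix(rbind(dosage, clone),
                     gm$sites, c(gm$samples, "S1clone"), gm$contigs)
  expect_gt(coancestry(gm2, "S1", "S1clone"), 0.9)
})

test_that("fd reproduces the hand-enumerated site table and edge identities", {
  # single informative site p1=0, p2=0.5, p3=1, pO=0
  hp1 <- matrix(0, 2, 1)
  hp2 <- rbind(0, 1)
  hp3 <- matrix(1, 2, 1)
  hpo <- matrix(0, 2, 1)
  gm <- gm_from_hap_matrix(rbind(hp1, hp2, hp3, hpo))
  s <- gm$samples
  got <- fd_window(gm, s[1:2], s[3:4], s[5:6], s[7:8], 1)
  expect_equal(got$value, 0.5)
  expect_equal(got$value, oracle_fd(0, 0.5, 1, 0))

  # multi-site random table checked against the enumeration oracle
  set.seed(46)
  for (rep in 1:10) {
    S <- 12
    freqs <- list(p1 = runif(S), p2 = runif(S), p3 = runif(S),
                  po = rbinom(S, 1, 0.2) * 0.0)   # outgroup fixed ancestral
    haps <- function(p) t(vapply(p, function(q) rbinom(4, 1, q), integer(4)))
    hm <- lapply(freqs, haps)
    gm <- gm_from_haps(unlist(lapply(hm, function(h) list(
      list(h[, 1], h[, 2]), list(h[, 3], h[, 4]))), recursive = FALSE))
    s <- gm$samples
    emp <- lapply(hm, function(h) colMeans(t(h)))
    got <- fd_window(gm, s[1:2], s[3:4], s[5:6], s[7:8], seq_len(S))
    expect_equal(got$value,
                 oracle_fd(emp$p1, emp$p2, emp$p3, emp$po),
                 tolerance = 1e-12)
  }
})

test_that("fd is 1 when P2 equals P3 and 0 when P1 equals P2", {
  set.seed(47)
  S <- 40
  shared <- matrix(rbinom(4 * S, 1, 0.5), 4)
  other <- matrix(rbinom(4 * S, 1, 0.5), 4)
  og <- matrix(0, 4, S)
  # P2 == P3 identically
  gm <- gm_from_hap_matrix(rbind(other, shared, shared, og))
  s <- gm$samples
  expect_equal(fd_window(gm, s[1:4], s[5:8], s[9:12], s[13:16],
                         seq_len(S))$value, 1)
  # P1 == P2 identically -> numerator 0 -> clamped 0
  gm2 <- gm_from_hap_matrix(rbind(shared, shared, other, og))
  s2 <- gm2$samples
  expect_equal(fd_window(gm2, s2[1:4], s2[5:8], s2[9:12], s2[13:16],
                         seq_len(S))$value, 0)
  expect_true(is.na(fd_window(gm2, s2[1:4], s2[5:8], s2[9:12], s2[13:16],
                              seq_len(S), clamp = FALSE)$value))
  expect_error(fd_window(gm2, s2[1:4], s2[4:8], s2[9:12], s2[13:16],
                         seq_len(S)), "disjoint")
})

test_that("windowed fd on no-admixture control populations is ~0", {
  # control design mirroring the study: recipient (P2) and its sister (P1)
  # drawn from the same large, nearly undifferentiated pool; candidate
  # donor (P3) and outgroup genuinely diverged; no gene flow anywhere
  set.seed(48)
  n_windows <- 500; sites_per <- 200
  S <- n_windows * sites_per
  p_anc <- runif(S, 0.05, 0.95)
  drift <- function(f, n_dip) {
    p <- rbeta(S, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    t(vapply(seq_len(n_dip), function(i) rbinom(S, 2, p), integer(S)))
  }
  n_dips <- c(120, 120, 30, 20)
  dosage <- do.call(rbind, Map(drift, c(0.002, 0.002, 0.3, 0.4), n_dips))
  gm <- geno_matrix(dosage,
                    data.frame(chrom = "c", pos = seq_len(S) - 1L, ref = "A",
                               alt = "T", site_dp = NA_integer_),
                    sprintf("S%d", seq_len(sum(n_dips))), c(c = S + 1))
  pops <- split(gm$samples, rep(1:4, times = n_dips))
  vals <- vapply(seq_len(n_windows), function(w) {
    idx <- ((w - 1) * sites_per + 1):(w * sites_per)
    v <- fd_window(gm, pops[[1]], pops[[2]], pops[[3]], pops[[4]], idx)$value
    if (is.na(v)) 0 else v
  }, 0)
  expect_lt(abs(mean(vals)), 0.01)
  expect_true(all(vals >= 0 & vals <= 1))
})
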