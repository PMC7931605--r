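# QTL scanning, permutation thresholds, CIM covariates, joint fitting.

test_that("genotype codes map F2 classes to (x, z)", {
  cz <- genotype_codes(c(1L, 2L, 3L, NA))
  expect_equal(cz[, "x"], c(1, 0, -1, NA))
  expect_equal(cz[, "z"], c(0, 1, 0, NA))
})

test_that("bin LOD equals the brute-force regression oracle", {
  set.seed(601)
  n <- 12
  g <- matrix(sample(1:3, 8 * n, replace = TRUE), nrow = 8)
  g[2, 1:2] <- NA  # pairwise-complete handling
  bm <- manual_binmap(g)
  y <- rnorm(n, sd = 2) + 0.8 * genotype_codes(g[5, ])[, "x"]
  sc <- scan_lod(y, bm)
  for (b in 1:8) {
    o <- oracle_bin_lod(y, g[b, ])
    expect_equal(sc$lod[b], o$lod, tolerance = 1e-9)
    expect_equal(sc$a[b], unname(o$a), tolerance = 1e-9)
    expect_equal(sc$d[b], unname(o$d), tolerance = 1e-9)
    expect_equal(sc$n[b], o$n)
  }
  # with a covariate column, against the covariate-aware oracle
  cov <- cbind(cv = rnorm(n))
  sc2 <- scan_lod(y, bm, covariates = cov)
  for (b in 1:8) {
    o <- oracle_bin_lod(y, g[b, ], covariates = cov)
    expect_equal(sc2$lod[b], o$lod, tolerance = 1e-9)
  }
})

test_that("LOD is zero for exact covariate-only fits and affine-invariant", {
  set.seed(602)
  g <- matrix(sample(1:3, 5 * 40, replace = TRUE), nrow = 5)
  bm <- manual_binmap(g)
  # constant phenotype: RSS0 = 0 -> all LOD 0
  expect_true(all(scan_lod(rep(3, 40), bm)$lod == 0))
  # affine transformation leaves LOD unchanged
  y <- rnorm(40) + genotype_codes(g[2, ])[, "x"]
  expect_equal(scan_lod(2 * y + 5, bm)$lod, scan_lod(y, bm)$lod,
               tolerance = 1e-9)
})

test_that("permutation threshold is deterministic, bounded, and refuses tiny runs", {
  set.seed(603)
  truth <- simulate_f2_population(small_config(seed = 604))
  bm <- truth_binmap(truth)
  y <- rnorm(60)
  t1 <- permutation_threshold(y, bm, n_perm = 100, seed = 9)
  t2 <- permutation_threshold(y, bm, n_perm = 100, seed = 9)
  expect_identical(t1$threshold, t2$threshold)
  # alpha -> 0 gives the maximum permuted LOD
  t3 <- permutation_threshold(y, bm, n_perm = 100, alpha = 1e-9, seed = 9)
  expect_equal(t3$threshold, max(t3$max_lods))
  expect_error(permutation_threshold(y, bm, n_perm = 10), "n_perm")
  # threshold stability across seeds (Monte-Carlo error at 1000 perms)
  th <- vapply(1:5, function(s)
    permutation_threshold(y, bm, n_perm = 1000, seed = s)$threshold, 0)
  expect_lt(sd(th), 0.15)
})

test_that("CIM reduces to the simple scan at n_cov = 0 and absorbs background", {
  truth <- simulate_f2_population(
    sim_config(chrom_lengths_bp = rep(20e6, 3), n_markers_per_chrom = 30,
               n_individuals = 150,
               qtls = data.frame(chrom = c("chr1", "chr2"),
                                 pos_bp = c(10e6, 10e6), a = c(1, 1),
                                 d = c(0, 0)),
               noise_sd = sqrt(1.5), seed = 610))
  bm <- truth_binmap(truth)
  y <- truth$phenotypes$value
  sc0 <- scan_cim(y, bm, n_cov = 0L)
  scs <- scan_lod(y, bm)
  expect_equal(sc0$lod, scs$lod)
  expect_length(attr(sc0, "covariate_bins"), 0L)

  # with covariates, the model never fits worse at the background peak;
  # repeat over replicates: CIM >= simple at the chr1 QTL in most
  wins <- 0L
  for (rep in 1:8) {
    tr <- simulate_f2_population(
      sim_config(chrom_lengths_bp = rep(20e6, 3), n_markers_per_chrom = 30,
                 n_individuals = 150,
                 qtls = data.frame(chrom = c("chr1", "chr2"),
                                   pos_bp = c(10e6, 10e6), a = c(1, 1),
                                   d = c(0, 0)),
                 noise_sd = sqrt(1.5), seed = 610 + rep))  # PVE 20% each
    bmr <- truth_binmap(tr)
    yr <- tr$phenotypes$value
    s_simple <- scan_lod(yr, bmr)
    s_cim <- scan_cim(yr, bmr, n_cov = 3L, window_cm = 10)
    q1 <- which(bmr$bins$chrom == "chr1")
    b1 <- q1[which.min(abs(bmr$bins$start_bp[q1] - 10e6))]
    if (s_cim$lod[b1] >= s_simple$lod[b1]) wins <- wins + 1L
  }
  expect_gte(wins, 6L)
})

test_that("covariates inside the exclusion window are dropped for the tested bin", {
  set.seed(611)
  g <- matrix(sample(1:3, 6 * 80, replace = TRUE), nrow = 6)
  bm <- manual_binmap(g)  # bins 1 Mb apart = 3 cM at the default rate
  y <- rnorm(80) + genotype_codes(g[3, ])[, "x"]
  covs <- binqtl:::.bin_codes(bm, 3L)
  excl <- lapply(1:6, function(b) if (b == 3L) 1:2 else integer())
  sc <- scan_lod(y, bm, covariates = covs, exclude_cov = excl)
  # at the covariate's own bin the exclusion makes it the plain single-bin fit
  expect_equal(sc$lod[3L], scan_lod(y, bm)$lod[3L], tolerance = 1e-9)
  # without the exclusion the covariate is collinear with the tested bin
  # and the bin adds nothing: LOD collapses to ~ 0 there
  sc_noex <- scan_lod(y, bm, covariates = covs)
  expect_lt(sc_noex$lod[3L], 1e-9)
})

test_that("declared QTLs are fitted jointly with drop-one PVE and merged intervals", {
  set.seed(620)
  n <- 120
  g <- matrix(sample(1:3, 10 * n, replace = TRUE), nrow = 10)
  bm <- manual_binmap(g)
  # noise-free single QTL: PVE = 100
  y0 <- genotype_codes(g[4, ])[, "x"] - 0.5 * genotype_codes(g[4, ])[, "z"]
  f0 <- fit_qtl(y0, bm, 4L)
  expect_equal(attr(f0, "model_pve"), 100, tolerance = 1e-6)
  expect_equal(f0$a, 1, tolerance = 1e-9)
  expect_equal(f0$d, -0.5, tolerance = 1e-9)

  # two QTLs: effects recovered, support intervals are peak +/- one bin
  y2 <- genotype_codes(g[2, ])[, "x"] + 2 * genotype_codes(g[8, ])[, "x"] +
    rnorm(n, sd = 0.5)
  f2 <- fit_qtl(y2, bm, c(2L, 8L))
  expect_equal(f2$a, c(1, 2), tolerance = 0.2)
  expect_equal(f2$support_start_bp, bm$bins$start_bp[c(1L, 7L)])
  expect_equal(f2$support_end_bp, bm$bins$end_bp[c(3L, 9L)])
  expect_gt(f2$pve[2L], f2$pve[1L])
  expect_error(fit_qtl(y2[1:4], manual_binmap(g[, 1:4]), c(2L, 8L)),
               "degrees of freedom")

  # peak declaration: overlapping support intervals merge, disjoint stay
  scan <- scan_lod(y2, bm)
  scan$lod <- c(0, 5, 4.8, 0, 0, 0, 0, 6, 0, 0)  # bins 2,3 overlap
  pk <- find_qtl_peaks(scan, 3)
  expect_equal(pk, c(2L, 8L))
  scan$lod <- c(0, 5, 0, 0, 4, 0, 0, 6, 0, 0)
  expect_equal(find_qtl_peaks(scan, 3), c(2L, 5L, 8L))
})

test_that("a simulated QTL is detected on the correct chromosome", {
  cfg <- sim_config(chrom_lengths_bp = rep(25e6, 4), n_markers_per_chrom = 40,
                    n_individuals = 200,
                    qtls = data.frame(chrom = "chr3", pos_bp = 12e6,
                                      a = 1, d = 0),
                    noise_sd = sqrt(2), seed = 630)  # PVE = 20%
  truth <- simulate_f2_population(cfg)
  obs <- simulate_observations(truth, seed = 631)
  bm <- build_bins(decode_population(obs), obs$markers)
  y <- truth$phenotypes$value
  sc <- scan_lod(y, bm)
  th <- permutation_threshold(y, bm, n_perm = 200, seed = 632)
  peak <- which.max(sc$lod)
  expect_equal(sc$chrom[peak], "chr3")
  expect_gt(sc$lod[peak], th$threshold)
  f <- fit_qtl(y, bm, find_qtl_peaks(sc, th), sc)
  expect_true(any(f$chrom == "chr3"))
})
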