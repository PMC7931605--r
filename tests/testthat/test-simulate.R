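# F2 simulator: meiosis, distortion, observations, phenotypes.

test_that("crossover counts follow the genetic length (Poisson, no interference)", {
  set.seed(11)
  # zero genetic length: never a crossover
  for (i in 1:20)
    expect_length(simulate_gamete(1e6, 0)$breaks, 0L)

  # 30 Mb at 3 cM/Mb: L = 90 cM, mean 0.9 crossovers per gamete
  n <- 10000
  counts <- vapply(seq_len(n), function(i)
    length(simulate_gamete(30e6, 3)$breaks), 0L)
  se <- sqrt(0.9 / n)
  expect_lt(abs(mean(counts) - 0.9), 3 * se)
  # chi-square GOF of counts against Poisson(0.9), alpha = 0.001
  kmax <- max(counts)
  obs <- tabulate(counts + 1L, nbins = kmax + 1L)
  p <- dpois(0:kmax, 0.9)
  p[kmax + 1L] <- p[kmax + 1L] + ppois(kmax, 0.9, lower.tail = FALSE)
  keep <- p * n >= 5
  chi2 <- sum((obs[keep] - n * p[keep])^2 / (n * p[keep]))
  expect_gt(pchisq(chi2, sum(keep) - 1L, lower.tail = FALSE), 0.001)
})

test_that("gametic distortion converges to the rejection-sampling equilibrium", {
  set.seed(12)
  dl <- data.frame(chrom = "chr1", pos_bp = 5e6, w_A = 1.0, w_B = 0.5,
                   stage = "gametic")
  n <- 10000
  alleles <- vapply(seq_len(n), function(i)
    gamete_origin(simulate_gamete(10e6, 3, dl), 5e6), 0L)
  fB <- mean(alleles == 2L)
  exp_fB <- 0.5 / 1.5  # w_B / (w_A + w_B)
  expect_lt(abs(fB - exp_fB), 3 * sqrt(exp_fB * (1 - exp_fB) / n))
})

test_that("recombination fraction between loci follows Haldane's map function", {
  set.seed(13)
  n <- 10000
  # loci 10 Mb apart at 2 cM/Mb: d = 0.2 Morgans
  rec <- vapply(seq_len(n), function(i) {
    g <- simulate_gamete(30e6, 2)
    gamete_origin(g, 5e6) != gamete_origin(g, 15e6)
  }, TRUE)
  r_exp <- (1 - exp(-2 * 0.2)) / 2
  expect_lt(abs(mean(rec) - r_exp), 3 * sqrt(r_exp * (1 - r_exp) / n))
})

test_that("F2 genotype frequencies are Mendelian without distortion", {
  cfg <- sim_config(chrom_lengths_bp = c(chr1 = 10e6), cm_per_mb = 3,
                    n_markers_per_chrom = 5, n_individuals = 10000,
                    seed = 21)
  truth <- simulate_f2_population(cfg)
  counts <- c(sum(truth$geno == 1L), sum(truth$geno == 2L),
              sum(truth$geno == 3L))
  p <- chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)
})

test_that("gametic selection distorts the locus but not unlinked loci", {
  dl <- data.frame(chrom = "chr1", pos_bp = 5e6, w_A = 1, w_B = 0.5,
                   stage = "gametic")
  cfg <- sim_config(chrom_lengths_bp = c(chr1 = 10e6, chr2 = 10e6),
                    n_markers_per_chrom = 3, n_individuals = 3000,
                    distortion_loci = dl, seed = 22)
  truth <- simulate_f2_population(cfg)
  near <- which(truth$markers$chrom == "chr1")[
    which.min(abs(truth$markers$pos[truth$markers$chrom == "chr1"] - 5e6))]
  fB_sel <- sum(truth$geno[, near] - 1) / (2 * nrow(truth$geno))
  far <- which(truth$markers$chrom == "chr2")[1L]
  fB_far <- sum(truth$geno[, far] - 1) / (2 * nrow(truth$geno))
  expect_lt(abs(fB_sel - 1 / 3), 0.03)
  expect_lt(abs(fB_far - 1 / 2), 0.03)
})

test_that("population structure is valid at n = 1 and reproducible by seed", {
  cfg <- sim_config(chrom_lengths_bp = rep(10e6, 2),
                    n_markers_per_chrom = 10, n_individuals = 1, seed = 30)
  truth <- simulate_f2_population(cfg)
  expect_equal(nrow(truth$geno), 1L)
  expect_true(all(truth$geno %in% 1:3))

  t1 <- simulate_f2_population(small_config(seed = 31))
  t2 <- simulate_f2_population(small_config(seed = 31))
  expect_identical(t1$geno, t2$geno)
  expect_identical(t1$crossovers, t2$crossovers)
  o1 <- simulate_observations(t1, seed = 5)
  o2 <- simulate_observations(t2, seed = 5)
  expect_identical(o1$n_A, o2$n_A)
  expect_identical(o1$n_B, o2$n_B)
})

test_that("observation depths and error structure match the read model", {
  truth <- simulate_f2_population(
    sim_config(chrom_lengths_bp = c(chr1 = 20e6), n_markers_per_chrom = 500,
               n_individuals = 200, seed = 40))
  # lambda = 0: everything missing
  o0 <- simulate_observations(truth, mean_depth = 0, seed = 1)
  expect_true(all(o0$n_A + o0$n_B == 0L))
  # lambda = 7 over 1e5 cells: empirical mean within 3 SE
  o7 <- simulate_observations(truth, mean_depth = 7, seed = 2)
  d <- o7$n_A + o7$n_B
  expect_gte(length(d), 1e5)
  expect_lt(abs(mean(d) - 7), 3 * sqrt(7 / length(d)))
  # heterozygotes emit symmetric reads
  het <- truth$geno == 2L & d >= 1L
  fA <- sum(o7$n_A[het]) / sum(d[het])
  expect_lt(abs(fA - 0.5), 0.01)
  # error rate recovered from homozygotes
  homA <- truth$geno == 1L
  eps_hat <- sum(o7$n_B[homA]) / sum(d[homA])
  expect_lt(abs(eps_hat - 0.01), 0.005)
  # extra dropout raises missingness to (1-p_extra)*P(pois>0) complement
  om <- simulate_observations(truth, mean_depth = 7, missing_extra = 0.2,
                              seed = 3)
  expect_lt(abs(mean(om$n_A + om$n_B == 0) -
                  (0.2 + 0.8 * dpois(0, 7))), 0.01)
})

test_that("phenotypes decompose into QTL effects plus noise", {
  cfg <- sim_config(chrom_lengths_bp = c(chr1 = 10e6),
                    n_markers_per_chrom = 11, n_individuals = 300, seed = 50)
  truth <- simulate_f2_population(cfg)
  q <- data.frame(chrom = "chr1", pos_bp = 5e6, a = 1, d = 0)
  ph <- simulate_phenotypes(truth, q, baseline = 10, noise_sd = 0, seed = 6)
  m <- which.min(abs(truth$markers$pos - 5e6))
  expect_equal(ph$value, 10 + c(1, 0, -1)[truth$geno[, m]])

  # no QTLs: variance is just sigma^2
  ph0 <- simulate_phenotypes(truth, q[0, ], baseline = 0, noise_sd = 2,
                             seed = 7)
  expect_lt(abs(var(ph0$value) - 4), 0.7)

  # PVE recovery: a = 2, sigma^2 = 0.8 * (a^2/2) / 0.2 = 8 gives PVE 20%
  big <- simulate_f2_population(
    sim_config(chrom_lengths_bp = c(chr1 = 10e6), n_markers_per_chrom = 11,
               n_individuals = 10000, seed = 51))
  ph2 <- simulate_phenotypes(big, data.frame(chrom = "chr1", pos_bp = 5e6,
                                             a = 2, d = 0),
                             noise_sd = sqrt(8), seed = 8)
  gv <- attr(ph2, "genetic_values")
  pve <- 100 * var(gv) / var(ph2$value)
  expect_lt(abs(pve - 20), 2)

  expect_error(simulate_phenotypes(truth,
    data.frame(chrom = "chr1", pos_bp = 99e6, a = 1, d = 0)),
    "off the simulated genome")
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(error_rate = 0.5), "error_rate")
  expect_error(sim_config(error_rate = NaN), "error_rate")
  expect_error(sim_config(chrom_lengths_bp = c(1e6, -1)), "positive")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(distortion_loci = data.frame(
    chrom = "chr1", pos_bp = 1e5, w_A = 0, w_B = 1, stage = "gametic")),
    "weights")
  expect_error(sim_config(qtls = data.frame(chrom = "chr99", pos_bp = 1,
                                            a = 1, d = 0)), "chromosome")
  expect_error(simulate_gamete(1e6, Inf), "cm_per_mb")
})
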