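# HMM imputation, crossover calling and bin construction.

test_that("emission probabilities follow the binomial read model", {
  # (5, 0) at eps = 0.01: proportional to (0.99^5, 0.5^5, 0.01^5)
  e <- emission_probs(5L, 0L, 0.01)
  raw <- c(0.99^5, 0.5^5, 0.01^5)
  expect_equal(as.numeric(e), raw / sum(raw), tolerance = 1e-12)
  # no data: uniform
  expect_equal(as.numeric(emission_probs(0L, 0L, 0.01)), rep(1 / 3, 3))
  # balanced reads: AB strictly dominant
  e33 <- emission_probs(3L, 3L, 0.01)
  expect_gt(e33[, "AB"], e33[, "AA"])
  expect_gt(e33[, "AB"], e33[, "BB"])
  # rows normalise
  e2 <- emission_probs(c(2L, 0L, 7L), c(1L, 3L, 0L), 0.05)
  expect_equal(rowSums(e2), rep(1, 3))
  expect_error(emission_probs(1L, 1L, 0.6), "error_rate")
  expect_error(emission_probs(1L, 1L, 0), "error_rate")
})

test_that("transition matrix is the two-gamete Haldane product chain", {
  expect_equal(transition_matrix(0, 3), diag(3),
               ignore_attr = TRUE)
  # choose the gap giving r = 0.1 at rho = 3
  gap <- -log(0.8) / 2 * 1e8 / 3
  tm <- transition_matrix(gap, 3)
  expect_equal(as.numeric(tm[1L, ]), c(0.81, 0.18, 0.01), tolerance = 1e-12)
  expect_equal(tm[2L, 2L], 0.82, tolerance = 1e-12)
  expect_equal(rowSums(tm), c(AA = 1, AB = 1, BB = 1))
  # infinite gap: stationary F2 distribution from every state
  tinf <- transition_matrix(1e12, 3)
  for (i in 1:3)
    expect_equal(as.numeric(tinf[i, ]), c(0.25, 0.5, 0.25),
                 tolerance = 1e-9)
})

test_that("Viterbi decoding equals exhaustive path maximization", {
  set.seed(301)
  params <- hmm_params(error_rate = 0.02, rho = 3)
  for (case in 1:60) {
    T_ <- sample(2:7, 1L)
    pos <- sort(sample.int(5e6, T_))
    d <- rpois(T_, 2)
    nB <- rbinom(T_, d, runif(1L))
    nA <- d - nB
    if (all(d == 0)) nA[1L] <- 1L
    bl <- decode_chromosome(nA, nB, pos, params)
    states <- rep(match(bl$state, c("AA", "AB", "BB")),
                  times = vapply(seq_len(nrow(bl)), function(k)
                    sum(pos >= bl$start_bp[k] & pos <= bl$end_bp[k]), 0L))
    got <- oracle_path_score(states, nA, nB, pos, 0.02, 3)
    best <- oracle_best_path_score(nA, nB, pos, 0.02, 3)
    expect_equal(got, best, tolerance = 1e-9)
  }
})

test_that("decoding collapses runs, absorbs isolated errors, flags missing", {
  params <- hmm_params()
  # ten concordant markers: one AA block, zero crossovers
  pos <- seq(1e6, 10e6, by = 1e6)
  bl <- decode_chromosome(rep(3L, 10), rep(0L, 10), pos, params)
  expect_equal(nrow(bl), 1L)
  expect_equal(bl$state, "AA")
  expect_equal(nrow(call_crossovers(bl)), 0L)

  # single depth-1 discordant marker inside a long AA run is absorbed
  nA <- rep(3L, 11); nB <- rep(0L, 11)
  nA[6L] <- 0L; nB[6L] <- 1L
  bl2 <- decode_chromosome(nA, nB, seq(1e6, 11e6, by = 1e6), params)
  expect_equal(bl2$state, "AA")

  # a real switch produces two blocks and one crossover with the right interval
  nA3 <- c(rep(4L, 4), rep(0L, 4)); nB3 <- c(rep(0L, 4), rep(4L, 4))
  pos3 <- seq(1e6, 8e6, by = 1e6)
  bl3 <- decode_chromosome(nA3, nB3, pos3, params)
  expect_equal(bl3$state, c("AA", "BB"))
  xo <- call_crossovers(bl3)
  expect_equal(nrow(xo), 1L)
  expect_equal(xo$left_bp, 4e6)
  expect_equal(xo$right_bp, 5e6)
  expect_equal(xo$mid_bp, 4.5e6)

  # AA | AB | BB: two crossovers
  bl4 <- data.frame(individual = 1L, chrom = "chr1",
                    start_bp = c(1, 11, 21) * 1e6,
                    end_bp = c(10, 20, 30) * 1e6,
                    state = c("AA", "AB", "BB"))
  expect_equal(nrow(call_crossovers(bl4)), 2L)

  # all-missing chromosome: one unknown block, excluded from crossovers
  bl5 <- decode_chromosome(rep(0L, 5), rep(0L, 5), pos[1:5], params)
  expect_equal(bl5$state, "unknown")
  expect_equal(nrow(call_crossovers(bl5)), 0L)
})

test_that("near-perfect data recovers essentially all true crossovers", {
  cfg <- sim_config(chrom_lengths_bp = rep(25e6, 2),
                    n_markers_per_chrom = 100, n_individuals = 50,
                    seed = 310)
  truth <- simulate_f2_population(cfg)
  obs <- simulate_observations(truth, mean_depth = 50, error_rate = 1e-4,
                               seed = 311)
  blocks <- decode_population(obs, hmm_params(error_rate = 1e-4))
  xo <- call_crossovers(blocks)

  mk <- truth$markers
  span <- tapply(mk$pos, mk$chrom, range)
  tr <- truth$crossovers
  inside <- mapply(function(ch, p) {
    p > span[[ch]][1L] && p < span[[ch]][2L]
  }, tr$chrom, tr$pos_bp)
  tr <- tr[inside, ]
  # a crossover with no marker between it and its same-gamete neighbour is
  # invisible to any marker-based method (the pair cancels): exclude
  detectable <- rep(TRUE, nrow(tr))
  key <- paste(tr$individual, tr$chrom, tr$gamete)
  for (k in unique(key)) {
    idx <- which(key == k)
    p <- sort(tr$pos_bp[idx])
    ch <- tr$chrom[idx[1L]]
    if (length(p) < 2L) next
    for (j in seq_len(length(p) - 1L)) {
      between <- sum(mk$pos[mk$chrom == ch] > p[j] &
                       mk$pos[mk$chrom == ch] < p[j + 1L])
      if (between == 0L)
        detectable[idx[order(tr$pos_bp[idx])][c(j, j + 1L)]] <- FALSE
    }
  }
  tr <- tr[detectable, ]
  mean_gap <- mean(unlist(tapply(mk$pos, mk$chrom, diff)))
  err <- rep(NA_real_, nrow(tr))
  hit <- vapply(seq_len(nrow(tr)), function(i) {
    cand <- xo[xo$individual == tr$individual[i] & xo$chrom == tr$chrom[i], ]
    if (nrow(cand) == 0L) return(FALSE)
    err[i] <<- min(abs(cand$mid_bp - tr$pos_bp[i]))
    # detected if the true position falls inside a called breakpoint
    # interval (marker gaps are irregular, so midpoints can sit a full
    # local gap away) or lands within a mean gap of a called midpoint
    any(cand$left_bp <= tr$pos_bp[i] & cand$right_bp >= tr$pos_bp[i]) ||
      err[i] < mean_gap
  }, TRUE)
  expect_gte(mean(hit), 0.99)
  expect_lt(mean(err[hit], na.rm = TRUE), mean_gap)
})

test_that("bins are delimited by pooled breakpoints and merged below 30 kb", {
  mk <- data.frame(chrom = "chr1", pos = c(1, seq_len(30)) * 1e6)
  blocks <- rbind(
    data.frame(individual = 1L, chrom = "chr1",
               start_bp = c(1e6, 11e6), end_bp = c(10e6, 30e6),
               state = c("AA", "AB")),
    data.frame(individual = 2L, chrom = "chr1",
               start_bp = c(1e6, 21e6), end_bp = c(20e6, 30e6),
               state = c("BB", "AB")))
  bm <- build_bins(blocks, mk, min_bin_bp = 30000)
  expect_equal(nrow(bm$bins), 3L)
  expect_equal(bm$bins$start_bp, c(1e6, 10.5e6 + 1, 20.5e6 + 1))
  expect_equal(bm$bins$end_bp, c(10.5e6, 20.5e6, 30e6))
  # genotypes follow each individual's block across each bin
  expect_equal(unname(bm$geno[, 1L]), c(1L, 2L, 2L))
  expect_equal(unname(bm$geno[, 2L]), c(3L, 3L, 2L))

  # 40 kb apart: both boundaries kept; 25 kb apart: merged to one
  mk2 <- data.frame(chrom = "chr1", pos = c(1e6, 10e6))
  mk2 <- data.frame(chrom = "chr1", pos = seq(1e6, 10e6, by = 0.5e6))
  mkblocks <- function(mid) rbind(
    data.frame(individual = 1L, chrom = "chr1", start_bp = 1e6,
               end_bp = 10e6, state = "AA"),
    data.frame(individual = 2L, chrom = "chr1",
               start_bp = c(1e6, mid[1] + 2), end_bp = c(mid[1] - 1, 10e6),
               state = c("AA", "AB")),
    data.frame(individual = 3L, chrom = "chr1",
               start_bp = c(1e6, mid[2] + 2), end_bp = c(mid[2] - 1, 10e6),
               state = c("AA", "BB")))
  wide <- build_bins(mkblocks(c(5e6, 5.04e6)), mk2, 30000)
  expect_equal(nrow(wide$bins), 3L)
  narrow <- build_bins(mkblocks(c(5e6, 5.025e6)), mk2, 30000)
  expect_equal(nrow(narrow$bins), 2L)
  # invariants: partition of covered span, every bin >= threshold
  for (bmx in list(wide, narrow)) {
    len <- bmx$bins$end_bp - bmx$bins$start_bp + 1
    expect_true(all(len >= 30000))
    expect_equal(sum(len), 10e6 - 1e6 + 1)
    expect_true(all(bmx$bins$start_bp[-1L] ==
                      bmx$bins$end_bp[-nrow(bmx$bins)] + 1))
  }

  # zero crossovers genome-wide: one bin per chromosome
  b1 <- data.frame(individual = 1:2, chrom = "chr1", start_bp = 1e6,
                   end_bp = 30e6, state = "AA")
  bm1 <- build_bins(b1, mk, 30000)
  expect_equal(nrow(bm1$bins), 1L)
})

test_that("imputation accuracy improves with depth and degrades with error", {
  accs <- matrix(NA_real_, 3, 3,
                 dimnames = list(paste0("l", c(1, 3, 7)),
                                 paste0("e", c(0.001, 0.01, 0.05))))
  truth <- simulate_f2_population(
    sim_config(chrom_lengths_bp = rep(20e6, 2), n_markers_per_chrom = 60,
               n_individuals = 80, seed = 320))
  params <- hmm_params()
  for (li in seq_along(c(1, 3, 7))) for (ei in seq_along(c(0.001, 0.01, 0.05))) {
    lam <- c(1, 3, 7)[li]; eps <- c(0.001, 0.01, 0.05)[ei]
    obs <- simulate_observations(truth, lam, eps, seed = 321)
    blocks <- decode_population(obs, hmm_params(error_rate = max(eps, 1e-3)))
    # marker-level accuracy of the decoded state vs true genotype
    st <- matrix(NA_integer_, nrow(truth$geno), nrow(truth$markers))
    for (k in seq_len(nrow(blocks))) {
      if (blocks$state[k] == "unknown") next
      cols <- which(truth$markers$chrom == blocks$chrom[k] &
                      truth$markers$pos >= blocks$start_bp[k] &
                      truth$markers$pos <= blocks$end_bp[k])
      st[blocks$individual[k], cols] <- match(blocks$state[k],
                                              c("AA", "AB", "BB"))
    }
    accs[li, ei] <- mean(st == truth$geno, na.rm = TRUE)
  }
  slack <- 0.002
  for (ei in 1:3) {
    expect_gte(accs[2L, ei], accs[1L, ei] - slack)  # deeper is better
    expect_gte(accs[3L, ei], accs[2L, ei] - slack)
  }
  for (li in 1:3) {
    expect_gte(accs[li, 1L], accs[li, 2L] - slack)  # noisier is worse
    expect_gte(accs[li, 2L], accs[li, 3L] - slack)
  }
  expect_gt(accs[3L, 2L], 0.98)  # study-like depth/error is near-perfect
})
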