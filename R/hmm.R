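# Hidden Markov model for F2 genotype-block imputation from sparse
# allele depths. States are AA/AB/BB; emissions are binomial read counts,
# transitions come from a Haldane-converted physical gap, and decoding is
# Viterbi in log space (vectorised across individuals for whole-population
# runs).

#' HMM parameters for genotype-block imputation
#'
#' @param error_rate per-read miscall probability (0 < eps < 0.5).
#' @param rho background genetic rate in cM/Mb used to convert physical
#'   gaps into transition probabilities.
#' @param min_bin_bp minimum retained bin length in bp (bins shorter than
#'   this are merged to avoid false recombination).
#' @return A validated list of class `hmm_params`.
#' @export
hmm_params <- function(error_rate = 0.01, rho = 3, min_bin_bp = 30000) {
  .check_number(error_rate, "error_rate", lower = 0, upper = 0.5,
                lower_open = TRUE, upper_open = TRUE)
  .check_number(rho, "rho", lower = 0, lower_open = TRUE)
  .check_number(min_bin_bp, "min_bin_bp", lower = 0)
  structure(list(error_rate = error_rate, rho = rho,
                 min_bin_bp = min_bin_bp), class = "hmm_params")
}

#' Emission probabilities for an allele-depth observation
#'
#' For read counts `(n_A, n_B)` with depth `d = n_A + n_B`:
#' `P(obs | AA) = C(d, n_B) eps^n_B (1-eps)^n_A`,
#' `P(obs | AB) = C(d, n_A) 0.5^d`, and `P(obs | BB)` symmetric to AA.
#' Depth 0 is uninformative and returns the uniform triple. Probabilities
#' are normalised to sum to one per observation.
#'
#' @param n_A,n_B integer vectors of reads supporting the female/male allele.
#' @param error_rate per-read miscall probability (0 < eps < 0.5).
#' @return Matrix with one row per observation and columns `AA`, `AB`, `BB`.
#' @export
emission_probs <- function(n_A, n_B, error_rate = 0.01) {
  .check_number(error_rate, "error_rate", lower = 0, upper = 0.5,
                lower_open = TRUE, upper_open = TRUE)
  if (any(n_A < 0) || any(n_B < 0)) stop("negative read counts")
  d <- n_A + n_B
  p <- cbind(AA = stats::dbinom(n_B, d, error_rate),
             AB = stats::dbinom(n_A, d, 0.5),
             BB = stats::dbinom(n_A, d, error_rate))
  p[d == 0L, ] <- 1
  p / rowSums(p)
}

#' F2 diploid transition matrix across a physical gap
#'
#' The per-gamete switch probability is Haldane's
#' `r = (1 - exp(-2 d_M)) / 2` with `d_M = gap_bp * rho / 1e6 / 100` Morgans;
#' the two gametes of the F2 chain switch independently, giving
#' `AA -> (AA, AB, BB) = ((1-r)^2, 2r(1-r), r^2)` and
#' `AB -> AB = (1-r)^2 + r^2`.
#'
#' @param gap_bp physical gap in bp (>= 0).
#' @param rho genetic rate (cM/Mb).
#' @return 3x3 row-stochastic matrix over states AA, AB, BB.
#' @export
transition_matrix <- function(gap_bp, rho = 3) {
  stopifnot(gap_bp >= 0)
  r <- 0.5 * (1 - exp(-2 * gap_bp * rho / 1e8))
  .f2_transition(r)
}

.f2_transition <- function(r) {
  s <- 1 - r
  m <- rbind(c(s^2, 2 * r * s, r^2),
             c(r * s, s^2 + r^2, r * s),
             c(r^2, 2 * r * s, s^2))
  dimnames(m) <- list(.GENO_LEVELS, .GENO_LEVELS)
  m
}

## Viterbi over one chromosome for a block of individuals.
## NA_mat/NB_mat: individuals x markers; pos: marker positions (sorted).
## Returns an individuals x markers integer state matrix (1/2/3); rows with
## zero total depth are returned as NA (caller emits an `unknown` block).
## Start distribution is the stationary F2 (1/4, 1/2, 1/4); ties in the
## predecessor choice are broken toward staying in the current state, then
## toward the lowest state index.
.viterbi_f2 <- function(NA_mat, NB_mat, pos, error_rate, rho) {
  n <- nrow(NA_mat)
  T_ <- length(pos)
  states <- matrix(NA_integer_, n, T_)
  depth_tot <- rowSums(NA_mat + NB_mat)
  act <- which(depth_tot > 0)
  if (length(act) == 0L) return(states)

  le <- function(t) log(emission_probs(NA_mat[act, t], NB_mat[act, t],
                                       error_rate))
  delta <- matrix(log(c(0.25, 0.5, 0.25)), length(act), 3L,
                  byrow = TRUE) + le(1L)
  psi <- array(0L, dim = c(length(act), 3L, T_))
  for (t in seq_len(T_)[-1L]) {
    lt <- log(transition_matrix(pos[t] - pos[t - 1L], rho))
    nd <- matrix(-Inf, length(act), 3L)
    for (j in 1:3) {
      cand <- delta + matrix(lt[, j], length(act), 3L, byrow = TRUE)
      m <- pmax(cand[, 1L], cand[, 2L], cand[, 3L])
      pick <- rep(NA_integer_, length(act))
      for (i in c(j, setdiff(1:3, j)))  # prefer staying, then lowest index
        pick[is.na(pick) & cand[, i] >= m] <- i
      psi[, j, t] <- pick
      nd[, j] <- m
    }
    delta <- nd + le(t)
  }
  cur <- max.col(delta, ties.method = "first")
  states[act, T_] <- cur
  if (T_ > 1L) for (t in rev(seq_len(T_ - 1L))) {
    cur <- psi[cbind(seq_along(cur), cur, t + 1L)]
    states[act, t] <- cur
  }
  states
}

#' Decode genotype blocks for one individual on one chromosome
#'
#' Runs Viterbi decoding over the chromosome's markers and collapses the
#' state path into maximal same-state runs. Each block spans from its first
#' to its last informative marker (1-based inclusive). A chromosome with no
#' covered marker yields a single block of state `"unknown"`, which is
#' excluded from crossover counting downstream.
#'
#' @param n_A,n_B integer vectors of allele depths along the chromosome.
#' @param pos marker positions (bp, sorted increasing).
#' @param params an [hmm_params()] object.
#' @param individual,chrom identifiers copied into the output.
#' @return Data frame with columns `individual`, `chrom`, `start_bp`,
#'   `end_bp`, `state`.
#' @export
decode_chromosome <- function(n_A, n_B, pos, params = hmm_params(),
                              individual = 1L, chrom = "chr1") {
  stopifnot(length(n_A) == length(pos), length(n_B) == length(pos),
            !is.unsorted(pos))
  st <- .viterbi_f2(matrix(as.integer(n_A), 1L),
                    matrix(as.integer(n_B), 1L),
                    pos, params$error_rate, params$rho)[1L, ]
  .states_to_blocks(st, pos, individual, chrom)
}

.states_to_blocks <- function(states, pos, individual, chrom) {
  if (all(is.na(states)))
    return(data.frame(individual = individual, chrom = chrom,
                      start_bp = pos[1L], end_bp = pos[length(pos)],
                      state = "unknown", stringsAsFactors = FALSE))
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(individual = individual, chrom = chrom,
             start_bp = pos[starts], end_bp = pos[ends],
             state = .GENO_LEVELS[r$values], stringsAsFactors = FALSE)
}

#' Decode genotype blocks for a whole population
#'
#' Vectorised Viterbi across individuals, one chromosome at a time.
#'
#' @param obs an `f2_obs` object.
#' @param params an [hmm_params()] object.
#' @return A `genotype_blocks` data frame (`individual`, `chrom`,
#'   `start_bp`, `end_bp`, `state`), ordered by individual within chromosome.
#' @export
decode_population <- function(obs, params = hmm_params()) {
  stopifnot(inherits(obs, "f2_obs"))
  mk <- obs$markers
  n <- nrow(obs$n_A)
  out <- list()
  for (ch in .chrom_order(mk$chrom)) {
    idx <- which(mk$chrom == ch)
    st <- .viterbi_f2(obs$n_A[, idx, drop = FALSE],
                      obs$n_B[, idx, drop = FALSE],
                      mk$pos[idx], params$error_rate, params$rho)
    out[[ch]] <- do.call(rbind, lapply(seq_len(n), function(i)
      .states_to_blocks(st[i, ], mk$pos[idx], i, ch)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("genotype_blocks", "data.frame")
  res
}

#' Call crossovers from decoded genotype blocks
#'
#' Every pair of adjacent blocks with different (known) states on the same
#' chromosome of the same individual is one crossover. The breakpoint
#' interval runs from the last marker of the left block to the first marker
#' of the right block; the point estimate is the interval midpoint.
#'
#' @param blocks a `genotype_blocks` data frame.
#' @return Data frame `individual`, `chrom`, `left_bp`, `right_bp`,
#'   `mid_bp`.
#' @export
call_crossovers <- function(blocks) {
  b <- blocks[blocks$state != "unknown", , drop = FALSE]
  if (nrow(b) < 2L)
    return(data.frame(individual = integer(), chrom = character(),
                      left_bp = numeric(), right_bp = numeric(),
                      mid_bp = numeric()))
  same <- b$individual[-1L] == b$individual[-nrow(b)] &
    b$chrom[-1L] == b$chrom[-nrow(b)]
  i <- which(same)
  out <- data.frame(individual = b$individual[i], chrom = b$chrom[i],
                    left_bp = b$end_bp[i], right_bp = b$start_bp[i + 1L])
  out$mid_bp <- floor((out$left_bp + out$right_bp) / 2)
  rownames(out) <- NULL
  out
}

#' Per-individual crossover counts
#' @param crossovers output of [call_crossovers()].
#' @param n_individuals total population size (so zero-event individuals are
#'   included).
#' @return Data frame `individual`, `n_events`.
#' @export
crossover_counts <- function(crossovers, n_individuals) {
  tab <- table(factor(crossovers$individual, levels = seq_len(n_individuals)))
  data.frame(individual = seq_len(n_individuals),
             n_events = as.integer(tab))
}
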