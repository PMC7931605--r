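# Independent oracles used by the unit and acceptance tests. These
# re-derive each quantity by brute force or from first principles and stay
# independent of the code paths they check.

## Best achievable log-probability over ALL 3^T state paths of the F2 HMM
## (exhaustive maximization; emissions and transitions written out here).
oracle_best_path_score <- function(n_A, n_B, pos, eps, rho) {
  T_ <- length(pos)
  lemis <- sapply(1:3, function(s) {
    d <- n_A + n_B
    p <- switch(s,
                dbinom(n_B, d, eps),
                dbinom(n_A, d, 0.5),
                dbinom(n_A, d, eps))
    norm <- dbinom(n_B, d, eps) + dbinom(n_A, d, 0.5) + dbinom(n_A, d, eps)
    ifelse(d == 0, log(1 / 3), log(p / norm))
  })  # T x 3
  lemis <- matrix(lemis, nrow = T_)
  ltrans <- lapply(seq_len(T_ - 1L), function(t) {
    r <- 0.5 * (1 - exp(-2 * (pos[t + 1L] - pos[t]) * rho / 1e8))
    s <- 1 - r
    log(rbind(c(s^2, 2 * r * s, r^2),
              c(r * s, s^2 + r^2, r * s),
              c(r^2, 2 * r * s, s^2)))
  })
  paths <- as.matrix(expand.grid(rep(list(1:3), T_)))
  score <- log(c(0.25, 0.5, 0.25))[paths[, 1L]] + lemis[1L, ][paths[, 1L]]
  if (T_ > 1L) for (t in 2:T_) {
    score <- score + lemis[t, ][paths[, t]] +
      ltrans[[t - 1L]][cbind(paths[, t - 1L], paths[, t])]
  }
  max(score)
}

## Log-probability of one decoded path under the same model (to compare the
## Viterbi path's score against the exhaustive maximum).
oracle_path_score <- function(states, n_A, n_B, pos, eps, rho) {
  d <- n_A + n_B
  em <- function(t, s) {
    p <- switch(s,
                dbinom(n_B[t], d[t], eps),
                dbinom(n_A[t], d[t], 0.5),
                dbinom(n_A[t], d[t], eps))
    norm <- dbinom(n_B[t], d[t], eps) + dbinom(n_A[t], d[t], 0.5) +
      dbinom(n_A[t], d[t], eps)
    if (d[t] == 0) log(1 / 3) else log(p / norm)
  }
  sc <- log(c(0.25, 0.5, 0.25))[states[1L]] + em(1L, states[1L])
  if (length(states) > 1L) for (t in 2:length(states)) {
    r <- 0.5 * (1 - exp(-2 * (pos[t] - pos[t - 1L]) * rho / 1e8))
    s <- 1 - r
    tr <- rbind(c(s^2, 2 * r * s, r^2),
                c(r * s, s^2 + r^2, r * s),
                c(r^2, 2 * r * s, s^2))
    sc <- sc + log(tr[states[t - 1L], states[t]]) + em(t, states[t])
  }
  sc
}

## Exact F2 two-locus joint genotype probabilities at recombination
## fraction r (coupling phase), written out from the gamete model.
oracle_f2_joint <- function(r) {
  p <- (1 - r) / 2   # parental gamete haplotype (per haplotype class)
  q <- r / 2         # recombinant
  rbind(c(p^2, 2 * p * q, q^2),
        c(2 * p * q, 2 * (p^2 + q^2), 2 * p * q),
        c(q^2, 2 * p * q, p^2))
}

## Grid-search ML recombination fraction for a 3x3 F2 genotype table.
oracle_rf_grid <- function(tab, step = 1e-4) {
  grid <- seq(0, 0.5, by = step)
  ll <- vapply(grid, function(r) {
    P <- oracle_f2_joint(r)
    if (any(P[tab > 0] == 0)) return(-Inf)
    sum(tab[tab > 0] * log(P[tab > 0]))
  }, 0)
  list(r = grid[which.max(ll)], loglik = max(ll))
}

## Midrank Mann-Whitney normal approximation with tie correction, computed
## on the expanded per-read observations via base rank().
oracle_midrank_z <- function(a, b) {
  x <- c(rep(seq_along(a), a), rep(seq_along(b), b))
  grp <- rep(1:2, c(sum(a), sum(b)))
  rk <- rank(x)
  m <- sum(a); n <- sum(b); N <- m + n
  W <- sum(rk[grp == 1L])
  EW <- m * (N + 1) / 2
  t_j <- table(x)
  varW <- m * n / 12 * ((N + 1) - sum(t_j^3 - t_j) / (N * (N - 1)))
  z <- if (varW > 0) (W - EW) / sqrt(varW) else 0
  list(z = z, p = 2 * pnorm(-abs(z)))
}

## Brute-force two-model regression LOD at one bin via lm().
oracle_bin_lod <- function(y, g, covariates = NULL) {
  cz <- binqtl::genotype_codes(g)
  df <- data.frame(y = y, x = cz[, 1L], z = cz[, 2L])
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  df <- df[complete.cases(df), , drop = FALSE]
  f1 <- lm(y ~ ., data = df)
  f0 <- lm(y ~ . - x - z, data = df)
  rss1 <- sum(resid(f1)^2)
  rss0 <- sum(resid(f0)^2)
  list(lod = nrow(df) / 2 * log10(rss0 / rss1),
       a = coef(f1)[["x"]], d = coef(f1)[["z"]], n = nrow(df))
}
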