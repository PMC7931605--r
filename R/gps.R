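# GradedPool-Seq mapping: phenotype-ranked graded pools, in-silico pooled
# allele counts, a per-variant Ridit (ordered-category midrank) test,
# sliding-window smoothing and candidate-region calling.

#' Build graded pools from ranked phenotypes
#'
#' Ranks phenotype values from high to low (ties broken by stable
#' individual order) and splits the ranking into `k` contiguous blocks of
#' size `ceiling(n/k)` or `floor(n/k)` (larger blocks first). Pool 1 holds
#' the highest phenotypes. Every phenotyped individual lands in exactly one
#' pool.
#'
#' @param phenotypes data frame with columns `id` and `value` (or a named
#'   numeric vector).
#' @param k number of pools (default 4; must be >= 2).
#' @return Object of class `graded_pools`: list with `members` (list of id
#'   vectors per pool) and `ranges` (data frame `pool`, `n`, `min`, `max`).
#' @export
build_pools <- function(phenotypes, k = 4L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (is.numeric(phenotypes) && !is.data.frame(phenotypes)) {
    ids <- if (!is.null(names(phenotypes))) names(phenotypes) else
      seq_along(phenotypes)
    phenotypes <- data.frame(id = ids, value = as.numeric(phenotypes))
  }
  ph <- phenotypes[!is.na(phenotypes$value), , drop = FALSE]
  n <- nrow(ph)
  if (n < k) stop("fewer phenotyped individuals than pools", call. = FALSE)
  ord <- order(-ph$value, seq_len(n))  # high to low, stable in id order
  base <- n %/% k
  extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  pool_of <- rep(seq_len(k), sizes)
  members <- split(ph$id[ord], pool_of)
  ranges <- data.frame(pool = seq_len(k), n = sizes,
                       min = vapply(split(ph$value[ord], pool_of), min, 0),
                       max = vapply(split(ph$value[ord], pool_of), max, 0))
  structure(list(members = members, ranges = ranges, k = k),
            class = "graded_pools")
}

#' @export
print.graded_pools <- function(x, ...) {
  cat(sprintf("%d graded pools (pool 1 = highest phenotype):\n", x$k))
  for (i in seq_len(x$k))
    cat(sprintf("  pool %d: n = %d, range %.4g-%.4g\n", i,
                x$ranges$n[i], x$ranges$min[i], x$ranges$max[i]))
  invisible(x)
}

#' Pool allele depths in silico
#'
#' Sums the member individuals' female- and male-allele read counts per
#' variant per pool (emulating read merging of a sequenced bulk). Variants
#' with total depth below `min_depth`, or with zero depth in any pool, are
#' flagged `filtered`.
#'
#' @param obs an `f2_obs` (individual ids must match pool member ids:
#'   rownames of the observation matrices, or row indices).
#' @param pools a `graded_pools` object.
#' @param min_depth minimum total depth across pools (default 10).
#' @return Object of class `pooled_counts`: list with `markers`, `A` and
#'   `B` (k x variants depth matrices) and `filtered` (logical).
#' @export
pool_allele_counts <- function(obs, pools, min_depth = 10) {
  stopifnot(inherits(obs, "f2_obs"), inherits(pools, "graded_pools"))
  rn <- rownames(obs$n_A)
  idx_of <- function(ids) {
    if (!is.null(rn) && all(as.character(ids) %in% rn))
      match(as.character(ids), rn)
    else as.integer(ids)
  }
  k <- pools$k
  A <- B <- matrix(0, k, ncol(obs$n_A))
  for (i in seq_len(k)) {
    rows <- idx_of(pools$members[[i]])
    A[i, ] <- colSums(obs$n_A[rows, , drop = FALSE])
    B[i, ] <- colSums(obs$n_B[rows, , drop = FALSE])
  }
  tot <- colSums(A + B)
  pool_tot <- A + B
  filtered <- tot < min_depth | apply(pool_tot == 0, 2L, any)
  structure(list(markers = obs$markers, A = A, B = B, filtered = filtered,
                 min_depth = min_depth), class = "pooled_counts")
}

## Vectorised Ridit/midrank z over many 2 x k tables.
## A, B: k x V matrices (counts of the two allele rows per ordered pool).
## Returns list(z, p, ridit_a, ridit_b).
.ridit_many <- function(A, B) {
  Nj <- A + B
  N <- colSums(Nj)
  m <- colSums(A)
  n <- colSums(B)
  csum <- apply(Nj, 2L, cumsum)
  before <- csum - Nj
  ridit <- sweep(before + Nj / 2, 2L, N, "/")
  midrank <- sweep(ridit, 2L, N, "*") + 0.5
  W <- colSums(A * midrank)
  EW <- m * (N + 1) / 2
  tie <- colSums(Nj^3 - Nj)
  varW <- m * n / 12 * ((N + 1) - tie / (N * (N - 1)))
  z <- ifelse(varW > 0, (W - EW) / sqrt(varW), 0)
  z[m == 0 | n == 0] <- 0
  p <- 2 * stats::pnorm(-abs(z))
  ## -log10(p) on the log scale: immune to underflow at extreme z
  logp <- -(log(2) + stats::pnorm(-abs(z), log.p = TRUE)) / log(10)
  ra <- ifelse(m > 0, colSums(A * ridit) / m, NA_real_)
  rb <- ifelse(n > 0, colSums(B * ridit) / n, NA_real_)
  list(z = z, p = p, logp = logp, ridit_a = ra, ridit_b = rb)
}

#' Ridit test for a 2 x k pooled count table
#'
#' Treats the k pools as ordered categories with the column totals as the
#' reference distribution; the ridit of pool j is its mid-cumulative
#' probability. The two allele rows are compared by their mean ridits,
#' standardised with the tie-corrected two-sample midrank (rank-sum)
#' variance; the p-value is the two-sided normal tail. `z > 0` means the
#' first row is concentrated in later pools. A zero-total row gives
#' `z = 0`, `p = 1`, flagged.
#'
#' @param a,b nonnegative counts of the two alleles across the k ordered
#'   pools.
#' @return List `z`, `p`, `ridit_a`, `ridit_b`, `ok` (FALSE when a row is
#'   empty).
#' @export
ridit_test <- function(a, b) {
  stopifnot(length(a) == length(b), all(a >= 0), all(b >= 0))
  res <- .ridit_many(matrix(a, ncol = 1L), matrix(b, ncol = 1L))
  list(z = res$z[1L], p = res$p[1L], ridit_a = res$ridit_a[1L],
       ridit_b = res$ridit_b[1L], ok = sum(a) > 0 && sum(b) > 0)
}

#' Per-variant Ridit scan of pooled counts
#'
#' @param pooled a `pooled_counts` object.
#' @return Data frame `chrom`, `pos`, `z`, `p`, `logp` (`-log10(p)`
#'   computed on the log scale, safe at extreme `z`), `filtered` (filtered
#'   variants keep `NA` statistics).
#' @export
ridit_scan <- function(pooled) {
  stopifnot(inherits(pooled, "pooled_counts"))
  res <- .ridit_many(pooled$B, pooled$A)  # male-allele row first; z > 0
                                          # when B piles up in later pools
  out <- data.frame(chrom = pooled$markers$chrom,
                    pos = pooled$markers$pos,
                    z = res$z, p = res$p, logp = res$logp,
                    filtered = pooled$filtered, stringsAsFactors = FALSE)
  out$z[out$filtered] <- NA_real_
  out$p[out$filtered] <- NA_real_
  out$logp[out$filtered] <- NA_real_
  out
}

#' Sliding-window smoothing and candidate-region calling
#'
#' Tiles each chromosome with windows of `window_bp` advanced by `step_bp`,
#' scores each window holding at least `min_variants` unfiltered variants
#' (mean `-log10(p)` by default, or Fisher's combination), and calls the
#' candidate region as the peak-score window extended by `flank_bp` on each
#' side, clipped to the chromosome.
#'
#' @param ridit output of [ridit_scan()].
#' @param chrom_lengths named vector of chromosome lengths (bp); defaults
#'   to the maximum variant position per chromosome.
#' @param window_bp window size (default 400 kb).
#' @param step_bp window step (default 100 kb).
#' @param min_variants minimum unfiltered variants per scored window.
#' @param flank_bp candidate-region extension (default 200 kb).
#' @param agg aggregation: `"mean_logp"` or `"fisher"` (-log10 of the
#'   chi-square combination p-value).
#' @return Object of class `gps_scan`: list with `windows` (data frame
#'   `chrom`, `start`, `end`, `n_variants`, `score`) and `candidate` (one
#'   row: `chrom`, `start`, `end`, `peak_score`), or empty with a warning
#'   when no window qualifies.
#' @export
window_scan <- function(ridit, chrom_lengths = NULL, window_bp = 4e5,
                        step_bp = 1e5, min_variants = 5L, flank_bp = 2e5,
                        agg = c("mean_logp", "fisher")) {
  agg <- match.arg(agg)
  use <- !ridit$filtered & !is.na(ridit$p)
  if (!any(use)) {
    warning("no unfiltered variants; empty scan", call. = FALSE)
    return(structure(list(windows = NULL, candidate = NULL),
                     class = "gps_scan"))
  }
  chroms <- .chrom_order(ridit$chrom)
  if (is.null(chrom_lengths))
    chrom_lengths <- vapply(chroms, function(ch)
      max(ridit$pos[ridit$chrom == ch]), 0)
  wins <- list()
  for (ch in chroms) {
    len <- chrom_lengths[[ch]]
    starts <- seq(1, max(1, len - window_bp + 1), by = step_bp)
    pos <- ridit$pos[use & ridit$chrom == ch]
    lp <- if ("logp" %in% names(ridit)) ridit$logp[use & ridit$chrom == ch]
    else -log10(ridit$p[use & ridit$chrom == ch])
    lp[is.infinite(lp)] <- 320  # guard direct -log10 underflow
    sc <- nv <- numeric(length(starts))
    for (w in seq_along(starts)) {
      inw <- pos >= starts[w] & pos <= starts[w] + window_bp - 1
      nv[w] <- sum(inw)
      sc[w] <- if (nv[w] < min_variants) NA_real_
      else if (agg == "mean_logp") mean(lp[inw])
      else {
        stat <- 2 * sum(lp[inw]) * log(10)
        -stats::pchisq(stat, df = 2 * nv[w], lower.tail = FALSE,
                       log.p = TRUE) / log(10)
      }
    }
    wins[[ch]] <- data.frame(chrom = ch, start = starts,
                             end = pmin(starts + window_bp - 1, len),
                             n_variants = nv, score = sc,
                             stringsAsFactors = FALSE)
  }
  windows <- do.call(rbind, wins)
  rownames(windows) <- NULL
  if (all(is.na(windows$score))) {
    warning("no window holds >= ", min_variants,
            " unfiltered variants; empty scan", call. = FALSE)
    return(structure(list(windows = windows, candidate = NULL),
                     class = "gps_scan"))
  }
  peak <- which.max(windows$score)
  ch <- windows$chrom[peak]
  candidate <- data.frame(
    chrom = ch,
    start = max(1, windows$start[peak] - flank_bp),
    end = min(chrom_lengths[[ch]], windows$end[peak] + flank_bp),
    peak_score = windows$score[peak], stringsAsFactors = FALSE)
  structure(list(windows = windows, candidate = candidate),
            class = "gps_scan")
}

#' @export
print.gps_scan <- function(x, ...) {
  if (is.null(x$candidate)) {
    cat("GradedPool-Seq scan: empty (no scored window)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "GradedPool-Seq scan: %d windows; candidate region %s:%d-%d (score %.2f)\n",
    nrow(x$windows), x$candidate$chrom, x$candidate$start, x$candidate$end,
    x$candidate$peak_score))
  invisible(x)
}

#' Plot a window-scan score track
#' @param x a `gps_scan`.
#' @param ... passed to [plot()].
#' @export
plot.gps_scan <- function(x, ...) {
  w <- x$windows[!is.na(x$windows$score), ]
  chroms <- .chrom_order(w$chrom)
  off <- c(0, cumsum(vapply(chroms, function(ch)
    max(w$end[w$chrom == ch]), 0)))
  names(off) <- c(chroms, "end")
  gx <- (w$start + w$end) / 2 + off[w$chrom]
  plot(gx / 1e6, w$score, type = "p", pch = 16, cex = 0.4,
       xlab = "genome position (Mb)", ylab = "window score", ...)
  abline(v = off[-1L] / 1e6, col = "grey80", lty = 3)
  invisible(x)
}
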