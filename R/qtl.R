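# LOD-based QTL scanning on the bin map: Haley-Knott-style regression on
# F2 genotype codes, composite-interval covariates, permutation
# genome-wide thresholds, and joint-model effect/PVE estimation.

## RSS of y (or a matrix of y columns) on design X, rank-aware.
.rss_cols <- function(X, Y) {
  if (is.null(dim(Y))) Y <- matrix(Y, ncol = 1L)
  qrx <- qr(X)
  qty <- qr.qty(qrx, Y)
  if (is.null(dim(qty))) qty <- matrix(qty, ncol = 1L)
  tot <- colSums(Y^2)
  fit <- colSums(qty[seq_len(qrx$rank), , drop = FALSE]^2)
  pmax(tot - fit, 0)
}

## x/z code matrix for a set of bins (individuals x 2*length(bins))
.bin_codes <- function(binmap, bins) {
  do.call(cbind, lapply(bins, function(b) {
    cz <- genotype_codes(binmap$geno[b, ])
    colnames(cz) <- paste0(c("x", "z"), b)
    cz
  }))
}

#' Single-bin LOD scan
#'
#' At each bin, fits `y = mu + a x + d z (+ covariates)` by least squares on
#' the individuals with known genotype at that bin (pairwise complete), and
#' compares against the covariate-only null refitted on the same
#' individuals: `LOD = (n/2) log10(RSS0 / RSS1)`.
#'
#' @param y numeric phenotype vector (one entry per individual).
#' @param binmap a `bin_map`.
#' @param covariates optional numeric matrix of covariate columns
#'   (individuals x k), e.g. genotype codes of background bins.
#' @param exclude_cov optional list, per bin, of covariate column indices to
#'   drop when testing that bin (used by the CIM window rule).
#' @return Data frame of class `qtl_scan`: `bin`, `chrom`, `start_bp`,
#'   `end_bp`, `pos_mid`, `lod`, `a`, `d`, `n`.
#' @export
scan_lod <- function(y, binmap, covariates = NULL, exclude_cov = NULL) {
  stopifnot(inherits(binmap, "bin_map"))
  n_ind <- ncol(binmap$geno)
  stopifnot(length(y) == n_ind)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == n_ind)
  }
  n_bins <- nrow(binmap$bins)
  lod <- a <- d <- rep(NA_real_, n_bins)
  nn <- integer(n_bins)
  for (b in seq_len(n_bins)) {
    cz <- genotype_codes(binmap$geno[b, ])
    cov_b <- covariates
    if (!is.null(cov_b) && !is.null(exclude_cov) &&
        length(exclude_cov[[b]]) > 0L)
      cov_b <- cov_b[, -exclude_cov[[b]], drop = FALSE]
    if (!is.null(cov_b) && ncol(cov_b) == 0L) cov_b <- NULL
    idx <- which(!is.na(y) & !is.na(cz[, 1L]) &
                   (if (is.null(cov_b)) TRUE else
                     stats::complete.cases(cov_b)))
    nn[b] <- length(idx)
    if (length(idx) < 10L) next
    yi <- y[idx]
    X0 <- cbind(rep(1, length(idx)),
                if (!is.null(cov_b)) cov_b[idx, , drop = FALSE])
    X1 <- cbind(X0, cz[idx, , drop = FALSE])
    rss0 <- .rss_cols(X0, yi)
    rss1 <- .rss_cols(X1, yi)
    lod[b] <- if (rss0 <= 0) 0 else if (rss1 <= 0) Inf else
      length(idx) / 2 * log10(rss0 / rss1)
    cf <- stats::lm.fit(X1, yi)$coefficients
    a[b] <- cf[length(cf) - 1L]
    d[b] <- cf[length(cf)]
  }
  out <- data.frame(binmap$bins,
                    pos_mid = (binmap$bins$start_bp +
                                 binmap$bins$end_bp) / 2,
                    lod = lod, a = a, d = d, n = nn,
                    stringsAsFactors = FALSE)
  class(out) <- c("qtl_scan", "data.frame")
  out
}

#' Select composite-interval-mapping covariate bins
#'
#' Forward selection of up to `n_cov` background bins: repeatedly scan with
#' the current covariate set and add the genome-wide peak bin (skipping bins
#' within `window_cm` of an already-selected covariate).
#'
#' @param y phenotype vector.
#' @param binmap a `bin_map`.
#' @param n_cov maximum number of covariate bins (default 3).
#' @param window_cm exclusion window around covariates, in cM (default 10).
#' @param pos_cm optional per-bin cM positions; defaults to physical
#'   midpoints converted at `cm_per_mb`.
#' @param cm_per_mb rate for the default position conversion.
#' @return Integer vector of covariate bin indices (possibly empty).
#' @export
cim_covariates <- function(y, binmap, n_cov = 3L, window_cm = 10,
                           pos_cm = NULL, cm_per_mb = 3) {
  if (n_cov < 1L) return(integer())
  pos_cm <- .bin_pos_cm(binmap, pos_cm, cm_per_mb)
  sel <- integer()
  for (k in seq_len(n_cov)) {
    sc <- scan_lod(y, binmap,
                   covariates = if (length(sel)) .bin_codes(binmap, sel))
    cand <- sc$lod
    cand[sel] <- NA
    for (s in sel)
      cand[sc$chrom == binmap$bins$chrom[s] &
             abs(pos_cm - pos_cm[s]) < window_cm] <- NA
    if (all(is.na(cand))) break
    peak <- which.max(cand)
    if (cand[peak] <= 0) break
    sel <- c(sel, peak)
  }
  sel
}

.bin_pos_cm <- function(binmap, pos_cm, cm_per_mb) {
  if (!is.null(pos_cm)) return(pos_cm)
  (binmap$bins$start_bp + binmap$bins$end_bp) / 2 * cm_per_mb / 1e6
}

#' Composite interval mapping scan
#'
#' Runs [cim_covariates()] then [scan_lod()] with the selected background
#' bins as covariates; when testing a bin, covariates within `window_cm` of
#' it (same chromosome) are excluded from the model. With `n_cov = 0` this
#' reduces exactly to the simple scan.
#'
#' @inheritParams cim_covariates
#' @return A `qtl_scan` data frame with attribute `covariate_bins`.
#' @export
scan_cim <- function(y, binmap, n_cov = 3L, window_cm = 10, pos_cm = NULL,
                     cm_per_mb = 3) {
  pos_cm <- .bin_pos_cm(binmap, pos_cm, cm_per_mb)
  sel <- cim_covariates(y, binmap, n_cov, window_cm, pos_cm)
  if (length(sel) == 0L) {
    out <- scan_lod(y, binmap)
    attr(out, "covariate_bins") <- integer()
    return(out)
  }
  covs <- .bin_codes(binmap, sel)
  excl <- lapply(seq_len(nrow(binmap$bins)), function(b) {
    near <- which(binmap$bins$chrom[sel] == binmap$bins$chrom[b] &
                    abs(pos_cm[sel] - pos_cm[b]) < window_cm)
    if (length(near)) as.vector(outer(c(-1L, 0L), 2L * near, `+`)) else
      integer()
  })
  out <- scan_lod(y, binmap, covariates = covs, exclude_cov = excl)
  attr(out, "covariate_bins") <- sel
  out
}

#' Genome-wide permutation LOD threshold
#'
#' Permutes the phenotype against whole genotype rows (preserving marker
#' correlation), records the genome-wide maximum LOD of each permuted scan,
#' and returns the empirical `1 - alpha` quantile (type-7 interpolation).
#'
#' @param y phenotype vector.
#' @param binmap a `bin_map`.
#' @param n_perm number of permutations (default 1000; < 20 is refused).
#' @param alpha genome-wide significance level (default 0.05).
#' @param seed optional RNG seed recorded in the result.
#' @return List of class `permutation_threshold`: `threshold`, `n_perm`,
#'   `alpha`, `seed`, `max_lods`.
#' @export
permutation_threshold <- function(y, binmap, n_perm = 1000L, alpha = 0.05,
                                  seed = NULL) {
  if (n_perm < 20L)
    stop("n_perm < 20: quantile too unstable", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_ind <- ncol(binmap$geno)
  stopifnot(length(y) == n_ind)
  ok <- which(!is.na(y))
  perm <- replicate(n_perm, sample(ok))
  Y <- matrix(NA_real_, n_ind, n_perm)
  Y[ok, ] <- matrix(y[perm], length(ok), n_perm)

  maxlod <- rep(0, n_perm)
  for (b in seq_len(nrow(binmap$bins))) {
    cz <- genotype_codes(binmap$geno[b, ])
    idx <- which(!is.na(cz[, 1L]))
    if (length(idx) < 10L) next
    Yi <- Y[idx, , drop = FALSE]
    ## rows with NA (permuted y shorter than idx) cannot occur: perms fill
    ## every non-missing individual
    X1 <- cbind(1, cz[idx, , drop = FALSE])
    rss1 <- .rss_cols(X1, Yi)
    rss0 <- colSums(Yi^2) - colSums(Yi)^2 / length(idx)
    lod <- ifelse(rss1 <= 0, Inf,
                  length(idx) / 2 * log10(pmax(rss0, 0) / rss1))
    lod[rss0 <= 0] <- 0
    maxlod <- pmax(maxlod, lod)
  }
  structure(list(threshold = as.numeric(
    stats::quantile(maxlod, 1 - alpha, type = 7)),
    n_perm = n_perm, alpha = alpha, seed = seed,
    max_lods = maxlod), class = "permutation_threshold")
}

#' @export
print.permutation_threshold <- function(x, ...) {
  cat(sprintf(
    "Permutation LOD threshold: %.3f (alpha = %g, %d permutations%s)\n",
    x$threshold, x$alpha, x$n_perm,
    if (!is.null(x$seed)) paste0(", seed ", x$seed) else ""))
  invisible(x)
}

#' Declare QTL peaks from a scan
#'
#' Bins above the threshold are grouped into contiguous significant runs
#' per chromosome; each run contributes its maximum-LOD bin as a peak. The
#' support interval of a peak is the peak bin plus both flanking bins;
#' peaks of the same trait whose support intervals overlap are merged
#' (higher peak kept).
#'
#' @param scan a `qtl_scan`.
#' @param threshold LOD threshold (number or `permutation_threshold`).
#' @return Integer vector of peak bin indices (rows of the scan).
#' @export
find_qtl_peaks <- function(scan, threshold) {
  if (inherits(threshold, "permutation_threshold"))
    threshold <- threshold$threshold
  sig <- !is.na(scan$lod) & scan$lod > threshold
  peaks <- integer()
  for (ch in unique(scan$chrom)) {
    idx <- which(scan$chrom == ch)
    s <- sig[idx]
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run <- idx[starts[k]:ends[k]]
      peaks <- c(peaks, run[which.max(scan$lod[run])])
    }
  }
  if (length(peaks) < 2L) return(peaks)
  ## merge peaks with overlapping support intervals (peak +/- one bin)
  repeat {
    sup <- lapply(peaks, function(p) {
      idx <- which(scan$chrom == scan$chrom[p])
      sort(intersect(c(p - 1L, p, p + 1L), idx))
    })
    merged <- FALSE
    for (i in seq_along(peaks)) {
      for (j in seq_along(peaks)) {
        if (j <= i) next
        if (scan$chrom[peaks[i]] == scan$chrom[peaks[j]] &&
            length(intersect(sup[[i]], sup[[j]])) > 0L) {
          drop <- if (scan$lod[peaks[i]] >= scan$lod[peaks[j]]) j else i
          peaks <- peaks[-drop]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  sort(peaks)
}

#' Fit a joint QTL model and estimate effects and PVE
#'
#' Fits `y ~ sum_q (a_q x_q + d_q z_q)` over the declared peak bins on the
#' individuals with complete genotypes at all of them. The model PVE is
#' `100 (1 - RSS_full / RSS_null)`; each QTL's PVE is its drop-one sum of
#' squares as a percentage of the total. Support intervals are the peak bin
#' plus both flanking bins.
#'
#' @param y phenotype vector.
#' @param binmap a `bin_map`.
#' @param peaks integer vector of peak bin indices (see [find_qtl_peaks()]).
#' @param scan optional `qtl_scan` supplying peak LODs.
#' @param trait trait name copied into the output.
#' @return Data frame of class `qtl_fit` (`trait`, `peak_bin`, `chrom`,
#'   `peak_start_bp`, `peak_end_bp`, `support_start_bp`, `support_end_bp`,
#'   `lod`, `a`, `d`, `pve`) with attribute `model_pve`.
#' @export
fit_qtl <- function(y, binmap, peaks, scan = NULL, trait = "trait") {
  stopifnot(length(peaks) >= 1L)
  codes <- .bin_codes(binmap, peaks)
  idx <- which(!is.na(y) & stats::complete.cases(codes))
  p_par <- 1L + 2L * length(peaks)
  if (length(idx) <= p_par)
    stop("fewer residual degrees of freedom than parameters", call. = FALSE)
  yi <- y[idx]
  Xf <- cbind(1, codes[idx, , drop = FALSE])
  rss_full <- .rss_cols(Xf, yi)
  rss_null <- sum((yi - mean(yi))^2)
  model_pve <- 100 * (1 - rss_full / rss_null)
  cf <- stats::lm.fit(Xf, yi)$coefficients

  pve <- a <- d <- numeric(length(peaks))
  for (q in seq_along(peaks)) {
    a[q] <- cf[2L * q]
    d[q] <- cf[2L * q + 1L]
    Xm <- Xf[, -c(2L * q, 2L * q + 1L), drop = FALSE]
    rss_m <- .rss_cols(Xm, yi)
    pve[q] <- 100 * (rss_m - rss_full) / rss_null
  }

  sup <- t(vapply(peaks, function(p) {
    idx_ch <- which(binmap$bins$chrom == binmap$bins$chrom[p])
    s <- sort(intersect(c(p - 1L, p, p + 1L), idx_ch))
    c(binmap$bins$start_bp[s[1L]], binmap$bins$end_bp[s[length(s)]])
  }, numeric(2L)))

  out <- data.frame(
    trait = trait, peak_bin = peaks,
    chrom = binmap$bins$chrom[peaks],
    peak_start_bp = binmap$bins$start_bp[peaks],
    peak_end_bp = binmap$bins$end_bp[peaks],
    support_start_bp = sup[, 1L], support_end_bp = sup[, 2L],
    lod = if (!is.null(scan)) scan$lod[peaks] else NA_real_,
    a = a, d = d, pve = pve, stringsAsFactors = FALSE)
  attr(out, "model_pve") <- model_pve
  class(out) <- c("qtl_fit", "data.frame")
  out
}

#' @export
print.qtl_scan <- function(x, ...) {
  cat(sprintf("QTL scan over %d bins; max LOD %.2f at bin %d (%s)\n",
              nrow(x), max(x$lod, na.rm = TRUE),
              x$bin[which.max(x$lod)], x$chrom[which.max(x$lod)]))
  invisible(x)
}

#' Plot a LOD curve along the genome
#' @param x a `qtl_scan`.
#' @param threshold optional LOD threshold drawn as a dashed line.
#' @param ... passed to [plot()].
#' @export
plot.qtl_scan <- function(x, threshold = NULL, ...) {
  chroms <- .chrom_order(x$chrom)
  off <- c(0, cumsum(vapply(chroms, function(ch)
    max(x$end_bp[x$chrom == ch]), 0)))
  names(off) <- c(chroms, "end")
  gx <- x$pos_mid + off[x$chrom]
  plot(gx / 1e6, x$lod, type = "l", xlab = "genome position (Mb)",
       ylab = "LOD", ...)
  abline(v = off[-1L] / 1e6, col = "grey80", lty = 3)
  if (!is.null(threshold)) {
    if (inherits(threshold, "permutation_threshold"))
      threshold <- threshold$threshold
    abline(h = threshold, lty = 2, col = "red")
  }
  invisible(x)
}
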