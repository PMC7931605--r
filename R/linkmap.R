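# Pairwise recombination-fraction estimation for codominant F2 markers,
# the Kosambi map function, and physical-order linkage-map construction.

#' Maximum-likelihood recombination fraction between two F2 markers
#'
#' EM over the ambiguous double-heterozygote class: an AB/AB pair arises
#' from two parental gametes (probability `2p^2`, `p = (1-r)/2`) or two
#' recombinant gametes (`2q^2`, `q = r/2`), so its expected recombinant
#' gamete count is `2q^2 / (p^2 + q^2)`. All other genotype classes carry a
#' fixed recombinant-gamete count. Unknown genotypes are excluded pairwise;
#' the estimate is clamped to [0, 0.5].
#'
#' @param g1,g2 integer genotype vectors (1/2/3, NA = unknown) across
#'   individuals.
#' @param tol EM convergence tolerance on `|delta r|`.
#' @param max_iter iteration cap.
#' @param r_init starting value.
#' @return List with `r_hat`, `loglik` (exact F2 log-likelihood at the
#'   optimum), `n` (informative individuals) and `ok` (FALSE when no
#'   informative pair exists).
#' @export
estimate_rf_f2 <- function(g1, g2, tol = 1e-8, max_iter = 200L,
                           r_init = 0.25) {
  keep <- !is.na(g1) & !is.na(g2)
  n <- sum(keep)
  if (n < 2L)
    return(list(r_hat = NA_real_, loglik = NA_real_, n = n, ok = FALSE))
  tab <- table(factor(g1[keep], levels = 1:3),
               factor(g2[keep], levels = 1:3))
  .rf_em(tab, tol, max_iter, r_init)
}

.rf_em <- function(tab, tol = 1e-8, max_iter = 200L, r_init = 0.25) {
  n <- sum(tab)
  ## recombinant gametes contributed by each genotype pair (double het
  ## handled by EM)
  R <- rbind(c(0, 1, 2), c(1, NA, 1), c(2, 1, 0))
  fixed <- sum(tab * R, na.rm = TRUE)
  n22 <- tab[2L, 2L]
  r <- r_init
  for (it in seq_len(max_iter)) {
    p <- (1 - r) / 2
    q <- r / 2
    e22 <- if (n22 > 0) n22 * 2 * q^2 / (p^2 + q^2) else 0
    r_new <- (fixed + e22) / (2 * n)
    r_new <- min(max(r_new, 0), 0.5)
    if (abs(r_new - r) < tol) { r <- r_new; break }
    r <- r_new
  }
  list(r_hat = r, loglik = .rf_loglik(tab, r), n = n, ok = TRUE)
}

## exact F2 joint genotype log-likelihood at recombination fraction r
.rf_loglik <- function(tab, r) {
  p <- (1 - r) / 2
  q <- r / 2
  P <- rbind(c(p^2, 2 * p * q, q^2),
             c(2 * p * q, 2 * (p^2 + q^2), 2 * p * q),
             c(q^2, 2 * p * q, p^2))
  sum(tab[tab > 0] * log(P[tab > 0]))
}

#' Kosambi map distance from a recombination fraction
#'
#' `d = 25 ln((1 + 2r) / (1 - 2r))` cM. `r = 0.5` maps to `Inf` with a
#' warning.
#' @param r recombination fraction(s) in [0, 0.5].
#' @return Distance(s) in cM.
#' @export
kosambi_cm <- function(r) {
  stopifnot(all(r >= 0 & r <= 0.5))
  if (any(r >= 0.5))
    warning("r = 0.5: infinite Kosambi distance", call. = FALSE)
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi: recombination fraction from cM
#' @param d distance(s) in cM.
#' @return Recombination fraction(s); round-trips with [kosambi_cm()] to
#'   better than 1e-12 over r in [0, 0.49].
#' @export
kosambi_r <- function(d) {
  stopifnot(all(d >= 0))
  0.5 * tanh(2 * d / 100)
}

#' Build a Kosambi linkage map from a bin genotype matrix
#'
#' Bins with more than `max_missing` unknown genotypes are excluded. Within
#' each chromosome, bins are ordered by physical position (reference
#' scaffolding; no de novo ordering), the adjacent-bin recombination
#' fraction is estimated by [estimate_rf_f2()], converted to a Kosambi cM
#' increment, and accumulated. Adjacent pairs with `r_hat > conflict_r` are
#' flagged as potential ordering conflicts.
#'
#' @param binmap a `bin_map` from [build_bins()].
#' @param max_missing per-bin missing-genotype threshold (default 0.2).
#' @param conflict_r adjacency diagnostic threshold.
#' @return An object of class `linkage_map`: data frame `chrom`, `bin`,
#'   `pos_cM`, `start_bp`, `end_bp`, `r_adj` (fraction to previous bin),
#'   `conflict`.
#' @export
build_linkage_map <- function(binmap, max_missing = 0.2, conflict_r = 0.3) {
  stopifnot(inherits(binmap, "bin_map"))
  miss <- rowMeans(is.na(binmap$geno))
  keep <- miss <= max_missing
  out <- list()
  for (ch in .chrom_order(binmap$bins$chrom)) {
    sel <- which(binmap$bins$chrom == ch & keep)
    if (length(sel) == 0L) {
      warning("chromosome ", ch, ": all bins filtered; empty linkage group",
              call. = FALSE)
      next
    }
    sel <- sel[order(binmap$bins$start_bp[sel])]
    r_adj <- rep(NA_real_, length(sel))
    d <- rep(0, length(sel))
    if (length(sel) > 1L) for (k in 2:length(sel)) {
      est <- estimate_rf_f2(binmap$geno[sel[k - 1L], ],
                            binmap$geno[sel[k], ])
      r_adj[k] <- est$r_hat
      d[k] <- if (!est$ok || is.na(est$r_hat)) 0 else
        kosambi_cm(min(est$r_hat, 0.4999))
    }
    out[[ch]] <- data.frame(chrom = ch, bin = binmap$bins$bin[sel],
                            pos_cM = cumsum(d),
                            start_bp = binmap$bins$start_bp[sel],
                            end_bp = binmap$bins$end_bp[sel],
                            r_adj = r_adj,
                            conflict = !is.na(r_adj) & r_adj > conflict_r,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(NULL)
  rownames(res) <- NULL
  class(res) <- c("linkage_map", "data.frame")
  res
}

#' Per-chromosome map summary with totals
#'
#' For a `linkage_map`, tabulates bin counts and genetic lengths per
#' chromosome plus a `Total` row. A plain data frame of per-chromosome rows
#' (first column chromosome labels, remaining columns numeric) is
#' re-tabulated the same way: the `Total` row is the column sums.
#'
#' @param x a `linkage_map` or a per-chromosome data frame.
#' @return Data frame of class `map_summary` ending in a `Total` row.
#' @export
map_summary <- function(x) {
  if (inherits(x, "linkage_map")) {
    per <- do.call(rbind, lapply(split(x, x$chrom)[.chrom_order(x$chrom)],
                                 function(d)
      data.frame(chrom = d$chrom[1L], n_bins = nrow(d),
                 length_cM = max(d$pos_cM), stringsAsFactors = FALSE)))
  } else {
    per <- as.data.frame(x)
    stopifnot(ncol(per) >= 2L)
    if (!is.character(per[[1L]]) && !is.factor(per[[1L]]))
      stop("first column must hold chromosome labels", call. = FALSE)
  }
  num <- vapply(per, is.numeric, TRUE)
  tot <- per[1L, , drop = FALSE]
  tot[[1L]] <- "Total"
  tot[num] <- lapply(per[num], sum)
  out <- rbind(per, tot)
  rownames(out) <- NULL
  class(out) <- c("map_summary", "data.frame")
  out
}

#' @export
print.linkage_map <- function(x, ...) {
  s <- map_summary(x)
  cat(sprintf("Linkage map: %d bins in %d groups, %.2f cM total\n",
              s$n_bins[nrow(s)], nrow(s) - 1L, s$length_cM[nrow(s)]))
  invisible(x)
}

#' Export a linkage map as TSV
#' @param map a `linkage_map`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_linkage_map <- function(map, file) {
  utils::write.table(
    map[, c("chrom", "bin", "pos_cM", "start_bp", "end_bp")],
    file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
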