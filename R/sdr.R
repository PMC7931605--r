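# Per-bin segregation-distortion chi-square tests at the zygotic
# (genotype, 1:2:1, df = 2) and gametic (allele, 1:1, df = 1) stages,
# direction labelling and SDR clustering.

#' Zygotic-stage chi-square test (1:2:1)
#'
#' Pearson chi-square of the genotype counts against the Mendelian
#' expectation (n/4, n/2, n/4), df = 2, no continuity correction.
#' @param n_AA,n_AB,n_BB genotype counts (vectorised).
#' @return Data frame `chi2`, `p`; `NA` for empty bins.
#' @export
zygotic_chi2 <- function(n_AA, n_AB, n_BB) {
  n <- n_AA + n_AB + n_BB
  e <- cbind(n / 4, n / 2, n / 4)
  o <- cbind(n_AA, n_AB, n_BB)
  chi2 <- rowSums((o - e)^2 / e)
  chi2[n == 0] <- NA_real_
  data.frame(chi2 = chi2,
             p = stats::pchisq(chi2, df = 2, lower.tail = FALSE))
}

#' Gametic-stage chi-square test (1:1 alleles)
#'
#' Tests allele counts `a = 2 n_AA + n_AB`, `b = 2 n_BB + n_AB` against 1:1
#' on the `2n` alleles, df = 1. Treating alleles as independent overstates
#' significance under true zygotic effects; this matches the construction
#' of the gametic track and is a documented caveat.
#' @inheritParams zygotic_chi2
#' @return Data frame `chi2`, `p`.
#' @export
gametic_chi2 <- function(n_AA, n_AB, n_BB) {
  a <- 2 * n_AA + n_AB
  b <- 2 * n_BB + n_AB
  tot <- a + b
  chi2 <- (a - tot / 2)^2 / (tot / 2) + (b - tot / 2)^2 / (tot / 2)
  chi2[tot == 0] <- NA_real_
  data.frame(chi2 = chi2,
             p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Per-bin segregation-distortion statistics
#'
#' Runs both stage tests on every bin of a bin map (unknown genotypes
#' excluded), labels the direction by the majority parental allele
#' (`female` when the female-parent allele frequency exceeds 0.5, `male`
#' when below, `none` at exact balance) and emits a signed
#' `-log10(p)` track (positive = female excess, negative = male excess;
#' magnitude from the smaller of the two stage p-values). A Bonferroni
#' column over the tested bins is included for reference; SDR calling uses
#' the raw p-values.
#'
#' @param binmap a `bin_map`.
#' @return Data frame of class `bin_distortion` with counts, `chi2_zyg`,
#'   `p_zyg`, `chi2_gam`, `p_gam`, `direction`, `signed_logp`,
#'   `p_zyg_bonf`, `p_gam_bonf`.
#' @export
bin_distortion <- function(binmap) {
  stopifnot(inherits(binmap, "bin_map"))
  g <- binmap$geno
  n_AA <- rowSums(g == 1L, na.rm = TRUE)
  n_AB <- rowSums(g == 2L, na.rm = TRUE)
  n_BB <- rowSums(g == 3L, na.rm = TRUE)
  zyg <- zygotic_chi2(n_AA, n_AB, n_BB)
  gam <- gametic_chi2(n_AA, n_AB, n_BB)
  fa <- (2 * n_AA + n_AB) / (2 * (n_AA + n_AB + n_BB))
  direction <- ifelse(fa > 0.5, "female", ifelse(fa < 0.5, "male", "none"))
  pmin2 <- pmin(zyg$p, gam$p)
  sgn <- ifelse(direction == "male", -1, 1)
  m <- sum(!is.na(zyg$p))
  out <- data.frame(binmap$bins, n_AA = n_AA, n_AB = n_AB, n_BB = n_BB,
                    chi2_zyg = zyg$chi2, p_zyg = zyg$p,
                    chi2_gam = gam$chi2, p_gam = gam$p,
                    direction = direction,
                    signed_logp = sgn * -log10(pmin2),
                    p_zyg_bonf = pmin(zyg$p * m, 1),
                    p_gam_bonf = pmin(gam$p * m, 1),
                    stringsAsFactors = FALSE)
  class(out) <- c("bin_distortion", "data.frame")
  out
}

#' Detect segregation-distortion regions
#'
#' An SDR is a maximal run of consecutive bins (map order, zero gap
#' tolerance) each significant at `alpha` at either stage. Single-bin runs
#' count. The region direction is the modal bin direction.
#'
#' @param distortion a `bin_distortion` data frame.
#' @param alpha significance threshold on the raw p-values (default 0.01).
#' @return Data frame `chrom`, `first_bin`, `last_bin`, `n_bins`,
#'   `start_bp`, `end_bp`, `span_bp`, `stages`, `direction`.
#' @export
detect_sdrs <- function(distortion, alpha = 0.01) {
  sig <- (!is.na(distortion$p_zyg) & distortion$p_zyg < alpha) |
    (!is.na(distortion$p_gam) & distortion$p_gam < alpha)
  out <- list()
  for (ch in .chrom_order(distortion$chrom)) {
    idx <- which(distortion$chrom == ch)
    idx <- idx[order(distortion$start_bp[idx])]
    s <- sig[idx]
    if (!any(s)) next
    r <- rle(s)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      rows <- idx[starts[k]:ends[k]]
      zs <- any(distortion$p_zyg[rows] < alpha, na.rm = TRUE)
      gs <- any(distortion$p_gam[rows] < alpha, na.rm = TRUE)
      dirs <- distortion$direction[rows]
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch,
        first_bin = distortion$bin[rows[1L]],
        last_bin = distortion$bin[rows[length(rows)]],
        n_bins = length(rows),
        start_bp = distortion$start_bp[rows[1L]],
        end_bp = distortion$end_bp[rows[length(rows)]],
        span_bp = distortion$end_bp[rows[length(rows)]] -
          distortion$start_bp[rows[1L]] + 1,
        stages = paste(c(if (zs) "zygotic", if (gs) "gametic"),
                       collapse = "+"),
        direction = names(which.max(table(dirs))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(), first_bin = integer(),
                      last_bin = integer(), n_bins = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      span_bp = numeric(), stages = character(),
                      direction = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
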