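# Internal helpers shared across modules.
#
# Genotypes are stored as integers throughout: 1 = AA (homozygous for the
# female-parent allele), 2 = AB (heterozygous), 3 = BB (homozygous for the
# male-parent allele), NA = unknown. Character export codes are A/H/B/U.

.GENO_LEVELS <- c("AA", "AB", "BB")
.GENO_CHAR <- c("A", "H", "B")

geno_to_char <- function(g) {
  out <- rep("U", length(g))
  ok <- !is.na(g)
  out[ok] <- .GENO_CHAR[g[ok]]
  out
}

char_to_geno <- function(ch) {
  g <- match(ch, .GENO_CHAR)
  g[ch == "U"] <- NA_integer_
  g
}

# x/z regression codes for an F2 genotype: x = +1/0/-1 for AA/AB/BB,
# z = 1 iff AB. Unknown genotypes give NA in both.
#' F2 genotype regression codes
#'
#' Converts integer-coded F2 genotypes into the additive and dominance
#' regression codes used by the QTL scan: `x` = +1, 0, -1 for AA, AB, BB and
#' `z` = 1 for AB, 0 otherwise. Unknown genotypes (`NA`) yield `NA` codes and
#' the corresponding individuals are dropped bin-wise by the scan.
#'
#' @param g integer vector of genotypes (1 = AA, 2 = AB, 3 = BB, NA = unknown).
#' @return A two-column matrix with columns `x` and `z`.
#' @export
genotype_codes <- function(g) {
  x <- c(1, 0, -1)[g]
  z <- c(0, 1, 0)[g]
  cbind(x = x, z = z)
}

.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          lower_open = FALSE, upper_open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  lo_ok <- if (lower_open) x > lower else x >= lower
  hi_ok <- if (upper_open) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(sprintf("'%s' = %g is outside its valid range", name, x),
         call. = FALSE)
  invisible(x)
}

# vcfR accessors drop to a named vector for single-record files
.as_matrix_rows <- function(x) {
  if (is.null(dim(x))) t(x) else x
}

# stable ordering of chromosome labels: numeric suffix when present
.chrom_order <- function(ch) {
  u <- unique(ch)
  num <- suppressWarnings(as.numeric(sub("^[^0-9]*", "", u)))
  u[order(is.na(num), num, u)]
}
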