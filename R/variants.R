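# Parent-informative SNP selection and progeny allele-depth encoding
# from VCF input (read through vcfR).

#' Select parent-informative SNPs from a VCF
#'
#' Keeps exactly the loci where both parents carry called homozygous
#' genotypes for different alleles, the site is a bi-allelic SNP, QUAL >= 20
#' and INFO/MQ >= 20 (both thresholds inclusive). Sites with a heterozygous
#' or missing parental call, a missing MQ field, indel alleles or duplicated
#' positions are dropped. The female parent's allele is read off its
#' genotype, so it may be either REF or ALT.
#'
#' @param vcf a `vcfR` object ([vcfR::read.vcfR()]) or a path to a VCF file.
#' @param parents length-2 character: female then male parent sample IDs.
#' @param min_qual,min_mq inclusive quality thresholds.
#' @return A `marker_set` data frame with columns `chrom`, `pos`,
#'   `allele_female`, `allele_male`, `qual`, `mq`, `ref_is_female`, sorted by
#'   (chrom, pos).
#' @export
select_informative_snps <- function(vcf, parents, min_qual = 20,
                                    min_mq = 20) {
  if (is.character(vcf))
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  stopifnot(length(parents) == 2L)
  samples <- colnames(vcf@gt)[-1L]
  if (!all(parents %in% samples))
    stop("parent sample(s) not found in VCF header: ",
         paste(setdiff(parents, samples), collapse = ", "), call. = FALSE)

  fix <- .as_matrix_rows(vcfR::getFIX(vcf))
  gt <- .as_matrix_rows(vcfR::extract.gt(vcf, element = "GT"))
  mq <- suppressWarnings(vcfR::extract.info(vcf, element = "MQ",
                                            as.numeric = TRUE))
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))

  gf <- gsub("|", "/", gt[, parents[1L]], fixed = TRUE)
  gm <- gsub("|", "/", gt[, parents[2L]], fixed = TRUE)
  hom <- c("0/0", "1/1")
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")

  keep <- snp &
    !is.na(gf) & !is.na(gm) & gf %in% hom & gm %in% hom & gf != gm &
    !is.na(qual) & qual >= min_qual &
    !is.na(mq) & mq >= min_mq
  keep[is.na(keep)] <- FALSE

  ref_is_female <- gf == "0/0"
  out <- data.frame(
    chrom = fix[keep, "CHROM"],
    pos = as.integer(fix[keep, "POS"]),
    allele_female = ifelse(ref_is_female[keep], ref[keep], alt[keep]),
    allele_male = ifelse(ref_is_female[keep], alt[keep], ref[keep]),
    qual = qual[keep],
    mq = mq[keep],
    ref_is_female = ref_is_female[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(match(out$chrom, .chrom_order(out$chrom)), out$pos), ,
             drop = FALSE]
  dup <- duplicated(out[, c("chrom", "pos")])
  out <- out[!dup, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_set", "data.frame")
  out
}

#' Encode progeny observations as parental-allele depths
#'
#' Orients each progeny allele-depth (AD) pair onto the parental alleles:
#' `n_A` counts reads supporting the female-parent allele and `n_B` the
#' male-parent allele, regardless of which is REF. Records without an AD
#' field fall back to genotype pseudo-depths (hom -> (2,0)/(0,2), het ->
#' (1,1)) and are flagged so downstream emission models can inflate their
#' uncertainty. Markers absent from the VCF are recorded as missing with a
#' warning.
#'
#' @param vcf a `vcfR` object or VCF path (progeny columns present).
#' @param markers a `marker_set` from [select_informative_snps()].
#' @param progeny character vector of progeny sample IDs; default all samples
#'   except `parents`.
#' @param parents parent IDs to exclude when `progeny` is `NULL`.
#' @return An `f2_obs` object (see [simulate_observations()]) with attribute
#'   `pseudo_depth`, a logical matrix marking genotype-derived cells.
#' @export
encode_observations <- function(vcf, markers, progeny = NULL,
                                parents = NULL) {
  if (is.character(vcf))
    vcf <- vcfR::read.vcfR(vcf, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1L]
  if (is.null(progeny))
    progeny <- setdiff(samples, parents)
  if (!all(progeny %in% samples))
    stop("progeny sample(s) not in VCF: ",
         paste(setdiff(progeny, samples), collapse = ", "), call. = FALSE)

  fix <- .as_matrix_rows(vcfR::getFIX(vcf))
  key_vcf <- paste(fix[, "CHROM"], fix[, "POS"])
  key_mk <- paste(markers$chrom, markers$pos)
  row <- match(key_mk, key_vcf)
  if (anyNA(row))
    warning(sum(is.na(row)), " marker(s) absent from the progeny VCF; ",
            "recorded as missing", call. = FALSE)

  n_mk <- nrow(markers)
  n_ind <- length(progeny)
  n_A <- n_B <- matrix(0L, nrow = n_ind, ncol = n_mk,
                       dimnames = list(progeny, NULL))
  pseudo <- matrix(FALSE, nrow = n_ind, ncol = n_mk,
                   dimnames = list(progeny, NULL))

  has_ad <- grepl("AD", unlist(vcf@gt[, "FORMAT"]), fixed = TRUE)
  ad <- if (any(has_ad))
    .as_matrix_rows(vcfR::extract.gt(vcf, element = "AD")) else NULL
  gt <- .as_matrix_rows(vcfR::extract.gt(vcf, element = "GT"))

  ok <- which(!is.na(row))
  vrow <- row[ok]
  for (j in seq_along(progeny)) {
    s <- progeny[j]
    adv <- if (!is.null(ad)) ad[vrow, s] else rep(NA_character_, length(vrow))
    gtv <- gsub("|", "/", gt[vrow, s], fixed = TRUE)
    have_ad <- !is.na(adv) & adv != "." & grepl(",", adv, fixed = TRUE)
    ref_d <- alt_d <- integer(length(vrow))
    if (any(have_ad)) {
      parts <- strsplit(adv[have_ad], ",", fixed = TRUE)
      ref_d[have_ad] <- as.integer(vapply(parts, `[`, "", 1L))
      alt_d[have_ad] <- as.integer(vapply(parts, `[`, "", 2L))
    }
    fb <- !have_ad & !is.na(gtv) & gtv %in% c("0/0", "0/1", "1/0", "1/1")
    if (any(fb)) {
      ref_d[fb] <- c("0/0" = 2L, "0/1" = 1L, "1/0" = 1L, "1/1" = 0L)[gtv[fb]]
      alt_d[fb] <- 2L - ref_d[fb]
      pseudo[j, ok[fb]] <- TRUE
    }
    rf <- markers$ref_is_female[ok]
    n_A[j, ok] <- ifelse(rf, ref_d, alt_d)
    n_B[j, ok] <- ifelse(rf, alt_d, ref_d)
  }

  structure(list(markers = as.data.frame(markers), n_A = n_A, n_B = n_B),
            class = "f2_obs", pseudo_depth = pseudo)
}
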