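# Plain-text exporters for simulated populations: minimal VCF 4.2
# (GT:AD, INFO/MQ), phenotype CSV and truth JSON.

#' Write simulated observations as a minimal VCF 4.2
#'
#' Emits two homozygous parent columns followed by one column per progeny,
#' with `GT:AD` genotype fields and a site-level `INFO/MQ`. REF/ALT
#' orientation follows the simulated `ref_is_female` flag so that roughly
#' half of the markers have the female allele as ALT, exercising the
#' orientation logic of the reader.
#'
#' @param obs an `f2_obs` object from [simulate_observations()].
#' @param file output path.
#' @param parents names of the two parent sample columns (female, male).
#' @param parent_depth depth written for the homozygous parent calls.
#' @param qual QUAL value written for every site.
#' @param mq INFO/MQ value written for every site.
#' @param chrom_lengths optional named vector for `##contig` headers.
#' @return `file`, invisibly.
#' @export
write_f2_vcf <- function(obs, file, parents = c("P_female", "P_male"),
                         parent_depth = 30L, qual = 60, mq = 60,
                         chrom_lengths = NULL) {
  stopifnot(inherits(obs, "f2_obs"), length(parents) == 2L)
  mk <- obs$markers
  n_ind <- nrow(obs$n_A)
  ref <- ifelse(mk$ref_is_female, mk$allele_female, mk$allele_male)
  alt <- ifelse(mk$ref_is_female, mk$allele_male, mk$allele_female)

  hdr <- c("##fileformat=VCFv4.2",
           paste0("##source=binqtl-", as.character(utils::packageVersion("binqtl"))))
  if (!is.null(chrom_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  hdr <- c(hdr,
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="RMS mapping quality">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">')

  ind_names <- rownames(obs$n_A)
  if (is.null(ind_names)) ind_names <- sprintf("F2_%03d", seq_len(n_ind))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", parents, ind_names),
                      collapse = "\t"))

  ## parent columns (female is REF when ref_is_female)
  fem <- ifelse(mk$ref_is_female,
                sprintf("0/0:%d,0", parent_depth),
                sprintf("1/1:0,%d", parent_depth))
  mal <- ifelse(mk$ref_is_female,
                sprintf("1/1:0,%d", parent_depth),
                sprintf("0/0:%d,0", parent_depth))

  ## progeny columns: AD is (ref, alt); naive GT from counts
  n_ref <- t(ifelse(matrix(mk$ref_is_female, nrow = n_ind,
                           ncol = nrow(mk), byrow = TRUE),
                    obs$n_A, obs$n_B))  # markers x individuals
  n_alt <- t(obs$n_A + obs$n_B) - n_ref
  gt <- matrix("./.", nrow = nrow(mk), ncol = n_ind)
  gt[n_ref > 0 & n_alt == 0] <- "0/0"
  gt[n_ref > 0 & n_alt > 0] <- "0/1"
  gt[n_ref == 0 & n_alt > 0] <- "1/1"
  cells <- matrix(sprintf("%s:%d,%d", gt, n_ref, n_alt),
                  nrow = nrow(mk))
  body <- paste(mk$chrom, mk$pos, ".", ref, alt, qual, "PASS",
                sprintf("MQ=%g", mq), "GT:AD", fem, mal, sep = "\t")
  body <- paste(body, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Write a long-format phenotype CSV (`id,trait,value`)
#' @param phenotypes data frame as returned by [simulate_phenotypes()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_phenotypes <- function(phenotypes, file) {
  utils::write.csv(phenotypes[, c("id", "trait", "value")], file,
                   row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Write simulator ground truth as JSON
#'
#' Stores true genotypes (A/H/B codes), crossover positions and phenotypes
#' for later recovery checks.
#' @param truth an `f2_truth` object.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_truth_json <- function(truth, file) {
  stopifnot(inherits(truth, "f2_truth"))
  obj <- list(
    markers = truth$markers,
    genotypes = apply(truth$geno, 1L, function(g)
      paste(geno_to_char(g), collapse = "")),
    crossovers = truth$crossovers,
    phenotypes = truth$phenotypes,
    seed = truth$config$seed
  )
  jsonlite::write_json(obj, file, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Export a marker table as TSV
#' @param markers a `marker_set` (or the `markers` element of a simulation).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_marker_table <- function(markers, file) {
  df <- data.frame(chrom = markers$chrom, pos = markers$pos,
                   allele_A = markers$allele_female,
                   allele_B = markers$allele_male,
                   qual = if ("qual" %in% names(markers)) markers$qual else NA,
                   mq = if ("mq" %in% names(markers)) markers$mq else NA)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
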