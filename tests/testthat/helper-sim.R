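# Shared fixture builders (everything generated in code at test time).

## Small fast simulation config.
small_config <- function(..., seed = 101) {
  binqtl::sim_config(chrom_lengths_bp = rep(20e6, 2),
                     n_markers_per_chrom = 40, n_individuals = 60,
                     seed = seed, ...)
}

## Treat the simulator's true marker genotypes as a one-marker-per-bin
## bin map (used by scan/threshold calibration tests, which exercise the
## scan machinery rather than the HMM).
truth_binmap <- function(truth) {
  mk <- truth$markers
  bins <- data.frame(bin = seq_len(nrow(mk)), chrom = mk$chrom,
                     start_bp = mk$pos, end_bp = mk$pos)
  structure(list(bins = bins, geno = t(truth$geno), min_bin_bp = 0),
            class = "bin_map")
}

## Hand-built bin map from an explicit genotype matrix (bins x individuals).
manual_binmap <- function(geno, chrom = "chr1", start = NULL, end = NULL) {
  nb <- nrow(geno)
  if (is.null(start)) start <- seq(1, by = 1e6, length.out = nb)
  if (is.null(end)) end <- start + 1e6 - 1
  structure(list(bins = data.frame(bin = seq_len(nb),
                                   chrom = rep(chrom, length.out = nb),
                                   start_bp = start, end_bp = end),
                 geno = geno, min_bin_bp = 0),
            class = "bin_map")
}

## A small literal VCF written to `path` for reader tests; returns path.
write_test_vcf <- function(path, records,
                           samples = c("mom", "dad", "k1", "k2"),
                           format = "GT:AD") {
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=MQ,Number=1,Type=Float,Description="MQ">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
           '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="AD">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, qual, mq, ..., format = "GT:AD") {
  cells <- c(...)
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS",
          if (is.na(mq)) "." else paste0("MQ=", mq), format, cells),
        collapse = "\t")
}
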