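# Orchestration: run the stages end to end from a single configuration,
# writing plain-text artifacts with provenance headers, plus the
# publication-style per-chromosome map summary report.

#' Pipeline configuration
#'
#' Builds (and lightly validates) the configuration consumed by
#' [run_pipeline()]. `config` may also be a path to a YAML file with the
#' same field names.
#'
#' @param vcf path to the input VCF (ignored when `simulate` is set).
#' @param phenotypes path to a phenotype CSV (`id,trait,value`).
#' @param out_dir output directory.
#' @param parents length-2 character (female, male sample IDs).
#' @param trait trait to analyse (default: first trait in the table).
#' @param simulate `NULL`, or a [sim_config()] (then the pipeline generates
#'   its own input VCF/phenotypes in `out_dir`).
#' @param seed global seed recorded in every output header.
#' @param hmm an [hmm_params()].
#' @param n_perm,alpha_qtl permutation count and genome-wide level for the
#'   QTL threshold.
#' @param alpha_sdr SDR significance level.
#' @param k_pools,window_kb,step_kb,min_depth GradedPool-Seq settings.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcf = NULL, phenotypes = NULL, out_dir = ".",
                            parents = c("P_female", "P_male"),
                            trait = NULL, simulate = NULL, seed = 1L,
                            hmm = hmm_params(), n_perm = 1000L,
                            alpha_qtl = 0.05, alpha_sdr = 0.01,
                            k_pools = 4L, window_kb = 400, step_kb = 100,
                            min_depth = 10) {
  if (is.character(hmm)) stop("'hmm' must be an hmm_params object")
  if (length(parents) != 2L || parents[1L] == parents[2L])
    stop("'parents' must be two distinct sample IDs", call. = FALSE)
  structure(list(vcf = vcf, phenotypes = phenotypes, out_dir = out_dir,
                 parents = parents, trait = trait, simulate = simulate,
                 seed = as.integer(seed), hmm = hmm,
                 n_perm = as.integer(n_perm), alpha_qtl = alpha_qtl,
                 alpha_sdr = alpha_sdr, k_pools = as.integer(k_pools),
                 window_kb = window_kb, step_kb = step_kb,
                 min_depth = min_depth),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments (`simulate` may be a mapping of [sim_config()] fields).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate) && !inherits(y$simulate, "sim_config"))
    y$simulate <- do.call(sim_config, y$simulate)
  if (!is.null(y$hmm)) y$hmm <- do.call(hmm_params, y$hmm)
  do.call(pipeline_config, y)
}

.provenance <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(config[setdiff(names(config), "out_dir")], tmp)
  hash <- unname(tools::md5sum(tmp))
  sprintf("# binqtl %s | seed=%d | config=%s",
          as.character(utils::packageVersion("binqtl")), config$seed, hash)
}

.write_with_header <- function(df, file, header, sep = ",") {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Run the full analysis pipeline
#'
#' Executes, as requested: simulate (optional) -> informative-SNP selection
#' -> allele-depth encoding -> HMM block decoding -> crossover calling ->
#' bin construction -> linkage map -> segregation-distortion scan -> QTL
#' scan with permutation threshold -> GradedPool-Seq scan. Every output
#' file starts with a provenance header (`# binqtl <version> | seed |
#' config hash`), so identical configuration and seed give identical files.
#'
#' @param config a [pipeline_config()] (or a YAML path).
#' @param stages subset of
#'   `c("simulate", "filter", "binmap", "map", "sdr", "qtl", "gps", "report")`.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "filter", "binmap", "map",
                                    "sdr", "qtl", "gps", "report")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- .provenance(config)
  out <- list(config = config)
  t0 <- proc.time()[["elapsed"]]
  say <- function(...) message(sprintf("[%6.1fs] ",
                                       proc.time()[["elapsed"]] - t0), ...)
  pth <- function(f) file.path(config$out_dir, f)

  vcf_path <- config$vcf
  phe_path <- config$phenotypes
  if ("simulate" %in% stages && !is.null(config$simulate)) {
    say("simulate: F2 population")
    truth <- simulate_f2_population(config$simulate)
    obs0 <- simulate_observations(truth, config$simulate$mean_depth,
                                  config$simulate$error_rate,
                                  config$simulate$missing_extra)
    vcf_path <- pth("simulated.vcf")
    write_f2_vcf(obs0, vcf_path,
                 chrom_lengths = config$simulate$chrom_lengths_bp)
    if (!is.null(truth$phenotypes)) {
      phe_path <- pth("phenotypes.csv")
      write_phenotypes(truth$phenotypes, phe_path)
    }
    write_truth_json(truth, pth("truth.json"))
    out$truth <- truth
    config$parents <- c("P_female", "P_male")
  }

  if ("filter" %in% stages) {
    if (is.null(vcf_path) || !file.exists(vcf_path))
      stop("input VCF not found: ", vcf_path, call. = FALSE)
    say("filter: parent-informative SNPs")
    vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
    out$markers <- select_informative_snps(vcf, config$parents)
    out$obs <- encode_observations(vcf, out$markers,
                                   parents = config$parents)
    write_marker_table(out$markers, pth("markers.tsv"))
  }

  if ("binmap" %in% stages) {
    if (is.null(out$obs)) stop("binmap needs the filter stage", call. = FALSE)
    say("binmap: HMM decoding and bin construction")
    out$blocks <- decode_population(out$obs, config$hmm)
    out$crossovers <- call_crossovers(out$blocks)
    out$binmap <- build_bins(out$blocks, out$obs$markers,
                             config$hmm$min_bin_bp)
    write_bin_map(out$binmap, pth("bins.tsv"))
    xo <- out$crossovers
    bed <- data.frame(chrom = xo$chrom, start = xo$left_bp,  # 0-based, half-open
                      end = xo$right_bp, name = paste0("ind", xo$individual))
    utils::write.table(bed, pth("crossovers.bed"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    .write_with_header(crossover_counts(xo, nrow(out$obs$n_A)),
                       pth("events_per_individual.csv"), hdr)
  }

  if ("map" %in% stages) {
    if (is.null(out$binmap)) stop("map needs the binmap stage", call. = FALSE)
    say("map: linkage map")
    out$map <- build_linkage_map(out$binmap)
    write_linkage_map(out$map, pth("linkage_map.tsv"))
  }

  if ("sdr" %in% stages) {
    if (is.null(out$binmap)) stop("sdr needs the binmap stage", call. = FALSE)
    say("sdr: segregation-distortion scan")
    out$distortion <- bin_distortion(out$binmap)
    out$sdrs <- detect_sdrs(out$distortion, config$alpha_sdr)
    .write_with_header(out$distortion, pth("distortion.csv"), hdr)
    if (nrow(out$sdrs) > 0) {
      bed <- data.frame(chrom = out$sdrs$chrom,
                        start = out$sdrs$start_bp - 1L,
                        end = out$sdrs$end_bp,
                        name = out$sdrs$direction)
      utils::write.table(bed, pth("sdr.bed"), sep = "\t",
                         row.names = FALSE, col.names = FALSE, quote = FALSE)
    }
  }

  phenos <- NULL
  if (!is.null(phe_path)) {
    if (!file.exists(phe_path))
      stop("phenotype file not found: ", phe_path, call. = FALSE)
    phenos <- utils::read.csv(phe_path)
  }
  trait <- config$trait
  if (is.null(trait) && !is.null(phenos)) trait <- phenos$trait[1L]

  if ("qtl" %in% stages) {
    if (is.null(out$binmap)) stop("qtl needs the binmap stage", call. = FALSE)
    if (is.null(phenos)) stop("qtl needs a phenotype table", call. = FALSE)
    say("qtl: LOD scan, ", config$n_perm, " permutations")
    y <- .trait_vector(phenos, trait, ncol(out$binmap$geno))
    out$scan <- scan_cim(y, out$binmap)
    out$threshold <- permutation_threshold(y, out$binmap, config$n_perm,
                                           config$alpha_qtl,
                                           seed = config$seed)
    peaks <- find_qtl_peaks(out$scan, out$threshold)
    out$qtl <- if (length(peaks))
      fit_qtl(y, out$binmap, peaks, out$scan, trait = trait)
    .write_with_header(out$scan, pth("qtl_scan.csv"), hdr)
    writeLines(c(hdr, sprintf("trait=%s threshold=%.4f n_perm=%d alpha=%g",
                              trait, out$threshold$threshold,
                              config$n_perm, config$alpha_qtl)),
               pth("qtl_threshold.txt"))
    if (!is.null(out$qtl))
      .write_with_header(out$qtl, pth("qtl_table.csv"), hdr)
  }

  if ("gps" %in% stages) {
    if (is.null(out$obs)) stop("gps needs the filter stage", call. = FALSE)
    if (is.null(phenos)) stop("gps needs a phenotype table", call. = FALSE)
    say("gps: graded pools and Ridit scan")
    ph <- phenos[phenos$trait == trait, c("id", "value")]
    pools <- build_pools(ph, config$k_pools)
    pooled <- pool_allele_counts(out$obs, pools, config$min_depth)
    rid <- ridit_scan(pooled)
    out$gps <- window_scan(rid, window_bp = config$window_kb * 1e3,
                           step_bp = config$step_kb * 1e3)
    out$pools <- pools
    .write_with_header(pools$ranges, pth("gps_pools.csv"), hdr)
    .write_with_header(rid, pth("gps_ridit.csv"), hdr)
    if (!is.null(out$gps$windows)) {
      w <- out$gps$windows[!is.na(out$gps$windows$score), ]
      utils::write.table(
        data.frame(w$chrom, w$start - 1L, w$end, w$score),
        pth("gps_windows.bedgraph"), sep = "\t", row.names = FALSE,
        col.names = FALSE, quote = FALSE)
    }
    if (!is.null(out$gps$candidate)) {
      cd <- out$gps$candidate
      utils::write.table(
        data.frame(cd$chrom, cd$start - 1L, cd$end, "candidate"),
        pth("gps_candidate.bed"), sep = "\t", row.names = FALSE,
        col.names = FALSE, quote = FALSE)
    }
  }

  if ("report" %in% stages && !is.null(out$map)) {
    say("report: map summary")
    rep <- report_summary(out$map,
                          n_events = if (!is.null(out$crossovers))
                            nrow(out$crossovers),
                          n_individuals = if (!is.null(out$obs))
                            nrow(out$obs$n_A),
                          binmap = out$binmap)
    .write_with_header(rep$table, pth("map_summary.csv"), hdr)
    writeLines(c(hdr, utils::capture.output(print(rep))),
               pth("report.txt"))
    out$report <- rep
  }
  say("done")
  invisible(out)
}

.trait_vector <- function(phenos, trait, n_ind) {
  ph <- phenos[phenos$trait == trait, , drop = FALSE]
  id <- suppressWarnings(as.integer(ph$id))
  if (anyNA(id)) id <- match(ph$id, unique(phenos$id))
  y <- rep(NA_real_, n_ind)
  ok <- !is.na(id) & id >= 1 & id <= n_ind
  y[id[ok]] <- ph$value[ok]
  y
}

#' Publication-style map summary report
#'
#' Per-chromosome bin counts and genetic lengths with a `Total` row
#' (column sums), plus derived quantities: mean recombination events per
#' individual (`total events / individuals`) and mean bin size
#' (`covered length / bin count`). Accepts either a fitted `linkage_map` or
#' a pre-tabulated per-chromosome data frame (first column chromosome,
#' numeric columns summed into the total row) for re-tabulation.
#'
#' @param map a `linkage_map` or per-chromosome data frame.
#' @param n_events total recombination events (optional).
#' @param n_individuals population size (optional).
#' @param binmap the `bin_map` (optional; supplies covered length).
#' @param covered_mb covered genome length in Mb (alternative to `binmap`).
#' @return List of class `map_report`: `table` (a [map_summary()]),
#'   `events_per_individual`, `mean_bin_kb`.
#' @export
report_summary <- function(map, n_events = NULL, n_individuals = NULL,
                           binmap = NULL, covered_mb = NULL) {
  tab <- map_summary(map)
  epi <- if (!is.null(n_events) && !is.null(n_individuals))
    n_events / n_individuals
  if (is.null(covered_mb) && !is.null(binmap)) {
    b <- binmap$bins
    covered_mb <- sum(b$end_bp - b$start_bp + 1) / 1e6
  }
  n_bins <- tab$n_bins[nrow(tab)]
  mbk <- if (!is.null(covered_mb) && !is.null(n_bins))
    covered_mb * 1e3 / n_bins
  structure(list(table = tab, events_per_individual = epi,
                 mean_bin_kb = mbk), class = "map_report")
}

#' @export
print.map_report <- function(x, ...) {
  print.data.frame(x$table, row.names = FALSE, digits = 6)
  if (!is.null(x$events_per_individual))
    cat(sprintf("Mean recombination events per individual: %.1f\n",
                x$events_per_individual))
  if (!is.null(x$mean_bin_kb))
    cat(sprintf("Mean bin size: %.1f Kb\n", x$mean_bin_kb))
  invisible(x)
}
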