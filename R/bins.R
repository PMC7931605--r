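# Genome-wide recombination-bin construction from decoded genotype blocks.
# Bins are delimited by the pooled crossover-breakpoint midpoints of the
# whole population; candidate bins shorter than `min_bin_bp` are merged into
# a flanking neighbour to avoid false recombination.

#' Build a bin genotype matrix from decoded blocks
#'
#' Per chromosome, breakpoint midpoints from every individual are pooled,
#' sorted and deduplicated; consecutive breakpoints delimit candidate bins
#' spanning the marker-covered interval (first to last marker). A candidate
#' bin shorter than `min_bin_bp` is merged into whichever flanking bin
#' shares the larger number of identical individual genotypes (tie: left
#' neighbour). Each (bin, individual) genotype is the state of the
#' individual's block covering the larger share of the bin (ties toward the
#' left block); all-missing stretches propagate as unknown.
#'
#' @param blocks a `genotype_blocks` data frame from [decode_population()].
#' @param markers marker table with `chrom` and `pos` (defines the covered
#'   span per chromosome).
#' @param min_bin_bp minimum retained bin length (bp), default 30 kb.
#' @return An object of class `bin_map`: list with `bins` (data frame `bin`,
#'   `chrom`, `start_bp`, `end_bp`) and `geno` (bins x individuals integer
#'   matrix, NA = unknown).
#' @export
build_bins <- function(blocks, markers, min_bin_bp = 30000) {
  .check_number(min_bin_bp, "min_bin_bp", lower = 0)
  xo <- call_crossovers(blocks)
  n_ind <- max(blocks$individual)
  chroms <- .chrom_order(markers$chrom)

  bins_list <- list()
  geno_list <- list()
  for (ch in chroms) {
    mpos <- markers$pos[markers$chrom == ch]
    lo <- min(mpos); hi <- max(mpos)
    mids <- sort(unique(xo$mid_bp[xo$chrom == ch]))
    mids <- mids[mids > lo & mids < hi]
    start <- c(lo, floor(mids) + 1)
    end <- c(floor(mids), hi)

    bl <- blocks[blocks$chrom == ch, , drop = FALSE]
    geno <- .assign_bin_geno(bl, n_ind, start, end)

    ## merge short candidate bins
    repeat {
      len <- end - start + 1
      short <- which(len < min_bin_bp)
      if (length(short) == 0L || length(start) == 1L) break
      i <- short[which.min(len[short])]
      nb <- c(if (i > 1L) i - 1L, if (i < length(start)) i + 1L)
      if (length(nb) == 2L) {
        agree <- vapply(nb, function(j) {
          a <- geno[i, ]; b <- geno[j, ]
          sum((is.na(a) & is.na(b)) | (!is.na(a) & !is.na(b) & a == b))
        }, 0L)
        j <- if (agree[2L] > agree[1L]) nb[2L] else nb[1L]
      } else j <- nb
      k <- min(i, j); l <- max(i, j)
      new_start <- start[k]; new_end <- end[l]
      start <- start[-l]; end <- end[-l]
      start[k] <- new_start; end[k] <- new_end
      merged <- .assign_bin_geno(bl, n_ind, new_start, new_end)
      geno <- geno[-l, , drop = FALSE]
      geno[k, ] <- merged
    }
    bins_list[[ch]] <- data.frame(chrom = ch, start_bp = start,
                                  end_bp = end, stringsAsFactors = FALSE)
    geno_list[[ch]] <- geno
  }
  bins <- do.call(rbind, bins_list)
  bins <- cbind(bin = seq_len(nrow(bins)), bins)
  rownames(bins) <- NULL
  geno <- do.call(rbind, geno_list)
  rownames(geno) <- NULL
  structure(list(bins = bins, geno = geno, min_bin_bp = min_bin_bp),
            class = "bin_map")
}

## majority-by-length state per (bin, individual); ties toward the earlier
## (left) block. start/end may be vectors (one entry per bin).
.assign_bin_geno <- function(chrom_blocks, n_ind, start, end) {
  n_bins <- length(start)
  geno <- matrix(NA_integer_, n_bins, n_ind)
  for (ind in unique(chrom_blocks$individual)) {
    b <- chrom_blocks[chrom_blocks$individual == ind, , drop = FALSE]
    cover <- matrix(0, n_bins, 3L)
    unk <- rep(FALSE, n_bins)
    for (k in seq_len(nrow(b))) {
      ov <- pmin(end, b$end_bp[k]) - pmax(start, b$start_bp[k])
      hit <- ov >= 0
      if (!any(hit)) next
      if (b$state[k] == "unknown") {
        unk[hit] <- TRUE
      } else {
        s <- match(b$state[k], .GENO_LEVELS)
        ## + 1 bp so that zero-width overlaps (single marker) still count;
        ## earlier blocks win ties because which.max takes the first max.
        cover[hit, s] <- cover[hit, s] + ov[hit] + 1
      }
    }
    g <- rep(NA_integer_, n_bins)
    has <- rowSums(cover) > 0
    g[has] <- max.col(cover[has, , drop = FALSE], ties.method = "first")
    geno[, ind] <- g
  }
  if (n_bins == 1L) geno <- matrix(geno, 1L, n_ind)
  geno
}

#' @export
print.bin_map <- function(x, ...) {
  cat(sprintf("F2 bin map: %d bins x %d individuals on %d chromosomes\n",
              nrow(x$bins), ncol(x$geno), length(unique(x$bins$chrom))))
  cat(sprintf("  min bin length %s bp; %.1f%% unknown genotypes\n",
              format(x$min_bin_bp, big.mark = ","),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Summarise a bin map
#'
#' Reports, per chromosome and in total: bin count, min/mean/max bin size
#' and covered Mb.
#'
#' @param object a `bin_map`.
#' @param ... unused.
#' @return Data frame with one row per chromosome plus a `Total` row.
#' @export
summary.bin_map <- function(object, ...) {
  b <- object$bins
  len <- b$end_bp - b$start_bp + 1
  per <- do.call(rbind, lapply(.chrom_order(b$chrom), function(ch) {
    l <- len[b$chrom == ch]
    data.frame(chrom = ch, n_bins = length(l), min_kb = min(l) / 1e3,
               mean_kb = mean(l) / 1e3, max_kb = max(l) / 1e3,
               covered_mb = sum(l) / 1e6)
  }))
  tot <- data.frame(chrom = "Total", n_bins = sum(per$n_bins),
                    min_kb = min(len) / 1e3, mean_kb = mean(len) / 1e3,
                    max_kb = max(len) / 1e3,
                    covered_mb = sum(per$covered_mb))
  rbind(per, tot)
}

#' Export a bin map as TSV (A/H/B/U genotype codes)
#' @param binmap a `bin_map`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_bin_map <- function(binmap, file) {
  g <- apply(binmap$geno, 2L, geno_to_char)
  colnames(g) <- paste0("ind", seq_len(ncol(g)))
  df <- cbind(binmap$bins, as.data.frame(g, stringsAsFactors = FALSE))
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
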