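#' Configuration for the F2 population simulator
#'
#' Bundles and validates every parameter of the synthetic F2 cross. The
#' defaults emulate a resequencing-based mapping study: 200 individuals, 12
#' chromosomes of 25 Mb at 3 cM/Mb (a 900 cM genome), 100 parent-informative
#' markers per chromosome, 7x mean progeny depth and a 1% per-read miscall
#' rate.
#'
#' @param chrom_lengths_bp numeric vector of physical chromosome lengths (bp).
#' @param cm_per_mb genetic rate in cM/Mb, uniform along every chromosome.
#' @param n_markers_per_chrom number of markers placed (uniformly at random)
#'   on each chromosome.
#' @param n_individuals F2 population size.
#' @param mean_depth expected sequencing depth per marker per individual
#'   (Poisson mean, x).
#' @param error_rate per-read miscall probability (a read from an AA
#'   individual supports the B allele with this probability).
#' @param missing_extra additional probability that an observation is dropped
#'   (depth zeroed) on top of Poisson zeros.
#' @param distortion_loci `NULL` or a data frame with columns `chrom`,
#'   `pos_bp`, `w_A`, `w_B`, `stage` (`"gametic"` or `"zygotic"`). Survival
#'   weights are in (0, 1]: a gametic locus retains a gamete carrying allele
#'   A (resp. B) with probability `w_A` (resp. `w_B`), rejected gametes are
#'   redrawn; a zygotic locus retains a zygote with probability
#'   `w_A^nA * w_B^nB` where `nA`, `nB` count its alleles.
#' @param qtls `NULL` or a data frame with columns `chrom`, `pos_bp`, `a`
#'   (additive effect, trait units) and `d` (dominance effect). Each QTL acts
#'   through the simulated marker nearest its position.
#' @param noise_sd residual phenotype standard deviation.
#' @param baseline trait mean.
#' @param seed integer RNG seed; all randomness in [simulate_f2_population()]
#'   flows from it.
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_f2_population()], [simulate_observations()]
#' @export
sim_config <- function(chrom_lengths_bp = rep(25e6, 12),
                       cm_per_mb = 3,
                       n_markers_per_chrom = 100,
                       n_individuals = 200,
                       mean_depth = 7,
                       error_rate = 0.01,
                       missing_extra = 0,
                       distortion_loci = NULL,
                       qtls = NULL,
                       noise_sd = 1,
                       baseline = 0,
                       seed = 1L) {
  if (!is.numeric(chrom_lengths_bp) || length(chrom_lengths_bp) < 1L ||
      any(!is.finite(chrom_lengths_bp)) || any(chrom_lengths_bp <= 0))
    stop("'chrom_lengths_bp' must be positive finite lengths", call. = FALSE)
  .check_number(cm_per_mb, "cm_per_mb", lower = 0)
  .check_number(n_markers_per_chrom, "n_markers_per_chrom", lower = 1)
  .check_number(n_individuals, "n_individuals", lower = 1)
  .check_number(mean_depth, "mean_depth", lower = 0)
  .check_number(error_rate, "error_rate", lower = 0, upper = 0.5,
                upper_open = TRUE)
  .check_number(missing_extra, "missing_extra", lower = 0, upper = 1)
  .check_number(noise_sd, "noise_sd", lower = 0)
  .check_number(baseline, "baseline")
  .check_number(seed, "seed")

  chroms <- names(chrom_lengths_bp)
  if (is.null(chroms)) chroms <- paste0("chr", seq_along(chrom_lengths_bp))

  if (!is.null(distortion_loci)) {
    distortion_loci <- as.data.frame(distortion_loci)
    need <- c("chrom", "pos_bp", "w_A", "w_B", "stage")
    if (!all(need %in% names(distortion_loci)))
      stop("'distortion_loci' needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(!distortion_loci$stage %in% c("gametic", "zygotic")))
      stop("distortion stage must be 'gametic' or 'zygotic'", call. = FALSE)
    w <- c(distortion_loci$w_A, distortion_loci$w_B)
    if (any(!is.finite(w)) || any(w <= 0) || any(w > 1))
      stop("survival weights must lie in (0, 1]", call. = FALSE)
    if (any(!distortion_loci$chrom %in% chroms))
      stop("distortion locus on unknown chromosome", call. = FALSE)
  }
  if (!is.null(qtls)) {
    qtls <- as.data.frame(qtls)
    need <- c("chrom", "pos_bp", "a", "d")
    if (!all(need %in% names(qtls)))
      stop("'qtls' needs columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (any(!qtls$chrom %in% chroms))
      stop("QTL on unknown chromosome", call. = FALSE)
    for (i in seq_len(nrow(qtls))) {
      len <- chrom_lengths_bp[match(qtls$chrom[i], chroms)]
      if (!is.finite(qtls$pos_bp[i]) || qtls$pos_bp[i] < 1 ||
          qtls$pos_bp[i] > len)
        stop("QTL position off the chromosome", call. = FALSE)
    }
  }

  structure(list(
    chrom_lengths_bp = stats::setNames(as.numeric(chrom_lengths_bp), chroms),
    cm_per_mb = cm_per_mb,
    n_markers_per_chrom = as.integer(n_markers_per_chrom),
    n_individuals = as.integer(n_individuals),
    mean_depth = mean_depth,
    error_rate = error_rate,
    missing_extra = missing_extra,
    distortion_loci = distortion_loci,
    qtls = qtls,
    noise_sd = noise_sd,
    baseline = baseline,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate one gamete for a chromosome
#'
#' Meiosis without crossover interference: the crossover count is
#' Poisson(L/100) where L (cM) = `chrom_length_bp * cm_per_mb / 1e6`, and
#' crossover positions are uniform on the chromosome. The returned haplotype
#' alternates parental origin at each crossover, starting from a fair coin.
#' Gametic-stage distortion loci are applied by rejection sampling: a gamete
#' carrying allele A (resp. B) at the locus survives with probability `w_A`
#' (resp. `w_B`), and rejected gametes are redrawn, so the allele-B frequency
#' at the locus converges to `w_B / (w_A + w_B)`.
#'
#' Uses the current RNG state; seed via [set.seed()] or run through
#' [simulate_f2_population()].
#'
#' @param chrom_length_bp chromosome length (bp).
#' @param cm_per_mb genetic rate (cM/Mb).
#' @param distortion_loci optional data frame (see [sim_config()]) already
#'   restricted to gametic-stage loci on this chromosome.
#' @return A list with `breaks` (sorted crossover positions, bp) and
#'   `start_origin` (1 = female/A, 2 = male/B at position 0).
#' @export
simulate_gamete <- function(chrom_length_bp, cm_per_mb,
                            distortion_loci = NULL) {
  .check_number(chrom_length_bp, "chrom_length_bp", lower = 0,
                lower_open = TRUE)
  .check_number(cm_per_mb, "cm_per_mb", lower = 0)
  L_morgan <- chrom_length_bp * cm_per_mb / 1e6 / 100
  repeat {
    n_co <- stats::rpois(1L, L_morgan)
    breaks <- sort(stats::runif(n_co, 0, chrom_length_bp))
    gam <- list(breaks = breaks,
                start_origin = sample(c(1L, 2L), 1L))
    if (is.null(distortion_loci) || nrow(distortion_loci) == 0L)
      return(gam)
    w <- 1
    for (i in seq_len(nrow(distortion_loci))) {
      al <- gamete_origin(gam, distortion_loci$pos_bp[i])
      w <- w * if (al == 1L) distortion_loci$w_A[i] else
        distortion_loci$w_B[i]
    }
    if (stats::runif(1L) < w) return(gam)
  }
}

#' Parental origin of a gamete at given positions
#'
#' @param gamete a gamete from [simulate_gamete()].
#' @param pos positions (bp).
#' @return Integer vector, 1 = female-parent (A) allele, 2 = male-parent (B).
#' @export
gamete_origin <- function(gamete, pos) {
  flips <- findInterval(pos, gamete$breaks)
  origin <- (gamete$start_origin - 1L + flips) %% 2L + 1L
  as.integer(origin)
}

#' Simulate an F2 mapping population with ground truth
#'
#' Draws marker positions, simulates two independent gametes per chromosome
#' per individual (see [simulate_gamete()]), applies zygotic-stage selection
#' by rejection sampling on the affected chromosome pair, and (when QTLs are
#' configured) generates phenotypes via [simulate_phenotypes()]. Without
#' distortion, per-marker genotype frequencies converge to the Mendelian
#' 1:2:1.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `f2_truth`: list with `markers` (data frame
#'   `chrom`, `pos`, `allele_female`, `allele_male`, `ref_is_female`), `geno`
#'   (individuals x markers integer matrix, 1/2/3 = AA/AB/BB), `crossovers`
#'   (data frame `individual`, `chrom`, `gamete`, `pos_bp`), `phenotypes`
#'   (data frame or `NULL`), `genetic_values`, and `config`.
#' @export
simulate_f2_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  chroms <- names(config$chrom_lengths_bp)
  n_ind <- config$n_individuals

  ## marker placement: uniform random, unique, 1-based
  bases <- c("A", "C", "G", "T")
  mk <- lapply(chroms, function(ch) {
    len <- config$chrom_lengths_bp[ch]
    pos <- sort(sample.int(len, config$n_markers_per_chrom))
    fa <- sample(bases, length(pos), replace = TRUE)
    shift <- sample.int(3L, length(pos), replace = TRUE)
    ma <- bases[(match(fa, bases) - 1L + shift) %% 4L + 1L]
    data.frame(chrom = ch, pos = pos, allele_female = fa, allele_male = ma,
               ref_is_female = sample(c(TRUE, FALSE), length(pos),
                                      replace = TRUE),
               stringsAsFactors = FALSE)
  })
  markers <- do.call(rbind, mk)
  rownames(markers) <- NULL

  dist_gam <- dist_zyg <- NULL
  if (!is.null(config$distortion_loci)) {
    dl <- config$distortion_loci
    dist_gam <- dl[dl$stage == "gametic", , drop = FALSE]
    dist_zyg <- dl[dl$stage == "zygotic", , drop = FALSE]
  }

  geno <- matrix(NA_integer_, nrow = n_ind, ncol = nrow(markers))
  co <- vector("list", n_ind)

  for (ind in seq_len(n_ind)) {
    ind_co <- vector("list", length(chroms))
    for (ci in seq_along(chroms)) {
      ch <- chroms[ci]
      len <- config$chrom_lengths_bp[ch]
      dg <- if (!is.null(dist_gam)) dist_gam[dist_gam$chrom == ch, ,
                                             drop = FALSE] else NULL
      dz <- if (!is.null(dist_zyg)) dist_zyg[dist_zyg$chrom == ch, ,
                                             drop = FALSE] else NULL
      repeat {
        g1 <- simulate_gamete(len, config$cm_per_mb, dg)
        g2 <- simulate_gamete(len, config$cm_per_mb, dg)
        if (is.null(dz) || nrow(dz) == 0L) break
        w <- 1
        for (i in seq_len(nrow(dz))) {
          nA <- sum(gamete_origin(g1, dz$pos_bp[i]) == 1L,
                    gamete_origin(g2, dz$pos_bp[i]) == 1L)
          w <- w * dz$w_A[i]^nA * dz$w_B[i]^(2L - nA)
        }
        if (stats::runif(1L) < w) break
      }
      idx <- which(markers$chrom == ch)
      o1 <- gamete_origin(g1, markers$pos[idx])
      o2 <- gamete_origin(g2, markers$pos[idx])
      geno[ind, idx] <- o1 + o2 - 1L  # (1,1)->AA=1, mixed->2, (2,2)->3
      ind_co[[ci]] <- list(g1 = g1$breaks, g2 = g2$breaks)
    }
    names(ind_co) <- chroms
    co[[ind]] <- ind_co
  }

  co_df <- do.call(rbind, lapply(seq_len(n_ind), function(ind) {
    do.call(rbind, lapply(chroms, function(ch) {
      b1 <- co[[ind]][[ch]]$g1
      b2 <- co[[ind]][[ch]]$g2
      if (length(b1) + length(b2) == 0L) return(NULL)
      data.frame(individual = ind, chrom = ch,
                 gamete = rep(1:2, c(length(b1), length(b2))),
                 pos_bp = c(b1, b2), stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(co_df))
    co_df <- data.frame(individual = integer(), chrom = character(),
                        gamete = integer(), pos_bp = numeric())

  truth <- structure(list(markers = markers, geno = geno,
                          crossovers = co_df, phenotypes = NULL,
                          genetic_values = NULL, config = config),
                     class = "f2_truth")
  if (!is.null(config$qtls)) {
    ph <- simulate_phenotypes(truth, config$qtls, baseline = config$baseline,
                              noise_sd = config$noise_sd)
    truth$phenotypes <- ph
    truth$genetic_values <- attr(ph, "genetic_values")
  }
  truth
}

#' Simulate phenotypes from QTL effects
#'
#' `y = baseline + sum_q (a_q * x_q + d_q * z_q) + N(0, noise_sd^2)` with
#' `x = +1/0/-1` for AA/AB/BB and `z = 1` iff AB, read from the simulated
#' marker nearest each QTL position. For a single QTL segregating 1:2:1 the
#' additive genetic variance is `a^2/2` and the dominance variance `d^2/4`.
#'
#' Uses the current RNG state unless `seed` is given.
#'
#' @param truth an `f2_truth` object.
#' @param qtls data frame with columns `chrom`, `pos_bp`, `a`, `d`.
#' @param baseline trait mean.
#' @param noise_sd residual standard deviation.
#' @param trait trait name for the output table.
#' @param seed optional seed.
#' @return Data frame `id`, `trait`, `value`, with per-individual genetic
#'   values in `attr(, "genetic_values")`.
#' @export
simulate_phenotypes <- function(truth, qtls, baseline = 0, noise_sd = 1,
                                trait = "trait", seed = NULL) {
  stopifnot(inherits(truth, "f2_truth"))
  if (!is.null(seed)) set.seed(seed)
  qtls <- as.data.frame(qtls)
  .check_number(noise_sd, "noise_sd", lower = 0)
  n <- nrow(truth$geno)
  gv <- numeric(n)
  for (i in seq_len(nrow(qtls))) {
    idx <- which(truth$markers$chrom == qtls$chrom[i])
    if (length(idx) == 0L)
      stop("QTL on chromosome without markers", call. = FALSE)
    len <- truth$config$chrom_lengths_bp[as.character(qtls$chrom[i])]
    if (!is.finite(qtls$pos_bp[i]) || qtls$pos_bp[i] < 1 ||
        qtls$pos_bp[i] > len)
      stop("QTL position off the simulated genome", call. = FALSE)
    m <- idx[which.min(abs(truth$markers$pos[idx] - qtls$pos_bp[i]))]
    cz <- genotype_codes(truth$geno[, m])
    gv <- gv + qtls$a[i] * cz[, "x"] + qtls$d[i] * cz[, "z"]
  }
  y <- baseline + gv + stats::rnorm(n, 0, noise_sd)
  out <- data.frame(id = seq_len(n), trait = trait, value = y,
                    stringsAsFactors = FALSE)
  attr(out, "genetic_values") <- gv
  out
}

#' Simulate allele-depth observations from true genotypes
#'
#' Per cell, depth ~ Poisson(`mean_depth`), then zeroed with probability
#' `missing_extra`. Given depth `d`, reads supporting the male (B) allele are
#' Binomial(`d`, `error_rate`) for a true AA, Binomial(`d`, 0.5) for AB and
#' Binomial(`d`, `1 - error_rate`) for BB; `n_A = d - n_B`. Depth 0 means
#' missing.
#'
#' @param truth an `f2_truth` object.
#' @param mean_depth Poisson mean depth (x).
#' @param error_rate per-read miscall probability.
#' @param missing_extra extra dropout probability.
#' @param seed optional seed (otherwise continues the current RNG stream).
#' @return An object of class `f2_obs`: list with `markers`, and integer
#'   matrices `n_A`, `n_B` (individuals x markers).
#' @export
simulate_observations <- function(truth, mean_depth = 7, error_rate = 0.01,
                                  missing_extra = 0, seed = NULL) {
  stopifnot(inherits(truth, "f2_truth"))
  .check_number(mean_depth, "mean_depth", lower = 0)
  .check_number(error_rate, "error_rate", lower = 0, upper = 0.5,
                upper_open = TRUE)
  .check_number(missing_extra, "missing_extra", lower = 0, upper = 1)
  if (!is.null(seed)) set.seed(seed)
  g <- truth$geno
  n <- length(g)
  d <- stats::rpois(n, mean_depth)
  if (missing_extra > 0)
    d[stats::runif(n) < missing_extra] <- 0L
  pB <- c(error_rate, 0.5, 1 - error_rate)[g]
  nB <- stats::rbinom(n, d, pB)
  nA <- d - nB
  dim(nA) <- dim(nB) <- dim(g)
  structure(list(markers = truth$markers,
                 n_A = nA, n_B = nB),
            class = "f2_obs")
}

#' @export
print.f2_truth <- function(x, ...) {
  cat("F2 simulation truth set\n")
  cat(sprintf("  %d individuals, %d markers on %d chromosomes\n",
              nrow(x$geno), nrow(x$markers),
              length(unique(x$markers$chrom))))
  cat(sprintf("  %d true crossovers (%.1f per individual)\n",
              nrow(x$crossovers), nrow(x$crossovers) / nrow(x$geno)))
  if (!is.null(x$phenotypes))
    cat(sprintf("  phenotypes: %s\n",
                paste(unique(x$phenotypes$trait), collapse = ", ")))
  invisible(x)
}

#' @export
print.f2_obs <- function(x, ...) {
  d <- x$n_A + x$n_B
  cat("F2 allele-depth observations\n")
  cat(sprintf("  %d individuals x %d markers, mean depth %.2f, %.1f%% missing\n",
              nrow(x$n_A), ncol(x$n_A), mean(d), 100 * mean(d == 0)))
  invisible(x)
}
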