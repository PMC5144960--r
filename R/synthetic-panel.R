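#' Array noise model
#'
#' Noise applied by the array-genotyping emulation: genotyping error (a
#' call replaced by a different one), no-calls, and Gaussian noise on the
#' log-scale hybridization intensity whose mean is proportional to copy
#' number (two copies = 0, one copy = -0.5, zero copies = -2, duplicated
#' = +0.4).
#'
#' @param genotype_error Per-call error rate (default 0.005).
#' @param no_call Per-call no-call rate (default 0.01).
#' @param lrr_sd Intensity noise standard deviation (default 0.12).
#' @param cn_means Named intensity means for copy numbers `"0"`, `"1"`,
#'   `"2"`, `"dup"`.
#' @param nonrobust_het_rate Spurious heterozygous-call rate on hemizygous
#'   male X at non-robust markers (the artifact the robust-marker filter
#'   removes; default 0.10).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(genotype_error = 0.005, no_call = 0.01,
                        lrr_sd = 0.12,
                        cn_means = c(`0` = -2, `1` = -0.5, `2` = 0,
                                     dup = 0.4),
                        nonrobust_het_rate = 0.10) {
  stopifnot(genotype_error >= 0, genotype_error <= 1,
            no_call >= 0, no_call <= 1, lrr_sd > 0)
  structure(list(genotype_error = genotype_error, no_call = no_call,
                 lrr_sd = lrr_sd, cn_means = cn_means,
                 nonrobust_het_rate = nonrobust_het_rate),
            class = "noise_model")
}

# draw class signature matrix: n_classes x n_probes binary, pairwise
# Hamming distance >= margin
.class_signatures <- function(classes, n_probes, margin) {
  K <- length(classes)
  repeat {
    sig <- matrix(stats::rbinom(K * n_probes, 1L, 0.5), K, n_probes,
                  dimnames = list(classes, NULL))
    d <- as.matrix(stats::dist(sig, method = "manhattan"))
    if (min(d[upper.tri(d)]) >= margin) return(sig)
  }
}

#' Generate a synthetic marker panel
#'
#' Builds an array-style panel over a [genome_map()]: biallelic founder
#' consensus alleles per marker (a configurable fraction of markers
#' private to a single founder, enabling private-allele analyses), PAR
#' markers and markers inside the CAST-extended PAR window on X,
#' uniparental probe sets with linearly separable class signatures (7 Y
#' probes, 40 mitochondrial probes by default), and robust-marker flags.
#' Deterministic under `seed`.
#'
#' @param map A [genome_map()].
#' @param private_fraction Fraction of map markers private to one founder
#'   (default 0.3).
#' @param n_y_probes,n_mito_probes Uniparental probe counts.
#' @param robust_fraction Fraction of markers with robust performance in
#'   hemizygous samples (default 0.95).
#' @param class_margin Minimum Hamming distance between haplogroup class
#'   signatures (default 2).
#' @param par A [par_info()]; PAR markers are added only when the map
#'   includes X.
#' @param seed Optional integer seed.
#' @return An object of class `synthetic_panel` with elements `markers`
#'   (marker, chrom, bp, compartment, robust, private_founder),
#'   `consensus` (8 x markers allele matrix), `y_probes`, `mito_probes`,
#'   `y_signatures`, `mito_signatures`, `par`.
#' @export
generate_panel <- function(map, private_fraction = 0.3, n_y_probes = 7,
                           n_mito_probes = 40, robust_fraction = 0.95,
                           class_margin = 2, par = par_info(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(private_fraction >= 0, private_fraction <= 1,
            n_y_probes >= 1, n_mito_probes >= 1)
  mk <- map$markers[, c("marker", "chrom", "bp")]
  has_x <- "X" %in% map$chromosomes$chrom
  mk$compartment <- ifelse(mk$chrom == "X", "X", "auto")
  if (has_x) {
    xlen <- chrom_length(map, "X")
    mk <- mk[!(mk$chrom == "X" & mk$bp >= par$standard), ]
    # PAR markers and markers inside the CAST-extended window
    extra <- data.frame(
      marker = c(sprintf("par_%d", 1:3), sprintf("xpar_%d", 1:2)),
      chrom = "X",
      bp = round(c(seq(par$standard, min(xlen - 1, par$standard + 8e5),
                       length.out = 3),
                   par$cast + c(1e5, 3e5))),
      compartment = c(rep("PAR", 3), rep("X", 2)))
    mk <- rbind(mk, extra)
  }
  mk <- mk[order(match(mk$chrom, map$chromosomes$chrom), mk$bp), ]
  n <- nrow(mk)
  mk$robust <- stats::runif(n) < robust_fraction
  mk$robust[mk$compartment == "PAR"] <- TRUE

  # founder consensus: private markers give the minor allele to one
  # founder; shared markers split the founders at random (polymorphic)
  consensus <- matrix(0L, 8L, n, dimnames = list(founder_codes(), mk$marker))
  private <- stats::runif(n) < private_fraction
  owner <- sample.int(8L, n, replace = TRUE)
  mk$private_founder <- ifelse(private, .i2f(owner), NA_character_)
  for (j in seq_len(n)) {
    if (private[j]) {
      consensus[owner[j], j] <- 1L
    } else {
      repeat {
        a <- stats::rbinom(8L, 1L, 0.5)
        if (any(a == 1L) && any(a == 0L)) break
      }
      consensus[, j] <- a
    }
  }

  y_lv <- haplogroup_levels("Y")
  mito_lv <- haplogroup_levels("mito")
  y_sig <- .class_signatures(y_lv, n_y_probes, class_margin)
  mito_sig <- .class_signatures(mito_lv, n_mito_probes, class_margin)
  y_probes <- sprintf("yprobe_%02d", seq_len(n_y_probes))
  mito_probes <- sprintf("mtprobe_%02d", seq_len(n_mito_probes))
  colnames(y_sig) <- y_probes
  colnames(mito_sig) <- mito_probes
  probe_rows <- data.frame(
    marker = c(y_probes, mito_probes),
    chrom = c(rep("Y", n_y_probes), rep("MT", n_mito_probes)),
    bp = c(seq_len(n_y_probes), seq_len(n_mito_probes)) * 1e5,
    compartment = c(rep("Y", n_y_probes), rep("mito", n_mito_probes)),
    robust = TRUE, private_founder = NA_character_)
  markers <- rbind(mk, probe_rows)
  rownames(markers) <- NULL
  structure(list(markers = markers, consensus = consensus,
                 y_probes = y_probes, mito_probes = mito_probes,
                 y_signatures = y_sig, mito_signatures = mito_sig,
                 par = par),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("<synthetic_panel> ", nrow(x$markers), " markers (",
      sum(!is.na(x$markers$private_founder)), " private), ",
      length(x$y_probes), " Y probes, ", length(x$mito_probes),
      " mito probes\n", sep = "")
  invisible(x)
}

#' Private-variant mask from a synthetic panel
#'
#' @param panel A [generate_panel()] result.
#' @return data.frame (`variant`, `chrom`, `bp`, `founder`) listing the
#'   panel's founder-private markers, the layout consumed by
#'   [private_allele_retention()].
#' @export
private_mask_from_panel <- function(panel) {
  m <- panel$markers
  m <- m[!is.na(m$private_founder), ]
  data.frame(variant = m$marker, chrom = m$chrom, bp = m$bp,
             founder = m$private_founder)
}
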