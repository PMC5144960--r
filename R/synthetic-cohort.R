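#' Quick cohort of unrelated mosaic individuals
#'
#' Generates individuals whose chromosomes are independent random founder
#' mosaics — a stand-in for a well-mixed outbred cohort at a later
#' generation — without running the breeding simulator. Useful for
#' karyotype and haplogroup studies where pedigree structure is
#' irrelevant.
#'
#' @param n_female,n_male Cohort composition.
#' @param map A [genome_map()].
#' @param mean_segments Expected mosaic segments per chromosome (default
#'   12, a well-recombined genome).
#' @param generation Generation index recorded on the individuals.
#' @return List of `do_individual`s.
#' @export
random_individuals <- function(n_female, n_male, map, mean_segments = 12,
                               generation = 11L) {
  chroms <- map$chromosomes$chrom
  lens <- stats::setNames(map$chromosomes$length_bp, chroms)
  autos <- setdiff(chroms, "X")
  has_x <- "X" %in% chroms
  build <- function(i, sex) {
    genome <- lapply(stats::setNames(autos, autos), function(cc)
      list(h1 = random_mosaic(cc, lens[[cc]], mean_segments),
           h2 = random_mosaic(cc, lens[[cc]], mean_segments)))
    if (has_x) {
      genome[["X"]] <- if (sex == "F")
        list(h1 = random_mosaic("X", lens[["X"]], mean_segments),
             h2 = random_mosaic("X", lens[["X"]], mean_segments))
      else list(h1 = random_mosaic("X", lens[["X"]], mean_segments), h2 = NULL)
    }
    new_individual(id = sprintf("S%s%04d", sex, i), sex = sex,
                   generation = generation, lineage = NA_character_,
                   genome = genome,
                   mito = haplogroup_of(.i2f(sample.int(8L, 1L)), "mito"),
                   y = if (sex == "M")
                     haplogroup_of(.i2f(sample.int(8L, 1L)), "Y")
                   else NA_character_)
  }
  c(lapply(seq_len(n_female), build, sex = "F"),
    lapply(seq_len(n_male), build, sex = "M"))
}

#' Emulate array genotyping of a cohort
#'
#' Produces allele calls and normalized hybridization intensities for each
#' individual at every panel marker. Calls are the summed consensus
#' alleles of the founders carried at the marker (dosage 0/1/2), with
#' genotyping error and no-calls per the noise model; hemizygous male X
#' markers are called homozygous (errors never produce heterozygotes at
#' robust markers, while non-robust markers suffer spurious het calls at
#' the model's rate — the artifact the robust-marker filter exists for).
#' Intensities are Gaussian around the copy-number mean: X markers have
#' two copies in females and one in males, except the PAR (two) and, for
#' males carrying the CAST/EiJ (F) Y, the CAST-extended PAR window, where
#' the Y contributes a CAST-derived copy (heterozygous where it differs).
#' Y probes carry the sample's Y-haplogroup signature (absent in
#' females); mitochondrial probes carry the mito-haplogroup signature.
#'
#' @param individuals List of `do_individual`s.
#' @param panel A [generate_panel()] result.
#' @param noise A [noise_model()].
#' @param seed Optional integer seed.
#' @return An object of class `array_cohort`: `calls` and `lrr`
#'   (markers x samples), `true_calls` (pre-noise), `samples`
#'   (data.frame id, sex, karyotype, mito, y, generation), `panel`,
#'   `noise`.
#' @export
genotype_cohort <- function(individuals, panel, noise = noise_model(),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- panel$markers
  M <- nrow(mk)
  N <- length(individuals)
  ids <- vapply(individuals, function(x) x$id, "")
  calls <- matrix(NA_integer_, M, N, dimnames = list(mk$marker, ids))
  cn <- matrix(2, M, N)
  xmask <- mk$chrom == "X"
  ymask <- mk$compartment == "Y"
  mtmask <- mk$compartment == "mito"
  parmask <- mk$compartment == "PAR"
  extmask <- xmask & !parmask & mk$bp >= panel$par$cast & mk$bp < panel$par$standard
  cast_code <- .f2i("F")
  genomic <- which(!ymask & !mtmask)
  chroms <- unique(mk$chrom[genomic])
  chroms <- setdiff(chroms, c("Y", "MT"))
  for (j in seq_len(N)) {
    ind <- individuals[[j]]
    for (cc in chroms) {
      rows <- which(mk$chrom == cc)
      pair <- ind$genome[[cc]]
      if (is.null(pair)) stop("individual ", ind$id, " lacks chromosome ", cc)
      bp <- mk$bp[rows]
      f1 <- pair$h1$founder[findInterval(bp, pair$h1$start)]
      a1 <- panel$consensus[cbind(f1, rows)]
      if (!is.null(pair$h2)) {
        f2 <- pair$h2$founder[findInterval(bp, pair$h2$start)]
        a2 <- panel$consensus[cbind(f2, rows)]
        calls[rows, j] <- a1 + a2
      } else {
        # hemizygous X: called homozygous; PAR behaves two-copy
        a2 <- a1
        if (cc == "X" && !is.na(ind$y) && ind$y == "F") {
          w <- which(extmask[rows])
          if (length(w))
            a2[w] <- panel$consensus[cbind(rep(cast_code, length(w)),
                                           rows[w])]
        }
        calls[rows, j] <- a1 + a2
        if (cc == "X") {
          one_copy <- !(parmask[rows] |
                          (extmask[rows] & !is.na(ind$y) & ind$y == "F"))
          cn[rows[one_copy], j] <- 1
        }
      }
    }
    # uniparental probes
    if (ind$sex == "M" || ind$karyotype %in% c("XY", "XY+dupX")) {
      calls[ymask, j] <- 2L * panel$y_signatures[ind$y, ]
      cn[ymask, j] <- 1
    } else {
      cn[ymask, j] <- 0
    }
    calls[mtmask, j] <- 2L * panel$mito_signatures[ind$mito, ]
  }
  true_calls <- calls

  # genotyping error: replace with a different legal call
  err <- which(matrix(stats::runif(M * N) < noise$genotype_error, M, N) &
                 !is.na(calls))
  if (length(err)) {
    hemi <- (cn == 1)[err] & xmask[row(calls)[err]]
    cur <- calls[err]
    new <- cur
    new[hemi] <- 2L - cur[hemi]                # 0 <-> 2, never het
    if (any(!hemi))
      new[!hemi] <- (cur[!hemi] +
                       sample(1:2, sum(!hemi), replace = TRUE)) %% 3L
    calls[err] <- new
  }
  # spurious het calls on hemizygous X at non-robust markers
  nonrob <- which(xmask & !mk$robust)
  if (length(nonrob)) {
    for (j in seq_len(N)) {
      hemi_rows <- nonrob[cn[nonrob, j] == 1]
      if (length(hemi_rows)) {
        flip <- stats::runif(length(hemi_rows)) < noise$nonrobust_het_rate
        calls[hemi_rows[flip], j] <- 1L
      }
    }
  }
  # no-calls
  nc <- matrix(stats::runif(M * N) < noise$no_call, M, N)
  calls[nc] <- NA_integer_

  cn_key <- as.character(cn)
  lrr <- matrix(noise$cn_means[cn_key], M, N,
                dimnames = list(mk$marker, ids)) +
    stats::rnorm(M * N, 0, noise$lrr_sd)
  samples <- data.frame(
    id = ids,
    sex = vapply(individuals, function(x) x$sex, ""),
    karyotype = vapply(individuals, function(x) x$karyotype, ""),
    mito = vapply(individuals, function(x) x$mito, ""),
    y = vapply(individuals, function(x) x$y, ""),
    generation = vapply(individuals, function(x) x$generation, 0L),
    dup_start = NA_real_, dup_end = NA_real_)
  structure(list(calls = calls, lrr = lrr, true_calls = true_calls,
                 samples = samples, panel = panel, noise = noise),
            class = "array_cohort")
}

#' @export
print.array_cohort <- function(x, ...) {
  cat("<array_cohort> ", ncol(x$calls), " samples x ", nrow(x$calls),
      " markers\n", sep = "")
  invisible(x)
}

#' Inject a sex-chromosome anomaly into a genotyped sample
#'
#' `"XO"` (females): all X-marker intensities are shifted to the one-copy
#' mean, heterozygous X calls are homozygized, and Y probes are silenced
#' to the zero-copy level. `"distal_dup"` (males): markers within
#' `dup_length` bp proximal of the standard PAR boundary receive
#' duplicated-copy intensity and heterozygous calls wherever the
#' duplicated source haplotype differs from the host X. The source founder
#' is drawn at random among founders with at least `min_informative`
#' differing markers in the interval — mirroring the ascertainment of real
#' duplication carriers, which are only identifiable through heterozygous
#' calls. A zero-length duplication leaves the sample unchanged.
#'
#' @param cohort An [genotype_cohort()] result.
#' @param sample_id Sample to modify.
#' @param kind `"XO"` or `"distal_dup"`.
#' @param dup_length Duplication length in bp (distal_dup only).
#' @param min_informative Minimum differing markers required of the
#'   duplication source (default 3).
#' @return The modified `array_cohort` (truth table updated).
#' @export
inject_anomaly <- function(cohort, sample_id, kind = c("XO", "distal_dup"),
                           dup_length = NULL, min_informative = 3) {
  kind <- match.arg(kind)
  j <- match(sample_id, cohort$samples$id)
  if (is.na(j)) stop("unknown sample: ", sample_id)
  mk <- cohort$panel$markers
  noise <- cohort$noise
  sex <- cohort$samples$sex[j]
  if (kind == "XO") {
    if (sex != "F") stop("XO injection requires a female sample")
    xr <- which(mk$chrom == "X")
    cohort$lrr[xr, j] <- noise$cn_means[["1"]] +
      stats::rnorm(length(xr), 0, noise$lrr_sd)
    het <- xr[!is.na(cohort$calls[xr, j]) & cohort$calls[xr, j] == 1L]
    if (length(het))
      cohort$calls[het, j] <- 2L * stats::rbinom(length(het), 1L, 0.5)
    yr <- which(mk$compartment == "Y")
    cohort$lrr[yr, j] <- noise$cn_means[["0"]] +
      stats::rnorm(length(yr), 0, noise$lrr_sd)
    cohort$calls[yr, j] <- NA_integer_
    cohort$samples$karyotype[j] <- "XO"
    return(cohort)
  }
  if (sex != "M") stop("distal-X duplication injection requires a male sample")
  if (is.null(dup_length)) stop("dup_length required")
  if (dup_length <= 0) return(cohort)
  par <- cohort$panel$par
  lo <- par$standard - dup_length
  rows <- which(mk$chrom == "X" & mk$compartment != "PAR" &
                  mk$bp >= lo & mk$bp < par$standard)
  if (!length(rows)) stop("no X markers in the duplicated interval")
  host <- cohort$true_calls[rows, j] / 2L  # hemizygous: 0 or 1
  cand <- sample(founder_codes())
  src <- NULL
  for (f in cand) {
    alt <- cohort$panel$consensus[.f2i(f), rows]
    if (sum(alt != host) >= min_informative) { src <- f; break }
  }
  if (is.null(src))
    stop("no founder provides ", min_informative,
         " informative markers in the interval; increase dup_length")
  alt <- cohort$panel$consensus[.f2i(src), rows]
  cohort$calls[rows, j] <- ifelse(alt != host, 1L, 2L * host)
  cohort$lrr[rows, j] <- noise$cn_means[["dup"]] +
    stats::rnorm(length(rows), 0, noise$lrr_sd)
  cohort$samples$karyotype[j] <- "XY+dupX"
  cohort$samples$dup_start[j] <- lo
  cohort$samples$dup_end[j] <- par$standard
  cohort
}

#' True diplotype-probability array for a set of individuals
#'
#' Emits the 36-state unphased diplotype probabilities implied by the true
#' mosaics: indicator vectors on the true founder pair, optionally mixed
#' with uniform noise (`smoothing`) to exercise the probabilistic path of
#' [condense_diplotypes()]. Hemizygous chromosomes are reported as the
#' corresponding homozygous state.
#'
#' @param individuals List of `do_individual`s.
#' @param positions bp positions.
#' @param chrom Chromosome name.
#' @param smoothing Weight in `[0, 1)` of the uniform component.
#' @return Array `n x length(positions) x 36` (state order
#'   [diplotype_states()]).
#' @export
true_diplotype_probs <- function(individuals, positions, chrom,
                                 smoothing = 0) {
  stopifnot(smoothing >= 0, smoothing < 1)
  n <- length(individuals)
  P <- length(positions)
  arr <- array(smoothing / 36, dim = c(n, P, 36L),
               dimnames = list(NULL, NULL, diplotype_states()))
  for (i in seq_len(n)) {
    pair <- individuals[[i]]$genome[[chrom]]
    if (is.null(pair)) stop("individual lacks chromosome ", chrom)
    f1 <- pair$h1$founder[findInterval(positions, pair$h1$start)]
    f2 <- if (!is.null(pair$h2))
      pair$h2$founder[findInterval(positions, pair$h2$start)] else f1
    idx <- .state_index(f1, f2)
    arr[cbind(i, seq_len(P), idx)] <-
      arr[cbind(i, seq_len(P), idx)] + (1 - smoothing)
  }
  arr
}

# index into diplotype_states() for an unphased founder pair
.state_index <- function(f1, f2) {
  i <- pmin(f1, f2); j <- pmax(f1, f2)
  ifelse(i == j, i, 8L + (i - 1L) * 8L - (i - 1L) * i / 2L + (j - i))
}
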