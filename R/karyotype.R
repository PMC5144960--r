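#' Pseudoautosomal-region annotation
#'
#' The X/Y-shared terminal region of the X chromosome. The boundary sits
#' 430 kb more proximal on the CAST/EiJ Y chromosome (an X-to-Y
#' translocation expanded its PAR), so heterozygosity between the CAST and
#' standard boundaries is diagnostic of a CAST Y, not of an X duplication.
#'
#' @param boundary_bp Standard PAR boundary (bp on X).
#' @param cast_offset_bp How far proximal the CAST/EiJ boundary lies
#'   (default 430 kb).
#' @return An object of class `par_info`.
#' @export
par_info <- function(boundary_bp = 169969759, cast_offset_bp = 430000) {
  stopifnot(cast_offset_bp > 0, boundary_bp > cast_offset_bp)
  structure(list(standard = boundary_bp,
                 cast = boundary_bp - cast_offset_bp),
            class = "par_info")
}

#' @rdname par_info
#' @param par A `par_info`.
#' @param y_haplogroup Y haplogroup label; `"F"` (CAST/EiJ) selects the
#'   extended boundary.
#' @export
applicable_par_boundary <- function(par, y_haplogroup) {
  if (!is.na(y_haplogroup) && y_haplogroup == "F") par$cast else par$standard
}

#' Karyotype-calling thresholds
#'
#' Decision thresholds derived from a [noise_model()]'s copy-number
#' intensity means rather than fixed absolute values: the Y-presence and
#' X-reduction cutoffs are midpoints between the relevant copy-number
#' levels. XO additionally requires near-zero X heterozygosity.
#'
#' @param noise A [noise_model()] supplying the copy-number means.
#' @param x_het_max Maximum X heterozygous fraction compatible with a
#'   single X.
#' @param min_x_markers,min_y_markers Minimum informative marker counts;
#'   below these the sample is a no-call.
#' @param dup_min_markers Minimum markers in a distal run to call a
#'   duplication.
#' @param dup_min_het Minimum heterozygous calls within the run.
#' @param dup_max_gap Consecutive below-threshold markers tolerated before
#'   the distal run is terminated.
#' @return An object of class `karyotype_thresholds`.
#' @export
karyotype_thresholds <- function(noise = noise_model(), x_het_max = 0.02,
                                 min_x_markers = 10, min_y_markers = 3,
                                 dup_min_markers = 3, dup_min_het = 2,
                                 dup_max_gap = 1) {
  cn <- noise$cn_means
  structure(list(y_present = (cn[["0"]] + cn[["1"]]) / 2,
                 x_reduced = (cn[["1"]] + cn[["2"]]) / 2,
                 dup_elevated = (cn[["1"]] + cn[["2"]]) / 2,
                 x_het_max = x_het_max,
                 min_x_markers = min_x_markers,
                 min_y_markers = min_y_markers,
                 dup_min_markers = dup_min_markers,
                 dup_min_het = dup_min_het,
                 dup_max_gap = dup_max_gap),
            class = "karyotype_thresholds")
}

# X markers used for intensity/heterozygosity summaries: robust, non-PAR
.x_summary_markers <- function(panel) {
  m <- panel$markers
  which(m$chrom == "X" & m$compartment == "X" & m$robust)
}

#' Call the sex-chromosome karyotype of a sample
#'
#' Y presence is decided from the mean Y-probe intensity; XO requires an
#' absent Y, a mean X intensity reduced to the one-copy level, and a
#' near-complete lack of X heterozygosity. PAR markers are excluded from
#' the X intensity mean. Distal-X duplications are a separate call
#' ([detect_x_duplication()]).
#'
#' @param calls Integer genotype vector for one sample (0/1/2 dosage, NA =
#'   no-call), indexed by the panel's markers; or a markers x samples
#'   matrix.
#' @param lrr Matching normalized log-scale intensity vector/matrix.
#' @param panel A [generate_panel()] object (or any list with a compatible
#'   `markers` table).
#' @param thresholds A [karyotype_thresholds()].
#' @return Character vector of calls `"XX"`, `"XY"`, `"XO"`, or NA
#'   (insufficient markers).
#' @export
call_sex_karyotype <- function(calls, lrr, panel,
                               thresholds = karyotype_thresholds()) {
  if (is.matrix(calls)) {
    return(vapply(seq_len(ncol(calls)), function(j)
      call_sex_karyotype(calls[, j], lrr[, j], panel, thresholds), ""))
  }
  m <- panel$markers
  xi <- .x_summary_markers(panel)
  yi <- which(m$compartment == "Y")
  if (length(xi) < thresholds$min_x_markers ||
      length(yi) < thresholds$min_y_markers) return(NA_character_)
  y_mean <- mean(lrr[yi], na.rm = TRUE)
  x_mean <- mean(lrr[xi], na.rm = TRUE)
  x_calls <- calls[xi]
  x_called <- !is.na(x_calls)
  if (sum(x_called) < thresholds$min_x_markers) return(NA_character_)
  het_frac <- mean(x_calls[x_called] == 1L)
  if (y_mean > thresholds$y_present) return("XY")
  if (x_mean < thresholds$x_reduced && het_frac < thresholds$x_het_max)
    return("XO")
  "XX"
}

#' Detect a distal-X duplication in a male sample
#'
#' Scans the distal X (outside the applicable PAR — the CAST-extended
#' boundary when the sample's Y haplogroup is F) from the telomere inward
#' for a run of robust markers with two-copy ("female-like") hybridization
#' intensity, tolerating up to `dup_max_gap` consecutive below-threshold
#' markers. A duplication is called when the run spans at least
#' `dup_min_markers` markers and contains at least `dup_min_het`
#' heterozygous calls — heterozygosity on the male X outside the PAR is
#' only possible with a second X copy. Because an X-to-Y translocation
#' cannot be excluded, the call is best read as "distal-X gain".
#'
#' @param calls,lrr One sample's genotype and intensity vectors (see
#'   [call_sex_karyotype()]).
#' @param panel A [generate_panel()] object.
#' @param par A [par_info()].
#' @param y_haplogroup The sample's Y haplogroup (`"F"` activates the
#'   CAST-extended PAR boundary).
#' @param thresholds A [karyotype_thresholds()].
#' @param sex Sample's called sex; non-males are an error.
#' @return NULL if no duplication; otherwise a list with `start`, `end`
#'   (bp, half-open; end is the applicable PAR boundary), `n_markers`,
#'   `n_het`.
#' @export
detect_x_duplication <- function(calls, lrr, panel, par = par_info(),
                                 y_haplogroup = NA_character_,
                                 thresholds = karyotype_thresholds(),
                                 sex = "M") {
  if (!identical(sex, "M")) stop("distal-X duplication calling requires a male sample")
  m <- panel$markers
  boundary <- applicable_par_boundary(par, y_haplogroup)
  idx <- which(m$chrom == "X" & m$compartment == "X" & m$robust &
                 m$bp < boundary)
  if (!length(idx)) return(NULL)
  idx <- idx[order(m$bp[idx], decreasing = TRUE)]  # distal -> proximal
  elevated <- lrr[idx] > thresholds$dup_elevated
  run <- logical(length(idx))
  gap <- 0L
  for (i in seq_along(idx)) {
    if (isTRUE(elevated[i])) {
      run[i] <- TRUE
      gap <- 0L
    } else {
      gap <- gap + 1L
      if (gap > thresholds$dup_max_gap) break
    }
  }
  hits <- idx[run]
  if (length(hits) < thresholds$dup_min_markers) return(NULL)
  n_het <- sum(calls[hits] == 1L, na.rm = TRUE)
  if (n_het < thresholds$dup_min_het) return(NULL)
  list(start = min(m$bp[hits]), end = boundary,
       n_markers = length(hits), n_het = n_het)
}
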