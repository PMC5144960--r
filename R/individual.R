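#' Drive locus description
#'
#' The locus subject to maternal meiotic drive, plus the tightly linked
#' selection markers used for marker-assisted purge bookkeeping and for the
#' array-genotyping emulation. The default is a chromosome 2 locus at
#' 85.65 Mb driven by the WSB/EiJ (H) allele, with three flanking selection
#' markers.
#'
#' @param chrom Chromosome carrying the locus.
#' @param pos Locus position (bp); the genotype at the locus is taken from
#'   the mosaic at this point.
#' @param driven Founder letter whose allele is driven (default `"H"`).
#' @param marker_pos Positions (bp) of the selection markers (>= 1).
#' @param marker_ids Names of the selection markers.
#' @return An object of class `drive_locus`.
#' @export
drive_locus <- function(chrom = "2", pos = 85650000, driven = "H",
                        marker_pos = c(84300000, 85650000, 87000000),
                        marker_ids = c("rs27943666", "rs28048346", "rs28030588")) {
  stopifnot(length(marker_pos) >= 1, length(marker_ids) == length(marker_pos))
  structure(list(chrom = as.character(chrom), pos = pos,
                 driven = driven, driven_code = .f2i(driven),
                 marker_pos = marker_pos, marker_ids = marker_ids),
            class = "drive_locus")
}

#' Construct an individual
#'
#' An individual carries a sex, generation index, matrilineal lineage id, a
#' genome of per-chromosome homologue pairs (`founder_mosaic`s), a
#' mitochondrial haplogroup, a Y haplogroup (males only), and a karyotype
#' flag. Males are hemizygous on X (`h2 = NULL`); XO females carry a single
#' X likewise.
#'
#' @param id Sample id.
#' @param sex `"F"` or `"M"`.
#' @param generation Generation index (0 = founding).
#' @param lineage Lineage id (matrilineal).
#' @param genome Named list (by chromosome) of `list(h1 =, h2 =)` mosaics.
#' @param mito Mitochondrial haplogroup label.
#' @param y Y haplogroup label (males; must be NA for females).
#' @param karyotype One of `"XX"`, `"XY"`, `"XO"`, `"XY+dupX"`.
#' @param dam_id,sire_id Parent ids (NA for founders).
#' @return An object of class `do_individual`.
#' @export
new_individual <- function(id, sex, generation, lineage, genome,
                           mito = NA_character_, y = NA_character_,
                           karyotype = if (sex == "F") "XX" else "XY",
                           dam_id = NA_character_, sire_id = NA_character_) {
  stopifnot(sex %in% c("F", "M"),
            karyotype %in% c("XX", "XY", "XO", "XY+dupX"))
  if (sex == "F" && !is.na(y)) stop("females carry no Y haplogroup")
  if (karyotype == "XO" && !is.null(genome[["X"]]) && !is.null(genome[["X"]]$h2))
    stop("XO individuals carry a single X mosaic")
  structure(list(id = as.character(id), sex = sex,
                 generation = as.integer(generation),
                 lineage = as.character(lineage), genome = genome,
                 mito = mito, y = y, karyotype = karyotype,
                 dam_id = as.character(dam_id), sire_id = as.character(sire_id)),
            class = "do_individual")
}

#' @export
print.do_individual <- function(x, ...) {
  cat("<do_individual> ", x$id, " (", x$sex, ", G", x$generation,
      ", lineage ", x$lineage, ", ", x$karyotype, ")\n", sep = "")
  invisible(x)
}

#' Driven-allele count at the drive locus
#'
#' Counts the homologues whose founder at the locus point equals the driven
#' founder: 0/1/2 correspond to the genotype labels aa / Wa / WW.
#'
#' @param individual A `do_individual` with a diploid mosaic on the locus
#'   chromosome.
#' @param locus A [drive_locus()].
#' @return Integer in `{0, 1, 2}`.
#' @export
#' @examples
#' w_label(2)  # "WW"
w_count <- function(individual, locus) {
  pair <- individual$genome[[locus$chrom]]
  if (is.null(pair)) stop("individual has no mosaic for chromosome ", locus$chrom)
  n <- 0L
  for (h in pair[c("h1", "h2")]) {
    if (is.null(h)) next
    if (h$founder[findInterval(locus$pos, h$start)] == locus$driven_code)
      n <- n + 1L
  }
  n
}

#' @rdname w_count
#' @param w Driven-allele count(s) in `{0, 1, 2}`.
#' @export
w_label <- function(w) c("aa", "Wa", "WW")[w + 1L]
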