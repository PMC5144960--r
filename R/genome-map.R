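#' Genome map: chromosomes, marker grid, and genetic positions
#'
#' A `genome_map` holds the chromosomes being simulated (physical length in
#' bp, genetic length in Morgans) and a marker grid with both bp and cM
#' positions. Coordinates are 0-based half-open throughout the package.
#' The genetic map is piecewise-linear between markers (anchored at the
#' chromosome ends), which is what [draw_crossovers()] inverts when it
#' places crossovers uniformly in genetic distance.
#'
#' @param chromosomes data.frame with columns `chrom`, `length_bp`,
#'   `length_M` (genetic length in Morgans, > 0).
#' @param markers data.frame with columns `marker`, `chrom`, `bp`, `cM`;
#'   positions must be strictly increasing within a chromosome.
#' @return An object of class `genome_map`.
#' @seealso [default_genome_map()], [read_genome_map()]
#' @export
genome_map <- function(chromosomes, markers) {
  stopifnot(all(c("chrom", "length_bp", "length_M") %in% names(chromosomes)),
            all(c("marker", "chrom", "bp", "cM") %in% names(markers)))
  chromosomes$chrom <- as.character(chromosomes$chrom)
  markers$chrom <- as.character(markers$chrom)
  if (any(chromosomes$length_M < 0)) stop("genetic lengths must be >= 0")
  if (anyDuplicated(chromosomes$chrom)) stop("duplicated chromosome names")
  bad <- setdiff(markers$chrom, chromosomes$chrom)
  if (length(bad)) stop("markers on unknown chromosomes: ", paste(bad, collapse = ","))
  for (cc in unique(markers$chrom)) {
    m <- markers[markers$chrom == cc, ]
    if (is.unsorted(m$bp, strictly = TRUE) || is.unsorted(m$cM, strictly = TRUE))
      stop("marker positions must be strictly increasing on chromosome ", cc)
    L <- chromosomes$length_bp[chromosomes$chrom == cc]
    if (any(m$bp < 0 | m$bp >= L)) stop("marker bp outside chromosome ", cc)
  }
  structure(list(chromosomes = chromosomes, markers = markers),
            class = "genome_map")
}

#' @export
print.genome_map <- function(x, ...) {
  cat("<genome_map> ", nrow(x$chromosomes), " chromosomes, ",
      nrow(x$markers), " markers\n", sep = "")
  invisible(x)
}

#' Chromosome lookup helpers
#' @param map A [genome_map()].
#' @param chrom Chromosome name.
#' @return Physical length in bp / genetic length in Morgans.
#' @export
chrom_length <- function(map, chrom) {
  i <- match(chrom, map$chromosomes$chrom)
  if (is.na(i)) stop("chromosome not in map: ", chrom)
  map$chromosomes$length_bp[i]
}

#' @rdname chrom_length
#' @export
chrom_morgans <- function(map, chrom) {
  i <- match(chrom, map$chromosomes$chrom)
  if (is.na(i)) stop("chromosome not in map: ", chrom)
  map$chromosomes$length_M[i]
}

#' Default synthetic genome map
#'
#' A mouse-like fixture: 19 autosomes with lengths descending from 195 Mb
#' plus an X chromosome of 171 Mb, a uniform recombination rate of
#' `cm_per_mb` (0.56 cM/Mb, the mouse genome-wide average), and an evenly
#' spaced marker grid. It is a stand-in for a real array annotation, not an
#' estimate of any particular genetic map.
#'
#' @param chroms Chromosome names to include (subset of `c(1:19, "X")`).
#'   Simulations that only interrogate the drive chromosome can pass
#'   `chroms = c("2", "X")` (or just `"2"`) to reduce work.
#' @param markers_per_chrom Number of evenly spaced markers per chromosome.
#' @param cm_per_mb Recombination rate used for the genetic positions.
#' @return A [genome_map()].
#' @export
#' @examples
#' map <- default_genome_map(chroms = c("2", "X"))
#' chrom_length(map, "2")
default_genome_map <- function(chroms = c(as.character(1:19), "X"),
                               markers_per_chrom = 100,
                               cm_per_mb = 0.56) {
  all_names <- c(as.character(1:19), "X")
  # descending autosome lengths 195 -> 61 Mb, X fixed at 171 Mb
  lens <- c(round(seq(195e6, 61e6, length.out = 19)), 171e6)
  names(lens) <- all_names
  chroms <- as.character(chroms)
  bad <- setdiff(chroms, all_names)
  if (length(bad)) stop("unknown chromosomes: ", paste(bad, collapse = ","))
  lens <- lens[chroms]
  chromosomes <- data.frame(chrom = chroms,
                            length_bp = unname(lens),
                            length_M = unname(lens) * cm_per_mb / 1e8)
  mk <- do.call(rbind, lapply(chroms, function(cc) {
    L <- lens[[cc]]
    bp <- round(seq(L / (markers_per_chrom + 1), L - L / (markers_per_chrom + 1),
                    length.out = markers_per_chrom))
    data.frame(marker = sprintf("m%s_%03d", cc, seq_len(markers_per_chrom)),
               chrom = cc, bp = bp, cM = bp * cm_per_mb / 1e6)
  }))
  genome_map(chromosomes, mk)
}

#' Read / write a genome map as TSV
#'
#' The marker table (`marker`, `chrom`, `bp`, `cM`) is the unit of exchange;
#' chromosome physical lengths are taken from an optional `#chrom` header
#' block or inferred as the last marker position plus one inter-marker gap,
#' and genetic lengths likewise from the cM column.
#'
#' @param path TSV file path.
#' @param map A [genome_map()] to write.
#' @return `read_genome_map` returns a [genome_map()].
#' @export
read_genome_map <- function(path) {
  mk <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  header <- grep("^#chrom\t", readLines(path, n = 200), value = TRUE)
  if (length(header)) {
    ch <- utils::read.delim(text = sub("^#chrom\t", "", header), header = FALSE)
    chromosomes <- data.frame(chrom = as.character(ch[[1]]),
                              length_bp = ch[[2]], length_M = ch[[3]])
  } else {
    chromosomes <- do.call(rbind, lapply(split(mk, mk$chrom), function(m) {
      gap <- if (nrow(m) > 1) stats::median(diff(m$bp)) else m$bp[1]
      data.frame(chrom = m$chrom[1], length_bp = max(m$bp) + gap,
                 length_M = (max(m$cM) + gap * max(m$cM) / max(m$bp)) / 100)
    }))
    rownames(chromosomes) <- NULL
  }
  genome_map(chromosomes, mk)
}

#' @rdname read_genome_map
#' @export
write_genome_map <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  ch <- map$chromosomes
  writeLines(sprintf("#chrom\t%s\t%s\t%s", ch$chrom, ch$length_bp, ch$length_M), con)
  utils::write.table(map$markers, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: map genetic position (cM) to bp on a chromosome by linear
# interpolation through the marker anchors plus the chromosome ends.
.cm_to_bp <- function(map, chrom, cm) {
  L <- chrom_length(map, chrom)
  Lcm <- chrom_morgans(map, chrom) * 100
  m <- map$markers[map$markers$chrom == chrom, ]
  xs <- c(0, m$cM, Lcm)
  ys <- c(0, m$bp, L)
  keep <- !duplicated(xs)
  stats::approx(xs[keep], ys[keep], xout = cm, rule = 2)$y
}
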