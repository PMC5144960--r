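#' Founder-mosaic chromosome
#'
#' A chromosome is represented as an ordered list of segments, each labelled
#' with the founder (A-H) it descends from. Segments are 0-based half-open:
#' a segment owns its start, not its end, so they tile `[0, length)` with no
#' gaps or overlaps, and adjacent segments always carry different founders
#' (equal-founder neighbours are collapsed by the constructor).
#'
#' Internally a mosaic stores only the segment start positions and integer
#' founder codes; ends are implicit.
#'
#' @param chrom Chromosome name.
#' @param length Chromosome physical length (bp).
#' @param start Numeric vector of segment starts; first must be 0, strictly
#'   increasing, all `< length`.
#' @param founder Founder letters (or integer codes 1-8), one per segment.
#' @return An object of class `founder_mosaic`.
#' @seealso [founder_at()], [mosaic_segments()]
#' @export
#' @examples
#' m <- founder_mosaic("2", 100e6, c(0, 50e6), c("A", "H"))
#' founder_at(m, 50e6)  # "H": the boundary belongs to the right segment
founder_mosaic <- function(chrom, length, start, founder) {
  f <- if (is.character(founder)) .f2i(founder) else as.integer(founder)
  m <- .new_mosaic(as.character(chrom), as.numeric(length),
                   as.numeric(start), f)
  validate_mosaic(m)
  m
}

# fast internal constructor: no checks, no collapsing
.new_mosaic <- function(chrom, length, start, founder) {
  structure(list(chrom = chrom, length = length,
                 start = start, founder = founder),
            class = "founder_mosaic")
}

# collapse runs of equal adjacent founders
.collapse_mosaic <- function(m) {
  n <- length(m$founder)
  if (n > 1L) {
    keep <- c(TRUE, m$founder[-1L] != m$founder[-n])
    if (!all(keep)) {
      m$start <- m$start[keep]
      m$founder <- m$founder[keep]
    }
  }
  m
}

#' Validate the segment-tiling invariant of a mosaic
#'
#' Checks that segments tile `[0, length)` exactly: first start 0, strictly
#' increasing starts below the chromosome length, founder codes in 1..8, and
#' no adjacent segments with equal founders.
#'
#' @param m A `founder_mosaic`.
#' @return `m`, invisibly; stops on violation.
#' @export
validate_mosaic <- function(m) {
  stopifnot(inherits(m, "founder_mosaic"))
  n <- length(m$start)
  if (n == 0L) stop("mosaic has no segments")
  if (length(m$founder) != n) stop("start/founder length mismatch")
  if (m$start[1L] != 0) stop("first segment must start at 0")
  if (n > 1L && any(diff(m$start) <= 0)) stop("segment starts must be strictly increasing")
  if (any(m$start >= m$length)) stop("segment start beyond chromosome length")
  if (any(m$founder < 1L | m$founder > 8L)) stop("founder codes must be in 1..8")
  if (n > 1L && any(m$founder[-1L] == m$founder[-n]))
    stop("adjacent segments must differ in founder")
  invisible(m)
}

#' @export
print.founder_mosaic <- function(x, ...) {
  cat("<founder_mosaic> chr", x$chrom, ": ", length(x$start), " segment(s)\n", sep = "")
  print(mosaic_segments(x))
  invisible(x)
}

#' Segment table of a mosaic
#'
#' @param m A `founder_mosaic`.
#' @return data.frame with `start`, `end` (half-open) and `founder` letters.
#' @export
mosaic_segments <- function(m) {
  data.frame(start = m$start,
             end = c(m$start[-1L], m$length),
             founder = .i2f(m$founder))
}

#' Build a mosaic from a segment table
#'
#' @param chrom,length Chromosome name and bp length.
#' @param segments data.frame with `start`, `end`, `founder`; must tile
#'   `[0, length)` contiguously.
#' @return A `founder_mosaic`.
#' @export
mosaic_from_segments <- function(chrom, length, segments) {
  o <- order(segments$start)
  segments <- segments[o, ]
  ends <- c(segments$start[-1L], length)
  if (any(abs(segments$end - ends) > 0)) stop("segments do not tile the chromosome")
  f <- if (is.character(segments$founder)) .f2i(segments$founder)
       else as.integer(segments$founder)
  m <- .collapse_mosaic(.new_mosaic(as.character(chrom), as.numeric(length),
                                    as.numeric(segments$start), f))
  validate_mosaic(m)
  m
}

#' Founder at a position
#'
#' Returns the founder label of the unique segment whose half-open interval
#' contains each query position.
#'
#' @param m A `founder_mosaic`.
#' @param pos Position(s) in bp; each must satisfy `0 <= pos < length`.
#' @param as Return founder `"letter"`s or internal `"integer"` codes.
#' @return Character (or integer) vector, one element per position.
#' @export
founder_at <- function(m, pos, as = c("letter", "integer")) {
  as <- match.arg(as)
  if (any(pos < 0 | pos >= m$length))
    stop("position outside chromosome [0, ", m$length, ")")
  f <- m$founder[findInterval(pos, m$start)]
  if (as == "letter") .i2f(f) else f
}

#' Random founder mosaic (G0-style chromosome)
#'
#' Draws a mosaic with `1 + Poisson(mean_segments - 1)` segments at uniform
#' breakpoints and i.i.d. uniform founder labels (adjacent duplicates are
#' collapsed). This is the stand-in for a chromosome sampled from a
#' well-mixed eight-founder population; it does not reproduce any
#' particular funnel structure.
#'
#' @param chrom,length Chromosome name and bp length.
#' @param mean_segments Expected segment count before collapsing (default 8).
#' @return A `founder_mosaic`.
#' @export
random_mosaic <- function(chrom, length, mean_segments = 8) {
  k <- stats::rpois(1L, max(mean_segments - 1, 0))
  start <- c(0, sort(stats::runif(k, 0, length)))
  f <- sample.int(8L, k + 1L, replace = TRUE)
  validate_mosaic(.collapse_mosaic(.new_mosaic(as.character(chrom),
                                               as.numeric(length), start, f)))
}

#' Recombine two homologous mosaics at given crossover positions
#'
#' Produces one meiotic product: material comes from homologue `first` up to
#' the first crossover, then alternates at each crossover. The complementary
#' product is obtained with the other `first`.
#'
#' @param h1,h2 Homologous `founder_mosaic`s (same chromosome and length).
#' @param xo Sorted crossover positions (bp), possibly empty.
#' @param first Which homologue contributes the first interval (1 or 2).
#' @return A `founder_mosaic`.
#' @export
recombine <- function(h1, h2, xo, first = 1L) {
  if (length(xo) == 0L) return(if (first == 1L) h1 else h2)
  L <- h1$length
  cuts <- c(0, xo)
  n_int <- length(cuts)
  ends <- c(xo, L)
  src <- rep_len(c(first, 3L - first), n_int)
  starts <- vector("list", n_int)
  fnds <- vector("list", n_int)
  for (i in seq_len(n_int)) {
    p <- if (src[i] == 1L) h1 else h2
    a <- cuts[i]; b <- ends[i]
    if (a >= b) { starts[[i]] <- numeric(0); fnds[[i]] <- integer(0); next }
    i1 <- findInterval(a, p$start)
    i2 <- findInterval(b, p$start)
    if (p$start[i2] == b) i2 <- i2 - 1L
    ss <- p$start[i1:i2]
    ss[1L] <- a
    starts[[i]] <- ss
    fnds[[i]] <- p$founder[i1:i2]
  }
  m <- .new_mosaic(h1$chrom, L, unlist(starts), unlist(fnds))
  .collapse_mosaic(m)
}
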