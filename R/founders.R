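#' Founder strain codes
#'
#' The eight founder strains of a Collaborative Cross / Diversity Outbred
#' style population are labelled with the conventional letters A-H.
#' Letter H (WSB/EiJ) is the carrier of the high-copy driven allele at the
#' drive locus in the default configuration.
#'
#' @return Named character vector mapping letters A-H to strain names.
#' @export
#' @examples
#' founder_strains()["H"]
founder_strains <- function() {
  c(A = "A/J", B = "C57BL/6J", C = "129S1/SvImJ", D = "NOD/ShiLtJ",
    E = "NZO/HlLtJ", F = "CAST/EiJ", G = "PWK/PhJ", H = "WSB/EiJ")
}

#' @rdname founder_strains
#' @export
founder_codes <- function() names(founder_strains())

# internal: letters <-> integer codes 1..8
.f2i <- function(x) {
  i <- match(x, founder_codes())
  if (anyNA(i)) stop("unknown founder code: ", paste(x[is.na(i)], collapse = ", "))
  i
}
.i2f <- function(i) founder_codes()[i]

#' Uniparental haplogroup of a founder strain
#'
#' Some founders are indistinguishable on the uniparental compartments:
#' the mitochondrial genome resolves five haplogroups (A/J, C57BL/6J,
#' 129S1/SvImJ and NOD/ShiLtJ share "ABCD") and the Y chromosome six
#' (C57BL/6J, 129S1/SvImJ and NZO/HlLtJ share "BCE").
#'
#' @param founder Founder letter(s) A-H.
#' @param compartment `"mito"` or `"Y"`.
#' @return Character vector of haplogroup labels.
#' @export
#' @examples
#' haplogroup_of("B", "Y")    # "BCE"
#' haplogroup_of("D", "mito") # "ABCD"
haplogroup_of <- function(founder, compartment = c("mito", "Y")) {
  compartment <- match.arg(compartment)
  map <- if (compartment == "mito") {
    c(A = "ABCD", B = "ABCD", C = "ABCD", D = "ABCD",
      E = "E", F = "F", G = "G", H = "H")
  } else {
    c(A = "A", B = "BCE", C = "BCE", D = "D",
      E = "BCE", F = "F", G = "G", H = "H")
  }
  unname(map[founder])
}

#' @rdname haplogroup_of
#' @export
haplogroup_levels <- function(compartment = c("mito", "Y")) {
  compartment <- match.arg(compartment)
  if (compartment == "mito") c("ABCD", "E", "F", "G", "H")
  else c("A", "BCE", "D", "F", "G", "H")
}
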