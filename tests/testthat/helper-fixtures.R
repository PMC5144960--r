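# Shared fixtures: small maps, individuals with known drive-locus
# genotypes, and haplogroup training matrices built from panel signatures.

small_map <- function(chroms = "2", markers = 20) {
  default_genome_map(chroms, markers_per_chrom = markers)
}

# an individual whose chr2 homologues are single-founder mosaics
locus_individual <- function(f1, f2, map = small_map(), sex = "F",
                             id = "ind1") {
  L <- chrom_length(map, "2")
  new_individual(id = id, sex = sex, generation = 1L, lineage = "L001",
                 genome = list(`2` = list(
                   h1 = founder_mosaic("2", L, 0, f1),
                   h2 = if (is.null(f2)) NULL
                        else founder_mosaic("2", L, 0, f2))),
                 mito = "ABCD", y = if (sex == "M") "A" else NA_character_)
}

# class-pure haplogroup training matrix from a panel's signatures
signature_training <- function(signatures, n_per_class = 10,
                               error_rate = 0) {
  classes <- rownames(signatures)
  x <- do.call(rbind, lapply(classes, function(cl)
    matrix(rep(2 * signatures[cl, ], n_per_class), n_per_class,
           ncol(signatures), byrow = TRUE)))
  colnames(x) <- colnames(signatures)
  if (error_rate > 0) {
    flip <- matrix(stats::runif(length(x)) < error_rate, nrow(x))
    x[flip] <- 2 - x[flip]
  }
  list(x = x, labels = rep(classes, each = n_per_class))
}
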