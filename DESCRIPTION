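Package: drivepurge
Title: Meiotic Drive, Marker-Assisted Purging, and Monitoring of
    Multiparent Breeding Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Forward-in-time simulation of a randomized multiparent
    outbreeding scheme (Diversity Outbred style, eight founder strains)
    with maternal meiotic drive at an autosomal locus, together with the
    mating-type algebra and deterministic predictions of a marker-assisted
    purge of the driven allele, and the colony-monitoring statistics used
    to track such an episode: founder haplotype frequency profiles from
    diplotype probabilities, SNP information content, private-allele
    retention, transmission-ratio-distortion tests, litter-size analysis,
    uniparental haplogroup classification by regularized linear
    discriminant analysis, and sex-chromosome anomaly calling (XO and
    distal-X duplication) from array hybridization intensities. Includes
    synthetic-data generators for marker panels, array genotype cohorts,
    and breeding-record tables so the full stack runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    yaml
Config/testthat/edition: 3
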