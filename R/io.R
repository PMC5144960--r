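#' Breeding-record table from a colony simulation
#'
#' One row per mating x litter (failed matings get a single flagged row),
#' with generation, lineage, dam/sire ids, parental genotypes at the drive
#' locus, and progeny counts by sex — the layout of a production-colony
#' breeding-record file.
#'
#' @param sim A [simulate_colony()] result (or any object with a
#'   `records` element).
#' @return data.frame of breeding records.
#' @export
emit_breeding_records <- function(sim) {
  if (is.data.frame(sim)) return(sim)
  if (is.null(sim$records)) stop("no records captured")
  sim$records
}

#' Read / write breeding records as TSV
#'
#' Round-trips exactly through [read_breeding_records()].
#'
#' @param records Breeding-record data.frame ([emit_breeding_records()]).
#' @param path TSV path.
#' @return The records (reader) or the path, invisibly (writer).
#' @export
write_breeding_records <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_breeding_records
#' @export
read_breeding_records <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(generation = "integer",
                                   lineage = "character",
                                   dam_id = "character",
                                   sire_id = "character",
                                   dam_geno = "character",
                                   sire_geno = "character",
                                   litter_index = "integer",
                                   n_female = "integer",
                                   n_male = "integer",
                                   failed = "logical",
                                   b_mating = "logical"))
}

#' Write / read an array cohort as a directory of TSV files
#'
#' `calls.tsv` and `lrr.tsv` are wide marker x sample tables;
#' `samples.tsv` holds the sample sheet (including anomaly truth). The
#' panel is written alongside via [write_panel()].
#'
#' @param cohort An [genotype_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory (writer) or an `array_cohort` without the noise
#'   model (reader).
#' @export
write_array_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) {
    df <- data.frame(marker = rownames(m), m, check.names = FALSE)
    utils::write.table(df, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wm(cohort$calls, "calls.tsv")
  wm(round(cohort$lrr, 5), "lrr.tsv")
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_panel(cohort$panel, dir)
  invisible(dir)
}

#' @rdname write_array_cohort
#' @export
read_array_cohort <- function(dir) {
  rm_ <- function(f, mode) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(m) <- mode
    rownames(m) <- df$marker
    m
  }
  structure(list(calls = rm_("calls.tsv", "integer"),
                 lrr = rm_("lrr.tsv", "double"),
                 true_calls = NULL,
                 samples = utils::read.delim(file.path(dir, "samples.tsv"),
                                             stringsAsFactors = FALSE,
                                             colClasses = c(id = "character")),
                 panel = read_panel(dir),
                 noise = NULL),
            class = "array_cohort")
}

#' Write / read a synthetic panel as TSV files
#'
#' `panel_markers.tsv` holds the marker annotation with the eight founder
#' consensus alleles as columns A-H; the uniparental class signatures go
#' to `panel_y_signatures.tsv` and `panel_mito_signatures.tsv`.
#'
#' @param panel A [generate_panel()] result.
#' @param dir Directory.
#' @return The directory (writer) or a `synthetic_panel` (reader).
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mk <- panel$markers
  cons <- matrix(NA_integer_, nrow(mk), 8L,
                 dimnames = list(NULL, founder_codes()))
  gi <- match(colnames(panel$consensus), mk$marker)
  cons[gi, ] <- t(panel$consensus)
  utils::write.table(cbind(mk, cons), file.path(dir, "panel_markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ws <- function(sig, f)
    utils::write.table(data.frame(class = rownames(sig), sig,
                                  check.names = FALSE),
                       file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  ws(panel$y_signatures, "panel_y_signatures.tsv")
  ws(panel$mito_signatures, "panel_mito_signatures.tsv")
  pb <- panel$par
  utils::write.table(data.frame(standard = pb$standard, cast = pb$cast),
                     file.path(dir, "panel_par.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_panel
#' @export
read_panel <- function(dir) {
  full <- utils::read.delim(file.path(dir, "panel_markers.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
  fc <- founder_codes()
  mk <- full[, setdiff(names(full), fc)]
  genomic <- !is.na(full$A)
  cons <- t(as.matrix(full[genomic, fc]))
  storage.mode(cons) <- "integer"
  colnames(cons) <- full$marker[genomic]
  rownames(cons) <- fc
  rs <- function(f) {
    df <- utils::read.delim(file.path(dir, f), check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$class
    m
  }
  pb <- utils::read.delim(file.path(dir, "panel_par.tsv"))
  y_sig <- rs("panel_y_signatures.tsv")
  mito_sig <- rs("panel_mito_signatures.tsv")
  structure(list(markers = mk, consensus = cons,
                 y_probes = colnames(y_sig),
                 mito_probes = colnames(mito_sig),
                 y_signatures = y_sig, mito_signatures = mito_sig,
                 par = par_info(pb$standard, pb$standard - pb$cast)),
            class = "synthetic_panel")
}

#' Write / read diplotype probabilities as wide TSV
#'
#' One row per sample x position with the 36 state probabilities as
#' columns (ordered as [diplotype_states()]).
#'
#' @param probs Array `n x P x 36` ([true_diplotype_probs()] layout).
#' @param sample_ids,positions Row annotations.
#' @param path TSV path.
#' @return The path (writer) or a list with `probs`, `sample_ids`,
#'   `positions` (reader).
#' @export
write_diplotype_probs <- function(probs, sample_ids, positions, path) {
  n <- dim(probs)[1]; P <- dim(probs)[2]
  flat <- matrix(aperm(probs, c(2, 1, 3)), n * P, 36L)
  colnames(flat) <- diplotype_states()
  df <- data.frame(sample = rep(sample_ids, each = P),
                   position = rep(positions, n), flat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_diplotype_probs
#' @export
read_diplotype_probs <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  sample_ids <- unique(df$sample)
  positions <- unique(df$position)
  n <- length(sample_ids); P <- length(positions)
  flat <- as.matrix(df[, diplotype_states()])
  probs <- aperm(array(flat, dim = c(P, n, 36L)), c(2, 1, 3))
  dimnames(probs) <- list(NULL, NULL, diplotype_states())
  list(probs = probs, sample_ids = sample_ids, positions = positions)
}

#' Run a colony simulation from a YAML/JSON config
#'
#' The config has named blocks `scheme`, `drive`, `litter`, `locus`,
#' `policy` (optional), plus top-level `generations`, `seed`,
#' `init_w_freq`, `map` (arguments to [default_genome_map()]). Block
#' entries are passed to the corresponding constructors.
#'
#' @param config A list, or a path to a YAML file (requires the `yaml`
#'   package) or JSON file (requires `jsonlite`).
#' @return A [simulate_colony()] result.
#' @export
simulate_colony_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("reading JSON configs requires the jsonlite package")
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs requires the yaml package")
      yaml::read_yaml(config)
    }
  }
  build <- function(ctor, block) do.call(ctor, as.list(block %||% list()))
  simulate_colony(
    generations = config$generations %||% stop("config needs 'generations'"),
    map = build(default_genome_map, config$map),
    scheme = build(scheme_params, config$scheme),
    litter = build(litter_model, config$litter),
    locus = build(drive_locus, config$locus),
    drive = build(drive_params, config$drive),
    policy = if (!is.null(config$policy)) build(purge_policy, config$policy),
    policy_start = config$policy_start %||% 1L,
    init_w_freq = config$init_w_freq,
    seed = config$seed)
}
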