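test_that("panel generation is deterministic and hits the private fraction", {
  map <- small_map(c("2", "X"), markers = 50)
  p1 <- generate_panel(map, seed = 51)
  p2 <- generate_panel(map, seed = 51)
  expect_identical(p1$consensus, p2$consensus)
  expect_identical(p1$markers, p2$markers)
  expect_identical(p1$y_signatures, p2$y_signatures)
  # fully informative panel: every marker private to exactly one founder
  pall <- generate_panel(map, private_fraction = 1, seed = 52)
  expect_true(all(colSums(pall$consensus) == 1L))
  # binomial check on the private fraction
  big <- generate_panel(default_genome_map("2", 2000),
                        private_fraction = 0.3, seed = 53)
  n_priv <- sum(!is.na(big$markers$private_founder))
  n_mark <- sum(big$markers$compartment %in% c("auto", "X"))
  expect_lt(abs(n_priv - 0.3 * n_mark), 3 * sqrt(n_mark * 0.3 * 0.7))
  # class signatures respect the separation margin
  d <- as.matrix(stats::dist(p1$y_signatures, method = "manhattan"))
  expect_gte(min(d[upper.tri(d)]), 2)
})

test_that("zero-noise genotyping round-trips the founder mosaics", {
  set.seed(54)
  map <- small_map("2", markers = 40)
  panel <- generate_panel(map, seed = 540)
  inds <- random_individuals(25, 0, map)
  quiet <- noise_model(genotype_error = 0, no_call = 0, lrr_sd = 1e-4)
  coh <- genotype_cohort(inds, panel, noise = quiet, seed = 541)
  expect_identical(coh$calls, coh$true_calls)
  # per-marker allele frequency from calls equals the mosaic-truth
  # frequency through the consensus map
  ids <- panel$markers$marker[panel$markers$compartment == "auto"]
  pos <- panel$markers$bp[match(ids, panel$markers$marker)]
  prof <- founder_frequency_profile(inds, pos, "2")
  freq_from_truth <- unname(colSums(prof * panel$consensus[, ids]))
  freq_from_calls <- rowMeans(coh$calls[ids, , drop = FALSE]) / 2
  expect_equal(unname(freq_from_calls), freq_from_truth, tolerance = 1e-12)
})

test_that("genotyping error rate is reproduced in call discordance", {
  set.seed(55)
  map <- small_map("2", markers = 150)
  panel <- generate_panel(map, seed = 550)
  inds <- random_individuals(120, 0, map)
  noisy <- noise_model(genotype_error = 0.02, no_call = 0)
  coh <- genotype_cohort(inds, panel, noise = noisy, seed = 551)
  gi <- panel$markers$compartment == "auto"
  obs <- coh$calls[gi, ]; tru <- coh$true_calls[gi, ]
  disc <- mean(obs != tru)
  n <- length(obs)
  expect_lt(abs(disc - 0.02), 3 * sqrt(0.02 * 0.98 / n))
  # no-call rate likewise
  coh2 <- genotype_cohort(inds[1:40], panel,
                          noise = noise_model(no_call = 0.05), seed = 552)
  nc_calls <- coh2$calls[gi, ]  # genomic rows: no structural missingness
  nc <- mean(is.na(nc_calls))
  expect_lt(abs(nc - 0.05), 3 * sqrt(0.05 * 0.95 / length(nc_calls)))
})

test_that("smoothed diplotype probabilities stay normalized and condense correctly", {
  set.seed(56)
  map <- small_map("2")
  inds <- random_individuals(10, 5, map)
  pos <- c(20e6, 90e6)
  probs <- true_diplotype_probs(inds, pos, "2", smoothing = 0.3)
  expect_equal(apply(probs, c(1, 2), sum),
               matrix(1, 15, 2), tolerance = 1e-12, ignore_attr = TRUE)
  prof <- founder_frequency_profile(probs)
  expect_equal(colSums(prof), c(1, 1), tolerance = 1e-9)
  # smoothing shrinks the profile toward uniform 1/8
  hard <- founder_frequency_profile(true_diplotype_probs(inds, pos, "2"))
  expect_equal(prof, 0.7 * hard + 0.3 * 0.125, tolerance = 1e-9)
})

test_that("breeding records have the expected shape and round-trip", {
  set.seed(57)
  map <- small_map(markers = 10)
  sim <- simulate_colony(2, map = map,
                         scheme = scheme_params(n_lineages = 20,
                                                failure_prob = 0),
                         seed = 570)
  rec <- emit_breeding_records(sim)
  # no failures: lineages x litters rows per generation
  expect_equal(nrow(rec), 2 * 20 * 2)
  expect_true(all(!rec$failed))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_breeding_records(rec, tsv)
  expect_identical(read_breeding_records(tsv), rec)
})

test_that("failed-mating fraction matches the configured probability", {
  set.seed(58)
  map <- small_map(markers = 10)
  sim <- simulate_colony(6, map = map,
                         scheme = scheme_params(n_lineages = 25,
                                                failure_prob = 0.1,
                                                duplicate_matings = FALSE),
                         seed = 580)
  rec <- sim$records
  # one failure row or litters_per_pair success rows per mating
  n_mat <- sum(rec$failed) + sum(!rec$failed) / 2
  frac <- sum(rec$failed) / n_mat
  # replacement redraws give surviving matings one extra failure chance,
  # so compare against the per-attempt rate with a binomial band
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / n_mat) + 0.02)
})

test_that("array cohorts, panels and diplotype tables round-trip as TSV", {
  set.seed(59)
  map <- small_map(c("2", "X"), markers = 15)
  panel <- generate_panel(map, seed = 590)
  inds <- random_individuals(6, 6, map)
  coh <- genotype_cohort(inds, panel, seed = 591)
  dir <- withr::local_tempdir()
  write_array_cohort(coh, dir)
  back <- read_array_cohort(dir)
  expect_identical(back$calls, coh$calls)
  expect_equal(back$lrr, coh$lrr, tolerance = 1e-4)
  expect_equal(back$samples$id, coh$samples$id)
  expect_identical(back$panel$consensus, panel$consensus)
  expect_identical(back$panel$y_signatures, panel$y_signatures)
  expect_equal(back$panel$par$standard, panel$par$standard)
  expect_equal(back$panel$markers$robust, panel$markers$robust)
  # diplotype wide TSV
  pos <- c(30e6, 60e6)
  probs <- true_diplotype_probs(inds, pos, "2", smoothing = 0.1)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_diplotype_probs(probs, coh$samples$id, pos, tsv)
  back2 <- read_diplotype_probs(tsv)
  expect_equal(back2$probs, probs, tolerance = 1e-12)
  expect_equal(back2$positions, pos)
})

test_that("config-driven simulation reproduces direct calls", {
  cfg <- list(generations = 2,
              map = list(chroms = "2", markers_per_chrom = 10),
              scheme = list(n_lineages = 8, failure_prob = 0),
              drive = list(tau = 0.7),
              litter = list(mean = 6),
              init_w_freq = 0.4,
              seed = 77)
  s1 <- simulate_colony_config(cfg)
  s2 <- simulate_colony(2, map = default_genome_map("2", 10),
                        scheme = scheme_params(8, failure_prob = 0),
                        litter = litter_model(mean = 6),
                        drive = drive_params(0.7),
                        init_w_freq = 0.4, seed = 77)
  expect_identical(s1$trajectory, s2$trajectory)
})
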