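test_that("haplogroup LDA separates clean class signatures perfectly", {
  set.seed(41)
  map <- small_map(c("2", "X"), markers = 30)
  panel <- generate_panel(map, seed = 410)
  tr <- signature_training(panel$y_signatures, n_per_class = 8)
  model <- train_haplogroup_classifier(tr$x, tr$labels,
                                       probes = panel$y_probes)
  pred <- assign_haplogroup(model, tr$x)
  expect_equal(pred$label, tr$labels)
  expect_true(all(pred$posterior > 0.99))
  # single class is degenerate
  expect_error(train_haplogroup_classifier(tr$x[1:8, ], tr$labels[1:8]),
               "two classes")
})

test_that("held-out haplogroup accuracy survives genotyping error", {
  set.seed(42)
  map <- small_map(c("2", "X"), markers = 30)
  panel <- generate_panel(map, seed = 420)
  tr <- signature_training(panel$y_signatures, n_per_class = 12,
                           error_rate = 0.02)
  model <- train_haplogroup_classifier(tr$x, tr$labels,
                                       probes = panel$y_probes)
  held <- signature_training(panel$y_signatures, n_per_class = 60,
                             error_rate = 0.02)
  pred <- assign_haplogroup(model, held$x)
  expect_gte(mean(pred$label == held$labels), 0.95)
  # mitochondrial panel, more probes, same machinery
  trm <- signature_training(panel$mito_signatures, n_per_class = 10,
                            error_rate = 0.02)
  mm <- train_haplogroup_classifier(trm$x, trm$labels,
                                    probes = panel$mito_probes)
  heldm <- signature_training(panel$mito_signatures, n_per_class = 40,
                              error_rate = 0.02)
  expect_gte(mean(assign_haplogroup(mm, heldm$x)$label == heldm$labels),
             0.98)
})

test_that("haplogroup assignment is invariant to probe order and flags ambiguity", {
  set.seed(43)
  map <- small_map(c("2", "X"), markers = 20)
  panel <- generate_panel(map, seed = 430)
  tr <- signature_training(panel$y_signatures, n_per_class = 6)
  model <- train_haplogroup_classifier(tr$x, tr$labels,
                                       probes = panel$y_probes)
  x <- tr$x[13, ]
  perm <- sample(seq_along(x))
  expect_equal(assign_haplogroup(model, x[perm])$label,
               assign_haplogroup(model, x)$label)
  # equidistant sample between two class centroids: low confidence
  mid <- (model$means[1, ] + model$means[2, ]) / 2
  names(mid) <- model$probes
  amb <- assign_haplogroup(model, mid)
  expect_true(amb$low_confidence)
  expect_lt(amb$posterior, 0.8)
  # missing more than half the probes is an error
  few <- x[1:3]
  expect_error(assign_haplogroup(model, few), "half")
})

test_that("regularized LDA agrees with reference LDA on a well-conditioned fixture", {
  # on jittered (nonsingular) training data with light shrinkage, the
  # in-package discriminant must reproduce MASS::lda assignments
  set.seed(47)
  map <- small_map(c("2", "X"), markers = 20)
  panel <- generate_panel(map, seed = 470)
  tr <- signature_training(panel$y_signatures, n_per_class = 25)
  x <- tr$x + matrix(stats::rnorm(length(tr$x), 0, 0.3), nrow(tr$x))
  model <- train_haplogroup_classifier(x, tr$labels,
                                       probes = panel$y_probes,
                                       lambda = 0.05, ridge = 1e-6)
  held <- signature_training(panel$y_signatures, n_per_class = 40)
  xh <- held$x + matrix(stats::rnorm(length(held$x), 0, 0.3), nrow(held$x))
  ours <- assign_haplogroup(model, xh)$label
  ref <- MASS::lda(x, grouping = tr$labels,
                   prior = rep(1 / 6, 6))
  theirs <- as.character(predict(ref, xh)$class)
  expect_gte(mean(ours == theirs), 0.99)
  expect_equal(ours, held$labels)
})

test_that("clean cohorts are karyotyped without error", {
  set.seed(44)
  map <- small_map(c("2", "X"), markers = 60)
  panel <- generate_panel(map, seed = 440)
  inds <- random_individuals(40, 40, map)
  coh <- genotype_cohort(inds, panel, seed = 441)
  k <- call_sex_karyotype(coh$calls, coh$lrr, panel)
  expect_equal(k, ifelse(coh$samples$sex == "F", "XX", "XY"))
  # and no male is flagged as a duplication carrier
  males <- which(coh$samples$sex == "M")
  hits <- vapply(males, function(j) !is.null(
    detect_x_duplication(coh$calls[, j], coh$lrr[, j], panel,
                         y_haplogroup = coh$samples$y[j])), TRUE)
  expect_identical(sum(hits), 0L)
})

test_that("injected anomalies are recovered by the callers", {
  set.seed(45)
  map <- small_map(c("2", "X"), markers = 100)
  panel <- generate_panel(map, seed = 450)
  inds <- random_individuals(10, 10, map)
  coh <- genotype_cohort(inds, panel, seed = 451)
  fid <- coh$samples$id[coh$samples$sex == "F"][1]
  mid <- coh$samples$id[coh$samples$sex == "M"][1]
  coh <- inject_anomaly(coh, fid, "XO")
  coh <- inject_anomaly(coh, mid, "distal_dup", dup_length = 20e6)
  jf <- match(fid, coh$samples$id); jm <- match(mid, coh$samples$id)
  expect_equal(call_sex_karyotype(coh$calls[, jf], coh$lrr[, jf], panel),
               "XO")
  dup <- detect_x_duplication(coh$calls[, jm], coh$lrr[, jm], panel,
                              y_haplogroup = coh$samples$y[jm])
  expect_false(is.null(dup))
  # interval overlap with the injected region (Jaccard >= 0.8)
  inj <- c(coh$samples$dup_start[jm], coh$samples$dup_end[jm])
  inter <- max(0, min(dup$end, inj[2]) - max(dup$start, inj[1]))
  uni <- max(dup$end, inj[2]) - min(dup$start, inj[1])
  expect_gte(inter / uni, 0.8)
  # XO sample characteristics by construction
  xi <- panel$markers$chrom == "X" & panel$markers$compartment == "X"
  expect_lt(mean(coh$lrr[xi, jf]), -0.25)
  expect_false(any(coh$calls[xi, jf] == 1L, na.rm = TRUE))
  # zero-length duplication leaves the sample unchanged
  before <- coh$calls[, jm]
  coh2 <- inject_anomaly(coh, mid, "distal_dup", dup_length = 0)
  expect_identical(coh2$calls[, jm], before)
  # sex compatibility enforced
  expect_error(inject_anomaly(coh, mid, "XO"), "female")
  expect_error(inject_anomaly(coh, fid, "distal_dup", dup_length = 5e6),
               "male")
})

test_that("CAST-extended PAR heterozygosity is not mistaken for a duplication", {
  set.seed(46)
  map <- small_map(c("2", "X"), markers = 60)
  panel <- generate_panel(map, seed = 460)
  # force a male with a CAST (F) Y chromosome
  inds <- random_individuals(2, 30, map)
  for (i in seq_along(inds)) if (inds[[i]]$sex == "M") inds[[i]]$y <- "F"
  coh <- genotype_cohort(inds, panel, seed = 461)
  males <- which(coh$samples$sex == "M")
  # with the CAST-aware boundary no duplication is called
  for (j in males) {
    expect_null(detect_x_duplication(coh$calls[, j], coh$lrr[, j], panel,
                                     y_haplogroup = "F"))
  }
  # the extended-PAR window does carry heterozygous, elevated markers
  ext <- which(panel$markers$chrom == "X" &
                 panel$markers$compartment == "X" &
                 panel$markers$bp >= panel$par$cast &
                 panel$markers$bp < panel$par$standard)
  expect_gte(length(ext), 2L)
  any_het <- any(vapply(males, function(j)
    any(coh$calls[ext, j] == 1L, na.rm = TRUE), TRUE))
  expect_true(any_het)
})
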