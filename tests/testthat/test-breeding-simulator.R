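test_that("crossover counts are Poisson in the genetic length", {
  set.seed(21)
  # custom 1-Morgan chromosome with a uniform cM <-> bp map
  chroms <- data.frame(chrom = "c1", length_bp = 100e6, length_M = 1)
  mk <- data.frame(marker = sprintf("m%d", 1:9), chrom = "c1",
                   bp = seq(10e6, 90e6, by = 10e6),
                   cM = seq(10, 90, by = 10))
  map <- genome_map(chroms, mk)
  draws <- replicate(4000, draw_crossovers(map, "c1"), simplify = FALSE)
  counts <- lengths(draws)
  expect_lt(abs(mean(counts) - 1), 3 * sqrt(1 / 4000))
  # positions uniform in bp under the uniform map
  pos <- unlist(draws)
  ks <- stats::ks.test(pos / 100e6, "punif")
  expect_gt(ks$p.value, 0.01)
  # zero genetic length: never any crossover
  map0 <- genome_map(data.frame(chrom = "c0", length_bp = 1e6, length_M = 0),
                     mk[0, ])
  expect_identical(replicate(50, length(draw_crossovers(map0, "c0"))),
                   rep(0L, 50))
})

test_that("gamete transmission from Wa dams converges to tau", {
  set.seed(22)
  map <- small_map()
  locus <- drive_locus()
  dam <- locus_individual("H", "B", map, sex = "F")
  frac_driven <- function(parent, tau, n = 2000) {
    hits <- vapply(seq_len(n), function(i) {
      g <- make_gamete(parent, map, locus, drive_params(tau))
      founder_at(g[["2"]], locus$pos) == "H"
    }, TRUE)
    mean(hits)
  }
  expect_equal(frac_driven(dam, 1.0, 500), 1.0)  # complete drive
  f66 <- frac_driven(dam, 0.66)
  expect_lt(abs(f66 - 0.66), 3 * sqrt(0.66 * 0.34 / 2000))
  # no drive through the male germline
  sire <- locus_individual("H", "B", map, sex = "M", id = "s1")
  fm <- frac_driven(sire, 0.95)
  expect_lt(abs(fm - 0.5), 3 * sqrt(0.25 / 2000))
  # homozygous dams are unbiased in founder terms too
  dam_hom <- locus_individual("H", "H", map)
  expect_equal(frac_driven(dam_hom, 0.9, 200), 1.0)
})

test_that("gamete mosaics always satisfy the tiling invariant", {
  set.seed(23)
  map <- small_map(c("2", "X"))
  pools <- founder_population(map, 2, candidates_per_sex = 2)
  parent <- pools[[1]][[1]]
  for (i in 1:50) {
    g <- make_gamete(parent, map, drive_locus(), drive_params(0.8))
    for (m in g) expect_silent(validate_mosaic(m))
  }
})

test_that("litter sizes respect the configured dam-genotype effect", {
  set.seed(24)
  m0 <- litter_model(mean = 8, wa_dam_effect = 0)
  x <- replicate(3000, draw_litter(1L, m0))
  se <- sqrt((8 + 8^2 / 20) / 3000)
  expect_lt(abs(mean(x) - 8), 3 * se)
  m1 <- litter_model(mean = 8, wa_dam_effect = 1)
  y <- replicate(3000, draw_litter(1L, m1))
  expect_lt(abs(mean(y) - 7), 3 * se)
  # the effect only applies to heterozygous dams
  z <- replicate(3000, draw_litter(2L, m1))
  expect_lt(abs(mean(z) - 8), 3 * se)
  expect_identical(unique(replicate(50, draw_litter(0L,
    litter_model(mean = 0)))), 0L)
})

test_that("each generation keeps every lineage populated with both sexes", {
  set.seed(25)
  map <- small_map()
  step <- breed_generation(founder_population(map, 12,
                                              candidates_per_sex = 4),
                           map, scheme_params(n_lineages = 12,
                                              failure_prob = 0),
                           generation = 1L)
  expect_equal(length(step$pools), 12L)
  for (pool in step$pools) {
    sexes <- vapply(pool, function(p) p$sex, "")
    expect_true(any(sexes == "F") && any(sexes == "M"))
  }
  # offspring lineage follows the dam (matrilineal), mito likewise
  for (lid in names(step$pools)) {
    dam <- step$dams[[match(lid, step$breeders$lineage)]]
    for (pup in step$pools[[lid]]) {
      expect_equal(pup$lineage, lid)
      expect_equal(pup$dam_id, dam$id)
      expect_equal(pup$mito, dam$mito)
    }
  }
})

test_that("uniparental haplogroup counts are conserved without failures", {
  # conservation is exact for every generation bred without cross-lineage
  # replacement; replacements (failed matings, or a sibship that lacks one
  # sex) are the only route by which the counts can move
  set.seed(26)
  map <- small_map()
  sim <- simulate_colony(5, map = map,
                         scheme = scheme_params(n_lineages = 15,
                                                failure_prob = 0),
                         seed = 260)
  tr <- sim$trajectory
  mito_cols <- grep("^mito_", names(tr))
  y_cols <- grep("^y_", names(tr))
  clean <- which(tr$n_replaced == 0)[-1]
  expect_gte(length(clean), 3L)
  for (g in clean) {
    expect_identical(unlist(tr[g, mito_cols]), unlist(tr[g - 1, mito_cols]))
    expect_identical(unlist(tr[g, y_cols]), unlist(tr[g - 1, y_cols]))
  }
  # and every change coincides with a replacement
  for (g in setdiff(2:5, clean)) {
    moved <- !identical(unlist(tr[g, mito_cols]), unlist(tr[g - 1, mito_cols])) ||
      !identical(unlist(tr[g, y_cols]), unlist(tr[g - 1, y_cols]))
    if (moved) expect_gt(tr$n_replaced[g], 0)
  }
})

test_that("mating failures open the only route to mito frequency change", {
  set.seed(27)
  map <- small_map(markers = 10)
  finals <- vapply(1:12, function(r) {
    sim <- simulate_colony(4, map = map,
                           scheme = scheme_params(n_lineages = 8,
                                                  failure_prob = 0.5,
                                                  duplicate_matings = FALSE),
                           litter = litter_model(mean = 6),
                           seed = 270 + r)
    sum(abs(unlist(sim$trajectory[4, grep("^mito_", names(sim$trajectory))]) -
              unlist(sim$trajectory[1, grep("^mito_", names(sim$trajectory))])))
  }, 0)
  expect_gt(var(finals), 0)   # haplogroup composition drifts across replicates
  expect_gt(sum(finals), 0)   # and actually changes within runs
})

test_that("colony trajectories are reproducible under a fixed seed", {
  map <- small_map(markers = 10)
  s1 <- simulate_colony(3, map = map, scheme = scheme_params(n_lineages = 8),
                        seed = 99)
  s2 <- simulate_colony(3, map = map, scheme = scheme_params(n_lineages = 8),
                        seed = 99)
  expect_identical(s1$trajectory, s2$trajectory)
  expect_identical(s1$records, s2$records)
})

test_that("sib-avoiding assignment never pairs full siblings", {
  set.seed(28)
  map <- small_map(markers = 10)
  pools <- founder_population(map, 10, candidates_per_sex = 3)
  for (i in 1:5) {
    step <- breed_generation(pools, map,
                             scheme_params(n_lineages = 10,
                                           failure_prob = 0),
                             generation = 1L)
    dk <- vapply(step$dams, function(x) paste(x$dam_id, x$sire_id), "")
    sk <- vapply(step$sires, function(x) paste(x$dam_id, x$sire_id), "")
    expect_true(all(dk != sk))
  }
})
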