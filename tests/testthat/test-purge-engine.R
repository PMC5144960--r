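test_that("mating classification flags the nine types correctly", {
  mt <- classify_mating(1, 1)
  expect_equal(mt$type, "WaxWa")
  expect_true(mt$produces_aa_possible)
  expect_true(mt$needs_genotyping)
  mt <- classify_mating(0, 2)
  expect_equal(mt$type, "aaxWW")
  expect_true(mt$forced_Wa)
  expect_false(mt$needs_genotyping)
  mt <- classify_mating(2, 2)
  expect_true(mt$discard)
  # exactly four types can yield aa progeny
  aa_types <- character(0)
  for (d in 0:2) for (s in 0:2) {
    m <- classify_mating(d, s)
    if (m$produces_aa_possible) aa_types <- c(aa_types, m$type)
  }
  expect_setequal(aa_types, c("aaxaa", "WaxWa", "Waxaa", "aaxWa"))
  expect_setequal(
    unlist(lapply(0:2, function(d) lapply(0:2, function(s)
      classify_mating(d, s)$type))),
    c("aaxaa","aaxWa","aaxWW","Waxaa","WaxWa","WaxWW","WWxaa","WWxWa","WWxWW"))
})

test_that("mating-type frequencies are the outer product of HWE marginals", {
  f <- mating_type_frequencies(0.5)
  expect_equal(f["WW", "WW"], 0.0625)
  expect_equal(sum(f), 1)
  f0 <- mating_type_frequencies(0)
  expect_equal(f0["aa", "aa"], 1)
  expect_equal(sum(f0 != 0), 1L)
  for (p in c(0.1, 0.33, 0.62, 0.9)) {
    f <- mating_type_frequencies(p)
    expect_equal(sum(f), 1)
    expect_equal(f, outer(rowSums(f), colSums(f)), tolerance = 1e-12)
  }
  # non-HWE states are accepted when internally consistent
  st <- allele_freq_state(0.5, c(WW = 0.4, Wa = 0.2, aa = 0.4))
  expect_equal(mating_type_frequencies(st)["WW", "aa"], 0.16)
  expect_error(allele_freq_state(0.5, c(WW = 0.5, Wa = 0.2, aa = 0.4)),
               "sum to 1")
  expect_error(allele_freq_state(0.3, c(WW = 0.4, Wa = 0.2, aa = 0.4)),
               "inconsistent")
})

test_that("progeny distributions follow maternal-only drive", {
  # independent oracle: enumerate the four gamete combinations explicitly
  oracle <- function(dam_w, sire_w, tau) {
    p_mat_W <- c(0, tau, 1)[dam_w + 1]       # drive in the female germline
    p_pat_W <- c(0, 0.5, 1)[sire_w + 1]      # Mendelian paternal gamete
    out <- c(aa = 0, Wa = 0, WW = 0)
    for (mw in 0:1) for (pw in 0:1) {
      pr <- (if (mw) p_mat_W else 1 - p_mat_W) *
            (if (pw) p_pat_W else 1 - p_pat_W)
      out[mw + pw + 1] <- out[mw + pw + 1] + pr
    }
    out
  }
  for (tau in c(0, 0.5, 0.66, 0.9, 1)) {
    for (d in 0:2) for (s in 0:2) {
      type <- paste0(w_label(d), "x", w_label(s))
      pd <- progeny_distribution(type, tau)
      expect_equal(sum(pd), 1)
      expect_equal(pd, oracle(d, s, tau), tolerance = 1e-12)
    }
  }
  expect_equal(progeny_distribution("WaxWa", 0.66),
               c(aa = 0.17, Wa = 0.5, WW = 0.33))
  # no paternal drive: aa dam x Wa sire is 1:1 regardless of tau
  expect_equal(progeny_distribution("aaxWa", 0.99),
               c(aa = 0.5, Wa = 0.5, WW = 0))
  # tau = 0.5 reproduces Mendelian ratios
  expect_equal(progeny_distribution("WaxWa", 0.5),
               c(aa = 0.25, Wa = 0.5, WW = 0.25))
})

test_that("breeder selection follows the minimum-W rule", {
  prog <- data.frame(sex = c("F", "F", "F", "M", "M"),
                     w = c(0L, 1L, 2L, 1L, 1L))
  sel <- select_breeders(prog, "WaxWa")
  expect_equal(sel$action, "select")
  expect_equal(sel$female_w, 0L)
  expect_equal(sel$male_w, 1L)
  expect_true(sel$genotyped)
  expect_equal(select_breeders(prog, "WWxWW")$action, "replace")
  # aa x aa needs no genotyping
  sel <- select_breeders(data.frame(sex = c("F", "M"), w = c(0L, 0L)),
                         "aaxaa")
  expect_false(sel$genotyped)
  expect_equal(sel$female_w, 0L)
  expect_equal(select_breeders(NULL, "WaxWa")$action, "replace")
  expect_equal(select_breeders(data.frame(sex = "F", w = 1L),
                               "WaxWa")$action, "replace")
  # WW x Wa with f = 1 is always retained and yields Wa
  sel <- select_breeders(data.frame(sex = c("F", "M"), w = c(1L, 2L)),
                         "WWxWa", purge_policy(retain_fraction = 1))
  expect_equal(sel$action, "select")
})

test_that("one-generation purge expectation matches independent enumeration", {
  # oracle: direct arithmetic over the nine types at p = 0.62, f = 0
  p <- 0.62
  g <- c(WW = p^2, Wa = 2 * p * (1 - p), aa = (1 - p)^2)
  forced <- g["aa"] * g["WW"] + g["WW"] * g["aa"]
  aa_capable <- g["aa"]^2 + g["Wa"]^2 + 2 * g["Wa"] * g["aa"]
  oracle <- unname(0.5 * forced / (forced + aa_capable))
  expect_equal(expected_post_selection_frequency(0.62, 0.66), oracle,
               tolerance = 1e-12)
  expect_equal(oracle, 0.1132854, tolerance = 1e-6)
  expect_equal(expected_post_selection_frequency(0, 0.66), 0)
  # retaining WW x Wa mass pulls the expectation up
  expect_gt(expected_post_selection_frequency(
    0.62, 0.66, purge_policy(retain_fraction = 0.5)), oracle)
  expect_error(
    expected_post_selection_frequency(
      1, 0.66, purge_policy(discard = c("WWxWW", "WWxWa", "WaxWW"))),
    "undefined")
})

test_that("finite-litter correction is small and vanishes for large litters", {
  inf <- expected_post_selection_frequency(0.62, 0.66)
  fin <- expected_post_selection_frequency(0.62, 0.66,
                                           infinite_litter = FALSE,
                                           litter = litter_model())
  expect_gt(fin, inf)   # finite litters sometimes fail to yield an aa pup
  expect_lt(fin, 0.35)
  big <- expected_post_selection_frequency(
    0.62, 0.66, infinite_litter = FALSE,
    litter = litter_model(mean = 60, wa_dam_effect = 0))
  expect_lt(abs(big - inf), 0.01)
  expect_error(expected_post_selection_frequency(0.62, 0.66,
                                                 infinite_litter = FALSE),
               "litter model")
})

test_that("drive recursion has the right fixed points and monotonicity", {
  expect_equal(drive_recursion(0.5, 0.5), 0.5)
  expect_equal(drive_recursion(0.125, 0.66), 0.1425)
  expect_equal(drive_recursion(1, 0.9), 1)
  expect_equal(drive_recursion(0, 0.9), 0)
  ps <- seq(0.01, 0.99, by = 0.07)
  expect_true(all(drive_recursion(ps, 0.75) > ps))   # sweep when tau > 1/2
  expect_equal(drive_recursion(ps, 0.5), ps)         # martingale at tau = 1/2
  expect_true(all(drive_recursion(ps, 0.75) < 1))
})

test_that("threshold-crossing generation counts match direct iteration", {
  expect_equal(generations_to_threshold(0.125, 0.75, 0.60, "up"), 10L)
  expect_equal(generations_to_threshold(0.62, 0.66, 0.15, "down"), 1L)
  expect_error(generations_to_threshold(0.125, 0.5, 0.60, "up",
                                        max_iter = 200),
               "divergence")
})
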