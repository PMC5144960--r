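#' Marker-assisted purge policy
#'
#' The breeder-selection policy used to purge the driven allele: matings in
#' the discard set (by default the WW x WW type) are replaced outright;
#' matings with one WW and one Wa parent, whose progeny are at best Wa, are
#' retained only with probability `retain_fraction`; among retained matings
#' the progeny carrying the minimum number of driven alleles are selected
#' as breeders (only offspring of crosses with a Wa parent need genotyping
#' — aa x aa progeny are all aa and aa x WW / WW x aa progeny are all Wa).
#'
#' @param discard Character vector of discarded mating types (as
#'   `"WWxWW"`-style labels, dam first).
#' @param retain_fraction Fraction `f` of WW x Wa / Wa x WW matings
#'   retained (default 0, the strictest purge).
#' @param min_w_selection Select minimum-W progeny as breeders (default
#'   TRUE).
#' @return An object of class `purge_policy`.
#' @export
purge_policy <- function(discard = "WWxWW", retain_fraction = 0,
                         min_w_selection = TRUE) {
  stopifnot(retain_fraction >= 0, retain_fraction <= 1, length(discard) >= 1)
  structure(list(discard = discard, retain_fraction = retain_fraction,
                 min_w_selection = min_w_selection),
            class = "purge_policy")
}

#' Classify a mating by parental drive-locus genotypes
#'
#' The nine mating types are the ordered pairs of dam and sire genotypes
#' `{WW, Wa, aa}`. Flags report whether the type can produce aa progeny
#' (aa x aa, Wa x Wa, Wa x aa, aa x Wa), whether all progeny are forced Wa
#' (aa x WW, WW x aa), whether a Wa parent makes progeny genotyping
#' necessary, and how the purge policy treats the type (`discard`, or
#' `fractional` retention for WW x Wa / Wa x WW).
#'
#' @param dam_w,sire_w Driven-allele counts (0/1/2) of dam and sire.
#' @param policy A [purge_policy()].
#' @return List with `type` (e.g. `"WaxWW"`), `dam`, `sire`,
#'   `produces_aa_possible`, `forced_Wa`, `needs_genotyping`, `discard`,
#'   `fractional`.
#' @export
#' @examples
#' classify_mating(1, 1)$produces_aa_possible  # TRUE
#' classify_mating(2, 2)$discard               # TRUE
classify_mating <- function(dam_w, sire_w, policy = purge_policy()) {
  stopifnot(dam_w %in% 0:2, sire_w %in% 0:2)
  dam <- w_label(dam_w); sire <- w_label(sire_w)
  type <- paste0(dam, "x", sire)
  list(type = type, dam = dam, sire = sire,
       produces_aa_possible = dam_w < 2 && sire_w < 2,
       forced_Wa = (dam_w == 0 && sire_w == 2) || (dam_w == 2 && sire_w == 0),
       needs_genotyping = dam_w == 1 || sire_w == 1,
       discard = type %in% policy$discard,
       fractional = type %in% c("WWxWa", "WaxWW"))
}

#' Genotype-frequency state at the drive locus
#'
#' Allele frequency `p` of the driven allele plus the genotype frequencies
#' (WW, Wa, aa), defaulting to Hardy-Weinberg proportions. Non-HWE states
#' may be supplied directly.
#'
#' @param p Driven-allele frequency in `[0, 1]`.
#' @param genotype_freqs Optional named numeric `c(WW=, Wa=, aa=)` summing
#'   to 1; must satisfy `p = WW + Wa/2`.
#' @return An object of class `allele_freq_state`.
#' @export
allele_freq_state <- function(p, genotype_freqs = NULL) {
  stopifnot(p >= 0, p <= 1)
  if (is.null(genotype_freqs)) {
    genotype_freqs <- c(WW = p^2, Wa = 2 * p * (1 - p), aa = (1 - p)^2)
  } else {
    genotype_freqs <- genotype_freqs[c("WW", "Wa", "aa")]
    if (abs(sum(genotype_freqs) - 1) > 1e-8)
      stop("genotype frequencies must sum to 1")
    if (abs(genotype_freqs[["WW"]] + genotype_freqs[["Wa"]] / 2 - p) > 1e-8)
      stop("genotype frequencies inconsistent with p")
  }
  structure(list(p = p, genotype_freqs = genotype_freqs),
            class = "allele_freq_state")
}

#' Mating-type frequency table
#'
#' Under random mating the nine mating-type frequencies are the outer
#' product of the dam and sire genotype frequencies; at the start of the
#' purge (p = 0.6 under HWE) this reproduces the published 3 x 3 table with
#' marginals 0.36 / 0.48 / 0.16.
#'
#' @param state An [allele_freq_state()] (or a bare allele frequency).
#' @return 3 x 3 matrix, rows = dam genotype, columns = sire genotype,
#'   entries summing to 1.
#' @export
#' @examples
#' mating_type_frequencies(0.6)["WW", "WW"]  # 0.1296
mating_type_frequencies <- function(state) {
  if (is.numeric(state)) state <- allele_freq_state(state)
  g <- state$genotype_freqs
  outer(g, g)
}

#' Progeny genotype distribution of a mating type under maternal drive
#'
#' The maternal gamete is biased by `tau` iff the dam is heterozygous; the
#' paternal gamete is always Mendelian (drive acts only through the female
#' germline). For Wa x Wa: P(WW) = tau/2, P(Wa) = 1/2, P(aa) = (1-tau)/2.
#'
#' @param mtype A mating type from [classify_mating()], or a `"WaxWW"`-style
#'   string (dam first).
#' @param tau Maternal transmission probability of the driven allele.
#' @return Named numeric `c(aa=, Wa=, WW=)` summing to 1.
#' @export
#' @examples
#' progeny_distribution("WaxWa", 0.66)  # (0.17, 0.50, 0.33)
progeny_distribution <- function(mtype, tau) {
  stopifnot(tau >= 0, tau <= 1)
  if (is.list(mtype)) mtype <- mtype$type
  parts <- strsplit(mtype, "x", fixed = TRUE)[[1]]
  w <- c(aa = 0L, Wa = 1L, WW = 2L)
  dam_w <- w[[parts[1]]]; sire_w <- w[[parts[2]]]
  # maternal P(gamete carries W)
  pm <- switch(as.character(dam_w), "0" = 0, "1" = tau, "2" = 1)
  pp <- sire_w / 2
  c(aa = (1 - pm) * (1 - pp),
    Wa = pm * (1 - pp) + (1 - pm) * pp,
    WW = pm * pp)
}

#' Select breeders from genotyped progeny under the purge policy
#'
#' Returns the minimum-W female and male among a mating's progeny (ties
#' broken at random), a replacement request for discarded or non-retained
#' mating types, or a replacement request when a required sex is missing.
#' Progeny of matings without a Wa parent are returned without genotyping
#' (their genotype is forced by the parents).
#'
#' @param progeny data.frame with columns `sex` (`"F"`/`"M"`) and `w`
#'   (0/1/2), or NULL/empty for a failed mating.
#' @param mtype Output of [classify_mating()] (or a type string).
#' @param policy A [purge_policy()].
#' @return List with `action` (`"select"` or `"replace"`), and for selects
#'   `female_w` and `male_w` (selected genotypes) plus `genotyped`.
#' @export
select_breeders <- function(progeny, mtype, policy = purge_policy()) {
  if (is.character(mtype)) {
    parts <- strsplit(mtype, "x", fixed = TRUE)[[1]]
    w <- c(aa = 0L, Wa = 1L, WW = 2L)
    mtype <- classify_mating(w[[parts[1]]], w[[parts[2]]], policy)
  }
  if (mtype$discard)
    return(list(action = "replace", reason = "discarded mating type"))
  if (mtype$fractional && stats::runif(1) >= policy$retain_fraction)
    return(list(action = "replace", reason = "fractional retention"))
  if (is.null(progeny) || nrow(progeny) == 0L)
    return(list(action = "replace", reason = "no progeny"))
  pick <- function(sex) {
    sub <- progeny[progeny$sex == sex, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    if (policy$min_w_selection && mtype$needs_genotyping) {
      sub <- sub[sub$w == min(sub$w), , drop = FALSE]
    }
    sub$w[if (nrow(sub) == 1L) 1L else sample.int(nrow(sub), 1L)]
  }
  fw <- pick("F"); mw <- pick("M")
  if (is.null(fw) || is.null(mw))
    return(list(action = "replace", reason = "missing sex among progeny"))
  list(action = "select", female_w = fw, male_w = mw,
       genotyped = mtype$needs_genotyping)
}

#' Expected driven-allele frequency among next-generation breeders
#'
#' Exact enumeration over the nine mating types under the purge policy:
#' discarded and non-retained mass is redistributed proportionally over the
#' retained matings; retained aa-capable matings contribute breeders of
#' genotype aa under the infinite-litter idealization (or the finite-litter
#' expectation of the per-sex minimum-W genotype when
#' `infinite_litter = FALSE`); forced-Wa matings contribute Wa; WW x Wa and
#' Wa x WW matings retained under a positive `retain_fraction` contribute
#' Wa. The result is the expected driven-allele count over 2 alleles per
#' breeder.
#'
#' @param state An [allele_freq_state()] or bare allele frequency.
#' @param tau Maternal transmission probability (enters only through the
#'   finite-litter path and WaxWW-type corrections).
#' @param policy A [purge_policy()].
#' @param infinite_litter If TRUE (default), assume an aa pup is always
#'   obtainable from an aa-capable mating.
#' @param litter A [litter_model()]; required when
#'   `infinite_litter = FALSE`.
#' @param litters Litters pooled per pair when genotyping progeny for the
#'   finite-litter expectation (default 2).
#' @return Expected driven-allele frequency in `[0, 1]`.
#' @export
#' @examples
#' expected_post_selection_frequency(0.62, 0.66)  # about 0.113
expected_post_selection_frequency <- function(state, tau,
                                              policy = purge_policy(),
                                              infinite_litter = TRUE,
                                              litter = NULL, litters = 2L) {
  if (is.numeric(state)) state <- allele_freq_state(state)
  stopifnot(tau >= 0, tau <= 1)
  if (!infinite_litter && is.null(litter))
    stop("finite-litter expectation requires a litter model")
  freqs <- mating_type_frequencies(state)
  genos <- c("WW", "Wa", "aa")
  total_mass <- 0
  w_mass <- 0
  for (dg in genos) for (sg in genos) {
    mass <- freqs[dg, sg]
    if (mass == 0) next
    type <- paste0(dg, "x", sg)
    if (type %in% policy$discard) next
    mt <- classify_mating(c(WW = 2L, Wa = 1L, aa = 0L)[[dg]],
                          c(WW = 2L, Wa = 1L, aa = 0L)[[sg]], policy)
    if (mt$fractional) {
      mass <- mass * policy$retain_fraction
      if (mass == 0) next
      ew <- 1  # progeny are WW or Wa; min-W selection takes Wa
    } else if (mt$forced_Wa) {
      ew <- 1
    } else if (type == "WWxWW") {
      ew <- 2
    } else if (infinite_litter) {
      ew <- 0  # aa obtainable from every aa-capable mating
    } else {
      ew <- .finite_litter_min_w(type, tau, litter, litters,
                                 dam_w = c(WW = 2L, Wa = 1L, aa = 0L)[[dg]])
    }
    total_mass <- total_mass + mass
    w_mass <- w_mass + mass * ew
  }
  if (total_mass <= 0) stop("all mating mass discarded; frequency undefined")
  w_mass / (2 * total_mass)
}

# expected min-W genotype of one breeder of each sex, averaged, for an
# aa-capable mating with finite litters: pooled litter size n (sum of
# `litters` neg. binomials), per-sex count k ~ Binomial(n, 1/2), genotypes
# i.i.d. from progeny_distribution; min over the k genotyped pups of that
# sex. A missing sex triggers replacement in the simulator; here it is
# conditioned away by renormalizing over k >= 1.
.finite_litter_min_w <- function(type, tau, litter, litters, dam_w) {
  pr <- progeny_distribution(type, tau)  # c(aa, Wa, WW)
  mu <- litter$mean
  if (dam_w == 1L) {
    mu <- if (litter$effect_type == "additive") max(mu - litter$wa_dam_effect, 0)
          else mu * (1 - litter$wa_dam_effect)
  }
  mu <- mu * litters
  size <- litter$dispersion * litters  # sum of iid NB shares the mean/size scaling
  nmax <- max(30, stats::qnbinom(1 - 1e-8, mu = mu, size = size))
  pn <- stats::dnbinom(0:nmax, mu = mu, size = size)
  pk <- numeric(nmax + 1L)
  for (n in 0:nmax) pk <- pk + pn[n + 1L] * stats::dbinom(0:nmax, n, 0.5)[1:(nmax + 1L)]
  ks <- 1:nmax
  pk1 <- pk[ks + 1L]
  pk1 <- pk1 / sum(pk1)  # condition on at least one pup of the sex
  # P(min over k pups = g)
  p_aa <- pr[["aa"]]; p_wa <- pr[["Wa"]]
  pmin_aa <- 1 - (1 - p_aa)^ks
  pmin_wa <- (1 - p_aa)^ks - (1 - p_aa - p_wa)^ks
  pmin_ww <- (1 - p_aa - p_wa)^ks
  sum(pk1 * (0 * pmin_aa + 1 * pmin_wa + 2 * pmin_ww))
}

#' Deterministic allele-frequency recursion under maternal drive
#'
#' One generation of random mating under HWE with maternal drive: the
#' maternal gamete frequency of the driven allele is
#' `p^2 + 2 p (1 - p) tau` and the paternal gamete frequency is Mendelian
#' (`p`), so `p' = (p^2 + 2 p (1 - p) tau + p) / 2`. For `tau = 0.5` this
#' is the Mendelian martingale `p' = p`; for `tau > 0.5` the only fixed
#' points are 0 and 1 and the frequency increases monotonically — a selfish
#' sweep.
#'
#' @param p Driven-allele frequency in `[0, 1]` (vectorized).
#' @param tau Maternal transmission probability.
#' @return Next-generation allele frequency.
#' @export
#' @examples
#' drive_recursion(0.125, 0.66)  # 0.1425
drive_recursion <- function(p, tau) {
  stopifnot(all(p >= 0 & p <= 1), tau >= 0, tau <= 1)
  (p^2 + 2 * p * (1 - p) * tau + p) / 2
}

#' Generations needed to cross a frequency threshold
#'
#' Iterates [drive_recursion()] (direction `"up"`, the unchecked sweep) or
#' [expected_post_selection_frequency()] with an HWE state at each step
#' (direction `"down"`, the purge) and returns the smallest generation
#' count at which the frequency passes the threshold.
#'
#' @param p0 Starting allele frequency.
#' @param tau Maternal transmission probability.
#' @param threshold Frequency threshold in `(0, 1)`.
#' @param direction `"up"` (exceed threshold) or `"down"` (fall below).
#' @param policy Purge policy for direction `"down"`.
#' @param max_iter Iteration cap; crossing failure raises a divergence
#'   error.
#' @return Integer generation count.
#' @export
#' @examples
#' generations_to_threshold(0.125, 0.75, 0.60, "up")  # 10
generations_to_threshold <- function(p0, tau, threshold,
                                     direction = c("up", "down"),
                                     policy = purge_policy(),
                                     max_iter = 1000L) {
  direction <- match.arg(direction)
  stopifnot(threshold > 0, threshold < 1, p0 >= 0, p0 <= 1)
  p <- p0
  for (n in seq_len(max_iter)) {
    p <- if (direction == "up") drive_recursion(p, tau)
         else expected_post_selection_frequency(allele_freq_state(p), tau, policy)
    if ((direction == "up" && p > threshold) ||
        (direction == "down" && p < threshold)) return(n)
  }
  stop("threshold ", threshold, " not crossed within ", max_iter,
       " generations (divergence)")
}
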