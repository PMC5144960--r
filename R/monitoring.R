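#' The 36 unphased diplotype states
#'
#' Canonical state order for eight founders: the 8 homozygous states
#' (`"AA"` ... `"HH"`) followed by the 28 heterozygous states `"fg"` with
#' `f < g` in letter order (`"AB"`, `"AC"`, ...).
#'
#' @return Character vector of length 36.
#' @export
diplotype_states <- function() {
  f <- founder_codes()
  hom <- paste0(f, f)
  het <- character(0)
  for (i in 1:7) for (j in (i + 1):8) het <- c(het, paste0(f[i], f[j]))
  c(hom, het)
}

# 36 x 8 condensation matrix: dosage contribution of each state to each
# founder (2 for the matching homozygote, 1 for each matching heterozygote)
.condense_matrix <- function() {
  states <- diplotype_states()
  f <- founder_codes()
  C <- matrix(0, 36L, 8L, dimnames = list(states, f))
  for (s in states) {
    a <- substr(s, 1, 1); b <- substr(s, 2, 2)
    C[s, a] <- C[s, a] + 1
    C[s, b] <- C[s, b] + 1
  }
  C
}

#' Condense diplotype probabilities to founder dosages
#'
#' Collapses a 36-state unphased diplotype probability vector to the eight
#' founder haplotype dosages: `dosage_f = 2 P(ff) + sum_{g != f} P(fg)`.
#' Dosages sum to 2; dividing by 2 gives the per-sample founder frequency
#' contribution.
#'
#' @param probs Numeric vector of length 36 (ordered as
#'   [diplotype_states()]), or a matrix with 36 columns (one row per
#'   sample-marker).
#' @param tol Normalization tolerance (each 36-vector must sum to 1 within
#'   `tol`).
#' @return Named dosage vector of length 8, or a matrix with 8 columns.
#' @export
#' @examples
#' p <- rep(1 / 36, 36)
#' condense_diplotypes(p)  # 0.25 for every founder
condense_diplotypes <- function(probs, tol = 1e-6) {
  C <- .condense_matrix()
  if (is.matrix(probs)) {
    if (ncol(probs) != 36L) stop("expected 36 columns of state probabilities")
    if (any(probs < -tol)) stop("negative diplotype probabilities")
    s <- rowSums(probs)
    if (any(abs(s - 1) > tol)) stop("diplotype probabilities must sum to 1")
    return(probs %*% C)
  }
  if (length(probs) != 36L) stop("expected a 36-state probability vector")
  if (any(probs < -tol)) stop("negative diplotype probabilities")
  if (abs(sum(probs) - 1) > tol) stop("diplotype probabilities must sum to 1")
  drop(probs %*% C)
}

#' Founder-frequency profile of a cohort
#'
#' Estimates the frequency of each founder haplotype at the given positions
#' by averaging per-sample founder dosages. Two input paths are supported
#' and agree exactly when the probabilistic input is the indicator of the
#' true mosaics: a list of `do_individual`s (alleles counted directly from
#' the mosaics) or a 3-d array of diplotype probabilities
#' (`samples x positions x 36`, condensed then averaged).
#'
#' @param x List of `do_individual`s, or a numeric array
#'   `n x length(positions) x 36`.
#' @param positions bp positions (for mosaic input).
#' @param chrom Chromosome name (for mosaic input).
#' @return 8 x positions matrix of founder frequencies; columns sum to 1.
#' @export
founder_frequency_profile <- function(x, positions = NULL, chrom = NULL) {
  if (is.array(x) && length(dim(x)) == 3L) {
    if (dim(x)[3] != 36L) stop("third dimension must hold 36 states")
    if (dim(x)[1] == 0L) stop("empty cohort")
    P <- dim(x)[2]
    out <- matrix(0, 8L, P, dimnames = list(founder_codes(), NULL))
    for (j in seq_len(P))
      out[, j] <- colMeans(condense_diplotypes(x[, j, , drop = TRUE])) / 2
    return(out)
  }
  if (!length(x)) stop("empty cohort")
  if (is.null(positions) || is.null(chrom))
    stop("mosaic input requires positions and chrom")
  counts <- matrix(0, 8L, length(positions),
                   dimnames = list(founder_codes(), NULL))
  total <- 0L
  for (ind in x) {
    pair <- ind$genome[[chrom]]
    if (is.null(pair)) stop("individual ", ind$id, " has no chromosome ", chrom)
    for (h in pair[c("h1", "h2")]) {
      if (is.null(h)) next
      f <- h$founder[findInterval(positions, h$start)]
      for (j in seq_along(positions)) counts[f[j], j] <- counts[f[j], j] + 1
      total <- total + 1L
    }
  }
  counts / total
}

#' Shannon entropy of a biallelic SNP
#'
#' Information content in bits: `H = -q log2 q - (1-q) log2(1-q)` with
#' `0 log 0 = 0`. The maximum (1 bit) is reached at minor allele frequency
#' 1/2; monomorphic SNPs carry none.
#'
#' @param q Allele frequency (vectorized, in `[0, 1]`).
#' @return Entropy in bits.
#' @export
#' @examples
#' snp_entropy(c(0, 0.5, 1))  # 0 1 0
snp_entropy <- function(q) {
  stopifnot(all(q >= 0 & q <= 1))
  term <- function(x) ifelse(x > 0, -x * log2(x), 0)
  term(q) + term(1 - q)
}

#' Retention of founder-private variants
#'
#' A variant private to one founder is retained in the cohort iff that
#' founder's haplotype frequency at the variant's position is positive.
#' Frequencies are looked up in a founder-frequency profile at the nearest
#' profiled position.
#'
#' @param mask data.frame with columns `variant`, `chrom`, `bp`, `founder`
#'   (owning founder letter).
#' @param profile 8 x P founder-frequency matrix
#'   ([founder_frequency_profile()] output).
#' @param positions bp positions of the profile columns.
#' @param chrom Chromosome of the profile (mask rows on other chromosomes
#'   are dropped).
#' @param region Optional `c(start, end)` bp filter.
#' @return List with `fraction` retained, and per-variant `retained`
#'   logicals.
#' @export
private_allele_retention <- function(mask, profile, positions, chrom,
                                     region = NULL) {
  if (is.null(mask) || nrow(mask) == 0L) stop("empty private-variant mask")
  mask <- mask[mask$chrom == chrom, , drop = FALSE]
  if (!is.null(region))
    mask <- mask[mask$bp >= region[1] & mask$bp < region[2], , drop = FALSE]
  if (nrow(mask) == 0L)
    return(list(fraction = NA_real_, retained = logical(0), mask = mask))
  idx <- vapply(mask$bp, function(b) which.min(abs(positions - b)), 0L)
  ret <- profile[cbind(match(mask$founder, founder_codes()), idx)] > 0
  list(fraction = mean(ret), retained = ret, mask = mask)
}

#' Transmission-ratio-distortion test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed
#' transmission counts against the Mendelian 1:1 expectation, plus the
#' estimated transmission ratio with a binomial confidence interval. The
#' default applies no continuity correction.
#'
#' @param n_driven Progeny count inheriting the driven allele.
#' @param n_other Progeny count inheriting the alternative.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @param ci `"wald"` or `"exact"` (Clopper-Pearson via
#'   [stats::binom.test()]).
#' @param conf_level Confidence level for the interval.
#' @return List with `statistic`, `p_value`, `ratio`, `ci` (length 2),
#'   `n`.
#' @export
#' @examples
#' trd_test(159, 108)$p_value  # 0.0018
trd_test <- function(n_driven, n_other, correct = FALSE,
                     ci = c("wald", "exact"), conf_level = 0.95) {
  ci <- match.arg(ci)
  stopifnot(n_driven >= 0, n_other >= 0)
  n <- n_driven + n_other
  if (n == 0) stop("no transmissions to test")
  e <- n / 2
  dev <- abs(c(n_driven, n_other) - e)
  if (correct) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / e)
  r <- n_driven / n
  interval <- if (ci == "exact") {
    as.numeric(stats::binom.test(n_driven, n,
                                 conf.level = conf_level)$conf.int)
  } else {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    se <- sqrt(r * (1 - r) / n)
    pmin(pmax(c(r - z * se, r + z * se), 0), 1)
  }
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       ratio = r, ci = interval, n = n)
}

#' One-way ANOVA of litter size by parental drive-locus genotype
#'
#' Fits litter size against the dam (or sire) genotype for one litter
#' index, as used to monitor the fitness cost of heterozygosity at the
#' drive locus: heterozygous dams produce smaller litters while sire
#' genotype has no effect.
#'
#' @param records Breeding-record data.frame with columns `dam_geno`,
#'   `sire_geno`, `litter_index`, `n_female`, `n_male`, `failed`.
#' @param parent Group by `"dam"` or `"sire"` genotype.
#' @param litter_index Which litter to analyze (default 1).
#' @return List with `F`, `p_value`, `medians` (per genotype), `n` (per
#'   genotype).
#' @export
litter_anova <- function(records, parent = c("dam", "sire"),
                         litter_index = 1) {
  parent <- match.arg(parent)
  d <- records[!records$failed & records$litter_index == litter_index, ,
               drop = FALSE]
  d$size <- d$n_female + d$n_male
  d$geno <- d[[paste0(parent, "_geno")]]
  tab <- table(d$geno)
  if (length(tab) < 2L || any(tab < 2L))
    stop("need at least two genotype groups with two or more litters")
  if (stats::var(d$size) == 0) {
    return(list(F = 0, p_value = 1,
                medians = tapply(d$size, d$geno, stats::median),
                n = as.integer(tab)))
  }
  fit <- stats::anova(stats::lm(size ~ geno, data = d))
  Fv <- fit[["F value"]][1]
  pv <- fit[["Pr(>F)"]][1]
  list(F = Fv,
       p_value = pv,
       medians = tapply(d$size, d$geno, stats::median),
       n = as.integer(tab))
}
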