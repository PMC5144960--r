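#' Meiotic-drive parameters
#'
#' Drive acts only through the female germline: in a dam heterozygous at the
#' drive locus the meiotic product carrying the driven allele at the locus
#' point is transmitted with probability `tau`; sires and homozygous dams
#' transmit each product with probability 1/2. Reported transmission ratios
#' range from 0.5 to 1 depending on genetic background; the optional
#' `tau_sampler` draws a per-dam tau once per mating to emulate that
#' background dependence.
#'
#' @param tau Transmission probability of the driven allele from
#'   heterozygous dams (in `[0, 1]`; biologically `[0.5, 1]`, default 0.66).
#' @param tau_sampler Optional `function(n)` returning `n` per-dam taus.
#' @return An object of class `drive_params`.
#' @export
drive_params <- function(tau = 0.66, tau_sampler = NULL) {
  stopifnot(tau >= 0, tau <= 1)
  structure(list(tau = tau, tau_sampler = tau_sampler), class = "drive_params")
}

#' Breeding-scheme parameters
#'
#' The randomized outbreeding scheme: a fixed number of matrilineal
#' lineages; at each generation one female and one male are selected from
#' each lineage's progeny (first litters when possible) and assigned to
#' mating pairs at random with avoidance of full-sibling pairs. Duplicate
#' "B" matings use full siblings of the primary pair and serve as a backup
#' when the primary mating fails; if both fail, another lineage provides
#' both parents.
#'
#' @param n_lineages Number of lineages (default 175).
#' @param duplicate_matings Keep a sibling backup pair per lineage (default
#'   TRUE).
#' @param failure_prob Per-mating failure probability (default 0.05, the
#'   middle of the observed 3-7% range; failures ran above 10% at the peak
#'   of the purge, so an elevated value is appropriate for purge studies).
#' @param litters_per_pair Litters produced per mated pair (default 2).
#' @param avoid_sibs Avoid pairing full siblings (default TRUE).
#' @return An object of class `scheme_params`.
#' @export
scheme_params <- function(n_lineages = 175, duplicate_matings = TRUE,
                          failure_prob = 0.05, litters_per_pair = 2,
                          avoid_sibs = TRUE) {
  stopifnot(n_lineages >= 2, failure_prob >= 0, failure_prob <= 1,
            litters_per_pair >= 1)
  structure(list(n_lineages = as.integer(n_lineages),
                 duplicate_matings = duplicate_matings,
                 failure_prob = failure_prob,
                 litters_per_pair = as.integer(litters_per_pair),
                 avoid_sibs = avoid_sibs),
            class = "scheme_params")
}

#' Litter-size model
#'
#' Litter sizes are drawn from a negative binomial (non-negative by
#' construction) whose mean is reduced for dams heterozygous at the drive
#' locus — heterozygous dams have smaller litters, while sire genotype has
#' no effect. The magnitude of the reduction is a free parameter.
#'
#' @param mean Base mean litter size (default 8).
#' @param wa_dam_effect Reduction applied to heterozygous (Wa) dams
#'   (default 1.5 pups for `"additive"`, a fraction for
#'   `"multiplicative"`).
#' @param effect_type `"additive"` or `"multiplicative"`.
#' @param dispersion Negative-binomial size parameter (larger = closer to
#'   Poisson; default 20).
#' @return An object of class `litter_model`.
#' @export
litter_model <- function(mean = 8, wa_dam_effect = 1.5,
                         effect_type = c("additive", "multiplicative"),
                         dispersion = 20) {
  effect_type <- match.arg(effect_type)
  stopifnot(mean >= 0, wa_dam_effect >= 0, dispersion > 0)
  structure(list(mean = mean, wa_dam_effect = wa_dam_effect,
                 effect_type = effect_type, dispersion = dispersion),
            class = "litter_model")
}

# ---- crossover machinery ---------------------------------------------------

# precompute per-chromosome interpolation anchors for cM -> bp inversion
.map_anchors <- function(map) {
  out <- vector("list", nrow(map$chromosomes))
  names(out) <- map$chromosomes$chrom
  for (i in seq_along(out)) {
    cc <- map$chromosomes$chrom[i]
    L <- map$chromosomes$length_bp[i]
    M <- map$chromosomes$length_M[i]
    m <- map$markers[map$markers$chrom == cc, ]
    xs <- c(0, m$cM, 100 * M)
    ys <- c(0, m$bp, L)
    keep <- !duplicated(xs)
    xs <- xs[keep]; ys <- ys[keep]
    out[[i]] <- list(M = M, Lcm = 100 * M, xs = xs, ys = ys,
                     slope = diff(ys) / diff(xs))
  }
  out
}

# fast crossover draw from precomputed anchors
.draw_xo <- function(a) {
  n <- stats::rpois(1L, a$M)
  if (n == 0L) return(numeric(0))
  u <- stats::runif(n, 0, a$Lcm)
  if (n > 1L) u <- sort.int(u, method = "quick")
  i <- findInterval(u, a$xs, rightmost.closed = TRUE)
  a$ys[i] + (u - a$xs[i]) * a$slope[i]
}

#' Draw crossover positions for one meiosis
#'
#' Crossover count is Poisson with mean equal to the chromosome's genetic
#' length in Morgans (no interference); positions are uniform in genetic
#' distance and mapped to bp by inverting the marker-anchored cM-to-bp map.
#'
#' @param map A [genome_map()].
#' @param chrom Chromosome name.
#' @return Sorted numeric vector of crossover positions in bp (possibly
#'   empty).
#' @export
draw_crossovers <- function(map, chrom) {
  a <- .map_anchors(map)[[chrom]]
  if (is.null(a)) stop("chromosome not in map: ", chrom)
  .draw_xo(a)
}

#' Draw a litter size
#'
#' @param dam_w Dam's driven-allele count (0/1/2); only `dam_w == 1`
#'   reduces the mean.
#' @param model A [litter_model()].
#' @return Non-negative integer litter size.
#' @export
draw_litter <- function(dam_w, model) {
  mu <- model$mean
  if (dam_w == 1L) {
    mu <- if (model$effect_type == "additive") max(mu - model$wa_dam_effect, 0)
          else mu * (1 - model$wa_dam_effect)
  }
  if (mu == 0) return(0L)
  as.integer(stats::rnbinom(1L, mu = mu, size = model$dispersion))
}

# fast internal gamete: anchors precomputed, no argument checking
.fast_gamete <- function(genome, anchors, locus, tau, is_female) {
  out <- genome  # reuse names/shape
  for (cc in names(genome)) {
    pair <- genome[[cc]]
    if (is.null(pair$h2)) { out[[cc]] <- pair$h1; next }
    xo <- .draw_xo(anchors[[cc]])
    first <- 0L
    if (is_female && !is.null(locus) && cc == locus$chrom) {
      h1 <- pair$h1; h2 <- pair$h2
      f1 <- h1$founder[findInterval(locus$pos, h1$start)]
      f2 <- h2$founder[findInterval(locus$pos, h2$start)]
      d1 <- f1 == locus$driven_code
      if (xor(d1, f2 == locus$driven_code)) {
        driven_first <- if (d1) 1L else 2L
        if (sum(xo <= locus$pos) %% 2 == 1) driven_first <- 3L - driven_first
        first <- if (stats::runif(1) < tau) driven_first else 3L - driven_first
      }
    }
    if (first == 0L) first <- if (stats::runif(1) < 0.5) 1L else 2L
    out[[cc]] <- recombine(pair$h1, pair$h2, xo, first)
  }
  out
}

#' Generate one gamete from a parent
#'
#' Each chromosome of the gamete is a recombinant of the parent's two
#' homologues given Poisson crossovers. For a dam heterozygous at the drive
#' locus, the recombinant product that carries the driven allele at the
#' locus point is transmitted with probability `tau`, so linked flanking
#' material hitchhikes with whichever product is chosen. Sires and
#' homozygous dams transmit either product with probability 1/2.
#' Hemizygous chromosomes (male X) are transmitted intact.
#'
#' @param parent A `do_individual`.
#' @param map A [genome_map()].
#' @param locus A [drive_locus()] or NULL (no drive anywhere).
#' @param drive A [drive_params()] or NULL.
#' @param tau Transmission probability override (e.g. a per-dam draw);
#'   defaults to `drive$tau`.
#' @return Named list of `founder_mosaic`s, one per chromosome of the
#'   parent's genome.
#' @export
make_gamete <- function(parent, map, locus = NULL, drive = NULL, tau = NULL) {
  if (is.null(tau)) tau <- if (!is.null(drive)) drive$tau else 0.5
  .fast_gamete(parent$genome, .map_anchors(map), locus, tau,
               parent$sex == "F")
}

# fast internal individual constructor (validated fields only come from
# internal call sites)
.fast_individual <- function(id, sex, generation, lineage, genome, mito, y,
                             dam_id, sire_id, litter) {
  structure(list(id = id, sex = sex, generation = generation,
                 lineage = lineage, genome = genome, mito = mito, y = y,
                 karyotype = if (sex == "F") "XX" else "XY",
                 dam_id = dam_id, sire_id = sire_id, litter = litter),
            class = "do_individual")
}

#' Founding (G0) population
#'
#' Builds one sibship pool per lineage: `candidates_per_sex` females and
#' males whose chromosomes are independent random founder mosaics
#' ([random_mosaic()]). Within a pool all individuals share a mitochondrial
#' and (for males) a Y haplogroup, drawn from a uniform founder of origin.
#' Optionally the allele at the drive locus is forced to the driven founder
#' with probability `init_w_freq` per homologue (Hardy-Weinberg at that
#' frequency), to start a simulation mid-sweep.
#'
#' @param map A [genome_map()].
#' @param n_lineages Number of lineages.
#' @param locus A [drive_locus()] (needed when `init_w_freq` is set).
#' @param init_w_freq Initial driven-allele frequency, or NULL for the
#'   unconstrained 1/8 expectation.
#' @param mean_segments Expected G0 segments per chromosome (default 8).
#' @param candidates_per_sex Pool size per sex per lineage (default 8,
#'   matching the roughly two litters a mated pair contributes).
#' @return Named list (lineage id) of lists of `do_individual`s.
#' @export
founder_population <- function(map, n_lineages = 175, locus = NULL,
                               init_w_freq = NULL, mean_segments = 8,
                               candidates_per_sex = 8) {
  if (!is.null(init_w_freq) && is.null(locus))
    stop("init_w_freq requires a drive locus")
  chroms <- map$chromosomes$chrom
  lens <- stats::setNames(map$chromosomes$length_bp, chroms)
  autos <- setdiff(chroms, "X")
  has_x <- "X" %in% chroms
  pools <- vector("list", n_lineages)
  names(pools) <- sprintf("L%03d", seq_len(n_lineages))
  for (li in seq_len(n_lineages)) {
    lid <- names(pools)[li]
    mito <- haplogroup_of(.i2f(sample.int(8L, 1L)), "mito")
    ychr <- haplogroup_of(.i2f(sample.int(8L, 1L)), "Y")
    pool <- vector("list", 2L * candidates_per_sex)
    k <- 0L
    for (sex in c("F", "M")) for (j in seq_len(candidates_per_sex)) {
      genome <- lapply(stats::setNames(autos, autos), function(cc)
        list(h1 = random_mosaic(cc, lens[[cc]], mean_segments),
             h2 = random_mosaic(cc, lens[[cc]], mean_segments)))
      if (has_x) {
        genome[["X"]] <- if (sex == "F")
          list(h1 = random_mosaic("X", lens[["X"]], mean_segments),
               h2 = random_mosaic("X", lens[["X"]], mean_segments))
        else list(h1 = random_mosaic("X", lens[["X"]], mean_segments),
                  h2 = NULL)
      }
      if (!is.null(init_w_freq)) {
        pair <- genome[[locus$chrom]]
        pair$h1 <- .force_locus_allele(pair$h1, locus,
                                       stats::runif(1) < init_w_freq)
        pair$h2 <- .force_locus_allele(pair$h2, locus,
                                       stats::runif(1) < init_w_freq)
        genome[[locus$chrom]] <- pair
      }
      k <- k + 1L
      pool[[k]] <- .fast_individual(
        id = sprintf("G0_%s_%s%d", lid, sex, j), sex = sex,
        generation = 0L, lineage = lid, genome = genome, mito = mito,
        y = if (sex == "M") ychr else NA_character_,
        dam_id = paste0("G0dam_", lid), sire_id = paste0("G0sire_", lid),
        litter = 1L + (j > ceiling(candidates_per_sex / 2)))
    }
    pools[[li]] <- pool
  }
  pools
}

# set (or clear) the driven allele on the segment containing the locus
.force_locus_allele <- function(h, locus, make_driven) {
  i <- findInterval(locus$pos, h$start)
  if (make_driven) {
    if (h$founder[i] != locus$driven_code) h$founder[i] <- locus$driven_code
  } else if (h$founder[i] == locus$driven_code) {
    h$founder[i] <- sample(setdiff(1:8, locus$driven_code), 1L)
  }
  .collapse_mosaic(h)
}

# ---- breeder selection from a lineage pool --------------------------------

# pick one individual of `sex`. Without a purge policy: uniform among the
# first litter with candidates of that sex ("first litters when possible").
# Under min-W selection all litters are genotyped and searched; ties prefer
# earlier litters, then random.
.pick_candidate <- function(pool, sex, locus = NULL, min_w = FALSE) {
  if (!length(pool)) return(NULL)
  sexes <- vapply(pool, function(p) p$sex, "")
  idx <- which(sexes == sex)
  if (!length(idx)) return(NULL)
  litters <- vapply(pool[idx], function(p) p$litter %||% 1L, 1L)
  if (min_w && !is.null(locus)) {
    ws <- vapply(pool[idx], w_count, 0L, locus = locus)
    idx <- idx[ws == min(ws)]
    litters <- litters[ws == min(ws)]
  }
  idx <- idx[litters == min(litters)]
  pool[[if (length(idx) == 1L) idx else sample(idx, 1L)]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-sibship key: two individuals with equal keys are full siblings
.sib_key <- function(ind) paste(ind$dam_id, ind$sire_id, sep = "|")

# random assignment of sires to dam slots avoiding full-sib pairs
.assign_sires <- function(dam_keys, sire_keys, avoid = TRUE, max_tries = 1000L) {
  n <- length(dam_keys)
  perm <- sample.int(n)
  if (!avoid) return(perm)
  for (t in seq_len(max_tries)) {
    bad <- which(dam_keys == sire_keys[perm])
    if (!length(bad)) return(perm)
    for (j in bad) {
      k <- sample.int(n, 1L)
      tmp <- perm[j]; perm[j] <- perm[k]; perm[k] <- tmp
    }
  }
  stop("could not find a sib-avoiding mate assignment")
}

#' Breed one generation
#'
#' Selects one dam and one sire per lineage from the candidate pools, pairs
#' them with a random sib-avoiding assignment, applies the purge policy (if
#' any) to the resulting mating types, simulates litters with maternal
#' meiotic drive, and returns the next generation's candidate pools plus a
#' breeding-record table. Offspring inherit the dam's mitochondrial
#' haplogroup and lineage and the sire's Y haplogroup. Failed matings fall
#' back on the duplicate sibling pair and then on a donor lineage that
#' provides both parents.
#'
#' @param pools Named list (lineage) of candidate `do_individual`s (the
#'   previous generation's progeny, or [founder_population()] output).
#' @param map,scheme,litter,locus,drive See the respective constructors.
#' @param policy A [purge_policy()], or NULL for unselected breeding.
#' @param generation Generation index of the offspring.
#' @return List with `pools` (next-generation candidates by lineage),
#'   `records` (one row per mating x litter; failed matings get one row
#'   with `failed = TRUE`), `breeders` (per-slot dam/sire summary), and
#'   the selected `dams` and `sires`.
#' @export
breed_generation <- function(pools, map, scheme = scheme_params(),
                             litter = litter_model(), locus = drive_locus(),
                             drive = drive_params(), policy = NULL,
                             generation = 1L) {
  lids <- names(pools)
  n <- length(lids)
  if (n < 2L) stop("need at least two lineages")
  min_w <- !is.null(policy) && policy$min_w_selection
  anchors <- .map_anchors(map)
  nonempty <- which(vapply(pools, length, 0L) > 0L)
  if (!length(nonempty)) stop("all lineage pools are empty")

  pick_pair_from <- function(li) {
    list(f = .pick_candidate(pools[[li]], "F", locus, min_w),
         m = .pick_candidate(pools[[li]], "M", locus, min_w))
  }
  donor_lineage <- function(exclude) {
    ok <- setdiff(nonempty, exclude)
    if (!length(ok)) stop("no donor lineage available")
    if (length(ok) == 1L) ok else sample(ok, 1L)
  }

  # 1. select a female and male candidate per lineage (donor on shortfall)
  dams <- vector("list", n); males <- vector("list", n)
  replaced <- logical(n)
  for (i in seq_len(n)) {
    pr <- pick_pair_from(i)
    tries <- 0L
    while ((is.null(pr$f) || is.null(pr$m)) && tries < 50L) {
      dpr <- pick_pair_from(donor_lineage(i))
      if (is.null(pr$f)) pr$f <- dpr$f
      if (is.null(pr$m)) pr$m <- dpr$m
      replaced[i] <- TRUE
      tries <- tries + 1L
    }
    if (is.null(pr$f) || is.null(pr$m))
      stop("could not populate lineage ", lids[i])
    dams[[i]] <- pr$f; males[[i]] <- pr$m
  }

  # 2. sib-avoiding assignment of the males to dam slots
  perm <- .assign_sires(vapply(dams, .sib_key, ""),
                        vapply(males, .sib_key, ""),
                        avoid = scheme$avoid_sibs)
  sires <- males[perm]

  # 3. purge policy: drop / replace non-retained mating types
  if (!is.null(policy)) {
    for (i in seq_len(n)) {
      tries <- 0L
      repeat {
        mt <- classify_mating(w_count(dams[[i]], locus),
                              w_count(sires[[i]], locus), policy)
        keep <- !mt$discard &&
          (!mt$fractional || stats::runif(1) < policy$retain_fraction)
        if (keep || tries >= 50L) break
        pr <- pick_pair_from(donor_lineage(integer(0)))
        if (!is.null(pr$f)) dams[[i]] <- pr$f
        pr2 <- pick_pair_from(donor_lineage(integer(0)))
        if (!is.null(pr2$m)) sires[[i]] <- pr2$m
        replaced[i] <- TRUE
        tries <- tries + 1L
      }
    }
  }

  # 4. matings and litters
  dam_w <- vapply(dams, w_count, 0L, locus = locus)
  sire_w <- vapply(sires, w_count, 0L, locus = locus)
  taus <- if (!is.null(drive$tau_sampler)) drive$tau_sampler(n)
          else rep(drive$tau, n)

  offspring <- vector("list", n)
  # record accumulators (one slot per mating x litter, failed = one slot)
  r_lin <- character(0); r_dam <- character(0); r_sire <- character(0)
  r_dg <- character(0); r_sg <- character(0); r_lit <- integer(0)
  r_nf <- integer(0); r_nm <- integer(0); r_fail <- logical(0)
  r_b <- logical(0)
  pup_counter <- 0L
  for (i in seq_len(n)) {
    dam <- dams[[i]]; sire <- sires[[i]]
    b_used <- FALSE
    # attempt chain: A pair, then the sibling B pair, then donor-lineage
    # replacements; every failed attempt is logged as a failed mating
    attempt <- 0L
    failed <- TRUE
    while (failed && attempt < 6L) {
      attempt <- attempt + 1L
      failed <- stats::runif(1) < scheme$failure_prob
      if (!failed) break
      # log the failed attempt
      r_lin <- c(r_lin, lids[i]); r_dam <- c(r_dam, dam$id)
      r_sire <- c(r_sire, sire$id)
      r_dg <- c(r_dg, w_label(w_count(dam, locus)))
      r_sg <- c(r_sg, w_label(w_count(sire, locus)))
      r_lit <- c(r_lit, NA_integer_); r_nf <- c(r_nf, 0L); r_nm <- c(r_nm, 0L)
      r_fail <- c(r_fail, TRUE); r_b <- c(r_b, b_used)
      # choose the next pair to try
      if (attempt == 1L && scheme$duplicate_matings) {
        bf <- .pick_candidate(pools[[dam$lineage]], "F", locus, min_w)
        bm <- .pick_candidate(pools[[sire$lineage]], "M", locus, min_w)
        if (!is.null(bf) && !is.null(bm)) {
          dam <- bf; sire <- bm; b_used <- TRUE
          next
        }
      }
      d <- donor_lineage(integer(0))
      pr <- pick_pair_from(d)
      pr2 <- pick_pair_from(donor_lineage(d))
      if (!is.null(pr$f) && !is.null(pr2$m)) {
        dam <- pr$f; sire <- pr2$m
        b_used <- FALSE
        replaced[i] <- TRUE
      }
    }
    dam_w[i] <- w_count(dam, locus); sire_w[i] <- w_count(sire, locus)
    dams[[i]] <- dam; sires[[i]] <- sire
    dg <- w_label(dam_w[i]); sg <- w_label(sire_w[i])
    if (failed) {
      offspring[[i]] <- list()
      next
    }
    dam_genome <- dam$genome; sire_genome <- sire$genome
    dam_female <- TRUE
    pups <- vector("list", 0L)
    for (lit in seq_len(scheme$litters_per_pair)) {
      sz <- draw_litter(dam_w[i], litter)
      nf <- if (sz > 0) stats::rbinom(1L, sz, 0.5) else 0L
      if (sz > 0) {
        newpups <- vector("list", sz)
        for (px in seq_len(sz)) {
          pup_counter <- pup_counter + 1L
          mg <- .fast_gamete(dam_genome, anchors, locus, taus[i], TRUE)
          pg <- .fast_gamete(sire_genome, anchors, locus, 0.5, FALSE)
          sex <- if (px <= nf) "F" else "M"
          genome <- mg
          for (cc in names(genome)) {
            genome[[cc]] <- if (cc == "X") {
              if (sex == "F") list(h1 = mg[[cc]], h2 = pg[[cc]])
              else list(h1 = mg[[cc]], h2 = NULL)
            } else list(h1 = mg[[cc]], h2 = pg[[cc]])
          }
          newpups[[px]] <- .fast_individual(
            id = sprintf("G%d_%s_%04d", generation, lids[i], pup_counter),
            sex = sex, generation = as.integer(generation),
            lineage = lids[i], genome = genome, mito = dam$mito,
            y = if (sex == "M") sire$y else NA_character_,
            dam_id = dam$id, sire_id = sire$id, litter = lit)
        }
        pups <- c(pups, newpups)
      }
      r_lin <- c(r_lin, lids[i]); r_dam <- c(r_dam, dam$id)
      r_sire <- c(r_sire, sire$id); r_dg <- c(r_dg, dg); r_sg <- c(r_sg, sg)
      r_lit <- c(r_lit, lit); r_nf <- c(r_nf, nf); r_nm <- c(r_nm, sz - nf)
      r_fail <- c(r_fail, FALSE); r_b <- c(r_b, b_used)
    }
    offspring[[i]] <- pups
  }
  names(offspring) <- lids
  records <- data.frame(generation = as.integer(generation), lineage = r_lin,
                        dam_id = r_dam, sire_id = r_sire, dam_geno = r_dg,
                        sire_geno = r_sg, litter_index = r_lit,
                        n_female = r_nf, n_male = r_nm, failed = r_fail,
                        b_mating = r_b)
  list(pools = offspring,
       records = records,
       breeders = data.frame(lineage = lids,
                             dam_id = vapply(dams, function(x) x$id, ""),
                             sire_id = vapply(sires, function(x) x$id, ""),
                             dam_w = dam_w, sire_w = sire_w,
                             dam_mito = vapply(dams, function(x) x$mito, ""),
                             sire_y = vapply(sires, function(x) x$y, ""),
                             replaced = replaced),
       dams = dams, sires = sires)
}

#' Simulate a breeding colony forward in time
#'
#' Runs [breed_generation()] for `generations` generations from a founding
#' population and records a per-generation trajectory: driven-allele
#' frequency among breeders and progeny, founder frequencies at monitor
#' positions on the drive chromosome (among breeders), mitochondrial and Y
#' haplogroup counts among breeders, litter statistics, and failure counts.
#'
#' @param generations Number of generations to simulate.
#' @param map A [genome_map()]. The default restricts the genome to the
#'   drive chromosome and X, which is sufficient for drive-locus and
#'   uniparental monitoring and keeps run time modest; pass a fuller map to
#'   track other chromosomes.
#' @param scheme,litter,locus,drive See the respective constructors.
#' @param policy A [purge_policy()] applied from `policy_start` on, or NULL.
#' @param policy_start First generation at which the policy applies.
#' @param init_w_freq Founding driven-allele frequency (NULL = neutral 1/8
#'   expectation).
#' @param monitor_positions bp positions on the drive chromosome at which
#'   founder frequencies are recorded (default: the locus).
#' @param candidates_per_sex G0 pool size per sex per lineage.
#' @param seed Optional integer seed (reproducible trajectories).
#' @return An object of class `colony_sim`: list with `trajectory`
#'   (data.frame, one row per generation), `records` (breeding records),
#'   and `final_pools`.
#' @export
#' @examples
#' sim <- simulate_colony(3, map = default_genome_map("2", 20),
#'                        scheme = scheme_params(n_lineages = 10),
#'                        seed = 1)
#' sim$trajectory$w_freq_breeders
simulate_colony <- function(generations,
                            map = default_genome_map(c("2", "X")),
                            scheme = scheme_params(),
                            litter = litter_model(),
                            locus = drive_locus(),
                            drive = drive_params(),
                            policy = NULL, policy_start = 1L,
                            init_w_freq = NULL,
                            monitor_positions = locus$pos,
                            candidates_per_sex = 8,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!locus$chrom %in% map$chromosomes$chrom)
    stop("map does not include the drive chromosome")
  pools <- founder_population(map, scheme$n_lineages, locus, init_w_freq,
                              candidates_per_sex = candidates_per_sex)
  mito_lv <- haplogroup_levels("mito")
  y_lv <- haplogroup_levels("Y")
  traj <- vector("list", generations)
  recs <- vector("list", generations)
  for (g in seq_len(generations)) {
    pol <- if (!is.null(policy) && g >= policy_start) policy else NULL
    step <- breed_generation(pools, map, scheme, litter, locus, drive,
                             policy = pol, generation = g)
    br <- step$breeders
    prog <- unlist(step$pools, recursive = FALSE, use.names = FALSE)
    prog_w <- if (length(prog)) vapply(prog, w_count, 0L, locus = locus) else integer(0)
    ffreq <- .breeder_founder_freq(c(step$dams, step$sires), locus$chrom,
                                   monitor_positions)
    sizes <- step$records$n_female + step$records$n_male
    ok <- !step$records$failed
    row <- data.frame(generation = g,
                      w_freq_breeders = sum(br$dam_w + br$sire_w) /
                        (4 * nrow(br)),
                      w_freq_progeny = if (length(prog_w)) mean(prog_w) / 2
                                       else NA_real_,
                      mean_litter = if (any(ok)) mean(sizes[ok]) else NA_real_,
                      n_failed = sum(step$records$failed),
                      n_replaced = sum(br$replaced))
    for (f in seq_len(8L))
      for (j in seq_along(monitor_positions))
        row[[sprintf("freq_%s%s", .i2f(f),
                     if (length(monitor_positions) > 1) paste0("_", j) else "")]] <-
          ffreq[f, j]
    for (h in mito_lv) row[[paste0("mito_", h)]] <- sum(br$dam_mito == h)
    for (h in y_lv) row[[paste0("y_", h)]] <- sum(br$sire_y == h)
    traj[[g]] <- row
    recs[[g]] <- step$records
    pools <- step$pools
  }
  structure(list(trajectory = do.call(rbind, traj),
                 records = do.call(rbind, recs),
                 final_pools = pools,
                 locus = locus),
            class = "colony_sim")
}

#' @export
print.colony_sim <- function(x, ...) {
  tr <- x$trajectory
  cat("<colony_sim> ", nrow(tr), " generations; final breeder W frequency ",
      signif(tr$w_freq_breeders[nrow(tr)], 3), "\n", sep = "")
  invisible(x)
}

# founder frequency among a set of breeders at positions on one chromosome
.breeder_founder_freq <- function(inds, chrom, positions) {
  counts <- matrix(0, 8L, length(positions))
  total <- 0L
  for (ind in inds) {
    pair <- ind$genome[[chrom]]
    for (h in pair[c("h1", "h2")]) {
      if (is.null(h)) next
      f <- h$founder[findInterval(positions, h$start)]
      for (j in seq_along(positions))
        counts[f[j], j] <- counts[f[j], j] + 1
      total <- total + 1L
    }
  }
  counts / total
}
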