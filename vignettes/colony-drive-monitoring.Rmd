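---
title: "Meiotic drive, marker-assisted purging, and colony monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Meiotic drive, marker-assisted purging, and colony monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drivepurge)
```

## The problem

Multiparent populations such as the Diversity Outbred (DO) mouse stock
derive their value from balanced founder-allele frequencies maintained by
randomized breeding. A meiotic-drive locus breaks that balance: the
high-copy allele at the chromosome 2 responder locus (carried by the
WSB/EiJ founder, written **W**; any other founder allele written **a**)
is transmitted preferentially through the female germline, and the
resulting selfish sweep, left alone, fixes one haplotype across a large
chromosomal region. `drivepurge` implements the three computational
layers of that episode: a forward simulator of the breeding scheme with
drive, the algebra of the marker-assisted purge that removed the allele,
and the statistics used to monitor the colony before, during and after.

## The drive model

Drive is modelled as biased post-meiotic transmission. A dam heterozygous
at the drive locus transmits the meiotic product that carries W *at the
locus point* with probability $\tau$; sires and homozygous dams are
Mendelian. Because the choice is between whole recombinant products,
linked flanking material hitchhikes with whichever product is chosen —
this is what generates the excess of the driven founder in regions
flanking the locus, and it falls naturally out of the representation
rather than being imposed.

Under random mating at allele frequency $p$ (Hardy–Weinberg genotypes)
the one-generation map is

$$p' = \tfrac{1}{2}\left[p^2 + 2p(1-p)\tau + p\right],$$

the average of the maternal gamete frequency under drive and the
Mendelian paternal frequency (`drive_recursion()`). For $\tau = 1/2$ this
is the neutral martingale $p' = p$; for $\tau > 1/2$ the only fixed
points are 0 and 1 and every interior frequency grows. Iterating from
the balanced eight-founder expectation $p_0 = 1/8$ with $\tau = 0.75$
(the midpoint of the reported 50–100% range) crosses 0.60 at iteration
10 — the time scale on which the real sweep was observed. Reported
transmission ratios vary with genetic background; `drive_params()`
accepts either a fixed $\tau$ (default 0.66, the original population
estimate) or a per-dam sampler on $[0.5, 1]$. The package does not model
the copy-number mechanics or modifier loci behind that variation; $\tau$
subsumes them.

## The breeding scheme

`simulate_colony()` reproduces the DO maintenance design: `n_lineages`
(default 175) matrilineal lineages; each generation one female and one
male are selected from every lineage's progeny (first litters preferred)
and re-paired by a random assignment that avoids full-sibling pairs.
Offspring take the dam's lineage and mitochondrial haplogroup and the
sire's Y haplogroup. Mating failure (default probability 0.05, the
middle of the observed 3–7% band) triggers, in order: the duplicate
sibling "B" pair, then a donor lineage that provides both parents. Every
failed attempt is logged in the breeding records.

Two consequences worth stating explicitly, both of which are tested:

* With no replacements, the multisets of mitochondrial and Y haplogroups
  among breeders are conserved *exactly* each generation — drift cannot
  touch the uniparental compartments under this design.
* Replacements are the only route by which those frequencies move. They
  arise from failed matings and, rarely, from a sibship that contains
  only one sex. The simulator's trajectory reports `n_replaced` so both
  cases are visible.

Founding (G0) individuals are random founder mosaics (expected 8
segments per chromosome, uniform founder labels) standing in for draws
from incipient Collaborative Cross lines; the exact CC funnel structure
is not reproduced. When a simulation must start mid-sweep,
`init_w_freq` forces the locus allele to W per homologue with the given
probability (Hardy–Weinberg at the founding generation).

Recombination is Poisson with mean equal to the chromosome's genetic
length (no crossover interference — the simplest defensible model, and
the quantities studied here are insensitive to interference), with
positions uniform in genetic distance, inverted to bp through the
marker-anchored map. Litter sizes are truncation-free negative binomials
(mean 8, dispersion 20); heterozygous dams lose 1.5 pups on average
(additive default). The direction of that effect — Wa dams, not sires —
is documented; its magnitude is not published numerically anywhere we
could verify, so it is a free parameter chosen once to give a clearly
detectable but not dramatic effect (about 0.45 within-group standard
deviations).

## The marker-assisted purge

Classifying each breeder as WW / Wa / aa from tightly linked selection
markers partitions matings into nine types (`classify_mating()`,
`mating_type_frequencies()`). The purge policy (`purge_policy()`):

* discards WW × WW matings outright;
* retains WW × Wa and Wa × WW matings only with probability `f`
  (default 0 — the colony kept "only a fraction" of these, without a
  published number, and the strict setting gives the cleanest bound);
* selects, among the genotyped progeny of every retained mating, the
  female and the male carrying the fewest W alleles (ties at random).
  Only crosses with a Wa parent need genotyping: aa × aa progeny are
  all aa, and aa × WW / WW × aa progeny are all Wa.

`expected_post_selection_frequency()` turns this into a deterministic
one-generation prediction by exact enumeration: discarded mass is
redistributed proportionally over retained matings; aa-capable matings
(aa × aa, Wa × Wa, Wa × aa, aa × Wa) contribute aa breeders under the
infinite-litter idealization; forced-Wa matings contribute Wa. From
$p = 0.62$ with $\tau = 0.66$ and $f = 0$ this yields 0.1133 — the
"62% to below 15% in one generation" calculation. The infinite-litter
idealization is the default because the correction is modest at
moderate $\tau$ (with two pooled litters of mean 8, the chance that a
Wa × Wa pair yields no aa pup of a given sex is small); the finite
version (`infinite_litter = FALSE`) computes the expected per-sex
minimum-W genotype under the litter model and shows where the
idealization breaks down — at high $\tau$, aa pups become rare and the
purge slows markedly, which is also visible in stochastic simulations
and matches the colony's experience that selection took longer than the
original estimate.

The stochastic counterpart (`simulate_colony()` with a policy) applies
min-W selection across all genotyped litters. At $\tau = 0.66$ from
$p \approx 0.62$ with 175 lineages, the driven allele is gone from the
breeder set within five generations in the median replicate, consistent
with the five generations the real purge required.

## Monitoring statistics

* `condense_diplotypes()` collapses 36-state unphased diplotype
  probabilities (8 homozygous + 28 heterozygous states, the output
  layout of DO haplotype-reconstruction HMMs) to eight founder dosages;
  `founder_frequency_profile()` averages them over a cohort, or counts
  alleles directly from simulated mosaics — the two paths agree exactly
  on indicator input, which is the package's round-trip test.
* `snp_entropy()` is the Shannon information content of a biallelic SNP
  in bits, maximal (1.0) at minor allele frequency 1/2.
* `private_allele_retention()` asks, for variants private to one
  founder, whether the owning founder survives at that position — the
  quantity that distinguishes "haplotype purged locally" from "variation
  lost".
* `trd_test()` is the one-degree-of-freedom chi-square against 1:1
  transmission, *without* continuity correction by default: at the
  pedigree-screen counts 159:108 the uncorrected statistic is 9.742 with
  p = 0.0018, matching the published screen; the Yates-corrected value
  would not. The correction is exposed as an option, and the estimated
  ratio is reported with a Wald or exact binomial interval.
* `litter_anova()` is a standard one-way ANOVA of litter size on dam or
  sire genotype, per litter index, via `stats::lm`/`anova`.

## Karyotype and haplogroup calling

Uniparental haplogroups are assigned by linear discriminant analysis on
small probe panels (7 Y probes, ~40 mitochondrial probes by default; 6 Y
classes because C57BL/6J, 129S1/SvImJ and NZO share a Y haplogroup, 5
mitochondrial classes because A/J, C57BL/6J, 129S1/SvImJ and NOD share
one). With so few probes and near-constant within-class genotypes the
pooled covariance is singular, so the discriminant is always shrunk
toward a scaled identity (`lambda`, default 0.5, plus a small ridge);
on well-conditioned data with light shrinkage it reproduces reference
LDA assignments, which is tested against `MASS::lda`.

Sex-chromosome calls use copy-number-proportional log-scale intensities
(two copies = 0, one = −0.5, zero = −2, duplicated ≈ +0.4; Gaussian
noise, default σ = 0.12) with thresholds set at midpoints between
copy-number levels rather than absolute constants. An XO female requires
an absent Y, X intensity at the one-copy level (PAR excluded from the
mean), and near-zero X heterozygosity. A distal-X duplication in a male
requires a distal run of robust markers with two-copy intensity *and*
heterozygous calls — heterozygosity on the male X outside the
pseudoautosomal region is only possible with a second X copy. The run
scan tolerates one below-threshold marker (`dup_max_gap`) so a single
noisy probe cannot truncate a real duplication; a minimum of 3 markers
and 2 heterozygous calls guards against false positives, which are
structurally suppressed anyway because robust markers never produce
spurious heterozygous calls in hemizygous samples under the noise model
(that is precisely what the robust-marker filter is for — non-robust
markers do produce them, at a 10% default rate, and are excluded).
The CAST/EiJ Y carries an X-derived translocation that extends its PAR
430 kb proximally; heterozygosity confined to that window is diagnostic
of a CAST Y, not of a duplication, so the scan boundary moves proximally
for Y-haplogroup-F males. An X-to-Y translocation cannot be
distinguished from an X duplication by these data; the call is best read
as "distal-X gain".

## Synthetic data: what it does and does not emulate

`generate_panel()` builds biallelic founder consensus panels (a
configurable fraction private to single founders), PAR and
extended-PAR-window markers, separable haplogroup signatures (minimum
pairwise Hamming distance `class_margin`), and robust-marker flags.
`genotype_cohort()` emulates array genotyping of simulated individuals:
dosage calls with error (default 0.005) and no-calls (0.01), and
intensities from the copy-number model, including hemizygous male X,
PAR, and CAST-extended-PAR behaviour. `inject_anomaly()` rewrites a
genotyped sample as XO (one-copy X intensity, homozygized X,
silenced Y) or as a distal-duplication carrier (duplicated-copy
intensity, heterozygous calls where the duplicated haplotype differs).
Injected duplications are required to contain at least three informative
markers: real duplication carriers are *ascertained through*
heterozygous calls, so an undetectable duplication would never have
entered the published counts, and the generator mirrors that
ascertainment. True diplotype probabilities are emitted as indicator
vectors, optionally smoothed toward uniform to exercise the
probabilistic code path; the reconstruction HMM itself is out of scope.

What passing tests therefore show: the algebra, the selection response,
the detector logic, and the round trips are correct under a noise model
whose structure (independent Gaussian intensities, independent call
errors) is idealized. What they do not show: robustness to array batch
effects, GC waves, cluster-file artifacts, or reconstruction uncertainty
correlated along the genome — none of which the generator produces.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere; a segment owns its start.
  Boundary queries are therefore unambiguous, and `founder_at()` at a
  segment boundary returns the right-hand segment.
* The drive locus is a single point (default chr2:85.65 Mb, the
  selection-assay position); the three selection markers are carried as
  annotation for genotyping emulation, with genotype defined by the
  mosaic at the locus point. The markers are tightly linked proxies, so
  collapsing them onto the locus loses nothing at simulation resolution.
* The default genome map is a synthetic fixture (19 autosomes + X,
  0.56 cM/Mb uniform, ~100 markers per chromosome): no genetic map for
  the DO is published alongside the episode, and none of the monitored
  quantities depends on map detail beyond total genetic length.
* Simulation problem sizes used by the tests and the acceptance script —
  a drive-chromosome-only map, 20 replicates for stochastic claims,
  cohorts of a few hundred samples — were chosen as the smallest sizes
  at which the binomial/3-SE bands quoted in the tests are meaningful;
  colony-scale parameters themselves (175 lineages, two litters, litter
  mean 8) are never scaled down.
* Published cohort-scale empirical numbers (chromosome-wide frequency
  profiles from thousands of real genotypes, private-variant counts from
  a variant database, real breeding-record p-values) are not
  reproducible from synthetic data at desk scale; the tests substitute
  conservation laws, martingale checks, parameter recovery, and
  qualitative sweep/purge shapes, and say so rather than pretending
  otherwise.
* One published table contains an internal arithmetic inconsistency in
  its later-generation row (a cell percentage that does not match its
  own numerator and denominator); only the earlier-generation row is
  used as a reference.

## Limitations

The simulator tracks a configurable chromosome subset, not a full
genome, and represents the X chromosome but not X-specific recombination
suppression or X drive. Background dependence of $\tau$ is a
distribution, not a mechanistic model. The A/B duplicate-mating
machinery is a backup pool, not a full model of the distribution colony.
Haplogroup classifiers are trained on synthetic signatures, not real
probe intensities. None of these affect the package's core claims, but
all bound how far its numbers should be extrapolated to a real colony.
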