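---
title: "The GSI transmission model and its companions: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The GSI transmission model and its companions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsicross)
```

## The model

Gametophytic self-incompatibility (GSI) in Rosaceae is controlled by a single
multi-allelic S-locus: the pistil expresses an S-RNase and each pollen
haplotype a battery of SLF F-box proteins that collectively detoxify all
*non-self* S-RNases. A haploid pollen grain is therefore rejected exactly
when its S-allele matches one of the two pistil S-alleles. `gsicross` encodes
this as a small probabilistic transmission model over *phased haplotypes*: an
S-allele label plus the alleles carried at linked trait loci (KSN, AP2, ...).

**Meiosis.** For a diploid parent with haplotypes $h_1, h_2$ and a linked
locus at recombination fraction $r \in [0, 0.5]$, gametes are parental with
probability $(1-r)/2$ each and recombinant with probability $r/2$ each.
Several linked loci recombine independently (no interference), each relative
to the S-locus; the model never needs, and does not represent, the order of
trait loci among themselves — the study system only ever scores one linked
locus per cross. Loci absent from the recombination map default to
$r = 0.5$ (unlinked).

**Tetraploid meiosis.** Diploid pollen from a tetraploid is modelled by
random bivalent pairing (each of the 3 pairings with probability 1/3), each
bivalent recombining like a diploid, and no double reduction. Marginally all
6 unordered haplotype pairs are equiprobable — the simplest model consistent
with the one observation it must reproduce, namely that chromosome doubling
of a diploid yields a self-compatible tetraploid.

**Acceptance.** Haploid pollen is rejected iff its S-allele matches either
pistil allele. *Anonymous* alleles (unidentified genotypes written `S_x`,
`S_y` in pollination tables) never match anything, including each other —
each stands for "some allele different from every named one in this cross".
Diploid pollen carrying two distinct S-alleles is unconditionally accepted:
under collaborative non-self recognition the two SLF batteries cover each
other's S-RNases (competitive interaction). Homoallelic diploid pollen
behaves like haploid pollen. The heteroallelic rule is a modelling choice —
the breakdown of SI in tetraploids is observed empirically, not mechanistically
dissected — but it is the standard non-self-recognition prediction and it
reproduces that observation.

**Cross prediction.** `cross()` filters the pollen gamete distribution by
acceptance, renormalizes, and multiplies with the (unselected) ovule
distribution. `accepted_fraction` of 0, 1, or anything between maps to
INCOMPATIBLE / FULLY_COMPATIBLE / HALF_COMPATIBLE. `expected_trait_fraction()`
integrates any genotype predicate over the offspring distribution; the
built-in predicate ("all alleles at the locus non-functional") expresses
recessive phenotypes such as continuous flowering (CF).

**The 20% prediction.** For a CF (ksn/ksn) seed parent crossed to a
*ksn–S1 / KSN–S3* donor sharing S1, all accepted pollen carries S3, on which
*ksn* arrives only by recombination; the expected CF fraction equals $r$
exactly (0.20 at $r = 0.20$). The published statement does not spell out the
parental configuration; the value is reproduced exactly when the seed parent
is ksn-homozygous, while with both parents heterozygous the same machinery
gives $r/2$. Both scenarios are exposed through the same API and neither is
silently assumed — the package simply computes whatever cross it is given.

## Estimators

* `infer_pollen_allele()` removes one maternal allele from a seed genotype;
  seeds whose two alleles are both maternal are AMBIGUOUS and excluded from
  `pollen_ratio_test()` (and counted in its report) rather than guessed.
  The ratio test is an exact binomial test of shared-allele transmission
  against 0.5, the expectation if SI did not filter pollen.
* `estimate_recombination()` counts non-parental two-locus gamete
  combinations of the informative parent: $\hat r = \text{recombinants}/n$.
  Percent values are presented with round-half-away-from-zero to match how
  such tables are conventionally printed (19/97 → 20%).
* `estimate_physical_position()` fits plain (unweighted) OLS of bp on cM over
  the `k_flank` nearest markers on each side of the target, defaulting to 3
  per side; the published figure does not state either the marker count or a
  weighting scheme, so the simplest choice is used and both knobs are
  exposed. Non-monotone cM-vs-bp among the chosen markers raises a warning
  rather than an error, since local inversions between map and assembly are
  common.

## Screening thresholds

`rank_candidates()` operationalizes the published screening logic — pistil
expression, similarity to reference S-RNases, allelic divergence — with
documented cutoffs:

* expression bins (FPKM): `***` > 100, `**` (50, 100], `*` [10, 50]; the
  conventional printed bins "50–100" and "10–50" overlap at their endpoints,
  resolved here half-open downward (100 → `**`, 50 → `*`);
* pistil specificity: pistil mean ≥ 10 FPKM and every other tissue < 2 FPKM,
  thresholds read off the observed patterns (S-RNases: pistil 44–100, stamen
  0; SLFs: stamen 4–22, pistil 0–1);
* allelic divergence: mean pairwise identity < 80% (true S-RNase alleles sit
  near 63–65%, relic RNase genes above 94%);
* reference similarity ≥ 30% identity — a deliberately coarse stand-in for
  phylogenetic clustering with Prunus S-RNases; tree building is out of
  scope.

`pairwise_identity()` is Needleman–Wunsch global alignment (match +1,
mismatch 0, linear gap −1) via `Biostrings::pairwiseAlignment()`, with
identity = matches / alignment columns, columns counting internal gaps but
not terminal overhangs. This denominator is a choice the literature rarely
states; it is fixed here so that the SNP arithmetic on gapless equal-length
comparisons holds exactly: 8 SNPs over 500 bases → 492/500 = 98.4%.
`classify_fbox()` calls a pollen-side F-box group SLF at ≥ 4 of 6 surveyed
haplotypes; exactly 3 of 6, undefined in the source convention, resolves to
FBX (the conservative call).

## Marker panels and history

Presence/absence PCR cannot see dosage, so `classify_ksn()` adopts the
diploid dosage assumption (a single non-functional marker without the wild
allele is homozygous). All $2^3$ presence patterns are classified: five KSN
types, a `missing` status, an `unknown` status for null+W (never observed in
the reference panel), and a `triploid` flag for copia+null+W, impossible in
a diploid. Breeding periods are I < 1850 ≤ II < 1900 ≤ III < 1940 ≤ IV <
1980 ≤ V, with closed lower bounds (boundary years are ambiguous in the
figure convention; 1850 is period II here) and an open-ended modern period.
`fisher_exact_2x2()` computes the standard two-sided Fisher p-value directly
from the hypergeometric distribution; the published per-period denominators
behind the quoted p-values are not printed, so the implementation is
validated against full enumeration for every table with total ≤ 30 rather
than against those p-values.

## The synthetic-data generators

The generators produce data with exactly the structure the estimators
assume: seeds drawn i.i.d. from a cross's offspring distribution, F1 gametes
drawn per parent with recombination at the set $r$, Bernoulli marker
carriership at per-period fractions (optionally with ksn→S_C hitchhiking),
and sequence sets at a target pairwise divergence. Allele sets are
independent mutants of a common ancestor; the per-allele substitution count
is solved from the target *pairwise* divergence
($d = 2d'(1-d') + d'^2 (k-2)/(k-1)$ for alphabet size $k$), so
`average_divergence()` recovers the requested value. SNP placement is
uniform without replacement and never back to the original residue;
transition/transversion bias is not modelled (only SNP counts matter
downstream). All generators take an explicit integer seed and are
byte-reproducible under it.

What the generators deliberately do **not** emulate: linkage disequilibrium
beyond the single ksn→S_C parameter, pedigree structure among cultivars,
genotyping error, segregation distortion other than GSI itself, alignment
gaps (indels) in allele sets, and read-level sequencing artefacts. Passing
tests therefore demonstrate correctness of the estimators under their own
assumptions, not robustness to real-data pathologies.

## Numerical choices and degenerate inputs

Probabilities are doubles; distributions are checked and compared at 1e−12,
with no rounding inside the engine (presentation rounding happens only in
print methods and percent fields). Zero-probability gamete classes are
dropped, so $r = 0$ yields parental classes only. An incompatible cross
returns an empty offspring distribution rather than an error; a zero-margin
2×2 table returns p = 1 with a `degenerate` flag; triploid parents are
accepted as genotypes (marker calling handles them) but refused by the
transmission engine, since aneuploid gamete viability is not modelled.
Problem sizes used in the test suite — e.g. 97 or 10 000 F1 individuals,
1000 replicate populations for estimator bias, 111 to 10 000 simulated
seeds, panels of 200–500 cultivars per period — mirror the study's designs
at the small end and standard Monte-Carlo practice at the large end.

## Known limitations

* Triploid meiosis (and hence crosses involving triploid parents) is out of
  scope; triploids are genotype-callable only.
* De-novo phasing is not performed: F1 tables must come with parental
  phases.
* The screening module ranks candidates from expression and divergence
  summaries; it does not run homology searches or build trees.
* Stylar-side quantitative effects (partial compatibility, pollen-tube
  competition dynamics) are outside the all-or-none acceptance model.
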