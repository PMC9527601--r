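# gsicross

Genetic computations for S-RNase-based gametophytic self-incompatibility
(GSI) in roses, written for breeders and geneticists working at the diploid
level where SI still constrains crossing designs.

In GSI, a haploid pollen grain carrying S-allele *S\_i* is rejected whenever
*S\_i* matches either S-allele of the diploid pistil. Two parents sharing
exactly one S-allele are therefore *half-compatible*: the shared allele never
transmits through pollen, and the seed S-genotype frequencies reveal which
pollen fertilized the ovules. When a trait locus (such as the floral
repressor *KSN*, whose non-functional alleles *ksn* confer continuous
flowering, CF) sits at recombination fraction *r* from the S-locus, pollen
selection distorts trait segregation: for a CF (ksn/ksn) seed parent crossed
with a *ksn–S1 / KSN–S3* donor that shares *S1*, all accepted pollen carries
*S3*, the *ksn* allele arrives on it only via recombination, and the expected
CF fraction among seedlings is exactly *r* (20% at *r* = 0.20).

The package implements, as plain R functions over small S3 containers:

- **Transmission model** — `gamete_distribution()` (diploid and tetraploid
  meiosis with per-locus recombination, no interference, no double
  reduction), `pollen_accepted()` (non-self recognition; heteroallelic
  diploid pollen unconditionally compatible, which is why chromosome-doubled
  tetraploids turn self-compatible), `cross()`,
  `expected_trait_fraction()`.
- **Segregation inference** — `infer_pollen_allele()` and
  `pollen_ratio_test()` (exact binomial test of shared-allele pollen
  transmission against the no-SI null), `estimate_recombination()` /
  `cosegregation_test()` on phased F1 gamete tables
  (r&#770; = recombinants/total), `estimate_physical_position()` (OLS of bp on
  cM over flanking markers).
- **Candidate S-RNase screening** — `pairwise_identity()` (global alignment),
  `average_divergence()`, `expression_class()`, `pistil_specific()`,
  `rank_candidates()`, `orf_pseudogene_check()`, `classify_fbox()`,
  `locus_span()`, `trace_allele_origin()`.
- **Breeding-history analysis** — `call_s_genotype()`, `classify_ksn()`,
  `period_frequencies()`, `fisher_exact_2x2()`.
- **Synthetic data** — seeded generators (`simulate_seed_set()`,
  `simulate_f1()`, `simulate_panel()`, `mutate_sequence()`,
  `simulate_allele_set()`, `simulate_screen_fixture()`) emulating every
  input the analyses consume.
- **IO / CLI** — TSV/CSV/FASTA/YAML readers and writers (including the
  filled-circle/cross presence glyphs of printed marker panels) and a
  `gsicross` command-line wrapper (`inst/scripts/gsicross`) over
  `gsicross_cli()`.

## Worked example

```r
library(gsicross)

mother <- plant_genotype("OldBlush_like",
  haplotype("S1", KSN = "ksn_null"),
  haplotype("S2", KSN = "ksn_null"))          # CF seed parent, ksn/ksn
father <- plant_genotype("donor",
  haplotype("S1", KSN = "ksn_null"),
  haplotype("S3", KSN = "KSN_W"))             # shares S1 with the mother

cr <- cross(mother, father, recomb_map(KSN = 0.2))
cr
#> <gsi_cross> OldBlush_like (seed) x donor (pollen)
#>   compatibility:    HALF_COMPATIBLE
#>   accepted pollen:  0.5
#>   offspring S-genotypes:
#>     S1/S3                0.5000
#>     S2/S3                0.5000

100 * expected_trait_fraction(cr, "KSN")
#> [1] 20
```

Half the pollen (everything carrying *S1*) is rejected, every seedling gets
*S3* from the father, and only the 20% of accepted pollen that recombined
onto *ksn* produces CF offspring. Simulating the matching pollination
experiment and testing transmission of the shared allele:

```r
sc <- simulate_seed_set(mother, father, n = 111, seed = 42, cross_id = "demo")
pollen_ratio_test(sc, "S1")
#> <pollen_ratio_test> cross demo, shared allele S1
#>   pollen-derived S1: 0 of 111 seeds (expected 55.5 under no SI)
#>   exact binomial p = 7.7e-34
```

Zero of 111 seeds derive from shared-allele pollen — the signature used to
validate S-RNase genotyping by pollination experiments.

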