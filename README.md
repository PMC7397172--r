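# vinekin

Marker-based characterization of germplasm collections of clonally
propagated crops — grapevine (*Vitis vinifera*) in particular — from
co-dominant genotype tables: diploid microsatellites (SSR), biallelic
SNPs, and haploid chloroplast microsatellites (cpSSR).

Curators of varietal collections face a recurring set of questions. Are
two accessions the same variety under different names (synonyms), or the
same name on different genotypes (homonyms)? How informative is a marker
panel for telling varieties apart? How does the collection cluster, and
from which ancestral gene pools does it draw? Which varieties are
parent–offspring trios, and which parent was the seed (maternal) side?
`vinekin` implements that whole workflow as composable, tibble-first R
functions with a seeded synthetic-data generator providing ground truth
for every stage.

## What it computes

* **Identity and curation** — allele-mismatch tolerant duplicate
  detection (`find_duplicates()`, default tolerance 2 alleles over the
  fingerprinting panel), transitive identity groups, and the nine-class
  accession status cascade (`classify_status()`).
* **Diversity and identity statistics** (`locus_stats()`) — per locus:
  missing rate, observed and effective allele counts (N<sub>e</sub> =
  1/Σp²), rarefied allelic richness (hypergeometric expectation at a
  fixed gene-copy count), Nei's H<sub>e</sub> = 1 − Σp², H<sub>o</sub>,
  fixation index F = 1 − H<sub>o</sub>/H<sub>e</sub>, exact /
  Monte Carlo Hardy–Weinberg tests, null-allele frequency
  (H<sub>e</sub> − H<sub>o</sub>)/(H<sub>e</sub> + H<sub>o</sub>), PIC,
  and the probability of identity for unrelated individuals and for full
  sibs; panel products via `cumulative_pid()` and SSR-vs-SNP panel
  equivalence via `panel_equivalence()`.
* **Distances and clustering** — proportion-of-shared-alleles
  dissimilarity d = −ln(PSA) with pairwise deletion and an overlap guard
  (`psa_distance()`), deterministic average-linkage `upgma()` with
  Newick export.
* **Population structure** — a Gibbs sampler for the Bayesian admixture
  model with correlated (F-model) or independent allele frequencies
  (`run_admixture()`, compiled core), `evanno()` ΔK model choice,
  CLUMPP-style replicate alignment (`align_replicates()`), Q ≥ 0.75
  membership assignment, and distance-matrix AMOVA with permutation
  tests (`amova()`).
* **Parentage and kinship** — Mendelian transmission likelihood ratios
  with a per-genotype error model (`transition_probability()`,
  `lod_parentage()`), simulation-calibrated critical LOD thresholds at
  95%/80% confidence (`simulate_critical_lod()`), trio-then-duo
  assignment under the one-locus-in-twenty mismatch budget
  (`assign_parentage()`), and a first-degree kinship screen
  (`halfkin_screen()`).
* **Chlorotypes** — cpSSR length-combination lookup
  (`assign_chlorotype()`), regional frequency summaries, and maternity
  designation inside accepted trios (`designate_mother()`): the
  chloroplast follows the seed parent.
* **Synthetic truth** — `gen_population()`, `gen_pedigree()`,
  `gen_clones()` emulate a 127-accession × 36-SSR/45-SNP germplasm panel
  (2–15 alleles per locus, mean ≈ 9; ≤5% missing with one pathological
  locus; clonal duplicates; admixed individuals; maternally inherited
  chlorotypes) as pure functions of a configuration and a seed.
* `run_pipeline()` chains everything into a deterministic report bundle;
  `tidy()`/`glance()`/`autoplot()` methods cover the result objects.

## A worked example

Published per-locus statistics for a 127-accession Croatian grapevine
panel ship with the package, so the panel-level arithmetic can be
reproduced without the underlying genotypes:

```r
library(vinekin)

panel_summary(ref_locus_stats("ssr9"))
#   n_loci total_a mean_na mean_ho mean_he mean_pic
#        9      92    10.2    0.84   0.788    0.758
cumulative_pid(ref_locus_stats("ssr9"))
#   n_loci cum_pid_u cum_pid_sib
#        9  4.04e-11    0.000145
```

Ninety-two alleles over the nine international fingerprinting loci, mean
PIC 0.76, and a full-sib probability of identity of 1.4 × 10⁻⁴: two
random full sibs share a nine-locus profile once in ~7000 pairs. Ranking
all 36 SSRs by P(ID)<sub>sib</sub> and multiplying until the 45-SNP
panel's discrimination is matched:

```r
panel_equivalence(ref_locus_stats("ssr36"),
                  cumulative_pid(ref_locus_stats("snp45"))$cum_pid_sib)
# [1] 19
```

— 19 microsatellites carry the same sib-discrimination power as the 45
SNPs. Parentage on synthetic data with known truth:

```r
sim  <- gen_population(sim_pop_config(n_pools = 1, pool_sizes = 60,
                                      n_ssr = 20, n_snp = 0, n_cp = 4,
                                      seed = 42, high_missing_locus = FALSE))
ped  <- gen_pedigree(sim$table, n_trios = 5, error_rate = 0.01, seed = 43)
crit <- simulate_critical_lod(sim$table,
          cfg = parentage_sim_config(n_offspring = 5000, prop_sampled = 0.9),
          seed = 44)
trios <- assign_parentage(ped$table, ped$truth$offspring, sim$table$id,
                          critical = crit, eps = 0.01)
designate_mother(trios, assign_chlorotype(ped$table, sim$map))
#   offspring parent1 parent2 type loci_compared mismatches   lod confidence     maternal
# 1    off001  acc007  acc044 trio            20          0 43.6    strict95       acc044
# 2    off002  acc039  acc040 trio            20          0 40.0    strict95       acc040
# 3    off003  acc002  acc004 trio            19          1 31.1    strict95       acc004
# 4    off004  acc021  acc031 trio            20          0 42.3    strict95 undetermined
# 5    off005  acc002  acc022 trio            18          0 31.6    strict95       acc002
```

All five planted trios are recovered at strict confidence; the trio with
one genotyping-error mismatch stays within the one-in-twenty budget, and
the seed parent is named wherever the two parents carry different
chlorotypes (off004's parents share one, so maternity stays open).

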