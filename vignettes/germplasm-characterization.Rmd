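---
title: "Models and methods for marker-based germplasm characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for marker-based germplasm characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models each
stage implements, the assumptions behind them, the tunable parameters
and why their defaults are what they are, what the synthetic-data
generator does and does not emulate, and the numerical choices made
where the design was genuinely open.

## Data model

A genotype table is a wide tibble: one row per accession, two integer
columns per diploid SSR locus (fragment lengths in bp, the unordered
pair stored sorted), two letter columns per SNP locus, one column per
haploid cpSSR locus. Missing data is whole-cell — a half-typed cell (one
allele present, one absent) is rejected at read time rather than
guessed, because per-locus missing-data percentages count accessions,
not alleles. A marker panel (locus, system, motif length, category)
travels with the table; categories follow the usual field split of
fingerprinting loci (cat1), diversity/parentage extensions (cat2),
structure support (cat3) and chloroplast loci (cat4).

## Harmonization and binning

Different machines and tailed-primer chemistries shift every allele at a
locus by a constant offset. `harmonize_alleles()` estimates that offset
per locus as the **mode** of the observed-minus-reference differences
over shared accessions — the mode, not the mean, so a single mistyped
reference profile cannot drag a locus — and refuses to shift a locus
whose modal difference explains less than 80% of comparisons (flagged
`"inconsistent"`). The 80% threshold is our choice; the estimator is
idempotent by construction. `bin_alleles()` clusters observed sizes by
single linkage with gaps strictly below the class spacing (default: the
repeat motif length) and replaces each class by its modal size, ties
broken toward the smaller size. Gaps exactly equal to the spacing are
*not* merged, and off-ladder singletons survive as their own class, so
genuine one-bp variants are preserved.

## Duplicate detection and accession status

Two accessions are duplicates when their profiles differ by at most two
alleles (counted as multiset mismatches per co-typed locus: a
homozygote shares at most one allele with a heterozygote carrying it) —
a tolerance that absorbs one genotyping error or somatic mutation per
clone pair. Identity groups are the transitive closure of that relation:
clone clusters chain in curation practice, and non-clique groups are
flagged for review. Pairs with too few co-typed loci (fewer than
two-thirds of the comparison panel, capped at six of the nine
fingerprinting loci) are reported but never merged automatically. The
representative of a group is the true-to-type member if the metadata
names one, else the lexicographically first id — deterministic by
design. The nine-class status cascade is a fixed rule order
(curation-error flags first, internal duplicates, external synonyms by
neighbouring/distant country, documented foreign origin, then unique
accessions split by ampelographic completeness); accessions with
conflicting flags come back `"unresolved"` rather than silently
resolved.

## Diversity and identity statistics

All statistics are closed forms in the allele frequencies `p`, counted
over typed individuals only:

* H<sub>e</sub> = 1 − Σp² (the uncorrected Nei estimator — the bundled
  reference tables show Ne = 2.00 coexisting with He = 0.50, which the
  n/(n−1)-corrected estimator cannot reproduce), Ne = 1/Σp².
* PIC = 1 − Σp² − Σ<sub>i&lt;j</sub> 2p<sub>i</sub>²p<sub>j</sub>².
* P(ID)<sub>unrelated</sub> = Σp⁴ + Σ<sub>i&lt;j</sub>(2p<sub>i</sub>p<sub>j</sub>)²;
  P(ID)<sub>sib</sub> = 0.25 + 0.5Σp² + 0.5(Σp²)² − 0.25Σp⁴. Both
  multiply across independent loci.
* Null-allele frequency defaults to Chakraborty's ratio
  (H<sub>e</sub> − H<sub>o</sub>)/(H<sub>e</sub> + H<sub>o</sub>);
  Brookfield's (H<sub>e</sub> − H<sub>o</sub>)/(1 + H<sub>e</sub>) is an
  option. Loci with an estimate above 0.1 are flagged out of parentage
  panels (`parentage_panel()`), because null alleles mimic exclusions.
* Rarefied allelic richness is the hypergeometric expectation of the
  number of distinct alleles in `g` gene copies drawn from the observed
  copies; `g` defaults to twice the smallest number of typed individuals
  over the loci, the fixed-sample convention. At g = 2 it reduces to one
  plus the unbiased gene diversity — a closed-form check in the tests.
* Hardy–Weinberg: biallelic loci get the full-enumeration exact test
  conditional on allele counts; multiallelic loci a Monte Carlo
  permutation of the gene-copy pool (default 10,000 replicates, seeded).
  Verdicts use the conventional stars; monomorphic loci are `"ND"`, with
  He = 0, Ne = 1, PIC = 0, P(ID) = 1, and F undefined.

`panel_equivalence()` sorts loci by increasing per-locus P(ID) and
returns the shortest prefix whose product reaches a target — the basis
of the SSR-versus-SNP panel comparison.

## Distances and UPGMA

The pairwise dissimilarity is d = −ln(PSA), with PSA the fraction of
shared alleles (multiset intersection per co-typed locus, divided by
twice the co-typed locus count). Missing loci are pairwise-deleted
behind a minimum-overlap guard (default half the loci) because real
panels carry loci with up to ~50% missing data; pairs below the guard
make the matrix unavailable rather than silently noisy. A fully disjoint
pair has PSA = 0; its distance is capped at ln(4L) — above any
observable finite value — and flagged, keeping UPGMA total.
`upgma()` is standard size-weighted average linkage with merge heights
at half the between-cluster mean distance; ties break deterministically
toward the pair whose smallest member ids sort first, so reruns are
byte-identical. The output is ultrametric by construction and exported
as Newick with height-difference branch lengths.

## Admixture model

`run_admixture()` implements the classic Bayesian admixture model by
Gibbs sampling (compiled core): each allele copy of individual *i*
originates in population *k* with probability q<sub>ik</sub>, and
population *k* carries allele frequencies p<sub>kl·</sub>. One sweep
samples the latent origins, then the conjugate Dirichlet updates for P
and Q, then Metropolis updates for the hyperparameters. Under the
default **correlated frequency model** the populations are
Dirichlet-dispersed around an ancestral frequency vector with
per-population drift F<sub>k</sub>: P given (p<sub>A</sub>, F) stays
conjugate, while p<sub>A</sub> moves by a Dirichlet-proposal Metropolis
step and F<sub>k</sub> by a random walk on the logit scale with a flat
prior. The ancestry concentration α has a uniform (0, 10] prior and a
normal random-walk proposal of sd 0.05. The model probability is
estimated from the post-burn-in log-likelihood trace as
mean(lnL) − var(lnL)/2. Everything is seeded; a run is a pure function
of (data, K, seed).

Run lengths: the defaults (2,000 burn-in + 2,000 sweeps) are desk-scale
settings for collections of a few hundred accessions and tens of loci,
where the sampler mixes within a few hundred sweeps; the classic
long-run protocol (150,000 + 150,000) is available as
`vk_mcmc_preset("publication")`. `evanno()` computes the
second-difference statistic ΔK = |L(K−1) − 2L(K) + L(K+1)| / sd(L(K))
from replicate runs and reports the arg-max as the suggestion **while
keeping the mean-lnP curve alongside** — when the two criteria disagree
the choice is the user's, so both are exposed. ΔK's denominator is a
replicate standard deviation: with only two replicates it is extremely
noisy, so we use at least three per K in our own checks (the classic
protocol uses ten). Replicate alignment maximizes the pairwise
similarity G = 1 − ‖Q<sub>a</sub> − Q<sub>b</sub>‖<sub>F</sub>/√(2n)
against an accumulating reference, exhaustively over column permutations
for K ≤ 7 and by greedy column pairing beyond, restarted over random
replicate orders. Membership uses the inclusive Q ≥ 0.75 rule; the
threshold is a parameter, and raising it can only grow the admixed
class.

## AMOVA

`amova()` partitions squared −ln(PSA) distances into among- and
within-group sums of squares (the squared-distance identity: a group's
SS is the sum of its squared pairwise distances divided by its size),
estimates variance components with the usual unequal-size correction
n₀, and reports Φ<sub>PT</sub> = σ²<sub>among</sub>/(σ²<sub>among</sub> +
σ²<sub>within</sub>) with a permutation p-value (individual relabelling,
+1 correction, 999 permutations by default, seeded). Pairwise Φ comes
from restricting the matrix to each group pair. Groups of one
individual carry no within-group information and are dropped with a
warning.

## Parentage likelihoods and calibration

The per-locus likelihood ratio compares H₁ (the candidate or candidate
pair is parental, any unknown parent integrated over the allele
frequencies) with H₂ (the offspring is a random Hardy–Weinberg draw).
Genotyping error is modelled as replacement: each observed genotype is,
independently with probability ε, a random Hardy–Weinberg genotype.
Because a replaced observation is independent of the true one, the
marginal likelihood mixes the Mendelian transmission probability with
the Hardy–Weinberg genotype probability in closed form, and an allele
incompatibility contributes a finite negative log-ratio instead of an
infinite exclusion whenever ε > 0. The default ε = 0.01 is a typical
capillary-electrophoresis error rate; the true value is never known and
the parameter is exposed everywhere. LOD is the sum of log ratios over
co-typed loci. Alleles absent from the frequency table (an offspring
allele unseen among candidates) enter at the floor frequency
1/(gene count + 1) with a warning.

Assignment accepts, per offspring, the best-LOD candidate pair as a trio
when its LOD reaches the critical value **and** its Mendelian mismatches
stay within ⌊0.05·L⌋ for the L-locus panel — the "one locus in twenty"
rule. The budget is panel-based, not per-pair: a per-pair basis cliffs
to zero tolerated mismatches whenever one parental genotype is missing
at a single locus, which rejects true trios on exactly the error rate
the budget exists to absorb. Unresolved offspring fall through to the
single-parent analysis under the same rules. The acceptance criterion is
the critical **LOD** (with the Δ statistic of the canonical
implementations left aside deliberately; the divergence matters when
several near-tied candidates exist, and the mismatch rule carries most
of that burden here).

The critical value comes from simulation (`simulate_critical_lod()`):
offspring are generated from parents that are in the candidate set with
probability `prop_sampled` (otherwise unsampled Hardy–Weinberg
genotypes), typed with the configured missingness and error rate, and
pushed through the same assignment machinery; the threshold for a
confidence level is the smallest LOD at which the proportion of correct
assignments among those at or above it reaches the level. Three
numerical choices matter:

* **Stratification.** The three parentage cases (both parents sampled /
  one / neither) are simulated as equal-size strata and re-weighted by
  their true probabilities (p², 2p(1−p), (1−p)²). The estimand is
  unchanged; the Monte Carlo variance of the reliability curve drops by
  orders of magnitude when `prop_sampled` is small, which is what makes
  desk-scale simulation sizes (10⁴ rather than the classic 10⁶) usable.
* **Mismatch-filtered reliability.** Simulated assignments that fail the
  mismatch budget are excluded from the reliability curve, since the
  real analysis would never accept them.
* **The evidence floor.** When no simulated spurious assignment survives
  the mismatch filter, the empirical reliability never dips below the
  level and the data place the boundary below the weakest simulated
  assignment; the naive choice (the minimum observed LOD) is an unstable
  order statistic, so the threshold falls back to LOD = 0 — assign only
  when the parentage hypothesis is actually favored. This keeps
  thresholds reproducible across simulation seeds.
* `prop_sampled` is the analyst's estimate of how complete the candidate
  set is. The default (0.01, with 10⁶ offspring) reflects an open
  candidate pool typical of large published studies; when the truth is
  known — as for synthetic benchmarks where nearly all parents are
  among the candidates — it should be set accordingly.

In the simulation the trio search evaluates pairs among the top-8
single-parent candidates plus the true pair (the real assignment scans
all pairs); a pair that is competitive without either member scoring as
a plausible single parent is not observed in practice, and the
approximation keeps 10⁴-offspring simulations in seconds.

The first-degree screen (`halfkin_screen()`) passes pairs sharing at
least one allele at every co-typed locus, tolerating ⌊0.05·L⌋ failing
loci, and attaches the single-parent LOD. Parent–offspring and full-sib
pairs are indistinguishable at this level without further data, and the
screen says so rather than guessing.

## Chlorotypes and maternity

Chloroplasts are maternally inherited in cultivated grapevine, so the
cpSSR length combination — looked up in an editable map to haplotype
letters A–H — travels from seed parent to offspring. The bundled default
map is **synthetic** (the published length-to-letter tables live in
appendices not reproduced here); all tests use synthetic maps, and real
analyses should supply their own. Maternity inside an accepted trio is
designated only when the parents carry different chlorotypes and the
offspring matches exactly one of them; identical parents or any
undetermined member leave maternity open, and an offspring matching
neither parent is flagged `"conflict"` — impossible under strict
maternal inheritance, hence a sign of a wrong trio or a cp scoring
error. Maternity is never inferred through missing data.

## The synthetic-data generator

`gen_population()` emulates the structure of a national grapevine
germplasm panel: 127 diploid accessions by default; 36 SSR loci with
2–15 alleles per locus and a realized mean of about nine (the
allele-count draw is a discretized normal recentred so the *observed*
mean hits the target after rare-allele loss); 45 biallelic SNPs with
uniform minor-allele frequencies in [0.05, 0.5]; a few percent missing
data with one pathological SSR locus near 50%; four cpSSR loci encoding
eight chlorotypes with C and D dominating; allele sizes on a
motif-consistent ladder so binning is meaningful. Population structure
follows the F-model: ancestral frequencies are flat-Dirichlet, pool
frequencies Dirichlet-dispersed with drift F (0.15 by default — moderate
between-region divergence); with a single pool the drift layer is
skipped, because the sample then *is* the population. Admixed
individuals draw each allele copy from a pool chosen by a Dirichlet
ancestry vector. An optional null-allele locus converts carriers to
apparent homozygotes and null homozygotes to missing cells, exercising
the Chakraborty estimator's intended failure mode. `gen_pedigree()`
transmits one allele per parent per locus, copies the maternal cpSSR
haplotype, and applies the replacement error model; `gen_clones()`
perturbs at most two allele copies by one repeat unit. Every generator
is a pure function of its configuration and seed.

What the generator does **not** emulate: linkage and recombination maps,
selection, serious demographic history beyond the F-model, lab-specific
artefacts (stutter, large-allele dropout beyond the single null-locus
preset), and the deep multi-generation pedigree tangles of real
germplasm. Passing tests therefore show that the estimators recover
truth under the model they assume at realistic marginals — not that any
particular real collection satisfies those assumptions.

## Problem sizes used in the checks

The test-suite and acceptance-script simulations use desk-scale sizes
chosen to make the checks sharp but quick: 10 × 5 tables against the
brute-force diversity oracle; 8-leaf matrices against the exhaustive
UPGMA reference; 127 candidates, a 20-locus panel, 50 planted trios and
10⁴ simulated offspring for parentage; 100–120 individuals at 20 loci
with 500–900 Gibbs sweeps for ancestry recovery and ΔK over K = 1..6
with three replicates each; 999 permutations for AMOVA. The admixture
sampler's long-run preset and the 10⁶-offspring simulation default
remain available for real analyses.

## Known limitations

* The Gibbs sampler has no linkage model and no location prior; severely
  unbalanced pool sizes or very low divergence (F ≲ 0.02) mix slowly at
  desk-scale run lengths — watch the α trace warning.
* Critical-LOD calibration assumes candidate genotypes are representative
  of the unsampled parent pool (frequencies come from the candidates).
* The status cascade resolves to the *first* matching rule; richer
  curation logic (e.g. literature priority among synonyms) is out of
  scope, as is fuzzy matching of varietal names.
* `harmonize_alleles()` assumes constant per-locus offsets; it cannot
  repair allele-specific sizing nonlinearities, which is what binning
  against reference ladders is for.
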