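---
title: "Methods: scoring, statistics and simulation design in selfmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, statistics and simulation design in selfmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfmeth)
```

## The study design this package serves

Mixed-mating organisms — those alternating self-fertilization with
occasional outcrossing — offer a natural experiment on whether epigenetic
variation compensates for the low genetic diversity of selfing. The field
design the package implements samples a fixed number of individuals from a
few isolated sites, where each site hosts one or more highly homozygous
*selfing lineages*. Three data layers are collected per individual:
codominant microsatellite genotypes, dual-digest MS-AFLP band profiles,
and parasite counts by morphotype. Bayesian clustering supplies a
membership (q-value) matrix over lineages. The analysis then asks: how
strongly are sites and lineages differentiated, genetically and
epigenetically; do selfed and outcrossed individuals differ in
homozygosity and parasite load; and is genome-wide methylation predicted
by lineage, parasite pressure, inbreeding status, or their interactions?

## MS-AFLP scoring model

HpaII and MspI are isoschizomers of CCGG with different methylation
sensitivity, so the four presence/absence patterns of the two digests are
interpretable as methylation states: (1,1) unmethylated, (1,0)
hemimethylated, (0,1) internal cytosine methylation, (0,0) ambiguous —
the last confounds hypermethylation with absence of the restriction
target. Both (1,0) and (0,1) count as "methylated" downstream.

* **MSL/NML partition.** A locus is methylation-susceptible when the
  frequency of (1,0)/(0,1) patterns across all scored individuals
  *strictly exceeds* the replicate error threshold (default 5%,
  `pipeline_config(error_threshold=)`). The strict comparison means a
  locus exactly at the threshold is non-methylated. Ambiguous cells count
  in the scored denominator (they are genuine profiles), missing cells do
  not. Loci with no scored cell are dropped and reported.
* **Per-individual proportion.** The default excludes ambiguous cells
  from both numerator and denominator, because (0,0) cannot be assigned
  to either class without asserting which of hypermethylation or target
  absence produced it. A flag (`include_ambiguous`) re-admits them as
  unmethylated for sensitivity analysis.
* **Group percentage.** The classical group formula is a *ratio* of
  methylated-pattern cells to unmethylated-plus-ambiguous cells, which
  exceeds the proportion of methylated cells whenever methylation is
  common. Both readings are implemented
  (`group_methylation_percentage(reading=)`); the ratio is the default
  because that is the formula as printed in the MS-AFLP literature, but
  reported "average methylation" percentages in that literature are on
  the scale of the proportion reading, so the pipeline's summary reports
  use `"proportion"`. Neither is asserted against published values.
* **Replicate error.** Reproducibility is the count of individual × locus
  cells whose pattern differs between original and replicate profiles
  (a difference in either digest counts once), over shared loci ×
  replicated individuals.

Fragment peak tables are binarized with GeneMapper-style filters: peaks
below 100 RFU or outside the 100–500 bp sizing window are discarded, and
a band is present in a half-open user-supplied locus bin if any surviving
peak falls in it. Bin width is configurable because fragment-binning
conventions vary between labs; 1 bp bins are a sensible default.
Half-scored cells (one digest present, the other absent for an
individual) are promoted to fully missing, since every state call needs
both digests.

## Population-genetic statistics

* He is the uncorrected 1 − Σpₐ² (GenAlEx-style); Nei's small-sample
  correction is available behind `unbiased = TRUE`.
* Multilocus F_IS is 1 − H̄o/H̄e with unweighted means over loci. This is
  Nei's ratio rather than the Weir–Cockerham estimator; at the sample
  sizes of such studies the two can differ by a few percent, which is one
  reason printed inbreeding statistics are not treated as exactly
  reproducible.
* HL weights each locus by its expected heterozygosity
  (Aparicio et al. 2006): homozygosity at an informative locus counts for
  more than at a near-monomorphic one. Allele frequencies include the
  focal individual; missing loci leave both sums.
* The selfing rate uses the inbreeding-equilibrium moment estimator
  s = 2F/(1+F). Published selfing rates estimated by Bayesian clustering
  software do not generally equal this transform of the printed F_IS, so
  the package reports its own estimator and labels it as such.
* Individuals are selfed iff max q ≥ 0.9 (inclusive); argmax ties break
  to the first cluster in column order, deterministically.

## Differentiation statistics

AMOVA follows the squared-distance variance decomposition: with k groups
of sizes n_g and N individuals, SS_total = Σ_{i<j} d²ᵢⱼ/N, SS_within sums
within-group pairwise d² over group size, σ²_within = SS_within/(N−k),
σ²_among = (SS_among/(k−1) − σ²_within)/n̄ with
n̄ = (N − Σn_g²/N)/(k−1), and Φ_ST = σ²_among/(σ²_among+σ²_within).
Negative variance components are retained rather than truncated, so small
negative Φ values are possible (truncation would bias the many
near-zero comparisons these studies report). The permutation test
reassigns individuals to groups with sizes fixed and uses the inclusive
estimator p = (1 + #{Φ* ≥ Φ})/(1 + B), which can never return zero.

Distances: microsatellites use mean allelic mismatches per jointly scored
locus (0, 1 or 2, i.e. 2 minus the shared-allele count); binary data (MSL
recoded methylated/unmethylated with ambiguous as missing, and NML band
presence) use the simple mismatch proportion over jointly scored columns.
These are documented choices — the exact metrics inside the original
software stack are unstated in the literature, which is why published
Φ tables are treated as qualitatively, not numerically, reproducible.

PCoA double-centers −d²/2, keeps positive-eigenvalue axes, reports
negative eigenvalues without correction. The Mantel statistic is the
Pearson correlation of upper triangles with joint row/column permutation
of the second matrix, one-tailed for positive association.

## Methylation GLMs and multimodel comparison

The response is the (methylated, scored) count pair per individual —
not the raw proportion — so individuals with more scored loci carry more
information, as a binomial likelihood requires. Models are fitted by
IRLS (logit link) with convergence tolerance 1e-8 and up to 100
iterations; the log-likelihood keeps the combinatorial constant (it
cancels in ΔAICc). Rank-deficient designs fail loudly with the aliased
columns named — with lineages nested almost entirely within sites, many
lineage+site models are inherently aliased and are simply dropped from
the candidate set at fitting time. Possible complete separation is
flagged when any coefficient exceeds 15 logits. Overdispersion is
reported as Pearson χ²/df but not corrected; with per-individual trial
counts in the hundreds and a correctly specified binomial response it
sits near 1.

Candidates are all subsets of the main effects {lineage, parasite,
inbreeding, site} — parasite being either the scaled load or the raw
count of the dominant morphotype — crossed with the lineage × parasite,
lineage × inbreeding and parasite × inbreeding interactions under
marginality. AICc = −2ℓ + 2k + 2k(k+1)/(n−k−1); models with n ≤ k+1 are
excluded. Weights are exp(−Δᵢ/2) normalized; the evidence ratio of the
best model over model i is exp(Δᵢ/2). This is the standard definition:
at ΔAICc = 1 it equals 1.649, and reported ratios elsewhere that
disagree with their own printed weights are not chased.

## The simulator: what it emulates, and what not

`simulate_dataset()` runs K lineages forward through G non-overlapping
generations at fixed site × lineage occupancy. Founders draw alleles in
Hardy–Weinberg proportions from lineage-specific Dirichlet pools (one
pool per lineage, shared across sites, so a lineage spanning two sites is
one gene pool). Each offspring derives from a parent of its lineage by
selfing with probability s — both gametes from the same parent, halving
heterozygosity in expectation — or otherwise from that parent and a
random partner anywhere in the same site (the isolated-mangrove
assumption: no migration between sites). Ancestry fractions are averaged
through the pedigree and emitted as the q-matrix, so "outcrossed
ancestry" persists under subsequent selfing and the q-threshold
classifier can legitimately disagree with the truth record's
final-generation status — a deliberate property used to test the
classifier rather than a bug.

Methylation: per individual, the probability a methylation-susceptible
locus is methylated is logistic in lineage baseline, scaled parasite
load, final-generation inbreeding status, and their configured
interactions; methylated loci are hemi- or internally-methylated with
equal probability (downstream analyses collapse the two, so the split is
inert). Non-susceptible loci carry lineage-fixed bands. A configurable
fraction of cells is replaced by the ambiguous (0,0) pattern (default 5%)
or set missing (default 2%). Parasite counts are negative-binomial with
site × lineage × morphotype means.

`default_study_config()` encodes the reference field design: occupancy
(14, 25, 22, 7) at site 1 (lineages 1, 2, 4, 6), (41, 1) at site 2
(lineages 3, 6), 18 at site 3 (lineage 5) — 128 fish — 27 microsatellite
loci, 381 MS-AFLP loci with 70% methylation-susceptible, s = 0.95 and
G = 15 (enough generations to reach the mixed-mating inbreeding
equilibrium F ≈ s/(2−s)). Defaults chosen once as realistic for this
design and documented here: allele pools of 6 alleles at Dirichlet
concentration 0.3 (skewed, near-fixed lineage pools); lineage methylation
baselines between logit(0.38) and logit(0.475), matching the ~38–48%
methylation range such studies report; parasite slope 0.4 per unit scaled
load; outcrossing effect −0.3; lineage-specific interaction deviations of
magnitude 0.3–0.6 logits (detectable but not dominant at N = 128, since
the literature gives no effect-size scale for them); negative-binomial
dispersion 1.5, reproducing count SDs of the same order as the means;
site-level mean counts taken from the reference design's printed
per-site means with mild lineage multipliers so that lineages differ in
load.

What the simulator does **not** emulate: microsatellite mutation (allele
diversity comes from founder pools; G is small), linkage, coalescent
history, environmental or transgenerational methylation inheritance, and
locus-specific methylation effects (all susceptible loci share one
per-individual probability). Passing recovery tests on this generator
therefore demonstrates correctness of the estimators under the stated
model, not robustness to real-data violations of it.

## Numerical choices and degenerate inputs

* Permutation p-values use the +1 inclusive estimator and a seeded RNG
  from `pipeline_config(rng_seed=)`; they lie on {1/(B+1), …, 1}.
* AMOVA on all-identical individuals (σ²_among + σ²_within = 0) reports
  Φ as missing rather than 0/0.
* Monomorphic loci give He = 0; pooled F_IS is missing when H̄e = 0.
  Individuals with no scored loci get missing HL and methylation
  proportions.
* Genotype calls canonicalize to (min, max); the 0/0 pair is the missing
  sentinel (GenAlEx convention). Half-missing band cells are promoted to
  fully missing with a warning.
* Negative F truncates to s = 0 with a warning rather than a negative
  selfing rate.
* Mann–Whitney uses the tie-corrected normal approximation with
  continuity correction; Kruskal–Wallis delegates to the tie-corrected
  chi-square approximation, with the all-tied degenerate case defined as
  H = 0, p = 1.

## Test problem sizes

The suite verifies exact identities on hand-computable fixtures, equates
AMOVA/Kruskal–Wallis/Mann–Whitney against brute-force oracles on
instances small enough to enumerate (N ≤ 12, groups of ≤ 6), and checks
stochastic properties at deliberately chosen sizes: heterozygosity decay
under pure selfing at N = 2000, G = 10, averaged over 8 replicate
simulations of 300 loci (single runs have ~15% Monte-Carlo spread because
pedigree clustering inflates the variance of rare-heterozygote counts);
selfing-rate recovery over 20 seeds at N = 100; Wald coverage of the
parasite slope over 200 simulated studies; interaction selection over 50;
and permutation-test calibration at 500 replicates × 500 permutations.
The end-to-end default study (10,000 permutations) runs in well under a
minute on one CPU.

## Known limitations

One-level AMOVA only (the reference analyses are each single-factor);
no F_ST-outlier scan, no Bayesian cluster inference (q-matrices are an
input), no Hardy–Weinberg/linkage exact tests, no quasi-likelihood
correction for overdispersion, and no model-averaged coefficient
inference — the model table reports ranking, weights and evidence ratios
only.
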