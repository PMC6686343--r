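# selfmeth

Analysis pipeline for population studies that link **genetic diversity**,
**genome-wide DNA methylation** and **parasite pressure** in mixed-mating
(self-fertilizing/outcrossing) organisms — the study design used for
selfing fish such as mangrove killifish, where a handful of highly
homozygous selfing lineages share a few isolated sites, occasional
outcrossing produces detectable hybrids, and methylation-sensitive AFLP
(MS-AFLP/MSAP) profiles are scored alongside microsatellites and parasite
counts.

## What it computes

**MS-AFLP scoring.** Parallel EcoRI/HpaII and EcoRI/MspI digests are scored
per locus as band patterns and mapped to methylation states: HPA+/MSP+ →
unmethylated, HPA+/MSP− → hemimethylated, HPA−/MSP+ → internal cytosine
methylation, HPA−/MSP− → ambiguous (hypermethylation or absent target).
Loci whose frequency of methylation-indicative patterns strictly exceeds an
error threshold (default 5%) are methylation-susceptible (MSL); the rest
(NML) serve as dominant AFLP genetic markers. Per-individual methylation is
the proportion of methylated loci among scored loci,

&nbsp;&nbsp;&nbsp;&nbsp;p&#770;ᵢ = (#HEMI + #INTERNAL) / (#scored loci of individual i).

**Population genetics.** Per-locus and pooled Na, Ho, He = 1 − Σpₐ²,
multilocus F_IS = 1 − H̄o/H̄e, homozygosity-by-locus
HL = Σ_hom E_ℓ / (Σ_hom E_ℓ + Σ_het E_ℓ), the equilibrium selfing-rate
estimate s&#770; = 2F/(1+F), and q-threshold classification of individuals as
selfed (max q ≥ 0.9) or outcrossed.

**Differentiation.** One-level AMOVA from squared pairwise distances with
Φ_ST = σ²_among/(σ²_among + σ²_within) and label-permutation p-values,
pairwise Φ_ST, principal coordinates analysis (Gower centering), and
one-tailed Mantel tests between epigenetic and genetic distance matrices.

**Parasites.** Scaled parasite load Σᵢ Nᵢ/Nᵢmax across morphotypes,
prevalence, Kruskal–Wallis among lineages and Mann–Whitney selfed vs
outcrossed comparisons.

**Methylation models.** Binomial-logit GLMs of (methylated, scored) counts
on lineage, parasite load, inbreeding status and site, with exhaustive
candidate enumeration under marginality, AICc = AIC + 2k(k+1)/(n−k−1),
Akaike weights and evidence ratios.

**Synthetic data.** A forward-in-time mixed-mating simulator (selfing with
probability s, within-site outcrossing otherwise, pedigree-tracked
ancestry, negative-binomial parasites, and a logistic methylation model
with lineage × parasite × inbreeding interactions) generates complete
datasets with a truth record for parameter-recovery testing.

## Worked example

```r
library(selfmeth)

dataset <- simulate_dataset(default_study_config(), seed = 1)
study <- run_study(dataset, pipeline_config(n_permutations = 999,
                                            rng_seed = 1))
study$diversity
#>  group mean_Na mean_Ho mean_He   Fis   n mean_HL s_hat
#>  site1    4.07  0.0980   0.650 0.849  68   0.901 0.918
#>  site2    2.96  0.0247   0.424 0.942  42   0.975 0.970
#>  site3    1.70  0.0247   0.224 0.890  18   0.975 0.942
#>    all    5.00  0.0637   0.721 0.912 128   0.936 0.954
```

The three sites show the hallmark selfing signature: near-zero observed
heterozygosity against substantial expected heterozygosity, hence F_IS
around 0.85–0.94, HL above 0.9, and equilibrium selfing rates above 0.9.

```r
print(study$glm$all_sites$table, top = 3)
#> Model comparison (18 candidates, sorted by AICc):
#>                                                                    model  k   loglik     aicc delta_aicc weight evidence_ratio
#>                       lineage + parasite + inbreeding + lineage:parasite 13 -493.713 1016.618     0.0000 0.5086          1.000
#> lineage + parasite + inbreeding + lineage:parasite + parasite:inbreeding 14 -492.485 1016.687     0.0688 0.4914          1.035
#>                                    lineage + parasite + lineage:parasite 12 -512.627 1051.968    35.3495 0.0000       4.74e+07
```

Under the default generating design (lineage-specific parasite slopes),
the AICc ranking concentrates essentially all Akaike weight on models
containing the lineage × parasite interaction — the model-selection
behaviour the pipeline is built to expose. `study$amova$table`,
`study$mantel` and `study$parasites` hold the remaining reports
(Φ-statistics with permutation p-values, epigenetic–genetic Mantel
correlations, prevalence and rank tests).

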