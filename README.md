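# traitSAM

Trait-specific expression profiling with quantitative-response SAM
(Significance Analysis of Microarrays).

## The problem

Stress-responsive genes are usually found by contrasting a handful of
genotypes with extreme phenotypes, which makes the answer
genotype-specific. An alternative is to treat a continuous
morpho-physiological trait — shoot Na⁺, shoot Na⁺/K⁺, root K⁺, biomass,
shoot Cl⁻, and so on — measured across a *diverse panel* of genotypes as a
quantitative response, and ask which probes' expression tracks that trait
across the panel. `traitSAM` implements this analysis for one-color
microarray designs of the form *genotypes × conditions × replicates*
(canonically 8 rice genotypes × {control, salt-stressed} × 3 replicates =
48 arrays), analyzing the two conditions separately.

## The statistic

For each trait, per-genotype values are weighted onto [0, 1]
(min–max by default, rank-based optionally) and every sample inherits its
genotype's weight as the response *y*. For probe *i* with (quantile
normalized, log₂) expression *x_ij*:

- slope: `r_i = Σ_j x_ij (y_j − ȳ) / Σ_j (y_j − ȳ)²`
- slope standard error: `s_i = sqrt(RSS_i/(n−2)) / sqrt(Σ_j (y_j − ȳ)²)`
- score (the "fold score"): `d_i = r_i / (s_i + s0)`

where the fudge factor `s0` is the percentile of the `s` distribution
that minimizes the coefficient of variation of binned score dispersions.
Significance comes from permutations of *y* (default B = 100; exact
enumeration for tiny designs): expected order statistics `d̄_(k)` are
compared with the observed `d_(k)`, a family of thresholds Δ defines
upper/lower cuts, false calls are counted in the permuted scores, and a
probe's *q*-value (in %) is the smallest estimated FDR at which it is
called. Probes are selected at the combined rule **q ≤ 5% and |d| ≥ 2**,
split into positively and negatively expressed lists.

Downstream stages: exact hypergeometric GO singular enrichment analysis
(Benjamini–Hochberg within namespace), chromosome assignment parsed from
rice RAP-DB locus ids (`Os09g0286400` → chromosome 9), RAP→MSU identifier
conversion, and extraction of the interaction subnetwork induced by the
significant genes (components, degrees, hubs). A synthetic-data module
generates the full study design with trait-linked spike-in probes, a
planted enriched GO term and a planted interactome hub, so the whole
pipeline is testable without any download.

## Worked example

```r
library(traitSAM)

cfg <- sim_config(n_probes = 1000, spiked_traits = "shoot_Na",
                  spike_fraction = 0.025, seed = 42)
sim <- generate_dataset(cfg)           # linear-scale intensities + traits
norm <- log2_transform(quantile_normalize(sim$expression))
stressed <- split_by_condition(norm)$stressed

res <- run_trait_sam(stressed, sim$traits, "shoot_Na", B = 100, seed = 42)
res
#> trait_sam_result: trait=shoot_Na condition=stressed
#>   s0=0.3239 (percentile 95), B=100
#>   selected: 24 positive, 24 negative

head(res$significant[order(-abs(res$significant$d)), ], 5)
#>        probe_id     d q direction
#> 43 Os06g8561139  4.85 0  positive
#> 21 Os10g7378535 -4.57 0  negative
#> 20 Os10g3837332 -4.39 0  negative
#> 40 Os09g5201536  4.11 0  positive
#> 28 Os07g5848161 -4.08 0  negative
```

The dataset plants 25 positive and 25 negative spike-in probes whose log₂
expression varies linearly with the weighted shoot-Na⁺ value of each
genotype; here all 48 selected probes are true spikes (q = 0 means no
permutation produced as many false calls as there were calls at the
probe's threshold). `run_all_traits()` loops every trait × condition and
tallies positive/negative counts; `run_sea()`, `chromosome_distribution()`
and `induce_subnetwork()` take the selected lists onward;
`run_pipeline()` wires all stages together and writes TSVs, reproducibly
for a fixed master seed.

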