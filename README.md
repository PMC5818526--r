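# traitpd

Trait-based diversity analysis for community ecology, built on **trait
probability distributions (TPDs)** with intraspecific variation. The package
is aimed at ecologists comparing communities across habitat or disturbance
classes — the motivating system is leaf-litter ant communities in native
rain forest versus *Eucalyptus* plantations — using individual-level
morphological measurements, site-by-species occurrence counts, and site
metadata.

## What it computes

**Trait space.** Each trait is allometrically standardized
(t → z(log(t / Weber's length)); Weber's length → z(log t)), a PCA is fitted
on *species means* and individuals are projected onto its leading axes.
Species with ≥ 6 measured individuals get their own per-axis standard
deviations; rarer species receive the donor-pool mean SD and are flagged.

**TPDs.** Species `s` becomes an axis-aligned Gaussian on a discretized
grid, trimmed to its 99% high-density region:

    TPDs_s(x) ∝ ∏_k N(x_k; μ_sk, σ_sk),  TPDc = Σ_s w_s · TPDs_s

with `w` the relative occurrence frequencies. From these:

* `FRic` — occupied trait-space volume (support cells × cell volume)
* `FRed` — mean species-overlap depth − 1: `Σ_cells TPDc·M − 1`
* Rao's `Q = Σ_ij w_i w_j d_ij`, `d_ij = 1 − Σ min(TPDs_i, TPDs_j)`
* CWM — occurrence-weighted community mean of each raw trait (mm)

**Beta diversity.** Pairwise Sorensen dissimilarity partitioned into
Simpson turnover and nestedness (β_sor = (b+c)/(2a+b+c),
β_sim = min(b,c)/(a+min(b,c)), β_nes = β_sor − β_sim), applied to species
incidences (taxonomic) and to occupied grid cells or probability overlap
(functional, two labelled modes), plus Bray–Curtis distances.

**Inference.** Shapiro–Wilk-gated one-way ANOVA + Tukey HSD (falling back to
Kruskal–Wallis + Dunn tests with Holm adjustment), one-factor PERMANOVA with
seeded label permutations, Moran's I with inverse-distance weights and
Monte-Carlo significance, and the Mantel test — all p-values follow the
add-one rule, so they are never zero and reruns are bit-identical.

**Synthetic landscapes.** `simulate_dataset()` generates 25-site landscapes
(10 forest, 3 × 5 plantation classes, 6 sampling points per site, 80-species
pool) with Gaussian habitat filtering in trait space — plantation classes
share one optimum (homogenization), the forest filter is broad — and known
ground truth for end-to-end validation.

## Worked example

```r
library(traitpd)

ds  <- simulate_dataset(simulation_config(seed = 42))
res <- analyze_dataset(ds$traits, ds$occurrences, ds$sites,
                       pipeline_config(n_perm = 999, seed = 42))

aggregate(cbind(richness, fric, fred, rao_q) ~ habitat, res$alpha, mean)
#>                habitat richness  fric  fred rao_q
#> 1       eucalyptus_28y      9.2  72.9 0.491 0.854
#> 2        eucalyptus_7y     12.0  82.7 0.620 0.879
#> 3 eucalyptus_unmanaged     16.0 122.0 0.536 0.920
#> 4               forest     21.9 149.4 0.620 0.937

res$group_tests$fric
#> Group comparison (anova+tukey): statistic = 8.707, p = 0.0006013 (Shapiro-Wilk gate p = 0.432)
#> Letters: eucalyptus_28y=a  eucalyptus_7y=a  eucalyptus_unmanaged=ab  forest=b

subset(res$permanova, component == "total")
#>       flavor component     F     R2     p
#> 1  taxonomic     total 1.952 0.2181 0.001
#> 4 functional     total 1.909 0.2143 0.002
```

Reading the output: the native forest holds the most species (21.9 on
average) and the largest occupied trait volume (FRic 149), managed
plantations the least; the Tukey letters say forest FRic differs from both
managed classes while the unmanaged plantation is intermediate; and the
PERMANOVA on both beta flavors confirms that habitat classes differ in
composition (p ≈ 0.001), the homogenization signature. `run_pipeline()`
does the same from three CSV files and writes every table (alpha indices,
six beta matrices, test results, a deterministic run manifest) to an output
directory; `inst/scripts/traitpd.R` wraps it for the shell.

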