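# ampdyn

Temporal dynamics of amplicon-surveyed microbial communities under primer
bias.

## The problem

16S rRNA amplicon surveys observe a community through a primer pair, and
primer pairs targeting different variable regions (V1–V3, V4, ...) amplify
taxa with different efficiencies. The observed share of taxon *i* is the
renormalized biased share

    p'_i = b_i p_i / Σ_j b_j p_j,   b_i > 0 unknown,

so *composition* is distorted — in activated sludge, a filamentous bloom
organism like *Thiothrix* can appear ten times more abundant with one primer
pair than another. The question for anyone monitoring a wastewater treatment
plant (or any microbial time series) is whether community *dynamics* survive
the distortion: month-to-month turnover, similarity decay with time lag,
taxon accumulation, the temporally stable core. Because each bias factor is
fixed per taxon and region, change-based summaries of two differently
biased views of the same community can agree even while compositions
disagree — and presence/absence summaries are identical by construction.

`ampdyn` is the full analysis chain for this question plus a synthetic
community generator that turns the claim into a testable property:

- depth normalization (subsampling without replacement), exact
  hypergeometric expected richness, Monte-Carlo rarefaction curves
- Shannon diversity (H = −Σ p ln p) and paired between-region comparison
- Bray-Curtis, unweighted and normalized weighted UniFrac distances
- PCoA; NMDS by stress majorization with isotonic regression (Kruskal
  stress-1); Procrustes/PROTEST; Mantel; CAP (distance-based RDA) with an
  ANOVA-like permutation test — all permutation p-values use
  p = (count ≥ observed + 1)/(n_perm + 1)
- temporal core detection (present at all T time points), order-level
  shared core across regions, moving-window analysis, similarity-decay
  regression (log10 similarity vs time lag, per replicate) with pooled-t
  slope comparison, and the taxa–time relationship S = c·T^w
- FISH biovolume quantification from paired probe/DAPI masks and its
  correlation with amplicon relative abundance
- a seeded generator producing a 12-month × 2-region × 2-replicate study
  with a dominant core, transient taxa, seasonal dynamics, a bloom taxon
  with a 12-fold between-region amplification difference, and PCR-replicate
  noise

Tables are plain matrices (taxa as rows, samples as columns), designs are
data frames, trees are `ape` `phylo` objects; everything composes with base
R and the usual ecology toolkit.

## Worked example

```r
library(ampdyn)

sim <- simulate_dataset(synthetic_params(seed = 1))  # one latent community,
                                                     # two biased regions
cmp <- run_region_comparison(sim$tables$V1V3, sim$tables$V4, sim$tree,
                             sim$design, n_perm = 999, seed = 1)
print(cmp)
```

```
Region comparison: V1V3 vs V4
  Mantel (bray_curtis): r = 0.904, p = 0.001
  Mantel (unifrac_unweighted): r = 0.984, p = 0.001
  Mantel (unifrac_weighted): r = 0.865, p = 0.001
  Procrustes correlation = 0.886, p = 0.001
  moving-window Pearson r (bray_curtis) = 0.826
  moving-window Pearson r (unifrac_unweighted) = 0.965
  moving-window Pearson r (unifrac_weighted) = 0.880
  decay slope difference (bray_curtis): p = 0.223
  decay slope difference (unifrac_unweighted): p = 0.583
  decay slope difference (unifrac_weighted): p = 0.598
  STR: w(V1V3) = 0.402, w(V4) = 0.401, p = 0.932
  core: 19 taxa (69.2%) / 18 taxa (65.5%)
```

Reading the report: the two regions' distance matrices are highly
correlated (Mantel r ≈ 0.87–0.98) and their NMDS ordinations congruent
(Procrustes 0.89); month-to-month change profiles track each other
(moving-window r ≈ 0.83–0.97); similarity-decay slopes and the taxa–time
exponents (w ≈ 0.40 for both) are statistically indistinguishable; both
regions recover essentially the planted 20-taxon core holding about two
thirds of total abundance. Meanwhile the bloom taxon's *composition*
disagrees ~25-fold at its peak months between the regions — dynamics are
robust where composition is not. Per-sample alpha diversity comes from
`alpha_records()`:

```
    sample_id depth observed_otus  shannon
1 V1V3_t01_r1  2125            36 3.172036
2 V1V3_t01_r2  2125            38 3.243503
3 V1V3_t02_r1  2125            51 3.220843
```

See `vignettes/community-dynamics.Rmd` for the model details, parameter
meanings and the design choices behind the generator.

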