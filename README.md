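# palaeodiv

Postglacial change in the latitudinal gradient of floristic diversity,
estimated from fossil pollen counts.

Multi-site pollen count data carry a continuous record of plant
diversity since the last glacial period, but three biases stand between
the raw counts and a richness gradient: analysts name the same
morphological type differently, the number of types found grows with
counting effort, and site samples are too small to register rare herbs.
`palaeodiv` is an R package for palaeoecologists and community
ecologists that implements the full analysis chain:

- **Harmonisation** — synonym/hierarchy tables map original names to
  accepted types at three nested levels (H0 ≈ type, H1 ≈ genus,
  H2 ≈ family), summing counts and excluding non-terrestrial taxa.
- **Cohort and binning** — study-area filtering, five-region
  assignment, a ≥ 32-identified-types site filter, 1000-year bins
  (half-open windows on millennial centres, 0–15 ka BP), and regional
  pooling of all bins (site bins under 500 grains are regional-only).
- **Rarefaction** — expected richness and its standard deviation in a
  subsample of fixed size *n* drawn without replacement,
  E[S_n] = Σ_i (1 − C(N−N_i, n)/C(N, n)),
  with the full Heck-style variance (pairwise joint-absence terms) and
  log-gamma arithmetic that is exact to pools of 10⁷ grains; sites are
  compared at 500 grains, regions at 50,000.
- **Gradient statistics** — per-slice OLS of richness on latitude
  (slope in types/°lat, R²), Meridional-minus-north regional richness
  differences, and beta diversity as the regional/median-site richness
  ratio.
- **Turnover and ordination** — β_cc = (b+c)/(a+b+c) between
  consecutive slices on taxa above 0.1% of the terrestrial sum;
  correspondence analysis axis 1 with detrending by segments and
  rescaling to species-turnover SD units; a time-constrained (canonical)
  variant whose consecutive score differences index the rate of change.
- **Taxon accumulation** — cumulative taxa vs cumulative grains per
  region, a shared power-law slope in log–log space with per-region
  intercepts, and residuals against time.
- **Synthetic data** — a seeded generator of EPD-style records with a
  built-in latitudinal gradient, forest closure (11.5→7 ka), late
  anthropogenic opening (after 3 ka), archaeophytes, Zipf pollen
  productivities and analyst naming noise, plus the ground-truth record
  every stage is scored against.

## Worked example

```r
library(palaeodiv)

# the hypergeometric worked case: counts {5, 3, 2}, subsample of 2
rarefy_expected(c(5, 3, 2), 2)
#> E[S_2] = 1.688889 (sd 0.4629481) from 10 grains
# 76/45 exactly: of the 45 possible pairs of grains, 17 are same-taxon

beta_cc(c("A", "B", "C"), c("B", "C", "D"))
#> beta_cc = 50% (shared 2, only-first 1, only-second 1)

# a full synthetic study: 125 sites, 16 millennial slices
cfg <- generator_config(seed = 42)
ds  <- generate_dataset(cfg)
seqs <- counts_from_columns(ds$counts)
res  <- run_pipeline(seqs, ds$synonyms, pipeline_config(levels = "H0"))

g <- merge(res$H0$gradient, ds$truth$slope_schedule, by = "slice_center_bp")
round(cor(abs(g$slope), g$true_slope, method = "spearman"), 3)
#> [1] 0.984
g$slope[g$slice_center_bp %in% c(15000, 7000, 0)]
#> [1] -1.783117 -1.167373 -0.289726
```

The recovered slope of richness on latitude is flat in the Lateglacial
(−0.29 types/°lat at 15 ka), steepens to a first maximum near 7 ka
(−1.17) as forest closure depresses northern site richness, and is
steepest at present (−1.78) after the late-Holocene opening — the
trajectory the generator encodes, recovered with rank correlation 0.98.

The numbered scripts under `analysis/` run the same workflow stage by
stage (simulate → prepare → rarefy → gradient → turnover → accumulation)
and write all tables under `results/`:

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

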