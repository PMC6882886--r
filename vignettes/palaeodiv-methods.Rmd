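---
title: "Methods: postglacial diversity gradients from pollen counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: postglacial diversity gradients from pollen counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(palaeodiv)
```

## The problem

Fossil pollen counts from lakes and bogs are one of the few records of
plant diversity that span the postglacial period. Counting a sediment
sample yields, per depth (age), a vector of identified pollen-type
counts. Aggregated over hundreds of sites, such data can answer how the
latitudinal gradient of floristic richness in Europe changed between the
Lateglacial (~15–11.5 ka BP) and the present: climate-tracking theory
predicts a weakening as species spread poleward with warming, while
vegetation structure (forest closure, later anthropogenic opening)
pushes the other way.

Pollen counts cannot be compared naively. Analysts use different names
for the same morphological type; the number of types found grows with
counting effort; and site-level samples are too small to register rare
herbs. `palaeodiv` implements the full chain that deals with each bias
in turn: synonym harmonisation, cohort selection, millennial binning
with regional pooling, rarefaction to common grain sums, and the
downstream statistics (gradient regression, turnover, ordination, taxon
accumulation). A seeded synthetic generator with recorded ground truth
makes every stage verifiable end to end.

## Harmonisation and cohort

A synonym/hierarchy table maps each original name to accepted names at
three nested levels: H0 (most detailed accepted pollen taxonomy), H1
(morphologically similar types combined, ~genus) and H2 (coarse,
readily identifiable groups, ~family), plus an inclusion flag that
restricts all sums to terrestrial pollen and spores of vascular plants.
`harmonise()` re-keys and sums counts at the requested level; totals of
included taxa are invariant and per-sample richness is non-increasing
from H0 to H2 — both are enforced by tests. Nesting violations in a
user-supplied table are an error at load: the levels are nested by
construction, so a split H0 group indicates a broken table, not a
judgement call. Analyses run at H0 and H2 in parallel
(`compare_levels()`), since conclusions should not depend on taxonomic
resolution; H1 is supported but skipped by default as it yields
intermediate results.

The cohort is restricted to 25°W–35°E and north of 35°N (bounds
inclusive) and split into five regions: Alps box (45–47°N, 5–15°E,
evaluated first), Boreal (strictly north of 57°N), Meridional/
Submeridional (strictly south of 45°N), and the Temperate belt split
into oceanic/continental at 11°E. These two meridians are sometimes
quoted in °W, which is geographically impossible (they would sit in
the Atlantic), so °E is the documented reading; both are config
parameters (`region_bounds()`), not hard-coded. Sequences with fewer
than 32 identified types over their whole span are removed — such
diagrams usually reflect analysts who did not resolve herbs, and 32 is
about the average type count of genuinely species-poor boreal samples.

## Binning

Samples are binned into 1000-year slices centred on full millennia,
0–15 ka. The window is half-open, `[c−500, c+500)`, an edge rule chosen
so no sample can be counted twice; a raw sample is atomic and joins
exactly one slice (no proportional splitting — there is no defensible
interpolation rule for point ages). Material older than 15.5 ka is
dropped; whether analyses should instead fold older material into the
15 ka slice is ambiguous, and the cut at 15.5 ka is the documented
choice. Bins with fewer than 500 grains are excluded from site-based
analysis but still contribute to the regional pool, which sums all
sites of a region per slice and can reach ~10^7 grains.

## Rarefaction

Richness is compared at a fixed grain sum `n` by analytic rarefaction
under sampling without replacement:

E[S_n] = Σ_i (1 − C(N−N_i, n)/C(N, n)),

with `N` the grain total and `N_i` the count of taxon `i`. The standard
deviation uses the full variance, including all pairwise joint-absence
terms — not the diagonal approximation — because the reported SDs are
SDs of the estimate. Every combinatorial ratio is a log-gamma
difference (`lchoose`); raw binomial coefficients are never formed, so
N = 10^7 is exact in double precision. Tests pin the implementation to
three independent routes: exhaustive enumeration of all C(N, n)
subsamples for N ≤ 12 (tolerance 1e−12 on E[S_n]), a direct `log1p`
product evaluation at N = 10^7 (1e−6 relative), and a seeded
Monte-Carlo oracle that subsamples by sequential conditional
hypergeometric draws (4 standard errors). When the exact variance is
~0 (e.g. n = 1), the pairwise sum cancels catastrophically and the SD
is only reliable to ~1e−8 — the tests use that floor.

Bins with fewer than `n` grains are reported `defined = FALSE` and
excluded downstream rather than rarefied to their own total: the whole
point is comparison at a *common* size. Site bins use n = 500, regional
pools n = 50,000.

## Gradient, regional differences, beta diversity

`fit_gradient()` is plain unweighted OLS of richness on latitude, per
slice; slope (types per degree) and R² index the strength of the
gradient. Fits need ≥ 3 sites and nonzero latitude spread; below that
they are flagged undefined, not raised as errors, because a thin slice
is an expected condition. A companion regression on absolute per-bin
type counts (`gradient_absolute()`) checks that rarefaction is not
manufacturing the pattern. Regional contrasts
(`regional_gap()`) difference Meridional richness against each northern
region at the common 50,000-grain sum.

Beta diversity is the regional pooled richness divided by the median
site richness per (region, slice). Conventions differ on which grain
sums to pair here; the default is 50,000 for the region and 500 for
the sites — the pair that matches how the two tables are actually
built — and both are configurable.

## Turnover and ordination

Presence/absence turnover between consecutive regional slices is
β_cc = (b+c)/(a+b+c) × 100, computed on taxa whose share of the
terrestrial sum strictly exceeds 0.1% (strict `>`, so a taxon at
exactly 0.1% is out; threshold 0 keeps everything with a positive
count).

Compositional change is summarised by the first correspondence-analysis
axis of each region's slice-by-taxon table (square-root transformed),
computed by SVD of the chi-square-standardized matrix. Sample scores
are row principal coordinates; the sign is fixed so the first (oldest)
sample does not score above the last, making runs reproducible.
Detrending by segments recentres axis-2 scores within 26 equal-width
axis-1 segments (26 being the conventional default of the original
algorithm). Axis 1 is
rescaled to species-turnover SD units: species scores obtained as
weighted averages of sample scores are shrunken by the eigenvalue, so
they are first expanded by the estimated shrinkage factor, the weighted
within-sample dispersion of the expanded scores is measured per
segment, and each segment is stretched by the inverse square root of
its (neighbour-smoothed, clamped to within 5× of the weighted mean)
dispersion. The single-pass, smoothed, clamped form was chosen after
the naive iterated version proved unstable on low-turnover series,
stretching near-constant Meridional sequences without bound; the
stretching is strictly monotone, so sample rank order — the property
the inferences rest on — is always preserved. Gradient lengths agree
with `vegan::decorana` to within tens of percent; exact replication of
any particular program's rescaling conventions is out of scope.

The time-constrained variant (`constrained_axis1()`) is canonical
correspondence analysis with the single covariate age: sample scores
are confined to linear functions of time, and consecutive-sample score
differences index the rate of directional compositional change. With
one covariate the solution reduces to projecting the chi-square matrix
onto the weighted time direction and taking the leading singular
vector; it matches `vegan::cca` to 1e−10 in tests. Whether
detrending/rescaling should be applied to a constrained axis before
differencing is unsettled, so both raw and SD-rescaled constrained
scores are returned.

## Taxon accumulation

Per region, cumulative new taxa are plotted against cumulative grains
over time-ordered slices (oldest first); the relation is close to a
power law, i.e. linear in log–log space. The sampling-effect exponent
is fitted as one slope shared across regions with free per-region
intercepts (`log10(taxa) ~ 0 + region + log10(counts)`), the
statistically standard joint formulation; averaging per-region slopes
is available behind `method = "average"` since the original derivation
is described only as empirical. Residuals against time show when a
region held more or fewer taxa than the common sampling effect
predicts. Exact power-law input is inverted to 1e−9; under multinomial
sampling from a fixed Zipf pool the fitted slope lies in (0, 1) and
residuals carry no time trend.

## The synthetic generator

`generate_dataset()` emulates the structure such analyses respond to,
with every parameter fixed by `generator_config()` defaults that define
the study conditions: 25 sites per region placed uniformly in the
region boxes; a continental herb pool of 220 taxa with Zipf
(exponent 1) pollen productivities and nested regional pools
(Meridional 170 … Boreal 85); 15 prolific tree taxa that carry a
time-varying dominance share of the pollen sum (0.35 rising to 0.75
across the forest-closure ramp 11.5→7 ka in northern regions, eased by
0.2 after the 3 ka opening outside the Boreal); 12 archaeophytes
entering non-Boreal pools after 3 ka; lognormal grain totals
(median 1500) over 1–3 raw samples per site-millennium; a 5%
long-distance background of the continental mean composition; 15% of
herb taxa per site recorded under finer "agg." synonym names; and
occasional aquatic taxa that the synonym table excludes. The site-level
latitudinal gradient is encoded directly: a site's herb pool is the
first `95 − 1.8·s(t)·(lat−35)` taxa of its site-specific priority
ordering, where the schedule `s(t)` rises from 0.45 (Lateglacial) to a
local maximum 1.2 at 7 ka, relaxes to ~1.0, and climbs to ~1.55 after
the opening — the trajectory the pipeline must recover (rank
correlation > 0.8 is the end-to-end acceptance bar, and the observed
value is ~0.98).

What the generator does *not* emulate, hence what passing tests do not
show about real data: age-model error (ages are exact), spatial
autocorrelation among sites, overdispersion beyond multinomial
sampling, and — most visibly — the long rare tail of a real continental
flora. A 250-type synthetic world saturates its regional pools quickly,
so regional rarefaction SDs come out well below 1 (real pools with
hundreds of rare types give single-digit SDs) and the fitted
accumulation exponent is far smaller than the ~0.18 a real database
yields. These quantities are reported as computed; they are properties
of the synthetic pool size, not defects of the estimators, which the
Zipf-pool null and exact-inversion tests pin down separately.

## Problem sizes and runtime

The default end-to-end run uses 125 sites × 16 slices (~300,000 count
rows, ~6.5 M grains), which keeps the full test suite under a minute
and the acceptance script under a minute on one CPU while leaving every
per-slice regression with ~125 sites. Rarefaction stability is tested
at 10^7 grains directly. The Monte-Carlo oracle uses 10^4 replicates;
gradient-recovery coverage uses 100 replicate seeds of 200 sites.

## Known limitations

Rarefaction SDs near zero are cancellation-limited (~1e−8). The CA sign
convention is anchored to the first/last rows, so row permutation can
flip the axis sign (rank structure is unaffected). The DCA gradient
length is in SD units but not numerically identical to any particular
legacy implementation. The generator's truth slope is a pool-level
quantity; the recovered rarefied-richness slope tracks it rank-wise but
is attenuated/inflated in absolute value by detection effects, which is
why end-to-end checks are rank-based.
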