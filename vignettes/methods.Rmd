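---
title: "Methods: gridded diversity, spatial statistics and dissimilarity models in oceandiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded diversity, spatial statistics and dissimilarity models in oceandiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oceandiv)
```

# The analysis this package implements

`oceandiv` packages the standard macroecological workflow for aggregated
marine occurrence records on a degree grid: curate the records, build a
presence–absence matrix (PAM), measure alpha/Shannon/beta diversity and its
spatial clustering, diagnose how much of the pattern is sampling effort,
and model richness and composition against environmental predictors while
accounting for residual spatial autocorrelation. The motivating application
is epipelagic (0–200 m) copepod diversity across an ocean basin over a
multi-decadal window, but nothing in the code is taxon-specific.

Aggregated occurrence data have two defining pathologies that shape every
design choice below: they are *dirty* (missing or zeroed coordinates,
records determined only to genus, duplicated uploads) and they are
*radically under-sampled and unevenly sampled*, so that raw richness maps
confound biology with effort. The package therefore treats the cleaning
report, the redundancy index, rarefaction curves and coverage tables as
first-class outputs, not afterthoughts.

# Record curation

Cleaning applies an ordered rule list — missing coordinates, (0,0)
coordinates, on-land, outside-basin, non-species rank, depth window, study
period, duplicates — and attributes every dropped record to the *first*
rule it violates, so the per-rule counts partition the input exactly
(`input = output + Σ dropped`, asserted on every run). Choices the
underlying field conventions leave open, fixed here once:

- **Depth filtering** uses the midpoint of the record's depth interval
  (a single reported depth is its own midpoint; records without depth
  pass). Min- or max-based filtering would silently bias against records
  with wide sampled intervals straddling 200 m.
- **Duplicates** are identical (name, coordinates rounded to 4 decimals,
  date, depth midpoint) tuples; the first occurrence is kept. Four decimals
  (~11 m) treats re-uploads with float jitter as duplicates without
  merging genuinely distinct stations.
- **Rank filtering** keys on `taxon_rank` when present; otherwise a
  binomial-name heuristic (two tokens, lowercase epithet) is used and its
  use is logged.
- **Grid cells** are half-open `[x, x+1) × [y, y+1)` squares identified by
  their south-west corner; longitudes are wrapped into [−180, 180) before
  flooring, and neighborhood construction treats −180/+180 as adjacent.
  The exclusion of a poorly covered longitude band and the
  minimum-richness cell filter (defaults −170…−110 and 10 species) are
  configuration values, not hard-coded constants.

# Diversity statistics

For two cells with `a` shared species and `b ≤ c` species unique to the
poorer/richer cell, Sørensen dissimilarity partitions exactly as

$$\beta_{sor} = \frac{b + c}{2a + b + c}
  = \underbrace{\frac{b}{b + a}}_{\beta_{sim}\ (\text{turnover})}
  + \underbrace{\left(\frac{c - b}{2a + b + c}\right)
    \left(\frac{a}{b + a}\right)}_{\beta_{sne}\ (\text{nestedness})}.$$

The identity is enforced to 1e−12 in the tests over 1,000 random incidence
pairs. Per-cell "mean beta" fields average the pairwise components against
a neighborhood — all pairs within the analysis region by default (queen
contiguity and distance bands are options), with the grand means reported
alongside, because the field literature rarely states its averaging window
and the choice materially changes the numbers.

The Shannon–Wiener index is computed on occurrence proportions
(`p_i = n_i/N` with N the cell's record count), i.e. occurrence counts
stand in for abundances. This is a documented proxy with a known caveat:
frequently resampled populations, not abundant ones, dominate the index.
Empty cells yield missing values, never 0. The redundancy index
`R = 1 − S/N` is clipped to [0, 1]; values near 0 mean nearly every record
added a new species — the signature of under-sampling.

Dominance extraction replaces by-eye selection from matrix plots with two
deterministic rules: ranking by occurrence count with alphabetical
tie-break, and (for a statistic's range) the species present in at least
one cell of every equal-width bin of that statistic.

# Sampling-effort diagnostics

Rarefaction interpolates expected richness with the hypergeometric formula
`E[S(m)] = S_obs − Σ_i C(n−x_i, m)/C(n, m)` (evaluated in log space:
binomial coefficients overflow fast) and extrapolates with the Chao-style
unseen-species estimate `f̂₀ = ((n−1)/n) f₁²/(2f₂)` (falling back to
`((n−1)/n) f₁(f₁−1)/2` without doubletons). The curve is continuous at the
reference size and anchored exactly at `S(n) = S_obs` and `E[S(1)] = 1`.
Confidence bounds come from a seeded multinomial bootstrap of the reference
sample with a normal approximation (default 200 resamples) — chosen over
analytic variances for uniformity across the rarefied/extrapolated ranges.
All-singleton samples flag the extrapolation as unreliable but still return
it. The reference sample is the occurrence-record frequency vector of a
region, treated as abundance-type data; if records are severely clumped
within sampling events this overstates coverage, which is exactly the
regime the redundancy index is reported to reveal.

Coverage tables count cells by the region mask containing the cell center
(first mask wins on boundary ties, in configured order) and convert to
areas with the spherical band formula `R²Δλ(sin φ₂ − sin φ₁)`,
R = 6371 km; the tests verify the full-sphere tiling sums to 4πR².

# Spatial statistics

Moran's I uses the standard cross-product form with expectation
`−1/(n−1)`, the analytic normality variance, and a seeded permutation test
(default 999 relabelings). Getis-Ord G\* uses binary queen weights
*including* the focal cell and the population standard deviation in the
denominator, matching the common GIS implementation; |z| thresholds
1.65/1.96/2.58 map to the 90/95/99 % hot/cold classes. No multiple-testing
correction is applied by default (an FDR option would be a one-liner for
users who want it); a uniform field returns all-zero z-scores rather than
an error, the degenerate limit of "no clustering anywhere". IDW predictions
are clamped to the sample range; ordinary kriging solves the
Lagrange-multiplier system with a nugget-0 spherical variogram fitted by
weighted least squares on the binned empirical semivariogram (range and
partial sill over a grid of candidate ranges, weights = pair counts), so it
remains an exact interpolator; a clamped output option is exposed
separately because raw kriging may lawfully exceed the data range.

# Environmental predictors

Stacks are averaged over the depth window and period with missing-aware
means; 0.25° layers are block-averaged onto the 1° grid (each coarse cell
the mean of its 16 fine cells). Temperature deviation groups slices into
consecutive 2-year windows, takes per-cell sample standard deviations
(n−1 denominator, used consistently throughout the package) of adjacent
window means divided by the lag, and averages; stability is the inverse
deviation rescaled by its maximum so the most stable cell is exactly 1,
with zero-deviation cells pinned to 1 before inversion. Standardization is
a sample-SD z-score, applied *before* variable selection (the order is
ambiguous in common practice; forests are scale-invariant, so this choice
only affects reported importances, and it is fixed and documented here).
Predictor redundancy is checked with a pairwise-complete Spearman matrix;
the synthetic generator deliberately builds temperature and oxygen at
ρ ≤ −0.9 to exercise this check.

# Variable selection, GAM + RAC, BIC

The two-stage forest selection ranks variables by permutation importance
averaged over several forests, discards those below a threshold derived
from the importance variability of the bottom half of the ranking, then
fits nested forests in rank order and keeps the smallest set within one
standard error of the minimum OOB error. The one-SE rule is this package's
concretization of "select by reduction of the out-of-bag error"; it is
deliberately parsimony-biased. The regression forest itself (bagged
variance-reduction CART with mtry feature sampling) is implemented
in-package because no forest library is available in the target
environment; it is small but complete (OOB predictions, permutation
importance) and its recovery behavior is property-tested.

Richness GAMs default to Poisson with log link (counts); composition
responses (per-cell mean Sørensen dissimilarity ∈ [0,1]) default to a
Gaussian fit on the logit scale. Smooths are thin-plate splines with REML
smoothing selection via `mgcv`; BIC uses the fit's effective degrees of
freedom through `logLik.gam`. The residual autocovariate (RAC) is the
row-standardized queen-neighborhood mean of the base model's residuals,
added as a linear term, and Moran's I of the residuals is reported before
and after. Two empirical properties worth knowing: (i) on simulated grids
with injected spatially autocorrelated residuals, |I| decreases after RAC
in ≥ 90 % of seeded runs (an acceptance property); (ii) because the RAC is
built from the same residuals it corrects, it tends to *overshoot* slightly
negative — "autocorrelation removed" should therefore be read one-sided (no
remaining positive clustering), and that is how the tests phrase it.
ΔBIC tables attach the standard evidence bands (<2 barely worth a mention,
2–6 positive, 6–10 strong, >10 very strong); ties for the minimum are
broken deterministically by candidate order. Where a published selection
table flags a "best" model whose BIC is not the minimum, this package does
not replicate the inconsistency: selection is strictly minimum-BIC.

# Generalized dissimilarity modelling

Site-pair dissimilarities (Sørensen by default; turnover is a switch)
are modelled as `d = 1 − exp(−η)` with
`η = α + Σ_p |f_p(x_p,i) − f_p(x_p,j)|`, each transform `f_p` a nonnegative
combination of three order-2 I-splines with knots at the predictor's
min/median/max. The coefficients (intercept included) are estimated by
iteratively reweighted NNLS (Lawson–Hanson active set) maximizing a
binomial-type deviance, with convergence on the maximum coefficient change.
Degenerate inputs collapse correctly: all-zero dissimilarities give an
all-zero fit, zero environmental contrast leaves only the intercept, and a
constant predictor contributes an all-zero basis rather than NaNs.
Predictor importance is the transform height `f_p(max) − f_p(min)` (the
coefficient sum); only positive-height predictors enter composition
mapping. The map applies the fitted transforms per cell, runs a PCA, fixes
each component's sign by forcing the first retained predictor's loading
positive (RGB maps are otherwise sign-ambiguous between runs), and min–max
scales the first three score axes to [0, 255]. Pair tables are capped at a
seeded subsample of 50,000 pairs for tractability. Geographic distance is
carried as a column but not fitted by default.

# The synthetic world and what a green test establishes

The generator states one fixed world rather than tunable difficulty:

- **Species pool** (default 178, the scale of a basin-wide epipelagic
  copepod list): Gaussian niche kernels on temperature and salinity with
  widths 0.15–0.4 of the gradient (broad enough to overlap, narrow enough
  to create turnover), baseline prevalences uniform on 0.05–0.6.
- **Environment**: a latitudinal mean gradient plus Gaussian-random-field
  noise (circularly smoothed white noise; an infinite smoothing scale
  degenerates to per-slice constant fields, which is tested), oxygen built
  as a strongly decreasing function of temperature with weak independent
  noise (realized Spearman ρ ≲ −0.99), small basin-wide interannual
  anomalies between yearly slices.
- **Effort**: gamma-distributed expected events per cell with shape 0.35 —
  the heavy right skew of real survey effort; most cells are near-empty.
- **Dirt**: a configurable fraction of records corrupted, cycling through
  missing coordinates, (0,0) coordinates, genus-rank truncation and exact
  duplication, each row carrying a hidden audit tag the cleaning stage
  never reads.

Ground truth is analytic: expected per-event richness `Σ_s p_cs`, the
effort-aware expectation of realized richness `Σ_s (1 − e^{−λ_c p_cs})`
under Poisson sampling (verified against 200-replicate Monte Carlo), and
top-decile hotspot flags. What the generator does *not* emulate: coastline
geometry, dispersal and advection, temporal autocorrelation of occupancy
within cells, taxonomic misidentification beyond rank truncation, and
effort correlated with environment (effort is independent of richness). A
green recovery test therefore establishes that the pipeline's mathematics
and bookkeeping are right — not that any real basin's pattern is
recoverable at any particular coverage.

# Numerical choices and degenerate inputs

- Sample (n−1) standard deviations everywhere, including two-point slice
  deviations.
- Rarefaction binomials in log space (`lchoose`), bootstrap seeded.
- Moran/G\* refuse constant fields where the statistic is undefined
  (Moran) or return the degenerate all-zero limit (G\*).
- Kriging refuses duplicate sample locations (singular system).
- NNLS tolerance 1e−10; GDM IRLS clamps fitted probabilities to
  [1e−6, 1−1e−6] and errors with a trace if the coefficient change fails
  to converge within `max_iter`.
- All stochastic operations take explicit integer seeds; generator
  sub-streams derive from one global seed by fixed offsets, so runs are
  byte-reproducible (asserted via manifest checksums in the pipeline
  tests).

# Known limitations

Multi-site beta diversity, abundance-weighted dissimilarities,
coverage-based rarefaction and Hill numbers beyond q = 0, local Moran
(LISA), anisotropic variograms, CAR/SAR alternatives to the RAC, and live
taxonomic-backbone matching are intentionally out of scope. NetCDF
ingestion is not provided (no NetCDF reader exists in the supported
dependency set); environmental stacks are read from long-format CSV.
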