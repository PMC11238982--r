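# oceandiv

Basin-scale biodiversity analysis of gridded marine species occurrence
records, built for the kind of question asked of aggregated portals such as
OBIS: given decades of heterogeneous, heavily under-sampled occurrence
records of epipelagic zooplankton (the motivating case is copepods in the
0–200 m layer of an ocean basin), where are the diversity hot and cold
spots, how does community composition turn over in space, which
environmental variables predict richness and composition, and how much of
the apparent pattern is a sampling artifact?

The package implements the full analysis chain as tested, reusable R code:

- **Record curation** — Darwin Core-style ingestion, ordered cleaning rules
  (missing/zero coordinates, land mask, basin mask, non-species ranks,
  depth window, study period, duplicates) with an exactly-conserving
  `CleaningReport`, offline synonym-table taxonomy harmonization, and
  gridding to half-open 1° cells (`cell_id = floor(lon):floor(lat)` with
  dateline wrap).
- **Diversity** — presence–absence matrix (PAM) construction; alpha
  richness; Shannon–Wiener index on occurrence proportions
  `H = −Σ pᵢ ln pᵢ, pᵢ = nᵢ/N`; pairwise Sørensen dissimilarity partitioned
  exactly into turnover and nestedness,
  `βsor = (b+c)/(2a+b+c) = βsim + βsne` with `βsim = b/(b+a)`; per-cell mean
  beta fields; redundancy index `R = 1 − S/N`; dominance rankings.
- **Sampling effort** — seamless sample-size-based rarefaction and
  extrapolation of species richness (hypergeometric interpolation in log
  space, Chao-style unseen-species extrapolation, seeded multinomial
  bootstrap intervals) and region coverage tables with spherical cell areas
  `R²Δλ(sin φ₂ − sin φ₁)`.
- **Spatial statistics** — queen/distance-band weights with dateline wrap,
  global Moran's I (analytic and permutation inference, `E[I] = −1/(n−1)`),
  Getis-Ord G\* hot/cold-spot classification at the 90/95/99 % thresholds,
  inverse-distance-weighted interpolation, and ordinary kriging with
  spherical/exponential variograms fitted to the empirical semivariogram.
- **Modelling** — two-stage random-forest variable selection (permutation
  importance ranking, then nested-model OOB selection; the forest is
  implemented in-package), `mgcv` GAMs with Poisson / Gaussian /
  logit-Gaussian families, residual-autocovariate (RAC) augmentation with
  before/after Moran's I, BIC/ΔBIC model tables with the standard evidence
  categories, and predicted-vs-observed diagnostics.
- **Generalized dissimilarity modelling** — monotone order-2 I-spline
  transforms (3 knots at min/median/max), negative-exponential link
  `d = 1 − e^(−η)` fitted by iteratively reweighted nonnegative least
  squares (Lawson–Hanson NNLS), predictor importance as maximum spline
  heights, and PCA→RGB composition maps.
- **Synthetic worlds** — a first-class generator of occurrence records with
  known ground truth (Gaussian niche responses, skewed sampling effort,
  audit-tagged dirty records, coupled temperature/oxygen fields) so every
  stage has a recovery test.
- **Pipeline** — `run_pipeline()` executes all stages from one declarative
  config and writes a checksummed manifest; a thin CLI lives in
  `inst/cli/oceandiv.R`.

## Worked example

A small synthetic basin (16° × 16°, 80-species pool, skewed effort,
8 % corrupted records), run end to end:

```r
library(oceandiv)
spec   <- grid_spec(1, c(-20, -4), c(-40, -24))
stack  <- make_env_fields(spec, n_time_slices = 4, seed = 42)
env    <- aggregate_mean(stack, depth_range = c(0, 200), period = c(1993, 2019))
pool   <- make_species_pool(n_species = 80, seed = 42)
effort <- make_effort_field(grid_cells(spec), mean_events = 3, seed = 42)
rec    <- simulate_occurrences(env, pool, effort, dirty_fraction = 0.08,
                               seed = 42, spec = spec)

f <- tempfile(fileext = ".csv"); write.csv(rec, f, row.names = FALSE)
cleaned <- clean_records(read_occurrences(f))
cleaned$report
#> cleaning report: 4466 in, 4116 out
#>   missing_coords     88
#>   zero_coords        88
#>   non_species_rank   87
#>   duplicate          87

pam <- build_pam(assign_cells(cleaned$records, spec))
pam
#> pam: 136 cells x 80 species, 4116 records

round(attr(beta_per_cell(pam), "grand_means"), 3)
#> beta_sor beta_sim beta_sne
#>    0.740    0.554    0.186
```

Every dropped record is attributed to exactly one rule (input = output +
drops — the 88+88+87+87 here are exactly the generator's corrupted rows),
and the mean Sørensen dissimilarity between cells (0.740) splits exactly
into turnover (0.554) plus nestedness (0.186).

```r
rich <- rowSums(pam$incidence)
ws   <- build_weights(pam$cells, "queen", include_self = TRUE, spec = spec)
table(getis_ord_gstar(rich, ws)$class)
#> cold90  hot90  hot95  hot99     ns
#>      2      9      4      4    117

w0 <- build_weights(pam$cells, "queen", spec = spec)
mi <- morans_i(rich, w0, n_perm = 999, seed = 42)
#> Moran's I = 0.081 (E[I] = -0.007, permutation p = 0.168)
```

17 of 136 cells classify as richness hot spots at ≥ 90 % confidence —
clusters of cells whose neighborhood-summed richness is improbably high
under spatial randomness.

```r
ts   <- temperature_deviation_stability(stack)
envz <- standardize_env(merge(env, ts, by = "cell_id"),
                        c("T_mean", "S", "Chla", "O2", "MLD", "T_sd"))
sel  <- rf_select(envz[match(pam$cells, envz$cell_id),
                       c("T_mean","S","Chla","O2","MLD","T_sd","T_stab")],
                  rich, n_trees = 60, n_runs = 3, seed = 42)
sel
#> rf_select: 5 of 7 variables selected: S, MLD, T_mean, O2, Chla

fit <- fit_gam_rac(rich, envz[match(pam$cells, envz$cell_id), sel$selected],
                   build_weights(pam$cells, "queen", spec = spec),
                   family = "poisson", seed = 42)
#> richness GAM+RAC: BIC 1390.9 (base 1424.1), adj-R2 0.24
#> residual Moran's I: -0.110 -> 0.086
```

The selection keeps both true niche drivers of the generator (`T_mean`,
`S`) along with their spatially confounded correlates (`O2` is constructed
at ρ ≈ −0.99 with temperature, exactly the redundancy the Spearman check is
there to flag). Adding the residual autocovariate improves BIC by 33.

```r
pairs <- build_site_pairs(pam, envz, seed = 42, spec = spec)
g <- fit_gdm(pairs)
#> gdm_fit: 9180 pairs, 7 predictors, 31.6% deviance explained
head(predictor_importance(g), 4)
#>  predictor height retained
#>          S  1.673     TRUE
#>         O2  0.609     TRUE
#>     T_mean  0.221     TRUE
#>       Chla  0.153     TRUE
```

`transform_and_map(g, envz)` then yields per-cell RGB channels — the first
three PCA axes of the monotone-transformed predictor space — for
composition mapping.

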