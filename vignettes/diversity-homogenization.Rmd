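---
title: "Partitioning diversity and detecting biotic homogenization with mangrovediv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning diversity and detecting biotic homogenization with mangrovediv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mangrovediv)
```

## The problem

Long-term permanent-plot networks are the best instrument we have for asking
whether a forest is *homogenizing* — losing compositional differences between
sites as generalists spread and specialists retreat. Answering that question
well requires more than species richness: it needs a diversity framework that
(a) works at several scales at once (plot, ecological zone, whole ecosystem),
(b) can emphasize or de-emphasize rare species explicitly, and (c) separates
"how diverse is this site" from "how typical is this site of the whole".
`mangrovediv` implements such a framework for tree-census tables of the kind
collected in the Sundarbans mangrove network — 110 permanent 0.2-ha plots in
three salinity zones (hyposaline, mesosaline, hypersaline), censused four
times between 1986 and 2014 — together with the species-level change indices
and the geostatistical mapping layer that turn plot-level numbers into
ecosystem-scale statements.

## The diversity framework

Everything rests on the joint relative abundance matrix. Write `p[s, j]` for
the fraction of all trees (over the whole *metacommunity*, MC) that belong to
species `s` and *subcommunity* (SC) `j`. Derived from it are

* the subcommunity weights `w[j] = sum_s p[s, j]` (each SC's share of trees),
* the within-SC compositions `phat[, j] = p[, j] / w[j]`, and
* the pooled species distribution `P[s] = sum_j p[s, j]`.

All measures are *effective numbers* built from weighted power means of
order `1 - q`, where the viewpoint parameter `q >= 0` sets how much weight
dominant species get. At `q = 0` every species counts equally (richness
viewpoint); `q = 1` weights by information content (exponential-Shannon);
`q = 2` is dominated by common species (inverse-Simpson). The package
computes, at any `q`:

* **Normalized alpha** `alpha_bar[j]`: the Hill number of `phat[, j]` — the
  effective species count of SC `j` in isolation.
* **Representativeness** `rho_bar[j]`: the order-`(1 - q)` power mean, over
  SC `j`'s species, of `P[s] / phat[s, j]`. It is 1 exactly when the SC's
  composition matches the MC's, and is bounded below by `w[j]` — a
  completely idiosyncratic SC represents nothing but its own share of the
  trees. Low spatial `rho_bar` means between-site heterogeneity; a rising
  trend over censuses is the signature of biotic homogenization.
* **Subcommunity gamma** `gamma[j]`: the order-`(1 - q)` power mean of
  `1 / P[s]` — SC `j`'s per-tree contribution to MC diversity.
* **Metacommunity gamma**: the Hill number of `P`.

Two framework identities double as the package's strongest self-checks,
enforced in the test suite to 1e-10 on random matrices: `w[j] <= rho_bar[j]
<= 1`, and the `w`-weighted power mean of order `1 - q` of the `gamma[j]`
equals the metacommunity gamma.

`q = 1` is computed from dedicated log-space limit formulas, not by
evaluating near `q = 1`; power means route through log space whenever value
ratios leave `[1e-6, 1e6]`. Species absent from a subcommunity carry zero
weight in its species-weighted means, which keeps `q = 0` quantities finite
and equal to richness-based forms.

### Averaging convention

When per-SC values are aggregated (zone means, ecosystem means), the package
uses the weighted power mean of order `1 - q` — arithmetic at `q = 0`,
geometric at `q = 1`, harmonic at `q = 2` — because that is the aggregation
under which subcommunity gammas reassemble into the metacommunity gamma.
Some reports instead state the mapping "arithmetic, harmonic, geometric for
q = 0, 1, 2"; that convention disagrees with the framework's algebra at
`q = 1` and `q = 2`, so it is not the default, but it is available as
`metacommunity_average(..., rule = "fixed_map")` for comparability. No
attempt is made to guess which was intended where the two conflict.

## Partitioning designs

Four MC/SC designs cover the spatial and temporal questions
(`design_spec()`):

1. **spatial_zone** — MC: one zone at one census; SCs: its plots.
2. **spatial_ecosystem** — MC: the whole network at one census; SCs: a
   balanced draw of `n_per_zone` plots from each zone.
3. **temporal_psp** — MC: one plot pooled over all censuses; SCs: its
   single-census compositions.
4. **temporal_zone** — as 3, with zone-pooled compositions.

Because plot allocation is uneven (50/30/30), the spatial designs subsample
larger zones to `n_per_zone` (default 30) without replacement, independently
across iterations (default 100), under a fixed seed. Summaries
(`summarize_design()`) report the order-`(1 - q)` mean over SCs per
iteration, averaged arithmetically across iterations. The 95% interval is a
seeded percentile bootstrap (B = 1000) resampling SC values pooled across
iterations — it therefore spans both subcommunity and iteration
variability; since the literature this workflow comes from does not pin the
interval's target down, a normal-approximation alternative is one switch
away, and neither is privileged. A single-SC group cannot support an
interval; it collapses to the point estimate and is flagged.

A caution worth stating explicitly: under steady *directional* change,
temporal representativeness (design 3/4) is hump-shaped across censuses —
middle censuses resemble the pooled series most — so "is the zone
homogenizing?" must be asked of the *spatial* `rho_bar` trajectory across
census years, not of the temporal one. The test suite asserts both shapes.

## Species-level change indices

For a zone and a year pair (default 1986/2014):

* **Percentage composition change**,
  `%CC = 100 (c2 - c1) / (c2 + c1)` on the two percentage contributions,
  runs from -100 (local extinction) to +100 (introduction) and is invariant
  to overall abundance change. A species absent at both times has no
  defined change and is excluded rather than reported as 0 — a 0 would
  fabricate stability.
* **Range-change index**, `(n2 - n1) / |occupied1 U occupied2|`, runs from
  -1 (vanished from all plots) to +1 (newly arrived). The standardizing
  count is read as the union of the occupied plot sets: an intersection
  reading cannot produce the ±1 endpoints at all, and between union and the
  plain sum of the two occupancy counts (both of which do), the union is the
  natural reading of "total plots at which the species was present"; the sum
  variant remains available (`denom = "sum"`) and halves the index for
  disjoint sets.

The package ships the published zone-level 1986/2014 Sundarbans abundance
table as a fixture (`table1_fixture()`) and reproduces its contribution and
%CC cells at printed precision — except where the source table is internally
inconsistent with itself: its hyposaline-2014 species counts sum to one more
tree than its printed total, which perturbs five %CC cells by 0.01 at the
second decimal, one contribution cell (41.43%) contradicts both its own
count and its own %CC, and one %CC cell prints +4.75 where the formula gives
+4.74 under either total. The per-species counts are treated as
authoritative throughout; the discrepancies are documented in the fixture's
help page and pinned down in the acceptance tests.

## Kriging layer

Per-plot diversity values are interpolated by ordinary kriging
(`map_diversity()`): Matheron method-of-moments semivariogram (12 bins to
half the maximum pairwise distance, both configurable), least-squares fits
of spherical, exponential and Gaussian models with deterministic
multi-start Nelder-Mead, selection by smallest SSE (ties break
spherical-first), and prediction at the centers of 25-m (625 m²) grid cells
over the one-cell-padded bounding box. The exponential and Gaussian models
are parameterized `c0 + c (1 - exp(-h/a))` and `c0 + c (1 - exp(-(h/a)^2))`;
`a` is the distance parameter, and the effective ranges `3a` and
`sqrt(3) a` are recorded in the fit because conventions differ across
geostatistics tools. SSE is unweighted across bins by default (pair-count
weighting is a switch). Uncertainty is summarized by leave-one-out NRMSE
(RMSE of held-out predictions divided by the observed value range) with the
variogram held fixed across folds — refitting per fold is available but
costs n extra fits and, at network sizes near 100 plots, does not change
the picture. Between-epoch change is the fraction of cells moving in a
given direction by more than a threshold `epsilon` (default 0); no default
threshold for "distinct" or "high-contribution" cells is asserted, because
none is canonical. Exact duplicate coordinates are averaged before solving
(the system is singular otherwise); coordinates are planar meters with no
geodetic handling, and no coastline masking is attempted since no such
geometry is in scope.

Numerical guards worth knowing: kriging weights are obtained from one LU
factorization of the bordered semivariogram system and always sum to 1 to
1e-10 (tested); with a zero nugget the predictor interpolates exactly; a
fitted model whose partial sill is negligible or whose effective range
falls below the first lag bin is flagged as pure-nugget, since its range is
not identified.

## The synthetic generator

No plot coordinates were ever published for the real network, so every
spatial claim in the package is exercised on synthetic data
(`scenario_config()`, `simulate_scenario()`). The generator emulates the
statistical structure the analysis assumes:

* 110 plots of 0.2 ha, 50/30/30 across three contiguous zone blocks along a
  salinity gradient (0.8 to 5.5 dS/m across a 5 km x 2 km extent, spanning
  the <2 / 2-4 / >4 dS/m zone bands), jittered within blocks;
* plot salinity = gradient + a Gaussian-process noise field (exponential
  covariance, sd 1.0 dS/m, range 250 m, built by direct Cholesky
  factorization — fine at a few hundred plots) + a per-census salinization
  increment;
* 22 species with Gaussian salinity niches in four guilds (low-salinity
  specialists, facultative halophytes, generalist halophytes, one invasive
  halophyte), named after familiar Sundarbans taxa purely for readable
  output; expected counts `A exp(r t) exp(-(s - mu)^2 / (2 sigma^2))` at
  census index `t`, realized as independent Poisson draws (a fixed-total
  multinomial mode exists for users who want closed plot totals).

Defaults were chosen once to make the stationary community quantitatively
plausible for this system and are not revisited: per-plot totals of a few
hundred trees (the published zone totals imply roughly 400 trees per
hyposaline plot), hyposaline plots the most species-rich and the most
heterogeneous, and specialists holding roughly a quarter of hyposaline
composition so that their decline is a visible signal rather than a
rounding error. Trends act on the census index 0..3, not the calendar year;
the irregular 1986/1994/1999/2014 spacing is presentational.

`homogenization_scenario(strength)` maps one dial in [0, 1] onto the three
drivers of homogenization: salinization (0.2 dS/m per census at strength
1), invasive expansion (`r = +1.0`) and specialist decline (`r = -0.9`;
facultative species at half that). At strength 1 these produce, by
construction and verified over 20 seeds in the acceptance suite, a
monotonically rising across-zone mean of spatial `rho_bar` over the four
censuses, positive %CC for the invasive in every zone, and negative range
indices for the narrow specialists in their home zone. At strength 0 the
community is stationary and the fitted `rho_bar` trend is
indistinguishable from zero.

What the generator does *not* emulate — and therefore what passing tests do
not show about real data: demography (growth, mortality, dispersal) and
spatial contagion of recruitment; observation error in species
identification; plot loss or relocation; non-Gaussian niches; interannual
climate variability. The generator is a statistical stand-in whose purpose
is parameter *recovery* — known signal in, measured signal out — not a
mechanistic model of the Sundarbans.

## Problem sizes and runtime choices

The shipped tests run the full feature surface at reduced problem sizes
chosen for tight feedback loops: design machinery on 24-40-plot networks,
kriging skill on 40-60-point fields, the homogenization recovery at the
full 110-plot network over 20 seeds, and bootstrap intervals at B = 200-400
where only calibration (not the default) is under test. The pipeline's
defaults (100 iterations, B = 1000, 25-m cells) are the analysis-grade
settings.

## Worked example

```{r example, eval = FALSE}
library(mangrovediv)

# the published two-census, zone-level table
tab <- table1_fixture()
chg <- abundance_change_table(tab, 1986, 2014)
subset(chg, species == "Ceriops decandra")

# diversity profile of the three 1986 zone communities
mc <- metacommunity(abundance_by_zone(tab, 1986))
diversity_profile(mc, c(0, 1, 2))

# a full synthetic run with a strong homogenization signal
cfg <- run_config(scenario = homogenization_scenario(1),
                  out_dir = "homog_run", seed = 1)
man <- run_pipeline(cfg)
```

## Known limitations

* The fixture is zone-level: range-change indices need plot-level occupancy
  and are `NA` there by design.
* Ordinary kriging is purely spatial; diversity surfaces inherit its
  assumptions (intrinsic stationarity, no covariates, no anisotropy) and
  cross-validation regularly shows more skill for alpha than for
  representativeness surfaces.
* Repeated-measures ANOVA and post-hoc contrasts on the design summaries
  are deliberately out of scope; the tidy CSVs the pipeline writes are the
  intended hand-off to standard tools.
* Confidence intervals answer "how variable are subcommunity values under
  resampling", not "how uncertain is the zone mean under survey redesign";
  with 30 plots per zone the distinction is minor but real.
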