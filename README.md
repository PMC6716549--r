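# mangrovediv

Diversity partitioning and biotic-homogenization analysis for long-term
forest census networks, built around the Sundarbans mangrove
permanent-sample-plot system (110 plots of 0.2 ha in three salinity zones,
censused in 1986, 1994, 1999 and 2014).

The package is for community ecologists who have long-format census tables
— one tree count per (plot, census year, species) — and want to know not
just how diverse each site is, but whether the system is *homogenizing*:
losing between-site compositional differences as generalists expand and
specialists retreat.

## What it computes

**Diversity partitioning.** For a metacommunity (MC) split into
subcommunities (SCs), with joint relative abundances `p[s, j]`, SC weights
`w[j] = Σ_s p[s, j]`, within-SC compositions `p̂[, j] = p[, j] / w[j]` and
pooled distribution `P[s] = Σ_j p[s, j]`, the package evaluates at any
viewpoint parameter `q ≥ 0` (q = 0 richness-viewpoint, q = 1
Shannon-viewpoint, q = 2 dominance-viewpoint):

- normalized SC alpha diversity `ᾱ_j` — the order-q Hill number of
  `p̂[, j]`;
- SC representativeness `ρ̄_j` — the order-(1−q) power mean over species of
  `P[s] / p̂[s, j]`, with `w_j ≤ ρ̄_j ≤ 1`; 1 means the SC mirrors the MC,
  low values mean compositional distinctness, and a rising spatial `ρ̄`
  across censuses is the homogenization signature;
- SC gamma `γ_j` — the order-(1−q) power mean of `1 / P[s]` (per-tree
  contribution to MC diversity), whose weighted order-(1−q) mean over SCs
  reassembles the MC gamma, the Hill number of `P`.

Four MC/SC designs (zone/plots, ecosystem/plots with balanced 30-per-zone
subsampling over 100 seeded iterations, plot/censuses, zone/censuses) with
power-mean-consistent summaries and bootstrap confidence intervals.

**Species-level change.** Percentage composition change
`%CC = 100 (c₂ − c₁)/(c₂ + c₁)` on percentage contributions (−100 =
local extinction, +100 = introduction) and the occupancy range-change index
`(n₂ − n₁)/|occupied₁ ∪ occupied₂| ∈ [−1, 1]`.

**Mapping.** Ordinary kriging of per-plot diversity onto 625 m² grid
cells: Matheron semivariogram, spherical/exponential/Gaussian fits selected
by least SSE, leave-one-out NRMSE, and directional change fractions
between epochs. Surfaces export as ESRI ASCII grids and tidy CSV.

**Synthetic data.** A seeded generator of salinity-structured census data
(Gaussian niches over a gradient-plus-correlated-noise salinity field,
Poisson counts) with a one-dial `homogenization_scenario(strength)` preset
driving invasive expansion, specialist decline and salinization.

The published zone-level 1986/2014 Sundarbans abundance table ships as a
fixture (`table1_fixture()`); the package reproduces its printed
contribution and %CC cells at 2 d.p. (see the fixture help page for the
source table's own internal off-by-one, which the tests pin down).

## Worked example

```r
library(mangrovediv)
tab <- table1_fixture()
chg <- abundance_change_table(tab, 1986, 2014)
subset(chg, species == "Ceriops decandra")
#>           species        zone count_start contrib_start count_end contrib_end
#>  Ceriops decandra  hyposaline           4          0.02       258        1.39
#>  Ceriops decandra  mesosaline          20          0.13      1098        6.65
#>  Ceriops decandra hypersaline         257          2.31      1669       11.62
#>  cc_percent range_index
#>       97.22          NA
#>       96.15          NA
#>       66.87          NA
```

The native invasive *Ceriops decandra* raised its share of the composition
in every zone — by +97.22 %CC in the hyposaline zone, where it grew from 4
to 258 trees (range indices are `NA` because the fixture is zone-level, so
plot occupancy is unavailable). The three-zone diversity profile at q = 1:

```r
mc <- metacommunity(abundance_by_zone(tab, 1986))
subset(diversity_profile(mc, c(0, 1, 2)), q == 1)
#>     measure q  subcommunity value
#>   alpha_bar 1    hyposaline 3.298
#>   alpha_bar 1    mesosaline 2.180
#>   alpha_bar 1   hypersaline 1.724
#>     rho_bar 1    hyposaline 0.960
#>     rho_bar 1    mesosaline 0.934
#>     rho_bar 1   hypersaline 0.784
#>   gamma_sub 1    hyposaline 3.435
#>   gamma_sub 1    mesosaline 2.335
#>   gamma_sub 1   hypersaline 2.200
#>  gamma_meta 1 metacommunity 2.723
```

In 1986 the hyposaline zone held the most effective species (ᾱ = 3.30
versus 1.72 in the hypersaline zone) while the hypersaline zone was the
most compositionally distinct from the pooled ecosystem (ρ̄ = 0.78). A full
synthetic analysis — four designs, summaries with CIs, change metrics,
kriged surfaces — runs as:

```r
cfg <- run_config(scenario = homogenization_scenario(1),
                  out_dir = "homog_run", seed = 1)
man <- run_pipeline(cfg)   # writes tidy CSVs, .asc grids, manifest.json
```

## Package layout

- `R/census.R` — census table container, validation, CSV I/O, fixture,
  abundance-matrix groupings
- `R/diversity.R` — power means, metacommunity normalization, the four
  diversity measures, profiles
- `R/designs.R` — the four partitioning designs, subsampling, summaries,
  temporal representativeness
- `R/change.R` — %CC and range-change indices, the zone-wise change report
- `R/geostat.R` — semivariograms, fitting, ordinary kriging, LOO NRMSE,
  change fractions, `.asc` export
- `R/synthetic.R` — species pool, scenario configs, network and census
  simulation, homogenization presets
- `R/pipeline.R` — end-to-end orchestration with a hashed run manifest
- `inst/cli/mangrovediv.R` — thin command-line wrapper
  (`simulate | diversity | change | map | all`)
- `vignettes/diversity-homogenization.Rmd` — methods, assumptions, design
  decisions and limitations
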