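Package: mangrovediv
Title: Diversity Partitioning and Biotic Homogenization Analysis for
    Long-Term Forest Census Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Hill-number diversity partitioning for permanent-sample-plot
    census data: normalized subcommunity alpha diversity, representativeness
    (rho-bar, a beta-diversity measure of how well a subcommunity matches its
    metacommunity), and subcommunity/metacommunity gamma diversity at any
    viewpoint parameter q >= 0. Implements four spatial and temporal
    metacommunity partitioning designs with balanced zone subsampling and
    bootstrap confidence intervals, percentage composition-change and
    occupancy-based range-change indices for species-level turnover, and
    ordinary kriging of per-plot diversity values with empirical semivariogram
    estimation, spherical/exponential/Gaussian model fitting by least squares,
    leave-one-out cross-validation (NRMSE), and between-epoch change
    fractions. Includes a seeded generator of salinity-structured synthetic
    census data for mangrove-like plot networks, and ships a published
    zone-level 1986/2014 Sundarbans abundance table as a worked fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
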