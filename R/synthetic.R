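#' Default synthetic species pool
#'
#' Twenty-two species profiles spanning the guilds a salinity-graded
#' mangrove network contains: low-salinity specialists (non-halophytes),
#' facultative halophytes, broadly tolerant generalist halophytes, and one
#' disturbance-adapted invasive halophyte. Names follow well-known
#' Sundarbans taxa purely for readable reports; niche parameters are
#' statistical stand-ins, not fitted values.
#'
#' Each profile has a Gaussian niche over salinity (optimum `mu`,
#' breadth `sigma`, both in dS/m), a base abundance `A` (expected trees per
#' 0.2 ha plot at the optimum) and a per-census log-abundance trend `r`
#' (default 0; scenario presets set it).
#'
#' @return data.frame: `name`, `guild`, `mu`, `sigma`, `A`, `r`.
#' @export
default_species_pool <- function() {
  pool <- rbind(
    # generalist halophytes: broad niches, high abundance everywhere salty
    data.frame(name = "Excoecaria agallocha", guild = "generalist_halophyte",
               mu = 4.0, sigma = 2.6, A = 330),
    data.frame(name = "Heritiera fomes", guild = "facultative",
               mu = 1.6, sigma = 1.6, A = 320),
    # the native invasive: halophyte expanding under disturbance/salinity
    data.frame(name = "Ceriops decandra", guild = "invasive",
               mu = 4.8, sigma = 2.2, A = 40),
    data.frame(name = "Bruguiera sexangula", guild = "facultative",
               mu = 1.8, sigma = 1.2, A = 14),
    data.frame(name = "Xylocarpus moluccensis", guild = "facultative",
               mu = 2.0, sigma = 1.3, A = 11),
    data.frame(name = "Xylocarpus granatum", guild = "facultative",
               mu = 2.6, sigma = 1.5, A = 3),
    data.frame(name = "Avicennia officinalis", guild = "facultative",
               mu = 1.4, sigma = 1.1, A = 22),
    data.frame(name = "Sonneratia apetala", guild = "facultative",
               mu = 1.5, sigma = 1.2, A = 17),
    # hyposaline specialists (non-halophytes): narrow niches at low salinity
    data.frame(name = "Amoora cucullata", guild = "specialist_hyposaline",
               mu = 1.1, sigma = 0.75, A = 72),
    data.frame(name = "Cynometra ramiflora", guild = "specialist_hyposaline",
               mu = 1.0, sigma = 0.7, A = 40),
    data.frame(name = "Cerbera manghas", guild = "specialist_hyposaline",
               mu = 0.9, sigma = 0.7, A = 28),
    data.frame(name = "Talipariti tiliaceum", guild = "specialist_hyposaline",
               mu = 1.2, sigma = 0.7, A = 16),
    data.frame(name = "Aegiceras corniculatum", guild = "specialist_hyposaline",
               mu = 1.3, sigma = 0.8, A = 10),
    data.frame(name = "Excoecaria indica", guild = "specialist_hyposaline",
               mu = 1.0, sigma = 0.6, A = 4.8),
    data.frame(name = "Tamarix dioica", guild = "specialist_hyposaline",
               mu = 1.1, sigma = 0.6, A = 4.8),
    data.frame(name = "Barringtonia racemosa", guild = "specialist_hyposaline",
               mu = 0.8, sigma = 0.6, A = 4),
    data.frame(name = "Sonneratia caseolaris", guild = "specialist_hyposaline",
               mu = 0.9, sigma = 0.6, A = 3.2),
    data.frame(name = "Intsia bijuga", guild = "specialist_hyposaline",
               mu = 1.0, sigma = 0.6, A = 2.4),
    data.frame(name = "Lannea coromandelica", guild = "specialist_hyposaline",
               mu = 1.1, sigma = 0.6, A = 2.4),
    data.frame(name = "Pongamia pinnata", guild = "specialist_hyposaline",
               mu = 1.2, sigma = 0.6, A = 2),
    data.frame(name = "Syzygium fruticosum", guild = "specialist_hyposaline",
               mu = 1.0, sigma = 0.6, A = 2),
    data.frame(name = "Hypobathrum racemosum", guild = "specialist_hyposaline",
               mu = 1.3, sigma = 0.7, A = 1.6))
  pool$r <- 0
  pool
}

#' Scenario configuration for the synthetic census generator
#'
#' Describes a Sundarbans-like permanent-plot network and the dynamics of
#' its community: 110 plots of 0.2 ha split 50/30/30 over three salinity
#' zones laid out as contiguous blocks along the salinity gradient, a
#' spatially correlated salinity field, four censuses, and per-census
#' trends (salinization, guild-level abundance trends).
#'
#' Salinity at a plot is `gradient(x) + correlated noise +
#' salinization_rate * census_index`, with the gradient spanning
#' `salinity_range` over the network extent and noise drawn from a Gaussian
#' process with exponential covariance (`noise_sd`, `noise_range`). Species
#' expected counts follow Gaussian niches:
#' `lambda = A * exp(r * census_index) * exp(-(s - mu)^2 / (2 sigma^2))`,
#' and observed counts are Poisson draws (plot totals then vary as real
#' censuses do; set `fixed_total` for a multinomial variant with fixed
#' per-plot totals).
#'
#' @param n_plots total plots (default 110).
#' @param zone_split plots per zone, hypo/meso/hyper (default 50/30/30).
#' @param extent network extent in meters, `c(x, y)` (default 5000 x 2000).
#' @param species species profile data.frame (default
#'   [default_species_pool()]).
#' @param years census years (default 1986, 1994, 1999, 2014). Trends act on
#'   the census index 0..3, not the calendar year.
#' @param salinity_range endpoints of the deterministic gradient in dS/m
#'   (default 0.8 to 5.5, spanning the three zone bands <2, 2-4, >4).
#' @param noise_sd,noise_range sd (dS/m) and correlation range (m) of the
#'   spatially correlated salinity noise.
#' @param salinization_rate dS/m added per census step (default 0).
#' @param fixed_total if not `NULL`, draw each plot-census as a multinomial
#'   with this total instead of independent Poissons.
#' @param seed RNG seed.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(n_plots = 110L, zone_split = c(50L, 30L, 30L),
                            extent = c(5000, 2000),
                            species = default_species_pool(),
                            years = c(1986L, 1994L, 1999L, 2014L),
                            salinity_range = c(0.8, 5.5),
                            noise_sd = 1.0, noise_range = 250,
                            salinization_rate = 0, fixed_total = NULL,
                            seed = 1L) {
  if (sum(zone_split) != n_plots) stop("zone_split must sum to n_plots")
  if (noise_range <= 0) stop("noise correlation range must be positive")
  stopifnot(all(species$sigma > 0), all(species$A > 0))
  structure(list(n_plots = as.integer(n_plots),
                 zone_split = as.integer(zone_split), extent = extent,
                 species = species, years = as.integer(years),
                 salinity_range = salinity_range, noise_sd = noise_sd,
                 noise_range = noise_range,
                 salinization_rate = salinization_rate,
                 fixed_total = fixed_total, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate a synthetic plot network
#'
#' Lays plots out in three contiguous zone blocks along the x axis (the
#' salinity gradient axis), jittered uniformly within each block, and
#' assigns zone labels by block. Deterministic under the config seed.
#'
#' @param config a [scenario_config()].
#' @return Plot metadata data.frame: `plot_id`, `zone`, `x`, `y`, `area_ha`.
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  restore <- .Random.seed_guard(config$seed)
  on.exit(restore(), add = TRUE)
  n <- config$n_plots
  # block x-extents proportional to plot allocation
  frac <- cumsum(c(0, config$zone_split)) / n
  xb <- frac * config$extent[1]
  zone <- rep(ZONES, config$zone_split)
  x <- numeric(n); k <- 0L
  for (i in seq_along(ZONES)) {
    ni <- config$zone_split[i]
    x[k + seq_len(ni)] <- stats::runif(ni, xb[i], xb[i + 1])
    k <- k + ni
  }
  y <- stats::runif(n, 0, config$extent[2])
  data.frame(plot_id = sprintf("psp%03d", seq_len(n)), zone = zone,
             x = x, y = y, area_ha = 0.2)
}

# Spatially correlated Gaussian field over plot locations via Cholesky
# factorization of an exponential covariance (fine at n <= a few hundred).
.correlated_noise <- function(x, y, sd, range) {
  n <- length(x)
  if (sd <= 0) return(numeric(n))
  D <- as.matrix(stats::dist(cbind(x, y)))
  C <- sd^2 * exp(-D / range) + diag(1e-8, n)
  as.vector(t(chol(C)) %*% stats::rnorm(n))
}

#' Salinity field of a synthetic network
#'
#' The static component of plot salinity: linear gradient along x plus the
#' spatially correlated noise. Exposed so tests can check the field's
#' spatial autocorrelation directly.
#'
#' @param network output of [generate_network()].
#' @param config the same [scenario_config()].
#' @return Numeric vector of salinities (dS/m) at census index 0.
#' @export
salinity_field <- function(network, config) {
  restore <- .Random.seed_guard(config$seed + 1L)
  on.exit(restore(), add = TRUE)
  sr <- config$salinity_range
  grad <- sr[1] + (sr[2] - sr[1]) * network$x / config$extent[1]
  grad + .correlated_noise(network$x, network$y, config$noise_sd,
                           config$noise_range)
}

#' Simulate censuses over a synthetic network
#'
#' Draws species counts for every plot and census year from the niche model
#' described in [scenario_config()]. Fully deterministic under
#' (seed, config); different seeds decorrelate counts.
#'
#' @param network output of [generate_network()] (or any metadata
#'   data.frame with `plot_id`, `zone`, `x`, `y`, `area_ha`).
#' @param config a [scenario_config()].
#' @return A validated [census_table] (zero-count records are omitted;
#'   absences are implicit).
#' @export
simulate_censuses <- function(network, config) {
  stopifnot(inherits(config, "scenario_config"))
  s0 <- salinity_field(network, config)
  restore <- .Random.seed_guard(config$seed + 2L)
  on.exit(restore(), add = TRUE)
  sp <- config$species
  rows <- vector("list", length(config$years))
  for (t in seq_along(config$years)) {
    ci <- t - 1L
    s <- s0 + config$salinization_rate * ci
    lam <- outer(s, sp$mu, function(si, mu) si - mu)
    lam <- exp(-(lam^2) / (2 * matrix(sp$sigma^2, nrow = length(s),
                                      ncol = nrow(sp), byrow = TRUE)))
    lam <- lam * matrix(sp$A * exp(sp$r * ci), nrow = length(s),
                        ncol = nrow(sp), byrow = TRUE)
    if (is.null(config$fixed_total)) {
      cnt <- matrix(stats::rpois(length(lam), lam), nrow = nrow(lam))
    } else {
      cnt <- t(apply(lam, 1L, function(l) {
        as.vector(stats::rmultinom(1L, config$fixed_total, prob = l / sum(l)))
      }))
    }
    nz <- which(cnt > 0, arr.ind = TRUE)
    rows[[t]] <- data.frame(
      plot_id = network$plot_id[nz[, 1]],
      zone = network$zone[nz[, 1]],
      year = config$years[t],
      species = sp$name[nz[, 2]],
      count = cnt[nz])
  }
  census_table(do.call(rbind, rows), network)
}

#' Preset scenarios with a controllable homogenization signal
#'
#' Maps a single strength in `[0, 1]` to the three drivers of biotic
#' homogenization the generator models: salinization (rising salinity
#' pushes every plot toward halophyte dominance), invasive expansion
#' (positive abundance trend for the invasive halophyte) and specialist
#' decline (negative trend for low-salinity specialists). Strength 0 is a
#' stationary community; strength 1 uses salinization 0.2 dS/m per census and
#' per-census log-abundance trends of +1.0 for the invasive and -0.9 for
#' the low-salinity specialists (facultative species decline at half the
#' specialist rate).
#'
#' @param strength homogenization strength in `[0, 1]`.
#' @param seed RNG seed for the resulting config.
#' @param ... further arguments passed to [scenario_config()].
#' @return A [scenario_config()].
#' @export
homogenization_scenario <- function(strength = 1, seed = 1L, ...) {
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  sp <- default_species_pool()
  sp$r[sp$guild == "invasive"] <- 1.0 * strength
  sp$r[sp$guild == "specialist_hyposaline"] <- -0.9 * strength
  sp$r[sp$guild == "facultative"] <- -0.45 * strength
  scenario_config(species = sp, salinization_rate = 0.2 * strength,
                  seed = seed, ...)
}

#' Simulate a full scenario in one call
#'
#' @param config a [scenario_config()].
#' @return A [census_table].
#' @export
simulate_scenario <- function(config) {
  simulate_censuses(generate_network(config), config)
}
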