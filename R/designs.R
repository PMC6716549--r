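#' Specify a metacommunity/subcommunity partitioning design
#'
#' Four designs cover the spatial and temporal questions a plot-network
#' census can answer:
#' \describe{
#'   \item{`spatial_zone`}{MC = one ecological zone at one census year, SCs =
#'     its plots. Zones with more than `n_per_zone` plots are randomly
#'     subsampled to `n_per_zone` (without replacement), once per iteration.}
#'   \item{`spatial_ecosystem`}{MC = the whole network at one census year,
#'     SCs = `n_per_zone` plots drawn from each zone per iteration, giving a
#'     balanced ecosystem metacommunity.}
#'   \item{`temporal_psp`}{one realization per plot: MC = the plot pooled
#'     over all census years, SCs = the plot at each year.}
#'   \item{`temporal_zone`}{one realization per zone: MC = the zone pooled
#'     over all census years, SCs = the pooled zone composition at each
#'     year.}
#' }
#' Subsampling balances the uneven plot allocation across zones (e.g. a
#' 50/30/30 network analysed at 30 plots per zone over 100 iterations).
#'
#' @param kind one of `"spatial_zone"`, `"spatial_ecosystem"`,
#'   `"temporal_psp"`, `"temporal_zone"`.
#' @param census_year census year (spatial kinds only).
#' @param zone zone name or `"all"` (spatial_zone / temporal_psp restriction).
#' @param n_per_zone plots drawn per zone for the spatial kinds (default 30).
#' @param iterations number of subsampling repeats (default 100). Forced to 1
#'   when no zone needs subsampling.
#' @param seed RNG seed for reproducible draws.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(kind = c("spatial_zone", "spatial_ecosystem",
                                 "temporal_psp", "temporal_zone"),
                        census_year = NULL, zone = "all",
                        n_per_zone = 30L, iterations = 100L, seed = 1L) {
  kind <- match.arg(kind)
  if (kind %in% c("spatial_zone", "spatial_ecosystem") && is.null(census_year)) {
    stop("spatial designs need a census_year")
  }
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(kind = kind, census_year = census_year, zone = zone,
                 n_per_zone = as.integer(n_per_zone),
                 iterations = as.integer(iterations), seed = as.integer(seed)),
            class = "design_spec")
}

#' Realize a partitioning design on a census table
#'
#' Builds the list of metacommunity realizations the design calls for. Draws
#' are seeded, without replacement within a zone, and independent across
#' iterations; the same seed reproduces the same plot draws.
#'
#' @param table a [census_table].
#' @param spec a [design_spec].
#' @return List of realizations; each has elements `metacommunity`,
#'   `groups` (data.frame mapping each subcommunity to its zone and year)
#'   and `iteration`.
#' @export
build_design <- function(table, spec) {
  stopifnot(inherits(table, "census_table"), inherits(spec, "design_spec"))
  meta <- table$metadata
  zones_used <- if (identical(spec$zone, "all")) {
    intersect(ZONES, unique(meta$zone))
  } else spec$zone
  plots_by_zone <- lapply(zones_used, function(z) meta$plot_id[meta$zone == z])
  names(plots_by_zone) <- zones_used

  if (spec$kind %in% c("spatial_zone", "spatial_ecosystem")) {
    if (!spec$census_year %in% table$years) {
      stop("census_year ", spec$census_year, " not present in table")
    }
    need_sub <- vapply(plots_by_zone, function(p) length(p) > spec$n_per_zone,
                       logical(1))
    short <- vapply(plots_by_zone, function(p) length(p) < spec$n_per_zone,
                    logical(1))
    if (spec$kind == "spatial_ecosystem" && any(short)) {
      stop("zone(s) with fewer than n_per_zone plots: ",
           paste(names(plots_by_zone)[short], collapse = ", "))
    }
    iters <- if (any(need_sub)) spec$iterations else 1L
    old <- .Random.seed_guard(spec$seed)
    on.exit(old(), add = TRUE)
    out <- lapply(seq_len(iters), function(i) {
      drawn <- lapply(names(plots_by_zone), function(z) {
        p <- plots_by_zone[[z]]
        if (length(p) > spec$n_per_zone) sort(sample(p, spec$n_per_zone)) else p
      })
      names(drawn) <- names(plots_by_zone)
      ids <- unlist(drawn, use.names = FALSE)
      m <- abundance_by_plot(table, spec$census_year, plots = ids)
      gz <- meta$zone[match(colnames(m), meta$plot_id)]
      list(metacommunity = metacommunity(m),
           groups = data.frame(subcommunity = colnames(m), group = gz,
                               year = spec$census_year),
           iteration = i)
    })
    return(out)
  }

  if (spec$kind == "temporal_psp") {
    ids <- unlist(plots_by_zone, use.names = FALSE)
    out <- lapply(ids, function(pid) {
      m <- abundance_by_year(table, plots = pid)
      miss <- union(setdiff(as.character(table$years), colnames(m)),
                    colnames(m)[colSums(m) == 0])
      if (length(miss) > 0L) {
        stop("plot ", pid, " has no trees in census(es): ",
             paste(miss, collapse = ", "))
      }
      z <- meta$zone[match(pid, meta$plot_id)]
      list(metacommunity = metacommunity(m),
           groups = data.frame(subcommunity = colnames(m), group = z,
                               year = as.integer(colnames(m)), unit = pid),
           iteration = 1L)
    })
    return(out)
  }

  # temporal_zone
  out <- lapply(zones_used, function(z) {
    m <- abundance_by_year(table, zone = z)
    miss <- union(setdiff(as.character(table$years), colnames(m)),
                  colnames(m)[colSums(m) == 0])
    if (length(miss) > 0L) {
      stop("zone ", z, " has no trees in census(es): ",
           paste(miss, collapse = ", "))
    }
    list(metacommunity = metacommunity(m),
         groups = data.frame(subcommunity = colnames(m), group = z,
                             year = as.integer(colnames(m)), unit = z),
         iteration = 1L)
  })
  out
}

# Seed the RNG restorably: returns a function restoring the previous state.
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
  }
}

#' Run the diversity measures over design realizations
#'
#' Evaluates normalized alpha, rho-bar, subcommunity gamma and metacommunity
#' gamma at every q in `q_list` for every realization.
#'
#' @param realizations output of [build_design()].
#' @param q_list viewpoint parameters (default 0, 1, 2).
#' @return Tidy data.frame: `iteration`, `measure`, `q`, `subcommunity`,
#'   `group`, `year`, `weight`, `value`. The subcommunity weight `w[j]` is
#'   carried along so summaries can use power-mean-consistent averaging.
#' @export
run_design <- function(realizations, q_list = c(0, 1, 2)) {
  if (length(realizations) == 0L) stop("no realizations to run")
  res <- lapply(realizations, function(r) {
    mc <- r$metacommunity
    prof <- diversity_profile(mc, q_list)
    sub <- prof[prof$measure != "gamma_meta", ]
    gi <- match(sub$subcommunity, r$groups$subcommunity)
    sub$group <- r$groups$group[gi]
    sub$year <- if ("year" %in% names(r$groups)) r$groups$year[gi] else NA
    sub$weight <- mc$w[match(sub$subcommunity, mc$subcommunities)]
    meta_rows <- prof[prof$measure == "gamma_meta", ]
    meta_rows$group <- "metacommunity"
    meta_rows$year <- NA
    meta_rows$weight <- 1
    out <- rbind(sub, meta_rows)
    out$iteration <- r$iteration
    out
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[, c("iteration", "measure", "q", "subcommunity", "group", "year",
          "weight", "value")]
}

#' Summarize design results with confidence intervals
#'
#' For each (measure, q) cell within each group, the point estimate is the
#' weighted power mean of order `1 - q` over subcommunities (the aggregation
#' consistent with the diversity framework), computed per iteration and then
#' averaged arithmetically across iterations. The 95% interval is a seeded
#' percentile bootstrap (default B = 1000) that resamples subcommunity
#' values (pooled over iterations, with their weights), spanning both
#' subcommunity and iteration variability. A normal-approximation interval
#' is available via `ci = "normal"`.
#'
#' @param results tidy output of [run_design()].
#' @param group_by column to group on (default `"group"`, the zone label).
#' @param B bootstrap replicates.
#' @param ci `"bootstrap"` (percentile) or `"normal"`.
#' @param seed RNG seed for the bootstrap.
#' @param rule aggregation rule passed to [metacommunity_average()].
#' @return data.frame with columns `measure`, `q`, group column, `mean`,
#'   `ci_low`, `ci_high`, `n_sub` (values pooled), plus a `degenerate` flag
#'   for single-subcommunity groups (interval collapses to the estimate).
#' @export
summarize_design <- function(results, group_by = "group", B = 1000L,
                             ci = c("bootstrap", "normal"), seed = 1L,
                             rule = "power_mean") {
  ci <- match.arg(ci)
  if (nrow(results) == 0L) stop("no results to summarize")
  results <- results[results$measure != "gamma_meta", ]
  keys <- unique(results[, c("measure", "q", group_by)])
  restore <- .Random.seed_guard(seed)
  on.exit(restore(), add = TRUE)
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- results$measure == keys$measure[k] & results$q == keys$q[k] &
      results[[group_by]] == keys[[group_by]][k]
    d <- results[sel, ]
    q <- keys$q[k]
    per_iter <- vapply(split(d, d$iteration), function(di) {
      metacommunity_average(di$value, di$weight, q, rule = rule)
    }, numeric(1))
    est <- mean(per_iter)
    n_u <- length(unique(d$subcommunity))
    if (n_u < 2L) {
      lo <- hi <- est
      degen <- TRUE
    } else {
      degen <- FALSE
      if (ci == "bootstrap") {
        n <- nrow(d)
        stat <- vapply(seq_len(B), function(b) {
          i <- sample.int(n, n, replace = TRUE)
          metacommunity_average(d$value[i], d$weight[i], q, rule = rule)
        }, numeric(1))
        qs <- stats::quantile(stat, c(0.025, 0.975), names = FALSE, type = 7)
        lo <- qs[1]; hi <- qs[2]
      } else {
        se <- stats::sd(d$value) / sqrt(nrow(d))
        lo <- est - 1.96 * se; hi <- est + 1.96 * se
      }
      # the point estimate is a different statistic than the bootstrap mean;
      # clamp so the interval always brackets it
      lo <- min(lo, est); hi <- max(hi, est)
    }
    out <- data.frame(measure = keys$measure[k], q = q, g = keys[[group_by]][k],
                      mean = est, ci_low = lo, ci_high = hi,
                      n_sub = n_u, degenerate = degen)
    names(out)[3] <- group_by
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Temporal representativeness of plots or zones
#'
#' For each unit (plot or pooled zone), the metacommunity is its composition
#' pooled over all census years and each year is a subcommunity; rho-bar per
#' year measures how representative that year's composition is of the
#' pooled whole. Low values mark high temporal turnover.
#'
#' @param table a [census_table]; every unit must be censused in every year.
#' @param level `"psp"` (per plot) or `"zone"` (plots pooled per zone).
#' @param q_list viewpoint parameters.
#' @return data.frame: `unit`, `zone`, `year`, `q`, `weight`, `rho_bar`.
#' @export
temporal_representativeness <- function(table, level = c("psp", "zone"),
                                        q_list = c(0, 1, 2)) {
  level <- match.arg(level)
  spec <- design_spec(if (level == "psp") "temporal_psp" else "temporal_zone")
  reals <- build_design(table, spec)
  rows <- lapply(reals, function(r) {
    mc <- r$metacommunity
    do.call(rbind, lapply(q_list, function(q) {
      rb <- subcommunity_rho_bar(mc, q)
      data.frame(unit = r$groups$unit[1], zone = r$groups$group[1],
                 year = as.integer(names(rb$values)), q = q,
                 weight = unname(mc$w), rho_bar = unname(rb$values))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
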