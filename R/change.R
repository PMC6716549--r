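#' Percentage contribution of each species to a zone's composition
#'
#' Divides each species' count by the total count, times 100. Computed from
#' unrounded ratios; rounding belongs to presentation only.
#'
#' @param counts named non-negative vector of species counts.
#' @return Named vector of percentages summing to 100.
#' @export
percent_contribution <- function(counts) {
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative")
  }
  tot <- sum(counts)
  if (tot <= 0) stop("degenerate input: zero total count")
  100 * counts / tot
}

#' Percentage composition change (%CC) between two censuses
#'
#' For each species, the difference of its percentage contributions at the
#' two times, standardized by their sum:
#' `cc = 100 * (contrib_end - contrib_start) / (contrib_end + contrib_start)`.
#' The index runs from -100 (present then absent: local extinction) to +100
#' (absent then present: introduction) and is invariant to overall abundance
#' change between the dates, since it depends only on contributions. Species
#' absent at both times have no defined change; they are flagged and, by
#' default, excluded (reporting 0 would fabricate stability).
#'
#' @param start,end named species-to-count vectors (zone totals at the two
#'   census years). Species missing from one vector are treated as count 0.
#' @param keep_undefined keep rows for species absent at both times
#'   (`cc = NA`)? Default `FALSE`.
#' @return data.frame: `species`, `count_start`, `count_end`,
#'   `contrib_start`, `contrib_end`, `cc`.
#' @export
percent_composition_change <- function(start, end, keep_undefined = FALSE) {
  spp <- union(names(start), names(end))
  if (is.null(spp)) stop("start and end must be named by species")
  s <- ifelse(is.na(start[spp]), 0, start[spp])
  e <- ifelse(is.na(end[spp]), 0, end[spp])
  cs <- percent_contribution(s)
  ce <- percent_contribution(e)
  denom <- cs + ce
  cc <- ifelse(denom > 0, 100 * (ce - cs) / denom, NA_real_)
  out <- data.frame(species = spp, count_start = unname(s),
                    count_end = unname(e), contrib_start = unname(cs),
                    contrib_end = unname(ce), cc = unname(cc))
  if (!keep_undefined) out <- out[!is.na(out$cc), ]
  rownames(out) <- NULL
  out
}

#' Occupancy-based range-change index between two censuses
#'
#' For each species, the change in the number of occupied plots,
#' standardized by the total plots at which the species was present at
#' either time: `index = (n_end - n_start) / |occupied_start U occupied_end|`.
#' The index lies in `[-1, 1]`: +1 for introduction (newly arrived in the
#' zone), -1 for local extinction, 0 when the species occupies exactly the
#' same plots at both times (stable range).
#'
#' The standardizing count is read as the union of the two occupied plot
#' sets; an intersection reading is impossible (it breaks the +/-1
#' endpoints for introductions and extinctions). The alternative reading —
#' the sum of the two occupancy counts — also honours the endpoints and is
#' available via `denom = "sum"` (it halves the index for disjoint sets).
#'
#' @param occupancy_start,occupancy_end named lists: species -> character
#'   vector of occupied plot ids.
#' @param denom `"union"` (default) or `"sum"`.
#' @param keep_undefined keep species with empty occupancy at both times
#'   (`index = NA`)? Default `FALSE`.
#' @return data.frame: `species`, `n_start`, `n_end`, `denom`, `index`.
#' @export
range_change_index <- function(occupancy_start, occupancy_end,
                               denom = c("union", "sum"),
                               keep_undefined = FALSE) {
  denom <- match.arg(denom)
  spp <- union(names(occupancy_start), names(occupancy_end))
  rows <- lapply(spp, function(sp) {
    a <- unique(occupancy_start[[sp]])
    b <- unique(occupancy_end[[sp]])
    na <- length(a); nb <- length(b)
    d <- if (denom == "union") length(union(a, b)) else na + nb
    idx <- if (d > 0) (nb - na) / d else NA_real_
    data.frame(species = sp, n_start = na, n_end = nb, denom = d, index = idx)
  })
  out <- do.call(rbind, rows)
  if (!keep_undefined) out <- out[!is.na(out$index), ]
  rownames(out) <- NULL
  out
}

#' Zone-wise abundance, composition-change and range-change report
#'
#' Builds, for each ecological zone, the species-level change report between
#' two census years: counts, percentage contributions, %CC, and — where the
#' table has plot-level resolution (more than one plot per zone) — the
#' occupancy-based range-change index. Layout mirrors the published
#' zone-wise abundance-change table.
#'
#' @param table a [census_table].
#' @param year_start,year_end census years (defaults 1986 and 2014).
#' @param denom passed to [range_change_index()].
#' @return data.frame: `species`, `zone`, `count_start`, `contrib_start`,
#'   `count_end`, `contrib_end`, `cc_percent`, `range_index` (NA when the
#'   zone has no plot-level resolution). Contributions and %CC are
#'   unrounded; round at presentation.
#' @export
abundance_change_table <- function(table, year_start = 1986L,
                                   year_end = 2014L, denom = "union") {
  stopifnot(inherits(table, "census_table"))
  if (!all(c(year_start, year_end) %in% table$years)) {
    stop("both census years must be present in the table")
  }
  meta <- table$metadata
  zones <- intersect(ZONES, unique(meta$zone))
  rows <- lapply(zones, function(z) {
    plots <- meta$plot_id[meta$zone == z]
    rec <- table$records[table$records$plot_id %in% plots, ]
    zc <- function(y) {
      r <- rec[rec$year == y, ]
      tapply(r$count, r$species, sum)
    }
    s <- zc(year_start); e <- zc(year_end)
    cc <- percent_composition_change(s, e, keep_undefined = FALSE)
    ri <- rep(NA_real_, nrow(cc))
    if (length(plots) > 1L) {
      occ <- function(y) {
        r <- rec[rec$year == y & rec$count > 0, ]
        split(r$plot_id, r$species)
      }
      rci <- range_change_index(occ(year_start), occ(year_end), denom = denom)
      ri <- rci$index[match(cc$species, rci$species)]
    }
    data.frame(species = cc$species, zone = z,
               count_start = cc$count_start, contrib_start = cc$contrib_start,
               count_end = cc$count_end, contrib_end = cc$contrib_end,
               cc_percent = cc$cc, range_index = ri)
  })
  out <- do.call(rbind, rows)
  # sort within zone by descending starting abundance, as change tables are
  # conventionally presented
  out <- out[order(match(out$zone, ZONES), -out$count_start, out$species), ]
  rownames(out) <- NULL
  out
}
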