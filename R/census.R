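ZONES <- c("hyposaline", "mesosaline", "hypersaline")

#' Construct a validated census table
#'
#' A census table is the package's central data container: a long-format
#' record set with one row per (plot, census year, species) holding an
#' integer tree tally, plus per-plot metadata (ecological zone, planar
#' coordinates in meters, plot area in hectares).
#'
#' Explicit absences (count 0) are allowed and are equivalent to a missing
#' row; both normalize to the same abundance matrix. Species names are
#' trimmed of surrounding whitespace and matched case-sensitively; no fuzzy
#' matching is attempted, since a silent merge of two taxa is worse than a
#' hard error.
#'
#' @param records data.frame with columns `plot_id`, `zone`, `year`,
#'   `species`, `count`.
#' @param metadata data.frame with columns `plot_id`, `zone`, `x`, `y`,
#'   `area_ha`. Coordinates may be all-`NA` (a network without surveyed
#'   positions); partial `NA` coordinates are rejected.
#' @return An object of class `census_table` with elements `records`,
#'   `metadata` and `years` (sorted ascending).
#' @export
census_table <- function(records, metadata) {
  req <- c("plot_id", "zone", "year", "species", "count")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L) {
    stop("census records are missing column(s): ", paste(miss, collapse = ", "))
  }
  reqm <- c("plot_id", "zone", "x", "y", "area_ha")
  missm <- setdiff(reqm, names(metadata))
  if (length(missm) > 0L) {
    stop("plot metadata is missing column(s): ", paste(missm, collapse = ", "))
  }
  records <- as.data.frame(records)[, req]
  metadata <- as.data.frame(metadata)[, reqm]
  records$plot_id <- as.character(records$plot_id)
  records$zone <- as.character(records$zone)
  records$species <- trimws(as.character(records$species))
  metadata$plot_id <- as.character(metadata$plot_id)
  metadata$zone <- as.character(metadata$zone)

  bad_zone <- setdiff(unique(c(records$zone, metadata$zone)), ZONES)
  if (length(bad_zone) > 0L) {
    stop("unknown ecological zone(s): ", paste(bad_zone, collapse = ", "),
         " (expected ", paste(ZONES, collapse = ", "), ")")
  }
  cnt <- records$count
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad) > 0L) {
    stop("count must be a non-negative integer; offending record row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  records$count <- as.integer(round(cnt))
  yr <- records$year
  if (anyNA(yr) || any(yr != round(yr))) stop("year must be an integer census year")
  records$year <- as.integer(yr)

  if (anyDuplicated(metadata$plot_id) > 0L) {
    stop("duplicated plot_id in metadata: ",
         paste(unique(metadata$plot_id[duplicated(metadata$plot_id)]), collapse = ", "))
  }
  orphan <- setdiff(unique(records$plot_id), metadata$plot_id)
  if (length(orphan) > 0L) {
    stop("plot(s) present in census but absent from metadata: ",
         paste(utils::head(orphan, 5L), collapse = ", "))
  }
  key <- paste(records$plot_id, records$year, records$species, sep = "\r")
  if (anyDuplicated(key) > 0L) {
    stop("duplicate (plot_id, year, species) record(s), e.g. ",
         gsub("\r", " / ", key[duplicated(key)][1L]))
  }
  # zone must be constant per plot and agree with metadata
  mz <- metadata$zone[match(records$plot_id, metadata$plot_id)]
  if (any(records$zone != mz)) {
    stop("zone in census records disagrees with metadata for plot(s): ",
         paste(unique(records$plot_id[records$zone != mz]), collapse = ", "))
  }
  xy_na <- is.na(metadata$x) | is.na(metadata$y)
  if (any(xy_na) && !all(xy_na)) {
    stop("plot coordinates must be all present or all absent")
  }
  if (!all(xy_na) && any(!is.finite(metadata$x) | !is.finite(metadata$y))) {
    stop("plot coordinates must be finite")
  }
  if (any(!is.finite(metadata$area_ha) | metadata$area_ha <= 0)) {
    stop("plot area_ha must be positive and finite")
  }

  structure(
    list(records = records, metadata = metadata,
         years = sort(unique(records$year))),
    class = "census_table")
}

#' @export
print.census_table <- function(x, ...) {
  cat("Census table:", nrow(x$metadata), "plots,",
      length(unique(x$records$species)), "species,",
      "censuses", paste(x$years, collapse = ", "), "\n")
  cat("  records:", nrow(x$records), " total trees:", sum(x$records$count), "\n")
  zn <- table(factor(x$metadata$zone, levels = ZONES))
  cat("  plots by zone:", paste(sprintf("%s=%d", names(zn), zn), collapse = ", "), "\n")
  if (all(is.na(x$metadata$x))) cat("  (no plot coordinates)\n")
  invisible(x)
}

#' @export
summary.census_table <- function(object, ...) {
  agg <- stats::aggregate(count ~ zone + year, data = object$records, sum)
  agg <- agg[order(agg$year, match(agg$zone, ZONES)), ]
  rownames(agg) <- NULL
  agg
}

#' Read a census table and its plot metadata from CSV
#'
#' Expects the long census schema `plot_id,zone,year,species,count` and the
#' metadata schema `plot_id,zone,x,y,area_ha`, both with headers. Rows with
#' count 0 are retained as explicit absences.
#'
#' @param path path to the census CSV.
#' @param metadata_path path to the plot metadata CSV.
#' @return A validated [census_table].
#' @export
read_census <- function(path, metadata_path) {
  if (!file.exists(path)) stop("census file not found: ", path)
  if (!file.exists(metadata_path)) stop("metadata file not found: ", metadata_path)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- utils::read.csv(metadata_path, stringsAsFactors = FALSE)
  census_table(rec, meta)
}

#' Write a census table and its metadata to CSV
#'
#' Output is deterministic: records are sorted by (year, zone, plot, species)
#' and metadata by plot id, so repeated writes of the same table are
#' byte-identical. `read_census(write_census(t))` reproduces `t`
#' record-for-record.
#'
#' @param table a [census_table].
#' @param path census CSV output path.
#' @param metadata_path metadata CSV output path.
#' @return Invisibly, the paths written.
#' @export
write_census <- function(table, path, metadata_path) {
  stopifnot(inherits(table, "census_table"))
  rec <- table$records
  rec <- rec[order(rec$year, match(rec$zone, ZONES), rec$plot_id, rec$species), ]
  meta <- table$metadata[order(table$metadata$plot_id), ]
  utils::write.csv(rec, path, row.names = FALSE, quote = FALSE)
  utils::write.csv(meta, metadata_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, metadata_path))
}

#' Zone-level 1986/2014 Sundarbans abundance fixture
#'
#' The published zone-wise species abundance table for the Sundarbans
#' permanent-sample-plot network (total tree counts per species in the
#' hyposaline, mesosaline and hypersaline zones, censuses 1986 and 2014),
#' packaged as a pseudo census table with one "plot" per ecological zone.
#' Dashes in the published table (species never recorded in a zone) are
#' encoded as explicit zero counts, matching how the source treats newly
#' arrived species (a +100% composition change from a zero baseline).
#'
#' Data note: in the published table the hyposaline-2014 per-species counts
#' sum to 18534 while its totals row prints 18533 — an internal off-by-one
#' of the source. This package treats the per-species cells as authoritative
#' and derives totals from them.
#'
#' No plot coordinates were ever published for the network, so the fixture
#' carries none; spatial interpolation is only possible on synthetic or
#' user-supplied networks.
#'
#' @return A [census_table] with 3 zone-level pseudo-plots, years 1986 and
#'   2014, and 25 species.
#' @export
table1_fixture <- function() {
  read_census(
    system.file("extdata", "sundarbans_zone_counts_1986_2014.csv",
                package = "mangrovediv", mustWork = TRUE),
    system.file("extdata", "sundarbans_zone_metadata.csv",
                package = "mangrovediv", mustWork = TRUE))
}

#' Aggregate a census table into a species-by-subcommunity count matrix
#'
#' The grouping specification selects (plot, year) cells and maps each to a
#' subcommunity label; counts are summed within each label. Species with a
#' zero total across all selected subcommunities are dropped. Column order
#' follows the order in which labels first appear in the grouping spec.
#'
#' @param table a [census_table].
#' @param groups data.frame with columns `plot_id`, `year`, `subcommunity`;
#'   each row selects one (plot, year) cell.
#' @return Integer matrix (species x subcommunities) with dimnames.
#' @seealso [abundance_by_zone()], [abundance_by_plot()],
#'   [abundance_by_year()] for the common groupings.
#' @export
to_abundance_matrix <- function(table, groups) {
  stopifnot(inherits(table, "census_table"))
  if (!all(c("plot_id", "year", "subcommunity") %in% names(groups))) {
    stop("groups must have columns plot_id, year, subcommunity")
  }
  if (nrow(groups) == 0L) stop("grouping spec selects nothing")
  rec <- table$records
  sel_key <- paste(groups$plot_id, groups$year, sep = "\r")
  rec_key <- paste(rec$plot_id, rec$year, sep = "\r")
  idx <- match(rec_key, sel_key)
  rec <- rec[!is.na(idx), ]
  if (nrow(rec) == 0L) stop("grouping spec selects nothing")
  lab <- as.character(groups$subcommunity)[idx[!is.na(idx)]]
  labs <- unique(as.character(groups$subcommunity))
  spp <- sort(unique(rec$species))
  m <- matrix(0L, nrow = length(spp), ncol = length(labs),
              dimnames = list(spp, labs))
  tt <- tapply(rec$count, list(factor(rec$species, levels = spp),
                               factor(lab, levels = labs)), sum)
  tt[is.na(tt)] <- 0L
  m[] <- as.integer(tt)
  m <- m[rowSums(m) > 0L, , drop = FALSE]
  m
}

#' Common abundance-matrix groupings
#'
#' Convenience wrappers around [to_abundance_matrix()]: zone-level columns at
#' one census year, plot-level columns at one census year, or year-level
#' columns for one plot or one pooled zone (the temporal designs).
#'
#' @param table a [census_table].
#' @param year a census year present in the table.
#' @param plots optional character vector restricting the plots used.
#' @name abundance_groupings
NULL

#' @rdname abundance_groupings
#' @export
abundance_by_zone <- function(table, year, plots = NULL) {
  meta <- table$metadata
  if (!is.null(plots)) meta <- meta[meta$plot_id %in% plots, ]
  g <- data.frame(plot_id = meta$plot_id, year = year,
                  subcommunity = factor(meta$zone, levels = ZONES))
  g <- g[order(g$subcommunity), ]
  g$subcommunity <- as.character(g$subcommunity)
  to_abundance_matrix(table, g)
}

#' @rdname abundance_groupings
#' @export
abundance_by_plot <- function(table, year, plots = NULL) {
  ids <- if (is.null(plots)) table$metadata$plot_id else plots
  to_abundance_matrix(table, data.frame(plot_id = ids, year = year,
                                        subcommunity = ids))
}

#' @param zone optional zone name; with `zone` set, each column pools all of
#'   that zone's plots at one census year.
#' @param years census years to use as columns (default: all in the table).
#' @rdname abundance_groupings
#' @export
abundance_by_year <- function(table, plots = NULL, zone = NULL,
                              years = table$years) {
  if (!is.null(zone)) {
    plots <- table$metadata$plot_id[table$metadata$zone == zone]
  }
  if (is.null(plots)) plots <- table$metadata$plot_id
  g <- do.call(rbind, lapply(years, function(y) {
    data.frame(plot_id = plots, year = y, subcommunity = as.character(y))
  }))
  to_abundance_matrix(table, g)
}
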