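#' Empirical semivariogram (Matheron method-of-moments)
#'
#' Bins all point pairs by separation distance and estimates the
#' semivariance per bin as `gamma_hat(h) = sum (z_i - z_j)^2 / (2 N(h))`.
#' Default binning: `n_bins` equal-width bins up to half the maximum
#' pairwise distance (the conventional cutoff beyond which pairs are scarce
#' and the estimate unstable). Empty bins are dropped.
#'
#' @param x,y point coordinates (planar meters).
#' @param z values at the points.
#' @param n_bins number of lag bins (default 12).
#' @param max_lag maximum lag; default half the maximum pairwise distance.
#' @return Object of class `empirical_semivariogram`: data.frame with
#'   columns `lag` (bin center), `gamma` (estimate), `n_pairs`.
#' @export
empirical_semivariogram <- function(x, y, z, n_bins = 12L, max_lag = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(z) == n)
  if (n < 2L) stop("need at least 2 points")
  d <- as.vector(stats::dist(cbind(x, y)))
  if (max(d) <= 0) stop("degenerate geometry: all points coincident")
  if (is.null(max_lag)) max_lag <- max(d) / 2
  if (max_lag <= 0) stop("max_lag must be positive")
  g <- as.vector(stats::dist(matrix(z, ncol = 1)))^2 / 2
  keep <- d <= max_lag & d > 0
  d <- d[keep]; g <- g[keep]
  if (length(d) == 0L) stop("no point pairs within max_lag")
  br <- seq(0, max_lag, length.out = n_bins + 1L)
  bin <- cut(d, br, include.lowest = TRUE, labels = FALSE)
  gamma_hat <- tapply(g, bin, mean)
  n_pairs <- tapply(g, bin, length)
  centers <- (br[-1] + br[-length(br)]) / 2
  out <- data.frame(lag = centers[as.integer(names(gamma_hat))],
                    gamma = as.vector(gamma_hat),
                    n_pairs = as.integer(n_pairs))
  rownames(out) <- NULL
  structure(out, class = c("empirical_semivariogram", "data.frame"))
}

#' Theoretical semivariogram models
#'
#' Evaluates a fitted or hand-built model at lags `h`. Families:
#' \describe{
#'   \item{spherical}{`c0 + c * (1.5 h/a - 0.5 (h/a)^3)` for `h <= a`, sill
#'     `c0 + c` beyond; the only family attaining its sill exactly at `h = a`.}
#'   \item{exponential}{`c0 + c * (1 - exp(-h/a))`; effective range `3a`.}
#'   \item{gaussian}{`c0 + c * (1 - exp(-(h/a)^2))`; effective range
#'     `sqrt(3) a`.}
#' }
#' `a` is the distance parameter, not the effective range; the effective
#' ranges above are recorded in fit output because conventions differ across
#' geostatistics tools. All families have `gamma(0) = 0` (the nugget is a
#' limit from the right, the standard geostatistical convention).
#'
#' @param h non-negative lags.
#' @param model list or `semivariogram_model` with `family`, `c0` (nugget
#'   `>= 0`), `c` (partial sill `> 0`), `a` (range parameter `> 0`).
#' @return Semivariance at each lag.
#' @export
semivariogram <- function(h, model) {
  c0 <- model$c0; cc <- model$c; a <- model$a
  stopifnot(c0 >= 0, cc > 0, a > 0, all(h >= 0))
  str_part <- switch(model$family,
    spherical = ifelse(h >= a, 1, 1.5 * (h / a) - 0.5 * (h / a)^3),
    exponential = 1 - exp(-h / a),
    gaussian = 1 - exp(-(h / a)^2),
    stop("unknown semivariogram family: ", model$family))
  out <- c0 + cc * str_part
  out[h == 0] <- 0
  out
}

#' Construct a semivariogram model
#'
#' @param family `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param c0 nugget (`>= 0`).
#' @param c partial sill (`> 0`).
#' @param a range parameter (`> 0`, coordinate units).
#' @return Object of class `semivariogram_model`.
#' @export
semivariogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                                c0, c, a) {
  family <- match.arg(family)
  stopifnot(c0 >= 0, c > 0, a > 0)
  structure(list(family = family, c0 = c0, c = c, a = a,
                 effective_range = switch(family, spherical = a,
                                          exponential = 3 * a,
                                          gaussian = sqrt(3) * a)),
            class = "semivariogram_model")
}

#' @export
print.semivariogram_model <- function(x, ...) {
  cat(sprintf("%s semivariogram: nugget %.4g, partial sill %.4g, range %.4g (effective %.4g)\n",
              x$family, x$c0, x$c, x$a, x$effective_range))
  invisible(x)
}

# SSE of one family against empirical bins for log-parameterized theta.
.sv_sse <- function(theta, emp, family, weighted) {
  m <- list(family = family, c0 = exp(theta[1]) - 1e-12, c = exp(theta[2]),
            a = exp(theta[3]))
  if (m$c0 < 0) m$c0 <- 0
  g <- semivariogram(emp$lag, m)
  w <- if (weighted) emp$n_pairs else rep(1, nrow(emp))
  sum(w * (g - emp$gamma)^2)
}

#' Fit semivariogram models and select by least SSE
#'
#' Least-squares fit of (nugget, partial sill, range) per candidate family
#' against the empirical bins, with multiple deterministic starts (range
#' starts spread over the lag span; nugget starts at 0 and at 25% of the
#' sample variance of the bin estimates). The family with the smallest sum
#' of squared errors wins; ties break in canonical order (spherical,
#' exponential, gaussian). SSE is unweighted across bins by default;
#' pair-count weighting is available.
#'
#' A fit with almost no resolvable spatial structure is flagged
#' (`pure_nugget_warning`): either the partial sill is negligible
#' (`c / (c0 + c) < 0.05`) or the fitted effective range falls below the
#' first bin lag (all structure sits inside the data's resolution, which is
#' how a flat empirical variogram gets fitted). The range is then poorly identified
#' and the selected family carries little information.
#'
#' @param emp an [empirical_semivariogram] (at least 3 retained bins).
#' @param families candidate families, in tie-break order.
#' @param weighted weight bin SSE by pair counts? Default `FALSE`.
#' @return Object of class `semivariogram_fit`: the selected
#'   [semivariogram_model()] plus `sse` (named per-family SSE vector),
#'   `fits` (per-family fitted models) and `pure_nugget_warning`.
#' @export
fit_semivariogram <- function(emp,
                              families = c("spherical", "exponential", "gaussian"),
                              weighted = FALSE) {
  stopifnot(inherits(emp, "empirical_semivariogram"))
  if (nrow(emp) < 3L) stop("need at least 3 semivariogram bins to fit")
  families <- match.arg(families, several.ok = TRUE)
  sill0 <- max(stats::var(emp$gamma), mean(emp$gamma), 1e-12)
  gmax <- max(emp$gamma)
  lagmax <- max(emp$lag)
  starts <- expand.grid(
    c0 = c(1e-10, 0.25 * gmax + 1e-10),
    c = c(0.5, 1) * max(gmax, 1e-10),
    a = c(0.25, 0.5, 1) * lagmax)
  fits <- lapply(families, function(fam) {
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      th0 <- log(c(starts$c0[i] + 1e-12, starts$c[i], starts$a[i]))
      opt <- try(stats::optim(th0, .sv_sse, emp = emp, family = fam,
                              weighted = weighted, method = "Nelder-Mead",
                              control = list(maxit = 2000, reltol = 1e-12)),
                 silent = TRUE)
      if (inherits(opt, "try-error")) next
      if (is.null(best) || opt$value < best$value) best <- opt
    }
    if (is.null(best)) stop("semivariogram fit failed for family ", fam)
    th <- best$par
    list(model = semivariogram_model(fam, max(exp(th[1]) - 1e-12, 0),
                                     exp(th[2]), exp(th[3])),
         sse = best$value)
  })
  names(fits) <- families
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  pick <- families[which.min(sse)]  # which.min takes the first on ties
  sel <- fits[[pick]]$model
  structure(c(unclass(sel),
              list(sse = sse,
                   fits = lapply(fits, `[[`, "model"),
                   pure_nugget_warning = sel$c / (sel$c0 + sel$c) < 0.05 ||
                     sel$effective_range < emp$lag[1])),
            class = c("semivariogram_fit", "semivariogram_model"))
}

#' @export
print.semivariogram_fit <- function(x, ...) {
  cat("Selected ")
  print.semivariogram_model(x)
  cat("  SSE by family:",
      paste(sprintf("%s=%.4g", names(x$sse), x$sse), collapse = ", "), "\n")
  if (isTRUE(x$pure_nugget_warning)) {
    cat("  warning: near-pure-nugget fit; range poorly identified\n")
  }
  invisible(x)
}

#' Regular prediction grid over a point set
#'
#' Axis-aligned bounding box of the points, padded by one cell on every
#' side, discretized at `cell_size` (default 25 m, i.e. 625 m2 cells).
#' Predictions are made at cell centers.
#'
#' @param x,y point coordinates.
#' @param cell_size cell edge length in coordinate units.
#' @return List with `origin` (lower-left corner), `cell_size`, `nx`, `ny`,
#'   and cell-center coordinate vectors `cx`, `cy`.
#' @export
grid_spec <- function(x, y, cell_size = 25) {
  stopifnot(cell_size > 0)
  x0 <- min(x) - cell_size; x1 <- max(x) + cell_size
  y0 <- min(y) - cell_size; y1 <- max(y) + cell_size
  nx <- max(1L, ceiling((x1 - x0) / cell_size))
  ny <- max(1L, ceiling((y1 - y0) / cell_size))
  list(origin = c(x0, y0), cell_size = cell_size, nx = nx, ny = ny,
       cx = x0 + (seq_len(nx) - 0.5) * cell_size,
       cy = y0 + (seq_len(ny) - 0.5) * cell_size)
}

# Average duplicate coordinates (exact ties) so the kriging system stays
# nonsingular. Returns deduplicated x, y, z and a flag.
.dedup_points <- function(x, y, z) {
  key <- paste(x, y, sep = "\r")
  if (anyDuplicated(key) == 0L) {
    return(list(x = x, y = y, z = z, deduplicated = FALSE))
  }
  zs <- tapply(z, key, mean)
  u <- !duplicated(key)
  ord <- match(key[u], names(zs))
  list(x = x[u], y = y[u], z = as.vector(zs)[ord], deduplicated = TRUE)
}

# Solve the ordinary-kriging system for prediction locations (px, py).
# Returns the predictions; weights for the last location are attached when
# keep_weights is TRUE (used by tests).
.ok_predict <- function(x, y, z, model, px, py, keep_weights = FALSE) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  A <- rbind(cbind(semivariogram(D, model), 1), c(rep(1, n), 0))
  # semivariogram() zeroes the diagonal (gamma(0) = 0) because D has a zero
  # diagonal, as the OK system requires
  Ainv <- solve(A)
  dx <- outer(x, px, "-"); dy <- outer(y, py, "-")
  B <- rbind(matrix(semivariogram(sqrt(dx^2 + dy^2), model), nrow = n), 1)
  L <- Ainv %*% B
  pred <- as.vector(crossprod(L[seq_len(n), , drop = FALSE], z))
  if (keep_weights) {
    attr(pred, "weights") <- L[seq_len(n), , drop = FALSE]
  }
  pred
}

#' Ordinary kriging onto a regular grid
#'
#' Solves the ordinary-kriging system (semivariogram form with a Lagrange
#' multiplier enforcing the unbiasedness constraint `sum(lambda) = 1`) at
#' every cell center of the grid. With a zero nugget the predictor
#' interpolates the data exactly. Points sharing identical coordinates are
#' averaged (with a warning) before solving, which keeps the system
#' nonsingular.
#'
#' @param x,y,z data coordinates and values (at least 2 non-coincident
#'   points).
#' @param model a [semivariogram_model()] or [fit_semivariogram()] result.
#' @param grid a [grid_spec()]; default builds one from the data at 25 m
#'   cells.
#' @return Object of class `kriged_surface`: the grid geometry plus a
#'   `ny x nx` matrix `values` (row i = y index, column j = x index) and the
#'   model used.
#' @export
ordinary_krige <- function(x, y, z, model, grid = grid_spec(x, y)) {
  stopifnot(inherits(model, "semivariogram_model"))
  dd <- .dedup_points(x, y, z)
  if (dd$deduplicated) warning("duplicate coordinates averaged before kriging")
  if (length(dd$x) < 2L) stop("need at least 2 non-coincident points")
  ctr <- expand.grid(px = grid$cx, py = grid$cy)
  pred <- .ok_predict(dd$x, dd$y, dd$z, model, ctr$px, ctr$py)
  vals <- matrix(pred, nrow = grid$ny, ncol = grid$nx, byrow = TRUE)
  structure(list(origin = grid$origin, cell_size = grid$cell_size,
                 nx = grid$nx, ny = grid$ny, cx = grid$cx, cy = grid$cy,
                 values = vals, model = model),
            class = "kriged_surface")
}

#' @export
print.kriged_surface <- function(x, ...) {
  cat(sprintf("Kriged surface: %d x %d cells of %g m (%g m2), values in [%.4g, %.4g]\n",
              x$nx, x$ny, x$cell_size, x$cell_size^2,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Leave-one-out cross-validation NRMSE of a kriging model
#'
#' Each point is withheld in turn and predicted by ordinary kriging from the
#' remaining points under the fixed (not refitted) semivariogram model; the
#' root-mean-square error of the held-out predictions is normalized by the
#' range of the observed values.
#'
#' @param x,y,z data coordinates and values (at least 3 points).
#' @param model a [semivariogram_model()].
#' @param refit refit the semivariogram per fold? Default `FALSE` (the model
#'   is held fixed; per-fold refitting costs n extra fits and rarely changes
#'   the picture at network sizes of ~100 plots).
#' @return Object of class `cv_report`: `predicted`, `observed`, `rmse`,
#'   `value_range`, `nrmse`.
#' @export
loo_nrmse <- function(x, y, z, model, refit = FALSE) {
  dd <- .dedup_points(x, y, z)
  x <- dd$x; y <- dd$y; z <- dd$z
  n <- length(x)
  if (n < 3L) stop("need at least 3 points for cross-validation")
  vr <- diff(range(z))
  if (vr <= 0) stop("undefined normalization: zero range of values")
  pred <- vapply(seq_len(n), function(i) {
    m <- model
    if (refit) {
      emp <- empirical_semivariogram(x[-i], y[-i], z[-i])
      m <- fit_semivariogram(emp, families = model$family)
    }
    .ok_predict(x[-i], y[-i], z[-i], m, x[i], y[i])
  }, numeric(1))
  rmse <- sqrt(mean((pred - z)^2))
  structure(list(predicted = pred, observed = z, rmse = rmse,
                 value_range = vr, nrmse = rmse / vr),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("Leave-one-out CV over %d points: RMSE %.4g, value range %.4g, NRMSE %.4g\n",
              length(x$observed), x$rmse, x$value_range, x$nrmse))
  invisible(x)
}

#' Fraction of grid cells changed in a given direction
#'
#' Compares two kriged surfaces on the same grid and returns the proportion
#' of cells where the value changed in the requested direction by more than
#' `epsilon` (default 0, i.e. any change counts).
#'
#' @param surface_a,surface_b `kriged_surface` objects on identical grids.
#' @param direction `"increase"` or `"decrease"`.
#' @param epsilon minimum absolute change to count (default 0).
#' @return Proportion in `[0, 1]`.
#' @export
change_fraction <- function(surface_a, surface_b,
                            direction = c("increase", "decrease"),
                            epsilon = 0) {
  direction <- match.arg(direction)
  same <- identical(dim(surface_a$values), dim(surface_b$values)) &&
    isTRUE(all.equal(surface_a$origin, surface_b$origin)) &&
    isTRUE(all.equal(surface_a$cell_size, surface_b$cell_size))
  if (!same) stop("surfaces are on different grids")
  d <- surface_b$values - surface_a$values
  if (direction == "increase") mean(d > epsilon) else mean(d < -epsilon)
}

#' Write a kriged surface as an ESRI ASCII grid
#'
#' Standard `.asc` layout: `ncols`/`nrows`/`xllcorner`/`yllcorner`/
#' `cellsize`/`NODATA_value` header followed by row-major values, top row
#' first.
#'
#' @param surface a `kriged_surface`.
#' @param path output path.
#' @param digits significant digits written.
#' @return Invisibly, the path.
#' @export
write_asc <- function(surface, path, digits = 6) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", surface$nx),
    paste("nrows", surface$ny),
    paste("xllcorner", format(surface$origin[1], scientific = FALSE)),
    paste("yllcorner", format(surface$origin[2], scientific = FALSE)),
    paste("cellsize", format(surface$cell_size, scientific = FALSE)),
    "NODATA_value -9999"), con)
  # values matrix row 1 = lowest y; .asc wants the top row first
  for (i in rev(seq_len(surface$ny))) {
    writeLines(paste(signif(surface$values[i, ], digits), collapse = " "), con)
  }
  invisible(path)
}

#' Tidy per-cell coordinates and values of a kriged surface
#'
#' @param surface a `kriged_surface`.
#' @return data.frame with columns `x`, `y`, `value` (cell centers).
#' @export
surface_to_df <- function(surface) {
  data.frame(x = rep(surface$cx, times = surface$ny),
             y = rep(surface$cy, each = surface$nx),
             value = as.vector(t(surface$values)))
}

#' Krige per-plot diversity values across census epochs
#'
#' Pipeline convenience reproducing the mapping workflow: for a chosen
#' measure and q, take per-plot subcommunity diversity values computed
#' against the all-plots metacommunity of each epoch, fit a semivariogram
#' (three candidate families, least SSE), krige onto a shared 625 m2 grid,
#' and report leave-one-out NRMSE. With two or more epochs, directional
#' change fractions between the first and last surfaces are included.
#'
#' @param table a [census_table] with plot coordinates.
#' @param measure `"alpha_bar"`, `"rho_bar"` or `"gamma_sub"`.
#' @param q viewpoint parameter.
#' @param years census epochs to map (default: all years in the table).
#' @param temporal if `TRUE`, map per-plot temporal representativeness
#'   (rho-bar of each plot-year against the plot's pooled series) instead of
#'   the spatial measure; `years` then selects which census's rho-bar is
#'   mapped.
#' @param cell_size grid cell edge (default 25 m).
#' @param families candidate semivariogram families.
#' @return List with one element per epoch (`surface`, `fit`, `cv`) plus
#'   `change` (increase/decrease fractions first-to-last epoch, when 2+
#'   epochs) and `grid`.
#' @export
map_diversity <- function(table, measure = "alpha_bar", q = 1,
                          years = table$years, temporal = FALSE,
                          cell_size = 25,
                          families = c("spherical", "exponential", "gaussian")) {
  stopifnot(inherits(table, "census_table"))
  meta <- table$metadata
  if (all(is.na(meta$x))) stop("table has no plot coordinates; cannot map")
  grid <- grid_spec(meta$x, meta$y, cell_size)
  per_epoch <- lapply(years, function(yr) {
    if (temporal) {
      tr <- temporal_representativeness(table, "psp", q_list = q)
      tr <- tr[tr$year == yr, ]
      vals <- tr$rho_bar[match(meta$plot_id, tr$unit)]
    } else {
      m <- abundance_by_plot(table, yr)
      mc <- metacommunity(m)
      dr <- switch(measure,
                   alpha_bar = subcommunity_alpha_bar(mc, q),
                   rho_bar = subcommunity_rho_bar(mc, q),
                   gamma_sub = subcommunity_gamma(mc, q),
                   stop("unknown measure: ", measure))
      vals <- dr$values[match(meta$plot_id, names(dr$values))]
    }
    ok <- !is.na(vals)
    emp <- empirical_semivariogram(meta$x[ok], meta$y[ok], vals[ok])
    fit <- fit_semivariogram(emp, families = families)
    surf <- ordinary_krige(meta$x[ok], meta$y[ok], vals[ok], fit, grid = grid)
    cv <- loo_nrmse(meta$x[ok], meta$y[ok], vals[ok], fit)
    list(year = yr, surface = surf, fit = fit, cv = cv)
  })
  names(per_epoch) <- as.character(years)
  change <- NULL
  if (length(years) >= 2L) {
    a <- per_epoch[[1]]$surface
    b <- per_epoch[[length(per_epoch)]]$surface
    change <- c(increase = change_fraction(a, b, "increase"),
                decrease = change_fraction(a, b, "decrease"))
  }
  c(per_epoch, list(change = change, grid = grid))
}
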