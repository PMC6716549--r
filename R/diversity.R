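#' Build a metacommunity from a raw count matrix
#'
#' Normalizes a species-by-subcommunity count (or abundance) matrix into the
#' joint relative-abundance representation on which all diversity measures
#' operate:
#' \describe{
#'   \item{`p`}{joint relative abundances, `p[s, j]`, grand sum 1}
#'   \item{`w`}{subcommunity weights, `w[j] = sum_s p[s, j]`}
#'   \item{`phat`}{within-subcommunity distributions, `p[, j] / w[j]`}
#'   \item{`P`}{species totals over the metacommunity, `P[s] = sum_j p[s, j]`}
#' }
#' All-zero species rows and all-zero subcommunity columns are pruned (and
#' recorded in the `pruned` element). Every diversity measure is invariant to
#' a uniform rescaling of `counts`.
#'
#' @param counts non-negative numeric matrix, species in rows, subcommunities
#'   in columns. Dimnames are kept if present.
#' @return An object of class `metacommunity`.
#' @export
metacommunity <- function(counts) {
  counts <- as.matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  tot <- sum(counts)
  if (tot <= 0) stop("degenerate input: all-zero count matrix")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("sp", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("sc", seq_len(ncol(counts)))
  keep_s <- rowSums(counts) > 0
  keep_j <- colSums(counts) > 0
  pruned <- list(species = rownames(counts)[!keep_s],
                 subcommunities = colnames(counts)[!keep_j])
  counts <- counts[keep_s, keep_j, drop = FALSE]
  p <- counts / tot
  w <- colSums(p)
  phat <- sweep(p, 2L, w, "/")
  P <- rowSums(p)
  structure(
    list(p = p, w = w, phat = phat, P = P,
         species = rownames(p), subcommunities = colnames(p),
         pruned = pruned),
    class = "metacommunity")
}

#' @export
print.metacommunity <- function(x, ...) {
  cat("Metacommunity:", length(x$species), "species x",
      length(x$subcommunities), "subcommunities\n")
  cat("  weights w:", paste(sprintf("%.3f", x$w), collapse = ", "), "\n")
  if (length(x$pruned$species) > 0L || length(x$pruned$subcommunities) > 0L) {
    cat("  pruned:", length(x$pruned$species), "empty species,",
        length(x$pruned$subcommunities), "empty subcommunities\n")
  }
  invisible(x)
}

#' Weighted power mean
#'
#' Computes `(sum_i w_i x_i^r)^(1/r)` for order `r != 0` and the weighted
#' geometric mean `exp(sum_i w_i log x_i)` at `r = 0`. The mean is continuous
#' in `r`; orders within `1e-9` of zero are routed to the geometric branch.
#' Entries with zero weight are ignored, so zero values are tolerated
#' wherever their weight is zero. A zero value carrying positive weight
#' yields 0 for `r <= 0` (the degenerate limit), flagged via the
#' `"degenerate"` attribute.
#'
#' Powers are evaluated in log space whenever the value range is extreme
#' (any ratio above 1e6 or below 1e-6), guarding against overflow at large
#' `|r|`.
#'
#' @param x non-negative values.
#' @param w non-negative weights; normalized to sum to 1.
#' @param order the order `r` of the mean.
#' @return Scalar mean; attribute `degenerate` is `TRUE` when the zero-value
#'   limit was taken.
#' @export
power_mean <- function(x, w, order) {
  if (length(x) != length(w)) stop("x and w must have equal length")
  if (any(w < 0) || !all(is.finite(w))) stop("weights must be finite and non-negative")
  sw <- sum(w)
  if (sw <= 0) stop("weights are not normalizable (sum <= 0)")
  w <- w / sw
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  if (any(!is.finite(x) | x < 0)) stop("values must be finite and non-negative")
  r <- order
  if (any(x == 0)) {
    if (r <= 0) return(structure(0, degenerate = TRUE))
    # r > 0: zero values contribute nothing
  }
  if (abs(r) < 1e-9) {
    return(exp(sum(w * log(x))))
  }
  pos <- x > 0
  xr <- range(x[pos])
  if (xr[2] / xr[1] > 1e6 || xr[1] < 1e-6 || xr[2] > 1e6) {
    # log-space: r-th power sums via log-sum-exp
    lx <- log(x[pos])
    m <- max(r * lx)
    s <- m + log(sum(w[pos] * exp(r * lx - m)))
    return(exp(s / r))
  }
  sum(w[pos] * x[pos]^r)^(1 / r)
}

# Hill number of a probability vector at viewpoint q.
# q = 1 uses the exponential-Shannon limit in log space.
hill_number <- function(prob, q) {
  prob <- prob[prob > 0]
  if (abs(q - 1) < 1e-9) {
    return(exp(-sum(prob * log(prob))))
  }
  # D_q = [sum p^q]^(1/(1-q)) = 1 / power_mean(p, weights p, order q-1)
  1 / power_mean(prob, prob, q - 1)
}

check_q <- function(q) {
  if (length(q) != 1L || !is.finite(q) || q < 0) {
    stop("viewpoint parameter q must be a single non-negative number")
  }
  q
}

new_diversity_result <- function(measure, q, values, design_label = NA_character_) {
  structure(list(measure = measure, q = q, values = values,
                 design_label = design_label),
            class = "diversity_result")
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("%s at q = %g", x$measure, x$q))
  if (!is.na(x$design_label)) cat(" [", x$design_label, "]", sep = "")
  cat("\n")
  print(round(x$values, 4))
  invisible(x)
}

#' Normalized subcommunity alpha diversity
#'
#' The effective number of species of each subcommunity considered in
#' isolation: the order-q Hill number of its within-subcommunity
#' distribution. At `q = 0` this is species richness; at `q = 1` the
#' exponential of Shannon entropy; at `q = 2` the inverse Simpson
#' concentration.
#'
#' @param mc a [metacommunity].
#' @param q viewpoint parameter, a single value `>= 0`. Larger q weights
#'   dominant species more heavily, giving a more conservative appraisal.
#' @return A `diversity_result` with one value per subcommunity.
#' @export
subcommunity_alpha_bar <- function(mc, q) {
  stopifnot(inherits(mc, "metacommunity"))
  check_q(q)
  v <- apply(mc$phat, 2L, hill_number, q = q)
  new_diversity_result("alpha_bar", q, v)
}

#' Subcommunity representativeness (rho-bar)
#'
#' How well each subcommunity's species distribution matches that of the
#' whole metacommunity: the order-(1-q) power mean, over the subcommunity's
#' species (weights `phat[, j]`), of the ratios `P[s] / phat[s, j]`.
#' Values lie in `(0, 1]`: 1 only when the subcommunity's composition is
#' identical to the metacommunity's, and bounded below by the subcommunity's
#' weight `w[j]` (a subcommunity wholly unlike the rest represents only
#' itself, i.e. its own share of the trees). In spatial designs low values
#' mean compositional distinctness/heterogeneity; in temporal designs they
#' mean high turnover.
#'
#' @inheritParams subcommunity_alpha_bar
#' @return A `diversity_result` with one value per subcommunity.
#' @export
subcommunity_rho_bar <- function(mc, q) {
  stopifnot(inherits(mc, "metacommunity"))
  check_q(q)
  v <- vapply(seq_along(mc$w), function(j) {
    ph <- mc$phat[, j]
    keep <- ph > 0
    power_mean(mc$P[keep] / ph[keep], ph[keep], 1 - q)
  }, numeric(1))
  names(v) <- mc$subcommunities
  new_diversity_result("rho_bar", q, v)
}

#' Subcommunity gamma diversity
#'
#' Each subcommunity's average contribution to metacommunity diversity per
#' individual: the order-(1-q) power mean, over the subcommunity's species,
#' of `1 / P[s]` — equivalently `[sum_s phat[s,j] * P[s]^(q-1)]^(1/(1-q))`
#' with the geometric limit at `q = 1`. Always `>= 1` since `P[s] <= 1`.
#'
#' @inheritParams subcommunity_alpha_bar
#' @return A `diversity_result` with one value per subcommunity.
#' @export
subcommunity_gamma <- function(mc, q) {
  stopifnot(inherits(mc, "metacommunity"))
  check_q(q)
  v <- vapply(seq_along(mc$w), function(j) {
    ph <- mc$phat[, j]
    keep <- ph > 0
    power_mean(1 / mc$P[keep], ph[keep], 1 - q)
  }, numeric(1))
  names(v) <- mc$subcommunities
  new_diversity_result("gamma_sub", q, v)
}

#' Metacommunity gamma diversity
#'
#' The conventional gamma diversity: the order-q Hill number of the pooled
#' species distribution `P`. At `q = 0` it equals pooled species richness.
#'
#' @inheritParams subcommunity_alpha_bar
#' @return Scalar.
#' @export
metacommunity_gamma <- function(mc, q) {
  stopifnot(inherits(mc, "metacommunity"))
  check_q(q)
  hill_number(mc$P, q)
}

#' Average subcommunity diversity values at viewpoint q
#'
#' Aggregates per-subcommunity values into a single number using the
#' weighted power mean of order `1 - q`: arithmetic at `q = 0`, geometric at
#' `q = 1`, harmonic at `q = 2`. This is the aggregation under which the
#' weighted mean of subcommunity gamma values equals the metacommunity
#' gamma. An alternative fixed mapping (`rule = "fixed_map"`: arithmetic,
#' harmonic, geometric for q = 0, 1, 2), found in some reports, is provided
#' for comparison; it is defined only at those three q values.
#'
#' @param values positive per-subcommunity values.
#' @param weights subcommunity weights (normalized internally).
#' @param q viewpoint parameter.
#' @param rule aggregation convention; default `"power_mean"`.
#' @return Scalar.
#' @export
metacommunity_average <- function(values, weights, q,
                                  rule = c("power_mean", "fixed_map")) {
  rule <- match.arg(rule)
  check_q(q)
  if (rule == "power_mean") {
    return(power_mean(values, weights, 1 - q))
  }
  ord <- switch(as.character(q), "0" = 1, "1" = -1, "2" = 0,
                stop("fixed_map rule is defined only for q in {0, 1, 2}"))
  power_mean(values, weights, ord)
}

#' Diversity profile over a grid of viewpoint parameters
#'
#' Evaluates all four measures (normalized subcommunity alpha,
#' representativeness rho-bar, subcommunity gamma, metacommunity gamma) at
#' each q in `q_grid`.
#'
#' @param mc a [metacommunity].
#' @param q_grid non-empty vector of viewpoints, all `>= 0` (default 0, 1, 2,
#'   the conventional reporting values).
#' @return data.frame with columns `measure`, `q`, `subcommunity`, `value`;
#'   metacommunity gamma rows carry subcommunity `"metacommunity"`.
#' @export
diversity_profile <- function(mc, q_grid = c(0, 1, 2)) {
  stopifnot(inherits(mc, "metacommunity"))
  if (length(q_grid) == 0L) stop("q_grid must be non-empty")
  vapply(q_grid, check_q, numeric(1))
  out <- lapply(q_grid, function(q) {
    a <- subcommunity_alpha_bar(mc, q)
    r <- subcommunity_rho_bar(mc, q)
    g <- subcommunity_gamma(mc, q)
    G <- metacommunity_gamma(mc, q)
    rbind(
      data.frame(measure = "alpha_bar", q = q,
                 subcommunity = mc$subcommunities, value = unname(a$values)),
      data.frame(measure = "rho_bar", q = q,
                 subcommunity = mc$subcommunities, value = unname(r$values)),
      data.frame(measure = "gamma_sub", q = q,
                 subcommunity = mc$subcommunities, value = unname(g$values)),
      data.frame(measure = "gamma_meta", q = q,
                 subcommunity = "metacommunity", value = G))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
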