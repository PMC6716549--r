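# Shared fixtures built in code.

toy_counts <- function() {
  m <- matrix(c(2, 1, 1, 2), nrow = 2,
              dimnames = list(c("spA", "spB"), c("sc1", "sc2")))
  m
}

# A minimal valid census table: 4 plots, 2 zones, 2 years, 3 species.
tiny_table <- function() {
  meta <- data.frame(plot_id = c("p1", "p2", "p3", "p4"),
                     zone = c("hyposaline", "hyposaline",
                              "mesosaline", "mesosaline"),
                     x = c(0, 100, 200, 300), y = c(0, 50, 0, 50),
                     area_ha = 0.2)
  rec <- expand.grid(plot_id = meta$plot_id, year = c(1986L, 2014L),
                     species = c("A", "B", "C"), stringsAsFactors = FALSE)
  rec$zone <- meta$zone[match(rec$plot_id, meta$plot_id)]
  set.seed(42)
  rec$count <- rpois(nrow(rec), 20)
  census_table(rec, meta)
}

# Random valid metacommunity count matrices for property tests.
random_counts <- function(ns = 6L, nj = 5L) {
  m <- matrix(rpois(ns * nj, 3) + stats::runif(ns * nj) * 2, ns, nj)
  # ensure no empty rows/cols
  m[cbind(seq_len(ns), sample(nj, ns, replace = TRUE))] <-
    m[cbind(seq_len(ns), sample(nj, ns, replace = TRUE))] + 1
  m + 0.1
}

# Simulate a Gaussian random field at given points from a semivariogram
# model (direct covariance factorization) -- independent of the kriging
# path under test.
simulate_field <- function(x, y, model) {
  n <- length(x)
  sill <- model$c0 + model$c
  D <- as.matrix(dist(cbind(x, y)))
  C <- sill - semivariogram(D, model)
  diag(C) <- sill
  L <- t(chol(C + diag(1e-8, n)))
  as.vector(L %*% rnorm(n))
}
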