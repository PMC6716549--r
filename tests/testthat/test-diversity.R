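test_that("power mean reproduces classic special cases and monotonicity", {
  expect_equal(power_mean(c(2, 8), c(0.5, 0.5), 0), 4)
  expect_equal(power_mean(c(2, 8), c(0.5, 0.5), 1), 5)
  expect_equal(power_mean(c(2, 8), c(0.5, 0.5), -1), 3.2)
  # zero-weight entries are ignored even when their value is zero
  expect_equal(power_mean(c(2, 0), c(1, 0), -1), 2)
  # degenerate zero value with positive weight at r <= 0
  z <- power_mean(c(2, 0), c(0.5, 0.5), -1)
  expect_equal(as.numeric(z), 0)
  expect_true(attr(z, "degenerate"))
  expect_error(power_mean(c(1, 2), c(0, 0), 1), "not normalizable")
  # power-mean inequality: non-decreasing in the order (brute force)
  set.seed(1)
  for (i in 1:20) {
    x <- runif(5, 0.1, 10)
    w <- runif(5); w <- w / sum(w)
    v <- vapply(seq(-2, 2, by = 0.25), function(r) power_mean(x, w, r),
                numeric(1))
    expect_true(all(diff(v) >= -1e-10))
  }
  # continuity at 0
  expect_equal(power_mean(c(2, 8), c(0.5, 0.5), 1e-10), 4)
  # log-space guard handles extreme ranges
  expect_equal(power_mean(c(1e-9, 1e9), c(0.5, 0.5), 2),
               sqrt(0.5) * 1e9, tolerance = 1e-9)
})

test_that("metacommunity normalization and its invariants", {
  mc <- metacommunity(toy_counts())
  expect_equal(unname(mc$w), c(0.5, 0.5))
  expect_equal(unname(mc$P), c(0.5, 0.5))
  expect_equal(unname(mc$phat[, 1]), c(2 / 3, 1 / 3))
  expect_equal(sum(mc$p), 1)
  # scale invariance of the container
  mc10 <- metacommunity(10 * toy_counts())
  expect_equal(mc10$p, mc$p)
  # pruning of empty rows/columns
  m <- rbind(toy_counts(), zero = c(0, 0))
  mc2 <- metacommunity(m)
  expect_equal(mc2$pruned$species, "zero")
  expect_equal(dim(mc2$p), c(2L, 2L))
  expect_error(metacommunity(matrix(0, 2, 2)), "all-zero")
})

test_that("alpha, gamma and rho reproduce hand oracles", {
  mc1 <- metacommunity(matrix(c(2, 1), 2, dimnames = list(c("a", "b"), "j")))
  expect_equal(unname(subcommunity_alpha_bar(mc1, 0)$values), 2)
  expect_equal(unname(subcommunity_alpha_bar(mc1, 2)$values), 1.8)
  expect_equal(unname(subcommunity_alpha_bar(mc1, 1)$values),
               exp(-(2 / 3) * log(2 / 3) - (1 / 3) * log(1 / 3)))
  mc <- metacommunity(toy_counts())
  expect_equal(unname(subcommunity_rho_bar(mc, 2)$values), c(0.9, 0.9))
  # hand oracle: exp((2/3) log(3/4) + (1/3) log(3/2)) = 0.94494
  expect_equal(unname(subcommunity_rho_bar(mc, 1)$values),
               rep(exp((2 / 3) * log(3 / 4) + (1 / 3) * log(3 / 2)), 2),
               tolerance = 1e-12)
  # P uniform -> subcommunity gamma = 2 at every q
  for (q in c(0, 0.5, 1, 2, 5)) {
    expect_equal(unname(subcommunity_gamma(mc, q)$values), c(2, 2))
  }
  # uniform pooled distribution -> metacommunity gamma = k for all q
  u <- metacommunity(matrix(rep(1, 8), 4))
  for (q in c(0, 1, 2, 3)) expect_equal(metacommunity_gamma(u, q), 4)
})

test_that("alpha and metacommunity gamma agree with an independent Hill-number oracle", {
  skip_if_not_installed("vegan")
  set.seed(7)
  m <- random_counts(8, 4)
  mc <- metacommunity(m)
  for (q in c(0, 1, 2)) {
    a <- subcommunity_alpha_bar(mc, q)$values
    ref <- exp(vegan::renyi(t(mc$phat), scales = q))
    expect_equal(unname(a), unname(ref), tolerance = 1e-10)
    expect_equal(metacommunity_gamma(mc, q),
                 unname(exp(vegan::renyi(mc$P, scales = q))),
                 tolerance = 1e-10)
  }
})

test_that("framework identities hold on random matrices", {
  set.seed(11)
  for (i in 1:25) {
    mc <- metacommunity(random_counts())
    for (q in c(0, 0.5, 1, 2)) {
      rho <- subcommunity_rho_bar(mc, q)$values
      # w_j <= rho_j <= 1
      expect_true(all(rho <= 1 + 1e-12))
      expect_true(all(rho >= mc$w - 1e-12))
      # weighted order-(1-q) mean of subcommunity gamma = metacommunity gamma
      g <- subcommunity_gamma(mc, q)$values
      expect_equal(metacommunity_average(g, mc$w, q),
                   metacommunity_gamma(mc, q), tolerance = 1e-10)
      expect_true(all(g >= 1 - 1e-12))
    }
    # q = 0 alpha equals per-column richness
    a0 <- subcommunity_alpha_bar(mc, 0)$values
    expect_equal(unname(a0), unname(colSums(mc$phat > 0)))
    expect_equal(metacommunity_gamma(mc, 0), sum(mc$P > 0))
  }
})

test_that("measures are invariant to scaling and species permutation", {
  set.seed(3)
  m <- random_counts()
  mc <- metacommunity(m)
  mcs <- metacommunity(m * 7.3)
  perm <- sample(nrow(m))
  mcp <- metacommunity(m[perm, ])
  for (q in c(0, 1, 2)) {
    expect_equal(subcommunity_alpha_bar(mcs, q)$values,
                 subcommunity_alpha_bar(mc, q)$values)
    expect_equal(sort(unname(subcommunity_rho_bar(mcp, q)$values)),
                 sort(unname(subcommunity_rho_bar(mc, q)$values)))
    expect_equal(metacommunity_gamma(mcp, q), metacommunity_gamma(mc, q))
  }
})

test_that("degenerate and identical-composition cases behave as the theory says", {
  # subcommunity identical in composition to the metacommunity -> rho = 1
  m <- cbind(a = c(4, 2, 2), b = c(8, 4, 4))
  mc <- metacommunity(m)
  for (q in c(0, 1, 2)) {
    expect_equal(unname(subcommunity_rho_bar(mc, q)$values), c(1, 1))
  }
  # two equal-weight subcommunities on disjoint species -> rho = 0.5
  md <- rbind(cbind(c(3, 1), 0), cbind(0, c(1, 3)))
  mcd <- metacommunity(md)
  for (q in c(0, 1, 2)) {
    expect_equal(unname(subcommunity_rho_bar(mcd, q)$values), c(0.5, 0.5))
  }
  # single subcommunity: rho = 1 and alpha = gamma_sub = gamma_meta
  m1 <- metacommunity(matrix(c(5, 3, 2), 3))
  for (q in c(0, 1, 2)) {
    expect_equal(unname(subcommunity_rho_bar(m1, q)$values), 1)
    a <- unname(subcommunity_alpha_bar(m1, q)$values)
    expect_equal(unname(subcommunity_gamma(m1, q)$values), a)
    expect_equal(metacommunity_gamma(m1, q), a)
  }
})

test_that("q = 1 branch is the limit of nearby orders", {
  set.seed(5)
  for (i in 1:10) {
    mc <- metacommunity(random_counts())
    for (fn in list(subcommunity_alpha_bar, subcommunity_rho_bar,
                    subcommunity_gamma)) {
      v1 <- fn(mc, 1)$values
      lo <- fn(mc, 1 - 1e-6)$values
      hi <- fn(mc, 1 + 1e-6)$values
      expect_equal(unname(v1), unname(lo), tolerance = 1e-4)
      expect_equal(unname(v1), unname(hi), tolerance = 1e-4)
    }
  }
})

test_that("diversity profile is monotone in q where theory requires", {
  set.seed(9)
  grid <- c(0, 0.5, 1, 1.5, 2)
  for (i in 1:10) {
    mc <- metacommunity(random_counts())
    prof <- diversity_profile(mc, grid)
    for (sc in mc$subcommunities) {
      a <- prof$value[prof$measure == "alpha_bar" & prof$subcommunity == sc]
      expect_true(all(diff(a) <= 1e-10))
    }
    g <- prof$value[prof$measure == "gamma_meta"]
    expect_true(all(diff(g) <= 1e-10))
  }
  # one-species metacommunity: everything is 1
  one <- metacommunity(matrix(2, 1, 1))
  p1 <- diversity_profile(one, grid)
  expect_true(all(abs(p1$value - 1) < 1e-12))
})

test_that("metacommunity averaging conventions", {
  expect_equal(metacommunity_average(c(1, 3), c(0.5, 0.5), 0), 2)
  expect_equal(metacommunity_average(c(2, 8), c(0.5, 0.5), 2), 3.2)
  expect_equal(metacommunity_average(c(2, 8), c(0.5, 0.5), 1), 4)
  # the alternative fixed mapping: harmonic at q=1, geometric at q=2
  expect_equal(metacommunity_average(c(2, 8), c(0.5, 0.5), 1, rule = "fixed_map"),
               3.2)
  expect_equal(metacommunity_average(c(2, 8), c(0.5, 0.5), 2, rule = "fixed_map"),
               4)
  expect_error(metacommunity_average(c(2, 8), c(0.5, 0.5), 0.5,
                                     rule = "fixed_map"), "only for q")
})
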