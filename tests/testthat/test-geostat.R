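test_that("empirical semivariogram matches hand-computable cases", {
  # two points with values 0 and 2: gamma = (2)^2 / 2 = 2
  emp <- empirical_semivariogram(c(0, 100), c(0, 0), c(0, 2),
                                 n_bins = 1L, max_lag = 150)
  expect_equal(nrow(emp), 1L)
  expect_equal(emp$gamma, 2)
  expect_equal(emp$n_pairs, 1L)
  # constant field: zero everywhere
  set.seed(1)
  x <- runif(30, 0, 1000); y <- runif(30, 0, 1000)
  emp0 <- empirical_semivariogram(x, y, rep(3.3, 30))
  expect_true(all(emp0$gamma == 0))
  expect_error(empirical_semivariogram(c(1, 1), c(2, 2), c(0, 1)),
               "coincident")
  # simulated field from a known model: binned estimate tracks the model
  mod <- semivariogram_model("spherical", c0 = 0, c = 1, a = 300)
  set.seed(42)
  xs <- runif(250, 0, 1000); ys <- runif(250, 0, 1000)
  zs <- simulate_field(xs, ys, mod)
  emp <- empirical_semivariogram(xs, ys, zs, n_bins = 10L)
  expect_equal(emp$gamma, semivariogram(emp$lag, mod), tolerance = 0.35)
})

test_that("semivariogram families honour their shape constraints", {
  h <- seq(0, 1000, by = 10)
  for (fam in c("spherical", "exponential", "gaussian")) {
    m <- semivariogram_model(fam, c0 = 0.2, c = 1.5, a = 300)
    g <- semivariogram(h, m)
    expect_equal(g[1], 0)            # gamma(0) = 0
    expect_true(all(diff(g) >= -1e-12))  # non-decreasing
    expect_true(all(g <= m$c0 + m$c + 1e-12))
  }
  sph <- semivariogram_model("spherical", 0.2, 1.5, 300)
  expect_equal(semivariogram(300, sph), 1.7)  # sill attained exactly at a
  expect_lt(semivariogram(300, semivariogram_model("exponential", 0.2, 1.5, 300)),
            1.7)
})

test_that("fit recovers parameters from noiseless model bins and breaks ties canonically", {
  lags <- seq(25, 600, by = 25)
  for (fam in c("spherical", "exponential", "gaussian")) {
    true <- semivariogram_model(fam, c0 = 0.1, c = 1.0, a = 300)
    emp <- structure(data.frame(lag = lags,
                                gamma = semivariogram(lags, true),
                                n_pairs = 50L),
                     class = c("empirical_semivariogram", "data.frame"))
    fit <- fit_semivariogram(emp)
    expect_equal(fit$family, fam)
    expect_equal(fit$c0, 0.1, tolerance = 0.01)
    expect_equal(fit$c, 1.0, tolerance = 0.01)
    expect_equal(fit$a, 300, tolerance = 0.01)
  }
  # pure nugget: flat empirical variogram flags the degenerate structure
  empn <- structure(data.frame(lag = lags, gamma = 1.0, n_pairs = 50L),
                    class = c("empirical_semivariogram", "data.frame"))
  fitn <- fit_semivariogram(empn)
  expect_true(fitn$pure_nugget_warning)
  expect_s3_class(fitn, "semivariogram_fit")
})

test_that("ordinary kriging is unbiased, exact and weight-normalized", {
  set.seed(8)
  x <- runif(25, 0, 1000); y <- runif(25, 0, 1000)
  mod <- semivariogram_model("spherical", c0 = 0, c = 1, a = 400)
  # constant field reproduces the constant everywhere
  g <- grid_spec(x, y, cell_size = 100)
  surf <- ordinary_krige(x, y, rep(7.7, 25), mod, grid = g)
  expect_true(all(abs(surf$values - 7.7) < 1e-8))
  expect_equal(dim(surf$values), c(g$ny, g$nx))
  # weights sum to 1 at every prediction point
  z <- simulate_field(x, y, mod)
  pred <- mangrovediv:::.ok_predict(x, y, z, mod, g$cx[3], g$cy[2],
                                    keep_weights = TRUE)
  w <- attr(pred, "weights")
  expect_equal(colSums(w), 1, tolerance = 1e-10, ignore_attr = TRUE)
  # nugget 0: prediction at a data point equals the datum
  at_data <- mangrovediv:::.ok_predict(x, y, z, mod, x[5], y[5])
  expect_equal(at_data, z[5], tolerance = 1e-8)
  # three collinear points against a hand-built linear-system oracle
  x3 <- c(0, 100, 200); y3 <- c(0, 0, 0); z3 <- c(1, 3, 2)
  px <- 150; py <- 0
  G <- semivariogram(as.matrix(dist(cbind(x3, y3))), mod)
  A <- rbind(cbind(G, 1), c(1, 1, 1, 0))
  b <- c(semivariogram(sqrt((x3 - px)^2 + (y3 - py)^2), mod), 1)
  lam <- solve(A, b)[1:3]
  expect_equal(mangrovediv:::.ok_predict(x3, y3, z3, mod, px, py),
               sum(lam * z3), tolerance = 1e-10)
  # duplicate coordinates are averaged with a warning
  expect_warning(
    sd <- ordinary_krige(c(x, x[1]), c(y, y[1]), c(z, z[1] + 2), mod, grid = g),
    "duplicate")
})

test_that("LOO NRMSE separates structured fields from noise", {
  mod <- semivariogram_model("spherical", c0 = 0.05, c = 1, a = 400)
  # constant field: exactly reproducible, but normalization is undefined
  expect_error(loo_nrmse(runif(10), runif(10), rep(1, 10), mod),
               "zero range")
  mean_nrmse <- function(z) {
    mu <- vapply(seq_along(z), function(i) mean(z[-i]), numeric(1))
    sqrt(mean((mu - z)^2)) / diff(range(z))
  }
  set.seed(12)
  x <- runif(40, 0, 1000); y <- runif(40, 0, 1000)
  # smooth field: kriging strictly beats the global-mean predictor
  z <- simulate_field(x, y, mod)
  cv <- loo_nrmse(x, y, z, mod)
  expect_lt(cv$nrmse, mean_nrmse(z))
  expect_equal(cv$nrmse, cv$rmse / diff(range(z)))
  # white noise: kriging about as good as predicting the mean
  zn <- rnorm(40)
  nug <- semivariogram_model("exponential", c0 = 1, c = 1e-6, a = 400)
  cvn <- loo_nrmse(x, y, zn, nug)
  expect_lt(abs(cvn$nrmse - mean_nrmse(zn)) / mean_nrmse(zn), 0.2)
})

test_that("change fractions count directional cell changes", {
  set.seed(3)
  x <- runif(12, 0, 300); y <- runif(12, 0, 300)
  mod <- semivariogram_model("spherical", 0, 1, 150)
  g <- grid_spec(x, y, cell_size = 50)
  a <- ordinary_krige(x, y, rnorm(12), mod, grid = g)
  expect_equal(change_fraction(a, a, "increase"), 0)
  expect_equal(change_fraction(a, a, "decrease"), 0)
  b <- a
  b$values <- a$values + 1
  expect_equal(change_fraction(a, b, "increase"), 1)
  expect_equal(change_fraction(a, b, "decrease"), 0)
  # half the cells up by 1
  h <- a
  half <- seq_len(floor(length(h$values) / 2))
  h$values[half] <- h$values[half] + 1
  expect_equal(change_fraction(a, h, "increase"),
               length(half) / length(h$values))
  # epsilon suppresses sub-threshold changes
  expect_equal(change_fraction(a, b, "increase", epsilon = 2), 0)
  g2 <- grid_spec(x, y, cell_size = 60)
  b2 <- ordinary_krige(x, y, rnorm(12), mod, grid = g2)
  expect_error(change_fraction(a, b2), "different grids")
})

test_that("asc writer emits a well-formed grid that round-trips", {
  set.seed(5)
  x <- runif(10, 0, 200); y <- runif(10, 0, 200)
  surf <- ordinary_krige(x, y, rnorm(10),
                         semivariogram_model("exponential", 0.1, 1, 100),
                         grid = grid_spec(x, y, cell_size = 50))
  p <- withr::local_tempfile(fileext = ".asc")
  write_asc(surf, p)
  lines <- readLines(p)
  expect_match(lines[1], "^ncols ")
  expect_match(lines[6], "^NODATA_value")
  vals <- do.call(rbind, lapply(lines[-(1:6)], function(l)
    as.numeric(strsplit(l, " ")[[1]])))
  expect_equal(dim(vals), c(surf$ny, surf$nx))
  # top row of the file is the highest-y row of the matrix
  expect_equal(vals[1, ], unname(surf$values[surf$ny, ]), tolerance = 1e-5)
  df <- surface_to_df(surf)
  expect_equal(nrow(df), surf$nx * surf$ny)
  expect_equal(df$value[1], surf$values[1, 1])
})

test_that("map_diversity krige-maps a synthetic network end to end", {
  tab <- simulate_scenario(scenario_config(n_plots = 30L,
                                           zone_split = c(12L, 9L, 9L),
                                           extent = c(1200, 500), seed = 2))
  mp <- map_diversity(tab, measure = "alpha_bar", q = 1,
                      years = c(1986L, 2014L), cell_size = 100)
  expect_named(mp, c("1986", "2014", "change", "grid"))
  expect_s3_class(mp[["1986"]]$surface, "kriged_surface")
  expect_equal(mp[["1986"]]$surface$cell_size, 100)
  expect_true(mp[["1986"]]$cv$nrmse >= 0)
  expect_length(mp$change, 2L)
  # single epoch: no change surface
  mp1 <- map_diversity(tab, measure = "alpha_bar", q = 1, years = 1986L,
                       cell_size = 100)
  expect_null(mp1$change)
  # fixture has no coordinates
  expect_error(map_diversity(table1_fixture()), "no plot coordinates")
})
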