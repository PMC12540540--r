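test_that("empirical semivariogram matches direct substitution on tiny inputs", {
  # constant field: gamma identically zero
  s <- random_samples(8, seed = 1, values = rep(5, 8))
  emp <- empirical_semivariogram(s, "v", lag_width = 20, max_distance = 160)
  expect_true(all(emp$semivariances[emp$pair_counts > 0] == 0))

  # two points 10 m apart, values 0 and 2: gamma = (1/2)(2-0)^2 / 1 = 2
  s2 <- sample_set(c("a", "b"), c(0, 10), c(0, 0),
                   matrix(c(0, 2), ncol = 1, dimnames = list(NULL, "v")))
  emp2 <- empirical_semivariogram(s2, "v", lag_width = 12, max_distance = 12)
  expect_equal(emp2$semivariances[1], 2.0)
  expect_equal(emp2$pair_counts[1], 1L)

  expect_error(empirical_semivariogram(s, "nope", 10, 100), "unknown property")
  expect_error(empirical_semivariogram(s, "v", 20, 10), "max_distance")
})

test_that("semivariogram estimator equals the exhaustive pair-enumeration oracle", {
  # 1-D transect from the worked example, then random scatters up to n = 50
  s <- sample_set(paste0("t", 1:6), 0:5, rep(0, 6),
                  matrix(c(1, 3, 2, 5, 4, 6), ncol = 1,
                         dimnames = list(NULL, "v")))
  emp <- empirical_semivariogram(s, "v", lag_width = 1, max_distance = 5)
  oracle <- brute_semivariogram(s$x, s$y, s$values[, 1], 1, 5)
  expect_equal(emp$semivariances, oracle$gamma)
  expect_equal(emp$pair_counts, as.integer(oracle$n))

  for (seed in 1:4) {
    n <- c(15, 30, 45, 50)[seed]
    s <- random_samples(n, seed = seed)
    emp <- empirical_semivariogram(s, "v", lag_width = 15, max_distance = 75)
    oracle <- brute_semivariogram(s$x, s$y, s$values[, 1], 15, 75)
    expect_equal(emp$semivariances, oracle$gamma, tolerance = 1e-12)
    expect_equal(emp$pair_counts, as.integer(oracle$n))
    ok <- emp$pair_counts > 0
    expect_equal(emp$lag_centers[ok], oracle$centers[ok], tolerance = 1e-12)
  }
})

test_that("model_value implements the three families with effective ranges", {
  sph <- variogram_model("spherical", 0, 1, 40)
  expect_equal(model_value(sph, 40), 1.0)
  expect_equal(model_value(sph, 100), 1.0)
  expect_equal(model_value(sph, 20), 0.6875)
  exp_m <- variogram_model("exponential", 0.2, 0.8, 60)
  gau <- variogram_model("gaussian", 0.1, 0.9, 60)
  # gamma(0) is the nugget for every family
  expect_equal(model_value(sph, 0), 0)
  expect_equal(model_value(exp_m, 0), 0.2)
  expect_equal(model_value(gau, 0), 0.1)
  # effective range: 95% of the partial sill at h = a
  expect_equal(model_value(exp_m, 60), 0.2 + 0.8 * (1 - exp(-3)))
  expect_equal(model_value(gau, 60), 0.1 + 0.9 * (1 - exp(-3)))
  expect_error(model_value(sph, -1), ">= 0")

  # non-decreasing in h for all families
  h <- seq(0, 200, by = 0.5)
  for (m in list(sph, exp_m, gau)) {
    expect_true(all(diff(model_value(m, h)) >= -1e-12))
  }
})

test_that("variogram fitting recovers noiseless inputs and handles degeneracy", {
  tru <- variogram_model("spherical", 0.3, 1.2, 55)
  h <- seq(5, 120, by = 12)
  emp <- structure(list(lag_centers = h, semivariances = model_value(tru, h),
                        pair_counts = rep(40L, length(h)), lag_width = 12,
                        max_distance = 125, property = "z"),
                   class = "empirical_variogram")
  fit <- fit_variogram(emp, "spherical")
  expect_equal(fit$nugget, 0.3, tolerance = 1e-6)
  expect_equal(fit$partial_sill, 1.2, tolerance = 1e-6)
  expect_equal(fit$range_param, 55, tolerance = 1e-6)

  # flat positive variogram: pure-nugget solution
  empf <- emp
  empf$semivariances <- rep(0.7, length(h))
  flat <- fit_variogram(empf, "spherical")
  expect_equal(flat$nugget, 0.7, tolerance = 1e-8)
  expect_equal(flat$partial_sill, 0, tolerance = 1e-8)

  # all-zero variogram: degenerate-fit warning and zero-variance model
  emp0 <- emp
  emp0$semivariances <- rep(0, length(h))
  expect_warning(z <- fit_variogram(emp0, "spherical"), "degenerate")
  expect_equal(z$sill, 0)
})

test_that("spatial-dependence and accuracy classes follow their thresholds", {
  m <- function(n, s) variogram_model("spherical", n, s - n, 50)
  expect_identical(classify_dependence(m(0, 1)), "strong")
  expect_identical(classify_dependence(m(0.0025, 0.0378)), "strong")  # 6.61%
  expect_identical(classify_dependence(m(0.25, 1)), "moderate")
  expect_identical(classify_dependence(m(0.5, 1)), "moderate")
  expect_identical(classify_dependence(m(0.75, 1)), "moderate")
  expect_identical(classify_dependence(m(0.76, 1)), "weak")
  expect_error(classify_dependence(m(0, 0)), "zero sill")

  expect_identical(classify_accuracy(1.38), "good")
  expect_identical(classify_accuracy(19.99), "good")
  expect_identical(classify_accuracy(20), "fair")
  expect_identical(classify_accuracy(25), "fair")
  expect_identical(classify_accuracy(30), "fair")
  expect_identical(classify_accuracy(30.01), "poor")
  expect_error(classify_accuracy(-1), ">= 0")
})

test_that("ordinary kriging matches a dense linear-algebra oracle", {
  set.seed(9)
  co <- cbind(runif(5, 0, 50), runif(5, 0, 50))
  z <- rnorm(5, 10, 2)
  mod <- variogram_model("spherical", 0, 1, 40)
  s <- sample_set(paste0("s", 1:5), co[, 1], co[, 2],
                  matrix(z, dimnames = list(NULL, "v")))
  tgt <- matrix(c(25, 25), 1)
  res <- ordinary_kriging(s, "v", mod, tgt)
  G <- model_value(mod, as.matrix(dist(co)))
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, 5), 0))
  b <- c(model_value(mod, sqrt(colSums((t(co) - c(25, 25))^2))), 1)
  sol <- solve(A, b)
  expect_equal(res$predictions, sum(sol[1:5] * z), tolerance = 1e-8)
  expect_equal(res$kriging_variance, sum(sol[1:5] * b[1:5]) + sol[6],
               tolerance = 1e-8)
  expect_equal(sum(res$weights), 1, tolerance = 1e-8)
})

test_that("kriging is exact at sample sites and unbiased with one neighbour", {
  s <- random_samples(20, seed = 5)
  mod <- variogram_model("exponential", 0, 2, 50)
  tgt <- cbind(s$x[1:10], s$y[1:10])
  res <- ordinary_kriging(s, "v", mod, tgt)
  expect_equal(res$predictions, s$values[1:10, "v"], tolerance = 1e-6)
  expect_true(all(res$kriging_variance >= 0))

  # single neighbour: weight 1 everywhere (unbiasedness constraint)
  one <- agrizone:::ok_solve(matrix(c(3, 4), 1), 7, mod,
                             matrix(c(100, -20, 0, 50), 2))
  expect_equal(unname(one$pred), c(7, 7))
  expect_equal(unname(one$weights[1, ]), c(1, 1))

  # continuity: prediction approaches the sample value as target -> sample
  eps <- c(5, 1, 0.1, 0.01)
  preds <- ordinary_kriging(s, "v", mod, cbind(s$x[3] + eps, s$y[3]))$predictions
  expect_true(all(diff(abs(preds - s$values[3, "v"])) < 0))
})

test_that("LOOCV metrics follow their definitions", {
  m <- agrizone:::cv_metrics(c(10, 12, 14), c(11, 12, 13))
  expect_equal(m$nrmse_percent, 100 * sqrt(2 / 3) / 12, tolerance = 1e-10)
  expect_equal(round(m$nrmse_percent, 2), 6.80)
  expect_identical(m$accuracy_class, "good")
  perfect <- agrizone:::cv_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$nrmse_percent, 0)
  expect_equal(perfect$r2, 1)
  expect_identical(perfect$accuracy_class, "good")

  s <- random_samples(25, seed = 8)
  cv <- cross_validate(s, "v", variogram_model("spherical", 0.5, 1.5, 60))
  expect_length(cv$residuals, 25)
  expect_true(cv$r2 >= 0 && cv$r2 <= 1)
})

test_that("kriged surfaces on long-range fields cross-validate well", {
  vg <- variogram_model("spherical", 0, 1, 113.16)
  cfg <- field_config(25, 20, 14.2,
                      list(property_spec("S", "mg/kg", 19, 29.42, vg,
                                         log_scale = TRUE)), seed = 5)
  f <- generate_field(cfg)
  sel <- select_variogram(f, "S", families = "spherical")
  expect_identical(sel$record$dependence, "strong")
  expect_gt(sel$cv$r2, 0.5)
})
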