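test_that("grid locations have the promised geometry", {
  expect_equal(make_grid_locations(1, 1, 14.2),
               cbind(x = 0, y = 0))
  g <- make_grid_locations(2, 2, 10)
  expect_equal(nrow(g), 4)
  expect_equal(min(dist(g)), 10)
  g2 <- make_grid_locations(20, 10, 14.2)
  expect_equal(nrow(g2), 200)
  expect_equal(max(g2[, "x"]), 269.8)
  expect_equal(max(g2[, "y"]), 127.8)
  # row-major: x varies fastest
  expect_equal(g2[2, ], c(x = 14.2, y = 0))
  expect_error(make_grid_locations(0, 5, 14.2), ">= 1")
  expect_error(make_grid_locations(2, 2, 0), "spacing")
})

test_that("field generation is deterministic and validates the config", {
  cfg <- telangana_maize_config(grid_nx = 5, grid_ny = 4, seed = 7)
  f1 <- generate_field(cfg)
  f2 <- generate_field(cfg)
  expect_identical(f1, f2)
  f3 <- generate_field(telangana_maize_config(grid_nx = 5, grid_ny = 4, seed = 8))
  expect_false(identical(f1$values, f3$values))

  vg <- variogram_model("spherical", 0, 1, 40)
  p1 <- property_spec("a", "", 10, 20, vg)
  expect_error(field_config(3, 3, 14.2, list(p1), cross_correlation = diag(2)),
               "one row per property")
  bad <- matrix(c(1, 0.5, 0.7, 1), 2)
  expect_error(field_config(3, 3, 14.2, list(p1, p1), cross_correlation = bad),
               "symmetric")
})

test_that("zero-sill variograms yield constant fields at the target mean", {
  vg0 <- variogram_model("spherical", 0, 0, 40)
  # zero partial sill with zero nugget => sill 0
  vg0$sill <- 0
  props <- list(property_spec("flat", "", 7.5, 0, vg0),
                property_spec("logflat", "", 3.2, 0, vg0, log_scale = TRUE))
  f <- generate_field(field_config(4, 4, 10, props, seed = 1))
  expect_true(all(f$values[, "flat"] == 7.5))
  expect_true(all(f$values[, "logflat"] == 3.2))
})

test_that("marginal means and CVs track their targets at n >= 1000", {
  vg <- variogram_model("spherical", 0, 1, 40)
  props <- list(
    property_spec("lin", "kg/ha", 111, 19.55, vg, log_scale = FALSE),
    property_spec("lgn", "mg/kg", 3.4, 44.12, vg, log_scale = TRUE))
  cfg <- field_config(32, 32, 14.2, props, seed = 1)
  fac <- field_factors(cfg)
  stats <- sapply(1:5, function(s) {
    cfg$seed <- s
    d <- describe(generate_field(cfg, fac))
    c(d$mean, d$cv_percent)
  })
  avg <- rowMeans(stats)
  expect_lt(abs(avg[1] / 111 - 1), 0.02)
  expect_lt(abs(avg[2] / 3.4 - 1), 0.02)
  expect_lt(abs(avg[3] / 19.55 - 1), 0.15)
  expect_lt(abs(avg[4] / 44.12 - 1), 0.15)
})

test_that("simulated fields reproduce the configured spatial structure", {
  # spherical, nugget 0, partial sill 1, range 40: near-sill semivariance
  # beyond the range, well below it at short lags (averaged over seeds)
  # 5 m spacing so the first lag bin (0, 10] is populated; the target sd is
  # mean * cv / 100 = 1, so the value-scale semivariance is the latent one
  vg <- variogram_model("spherical", 0, 1, 40)
  cfg <- field_config(50, 40, 5, list(property_spec("z", "", 10, 10, vg)),
                      seed = 1)
  fac <- field_factors(cfg)
  g60 <- g10 <- numeric(20)
  for (s in 1:20) {
    cfg$seed <- s
    f <- generate_field(cfg, fac)
    emp <- empirical_semivariogram(f, "z", lag_width = 10, max_distance = 80)
    g60[s] <- emp$semivariances[6]
    g10[s] <- emp$semivariances[1]
  }
  expect_lt(abs(mean(g60) - 1), 0.15)
  expect_lt(mean(g10), 0.5)
})

test_that("cross-correlated properties reach their target correlation", {
  vg <- variogram_model("spherical", 0, 1, 40)
  props <- list(property_spec("a", "", 10, 25, vg),
                property_spec("b", "", 5, 25, vg))
  R <- matrix(c(1, 0.9, 0.9, 1), 2)
  cfg <- field_config(50, 40, 14.2, props, cross_correlation = R, seed = 2)
  f <- generate_field(cfg)
  r <- cor(f$values[, "a"], f$values[, "b"])
  expect_gt(r, 0.8)
  expect_lt(r, 0.97)
})

test_that("strong anticorrelation survives log-normal marginals", {
  # Zn-like vs OC-like marginals (log-normal, very different CVs) built on a
  # common spatial structure with latent target -0.95; the observed-scale
  # estimate attenuates only through the log transform
  vg <- variogram_model("spherical", 0, 1, 40)
  props <- list(property_spec("OC", "g/kg", 3.7, 1.89, vg, log_scale = TRUE),
                property_spec("Zn", "mg/kg", 3.4, 44.12, vg, log_scale = TRUE))
  R <- matrix(c(1, -0.95, -0.95, 1), 2)
  cfg <- field_config(50, 40, 14.2, props, cross_correlation = R, seed = 4)
  f <- generate_field(cfg)
  r <- correlation_matrix(f)$r["Zn", "OC"]
  expect_gt(r, -0.99)
  expect_lt(r, -0.85)
})

test_that("a slightly indefinite correlation target is repaired, not rejected", {
  # three mutually high correlations that are jointly infeasible
  R <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  vg <- variogram_model("spherical", 0, 1, 40)
  props <- lapply(c("a", "b", "c"), function(nm) property_spec(nm, "", 10, 20, vg))
  cfg <- field_config(4, 4, 10, props, cross_correlation = R, seed = 1)
  ev <- eigen(cfg$cross_correlation, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), 0)
  expect_equal(diag(cfg$cross_correlation), rep(1, 3))
  expect_no_error(generate_field(cfg))
})
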