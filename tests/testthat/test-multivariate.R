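test_that("descriptive statistics match textbook arithmetic", {
  s <- random_samples(5, seed = 1, values = c(1, 2, 3, 4, 5))
  d <- describe(s)
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2.5), tolerance = 1e-12)
  expect_equal(round(d$sd, 4), 1.5811)
  expect_equal(d$skewness, 0)
  expect_equal(d$range, 4)
  expect_equal(d$cv_percent, 100 * sqrt(2.5) / 3)

  # constant column: zero sd and cv, undefined shape statistics
  sc <- random_samples(6, seed = 2, values = rep(4, 6))
  dc <- describe(sc)
  expect_equal(dc$sd, 0)
  expect_equal(dc$cv_percent, 0)
  expect_true(is.na(dc$skewness) && is.na(dc$kurtosis))
})

test_that("describe matches the reference implementation on random input", {
  set.seed(42)
  for (i in 1:3) {
    v <- rlnorm(50, 2, 0.6)
    d <- describe(random_samples(50, seed = i, values = v))
    expect_equal(d$skewness, e1071::skewness(v, type = 2), tolerance = 1e-12)
    expect_equal(d$kurtosis, e1071::kurtosis(v, type = 2), tolerance = 1e-12)
    expect_equal(d$sd, sd(v))
    expect_equal(d$cv_percent, 100 * sd(v) / mean(v))
  }
})

test_that("correlation matrix carries r, p and significance stars", {
  v <- cbind(a = c(1, 2, 3), b = c(3, 2, 1), c = c(2, 1, 3))
  s <- sample_set(paste0("s", 1:3), c(0, 10, 20), c(0, 0, 0), v)
  cm <- correlation_matrix(s)
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r["a", "b"], -1)
  expect_true(all(abs(cm$r) <= 1 + 1e-12, na.rm = TRUE))
  expect_equal(cm$r, t(cm$r))

  set.seed(1)
  v2 <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("p", "q")))
  v2[, 2] <- 0.9 * v2[, 1] + 0.3 * v2[, 2]
  s2 <- sample_set(paste0("s", 1:40), runif(40, 0, 100), runif(40, 0, 100), v2)
  cm2 <- correlation_matrix(s2)
  ct <- cor.test(v2[, 1], v2[, 2])
  expect_equal(cm2$r["p", "q"], unname(ct$estimate), tolerance = 1e-12)
  expect_equal(cm2$p["p", "q"], ct$p.value, tolerance = 1e-12)
  expect_identical(cm2$stars["p", "q"], "**")

  # constant column: correlations undefined, marked missing
  v3 <- cbind(a = rnorm(10), k = rep(2, 10))
  s3 <- sample_set(paste0("s", 1:10), 1:10, rep(0, 10), v3)
  expect_true(all(is.na(correlation_matrix(s3)$r[, "k"])))
})

test_that("covariance PCA conserves variance and reconstructs the data", {
  set.seed(3)
  X <- matrix(rnorm(200), 40, 5)
  X[, 2] <- 2 * X[, 1] + 0.5 * X[, 2]
  colnames(X) <- paste0("v", 1:5)
  p <- soil_pca(X)
  expect_equal(sum(p$eigenvalues), sum(diag(cov(X))), tolerance = 1e-8)
  expect_equal(sum(p$variance_percent), 100, tolerance = 1e-6)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # eigenvector columns orthonormal
  expect_equal(crossprod(p$eigenvectors), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # full reconstruction
  rec <- p$scores %*% t(p$eigenvectors) + rep(1, 40) %o% p$center
  expect_equal(rec, X, tolerance = 1e-8, ignore_attr = TRUE)
  # agreement with prcomp up to sign
  pr <- prcomp(X)
  expect_equal(p$eigenvalues, unname(pr$sdev^2), tolerance = 1e-10)
  expect_equal(abs(p$scores), abs(pr$x), tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("loadings are property-score correlations and communalities add up", {
  set.seed(4)
  X <- matrix(rnorm(300), 60, 5)
  X[, 2] <- X[, 1] + 0.2 * X[, 2]
  colnames(X) <- paste0("v", 1:5)
  p <- soil_pca(X)
  for (j in 1:5) for (k in 1:5) {
    expect_equal(p$loadings[j, k], cor(X[, j], p$scores[, k]),
                 tolerance = 1e-8)
  }
  expect_equal(p$communalities,
               rowSums(p$loadings[, seq_len(p$n_retained), drop = FALSE]^2))
  expect_true(all(abs(p$loadings) <= 1 + 1e-8))
})

test_that("eigenvalue retention follows the threshold rule", {
  # build data whose sample covariance is exactly diag(3, 1.5, 1.0, 0.4)
  set.seed(5)
  X <- matrix(rnorm(160), 40, 4)
  X <- scale(X, center = TRUE, scale = FALSE)
  W <- chol(cov(X))
  X <- X %*% solve(W) %*% diag(sqrt(c(3, 1.5, 1.0, 0.4)))
  colnames(X) <- paste0("v", 1:4)
  p <- soil_pca(X)
  expect_equal(p$eigenvalues, c(3, 1.5, 1.0, 0.4), tolerance = 1e-8)
  expect_identical(p$n_retained, 3L)  # threshold is inclusive at 1.0

  # two independent unit-variance properties: isotropic spectrum
  X2 <- matrix(rnorm(80), 40, 2)
  X2 <- scale(X2, center = TRUE, scale = FALSE)
  X2 <- X2 %*% solve(chol(cov(X2)))
  colnames(X2) <- c("a", "b")
  p2 <- soil_pca(X2)
  expect_equal(p2$eigenvalues, c(1, 1), tolerance = 1e-8)
  expect_equal(p2$variance_percent, c(50, 50), tolerance = 1e-6)

  # all eigenvalues below threshold: PC1 kept with a warning
  expect_warning(p3 <- soil_pca(0.1 * X2), "PC1")
  expect_identical(p3$n_retained, 1L)
})

test_that("a dominant latent factor concentrates variance on PC1", {
  set.seed(6)
  f <- rnorm(300)
  X <- cbind(a = 0.95 * f + 0.1 * rnorm(300),
             b = 0.95 * f + 0.1 * rnorm(300),
             c = 0.95 * f + 0.1 * rnorm(300))
  p <- soil_pca(X)
  expect_gt(p$variance_percent[1], 80)
})

test_that("select_components standardizes retained scores by default", {
  set.seed(7)
  X <- matrix(rnorm(500), 100, 5) %*% diag(c(30, 10, 3, 1.5, 0.5))
  colnames(X) <- paste0("v", 1:5)
  p <- soil_pca(X)
  S <- select_components(p)
  expect_equal(ncol(S), p$n_retained)
  expect_true(all(abs(colMeans(S)) < 1e-10))
  expect_equal(apply(S, 2, sd), rep(1, ncol(S)), ignore_attr = TRUE)
  raw <- select_components(p, standardize = FALSE)
  expect_equal(raw, p$scores[, seq_len(p$n_retained)], ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(apply(raw, 2, sd), rep(1, ncol(raw)))))
})
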