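# fixtures and independent oracles, built in code

# scattered sample set with one property
random_samples <- function(n, seed = 1, extent = 100, name = "v",
                           values = NULL) {
  set.seed(seed)
  repeat {
    x <- runif(n, 0, extent)
    y <- runif(n, 0, extent)
    if (min(dist(cbind(x, y))) > 1e-6) break
  }
  v <- if (is.null(values)) rnorm(n, 10, 2) else values
  sample_set(paste0("s", seq_len(n)), x, y,
             matrix(v, ncol = 1, dimnames = list(NULL, name)))
}

# brute-force empirical semivariogram: explicit loop over all unordered pairs
brute_semivariogram <- function(x, y, z, lag_width, max_distance) {
  nbin <- ceiling(max_distance / lag_width)
  ssq <- cnt <- dsum <- numeric(nbin)
  n <- length(z)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
    if (d > 0 && d <= max_distance) {
      k <- ceiling(d / lag_width)
      ssq[k] <- ssq[k] + (z[i] - z[j])^2
      cnt[k] <- cnt[k] + 1
      dsum[k] <- dsum[k] + d
    }
  }
  list(gamma = ifelse(cnt > 0, ssq / (2 * cnt), NA_real_), n = cnt,
       centers = ifelse(cnt > 0, dsum / pmax(cnt, 1), NA_real_))
}

# independent straight-line fuzzy C-means (Bezdek alternating updates),
# deliberately written loop-by-loop, no shared code with the package
brute_fcm <- function(X, u0, m, max_iter, tol) {
  u <- u0
  cc <- nrow(u); n <- nrow(X); p <- ncol(X)
  for (it in seq_len(max_iter)) {
    ctr <- matrix(0, cc, p)
    for (i in seq_len(cc)) {
      wsum <- 0
      for (k in seq_len(n)) {
        w <- u[i, k]^m
        ctr[i, ] <- ctr[i, ] + w * X[k, ]
        wsum <- wsum + w
      }
      ctr[i, ] <- ctr[i, ] / wsum
    }
    u_new <- matrix(0, cc, n)
    for (k in seq_len(n)) {
      d2 <- sapply(seq_len(cc), function(i) sum((X[k, ] - ctr[i, ])^2))
      if (any(d2 == 0)) {
        u_new[d2 == 0, k] <- 1 / sum(d2 == 0)
      } else {
        for (i in seq_len(cc)) {
          u_new[i, k] <- 1 / sum((d2[i] / d2)^(1 / (m - 1)))
        }
      }
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  ctr <- matrix(0, cc, p)
  for (i in seq_len(cc)) {
    w <- u[i, ]^m
    ctr[i, ] <- colSums(w * X) / sum(w)
  }
  d2 <- matrix(0, cc, n)
  for (i in seq_len(cc)) for (k in seq_len(n)) {
    d2[i, k] <- sum((X[k, ] - ctr[i, ])^2)
  }
  list(membership = u, centroids = ctr, objective = sum(u^m * d2))
}

# planted Gaussian blobs: k clusters of n_per points in 2-D at >= sep apart
make_blobs <- function(k, n_per, sep = 8, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- cbind(sep * seq_len(k), sep * (seq_len(k) %% 2))
  X <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  stot <- comb2(sum(tab))
  expected <- si * sj / stot
  (sij - expected) / ((si + sj) / 2 - expected)
}

# zoned field: 3 spatial bands with shifted nutrient means, equal pH mean
make_zoned_field <- function(seed = 1, n_per = 30, shift = c(0, 25, 50)) {
  set.seed(seed)
  n <- 3 * n_per
  x <- runif(n, 0, 300)
  y <- runif(n, 0, 100)
  zone <- rep(1:3, each = n_per)
  vals <- cbind(
    pH = rnorm(n, 8, 0.1),
    N = rnorm(n, 100 + shift[zone], 5),
    P2O5 = rnorm(n, 90 + 0.5 * shift[zone], 4),
    K2O = rnorm(n, 400 + 2 * shift[zone], 15))
  list(samples = sample_set(paste0("s", 1:n), x, y, vals), zone = zone)
}
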