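#' Descriptive statistics per soil property
#'
#' Min, max, range, mean, sample SD (n−1), CV in percent, adjusted
#' Fisher–Pearson skewness and excess kurtosis for every property. Skewness
#' and kurtosis are \code{NA} for constant columns (and CV is 0).
#'
#' @param samples a \code{\link{sample_set}}.
#' @return A data.frame, one row per property.
#' @export
describe <- function(samples) {
  if (n_samples(samples) < 2) stop("need at least 2 samples")
  out <- do.call(rbind, lapply(samples$property_names, function(p) {
    v <- samples$values[, p]
    n <- length(v)
    m <- mean(v)
    s <- stats::sd(v)
    if (s > 0) {
      g1 <- sum(((v - m) / sqrt(sum((v - m)^2) / n))^3) / n
      skew <- g1 * sqrt(n * (n - 1)) / (n - 2)  # adjusted Fisher-Pearson G1
      m4 <- sum((v - m)^4) / n
      m2 <- sum((v - m)^2) / n
      kurt <- (n - 1) / ((n - 2) * (n - 3)) *
        ((n + 1) * (m4 / m2^2 - 3) + 6)
    } else {
      skew <- NA_real_
      kurt <- NA_real_
    }
    data.frame(property = p, min = min(v), max = max(v),
               range = max(v) - min(v), mean = m, sd = s,
               cv_percent = if (m != 0) 100 * s / m else NA_real_,
               skewness = skew, kurtosis = kurt)
  }))
  if (any(vapply(seq_along(samples$property_names), function(j)
    stats::sd(samples$values[, j]) == 0, logical(1)))) {
    out$cv_percent[out$sd == 0] <- 0
  }
  rownames(out) <- NULL
  out
}

#' Pearson correlation matrix with significance stars
#'
#' Pairwise Pearson correlations among properties with two-sided p-values;
#' stars mark significance at 0.05 (*) and 0.01 (**). Pairs involving a
#' constant column are \code{NA}.
#'
#' @param samples a \code{\link{sample_set}}.
#' @return A list with \code{r} (correlation matrix), \code{p} (p-values),
#'   \code{stars} (character matrix).
#' @export
correlation_matrix <- function(samples) {
  n <- n_samples(samples)
  if (n < 3) stop("need at least 3 samples")
  X <- samples$values
  p <- ncol(X)
  const <- apply(X, 2, stats::sd) == 0
  r <- suppressWarnings(stats::cor(X))
  r[const, ] <- NA
  r[, const] <- NA
  diag(r)[!const] <- 1
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pv <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  diag(pv) <- 0
  stars <- matrix("", p, p, dimnames = dimnames(r))
  stars[!is.na(pv) & pv < 0.05] <- "*"
  stars[!is.na(pv) & pv < 0.01] <- "**"
  diag(stars) <- ""
  list(r = r, p = pv, stars = stars)
}

#' Principal component analysis of soil properties
#'
#' Eigendecomposition of the covariance matrix (the default basis) or the
#' correlation matrix of the mean-centred property data. Loadings are
#' reported as correlations between properties and component scores
#' (eigenvector times the square root of the eigenvalue, scaled by the
#' property standard deviation), bounded by 1 in magnitude. Communality of a
#' property is the sum of its squared loadings over the retained components.
#' Components with eigenvalue at or above \code{threshold} are retained; if
#' none qualifies, the first component is retained with a warning.
#'
#' Eigenvector signs are fixed so that each component's largest-magnitude
#' loading is positive, for reproducibility across platforms.
#'
#' @param samples a \code{\link{sample_set}}, or a plain numeric matrix.
#' @param basis \code{"covariance"} (default) or \code{"correlation"}.
#' @param threshold eigenvalue retention threshold (default 1).
#' @return An object of class \code{pca_result}: \code{eigenvalues},
#'   \code{eigenvectors}, \code{loadings}, \code{scores},
#'   \code{variance_percent}, \code{communalities}, \code{n_retained},
#'   \code{center}, \code{basis}.
#' @export
soil_pca <- function(samples, basis = c("covariance", "correlation"),
                     threshold = 1) {
  basis <- match.arg(basis)
  X <- if (inherits(samples, "sample_set")) samples$values else as.matrix(samples)
  n <- nrow(X)
  p <- ncol(X)
  if (n < p + 1) stop("need at least n_properties + 1 samples")
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  S <- stats::cov(X)
  sds <- sqrt(diag(S))
  M <- if (basis == "correlation") stats::cov2cor(S) else S
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (any(e$values < -1e-8 * max(lam))) {
    warning("rank-deficient input: negative eigenvalues clipped to zero")
  }
  V <- e$vectors
  # sign convention: largest-|entry| of each eigenvector positive
  for (k in seq_len(p)) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  scale_in <- if (basis == "correlation") sds else rep(1, p)
  scores <- sweep(Xc, 2, scale_in, "/") %*% V
  load_sd <- if (basis == "correlation") rep(1, p) else sds
  loadings <- sweep(V, 2, sqrt(lam), "*") / load_sd
  n_ret <- sum(lam >= threshold)
  if (n_ret == 0) {
    warning("no eigenvalue reaches the retention threshold; keeping PC1 only")
    n_ret <- 1L
  }
  comm <- rowSums(loadings[, seq_len(n_ret), drop = FALSE]^2)
  dimnames(V) <- dimnames(loadings) <-
    list(colnames(X), paste0("PC", seq_len(p)))
  colnames(scores) <- paste0("PC", seq_len(p))
  names(comm) <- colnames(X)
  structure(
    list(eigenvalues = lam, eigenvectors = V, loadings = loadings,
         scores = scores, variance_percent = 100 * lam / sum(lam),
         communalities = comm, n_retained = n_ret, center = ctr,
         scale = scale_in, basis = basis, threshold = threshold),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> basis:", x$basis, "-", x$n_retained,
      "component(s) retained (eigenvalue >=", x$threshold, ")\n")
  tab <- rbind(eigenvalue = x$eigenvalues,
               `variance %` = x$variance_percent)
  colnames(tab) <- paste0("PC", seq_along(x$eigenvalues))
  print(round(tab[, seq_len(min(6, ncol(tab))), drop = FALSE], 3))
  invisible(x)
}

#' Retained-component score matrix for clustering
#'
#' Restricts the PCA scores to the retained components and (by default)
#' standardizes each retained column to zero mean and unit variance.
#' Covariance-basis scores can differ by orders of magnitude across
#' components, which would otherwise let PC1 dominate the Euclidean metric
#' of the fuzzy clustering entirely.
#'
#' @param result a \code{\link{soil_pca}} result.
#' @param standardize logical; disable to keep raw score scales.
#' @return Numeric matrix [samples × retained components].
#' @export
select_components <- function(result, standardize = TRUE) {
  if (!inherits(result, "pca_result")) stop("expected a pca_result")
  S <- result$scores[, seq_len(result$n_retained), drop = FALSE]
  if (standardize) {
    sds <- apply(S, 2, stats::sd)
    sds[sds == 0] <- 1
    S <- sweep(sweep(S, 2, colMeans(S)), 2, sds, "/")
  }
  S
}
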