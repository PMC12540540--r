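#' Fuzzy C-means configuration
#'
#' Defaults follow the Management Zone Analyst parameterization used for
#' soil-fertility zoning: fuzziness exponent 1.5, convergence threshold 1e-4
#' on the maximum membership change, at most 300 iterations, Euclidean
#' distance, clusters swept from 3 to 8. Restarts (best objective kept) add
#' robustness to the random simplex initialization.
#'
#' @param c number of clusters (>= 2).
#' @param m fuzziness exponent (> 1).
#' @param max_iter maximum iterations per run.
#' @param tol convergence threshold on max |u change|.
#' @param n_restarts random restarts, best objective kept.
#' @param seed integer seed; restart r uses \code{seed + r - 1}.
#' @return A list of class \code{fcm_config}.
#' @export
fcm_config <- function(c = 3L, m = 1.5, max_iter = 300L, tol = 1e-4,
                       n_restarts = 10L, seed = 1L) {
  if (c < 2) stop("c must be >= 2")
  if (m <= 1) stop("fuzziness exponent m must be > 1")
  if (tol <= 0) stop("tol must be > 0")
  structure(list(c = as.integer(c), m = m, max_iter = as.integer(max_iter),
                 tol = tol, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed)),
            class = "fcm_config")
}

# one alternating-optimization run from a given initial membership (c x n)
fcm_run <- function(X, u, m, max_iter, tol) {
  n <- nrow(X)
  cc <- nrow(u)
  obj <- Inf
  obj_trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  repeat {
    iter <- iter + 1L
    um <- u^m
    centroids <- (um %*% X) / rowSums(um)
    # squared Euclidean distances cluster x sample
    d2 <- outer(rowSums(centroids^2), rep(1, n)) -
      2 * centroids %*% t(X) + outer(rep(1, cc), rowSums(X^2))
    d2 <- pmax(d2, 0)
    u_new <- matrix(0, cc, n)
    zero <- colSums(d2 < 1e-300) > 0
    if (any(zero)) {
      for (k in which(zero)) {
        z <- d2[, k] < 1e-300
        u_new[z, k] <- 1 / sum(z)
      }
    }
    if (any(!zero)) {
      w <- d2[, !zero, drop = FALSE]^(-1 / (m - 1))
      u_new[, !zero] <- sweep(w, 2, colSums(w), "/")
    }
    obj <- sum(u_new^m * d2)
    obj_trace <- c(obj_trace, obj)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
  }
  um <- u^m
  centroids <- (um %*% X) / rowSums(um)
  list(membership = u, centroids = centroids, objective = obj,
       objective_trace = obj_trace, iterations = iter, converged = converged)
}

#' Fuzzy C-means clustering
#'
#' Standard alternating optimization: memberships
#' \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{jk})^{2/(m-1)}} and centroids
#' \eqn{c_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m}, iterated until the
#' maximum membership change falls below the tolerance. A sample coinciding
#' with a centroid receives membership 1 for that cluster. The best of
#' \code{n_restarts} seeded runs (lowest objective) is returned, with FPI
#' and NCE attached.
#'
#' @param data numeric matrix [samples × features].
#' @param config an \code{\link{fcm_config}} (its \code{c} is used unless
#'   \code{c} is given).
#' @param c optional cluster-count override.
#' @return An object of class \code{fcm_result}: \code{membership}
#'   (clusters × samples), \code{centroids}, \code{objective},
#'   \code{iterations}, \code{converged}, \code{fpi}, \code{nce}.
#' @export
fcm <- function(data, config = fcm_config(), c = NULL) {
  X <- as.matrix(data)
  if (!all(is.finite(X))) stop("data contains non-finite values")
  cc <- if (is.null(c)) config$c else as.integer(c)
  n <- nrow(X)
  if (cc >= n) stop("need more samples than clusters (c = ", cc, ", n = ", n, ")")
  if (cc < 2) stop("c must be >= 2")
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    u0 <- with_seed(config$seed + r - 1L, {
      g <- matrix(stats::rexp(cc * n), cc, n)  # uniform on the simplex
      sweep(g, 2, colSums(g), "/")
    })
    run <- fcm_run(X, u0, config$m, config$max_iter, config$tol)
    if (is.null(best) || run$objective < best$objective) best <- run
  }
  res <- structure(c(best, list(c = cc, m = config$m, n = n)),
                   class = "fcm_result")
  res$fpi <- fpi(res)
  res$nce <- if (n > cc) nce(res) else NA_real_
  res
}

#' @export
print.fcm_result <- function(x, ...) {
  cat(sprintf("<fcm_result> c = %d, m = %.2f: objective %.4g after %d iteration(s)%s\n",
              x$c, x$m, x$objective, x$iterations,
              if (x$converged) "" else " (not converged)"))
  cat(sprintf("  FPI %.4f, NCE %.4f\n", x$fpi, x$nce))
  invisible(x)
}

#' Fuzzy performance index
#'
#' \eqn{FPI = \frac{C}{C-1}(1 - F)} with partition coefficient
#' \eqn{F = \frac{1}{n}\sum_k\sum_i u_{ik}^2}: 0 for a crisp partition, 1
#' for maximally fuzzy (uniform) memberships; minimized over candidate
#' cluster counts. \code{convention = "as_printed"} gives the complementary
#' form \eqn{1 - \frac{C}{C-1}(1 - F)} occasionally seen in print, which
#' reverses the scale (1 = crisp).
#'
#' @param result an \code{\link{fcm}} result (or any list with a
#'   \code{membership} matrix clusters × samples).
#' @param convention \code{"fridgen"} (default) or \code{"as_printed"}.
#' @return FPI in [0, 1].
#' @export
fpi <- function(result, convention = c("fridgen", "as_printed")) {
  convention <- match.arg(convention)
  u <- result$membership
  cc <- nrow(u)
  if (cc < 2) stop("FPI undefined for a single cluster")
  f <- sum(u^2) / ncol(u)
  val <- cc / (cc - 1) * (1 - f)
  if (convention == "as_printed") 1 - val else val
}

#' Normalized classification entropy
#'
#' \eqn{NCE = \frac{n}{n-C} H} with partition entropy
#' \eqn{H = -\frac{1}{n}\sum_k\sum_i u_{ik}\ln u_{ik}} (natural logarithm,
#' \eqn{0\ln 0 := 0}): 0 for a crisp partition, \eqn{\frac{n}{n-C}\ln C}
#' for uniform memberships; minimized over candidate cluster counts.
#'
#' @param result an \code{\link{fcm}} result.
#' @return NCE >= 0.
#' @export
nce <- function(result) {
  u <- result$membership
  cc <- nrow(u)
  n <- ncol(u)
  if (n <= cc) stop("NCE undefined for n <= C")
  h <- -sum(ifelse(u > 0, u * log(u), 0)) / n
  n / (n - cc) * h
}

#' Sweep the cluster count and pick the optimum by validity indices
#'
#' Runs fuzzy C-means for every cluster count in \code{[c_min, c_max]} and
#' records FPI, NCE and the objective. The optimum minimizes FPI; when the
#' NCE minimizer differs, the smaller of the two counts is preferred
#' (parsimony) and a warning notes the disagreement.
#'
#' @param data numeric matrix [samples × features].
#' @param c_min,c_max sweep bounds (defaults 3 and 8).
#' @param config an \code{\link{fcm_config}} (its \code{c} is ignored).
#' @return An object of class \code{sweep_table}: data.frame \code{table}
#'   (c, fpi, nce, objective), \code{optimal_c}, \code{results} (per-c
#'   \code{fcm_result}s).
#' @export
sweep_clusters <- function(data, c_min = 3L, c_max = 8L, config = fcm_config()) {
  if (c_min > c_max) stop("c_min must be <= c_max")
  if (c_max >= nrow(as.matrix(data))) stop("c_max must be below the sample count")
  cs <- seq.int(c_min, c_max)
  results <- lapply(cs, function(cc) fcm(data, config, c = cc))
  tab <- data.frame(
    c = cs,
    fpi = vapply(results, `[[`, numeric(1), "fpi"),
    nce = vapply(results, `[[`, numeric(1), "nce"),
    objective = vapply(results, `[[`, numeric(1), "objective"))
  c_fpi <- cs[which.min(tab$fpi)]
  c_nce <- cs[which.min(tab$nce)]
  if (c_fpi != c_nce) {
    warning("FPI (c = ", c_fpi, ") and NCE (c = ", c_nce,
            ") disagree; choosing the smaller count")
  }
  optimal <- min(c_fpi, c_nce)
  structure(list(table = tab, optimal_c = optimal,
                 fpi_argmin = c_fpi, nce_argmin = c_nce,
                 results = stats::setNames(results, paste0("c", cs))),
            class = "sweep_table")
}

#' @export
print.sweep_table <- function(x, ...) {
  print(transform(x$table, fpi = round(fpi, 4), nce = round(nce, 4),
                  objective = signif(objective, 5)))
  cat("optimal c =", x$optimal_c, "\n")
  invisible(x)
}

#' @export
plot.sweep_table <- function(x, ...) {
  graphics::matplot(x$table$c, cbind(x$table$fpi, x$table$nce), type = "b",
                    pch = c(1, 2), lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "number of clusters", ylab = "index value", ...)
  graphics::legend("topleft", c("FPI", "NCE"), pch = c(1, 2),
                   col = c("steelblue", "firebrick"), bty = "n")
  graphics::abline(v = x$optimal_c, lty = 3)
  invisible(x)
}

#' Crisp management zones from fuzzy memberships
#'
#' Assigns each sample to its maximum-membership cluster and renumbers
#' zones by decreasing area (sample) fraction, so MZ 1 is always the
#' largest. Exact membership ties go to the lowest original cluster index;
#' the number of ties is recorded.
#'
#' @param result an \code{\link{fcm}} result.
#' @param samples optional \code{\link{sample_set}} whose ids/coordinates
#'   are attached to the zone map.
#' @return An object of class \code{zone_map}: \code{labels} (1-based zone
#'   per sample), \code{area_fraction}, \code{n_zones}, \code{max_membership},
#'   \code{ties}, and optionally \code{ids}, \code{x}, \code{y}.
#' @export
defuzzify <- function(result, samples = NULL) {
  u <- result$membership
  raw <- apply(u, 2, which.max)          # ties -> lowest cluster index
  ties <- sum(apply(u, 2, function(col) sum(col == max(col)) > 1))
  counts <- tabulate(raw, nbins = nrow(u))
  ord <- order(counts, decreasing = TRUE)
  renum <- integer(nrow(u))
  renum[ord] <- seq_along(ord)
  labels <- renum[raw]
  counts <- tabulate(labels, nbins = nrow(u))
  keep <- counts > 0
  out <- list(labels = labels,
              area_fraction = counts[keep] / length(labels),
              n_zones = sum(keep),
              max_membership = apply(u, 2, max),
              cluster_order = ord, ties = ties)
  if (!is.null(samples)) {
    out$ids <- samples$ids
    out$x <- samples$x
    out$y <- samples$y
  }
  structure(out, class = "zone_map")
}

#' @export
print.zone_map <- function(x, ...) {
  cat("<zone_map>", x$n_zones, "zones; area fractions:",
      paste(sprintf("MZ-%d %.1f%%", seq_len(x$n_zones),
                    100 * x$area_fraction), collapse = ", "), "\n")
  if (x$ties) cat("  ", x$ties, "membership tie(s) broken by cluster index\n")
  invisible(x)
}

#' @export
as.data.frame.zone_map <- function(x, ...) {
  df <- data.frame(zone = x$labels, max_membership = x$max_membership)
  if (!is.null(x$ids)) df <- cbind(data.frame(id = x$ids, x = x$x, y = x$y), df)
  df
}
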