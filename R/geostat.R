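#' Theoretical semivariogram model
#'
#' Isotropic variogram with nugget, partial sill and range. The range
#' parameter is the \emph{effective} range for all three families: the
#' exponential and Gaussian forms use \eqn{1 - e^{-3h/a}} and
#' \eqn{1 - e^{-3h^2/a^2}}, reaching 95\% of the sill at \eqn{h = a}, the
#' convention of applied soil-science reports.
#'
#' @param family \code{"spherical"}, \code{"exponential"} or \code{"gaussian"}.
#' @param nugget non-negative nugget variance.
#' @param partial_sill non-negative structured variance (sill − nugget).
#' @param range_param effective range in metres, > 0.
#' @return An object of class \code{variogram_model}.
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget, partial_sill, range_param) {
  family <- match.arg(family)
  if (nugget < 0 || partial_sill < 0) stop("nugget and partial_sill must be >= 0")
  if (range_param <= 0) stop("range_param must be > 0")
  structure(
    list(family = family, nugget = nugget, partial_sill = partial_sill,
         range_param = range_param, sill = nugget + partial_sill),
    class = "variogram_model")
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("<variogram_model> %s: nugget %.4g, partial sill %.4g, range %.4g m\n",
              x$family, x$nugget, x$partial_sill, x$range_param))
  if (x$sill > 0) {
    cat(sprintf("  nugget/sill %.2f%% (%s spatial dependence)\n",
                100 * x$nugget / x$sill, classify_dependence(x)))
  }
  invisible(x)
}

#' Evaluate a variogram model at lag h
#'
#' \eqn{\gamma(0)} is defined as the nugget (the discontinuity at the origin
#' is carried by the nugget term); for the spherical model the sill is
#' reached exactly at the range.
#'
#' @param model a \code{\link{variogram_model}}.
#' @param h vector of non-negative lag distances (m).
#' @return Semivariance at each lag.
#' @export
model_value <- function(model, h) {
  if (any(h < 0)) stop("lag distances must be >= 0")
  a <- model$range_param
  ps <- model$partial_sill
  g <- switch(model$family,
    spherical = ifelse(h >= a, ps, ps * (1.5 * h / a - 0.5 * (h / a)^3)),
    exponential = ps * (1 - exp(-3 * h / a)),
    gaussian = ps * (1 - exp(-3 * h^2 / a^2)))
  model$nugget + g
}

#' Empirical (experimental) semivariogram
#'
#' Omnidirectional method-of-moments estimator: for each lag bin,
#' \eqn{\hat\gamma(h) = \frac{1}{2N(h)}\sum (Z(x_i) - Z(x_i+h))^2} over all
#' unordered pairs whose separation distance falls in the bin. Bins are
#' \code{(k-1, k] * lag_width}; empty bins carry \code{NA}.
#'
#' @param samples a \code{\link{sample_set}}. Log-flagged properties should be
#'   transformed with \code{\link{apply_transform}} before calling.
#' @param property property name.
#' @param lag_width bin width in metres.
#' @param max_distance maximum pair separation considered; defaults to half
#'   the maximum inter-point distance.
#' @return An object of class \code{empirical_variogram} with fields
#'   \code{lag_centers}, \code{semivariances}, \code{pair_counts}.
#' @export
empirical_semivariogram <- function(samples, property, lag_width = NULL,
                                    max_distance = NULL) {
  z <- property_values(samples, property)
  n <- n_samples(samples)
  if (n < 2) stop("need at least 2 samples")
  d <- stats::dist(cbind(samples$x, samples$y))
  if (is.null(max_distance)) max_distance <- max(d) / 2
  if (is.null(lag_width)) lag_width <- max_distance / 15
  if (lag_width <= 0) stop("lag_width must be > 0")
  if (max_distance < lag_width) stop("max_distance must be >= lag_width")
  dz2 <- stats::dist(z)^2
  keep <- d <= max_distance & d > 0
  bin <- ceiling(d[keep] / lag_width)
  nbin <- ceiling(max_distance / lag_width)
  counts <- tabulate(bin, nbins = nbin)
  ssq <- vapply(seq_len(nbin), function(k) sum(dz2[keep][bin == k]), numeric(1))
  dsum <- vapply(seq_len(nbin), function(k) sum(d[keep][bin == k]), numeric(1))
  gamma <- ifelse(counts > 0, ssq / (2 * counts), NA_real_)
  # lag centers are the mean pair distance per bin (nominal centre when
  # empty): on gridded samples the first bins are populated only near their
  # upper edge, and nominal centres would bias the fitted nugget upward
  centers <- ifelse(counts > 0, dsum / pmax(counts, 1),
                    (seq_len(nbin) - 0.5) * lag_width)
  structure(
    list(lag_centers = centers,
         semivariances = gamma, pair_counts = counts,
         lag_width = lag_width, max_distance = max_distance,
         property = property),
    class = "empirical_variogram")
}

#' @export
print.empirical_variogram <- function(x, ...) {
  cat("<empirical_variogram>", x$property, "-", sum(x$pair_counts), "pairs in",
      sum(x$pair_counts > 0), "non-empty lags up to", round(x$max_distance, 1), "m\n")
  invisible(x)
}

#' @export
plot.empirical_variogram <- function(x, model = NULL, ...) {
  ok <- x$pair_counts > 0
  graphics::plot(x$lag_centers[ok], x$semivariances[ok],
                 xlab = "lag distance (m)", ylab = "semivariance",
                 main = x$property, ...)
  if (!is.null(model)) {
    h <- seq(0, x$max_distance, length.out = 200)
    graphics::lines(h, model_value(model, h), col = "steelblue")
  }
  invisible(x)
}

# deterministic multistart grid for WLS variogram fitting
fit_starts <- function(emp) {
  ok <- which(emp$pair_counts > 0)
  g <- emp$semivariances[ok]
  h <- emp$lag_centers[ok]
  s <- max(g)
  hmax <- max(h)
  list(c(0, s, 0.3 * hmax),
       c(0, s, 0.7 * hmax),
       c(0.5 * min(g), s, 0.5 * hmax),
       c(0.1 * s, 0.9 * s, 1.2 * hmax),
       c(0, mean(g), 0.15 * hmax))
}

#' Fit a theoretical variogram model by weighted least squares
#'
#' Minimizes \eqn{\sum_h w_h (\hat\gamma(h) - \gamma(h;\theta))^2} over
#' nugget, partial sill and range, with \eqn{w_h = N(h)} by default.
#' Bound-constrained (nugget, partial sill ≥ 0; range in (0, 2·max_distance])
#' L-BFGS-B from five deterministic starting points; the best solution wins.
#'
#' @param emp an \code{\link{empirical_semivariogram}} result.
#' @param family model family to fit.
#' @param weights \code{"npairs"} (default) or \code{"uniform"}.
#' @return A \code{\link{variogram_model}} with attribute \code{"wss"}
#'   (attained weighted sum of squares).
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential", "gaussian"),
                          weights = c("npairs", "uniform")) {
  family <- match.arg(family)
  weights <- match.arg(weights)
  ok <- which(emp$pair_counts > 0 & !is.na(emp$semivariances))
  if (length(ok) < 3) stop("need at least 3 non-empty lag bins")
  h <- emp$lag_centers[ok]
  g <- emp$semivariances[ok]
  w <- if (weights == "npairs") emp$pair_counts[ok] else rep(1, length(ok))
  if (all(g == 0)) {
    warning("degenerate flat variogram; returning zero-variance model")
    m <- variogram_model(family, 0, 0, emp$max_distance)
    attr(m, "wss") <- 0
    return(m)
  }
  obj <- function(par) {
    m <- model_value(variogram_model(family, par[1], par[2], par[3]), h)
    sum(w * (g - m)^2)
  }
  lower <- c(0, 0, emp$lag_width * 1e-3)
  upper <- c(Inf, Inf, 2 * emp$max_distance)
  # parameter scaling: sills and the range live on very different scales,
  # and unscaled finite-difference gradients stall the optimizer
  pscale <- c(max(g), max(g), max(h))
  best <- NULL
  for (p0 in fit_starts(emp)) {
    p0 <- pmin(pmax(p0, lower + 1e-12), upper)
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 1000, factr = 10, parscale = pscale,
                                  ndeps = rep(1e-6, 3))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) stop("variogram fit failed for all starting points")
  # parsimony: when a pure-nugget model fits (weighted) as well as the best
  # structured fit -- e.g. a flat empirical variogram, where nugget/partial
  # sill/range lie on an equivalent-fit ridge -- prefer pure nugget
  pn <- c(sum(w * g) / sum(w), 0, emp$max_distance)
  if (obj(pn) <= best$value * (1 + 1e-9) + 1e-12 * sum(w * g^2)) {
    best <- list(par = pn, value = obj(pn))
  }
  m <- variogram_model(family, best$par[1], best$par[2], best$par[3])
  attr(m, "wss") <- best$value
  m
}

#' Cambardella spatial-dependence class
#'
#' Nugget-to-sill ratio below 0.25 indicates strong spatial dependence,
#' 0.25–0.75 (bounds inclusive) moderate, above 0.75 weak.
#'
#' @param model a \code{\link{variogram_model}} with positive sill.
#' @return \code{"strong"}, \code{"moderate"} or \code{"weak"}.
#' @export
classify_dependence <- function(model) {
  if (model$sill <= 0) stop("spatial dependence undefined for zero sill")
  r <- model$nugget / model$sill
  if (r < 0.25) "strong" else if (r <= 0.75) "moderate" else "weak"
}

#' Interpolation accuracy class from nRMSE
#'
#' Below 20\% good, 20–30\% (inclusive) fair, above 30\% poor.
#'
#' @param nrmse_percent non-negative nRMSE in percent.
#' @return \code{"good"}, \code{"fair"} or \code{"poor"}.
#' @export
classify_accuracy <- function(nrmse_percent) {
  if (nrmse_percent < 0) stop("nRMSE must be >= 0")
  if (nrmse_percent < 20) "good" else if (nrmse_percent <= 30) "fair" else "poor"
}

# Solve the ordinary-kriging system for a set of targets sharing the same
# neighbourhood. Gamma diagonal is 0 (gamma(0) = 0 at coincident points; the
# nugget discontinuity applies only for h > 0), which makes kriging an exact
# interpolator at the data locations.
ok_solve <- function(coords, z, model, targets, jitter = 1e-10) {
  n <- nrow(coords)
  D <- as.matrix(stats::dist(coords))
  G <- model_value(model, D)
  diag(G) <- 0
  A <- rbind(cbind(G, 1), c(rep(1, n), 0))
  diag(A)[1:n] <- diag(A)[1:n] + jitter
  dt <- sqrt(outer(targets[, 1], coords[, 1], "-")^2 +
             outer(targets[, 2], coords[, 2], "-")^2)
  g0 <- model_value(model, dt)
  g0[dt == 0] <- 0
  B <- rbind(t(g0), 1)
  sol <- tryCatch(solve(A, B), error = function(e) {
    stop("singular kriging system (", conditionMessage(e), ")")
  })
  W <- sol[1:n, , drop = FALSE]
  mu <- sol[n + 1, ]
  pred <- drop(crossprod(W, z))
  kvar <- colSums(W * t(g0)) + mu
  list(pred = pred, var = kvar, weights = W, lagrange = mu)
}

#' Ordinary kriging prediction
#'
#' Best linear unbiased prediction at target locations from a fitted
#' variogram. With up to \code{max_global} samples the full ordinary-kriging
#' system is solved once for all targets; beyond that, each target is
#' predicted from its \code{k} nearest neighbours.
#'
#' @param samples a \code{\link{sample_set}} (transform applied if needed).
#' @param property property name.
#' @param model a fitted \code{\link{variogram_model}}.
#' @param targets either a two-column matrix of target coordinates or a
#'   \code{grid} list as returned by \code{\link{prediction_grid}}.
#' @param k neighbourhood size used when \code{n > max_global}.
#' @param max_global sample count up to which all samples are used for every
#'   target (default 300).
#' @return If \code{targets} is a grid, a \code{kriged_surface}; otherwise a
#'   list with \code{predictions}, \code{kriging_variance}, \code{weights}.
#' @export
ordinary_kriging <- function(samples, property, model, targets,
                             k = 32, max_global = 300) {
  z <- property_values(samples, property)
  coords <- cbind(samples$x, samples$y)
  n <- nrow(coords)
  if (n < 2) stop("need at least 2 samples")
  grid <- NULL
  if (is.list(targets) && !is.null(targets$nx)) {
    grid <- targets
    targets <- grid_coords(grid)
  }
  targets <- matrix(as.numeric(targets), ncol = 2)
  if (n <= max_global) {
    res <- ok_solve(coords, z, model, targets)
    pred <- res$pred
    kvar <- res$var
    weights <- res$weights
  } else {
    pred <- kvar <- numeric(nrow(targets))
    weights <- NULL
    for (i in seq_len(nrow(targets))) {
      d <- (coords[, 1] - targets[i, 1])^2 + (coords[, 2] - targets[i, 2])^2
      nb <- order(d)[seq_len(min(k, n))]
      res <- tryCatch(
        ok_solve(coords[nb, , drop = FALSE], z[nb], model,
                 targets[i, , drop = FALSE]),
        error = function(e) stop("kriging failed at target ", i, ": ",
                                 conditionMessage(e)))
      pred[i] <- res$pred
      kvar[i] <- res$var
    }
  }
  kvar <- pmax(kvar, 0)  # clip tiny negative round-off (tolerance -1e-9 tested)
  if (!is.null(grid)) {
    structure(
      list(origin = grid$origin, spacing = grid$spacing,
           nx = grid$nx, ny = grid$ny,
           predictions = matrix(pred, nrow = grid$ny, ncol = grid$nx, byrow = TRUE),
           kriging_variance = matrix(kvar, nrow = grid$ny, ncol = grid$nx, byrow = TRUE),
           property_name = property, back_transformed = FALSE),
      class = "kriged_surface")
  } else {
    list(predictions = pred, kriging_variance = kvar, weights = weights)
  }
}

#' Regular prediction grid over a sample bounding box
#'
#' @param samples a \code{\link{sample_set}}.
#' @param cellsize cell size in metres (default 5).
#' @return A grid description list (\code{origin}, \code{spacing},
#'   \code{nx}, \code{ny}); origin is the lower-left cell centre.
#' @export
prediction_grid <- function(samples, cellsize = 5) {
  x0 <- min(samples$x); x1 <- max(samples$x)
  y0 <- min(samples$y); y1 <- max(samples$y)
  list(origin = c(x0, y0), spacing = cellsize,
       nx = max(1L, ceiling((x1 - x0) / cellsize) + 1L),
       ny = max(1L, ceiling((y1 - y0) / cellsize) + 1L))
}

# row-major, north-to-south ordering matching the raster writer:
# first row of coords is the northernmost grid row
grid_coords <- function(grid) {
  xs <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$spacing
  ys <- grid$origin[2] + (rev(seq_len(grid$ny)) - 1) * grid$spacing
  cbind(rep(xs, times = grid$ny), rep(ys, each = grid$nx))
}

#' Leave-one-out cross-validation of a kriging model
#'
#' Each sample is predicted by ordinary kriging from all remaining samples;
#' nRMSE = 100·RMSE/mean(observed) and R² is the squared Pearson correlation
#' between observed and predicted values. For log-flagged properties the
#' metrics refer to the (transformed) scale on which kriging was performed.
#'
#' @param samples a \code{\link{sample_set}} (transform applied if needed).
#' @param property property name.
#' @param model a fitted \code{\link{variogram_model}}.
#' @param k,max_global neighbourhood rule, as in
#'   \code{\link{ordinary_kriging}}: all remaining samples predict the
#'   held-out one up to \code{max_global} samples, the \code{k} nearest
#'   beyond that.
#' @return An object of class \code{cross_validation} with
#'   \code{nrmse_percent}, \code{r2}, \code{accuracy_class},
#'   \code{residuals} (observed − predicted).
#' @export
cross_validate <- function(samples, property, model, k = 32, max_global = 300) {
  z <- property_values(samples, property)
  coords <- cbind(samples$x, samples$y)
  n <- length(z)
  if (n < 3) stop("need at least 3 samples")
  if (abs(mean(z)) < .Machine$double.eps) stop("nRMSE undefined: zero observed mean")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    keep <- if (n - 1 <= max_global) seq_len(n)[-i] else {
      d <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2
      d[i] <- Inf
      order(d)[seq_len(k)]
    }
    res <- ok_solve(coords[keep, , drop = FALSE], z[keep], model,
                    coords[i, , drop = FALSE])
    pred[i] <- res$pred
  }
  cv_metrics(z, pred)
}

# LOOCV summary metrics; |mean|: on the log scale the observed mean can be
# negative (values < 1)
cv_metrics <- function(observed, predicted) {
  rmse <- sqrt(mean((observed - predicted)^2))
  nrmse <- 100 * rmse / abs(mean(observed))
  r2 <- if (stats::sd(predicted) == 0) 0 else stats::cor(observed, predicted)^2
  structure(
    list(nrmse_percent = nrmse, r2 = r2,
         accuracy_class = classify_accuracy(nrmse),
         residuals = observed - predicted, predicted = predicted,
         observed = observed),
    class = "cross_validation")
}

#' @export
print.cross_validation <- function(x, ...) {
  cat(sprintf("<cross_validation> nRMSE %.2f%% (%s), R^2 %.3f\n",
              x$nrmse_percent, x$accuracy_class, x$r2))
  invisible(x)
}

#' Fit and cross-validate all candidate variogram families for one property
#'
#' Applies the property's log transform if flagged, estimates the empirical
#' semivariogram, fits each candidate family, and selects the family with the
#' lowest LOOCV nRMSE (ties broken by higher R²) — the model-selection rule
#' used for soil-property interpolation.
#'
#' @param samples a \code{\link{sample_set}} (raw scale).
#' @param property property name.
#' @param families candidate families.
#' @param lag_width,max_distance passed to
#'   \code{\link{empirical_semivariogram}}.
#' @return A list: \code{model} (best \code{variogram_model}), \code{cv}
#'   (its \code{cross_validation}), \code{transformation}, \code{empirical},
#'   \code{candidates} (per-family fit + cv), and a Table-2-style
#'   \code{record} list (transformation, model, nugget, partial sill, sill,
#'   nugget/sill \%, range m, dependence class, nRMSE, R²).
#' @export
select_variogram <- function(samples, property,
                             families = c("spherical", "exponential", "gaussian"),
                             lag_width = NULL, max_distance = NULL) {
  trans <- samples$transforms[[property]]
  s <- if (trans == "log") apply_transform(samples, property, "forward") else samples
  emp <- empirical_semivariogram(s, property, lag_width, max_distance)
  cand <- lapply(families, function(f) {
    m <- fit_variogram(emp, f)
    list(family = f, model = m, cv = cross_validate(s, property, m))
  })
  names(cand) <- families
  nr <- vapply(cand, function(cc) cc$cv$nrmse_percent, numeric(1))
  r2 <- vapply(cand, function(cc) cc$cv$r2, numeric(1))
  best <- cand[[order(nr, -r2)[1]]]
  m <- best$model
  record <- list(
    property = property, transformation = trans, model = best$family,
    nugget = m$nugget, partial_sill = m$partial_sill, sill = m$sill,
    nugget_sill_percent = if (m$sill > 0) 100 * m$nugget / m$sill else NA_real_,
    range_m = m$range_param,
    dependence = if (m$sill > 0) classify_dependence(m) else NA_character_,
    nrmse_percent = best$cv$nrmse_percent, r2 = best$cv$r2,
    accuracy_class = best$cv$accuracy_class,
    cv_scale = if (trans == "log") "log" else "original")
  list(model = m, cv = best$cv, transformation = trans, empirical = emp,
       candidates = cand, record = record)
}
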