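#' Regular sampling-grid locations
#'
#' Planar grid of sample points in row-major order (x varies fastest),
#' starting at the origin. Minimum inter-point distance equals the spacing.
#'
#' @param nx,ny positive grid dimensions.
#' @param spacing grid spacing in metres (default 14.2, a common soil-survey
#'   grid interval yielding roughly 200 points over 4 ha at 20 x 10).
#' @return A two-column matrix of (x, y) coordinates, nx·ny rows.
#' @export
make_grid_locations <- function(nx, ny, spacing = 14.2) {
  if (nx < 1 || ny < 1) stop("grid dimensions must be >= 1")
  if (spacing <= 0) stop("spacing must be > 0")
  cbind(x = rep((seq_len(nx) - 1) * spacing, times = ny),
        y = rep((seq_len(ny) - 1) * spacing, each = nx))
}

#' Marginal + spatial specification of one synthetic soil property
#'
#' @param name property name.
#' @param units unit label.
#' @param mean target marginal mean (on the observation scale).
#' @param cv_percent target coefficient of variation in percent.
#' @param variogram a \code{\link{variogram_model}} on the standardized
#'   latent scale (the sill is the latent variance; the marginal is rescaled
#'   to \code{mean}/\code{cv_percent} afterwards).
#' @param log_scale logical; if \code{TRUE} the observed marginal is the
#'   exponential of the latent Gaussian field (log-normal marginal).
#' @return An object of class \code{property_spec}.
#' @export
property_spec <- function(name, units, mean, cv_percent, variogram,
                          log_scale = FALSE) {
  if (cv_percent < 0) stop("cv_percent must be >= 0")
  if (log_scale && mean <= 0) stop("log-scale properties need a positive mean")
  if (!inherits(variogram, "variogram_model")) stop("variogram must be a variogram_model")
  structure(list(name = name, units = units, mean = mean,
                 cv_percent = cv_percent, variogram = variogram,
                 log_scale = log_scale),
            class = "property_spec")
}

#' Synthetic field configuration
#'
#' @param grid_nx,grid_ny sample-grid dimensions (product >= 4).
#' @param spacing grid spacing in metres.
#' @param properties list of \code{\link{property_spec}}.
#' @param cross_correlation target Pearson correlation matrix among the
#'   latent fields; symmetric, unit diagonal, one row per property. Repaired
#'   to the nearest correlation matrix if slightly non-positive-semidefinite.
#' @param seed integer RNG seed.
#' @return An object of class \code{field_config}.
#' @export
field_config <- function(grid_nx, grid_ny, spacing = 14.2, properties,
                         cross_correlation = NULL, seed = 1L) {
  if (grid_nx * grid_ny < 4) stop("need at least 4 grid points")
  if (spacing <= 0) stop("spacing must be > 0")
  p <- length(properties)
  if (!p) stop("need at least one property_spec")
  if (is.null(cross_correlation)) cross_correlation <- diag(p)
  cross_correlation <- as.matrix(cross_correlation)
  if (!isTRUE(all.equal(dim(cross_correlation), c(p, p)))) {
    stop("cross_correlation must be ", p, " x ", p,
         " (one row per property)")
  }
  if (max(abs(cross_correlation - t(cross_correlation))) > 1e-8) {
    stop("cross_correlation must be symmetric")
  }
  if (max(abs(diag(cross_correlation) - 1)) > 1e-8) {
    stop("cross_correlation must have unit diagonal")
  }
  cross_correlation <- nearest_correlation(cross_correlation)
  structure(list(grid_nx = as.integer(grid_nx), grid_ny = as.integer(grid_ny),
                 spacing = spacing, properties = properties,
                 cross_correlation = cross_correlation, seed = as.integer(seed)),
            class = "field_config")
}

# Eigenvalue-clipped nearest correlation matrix (one-step Higham-style
# projection: clip eigenvalues at a small floor, rescale to unit diagonal).
nearest_correlation <- function(R, floor = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= 0) return(R)
  v <- pmax(e$values, floor)
  A <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(A))
  A <- A / tcrossprod(d)
  diag(A) <- 1
  (A + t(A)) / 2
}

# evaluate and restore the global RNG state around seeded simulation
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Symmetric (eigen) square root of the spatial correlation among locations
# implied by the structured part of a unit-sill variogram:
# rho(h) = 1 - gamma_s(h)/ps. The symmetric root, unlike a Cholesky factor,
# carries no ordering artifacts, which keeps cross-property correlations
# (induced through shared innovations) close to their targets even when two
# properties' spatial structures differ.
structured_root <- function(vg, D, jitter = 1e-10) {
  ps <- vg$partial_sill
  struct <- variogram_model(vg$family, 0, ps, vg$range_param)
  C <- (ps - model_value(struct, D)) / ps
  diag(C) <- diag(C) + jitter
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < -1e-6) {
    stop("latent covariance not positive semidefinite after jitter (min eigenvalue ",
         format(min(e$values)), ")")
  }
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Precompute the spatial factors of a field configuration
#'
#' The square-root factorization of each property's latent spatial
#' correlation matrix depends only on the configuration (grid and
#' variograms), not on the seed. Precomputing it once and passing it to
#' \code{\link{generate_field}} makes repeated simulation under different
#' seeds cheap.
#'
#' @param config a \code{\link{field_config}}.
#' @return An opaque list of per-property factors.
#' @export
field_factors <- function(config) {
  coords <- make_grid_locations(config$grid_nx, config$grid_ny, config$spacing)
  D <- as.matrix(stats::dist(coords))
  lapply(config$properties, function(sp) {
    vg <- sp$variogram
    if (vg$sill <= 0 || vg$partial_sill <= 0) NULL
    else structured_root(vg, D)
  })
}

#' Simulate a spatially autocorrelated multi-property soil field
#'
#' Latent unit-variance Gaussian random fields are drawn per property with
#' covariance \eqn{C(h) = sill - \gamma(h)} of the configured variogram
#' (second-order stationarity), the nugget realized as independent noise per
#' location. Cross-property correlation is induced by mixing a shared set of
#' independent Gaussian innovation factors through a Cholesky factor of the
#' target correlation matrix before each property's spatial factor is
#' applied; each property therefore keeps its own variogram exactly, while
#' cross-correlations are attenuated slightly when two properties' spatial
#' structures differ. Marginals are set by population-parameter rescaling:
#' linear for ordinary properties, exact log-normal moment matching
#' (\eqn{\sigma^2 = \ln(1 + cv^2)}, \eqn{\mu = \ln(mean) - \sigma^2/2}) for
#' log-scale ones. A zero-sill variogram yields a constant field at the
#' target mean. Identical configurations and seeds give identical output.
#'
#' @param config a \code{\link{field_config}}.
#' @param factors optional precomputed \code{\link{field_factors}(config)}.
#' @return A \code{\link{sample_set}} with ids \code{S0001, S0002, ...}.
#' @export
generate_field <- function(config, factors = NULL) {
  coords <- make_grid_locations(config$grid_nx, config$grid_ny, config$spacing)
  n <- nrow(coords)
  p <- length(config$properties)
  if (is.null(factors)) factors <- field_factors(config)
  U <- chol(config$cross_correlation + diag(1e-10, p))
  vals <- with_seed(config$seed, {
    E <- matrix(stats::rnorm(n * p), n, p)       # shared innovation factors
    W <- E %*% U                                 # cross-correlated innovations
    out <- matrix(0, n, p)
    for (j in seq_len(p)) {
      sp <- config$properties[[j]]
      vg <- sp$variogram
      if (vg$sill <= 0) {
        out[, j] <- sp$mean
        next
      }
      z <- if (vg$partial_sill > 0) {
        g <- factors[[j]] %*% W[, j]
        if (vg$nugget > 0) {
          sqrt(vg$partial_sill / vg$sill) * g +
            sqrt(vg$nugget / vg$sill) * stats::rnorm(n)
        } else g
      } else {
        stats::rnorm(n)                          # pure nugget
      }
      out[, j] <- if (sp$log_scale) {
        s2 <- log(1 + (sp$cv_percent / 100)^2)
        exp(log(sp$mean) - s2 / 2 + sqrt(s2) * z)
      } else {
        sp$mean + sp$mean * sp$cv_percent / 100 * z
      }
    }
    out
  })
  colnames(vals) <- vapply(config$properties, `[[`, "", "name")
  sample_set(sprintf("S%04d", seq_len(n)), coords[, 1], coords[, 2], vals,
             units = vapply(config$properties, `[[`, "", "units"),
             transforms = ifelse(
               vapply(config$properties, `[[`, TRUE, "log_scale"),
               "log", "none"))
}

#' Preset: a paper-like Telangana maize field
#'
#' Encodes the study conditions of a 4-ha maize field sampled on a
#' 14.2 m grid (default 20 x 10 = 200 points): per-property marginal means
#' and CVs, variogram families, effective ranges and nugget/sill fractions
#' of the eleven measured soil fertility attributes (pH, EC, organic carbon,
#' available N/P2O5/K2O/S, DTPA Fe/Mn/Zn/Cu), log-normal marginals where the
#' field data were log-transformed, and the strongly collinear inter-property
#' correlation structure with Zn anti-correlated to the fertility block.
#'
#' @param grid_nx,grid_ny sample-grid dimensions.
#' @param spacing grid spacing in metres.
#' @param seed RNG seed.
#' @return A \code{\link{field_config}}.
#' @export
telangana_maize_config <- function(grid_nx = 20, grid_ny = 10,
                                   spacing = 14.2, seed = 42L) {
  # name, units, mean, cv%, family, nugget fraction, range m, log?
  tab <- list(
    list("pH",   "",            7.99, 2.88,  "spherical",   0,      49.79,  TRUE),
    list("EC",   "dS/m",        0.14, 19.05, "exponential", 0,      32.25,  TRUE),
    list("OC",   "g/kg",        3.70, 1.89,  "exponential", 0,      70.59,  TRUE),
    list("N",    "kg/ha",       111,  19.55, "spherical",   0,      38.95,  FALSE),
    list("P2O5", "kg/ha",       108,  14.51, "spherical",   0,      42.01,  TRUE),
    list("K2O",  "kg/ha",       420,  12.74, "spherical",   0,      40.07,  TRUE),
    list("S",    "mg/kg",       19,   29.42, "spherical",   0,      113.16, TRUE),
    list("Fe",   "mg/kg",       11.1, 44.14, "spherical",   0,      44.04,  FALSE),
    list("Mn",   "mg/kg",       7.1,  46.48, "spherical",   0,      55.23,  TRUE),
    list("Zn",   "mg/kg",       3.4,  44.12, "gaussian",    0.0661, 40.45,  TRUE),
    list("Cu",   "mg/kg",       4.7,  40.43, "gaussian",    0,      31.35,  TRUE))
  props <- lapply(tab, function(r) {
    property_spec(r[[1]], r[[2]], r[[3]], r[[4]],
                  variogram_model(r[[5]], nugget = r[[6]],
                                  partial_sill = 1 - r[[6]],
                                  range_param = r[[7]]),
                  log_scale = r[[8]])
  })
  field_config(grid_nx, grid_ny, spacing, props,
               cross_correlation = telangana_correlation(), seed = seed)
}

# The field's Pearson correlation structure: a near-collinear fertility
# block (EC, OC, N, P, K, Fe, Mn, Cu), weakly coupled pH and S, and Zn
# anti-correlated with the block.
telangana_correlation <- function() {
  p <- c("pH", "EC", "OC", "N", "P2O5", "K2O", "S", "Fe", "Mn", "Zn", "Cu")
  lower <- list(
    EC   = c(0.25),
    OC   = c(0.18, 0.81),
    N    = c(0.24, 0.95, 0.85),
    P2O5 = c(0.14, 0.89, 0.90, 0.90),
    K2O  = c(0.10, 0.88, 0.86, 0.88, 0.93),
    S    = c(0.07, 0.26, 0.48, 0.35, 0.42, 0.26),
    Fe   = c(0.17, 0.83, 0.92, 0.86, 0.94, 0.90, 0.51),
    Mn   = c(0.16, 0.87, 0.92, 0.90, 0.95, 0.94, 0.45, 0.96),
    Zn   = c(-0.15, -0.84, -0.95, -0.88, -0.96, -0.91, -0.52, -0.96, -0.96),
    Cu   = c(0.12, 0.88, 0.85, 0.89, 0.95, 0.92, 0.42, 0.92, 0.94, -0.90))
  R <- diag(length(p))
  dimnames(R) <- list(p, p)
  for (i in 2:length(p)) {
    R[i, 1:(i - 1)] <- lower[[p[i]]]
    R[1:(i - 1), i] <- lower[[p[i]]]
  }
  R
}
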