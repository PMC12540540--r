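#' Write a kriged surface as a raster file
#'
#' The mandatory interchange format is the ESRI ASCII grid
#' (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value header followed by
#' row-major data, north to south). GeoTIFF is not supported by this build
#' and raises an error.
#'
#' @param surface a \code{kriged_surface}.
#' @param path output path.
#' @param format \code{"ascii_grid"} (default) or \code{"geotiff"}.
#' @param layer \code{"predictions"} (default) or \code{"kriging_variance"}.
#' @param nodata NODATA sentinel (default -9999).
#' @return \code{path}, invisibly.
#' @export
write_raster <- function(surface, path, format = c("ascii_grid", "geotiff"),
                         layer = c("predictions", "kriging_variance"),
                         nodata = -9999) {
  format <- match.arg(format)
  layer <- match.arg(layer)
  if (format == "geotiff") {
    stop("GeoTIFF output is not supported; use format = 'ascii_grid'")
  }
  M <- surface[[layer]]
  M[!is.finite(M)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  # origin is the lower-left cell centre -> llcorner = centre - cellsize/2
  writeLines(c(
    paste("ncols", surface$nx),
    paste("nrows", surface$ny),
    paste("xllcorner", format(surface$origin[1] - surface$spacing / 2, digits = 12)),
    paste("yllcorner", format(surface$origin[2] - surface$spacing / 2, digits = 12)),
    paste("cellsize", format(surface$spacing, digits = 12)),
    paste("NODATA_value", nodata)), con)
  utils::write.table(format(M, digits = 8, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid written by \code{\link{write_raster}}
#'
#' @param path file path.
#' @return A \code{kriged_surface}-compatible list (predictions only;
#'   NODATA cells become \code{NA}).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  nx <- as.integer(vals["ncols"])
  ny <- as.integer(vals["nrows"])
  M <- matrix(scan(text = lines[-(1:6)], quiet = TRUE), nrow = ny,
              ncol = nx, byrow = TRUE)
  M[M == vals["nodata_value"]] <- NA
  structure(
    list(origin = c(vals["xllcorner"] + vals["cellsize"] / 2,
                    vals["yllcorner"] + vals["cellsize"] / 2),
         spacing = unname(vals["cellsize"]), nx = nx, ny = ny,
         predictions = M, kriging_variance = NULL,
         property_name = NA_character_, back_transformed = NA),
    class = "kriged_surface")
}

#' Pipeline configuration
#'
#' Exactly one of \code{input} (a sample CSV path) or \code{simulate} (a
#' \code{\link{field_config}}) must be supplied.
#'
#' @param input path to a sample-set CSV, or \code{NULL}.
#' @param simulate a \code{\link{field_config}}, or \code{NULL}.
#' @param out_dir output directory (\code{NULL} = write nothing).
#' @param seed master seed for the stochastic stages (clustering restarts).
#' @param cellsize kriging grid cell size (m).
#' @param krige logical; compute prediction surfaces (LOOCV always runs).
#' @param pca_basis,pca_threshold,standardize_scores PCA stage options.
#' @param c_min,c_max,fuzziness,n_restarts zoning stage options.
#' @param alpha ANOVA significance level.
#' @param target_yield target yield (q/ha) for the fertilizer plan.
#' @param reference_practice reference dose triple (N, P2O5, K2O kg/ha).
#' @param grain_price grain price (currency/kg) for economics; \code{NULL}
#'   skips the economics stage.
#' @param zone_yields,zone_costs optional per-zone grain yields (kg/ha) and
#'   cultivation costs (currency/ha) for economics (recycled if length 1).
#' @param lognormal_correction back-transform log-kriged surfaces with the
#'   kriging-variance bias correction.
#' @param verbose print stage progress.
#' @return A list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL, out_dir = NULL,
                            seed = 1L, cellsize = 5,
                            krige = TRUE,
                            pca_basis = "covariance", pca_threshold = 1,
                            standardize_scores = TRUE,
                            c_min = 3L, c_max = 8L, fuzziness = 1.5,
                            n_restarts = 10L, alpha = 0.01,
                            target_yield = 65,
                            reference_practice = c(240, 80, 80),
                            grain_price = NULL, zone_yields = NULL,
                            zone_costs = NULL,
                            lognormal_correction = FALSE,
                            verbose = TRUE) {
  if (is.null(input) == is.null(simulate)) {
    stop("exactly one of 'input' or 'simulate' must be given")
  }
  if (!is.null(input) && !file.exists(input)) stop("input not found: ", input)
  if (c_min > c_max) stop("c_min must be <= c_max")
  structure(as.list(environment()), class = "pipeline_config")
}

pipe_log <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(...)

#' Run the full management-zone delineation pipeline
#'
#' Stages, in order: load or simulate the sample set; descriptive statistics
#' and Pearson correlations; per-property variogram selection (log transform
#' where flagged, family chosen by LOOCV nRMSE) with spatial-dependence
#' classification and, optionally, ordinary-kriging surfaces; covariance PCA
#' with eigenvalue retention; fuzzy C-means cluster sweep with FPI/NCE
#' selection and crisp zone assignment; one-way ANOVA zone validation and
#' the CV-reduction ledger; targeted-yield fertilizer plan and (if a grain
#' price is given) per-zone economics. When \code{out_dir} is set, every
#' stage artifact is written (CSV/JSON/ASCII grids) together with a run
#' manifest.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @return A result bundle (list) with elements \code{samples},
#'   \code{descriptives}, \code{correlations}, \code{variograms} (per-property
#'   records), \code{surfaces}, \code{pca}, \code{sweep}, \code{fcm},
#'   \code{zones}, \code{anova}, \code{reduction}, \code{plan},
#'   \code{economics}, \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- "load"
  res <- list()
  withCallingHandlers({
    samples <- if (!is.null(config$input)) {
      pipe_log(config, "loading samples from ", config$input)
      read_samples(config$input)
    } else {
      pipe_log(config, "simulating field (seed ", config$simulate$seed, ")")
      generate_field(config$simulate)
    }
    res$samples <- samples

    stage <- "descriptives"
    res$descriptives <- describe(samples)
    res$correlations <- correlation_matrix(samples)

    stage <- "geostatistics"
    grid <- prediction_grid(samples, config$cellsize)
    res$variograms <- list()
    res$surfaces <- list()
    for (p in samples$property_names) {
      sel <- select_variogram(samples, p)
      res$variograms[[p]] <- sel
      pipe_log(config, sprintf(
        "  %s: %s model, range %.1f m, %s dependence, nRMSE %.2f%% (%s)",
        p, sel$record$model, sel$record$range_m, sel$record$dependence,
        sel$record$nrmse_percent, sel$record$accuracy_class))
      if (isTRUE(config$krige)) {
        s <- if (sel$transformation == "log")
          apply_transform(samples, p, "forward") else samples
        surf <- ordinary_kriging(s, p, sel$model, grid)
        if (sel$transformation == "log") {
          surf <- apply_transform(surf, direction = "back",
                                  lognormal_correction = config$lognormal_correction)
        }
        res$surfaces[[p]] <- surf
      }
    }

    stage <- "pca"
    res$pca <- soil_pca(samples, basis = config$pca_basis,
                        threshold = config$pca_threshold)
    pipe_log(config, "  PCA retained ", res$pca$n_retained,
             " component(s) explaining ",
             round(sum(res$pca$variance_percent[seq_len(res$pca$n_retained)]), 2),
             "% of variance")
    scores <- select_components(res$pca, standardize = config$standardize_scores)

    stage <- "zoning"
    fc <- fcm_config(m = config$fuzziness, n_restarts = config$n_restarts,
                     seed = config$seed)
    res$sweep <- sweep_clusters(scores, config$c_min, config$c_max, fc)
    pipe_log(config, "  optimal cluster count: ", res$sweep$optimal_c)
    res$fcm <- res$sweep$results[[paste0("c", res$sweep$optimal_c)]]
    res$zones <- defuzzify(res$fcm, samples)
    pipe_log(config, "  zone area fractions: ",
             paste(round(100 * res$zones$area_fraction, 1), collapse = "/"), "%")

    stage <- "validation"
    res$anova <- zone_anova(samples, res$zones, alpha = config$alpha)
    res$reduction <- variability_reduction(samples, res$zones)

    stage <- "recommendation"
    nutrients <- intersect(c("N", "P2O5", "K2O"), samples$property_names)
    if (length(nutrients) == 3) {
      res$plan <- zone_plan(res$anova, config$target_yield,
                            config$reference_practice)
      if (!is.null(config$grain_price) && !is.null(config$zone_yields)) {
        ny <- res$zones$n_zones
        yields <- rep_len(config$zone_yields, ny)
        costs <- rep_len(config$zone_costs %||% stop("zone_costs required"), ny)
        res$economics <- do.call(rbind, lapply(seq_len(ny), function(z) {
          ec <- crop_economics(yields[z], config$grain_price, costs[z])
          data.frame(zone = paste0("MZ-", z), as.data.frame(ec))
        }))
      }
    } else {
      pipe_log(config, "  N/P2O5/K2O not all present; skipping fertilizer plan")
    }

    stage <- "outputs"
    res$manifest <- pipeline_manifest(config, res)
    if (!is.null(config$out_dir)) write_bundle(res, config)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(res) <- "pipeline_result"
  res
}

pipeline_manifest <- function(config, res) {
  list(
    package_version = as.character(utils::packageVersion("agrizone")),
    seed = config$seed,
    input = config$input %||% "simulated",
    simulate_seed = if (!is.null(config$simulate)) config$simulate$seed,
    n_samples = n_samples(res$samples),
    properties = res$samples$property_names,
    pca = list(basis = config$pca_basis, threshold = config$pca_threshold,
               n_retained = res$pca$n_retained,
               standardized_scores = config$standardize_scores),
    zoning = list(c_min = config$c_min, c_max = config$c_max,
                  fuzziness = config$fuzziness,
                  n_restarts = config$n_restarts,
                  optimal_c = res$sweep$optimal_c,
                  fpi_argmin = res$sweep$fpi_argmin,
                  nce_argmin = res$sweep$nce_argmin,
                  membership_ties = res$zones$ties),
    decisions = list(
      nrmse = "100*RMSE/mean(observed), LOOCV on the transformed scale",
      r2 = "squared Pearson correlation of observed vs predicted",
      fpi_convention = "C/(C-1)*(1-F), 0 = crisp",
      nce_convention = "non-negative entropy form, 0*ln0 = 0",
      moderate_class = "[0.25, 0.75] inclusive",
      fair_class = "[20, 30] inclusive",
      zone_avg_cv = "unweighted mean of per-zone CVs"))
}

write_bundle <- function(res, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  write_samples(res$samples, out("samples.csv"))
  utils::write.csv(res$descriptives, out("descriptives.csv"), row.names = FALSE)
  utils::write.csv(res$correlations$r, out("correlations.csv"))
  jsonlite::write_json(lapply(res$variograms, `[[`, "record"),
                       out("variograms.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  for (p in names(res$surfaces)) {
    write_raster(res$surfaces[[p]], out(paste0("krige_", p, ".asc")))
  }
  jsonlite::write_json(
    list(eigenvalues = res$pca$eigenvalues,
         variance_percent = res$pca$variance_percent,
         n_retained = res$pca$n_retained,
         loadings = as.data.frame(res$pca$loadings),
         communalities = as.list(res$pca$communalities)),
    out("pca.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(res$sweep$table, out("sweep.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(res$zones), out("zones.csv"), row.names = FALSE)
  utils::write.csv(res$anova$anova, out("zone_anova.csv"), row.names = FALSE)
  utils::write.csv(cbind(zone = rownames(res$anova$means), res$anova$means),
                   out("zone_means.csv"), row.names = FALSE)
  utils::write.csv(res$reduction, out("variability_reduction.csv"),
                   row.names = FALSE)
  if (!is.null(res$plan)) {
    utils::write.csv(res$plan$plan, out("fertilizer_plan.csv"), row.names = FALSE)
  }
  if (!is.null(res$economics)) {
    utils::write.csv(res$economics, out("economics.csv"), row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$samples)
  cat("\nvariogram records:\n")
  rec <- do.call(rbind, lapply(x$variograms, function(v)
    as.data.frame(v$record[c("property", "transformation", "model", "range_m",
                             "dependence", "nrmse_percent", "r2")])))
  print(rec, row.names = FALSE, digits = 3)
  cat("\n")
  print(x$sweep)
  print(x$zones)
  invisible(x)
}
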