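#' Geo-referenced soil sample set
#'
#' The universal input container of the package: a set of point samples on a
#' planar (metre) coordinate system, with one numeric column per measured soil
#' property. Properties flagged \code{"log"} in \code{transforms} are treated
#' as log-normally distributed and are analysed on the natural-log scale by
#' the geostatistical stage.
#'
#' @param ids character vector of unique sample identifiers.
#' @param x,y numeric planar coordinates in metres.
#' @param values numeric matrix, one row per sample, one column per property.
#' @param units character vector of unit labels, one per property.
#' @param transforms per-property transform flag, \code{"none"} or
#'   \code{"log"}; recycled if length 1.
#'
#' @return An object of class \code{sample_set}.
#' @export
sample_set <- function(ids, x, y, values, units = NULL, transforms = "none") {
  values <- as.matrix(values)
  n <- nrow(values)
  p <- ncol(values)
  if (is.null(colnames(values))) {
    stop("'values' must have property names as column names")
  }
  if (length(ids) != n || length(x) != n || length(y) != n) {
    stop("ids, x, y and values must describe the same number of samples")
  }
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)
    stop("non-finite values at sample(s) ",
         paste(ids[unique(bad[, 1])], collapse = ", "))
  }
  dup <- duplicated_coords(x, y)
  if (length(dup)) {
    stop("duplicate coordinates (within 1e-9 m) at rows ",
         paste(dup, collapse = ", "))
  }
  if (is.null(units)) units <- rep("", p)
  transforms <- rep_len(as.character(transforms), p)
  if (!all(transforms %in% c("none", "log"))) {
    stop("transforms must be 'none' or 'log'")
  }
  logged <- transforms == "log"
  if (any(logged)) {
    neg <- values[, logged, drop = FALSE] <= 0
    if (any(neg)) {
      stop("log-flagged properties must be strictly positive (",
           paste(colnames(values)[logged][colSums(neg) > 0], collapse = ", "), ")")
    }
  }
  structure(
    list(ids = ids, x = as.numeric(x), y = as.numeric(y), values = values,
         property_names = colnames(values), units = units,
         transforms = stats::setNames(transforms, colnames(values))),
    class = "sample_set")
}

duplicated_coords <- function(x, y, tol = 1e-9) {
  key <- paste(round(x / tol), round(y / tol))
  which(duplicated(key) | duplicated(key, fromLast = TRUE))
}

#' @export
print.sample_set <- function(x, ...) {
  cat("<sample_set> ", length(x$ids), " samples, ",
      length(x$property_names), " properties\n", sep = "")
  cat("  extent: x [", min(x$x), ",", max(x$x), "] m, y [",
      min(x$y), ",", max(x$y), "] m\n")
  cat("  properties:", paste(x$property_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.sample_set <- function(x, ...) {
  data.frame(id = x$ids, x = x$x, y = x$y, x$values,
             check.names = FALSE, stringsAsFactors = FALSE)
}

n_samples <- function(samples) length(samples$ids)

property_values <- function(samples, property) {
  if (!property %in% samples$property_names) {
    stop("unknown property '", property, "'")
  }
  samples$values[, property]
}

#' Log-transform a property (or back-transform kriged predictions)
#'
#' Forward direction replaces a property's values with their natural
#' logarithms and flags the property as transformed; back direction
#' exponentiates. Applied to a \code{kriged_surface}, the back direction
#' exponentiates the prediction grid (optionally with the lognormal bias
#' correction \eqn{\exp(\hat Z + \sigma_k^2/2)}).
#'
#' @param x a \code{sample_set} or \code{kriged_surface}.
#' @param property property name (ignored for surfaces).
#' @param direction \code{"forward"} or \code{"back"}.
#' @param lognormal_correction logical; for surfaces, apply the kriging
#'   variance bias correction on back-transform. Default \code{FALSE}
#'   (plain exponentiation).
#' @return Object of the same class with transformed values.
#' @export
apply_transform <- function(x, property = NULL, direction = c("forward", "back"),
                            lognormal_correction = FALSE) {
  direction <- match.arg(direction)
  UseMethod("apply_transform")
}

#' @export
apply_transform.sample_set <- function(x, property = NULL,
                                       direction = c("forward", "back"),
                                       lognormal_correction = FALSE) {
  direction <- match.arg(direction)
  v <- property_values(x, property)
  if (direction == "forward") {
    if (any(v <= 0)) {
      stop("cannot log-transform non-positive values (samples ",
           paste(x$ids[v <= 0], collapse = ", "), ")")
    }
    x$values[, property] <- log(v)
    x$transforms[property] <- "log"
  } else {
    x$values[, property] <- exp(v)
    x$transforms[property] <- "none"
  }
  x
}

#' @export
apply_transform.kriged_surface <- function(x, property = NULL,
                                           direction = c("forward", "back"),
                                           lognormal_correction = FALSE) {
  direction <- match.arg(direction)
  if (direction == "forward") {
    x$predictions <- log(x$predictions)
    x$back_transformed <- FALSE
  } else {
    if (lognormal_correction) {
      x$predictions <- exp(x$predictions + 0.5 * x$kriging_variance)
    } else {
      x$predictions <- exp(x$predictions)
    }
    x$back_transformed <- TRUE
  }
  x
}

#' Read a sample-set CSV
#'
#' Expects columns \code{id}, \code{x}, \code{y} (case-insensitive) followed
#' by one numeric column per property. An optional leading comment line
#' \code{#units: u1,u2,...} carries unit labels; an optional
#' \code{#transforms:} line carries per-property none/log flags.
#'
#' @param path file path.
#' @return A \code{\link{sample_set}}.
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  head_lines <- readLines(path, n = 5L)
  units <- NULL
  transforms <- "none"
  for (ln in head_lines) {
    if (startsWith(ln, "#units:")) {
      units <- trimws(strsplit(sub("^#units:", "", ln), ",")[[1]])
    }
    if (startsWith(ln, "#transforms:")) {
      transforms <- trimws(strsplit(sub("^#transforms:", "", ln), ",")[[1]])
    }
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE,
                        stringsAsFactors = FALSE)
  names(df)[1:3] <- tolower(names(df)[1:3])
  need <- c("id", "x", "y")
  if (!all(need %in% tolower(names(df)[1:3]))) {
    stop("missing mandatory column(s): ",
         paste(setdiff(need, tolower(names(df))), collapse = ", "))
  }
  prop_cols <- setdiff(names(df), need)
  if (!length(prop_cols)) stop("no property columns found")
  for (p in c("x", "y", prop_cols)) {
    if (!is.numeric(df[[p]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[p]]))))
      stop("non-numeric cells in column '", p, "' at row(s) ",
           paste(bad, collapse = ", "))
    }
  }
  vals <- as.matrix(df[prop_cols])
  rownames(vals) <- NULL
  sample_set(df$id, df$x, df$y, vals, units = units, transforms = transforms)
}

#' Write a sample-set CSV
#'
#' Inverse of \code{\link{read_samples}}: writes the \code{#units:} and
#' \code{#transforms:} comment lines followed by the data.
#'
#' @param samples a \code{sample_set}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_samples <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#units: ", paste(samples$units, collapse = ",")), con)
  writeLines(paste0("#transforms: ", paste(samples$transforms, collapse = ",")), con)
  utils::write.csv(as.data.frame(samples), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
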