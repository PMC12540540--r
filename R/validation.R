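#' Per-zone means and one-way ANOVA validation of management zones
#'
#' For each property: per-zone mean, SD, CV and n; the classical one-way
#' ANOVA F statistic and p-value across zones; and compact letter groupings
#' from Tukey's HSD at \code{alpha} (the zone with the highest mean gets
#' \code{"a"}). A non-significant omnibus test gives all zones the same
#' letter. Properties with any zone smaller than 2 samples are flagged
#' untestable.
#'
#' @param samples a \code{\link{sample_set}} (original scale).
#' @param zones a \code{\link{defuzzify}} zone map (or integer label vector).
#' @param alpha significance level (default 0.01).
#' @return An object of class \code{zone_summary}: \code{means}, \code{sds},
#'   \code{cvs}, \code{n} (zones × properties tables), \code{anova}
#'   (data.frame with F, p, significant, letters per property).
#' @export
zone_anova <- function(samples, zones, alpha = 0.01) {
  labels <- if (inherits(zones, "zone_map")) zones$labels else as.integer(zones)
  if (length(labels) != n_samples(samples)) {
    stop("zone labels and samples disagree in length")
  }
  zl <- sort(unique(labels))
  if (length(zl) < 2) stop("need at least 2 zones")
  fz <- factor(labels, levels = zl)
  props <- samples$property_names
  agg <- function(f) {
    m <- vapply(zl, function(z)
      apply(samples$values[labels == z, , drop = FALSE], 2, f),
      numeric(length(props)))
    t(matrix(m, nrow = length(props), ncol = length(zl)))
  }
  means <- agg(mean)
  sds <- agg(stats::sd)
  ns <- table(fz)
  cvs <- 100 * sds / means
  dimnames(means) <- dimnames(sds) <- dimnames(cvs) <-
    list(paste0("MZ-", zl), props)
  res <- lapply(props, function(p) {
    v <- samples$values[, p]
    if (min(ns) < 2) {
      return(data.frame(property = p, F = NA_real_, p_value = NA_real_,
                        significant = NA,
                        letters = NA_character_, testable = FALSE))
    }
    fit <- stats::aov(v ~ fz)
    at <- stats::anova(fit)
    Fv <- at$`F value`[1]
    pv <- at$`Pr(>F)`[1]
    sig <- is.finite(pv) && pv < alpha
    letters <- if (!sig || !is.finite(Fv)) {
      rep("a", length(zl))
    } else {
      tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$fz
      mz <- stats::setNames(means[, p], as.character(zl))
      cld_letters(mz, rownames(tk), tk[, "p adj"] < alpha)
    }
    data.frame(property = p, F = Fv, p_value = pv, significant = sig,
               letters = paste(letters, collapse = ","), testable = TRUE)
  })
  structure(list(means = means, sds = sds, cvs = cvs,
                 n = as.integer(ns), zone_levels = zl, alpha = alpha,
                 anova = do.call(rbind, res)),
            class = "zone_summary")
}

# Compact letter display by insert-and-absorb: start with one letter
# shared by all groups; for every significantly different pair, split each
# letter column containing both; absorb redundant columns; order letters so
# the highest mean gets 'a'.
cld_letters <- function(means, pair_names, sig) {
  g <- length(means)
  groups <- names(means)
  if (is.null(groups)) groups <- as.character(seq_len(g))
  cols <- list(rep(TRUE, g))  # letter columns: logical membership vectors
  pairs <- strsplit(pair_names, "-", fixed = TRUE)
  for (k in seq_along(pairs)) {
    if (!isTRUE(sig[k])) next
    i <- match(pairs[[k]][1], groups)
    j <- match(pairs[[k]][2], groups)
    if (is.na(i) || is.na(j)) next
    new_cols <- list()
    for (col in cols) {
      if (col[i] && col[j]) {
        a <- col; a[i] <- FALSE
        b <- col; b[j] <- FALSE
        new_cols <- c(new_cols, list(a, b))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns contained in another
    keep <- rep(TRUE, length(new_cols))
    for (u in seq_along(new_cols)) for (v in seq_along(new_cols)) {
      if (u != v && keep[u] && keep[v] &&
          all(new_cols[[u]] <= new_cols[[v]]) &&
          any(new_cols[[u]] < new_cols[[v]])) keep[u] <- FALSE
      else if (u < v && keep[u] && keep[v] &&
               all(new_cols[[u]] == new_cols[[v]])) keep[v] <- FALSE
    }
    cols <- new_cols[keep]
  }
  # order columns by the highest mean they contain, descending
  top <- vapply(cols, function(col) max(means[col]), numeric(1))
  cols <- cols[order(top, decreasing = TRUE)]
  out <- vapply(seq_len(g), function(i) {
    paste(letters[which(vapply(cols, `[`, TRUE, i))], collapse = "")
  }, character(1))
  names(out) <- groups
  out
}

#' @export
print.zone_summary <- function(x, ...) {
  cat("<zone_summary>", length(x$zone_levels), "zones, n =",
      paste(x$n, collapse = "/"), "\n")
  print(x$anova[c("property", "F", "p_value", "significant", "letters")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Field-versus-zone variability-reduction ledger
#'
#' For each property: overall (whole-field) mean and CV; the unweighted
#' arithmetic mean of the per-zone means and CVs; and the relative CV
#' reduction \eqn{100(CV_{field} - \overline{CV}_{zone})/CV_{field}},
#' reported to 2 decimals. Zero overall CV flags the reduction undefined.
#'
#' @param samples a \code{\link{sample_set}} (original scale).
#' @param zones a \code{\link{defuzzify}} zone map (or integer label vector).
#' @return A data.frame with columns property, overall_mean, overall_cv,
#'   zone_avg_mean, zone_avg_cv, reduction_percent.
#' @export
variability_reduction <- function(samples, zones) {
  labels <- if (inherits(zones, "zone_map")) zones$labels else as.integer(zones)
  zl <- sort(unique(labels))
  out <- do.call(rbind, lapply(samples$property_names, function(p) {
    v <- samples$values[, p]
    om <- mean(v)
    ocv <- if (om != 0) 100 * stats::sd(v) / om else NA_real_
    zm <- vapply(zl, function(z) mean(v[labels == z]), numeric(1))
    zcv <- vapply(zl, function(z) {
      vz <- v[labels == z]
      if (length(vz) < 2 || mean(vz) == 0) NA_real_
      else 100 * stats::sd(vz) / mean(vz)
    }, numeric(1))
    red <- if (!is.na(ocv) && ocv > 0) cv_reduction(ocv, mean(zcv)) else NA_real_
    data.frame(property = p, overall_mean = om, overall_cv = ocv,
               zone_avg_mean = mean(zm), zone_avg_cv = mean(zcv),
               reduction_percent = red)
  }))
  rownames(out) <- NULL
  out
}

#' Relative CV reduction, in percent
#'
#' \eqn{100 (CV_{field} - CV_{zone})/CV_{field}}, rounded to 2 decimals —
#' the zone-delineation variability-reduction measure.
#'
#' @param overall_cv whole-field CV (percent), > 0.
#' @param zone_avg_cv zone-average CV (percent).
#' @return Reduction in percent (2 decimals).
#' @export
cv_reduction <- function(overall_cv, zone_avg_cv) {
  if (any(overall_cv <= 0)) stop("overall CV must be > 0")
  round(100 * (overall_cv - zone_avg_cv) / overall_cv, 2)
}
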