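#' Targeted-yield fertilizer dose for maize
#'
#' Soil-test-based targeted-yield equations (PJTSAU calibration for maize):
#' \deqn{F_N = 4.25T - 0.24\,SN,\quad F_{P_2O_5} = 0.9T - 0.3\,SP,\quad
#'       F_{K_2O} = 1.41T - 0.05\,SK}
#' with target yield \eqn{T} in quintal/ha and soil-test values SN, SP, SK
#' in kg/ha of available N, P2O5 and K2O. Negative computed doses are
#' floored at zero and flagged.
#'
#' @param T target yield in q/ha (> 0).
#' @param sn,sp,sk soil-test values, kg/ha (>= 0).
#' @return A list: \code{dose} named vector (N, P2O5, K2O in kg/ha),
#'   \code{raw} (pre-flooring values), \code{floored} logical vector.
#' @export
fertilizer_dose <- function(T, sn, sp, sk) {
  if (T <= 0) stop("target yield must be > 0")
  if (any(c(sn, sp, sk) < 0)) stop("soil-test values must be >= 0")
  raw <- c(N = 4.25 * T - 0.24 * sn,
           P2O5 = 0.90 * T - 0.30 * sp,
           K2O = 1.41 * T - 0.05 * sk)
  list(dose = pmax(raw, 0), raw = raw, floored = raw < 0)
}

#' Fertilizer savings against a reference practice
#'
#' Component-wise \code{reference − dose}; negative entries mean the plan
#' exceeds the reference (over-recommendation) and are reported as such.
#'
#' @param dose named or plain length-3 dose vector (N, P2O5, K2O kg/ha).
#' @param reference reference-practice dose triple (same order).
#' @return Named saving vector (kg/ha).
#' @export
fertilizer_savings <- function(dose, reference) {
  dose <- unlist(dose)[1:3]
  reference <- unlist(reference)[1:3]
  out <- reference - dose
  names(out) <- c("N", "P2O5", "K2O")
  out
}

#' Gross/net return and benefit:cost ratio
#'
#' Gross return = grain yield × grain price; net return = gross − cost of
#' cultivation; B:C = gross/cost (reported to 2 decimals, full precision
#' kept in \code{bc_ratio_exact}).
#'
#' @param grain_yield kg/ha (>= 0).
#' @param grain_price currency per kg (>= 0).
#' @param cost cost of cultivation, currency per ha (> 0).
#' @return A list: \code{grain_yield}, \code{cost}, \code{gross_return},
#'   \code{net_return}, \code{bc_ratio} (2 dp), \code{bc_ratio_exact}.
#' @export
crop_economics <- function(grain_yield, grain_price, cost) {
  if (any(c(grain_yield, grain_price) < 0)) stop("inputs must be >= 0")
  if (cost <= 0) stop("B:C undefined for non-positive cost")
  gross <- grain_yield * grain_price
  bc <- gross / cost
  list(grain_yield = grain_yield, cost = cost, gross_return = gross,
       net_return = gross - cost, bc_ratio = round(bc, 2),
       bc_ratio_exact = bc)
}

#' Per-zone fertilizer plan from zone soil-test means
#'
#' Applies the targeted-yield equations to each zone's mean available
#' N/P2O5/K2O and attaches savings against the reference (farmer) practice.
#'
#' @param zone_summary a \code{\link{zone_anova}} result (its \code{means}
#'   table must contain columns for the nutrient properties), or a plain
#'   matrix/data.frame of zone means with those columns.
#' @param T target yield, q/ha.
#' @param reference reference dose triple (N, P2O5, K2O kg/ha).
#' @param nutrients names of the soil-test columns for N, P2O5, K2O.
#' @return An object of class \code{fertilizer_plan}: data.frame \code{plan}
#'   with per-zone soil tests, doses, savings and flooring flags, plus
#'   \code{target_yield} and \code{reference}.
#' @export
zone_plan <- function(zone_summary, T, reference = c(240, 80, 80),
                      nutrients = c("N", "P2O5", "K2O")) {
  means <- if (inherits(zone_summary, "zone_summary")) zone_summary$means
           else as.matrix(zone_summary)
  missing_col <- setdiff(nutrients, colnames(means))
  if (length(missing_col)) {
    stop("zone means lack nutrient column(s): ",
         paste(missing_col, collapse = ", "))
  }
  reference <- unlist(reference)[1:3]
  rows <- lapply(seq_len(nrow(means)), function(z) {
    st <- means[z, nutrients]
    d <- fertilizer_dose(T, st[1], st[2], st[3])
    s <- fertilizer_savings(d$dose, reference)
    data.frame(zone = rownames(means)[z] %||% paste0("MZ-", z),
               soil_N = st[1], soil_P2O5 = st[2], soil_K2O = st[3],
               dose_N = d$dose[1], dose_P2O5 = d$dose[2], dose_K2O = d$dose[3],
               saving_N = s[1], saving_P2O5 = s[2], saving_K2O = s[3],
               floored = any(d$floored))
  })
  plan <- do.call(rbind, rows)
  rownames(plan) <- NULL
  structure(list(plan = plan, target_yield = T, reference = reference),
            class = "fertilizer_plan")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fertilizer_plan <- function(x, ...) {
  cat("<fertilizer_plan> target yield", x$target_yield, "q/ha; reference",
      paste(x$reference, collapse = "/"), "kg/ha N/P2O5/K2O\n")
  print(transform(x$plan,
                  dose_N = round(dose_N, 1), dose_P2O5 = round(dose_P2O5, 1),
                  dose_K2O = round(dose_K2O, 1),
                  saving_N = round(saving_N, 1),
                  saving_P2O5 = round(saving_P2O5, 1),
                  saving_K2O = round(saving_K2O, 1)),
        row.names = FALSE, digits = 4)
  invisible(x)
}
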