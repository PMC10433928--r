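#' Mechanistic constant linking sap flux, deficit and stomatal conductance
#'
#' For a canopy tightly coupled to the atmosphere, inverting the simplified
#' Penman-Monteith equation gives stomatal conductance as
#' \eqn{g_s = \lambda \gamma E / (\rho_{air} C_p D)}, with \eqn{E} the
#' transpiration flux and \eqn{D} the vapour pressure deficit. All four
#' meteorological factors vary far less than \eqn{E} and \eqn{D} over a
#' measurement day, so they are collapsed into a single constant
#' \eqn{C = \lambda\gamma/(\rho_{air} C_p)} evaluated at one reference
#' temperature and pressure.
#'
#' Substituting \eqn{E = H_v J_s} (sap flux density scaled from sapwood area
#' to leaf area by the Huber value) yields the trait-based model
#' \eqn{g_s = C \, H_v \, J_s / D}. Because field units are mixed
#' (\eqn{J_s} in cm h-1, \eqn{D} in kPa, \eqn{g_s} in mol m-2 s-1), the
#' object also carries the full unit-harmonised factor `js_gs_factor` such
#' that `gs_mol_m2_s = js_gs_factor * hv * js_cm_h / d_kpa`; the algebra of
#' the conversion is recorded step by step in `$audit`.
#'
#' Constituents are computed from standard meteorological formulae:
#' latent heat \eqn{\lambda = (2.501 - 2.361\times10^{-3} T)\times 10^6}
#' J kg-1, psychrometric constant \eqn{\gamma = C_p P / (0.622 \lambda)}
#' kPa K-1, dry-air density \eqn{\rho_{air} = P/(R_{dry} T_K)} kg m-3, with
#' \eqn{C_p} = 1013 J kg-1 K-1.
#'
#' @param tair_c Reference air temperature, degrees C. Default 20.
#' @param pressure_kpa Atmospheric pressure, kPa. Default 101.3.
#' @return An object of class `mechanistic_constant`: a list with `lambda`
#'   (J kg-1), `gamma` (kPa K-1), `rho_air` (kg m-3), `cp` (J kg-1 K-1),
#'   `C` (kPa m3 kg-1), `molar_volume` (m3 mol-1), `js_gs_factor`
#'   (mol m-2 s-1 per (cm h-1 kPa-1), i.e. the factor applied to
#'   `hv * js / d`), the reference conditions, and the `audit` trail.
#' @examples
#' mc <- mechanistic_constant(20, 101.3)
#' mc$C
#' @export
mechanistic_constant <- function(tair_c = 20, pressure_kpa = 101.3) {
  if (!is.finite(tair_c) || tair_c < -40 || tair_c > 60) {
    abort("`tair_c` must be a plausible air temperature in degrees C.")
  }
  if (!is.finite(pressure_kpa) || pressure_kpa < 50 || pressure_kpa > 110) {
    abort("`pressure_kpa` must be a plausible surface pressure in kPa.")
  }
  u <- hydro_units()
  tk <- tair_c + 273.15
  lambda <- (2.501 - 2.361e-3 * tair_c) * 1e6      # J kg-1
  cp <- 1013                                        # J kg-1 K-1, moist air
  gamma <- cp * pressure_kpa / (0.622 * lambda)     # kPa K-1
  rho_air <- pressure_kpa * 1000 / (287.058 * tk)   # kg m-3
  C <- lambda * gamma / (rho_air * cp)              # kPa m3 kg-1
  v <- molar_volume_air(tair_c, pressure_kpa)       # m3 mol-1
  js_factor <- u$m_per_cm / u$s_per_h * u$rho_water # cm h-1 -> kg m-2 s-1
  js_gs_factor <- C * js_factor / v
  structure(
    list(
      lambda = lambda, gamma = gamma, rho_air = rho_air, cp = cp,
      C = C, molar_volume = v, js_gs_factor = js_gs_factor,
      tair_c = tair_c, pressure_kpa = pressure_kpa,
      audit = c(
        sprintf("lambda = (2.501 - 2.361e-3 * %.6g) * 1e6 = %.6g J kg-1", tair_c, lambda),
        sprintf("gamma = 1013 * %.6g / (0.622 * lambda) = %.6g kPa K-1", pressure_kpa, gamma),
        sprintf("rho_air = %.6g kPa / (287.058 J kg-1 K-1 * %.6g K) = %.6g kg m-3", pressure_kpa, tk, rho_air),
        sprintf("C = lambda * gamma / (rho_air * cp) = %.6g kPa m3 kg-1", C),
        sprintf("Js cm h-1 -> kg m-2 s-1: * 0.01 / 3600 * %.6g = * %.6g", u$rho_water, js_factor),
        sprintf("m s-1 -> mol m-2 s-1: / molar volume %.6g m3 mol-1", v),
        sprintf("gs[mol m-2 s-1] = %.8g * Hv * Js[cm h-1] / D[kPa]", js_gs_factor)
      )
    ),
    class = "mechanistic_constant"
  )
}

#' @export
print.mechanistic_constant <- function(x, ...) {
  cat("Mechanistic constant (Penman-Monteith inversion, coupled canopy)\n")
  cat(sprintf("  reference: %.1f degC, %.1f kPa\n", x$tair_c, x$pressure_kpa))
  cat(sprintf("  C = %.4f kPa m3 kg-1;  gs = %.5f * Hv * Js[cm h-1] / D[kPa]\n",
              x$C, x$js_gs_factor))
  invisible(x)
}

#' Calibrate stomatal conductance against the sap-flux-to-deficit ratio
#'
#' Establishes, per tree, the empirical calibration between spot-measured
#' stomatal conductance and the ratio \eqn{J_s/D} of half-hourly sap flux
#' density to vapour pressure deficit: an ordinary least-squares fit of
#' \eqn{g_s} on \eqn{J_s/D}. Under the trait-based model the slope equals
#' \eqn{C \, H_v}, so calibration slopes across trees carry the Huber-value
#' signal. Conductance spot readings are paired to the flux series by nearest
#' timestamp within `max_gap_min` minutes; unmatched readings are dropped
#' with a message.
#'
#' @param gs_data Tibble of conductance measurements: `timestamp`, `tree_id`,
#'   `gs_mol_m2_s`.
#' @param flux_data Tibble of sap flux: `timestamp`, `tree_id`, `js_cm_h`.
#' @param met_data Tibble of microclimate with `timestamp` and `d_kpa`
#'   (deficit shared across trees).
#' @param intercept Include an intercept (default `TRUE`; the strict
#'   proportional model of the trait equation is `intercept = FALSE`).
#' @param window `"morning"` (default) restricts both series to the
#'   dawn-to-midday window via [filter_morning()] before pairing, avoiding
#'   the afternoon hysteresis loop; `"all"` uses every aligned pair.
#' @param max_gap_min Maximum timestamp mismatch when pairing, minutes.
#' @param n_band Sanity band on the per-tree sample size; a size outside it
#'   produces a warning, not an error.
#' @return A tibble of class `gs_calibration`, one row per tree: `tree_id`,
#'   `slope`, `intercept`, `r_squared`, `p_value` (two-sided t test on the
#'   slope), `n`, `intercept_fitted`.
#' @export
calibrate_gs <- function(gs_data, flux_data, met_data,
                         intercept = TRUE, window = c("morning", "all"),
                         max_gap_min = 15, n_band = c(10, 100)) {
  window <- match.arg(window)
  check_columns(gs_data, c("timestamp", "tree_id", "gs_mol_m2_s"), "gs_data")
  check_columns(flux_data, c("timestamp", "tree_id", "js_cm_h"), "flux_data")
  check_columns(met_data, c("timestamp", "d_kpa"), "met_data")
  if (window == "morning") {
    gs_data <- dplyr::inner_join(
      tibble::as_tibble(gs_data),
      tibble::as_tibble(met_data)[, c("timestamp", "d_kpa")],
      by = "timestamp"
    ) |>
      filter_morning(quiet = TRUE) |>
      dplyr::select(-"d_kpa")
  }
  paired <- pair_nearest(gs_data, flux_data, met_data, max_gap_min)
  fits <- paired |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::group_modify(function(df, key) {
      n <- nrow(df)
      if (n < max(3, n_band[1]) || n > n_band[2]) {
        warn(sprintf("tree %s: calibration n = %d outside band [%d, %d]",
                     as.character(key$tree_id), n, n_band[1], n_band[2]))
      }
      calibrate_tree(df$gs_mol_m2_s, df$js_cm_h, df$d_kpa, intercept = intercept)
    }) |>
    dplyr::ungroup()
  class(fits) <- c("gs_calibration", class(fits))
  attr(fits, "intercept") <- intercept
  fits
}

#' One-tree conductance calibration on aligned vectors
#'
#' Vector workhorse behind [calibrate_gs()]: OLS of `gs` on `js / d`.
#'
#' @param gs Stomatal conductance, mol m-2 s-1.
#' @param js Sap flux density, cm h-1, aligned with `gs`.
#' @param d Vapour pressure deficit, kPa, aligned; must be positive.
#' @param intercept Include an intercept.
#' @return One-row tibble with `slope`, `intercept_fitted`, `r_squared`,
#'   `p_value`, `n`.
#' @export
calibrate_tree <- function(gs, js, d, intercept = TRUE) {
  if (length(gs) < 3) abort("calibration needs at least 3 aligned points")
  if (any(d <= 0)) abort("`d` must be positive at every retained point")
  x <- js / d
  if (sd(x) == 0) abort("zero variance in js/d: calibration is undefined")
  fit <- if (intercept) lm(gs ~ x) else lm(gs ~ x + 0)
  sm <- summary(fit)
  slope_row <- sm$coefficients["x", ]
  rss <- sum(fit$residuals^2)
  tss <- sum((gs - mean(gs))^2)
  tibble::tibble(
    slope = unname(slope_row["Estimate"]),
    intercept_fitted = if (intercept) unname(coef(fit)[1]) else 0,
    r_squared = 1 - rss / tss,
    p_value = unname(slope_row["Pr(>|t|)"]),
    n = length(gs)
  )
}

#' Predict continuous stomatal conductance from sap flux and deficit
#'
#' Applies the trait-based model \eqn{g_s = C \, H_v \, J_s / D} pointwise to
#' a sap-flux series, turning half-hourly flux and a weather-station deficit
#' into a continuous conductance estimate. Rows with `d_kpa <= 0` are dropped
#' (their count is reported); timestamps are preserved.
#'
#' @param flux_data Tibble with `timestamp`, `js_cm_h`, a `d_kpa` column or
#'   joined via `met_data`, and optionally `tree_id`.
#' @param hv Huber value, cm2 sapwood per cm2 leaf.
#' @param constant A [mechanistic_constant()] object.
#' @param met_data Optional microclimate tibble (`timestamp`, `d_kpa`) to be
#'   joined when `flux_data` lacks `d_kpa`.
#' @return Tibble with the input identifiers plus `gs_pred_mol_m2_s`.
#' @export
predict_gs <- function(flux_data, hv, constant = mechanistic_constant(),
                       met_data = NULL) {
  stopifnot(inherits(constant, "mechanistic_constant"))
  if (!is.finite(hv) || hv <= 0) abort("`hv` must be a positive Huber value.")
  if (!("d_kpa" %in% names(flux_data))) {
    if (is.null(met_data)) abort("`flux_data` lacks `d_kpa` and no `met_data` given.")
    check_columns(met_data, c("timestamp", "d_kpa"), "met_data")
    flux_data <- dplyr::inner_join(flux_data, met_data[, c("timestamp", "d_kpa")],
                                   by = "timestamp")
  }
  check_columns(flux_data, c("js_cm_h", "d_kpa"), "flux_data")
  bad <- flux_data$d_kpa <= 0
  if (any(bad)) {
    inform(sprintf("dropping %d row(s) with non-positive deficit", sum(bad)))
    flux_data <- flux_data[!bad, , drop = FALSE]
  }
  dplyr::mutate(
    tibble::as_tibble(flux_data),
    gs_pred_mol_m2_s = constant$js_gs_factor * hv * .data$js_cm_h / .data$d_kpa
  )
}

#' Regress calibration slopes on the Huber value across trees
#'
#' Cross-tree test of the trait-based model: if calibration slopes equal
#' \eqn{C H_v}, they must increase linearly with the Huber value, with slope
#' \eqn{C} and zero intercept. Only trees whose conductance calibration is
#' statistically significant at `alpha` enter the regression.
#'
#' @param calib A `gs_calibration` tibble from [calibrate_gs()].
#' @param hv_data Tibble with `tree_id` and `hv_cm2_cm2`.
#' @param alpha Significance threshold on the calibration p-value.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`
#'   (slope t test), `n_trees`.
#' @export
slope_vs_hv <- function(calib, hv_data, alpha = 0.05) {
  check_columns(calib, c("tree_id", "slope", "p_value"), "calib")
  check_columns(hv_data, c("tree_id", "hv_cm2_cm2"), "hv_data")
  df <- dplyr::inner_join(tibble::as_tibble(calib), tibble::as_tibble(hv_data),
                          by = "tree_id")
  df <- df[df$p_value < alpha, , drop = FALSE]
  if (nrow(df) < 3) {
    abort(sprintf("only %d tree(s) with significant calibration; need >= 3", nrow(df)))
  }
  if (sd(df$hv_cm2_cm2) == 0) abort("all qualifying trees share one Huber value")
  fit <- lm(slope ~ hv_cm2_cm2, data = df)
  sm <- summary(fit)
  tibble::tibble(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = sm$r.squared,
    p_value = sm$coefficients[2, 4],
    n_trees = nrow(df)
  )
}

# Nearest-timestamp pairing of spot gs readings with the half-hourly flux
# and deficit series. Gap beyond max_gap_min drops the reading.
pair_nearest <- function(gs_data, flux_data, met_data, max_gap_min) {
  met <- tibble::as_tibble(met_data)[, c("timestamp", "d_kpa")]
  flux <- dplyr::inner_join(tibble::as_tibble(flux_data), met, by = "timestamp")
  out <- dplyr::group_by(tibble::as_tibble(gs_data), .data$tree_id) |>
    dplyr::group_modify(function(gdf, key) {
      fdf <- flux[flux$tree_id == key$tree_id, , drop = FALSE]
      if (nrow(fdf) == 0) return(gdf[0, setdiff(names(gdf), "tree_id"), drop = FALSE])
      idx <- vapply(gdf$timestamp, function(ts) {
        which.min(abs(as.numeric(difftime(fdf$timestamp, ts, units = "mins"))))
      }, integer(1))
      gap <- abs(as.numeric(difftime(fdf$timestamp[idx], gdf$timestamp, units = "mins")))
      keep <- gap <= max_gap_min
      if (any(!keep)) {
        inform(sprintf("tree %s: %d conductance reading(s) unmatched within %g min",
                       as.character(key$tree_id), sum(!keep), max_gap_min))
      }
      dplyr::bind_cols(
        gdf[keep, setdiff(names(gdf), "tree_id"), drop = FALSE],
        fdf[idx[keep], c("js_cm_h", "d_kpa"), drop = FALSE]
      )
    }) |>
    dplyr::ungroup()
  out
}

check_columns <- function(df, cols, name) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("`%s` lacks required column(s): %s",
                  name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
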