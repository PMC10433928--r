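#' Restrict a timestamped series to the dawn-to-midday window
#'
#' The sap-flux response to vapour pressure deficit is fitted on morning data
#' only, to avoid the afternoon hysteresis loop. The window is defined per
#' calendar day as the rows from the day's first deficit reading above
#' `d_threshold` (exclusive) through solar noon (`noon_hour`, inclusive).
#' A day whose deficit never rises above the threshold has no window and is
#' an error, naming the day.
#'
#' @param data Tibble with a `timestamp` (POSIXct) and a `d_kpa` column.
#' @param d_threshold Deficit threshold defining dawn, kPa.
#' @param noon_hour Solar-noon hour ending the window.
#' @param quiet Suppress the retained-row message.
#' @return The filtered tibble.
#' @export
filter_morning <- function(data, d_threshold = 0.1, noon_hour = 12,
                           quiet = FALSE) {
  check_columns(data, c("timestamp", "d_kpa"), "data")
  data <- tibble::as_tibble(data)
  day <- format(data$timestamp, "%Y-%m-%d")
  keep <- logical(nrow(data))
  for (d in unique(day)) {
    idx <- which(day == d)
    hours <- as.POSIXlt(data$timestamp[idx])$hour +
      as.POSIXlt(data$timestamp[idx])$min / 60
    above <- data$d_kpa[idx] > d_threshold
    if (!any(above)) {
      abort(sprintf("day %s: deficit never exceeds %.2g kPa, empty morning window",
                    d, d_threshold))
    }
    dawn <- min(hours[above])
    keep[idx] <- hours >= dawn & hours <= noon_hour & above
  }
  out <- data[keep, , drop = FALSE]
  if (!quiet) {
    inform(sprintf("morning window: retained %d of %d rows over %d day(s)",
                   nrow(out), nrow(data), length(unique(day))))
  }
  out
}

#' Fit the parabolic sap-flux response to vapour pressure deficit
#'
#' Least-squares fit of \eqn{J_s = a D^2 + b D} (no intercept: flux vanishes
#' with the deficit), the form used to locate the deficit at which sap flux
#' peaks. The vertex is computed analytically, \eqn{D_{Jsmax} = -b/(2a)}, and
#' the maximum flux by substituting it back,
#' \eqn{J_{smax} = a D_{Jsmax}^2 + b D_{Jsmax}}. When the fitted curvature is
#' non-negative the response has no interior maximum; the vertex fields are
#' `NA`, the status is `"no_vertex"`, and a warning is raised rather than
#' returning silent `NaN`s.
#'
#' Because the default model has no intercept, its R-squared is computed
#' against the mean-of-flux baseline (\eqn{1 - RSS/TSS_{mean}}) so that it is
#' directly comparable with the logarithmic model's R-squared; it can be
#' negative for a fit worse than the mean.
#'
#' @param d Vapour pressure deficit, kPa; non-negative.
#' @param js Sap flux density, cm h-1.
#' @param intercept Add a free intercept (off by default).
#' @return Object of class `parabolic_fit`: coefficients `a` (cm h-1 kPa-2)
#'   and `b` (cm h-1 kPa-1), optional `c0`, `r_squared`, `d_jsmax` (kPa),
#'   `jsmax` (cm h-1), `n`, `status`.
#' @examples
#' d <- c(0.5, 1, 2, 3, 4)
#' fit <- fit_parabolic(d, -1 * d^2 + 4 * d)
#' c(fit$d_jsmax, fit$jsmax) # vertex at (2, 4)
#' @export
fit_parabolic <- function(d, js, intercept = FALSE) {
  stopifnot(length(d) == length(js))
  if (length(d) < 3) abort("parabolic fit needs at least 3 points")
  if (any(d < 0)) abort("`d` must be non-negative")
  if (length(unique(d)) < (2 + intercept)) {
    abort("rank-deficient design: too few distinct deficit values")
  }
  fit <- if (intercept) lm(js ~ I(d^2) + d) else lm(js ~ 0 + I(d^2) + d)
  cf <- coef(fit)
  a <- unname(cf[["I(d^2)"]])
  b <- unname(cf[["d"]])
  c0 <- if (intercept) unname(cf[["(Intercept)"]]) else 0
  rss <- sum(fit$residuals^2)
  tss <- sum((js - mean(js))^2)
  status <- "ok"
  if (a < 0) {
    d_jsmax <- -b / (2 * a)
    jsmax <- a * d_jsmax^2 + b * d_jsmax + c0
  } else {
    warn("fitted curvature is non-negative: no interior flux maximum")
    status <- "no_vertex"
    d_jsmax <- NA_real_
    jsmax <- NA_real_
  }
  structure(
    list(a = a, b = b, c0 = c0, r_squared = 1 - rss / tss,
         d_jsmax = d_jsmax, jsmax = jsmax, n = length(d),
         status = status, intercept = intercept, model = fit),
    class = "parabolic_fit"
  )
}

#' Fit the logarithmic sap-flux response to vapour pressure deficit
#'
#' Ordinary least squares of \eqn{J_s = J_{sref} + m_{Js} \ln D}: the slope
#' `m_js` is the sensitivity of sap flux to atmospheric drought
#' (cm h-1 per ln kPa) and the intercept `jsref` the flux at D = 1 kPa.
#'
#' @param d Vapour pressure deficit, kPa; strictly positive.
#' @param js Sap flux density, cm h-1.
#' @return Object of class `log_fit` with `jsref`, `m_js`, `r_squared`, `n`.
#' @export
fit_log <- function(d, js) {
  stopifnot(length(d) == length(js))
  if (length(d) < 3) abort("logarithmic fit needs at least 3 points")
  if (any(d <= 0)) abort("`d` must be strictly positive for the log model")
  if (length(unique(d)) < 2) abort("degenerate regressor: all deficits equal")
  ld <- log(d)
  fit <- lm(js ~ ld)
  structure(
    list(jsref = unname(coef(fit)[1]), m_js = unname(coef(fit)[2]),
         r_squared = summary(fit)$r.squared, n = length(d), model = fit),
    class = "log_fit"
  )
}

#' Select the better-fitting response model
#'
#' Compares the parabolic and logarithmic fits of the same points by
#' R-squared and returns the winning label; ties go to the parabolic form,
#' the adopted model for extracting the flux maximum.
#'
#' @param parabolic A `parabolic_fit`.
#' @param logarithmic A `log_fit`.
#' @return `"parabolic"` or `"logarithmic"`.
#' @export
select_model <- function(parabolic, logarithmic) {
  stopifnot(inherits(parabolic, "parabolic_fit"), inherits(logarithmic, "log_fit"))
  if (parabolic$n != logarithmic$n) {
    abort("fits were made on differing numbers of points")
  }
  if (logarithmic$r_squared > parabolic$r_squared) "logarithmic" else "parabolic"
}

#' Fit per-tree sap-flux response curves for a whole campaign
#'
#' Data-frame-first driver: joins the deficit onto the flux series if needed,
#' restricts to the dawn-to-midday window, pools all measurement days, and
#' fits both response forms per tree.
#'
#' @param flux_data Tibble with `timestamp`, `tree_id`, `js_cm_h` and
#'   optionally `d_kpa`.
#' @param met_data Microclimate tibble (`timestamp`, `d_kpa`) joined when
#'   `flux_data` lacks the deficit.
#' @param window `"morning"` (default) applies [filter_morning()]; `"all"`
#'   fits every row.
#' @param intercept Passed to [fit_parabolic()].
#' @return Tibble of class `flux_fits`, one row per tree: parabolic
#'   coefficients and vertex, logarithmic coefficients, both R-squared
#'   values, `n`, `model_selected`, `status`.
#' @export
fit_flux_response <- function(flux_data, met_data = NULL,
                              window = c("morning", "all"),
                              intercept = FALSE) {
  window <- match.arg(window)
  check_columns(flux_data, c("timestamp", "tree_id", "js_cm_h"), "flux_data")
  if (!("d_kpa" %in% names(flux_data))) {
    if (is.null(met_data)) abort("`flux_data` lacks `d_kpa` and no `met_data` given.")
    check_columns(met_data, c("timestamp", "d_kpa"), "met_data")
    flux_data <- dplyr::inner_join(tibble::as_tibble(flux_data),
                                   tibble::as_tibble(met_data)[, c("timestamp", "d_kpa")],
                                   by = "timestamp")
  }
  if (window == "morning") flux_data <- filter_morning(flux_data, quiet = TRUE)
  out <- dplyr::group_by(tibble::as_tibble(flux_data), .data$tree_id) |>
    dplyr::group_modify(function(df, key) {
      pfit <- withCallingHandlers(
        fit_parabolic(df$d_kpa, df$js_cm_h, intercept = intercept),
        warning = function(w) invokeRestart("muffleWarning")
      )
      lfit <- fit_log(df$d_kpa, df$js_cm_h)
      tibble::tibble(
        a = pfit$a, b = pfit$b,
        d_jsmax_kpa = pfit$d_jsmax, jsmax_cm_h = pfit$jsmax,
        r2_parabolic = pfit$r_squared,
        jsref_cm_h = lfit$jsref, m_js = lfit$m_js, r2_log = lfit$r_squared,
        n = pfit$n,
        model_selected = select_model(pfit, lfit),
        status = pfit$status
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("flux_fits", class(out))
  out
}

#' @export
print.parabolic_fit <- function(x, ...) {
  cat(sprintf("Parabolic flux response: Js = %.4g D^2 + %.4g D%s  (n = %d)\n",
              x$a, x$b,
              if (x$intercept) sprintf(" + %.4g", x$c0) else "", x$n))
  if (x$status == "ok") {
    cat(sprintf("  vertex: D = %.3g kPa, Jsmax = %.3g cm h-1;  R2 = %.3f\n",
                x$d_jsmax, x$jsmax, x$r_squared))
  } else {
    cat(sprintf("  no interior maximum (curvature >= 0);  R2 = %.3f\n", x$r_squared))
  }
  invisible(x)
}

#' @export
print.log_fit <- function(x, ...) {
  cat(sprintf("Logarithmic flux response: Js = %.4g + %.4g ln D  (n = %d, R2 = %.3f)\n",
              x$jsref, x$m_js, x$n, x$r_squared))
  invisible(x)
}

#' @rdname fit_parabolic
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.parabolic_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  terms <- rownames(sm)
  tibble::tibble(
    term = sub("I\\(d\\^2\\)", "d^2", terms),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname fit_parabolic
#' @export
glance.parabolic_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared, d_jsmax = x$d_jsmax, jsmax = x$jsmax,
    nobs = x$n, status = x$status
  )
}

#' @rdname fit_log
#' @param x A fitted object.
#' @param ... Unused.
#' @export
tidy.log_fit <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("jsref", "m_js"),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname fit_log
#' @export
glance.log_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, nobs = x$n)
}
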