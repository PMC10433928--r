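#' Plot sap-flux response curves with their fitted models
#'
#' Morning-window flux against deficit per tree, overlaid with the fitted
#' no-intercept parabola; the vertex (deficit of maximum flux) is marked
#' where defined.
#'
#' @param flux_data Tibble with `timestamp`, `tree_id`, `js_cm_h`.
#' @param met_data Tibble with `timestamp`, `d_kpa`.
#' @param fits A `flux_fits` tibble from [fit_flux_response()].
#' @return A ggplot object (faceted by tree).
#' @export
plot_flux_response <- function(flux_data, met_data, fits) {
  df <- dplyr::inner_join(tibble::as_tibble(flux_data),
                          tibble::as_tibble(met_data)[, c("timestamp", "d_kpa")],
                          by = "timestamp") |>
    filter_morning(quiet = TRUE)
  curves <- tibble::as_tibble(fits) |>
    dplyr::reframe(d_kpa = seq(0, max(df$d_kpa), length.out = 100),
                   js_cm_h = .data$a * .data$d_kpa^2 + .data$b * .data$d_kpa,
                   .by = "tree_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_kpa, y = .data$js_cm_h)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(data = curves, colour = "firebrick") +
    ggplot2::geom_vline(
      data = tibble::as_tibble(fits)[!is.na(fits$d_jsmax_kpa), ],
      ggplot2::aes(xintercept = .data$d_jsmax_kpa),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(~tree_id, scales = "free_y") +
    ggplot2::labs(x = "Vapour pressure deficit (kPa)",
                  y = expression(J[s] ~ (cm ~ h^-1)))
}

#' @rdname trait_pca
#' @param object A `trait_pca`.
#' @param components Which two components to display.
#' @export
autoplot.trait_pca <- function(object, components = c(1, 2), ...) {
  pcx <- paste0("PC", components[1]); pcy <- paste0("PC", components[2])
  load_df <- tibble::as_tibble(object$loadings, rownames = "trait")
  score_df <- object$scores
  scl <- max(abs(as.matrix(score_df[, c(pcx, pcy)]))) /
    max(abs(as.matrix(load_df[, c(pcx, pcy)])))
  colour_aes <- if ("species" %in% names(score_df)) {
    ggplot2::aes(x = .data[[pcx]], y = .data[[pcy]], colour = .data$species)
  } else {
    ggplot2::aes(x = .data[[pcx]], y = .data[[pcy]])
  }
  ggplot2::ggplot() +
    ggplot2::geom_point(data = score_df, colour_aes) +
    ggplot2::geom_segment(
      data = load_df,
      ggplot2::aes(x = 0, y = 0, xend = .data[[pcx]] * scl,
                   yend = .data[[pcy]] * scl),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
      colour = "grey30"
    ) +
    ggplot2::geom_text(
      data = load_df,
      ggplot2::aes(x = .data[[pcx]] * scl * 1.07,
                   y = .data[[pcy]] * scl * 1.07, label = .data$trait),
      size = 3, colour = "grey30"
    ) +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcx, 100 * object$var_frac[components[1]]),
      y = sprintf("%s (%.1f%%)", pcy, 100 * object$var_frac[components[2]])
    )
}

#' @rdname lmg
#' @param object A `relimp_result`.
#' @export
autoplot.relimp_result <- function(object, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$term, y = .data$lmg_share)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = expression("LMG share of" ~ R^2))
  if (all(c("ci_lower", "ci_upper") %in% names(object))) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_lower, ymax = .data$ci_upper), width = 0.2)
  }
  p
}

#' @rdname tukey_compare
#' @param object A `tukey_comparison`.
#' @export
autoplot.tukey_comparison <- function(object, ...) {
  g <- object$groups
  ggplot2::ggplot(g, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::geom_text(ggplot2::aes(y = .data$mean + 1.6 * .data$se,
                                    label = .data$letters), vjust = 0) +
    ggplot2::labs(x = NULL,
                  y = sprintf("group mean (%s scale) ± SE", object$transform))
}

#' @rdname calibrate_gs
#' @param object A `gs_calibration`.
#' @export
autoplot.gs_calibration <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$significant <- df$p_value < 0.05
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tree_id, y = .data$slope,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "steelblue",
                                          `FALSE` = "grey70")) +
    ggplot2::labs(x = NULL, y = expression("calibration slope" ~
                                             (g[s] ~ "vs" ~ J[s] / D))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
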