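#' Anatomical maximum stomatal conductance
#'
#' Upper bound on leaf diffusive conductance to water vapour set by stomatal
#' anatomy alone: all stomata fully open, pore depth and end-correction
#' limiting diffusion. The default formula is the canonical diffusion form
#' \deqn{g_{smax} = \frac{d \, n \, a_{max}}{v \left(p_d + \frac{\pi}{2}\sqrt{a_{max}/\pi}\right)}}
#' with \eqn{d} the diffusivity of water vapour in air, \eqn{n} the stomatal
#' density, \eqn{a_{max}} the mean maximum pore area, \eqn{v} the molar
#' volume of air, and \eqn{p_d} the pore depth. By default the pore depth is
#' derived from the stomatal size \eqn{S} (length x width, um2) as half the
#' guard-cell width under a 2:1 length:width outline,
#' \eqn{p_d = \sqrt{S/2}/2}. The formula is a swappable function argument so
#' alternative algebraic arrangements can be substituted and compared without
#' touching callers.
#'
#' Stomata are assumed on the abaxial side only (hypostomatous leaves);
#' `amphistomatous = TRUE` doubles the density-borne flux.
#'
#' @param density_mm2 Stomatal density, stomata per mm2 of abaxial epidermis.
#' @param size_um2 Stomatal size (length x width), um2.
#' @param amax_um2 Mean maximum pore area, um2; must be below `size_um2`.
#' @param d Diffusivity of water vapour in air, m2 s-1 (default 2.49e-5 at
#'   25 degrees C).
#' @param v Molar volume of air, m3 mol-1 (default 0.0245 at 25 degrees C).
#' @param pore_depth_um Pore depth, um; derived from `size_um2` when `NULL`.
#' @param amphistomatous Stomata on both leaf sides.
#' @param formula Function `(d, v, density_m2, amax_m2, pore_depth_m)` giving
#'   the conductance in mol m-2 s-1; the default implements the expression
#'   above.
#' @return Theoretical maximum stomatal conductance, mol m-2 s-1
#'   (vectorised).
#' @examples
#' theoretical_gsmax(300, 150, 22.5)
#' @export
theoretical_gsmax <- function(density_mm2, size_um2, amax_um2,
                              d = 2.49e-5, v = 0.0245,
                              pore_depth_um = NULL,
                              amphistomatous = FALSE,
                              formula = gsmax_diffusion) {
  if (any(density_mm2 < 0)) abort("`density_mm2` must be non-negative")
  if (any(size_um2 <= 0) || any(amax_um2 <= 0)) {
    abort("stomatal size and pore area must be positive")
  }
  alpha <- amax_um2 / size_um2
  if (any(alpha >= 1)) abort("pore area must be smaller than stomatal size (alpha < 1)")
  if (d <= 0 || v <= 0) abort("`d` and `v` must be positive")
  if (is.null(pore_depth_um)) pore_depth_um <- sqrt(size_um2 / 2) / 2
  if (any(pore_depth_um <= 0)) abort("pore depth must be positive")
  n_m2 <- density_mm2 * 1e6 * (1 + amphistomatous)
  formula(d, v, n_m2, amax_um2 * 1e-12, pore_depth_um * 1e-6)
}

#' @rdname theoretical_gsmax
#' @param density_m2,amax_m2,pore_depth_m SI-unit inputs of the formula
#'   function.
#' @export
gsmax_diffusion <- function(d, v, density_m2, amax_m2, pore_depth_m) {
  d * density_m2 * amax_m2 /
    (v * (pore_depth_m + (pi / 2) * sqrt(amax_m2 / pi)))
}

#' Theoretical specific hydraulic conductivity of a xylem transect
#'
#' Hagen-Poiseuille conductivity from the equivalent diameters of every
#' vessel in a sapwood transect:
#' \deqn{k_s = \frac{\pi \rho}{128 \eta A} \sum_i d_i^4}
#' with water density and viscosity fixed at their 20-degree values
#' (998.2 kg m-3, 1.002e-9 MPa s). The fourth-power law makes the result
#' extremely sensitive to the widest vessels.
#'
#' @param diameters_um Equivalent vessel diameters, um.
#' @param area_mm2 Transect area, mm2.
#' @param rho Water density, kg m-3.
#' @param eta Water viscosity, MPa s.
#' @return Conductivity in kg m-1 MPa-1 s-1.
#' @examples
#' hagen_poiseuille_ks(c(30, 40, 55), area_mm2 = 1.5)
#' @export
hagen_poiseuille_ks <- function(diameters_um, area_mm2,
                                rho = hydro_units()$rho_water,
                                eta = hydro_units()$eta_water) {
  if (length(diameters_um) == 0) abort("empty vessel list")
  if (any(diameters_um <= 0)) abort("vessel diameters must be positive")
  if (area_mm2 <= 0) abort("transect area must be positive")
  d_m <- diameters_um * 1e-6
  a_m2 <- area_mm2 * 1e-6
  pi * rho / (128 * eta * a_m2) * sum(d_m^4)
}

#' Whole-plant hydraulic conductance
#'
#' Transpiration flux per unit water-potential drawdown between pre-dawn and
#' midday: \eqn{K_{plant} = g_s D / (\Psi_{pd} - \Psi_{min})}. The conductance
#' must be measured at the same time of day as the midday potential. Units
#' follow the field convention: `gs` in mol m-2 s-1, `d` numerically in kPa,
#' the potential difference in MPa, giving `kplant` in mol m-2 s-1 MPa-1.
#'
#' @param gs Stomatal conductance at the midday sampling time, mol m-2 s-1.
#' @param d Vapour pressure deficit at that time, kPa.
#' @param psi_pd Pre-dawn leaf water potential, MPa (<= 0).
#' @param psi_min Minimum (midday) leaf water potential, MPa.
#' @return Plant hydraulic conductance, mol m-2 s-1 MPa-1 (vectorised).
#' @examples
#' kplant(0.2, 2, -0.4, -0.9) # 0.8
#' @export
kplant <- function(gs, d, psi_pd, psi_min) {
  if (any(psi_pd < psi_min)) {
    abort("inverted gradient: psi_pd below psi_min")
  }
  if (any(psi_pd == psi_min)) {
    abort("psi_pd equals psi_min: zero drawdown, conductance undefined")
  }
  gs * d / (psi_pd - psi_min)
}

#' Huber value
#'
#' Ratio of sapwood cross-sectional area to the leaf area it supplies
#' (cm2 cm-2), the allocation trait linking xylem supply with transpiring
#' area.
#'
#' @param sapwood_area_cm2 Sapwood area, cm2.
#' @param leaf_area_cm2 Supported leaf area, cm2.
#' @return Huber value (vectorised).
#' @export
huber_value <- function(sapwood_area_cm2, leaf_area_cm2) {
  if (any(sapwood_area_cm2 <= 0)) abort("sapwood area must be positive")
  if (any(leaf_area_cm2 <= 0)) abort("leaf area must be positive")
  sapwood_area_cm2 / leaf_area_cm2
}

#' Branch allometry between diameter and leaf area
#'
#' Power-law allometry fitted by OLS on the log-log scale,
#' \eqn{\ln LA = c_0 + c_1 \ln diam}, used to estimate the leaf area of
#' instrumented trees from branch diameters. Predictions outside the fitted
#' diameter range are allowed but always flagged as extrapolations.
#'
#' @param diameter_mm Branch diameters, mm; positive.
#' @param leaf_area_cm2 Measured leaf areas, cm2; positive.
#' @return Object of class `allometry_model` with coefficients `c0`, `c1`,
#'   the fitted diameter `range`, `r_squared` and `n`.
#' @export
allometry_fit <- function(diameter_mm, leaf_area_cm2) {
  if (length(diameter_mm) < 3) abort("allometry needs at least 3 branches")
  if (any(diameter_mm <= 0) || any(leaf_area_cm2 <= 0)) {
    abort("diameters and leaf areas must be positive")
  }
  ld <- log(diameter_mm)
  fit <- lm(log(leaf_area_cm2) ~ ld)
  structure(
    list(c0 = unname(coef(fit)[1]), c1 = unname(coef(fit)[2]),
         range = range(diameter_mm),
         r_squared = summary(fit)$r.squared,
         n = length(diameter_mm), model = fit),
    class = "allometry_model"
  )
}

#' @rdname allometry_fit
#' @param model An `allometry_model`.
#' @param diameter_mm Diameters at which to predict.
#' @return For `allometry_predict()`: tibble with `diameter_mm`,
#'   `leaf_area_cm2` (back-transformed) and the `extrapolated` flag.
#' @export
allometry_predict <- function(model, diameter_mm) {
  stopifnot(inherits(model, "allometry_model"))
  if (any(diameter_mm <= 0)) abort("diameters must be positive")
  tibble::tibble(
    diameter_mm = diameter_mm,
    leaf_area_cm2 = exp(model$c0 + model$c1 * log(diameter_mm)),
    extrapolated = diameter_mm < model$range[1] | diameter_mm > model$range[2]
  )
}

#' @export
print.allometry_model <- function(x, ...) {
  cat(sprintf(
    "Branch allometry: ln(LA cm2) = %.3f + %.3f ln(diam mm)  [%.1f-%.1f mm, n = %d, R2 = %.3f]\n",
    x$c0, x$c1, x$range[1], x$range[2], x$n, x$r_squared))
  invisible(x)
}

#' @rdname allometry_fit
#' @param x An `allometry_model`.
#' @param ... Unused.
#' @export
tidy.allometry_model <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  tibble::tibble(term = c("c0", "c1"), estimate = sm[, 1],
                 std.error = sm[, 2], statistic = sm[, 3], p.value = sm[, 4])
}

#' Stomatal-conductance reduction at the flux maximum
#'
#' Fraction of the maximum measured conductance still realised at the deficit
#' where sap flux peaks: \eqn{g_s(D_{Jsmax}) / g_{smax}}. Values marginally
#' above 1 (sampling noise) are clipped to 1 with a warning.
#'
#' @param gs_at_djsmax Conductance at the deficit of maximum flux.
#' @param gsmax_measured Maximum measured conductance (mean over measurement
#'   days of the tree's daily maximum).
#' @return Fraction in (0, 1] (vectorised).
#' @export
gs_reduction <- function(gs_at_djsmax, gsmax_measured) {
  if (any(gsmax_measured <= 0)) abort("measured gsmax must be positive")
  ratio <- gs_at_djsmax / gsmax_measured
  if (any(ratio > 1, na.rm = TRUE)) {
    warn(sprintf("%d reduction value(s) above 1 clipped (sampling noise)",
                 sum(ratio > 1, na.rm = TRUE)))
    ratio <- pmin(ratio, 1)
  }
  ratio
}

#' Ratio of maximum sap flux to maximum stomatal conductance
#'
#' Functional analogue of the Huber value: trees investing more sapwood per
#' leaf area need less flux per unit conductance, so this ratio declines as
#' the Huber value rises. Units: (cm h-1) / (mol m-2 s-1).
#'
#' @param jsmax Maximum sap flux density, cm h-1.
#' @param gsmax_measured Maximum measured conductance, mol m-2 s-1.
#' @return The quotient (vectorised).
#' @export
jsmax_over_gsmax <- function(jsmax, gsmax_measured) {
  if (any(gsmax_measured <= 0)) abort("measured gsmax must be positive")
  jsmax / gsmax_measured
}

#' Leaf vein density
#'
#' Length of minor vein per unit leaf area (mm mm-2); the major first vein is
#' excluded upstream in the measurement protocol.
#'
#' @param vein_length_mm Total measured vein length, mm.
#' @param leaf_area_mm2 Leaf area of the imaged region, mm2.
#' @return Vein density, mm mm-2 (vectorised).
#' @export
vein_density <- function(vein_length_mm, leaf_area_mm2) {
  if (any(leaf_area_mm2 <= 0)) abort("leaf area must be positive")
  if (any(vein_length_mm < 0)) abort("vein length must be non-negative")
  vein_length_mm / leaf_area_mm2
}

#' Species-level anatomical traits from sample tables
#'
#' Aggregates the three anatomical sample tables to one row per species:
#' Hagen-Poiseuille conductivity per transect averaged over samples,
#' theoretical maximum stomatal conductance from mean stomatal density and
#' geometry, and mean leaf vein density.
#'
#' @param vessels Tibble: `species`, `sample_id`, `transect_area_mm2`,
#'   `vessel_diameter_um`.
#' @param stomata Tibble: `species`, `stomatal_density_mm2`,
#'   `stomatal_size_um2`, `amax_um2`.
#' @param veins Tibble: `species`, `vein_length_mm`, `leaf_area_mm2`.
#' @param ... Passed to [theoretical_gsmax()] (e.g. `d`, `v`, `formula`).
#' @return Tibble: `species`, `ks_kg_m_mpa_s`, `gsmax_theoretical_mol_m2_s`,
#'   `vein_density_mm_mm2`.
#' @export
species_anatomy_traits <- function(vessels, stomata, veins, ...) {
  check_columns(vessels, c("species", "sample_id", "transect_area_mm2",
                           "vessel_diameter_um"), "vessels")
  check_columns(stomata, c("species", "stomatal_density_mm2",
                           "stomatal_size_um2", "amax_um2"), "stomata")
  check_columns(veins, c("species", "vein_length_mm", "leaf_area_mm2"), "veins")
  ks <- dplyr::group_by(tibble::as_tibble(vessels), .data$species, .data$sample_id) |>
    dplyr::summarise(
      ks = hagen_poiseuille_ks(.data$vessel_diameter_um,
                               .data$transect_area_mm2[1]),
      .groups = "drop_last"
    ) |>
    dplyr::summarise(ks_kg_m_mpa_s = mean(.data$ks), .groups = "drop")
  st <- dplyr::group_by(tibble::as_tibble(stomata), .data$species) |>
    dplyr::summarise(
      gsmax_theoretical_mol_m2_s = theoretical_gsmax(
        mean(.data$stomatal_density_mm2), mean(.data$stomatal_size_um2),
        mean(.data$amax_um2), ...),
      .groups = "drop"
    )
  vn <- dplyr::group_by(tibble::as_tibble(veins), .data$species) |>
    dplyr::summarise(
      vein_density_mm_mm2 = mean(vein_density(.data$vein_length_mm,
                                              .data$leaf_area_mm2)),
      .groups = "drop"
    )
  dplyr::left_join(ks, st, by = "species") |>
    dplyr::left_join(vn, by = "species")
}

#' Per-tree functional trait table
#'
#' Assembles the instrumented-tree trait record from the upstream stage
#' outputs: the Huber value from the species allometry applied to the tree's
#' branch diameter (extrapolations flagged), plant hydraulic conductance from
#' midday water-potential pairs averaged over measurement days, maximum
#' measured conductance (mean over days of the daily maximum), conductance at
#' the deficit of maximum flux (evaluated from a per-tree log-linear
#' conductance-deficit fit on morning data), the conductance reduction, and
#' the flux-to-conductance maximum ratio.
#'
#' @param fits A `flux_fits` tibble from [fit_flux_response()].
#' @param gas_exchange Tibble: `timestamp`, `tree_id`, `gs_mol_m2_s`.
#' @param met_data Tibble: `timestamp`, `d_kpa`.
#' @param water_potentials Tibble: `tree_id`, `psi_pd_mpa`, `psi_min_mpa`,
#'   `gs_midday_mol_m2_s`, `d_midday_kpa`.
#' @param instrumented Tibble: `tree_id`, `species`, `branch_diameter_mm`,
#'   `sapwood_area_cm2`.
#' @param branches Allometry sample tibble: `species`, `diameter_mm`,
#'   `leaf_area_cm2`.
#' @return Tibble, one row per tree, with `hv_cm2_cm2`, `hv_extrapolated`,
#'   `kplant_mol_m2_s_mpa`, `gsmax_measured_mol_m2_s`, `gs_at_djsmax`,
#'   `gs_reduction`, `jsmax_over_gsmax`, joined to the flux-fit columns.
#' @export
tree_traits <- function(fits, gas_exchange, met_data, water_potentials,
                        instrumented, branches) {
  check_columns(instrumented, c("tree_id", "species", "branch_diameter_mm",
                                "sapwood_area_cm2"), "instrumented")
  check_columns(branches, c("species", "diameter_mm", "leaf_area_cm2"), "branches")

  # Huber value via the species allometry
  hv_tbl <- dplyr::group_by(tibble::as_tibble(instrumented), .data$species) |>
    dplyr::group_modify(function(df, key) {
      br <- branches[branches$species == key$species, , drop = FALSE]
      mod <- allometry_fit(br$diameter_mm, br$leaf_area_cm2)
      pred <- allometry_predict(mod, df$branch_diameter_mm)
      df$hv_cm2_cm2 <- huber_value(df$sapwood_area_cm2, pred$leaf_area_cm2)
      df$hv_extrapolated <- pred$extrapolated
      df
    }) |>
    dplyr::ungroup()

  # Plant conductance: one value per pair, averaged per tree
  kp_tbl <- dplyr::group_by(tibble::as_tibble(water_potentials), .data$tree_id) |>
    dplyr::summarise(
      kplant_mol_m2_s_mpa = mean(kplant(.data$gs_midday_mol_m2_s,
                                        .data$d_midday_kpa,
                                        .data$psi_pd_mpa, .data$psi_min_mpa)),
      .groups = "drop"
    )

  # Measured gsmax: mean over days of the daily maximum, morning window
  ge <- dplyr::inner_join(tibble::as_tibble(gas_exchange),
                          tibble::as_tibble(met_data)[, c("timestamp", "d_kpa")],
                          by = "timestamp")
  ge_morning <- filter_morning(ge, quiet = TRUE)
  gsmax_tbl <- ge_morning |>
    dplyr::mutate(day = format(.data$timestamp, "%Y-%m-%d")) |>
    dplyr::group_by(.data$tree_id, .data$day) |>
    dplyr::summarise(gs_day_max = max(.data$gs_mol_m2_s), .groups = "drop_last") |>
    dplyr::summarise(gsmax_measured_mol_m2_s = mean(.data$gs_day_max),
                     .groups = "drop")

  # gs at the deficit of maximum flux from a log-linear gs-D fit per tree
  gs_at <- dplyr::group_by(ge_morning, .data$tree_id) |>
    dplyr::group_modify(function(df, key) {
      ok <- df$d_kpa > 0
      fit <- lm(gs_mol_m2_s ~ log(d_kpa), data = df[ok, ])
      tibble::tibble(gs_intercept = unname(coef(fit)[1]),
                     gs_slope_ln = unname(coef(fit)[2]))
    }) |>
    dplyr::ungroup()

  out <- tibble::as_tibble(fits) |>
    dplyr::left_join(hv_tbl, by = "tree_id") |>
    dplyr::left_join(kp_tbl, by = "tree_id") |>
    dplyr::left_join(gsmax_tbl, by = "tree_id") |>
    dplyr::left_join(gs_at, by = "tree_id") |>
    dplyr::mutate(
      gs_at_djsmax = pmax(0, .data$gs_intercept +
                             .data$gs_slope_ln * log(.data$d_jsmax_kpa)),
      gs_reduction = gs_reduction(.data$gs_at_djsmax,
                                  .data$gsmax_measured_mol_m2_s),
      jsmax_over_gsmax = jsmax_over_gsmax(.data$jsmax_cm_h,
                                          .data$gsmax_measured_mol_m2_s)
    ) |>
    dplyr::select(-"gs_intercept", -"gs_slope_ln")
  out
}
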