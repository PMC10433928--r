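#' Species trait presets for the campaign simulator
#'
#' Ground-truth trait bundles for five Mediterranean orchard species spanning
#' the observed ranges of the system: Huber value about 1--4 x 10-3 cm2 cm-2,
#' maximum stomatal conductance 0.11--0.27 mol m-2 s-1, deficit-at-maximum-flux
#' 2.9--4.9 kPa. `gsref` (conductance at D = 1 kPa) and `m_sens` (decline per
#' ln kPa) are back-solved per species from the target deficit at maximum flux
#' via \eqn{D^* = \exp(g_{sref}/m - 1)} and the target maximum conductance at
#' D = 0.1 kPa. Anatomical presets (vessel size/density, stomatal geometry,
#' branch allometry, vein density) are set so the derived theoretical traits
#' land in realistic ranges (e.g. measured:theoretical maximum-conductance
#' ratios of roughly 0.16--0.28).
#'
#' @return Tibble, one row per species, with columns `species`, `hv_cm2_cm2`,
#'   `gsref_mol_m2_s`, `m_sens`, `kplant_mol_m2_s_mpa`, `vessel_meanlog_um`,
#'   `vessel_sdlog`, `vessel_density_mm2`, `stomatal_density_mm2`,
#'   `stomatal_size_um2`, `amax_um2`, `allom_c0`, `allom_c1` (natural-log
#'   allometry of leaf area, cm2, on branch diameter, mm), and
#'   `vein_density_mm_mm2`.
#' @export
species_presets <- function() {
  tibble::tribble(
    ~species,     ~hv_cm2_cm2, ~gsref_mol_m2_s, ~m_sens, ~kplant_mol_m2_s_mpa,
    "almond",     3.83e-3,     0.14265,         0.05531, 3.94,
    "olive",      2.50e-3,     0.12383,         0.05046, 5.04,
    "orange",     1.50e-3,     0.07814,         0.03121, 2.00,
    "grapefruit", 1.20e-3,     0.06923,         0.03073, 1.80,
    "lemon",      1.00e-3,     0.05192,         0.02523, 1.25
  ) |>
    dplyr::mutate(
      vessel_meanlog_um = c(3.55, 3.20, 3.65, 3.70, 3.60),
      vessel_sdlog = 0.30,
      vessel_density_mm2 = c(60, 100, 50, 48, 52),
      stomatal_density_mm2 = c(350, 500, 300, 280, 260),
      stomatal_size_um2 = c(160, 180, 150, 150, 150),
      amax_um2 = 0.15 * .data$stomatal_size_um2,
      allom_c0 = c(0.207, 0.630, 1.141, 1.366, 1.548),
      allom_c1 = 2.0,
      vein_density_mm_mm2 = c(11.51, 8.2, 6.0, 5.5, 5.8)
    )
}

#' Simulation configuration for a synthetic field campaign
#'
#' Bundles every knob of the forward simulator: species presets, campaign
#' design (trees per species, days, cadence), the diurnal deficit ramp, noise
#' standard deviations, and the single seed that fixes all randomness. The
#' defaults mimic the emulated field design: three measurement days at 30-min
#' cadence, four instrumented trees for each of five species, deficit ramping
#' 0.1--4.5 kPa from dawn to solar noon.
#'
#' @param species Preset tibble as returned by [species_presets()] (may be
#'   subset or modified).
#' @param n_trees Instrumented trees per species.
#' @param n_days Measurement days.
#' @param interval_min Sampling cadence in minutes; must divide 24 h.
#' @param d_min,d_max Diurnal deficit ramp bounds, kPa.
#' @param tair_min,tair_max Diurnal air-temperature range, degrees C.
#' @param tleaf_offset_max Maximum midday leaf-minus-air temperature, degrees C.
#' @param sigma_js Gaussian noise SD on sap flux density, cm h-1.
#' @param sigma_gs Gaussian noise SD on measured conductance, mol m-2 s-1.
#' @param sigma_la Log-scale noise SD on branch leaf areas.
#' @param sigma_anat Log-scale noise SD on per-sample anatomical measurements.
#' @param sigma_trait Log-scale SD of tree-to-tree trait variation (Huber
#'   value, plant conductance) around the species preset.
#' @param psi_pd_range Well-watered pre-dawn water-potential range, MPa.
#' @param n_border Border (anatomy-sampled) trees per species.
#' @param start_date Date of the first measurement day.
#' @param ref_tair_c,ref_pressure_kpa Reference conditions at which the
#'   mechanistic constant is evaluated.
#' @param seed Integer seed fixing the full campaign byte-for-byte.
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_campaign()]
#' @export
sim_config <- function(species = species_presets(),
                       n_trees = 4, n_days = 3, interval_min = 30,
                       d_min = 0.1, d_max = 4.5,
                       tair_min = 18, tair_max = 35, tleaf_offset_max = 1,
                       sigma_js = 0.25, sigma_gs = 0.02,
                       sigma_la = 0.08, sigma_anat = 0.05,
                       sigma_trait = 0.25,
                       psi_pd_range = c(-0.5, -0.3),
                       n_border = 6,
                       start_date = "2020-06-01",
                       ref_tair_c = 20, ref_pressure_kpa = 101.3,
                       seed = 42L) {
  cfg <- list(
    species = tibble::as_tibble(species), n_trees = n_trees, n_days = n_days,
    interval_min = interval_min, d_min = d_min, d_max = d_max,
    tair_min = tair_min, tair_max = tair_max,
    tleaf_offset_max = tleaf_offset_max,
    sigma_js = sigma_js, sigma_gs = sigma_gs, sigma_la = sigma_la,
    sigma_anat = sigma_anat, sigma_trait = sigma_trait,
    psi_pd_range = psi_pd_range, n_border = n_border,
    start_date = as.Date(start_date),
    ref_tair_c = ref_tair_c, ref_pressure_kpa = ref_pressure_kpa,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  need <- c("species", "hv_cm2_cm2", "gsref_mol_m2_s", "m_sens",
            "kplant_mol_m2_s_mpa", "vessel_meanlog_um", "vessel_sdlog",
            "vessel_density_mm2", "stomatal_density_mm2", "stomatal_size_um2",
            "amax_um2", "allom_c0", "allom_c1", "vein_density_mm_mm2")
  check_columns(cfg$species, need, "species presets")
  pos_cols <- setdiff(need, c("species", "allom_c0", "allom_c1"))
  for (col in pos_cols) {
    if (any(!is.finite(cfg$species[[col]]) | cfg$species[[col]] <= 0)) {
      abort(sprintf("species preset column `%s` must be strictly positive", col))
    }
  }
  if (1440 %% cfg$interval_min != 0) {
    abort("`interval_min` must divide 24 h (1440 min)")
  }
  if (cfg$d_min >= cfg$d_max) abort("`d_min` must be below `d_max`")
  if (cfg$d_min < 0) abort("`d_min` must be non-negative")
  sig <- c(cfg$sigma_js, cfg$sigma_gs, cfg$sigma_la, cfg$sigma_anat, cfg$sigma_trait)
  if (any(sig < 0)) abort("noise standard deviations must be non-negative")
  if (cfg$n_trees < 1 || cfg$n_days < 1) abort("`n_trees` and `n_days` must be >= 1")
  if (length(cfg$psi_pd_range) != 2 || any(cfg$psi_pd_range > 0) ||
      cfg$psi_pd_range[1] > cfg$psi_pd_range[2]) {
    abort("`psi_pd_range` must be an increasing pair of non-positive MPa values")
  }
  invisible(cfg)
}

# Deterministic diurnal drivers shared by all trees: a truncated-sine deficit
# ramp from d_min (night) up to d_max at solar noon (12:00), air temperature
# tracking the ramp, leaf temperature warmed above air in proportion to the
# ramp, and relative humidity back-solved so that
# leaf_vpd(tleaf, tair, rh) reproduces the stored deficit exactly.
diurnal_met <- function(cfg) {
  step <- cfg$interval_min / 60
  days <- seq_len(cfg$n_days) - 1
  hours <- seq(0, 24 - step, by = step)
  grid <- expand.grid(hour = hours, day = days)
  frac <- pmax(0, sin(pi * (grid$hour - 6) / 12)) # 0 outside 06-18 h
  d <- cfg$d_min + (cfg$d_max - cfg$d_min) * frac
  tair <- cfg$tair_min + (cfg$tair_max - cfg$tair_min) * frac
  tleaf <- tair + cfg$tleaf_offset_max * frac
  rh <- (es_tetens(tleaf) - d) / es_tetens(tair)
  ts <- as.POSIXct(cfg$start_date, tz = "UTC") + (grid$day * 24 + grid$hour) * 3600
  tibble::tibble(
    timestamp = ts,
    tair_c = tair, tleaf_c = tleaf, rh_frac = rh, d_kpa = d,
    rs_w_m2 = 1000 * frac,
    u_m_s = 1.5
  )
}

#' Simulate the diurnal series for one tree
#'
#' Forward model for a single instrumented tree over the full campaign:
#' microclimate (shared deterministic drivers), stomatal conductance
#' declining log-linearly with deficit, \eqn{g_s = \max(0, g_{sref} - m \ln D)},
#' and sap flux density obtained by inverting the trait-based conductance
#' model, \eqn{J_s = g_s D / (C_{full} H_v) + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma_{Js}^2)}, with \eqn{C_{full}} the fully
#' unit-harmonised mechanistic factor. Measured conductance carries its own
#' Gaussian error and is floored at zero. Noise-free flux is non-negative by
#' construction.
#'
#' @param config A [sim_config()].
#' @param gsref,m_sens,hv Tree-level reference conductance (mol m-2 s-1 at
#'   D = 1 kPa), log-deficit sensitivity, and Huber value.
#' @param tree_id Identifier stamped on the series.
#' @param seed Optional integer; when given, the RNG is seeded locally so the
#'   call is reproducible in isolation.
#' @return List with tibbles `met`, `gas_exchange` (daytime conductance
#'   readings), `sap_flux` (half-hourly flux with `js_true_cm_h` retained).
#' @export
simulate_diurnal <- function(config, gsref, m_sens, hv, tree_id = "tree_1",
                             seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(gsref) || gsref <= 0) abort("`gsref` must be positive")
  if (!is.finite(m_sens) || m_sens <= 0) abort("`m_sens` must be positive")
  if (!is.finite(hv) || hv <= 0) abort("`hv` must be positive")
  if (!is.null(seed)) set.seed(seed)
  mc <- mechanistic_constant(config$ref_tair_c, config$ref_pressure_kpa)
  met <- diurnal_met(config)
  gs_true <- pmax(0, gsref - m_sens * log(met$d_kpa))
  js_true <- gs_true * met$d_kpa / (mc$js_gs_factor * hv)
  js_obs <- js_true + rnorm(length(js_true), 0, config$sigma_js)
  sap_flux <- tibble::tibble(
    timestamp = met$timestamp, tree_id = tree_id,
    js_cm_h = js_obs, js_true_cm_h = js_true
  )
  day <- met$rs_w_m2 > 0
  gas_exchange <- tibble::tibble(
    timestamp = met$timestamp[day], tree_id = tree_id,
    gs_mol_m2_s = pmax(0, gs_true[day] +
                          rnorm(sum(day), 0, config$sigma_gs)),
    gs_true_mol_m2_s = gs_true[day],
    tleaf_c = met$tleaf_c[day]
  )
  list(met = met, gas_exchange = gas_exchange, sap_flux = sap_flux)
}

#' Simulate anatomical sample tables for one species
#'
#' Draws the four measurement tables the trait calculators consume, for the
#' border trees of one species: vessel transects (lognormal equivalent
#' diameters on a fixed transect area), stomatal counts and sizes, branch
#' diameter--leaf-area pairs following the species' log-log allometry, and
#' leaf vein densities. All tables carry sample identifiers and unit-bearing
#' column names.
#'
#' @param config A [sim_config()].
#' @param species Species name; must match a preset row.
#' @param seed Optional local seed.
#' @return List of tibbles `vessels`, `stomata`, `branches`, `veins`.
#' @export
simulate_anatomy <- function(config, species, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  preset <- config$species[config$species$species == species, ]
  if (nrow(preset) != 1) abort(sprintf("no preset for species '%s'", species))
  if (!is.null(seed)) set.seed(seed)
  nb <- config$n_border
  transect_area_mm2 <- 1.5

  vessels <- purrr::map_dfr(seq_len(nb), function(i) {
    n_v <- max(1L, round(preset$vessel_density_mm2 * transect_area_mm2))
    tibble::tibble(
      species = species, sample_id = paste0(species, "_branch_", i),
      transect_area_mm2 = transect_area_mm2,
      vessel_diameter_um = rlnorm(n_v, preset$vessel_meanlog_um, preset$vessel_sdlog)
    )
  })

  stomata <- tibble::tibble(
    species = species,
    sample_id = paste0(species, "_leaf_", seq_len(nb)),
    stomatal_density_mm2 = preset$stomatal_density_mm2 *
      exp(rnorm(nb, 0, config$sigma_anat)),
    stomatal_size_um2 = preset$stomatal_size_um2 *
      exp(rnorm(nb, 0, config$sigma_anat)),
    side = "abaxial"
  )
  stomata$amax_um2 <- 0.15 * stomata$stomatal_size_um2

  n_branches <- nb + 2
  diam <- runif(n_branches, 6.2, 20)
  branches <- tibble::tibble(
    species = species,
    sample_id = paste0(species, "_allom_", seq_len(n_branches)),
    diameter_mm = diam,
    leaf_area_cm2 = exp(preset$allom_c0 + preset$allom_c1 * log(diam) +
                          rnorm(n_branches, 0, config$sigma_la))
  )

  veins <- tibble::tibble(
    species = species,
    sample_id = paste0(species, "_vein_", seq_len(nb)),
    leaf_area_mm2 = 10,
    vein_length_mm = 10 * preset$vein_density_mm_mm2 *
      exp(rnorm(nb, 0, config$sigma_anat))
  )

  list(vessels = vessels, stomata = stomata, branches = branches, veins = veins)
}

#' Simulate a pre-dawn / midday water-potential pair
#'
#' Inverts the whole-plant conductance definition so that the conductance is
#' recoverable downstream: the midday potential is the pre-dawn potential
#' minus the transpiration-driven drawdown
#' \eqn{g_s D / K_{plant}} (MPa, with D in kPa under the documented
#' convention). The pre-dawn potential is drawn uniformly from the configured
#' well-watered range.
#'
#' @param config A [sim_config()].
#' @param kplant_true Whole-plant hydraulic conductance, mol m-2 s-1 MPa-1.
#' @param gs_midday Conductance at the midday sampling time, mol m-2 s-1.
#' @param d_midday Deficit at the midday sampling time, kPa.
#' @param tree_id Identifier.
#' @param seed Optional local seed.
#' @return One-row tibble: `tree_id`, `psi_pd_mpa`, `psi_min_mpa`,
#'   `gs_midday_mol_m2_s`, `d_midday_kpa`.
#' @export
simulate_water_potentials <- function(config, kplant_true, gs_midday, d_midday,
                                      tree_id = "tree_1", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(kplant_true) || kplant_true <= 0) {
    abort("`kplant_true` must be positive")
  }
  if (gs_midday < 0 || d_midday < 0) abort("conductance and deficit must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  psi_pd <- runif(1, config$psi_pd_range[1], config$psi_pd_range[2])
  drawdown <- gs_midday * d_midday / kplant_true
  psi_min <- psi_pd - drawdown
  if (psi_min > psi_pd) abort("midday potential above pre-dawn potential")
  tibble::tibble(
    tree_id = tree_id,
    psi_pd_mpa = psi_pd, psi_min_mpa = psi_min,
    gs_midday_mol_m2_s = gs_midday, d_midday_kpa = d_midday
  )
}

#' Simulate a full multi-species field campaign
#'
#' Runs the forward model for every instrumented tree of every species in the
#' configuration: shared microclimate, per-tree conductance and sap-flux
#' series, midday water-potential pairs, per-species anatomical tables, and a
#' ground-truth sidecar holding each tree's true traits. Tree-level Huber
#' value and plant conductance vary lognormally around the species preset
#' with SD `sigma_trait`, and each tree's conductance curve (`gsref`, `m`)
#' scales with its Huber value — the hydraulic coordination between sapwood
#' allocation and gas exchange that the trait-based model describes — which
#' leaves the hump position \eqn{\exp(g_{sref}/m - 1)} a species property.
#' A branch diameter is drawn for each instrumented
#' tree and its sapwood area set to `hv_tree` times the allometric leaf area,
#' so the downstream Huber pipeline can be audited end to end. All randomness
#' flows from `config$seed`; the same configuration reproduces the campaign
#' byte-for-byte.
#'
#' @param config A [sim_config()].
#' @return Object of class `hydro_campaign`: list with tibbles `met`,
#'   `sap_flux`, `gas_exchange`, `water_potentials`, `instrumented` (branch
#'   diameter + sapwood area per tree), anatomy tables (`vessels`, `stomata`,
#'   `branches`, `veins`), `truth` (per-tree ground truth), and the `config`.
#' @examples
#' cfg <- sim_config(species = species_presets()[1:2, ], n_trees = 2, seed = 1)
#' camp <- simulate_campaign(cfg)
#' names(camp)
#' @export
simulate_campaign <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  mc <- mechanistic_constant(config$ref_tair_c, config$ref_pressure_kpa)

  sap_flux <- list(); gas_exchange <- list(); wp <- list()
  truth <- list(); instrumented <- list()
  vessels <- list(); stomata <- list(); branches <- list(); veins <- list()
  met <- diurnal_met(config)
  noon_idx <- which(format(met$timestamp, "%H:%M") == "12:00")

  for (si in seq_len(nrow(config$species))) {
    preset <- config$species[si, ]
    anat <- simulate_anatomy(config, preset$species)
    vessels[[si]] <- anat$vessels; stomata[[si]] <- anat$stomata
    branches[[si]] <- anat$branches; veins[[si]] <- anat$veins

    for (ti in seq_len(config$n_trees)) {
      id <- paste0(preset$species, "_", ti)
      hv_tree <- preset$hv_cm2_cm2 * exp(rnorm(1, 0, config$sigma_trait))
      kp_tree <- preset$kplant_mol_m2_s_mpa * exp(rnorm(1, 0, config$sigma_trait))
      # Tree-level hydraulic coordination: a tree's conductance curve scales
      # with its sapwood allocation (gs tracks leaf-area-specific supply,
      # K_L = ks * Hv), so gsref and m scale together with Hv -- the hump
      # position exp(gsref/m - 1) is a species property and is preserved.
      coord <- hv_tree / preset$hv_cm2_cm2
      gsref_tree <- preset$gsref_mol_m2_s * coord
      m_tree <- preset$m_sens * coord
      series <- simulate_diurnal(config, gsref_tree, m_tree,
                                 hv_tree, tree_id = id)
      sap_flux[[id]] <- series$sap_flux
      gas_exchange[[id]] <- series$gas_exchange

      gs_noon <- max(0, gsref_tree - m_tree * log(config$d_max))
      wp_days <- purrr::map_dfr(seq_len(config$n_days), function(day) {
        simulate_water_potentials(config, kp_tree, gs_noon, config$d_max,
                                  tree_id = id)
      })
      wp_days$day <- seq_len(config$n_days)
      wp[[id]] <- wp_days

      diam <- runif(1, 8, 18)
      la_true <- exp(preset$allom_c0 + preset$allom_c1 * log(diam))
      instrumented[[id]] <- tibble::tibble(
        tree_id = id, species = preset$species,
        branch_diameter_mm = diam,
        sapwood_area_cm2 = hv_tree * la_true
      )
      truth[[id]] <- tibble::tibble(
        tree_id = id, species = preset$species,
        hv_cm2_cm2 = hv_tree,
        kplant_mol_m2_s_mpa = kp_tree,
        gsref_mol_m2_s = gsref_tree,
        m_sens = m_tree,
        d_star_kpa = exp(gsref_tree / m_tree - 1),
        allom_c0 = preset$allom_c0, allom_c1 = preset$allom_c1,
        vein_density_mm_mm2 = preset$vein_density_mm_mm2,
        js_gs_factor = mc$js_gs_factor
      )
    }
  }

  structure(
    list(
      met = met,
      sap_flux = dplyr::bind_rows(sap_flux),
      gas_exchange = dplyr::bind_rows(gas_exchange),
      water_potentials = dplyr::bind_rows(wp),
      instrumented = dplyr::bind_rows(instrumented),
      vessels = dplyr::bind_rows(vessels),
      stomata = dplyr::bind_rows(stomata),
      branches = dplyr::bind_rows(branches),
      veins = dplyr::bind_rows(veins),
      truth = dplyr::bind_rows(truth),
      config = config,
      constant = mc
    ),
    class = "hydro_campaign"
  )
}

#' @export
print.hydro_campaign <- function(x, ...) {
  cat("Synthetic hydraulic-trait campaign\n")
  cat(sprintf("  %d species x %d trees, %d day(s) at %d-min cadence\n",
              nrow(x$config$species), x$config$n_trees, x$config$n_days,
              x$config$interval_min))
  cat(sprintf("  deficit ramp %.2f-%.2f kPa; seed %d\n",
              x$config$d_min, x$config$d_max, x$config$seed))
  invisible(x)
}

#' Write a campaign to tidy CSV files plus a ground-truth sidecar
#'
#' One CSV per table (ISO-8601 timestamps, unit-bearing column names) and a
#' JSON sidecar with the per-tree ground truth and the configuration scalars,
#' so a written campaign is fully reconstructable and auditable.
#'
#' @param campaign A `hydro_campaign`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_campaign <- function(campaign, dir) {
  stopifnot(inherits(campaign, "hydro_campaign"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("met", "sap_flux", "gas_exchange", "water_potentials",
              "instrumented", "vessels", "stomata", "branches", "veins")
  files <- character(0)
  for (tb in tables) {
    path <- file.path(dir, paste0(tb, ".csv"))
    df <- campaign[[tb]]
    if ("timestamp" %in% names(df)) {
      df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
    readr::write_csv(df, path)
    files <- c(files, path)
  }
  sidecar <- file.path(dir, "ground_truth.json")
  cfg <- campaign$config
  jsonlite::write_json(
    list(
      truth = campaign$truth,
      config = cfg[setdiff(names(cfg), "species")],
      species_presets = cfg$species
    ),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(files, sidecar))
}
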