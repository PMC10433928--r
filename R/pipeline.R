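# Table schemas for the interchange CSVs. Column names carry their units;
# `aliases` maps accepted alternative unit headers to (canonical name,
# multiplicative factor). Mandatory columns missing after alias resolution
# are errors naming the column and expected unit.
.hydro_schemas <- list(
  microclimate = list(
    mandatory = c("timestamp", "d_kpa"),
    optional = c("tair_c", "tleaf_c", "rh_frac", "rs_w_m2", "u_m_s"),
    aliases = list(
      d_hpa = list(to = "d_kpa", factor = 0.1),
      d_pa = list(to = "d_kpa", factor = 1e-3)
    )
  ),
  sapflux = list(
    mandatory = c("timestamp", "tree_id", "js_cm_h"),
    optional = c("js_true_cm_h"),
    aliases = list(
      js_mm_h = list(to = "js_cm_h", factor = 0.1),
      js_m_h = list(to = "js_cm_h", factor = 100)
    )
  ),
  gas_exchange = list(
    mandatory = c("timestamp", "tree_id", "gs_mol_m2_s"),
    optional = c("tleaf_c", "gs_true_mol_m2_s"),
    aliases = list(
      gs_mmol_m2_s = list(to = "gs_mol_m2_s", factor = 1e-3)
    )
  ),
  vessels = list(
    mandatory = c("species", "sample_id", "transect_area_mm2", "vessel_diameter_um"),
    optional = character(0),
    aliases = list(
      vessel_diameter_mm = list(to = "vessel_diameter_um", factor = 1000)
    )
  ),
  stomata = list(
    mandatory = c("species", "sample_id", "stomatal_density_mm2",
                  "stomatal_size_um2", "amax_um2"),
    optional = c("side"),
    aliases = list()
  ),
  branches = list(
    mandatory = c("species", "sample_id", "diameter_mm", "leaf_area_cm2"),
    optional = character(0),
    aliases = list(
      diameter_cm = list(to = "diameter_mm", factor = 10),
      leaf_area_m2 = list(to = "leaf_area_cm2", factor = 1e4)
    )
  )
)

#' Read an interchange CSV against a declared schema
#'
#' Strict reader for the six measurement-table schemas (`microclimate`,
#' `sapflux`, `gas_exchange`, `vessels`, `stomata`, `branches`). Column
#' headers carry units; recognised alternative unit headers (e.g.
#' `js_mm_h` where `js_cm_h` is expected) are converted with the declared
#' factor and the conversion reported. A mandatory column that is absent
#' under any recognised unit is an error naming the column; unknown extra
#' columns are preserved. Timestamps must parse as ISO-8601; malformed rows
#' are errors reporting the line number.
#'
#' @param path CSV path.
#' @param schema One of the schema names above.
#' @return Tibble in canonical units.
#' @export
read_hydro_csv <- function(path, schema) {
  if (!schema %in% names(.hydro_schemas)) {
    abort(sprintf("unknown schema '%s'; available: %s", schema,
                  paste(names(.hydro_schemas), collapse = ", ")))
  }
  sc <- .hydro_schemas[[schema]]
  ct <- if ("timestamp" %in% sc$mandatory) {
    readr::cols(timestamp = readr::col_character(),
                .default = readr::col_guess())
  } else {
    readr::cols(.default = readr::col_guess())
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        col_types = ct)
  for (alias in names(sc$aliases)) {
    if (alias %in% names(df)) {
      spec_al <- sc$aliases[[alias]]
      inform(sprintf("%s: converting column '%s' to '%s' (factor %g)",
                     basename(path), alias, spec_al$to, spec_al$factor))
      df[[spec_al$to]] <- df[[alias]] * spec_al$factor
      df[[alias]] <- NULL
    }
  }
  missing <- setdiff(sc$mandatory, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing mandatory column(s) %s for schema '%s'",
                  basename(path), paste(missing, collapse = ", "), schema))
  }
  if ("timestamp" %in% sc$mandatory) {
    raw <- as.character(df$timestamp)
    ts <- as.POSIXct(rep(NA_real_, length(raw)), origin = "1970-01-01", tz = "UTC")
    for (fmt in c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                  "%Y-%m-%d %H:%M:%S")) {
      need <- is.na(ts) & !is.na(raw)
      if (!any(need)) break
      ts[need] <- as.POSIXct(strptime(raw[need], fmt, tz = "UTC"), tz = "UTC")
    }
    bad <- which(is.na(ts) & !is.na(raw))
    if (length(bad)) {
      abort(sprintf("%s: malformed ISO-8601 timestamp at data line %d ('%s')",
                    basename(path), bad[1], raw[bad[1]]))
    }
    df$timestamp <- ts
  }
  tibble::as_tibble(df)
}

#' Write an interchange CSV
#'
#' Companion writer to [read_hydro_csv()]: ISO-8601 timestamps, canonical
#' unit-bearing headers, full double precision (a write-read round trip
#' preserves values to better than 1e-12).
#'
#' @param data Tibble to write.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_hydro_csv <- function(data, path) {
  df <- tibble::as_tibble(data)
  if ("timestamp" %in% names(df)) {
    df$timestamp <- format(df$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  readr::write_csv(df, path)
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects everything the end-to-end driver needs: either a simulation
#' configuration (synthetic campaign) or a set of input CSV paths, the
#' calibration mode, the significance level, and an optional output
#' directory. Serialises losslessly to YAML via [write_pipeline_config()].
#'
#' @param sim A [sim_config()], or `NULL` when reading measured CSVs.
#' @param inputs Named list of CSV paths (`microclimate`, `sapflux`,
#'   `gas_exchange`, `vessels`, `stomata`, `branches`, ...) used when
#'   `sim` is `NULL`. Paths must resolve at validation time.
#' @param calibration_intercept Calibrate with an intercept (`TRUE`) or in
#'   strict proportional mode.
#' @param alpha Significance level used throughout.
#' @param out_dir Directory for stage outputs and the JSON summary; `NULL`
#'   keeps everything in memory.
#' @param n_boot Bootstrap resamples for relative-importance intervals.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), inputs = NULL,
                            calibration_intercept = TRUE, alpha = 0.05,
                            out_dir = NULL, n_boot = 1000) {
  if (is.null(sim) && is.null(inputs)) {
    abort("either a simulation block or input paths must be given")
  }
  if (!is.null(inputs)) {
    unresolved <- names(inputs)[!vapply(inputs, file.exists, logical(1))]
    if (length(unresolved)) {
      abort(sprintf("unresolvable input path(s): %s",
                    paste(unresolved, collapse = ", ")))
    }
  }
  structure(
    list(sim = sim, inputs = inputs,
         calibration_intercept = calibration_intercept,
         alpha = alpha, out_dir = out_dir, n_boot = n_boot),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @param path YAML destination / source.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- config$sim
  sim_list <- if (is.null(sim)) NULL else {
    scalars <- sim[setdiff(names(sim), "species")]
    scalars$start_date <- as.character(scalars$start_date)
    list(scalars = scalars,
         species = lapply(seq_len(nrow(sim$species)),
                          function(i) as.list(sim$species[i, ])))
  }
  yaml::write_yaml(
    list(sim = sim_list,
         inputs = config$inputs,
         calibration_intercept = config$calibration_intercept,
         alpha = config$alpha, out_dir = config$out_dir,
         n_boot = config$n_boot),
    path
  )
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(raw$sim)) {
    species <- dplyr::bind_rows(lapply(raw$sim$species, tibble::as_tibble))
    args <- raw$sim$scalars
    args$psi_pd_range <- as.numeric(args$psi_pd_range)
    sim <- do.call(sim_config, c(list(species = species), args))
  }
  pipeline_config(sim = sim, inputs = raw$inputs,
                  calibration_intercept = raw$calibration_intercept %||% TRUE,
                  alpha = raw$alpha %||% 0.05,
                  out_dir = raw$out_dir, n_boot = raw$n_boot %||% 1000)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: simulate (or load) the campaign, fit per-tree sap-flux
#' response curves, compute anatomical and functional traits, calibrate the
#' conductance model, and run the cross-species statistical layer (principal
#' components, sensitivity-on-scores regression, calibration-quality trait
#' model with LMG shares, Tukey comparisons per variable). A stage failure
#' halts the run naming the stage. For a fixed seed the result — including
#' the written summary — is identical across runs.
#'
#' @param config A [pipeline_config()].
#' @return Object of class `hydro_pipeline`: the campaign tables plus
#'   `flux_fits`, `calibration`, `tree_traits`, `species_traits`, `pca`,
#'   `m_js_on_pcs`, `slope_hv`, `r2_model`, `tukey` (list per variable), and
#'   `summary` (the flattened numeric summary that is also written to JSON
#'   when `out_dir` is set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))

  data <- run_stage("load", {
    if (!is.null(config$sim)) {
      simulate_campaign(config$sim)
    } else {
      req <- c("microclimate", "sapflux", "vessels", "stomata", "branches")
      missing <- setdiff(req, names(config$inputs))
      if (length(missing)) {
        abort(sprintf("missing input path(s): %s", paste(missing, collapse = ", ")))
      }
      list(
        met = read_hydro_csv(config$inputs$microclimate, "microclimate"),
        sap_flux = read_hydro_csv(config$inputs$sapflux, "sapflux"),
        gas_exchange = if (!is.null(config$inputs$gas_exchange))
          read_hydro_csv(config$inputs$gas_exchange, "gas_exchange")
          else NULL,
        vessels = read_hydro_csv(config$inputs$vessels, "vessels"),
        stomata = read_hydro_csv(config$inputs$stomata, "stomata"),
        branches = read_hydro_csv(config$inputs$branches, "branches"),
        water_potentials = if (!is.null(config$inputs$water_potentials))
          readr::read_csv(config$inputs$water_potentials, show_col_types = FALSE)
          else NULL,
        instrumented = if (!is.null(config$inputs$instrumented))
          readr::read_csv(config$inputs$instrumented, show_col_types = FALSE)
          else NULL,
        veins = if (!is.null(config$inputs$veins))
          readr::read_csv(config$inputs$veins, show_col_types = FALSE)
          else NULL
      )
    }
  })

  fits <- run_stage("fit-flux", {
    fit_flux_response(data$sap_flux, data$met, window = "morning")
  })

  calib <- run_stage("calibrate-gs", {
    if (is.null(data$gas_exchange)) abort("gas-exchange table is required")
    suppressMessages(calibrate_gs(
      data$gas_exchange, data$sap_flux, data$met,
      intercept = config$calibration_intercept
    ))
  })

  traits_tree <- run_stage("traits", {
    tree_traits(fits, data$gas_exchange, data$met, data$water_potentials,
                data$instrumented, data$branches)
  })
  species_tr <- run_stage("traits", {
    species_anatomy_traits(data$vessels, data$stomata, data$veins)
  })

  traits_full <- run_stage("multitrait", {
    dplyr::left_join(traits_tree,
                     dplyr::select(calib, "tree_id", calib_slope = "slope",
                                   calib_r2 = "r_squared",
                                   calib_p = "p_value"),
                     by = "tree_id") |>
      dplyr::left_join(species_tr, by = "species")
  })

  pca <- run_stage("multitrait", {
    trait_pca(dplyr::select(
      traits_full, "tree_id", "species",
      "hv_cm2_cm2", "kplant_mol_m2_s_mpa", "gsmax_measured_mol_m2_s",
      "jsmax_over_gsmax", "gs_reduction",
      "ks_kg_m_mpa_s", "gsmax_theoretical_mol_m2_s", "vein_density_mm_mm2"
    ))
  })
  m_js_on_pcs <- run_stage("multitrait", {
    regress_on_pcs(traits_full$m_js, pca, k = 2)
  })
  slope_hv <- run_stage("multitrait", {
    slope_vs_hv(calib, traits_full[, c("tree_id", "hv_cm2_cm2")],
                alpha = config$alpha)
  })
  r2_model <- run_stage("multitrait", {
    fit_r2_model(dplyr::rename(traits_full, r_squared = "calib_r2"),
                 n_boot = config$n_boot, seed = config$sim$seed %||% 1)
  })
  tukey <- run_stage("multitrait", {
    vars <- c("d_jsmax_kpa", "m_js", "gs_reduction", "hv_cm2_cm2",
              "jsmax_over_gsmax", "kplant_mol_m2_s_mpa")
    out <- lapply(vars, function(v) {
      ok <- is.finite(traits_full[[v]])
      tukey_compare(traits_full[[v]][ok], traits_full$species[ok],
                    alpha = config$alpha)
    })
    names(out) <- vars
    out
  })

  summary <- list(
    n_trees = nrow(traits_full),
    n_species = length(unique(traits_full$species)),
    flux_fits = fits,
    calibration = calib,
    slope_vs_hv = slope_hv,
    r2_model_r_squared = r2_model$r_squared,
    r2_model_p = r2_model$p_value,
    lmg_shares = r2_model$relimp,
    pca_var_frac = pca$var_frac,
    m_js_model_r2 = m_js_on_pcs$r_squared
  )

  result <- structure(
    list(
      campaign = data, flux_fits = fits, calibration = calib,
      tree_traits = traits_full, species_traits = species_tr,
      pca = pca, m_js_on_pcs = m_js_on_pcs, slope_hv = slope_hv,
      r2_model = r2_model, tukey = tukey, summary = summary,
      config = config
    ),
    class = "hydro_pipeline"
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_hydro_csv(fits, file.path(config$out_dir, "flux_fits.csv"))
    write_hydro_csv(calib, file.path(config$out_dir, "calibration.csv"))
    write_hydro_csv(traits_full, file.path(config$out_dir, "tree_traits.csv"))
    write_hydro_csv(species_tr, file.path(config$out_dir, "species_traits.csv"))
    letters_tbl <- purrr::imap_dfr(tukey, function(tc, v) {
      dplyr::mutate(tc$groups, variable = v, .before = 1)
    })
    write_hydro_csv(letters_tbl, file.path(config$out_dir, "tukey_letters.csv"))
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' @export
print.hydro_pipeline <- function(x, ...) {
  cat("Hydraulic-trait pipeline result\n")
  cat(sprintf("  %d trees, %d species\n", x$summary$n_trees, x$summary$n_species))
  cat(sprintf("  calibration slope ~ Hv: slope = %.3g, R2 = %.3f, p = %.3g\n",
              x$slope_hv$slope, x$slope_hv$r_squared, x$slope_hv$p_value))
  cat(sprintf("  calibration R2 ~ (Hv, Kplant): R2 = %.3f; LMG shares %s\n",
              x$r2_model$r_squared,
              paste(sprintf("%s %.3f", x$r2_model$relimp$term,
                            x$r2_model$relimp$lmg_share), collapse = ", ")))
  invisible(x)
}
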