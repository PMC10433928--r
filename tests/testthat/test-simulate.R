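test_that("identical configuration and seed reproduce the campaign byte-for-byte", {
  c1 <- simulate_campaign(small_config(seed = 11))
  c2 <- simulate_campaign(small_config(seed = 11))
  for (tb in c("met", "sap_flux", "gas_exchange", "water_potentials", "truth",
               "vessels", "stomata", "branches", "veins")) {
    expect_identical(c1[[tb]], c2[[tb]], label = tb)
  }
  # and byte-for-byte on serialized CSV
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_campaign(c1, d1); write_campaign(c2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})

test_that("noise-free flux equals the inverted conductance model at every timestamp", {
  cfg <- zero_noise_config()
  camp <- simulate_campaign(cfg)
  mc <- camp$constant
  joined <- dplyr::inner_join(camp$sap_flux, camp$met[, c("timestamp", "d_kpa")],
                              by = "timestamp") |>
    dplyr::left_join(camp$truth[, c("tree_id", "hv_cm2_cm2", "gsref_mol_m2_s",
                                    "m_sens")], by = "tree_id")
  gs_true <- pmax(0, joined$gsref_mol_m2_s - joined$m_sens * log(joined$d_kpa))
  expect_equal(joined$js_cm_h,
               gs_true * joined$d_kpa / (mc$js_gs_factor * joined$hv_cm2_cm2),
               tolerance = 1e-12)
  expect_true(all(joined$js_true_cm_h >= 0))
})

test_that("the noise-free flux hump sits at the closed-form deficit", {
  cfg <- small_config()
  # hump outside a 4.5 kPa ramp: exp(0.2/0.05 - 1) = exp(3), flux monotone
  s1 <- simulate_diurnal(cfg, gsref = 0.2, m_sens = 0.05, hv = 2e-3, seed = 1)
  expect_equal(d_star(0.2, 0.05), exp(3), tolerance = 1e-12)
  morning <- dplyr::inner_join(s1$sap_flux, s1$met[, c("timestamp", "d_kpa")],
                               by = "timestamp")
  morning <- morning[format(morning$timestamp, "%H") < "12" &
                       format(morning$timestamp, "%d") == "01" &
                       morning$d_kpa > 0.1, ]
  ord <- order(morning$d_kpa)
  expect_true(all(diff(morning$js_true_cm_h[ord]) > 0))
  # hump inside the ramp at exp(1.4) ~ 4.055 kPa, found by grid search
  s2 <- simulate_diurnal(cfg, gsref = 0.24, m_sens = 0.10, hv = 2e-3, seed = 1)
  expect_equal(d_star(0.24, 0.10), exp(1.4), tolerance = 1e-12)
  grid <- seq(0.1, 4.5, by = 1e-4)
  curve <- pmax(0, 0.24 - 0.10 * log(grid)) * grid
  expect_equal(grid[which.max(curve)], exp(1.4), tolerance = 1e-3)
  j2 <- dplyr::inner_join(s2$sap_flux, s2$met[, c("timestamp", "d_kpa")],
                          by = "timestamp")
  expect_equal(j2$d_kpa[which.max(j2$js_true_cm_h)], exp(1.4), tolerance = 0.15)
})

test_that("the simulator rejects degenerate parameters", {
  cfg <- small_config()
  expect_error(simulate_diurnal(cfg, gsref = -0.1, m_sens = 0.05, hv = 1e-3), "gsref")
  expect_error(simulate_diurnal(cfg, gsref = 0.2, m_sens = 0, hv = 1e-3), "m_sens")
  expect_error(simulate_diurnal(cfg, gsref = 0.2, m_sens = 0.05, hv = 0), "hv")
  expect_error(sim_config(d_min = 2, d_max = 1), "d_min")
  expect_error(sim_config(sigma_js = -1), "non-negative")
  expect_error(sim_config(interval_min = 7), "divide")
  bad <- species_presets(); bad$hv_cm2_cm2[1] <- -1
  expect_error(sim_config(species = bad), "positive")
})

test_that("stored deficit is consistent with leaf temperature and humidity", {
  camp <- simulate_campaign(small_config())
  recomputed <- es_tetens(camp$met$tleaf_c) - camp$met$rh_frac * es_tetens(camp$met$tair_c)
  expect_equal(recomputed, camp$met$d_kpa, tolerance = 1e-9)
  expect_true(all(camp$met$rh_frac > 0 & camp$met$rh_frac <= 1))
  expect_true(all(camp$met$d_kpa >= 0))
})

test_that("noise-free anatomy recovers the allometry coefficients exactly", {
  cfg <- zero_noise_config()
  anat <- simulate_anatomy(cfg, "almond", seed = 3)
  mod <- suppressWarnings(allometry_fit(anat$branches$diameter_mm, anat$branches$leaf_area_cm2))
  preset <- cfg$species[cfg$species$species == "almond", ]
  expect_equal(mod$c0, preset$allom_c0, tolerance = 1e-10)
  expect_equal(mod$c1, preset$allom_c1, tolerance = 1e-10)
})

test_that("simulated vessel diameters honour the lognormal moments", {
  set.seed(42)
  draws <- rlnorm(500, 3.5, 0.3)
  mu <- exp(3.5 + 0.3^2 / 2)
  sdev <- sqrt((exp(0.3^2) - 1) * exp(2 * 3.5 + 0.3^2))
  expect_lt(abs(mean(draws) - mu), 3 * sdev / sqrt(500))
})

test_that("water-potential pairs invert the plant-conductance definition", {
  cfg <- small_config()
  wp <- simulate_water_potentials(cfg, kplant_true = 0.8, gs_midday = 0.2,
                                  d_midday = 2, seed = 5)
  expect_equal(wp$psi_pd_mpa - wp$psi_min_mpa, 0.5, tolerance = 1e-12)
  # recovery round trip
  expect_equal(kplant(wp$gs_midday_mol_m2_s, wp$d_midday_kpa,
                      wp$psi_pd_mpa, wp$psi_min_mpa), 0.8, tolerance = 1e-12)
  # infinite-conductance limit: no drawdown
  wp2 <- simulate_water_potentials(cfg, kplant_true = 1e12, gs_midday = 0.2,
                                   d_midday = 2, seed = 5)
  expect_equal(wp2$psi_min_mpa, wp2$psi_pd_mpa, tolerance = 1e-9)
  expect_error(simulate_water_potentials(cfg, kplant_true = 0, gs_midday = 0.2,
                                         d_midday = 2), "positive")
})
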