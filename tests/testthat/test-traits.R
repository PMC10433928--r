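test_that("anatomical maximum conductance follows the diffusion form", {
  # hand evaluation of the same expression with explicit unit conversions
  d <- 2.49e-5; v <- 0.0245
  n_sto <- 300; amax <- 60; size <- 150
  pd_um <- sqrt(size / 2) / 2
  by_hand <- d * (n_sto * 1e6) * (amax * 1e-12) /
    (v * (pd_um * 1e-6 + (pi / 2) * sqrt(amax * 1e-12 / pi)))
  expect_equal(theoretical_gsmax(n_sto, size, amax, d = d, v = v),
               by_hand, tolerance = 1e-12)

  expect_equal(theoretical_gsmax(0, 150, 22.5), 0)
  expect_equal(theoretical_gsmax(600, 150, 22.5),
               2 * theoretical_gsmax(300, 150, 22.5), tolerance = 1e-12)
  expect_error(theoretical_gsmax(300, 100, 120), "alpha")
  expect_error(theoretical_gsmax(300, -1, 20), "positive")
  # swappable formula object
  flat <- function(d, v, density_m2, amax_m2, pore_depth_m) density_m2 * amax_m2
  expect_equal(theoretical_gsmax(300, 150, 22.5, formula = flat),
               300 * 1e6 * 22.5e-12, tolerance = 1e-12)
})

test_that("Hagen-Poiseuille conductivity honours its closed form and scaling", {
  u <- hydro_units()
  # one-term sum
  expect_equal(hagen_poiseuille_ks(50, 2),
               pi * u$rho_water * (50e-6)^4 / (128 * u$eta_water * 2e-6),
               tolerance = 1e-12)
  # doubling the transect area halves the conductivity
  dd <- c(30, 45, 60)
  expect_equal(hagen_poiseuille_ks(dd, 2), hagen_poiseuille_ks(dd, 1) / 2,
               tolerance = 1e-12)
  # splitting one vessel into two of half the diameter costs a factor 8
  expect_equal(hagen_poiseuille_ks(c(25, 25), 1),
               hagen_poiseuille_ks(50, 1) / 8, tolerance = 1e-14)
  expect_error(hagen_poiseuille_ks(numeric(0), 1), "empty")
  expect_error(hagen_poiseuille_ks(c(30, 40), 0), "positive")
})

test_that("500-vessel transects match a compensated per-term summation", {
  set.seed(13)
  dd <- rlnorm(500, 3.5, 0.3)
  # oracle: Kahan-compensated accumulation of the per-vessel terms
  kahan <- function(x) {
    s <- 0; c <- 0
    for (xi in x) { y <- xi - c; t <- s + y; c <- (t - s) - y; s <- t }
    s
  }
  u <- hydro_units()
  oracle <- pi * u$rho_water / (128 * u$eta_water * 1.5e-6) * kahan((dd * 1e-6)^4)
  expect_equal(hagen_poiseuille_ks(dd, 1.5), oracle, tolerance = 1e-12)
})

test_that("plant hydraulic conductance follows the declared unit convention", {
  expect_equal(kplant(0.2, 2, -0.4, -0.9), 0.8, tolerance = 1e-12)
  expect_error(kplant(0.2, 2, -0.5, -0.5), "zero drawdown")
  expect_error(kplant(0.2, 2, -0.9, -0.4), "inverted")
})

test_that("Huber value and vein density are guarded ratios", {
  expect_equal(huber_value(1, 1000), 1e-3, tolerance = 1e-15)
  expect_error(huber_value(1, 0), "positive")
  expect_equal(vein_density(115, 10), 11.5, tolerance = 1e-12)
  expect_equal(vein_density(0, 10), 0)
  expect_error(vein_density(10, 0), "positive")
})

test_that("allometry fits recover power laws and flag extrapolation", {
  diam <- c(7, 9, 12, 15, 18)
  la <- exp(0.5 + 2 * log(diam))
  mod <- suppressWarnings(allometry_fit(diam, la))
  expect_equal(mod$c0, 0.5, tolerance = 1e-10)
  expect_equal(mod$c1, 2, tolerance = 1e-10)

  pred <- allometry_predict(mod, c(5, 10, 25))
  expect_identical(pred$extrapolated, c(TRUE, FALSE, TRUE))
  expect_equal(pred$leaf_area_cm2[2], exp(0.5 + 2 * log(10)), tolerance = 1e-10)

  set.seed(3)
  la_noisy <- exp(0.5 + 2 * log(diam) + rnorm(5, 0, 0.1))
  m2 <- allometry_fit(diam, la_noisy)
  X <- cbind(1, log(diam))
  beta <- solve(t(X) %*% X, t(X) %*% log(la_noisy))
  expect_equal(m2$c0, beta[1], tolerance = 1e-10)
  expect_equal(m2$c1, beta[2], tolerance = 1e-10)
  expect_error(allometry_fit(c(1, 2), c(1, 2)), "3 branches")
  expect_error(allometry_fit(c(-1, 2, 3), c(1, 2, 3)), "positive")
})

test_that("conductance reduction and flux-to-conductance ratio behave", {
  expect_equal(gs_reduction(0.2, 0.2), 1)
  expect_equal(gs_reduction(0.1, 0.2), 0.5)
  expect_warning(out <- gs_reduction(0.25, 0.2), "clipped")
  expect_equal(out, 1)
  expect_error(gs_reduction(0.1, 0), "positive")

  expect_equal(jsmax_over_gsmax(60, 0.12), 500, tolerance = 1e-12)
  expect_error(jsmax_over_gsmax(60, 0), "positive")
})

test_that("doubling the Huber value halves noise-free flux at fixed conductance", {
  cfg <- zero_noise_config()
  s1 <- simulate_diurnal(cfg, gsref = 0.12, m_sens = 0.05, hv = 1.5e-3, seed = 4)
  s2 <- simulate_diurnal(cfg, gsref = 0.12, m_sens = 0.05, hv = 3.0e-3, seed = 4)
  expect_equal(s1$sap_flux$js_cm_h, 2 * s2$sap_flux$js_cm_h, tolerance = 1e-12)
})

test_that("species-level anatomy traits preserve the preset ranking", {
  cfg <- sim_config(seed = 31)
  camp <- simulate_campaign(cfg)
  sp <- species_anatomy_traits(camp$vessels, camp$stomata, camp$veins)
  presets <- cfg$species
  ord_pred <- presets$species[order(presets$vein_density_mm_mm2)]
  ord_est <- sp$species[order(sp$vein_density_mm_mm2)]
  expect_identical(ord_est, ord_pred)
  # theoretical vs measured maximum conductance in a plausible regime
  expect_true(all(sp$gsmax_theoretical_mol_m2_s > 0.3 &
                    sp$gsmax_theoretical_mol_m2_s < 3))
})

test_that("the per-tree trait table recovers ground truth on a noise-free campaign", {
  cfg <- zero_noise_config()
  camp <- simulate_campaign(cfg)
  fits <- fit_flux_response(camp$sap_flux, camp$met)
  tt <- suppressWarnings(tree_traits(fits, camp$gas_exchange, camp$met,
                                     camp$water_potentials, camp$instrumented,
                                     camp$branches))
  joined <- dplyr::left_join(tt, camp$truth, by = "tree_id",
                             suffix = c("", "_true"))
  expect_equal(joined$hv_cm2_cm2, joined$hv_cm2_cm2_true, tolerance = 1e-10)
  expect_equal(joined$kplant_mol_m2_s_mpa, joined$kplant_mol_m2_s_mpa_true,
               tolerance = 1e-10)
  expect_true(all(joined$gs_reduction > 0 & joined$gs_reduction <= 1))
})

test_that("unit-aliased columns give identical traits after conversion", {
  dir <- withr::local_tempdir()
  v_um <- tibble::tibble(species = "x", sample_id = "s1",
                         transect_area_mm2 = 1.5,
                         vessel_diameter_um = c(30, 45, 60))
  v_mm <- dplyr::rename(dplyr::mutate(v_um, vessel_diameter_um = vessel_diameter_um / 1000),
                        vessel_diameter_mm = "vessel_diameter_um")
  readr::write_csv(v_um, file.path(dir, "um.csv"))
  readr::write_csv(v_mm, file.path(dir, "mm.csv"))
  a <- read_hydro_csv(file.path(dir, "um.csv"), "vessels")
  expect_message(b <- read_hydro_csv(file.path(dir, "mm.csv"), "vessels"),
                 "converting")
  expect_equal(hagen_poiseuille_ks(a$vessel_diameter_um, 1.5),
               hagen_poiseuille_ks(b$vessel_diameter_um, 1.5), tolerance = 1e-12)
})
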