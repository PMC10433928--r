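test_that("the mechanistic constant matches an independent hand computation", {
  mc <- mechanistic_constant(20, 101.3)
  # oracle: constituents evaluated by hand from the standard formulae
  lambda <- (2.501 - 2.361e-3 * 20) * 1e6
  gamma <- 1013 * 101.3 / (0.622 * lambda)
  rho_air <- 101300 / (287.058 * 293.15)
  C <- lambda * gamma / (rho_air * 1013)
  expect_equal(mc$C, C, tolerance = 1e-10)
  v <- 8.31446 * 293.15 / 101300
  expect_equal(mc$js_gs_factor, C * (0.01 / 3600 * 998.2) / v, tolerance = 1e-10)
  # frozen value of the full conversion factor
  expect_equal(mc$js_gs_factor, 15.59084780, tolerance = 1e-8)
  # purity
  expect_identical(mc$C, mechanistic_constant(20, 101.3)$C)
  # C is, by definition, linear in the psychrometric constant
  expect_equal(mc$C, mc$lambda * mc$gamma / (mc$rho_air * mc$cp), tolerance = 1e-12)
  expect_error(mechanistic_constant(200, 101.3), "plausible")
})

test_that("exact proportionality calibrates to slope k with zero intercept", {
  d <- seq(0.5, 4, length.out = 24)
  js <- seq(2, 6, length.out = 24)
  gs <- 0.003 * js / d
  fit <- suppressWarnings(calibrate_tree(gs, js, d))
  expect_equal(fit$slope, 0.003, tolerance = 1e-10)
  expect_equal(fit$intercept_fitted, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_error(calibrate_tree(gs, rep(2, 24), rep(1, 24)), "zero variance")
  expect_error(calibrate_tree(gs[1:2], js[1:2], d[1:2]), "3 aligned")
})

test_that("conductance unrelated to the flux ratio is not significant", {
  set.seed(55)
  d <- runif(24, 0.3, 4.4)
  js <- 2 + runif(24)
  gs <- rnorm(24, 0.1, 0.02) # independent of js/d
  fit <- calibrate_tree(gs, js, d)
  expect_lt(fit$r_squared, 0.2)
  expect_gt(fit$p_value, 0.05)
})

test_that("noise-free calibration recovers the trait-model slope per tree", {
  camp <- simulate_campaign(zero_noise_config())
  calib <- suppressWarnings(suppressMessages(calibrate_gs(
    camp$gas_exchange, camp$sap_flux, camp$met)))
  joined <- dplyr::left_join(calib, camp$truth, by = "tree_id")
  expected <- joined$js_gs_factor * joined$hv_cm2_cm2
  expect_equal(joined$slope, expected, tolerance = 1e-8)
  expect_true(all(joined$r_squared > 1 - 1e-10))
})

test_that("pointwise prediction is linear, exact on round trips, and guarded", {
  camp <- simulate_campaign(zero_noise_config())
  truth1 <- camp$truth[1, ]
  flux1 <- camp$sap_flux[camp$sap_flux$tree_id == truth1$tree_id, ]
  pred <- predict_gs(flux1, hv = truth1$hv_cm2_cm2, constant = camp$constant,
                     met_data = camp$met)
  ge1 <- camp$gas_exchange[camp$gas_exchange$tree_id == truth1$tree_id, ]
  cmp <- dplyr::inner_join(pred, ge1[, c("timestamp", "gs_true_mol_m2_s")],
                           by = "timestamp")
  expect_equal(cmp$gs_pred_mol_m2_s, cmp$gs_true_mol_m2_s, tolerance = 1e-10)

  df <- tibble::tibble(timestamp = Sys.time() + 1:3, js_cm_h = c(0, 2, 4),
                       d_kpa = c(1, 2, 2))
  out <- predict_gs(df, hv = 2e-3)
  expect_equal(out$gs_pred_mol_m2_s[1], 0)
  out2 <- predict_gs(dplyr::mutate(df, js_cm_h = js_cm_h), hv = 4e-3)
  expect_equal(out2$gs_pred_mol_m2_s, 2 * out$gs_pred_mol_m2_s, tolerance = 1e-12)

  df$d_kpa[2] <- 0
  expect_message(out3 <- predict_gs(df, hv = 2e-3), "dropping 1")
  expect_equal(nrow(out3), 2)
  expect_error(predict_gs(df, hv = -1), "positive")
})

test_that("the cross-tree slope regression recovers the universal constant", {
  camp <- simulate_campaign(zero_noise_config(n_trees = 4))
  calib <- suppressWarnings(suppressMessages(calibrate_gs(
    camp$gas_exchange, camp$sap_flux, camp$met)))
  hv_tbl <- camp$truth[, c("tree_id", "hv_cm2_cm2")]
  fit <- suppressWarnings(slope_vs_hv(calib, hv_tbl))
  expect_equal(fit$slope, camp$constant$js_gs_factor, tolerance = 1e-6)
  expect_lt(abs(fit$intercept), 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-8)

  # with 10 percent flux noise the slope stays positive and significant
  noisy <- simulate_campaign(sim_config(seed = 77, sigma_js = 0.5))
  calib_n <- suppressMessages(calibrate_gs(noisy$gas_exchange, noisy$sap_flux,
                                           noisy$met))
  fit_n <- slope_vs_hv(calib_n, noisy$truth[, c("tree_id", "hv_cm2_cm2")])
  expect_gt(fit_n$slope, 0)
  expect_lt(fit_n$p_value, 0.05)

  same_hv <- dplyr::mutate(hv_tbl, hv_cm2_cm2 = 2e-3)
  expect_error(slope_vs_hv(calib, same_hv), "one Huber value")
  expect_error(slope_vs_hv(calib[calib$p_value > 2, ], hv_tbl), ">= 3")
})

test_that("calibration-slope recovery of the constant is accurate at low noise", {
  # parameter-recovery surface: 5 percent flux noise, full default cohort
  camp <- simulate_campaign(sim_config(seed = 19))
  calib <- suppressMessages(calibrate_gs(camp$gas_exchange, camp$sap_flux,
                                         camp$met))
  fit <- slope_vs_hv(calib, camp$truth[, c("tree_id", "hv_cm2_cm2")])
  expect_lt(abs(fit$slope / camp$constant$js_gs_factor - 1), 0.05)
})
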