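make_day <- function(date, d_values, step_h = 0.5, start_h = 6) {
  ts <- as.POSIXct(date, tz = "UTC") + (start_h + step_h * (seq_along(d_values) - 1)) * 3600
  tibble::tibble(timestamp = ts, d_kpa = d_values)
}

test_that("morning window keeps dawn-to-noon rows and rejects flat days", {
  # symmetric deficit around noon: exactly the rising half is retained
  d <- c(0.05, 0.5, 1.5, 3, 4, 4.5, 4, 3, 1.5, 0.5, 0.05)
  day <- make_day("2020-06-01", d, step_h = 1, start_h = 7) # noon at index 6
  out <- filter_morning(day, quiet = TRUE)
  expect_equal(nrow(out), 5) # rows 2..6 (above 0.1 kPa up to 12:00)
  expect_true(all(format(out$timestamp, "%H") <= "12"))

  expect_error(filter_morning(make_day("2020-06-02", rep(0.05, 5)), quiet = TRUE),
               "2020-06-02")

  # multi-day total equals the sum of per-day counts (brute-force scan)
  days <- dplyr::bind_rows(
    make_day("2020-06-01", c(0.2, 1, 2, 3)),
    make_day("2020-06-02", c(0.05, 0.3, 2)),
    make_day("2020-06-03", c(1, 2, 3, 4, 4.4))
  )
  brute <- sum(vapply(split(days, format(days$timestamp, "%d")), function(df) {
    h <- as.POSIXlt(df$timestamp)$hour + as.POSIXlt(df$timestamp)$min / 60
    above <- df$d_kpa > 0.1
    sum(above & h >= min(h[above]) & h <= 12)
  }, numeric(1)))
  expect_equal(nrow(filter_morning(days, quiet = TRUE)), brute)
  expect_message(filter_morning(days), "retained")
})

test_that("exact parabolas are recovered with their analytic vertex", {
  d <- c(0.5, 1, 2, 3, 4)
  f1 <- fit_parabolic(d, -1 * d^2 + 4 * d)
  expect_equal(f1$a, -1, tolerance = 1e-12)
  expect_equal(f1$b, 4, tolerance = 1e-12)
  expect_equal(f1$r_squared, 1, tolerance = 1e-12)
  expect_equal(f1$d_jsmax, 2, tolerance = 1e-12)
  expect_equal(f1$jsmax, 4, tolerance = 1e-12)

  f2 <- fit_parabolic(d, -2 * d^2 + 8 * d)
  expect_equal(f2$d_jsmax, 2, tolerance = 1e-12)
  expect_equal(f2$jsmax, 8, tolerance = 1e-12)

  expect_warning(f3 <- fit_parabolic(d, 2 * d^2 + 1 * d), "no interior")
  expect_identical(f3$status, "no_vertex")
  expect_true(is.na(f3$d_jsmax) && is.na(f3$jsmax))

  expect_error(fit_parabolic(rep(2, 5), 1:5), "rank-deficient")
  expect_error(fit_parabolic(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_parabolic(c(-1, 1, 2), c(1, 2, 3)), "non-negative")
})

test_that("least-squares coefficients match the normal-equations oracle", {
  set.seed(7)
  d <- runif(40, 0.2, 4.5)
  js <- -0.5 * d^2 + 3 * d + rnorm(40, 0, 0.3)
  fit <- fit_parabolic(d, js)
  X <- cbind(d^2, d)
  beta <- solve(t(X) %*% X, t(X) %*% js)
  expect_equal(fit$a, beta[1], tolerance = 1e-10)
  expect_equal(fit$b, beta[2], tolerance = 1e-10)

  lfit <- fit_log(d, js)
  Xl <- cbind(1, log(d))
  bl <- solve(t(Xl) %*% Xl, t(Xl) %*% js)
  expect_equal(lfit$jsref, bl[1], tolerance = 1e-10)
  expect_equal(lfit$m_js, bl[2], tolerance = 1e-10)
})

test_that("exact logarithmic responses are recovered", {
  d <- c(0.3, 0.8, 1.5, 2.5, 4)
  f <- suppressWarnings(fit_log(d, 10 + 5 * log(d)))
  expect_equal(f$jsref, 10, tolerance = 1e-10)
  expect_equal(f$m_js, 5, tolerance = 1e-10)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  # flux at D = 1 kPa equals the reference flux exactly
  expect_equal(predict(f$model, newdata = data.frame(ld = 0))[[1]], f$jsref,
               tolerance = 1e-12)
  expect_error(fit_log(rep(1, 5), 1:5), "degenerate")
  expect_error(fit_log(c(0, 1, 2), c(1, 2, 3)), "positive")
})

test_that("model selection prefers the higher R-squared with parabolic ties", {
  d <- seq(0.3, 4.2, length.out = 25)
  par_js <- -1 * d^2 + 4.5 * d
  p1 <- suppressWarnings(fit_parabolic(d, par_js))
  l1 <- suppressWarnings(fit_log(d, par_js))
  expect_identical(select_model(p1, l1), "parabolic")

  log_js <- 2 + 3 * log(seq(0.2, 4.5, length.out = 25))
  d2 <- seq(0.2, 4.5, length.out = 25)
  p2 <- suppressWarnings(fit_parabolic(d2, log_js))
  l2 <- suppressWarnings(fit_log(d2, log_js))
  expect_identical(select_model(p2, l2), "logarithmic")

  # tie: force equal R-squared fields
  l1_tied <- l1; l1_tied$r_squared <- p1$r_squared
  expect_identical(select_model(p1, l1_tied), "parabolic")

  l_short <- fit_log(d[1:10], par_js[1:10])
  expect_error(select_model(p1, l_short), "differing")
})

test_that("the vertex identity holds for every concave fit", {
  set.seed(99)
  for (i in 1:25) {
    d <- runif(30, 0.2, 4.5)
    js <- -runif(1, 0.2, 1.5) * d^2 + runif(1, 2, 6) * d + rnorm(30, 0, 0.4)
    fit <- fit_parabolic(d, js)
    if (fit$status == "ok") {
      expect_lt(abs(fit$a * fit$d_jsmax^2 + fit$b * fit$d_jsmax - fit$jsmax), 1e-12)
      expect_equal(fit$d_jsmax, -fit$b / (2 * fit$a), tolerance = 1e-12)
    }
  }
})

test_that("noise-free trees with an interior hump recover it within 10 percent", {
  cfg <- zero_noise_config(species = species_presets()[5, ], n_trees = 2) # lemon
  camp <- simulate_campaign(cfg)
  fits <- fit_flux_response(camp$sap_flux, camp$met)
  truth <- camp$truth
  joined <- dplyr::left_join(fits, truth, by = "tree_id")
  expect_true(all(abs(joined$d_jsmax_kpa / joined$d_star_kpa - 1) < 0.10))
})

test_that("per-tree fit table carries both models and tidy methods work", {
  camp <- simulate_campaign(small_config())
  fits <- fit_flux_response(camp$sap_flux, camp$met)
  expect_s3_class(fits, "flux_fits")
  expect_equal(nrow(fits), 4)
  expect_true(all(c("a", "b", "d_jsmax_kpa", "m_js", "model_selected") %in% names(fits)))

  d <- c(0.5, 1, 2, 3, 4)
  pfit <- suppressWarnings(fit_parabolic(d, -1 * d^2 + 4 * d + rnorm(5, 0, 1e-6)))
  td <- tidy(pfit)
  expect_identical(td$term, c("d^2", "d"))
  expect_equal(glance(pfit)$d_jsmax, pfit$d_jsmax)
  lfit <- suppressWarnings(fit_log(d, 10 + 5 * log(d)))
  expect_identical(suppressWarnings(tidy(lfit))$term, c("jsref", "m_js"))
})
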