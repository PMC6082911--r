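make_trace <- function(temperature, signal, scan_rate = 1, direction = "melt")
  th_trace(temperature, signal, scan_rate, direction)

test_that("baseline fitting recovers exact lines and flags bad ranges", {
  Tg <- seq(0, 80, by = 0.5)
  sig <- 0.50 + 0.001 * Tg
  tr <- make_trace(Tg, sig)
  bl <- fit_baselines(tr, folded_range = c(0, 12), unfolded_range = c(68, 80))
  expect_equal(unname(bl$folded_intercept), 0.50, tolerance = 1e-10)
  expect_equal(unname(bl$folded_slope), 0.001, tolerance = 1e-10)
  expect_equal(unname(bl$unfolded_slope), 0.001, tolerance = 1e-10)

  flat <- make_trace(Tg, rep(0.3, length(Tg)))
  blf <- fit_baselines(flat)
  expect_equal(unname(blf$folded_slope), 0, tolerance = 1e-12)
  expect_equal(unname(blf$unfolded_slope), 0, tolerance = 1e-12)

  expect_error(fit_baselines(tr, c(0, 0.6), c(70, 80)), "fewer than 3")
  expect_error(fit_baselines(tr, c(0, 50), c(40, 80)), "overlap")
})

test_that("baseline recovery from noisy synthetic traces is within 3 SE", {
  cfg <- synth_config(dimer_template(k_app = 0.3), scan_rates = 1,
                      T_range = c(20, 80), C_T = 1e-4, hold = 5,
                      directions = "melt", noise_sd = 0.002, seed = 7)
  ds <- generate_dataset(cfg)[[1]]
  tr <- ds$traces[[1]]
  bl <- fit_baselines(tr, folded_range = c(20, 28), unfolded_range = c(72, 80))
  # standard error of the slope on ~17 points spanning 8 C with sd 0.002
  sel <- tr$temperature <= 28
  x <- tr$temperature[sel]
  se_slope <- 0.002 / sqrt(sum((x - mean(x))^2))
  expect_lt(abs(bl$folded_slope - cfg$baselines$folded_slope), 3 * se_slope)
})

test_that("fraction unfolded is exact, affine-invariant, and guards the denominator", {
  Tg <- seq(0, 60, by = 0.5)
  fold <- 0.2 + 0.001 * Tg
  unf <- 0.8 + 0.002 * Tg
  # linear transition ramp with exactly flat baselines outside 25..35 C
  theta <- pmin(1, pmax(0, (Tg - 25) / 10))
  sig <- fold * (1 - theta) + unf * theta
  tr <- make_trace(Tg, sig)
  bl <- fit_baselines(tr, c(0, 9), c(51, 60))
  fc <- compute_fraction_unfolded(tr, bl)
  expect_lt(max(abs(fc$theta_U - theta)), 1e-9)

  # signal midway between the lines -> theta exactly 0.5
  i <- which.min(abs(Tg - 30))
  expect_equal(fc$theta_U[i], 0.5, tolerance = 1e-9)

  # affine transform of the signal leaves theta untouched
  tr2 <- make_trace(Tg, 3.7 * sig - 0.9)
  bl2 <- fit_baselines(tr2, c(0, 9), c(51, 60))
  fc2 <- compute_fraction_unfolded(tr2, bl2)
  expect_equal(fc2$theta_U, fc$theta_U, tolerance = 1e-9)

  # signal exactly on the folded line -> theta 0
  tr3 <- make_trace(Tg, fold)
  fc3 <- compute_fraction_unfolded(tr3, bl)
  expect_lt(max(abs(fc3$theta_U)), 1e-9)

  # intersecting baselines -> degenerate denominator
  bad <- bl
  bad$unfolded_intercept <- bl$folded_intercept
  bad$unfolded_slope <- bl$folded_slope
  expect_error(compute_fraction_unfolded(tr, bad), "degenerate")
})

test_that("Savitzky-Golay derivative reproduces polynomials exactly", {
  Tg <- seq(10, 60, by = 0.5)
  lin <- make_fraction_curve(Tg, 0.01 * Tg + 0.2, 1, "melt")
  d1 <- smooth_derivative(lin)
  expect_lt(max(abs(d1$dtheta_dT - 0.01)), 1e-10)

  quad <- make_fraction_curve(Tg, 1e-4 * Tg^2 - 0.002 * Tg + 0.1, 1, "melt")
  d2 <- smooth_derivative(quad, polyorder = 2)
  expect_lt(max(abs(d2$dtheta_dT - (2e-4 * d2$temperature - 0.002))), 1e-10)

  expect_error(smooth_derivative(lin, window = 200), "window")
})

test_that("smoothed derivative of a noisy sigmoid is close to the truth", {
  Tg <- seq(10, 60, by = 0.5)
  theta <- plogis((Tg - 35) / 3)
  dtruth <- dlogis((Tg - 35) / 3) / 3
  set.seed(11)
  noisy <- make_fraction_curve(Tg, theta + rnorm(length(Tg), 0, 0.004), 1, "melt")
  sm <- smooth_derivative(noisy, window = 2.5, polyorder = 2)
  dref <- approx(Tg, dtruth, xout = sm$temperature)$y
  rms <- sqrt(mean((sm$dtheta_dT - dref)^2))
  expect_lt(rms / max(dtruth), 0.05)
})

test_that("temperature-lag correction shifts by the signed scan rate", {
  Tg <- seq(10, 60, by = 1)
  tr_a <- th_trace(Tg, runif(length(Tg)), scan_rate = 2, direction = "anneal")
  tr_m <- th_trace(Tg, runif(length(Tg)), scan_rate = 2, direction = "melt")
  expect_equal(correct_temperature_lag(tr_a, 0.5)$temperature, Tg + 1)
  expect_equal(correct_temperature_lag(tr_m, 0.5)$temperature, Tg - 1)
  expect_identical(correct_temperature_lag(tr_a, 0), tr_a)
})

test_that("apparent Tm interpolates the theta = 0.5 crossing", {
  fc <- make_fraction_curve(c(47, 48, 49, 50, 51, 52), c(0.1, 0.2, 0.4, 0.6, 0.8, 0.9), 1, "melt")
  expect_equal(apparent_tm(fc), 49.5, tolerance = 1e-12)
  low <- make_fraction_curve(47:52, rep(0.2, 6), 1, "melt")
  expect_error(apparent_tm(low), "never crosses")
})

test_that("hysteresis diagnostics apply the shift and slope-ratio thresholds", {
  Tg <- seq(10, 80, by = 0.5)
  curve_at <- function(tm) plogis((Tg - tm) / 2.5)
  sharp_at <- function(tm) plogis((Tg - tm) / 0.5)
  mk <- function(theta, dir) smooth_derivative(make_fraction_curve(Tg, theta, 0.5, dir))

  # identical melt and anneal: no hysteresis
  same <- list(mk(curve_at(45), "anneal"), mk(curve_at(45), "melt"))
  d0 <- hysteresis_diagnostics(same)
  expect_equal(d0$tm_shift, 0, tolerance = 1e-6)
  expect_false(d0$adequate)

  # shift just below 1 C: inadequate even with a large slope ratio
  d1 <- hysteresis_diagnostics(list(mk(curve_at(45), "anneal"),
                                    mk(sharp_at(45.99), "melt")))
  expect_false(d1$adequate)

  # shift just above 1 C with slope ratio >= 3: adequate
  d2 <- hysteresis_diagnostics(list(mk(sharp_at(45), "anneal"),
                                    mk(curve_at(46.01), "melt")))
  expect_gte(d2$slope_ratio, 3)
  expect_true(d2$adequate)

  # strongly hysteretic simulated tetramer dataset is flagged adequate
  mech <- one_step_template(N = 4)
  ds <- simulate_th_dataset(mech, c(0.5, 2), c(10, 95), 1e-3, hold = 10)
  fr <- suppressWarnings(dataset_fractions(ds))
  expect_true(suppressWarnings(hysteresis_diagnostics(fr))$adequate)
})
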