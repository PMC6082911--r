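test_that("trace construction validates monotonicity and normalizes anneals", {
  expect_error(th_trace(c(1:5, 4, 6:9, 10), rnorm(11), 1, "melt"),
               "monotone")
  tr <- th_trace(seq(50, 10, by = -4), 1:11 / 11, scan_rate = 1,
                 direction = "anneal")
  expect_true(all(diff(tr$temperature) > 0))
  expect_identical(attr(tr, "direction"), "anneal")
  expect_error(th_trace(1:5, 1:5, 1, "melt"), ">= 10")
})

test_that("dataset write/read round trip preserves values and metadata", {
  mech <- dimer_template(k_app = 1)
  ds <- simulate_th_dataset(mech, c(1, 2), c(20, 80), 1e-4, hold = 2)
  dir <- withr::local_tempdir()
  write_th_dataset(ds, dir)
  ds2 <- load_th_dataset(dir)
  expect_length(ds2$traces, 4)
  expect_equal(ds2$C_T, 1e-4, tolerance = 1e-12)
  for (i in seq_along(ds$traces)) {
    expect_equal(ds2$traces[[i]]$temperature, ds$traces[[i]]$temperature,
                 tolerance = 1e-12)
    expect_equal(ds2$traces[[i]]$signal, ds$traces[[i]]$signal,
                 tolerance = 1e-12)
    expect_identical(attr(ds2$traces[[i]], "direction"),
                     attr(ds$traces[[i]], "direction"))
    expect_equal(attr(ds2$traces[[i]], "scan_rate"),
                 attr(ds$traces[[i]], "scan_rate"))
  }
})

test_that("sidecar metadata is honored and missing metadata errors", {
  dir <- withr::local_tempdir()
  tab <- data.frame(temperature_C = seq(10, 60, by = 5), signal = runif(11))
  write.csv(tab, file.path(dir, "t1.csv"), row.names = FALSE)
  expect_error(load_th_dataset(dir, C_T = 1e-4), "scan_rate")
  yaml::write_yaml(list(scan_rate = 1.5, direction = "melt", wavelength = 295),
                   file.path(dir, "t1.yaml"))
  ds <- suppressWarnings(load_th_dataset(dir, C_T = 1e-4))
  expect_equal(attr(ds$traces[[1]], "scan_rate"), 1.5)
  expect_equal(attr(ds$traces[[1]], "wavelength"), 295)
  expect_true(attr(ds, "few_rates"))
})

test_that("order profiles and fit reports round-trip through files", {
  surf <- structure(
    data.frame(temperature = rep(seq(20, 59.5, by = 0.5), each = 3),
               M = rep(c(1e-4, 2e-4, 4e-4), 80),
               rate = -1e3 * rep(c(1e-4, 2e-4, 4e-4), 80)^2,
               theta = rep(c(0.2, 0.4, 0.8), 80),
               scan_rate = rep(c(0.5, 1, 2), 80),
               direction = "anneal", replicate_id = NA),
    class = c("rate_surface", "data.frame"), C_T = 5e-4)
  prof <- order_profile(surf, "anneal")
  f <- withr::local_tempfile(fileext = ".csv")
  write_results(prof, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(prof))
  expect_equal(back$order, prof$order, tolerance = 1e-10)

  empty <- prof[0, ]
  class(empty) <- class(prof)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_results(empty, f2)
  expect_equal(nrow(read.csv(f2)), 0)

  fit <- structure(list(mechanism = dimer_template(),
                        par = c(log10k_f1 = 3.52, log10k_r1 = -0.48),
                        se = c(log10k_f1 = 0.01, log10k_r1 = 0.02),
                        rss = 0.0123, n_points = 400L, n_params = 2L,
                        aic = -4100.5, converged = TRUE, message = "ok",
                        residual_table = data.frame()),
                   class = "fit_result")
  f3 <- withr::local_tempfile(fileext = ".json")
  write_results(fit, f3)
  rep <- read_fit_report(f3)
  expect_equal(rep$parameters$log10k_f1, 3.52, tolerance = 1e-12)
  expect_equal(rep$rss, 0.0123, tolerance = 1e-12)
  expect_equal(rep$aic, -4100.5, tolerance = 1e-12)
})
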