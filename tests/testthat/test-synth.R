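test_that("zero noise with identity baselines returns theta itself", {
  cfg <- synth_config(dimer_template(k_app = 1), scan_rates = 1,
                      T_range = c(20, 80), C_T = 1e-4, hold = 2,
                      baselines = list(folded_intercept = 0, folded_slope = 0,
                                       unfolded_intercept = 1, unfolded_slope = 0),
                      noise_sd = 0, seed = 1)
  reps <- generate_dataset(cfg)
  truth <- attr(reps, "truth")
  for (i in seq_along(reps[[1]]$traces))
    expect_equal(reps[[1]]$traces[[i]]$signal, truth$traces[[i]]$signal,
                 tolerance = 1e-14)
})

test_that("generation is deterministic given the seed", {
  cfg <- synth_config(dimer_template(k_app = 1), scan_rates = c(1, 2),
                      T_range = c(25, 75), C_T = 1e-4, hold = 2,
                      noise_sd = 0.002, seed = 99, replicates = 2)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(cfg, out_dir = d1)
  generate_dataset(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_true(length(f1) > 0)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("generator plus preprocessing recovers the ground-truth theta", {
  cfg <- synth_config(dimer_template(k_app = 30, Tm = 50), scan_rates = c(0.5, 2),
                      T_range = c(0, 90), C_T = 1e-4, hold = 10,
                      noise_sd = 0.002, seed = 3)
  reps <- generate_dataset(cfg)
  truth <- attr(reps, "truth")
  sep <- with(cfg$baselines, (unfolded_intercept + unfolded_slope * 50) -
                (folded_intercept + folded_slope * 50))
  err <- unlist(lapply(seq_along(reps[[1]]$traces), function(i) {
    tr <- reps[[1]]$traces[[i]]
    # generous baseline regions where the true theta is flat to < 0.005
    bl <- fit_baselines(tr, folded_range = c(0, 15), unfolded_range = c(72, 90))
    th <- compute_fraction_unfolded(tr, bl)$theta_U
    abs(th - truth$traces[[i]]$signal)
  }))
  expect_gt(mean(err < 3 * cfg$noise_sd / sep), 0.95)
})

test_that("generated datasets reload identically from disk", {
  cfg <- synth_config(dimer_template(k_app = 1), scan_rates = 1,
                      T_range = c(25, 75), C_T = 1e-4, hold = 2,
                      noise_sd = 0.002, seed = 5)
  dir <- withr::local_tempdir()
  reps <- generate_dataset(cfg, out_dir = dir)
  back <- load_th_dataset(file.path(dir, "rep1"))
  for (i in seq_along(back$traces)) {
    expect_equal(back$traces[[i]]$signal, reps[[1]]$traces[[i]]$signal,
                 tolerance = 1e-12)
  }
  truth_meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                                    simplifyVector = TRUE)
  expect_equal(truth_meta$seed, 5)
  expect_equal(truth_meta$noise_sd, 0.002)
})

test_that("hysteresis vanishes for fast kinetics and grows monotonically as kinetics slow", {
  surv <- kinetic_limit_survey(c(0.3, 3, 1000), scan_rate = 2)
  expect_lt(surv$shift[3], 0.05)
  expect_true(all(diff(surv$shift) < 0))
})
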