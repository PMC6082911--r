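# an exact power-law surface: rate = -k [M]^n at every grid temperature,
# sampled at several scan rates (monomer values differing per rate)
power_law_surface <- function(n, k, temps = seq(20, 59.5, by = 0.5),
                              thetas = c(0.2, 0.35, 0.55, 0.8), C_T = 1e-3) {
  M <- thetas * C_T
  structure(
    data.frame(temperature = rep(temps, each = length(M)),
               M = rep(M, length(temps)),
               rate = -k * rep(M, length(temps))^n,
               theta = rep(thetas, length(temps)),
               scan_rate = rep(seq_along(M), length(temps)),
               direction = "anneal", replicate_id = NA),
    class = c("rate_surface", "data.frame"), C_T = C_T)
}

test_that("the rate surface implements rate = C_T (dtheta/dT)(dT/dt)", {
  Tg <- seq(20, 40, by = 0.5)
  fc <- make_fraction_curve(Tg, 0.05 * (Tg - 20) / 20 + 0.4, 1, "anneal")
  fc <- smooth_derivative(fc)
  fc$dtheta_dT <- rep(0.05, nrow(fc))  # exact slope, deg C^-1
  ds <- list(C_T = 5e-5)
  class(ds) <- "th_dataset"
  ds$traces <- list(1)  # length check only
  surf <- build_rate_surface(structure(list(traces = list(1), C_T = 5e-5,
                                            t_range = c(20, 40), hold = 0),
                                       class = "th_dataset"), list(fc))
  # anneal: signed dT/dt = -1 C/min -> d[M]/dt = -2.5e-6 M/min
  expect_equal(unique(round(surf$rate, 12)), -2.5e-6, tolerance = 1e-9)
  # flat region gives zero rate
  fc0 <- fc; fc0$dtheta_dT <- 0
  surf0 <- build_rate_surface(structure(list(traces = list(1), C_T = 5e-5,
                                             t_range = c(20, 40), hold = 0),
                                        class = "th_dataset"), list(fc0))
  expect_true(all(surf0$rate == 0))
})

test_that("slices of an exact power law recover slope and intercept", {
  surf <- power_law_surface(n = 2, k = 1e5)
  sl <- extract_order_slice(surf, 30, "anneal")
  expect_equal(sl$order, 2, tolerance = 1e-10)
  expect_equal(sl$intercept, log(1e5), tolerance = 1e-8)

  # melt slice of a one-step mechanism: m = 1, intercept = ln k_off
  # independently of N, since (1 - m) ln N vanishes
  C_T <- 1e-3
  k_off <- 0.31
  A <- c(0.1, 0.25, 0.5, 0.75) * C_T      # assembled monomer equivalents
  surf_m <- structure(
    data.frame(temperature = 55, M = C_T - A, rate = k_off * A,
               theta = (C_T - A) / C_T, scan_rate = seq_along(A),
               direction = "melt", replicate_id = NA),
    class = c("rate_surface", "data.frame"), C_T = C_T)
  slm <- extract_order_slice(surf_m, 55, "melt")
  expect_equal(slm$order, 1, tolerance = 1e-10)
  expect_equal(slm$intercept, log(k_off), tolerance = 1e-10)

  # insufficient points: slice is skipped
  one <- surf[surf$scan_rate == 1, ]
  class(one) <- class(surf); attr(one, "C_T") <- attr(surf, "C_T")
  expect_null(extract_order_slice(one, 30, "anneal"))
})

test_that("profiles cover the full grid and are constant for a power law", {
  surf <- power_law_surface(n = 3, k = 2e7)
  prof <- order_profile(surf, "anneal")
  expect_equal(nrow(prof), 80)   # 40 C span at 0.5 C steps
  expect_lt(max(abs(prof$order - 3)), 1e-9)
})

test_that("replicate profiles aggregate as mean and standard deviation", {
  p1 <- structure(data.frame(temperature = c(20, 20.5), order = c(2.9, 3.0),
                             order_stderr = NA, intercept = c(1, 1.1),
                             intercept_stderr = NA, n_points = 4L),
                  class = c("order_profile", "data.frame"), direction = "anneal")
  p2 <- p1; p2$order <- c(3.1, 3.4)
  agg <- aggregate_profiles(list(p1, p2))
  expect_equal(agg$order, c(3.0, 3.2))
  expect_equal(agg$order_stderr, c(sd(c(2.9, 3.1)), sd(c(3.0, 3.4))))
})

test_that("removing the fastest scan rate barely moves noiseless estimates", {
  mech <- one_step_template(N = 3)
  full <- modelfree_orders_midtransition(mech, scan_rates = c(0.5, 1, 2, 4))
  drop <- modelfree_orders_midtransition(mech, scan_rates = c(0.5, 1, 2))
  expect_lt(abs(full$n - drop$n), 0.1)
})
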