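test_that("rate law evaluates the integrated Arrhenius / heat-capacity form", {
  rl <- rate_law(2.5e4, T_ref = 310, dH = 8e4, dCp = -1500)
  expect_equal(rate_constant(rl, 310), 2.5e4, tolerance = 1e-12)

  # closed-form check, dCp = 0
  rl2 <- rate_law(1e5, T_ref = 298.15, dH = 1e5)
  expected <- 1e5 * exp(-(1e5 / 8.314) * (1 / 308.15 - 1 / 298.15))
  expect_equal(rate_constant(rl2, 308.15), expected, tolerance = 1e-12)
  expect_equal(rate_constant(rl2, 308.15) / 1e5, 3.703, tolerance = 1e-3)

  # athermal law is flat
  rl3 <- rate_law(7, T_ref = 300)
  expect_equal(rate_constant(rl3, c(260, 300, 390)), rep(7, 3), tolerance = 1e-12)
})

test_that("irreversible dimerization follows the 1/(1 + 2 k c0 t) closed form", {
  # event-rate convention: one dimerization event consumes two monomers, so
  # d[M]/dt = -2 kf [M]^2; kf = 0.5 gives d[M]/dt = -[M]^2
  mech <- one_step_mechanism(2, kf = rate_law(0.5, 298.15),
                             kr = rate_law(1e-12, 298.15))
  prog <- temperature_program(data.frame(duration = 1, T_start = 25, T_end = 25))
  sim <- simulate_mechanism(mech, prog, C_T = 1, hold_points = 11)
  M1 <- sim$trajectory$theta_U[nrow(sim$trajectory)] * 1
  expect_equal(M1, 0.5, tolerance = 1e-6)
})

test_that("mass is conserved on every trajectory for all mechanism kinds", {
  mechs <- list(one_step_template(N = 4),
                test_stepwise_mechanism(),
                test_dod_mechanism(),
                polya_like_mechanism(N_max = 40))
  cts <- c(1e-3, 1e-3, 1e-3, 5e-5)
  for (i in seq_along(mechs)) {
    ds_prog <- th_program(c(10, 80), 2, hold = 5)
    sim <- simulate_mechanism(mechs[[i]], ds_prog, cts[i])
    expect_lt(sim$mass_error, 1e-8)
  }
})

test_that("long holds converge to the algebraic equilibrium root", {
  mech <- one_step_template(N = 4, k_off_Tm = 0.5)
  TT <- 44
  prog <- temperature_program(data.frame(duration = 1e4, T_start = TT, T_end = TT))
  sim <- simulate_mechanism(mech, prog, 1e-3)
  eq <- equilibrium_state(mech, TT, 1e-3)
  theta_end <- sim$trajectory$theta_U[nrow(sim$trajectory)]
  expect_equal(theta_end, eq[1] / 1e-3, tolerance = 1e-6)

  # detailed balance: K from the relaxed state equals kr/kf
  T_K <- TT + 273.15
  K_D <- rate_constant(mech$steps[[1]]$kr, T_K) /
    rate_constant(mech$steps[[1]]$kf, T_K)
  st <- sim$states[nrow(sim$states), ]
  expect_equal(st[1]^4 / st[2], K_D, tolerance = 1e-6)
})

test_that("melt and anneal coincide in the equilibrium (slow-scan) limit", {
  mech <- dimer_template(k_app = 1e3, Tm = 50, C_T = 1e-4)
  ds <- suppressWarnings(
    simulate_th_dataset(mech, 0.01, c(35, 65), 1e-4, hold = 1, grid_dT = 2))
  fr <- suppressWarnings(dataset_fractions(ds, window = 6, grid_dT = 2))
  th_a <- fr[[1]]$theta_U
  th_m <- approx(fr[[2]]$temperature, fr[[2]]$theta_U, fr[[1]]$temperature)$y
  expect_lt(max(abs(th_a - th_m), na.rm = TRUE), 0.01)
})

test_that("faster scans shift anneal Tm down and melt Tm up, monotonically", {
  mech <- one_step_template(N = 2)
  ds <- simulate_th_dataset(mech, c(0.5, 1, 2, 4), c(10, 95), 1e-3, hold = 10)
  fr <- suppressWarnings(dataset_fractions(ds))
  dirs <- vapply(fr, function(f) attr(f, "direction"), "")
  rates <- vapply(fr, function(f) attr(f, "scan_rate"), 0)
  tms <- vapply(fr, function(f) suppressWarnings(apparent_tm(f)), 0)
  ord <- order(rates[dirs == "anneal"])
  expect_true(all(diff(tms[dirs == "anneal"][ord]) < 0))
  expect_true(all(diff(tms[dirs == "melt"][ord]) > 0))
})

test_that("stepwise with fleeting intermediates matches the one-step limit", {
  # pre-equilibrium construction: unstable, fast steps 1-2 collapse the
  # ladder to an effective one-step tetramer with kf_eff = kf3/(K1 K2)
  T_ref <- 318.15
  K1 <- 10; K2 <- 1e-2; kf3 <- 5e4; kr3 <- 0.25
  fast <- 1e8
  sw <- stepwise_mechanism(4, list(
    list(kf = rate_law(fast / K1, T_ref), kr = rate_law(fast, T_ref)),
    list(kf = rate_law(fast * 1e-2 / K2, T_ref), kr = rate_law(fast * 1e-2, T_ref)),
    list(kf = rate_law(kf3, T_ref, dH = -5e4), kr = rate_law(kr3, T_ref, dH = 1.2e5))))
  os <- one_step_mechanism(4, kf = rate_law(kf3 / (K1 * K2), T_ref, dH = -5e4),
                           kr = rate_law(kr3, T_ref, dH = 1.2e5))
  prog <- th_program(c(20, 70), 1, hold = 5)
  s1 <- simulate_mechanism(sw, prog, 1e-3)
  s2 <- simulate_mechanism(os, prog, 1e-3)
  expect_lt(max(abs(s1$trajectory$theta_U - s2$trajectory$theta_U)), 2e-3)
})

test_that("isodesmic equilibrium distribution is geometric", {
  # s = 1, sub-saturating: c1 stays below K_D so the tail is negligible
  T_ref <- 298.15
  mech <- goldstein_stryer_mechanism(s = 1, N_max = 30,
                                     kn_r = rate_law(100, T_ref),
                                     ke_f = rate_law(1e6, T_ref),
                                     ke_r = rate_law(100, T_ref))
  K_D <- 1e-4
  C_T <- 3e-5
  prog <- temperature_program(data.frame(duration = 5e3, T_start = 25, T_end = 25))
  sim <- simulate_mechanism(mech, prog, C_T)
  st <- sim$states[nrow(sim$states), ]
  oracle <- isodesmic_equilibrium_oracle(K_D, C_T, 30)
  expect_equal(st[1:10], oracle[1:10], tolerance = 1e-5)
  # geometric ratio c_{N+1}/c_N = c1/K_D
  ratio <- st[2:8] / st[1:7]
  expect_equal(ratio, rep(st[1] / K_D, 7), tolerance = 1e-5)
})

test_that("irreversible polymerization never loses oligomer number", {
  T_ref <- 298.15
  mech <- goldstein_stryer_mechanism(s = 2, N_max = 25,
                                     kn_r = rate_law(1e-10, T_ref),
                                     ke_f = rate_law(1e5, T_ref),
                                     ke_r = rate_law(1e-10, T_ref))
  prog <- temperature_program(data.frame(duration = 30, T_start = 25, T_end = 25))
  sim <- simulate_mechanism(mech, prog, 5e-5, hold_points = 50)
  n_olig <- rowSums(sim$states[, 2:25]) + sim$states[, 26]
  expect_true(all(diff(n_olig) > -1e-15))
})

test_that("the unstable trimeric nucleus never outnumbers monomers at >= 25 C", {
  mech <- polya_like_mechanism(N_max = 60)
  prog <- th_program(c(2, 65), 1, hold = 5, both = FALSE)
  sim <- simulate_mechanism(mech, prog, 5e-5)
  keep <- sim$trajectory$temperature >= 25
  expect_true(all(sim$states[keep, 3] <= sim$states[keep, 1] + 1e-18))
})

test_that("tail closure is insensitive to the explicit cutoff", {
  m100 <- polya_like_mechanism(N_max = 100)
  m200 <- polya_like_mechanism(N_max = 200)
  prog <- th_program(c(20, 65), 2, hold = 5, both = FALSE)
  s100 <- simulate_mechanism(m100, prog, 5e-5)
  s200 <- simulate_mechanism(m200, prog, 5e-5)
  expect_lt(max(abs(s100$trajectory$theta_U - s200$trajectory$theta_U)), 1e-3)
})

test_that("temperature programs are continuous and invertible", {
  tp <- th_program(c(10, 80), 2, hold = 5)
  expect_equal(program_temperature(tp, 0), 80)
  expect_equal(program_temperature(tp, 5), 80)
  expect_equal(program_temperature(tp, 5 + 35 / 2), 45)
  expect_equal(program_temperature(tp, tp$total_time), 80)
  expect_error(temperature_program(data.frame(duration = c(1, 1),
                                              T_start = c(0, 50),
                                              T_end = c(10, 60))),
               "continuous")
})
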