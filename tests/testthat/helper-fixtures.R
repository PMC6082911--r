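# Shared fixtures: small, identifiable mechanisms and dataset builders used
# across the test files. All heavier simulations keep coarse grids and few
# scan rates so the suite stays fast.

# cache for expensive fixtures shared across test blocks in one session
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# triplicate noisy theta dataset from the balanced step-wise ladder, plus
# the global fit of the generating mechanism to it (used by the parameter
# recovery and the model-selection tests)
noisy_stepwise_dataset <- function() {
  cached("sw_noisy_ds", {
    gen <- test_stepwise_mechanism()
    base <- simulate_th_dataset(gen, c(0.5, 2), c(0, 85), 1e-3, hold = 10,
                                grid_dT = 1)
    replicate_theta_noisy(base, sd = 0.01, n_rep = 3, seed = 101)
  })
}

noisy_stepwise_fit <- function() {
  cached("sw_noisy_fit", {
    gen <- test_stepwise_mechanism()
    truth <- mechanism_params(gen)
    free <- c("log10k_f1", "log10k_r1", "log10k_f2", "log10k_r2",
              "log10k_f3", "log10k_r3")
    start <- truth[free] + c(0.5, -0.4, 0.4, -0.5, 0.3, 0.5)
    global_fit(noisy_stepwise_dataset(), gen, par = start)
  })
}

# Step-wise tetramer with branch ratios near unity at each intermediate:
# every forward and reverse constant leaves a visible fingerprint in the TH
# curves, so parameter-recovery tests are well posed.
test_stepwise_mechanism <- function() {
  T_ref <- 318.15
  mk <- function(kf, kd, dHf, dHs)
    list(kf = rate_law(kf, T_ref, dH = dHf),
         kr = rate_law(kf * kd, T_ref, dH = dHf + dHs))
  stepwise_mechanism(4, list(mk(1e3, 1, -5e4, 6e4),
                             mk(2e5, 1e-4, -5e4, 1.7e5),
                             mk(5e4, 5e-6, -5e4, 1.7e5)))
}

# Dimer-of-dimers competitor with the same overall stability at 45 C
# (KD1^2 * KD2 matches the step-wise ladder product).
test_dod_mechanism <- function() {
  T_ref <- 318.15
  mk <- function(kf, kd, dHf, dHs)
    list(kf = rate_law(kf, T_ref, dH = dHf),
         kr = rate_law(kf * kd, T_ref, dH = dHf + dHs))
  dimer_of_dimers_mechanism(list(mk(1e3, 0.1, -5e4, 1e5),
                                 mk(1e5, 5.1e-8, -5e4, 3e5)))
}

# add i.i.d. Gaussian noise to the theta traces of a simulated dataset
add_theta_noise <- function(ds, sd, seed) {
  set.seed(seed)
  for (i in seq_along(ds$traces))
    ds$traces[[i]]$signal <- ds$traces[[i]]$signal +
      rnorm(nrow(ds$traces[[i]]), 0, sd)
  ds
}

# replicate a simulated theta dataset with independent noise; traces from
# all replicates are pooled into one dataset (joint fitting)
replicate_theta_noisy <- function(ds, sd, n_rep, seed) {
  set.seed(seed)
  traces <- list()
  for (k in seq_len(n_rep)) {
    for (tr in ds$traces) {
      tr$signal <- tr$signal + rnorm(nrow(tr), 0, sd)
      attr(tr, "replicate_id") <- sprintf("rep%d", k)
      traces[[length(traces) + 1]] <- tr
    }
  }
  out <- th_dataset(traces, C_T = ds$C_T, label = ds$label,
                    t_range = ds$t_range, hold = ds$hold)
  attr(out, "signal_is_theta") <- TRUE
  out
}

# fraction curve built directly from vectors (bypasses baseline machinery)
make_fraction_curve <- function(temperature, theta, scan_rate, direction) {
  structure(data.frame(temperature = temperature, theta_U = theta),
            class = c("fraction_curve", "data.frame"),
            scan_rate = scan_rate, direction = direction,
            replicate_id = NA_character_)
}

# model-free order at the mid-transition of a simulated one-step N-mer
# dataset; returns list(n, m, diagnostics)
modelfree_orders_midtransition <- function(mech, scan_rates = c(0.5, 1, 2, 4),
                                           T_range = c(10, 95), C_T = 1e-3,
                                           hold = 10) {
  ds <- simulate_th_dataset(mech, scan_rates, T_range, C_T, hold = hold)
  fr <- suppressWarnings(dataset_fractions(ds))
  hd <- suppressWarnings(hysteresis_diagnostics(fr))
  surf <- build_rate_surface(ds, fr)
  pa <- order_profile(surf, "anneal", theta_window = c(0.2, 0.8), min_points = 3)
  pm <- order_profile(surf, "melt", theta_window = c(0.2, 0.8), min_points = 3)
  dirs <- vapply(fr, function(f) attr(f, "direction"), "")
  tm_a <- mean(vapply(fr[dirs == "anneal"],
                      function(f) suppressWarnings(apparent_tm(f)), 0))
  tm_m <- mean(vapply(fr[dirs == "melt"],
                      function(f) suppressWarnings(apparent_tm(f)), 0))
  list(n = pa$order[which.min(abs(pa$temperature - tm_a))],
       m = pm$order[which.min(abs(pm$temperature - tm_m))],
       diagnostics = hd, profile_anneal = pa, profile_melt = pm)
}

# truncated isodesmic equilibrium oracle: solve the mass balance for c1 on
# the explicit ladder c_N = c1 (c1/K_D)^(N-1), N = 1..N_max (tail negligible
# by construction in the tests that use it)
isodesmic_equilibrium_oracle <- function(K_D, C_T, N_max) {
  mass <- function(c1) {
    x <- c1 / K_D
    sum(seq_len(N_max) * c1 * x^(seq_len(N_max) - 1))
  }
  c1 <- uniroot(function(z) mass(z) - C_T, lower = C_T * 1e-12,
                upper = min(C_T, K_D * (1 - 1e-9)), tol = C_T * 1e-13)$root
  c1 * (c1 / K_D)^(seq_len(N_max) - 1)
}
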