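# thermhyst

Mapping supramolecular assembly energy landscapes from multi-scan-rate
**thermal hysteresis (TH)** melting/annealing experiments.

When a self-assembling system — a tetramolecular quadruplex, a nucleated
nucleic-acid fiber, a protein polymer — is heated and cooled faster than it
can relax, its melting and annealing curves separate. That lag is data:
each scan rate samples a different non-equilibrium trajectory, so the
family of curves provides, at every temperature inside the transition,
several pairs of instantaneous monomer concentration and net reaction
rate,

```
[M] = theta_U * C_T,        d[M]/dt = C_T * (d theta_U / dT) * (dT/dt).
```

Log–log slices of this temperature–concentration–rate surface yield the
**effective reaction orders** of assembly (*n*, from annealing) and
disassembly (*m*, from melting) as continuous functions of temperature:

```
anneal:  ln(-d[M]/dt) = n ln[M] + ln k_on
melt:    ln( d[M]/dt) = m ln(C_T - [M]) + (1 - m) ln N + ln k_off
```

The order profile reveals the molecularity of the dominant transition
states (discrete assemblies) or the critical nucleus size (polymerization).
Explicit kinetic mechanisms are then fitted globally to the same datasets.

The package is aimed at biophysical chemists running UV/CD melting
experiments on associating systems, and at modellers studying
nucleation–elongation kinetics.

## What is in the box

* `load_th_dataset()` / `write_th_dataset()` — CSV traces with metadata
  headers or YAML/JSON sidecars.
* `fit_baselines()`, `compute_fraction_unfolded()`, `smooth_derivative()`,
  `apparent_tm()`, `hysteresis_diagnostics()` — signal to θ_U(T) with
  Savitzky–Golay derivatives and the adequacy heuristics (apparent-Tm
  shift ≥ 1 °C, anneal/melt slope ratio ≥ 3).
* `build_rate_surface()`, `extract_order_slice()`, `order_profile()` —
  the model-free analysis, 0.5 °C resolution across the transition.
* `simulate_mechanism()`, `simulate_th_dataset()` — stiff-ODE forward
  simulation of chained hold/anneal/hold/melt protocols for one-step,
  step-wise, dimer-of-dimers, and Goldstein–Stryer nucleation–elongation
  mechanisms (explicit oligomers plus a two-moment fiber-tail closure),
  with Arrhenius/heat-capacity temperature laws.
* `global_fit()`, `aic_compare()`, `nucleus_scan()` — global
  Levenberg–Marquardt fitting in θ_U space, AIC evidence ratios, critical
  nucleus-size scans (s = 1…7).
* `compute_fluxes()`, `effective_order()`, `scaling_experiment()` —
  per-oligomer flux decomposition Φ_N, flux-weighted effective orders
  (n_eff = Σ (Φ_N/R) ∂lnΦ_N/∂ln c₁, an exact identity by construction),
  and the nucleus-size scaling laws ((s+3)/2 isothermal, (s+1)/2 in TH).
* `generate_dataset()`, `kinetic_limit_survey()` — seeded synthetic
  datasets emulating standard acquisition designs, and the how-fast-can-it-
  relax applicability survey.
* `inst/cli/thermhyst.R` — a thin command-line wrapper
  (`simulate | synth | modelfree | fit | fluxes`) over the same functions.

## Worked example

Generate a realistic noisy annealing dataset for a nucleated fiber
(nucleus of three strands, forward constants 7×10⁴ M⁻¹min⁻¹, nucleus
K_D = 100 µM, elongation K_D = 1 µM at 25 °C; 50 µM strands, six scan
rates 0.2–4 °C/min over 2–65 °C), then extract the temperature-resolved
assembly order:

```r
library(thermhyst)
cfg  <- polya_like_config(mech = polya_like_mechanism(N_max = 60), seed = 1)
reps <- generate_dataset(cfg)
ds   <- reps[[1]]
ds
#> <th_dataset> 'synthetic_rep1': 6 trace(s), C_T = 5e-05 M, T 2.0..65.0 C
#>   anneal: rates 0.2, 0.5, 1, 2, 3, 4 C/min

fr   <- dataset_fractions(ds)          # baselines -> theta_U -> d theta/dT
surf <- build_rate_surface(ds, fr)     # (T, [M], d[M]/dt) across scan rates
prof <- order_profile(surf, "anneal", min_points = 3)
prof
#> <order_profile> anneal: 27 temperatures, order 2.21..4.26 over 20.0..33.0 C

subset(as.data.frame(prof), temperature %in% c(26, 28, 30, 32))
#>    temperature order order_stderr intercept intercept_stderr n_points
#> 13          26 2.700        0.246    17.406            2.684        5
#> 17          28 2.214        0.221    11.393            2.374        6
#> 21          30 2.568        0.341    14.428            3.548        6
#> 25          32 2.570        0.628    13.397            6.368        6
```

The extracted assembly orders cluster between 2 and 3 across the
transition — the fingerprint of a trimeric nucleus whose pre-nucleus
species hold an appreciable share of the consumed monomer. The same
number emerges from the mechanism's flux decomposition at mid-reaction:

```r
fd <- effective_order(polya_like_mechanism(N_max = 60), C_T = 5e-5,
                      temperature_C = 25, at_theta = 0.5)
fd
#> <flux_decomposition> 61 fluxes at 25.0 C, R = 6.077e-06 M/min
#>   flux-weighted effective order n_eff = 2.391
```

Here `R` is the total association flux (monomers consumed per minute at
50 % conversion) and `n_eff` its logarithmic sensitivity to the monomer
concentration, decomposed exactly over the per-oligomer fluxes.

To fit mechanisms and scan the nucleus size:

```r
# fits run on fraction-unfolded curves; simulate_th_dataset() returns them
# directly, experimental data go through dataset_fractions() first
mech <- polya_like_mechanism(N_max = 40)
ds_theta <- simulate_th_dataset(mech, c(0.5, 2), c(2, 65), C_T = 5e-5,
                                hold = 5, directions = "anneal")
fit <- global_fit(ds_theta, mech,
                  par = mechanism_params(mech)[c("log10k_ef", "log10k_nr", "log10k_er")])
scan <- nucleus_scan(ds_theta, mech, s_values = 1:5, par = fit$par)
scan$best_s
```

See the methods vignette (`vignettes/thermal-hysteresis-methods.Rmd`) for
the models, assumptions, numerical choices, and limitations.

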