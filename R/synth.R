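#' Synthetic thermal-hysteresis dataset generation
#'
#' Generates realistic noisy TH datasets in signal space from any mechanism:
#' the mechanism is simulated under the full acquisition protocol at each
#' scan rate, the fraction-unfolded curves are mapped to a spectroscopic
#' signal through linear folded/unfolded baselines,
#' \deqn{signal(T) = folded(T)(1 - \theta_U) + unfolded(T)\,\theta_U + \epsilon,}
#' and i.i.d. Gaussian noise of standard deviation \code{noise_sd} is added
#' with a reproducible seed. Two preset configurations emulate common UV
#' melting designs: a tetramolecular-quadruplex-like design (1 mM strands,
#' six rates 0.2-2 deg C/min, 0-85 deg C, 10 min holds) and a
#' fiber-assembly-like design (50 uM strands, six rates 0.2-4 deg C/min,
#' 2-65 deg C, 5 min holds, annealing only).
#'
#' @param mech mechanism to simulate.
#' @param scan_rates scan rate magnitudes, deg C/min.
#' @param T_range temperature window, deg C.
#' @param C_T total subunit concentration, M.
#' @param hold equilibration hold, min.
#' @param directions subset of c("anneal", "melt").
#' @param baselines list with folded/unfolded intercepts and slopes (signal
#'   units and per deg C).
#' @param noise_sd signal noise standard deviation (default 0.002).
#' @param seed integer seed (mandatory for reproducibility).
#' @param replicates number of replicate datasets (same truth, fresh noise).
#' @param wavelength metadata, nm.
#' @param grid_dT sampling step, deg C.
#' @return object of class \code{synth_config} (a list).
#' @export
synth_config <- function(mech, scan_rates, T_range, C_T, hold = 10,
                         directions = c("anneal", "melt"),
                         baselines = list(folded_intercept = 0.50,
                                          folded_slope = 0.0010,
                                          unfolded_intercept = 0.80,
                                          unfolded_slope = 0.0008),
                         noise_sd = 0.002, seed = 1L, replicates = 1L,
                         wavelength = NA_real_, grid_dT = 0.5) {
  stopifnot(inherits(mech, "mechanism"), noise_sd >= 0, replicates >= 1)
  structure(list(mech = mech, scan_rates = scan_rates, T_range = T_range,
                 C_T = C_T, hold = hold, directions = directions,
                 baselines = baselines, noise_sd = noise_sd,
                 seed = as.integer(seed), replicates = as.integer(replicates),
                 wavelength = wavelength, grid_dT = grid_dT),
            class = "synth_config")
}

#' Quadruplex-like preset design
#' @param ... overrides passed to \code{\link{synth_config}}.
#' @export
tg4t_like_config <- function(...) {
  over <- list(...)
  defaults <- list(mech = tg4t_like_mechanism(),
                   scan_rates = c(0.2, 0.3, 0.5, 1, 1.5, 2),
                   T_range = c(0, 85), C_T = 1e-3, hold = 10,
                   directions = c("anneal", "melt"), wavelength = 295)
  do.call(synth_config, utils::modifyList(defaults, over))
}

#' Fiber-assembly-like preset design (annealing scans only)
#' @param ... overrides passed to \code{\link{synth_config}}.
#' @export
polya_like_config <- function(...) {
  over <- list(...)
  defaults <- list(mech = polya_like_mechanism(),
                   scan_rates = c(0.2, 0.5, 1, 2, 3, 4),
                   T_range = c(2, 65), C_T = 5e-5, hold = 5,
                   directions = "anneal", wavelength = 252)
  do.call(synth_config, utils::modifyList(defaults, over))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a synthetic TH dataset
#'
#' @param config a \code{\link{synth_config}}.
#' @param out_dir optional directory; when given, each replicate is written
#'   as a set of trace CSVs (with metadata headers) in
#'   \code{<out_dir>/rep<k>/}, together with the ground-truth theta curves
#'   (\code{*_theta.csv}) and the generating parameters
#'   (\code{truth.json}).
#' @return a list of \code{\link{th_dataset}}s, one per replicate (signal
#'   space). The noiseless theta dataset is attached as attribute
#'   \code{"truth"}.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "synth_config"))
  truth <- simulate_th_dataset(config$mech, config$scan_rates, config$T_range,
                               config$C_T, hold = config$hold,
                               directions = config$directions,
                               grid_dT = config$grid_dT)
  bl <- config$baselines
  reps <- with_seed(config$seed, {
    lapply(seq_len(config$replicates), function(k) {
      traces <- lapply(truth$traces, function(tr) {
        fold <- bl$folded_intercept + bl$folded_slope * tr$temperature
        unf <- bl$unfolded_intercept + bl$unfolded_slope * tr$temperature
        sig <- fold * (1 - tr$signal) + unf * tr$signal
        if (config$noise_sd > 0)
          sig <- sig + stats::rnorm(length(sig), 0, config$noise_sd)
        th_trace(tr$temperature, sig,
                 scan_rate = attr(tr, "scan_rate"),
                 direction = attr(tr, "direction"),
                 wavelength = config$wavelength,
                 replicate_id = sprintf("rep%d", k))
      })
      th_dataset(traces, C_T = config$C_T,
                 label = sprintf("synthetic_rep%d", k),
                 t_range = range(config$T_range), hold = config$hold)
    })
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(reps)) {
      sub <- file.path(out_dir, sprintf("rep%d", k))
      write_th_dataset(reps[[k]], sub)
      for (i in seq_along(truth$traces)) {
        tr <- truth$traces[[i]]
        f <- file.path(sub, sprintf("trace_%02d_theta.csv", i))
        writeLines(c("temperature_C,theta_U",
                     sprintf("%.15g,%.15g", tr$temperature, tr$signal)), f)
      }
    }
    truth_meta <- list(seed = config$seed, noise_sd = config$noise_sd,
                       baselines = bl, C_T = config$C_T,
                       scan_rates = config$scan_rates, hold = config$hold,
                       T_range = as.numeric(config$T_range),
                       mechanism = config$mech$kind,
                       parameters = as.list(mechanism_params(config$mech)))
    jsonlite::write_json(truth_meta, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  attr(reps, "truth") <- truth
  reps
}

#' Kinetic applicability survey
#'
#' How fast can a reaction be and still display measurable hysteresis? For a
#' series of apparent relaxation rates \code{k_app} (defined at the
#' equilibrium Tm of a reversible bimolecular template), the melt and anneal
#' scans are simulated at the fastest experimentally accessible rate and the
#' apparent-Tm shift is tabulated. The shift decreases monotonically with
#' \code{k_app}; reactions with \code{k_app} of order 1/min or slower retain
#' shifts of a degree or more.
#'
#' @param k_app_values apparent relaxation rates at Tm, 1/min.
#' @param scan_rate scan rate, deg C/min (default 2, a typical maximum).
#' @param Tm,C_T,dH_diss,dH_act_f passed to \code{\link{dimer_template}}.
#' @param T_range scan window, deg C.
#' @param hold equilibration hold, min.
#' @param ... passed to \code{\link{simulate_th_dataset}}.
#' @return data.frame: k_app, tm_melt, tm_anneal, shift (deg C).
#' @export
kinetic_limit_survey <- function(k_app_values, scan_rate = 2, Tm = 50,
                                 C_T = 1e-4, dH_diss = 3e5, dH_act_f = 5e4,
                                 T_range = c(20, 80), hold = 10, ...) {
  rows <- lapply(k_app_values, function(ka) {
    mech <- dimer_template(k_app = ka, Tm = Tm, C_T = C_T,
                           dH_diss = dH_diss, dH_act_f = dH_act_f)
    # single-scan-rate datasets are expected here: the survey measures Tm
    # shifts, not reaction orders
    ds <- suppressWarnings(
      simulate_th_dataset(mech, scan_rate, T_range, C_T, hold = hold,
                          directions = c("anneal", "melt"), ...))
    fr <- dataset_fractions(ds)
    dirs <- vapply(fr, function(fc) attr(fc, "direction"), "")
    tma <- apparent_tm(fr[[which(dirs == "anneal")[1]]])
    tmm <- apparent_tm(fr[[which(dirs == "melt")[1]]])
    data.frame(k_app = ka, tm_melt = tmm, tm_anneal = tma, shift = tmm - tma)
  })
  do.call(rbind, rows)
}
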