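#' Mass-action right-hand sides for assembly mechanisms
#'
#' Computes time derivatives of the species state vector at a given
#' temperature. States are oligomer concentrations in M (number
#' concentration of i-mers); for Goldstein-Stryer mechanisms the last two
#' entries are the fiber-tail number and mass moments (see
#' \code{\link{goldstein_stryer_rhs}}).
#'
#' @param mech a \code{\link{mechanisms}} object.
#' @param y state vector.
#' @param temperature_C temperature, deg C.
#' @return numeric vector of time derivatives (M/min).
#' @export
mechanism_rhs <- function(mech, y, temperature_C) {
  T_K <- C_to_K(temperature_C)
  switch(mech$kind,
         one_step = rhs_one_step(mech, y, T_K),
         stepwise = rhs_stepwise(mech, y, T_K),
         dimer_of_dimers = rhs_dod(mech, y, T_K),
         goldstein_stryer = rhs_gs(mech, y, T_K),
         stop("unknown mechanism kind"))
}

rhs_one_step <- function(mech, y, T_K) {
  kf <- rate_constant(mech$steps[[1]]$kf, T_K)
  kr <- rate_constant(mech$steps[[1]]$kr, T_K)
  phi <- kf * y[1]^mech$N - kr * y[2]
  c(-mech$N * phi, phi)
}

rhs_stepwise <- function(mech, y, T_K) {
  N <- mech$N
  dy <- numeric(N)
  for (i in seq_len(N - 1)) {
    kf <- rate_constant(mech$steps[[i]]$kf, T_K)
    kr <- rate_constant(mech$steps[[i]]$kr, T_K)
    phi <- kf * y[1] * y[i] - kr * y[i + 1]
    dy[i] <- dy[i] - phi
    dy[i + 1] <- dy[i + 1] + phi
    dy[1] <- dy[1] - phi
  }
  dy
}

rhs_dod <- function(mech, y, T_K) {
  k1f <- rate_constant(mech$steps[[1]]$kf, T_K)
  k1r <- rate_constant(mech$steps[[1]]$kr, T_K)
  k2f <- rate_constant(mech$steps[[2]]$kf, T_K)
  k2r <- rate_constant(mech$steps[[2]]$kr, T_K)
  phi1 <- k1f * y[1]^2 - k1r * y[2]
  phi2 <- k2f * y[2]^2 - k2r * y[3]
  c(-2 * phi1, phi1 - 2 * phi2, phi2)
}

# Step-resolved rate constants for a Goldstein-Stryer mechanism.
# Step N -> N+1 (product size N+1): nucleation constants while the product is
# no larger than the nucleus (N+1 <= s), elongation constants otherwise. The
# critical nucleus therefore grows with k_e+ and decays with k_n-.
gs_step_constants <- function(mech, T_K) {
  Nmax <- mech$N_max
  prod_size <- 2:Nmax
  kn_f <- rate_constant(mech$rates$kn_f, T_K)
  kn_r <- rate_constant(mech$rates$kn_r, T_K)
  ke_f <- rate_constant(mech$rates$ke_f, T_K)
  ke_r <- rate_constant(mech$rates$ke_r, T_K)
  list(kf = ifelse(prod_size <= mech$s, kn_f, ke_f),
       kr = ifelse(prod_size <= mech$s, kn_r, ke_r),
       ke_f = ke_f, ke_r = ke_r)
}

# Estimated concentration of minimal-length (N_max + 1) tail fibers under the
# two-moment closure: geometric length distribution with the observed mean,
# c_b = P^2 / (Mt - N_max * P). When the tail is entirely minimal-length
# (Mt = (N_max+1) P) this reduces to c_b = P.
gs_tail_boundary <- function(P, Mt, Nmax) {
  if (P <= 0) return(0)
  denom <- Mt - Nmax * P
  P^2 / max(denom, P)
}

#' Goldstein-Stryer right-hand side with two-moment tail closure
#'
#' Explicit oligomers \eqn{c_1 \dots c_{N_{max}}} evolve under monomer-addition
#' fluxes \eqn{\Phi_N = k^+(N) c_1 c_N - k^-(N+1) c_{N+1}}. Fibers longer than
#' \code{N_max} are lumped into a number moment \eqn{P} and a mass moment
#' \eqn{M_t} (monomer equivalents). Tail fibers elongate at \eqn{k_{e+} c_1}
#' and shed monomers at \eqn{k_{e-}} each; the sub-population at the minimal
#' tail length \eqn{N_{max}+1}, estimated from a geometric length
#' distribution with the current mean, re-enters the explicit region on
#' monomer loss. The closure conserves monomer mass exactly and its adequacy
#' is checked by doubling \code{N_max}.
#'
#' @param state state vector \code{c(c_1..c_Nmax, tail_number, tail_mass)}.
#' @param temperature_C temperature, deg C.
#' @param mech a \code{goldstein_stryer} mechanism.
#' @return vector of time derivatives.
#' @export
goldstein_stryer_rhs <- function(state, temperature_C, mech) {
  stopifnot(mech$kind == "goldstein_stryer")
  rhs_gs(mech, state, C_to_K(temperature_C))
}

rhs_gs <- function(mech, y, T_K) {
  Nmax <- mech$N_max
  c1 <- y[1]
  cc <- y[seq_len(Nmax)]
  P <- y[Nmax + 1L]
  Mt <- y[Nmax + 2L]
  ks <- gs_step_constants(mech, T_K)

  # interior fluxes N -> N+1 for N = 1..Nmax-1
  phi <- ks$kf * c1 * cc[1:(Nmax - 1)] - ks$kr * cc[2:Nmax]

  cb <- gs_tail_boundary(P, Mt, Nmax)
  J_in <- ks$ke_f * c1 * cc[Nmax]       # Nmax-mer + M -> tail
  J_grow <- ks$ke_f * c1 * P            # tail fiber + M -> longer tail fiber
  J_shed <- ks$ke_r * max(P - cb, 0)    # monomer loss from non-minimal tail
  J_ret <- ks$ke_r * cb                 # minimal tail fiber -> Nmax-mer + M

  dc <- numeric(Nmax)
  dc[1:(Nmax - 1)] <- dc[1:(Nmax - 1)] - phi
  dc[2:Nmax] <- dc[2:Nmax] + phi
  dc[1] <- dc[1] - sum(phi) - J_in - J_grow + J_shed + J_ret
  dc[Nmax] <- dc[Nmax] - J_in + J_ret
  dP <- J_in - J_ret
  dMt <- (Nmax + 1) * (J_in - J_ret) + J_grow - J_shed
  c(dc, dP, dMt)
}

initial_state <- function(mech, C_T, init = "monomer", temperature_C = NULL) {
  n <- n_species(mech)
  if (is.numeric(init)) {
    stopifnot(length(init) == n)
    return(init)
  }
  if (identical(init, "monomer")) {
    y <- numeric(n)
    y[1] <- C_T
    return(y)
  }
  if (identical(init, "equilibrium")) {
    stopifnot(!is.null(temperature_C))
    return(equilibrium_state(mech, temperature_C, C_T))
  }
  stop("init must be 'monomer', 'equilibrium', or a numeric state vector")
}

#' Equilibrium species distribution at a temperature
#'
#' Solves the detailed-balance ladder for the monomer concentration that
#' satisfies the total mass balance, by bisection on \eqn{c_1}. For
#' Goldstein-Stryer mechanisms the tail beyond \code{N_max} is summed in
#' closed form from the geometric distribution with ratio
#' \eqn{x = c_1 k_{e+} / k_{e-}} (requires \eqn{x < 1}).
#'
#' @param mech a mechanism.
#' @param temperature_C temperature, deg C.
#' @param C_T total subunit concentration, M (monomer equivalents).
#' @return state vector at equilibrium.
#' @export
equilibrium_state <- function(mech, temperature_C, C_T) {
  T_K <- C_to_K(temperature_C)
  ladder <- function(c1) {
    switch(mech$kind,
      one_step = {
        K <- rate_constant(mech$steps[[1]]$kf, T_K) / rate_constant(mech$steps[[1]]$kr, T_K)
        c(c1, K * c1^mech$N)
      },
      stepwise = {
        cc <- numeric(mech$N)
        cc[1] <- c1
        for (i in seq_len(mech$N - 1)) {
          K <- rate_constant(mech$steps[[i]]$kf, T_K) / rate_constant(mech$steps[[i]]$kr, T_K)
          cc[i + 1] <- K * c1 * cc[i]
        }
        cc
      },
      dimer_of_dimers = {
        K1 <- rate_constant(mech$steps[[1]]$kf, T_K) / rate_constant(mech$steps[[1]]$kr, T_K)
        K2 <- rate_constant(mech$steps[[2]]$kf, T_K) / rate_constant(mech$steps[[2]]$kr, T_K)
        c2 <- K1 * c1^2
        c(c1, c2, K2 * c2^2)
      },
      goldstein_stryer = {
        ks <- gs_step_constants(mech, T_K)
        cc <- numeric(mech$N_max)
        cc[1] <- c1
        for (i in seq_len(mech$N_max - 1))
          cc[i + 1] <- (ks$kf[i] / ks$kr[i]) * c1 * cc[i]
        x <- c1 * ks$ke_f / ks$ke_r
        if (x < 1) {
          P <- cc[mech$N_max] * x / (1 - x)
          Mt <- cc[mech$N_max] * x * (mech$N_max / (1 - x) + 1 / (1 - x)^2)
        } else {
          P <- Inf; Mt <- Inf
        }
        c(cc, P, Mt)
      })
  }
  mass_of <- function(c1) state_mass(mech, ladder(c1))
  hi <- C_T
  if (mech$kind == "goldstein_stryer") {
    ks <- gs_step_constants(mech, T_K)
    hi <- min(C_T, (ks$ke_r / ks$ke_f) * (1 - 1e-12))
  }
  if (mass_of(hi) <= C_T) return(ladder(hi))
  c1 <- uniroot(function(z) mass_of(z) - C_T, lower = C_T * 1e-14, upper = hi,
                tol = C_T * 1e-13)$root
  ladder(c1)
}

#' Simulate a kinetic mechanism under a temperature program
#'
#' Integrates the mass-action ODEs with a stiff-capable adaptive BDF solver
#' (\code{deSolve::vode}), segment by segment so ramp corners are exact.
#' Within ramps the solution is sampled on a regular temperature grid.
#'
#' @param mech a \code{\link{mechanisms}} object.
#' @param program a \code{\link{temperature_program}}.
#' @param C_T total subunit concentration, M.
#' @param init \code{"monomer"} (all subunits free), \code{"equilibrium"}
#'   (equilibrium at the program's start temperature), or a numeric state
#'   vector.
#' @param rtol,atol integrator tolerances; defaults \code{1e-8} and
#'   \code{1e-12 * C_T}.
#' @param sample_dT output sampling interval along ramps, deg C.
#' @param hold_points number of output points per hold segment.
#' @return object of class \code{th_trajectory}: list with \code{trajectory}
#'   (data.frame: time, temperature, theta_U, segment), \code{states}
#'   (matrix, one row per output point), \code{mass_error} (max relative
#'   mass-conservation error), plus the inputs.
#' @export
simulate_mechanism <- function(mech, program, C_T, init = "monomer",
                               rtol = 1e-8, atol = NULL, sample_dT = 0.5,
                               hold_points = 10L) {
  stopifnot(inherits(program, "temperature_program"), C_T > 0)
  if (is.null(atol)) atol <- 1e-12 * C_T
  seg <- program$segments
  y <- initial_state(mech, C_T, init, temperature_C = seg$T_start[1])
  nsp <- n_species(mech)

  all_t <- numeric(0); all_T <- numeric(0); all_seg <- character(0)
  all_y <- matrix(NA_real_, nrow = 0, ncol = nsp)

  for (k in seq_len(nrow(seg))) {
    t0 <- seg$t0[k]; t1 <- seg$t1[k]
    if (abs(seg$rate[k]) < 1e-12) {
      times <- seq(t0, t1, length.out = hold_points)
    } else {
      Ta <- seg$T_start[k]; Tb <- seg$T_end[k]
      grid <- seq(min(Ta, Tb), max(Ta, Tb), by = sample_dT)
      times <- sort(unique(c(t0, t0 + (grid - Ta) / seg$rate[k], t1)))
      times <- times[times >= t0 - 1e-9 & times <= t1 + 1e-9]
    }
    f <- function(t, y, parms) {
      TC <- seg$T_start[k] + seg$rate[k] * (t - t0)
      list(mechanism_rhs(mech, y, TC))
    }
    sol <- deSolve::vode(y, times, f, parms = NULL, rtol = rtol, atol = atol,
                         maxsteps = 100000, mf = 22)
    if (attr(sol, "istate")[1] < 0)
      stop(sprintf("integration failed in segment %d (t = %.2f..%.2f min, T = %.1f..%.1f C); final state min = %.3g",
                   k, t0, t1, seg$T_start[k], seg$T_end[k], min(sol[nrow(sol), -1])))
    ys <- unname(sol[, -1, drop = FALSE])
    if (min(ys) < -1e-6 * C_T)
      stop("negative concentrations beyond tolerance in simulation")
    ys[ys < 0] <- 0
    keep <- if (nrow(all_y) > 0) -1L else TRUE  # drop duplicated segment joint
    all_t <- c(all_t, sol[keep, 1])
    all_T <- c(all_T, seg$T_start[k] + seg$rate[k] * (sol[keep, 1] - t0))
    lbl <- if ("label" %in% names(seg)) seg$label[k] else paste0("seg", k)
    all_seg <- c(all_seg, rep(lbl, length(sol[keep, 1])))
    all_y <- rbind(all_y, ys[keep, , drop = FALSE])
    y <- ys[nrow(ys), ]
  }

  mass <- apply(all_y, 1, function(z) state_mass(mech, z))
  mass_error <- max(abs(mass - C_T)) / C_T
  theta <- all_y[, 1] / C_T
  structure(list(
    trajectory = data.frame(time = all_t, temperature = all_T,
                            theta_U = theta, segment = all_seg),
    states = all_y, mass_error = mass_error,
    mechanism = mech, program = program, C_T = C_T), class = "th_trajectory")
}

#' @export
print.th_trajectory <- function(x, ...) {
  cat(sprintf("<th_trajectory> %d points, %.1f min, T %.1f..%.1f C, mass error %.2e\n",
              nrow(x$trajectory), max(x$trajectory$time),
              min(x$trajectory$temperature), max(x$trajectory$temperature),
              x$mass_error))
  invisible(x)
}

#' Simulate a multi-scan-rate thermal-hysteresis dataset
#'
#' For each scan rate, runs the chained protocol (hold at the high end,
#' anneal, hold at the low end, melt) and extracts the fraction-unfolded
#' curve of each scan on the regular temperature grid. The melt therefore
#' starts from the annealed end state, as in the experiment.
#'
#' @param mech a mechanism.
#' @param scan_rates vector of scan rate magnitudes, deg C/min.
#' @param T_range numeric length 2, deg C.
#' @param C_T total subunit concentration, M.
#' @param hold equilibration hold at the extremes, min.
#' @param directions which scans to keep: subset of c("anneal", "melt").
#'   Both are always simulated when "melt" is requested (the melt is chained
#'   after the anneal); requesting only "anneal" skips the return scan.
#' @param grid_dT temperature sampling step, deg C.
#' @param init initial condition at the high-temperature start.
#' @param ... passed to \code{\link{simulate_mechanism}}.
#' @return a \code{\link{th_dataset}} whose traces hold theta_U directly as
#'   the signal column (attribute \code{signal_is_theta = TRUE}).
#' @export
simulate_th_dataset <- function(mech, scan_rates, T_range, C_T, hold = 10,
                                directions = c("anneal", "melt"),
                                grid_dT = 0.5, init = "monomer", ...) {
  directions <- match.arg(directions, several.ok = TRUE)
  traces <- list()
  for (sr in scan_rates) {
    prog <- th_program(T_range, sr, hold = hold, first = "anneal",
                       both = "melt" %in% directions)
    sim <- simulate_mechanism(mech, prog, C_T, init = init,
                              sample_dT = grid_dT, ...)
    tr <- sim$trajectory
    if ("anneal" %in% directions) {
      sc <- tr[tr$segment == "scan1", ]
      traces[[length(traces) + 1]] <- th_trace(
        temperature = sc$temperature, signal = sc$theta_U,
        scan_rate = sr, direction = "anneal")
    }
    if ("melt" %in% directions) {
      sc <- tr[tr$segment == "scan2", ]
      traces[[length(traces) + 1]] <- th_trace(
        temperature = sc$temperature, signal = sc$theta_U,
        scan_rate = sr, direction = "melt")
    }
  }
  ds <- th_dataset(traces, C_T = C_T, label = "simulated",
                   t_range = range(T_range), hold = hold)
  attr(ds, "signal_is_theta") <- TRUE
  ds
}
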