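#' Kinetic mechanisms for supramolecular assembly
#'
#' Four mechanism kinds are supported, all built from mass-action monomer
#' (or dimer) association steps with temperature-dependent rate constants:
#' \describe{
#'   \item{one_step}{\eqn{N M \rightleftharpoons A_N} in a single step.}
#'   \item{stepwise}{sequential monomer addition
#'     \eqn{M \rightleftharpoons D \rightleftharpoons \dots \rightleftharpoons A_N}.}
#'   \item{dimer_of_dimers}{\eqn{M \rightleftharpoons D}, then
#'     \eqn{D + D \rightleftharpoons A_4}.}
#'   \item{goldstein_stryer}{open-ended nucleation--elongation polymerization:
#'     oligomers up to \code{N_max} are tracked explicitly, longer fibers are
#'     lumped into two tail moments (number and mass). Steps producing
#'     oligomers of size \eqn{\le s} (the critical nucleus) use the nucleation
#'     constants \eqn{k_{n+}, k_{n-}}; larger sizes use the elongation
#'     constants \eqn{k_{e+}, k_{e-}}. The nucleus itself associates with
#'     \eqn{k_{e+}} and dissociates with \eqn{k_{n-}}.}
#' }
#'
#' Fluxes are event rates: a dimerization event consumes two monomers, every
#' other association step consumes one. Phenomenological rate constants
#' obtained from model-free analysis absorb such stoichiometric factors and
#' are not directly comparable to the microscopic constants here.
#'
#' @name mechanisms
NULL

new_mechanism <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = c(paste0("mech_", kind), "mechanism"))
}

#' One-step (all-or-none) N-mer mechanism
#'
#' @param N stoichiometry of the assembly (>= 2).
#' @param kf,kr \code{\link{rate_law}}s for association (M^-(N-1) min^-1) and
#'   dissociation (min^-1).
#' @return a \code{mechanism} object.
#' @export
one_step_mechanism <- function(N, kf, kr) {
  stopifnot(N >= 2, inherits(kf, "rate_law"), inherits(kr, "rate_law"))
  new_mechanism("one_step", N = as.integer(N), steps = list(list(kf = kf, kr = kr)))
}

#' Step-wise monomer-association mechanism
#'
#' @param N final stoichiometry (number of subunits, >= 2).
#' @param steps list of \code{N - 1} steps, each a list with elements
#'   \code{kf} and \code{kr} (\code{\link{rate_law}}s). Step \code{i} is
#'   \eqn{M + A_i \rightleftharpoons A_{i+1}}.
#' @return a \code{mechanism} object.
#' @export
stepwise_mechanism <- function(N, steps) {
  stopifnot(N >= 2, length(steps) == N - 1)
  for (st in steps) stopifnot(inherits(st$kf, "rate_law"), inherits(st$kr, "rate_law"))
  new_mechanism("stepwise", N = as.integer(N), steps = steps)
}

#' Dimer-of-dimers mechanism (monomer -> dimer -> tetramer)
#'
#' @param steps list of 2 steps: \code{M + M <-> D} then \code{D + D <-> T},
#'   each with \code{kf}, \code{kr} rate laws.
#' @return a \code{mechanism} object.
#' @export
dimer_of_dimers_mechanism <- function(steps) {
  stopifnot(length(steps) == 2)
  for (st in steps) stopifnot(inherits(st$kf, "rate_law"), inherits(st$kr, "rate_law"))
  new_mechanism("dimer_of_dimers", N = 4L, steps = steps)
}

#' Goldstein-Stryer nucleation-elongation mechanism
#'
#' @param s critical nucleus size (1 = isodesmic, non-cooperative).
#' @param N_max largest explicitly tracked oligomer (>= s + 1).
#' @param kn_f,kn_r nucleation association/dissociation \code{\link{rate_law}}s.
#' @param ke_f,ke_r elongation association/dissociation \code{\link{rate_law}}s.
#' @param tie_forward if \code{TRUE} (default), the nucleation association
#'   constant is slaved to the elongation one (\eqn{k_{n+} = k_{e+}}), the
#'   simplification commonly applied in nucleated-polymerization fitting;
#'   \code{kn_f} is then ignored.
#' @return a \code{mechanism} object.
#' @export
goldstein_stryer_mechanism <- function(s, N_max, kn_f = NULL, kn_r, ke_f, ke_r,
                                       tie_forward = TRUE) {
  stopifnot(s >= 1, N_max >= s + 1, N_max >= 3)
  if (tie_forward) kn_f <- ke_f
  stopifnot(inherits(kn_f, "rate_law"), inherits(kn_r, "rate_law"),
            inherits(ke_f, "rate_law"), inherits(ke_r, "rate_law"))
  new_mechanism("goldstein_stryer", s = as.integer(s), N_max = as.integer(N_max),
                rates = list(kn_f = kn_f, kn_r = kn_r, ke_f = ke_f, ke_r = ke_r),
                tie_forward = isTRUE(tie_forward))
}

#' @export
print.mechanism <- function(x, ...) {
  cat(sprintf("<mechanism: %s>\n", x$kind))
  if (x$kind == "goldstein_stryer") {
    cat(sprintf("  s = %d, N_max = %d, tie_forward = %s\n", x$s, x$N_max, x$tie_forward))
    for (nm in names(x$rates))
      cat(sprintf("  %s: k_ref = %.4g at %.2f K (dH = %.3g)\n", nm,
                  x$rates[[nm]]$k_ref, x$rates[[nm]]$T_ref, x$rates[[nm]]$dH))
  } else {
    cat(sprintf("  N = %d, %d step(s)\n", x$N, length(x$steps)))
    for (i in seq_along(x$steps))
      cat(sprintf("  step %d: kf_ref = %.4g, kr_ref = %.4g\n", i,
                  x$steps[[i]]$kf$k_ref, x$steps[[i]]$kr$k_ref))
  }
  invisible(x)
}

n_species <- function(mech) {
  switch(mech$kind,
         one_step = 2L,
         stepwise = mech$N,
         dimer_of_dimers = 3L,
         goldstein_stryer = mech$N_max + 2L,
         stop("unknown mechanism kind"))
}

species_sizes <- function(mech) {
  # monomer-equivalents carried by each state-vector entry (tail moments
  # handled separately)
  switch(mech$kind,
         one_step = c(1L, mech$N),
         stepwise = seq_len(mech$N),
         dimer_of_dimers = c(1L, 2L, 4L),
         goldstein_stryer = seq_len(mech$N_max),
         stop("unknown mechanism kind"))
}

#' Total monomer-equivalent mass of a state
#'
#' @param mech a mechanism.
#' @param y state vector (oligomer concentrations, plus tail number and tail
#'   mass for Goldstein-Stryer).
#' @return total concentration in monomer equivalents (M).
#' @export
state_mass <- function(mech, y) {
  sz <- species_sizes(mech)
  if (mech$kind == "goldstein_stryer") {
    sum(sz * y[seq_len(mech$N_max)]) + y[mech$N_max + 2L]
  } else {
    sum(sz * y)
  }
}

## ---- flat parameter access (used by the fitting module) -------------------

# Parameter names:
#   finite mechanisms: log10k_f1, log10k_r1, ..., dH_f1, dH_r1, ...
#   goldstein_stryer:  log10k_nf, log10k_nr, log10k_ef, log10k_er,
#                      dH_nf, dH_nr, dH_ef, dH_er
# With tie_forward, setting log10k_ef / dH_ef also updates the nucleation
# forward law; log10k_nf is then not an independent parameter.

#' Get mechanism parameters as a flat named vector
#' @param mech a mechanism.
#' @return named numeric vector (log10 rate constants and enthalpies in J/mol).
#' @export
mechanism_params <- function(mech) {
  if (mech$kind == "goldstein_stryer") {
    r <- mech$rates
    out <- c(log10k_nf = log10(r$kn_f$k_ref), log10k_nr = log10(r$kn_r$k_ref),
             log10k_ef = log10(r$ke_f$k_ref), log10k_er = log10(r$ke_r$k_ref),
             dH_nf = r$kn_f$dH, dH_nr = r$kn_r$dH,
             dH_ef = r$ke_f$dH, dH_er = r$ke_r$dH)
    return(out)
  }
  out <- numeric(0)
  for (i in seq_along(mech$steps)) {
    st <- mech$steps[[i]]
    v <- c(log10(st$kf$k_ref), log10(st$kr$k_ref), st$kf$dH, st$kr$dH)
    names(v) <- paste0(c("log10k_f", "log10k_r", "dH_f", "dH_r"), i)
    out <- c(out, v)
  }
  out
}

#' Update mechanism parameters from a flat named vector
#' @param mech a mechanism.
#' @param par named numeric vector; any subset of \code{\link{mechanism_params}}
#'   names.
#' @return the modified mechanism.
#' @export
set_mechanism_params <- function(mech, par) {
  stopifnot(!is.null(names(par)), all(nzchar(names(par))))
  if (mech$kind == "goldstein_stryer") {
    map <- c(log10k_nf = "kn_f", log10k_nr = "kn_r",
             log10k_ef = "ke_f", log10k_er = "ke_r",
             dH_nf = "kn_f", dH_nr = "kn_r", dH_ef = "ke_f", dH_er = "ke_r")
    for (nm in names(par)) {
      if (!nm %in% names(map)) stop("unknown parameter: ", nm)
      slot <- map[[nm]]
      if (startsWith(nm, "log10k")) mech$rates[[slot]]$k_ref <- 10^par[[nm]]
      else mech$rates[[slot]]$dH <- par[[nm]]
    }
    if (mech$tie_forward) mech$rates$kn_f <- mech$rates$ke_f
    return(mech)
  }
  for (nm in names(par)) {
    m <- regmatches(nm, regexec("^(log10k|dH)_([fr])([0-9]+)$", nm))[[1]]
    if (length(m) == 0) stop("unknown parameter: ", nm)
    i <- as.integer(m[4])
    if (i > length(mech$steps)) stop("no such step: ", nm)
    which_k <- if (m[3] == "f") "kf" else "kr"
    if (m[2] == "log10k") mech$steps[[i]][[which_k]]$k_ref <- 10^par[[nm]]
    else mech$steps[[i]][[which_k]]$dH <- par[[nm]]
  }
  mech
}
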