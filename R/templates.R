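#' Built-in mechanism templates
#'
#' Ready-made parameterizations used by the synthetic-data generator, the
#' kinetic-applicability survey, and the examples. Rate-constant magnitudes
#' for the quadruplex-like and fiber-like templates follow published
#' estimates for those systems; temperature dependences (activation and
#' dissociation enthalpies) are generic nucleic-acid-like values chosen so
#' the transitions fall inside the respective scan windows. All defaults are
#' documented in the methods vignette.
#'
#' @name templates
NULL

#' Reversible bimolecular (one-step dimer) template
#'
#' A DNA-duplex-like dimerization whose equilibrium melting temperature is
#' \code{Tm} at total strand concentration \code{C_T} (i.e.
#' \eqn{K_D(T_m) = C_T}), and whose apparent relaxation rate at the
#' equilibrium Tm is \code{k_app}. For a dimerization the relaxation rate at
#' equilibrium is \eqn{k_{app} = k_{off} + 4 k_{on} [M]_{eq}}; with
#' \eqn{[M]_{eq} = C_T/2} and \eqn{K_D = C_T} this gives
#' \eqn{k_{app} = 3 k_{off}(T_m)}.
#'
#' @param k_app apparent relaxation rate at the equilibrium Tm, 1/min.
#' @param Tm equilibrium melting temperature, deg C.
#' @param C_T total strand concentration, M.
#' @param dH_diss dissociation (van't Hoff) enthalpy, J/mol.
#' @param dH_act_f association activation enthalpy, J/mol.
#' @return a one-step dimer \code{mechanism}.
#' @export
dimer_template <- function(k_app = 1, Tm = 50, C_T = 1e-4,
                           dH_diss = 3e5, dH_act_f = 5e4) {
  T_ref <- C_to_K(Tm)
  k_off <- k_app / 3
  k_on <- k_off / C_T
  one_step_mechanism(2,
    kf = rate_law(k_on, T_ref, dH = dH_act_f),
    kr = rate_law(k_off, T_ref, dH = dH_act_f + dH_diss))
}

#' Generic one-step N-mer template with controlled hysteresis
#'
#' All-or-none association of N subunits, parameterized by the equilibrium
#' Tm at concentration \code{C_T} (the step dissociation constant at Tm is
#' \eqn{N (C_T/2)^{N-1}}) and by the dissociation rate constant at Tm,
#' which sets the relaxation timescale and hence the degree of hysteresis.
#'
#' @param N stoichiometry.
#' @param Tm equilibrium melting temperature at \code{C_T}, deg C.
#' @param C_T total subunit concentration, M.
#' @param k_off_Tm dissociation rate constant at Tm, 1/min; small values
#'   (slow relaxation) give strong hysteresis at ordinary scan rates.
#' @param dH_diss,dH_act_f enthalpies, J/mol. The default association
#'   activation enthalpy is negative (association speeds up on cooling), the
#'   behaviour commonly observed for nucleic-acid association below the Tm;
#'   it lets annealing run to completion at low temperature while remaining
#'   far from equilibrium through the transition.
#' @return a one-step \code{mechanism}.
#' @export
one_step_template <- function(N = 4, Tm = 45, C_T = 1e-3, k_off_Tm = 0.01,
                              dH_diss = 3.5e5, dH_act_f = -1.8e5) {
  T_ref <- C_to_K(Tm)
  K_D <- N * (C_T / 2)^(N - 1)
  one_step_mechanism(N,
    kf = rate_law(k_off_Tm / K_D, T_ref, dH = dH_act_f),
    kr = rate_law(k_off_Tm, T_ref, dH = dH_act_f + dH_diss))
}

#' Step-wise tetramer template (tetramolecular quadruplex-like)
#'
#' Sequential monomer association M <-> D <-> Tr <-> Te with a highly
#' unstable, slowly forming dimer (K_D of order 10 M, association of order
#' 1e2 per M min) and much more favorable later additions (micromolar
#' K_Ds, association of order 1e5 per M min), as estimated for
#' tetramolecular quadruplex assembly. Reference temperature 45 deg C.
#'
#' @param kf1,kd1,kf2,kd2,kf3,kd3 per-step association rate constants
#'   (M^-1 min^-1) and dissociation constants (M) at 45 deg C.
#' @param dH_f per-step association activation enthalpies, J/mol (length 3).
#' @param dH_step per-step dissociation enthalpies, J/mol (length 3).
#' @return a stepwise tetramer \code{mechanism}.
#' @export
tg4t_like_mechanism <- function(kf1 = 300, kd1 = 17,
                                kf2 = 2e5, kd2 = 2e-6,
                                kf3 = 2e5, kd3 = 1.5e-5,
                                dH_f = c(-5e4, -5e4, -5e4),
                                dH_step = c(6e4, 1.7e5, 1.7e5)) {
  T_ref <- C_to_K(45)
  mk <- function(kf, kd, dHf, dHs)
    list(kf = rate_law(kf, T_ref, dH = dHf),
         kr = rate_law(kf * kd, T_ref, dH = dHf + dHs))
  stepwise_mechanism(4, list(mk(kf1, kd1, dH_f[1], dH_step[1]),
                             mk(kf2, kd2, dH_f[2], dH_step[2]),
                             mk(kf3, kd3, dH_f[3], dH_step[3])))
}

#' Dimer-of-dimers tetramer template
#'
#' M + M <-> D, D + D <-> Te, with overall stability matched to the
#' step-wise template at the reference temperature (the product of step
#' dissociation constants, in the appropriate powers, equals that of the
#' step-wise ladder) so the two mechanisms produce comparable equilibrium
#' melting curves and differ mainly in kinetics.
#'
#' @param kf1,kd1 dimerization rate constant (M^-1 min^-1) and K_D (M).
#' @param kf2,kd2 dimer-dimer association and K_D.
#' @param dH_f,dH_step enthalpies, J/mol (length 2 each).
#' @return a dimer-of-dimers \code{mechanism}.
#' @export
dod_like_mechanism <- function(kf1 = 1e3, kd1 = 0.1,
                               kf2 = 1e5, kd2 = 5.1e-8,
                               dH_f = c(5e4, 5e4),
                               dH_step = c(1e5, 3e5)) {
  T_ref <- C_to_K(45)
  mk <- function(kf, kd, dHf, dHs)
    list(kf = rate_law(kf, T_ref, dH = dHf),
         kr = rate_law(kf * kd, T_ref, dH = dHf + dHs))
  dimer_of_dimers_mechanism(list(mk(kf1, kd1, dH_f[1], dH_step[1]),
                                 mk(kf2, kd2, dH_f[2], dH_step[2])))
}

#' Nucleation-elongation fiber template (poly(A)/cyanuric-acid-like)
#'
#' Goldstein-Stryer mechanism with nucleus size 3, equal forward constants
#' \eqn{k_{n+} = k_{e+} = 7\times10^4\,\mathrm{M^{-1}min^{-1}}}, nucleation
#' \eqn{K_D = 100\,\mu M} and elongation \eqn{K_D = 1\,\mu M} at 25 deg C,
#' the constants estimated for cyanuric-acid-mediated poly(A) fiber
#' assembly. Both dissociation constants share a generic dissociation
#' enthalpy so their 100-fold ratio is temperature independent.
#'
#' @param s nucleus size.
#' @param N_max explicit-oligomer cutoff.
#' @param k_plus forward rate constant (both nucleation and elongation),
#'   M^-1 min^-1 at 25 deg C.
#' @param KD_n,KD_e nucleation and elongation dissociation constants, M, at
#'   25 deg C.
#' @param dH_f association activation enthalpy, J/mol.
#' @param dH_diss dissociation enthalpy, J/mol.
#' @return a \code{goldstein_stryer} mechanism.
#' @export
polya_like_mechanism <- function(s = 3, N_max = 100, k_plus = 7e4,
                                 KD_n = 1e-4, KD_e = 1e-6,
                                 dH_f = 3e4, dH_diss = 2.5e5) {
  T_ref <- C_to_K(25)
  goldstein_stryer_mechanism(
    s = s, N_max = N_max,
    kn_r = rate_law(k_plus * KD_n, T_ref, dH = dH_f + dH_diss),
    ke_f = rate_law(k_plus, T_ref, dH = dH_f),
    ke_r = rate_law(k_plus * KD_e, T_ref, dH = dH_f + dH_diss),
    tie_forward = TRUE)
}

#' Canonical nucleated assembly template
#'
#' A strongly cooperative Goldstein-Stryer mechanism: equal forward
#' constants and a nucleation dissociation constant 1000-fold weaker than
#' elongation, the regime in which the classical nucleus-size scaling laws
#' apply.
#'
#' @inheritParams polya_like_mechanism
#' @param ratio nucleation-to-elongation K_D ratio (>= 1e3 for the
#'   canonical regime).
#' @export
canonical_nucleated_mechanism <- function(s = 3, N_max = 60, k_plus = 1e5,
                                          KD_e = 1e-6, ratio = 1e3,
                                          dH_f = 3e4, dH_diss = 2.5e5) {
  polya_like_mechanism(s = s, N_max = N_max, k_plus = k_plus,
                       KD_n = KD_e * ratio, KD_e = KD_e,
                       dH_f = dH_f, dH_diss = dH_diss)
}
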