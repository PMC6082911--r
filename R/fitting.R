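#' Global mechanistic fitting of thermal-hysteresis datasets
#'
#' Fits an explicit kinetic mechanism simultaneously to all traces of a
#' multi-scan-rate TH dataset by minimizing the sum of squared
#' fraction-unfolded residuals over every trace and grid point
#' (Levenberg-Marquardt, \code{minpack.lm::nls.lm}). Rate constants are
#' optimized as log10 values; activation enthalpies linearly. Each candidate
#' parameter set is evaluated by re-simulating the full acquisition protocol
#' (hold, anneal, hold, melt) at every scan rate in the dataset and
#' interpolating the model \eqn{\theta_U} onto the observed temperature
#' grids. Replicate traces at the same rate and direction are fitted jointly
#' with shared parameters.
#'
#' @param dataset a \code{\link{th_dataset}} of fraction-unfolded traces
#'   (e.g. from \code{\link{simulate_th_dataset}} or
#'   \code{\link{generate_dataset}} after preprocessing; traces must hold
#'   theta_U as signal, or supply \code{fractions}).
#' @param mech the mechanism to fit (its current parameter values seed the
#'   optimizer unless \code{par} overrides them).
#' @param par named vector of starting values for the free parameters
#'   (names as in \code{\link{mechanism_params}}).
#' @param lower,upper bounds on \code{par} (same names); defaults are wide.
#' @param fractions optional list of \code{fraction_curve}s to fit instead of
#'   the raw traces.
#' @param hold equilibration hold (min); default from the dataset metadata,
#'   falling back to 10.
#' @param rtol,atol integrator tolerances used during fitting.
#' @param maxiter maximum optimizer iterations.
#' @param restarts maximum Levenberg-Marquardt restarts from the current
#'   optimum (fresh damping; helps leave shallow ridges).
#' @param warn_hysteresis check hysteresis adequacy and warn if inadequate.
#' @return object of class \code{fit_result}: optimized mechanism,
#'   parameters and asymptotic standard errors, RSS, AIC, convergence flag,
#'   and per-trace residual table.
#' @export
global_fit <- function(dataset, mech, par = NULL, lower = NULL, upper = NULL,
                       fractions = NULL, hold = NULL, rtol = 1e-8, atol = NULL,
                       maxiter = 100, restarts = 2, warn_hysteresis = FALSE) {
  stopifnot(inherits(dataset, "th_dataset"), inherits(mech, "mechanism"))
  if (is.null(hold)) hold <- if (is.finite(dataset$hold)) dataset$hold else 10
  obs <- if (!is.null(fractions)) {
    lapply(fractions, function(fc) list(
      temperature = fc$temperature, theta = fc$theta_U,
      scan_rate = attr(fc, "scan_rate"), direction = attr(fc, "direction")))
  } else {
    if (!isTRUE(attr(dataset, "signal_is_theta")))
      stop("dataset traces are not theta_U curves; preprocess first and pass fractions =")
    lapply(dataset$traces, function(tr) list(
      temperature = tr$temperature, theta = tr$signal,
      scan_rate = attr(tr, "scan_rate"), direction = attr(tr, "direction")))
  }
  if (warn_hysteresis) {
    fcs <- lapply(obs, function(o) structure(
      data.frame(temperature = o$temperature, theta_U = o$theta),
      class = c("fraction_curve", "data.frame"),
      scan_rate = o$scan_rate, direction = o$direction))
    fcs <- lapply(fcs, function(fc) tryCatch(smooth_derivative(fc),
                                             error = function(e) fc))
    hd <- hysteresis_diagnostics(fcs)
    if (!hd$adequate) warning("hysteresis may be inadequate for reliable fitting")
  }
  rates <- sort(unique(vapply(obs, `[[`, 0, "scan_rate")))
  dirs <- unique(vapply(obs, `[[`, "", "direction"))
  t_range <- dataset$t_range
  if (is.null(par)) par <- mechanism_params(mech)
  pnames <- names(par)
  if (is.null(lower)) lower <- ifelse(startsWith(pnames, "log10k"), -6, -1e6)
  if (is.null(upper)) upper <- ifelse(startsWith(pnames, "log10k"), 12, 1e6)

  model_curves <- function(m) {
    sims <- list()
    for (sr in rates) {
      prog <- th_program(t_range, sr, hold = hold, first = "anneal",
                         both = "melt" %in% dirs)
      sim <- simulate_mechanism(m, prog, dataset$C_T, init = "monomer",
                                rtol = rtol, atol = atol, sample_dT = 0.5)
      tr <- sim$trajectory
      sims[[paste0("anneal_", sr)]] <- tr[tr$segment == "scan1", ]
      if ("melt" %in% dirs) sims[[paste0("melt_", sr)]] <- tr[tr$segment == "scan2", ]
    }
    sims
  }
  resid_fn <- function(p) {
    names(p) <- pnames
    m <- set_mechanism_params(mech, p)
    sims <- tryCatch(model_curves(m), error = function(e) NULL)
    if (is.null(sims)) return(rep(1e3, sum(vapply(obs, function(o) length(o$theta), 0L))))
    unlist(lapply(obs, function(o) {
      sm <- sims[[paste0(o$direction, "_", o$scan_rate)]]
      pred <- stats::approx(sm$temperature, sm$theta_U, xout = o$temperature,
                            rule = 2)$y
      o$theta - pred
    }))
  }
  # forward-difference Jacobian steps must clear the ODE integration noise:
  # epsfcn = 1e-6 gives relative steps of ~1e-3 on log10-scaled parameters
  ctrl <- minpack.lm::nls.lm.control(maxiter = maxiter, ftol = 1e-12,
                                     ptol = 1e-10, epsfcn = 1e-6)
  res <- minpack.lm::nls.lm(par = par, lower = lower, upper = upper,
                            fn = resid_fn, control = ctrl)
  # restart with fresh damping: helps escape shallow ridges of
  # weakly identified parameter combinations
  for (r in seq_len(restarts)) {
    prev <- res$deviance
    res2 <- minpack.lm::nls.lm(par = res$par, lower = lower, upper = upper,
                               fn = resid_fn, control = ctrl)
    if (res2$deviance <= prev) res <- res2
    if (prev - res2$deviance < 0.01 * prev) break
  }
  best <- res$par; names(best) <- pnames
  mech_fit <- set_mechanism_params(mech, best)
  rvec <- resid_fn(best)
  rss <- sum(rvec^2)
  n_points <- length(rvec)
  n_params <- length(par)
  dof <- max(n_points - n_params, 1)
  se <- rep(NA_real_, n_params); names(se) <- pnames
  covm <- tryCatch(solve(0.5 * res$hessian) * (rss / dof), error = function(e) NULL)
  if (!is.null(covm)) {
    dg <- diag(covm); dg[dg < 0] <- NA_real_
    se <- sqrt(dg); names(se) <- pnames
  }
  at_bound <- best <= lower + 1e-9 | best >= upper - 1e-9
  if (any(at_bound)) warning("parameter(s) at bound: ",
                             paste(pnames[at_bound], collapse = ", "))
  converged <- res$info %in% 1:4
  if (!converged) warning("fit did not converge (", res$message,
                          "); best-so-far returned")
  # per-trace residual table
  idx <- 0; rtab <- list()
  for (o in obs) {
    k <- length(o$theta)
    rtab[[length(rtab) + 1]] <- data.frame(
      direction = o$direction, scan_rate = o$scan_rate,
      temperature = o$temperature, residual = rvec[idx + seq_len(k)])
    idx <- idx + k
  }
  structure(list(mechanism = mech_fit, par = best, se = se, rss = rss,
                 n_points = n_points, n_params = n_params,
                 aic = aic_from_rss(rss, n_points, n_params),
                 converged = converged, message = res$message,
                 niter = res$niter, rsstrace = res$rsstrace,
                 residual_table = do.call(rbind, rtab)),
            class = "fit_result")
}

# Gaussian-residual AIC: n ln(RSS/n) + 2p
aic_from_rss <- function(rss, n, p) n * log(rss / n) + 2 * p

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s: RSS = %.4g over %d points (%d params), AIC = %.2f, %s\n",
              x$mechanism$kind, x$rss, x$n_points, x$n_params, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  tab <- data.frame(estimate = x$par, stderr = x$se)
  print(signif(tab, 5))
  invisible(x)
}

#' Compare fitted mechanisms by AIC
#'
#' Uses the Gaussian-residual form \eqn{AIC = n \ln(RSS/n) + 2p} (optionally
#' the small-sample AICc) and reports the relative likelihood of each model,
#' \eqn{\exp((AIC_{min} - AIC_i)/2)}: the evidence ratio of model i versus
#' the best model.
#'
#' @param fits list of \code{fit_result}s on the same dataset.
#' @param labels model labels (default: mechanism kinds).
#' @param aicc use the small-sample correction?
#' @return data.frame with n_params, RSS, AIC, delta AIC and relative
#'   likelihood, ordered best-first.
#' @export
aic_compare <- function(fits, labels = NULL, aicc = FALSE) {
  stopifnot(length(fits) >= 2)
  n <- unique(vapply(fits, `[[`, 0, "n_points"))
  if (length(n) != 1) stop("fits were not performed on the same data points")
  if (is.null(labels))
    labels <- vapply(fits, function(f) f$mechanism$kind, "")
  aic <- vapply(fits, function(f) {
    a <- aic_from_rss(f$rss, f$n_points, f$n_params)
    if (aicc) a <- a + 2 * f$n_params * (f$n_params + 1) /
        max(f$n_points - f$n_params - 1, 1)
    a
  }, 0)
  d <- aic - min(aic)
  out <- data.frame(model = labels,
                    n_params = vapply(fits, function(f) as.integer(f$n_params), 0L),
                    rss = vapply(fits, `[[`, 0, "rss"),
                    aic = aic, delta_aic = d,
                    rel_likelihood = exp(-d / 2))
  out[order(out$aic), ]
}

#' Scan the critical nucleus size of a Goldstein-Stryer fit
#'
#' Repeats \code{\link{global_fit}} for each candidate nucleus size with
#' otherwise shared settings and tabulates RSS and AIC versus s. The RSS
#' minimum identifies the preferred nucleus size; s = 1 corresponds to
#' non-cooperative (isodesmic) assembly.
#'
#' @param dataset a \code{\link{th_dataset}} of theta_U traces.
#' @param mech a \code{goldstein_stryer} template mechanism (s is overridden).
#' @param s_values candidate nucleus sizes (default 1:7).
#' @param ... passed to \code{\link{global_fit}}.
#' @return list: \code{table} (data.frame s, rss, aic, converged),
#'   \code{best_s}, \code{fits} (list of fit_results),
#'   \code{low_identifiability} flag (single-trace datasets).
#' @export
nucleus_scan <- function(dataset, mech, s_values = 1:7, ...) {
  stopifnot(mech$kind == "goldstein_stryer")
  low_id <- length(dataset$traces) < 2
  if (low_id) warning("single-trace dataset: nucleus size may be poorly identifiable")
  fits <- list(); rows <- list()
  for (s in s_values) {
    m <- mech; m$s <- as.integer(s)
    f <- global_fit(dataset, m, ...)
    fits[[as.character(s)]] <- f
    rows[[length(rows) + 1]] <- data.frame(s = s, rss = f$rss, aic = f$aic,
                                           converged = f$converged)
  }
  tab <- do.call(rbind, rows)
  list(table = tab, best_s = tab$s[which.min(tab$rss)], fits = fits,
       low_identifiability = low_id)
}
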