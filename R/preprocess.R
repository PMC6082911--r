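#' Baseline fitting for melting traces
#'
#' Fits ordinary least-squares lines to the folded (low-temperature,
#' assembled) and unfolded (high-temperature, dissociated) baseline regions
#' of a trace. Default ranges are the lowest and highest 15\% of the trace's
#' temperature span, the usual convention for UV melting curves; override
#' them to match instrument- or system-specific choices.
#'
#' @param trace a \code{\link{th_trace}}.
#' @param folded_range,unfolded_range numeric length-2 temperature intervals
#'   (deg C), or \code{NULL} for the defaults.
#' @param frac fraction of the span used for default ranges.
#' @return object of class \code{baseline_model} with folded/unfolded
#'   intercepts and slopes and the ranges used.
#' @export
fit_baselines <- function(trace, folded_range = NULL, unfolded_range = NULL,
                          frac = 0.15) {
  stopifnot(inherits(trace, "th_trace"))
  Tr <- range(trace$temperature)
  span <- diff(Tr)
  if (is.null(folded_range)) folded_range <- c(Tr[1], Tr[1] + frac * span)
  if (is.null(unfolded_range)) unfolded_range <- c(Tr[2] - frac * span, Tr[2])
  folded_range <- sort(folded_range); unfolded_range <- sort(unfolded_range)
  if (folded_range[2] > unfolded_range[1])
    stop("baseline ranges overlap")
  fit_one <- function(rng) {
    sel <- trace$temperature >= rng[1] & trace$temperature <= rng[2]
    if (sum(sel) < 3) stop("baseline range contains fewer than 3 points")
    co <- stats::coef(stats::lm(signal ~ temperature, data = trace[sel, ]))
    c(intercept = unname(co[1]), slope = unname(co[2]))
  }
  f <- fit_one(folded_range); u <- fit_one(unfolded_range)
  structure(list(folded_intercept = f["intercept"], folded_slope = f["slope"],
                 unfolded_intercept = u["intercept"], unfolded_slope = u["slope"],
                 folded_range = folded_range, unfolded_range = unfolded_range),
            class = "baseline_model")
}

baseline_lines <- function(bl, temperature) {
  list(folded = unname(bl$folded_intercept + bl$folded_slope * temperature),
       unfolded = unname(bl$unfolded_intercept + bl$unfolded_slope * temperature))
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("<baseline_model> folded: %.5g + %.5g*T (%.1f..%.1f C); unfolded: %.5g + %.5g*T (%.1f..%.1f C)\n",
              x$folded_intercept, x$folded_slope, x$folded_range[1], x$folded_range[2],
              x$unfolded_intercept, x$unfolded_slope, x$unfolded_range[1], x$unfolded_range[2]))
  invisible(x)
}

#' Fraction-unfolded curve from a trace and baselines
#'
#' \deqn{\theta_U(T) = \frac{signal(T) - folded(T)}{unfolded(T) - folded(T)}}
#' \eqn{\theta_U} is invariant under affine transformations of the signal.
#' Values outside [0, 1] are retained by default (they carry rate
#' information); they are excluded later from log-log order fits.
#'
#' @param trace a \code{\link{th_trace}}.
#' @param baselines a \code{baseline_model} (from this trace, or shared
#'   across a dataset).
#' @param clip clip theta to [0, 1]?
#' @return object of class \code{fraction_curve}: data.frame with columns
#'   \code{temperature}, \code{theta_U} (and \code{dtheta_dT} after
#'   \code{\link{smooth_derivative}}), carrying the trace metadata.
#' @export
compute_fraction_unfolded <- function(trace, baselines, clip = FALSE) {
  stopifnot(inherits(trace, "th_trace"), inherits(baselines, "baseline_model"))
  bl <- baseline_lines(baselines, trace$temperature)
  den <- bl$unfolded - bl$folded
  if (any(den <= 0) || min(abs(den)) < 1e-3 * max(abs(den)))
    stop("degenerate denominator: baselines intersect within the trace span")
  theta <- (trace$signal - bl$folded) / den
  if (clip) theta <- pmin(1, pmax(0, theta))
  m <- trace_meta(trace)
  structure(data.frame(temperature = trace$temperature, theta_U = theta),
            class = c("fraction_curve", "data.frame"),
            scan_rate = m$scan_rate, direction = m$direction,
            replicate_id = m$replicate_id)
}

# fraction curve directly from a theta-valued trace (simulated datasets)
fraction_from_theta_trace <- function(trace) {
  m <- trace_meta(trace)
  structure(data.frame(temperature = trace$temperature, theta_U = trace$signal),
            class = c("fraction_curve", "data.frame"),
            scan_rate = m$scan_rate, direction = m$direction,
            replicate_id = m$replicate_id)
}

#' Smoothed derivative of a fraction curve
#'
#' Resamples \eqn{\theta_U} onto a uniform temperature grid (linear
#' interpolation) and applies a Savitzky-Golay local-polynomial filter to
#' obtain both the smoothed curve and its temperature derivative. The filter
#' matrix (\code{signal::sgolay}) uses one-sided fits at the ends, so
#' polynomials up to the filter order are differentiated exactly everywhere.
#'
#' @param curve a \code{fraction_curve}.
#' @param window smoothing window width, deg C (default 2.5).
#' @param polyorder local polynomial order (default 2).
#' @param grid_dT uniform grid step, deg C (default 0.5).
#' @return a \code{fraction_curve} on the uniform grid with a
#'   \code{dtheta_dT} column (per deg C).
#' @export
smooth_derivative <- function(curve, window = 2.5, polyorder = 2, grid_dT = 0.5) {
  stopifnot(inherits(curve, "fraction_curve"))
  Tr <- range(curve$temperature)
  if (window > diff(Tr)) stop("smoothing window larger than trace span")
  grid <- seq(ceiling(Tr[1] / grid_dT) * grid_dT, Tr[2], by = grid_dT)
  th <- stats::approx(curve$temperature, curve$theta_U, xout = grid)$y
  np <- 2 * floor(window / (2 * grid_dT)) + 1  # odd window in points
  np <- max(np, polyorder + 2 + (polyorder %% 2 == 1))  # n > p, odd
  if (np %% 2 == 0) np <- np + 1
  if (np > length(grid)) stop("smoothing window larger than resampled trace")
  F0 <- signal::sgolay(p = polyorder, n = np, m = 0)
  F1 <- signal::sgolay(p = polyorder, n = np, m = 1)
  sm <- apply_sgolay(F0, th)
  dd <- apply_sgolay(F1, th) / grid_dT
  structure(data.frame(temperature = grid, theta_U = sm, dtheta_dT = dd),
            class = c("fraction_curve", "data.frame"),
            scan_rate = attr(curve, "scan_rate"),
            direction = attr(curve, "direction"),
            replicate_id = attr(curve, "replicate_id"))
}

# Apply an sgolay projection matrix with proper one-sided end handling:
# interior points use the central row, the first/last (n-1)/2 points use the
# corresponding off-center rows on the first/last n samples.
apply_sgolay <- function(Fm, x) {
  n <- nrow(Fm)
  half <- (n - 1) / 2
  len <- length(x)
  out <- numeric(len)
  centre <- Fm[half + 1, ]
  for (i in seq_len(len)) {
    if (i <= half) out[i] <- sum(Fm[i, ] * x[1:n])
    else if (i > len - half) out[i] <- sum(Fm[n - (len - i), ] * x[(len - n + 1):len])
    else out[i] <- sum(centre * x[(i - half):(i + half)])
  }
  out
}

#' Apparent melting temperature of a fraction curve
#'
#' Temperature of the first upward or downward crossing of
#' \eqn{\theta_U = 0.5}, by linear interpolation between the bracketing grid
#' points. On a non-equilibrium scan this apparent Tm is shifted above the
#' equilibrium Tm for melts and below it for anneals.
#'
#' @param curve a \code{fraction_curve}.
#' @return apparent Tm, deg C.
#' @export
apparent_tm <- function(curve) {
  th <- curve$theta_U; Tg <- curve$temperature
  cross <- which(diff(sign(th - 0.5)) != 0)
  if (length(cross) == 0) stop("theta_U never crosses 0.5: apparent Tm undefined")
  if (length(cross) > 1)
    warning("multiple theta = 0.5 crossings; using the first")
  i <- cross[1]
  Tg[i] + (0.5 - th[i]) * (Tg[i + 1] - Tg[i]) / (th[i + 1] - th[i])
}

#' Hysteresis adequacy diagnostics
#'
#' The model-free order extraction assumes that one term of the two-term
#' phenomenological rate law dominates each scan direction, which requires
#' pronounced hysteresis. Two heuristics are evaluated on the slowest scans:
#' the melt-minus-anneal apparent-Tm shift (adequate when >= 1 deg C) and
#' the ratio of the anneal to melt curve slopes at the anneal mid-transition
#' temperature (adequate when >= 3).
#'
#' @param fractions list of \code{fraction_curve}s with derivatives
#'   (\code{\link{smooth_derivative}}), at least one melt and one anneal.
#' @param tm_threshold,slope_threshold adequacy thresholds.
#' @return list: \code{tm_shift} (deg C, max over matched rates),
#'   \code{slope_ratio}, \code{adequate} flag, and per-rate shift table.
#' @export
hysteresis_diagnostics <- function(fractions, tm_threshold = 1,
                                   slope_threshold = 3) {
  dirs <- vapply(fractions, function(fc) attr(fc, "direction"), "")
  rates <- vapply(fractions, function(fc) attr(fc, "scan_rate"), 0)
  melts <- fractions[dirs == "melt"]; anneals <- fractions[dirs == "anneal"]
  if (length(melts) == 0 || length(anneals) == 0)
    return(list(tm_shift = 0, slope_ratio = NA_real_, adequate = FALSE,
                shifts = data.frame()))
  tm_of <- function(fc) tryCatch(apparent_tm(fc), error = function(e) NA_real_)
  mr <- rates[dirs == "melt"]; ar <- rates[dirs == "anneal"]
  shifts <- data.frame(scan_rate = numeric(0), tm_melt = numeric(0),
                       tm_anneal = numeric(0), shift = numeric(0))
  for (r in intersect(mr, ar)) {
    tmm <- tm_of(melts[[which(mr == r)[1]]])
    tma <- tm_of(anneals[[which(ar == r)[1]]])
    shifts <- rbind(shifts, data.frame(scan_rate = r, tm_melt = tmm,
                                       tm_anneal = tma, shift = tmm - tma))
  }
  tm_shift <- if (nrow(shifts) && any(is.finite(shifts$shift)))
    max(shifts$shift, na.rm = TRUE) else 0
  # slope ratio at the slowest-anneal mid-transition temperature
  sa <- anneals[[which.min(ar)]]
  sm <- melts[[which.min(mr)]]
  ratio <- NA_real_
  tmid <- tryCatch(apparent_tm(sa), error = function(e) NA_real_)
  if (is.finite(tmid) && !is.null(sa$dtheta_dT) && !is.null(sm$dtheta_dT)) {
    da <- stats::approx(sa$temperature, sa$dtheta_dT, xout = tmid)$y
    dm <- stats::approx(sm$temperature, sm$dtheta_dT, xout = tmid)$y
    ratio <- abs(da) / max(abs(dm), .Machine$double.eps)
  }
  adequate <- isTRUE(tm_shift >= tm_threshold) &&
    (is.finite(ratio) && ratio >= slope_threshold)
  list(tm_shift = tm_shift, slope_ratio = ratio, adequate = adequate,
       shifts = shifts)
}

#' Correct for instrument temperature lag
#'
#' During fast scanning the sample temperature lags the block temperature
#' roughly in proportion to the scan rate:
#' \eqn{T_{sample} = T_{block} - \lambda\, dT/dt} with the signed scan rate
#' (negative on anneals, so anneal temperatures are corrected upward). The
#' lag constant \eqn{\lambda} (minutes) is instrument specific and must be
#' calibrated; the default everywhere in the package is \eqn{\lambda = 0}
#' (no correction).
#'
#' @param trace a \code{\link{th_trace}}.
#' @param lambda lag constant, min.
#' @return the trace with corrected temperatures.
#' @export
correct_temperature_lag <- function(trace, lambda = 0) {
  stopifnot(inherits(trace, "th_trace"), is.numeric(lambda))
  if (lambda == 0) return(trace)
  signed <- if (attr(trace, "direction") == "anneal") -attr(trace, "scan_rate")
            else attr(trace, "scan_rate")
  m <- trace_meta(trace)
  th_trace(trace$temperature - lambda * signed, trace$signal,
           scan_rate = m$scan_rate, direction = m$direction,
           wavelength = m$wavelength, replicate_id = m$replicate_id)
}

#' Fraction curves with derivatives for a whole dataset
#'
#' Convenience wrapper: per-trace baselines (or shared baselines fitted on
#' the slowest melt), fraction-unfolded conversion, and smoothed
#' derivatives. Datasets whose traces already hold theta_U (simulated
#' datasets) skip the baseline step.
#'
#' @param dataset a \code{\link{th_dataset}}.
#' @param shared_baselines fit one baseline model on the slowest melt and
#'   reuse it for every trace?
#' @param lag_lambda temperature-lag constant passed to
#'   \code{\link{correct_temperature_lag}} (default 0: off).
#' @param ... passed to \code{\link{smooth_derivative}}.
#' @inheritParams fit_baselines
#' @return list of \code{fraction_curve}s parallel to \code{dataset$traces}.
#' @export
dataset_fractions <- function(dataset, shared_baselines = FALSE,
                              folded_range = NULL, unfolded_range = NULL,
                              lag_lambda = 0, ...) {
  stopifnot(inherits(dataset, "th_dataset"))
  if (lag_lambda != 0)
    dataset$traces <- lapply(dataset$traces, correct_temperature_lag,
                             lambda = lag_lambda)
  is_theta <- isTRUE(attr(dataset, "signal_is_theta"))
  shared <- NULL
  if (!is_theta && shared_baselines) {
    dirs <- vapply(dataset$traces, function(tr) attr(tr, "direction"), "")
    rates <- vapply(dataset$traces, function(tr) attr(tr, "scan_rate"), 0)
    pick <- if (any(dirs == "melt")) which(dirs == "melt")[which.min(rates[dirs == "melt"])]
            else which.min(rates)
    shared <- fit_baselines(dataset$traces[[pick]], folded_range, unfolded_range)
  }
  lapply(dataset$traces, function(tr) {
    fc <- if (is_theta) fraction_from_theta_trace(tr)
          else compute_fraction_unfolded(tr, if (is.null(shared))
            fit_baselines(tr, folded_range, unfolded_range) else shared)
    smooth_derivative(fc, ...)
  })
}
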