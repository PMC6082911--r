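#' Build the temperature-concentration-rate surface
#'
#' For each trace, the instantaneous monomer concentration and reaction rate
#' follow from the fraction-unfolded curve:
#' \deqn{[M] = \theta_U C_T, \qquad
#'   \frac{d[M]}{dt} = C_T \frac{d\theta_U}{dT}\frac{dT}{dt}}
#' with the signed scan rate (negative for anneals). Pooled across scan
#' rates, each temperature slice of the surface samples several
#' \eqn{([M], d[M]/dt)} pairs, from which effective reaction orders are
#' extracted.
#'
#' @param dataset a \code{\link{th_dataset}} (supplies \code{C_T}).
#' @param fractions list of \code{fraction_curve}s with derivatives, parallel
#'   to the dataset traces (see \code{\link{dataset_fractions}}).
#' @return object of class \code{rate_surface}: data.frame with columns
#'   \code{temperature}, \code{M}, \code{rate}, \code{theta},
#'   \code{scan_rate}, \code{direction}, \code{replicate_id}, with
#'   \code{C_T} attached as an attribute.
#' @export
build_rate_surface <- function(dataset, fractions) {
  stopifnot(inherits(dataset, "th_dataset"),
            length(fractions) == length(dataset$traces))
  C_T <- dataset$C_T
  rows <- lapply(fractions, function(fc) {
    if (is.null(fc$dtheta_dT)) stop("fraction curves must carry dtheta_dT ",
                                    "(run smooth_derivative first)")
    sr <- attr(fc, "scan_rate"); dir <- attr(fc, "direction")
    signed <- if (dir == "anneal") -sr else sr
    data.frame(temperature = fc$temperature,
               M = fc$theta_U * C_T,
               rate = C_T * fc$dtheta_dT * signed,
               theta = fc$theta_U,
               scan_rate = sr, direction = dir,
               replicate_id = attr(fc, "replicate_id"))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("rate_surface", "data.frame"), C_T = C_T)
}

#' Extract the effective reaction order at one temperature
#'
#' At a fixed temperature, with pronounced hysteresis, the annealing rate is
#' dominated by the association term, so
#' \eqn{\ln(-d[M]/dt) = n \ln [M] + \ln k_{on}} across scan rates; the
#' melting rate is dominated by dissociation, so
#' \eqn{\ln(d[M]/dt) = m \ln(C_T - [M]) + (1-m)\ln N + \ln k_{off}}.
#' Ordinary least squares on the pooled points of one slice yields the order
#' (slope) and intercept with their standard errors. Natural logarithms are
#' used; the slope is invariant to the base.
#'
#' @param surface a \code{rate_surface}.
#' @param temperature slice temperature, deg C (matched to the grid within
#'   \code{1e-6}).
#' @param direction "anneal" or "melt".
#' @param theta_window usable \eqn{\theta_U} window; anneal slices keep
#'   points with \eqn{\theta_U} inside it, melt slices apply it to
#'   \eqn{1 - \theta_U}. Default c(0.1, 0.9): only the transition region is
#'   fitted.
#' @param rate_floor minimum |rate| in M/min; default \code{1e-4 * C_T}.
#' @return list: \code{order}, \code{order_stderr}, \code{intercept}
#'   (\eqn{\ln k_{on}} for anneal; \eqn{(1-m)\ln N + \ln k_{off}} for melt),
#'   \code{intercept_stderr}, \code{n_points}, or \code{NULL} with a reason
#'   attribute when the slice has < 2 usable points.
#' @export
extract_order_slice <- function(surface, temperature, direction = c("anneal", "melt"),
                                theta_window = c(0.1, 0.9), rate_floor = NULL) {
  direction <- match.arg(direction)
  C_T <- attr(surface, "C_T")
  if (is.null(rate_floor)) rate_floor <- 1e-4 * C_T
  sl <- surface[abs(surface$temperature - temperature) < 1e-6 &
                  surface$direction == direction, ]
  if (direction == "anneal") {
    sl <- sl[is.finite(sl$rate) & sl$rate < -rate_floor &
               sl$theta > theta_window[1] & sl$theta < theta_window[2] &
               sl$M > 0, ]
    x <- log(sl$M); y <- log(-sl$rate)
  } else {
    omt <- 1 - sl$theta
    sl <- sl[is.finite(sl$rate) & sl$rate > rate_floor &
               omt > theta_window[1] & omt < theta_window[2] &
               (C_T - sl$M) > 0, ]
    x <- log(C_T - sl$M); y <- log(sl$rate)
  }
  if (nrow(sl) < 2 || length(unique(round(x, 12))) < 2)
    return(structure(list(NULL), reason = "fewer than 2 usable points")[[1]])
  fit <- stats::lm(y ~ x)
  # zero-residual slices (noise-free data) make summary() grumble harmlessly
  co <- suppressWarnings(summary(fit))$coefficients
  list(order = unname(co["x", "Estimate"]),
       order_stderr = if (nrow(sl) > 2) unname(co["x", "Std. Error"]) else NA_real_,
       intercept = unname(co["(Intercept)", "Estimate"]),
       intercept_stderr = if (nrow(sl) > 2) unname(co["(Intercept)", "Std. Error"]) else NA_real_,
       n_points = nrow(sl))
}

#' Effective reaction orders across the thermal transition
#'
#' Applies \code{\link{extract_order_slice}} at every temperature of the
#' surface grid where the usable-point condition holds, yielding the
#' temperature-resolved order profile (typically one point every 0.5 deg C
#' across the transition).
#'
#' @inheritParams extract_order_slice
#' @param min_points minimum usable points per slice (>= 2).
#' @return object of class \code{order_profile}: data.frame with columns
#'   \code{temperature}, \code{order}, \code{order_stderr},
#'   \code{intercept}, \code{intercept_stderr}, \code{n_points}.
#' @export
order_profile <- function(surface, direction = c("anneal", "melt"),
                          theta_window = c(0.1, 0.9), rate_floor = NULL,
                          min_points = 2) {
  direction <- match.arg(direction)
  temps <- sort(unique(surface$temperature[surface$direction == direction]))
  rows <- list()
  for (tt in temps) {
    sl <- extract_order_slice(surface, tt, direction, theta_window, rate_floor)
    if (is.null(sl) || sl$n_points < min_points) next
    rows[[length(rows) + 1]] <- data.frame(
      temperature = tt, order = sl$order, order_stderr = sl$order_stderr,
      intercept = sl$intercept, intercept_stderr = sl$intercept_stderr,
      n_points = sl$n_points)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(temperature = numeric(0), order = numeric(0),
               order_stderr = numeric(0), intercept = numeric(0),
               intercept_stderr = numeric(0), n_points = integer(0))
  structure(out, class = c("order_profile", "data.frame"),
            direction = direction)
}

#' Aggregate order profiles across replicate datasets
#'
#' Replicates are analysed independently and combined as mean +/- standard
#' deviation at each shared grid temperature, matching the usual triplicate
#' treatment of TH measurements.
#'
#' @param profiles list of \code{order_profile}s from replicate datasets.
#' @return an \code{order_profile} whose \code{order_stderr} column holds the
#'   across-replicate standard deviation.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  all_t <- sort(unique(unlist(lapply(profiles, function(p) p$temperature))))
  rows <- list()
  for (tt in all_t) {
    vals <- unlist(lapply(profiles, function(p) p$order[abs(p$temperature - tt) < 1e-9]))
    ints <- unlist(lapply(profiles, function(p) p$intercept[abs(p$temperature - tt) < 1e-9]))
    if (length(vals) == 0) next
    rows[[length(rows) + 1]] <- data.frame(
      temperature = tt, order = mean(vals),
      order_stderr = if (length(vals) > 1) stats::sd(vals) else NA_real_,
      intercept = mean(ints),
      intercept_stderr = if (length(ints) > 1) stats::sd(ints) else NA_real_,
      n_points = length(vals))
  }
  structure(do.call(rbind, rows), class = c("order_profile", "data.frame"),
            direction = attr(profiles[[1]], "direction"))
}

#' @export
print.order_profile <- function(x, ...) {
  cat(sprintf("<order_profile> %s: %d temperatures", attr(x, "direction"),
              nrow(x)))
  if (nrow(x))
    cat(sprintf(", order %.2f..%.2f over %.1f..%.1f C",
                min(x$order), max(x$order),
                min(x$temperature), max(x$temperature)))
  cat("\n")
  invisible(x)
}
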