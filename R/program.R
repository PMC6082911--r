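#' Programmed temperature protocols
#'
#' A temperature program is a sequence of segments, each a linear ramp or a
#' constant-temperature hold, mirroring the melt/anneal protocols of a
#' Peltier-controlled spectrophotometer. Temperatures are in deg C, durations
#' in minutes.
#'
#' @param segments data.frame with columns \code{duration} (min),
#'   \code{T_start}, \code{T_end} (deg C). A hold has \code{T_start == T_end}.
#' @return object of class \code{temperature_program}.
#' @export
temperature_program <- function(segments) {
  stopifnot(is.data.frame(segments),
            all(c("duration", "T_start", "T_end") %in% names(segments)),
            all(segments$duration > 0))
  if (nrow(segments) > 1) {
    gap <- abs(segments$T_start[-1] - segments$T_end[-nrow(segments)])
    if (any(gap > 1e-9)) stop("temperature program must be continuous")
  }
  segments$t0 <- cumsum(c(0, segments$duration[-nrow(segments)]))
  segments$t1 <- segments$t0 + segments$duration
  segments$rate <- (segments$T_end - segments$T_start) / segments$duration
  structure(list(segments = segments, total_time = sum(segments$duration)),
            class = "temperature_program")
}

#' Standard thermal-hysteresis scan program
#'
#' Builds the chained protocol used throughout: equilibration hold at the
#' start temperature, scan to the other end, hold, and (optionally) scan
#' back, at a single scan rate.
#'
#' @param T_range numeric length 2, low and high temperature (deg C).
#' @param scan_rate scan rate magnitude, deg C / min (> 0).
#' @param hold equilibration hold at the extremes, min.
#' @param first direction of the first scan: \code{"anneal"} (start high,
#'   cool) or \code{"melt"} (start low, heat).
#' @param both if \code{TRUE} (default) append the return scan after the
#'   second hold, so melt curves start from the annealed state (or vice
#'   versa).
#' @return a \code{temperature_program} whose segments carry a
#'   \code{label} column (\code{hold1}, \code{scan1}, \code{hold2},
#'   \code{scan2}).
#' @export
th_program <- function(T_range, scan_rate, hold = 10, first = c("anneal", "melt"),
                       both = TRUE) {
  first <- match.arg(first)
  stopifnot(length(T_range) == 2, scan_rate > 0, hold >= 0)
  Tlo <- min(T_range); Thi <- max(T_range)
  span <- Thi - Tlo
  ramp <- span / scan_rate
  from <- if (first == "anneal") Thi else Tlo
  to <- if (first == "anneal") Tlo else Thi
  seg <- data.frame(duration = numeric(0), T_start = numeric(0), T_end = numeric(0),
                    label = character(0))
  add <- function(seg, duration, T_start, T_end, label)
    rbind(seg, data.frame(duration = duration, T_start = T_start, T_end = T_end,
                          label = label))
  if (hold > 0) seg <- add(seg, hold, from, from, "hold1")
  seg <- add(seg, ramp, from, to, "scan1")
  if (both) {
    if (hold > 0) seg <- add(seg, hold, to, to, "hold2")
    seg <- add(seg, ramp, to, from, "scan2")
  }
  tp <- temperature_program(seg)
  tp$scan_rate <- scan_rate
  tp$first <- first
  tp
}

#' Temperature at program time
#' @param program a \code{temperature_program}.
#' @param t time(s) since program start, min.
#' @return temperature(s), deg C.
#' @export
program_temperature <- function(program, t) {
  seg <- program$segments
  i <- findInterval(t, seg$t0, rightmost.closed = FALSE)
  i[i < 1L] <- 1L
  i[i > nrow(seg)] <- nrow(seg)
  seg$T_start[i] + seg$rate[i] * (t - seg$t0[i])
}

#' @export
print.temperature_program <- function(x, ...) {
  cat(sprintf("<temperature_program> %d segment(s), %.1f min total\n",
              nrow(x$segments), x$total_time))
  print(x$segments[, c("duration", "T_start", "T_end", "rate",
                       intersect("label", names(x$segments)))], row.names = FALSE)
  invisible(x)
}
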