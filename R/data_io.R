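#' Thermal-hysteresis traces and datasets
#'
#' A \code{th_trace} is one temperature scan: a temperature/signal table plus
#' scan metadata. Anneal scans may be supplied as recorded (decreasing
#' temperature); they are normalized to increasing temperature order on
#' construction, with the \code{direction} flag preserving the scan sense --
#' direction is never inferred from the ordering.
#'
#' @param temperature temperatures, deg C; must be strictly monotone.
#' @param signal spectroscopic signal (arbitrary units), same length.
#' @param scan_rate scan rate magnitude, deg C/min (> 0).
#' @param direction "melt" or "anneal".
#' @param wavelength optional wavelength, nm.
#' @param replicate_id optional replicate label.
#' @return object of class \code{th_trace}: data.frame with columns
#'   \code{temperature}, \code{signal} and metadata attributes.
#' @export
th_trace <- function(temperature, signal, scan_rate, direction,
                     wavelength = NA_real_, replicate_id = NA_character_) {
  stopifnot(length(temperature) == length(signal),
            length(temperature) >= 10,
            is.numeric(scan_rate), scan_rate > 0)
  direction <- match.arg(direction, c("melt", "anneal"))
  d <- diff(temperature)
  if (!(all(d > 0) || all(d < 0)))
    stop("th_trace: temperature must be strictly monotone within a scan")
  if (d[1] < 0) { temperature <- rev(temperature); signal <- rev(signal) }
  x <- data.frame(temperature = temperature, signal = signal)
  structure(x, class = c("th_trace", "data.frame"),
            scan_rate = scan_rate, direction = direction,
            wavelength = wavelength, replicate_id = replicate_id)
}

trace_meta <- function(tr) {
  list(scan_rate = attr(tr, "scan_rate"), direction = attr(tr, "direction"),
       wavelength = attr(tr, "wavelength"), replicate_id = attr(tr, "replicate_id"))
}

#' @rdname th_trace
#' @param traces list of \code{th_trace} objects.
#' @param C_T total subunit concentration, M (monomer equivalents), shared by
#'   all traces.
#' @param N assembly stoichiometry when finite (optional).
#' @param label dataset label.
#' @param t_range,hold acquisition design metadata (deg C range and hold
#'   minutes), used when re-simulating the protocol during fitting.
#' @return \code{th_dataset}: list of traces with dataset metadata. A
#'   \code{few_rates} attribute flags datasets with fewer than two distinct
#'   scan rates in some direction (order extraction needs >= 2, >= 3
#'   recommended).
#' @export
th_dataset <- function(traces, C_T, N = NA_integer_, label = "dataset",
                       t_range = NULL, hold = NA_real_) {
  stopifnot(length(traces) >= 1, is.numeric(C_T), C_T > 0)
  for (tr in traces) stopifnot(inherits(tr, "th_trace"))
  if (is.null(t_range))
    t_range <- range(unlist(lapply(traces, function(tr) range(tr$temperature))))
  dirs <- vapply(traces, function(tr) attr(tr, "direction"), "")
  rates <- vapply(traces, function(tr) attr(tr, "scan_rate"), 0)
  few <- any(vapply(unique(dirs), function(d)
    length(unique(rates[dirs == d])) < 2, TRUE))
  if (few) warning("fewer than 2 distinct scan rates in some direction; ",
                   "order extraction will not be possible there")
  structure(list(traces = traces, C_T = C_T, N = N, label = label,
                 t_range = t_range, hold = hold),
            class = "th_dataset", few_rates = few)
}

#' @export
print.th_dataset <- function(x, ...) {
  dirs <- vapply(x$traces, function(tr) attr(tr, "direction"), "")
  rates <- vapply(x$traces, function(tr) attr(tr, "scan_rate"), 0)
  cat(sprintf("<th_dataset> '%s': %d trace(s), C_T = %.3g M, T %.1f..%.1f C\n",
              x$label, length(x$traces), x$C_T, x$t_range[1], x$t_range[2]))
  for (d in unique(dirs))
    cat(sprintf("  %s: rates %s C/min\n", d,
                paste(sort(unique(rates[dirs == d])), collapse = ", ")))
  invisible(x)
}

## ---- trace files -----------------------------------------------------------
# One CSV per trace: optional '#'-prefixed 'key: value' header lines, then
# 'temperature_C,signal'. Metadata may instead live in a YAML/JSON sidecar
# '<file>.yaml' / '<file>.json'; header lines win over sidecar values.

parse_header_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    ln <- sub("^#\\s*", "", ln)
    kv <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) {
      val <- trimws(kv[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[kv[2]]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

read_trace_file <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  meta <- parse_header_meta(lines[hdr])
  for (ext in c(".yaml", ".yml", ".json")) {
    side <- paste0(tools::file_path_sans_ext(path), ext)
    if (file.exists(side)) {
      sm <- if (ext == ".json") jsonlite::read_json(side, simplifyVector = TRUE)
            else yaml::read_yaml(side)
      for (nm in names(sm)) if (is.null(meta[[nm]])) meta[[nm]] <- sm[[nm]]
      break
    }
  }
  body <- if (length(hdr)) lines[-hdr] else lines
  tab <- utils::read.csv(text = paste(body, collapse = "\n"))
  if (ncol(tab) < 2) stop("trace file must have two numeric columns: ", path)
  if (is.null(meta$scan_rate) || is.null(meta$direction))
    stop("missing scan_rate/direction metadata for trace: ", path)
  list(temperature = tab[[1]], signal = tab[[2]], meta = meta)
}

#' Load a thermal-hysteresis dataset from a directory of trace files
#'
#' Reads every \code{*.csv} in \code{path} (ignoring files whose names end in
#' \code{_theta.csv}, which are generator ground truth). Each file carries two
#' numeric columns (\code{temperature_C}, \code{signal}); per-trace metadata
#' (\code{scan_rate}, \code{direction}, optionally \code{wavelength},
#' \code{replicate_id}, and dataset-level \code{C_T}, \code{hold}) come from
#' \code{#} header lines or a YAML/JSON sidecar. \code{C_T} may instead be
#' given as an argument or in a dataset-level \code{dataset.(yaml|json)}.
#'
#' @param path directory containing trace CSVs.
#' @param C_T total subunit concentration, M; overrides file metadata.
#' @param label dataset label (defaults to the directory name).
#' @return a \code{\link{th_dataset}}.
#' @export
load_th_dataset <- function(path, C_T = NULL, label = basename(path)) {
  stopifnot(dir.exists(path))
  files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
  files <- files[!grepl("_theta\\.csv$", files)]
  if (length(files) == 0) stop("no trace CSVs found in ", path)
  ds_meta <- list()
  for (ext in c("yaml", "yml", "json")) {
    side <- file.path(path, paste0("dataset.", ext))
    if (file.exists(side)) {
      ds_meta <- if (ext == "json") jsonlite::read_json(side, simplifyVector = TRUE)
                 else yaml::read_yaml(side)
      break
    }
  }
  traces <- list(); cts <- numeric(0); hold <- NA_real_
  for (f in files) {
    raw <- read_trace_file(f)
    m <- raw$meta
    traces[[length(traces) + 1]] <- th_trace(
      raw$temperature, raw$signal, scan_rate = m$scan_rate,
      direction = m$direction,
      wavelength = if (is.null(m$wavelength)) NA_real_ else m$wavelength,
      replicate_id = if (is.null(m$replicate_id)) NA_character_ else as.character(m$replicate_id))
    if (!is.null(m$C_T)) cts <- c(cts, m$C_T)
    if (!is.null(m$hold)) hold <- m$hold
  }
  if (is.null(C_T)) {
    if (!is.null(ds_meta$C_T)) C_T <- ds_meta$C_T
    else if (length(cts)) C_T <- cts[1]
    else stop("C_T not supplied and absent from metadata")
  }
  if (length(cts) && any(abs(cts - C_T) > 1e-12 * C_T))
    stop("traces disagree on C_T")
  if (!is.null(ds_meta$hold)) hold <- ds_meta$hold
  th_dataset(traces, C_T = C_T, label = label, hold = hold)
}

#' Write a thermal-hysteresis dataset to a directory of trace files
#'
#' One CSV per trace with \code{#}-header metadata, plus a
#' \code{dataset.yaml} holding dataset-level metadata. Numbers are written
#' with 15 significant digits so that a write/read round trip is lossless to
#' well below 1e-12 relative.
#'
#' @param dataset a \code{\link{th_dataset}}.
#' @param path output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_th_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "th_dataset"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (i in seq_along(dataset$traces)) {
    tr <- dataset$traces[[i]]
    m <- trace_meta(tr)
    f <- file.path(path, sprintf("trace_%02d_%s_%s.csv", i, m$direction,
                                 gsub("[^0-9p]", "p", format(m$scan_rate))))
    hdr <- c(sprintf("# scan_rate: %.15g", m$scan_rate),
             sprintf("# direction: %s", m$direction),
             sprintf("# C_T: %.15g", dataset$C_T))
    if (!is.na(m$wavelength)) hdr <- c(hdr, sprintf("# wavelength: %.15g", m$wavelength))
    if (!is.na(m$replicate_id)) hdr <- c(hdr, sprintf("# replicate_id: %s", m$replicate_id))
    body <- c("temperature_C,signal",
              sprintf("%.15g,%.15g", tr$temperature, tr$signal))
    writeLines(c(hdr, body), f)
    written <- c(written, f)
  }
  meta <- list(label = dataset$label, C_T = dataset$C_T,
               t_range = as.numeric(dataset$t_range))
  if (!is.na(dataset$hold)) meta$hold <- dataset$hold
  yaml::write_yaml(meta, file.path(path, "dataset.yaml"))
  invisible(written)
}

#' Write analysis results to disk
#'
#' Order profiles are written as tidy CSV tables (one row per temperature).
#' Fit results are written as a JSON report holding all parameter values,
#' standard errors, RSS, AIC, and convergence information; the per-trace
#' residuals go to a companion CSV when \code{residuals = TRUE}.
#'
#' @param x an \code{order_profile} or \code{fit_result}.
#' @param path output file path (.csv for profiles, .json for fits).
#' @param residuals for fit results, also write residual tables.
#' @return invisibly, \code{path}.
#' @export
write_results <- function(x, path, residuals = FALSE) {
  if (inherits(x, "order_profile")) {
    df <- as.data.frame(x)
    utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = NA),
                     path, row.names = FALSE, quote = FALSE)
  } else if (inherits(x, "fit_result")) {
    rep <- list(mechanism = x$mechanism$kind,
                parameters = as.list(x$par),
                stderr = as.list(x$se),
                rss = x$rss, n_points = x$n_points, n_params = x$n_params,
                aic = x$aic, converged = x$converged, message = x$message)
    if (x$mechanism$kind == "goldstein_stryer")
      rep$mechanism_detail <- list(s = x$mechanism$s, N_max = x$mechanism$N_max,
                                   tie_forward = x$mechanism$tie_forward)
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (residuals) {
      rf <- sub("\\.json$", "_residuals.csv", path)
      utils::write.csv(x$residual_table, rf, row.names = FALSE)
    }
  } else stop("write_results: unsupported object of class ", class(x)[1])
  invisible(path)
}

#' Read a fit report written by \code{\link{write_results}}
#' @param path JSON report path.
#' @return list with parameters, stderr, rss, aic, etc.
#' @export
read_fit_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
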