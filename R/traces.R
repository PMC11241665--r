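#' Construct a voltage-clamp sweep trace
#'
#' The universal I/O unit of the package: a regularly sampled membrane current
#' recording (pA) with stimulus timestamps and labels. Internally all times are
#' milliseconds, currents picoamperes and charges picocoulombs.
#'
#' @param samples numeric vector of membrane current (pA); all finite.
#' @param dt sampling interval (ms), > 0.
#' @param t0 time of the first sample (ms).
#' @param stim_times stimulus timestamps (ms), strictly increasing and inside
#'   the recorded interval. Empty for spontaneous recordings.
#' @param holding_potential holding potential (mV), informational.
#' @param cell_id cell identifier string.
#' @param condition condition tag: `"sham"`, `"bbbd"` or `"unknown"`.
#' @param protocol protocol tag: one of `"minis"`, `"single"`, `"paired"`,
#'   `"train"`, `"io_curve"`.
#' @return an object of class `"sweep_trace"`.
#' @examples
#' tr <- sweep_trace(rnorm(1000, 0, 3), dt = 0.1, protocol = "minis")
#' @export
sweep_trace <- function(samples, dt, t0 = 0, stim_times = numeric(0),
                        holding_potential = -70, cell_id = "cell",
                        condition = c("unknown", "sham", "bbbd"),
                        protocol = c("minis", "single", "paired", "train",
                                     "io_curve")) {
  condition <- match.arg(condition)
  protocol <- match.arg(protocol)
  tr <- list(samples = as.numeric(samples), dt = as.numeric(dt),
             t0 = as.numeric(t0), stim_times = as.numeric(stim_times),
             holding_potential = as.numeric(holding_potential),
             cell_id = as.character(cell_id), condition = condition,
             protocol = protocol)
  class(tr) <- "sweep_trace"
  validate_sweep_trace(tr)
  tr
}

validate_sweep_trace <- function(tr) {
  if (!is.finite(tr$dt) || tr$dt <= 0) stop("dt must be > 0", call. = FALSE)
  if (length(tr$samples) < 2L) stop("trace needs at least 2 samples", call. = FALSE)
  if (anyNA(tr$samples) || any(!is.finite(tr$samples)))
    stop("all samples must be finite", call. = FALSE)
  st <- tr$stim_times
  if (length(st)) {
    if (any(diff(st) <= 0))
      stop("stim_times must be strictly increasing", call. = FALSE)
    tend <- tr$t0 + (length(tr$samples) - 1) * tr$dt
    if (st[1] < tr$t0 || st[length(st)] > tend)
      stop("stim_times must lie within the recorded interval", call. = FALSE)
  }
  n_st <- length(st)
  ok <- switch(tr$protocol,
               minis = n_st == 0L,
               paired = n_st == 2L,
               train = n_st >= 100L,
               TRUE)
  if (!isTRUE(ok))
    stop(sprintf("protocol '%s' inconsistent with %d stimulus times",
                 tr$protocol, n_st), call. = FALSE)
  invisible(tr)
}

#' Time axis of a trace
#' @param trace a [sweep_trace()].
#' @return numeric vector of sample times (ms).
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$samples) - 1) * trace$dt
}

trace_end <- function(trace) {
  trace$t0 + (length(trace$samples) - 1) * trace$dt
}

# index of the sample at or just before time t (ms)
time_to_index <- function(trace, t) {
  pmax(1L, pmin(length(trace$samples),
                as.integer(floor((t - trace$t0) / trace$dt + 1e-9)) + 1L))
}

#' @export
print.sweep_trace <- function(x, ...) {
  cat(sprintf(
    "sweep_trace: %s / %s / %s\n  %d samples @ dt = %g ms (%.3g s), %d stimuli\n",
    x$cell_id, x$condition, x$protocol, length(x$samples), x$dt,
    length(x$samples) * x$dt / 1000, length(x$stim_times)))
  invisible(x)
}

#' @export
plot.sweep_trace <- function(x, xlim = NULL, ...) {
  t <- trace_times(x)
  keep <- if (is.null(xlim)) TRUE else t >= xlim[1] & t <= xlim[2]
  plot(t[keep], x$samples[keep], type = "l", xlab = "time (ms)",
       ylab = "current (pA)", main = sprintf("%s (%s)", x$cell_id, x$protocol),
       ...)
  if (length(x$stim_times))
    graphics::abline(v = x$stim_times, col = "grey70", lty = 3)
  invisible(x)
}

#' Estimate the baseline current in a window
#'
#' Median of the samples inside the window; the median is used rather than the
#' mean so that occasional spontaneous events inside the window do not bias the
#' baseline.
#'
#' @param trace a [sweep_trace()].
#' @param window numeric length-2, `c(t_start, t_end)` in ms.
#' @return baseline current level (pA).
#' @export
estimate_baseline <- function(trace, window) {
  idx <- window_indices(trace, window, min_samples = 10L)
  stats::median(trace$samples[idx])
}

window_indices <- function(trace, window, min_samples = 1L) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  if (window[1] < trace$t0 - 1e-9 || window[2] > trace_end(trace) + 1e-9)
    stop("window lies outside the trace", call. = FALSE)
  t <- trace_times(trace)
  idx <- which(t >= window[1] - 1e-9 & t <= window[2] + 1e-9)
  if (length(idx) < min_samples)
    stop(sprintf("window contains %d samples; need at least %d",
                 length(idx), min_samples), call. = FALSE)
  idx
}

#' Blank stimulus artifacts by linear interpolation
#'
#' Field stimulation leaves a brief artifact after each stimulus. Samples in
#' `[t_stim, t_stim + blank_ms]` are replaced by the straight line between the
#' bounding samples. The input trace is not modified.
#'
#' @param trace a [sweep_trace()].
#' @param blank_ms blanking duration per stimulus (ms), >= 0. Default 0.5 ms,
#'   a typical field-stimulation artifact width.
#' @return a new `sweep_trace` with artifacts blanked.
#' @export
blank_artifact <- function(trace, blank_ms = 0.5) {
  if (!is.finite(blank_ms) || blank_ms < 0)
    stop("blank_ms must be >= 0", call. = FALSE)
  if (blank_ms == 0 || length(trace$stim_times) == 0L) return(trace)
  s <- trace$samples
  n <- length(s)
  t_all <- trace_times(trace)
  for (ts in trace$stim_times) {
    i0 <- max(1L, time_to_index(trace, ts))
    # anchor on the last clean sample strictly before the stimulus
    if (t_all[i0] >= ts - 1e-9) i0 <- max(1L, i0 - 1L)
    i1 <- min(n, time_to_index(trace, ts + blank_ms) + 1L)
    if (i1 - i0 >= 2L) {
      k <- (i0 + 1L):(i1 - 1L)
      s[k] <- s[i0] + (s[i1] - s[i0]) * (k - i0) / (i1 - i0)
    }
  }
  out <- trace
  out$samples <- s
  out
}

#' Integrate charge in a window
#'
#' Computes the charge transferred in a time window relative to a baseline.
#' With a high-chloride internal solution IPSCs are inward (negative-going), so
#' the integrand is rectified toward the event polarity before summation:
#' excursions above baseline are clipped at zero and do not cancel event
#' charge. The reported charge is a magnitude.
#'
#' @param trace a [sweep_trace()].
#' @param window numeric length-2, `c(t_start, t_end)` in ms.
#' @param baseline baseline current (pA) subtracted before integration.
#' @param polarity event polarity: `-1` (inward, default) or `+1`.
#' @return an object of class `"charge_measure"`: list with `q` (pC),
#'   `window` (ms) and `baseline` (pA).
#' @examples
#' tr <- sweep_trace(c(rep(0, 10), rep(-100, 100), rep(0, 10)), dt = 0.1)
#' integrate_charge(tr, c(0, 11.9), baseline = 0)$q  # 1 pC
#' @export
integrate_charge <- function(trace, window, baseline, polarity = -1) {
  stopifnot(polarity %in% c(-1, 1))
  idx <- window_indices(trace, window, min_samples = 1L)
  dev <- (trace$samples[idx] - baseline) * polarity # event polarity -> positive
  dev[dev < 0] <- 0                                 # rectify
  q_fc <- sum(dev) * trace$dt                       # pA * ms = fC
  out <- list(q = q_fc / 1000, window = as.numeric(window),
              baseline = baseline)
  class(out) <- "charge_measure"
  out
}

#' @export
print.charge_measure <- function(x, ...) {
  cat(sprintf("charge: %.4g pC over [%g, %g] ms (baseline %.3g pA)\n",
              x$q, x$window[1], x$window[2], x$baseline))
  invisible(x)
}

# ---------------------------------------------------------------------------
# File I/O
#
# Tabular dialect: UTF-8 text, '#'-prefixed header lines carrying key=value
# metadata (dt_ms, t0_ms, cell_id, condition, protocol, holding_mV,
# stim_times_ms as comma-separated values), then time_ms<TAB>current_pA rows.

#' Read a sweep trace from disk
#'
#' @param path file path.
#' @param format `"tabular"` (single sweep, text) or `"container"` (JSON, may
#'   hold several sweeps; the first is returned unless `sweep` is given).
#' @param sweep for `format = "container"`, index or name of the sweep.
#' @return a [sweep_trace()].
#' @seealso [write_trace()]
#' @export
read_trace <- function(path, format = c("tabular", "container"), sweep = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "container") {
    sweeps <- read_trace_container(path)
    if (is.character(sweep)) {
      if (!sweep %in% names(sweeps))
        stop("no sweep named '", sweep, "' in container", call. = FALSE)
      return(sweeps[[sweep]])
    }
    return(sweeps[[sweep]])
  }
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) stop("malformed header line (no '='): ", h, call. = FALSE)
    meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) && grepl("^time_ms", body[1])) body <- body[-1]
  if (!length(body)) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("parse error at data row %d: expected 2 tab-separated fields",
                 bad[1]), call. = FALSE)
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 2, byrow = TRUE)
  if (anyNA(m))
    stop("parse error: non-numeric time or current field", call. = FALSE)
  tm <- m[, 1]
  if (any(diff(tm) <= 0))
    stop("parse error: time column must be strictly increasing", call. = FALSE)
  dt <- if (!is.null(meta$dt_ms)) as.numeric(meta$dt_ms) else stats::median(diff(tm))
  stim <- if (!is.null(meta$stim_times_ms) && nzchar(meta$stim_times_ms)) {
    as.numeric(strsplit(meta$stim_times_ms, ",", fixed = TRUE)[[1]])
  } else numeric(0)
  protocol <- if (!is.null(meta$protocol)) meta$protocol else "minis"
  if (protocol == "train" && length(stim) == 0L)
    stop("validation error: protocol=train requires stim_times_ms", call. = FALSE)
  sweep_trace(samples = m[, 2], dt = dt, t0 = tm[1], stim_times = stim,
              holding_potential = if (!is.null(meta$holding_mV))
                as.numeric(meta$holding_mV) else -70,
              cell_id = if (!is.null(meta$cell_id)) meta$cell_id else "cell",
              condition = if (!is.null(meta$condition)) meta$condition else "unknown",
              protocol = protocol)
}

#' Write a sweep trace to disk
#'
#' Round-trips losslessly with [read_trace()] (samples to full double
#' precision).
#'
#' @param trace a [sweep_trace()], or for `format = "container"` optionally a
#'   list of them.
#' @param path output file path.
#' @param format `"tabular"` or `"container"` (JSON).
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("tabular", "container")) {
  format <- match.arg(format)
  if (format == "container") return(write_trace_container(trace, path))
  validate_sweep_trace(trace)
  hdr <- c(
    sprintf("# dt_ms=%.17g", trace$dt),
    sprintf("# t0_ms=%.17g", trace$t0),
    sprintf("# cell_id=%s", trace$cell_id),
    sprintf("# condition=%s", trace$condition),
    sprintf("# protocol=%s", trace$protocol),
    sprintf("# holding_mV=%.17g", trace$holding_potential),
    sprintf("# stim_times_ms=%s",
            paste(sprintf("%.17g", trace$stim_times), collapse = ",")),
    "time_ms\tcurrent_pA")
  t <- trace_times(trace)
  rows <- sprintf("%.17g\t%.17g", t, trace$samples)
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}

trace_to_list <- function(trace) {
  trace[c("samples", "dt", "t0", "stim_times", "holding_potential",
          "cell_id", "condition", "protocol")]
}

write_trace_container <- function(traces, path) {
  if (inherits(traces, "sweep_trace")) traces <- list(traces)
  lapply(traces, validate_sweep_trace)
  nm <- names(traces)
  if (is.null(nm)) nm <- vapply(traces, `[[`, "", "cell_id")
  if (anyDuplicated(nm)) nm <- make.unique(nm)
  obj <- stats::setNames(lapply(traces, trace_to_list), nm)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

read_trace_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(obj) || !length(obj))
    stop("parse error: container holds no sweeps", call. = FALSE)
  lapply(obj, function(x) {
    need <- c("samples", "dt", "protocol")
    miss <- setdiff(need, names(x))
    if (length(miss))
      stop("validation error: container sweep missing field(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    if (identical(x$protocol, "train") && length(x$stim_times) == 0L)
      stop("validation error: protocol=train requires stim_times", call. = FALSE)
    sweep_trace(samples = x$samples, dt = x$dt,
                t0 = if (is.null(x$t0)) 0 else x$t0,
                stim_times = if (is.null(x$stim_times)) numeric(0) else x$stim_times,
                holding_potential = if (is.null(x$holding_potential)) -70
                else x$holding_potential,
                cell_id = if (is.null(x$cell_id)) "cell" else x$cell_id,
                condition = if (is.null(x$condition)) "unknown" else x$condition,
                protocol = x$protocol)
  })
}
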