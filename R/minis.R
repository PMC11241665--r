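# Detection and kinetic analysis of spontaneous miniature IPSCs.

#' Detection configuration for miniature events
#'
#' Constants of the two-stage detector: candidate onsets from a smoothed
#' derivative crossing `k_deriv` times the MAD-based noise scale in the event
#' polarity, confirmed by normalized cross-correlation `>= c_min` against a
#' template built from `kinetics`. Candidates closer than `merge_ms` are
#' merged (they cannot be resolved as separate events); events with a
#' neighbour inside the kinetics window are still counted but flagged
#' `overlapping` and excluded from waveform averaging.
#'
#' @param k_deriv derivative threshold in noise-scale units (default 3.5).
#' @param c_min minimum template correlation (default 0.5).
#' @param merge_ms merge distance for candidate onsets (ms).
#' @param smooth_ms running-mean smoothing width before differentiation (ms).
#' @param deriv_span_ms span of the central-difference derivative (ms).
#' @param peak_win_ms window after onset searched for the event peak (ms).
#' @param corr_win_ms template-correlation window (ms).
#' @param baseline_win_ms pre-event window for the local baseline median (ms).
#' @param abs_thresh absolute derivative threshold (pA per span) used when the
#'   noise estimate is zero (noise-free data).
#' @param amp_bypass_k candidates whose amplitude exceeds this multiple of
#'   the noise SD skip the template gate (the gate exists to reject
#'   near-threshold noise shapes; large events riding on the decay of a
#'   neighbour can fail it spuriously).
#' @param overlap_ms neighbour distance below which an event is flagged as
#'   overlapping for kinetics purposes (ms).
#' @param kinetics [event_kinetics()] used to build the template.
#' @return list of class `"mini_config"`.
#' @export
mini_config <- function(k_deriv = 3.5, c_min = 0.5, merge_ms = 0.4,
                        smooth_ms = 0.3, deriv_span_ms = 0.4,
                        peak_win_ms = 5, corr_win_ms = 4,
                        baseline_win_ms = 10, abs_thresh = 2,
                        amp_bypass_k = 8, overlap_ms = 25,
                        kinetics = event_kinetics(0.2, 0.7, 1.3, 9)) {
  stopifnot(k_deriv > 0, c_min > 0, c_min < 1, merge_ms >= 0)
  cfg <- list(k_deriv = k_deriv, c_min = c_min, merge_ms = merge_ms,
              smooth_ms = smooth_ms, deriv_span_ms = deriv_span_ms,
              peak_win_ms = peak_win_ms, corr_win_ms = corr_win_ms,
              baseline_win_ms = baseline_win_ms, abs_thresh = abs_thresh,
              amp_bypass_k = amp_bypass_k, overlap_ms = overlap_ms,
              kinetics = kinetics)
  class(cfg) <- "mini_config"
  cfg
}

running_mean <- function(x, w) {
  if (w <= 1L) return(x)
  f <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  na <- is.na(f)
  f[na] <- x[na]
  f
}

#' Detect miniature IPSCs in a spontaneous recording
#'
#' Two-stage detector for inward quantal events: (1) candidate onsets where
#' the smoothed current derivative crosses a robust noise threshold in the
#' inward direction; (2) confirmation by normalized cross-correlation with a
#' kinetics template. Amplitude is the peak deviation from a local pre-event
#' baseline median. See [mini_config()] for all constants.
#'
#' @param trace a [sweep_trace()] with `protocol = "minis"`, at least 1 s long.
#' @param cfg a [mini_config()].
#' @return data frame of class `"mini_events"`, one row per detected event:
#'   `onset`, `peak_time` (ms), `amplitude` (pA, magnitude), `rise_time_20_80`
#'   (ms), `correlation`, `overlapping` (logical). Attributes: `duration_s`,
#'   `frequency` (Hz), `cell_id`, `condition`, `noise_sd` estimate.
#' @export
detect_minis <- function(trace, cfg = mini_config()) {
  if (trace$protocol != "minis")
    stop("detect_minis expects a 'minis' protocol trace", call. = FALSE)
  dur_ms <- length(trace$samples) * trace$dt
  if (dur_ms < 1000) stop("trace shorter than 1 s", call. = FALSE)
  dt <- trace$dt
  x <- trace$samples
  n <- length(x)

  f <- running_mean(x, max(1L, as.integer(round(cfg$smooth_ms / dt))))
  h <- max(1L, as.integer(round(cfg$deriv_span_ms / 2 / dt)))
  d <- c(rep(0, h), f[(1 + 2 * h):n] - f[1:(n - 2 * h)], rep(0, h))

  sigma_d <- stats::mad(d)
  thr <- if (sigma_d > 0) -cfg$k_deriv * sigma_d else -cfg$abs_thresh
  noise_sd <- stats::mad(diff(x)) / sqrt(2)

  below <- d < thr
  if (!any(below)) return(empty_mini_events(trace, dur_ms, noise_sd))
  run_start <- which(below & !c(FALSE, below[-n]))
  run_end <- which(below & !c(below[-1], FALSE))

  # backtrack each run start to the preceding derivative zero crossing
  onsets_idx <- vapply(run_start, function(i) {
    j <- i
    while (j > 1L && d[j - 1L] < 0) j <- j - 1L
    j
  }, integer(1))

  # near-coincident events fuse into a single threshold run; split a run at
  # interior derivative minima separated by a clear partial recovery
  min_sep <- max(2L, as.integer(round(0.4 / dt)))
  extra <- integer(0)
  for (r in which(run_end - run_start >= 2L * min_sep)) {
    seg <- d[run_start[r]:run_end[r]]
    m <- length(seg)
    loc_min <- which(seg < c(seg[-1], Inf) & seg < c(Inf, seg[-m]))
    if (length(loc_min) < 2L) next
    acc <- loc_min[1]
    for (i in loc_min[-1]) {
      prev <- acc[length(acc)]
      if (i - prev >= min_sep && max(seg[prev:i]) - seg[i] > 0.6 * abs(thr))
        acc <- c(acc, i)
    }
    if (length(acc) > 1L)
      extra <- c(extra, run_start[r] + acc[-1] - 1L)
  }
  onsets_idx <- sort(unique(c(onsets_idx, extra)))

  # merge onsets closer than merge_ms (unresolvable as separate events)
  if (length(onsets_idx) > 1L && cfg$merge_ms > 0) {
    keep <- c(TRUE, diff(onsets_idx) * dt >= cfg$merge_ms)
    onsets_idx <- onsets_idx[keep]
  }

  template <- make_kernel(cfg$kinetics, dt)
  tpk <- attr(template, "peak_index")
  L <- min(length(template), as.integer(round(cfg$corr_win_ms / dt)))
  template <- template[seq_len(L)]
  bw <- as.integer(round(cfg$baseline_win_ms / dt))
  gap <- max(1L, as.integer(round(0.5 / dt)))
  pw <- as.integer(round(cfg$peak_win_ms / dt))

  res <- lapply(onsets_idx, function(o) {
    # the smoothed central-difference derivative leads the raw signal by its
    # half-span; compensate when reporting the onset time
    o_rep <- o + h
    b0 <- max(1L, o - gap - bw)
    b1 <- max(1L, o - gap)
    baseline <- stats::median(x[b0:b1])
    p_end <- min(n, o + pw)
    pk <- o + which.min(f[o:p_end]) - 1L
    amp <- baseline - x[pk]
    if (!is.finite(amp) || amp <= 0) return(NULL)
    # template correlation, peak-aligned (robust to onset jitter in noise)
    s0 <- pk - (tpk - 1L)
    s_end <- s0 + L - 1L
    if (s0 < 1L || s_end > n) return(NULL)
    seg <- baseline - x[s0:s_end]
    if (stats::sd(seg) == 0) return(NULL)
    cc <- suppressWarnings(stats::cor(seg, template))
    strong <- amp >= cfg$amp_bypass_k * noise_sd
    if (!strong && (!is.finite(cc) || cc < cfg$c_min)) return(NULL)
    rt <- tryCatch({
      ry <- baseline - f[o:pk]
      if (length(ry) >= 2) rise_time(ry, dt) else dt
    }, error = function(e) NA_real_)
    c(onset = trace$t0 + (min(o_rep, pk) - 1) * dt,
      peak_time = trace$t0 + (pk - 1) * dt,
      amplitude = amp, rise_time_20_80 = rt, correlation = cc)
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(empty_mini_events(trace, dur_ms, noise_sd))
  ev <- as.data.frame(do.call(rbind, res))
  ev <- ev[order(ev$onset), , drop = FALSE]
  iei_prev <- c(Inf, diff(ev$onset))
  iei_next <- c(diff(ev$onset), Inf)
  ev$overlapping <- pmin(iei_prev, iei_next) < cfg$overlap_ms
  rownames(ev) <- NULL
  class(ev) <- c("mini_events", "data.frame")
  attr(ev, "duration_s") <- dur_ms / 1000
  attr(ev, "frequency") <- nrow(ev) / (dur_ms / 1000)
  attr(ev, "cell_id") <- trace$cell_id
  attr(ev, "condition") <- trace$condition
  attr(ev, "noise_sd") <- noise_sd
  ev
}

empty_mini_events <- function(trace, dur_ms, noise_sd) {
  ev <- data.frame(onset = numeric(0), peak_time = numeric(0),
                   amplitude = numeric(0), rise_time_20_80 = numeric(0),
                   correlation = numeric(0), overlapping = logical(0))
  class(ev) <- c("mini_events", "data.frame")
  attr(ev, "duration_s") <- dur_ms / 1000
  attr(ev, "frequency") <- 0
  attr(ev, "cell_id") <- trace$cell_id
  attr(ev, "condition") <- trace$condition
  attr(ev, "noise_sd") <- noise_sd
  ev
}

#' @export
print.mini_events <- function(x, ...) {
  cat(sprintf("mini events: %d detected in %.3g s (%.3g Hz), cell %s\n",
              nrow(x), attr(x, "duration_s"), attr(x, "frequency"),
              attr(x, "cell_id")))
  if (nrow(x)) {
    cat(sprintf("  median amplitude %.3g pA, median rise (20-80%%) %.3g ms\n",
                stats::median(x$amplitude),
                stats::median(x$rise_time_20_80, na.rm = TRUE)))
  }
  invisible(x)
}

#' 20-80% rise time of an event segment
#'
#' Time between the 20% and 80% crossings of the peak amplitude, with linear
#' interpolation between samples. For non-monotone rises the first 20%
#' crossing and the last 80% crossing before the peak are used.
#'
#' @param y magnitude segment from onset to peak (positive-going; the last
#'   maximum is treated as the peak).
#' @param dt sampling interval (ms).
#' @return rise time (ms); bounded below by 0.
#' @examples
#' rise_time(seq(0, 1, 0.1), dt = 0.1)  # linear ramp over 1 ms -> 0.6
#' @export
rise_time <- function(y, dt) {
  y <- as.numeric(y)
  n <- length(y)
  if (n < 1L) stop("empty segment", call. = FALSE)
  pk_i <- which.max(y)
  pk <- y[pk_i]
  if (pk <= 0) stop("segment has no positive peak", call. = FALSE)
  if (pk_i == 1L) return(0)
  y <- y[seq_len(pk_i)]
  cross_t <- function(level, first) {
    above <- y >= level
    idx <- which(above & !c(FALSE, above[-length(y)]))  # upward crossings
    if (!length(idx)) return(NA_real_)
    i <- if (first) idx[1] else idx[length(idx)]
    if (i == 1L) return(0)
    frac <- (level - y[i - 1]) / (y[i] - y[i - 1])
    (i - 2 + frac) * dt
  }
  t20 <- cross_t(0.2 * pk, first = TRUE)
  t80 <- cross_t(0.8 * pk, first = FALSE)
  if (is.na(t20) || is.na(t80)) return((pk_i - 1) * dt)
  max(0, t80 - t20)
}

#' Empirical CDF of inter-event intervals
#'
#' @param events a `mini_events` data frame or a numeric vector of event
#'   onset times (ms); at least 2 events.
#' @return an `ecdf` function over the inter-event intervals (ms), with the
#'   sorted intervals in attribute `"ieis"`.
#' @examples
#' f <- iei_cdf(c(0, 10, 20))
#' f(10)  # 1
#' @export
iei_cdf <- function(events) {
  times <- if (is.data.frame(events)) events$onset else as.numeric(events)
  if (length(times) < 2L) stop("need at least 2 events", call. = FALSE)
  ieis <- diff(sort(times))
  f <- stats::ecdf(ieis)
  attr(f, "ieis") <- sort(ieis)
  f
}

#' Peak-aligned trough-normalized mean event waveform
#'
#' Averages the detected events after aligning each segment at its trough and
#' scaling it to unit trough magnitude, the standard way to compare current
#' kinetics independent of amplitude. Events flagged as overlapping are
#' excluded.
#'
#' @param trace the [sweep_trace()] the events were detected in.
#' @param events a `mini_events` data frame from [detect_minis()].
#' @param pre_ms,post_ms segment extent before/after the trough (ms).
#' @param min_events minimum number of clean events required (default 10).
#' @return list of class `"mini_waveform"`: `t` (ms, 0 at the trough),
#'   `w` (mean normalized waveform, trough = -1), `n_used`.
#' @export
mean_normalized_waveform <- function(trace, events, pre_ms = 5, post_ms = 25,
                                     min_events = 10) {
  clean <- events[!events$overlapping, , drop = FALSE]
  dt <- trace$dt
  pre <- as.integer(round(pre_ms / dt))
  post <- as.integer(round(post_ms / dt))
  n <- length(trace$samples)
  segs <- list()
  for (i in seq_len(nrow(clean))) {
    pk <- time_to_index(trace, clean$peak_time[i])
    if (pk - pre < 1L || pk + post > n) next
    seg <- trace$samples[(pk - pre):(pk + post)]
    o <- time_to_index(trace, clean$onset[i])
    b0 <- max(1L, o - as.integer(round(10 / dt)))
    base <- stats::median(trace$samples[b0:max(b0, o - 1L)])
    seg <- seg - base
    tr_mag <- abs(seg[pre + 1L])
    if (tr_mag <= 0) next
    segs[[length(segs) + 1L]] <- seg / tr_mag
  }
  if (length(segs) < min_events)
    stop(sprintf("only %d clean events; need at least %d", length(segs),
                 min_events), call. = FALSE)
  w <- Reduce(`+`, segs) / length(segs)
  out <- list(t = (seq_along(w) - pre - 1L) * dt, w = w,
              n_used = length(segs), dt = dt)
  class(out) <- "mini_waveform"
  out
}

#' @export
print.mini_waveform <- function(x, ...) {
  cat(sprintf("mean normalized mini waveform: %d events, %g to %g ms, trough %.3f\n",
              x$n_used, x$t[1], x$t[length(x$t)], min(x$w)))
  invisible(x)
}

#' @export
plot.mini_waveform <- function(x, ...) {
  plot(x$t, x$w, type = "l", xlab = "time from trough (ms)",
       ylab = "normalized current", ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Summarize mini detection for one cell
#'
#' Per-cell summary combining event counts, amplitude and rise-time medians,
#' and decay kinetics fitted on the mean normalized waveform (the group-level
#' workflow: kinetics are compared across cells via each cell's mean
#' waveform fit).
#'
#' @param trace a [sweep_trace()].
#' @param events result of [detect_minis()]; computed if missing.
#' @param cfg a [mini_config()] (used if `events` is missing).
#' @param fit_kinetics fit the mean-waveform decay (default TRUE).
#' @return list of class `"mini_summary"`: `frequency` (Hz), `n_events`,
#'   `median_amplitude` (pA), `median_rise` (ms), `a1`, `tau1`, `a2`, `tau2`
#'   (mean-waveform decay fit, `NA` if unavailable), `duration_s`, `cell_id`,
#'   `condition`.
#' @export
summarize_minis <- function(trace, events = NULL, cfg = mini_config(),
                            fit_kinetics = TRUE) {
  if (is.null(events)) events <- detect_minis(trace, cfg)
  out <- list(frequency = attr(events, "frequency"),
              n_events = nrow(events),
              median_amplitude = if (nrow(events))
                stats::median(events$amplitude) else NA_real_,
              median_rise = if (nrow(events))
                stats::median(events$rise_time_20_80, na.rm = TRUE) else NA_real_,
              a1 = NA_real_, tau1 = NA_real_, a2 = NA_real_, tau2 = NA_real_,
              duration_s = attr(events, "duration_s"),
              cell_id = attr(events, "cell_id"),
              condition = attr(events, "condition"))
  if (fit_kinetics && nrow(events) >= 10) {
    fit <- tryCatch({
      wf <- mean_normalized_waveform(trace, events)
      i0 <- which.min(wf$w)
      decay <- wf$w[i0:length(wf$w)]
      fit_biexp_decay(decay, dt = wf$dt)
    }, error = function(e) NULL)
    if (!is.null(fit)) {
      out$a1 <- fit$a1; out$tau1 <- fit$tau1
      out$a2 <- fit$a2; out$tau2 <- fit$tau2
    }
  }
  class(out) <- "mini_summary"
  out
}

#' @export
print.mini_summary <- function(x, ...) {
  cat(sprintf("cell %s (%s): %.3g Hz, %d events, amp %.3g pA, rise %.3g ms\n",
              x$cell_id, x$condition, x$frequency, x$n_events,
              x$median_amplitude, x$median_rise))
  if (!is.na(x$tau1))
    cat(sprintf("  mean-waveform decay: a1 %.2f tau1 %.3g ms, a2 %.2f tau2 %.3g ms\n",
                x$a1, x$tau1, x$a2, x$tau2))
  invisible(x)
}
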