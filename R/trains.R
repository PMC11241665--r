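# High-frequency train analysis: tonic/phasic decomposition, per-pulse
# charges, normalized cumulative charge, biphasic linear fits
# (back-extrapolated RRP size and replenishment rate), recovery pulses.

#' Split a train response into phasic and tonic components
#'
#' The tonic envelope is the piecewise-linear interpolation through anchor
#' values, each anchor being the median of the 0.5 ms of trace immediately
#' preceding a stimulus, measured relative to the pre-train baseline. The
#' phasic component is the trace minus this envelope, so each stimulus-locked
#' transient is measured from the slowly accumulating pedestal rather than
#' from the resting baseline.
#'
#' @param trace a [sweep_trace()] with `protocol = "train"` (>= 100 stimuli).
#' @param baseline_win pre-train window for the resting baseline (ms).
#' @return list of class `"tonic_phasic"`: `phasic` (a [sweep_trace()] of
#'   baseline- and envelope-subtracted current), `envelope` (pA, per sample),
#'   `tonic_charge` (pC, rectified integral of the envelope over the train),
#'   `anchors` (data frame), `baseline` (pA).
#' @export
tonic_phasic_split <- function(trace, baseline_win = 20) {
  if (trace$protocol != "train")
    stop("tonic_phasic_split expects a 'train' protocol trace", call. = FALSE)
  st <- trace$stim_times
  if (length(st) < 100L) stop("train needs >= 100 stimuli", call. = FALSE)
  if (min(diff(st)) < 2)
    stop("stimulus spacing < 2 ms not supported", call. = FALSE)
  t1 <- st[1]
  baseline <- estimate_baseline(trace, c(max(trace$t0, t1 - baseline_win),
                                         t1 - 1))
  dt <- trace$dt
  anchor_t <- st - 0.25
  anchor_v <- vapply(st, function(ts) {
    idx <- window_indices(trace, c(ts - 0.5, ts))
    stats::median(trace$samples[idx]) - baseline
  }, numeric(1))
  # envelope: zero before the train, linear between anchors, held after last
  t_all <- trace_times(trace)
  env <- stats::approx(x = c(trace$t0, t1 - 0.5, anchor_t),
                       y = c(0, 0, anchor_v), xout = t_all, rule = 2)$y
  # tonic charge over the train (first 100 stimuli + one ISI)
  isi <- stats::median(diff(st[1:100]))
  tr_win <- c(t1, st[100] + isi)
  idx <- window_indices(trace, tr_win)
  tonic_dev <- -env[idx]          # inward envelope -> positive magnitude
  tonic_dev[tonic_dev < 0] <- 0
  tonic_charge <- sum(tonic_dev) * dt / 1000
  phasic <- trace
  phasic$samples <- trace$samples - baseline - env
  out <- list(phasic = phasic, envelope = env, tonic_charge = tonic_charge,
              anchors = data.frame(t = anchor_t, value = anchor_v),
              baseline = baseline)
  class(out) <- "tonic_phasic"
  out
}

#' @export
print.tonic_phasic <- function(x, ...) {
  cat(sprintf("tonic/phasic split: tonic charge %.4g pC, envelope trough %.3g pA\n",
              x$tonic_charge, min(x$anchors$value)))
  invisible(x)
}

#' Per-pulse phasic charges
#'
#' Rectified integral of the (envelope-subtracted) phasic trace in the window
#' from each stimulus (plus an artifact blank) to the next stimulus, capped at
#' 10 ms; the last pulse uses a 10 ms window. Window construction makes
#' successive kernel tails fall into the following pulse's window, so per-
#' pulse charges track the released quanta without explicit tail subtraction.
#'
#' @param phasic the phasic [sweep_trace()] from [tonic_phasic_split()] (or
#'   the `"tonic_phasic"` object itself).
#' @param stim_times stimulus times (ms); defaults to the trace's.
#' @param blank_ms post-stimulus blank excluded from each window (ms).
#' @param max_win_ms window cap (ms, default 10 so that widely spaced
#'   recovery pulses are measured over the same window as train pulses).
#' @return numeric vector of charges (pC), one per stimulus, all >= 0.
#' @export
per_pulse_phasic_charge <- function(phasic, stim_times = NULL, blank_ms = 0.5,
                                    max_win_ms = 10) {
  if (inherits(phasic, "tonic_phasic")) phasic <- phasic$phasic
  if (is.null(stim_times)) stim_times <- phasic$stim_times
  m <- length(stim_times)
  dt <- phasic$dt
  ends <- c(stim_times[-1], Inf)
  vapply(seq_len(m), function(k) {
    w0 <- stim_times[k] + blank_ms
    w1 <- min(ends[k], stim_times[k] + max_win_ms, trace_end(phasic))
    if (w1 <= w0) return(0)
    idx <- window_indices(phasic, c(w0, w1))
    dev <- -phasic$samples[idx]
    dev[dev < 0] <- 0
    sum(dev) * dt / 1000
  }, numeric(1))
}

#' Normalized cumulative charge series
#'
#' `C_k = sum(Q_1..Q_k) / Q_1`: the cumulative phasic charge in units of the
#' first response ("first-response equivalents"), so `C_1 = 1` and back-
#' extrapolated y-intercepts are dimensionless pool sizes.
#'
#' @param Q per-pulse charges (pC); `Q[1]` must be > 0.
#' @return numeric vector `C_k`, nondecreasing with `C[1] = 1`.
#' @export
cumulative_series <- function(Q) {
  if (!length(Q)) stop("empty charge series", call. = FALSE)
  if (Q[1] <= 0)
    stop(structure(class = c("first_pulse_failure", "error", "condition"),
                   list(message = "first-pulse charge is zero; cell excluded from normalized analysis",
                        call = NULL)))
  cumsum(Q) / Q[1]
}

#' Biphasic linear fit of the cumulative charge
#'
#' Fits two ordinary least-squares lines to the normalized cumulative charge
#' versus time: a first steep phase (default pulses 2-10) and a second slower
#' phase (default pulses 60-100). Each line is extrapolated back to the
#' y-axis at the onset of the train (one inter-stimulus interval before the
#' first pulse, so that a train of identical responses extrapolates to zero).
#' The y-intercept estimates pool size in first-response equivalents: the
#' first phase reflects the tightly docked (immediately releasable) vesicles,
#' the second the whole readily releasable pool. The slopes estimate
#' replenishment rates (first-response equivalents per second).
#'
#' With `auto = TRUE` the phase-1/phase-2 breakpoint is chosen by minimizing
#' the total two-segment SSE over breakpoints in pulses 5-50 (phase 1 always
#' starting at pulse 2, phase 2 always ending at the last pulse).
#'
#' @param C normalized cumulative series from [cumulative_series()].
#' @param stim_times train stimulus times (ms), same length as `C`.
#' @param phase1,phase2 pulse-index windows for the two fits.
#' @param auto select the breakpoint by exhaustive SSE search.
#' @return object of class `"biphasic_fit"`: `phase1` and `phase2` (each
#'   with `pulse_range`, `slope` in 1/s, `y_intercept`, `r_squared`),
#'   `breakpoint` (when `auto`), `no_steep_phase` flag (phase-1 slope <=
#'   phase-2 slope), and the fitted series.
#' @examples
#' st <- 50 + (0:99) * 10
#' C <- cumulative_series(rep(2, 100))   # identical responses
#' coef(fit_biphasic(C, st))             # intercepts ~ 0
#' @export
fit_biphasic <- function(C, stim_times, phase1 = c(2, 10), phase2 = c(60, 100),
                         auto = FALSE) {
  m <- length(C)
  if (m < 100) stop("cumulative series needs >= 100 points", call. = FALSE)
  if (length(stim_times) != m)
    stop("stim_times must match the series length", call. = FALSE)
  isi <- stats::median(diff(stim_times))
  x <- (stim_times - stim_times[1] + isi) / 1000   # s; train onset at x = 0

  fit_window <- function(lo, hi) {
    k <- lo:hi
    if (length(k) < 3) stop("fit window needs >= 3 points", call. = FALSE)
    fx <- x[k]; fy <- C[k]
    fit <- stats::lm.fit(cbind(1, fx), fy)
    ss_res <- sum(fit$residuals^2)
    ss_tot <- sum((fy - mean(fy))^2)
    list(pulse_range = c(lo, hi),
         slope = unname(fit$coefficients[2]),
         y_intercept = unname(fit$coefficients[1]),
         r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
         sse = ss_res)
  }

  breakpoint <- NA_integer_
  if (auto) {
    cand <- 5:min(50, m - 3)
    sse <- vapply(cand, function(b)
      fit_window(2, b)$sse + fit_window(b, m)$sse, numeric(1))
    breakpoint <- cand[which.min(sse)]
    phase1 <- c(2, breakpoint)
    phase2 <- c(breakpoint, m)
  }
  p1 <- fit_window(phase1[1], phase1[2])
  p2 <- fit_window(phase2[1], phase2[2])
  out <- list(phase1 = p1, phase2 = p2, breakpoint = breakpoint,
              no_steep_phase = p1$slope <= p2$slope,
              data = data.frame(pulse = seq_len(m), x = x, C = C),
              isi = isi)
  if (out$no_steep_phase)
    warning("phase-1 slope is not steeper than phase-2 slope", call. = FALSE)
  class(out) <- "biphasic_fit"
  out
}

#' @export
coef.biphasic_fit <- function(object, ...) {
  c(slope1 = object$phase1$slope, intercept1 = object$phase1$y_intercept,
    slope2 = object$phase2$slope, intercept2 = object$phase2$y_intercept)
}

#' @export
print.biphasic_fit <- function(x, ...) {
  cat("biphasic cumulative-charge fit (first-response equivalents)\n")
  cat(sprintf("  phase 1 (pulses %d-%d): slope %.4g /s, y-intercept %.4g (R2 %.3f)\n",
              x$phase1$pulse_range[1], x$phase1$pulse_range[2],
              x$phase1$slope, x$phase1$y_intercept, x$phase1$r_squared))
  cat(sprintf("  phase 2 (pulses %d-%d): slope %.4g /s, y-intercept %.4g (R2 %.3f)\n",
              x$phase2$pulse_range[1], x$phase2$pulse_range[2],
              x$phase2$slope, x$phase2$y_intercept, x$phase2$r_squared))
  if (!is.na(x$breakpoint))
    cat(sprintf("  auto breakpoint at pulse %d\n", x$breakpoint))
  if (x$no_steep_phase) cat("  [warning: no steep early phase]\n")
  invisible(x)
}

#' @export
summary.biphasic_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  interpretation: tightly docked pool ~ %.3g, total RRP ~ %.3g first-response equivalents\n",
              object$phase1$y_intercept, object$phase2$y_intercept))
  invisible(object)
}

#' @export
predict.biphasic_fit <- function(object, phase = 2, x = NULL, ...) {
  p <- if (phase == 1) object$phase1 else object$phase2
  if (is.null(x)) x <- object$data$x
  p$y_intercept + p$slope * x
}

#' @export
plot.biphasic_fit <- function(x, ...) {
  plot(x$data$x, x$data$C, pch = 16, cex = 0.5,
       xlab = "time from train onset (s)",
       ylab = "cumulative charge (first-response equiv.)", ...)
  graphics::abline(x$phase1$y_intercept, x$phase1$slope, lty = 2, col = "red3")
  graphics::abline(x$phase2$y_intercept, x$phase2$slope, lty = 3, col = "blue3")
  graphics::legend("bottomright", c("phase 1", "phase 2"), lty = c(2, 3),
                   col = c("red3", "blue3"), bty = "n")
  invisible(x)
}

#' Readily-releasable-pool report from a biphasic fit
#'
#' Converts the two back-extrapolated intercepts into pool-size estimates and
#' the slopes into replenishment rates. In normalized units the estimates are
#' in first-response equivalents; when the first-response charge and the
#' quantal charge are supplied they are additionally expressed as vesicle
#' counts (and vesicles/s).
#'
#' @param fit a [fit_biphasic()] object.
#' @param q1_pC charge of the first train response (pC), for unit conversion.
#' @param q_charge quantal charge (pC/vesicle), for unit conversion.
#' @return list of class `"rrp_report"`: `rrp_tight` and `rrp_total`
#'   (intercepts, first-response equivalents), `replenishment_phase1/2`
#'   (1/s), optional `rrp_tight_vesicles`, `rrp_total_vesicles`,
#'   `replenishment_vesicles_s`, plus the `no_steep_phase` flag.
#' @export
rrp_report <- function(fit, q1_pC = NULL, q_charge = NULL) {
  stopifnot(inherits(fit, "biphasic_fit"))
  out <- list(rrp_tight = fit$phase1$y_intercept,
              rrp_total = fit$phase2$y_intercept,
              replenishment_phase1 = fit$phase1$slope,
              replenishment_phase2 = fit$phase2$slope,
              no_steep_phase = fit$no_steep_phase)
  if (!is.null(q1_pC) && !is.null(q_charge) && q_charge > 0) {
    scale <- q1_pC / q_charge      # vesicles per first-response equivalent
    out$rrp_tight_vesicles <- out$rrp_tight * scale
    out$rrp_total_vesicles <- out$rrp_total * scale
    out$replenishment_vesicles_s <- out$replenishment_phase2 * scale
  }
  class(out) <- "rrp_report"
  out
}

#' @export
print.rrp_report <- function(x, ...) {
  cat(sprintf("RRP estimates: tightly docked %.4g, total %.4g first-response equiv.\n",
              x$rrp_tight, x$rrp_total))
  cat(sprintf("  replenishment (phase 2): %.4g /s\n", x$replenishment_phase2))
  if (!is.null(x$rrp_tight_vesicles))
    cat(sprintf("  in vesicles: tight %.4g, total %.4g; replenishment %.4g vesicles/s\n",
                x$rrp_tight_vesicles, x$rrp_total_vesicles,
                x$replenishment_vesicles_s))
  if (x$no_steep_phase) cat("  [warning: no steep early phase]\n")
  invisible(x)
}

#' Recovery from pool depletion after a train
#'
#' Recovery fraction at each interval:
#' `(Q_rec - Q_ss) / (Q_1 - Q_ss)`, clipped to \[0, 1.5\], where `Q_ss` is
#' the steady-state (late-train) charge. A single-exponential recovery
#' `1 - exp(-t/tau)` is fitted to the fractions.
#'
#' @param interval_ms recovery intervals after the end of the train (ms),
#'   >= 3 values.
#' @param q_rec recovery-pulse charges (pC), one per interval.
#' @param q1 first train response charge (pC).
#' @param q_ss steady-state charge (pC), e.g. the mean over pulses 91-100.
#' @return list of class `"recovery_fit"`: `table` (data frame of interval
#'   and fraction), `tau_rec` (ms), `flagged` (TRUE when `q1 <= q_ss` makes
#'   the fractions undefined).
#' @export
recovery_analysis <- function(interval_ms, q_rec, q1, q_ss) {
  if (length(interval_ms) < 3) stop("need >= 3 recovery intervals", call. = FALSE)
  stopifnot(length(q_rec) == length(interval_ms))
  if (q1 <= q_ss) {
    out <- list(table = data.frame(interval_ms = interval_ms,
                                   fraction = NA_real_),
                tau_rec = NA_real_, flagged = TRUE)
    class(out) <- "recovery_fit"
    return(out)
  }
  frac <- pmin(1.5, pmax(0, (q_rec - q_ss) / (q1 - q_ss)))
  tau <- tryCatch({
    df <- data.frame(t = interval_ms, y = frac)
    fit <- minpack.lm::nlsLM(y ~ 1 - exp(-t / tau), data = df,
                             start = list(tau = 300), lower = 1e-3)
    unname(stats::coef(fit)[["tau"]])
  }, error = function(e) NA_real_)
  if (is.na(tau)) {
    # degenerate fractions (e.g. already fully recovered): 1-D grid fallback
    sse <- function(tt) sum((frac - (1 - exp(-interval_ms / tt)))^2)
    tau <- stats::optimize(sse, c(1e-3, 2 * max(interval_ms)))$minimum
  }
  out <- list(table = data.frame(interval_ms = interval_ms, fraction = frac),
              tau_rec = tau, flagged = FALSE)
  class(out) <- "recovery_fit"
  out
}

#' @export
print.recovery_fit <- function(x, ...) {
  if (x$flagged) {
    cat("recovery analysis: undefined (Q1 <= steady state)\n")
  } else {
    cat(sprintf("recovery from depletion: tau_rec %.4g ms; fractions %s\n",
                x$tau_rec, paste(sprintf("%.2f", x$table$fraction),
                                 collapse = ", ")))
  }
  invisible(x)
}

#' Full train analysis for one cell
#'
#' Runs the complete train pipeline on a single sweep: tonic/phasic split,
#' per-pulse phasic charges, normalized cumulative series, biphasic fit, and
#' (when the sweep includes recovery pulses after the 100-pulse train)
#' recovery analysis.
#'
#' @param trace a [sweep_trace()] with `protocol = "train"`; the first
#'   `n_train` stimuli are the train, any later ones are recovery pulses.
#' @param n_train number of train pulses (default 100).
#' @param phase1,phase2,auto passed to [fit_biphasic()].
#' @param blank_ms artifact blank per stimulus (ms).
#' @param ss_pulses pulse indices defining the steady state.
#' @return object of class `"train_fit"`: `Q` (per-pulse charges, pC),
#'   `C` (normalized cumulative series), `fit` (a `biphasic_fit`),
#'   `tonic_charge` (pC), `recovery` (a `recovery_fit` or `NULL`),
#'   `q1` (pC), `excluded` flag with `reason` when the cell cannot be
#'   analyzed (first-pulse failure).
#' @export
analyze_train <- function(trace, n_train = 100, phase1 = c(2, 10),
                          phase2 = c(60, 100), auto = FALSE, blank_ms = 0.5,
                          ss_pulses = 91:100) {
  split <- tonic_phasic_split(trace)
  Q_all <- per_pulse_phasic_charge(split, blank_ms = blank_ms)
  st <- trace$stim_times
  Q_train <- Q_all[seq_len(n_train)]
  out <- list(Q = Q_all, C = NULL, fit = NULL,
              tonic_charge = split$tonic_charge, recovery = NULL,
              q1 = Q_train[1], excluded = FALSE, reason = NULL,
              cell_id = trace$cell_id, condition = trace$condition)
  class(out) <- "train_fit"
  C <- tryCatch(cumulative_series(Q_train), first_pulse_failure = function(e) {
    out$excluded <<- TRUE
    out$reason <<- conditionMessage(e)
    NULL
  })
  if (is.null(C)) return(out)
  out$C <- C
  out$fit <- fit_biphasic(C, st[seq_len(n_train)], phase1 = phase1,
                          phase2 = phase2, auto = auto)
  if (length(st) > n_train) {
    rec_idx <- (n_train + 1L):length(st)
    if (length(rec_idx) >= 3) {
      q_ss <- mean(Q_train[ss_pulses])
      out$recovery <- recovery_analysis(st[rec_idx] - st[n_train],
                                        Q_all[rec_idx], Q_train[1], q_ss)
    }
  }
  out
}

#' @export
print.train_fit <- function(x, ...) {
  cat(sprintf("train analysis: cell %s (%s)\n", x$cell_id, x$condition))
  if (x$excluded) {
    cat("  EXCLUDED:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf("  Q1 %.4g pC, tonic charge %.4g pC\n", x$q1, x$tonic_charge))
  print(x$fit)
  if (!is.null(x$recovery)) print(x$recovery)
  invisible(x)
}

#' @export
coef.train_fit <- function(object, ...) {
  if (object$excluded) return(c(slope1 = NA, intercept1 = NA,
                                slope2 = NA, intercept2 = NA))
  coef(object$fit)
}

#' @export
plot.train_fit <- function(x, ...) {
  if (!x$excluded) plot(x$fit, ...)
  invisible(x)
}
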