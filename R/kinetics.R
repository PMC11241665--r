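#' Event kinetics for postsynaptic current waveforms
#'
#' Describes the stereotyped shape of a (inhibitory) postsynaptic current as an
#' exponential rise multiplying a double-exponential decay. The decay amplitudes
#' are fractional: `a1 + a2 = 1`, so the shape is fully determined by
#' `tau_rise`, `a1`, `tau1` and `tau2`.
#'
#' @param tau_rise rise time constant (ms), > 0.
#' @param a1 fractional amplitude of the fast decay component, in \[0, 1\].
#' @param tau1 fast decay time constant (ms), > 0.
#' @param tau2 slow decay time constant (ms), > `tau1`.
#' @return an object of class `"event_kinetics"`.
#' @examples
#' k <- event_kinetics(tau_rise = 0.15, a1 = 0.75, tau1 = 1.52, tau2 = 10)
#' @export
event_kinetics <- function(tau_rise, a1, tau1, tau2) {
  k <- list(tau_rise = as.numeric(tau_rise), a1 = as.numeric(a1),
            a2 = 1 - as.numeric(a1), tau1 = as.numeric(tau1),
            tau2 = as.numeric(tau2))
  class(k) <- "event_kinetics"
  validate_event_kinetics(k)
  k
}

validate_event_kinetics <- function(k) {
  stopifnot(is.list(k))
  if (!is.finite(k$tau_rise) || k$tau_rise <= 0)
    stop("tau_rise must be a positive number", call. = FALSE)
  if (!is.finite(k$a1) || k$a1 < 0 || k$a1 > 1)
    stop("a1 must lie in [0, 1]", call. = FALSE)
  if (abs(k$a1 + k$a2 - 1) > 1e-8)
    stop("decay amplitudes must satisfy a1 + a2 = 1", call. = FALSE)
  if (!is.finite(k$tau1) || k$tau1 <= 0 || !is.finite(k$tau2) || k$tau2 <= 0)
    stop("decay time constants must be positive", call. = FALSE)
  if (k$tau1 >= k$tau2)
    stop("tau1 must be smaller than tau2", call. = FALSE)
  invisible(k)
}

#' @export
print.event_kinetics <- function(x, ...) {
  cat(sprintf(
    "event kinetics: rise tau %.3g ms; decay %.2f*exp(-t/%.3g) + %.2f*exp(-t/%.3g) ms\n",
    x$tau_rise, x$a1, x$tau1, x$a2, x$tau2))
  invisible(x)
}

#' Build a unit-peak event waveform from kinetics
#'
#' Samples `w(t) = (1 - exp(-t/tau_rise)) * (a1*exp(-t/tau1) + a2*exp(-t/tau2))`
#' on a regular grid and rescales it so its peak magnitude is exactly 1. The
#' waveform spans at least `5 * tau2` so that the slow component has decayed to
#' below 1% at the end.
#'
#' @param kinetics an [event_kinetics()] object.
#' @param dt sampling interval (ms); must resolve the fast decay
#'   (`dt < tau1 / 5`).
#' @param n_tau2 length of the waveform in units of `tau2` (default 5).
#' @return numeric vector, the unit-peak waveform starting at `t = 0`
#'   (value 0 at the first sample), with attributes `dt` and `peak_index`.
#' @examples
#' w <- make_kernel(event_kinetics(0.15, 0.75, 1.52, 10), dt = 0.1)
#' max(w)  # 1 by construction
#' @export
make_kernel <- function(kinetics, dt, n_tau2 = 5) {
  validate_event_kinetics(kinetics)
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive", call. = FALSE)
  if (dt >= kinetics$tau1 / 5)
    stop("dt must be smaller than tau1 / 5 to resolve the fast decay",
         call. = FALSE)
  n <- ceiling(n_tau2 * kinetics$tau2 / dt) + 1L
  t <- (seq_len(n) - 1) * dt
  w <- (1 - exp(-t / kinetics$tau_rise)) *
    (kinetics$a1 * exp(-t / kinetics$tau1) +
       kinetics$a2 * exp(-t / kinetics$tau2))
  pk <- which.max(w)
  w <- w / w[pk]
  attr(w, "dt") <- dt
  attr(w, "peak_index") <- pk
  w
}

#' Charge carried by a unit-peak waveform
#'
#' Time integral of [make_kernel()] output in pA*ms (fC) per pA of peak
#' amplitude. Used to convert between quantal charge and quantal peak
#' amplitude.
#'
#' @param kernel output of [make_kernel()].
#' @return integral in ms (fC per pA of peak).
#' @export
kernel_unit_charge <- function(kernel) {
  sum(kernel) * attr(kernel, "dt")
}
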