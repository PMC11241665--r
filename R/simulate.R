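# Synthetic recording generator: spontaneous (mini) traces and evoked
# responses driven by the two-pool quantal release model.

# Evaluate a function with a temporarily seeded RNG, restoring global state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a per-cell seed from a master seed
#'
#' Deterministic splitting rule used throughout the package: each simulated
#' cell receives its own substream seed computed from the master seed and
#' small integer indices (condition, cell, protocol). All arithmetic stays
#' below 2^31.
#'
#' @param master master seed (integer).
#' @param ... one or more nonnegative integer indices.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- (abs(as.numeric(master)) %% 1000003) * 2011
  mult <- c(10007, 101, 7919, 13, 7)
  for (i in seq_along(idx))
    s <- (s + as.numeric(idx[i]) * mult[((i - 1) %% length(mult)) + 1]) %% 2147483646
  as.integer(s %% 2147483646 + 1)
}

# lognormal multiplier(s) with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# add a scaled kernel to `samples` starting at sample index i0 (1-based)
add_event <- function(samples, kernel, i0, amp) {
  n <- length(samples)
  if (i0 > n) return(samples)
  k_len <- min(length(kernel), n - i0 + 1L)
  idx <- i0:(i0 + k_len - 1L)
  samples[idx] <- samples[idx] + amp * kernel[seq_len(k_len)]
  samples
}

#' Simulate a spontaneous (miniature IPSC) recording
#'
#' Event times are drawn from a homogeneous Poisson process at the model's
#' `mini_rate`; each event is the unit kernel scaled to the quantal amplitude
#' (quantal charge divided by the kernel's unit charge) with multiplicative
#' lognormal jitter of CV `amp_cv`, pointing inward (negative). Gaussian
#' recording noise is added. The same seed gives an identical trace.
#'
#' @param params a [pool_model_params()] object.
#' @param duration_s recording duration (s).
#' @param dt sampling interval (ms), default 0.1 (10 kHz).
#' @param seed RNG seed (optional but recommended).
#' @param cell_id,condition labels for the generated trace.
#' @return list with `trace` (a [sweep_trace()]) and `truth`, a data frame of
#'   ground-truth events (`time` ms, `amplitude` pA, `charge` pC).
#' @export
simulate_minis <- function(params, duration_s = 100, dt = 0.1, seed = NULL,
                           cell_id = "sim", condition = "unknown") {
  validate_pool_model_params(params)
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("duration_s must be > 0", call. = FALSE)
  with_seed(seed, {
    dur_ms <- duration_s * 1000
    n <- as.integer(round(dur_ms / dt)) + 1L
    kernel <- make_kernel(params$kernel, dt)
    uq <- kernel_unit_charge(kernel)          # fC per pA peak
    amp_mean <- params$q_charge * 1000 / uq   # pA
    n_ev <- stats::rpois(1, params$mini_rate * duration_s)
    times <- sort(stats::runif(n_ev, 0, dur_ms))
    amps <- amp_mean * rlnorm_cv(n_ev, params$amp_cv)
    samples <- if (params$noise_sd > 0)
      stats::rnorm(n, 0, params$noise_sd) else numeric(n)
    for (i in seq_len(n_ev))
      samples <- add_event(samples, kernel,
                           as.integer(floor(times[i] / dt)) + 1L, -amps[i])
    trace <- sweep_trace(samples, dt = dt, t0 = 0,
                         cell_id = cell_id, condition = condition,
                         protocol = "minis")
    truth <- data.frame(time = times, amplitude = amps,
                        charge = amps * uq / 1000)
    list(trace = trace, truth = truth)
  })
}

# One step of the release recurrence shared by both engines.
#
# State: n (pool occupancy), F (facilitation). For stimulus k with gap
# delta_ms to the NEXT stimulus:
#   p_k = min(1, p_rel + F_k);  r_k ~ Binomial(n_k, p_k) or n_k * p_k
#   pool refill over the gap: Poisson(replenish_rate * delta / 1000) (or its
#   mean) for gaps <= 20 ms; for longer gaps the pool relaxes toward n_tight
#   with time constant recovery_tau (post-train / inter-sweep recovery)
#   F_{k+1} = (F_k + facil_increment) * exp(-delta / facil_tau)

#' Run the release recurrence over a stimulus protocol
#'
#' The per-stimulus state update of the two-pool model, without trace
#' synthesis. Exposed because it is the exact oracle for the train analysis:
#' the deterministic engine gives real-valued released counts whose
#' cumulative sum has a closed form in simple regimes.
#'
#' @param params a [pool_model_params()] object.
#' @param stim_times stimulus times (ms), sorted.
#' @param engine `"stochastic"` or `"deterministic"`.
#' @return data frame with one row per stimulus: `pulse`, `t_stim`,
#'   `n_before` (pool occupancy before release), `p_eff`, `released`,
#'   `charge` (pC, = released * q_charge).
#' @export
release_sequence <- function(params, stim_times,
                             engine = c("stochastic", "deterministic")) {
  engine <- match.arg(engine)
  if (!length(stim_times)) stop("protocol must be nonempty", call. = FALSE)
  if (is.unsorted(stim_times, strictly = TRUE))
    stop("protocol stimulus times must be sorted increasing", call. = FALSE)
  m <- length(stim_times)
  stoch <- engine == "stochastic"
  n <- params$n_tight
  Fst <- 0
  out_n <- out_p <- out_r <- numeric(m)
  for (k in seq_len(m)) {
    p_k <- min(1, params$p_rel + Fst)
    r_k <- if (stoch) stats::rbinom(1, as.integer(round(n)), p_k) else n * p_k
    out_n[k] <- n; out_p[k] <- p_k; out_r[k] <- r_k
    n <- n - r_k
    if (k < m) {
      delta <- stim_times[k + 1] - stim_times[k]
      if (delta <= 20) {
        mean_rho <- params$replenish_rate * delta / 1000
        rho <- if (stoch) stats::rpois(1, mean_rho) else mean_rho
        n <- min(params$n_max, n + rho)
      } else {
        gap_fill <- (params$n_tight - n) * (1 - exp(-delta / params$recovery_tau))
        if (stoch) {
          miss <- max(0, round(params$n_tight - n))
          fill <- stats::rbinom(1, miss, 1 - exp(-delta / params$recovery_tau))
          n <- min(params$n_max, n + fill)
        } else {
          n <- min(params$n_max, n + max(0, gap_fill))
        }
      }
      Fst <- (Fst + params$facil_increment) * exp(-delta / params$facil_tau)
    }
  }
  data.frame(pulse = seq_len(m), t_stim = stim_times, n_before = out_n,
             p_eff = out_p, released = out_r,
             charge = out_r * params$q_charge)
}

#' Simulate an evoked-response sweep
#'
#' Runs the release recurrence over the stimulus protocol and synthesizes the
#' current trace: each stimulus injects its phasic charge as a kernel-shaped
#' inward current at a fixed synaptic latency, while a fraction
#' `tonic_fraction` of the released charge is spread as a slow exponential
#' (tau = 50 ms) asynchronous current. The stochastic engine adds per-quantum
#' lognormal amplitude jitter and Gaussian recording noise; the deterministic
#' engine is noise-free with a real-valued pool.
#'
#' @param params a [pool_model_params()] object.
#' @param protocol stimulus times (ms), sorted; see [protocol_paired()] and
#'   [protocol_train()].
#' @param dt sampling interval (ms).
#' @param seed RNG seed.
#' @param engine `"stochastic"` or `"deterministic"`.
#' @param pre_ms quiet baseline recorded before the first stimulus (ms).
#' @param post_ms recording continued after the last stimulus (ms).
#' @param cell_id,condition,protocol_tag labels for the generated trace.
#' @return list with `trace` (a [sweep_trace()]) and `truth` (the
#'   [release_sequence()] data frame, plus attribute `latency_ms`).
#' @export
simulate_evoked <- function(params, protocol, dt = 0.1, seed = NULL,
                            engine = c("stochastic", "deterministic"),
                            pre_ms = 50, post_ms = 120, cell_id = "sim",
                            condition = "unknown",
                            protocol_tag = NULL) {
  engine <- match.arg(engine)
  validate_pool_model_params(params)
  latency_ms <- 2.5
  tau_tonic <- 50
  with_seed(seed, {
    seq_df <- release_sequence(params, protocol, engine)
    t_end <- protocol[length(protocol)] + post_ms
    n <- as.integer(round((t_end + pre_ms) / dt)) + 1L
    t0 <- protocol[1] - pre_ms
    kernel <- make_kernel(params$kernel, dt)
    uq <- kernel_unit_charge(kernel)  # fC per pA peak
    stoch <- engine == "stochastic"
    samples <- if (stoch && params$noise_sd > 0)
      stats::rnorm(n, 0, params$noise_sd) else numeric(n)
    tonic_len <- as.integer(round(5 * tau_tonic / dt))
    tonic_shape <- exp(-(seq_len(tonic_len) - 1) * dt / tau_tonic)
    for (k in seq_len(nrow(seq_df))) {
      r_k <- seq_df$released[k]
      if (r_k <= 0) next
      jit <- if (stoch) sum(rlnorm_cv(r_k, params$amp_cv)) / r_k else 1
      q_tot <- r_k * params$q_charge * jit          # pC
      q_phasic <- q_tot * (1 - params$tonic_fraction)
      q_tonic <- q_tot * params$tonic_fraction
      i0 <- as.integer(floor((protocol[k] + latency_ms - t0) / dt)) + 1L
      samples <- add_event(samples, kernel, i0, -(q_phasic * 1000 / uq))
      if (q_tonic > 0)
        samples <- add_event(samples, tonic_shape, i0,
                             -(q_tonic * 1000 / tau_tonic))
    }
    tag <- if (!is.null(protocol_tag)) protocol_tag
    else if (length(protocol) >= 100) "train"
    else if (length(protocol) == 2) "paired"
    else "single"
    trace <- sweep_trace(samples, dt = dt, t0 = t0, stim_times = protocol,
                         cell_id = cell_id, condition = condition,
                         protocol = tag)
    attr(seq_df, "latency_ms") <- latency_ms
    list(trace = trace, truth = seq_df)
  })
}

#' Stimulus protocols
#'
#' `protocol_paired()` gives two stimuli separated by `isi`;
#' `protocol_train()` gives `n_pulses` at `freq_hz` optionally followed by
#' recovery pulses at the given intervals after the last train pulse.
#'
#' @param isi inter-stimulus interval (ms).
#' @param t_first time of the first stimulus (ms).
#' @param n_pulses number of train pulses.
#' @param freq_hz train frequency (Hz).
#' @param recovery_ms intervals of recovery pulses after the end of the train
#'   (ms); use `NULL` for none. Defaults to the standard 25, 50, 100, 300,
#'   1000, 3000 ms set.
#' @return numeric vector of stimulus times (ms).
#' @export
protocol_paired <- function(isi, t_first = 50) c(t_first, t_first + isi)

#' @rdname protocol_paired
#' @export
protocol_train <- function(n_pulses = 100, freq_hz = 100, t_first = 50,
                           recovery_ms = c(25, 50, 100, 300, 1000, 3000)) {
  train <- t_first + (seq_len(n_pulses) - 1) * 1000 / freq_hz
  if (length(recovery_ms)) c(train, train[n_pulses] + sort(recovery_ms))
  else train
}
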