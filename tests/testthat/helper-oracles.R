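# Independent oracles used across the suite. These deliberately re-implement
# the checked quantities by brute force and must stay independent of the
# package's own code paths.

# Exact two-sided Mann-Whitney p by full enumeration of group labelings.
mw_exact_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  labelings <- utils::combn(nx + ny, nx)
  us <- apply(labelings, 2, function(idx) sum(ranks[idx]) - nx * (nx + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Dense-grid least-squares biexponential fit (amplitudes solved linearly).
biexp_grid_oracle <- function(y, dt, tau_lo = 0.2, tau_hi = 40, n_grid = 80) {
  t <- (seq_along(y) - 1) * dt
  taus <- exp(seq(log(tau_lo), log(tau_hi), length.out = n_grid))
  best <- NULL
  for (t1 in taus) for (t2 in taus) {
    if (t2 <= t1 * 1.05) next
    X <- cbind(exp(-t / t1), exp(-t / t2))
    cf <- tryCatch(stats::.lm.fit(X, y)$coefficients, error = function(e) NULL)
    if (is.null(cf) || any(cf < 0)) next
    sse <- sum((y - X %*% cf)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(a1 = cf[1], tau1 = t1, a2 = cf[2], tau2 = t2, sse = sse)
  }
  best
}

# Exhaustive two-segment breakpoint search (independent re-implementation of
# the auto-breakpoint rule).
biphasic_breakpoint_oracle <- function(C, x, candidates = 5:50) {
  sse_of <- function(k) {
    f <- function(idx) {
      fit <- stats::lm(C[idx] ~ x[idx])
      sum(stats::residuals(fit)^2)
    }
    f(2:k) + f(k:length(C))
  }
  sse <- vapply(candidates, sse_of, numeric(1))
  candidates[which.min(sse)]
}

# Build a trace by summing unit-peak kernels at given onsets (ms).
kernel_trace <- function(onsets, amps, kinetics, dt = 0.1, dur_ms = NULL,
                         noise_sd = 0, stim_times = numeric(0),
                         protocol = "minis", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- make_kernel(kinetics, dt)
  if (is.null(dur_ms)) dur_ms <- max(onsets, stim_times, 0) + 100
  n <- as.integer(round(dur_ms / dt)) + 1L
  s <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  for (i in seq_along(onsets)) {
    i0 <- as.integer(floor(onsets[i] / dt)) + 1L
    L <- min(length(w), n - i0 + 1L)
    if (L > 0) s[i0:(i0 + L - 1L)] <- s[i0:(i0 + L - 1L)] - amps[i] * w[1:L]
  }
  sweep_trace(s, dt = dt, stim_times = stim_times, protocol = protocol)
}

fast_kinetics <- function() event_kinetics(0.15, 0.8, 1.0, 3)

# Deterministic test parameters with no facilitation/tonic/noise.
plain_params <- function(p_rel, rho = 0, n_tight = 500, kernel = fast_kinetics(),
                         ...) {
  pool_model_params(n_tight = n_tight, p_rel = p_rel, q_charge = 0.14,
                    replenish_rate = rho * n_tight / 0.01, n_max = 2 * n_tight,
                    facil_increment = 0, tonic_fraction = 0, noise_sd = 0,
                    kernel = kernel, ...)
}

with_seed_local <- function(seed, expr) {
  set.seed(seed)
  expr
}
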