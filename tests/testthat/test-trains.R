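make_train_trace <- function(par, seed = NULL, engine = "stochastic",
                             recovery = NULL) {
  simulate_evoked(par, protocol_train(recovery_ms = recovery), seed = seed,
                  engine = engine)
}

test_that("tonic/phasic split isolates a DC shift and a decaying train", {
  # pure DC shift of -20 pA during the train: all tonic, no phasic
  dt <- 0.1
  st <- 50 + (0:99) * 10
  n <- round(1200 / dt) + 1
  s <- numeric(n)
  t <- (seq_len(n) - 1) * dt
  s[t >= 50 & t < 1050] <- -20
  tr <- sweep_trace(s, dt = dt, stim_times = st, protocol = "train")
  sp <- tonic_phasic_split(tr)
  expect_equal(sp$tonic_charge, 20 * 1000 / 1000, tolerance = 0.03) # 20 pC
  Q <- per_pulse_phasic_charge(sp)
  expect_lt(sum(Q), 0.4)

  # fully decaying responses: envelope ~ 0, phasic ~ original
  par <- plain_params(p_rel = 0.1, rho = 0.05, n_tight = 60,
                      kernel = event_kinetics(0.1, 0.9, 0.6, 1.8))
  sim <- make_train_trace(par, engine = "deterministic")
  sp2 <- tonic_phasic_split(sim$trace)
  expect_lt(abs(sp2$tonic_charge), 0.05 * sum(sim$truth$charge))
  expect_lt(max(abs(sp2$envelope)), 0.01 * max(abs(sim$trace$samples)))
})

test_that("tonic fraction of released charge is recovered from the envelope", {
  par <- pool_model_params(n_tight = 1000, p_rel = 0.15, q_charge = 0.14,
                           replenish_rate = 4000, n_max = 1400,
                           facil_increment = 0, tonic_fraction = 0.3,
                           noise_sd = 0,
                           kernel = event_kinetics(0.1, 0.9, 0.6, 1.8))
  sim <- make_train_trace(par, engine = "deterministic")
  sp <- tonic_phasic_split(sim$trace)
  Q <- per_pulse_phasic_charge(sp)[1:100]
  ratio <- sp$tonic_charge / (sp$tonic_charge + sum(Q))
  expect_equal(ratio, 0.3, tolerance = 0.15)  # within 15% of 0.3
})

test_that("per-pulse phasic charges track the released quanta", {
  par <- plain_params(p_rel = 0.35, rho = 0.08)
  sim <- make_train_trace(par, engine = "deterministic")
  sp <- tonic_phasic_split(sim$trace)
  Q <- per_pulse_phasic_charge(sp)[1:100]
  expect_true(all(Q >= 0))
  r <- sim$truth$released[1:100]
  ratio <- Q / (r * par$q_charge)
  expect_lt(max(abs(ratio / stats::median(ratio) - 1)), 0.05)

  # zero-response train
  par0 <- plain_params(p_rel = 0)
  sim0 <- make_train_trace(par0, engine = "deterministic")
  Q0 <- per_pulse_phasic_charge(tonic_phasic_split(sim0$trace))
  expect_true(all(Q0 == 0))
})

test_that("normalized cumulative series has the stated closed forms", {
  expect_equal(cumulative_series(rep(3, 100)), 1:100)
  # geometric charges, p = 0.5: limit 1/p = 2
  Q <- 2 * 0.5^(0:99)
  C <- cumulative_series(Q)
  expect_equal(C[1], 1)
  expect_true(all(diff(C) >= 0))
  expect_equal(C[100], 2, tolerance = 1e-9)
  expect_equal(cumulative_series(c(5, rep(0, 99))), rep(1, 100))
  expect_error(cumulative_series(c(0, 1, 2)), class = "first_pulse_failure")
})

test_that("biphasic fit back-extrapolates pool size and replenishment", {
  st <- 50 + (0:99) * 10
  # identical responses: exactly linear, both intercepts 0
  fit <- suppressWarnings(fit_biphasic(cumulative_series(rep(2, 100)), st))
  expect_equal(fit$phase1$y_intercept, 0, tolerance = 1e-9)
  expect_equal(fit$phase2$y_intercept, 0, tolerance = 1e-9)
  expect_equal(fit$phase1$slope, fit$phase2$slope, tolerance = 1e-9)
  expect_equal(fit$phase1$slope, 100, tolerance = 1e-9)  # one per 10 ms
  expect_true(fit$no_steep_phase)

  # pure depletion p = 0.5: late slope -> 0, phase-2 intercept -> 1/p
  C <- (1 - 0.5^(1:100)) / 0.5
  fit2 <- suppressWarnings(fit_biphasic(C / C[1], st))
  expect_equal(fit2$phase2$y_intercept, 2, tolerance = 1e-6)
  expect_equal(fit2$phase2$slope, 0, tolerance = 1e-6)

  expect_error(fit_biphasic(C[1:50], st[1:50]), ">= 100")
})

test_that("automatic breakpoint equals the exhaustive search", {
  set.seed(17)
  st <- 50 + (0:99) * 10
  x <- (st - st[1] + 10) / 1000
  for (i in 1:10) {
    b_true <- sample(8:40, 1)
    s1 <- runif(1, 150, 300); s2 <- runif(1, 5, 40)
    C <- numeric(100)
    C[1] <- 1
    for (k in 2:100) {
      sl <- if (k <= b_true) s1 else s2
      C[k] <- C[k - 1] + sl * 0.01
    }
    C <- C + rnorm(100, 0, 0.05)
    C <- cummax(C)
    fit <- fit_biphasic(C, st, auto = TRUE)
    expect_equal(fit$breakpoint, biphasic_breakpoint_oracle(C, x))
  }
})

test_that("deterministic-engine pipeline matches the recurrence oracle", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(1, 0.2, 0.9)
    rho <- runif(1, 0, 0.15)        # replenishment per ISI / n_tight < 0.2
    par <- plain_params(p_rel = p, rho = rho)
    sim <- make_train_trace(par, engine = "deterministic")
    tf <- analyze_train(sim$trace)
    # oracle: same fits computed from the recurrence itself
    rs <- release_sequence(par, protocol_train(recovery_ms = NULL),
                           engine = "deterministic")
    C_or <- cumsum(rs$released) / rs$released[1]
    fit_or <- suppressWarnings(fit_biphasic(C_or, rs$t_stim))
    expect_equal(coef(tf)[["intercept2"]], fit_or$phase2$y_intercept,
                 tolerance = 0.05)
    expect_equal(coef(tf)[["slope2"]], fit_or$phase2$slope,
                 tolerance = 0.05 * max(1, abs(fit_or$phase2$slope)))
    # steady state: phase-2 slope estimates the replenishment rate R*q/Q1
    slope_expected <- par$replenish_rate / (par$n_tight * p)
    if (slope_expected > 1)
      expect_equal(fit_or$phase2$slope, slope_expected,
                   tolerance = 0.10 * slope_expected)
  }
})

test_that("rrp report converts intercepts to vesicle counts", {
  # p = 1, no replenishment: everything released on pulse 1, intercept2 = 1
  par <- plain_params(p_rel = 1, kernel = event_kinetics(0.1, 0.9, 0.6, 1.8))
  sim <- make_train_trace(par, engine = "deterministic")
  tf <- suppressWarnings(analyze_train(sim$trace))
  rep1 <- rrp_report(tf$fit, q1_pC = tf$q1, q_charge = par$q_charge)
  expect_equal(rep1$rrp_total, 1, tolerance = 0.02)
  expect_equal(rep1$rrp_total_vesicles / par$n_tight, 1, tolerance = 0.03)

  # vesicle-scale RRP estimates scale with the true pool size
  meds <- vapply(c(500, 1000), function(n) {
    par <- pool_model_params(n_tight = n, p_rel = 0.25, q_charge = 0.14,
                             replenish_rate = 0.03 * n / 0.01, n_max = 2 * n,
                             facil_increment = 0.05, tonic_fraction = 0,
                             noise_sd = 0, kernel = fast_kinetics())
    est <- vapply(1:12, function(j) {
      sim <- make_train_trace(par, seed = derive_seed(31, n, j))
      tf <- analyze_train(sim$trace)
      rrp_report(tf$fit, q1_pC = tf$q1,
                 q_charge = par$q_charge)$rrp_tight_vesicles
    }, numeric(1))
    stats::median(est)
  }, numeric(1))
  expect_equal(meds[2] / meds[1], 2, tolerance = 0.25)
})

test_that("recovery pulses recover with the generative time constant", {
  # trivial fractions
  rec <- suppressWarnings(recovery_analysis(c(25, 100, 1000),
                                            q_rec = c(5, 5, 5),
                                            q1 = 5, q_ss = 1))
  expect_equal(rec$table$fraction, rep(1, 3))
  expect_lt(rec$tau_rec, 30)
  rec0 <- suppressWarnings(recovery_analysis(c(25, 100, 1000),
                                             q_rec = c(1, 1, 1),
                                             q1 = 5, q_ss = 1))
  expect_equal(rec0$table$fraction, rep(0, 3))
  expect_true(recovery_analysis(c(25, 50, 100), c(1, 1, 1), 1, 2)$flagged)

  # isolated recovery intervals, no facilitation: tau_rec within 20%
  par <- pool_model_params(n_tight = 1200, p_rel = 0.2, q_charge = 0.14,
                           replenish_rate = 6000, n_max = 1600,
                           facil_increment = 0, amp_cv = 0.2,
                           tonic_fraction = 0, noise_sd = 2,
                           recovery_tau = 500, kernel = fast_kinetics())
  iv <- c(25, 50, 100, 300, 1000, 3000)
  taus <- vapply(1:4, function(j) {
    qs <- vapply(iv, function(i) {
      s <- simulate_evoked(par, protocol_train(recovery_ms = i),
                           seed = derive_seed(j, i))
      sp <- tonic_phasic_split(s$trace)
      Q <- per_pulse_phasic_charge(sp)
      c(Q[1], mean(Q[91:100]), Q[101])
    }, numeric(3))
    recovery_analysis(iv, qs[3, ], mean(qs[1, ]), mean(qs[2, ]))$tau_rec
  }, numeric(1))
  expect_equal(stats::median(taus), 500, tolerance = 0.2)
})

test_that("full train analysis flags first-pulse failures", {
  par <- plain_params(p_rel = 0)   # no release at all
  sim <- make_train_trace(par, engine = "deterministic")
  tf <- analyze_train(sim$trace)
  expect_true(tf$excluded)
  expect_match(tf$reason, "first-pulse")
  expect_true(all(is.na(coef(tf))))
})
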