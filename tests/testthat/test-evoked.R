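test_that("input-output curve interpolates the 65% calibration point", {
  # saturating curve q(s) = Qmax * s / (s + K): 65% point at s = 0.65K/0.35
  K <- 20
  s <- seq(1, 200, by = 1)
  q <- 10 * s / (s + K)
  io <- io_curve(s, q)
  q_target <- 0.65 * max(q)
  s_star <- K * q_target / (10 - q_target)   # exact inverse of the sampled max
  expect_equal(io$calibration, s_star, tolerance = 0.01)
  expect_true(io$plateau_ok)

  # flat curve: calibration at the smallest stimulus
  io2 <- io_curve(1:5, rep(4, 5))
  expect_equal(io2$calibration, 1)

  # step curve: interpolated at 65% of the step (max at last point warns)
  io3 <- suppressWarnings(io_curve(1:4, c(0, 0, 0, 8)))
  expect_equal(io3$calibration, 3.65)

  # still rising at the last point -> warning, last point used as max
  expect_warning(io4 <- io_curve(1:4, c(1, 2, 4, 8)), "plateau")
  expect_false(io4$plateau_ok)
  expect_error(io_curve(1:3, 1:3), ">= 4")
  expect_error(io_curve(c(1, 3, 2, 4), 1:4), "monotone")
})

test_that("single-stimulus statistics summarize charge variability", {
  s <- single_stim_stats(rep(2, 12))
  expect_equal(s$cv, 0)
  expect_equal(s$failure_rate, 0)

  s2 <- single_stim_stats(runif(20), is_failure = rep(c(TRUE, FALSE), c(5, 15)))
  expect_equal(s2$failure_rate, 0.25)

  # CV is sd/mean of the non-failure charges (for {1,2,3}: 1/2)
  charges <- c(1, 2, 3, runif(9))
  fails <- c(FALSE, FALSE, FALSE, rep(TRUE, 9))
  s3 <- single_stim_stats(charges, is_failure = fails)
  expect_equal(s3$cv, 0.5)
  expect_equal(s3$median_charge, 2)

  s4 <- single_stim_stats(rep(0, 10), is_failure = rep(TRUE, 10))
  expect_true(s4$all_failures)
  expect_true(is.na(s4$cv))
  expect_error(single_stim_stats(1:5), ">= 10")
})

test_that("wash time course quantifies the blocked fraction", {
  expect_equal(charge_timecourse(c(2, 2, 2, 0, 0), time_s = 1:5,
                                 drug_period = c(4, 5))$block_fraction, 1)
  expect_equal(charge_timecourse(c(2, 2, 2, 2, 2), time_s = 1:5,
                                 drug_period = c(4, 5))$block_fraction, 0)
  expect_equal(charge_timecourse(c(2, 2, 2, 0.4, 0.4), time_s = 1:5,
                                 drug_period = c(4, 5))$block_fraction, 0.8)
  tc <- charge_timecourse(c(2, 1, 2))
  expect_true(is.na(tc$block_fraction))
  expect_error(charge_timecourse(c(2, 2, 0), time_s = 1:3,
                                 drug_period = c(3, 3)), ">= 3")
})

test_that("failure classification never flags clear responses", {
  set.seed(14)
  k <- fast_kinetics()
  for (amp in c(15, 25, 60)) {   # >= 5x the 3 pA noise floor
    tr <- kernel_trace(52.5, amp, k, dur_ms = 200, noise_sd = 3,
                       stim_times = 50, protocol = "single")
    r <- measure_evoked_response(tr)
    expect_false(r$is_failure)
    expect_equal(r$amplitude, amp, tolerance = 0.25)
  }
  # no response at all -> failure
  tr0 <- sweep_trace(rnorm(2000, 0, 3), dt = 0.1, stim_times = 50,
                     protocol = "single")
  expect_true(measure_evoked_response(tr0)$is_failure)
})

test_that("overlap correction recovers the true paired-pulse ratio", {
  k <- event_kinetics(0.15, 0.75, 1.5, 10)
  # identical superposed responses at 10 ms: true ratio is exactly 1
  tr <- kernel_trace(c(50, 60), c(50, 50), k, dur_ms = 400,
                     stim_times = c(47.5, 57.5), protocol = "paired")
  pp <- paired_pulse_ratio(tr)
  expect_equal(pp$ppr, 1, tolerance = 0.01)

  # deterministic depletion without facilitation: PPR = 1 - p
  par <- plain_params(p_rel = 0.2, kernel = k)
  sim <- simulate_evoked(par, protocol_paired(10), engine = "deterministic")
  expect_equal(paired_pulse_ratio(sim$trace)$ppr, 0.8, tolerance = 0.01)

  # amplitude- and charge-based ratios agree on non-overlapping pairs
  sim2 <- simulate_evoked(plain_params(p_rel = 0.3), protocol_paired(100),
                          engine = "deterministic")
  pp2 <- paired_pulse_ratio(sim2$trace)
  expect_equal(pp2$ppr_charge / pp2$ppr, 1, tolerance = 0.05)

  # first-response failure flags the sweep
  set.seed(2)
  tr_fail <- kernel_trace(112.5, 60, k, dur_ms = 300, noise_sd = 3,
                          stim_times = c(50, 110), protocol = "paired")
  pf <- paired_pulse_ratio(tr_fail)
  expect_true(pf$first_failure)
  expect_true(is.na(pf$ppr))

  expect_error(paired_pulse_ratio(sim2$trace, isi = 10), "ISI")
  expect_error(paired_pulse_ratio(kernel_trace(60, 50, k, dur_ms = 200)),
               "2 stimuli")
})

test_that("preset cohorts show facilitation at the 10 ms interval", {
  for (cond in c("sham", "bbbd")) {
    par <- pool_preset(cond)
    pprs <- vapply(1:8, function(j) {
      sim <- simulate_evoked(par, protocol_paired(10),
                             seed = derive_seed(11, j))
      paired_pulse_ratio(sim$trace)$ppr
    }, numeric(1))
    expect_true(median(pprs) > 1)      # facilitating connection
  }
})
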