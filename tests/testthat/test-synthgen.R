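test_that("condition presets carry the calibrated study parameters", {
  sham <- pool_preset("sham")
  bbbd <- pool_preset("bbbd")
  expect_equal(sham$kernel$tau1, 1.52)
  expect_equal(bbbd$kernel$tau1, 1.11)
  expect_equal(sham$mini_rate, 20.25)
  expect_equal(bbbd$mini_rate, 12.15)
  for (p in list(sham, bbbd)) {
    expect_true(p$p_rel >= 0 && p$p_rel <= 1)
    expect_true(p$n_tight > 0 && p$n_max >= p$n_tight)
    expect_silent(gabapool:::validate_pool_model_params(p))
  }
  expect_error(pool_preset("naive"))
})

test_that("parameter validation catches out-of-range values", {
  expect_error(pool_model_params(p_rel = 1.2), "p_rel")
  expect_error(pool_model_params(n_tight = 100, n_max = 50), "n_max")
  expect_error(pool_model_params(q_charge = 0), "q_charge")
  expect_error(pool_model_params(tonic_fraction = 2), "tonic_fraction")
})

test_that("spontaneous generator is Poisson with the requested rate", {
  par <- pool_model_params(mini_rate = 0, noise_sd = 2)
  sim <- simulate_minis(par, duration_s = 2, seed = 1)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(sd(sim$trace$samples), 2, tolerance = 0.05)

  par5 <- pool_model_params(mini_rate = 5, noise_sd = 0,
                            kernel = fast_kinetics())
  counts <- vapply(1:100, function(s)
    nrow(simulate_minis(par5, duration_s = 10, dt = 0.1, seed = s)$truth),
    numeric(1))
  rate_hat <- mean(counts) / 10
  se <- sd(counts / 10) / sqrt(100)
  expect_lt(abs(rate_hat - 5), 2 * se + 1e-9)
})

test_that("generators are reproducible under a fixed seed", {
  par <- pool_preset("sham")
  a <- simulate_minis(par, duration_s = 2, seed = 42)
  b <- simulate_minis(par, duration_s = 2, seed = 42)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth, b$truth)

  e1 <- simulate_evoked(par, protocol_paired(10), seed = 9)
  e2 <- simulate_evoked(par, protocol_paired(10), seed = 9)
  expect_identical(e1$trace$samples, e2$trace$samples)

  expect_false(identical(
    simulate_minis(par, duration_s = 2, seed = 1)$trace$samples,
    simulate_minis(par, duration_s = 2, seed = 2)$trace$samples))

  # seed derivation is deterministic and in integer range
  expect_identical(derive_seed(1, 2, 3), derive_seed(1, 2, 3))
  expect_true(derive_seed(2147483646, 99, 99) < 2^31)
})

test_that("deterministic release follows the depletion closed forms", {
  prot <- 50 + (0:19) * 10

  # full release on the first pulse when p = 1
  par1 <- plain_params(p_rel = 1)
  rs <- release_sequence(par1, prot, engine = "deterministic")
  expect_equal(rs$released[1], 500)
  expect_equal(rs$released[-1], rep(0, 19))

  # geometric depletion: r_k / r_1 = (1 - p)^(k-1)
  par2 <- plain_params(p_rel = 0.5)
  rs2 <- release_sequence(par2, prot, engine = "deterministic")
  expect_equal(rs2$released / rs2$released[1], 0.5^(0:19), tolerance = 1e-10)

  # telescoping: cumulative released charge -> n_tight * q_charge
  expect_equal(sum(rs2$released) * par2$q_charge,
               par2$n_tight * par2$q_charge * (1 - 0.5^20), tolerance = 1e-9)

  # geometric decrease of per-pulse charges without facilitation/replenishment
  expect_true(all(diff(rs2$released) < 0))

  expect_error(release_sequence(par2, c(50, 40)), "sorted")
  expect_error(release_sequence(par2, numeric(0)), "nonempty")
})

test_that("pool occupancy stays within bounds in the stochastic engine", {
  par <- pool_model_params(n_tight = 50, p_rel = 0.4, q_charge = 0.14,
                           replenish_rate = 3000, n_max = 60,
                           facil_increment = 0.1, noise_sd = 0)
  prot <- 50 + (0:99) * 10
  for (s in 1:20) {
    rs <- with_seed_local(s, release_sequence(par, prot))
    expect_true(all(rs$n_before >= 0))
    expect_true(all(rs$n_before <= 60 + 1e-9))
    expect_true(all(rs$released <= rs$n_before))
  }
})

test_that("stochastic engine means match the deterministic engine", {
  par <- pool_model_params(n_tight = 200, p_rel = 0.3, q_charge = 0.14,
                           replenish_rate = 500, n_max = 400,
                           facil_increment = 0.1, facil_tau = 50,
                           noise_sd = 0)
  prot <- 50 + (0:9) * 10
  det <- release_sequence(par, prot, engine = "deterministic")
  set.seed(99)
  rel <- replicate(200, release_sequence(par, prot)$released)
  m <- rowMeans(rel)
  se <- apply(rel, 1, sd) / sqrt(200)
  expect_true(all(abs(m - det$released) <= 3 * se))
})

test_that("evoked traces carry the injected charge", {
  par <- plain_params(p_rel = 0.4)
  sim <- simulate_evoked(par, protocol_paired(100), engine = "deterministic")
  r1 <- sim$truth$released[1]
  q <- integrate_charge(sim$trace, c(50, 149), baseline = 0)$q
  expect_equal(q, r1 * par$q_charge, tolerance = 0.02)
})
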