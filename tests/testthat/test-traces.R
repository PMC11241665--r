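test_that("baseline estimation returns the window median", {
  tr <- sweep_trace(rep(-50, 200), dt = 0.1)
  expect_equal(estimate_baseline(tr, c(0, 10)), -50)

  # constant level plus one event outside the window
  s <- rep(-20, 1000)
  s[500:600] <- -120
  tr <- sweep_trace(s, dt = 0.1)
  expect_equal(estimate_baseline(tr, c(0, 20)), -20)

  # outlier robustness: median, not mean
  tr <- sweep_trace(c(rep(1, 5), rep(2, 5), rep(100, 5)), dt = 1)
  expect_equal(estimate_baseline(tr, c(0, 14)), 2)

  expect_error(estimate_baseline(tr, c(0, 50)), "outside")
  expect_error(estimate_baseline(sweep_trace(rep(0, 100), dt = 1), c(0, 3)),
               "at least")
})

test_that("artifact blanking interpolates linearly and is idempotent", {
  s <- rep(-10, 500)
  s[101:105] <- 200   # square artifact right after the stimulus
  tr <- sweep_trace(s, dt = 0.1, stim_times = 10, protocol = "single")

  expect_identical(blank_artifact(tr, 0)$samples, tr$samples)

  b <- blank_artifact(tr, 0.6)
  expect_equal(b$samples, rep(-10, 500), tolerance = 1e-12)
  expect_identical(tr$samples[103], 200)  # input unmodified

  # a ramp is reproduced exactly by linear interpolation
  ramp <- seq(0, 50, length.out = 501)
  tr2 <- sweep_trace(ramp, dt = 0.1, stim_times = 25, protocol = "single")
  expect_equal(blank_artifact(tr2, 1)$samples, ramp, tolerance = 1e-9)

  # idempotence
  b2 <- blank_artifact(b, 0.6)
  expect_identical(b2$samples, b$samples)
})

test_that("charge integration is rectified, additive and linear", {
  s <- c(rep(0, 100), rep(-100, 100), rep(0, 100))
  tr <- sweep_trace(s, dt = 0.1)
  q <- integrate_charge(tr, c(10, 19.9), baseline = 0)
  expect_equal(q$q, 1, tolerance = 1e-6)   # 100 pA x 10 ms = 1 pC

  expect_equal(integrate_charge(sweep_trace(rep(-5, 100), dt = 1),
                                c(0, 99), baseline = -5)$q, 0)

  # exponential decay: |A| * tau
  dt <- 0.01
  t <- seq(0, 40, dt)
  tr3 <- sweep_trace(-50 * exp(-t / 2), dt = dt)
  expect_equal(integrate_charge(tr3, c(0, 40), baseline = 0)$q, 0.1,
               tolerance = 0.01)

  # additivity over disjoint adjacent windows (single polarity, noise free)
  qa <- integrate_charge(tr3, c(0, 10), 0)$q
  qb <- integrate_charge(tr3, c(10 + dt, 40), 0)$q
  expect_equal(qa + qb, integrate_charge(tr3, c(0, 40), 0)$q,
               tolerance = 1e-9)

  # linear amplitude scaling
  tr4 <- sweep_trace(-150 * exp(-t / 2), dt = dt)
  expect_equal(integrate_charge(tr4, c(0, 40), 0)$q,
               3 * integrate_charge(tr3, c(0, 40), 0)$q, tolerance = 1e-9)

  # positive excursions do not cancel inward charge
  s5 <- c(rep(-100, 100), rep(100, 100))
  tr5 <- sweep_trace(s5, dt = 0.1)
  expect_equal(integrate_charge(tr5, c(0, 19.9), 0)$q, 1, tolerance = 1e-6)
})

test_that("trace validation enforces the protocol contracts", {
  expect_error(sweep_trace(c(1, NA, 3), dt = 0.1), "finite")
  expect_error(sweep_trace(1:100, dt = -1), "dt")
  expect_error(sweep_trace(1:100, dt = 0.1, stim_times = c(5, 3),
                           protocol = "paired"), "increasing")
  expect_error(sweep_trace(1:100, dt = 0.1, stim_times = 5,
                           protocol = "paired"), "inconsistent")
  expect_error(sweep_trace(1:100, dt = 0.1, stim_times = c(1, 2),
                           protocol = "minis"), "inconsistent")
  expect_error(sweep_trace(1:100, dt = 0.1, stim_times = 1e6,
                           protocol = "single"), "within")
})

test_that("tabular round trip is lossless over many random traces", {
  set.seed(11)
  tmp <- tempfile(fileext = ".txt")
  for (i in 1:1000) {
    n <- sample(20:80, 1)
    proto <- sample(c("minis", "single", "paired"), 1)
    dt <- runif(1, 0.05, 1)
    t0 <- runif(1, -5, 5)
    stim <- t0 + switch(proto, minis = numeric(0),
                        single = (n - 1) * dt * runif(1, 0.2, 0.8),
                        paired = sort((n - 1) * dt * runif(2, 0.1, 0.9)))
    tr <- sweep_trace(rnorm(n, -30, 20), dt = dt, t0 = t0,
                      stim_times = stim, cell_id = sprintf("c%03d", i),
                      condition = sample(c("sham", "bbbd", "unknown"), 1),
                      protocol = proto)
    write_trace(tr, tmp)
    tr2 <- read_trace(tmp)
    expect_identical(tr2$samples, tr$samples)
    expect_identical(tr2[c("dt", "t0", "stim_times", "cell_id", "condition",
                           "protocol", "holding_potential")],
                     tr[c("dt", "t0", "stim_times", "cell_id", "condition",
                          "protocol", "holding_potential")])
  }
})

test_that("container round trip preserves multiple sweeps", {
  tmp <- tempfile(fileext = ".json")
  set.seed(3)
  trs <- list(a = sweep_trace(rnorm(50), dt = 0.2, cell_id = "a"),
              b = sweep_trace(rnorm(80), dt = 0.1, stim_times = c(2, 4),
                              cell_id = "b", protocol = "paired"))
  write_trace(trs, tmp, format = "container")
  back <- read_trace(tmp, format = "container", sweep = "b")
  expect_equal(back$samples, trs$b$samples)
  expect_equal(back$stim_times, c(2, 4))
  first <- read_trace(tmp, format = "container")
  expect_equal(first$cell_id, "a")
})

test_that("malformed files produce informative parse errors", {
  tmp <- tempfile(fileext = ".txt")
  # non-monotone time column
  writeLines(c("# dt_ms=1", "time_ms\tcurrent_pA", "0\t1", "2\t1", "1\t1"), tmp)
  expect_error(read_trace(tmp), "increasing")
  # wrong field count
  writeLines(c("time_ms\tcurrent_pA", "0\t1\t9"), tmp)
  expect_error(read_trace(tmp), "row 1")
  # train without stimulus times
  writeLines(c("# dt_ms=1", "# protocol=train", "time_ms\tcurrent_pA",
               "0\t1", "1\t1"), tmp)
  expect_error(read_trace(tmp), "stim_times")
  expect_error(read_trace(tempfile()), "not found")
})
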