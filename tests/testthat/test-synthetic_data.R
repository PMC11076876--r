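test_that("every shipped reaction closes its element balances exactly", {
  rs <- reaction_set()
  reg <- compound_registry()
  rows <- reg[match(rownames(rs$stoich), reg$name), ]
  for (el in c("n_C", "n_H", "n_O", "n_N")) {
    expect_equal(unname(as.vector(rows[[el]] %*% rs$stoich)),
                 rep(0, ncol(rs$stoich)))
  }
  # a broken reaction is rejected
  bad <- default_reactions()
  bad$CE1$stoich["h2o"] <- 2
  expect_error(reaction_set(bad), "balance")
})

test_that("with no reactions the simulator reproduces the CSTR wash-in curve", {
  feed <- feed_definition()
  phases <- phase_schedule("P", 0, 20, 0, 0)
  sched <- rate_schedule("CE1", "P", 0)
  sim <- simulate_reactor(feed, phases, sched, init = "empty",
                          sample_every = 1)
  ts <- sim$timeseries
  tau <- 1 / 0.522           # V/Q with no base dosing
  for (cc in c("ethanol", "acetate", "n-butyrate")) {
    cf <- feed$composition[[cc]]
    pred <- cf * (1 - exp(-ts$broth$time / tau))
    expect_equal(ts$broth[[cc]], pred, tolerance = 1e-6)
  }
})

test_that("CE1-only run reaches the algebraic CSTR steady state", {
  feed <- feed_definition()
  phases <- phase_schedule("P", 0, 40, 0, 0)
  sched <- rate_schedule("CE1", "P", 10)
  sim <- simulate_reactor(feed, phases, sched, sample_every = 1)
  b <- sim$timeseries$broth
  qb <- utils::tail(sim$timeseries$scalars$base_flow, 1)
  expect_equal(qb, 10)       # 10 mmol acid/d neutralised by 1 M KOH
  q_out <- (522 + qb) / 1000
  # C_ss = (Q_f C_f + R V)/Q_out, in mmol/L, reported as mCmol
  expect_equal(utils::tail(b$acetate, 1),
               2 * (0.522 * 25 - 10) / q_out, tolerance = 1e-6)
  expect_equal(utils::tail(b[["n-butyrate"]], 1),
               4 * (0.522 * 150 + 10) / q_out, tolerance = 1e-6)
  # acetate drawn below feed, butyrate accumulated at the 1:1 ratio
  expect_lt(utils::tail(b$acetate, 1), 50)
  expect_gt(utils::tail(b[["n-butyrate"]], 1), 600)
})

test_that("homoacetogenesis consumes dosed CO2 in the gas balance", {
  feed <- feed_definition()
  phases <- phase_schedule("P", 0, 20, 6, 6)
  sched <- rate_schedule(c("EO", "HAC"), c("P", "P"), c(20, 8))
  sim <- simulate_reactor(feed, phases, sched, sample_every = 1)
  rr <- reactor_rates(sim$timeseries, feed)
  last <- nrow(rr$interval)
  expect_lt(rr$interval$co2_out_gas[last], rr$interval$co2_in[last])
  expect_equal(rr$interval$co2_utilization[last], 16, tolerance = 1e-6)
  expect_false(any(sim$truth$underpressure))
})

test_that("CO2 demand beyond supply is capped and flagged as underpressure", {
  feed <- feed_definition()
  phases <- phase_schedule("P", 0, 10, 0.1, 0)
  sched <- rate_schedule(c("EO", "HAC"), c("P", "P"), c(80, 30))
  sim <- simulate_reactor(feed, phases, sched)
  expect_true(all(sim$truth$underpressure))
  # effective HAC rate is capped at the CO2 supply (6.43 mmol/L/d / 2)
  supply <- gas_volume_to_moles(0.1 * 1440)
  expect_equal(unname(sim$truth$reaction_rates[1, "HAC"]), supply / 2,
               tolerance = 1e-9)
})

test_that("measurement noise is multiplicative, truncated and seeded", {
  sim <- simulate_preset("phaseI", noise_cv = 0)
  ts <- sim$timeseries
  expect_identical(apply_measurement_noise(ts, cv = 0), ts)
  n1 <- apply_measurement_noise(ts, cv = 0.05, seed = 99)
  n2 <- apply_measurement_noise(ts, cv = 0.05, seed = 99)
  expect_identical(n1, n2)
  expect_false(identical(n1$broth$ethanol, ts$broth$ethanol))
  # empirical CV over many replicate measurements of one true value
  flat <- make_series(1:1000, data.frame(ethanol = rep(500, 1000)))
  noisy <- apply_measurement_noise(flat, cv = 0.05, seed = 4)
  emp <- stats::sd(noisy$broth$ethanol) / mean(noisy$broth$ethanol)
  expect_equal(emp, 0.05, tolerance = 0.005 / 0.05)
  # duplicate analyses shrink the reported scatter by ~sqrt(2)
  dup <- apply_measurement_noise(flat, cv = 0.05, seed = 4, replicates = 2)
  expect_equal(stats::sd(dup$broth$ethanol) / mean(dup$broth$ethanol),
               0.05 / sqrt(2), tolerance = 0.1)
})

test_that("presets carry their documented ground truth", {
  expect_error(scenario_preset("phaseX"), "unknown preset")
  p1 <- simulate_preset("phaseI", noise_cv = 0)
  t1 <- true_phase_metrics(p1)
  expect_gte(t1$selectivity[["n-caproate"]], 95)
  expect_lte(t1$eeo, 0)
  for (nm in c(phaseII = 0.1, phaseIII_R2 = 0.5, phaseIV = 0)) NULL
  cfg <- c(phaseII = 0.1, phaseIII_R2 = 0.5, phaseIV = 0)
  for (nm in names(cfg)) {
    tp <- true_phase_metrics(simulate_preset(nm, noise_cv = 0))
    expect_equal(tp$eeo, 100 * cfg[[nm]], tolerance = 1e-6)
  }
  t4 <- true_phase_metrics(simulate_preset("phaseIV", noise_cv = 0))
  alc <- t4$alcohol_selectivity
  expect_gte(alc, 5); expect_lte(alc, 6)
})

test_that("a fixed seed gives byte-identical simulation output files", {
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_timeseries(simulate_preset("phaseII", seed = 5)$timeseries, f1)
  write_timeseries(simulate_preset("phaseII", seed = 5)$timeseries, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("logistic ingrowth profiles are honoured and infeasible profiles abort", {
  feed <- feed_definition()
  phases <- phase_schedule("P", 0, 30, 2, 0)
  sched <- rate_schedule("EO", "P", rate = 20, type = "logistic",
                         rate0 = 0, t_mid = 15, k_rate = 0.5)
  sim <- simulate_reactor(feed, phases, sched, sample_every = 1)
  r <- sim$truth$reaction_rates[, "EO"]
  expect_lt(r[2], 2)                    # early: barely any activity
  expect_gt(utils::tail(r, 1), 18)      # late: near the plateau
  expect_true(all(diff(r) >= -1e-9))    # monotone ingrowth
  # a rate profile that would drive acetate negative aborts with a diagnostic
  bad <- rate_schedule("CE1", "P", 60)
  expect_error(simulate_reactor(feed, phases, bad), "infeasible")
})
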