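test_that("Cmol%% selectivity divides product carbon by total formed carbon", {
  expect_equal(product_selectivity(c("n-caproate" = 300)),
               c("n-caproate" = 100))
  s <- product_selectivity(c("n-caproate" = 480, butanol = 10, hexanol = 10))
  expect_equal(unname(s["n-caproate"]), 96)
  s <- product_selectivity(c("n-caproate" = 291, "i-butyrate" = 3,
                             butanol = 2, hexanol = 4))
  expect_equal(unname(s["n-caproate"]), 97)
  # substrates (negative) and the fed donor never appear
  s <- product_selectivity(c(ethanol = 50, "n-butyrate" = -40,
                             "n-caproate" = 200))
  expect_false(any(c("ethanol", "n-butyrate") %in% names(s)))
  expect_warning(out <- product_selectivity(c("n-caproate" = -10,
                                              ethanol = -5)),
                 "undefined")
  expect_length(out, 0)
})

test_that("selectivity is scale invariant and sums to 100", {
  set.seed(7)
  for (i in 1:25) {
    r <- stats::setNames(stats::rnorm(4, 50, 60),
                         c("acetate", "n-caproate", "butanol", "hexanol"))
    if (all(r <= 0)) next
    s1 <- suppressWarnings(product_selectivity(r))
    if (!length(s1)) next
    expect_equal(sum(s1), 100)
    expect_equal(s1, suppressWarnings(product_selectivity(r * 3.7)))
  }
})

test_that("EEO implements the 1-per-5-elongations excess formula", {
  # E_cons = 1.2 S: exactly the assumed stoichiometry -> 0
  r0 <- c(ethanol = -24, "n-butyrate" = -40, "n-caproate" = 60)
  expect_equal(excessive_ethanol_oxidation(r0)$eeo, 0)
  # E_cons 12, S 5 -> 100*(12-5-1)/12 = 50
  r1 <- c(ethanol = -24, "n-butyrate" = -20, "n-caproate" = 30)
  out <- excessive_ethanol_oxidation(r1)
  expect_equal(out$eeo, 50)
  expect_equal(unname(out$allocation),
               c(5, 1, 0, 6))   # elongation, expected, reduction, excess
  expect_equal(sum(out$allocation), out$ethanol_consumption)
  expect_equal(out$allocation_cmol, 2 * out$allocation)
  # E_cons 5.5, S 5 -> negative regime
  r2 <- c(ethanol = -11, "n-butyrate" = -20, "n-caproate" = 30)
  expect_equal(excessive_ethanol_oxidation(r2)$eeo, 100 * (5.5 - 6) / 5.5)
  # ethanol not consumed -> undefined with warning
  expect_warning(out <- excessive_ethanol_oxidation(c(ethanol = 5)),
                 "undefined")
  expect_true(is.na(out$eeo))
})

test_that("EEO step accounting routes acceptors and alcohols correctly", {
  # C6 formed beyond available C4 uptake is attributed to acetate (2 steps):
  # C4 consumed 2, C6 produced 5 -> S = 2*1 + 3*2 = 8
  r <- c(ethanol = -40, "n-butyrate" = -8, "n-caproate" = 30)
  out <- excessive_ethanol_oxidation(r)
  expect_equal(unname(out$allocation["elongation"]), 8)
  # net C4 production counts one step per mol
  r <- c(ethanol = -40, "n-butyrate" = 20, "n-caproate" = 30)
  expect_equal(
    unname(excessive_ethanol_oxidation(r)$allocation["elongation"]),
    5 + 2 * 5)
  # alcohols count as their precursor acid plus one reduction ethanol
  r <- c(ethanol = -40, "n-butyrate" = -24, "n-caproate" = 30, hexanol = 6)
  out <- excessive_ethanol_oxidation(r)
  expect_equal(unname(out$allocation["elongation"]), 6)
  expect_equal(unname(out$allocation["reduction_exchange"]), 1)
  # isobutyrate: isomerisation by default, one step if configured
  r <- c(ethanol = -40, "n-butyrate" = -14, "n-caproate" = 30,
         "i-butyrate" = 8)
  expect_equal(
    unname(excessive_ethanol_oxidation(r)$allocation["elongation"]), 6.5)
  expect_equal(
    unname(excessive_ethanol_oxidation(r, isomer_steps = 1)$
             allocation["elongation"]), 8.5)
})

test_that("balances close at 100% on noiseless simulations of any reaction subset", {
  feed <- feed_definition()
  phases <- phase_schedule("P", 0, 30, 2, 2)
  subsets <- list(
    c(CE1 = 5, CE2 = 30),
    c(CE2 = 30, EO = 10),
    c(EO = 20, HAC = 8),
    c(CE1 = 5, CE2 = 30, EO = 10, HAC = 4, REDX4 = 1, REDX6 = 1, ISO = 1))
  for (rates in subsets) {
    sched <- rate_schedule(names(rates), "P", unname(rates))
    sim <- simulate_reactor(feed, phases, sched)
    m <- reactor_metrics(sim$timeseries, feed, n_last = 5)
    expect_equal(m$phase_summary$carbon_balance_pct, 100, tolerance = 0.5 / 100)
    expect_equal(m$phase_summary$electron_balance_pct, 100,
                 tolerance = 0.5 / 100)
  }
})

test_that("untracked carbon sinks open the carbon balance", {
  # divert ~5% of feed carbon into (unmeasured) biomass:
  # EtOH + 0.4 NH3 -> 2 CH1.8O0.5N0.2 + 1.8 H2 closes CHON exactly
  rxns <- default_reactions()
  rxns$GROWTH <- list(stoich = c(ethanol = -1, nh3 = -0.4, biomass = 2,
                                 h2 = 1.8), steps = 0)
  feed <- feed_definition()
  phases <- phase_schedule("P", 0, 30, 0, 0)
  sched <- rate_schedule(c("CE2", "GROWTH"), "P", c(30, 24))
  sim <- simulate_reactor(feed, phases, sched, reactions = reaction_set(rxns))
  m <- reactor_metrics(sim$timeseries, feed, n_last = 5)
  # feed carbon 1850 mCM * 0.522 L/d; 48 mCmol/L/d diverted -> ~95%
  expect_equal(m$phase_summary$carbon_balance_pct, 95, tolerance = 1 / 95)
  # the biomass H2 is seen, so electrons close better than carbon
  expect_gt(m$phase_summary$electron_balance_pct,
            m$phase_summary$carbon_balance_pct)
})

test_that("zeroing the H2 measurement opens the electron balance only", {
  feed <- feed_definition()
  phases <- phase_schedule("P", 0, 30, 2, 2)
  sched <- rate_schedule(c("CE2", "EO"), "P", c(30, 15))
  sim <- simulate_reactor(feed, phases, sched)
  ts <- sim$timeseries
  ts$headspace$h2 <- 0
  m <- reactor_metrics(ts, feed, n_last = 5)
  expect_lt(m$phase_summary$electron_balance_pct, 99.5)
  expect_equal(m$phase_summary$carbon_balance_pct, 100, tolerance = 0.5 / 100)
})

test_that("phase averaging takes the mean of the trailing records", {
  df <- data.frame(phase = rep("IV", 6), time = 1:6, eeo = c(9, 9, 9, 1, 2, 3))
  expect_equal(phase_average(df, "IV", 3)$eeo, 2)
  expect_equal(phase_average(df, "IV", 1)$eeo, 3)
  const <- data.frame(phase = "I", time = 1:4, eeo = 5)
  expect_equal(phase_average(const, "I", 4)$eeo, 5)
  expect_warning(out <- phase_average(df, "IV", 10), "only")
  expect_equal(out$n_used, 6)
  expect_error(phase_average(df, "VII", 2), "no records")
})
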