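test_that("tidy CSV fixture reads into a validated series", {
  f <- write_tidy_fixture(tempfile(fileext = ".csv"))
  ts <- read_timeseries(f)
  expect_s3_class(ts, "reactor_timeseries")
  expect_equal(nrow(ts$broth), 3)
  expect_equal(sort(setdiff(names(ts$broth), "time")),
               sort(c("ethanol", "acetate", "n-butyrate", "n-caproate",
                      "hexanol")))
  expect_equal(ts$scalars$feed_flow, rep(522, 3))
})

test_that("broth units are normalised through the registry", {
  # 1 g/L ethanol = 1000/46.069 mmol * 2 C = 43.41 mCmol/L
  f <- write_tidy_fixture(tempfile(fileext = ".csv"), compounds = "EtOH",
                          units = "g/L", value = 1)
  ts <- read_timeseries(f)
  expect_equal(ts$broth$ethanol, rep(1000 / 46.069 * 2, 3), tolerance = 1e-6)
  # mM converts with the carbon number, synonym collapses to registry name
  f2 <- write_tidy_fixture(tempfile(fileext = ".csv"), compounds = "n-C6",
                           units = "mM", value = 10)
  expect_equal(read_timeseries(f2)$broth[["n-caproate"]], rep(60, 3))
})

test_that("reader rejects malformed input naming the offender", {
  f <- write_tidy_fixture(tempfile(fileext = ".csv"), compounds = "kryptonite")
  expect_error(read_timeseries(f), "kryptonite")
  f <- write_tidy_fixture(tempfile(fileext = ".csv"), units = "furlongs")
  expect_error(read_timeseries(f), "furlongs")
  f <- write_tidy_fixture(tempfile(fileext = ".csv"), value = -5)
  expect_error(read_timeseries(f), "negative")
  f <- write_tidy_fixture(tempfile(fileext = ".csv"), times = c(0, 2, 2))
  expect_error(read_timeseries(f), "increasing")
})

test_that("write/read round trip is lossless at full float precision", {
  sim <- simulate_preset("phaseII", seed = 11)
  ts <- sim$timeseries
  f <- tempfile(fileext = ".csv")
  write_timeseries(ts, f)
  back <- read_timeseries(f, volume = ts$volume, reactor_id = ts$reactor_id)
  for (cc in setdiff(names(ts$broth), "time")) {
    expect_identical(back$broth[[cc]], ts$broth[[cc]])
  }
  expect_identical(back$headspace$co2, ts$headspace$co2)
  expect_identical(back$scalars$gas_out_flow, ts$scalars$gas_out_flow)
  # idempotence: another round trip reproduces the same file byte for byte
  f2 <- tempfile(fileext = ".csv")
  write_timeseries(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("phase assignment follows the half-open convention", {
  ts <- make_series(c(30, 40, 57, 100),
                    data.frame(ethanol = c(1, 1, 1, 1)))
  ts <- assign_phases(ts, default_phases())
  expect_equal(ts$scalars$phase, c("I", "II", "III", "IV"))
  # boundary sample (day 57) went to the later phase III
  expect_error(assign_phases(make_series(c(200), data.frame(ethanol = 1)),
                             default_phases()), "not covered")
  expect_error(assign_phases(ts, NULL), "empty")
  expect_error(phase_schedule(character(0), numeric(0), numeric(0),
                              numeric(0)), "empty")
  expect_error(phase_schedule(c("A", "B"), c(0, 5), c(10, 15), c(0, 0)),
               "overlap")
})

test_that("series invariants are enforced", {
  expect_error(make_series(c(0, 1), data.frame(ethanol = c(-1, 1))),
               "negative")
  expect_error(make_series(c(0, 1), data.frame(ethanol = c(1, 1)),
                           headspace = list(co2 = c(0.9, 0.9),
                                            n2 = c(0.2, 0.2))),
               "1.02")
  expect_error(make_series(c(0, 1), data.frame(ethanol = c(1, 1)),
                           volume = 0), "positive")
})
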