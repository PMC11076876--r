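# in-code fixtures: small handmade reactor series and tidy CSV files

# minimal series with constant flows/pH and zero gas unless overridden
make_series <- function(time, broth, feed_flow = 522, base_flow = 0,
                        gas_out_flow = 0, co2_load = 0, n2_load = 0,
                        headspace = NULL, ph = 6.5, volume = 1,
                        reactor_id = "fixture") {
  n <- length(time)
  hs <- data.frame(time = time, co2 = 0, h2 = 0, n2 = 0, ch4 = 0, o2 = 0)
  if (!is.null(headspace)) for (nm in names(headspace)) hs[[nm]] <- headspace[[nm]]
  reactor_timeseries(
    broth = cbind(data.frame(time = time), broth),
    scalars = data.frame(time = time, gas_out_flow = gas_out_flow,
                         feed_flow = feed_flow, base_flow = base_flow,
                         base_molarity = 1, ph = ph, temperature = 35),
    gas_in = data.frame(time = time, co2 = co2_load, n2 = n2_load),
    headspace = hs, volume = volume, reactor_id = reactor_id)
}

# tidy long CSV rows for a handful of broth measurements
write_tidy_fixture <- function(path, times = c(0, 2, 4),
                               compounds = c("ethanol", "acetate",
                                             "n-butyrate", "n-caproate",
                                             "hexanol"),
                               units = "mCmol/L", value = 100) {
  rows <- expand.grid(time = times, species = compounds,
                      stringsAsFactors = FALSE)
  rows$variable <- "broth"
  rows$value <- value
  rows$unit <- units
  scal <- expand.grid(time = times,
                      variable = c("feed_flow", "base_flow", "gas_out_flow",
                                   "ph", "temperature"),
                      stringsAsFactors = FALSE)
  scal$species <- ""
  scal$value <- c(522, 0, 0, 6.5, 35)[match(scal$variable,
                                            c("feed_flow", "base_flow",
                                              "gas_out_flow", "ph",
                                              "temperature"))]
  scal$unit <- c(feed_flow = "mL/d", base_flow = "mL/d",
                 gas_out_flow = "NmL/min", ph = "", temperature = "C")[
                   scal$variable]
  out <- rbind(rows[c("time", "variable", "species", "value", "unit")],
               scal[c("time", "variable", "species", "value", "unit")])
  utils::write.csv(out, path, row.names = FALSE)
  path
}
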