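# Per-interval volumetric conversion rates and gas-phase CO2/H2 accounting.
#
# The reactor is treated as a constant-volume overflow CSTR: the effluent
# flow equals feed plus base flow, the base stream carries no carbon, and
# each measurement interval (t_prev, t] yields one rates record attached to
# its right endpoint.

#' Hydraulic retention time
#'
#' `HRT = V / (Q_feed + Q_base)`, in hours. Base dosing for pH control adds
#' to the effluent flow of an overflow reactor, so it shortens the HRT.
#'
#' @param volume working volume, L.
#' @param feed_flow feed flow, mL/d.
#' @param base_flow base (lye) flow, mL/d.
#' @return HRT in hours.
#' @examples
#' hydraulic_retention_time(1, 522, 39) # ~42.8 h
#' @export
hydraulic_retention_time <- function(volume, feed_flow, base_flow = 0) {
  total <- feed_flow + base_flow
  if (any(total <= 0)) {
    stop("total liquid flow must be positive; HRT is undefined in batch mode",
         call. = FALSE)
  }
  24 * 1000 * volume / total
}

#' Dissolved inorganic carbon leaving with the effluent
#'
#' Assumes gas-liquid equilibrium between the measured headspace CO2
#' partial pressure and the broth (no mass-transfer kinetics):
#' `DIC = KH * pCO2 * (1 + 10^(pH - pKa1))` mol/L, where the parenthesis
#' adds bicarbonate; set `speciation = FALSE` to count free CO2(aq) only.
#' The defaults `kh = 0.026` mol/L/atm and `pka1 = 6.31` are values for
#' 35 degC and are configurable.
#'
#' @param ph broth pH. Values outside \[3, 9\] trigger a validity warning.
#' @param headspace_co2_fraction CO2 mole fraction in the off-gas.
#' @param total_pressure headspace pressure, atm.
#' @param effluent_flow liquid outflow, mL/d.
#' @param volume working volume, L.
#' @param temperature broth temperature, deg C (documentation of the
#'   constants' validity; not used in the computation).
#' @param kh Henry constant for CO2, mol/L/atm.
#' @param pka1 first dissociation pKa of carbonic acid.
#' @param speciation include bicarbonate (default) or free CO2 only.
#' @return Dissolved CO2 leaving in the effluent, mCmol L^-1 d^-1.
#' @export
dissolved_co2_effluent <- function(ph, headspace_co2_fraction,
                                   effluent_flow, volume = 1,
                                   total_pressure = 1, temperature = 35,
                                   kh = 0.026, pka1 = 6.31,
                                   speciation = TRUE) {
  if (any(headspace_co2_fraction < 0 | headspace_co2_fraction > 1)) {
    stop("headspace CO2 fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(ph < 3 | ph > 9)) {
    warning("pH outside [3, 9]; the equilibrium speciation model was not ",
            "meant for that range", call. = FALSE)
  }
  spec <- if (speciation) 1 + 10^(ph - pka1) else 1
  pco2 <- total_pressure * headspace_co2_fraction
  kh * pco2 * spec * (effluent_flow / 1000 / volume) * 1000
}

#' CO2 utilisation from the gas-phase balance
#'
#' Difference between dosed CO2 and outgoing CO2 (gaseous plus dissolved in
#' the effluent), all in mCmol per L reactor per day. Positive values mean
#' net CO2 consumption; without dosing, fermentative CO2 production shows
#' up as a negative utilisation.
#'
#' @param gas_in_co2 CO2 dosing, NmL L^-1 min^-1.
#' @param gas_out_flow off-gas flow, NmL/min.
#' @param headspace_co2_fraction CO2 mole fraction in the off-gas.
#' @param dissolved_out dissolved CO2 leaving with the effluent,
#'   mCmol L^-1 d^-1 (see [dissolved_co2_effluent()]).
#' @param volume working volume, L.
#' @param molar_volume NmL/mmol at the gas reference conditions.
#' @return CO2 utilisation, mCmol L^-1 d^-1.
#' @export
co2_utilization <- function(gas_in_co2, gas_out_flow, headspace_co2_fraction,
                            dissolved_out = 0, volume = 1,
                            molar_volume = .MOLAR_VOLUME_NORMAL) {
  if (any(headspace_co2_fraction > 1)) {
    stop("headspace CO2 fraction cannot exceed 1", call. = FALSE)
  }
  if (any(c(gas_in_co2, gas_out_flow, headspace_co2_fraction, dissolved_out) < 0)) {
    stop("co2_utilization() inputs must be non-negative", call. = FALSE)
  }
  co2_in <- gas_volume_to_moles(gas_in_co2 * 1440, molar_volume)
  co2_out <- gas_volume_to_moles(gas_out_flow * headspace_co2_fraction * 1440,
                                 molar_volume) / volume
  co2_in - co2_out - dissolved_out
}

#' H2 leaving in the off-gas
#'
#' @param gas_out_flow off-gas flow, NmL/min.
#' @param headspace_h2_fraction H2 mole fraction in the off-gas.
#' @param volume working volume, L.
#' @param molar_volume NmL/mmol at the gas reference conditions.
#' @return H2 output, mmol L^-1 d^-1.
#' @examples
#' h2_output(10, 0.05) # ~32.1 mmol/L/d
#' @export
h2_output <- function(gas_out_flow, headspace_h2_fraction, volume = 1,
                      molar_volume = .MOLAR_VOLUME_NORMAL) {
  if (any(c(gas_out_flow, headspace_h2_fraction) < 0)) {
    stop("h2_output() inputs must be non-negative", call. = FALSE)
  }
  gas_volume_to_moles(gas_out_flow * headspace_h2_fraction * 1440,
                      molar_volume) / volume
}

# interval-mean of a sampled signal: midpoint (trapezoid) or right endpoint
.interval_mean <- function(x, method) {
  n <- length(x)
  if (method == "midpoint") (x[-n] + x[-1]) / 2 else x[-1]
}

#' Per-compound liquid conversion rates over each measurement interval
#'
#' For every interval between consecutive samples the net volumetric
#' conversion rate of compound i is
#' `r_i = (C_i * Q_out - C_feed,i * Q_feed) / V + dC_i/dt`
#' in mCmol L^-1 d^-1 (positive = production): the flow-through difference
#' plus the accumulation term, since the reactors are frequently not at
#' steady state. `Q_out = Q_feed + Q_base` (constant-volume overflow; the
#' base stream carries no carbon). With `method = "midpoint"` (default) the
#' outflow term uses the interval-mean concentration and flows
#' (second-order accurate); `"endpoint"` uses the right endpoint.
#' Set `accumulation = FALSE` for the pure flow-through estimate.
#'
#' @param ts a [reactor_timeseries()] with at least two samples.
#' @param feed a [feed_definition()].
#' @param method interval-averaging rule for concentrations and flows.
#' @param accumulation include the `dC/dt` term (default `TRUE`).
#' @param registry a [compound_registry()].
#' @return A list with `time` (interval right endpoints), `t_prev`, and
#'   `rates`, an intervals x compounds matrix in mCmol L^-1 d^-1 covering
#'   the union of broth and feed compounds, plus `influx`, the feed carbon
#'   influx matrix `C_feed,i * Q_feed / V` on the same shape.
#' @export
liquid_conversion_rates <- function(ts, feed, method = c("midpoint", "endpoint"),
                                    accumulation = TRUE,
                                    registry = compound_registry()) {
  method <- match.arg(method)
  times <- ts$broth$time
  n <- length(times)
  if (n < 2) stop("need at least two samples to form an interval", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("sample times must be strictly increasing", call. = FALSE)

  comps <- union(setdiff(names(ts$broth), "time"), names(feed$composition))
  conc <- matrix(0, n, length(comps), dimnames = list(NULL, comps))
  for (cc in intersect(comps, names(ts$broth))) conc[, cc] <- ts$broth[[cc]]
  cfeed <- stats::setNames(numeric(length(comps)), comps)
  cfeed[names(feed$composition)] <- feed$composition

  qf <- .interval_mean(ts$scalars$feed_flow, method) / 1000    # L/d
  qb <- .interval_mean(ts$scalars$base_flow, method) / 1000
  qout <- qf + qb
  cbar <- apply(conc, 2, .interval_mean, method = method)
  if (n == 2) cbar <- matrix(cbar, nrow = 1, dimnames = list(NULL, comps))
  dcdt <- apply(conc, 2, diff) / dt
  if (n == 2) dcdt <- matrix(dcdt, nrow = 1, dimnames = list(NULL, comps))

  influx <- outer(qf / ts$volume, cfeed)
  rates <- cbar * (qout / ts$volume) - influx
  if (accumulation) rates <- rates + dcdt
  colnames(rates) <- colnames(influx) <- comps
  list(time = times[-1], t_prev = times[-n], rates = rates, influx = influx)
}

#' Full per-interval rates record: liquid rates, gas balances, HRT
#'
#' Combines [liquid_conversion_rates()] with the gas-phase bookkeeping:
#' dosed CO2, gaseous and dissolved CO2 leaving, the CO2 utilisation
#' identity `in - out_gas - out_dissolved`, H2 and CH4 output, and the
#' hydraulic retention time, one record per measurement interval (attached
#' to its right endpoint).
#'
#' @inheritParams liquid_conversion_rates
#' @param kh,pka1,total_pressure,speciation dissolved-CO2 model constants,
#'   see [dissolved_co2_effluent()].
#' @param molar_volume NmL/mmol at the gas reference conditions.
#' @return An object of class `ce_rates`: list with `interval` (data frame:
#'   `t_prev`, `time`, `phase` if assigned, flows, `hrt_h`, `co2_in`,
#'   `co2_out_gas`, `co2_out_dissolved`, `co2_utilization`, `h2_out`,
#'   `ch4_out`), the `rates` and `influx` matrices, and the analysis
#'   constants used.
#' @export
reactor_rates <- function(ts, feed, method = c("midpoint", "endpoint"),
                          accumulation = TRUE,
                          kh = 0.026, pka1 = 6.31, total_pressure = 1,
                          speciation = TRUE,
                          molar_volume = .MOLAR_VOLUME_NORMAL,
                          registry = compound_registry()) {
  method <- match.arg(method)
  lr <- liquid_conversion_rates(ts, feed, method, accumulation, registry)

  qf <- .interval_mean(ts$scalars$feed_flow, method)   # mL/d
  qb <- .interval_mean(ts$scalars$base_flow, method)
  gas_out <- .interval_mean(ts$scalars$gas_out_flow, method)
  ph <- .interval_mean(ts$scalars$ph, method)
  y_co2 <- .interval_mean(ts$headspace$co2, method)
  y_h2 <- .interval_mean(ts$headspace$h2, method)
  y_ch4 <- .interval_mean(ts$headspace$ch4, method)
  co2_load <- .interval_mean(ts$gas_in$co2, method)

  co2_in <- gas_volume_to_moles(co2_load * 1440, molar_volume)
  co2_out_gas <- gas_volume_to_moles(gas_out * y_co2 * 1440, molar_volume) /
    ts$volume
  co2_diss <- dissolved_co2_effluent(
    ph = ph, headspace_co2_fraction = y_co2, effluent_flow = qf + qb,
    volume = ts$volume, total_pressure = total_pressure, kh = kh,
    pka1 = pka1, speciation = speciation)
  h2 <- h2_output(gas_out, y_h2, ts$volume, molar_volume)
  ch4 <- gas_volume_to_moles(gas_out * y_ch4 * 1440, molar_volume) / ts$volume

  interval <- data.frame(
    t_prev = lr$t_prev, time = lr$time,
    q_feed = qf, q_base = qb, q_out = qf + qb,
    hrt_h = hydraulic_retention_time(ts$volume, qf, qb),
    co2_in = co2_in, co2_out_gas = co2_out_gas,
    co2_out_dissolved = co2_diss,
    co2_utilization = co2_in - co2_out_gas - co2_diss,
    h2_out = h2, ch4_out = ch4)
  if (!is.null(ts$scalars$phase)) {
    interval$phase <- ts$scalars$phase[-1]  # right-endpoint convention
  }
  structure(list(interval = interval, rates = lr$rates, influx = lr$influx,
                 feed = feed, volume = ts$volume, reactor_id = ts$reactor_id,
                 method = method,
                 constants = list(kh = kh, pka1 = pka1,
                                  total_pressure = total_pressure,
                                  speciation = speciation,
                                  molar_volume = molar_volume)),
            class = "ce_rates")
}

#' @export
print.ce_rates <- function(x, ...) {
  cat("Conversion rates for reactor '", x$reactor_id, "': ",
      nrow(x$interval), " intervals, ", ncol(x$rates), " compounds\n", sep = "")
  cat(sprintf("  mean HRT %.1f h; CO2 utilisation %.3g to %.3g mCmol/L/d\n",
              mean(x$interval$hrt_h), min(x$interval$co2_utilization),
              max(x$interval$co2_utilization)))
  invisible(x)
}

#' Export a rates record as a tidy data frame / CSV
#'
#' One row per interval x compound with the gas and HRT columns repeated,
#' units spelled out in the column names.
#'
#' @param rr a [reactor_rates()] record.
#' @param path optional CSV path; when given the table is also written.
#' @return The tidy data frame, invisibly when `path` is given.
#' @export
rates_table <- function(rr, path = NULL) {
  k <- nrow(rr$interval)
  comps <- colnames(rr$rates)
  out <- data.frame(
    reactor = rr$reactor_id,
    rr$interval[rep(seq_len(k), each = length(comps)),
                c("t_prev", "time", if ("phase" %in% names(rr$interval)) "phase",
                  "hrt_h", "co2_in", "co2_out_gas", "co2_out_dissolved",
                  "co2_utilization", "h2_out")],
    compound = rep(comps, times = k),
    rate_mCmol_L_d = as.vector(t(rr$rates)),
    row.names = NULL)
  names(out)[names(out) == "hrt_h"] <- "hrt_h"
  names(out)[names(out) == "co2_in"] <- "co2_in_mCmol_L_d"
  names(out)[names(out) == "co2_out_gas"] <- "co2_out_gas_mCmol_L_d"
  names(out)[names(out) == "co2_out_dissolved"] <- "co2_out_dissolved_mCmol_L_d"
  names(out)[names(out) == "co2_utilization"] <- "co2_utilization_mCmol_L_d"
  names(out)[names(out) == "h2_out"] <- "h2_out_mmol_L_d"
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
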