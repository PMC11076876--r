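# Reactor time-series container, tidy-CSV reader/writer, feed and phase
# definitions.

.SCALAR_VARS <- c("gas_out_flow", "feed_flow", "base_flow", "base_molarity",
                  "ph", "temperature")
.HEADSPACE_SPECIES <- c("co2", "h2", "n2", "ch4", "o2")

#' Reactor time series
#'
#' Container for the measurements taken at each reactor check-up: broth
#' concentrations of acids and alcohols (mCmol/L), gas dosing set-points
#' (NmL per L reactor per min), off-gas flow (NmL/min) and headspace mole
#' fractions, feed and base flows (mL/d), base molarity, pH and temperature.
#'
#' @param broth data frame with a `time` column (days) and one column per
#'   compound, concentrations in mCmol/L.
#' @param scalars data frame with columns `time`, `gas_out_flow` (NmL/min),
#'   `feed_flow`, `base_flow` (mL/d), `base_molarity` (mol/L), `ph`,
#'   `temperature` (deg C). Must share `broth`'s time grid.
#' @param gas_in data frame `time`, `co2`, `n2` dosing loads in
#'   NmL L^-1 min^-1.
#' @param headspace data frame `time` plus mole fractions for
#'   `co2, h2, n2, ch4, o2`.
#' @param volume working volume in L (carrier included).
#' @param reactor_id identifier used in reports.
#' @return An object of class `reactor_timeseries`.
#' @export
reactor_timeseries <- function(broth, scalars, gas_in, headspace,
                               volume = 1, reactor_id = "R1") {
  ts <- structure(
    list(reactor_id = reactor_id, volume = volume,
         broth = as.data.frame(broth), scalars = as.data.frame(scalars),
         gas_in = as.data.frame(gas_in), headspace = as.data.frame(headspace)),
    class = "reactor_timeseries")
  validate_timeseries(ts)
}

#' Validate a reactor time series
#'
#' Checks the container invariants: strictly increasing sample times shared
#' by all measurement blocks, non-negative concentrations and loads,
#' headspace mole fractions within \[0, 1\] summing to at most 1.02
#' (measurement tolerance), and a positive working volume.
#'
#' @param ts a [reactor_timeseries()].
#' @return `ts`, invisibly classed, after passing all checks.
#' @export
validate_timeseries <- function(ts) {
  t0 <- ts$broth$time
  if (length(t0) < 1) stop("time series contains no samples", call. = FALSE)
  if (any(diff(t0) <= 0)) {
    stop("sample times must be strictly increasing; offending index(es): ",
         paste(which(diff(t0) <= 0) + 1, collapse = ", "), call. = FALSE)
  }
  for (blk in c("scalars", "gas_in", "headspace")) {
    if (!isTRUE(all.equal(ts[[blk]]$time, t0))) {
      stop("'", blk, "' block is not on the same time grid as 'broth'",
           call. = FALSE)
    }
  }
  conc <- as.matrix(ts$broth[setdiff(names(ts$broth), "time")])
  if (any(conc < 0, na.rm = TRUE)) {
    bad <- which(conc < 0, arr.ind = TRUE)
    stop("negative broth concentration(s): ",
         paste(unique(colnames(conc)[bad[, 2]]), collapse = ", "),
         " at time(s) ", paste(unique(t0[bad[, 1]]), collapse = ", "),
         call. = FALSE)
  }
  hs <- as.matrix(ts$headspace[setdiff(names(ts$headspace), "time")])
  if (any(hs < 0 | hs > 1, na.rm = TRUE)) {
    stop("headspace mole fractions must lie in [0, 1]", call. = FALSE)
  }
  if (any(rowSums(hs, na.rm = TRUE) > 1.02)) {
    stop("headspace mole fractions sum to more than 1.02 at time(s) ",
         paste(t0[rowSums(hs, na.rm = TRUE) > 1.02], collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(ts$volume) || length(ts$volume) != 1 || ts$volume <= 0) {
    stop("working volume must be a single positive number (L)", call. = FALSE)
  }
  invisible(ts)
}

#' @export
print.reactor_timeseries <- function(x, ...) {
  comps <- setdiff(names(x$broth), "time")
  cat("Reactor time series '", x$reactor_id, "'\n", sep = "")
  cat(sprintf("  %d samples over days %.4g-%.4g, working volume %g L\n",
              nrow(x$broth), min(x$broth$time), max(x$broth$time), x$volume))
  cat("  broth compounds:", paste(comps, collapse = ", "), "\n")
  if (!is.null(x$scalars$phase)) {
    cat("  phases:", paste(unique(x$scalars$phase), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.reactor_timeseries <- function(x, compounds = NULL, ...) {
  comps <- setdiff(names(x$broth), "time")
  if (!is.null(compounds)) comps <- intersect(comps, compounds)
  m <- as.matrix(x$broth[comps])
  graphics::matplot(x$broth$time, m, type = "l", lty = 1,
                    xlab = "time (d)", ylab = "broth concentration (mCmol/L)",
                    ...)
  graphics::legend("topright", legend = comps, col = seq_along(comps),
                   lty = 1, cex = 0.8, bty = "n")
  invisible(x)
}

# convert one (value, unit) pair to the canonical unit for its variable.
# broth -> mCmol/L; gas_in -> NmL/L/min; fractions accepted as "%" too.
.normalise_value <- function(value, unit, variable, species, registry) {
  u <- tolower(gsub("\\s", "", unit))
  if (variable == "broth") {
    row <- .compound_row(species, registry)
    switch(u,
      "mcmol/l" = , "mcm" = , "mmc" = value,
      "mmol/l" = , "mm" = value * row$n_C,
      "g/l" = value * 1000 / row$molar_mass * row$n_C,
      "mg/l" = value / row$molar_mass * row$n_C,
      stop("unparseable unit '", unit, "' for broth compound '", species, "'",
           call. = FALSE))
  } else if (variable == "gas_in") {
    switch(u,
      "nml/l/min" = , "nml/lreactor/min" = value,
      stop("unparseable unit '", unit, "' for gas_in", call. = FALSE))
  } else if (variable == "headspace") {
    if (u %in% c("fraction", "molfraction", "-", "")) {
      value
    } else if (u %in% c("%", "percent")) {
      value / 100
    } else {
      stop("unparseable unit '", unit, "' for headspace", call. = FALSE)
    }
  } else if (variable == "gas_out_flow") {
    switch(u,
      "nml/min" = value,
      stop("unparseable unit '", unit, "' for gas_out_flow", call. = FALSE))
  } else if (variable %in% c("feed_flow", "base_flow")) {
    switch(u,
      "ml/d" = , "ml/day" = value,
      "l/d" = , "l/day" = value * 1000,
      stop("unparseable unit '", unit, "' for ", variable, call. = FALSE))
  } else if (variable == "base_molarity") {
    switch(u,
      "mol/l" = , "m" = value,
      stop("unparseable unit '", unit, "' for base_molarity", call. = FALSE))
  } else if (variable %in% c("ph", "temperature")) {
    value
  } else {
    stop("unknown variable '", variable, "' in time-series file", call. = FALSE)
  }
}

#' Read a reactor time series from a tidy CSV
#'
#' Expects the long layout `time, variable, species, value, unit` where
#' `variable` is one of `broth`, `gas_in`, `headspace`, `gas_out_flow`,
#' `feed_flow`, `base_flow`, `base_molarity`, `ph`, `temperature`.
#' Broth concentrations are accepted in mCmol/L, mmol/L, g/L or mg/L and
#' normalised to mCmol/L through the compound registry; compound names may
#' use any registry synonym (`n-C6`, `EtOH`, ...). Unknown compounds, an
#' unparseable unit, non-increasing times and negative concentrations are
#' rejected with an error naming the offender.
#'
#' @param path CSV file path.
#' @param volume working volume in L.
#' @param reactor_id identifier; defaults to the file name.
#' @param registry a [compound_registry()].
#' @return A [reactor_timeseries()].
#' @export
read_timeseries <- function(path, volume = 1, reactor_id = NULL,
                            registry = compound_registry()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(reactor_id)) {
    reactor_id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("time", "variable", "species", "value", "unit")
  if (length(miss <- setdiff(needed, names(raw)))) {
    stop("time-series file lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  raw$species[is.na(raw$species)] <- ""
  raw$unit[is.na(raw$unit)] <- ""
  dup <- duplicated(raw[c("time", "variable", "species")])
  if (any(dup)) {
    stop("duplicated measurement row(s) at time(s) ",
         paste(unique(raw$time[dup]), collapse = ", "),
         "; sample times must be strictly increasing", call. = FALSE)
  }
  # canonicalise broth compound names up front so aliases collapse
  is_broth <- raw$variable == "broth"
  raw$species[is_broth] <- resolve_compound(raw$species[is_broth], registry)
  raw$value <- mapply(.normalise_value, raw$value, raw$unit, raw$variable,
                      raw$species, MoreArgs = list(registry = registry))

  times <- sort(unique(raw$time))
  wide <- function(rows, cols) {
    out <- data.frame(time = times)
    for (cc in cols) {
      sel <- rows[rows$species == cc, ]
      out[[cc]] <- sel$value[match(times, sel$time)]
    }
    out
  }
  broth_cols <- unique(raw$species[is_broth])
  broth <- wide(raw[is_broth, ], broth_cols)
  gi <- raw[raw$variable == "gas_in", ]
  gi$species <- tolower(gi$species)
  gas_in <- wide(gi, c("co2", "n2"))
  gas_in[is.na(gas_in)] <- 0
  hs <- raw[raw$variable == "headspace", ]
  hs$species <- tolower(hs$species)
  headspace <- wide(hs, .HEADSPACE_SPECIES)
  headspace[is.na(headspace)] <- 0
  scalars <- data.frame(time = times)
  for (v in .SCALAR_VARS) {
    sel <- raw[raw$variable == v, ]
    scalars[[v]] <- sel$value[match(times, sel$time)]
  }
  reactor_timeseries(broth, scalars, gas_in, headspace,
                     volume = volume, reactor_id = reactor_id)
}

#' Write a reactor time series to a tidy CSV
#'
#' Emits the same long layout [read_timeseries()] accepts, in canonical
#' units, with values formatted at full double precision so a
#' write-then-read round trip is lossless.
#'
#' @param ts a [reactor_timeseries()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  fmt <- function(x) {
    ifelse(is.na(x), "", sprintf("%.17g", x))
  }
  rows <- list()
  add <- function(variable, species, time, value, unit) {
    keep <- !is.na(value)
    rows[[length(rows) + 1]] <<- data.frame(
      time = time[keep], variable = variable, species = species,
      value = fmt(value[keep]), unit = unit, stringsAsFactors = FALSE)
  }
  for (cc in setdiff(names(ts$broth), "time")) {
    add("broth", cc, ts$broth$time, ts$broth[[cc]], "mCmol/L")
  }
  for (gg in setdiff(names(ts$gas_in), "time")) {
    add("gas_in", gg, ts$gas_in$time, ts$gas_in[[gg]], "NmL/L/min")
  }
  for (hh in setdiff(names(ts$headspace), "time")) {
    add("headspace", hh, ts$headspace$time, ts$headspace[[hh]], "fraction")
  }
  units <- c(gas_out_flow = "NmL/min", feed_flow = "mL/d", base_flow = "mL/d",
             base_molarity = "mol/L", ph = "", temperature = "C")
  for (v in .SCALAR_VARS) {
    if (!is.null(ts$scalars[[v]])) {
      add(v, "", ts$scalars$time, ts$scalars[[v]], units[[v]])
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Feed (medium) definition
#'
#' Carbon-source composition of the medium in mCmol/L. The default mirrors
#' a caproate-oriented chain-elongation medium: 600 mMC n-butyrate, 50 mMC
#' acetate and 1200 mMC ethanol (acetate:ethanol = 1:24 on a Cmol basis),
#' plus 1 g/L yeast extract whose carbon is not tracked in the balances.
#'
#' @param composition named numeric vector, compound -> mCmol/L; names may
#'   be registry synonyms.
#' @param yeast_extract g/L, carbon-untracked.
#' @param registry a [compound_registry()].
#' @return An object of class `feed_definition`.
#' @export
feed_definition <- function(composition = c(ethanol = 1200, acetate = 50,
                                            "n-butyrate" = 600),
                            yeast_extract = 1,
                            registry = compound_registry()) {
  if (any(composition < 0) || yeast_extract < 0) {
    stop("feed composition must be non-negative", call. = FALSE)
  }
  names(composition) <- resolve_compound(names(composition), registry)
  structure(list(composition = composition, yeast_extract = yeast_extract),
            class = "feed_definition")
}

#' Phase schedule
#'
#' Named, ordered, non-overlapping operating phases with their CO2 and N2
#' dosing set-points. Intervals are half-open `[start_day, end_day)`: a
#' sample taken on the day a set-point changes belongs to the new phase.
#'
#' @param name phase labels.
#' @param start_day,end_day phase bounds in days.
#' @param co2_load,n2_load dosing in NmL per L reactor per min.
#' @return A data frame of class `phase_schedule`.
#' @seealso [default_phases()] for the four-phase CO2 regime used
#'   throughout the package examples.
#' @export
phase_schedule <- function(name, start_day, end_day, co2_load, n2_load = 0) {
  ph <- data.frame(name = as.character(name), start_day = start_day,
                   end_day = end_day, co2_load = co2_load,
                   n2_load = rep_len(n2_load, length(name)),
                   stringsAsFactors = FALSE)
  if (nrow(ph) == 0) stop("phase schedule is empty", call. = FALSE)
  if (any(ph$end_day <= ph$start_day)) {
    stop("each phase must end after it starts", call. = FALSE)
  }
  ph <- ph[order(ph$start_day), ]
  if (nrow(ph) > 1 && any(ph$start_day[-1] < ph$end_day[-nrow(ph)])) {
    stop("phases overlap", call. = FALSE)
  }
  if (any(ph$co2_load < 0) || any(ph$n2_load < 0)) {
    stop("gas loads must be non-negative", call. = FALSE)
  }
  class(ph) <- c("phase_schedule", "data.frame")
  ph
}

#' Default four-phase CO2 dosing regime
#'
#' Phase I (days 0-34): no CO2; phase II (34-57): 2.0 NmL CO2 L^-1 min^-1;
#' phase III (57-91): 6.0 NmL CO2 plus 6.0 NmL N2 L^-1 min^-1 (N2 added to
#' prevent headspace underpressure); phase IV (91-133): 0.5 NmL CO2 with N2
#' continued.
#'
#' @return A [phase_schedule()].
#' @export
default_phases <- function() {
  phase_schedule(name = c("I", "II", "III", "IV"),
                 start_day = c(0, 34, 57, 91),
                 end_day = c(34, 57, 91, 133),
                 co2_load = c(0, 2, 6, 0.5),
                 n2_load = c(0, 0, 6, 6))
}

#' Label every sample with its operating phase
#'
#' Phase intervals are half-open `[start, end)`, so a sample taken exactly
#' at a phase boundary is assigned to the later phase. A sample not covered
#' by any phase is an error.
#'
#' @param ts a [reactor_timeseries()].
#' @param phases a [phase_schedule()].
#' @return `ts` with a `phase` column added to its `scalars` block.
#' @export
assign_phases <- function(ts, phases) {
  if (missing(phases) || is.null(phases) || nrow(phases) == 0) {
    stop("phase schedule is empty", call. = FALSE)
  }
  t0 <- ts$broth$time
  lab <- rep(NA_character_, length(t0))
  for (i in seq_len(nrow(phases))) {
    sel <- t0 >= phases$start_day[i] & t0 < phases$end_day[i]
    lab[sel] <- phases$name[i]
  }
  # the final right edge closes the last phase
  lab[t0 == max(phases$end_day)] <- phases$name[which.max(phases$end_day)]
  if (anyNA(lab)) {
    stop("sample time(s) not covered by any phase: ",
         paste(t0[is.na(lab)], collapse = ", "), call. = FALSE)
  }
  ts$scalars$phase <- lab
  attr(ts, "phases") <- phases
  ts
}
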