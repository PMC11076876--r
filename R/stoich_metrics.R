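# Derived stoichiometric metrics: Cmol% product selectivity, carbon and
# electron balance closure, excessive ethanol oxidation (EEO), phase
# averages.

# species never reported as fermentation products in the Cmol% spectrum
.NON_PRODUCTS <- c("co2", "ch4", "h2", "n2", "o2", "h2o", "nh3", "biomass")

#' Cmol% product selectivity
#'
#' Carbon in each formed product divided by the carbon in all formed
#' products, times 100. A compound counts as a product when its net rate is
#' positive and it is not a fed electron donor: ethanol is never a product,
#' and fed acceptors (acetate, butyrate) are excluded automatically while
#' net-consumed because their rates are negative. Gases and untracked
#' species (CO2, CH4, H2, water, biomass) never enter the product spectrum.
#'
#' @param rates named numeric vector of net conversion rates in
#'   mCmol L^-1 d^-1 (positive = production); names may be registry
#'   synonyms.
#' @param fed compounds never counted as products (default the ethanol
#'   electron donor).
#' @param registry a [compound_registry()].
#' @return Named vector of selectivities in Cmol% summing to 100, or an
#'   empty vector with a warning when nothing is formed.
#' @examples
#' product_selectivity(c("n-caproate" = 480, butanol = 10, hexanol = 10))
#' @export
product_selectivity <- function(rates, fed = "ethanol",
                                registry = compound_registry()) {
  names(rates) <- resolve_compound(names(rates), registry)
  fed <- resolve_compound(fed, registry)
  keep <- !(names(rates) %in% c(fed, .NON_PRODUCTS)) & rates > 0
  prod <- rates[keep]
  if (!length(prod) || sum(prod) <= 0) {
    warning("no net product formation; selectivity undefined", call. = FALSE)
    return(stats::setNames(numeric(0), character(0)))
  }
  100 * prod / sum(prod)
}

# shared balance arithmetic for one (possibly averaged) rates record.
# rates/influx: named vectors (mCmol/L/d); gas: list with co2_in,
# co2_out_gas, co2_out_dissolved, h2_out, ch4_out.
.balance_one <- function(rates, influx, gas, registry, what) {
  comps <- names(rates)
  rows <- registry[match(comps, registry$name), ]
  if (what == "carbon") {
    w <- ifelse(rows$n_C >= 1, 1, 0)            # already Cmol-based
    gin <- gas$co2_in
    gout <- gas$co2_out_gas + gas$co2_out_dissolved + gas$ch4_out
  } else {
    w <- rows$gamma                              # electron equiv per Cmol
    w[is.na(w)] <- 0
    gin <- 0                                      # dosed CO2 carries none
    gout <- 2 * gas$h2_out + 8 * gas$ch4_out
  }
  total_in <- sum(w * influx) + gin
  if (total_in <= 0) {
    stop("no ", what, " enters the reactor over this interval; ",
         "balance undefined", call. = FALSE)
  }
  total_out <- sum(w * (influx + rates)) + gout
  100 * total_out / total_in
}

#' Carbon balance closure
#'
#' Accumulation-corrected carbon recovery per measurement interval:
#' `100 * (effluent organics + accumulation + gaseous CO2 + dissolved CO2 +
#' CH4) / (feed organics + dosed CO2)`. Because conversion rates already
#' contain the accumulation term, the outgoing side is
#' `influx + rate` summed over compounds. Yeast-extract carbon and biomass
#' are untracked, so real datasets close slightly off 100%.
#'
#' @param rr a [reactor_rates()] record.
#' @return Numeric vector, one closure percentage per interval.
#' @export
carbon_balance <- function(rr) {
  registry <- compound_registry()
  vapply(seq_len(nrow(rr$interval)), function(k) {
    .balance_one(rr$rates[k, ], rr$influx[k, ],
                 as.list(rr$interval[k, ]), registry, "carbon")
  }, numeric(1))
}

#' Electron balance closure
#'
#' As [carbon_balance()] but on the available-electron scale: each
#' compound's Cmol rate is weighted by its degree of reduction, H2 carries
#' 2 electron equivalents per mmol and CH4 8; CO2 carries none, so dosed
#' CO2 does not enter the denominator.
#'
#' @param rr a [reactor_rates()] record.
#' @return Numeric vector, one closure percentage per interval.
#' @export
electron_balance <- function(rr) {
  registry <- compound_registry()
  vapply(seq_len(nrow(rr$interval)), function(k) {
    .balance_one(rr$rates[k, ], rr$influx[k, ],
                 as.list(rr$interval[k, ]), registry, "electron")
  }, numeric(1))
}

# infer 2-carbon elongation steps (mol basis) from net product rates.
# mol: named vector of net rates in mmol/L/d on a molecule (not carbon)
# basis, alcohols already folded into their precursor acids upstream.
.elongation_steps <- function(c4_eff, c6_eff, c8_eff, c5_eff, isomer_iC4 = 0,
                              isomer_steps = 0) {
  steps <- 0
  p8 <- max(c8_eff, 0)
  steps <- steps + p8                              # C6 -> C8
  used6 <- min(max(-c6_eff, 0), p8)                # C8 fed by net C6 uptake
  demand6 <- max(c6_eff, 0) + (p8 - used6)
  from_c4 <- min(max(-c4_eff, 0), demand6)         # consumed C4 routed first
  steps <- steps + from_c4                         # C4 -> C6
  steps <- steps + 2 * (demand6 - from_c4)         # C2 -> C6 (two events)
  steps <- steps + max(c4_eff, 0)                  # C2 -> C4
  steps <- steps + max(c5_eff, 0)                  # C3 -> C5
  steps <- steps + isomer_steps * max(isomer_iC4, 0)
  steps
}

#' Excessive ethanol oxidation (EEO)
#'
#' Chain elongators are assumed to oxidise one ethanol to acetate for every
#' five elongation events (their ATP-generating side reaction); ethanol
#' consumed beyond elongation, that expected oxidation and
#' carboxyl-hydroxyl exchange is "excess":
#' `EEO% = 100 * (E_cons - S - E_red - S/5) / E_cons`,
#' all terms in mol (not Cmol) ethanol. Negative values are permitted and
#' reported; they indicate elongation running with less ancillary oxidation
#' than the assumed 5:1 stoichiometry.
#'
#' Elongation steps `S` are inferred from net product rates: one step per
#' 2-carbon extension (C4-from-C2 one step, C6-from-C2 two, C8 analogously;
#' valerate one step from propionate). Net-consumed butyrate is routed to
#' caproate before any caproate is attributed to acetate. Alcohols count as
#' their precursor acid for step accounting and each mol of higher alcohol
#' assigns one extra ethanol to carboxylate reduction (`E_red`, the
#' carboxyl-hydroxyl exchange, which also credits one acetate produced).
#' Isobutyrate formation is treated as an isomerisation (0 steps) by
#' default; set `isomer_steps = 1` to count it as an elongation event.
#'
#' @param rates named numeric vector of net conversion rates in
#'   mCmol L^-1 d^-1.
#' @param isomer_steps elongation steps credited per mol isobutyrate formed
#'   (0 or 1).
#' @param quiet suppress the warning on undefined EEO.
#' @param registry a [compound_registry()].
#' @return A list: `eeo` (percent, `NA` when ethanol is not net consumed),
#'   `allocation` (mmol L^-1 d^-1: `elongation`, `expected_oxidation`,
#'   `reduction_exchange`, `excess`; they sum to `ethanol_consumption`),
#'   `allocation_cmol` (same on the mCmol scale) and
#'   `ethanol_consumption` (mmol L^-1 d^-1).
#' @examples
#' # 12 ethanol consumed, 5 C4->C6 elongation steps: 100*(12-5-1)/12 = 50%
#' excessive_ethanol_oxidation(
#'   c(ethanol = -24, "n-butyrate" = -20, "n-caproate" = 30))
#' @export
excessive_ethanol_oxidation <- function(rates, isomer_steps = 0,
                                        quiet = FALSE,
                                        registry = compound_registry()) {
  names(rates) <- resolve_compound(names(rates), registry)
  nc <- registry$n_C[match(names(rates), registry$name)]
  mol <- ifelse(nc >= 1, rates / nc, 0)
  names(mol) <- names(rates)
  g <- function(nm) if (nm %in% names(mol)) mol[[nm]] else 0

  e_cons <- -g("ethanol")
  empty <- list(eeo = NA_real_,
                allocation = c(elongation = NA_real_,
                               expected_oxidation = NA_real_,
                               reduction_exchange = NA_real_,
                               excess = NA_real_),
                allocation_cmol = NULL, ethanol_consumption = e_cons)
  if (e_cons <= 0) {
    if (!quiet) warning("ethanol is not net consumed; EEO undefined",
                        call. = FALSE)
    return(empty)
  }
  c4_eff <- g("n-butyrate") + max(g("butanol"), 0)
  c6_eff <- g("n-caproate") + max(g("hexanol"), 0)
  c8_eff <- g("n-caprylate")
  c5_eff <- g("n-valerate")
  s <- .elongation_steps(c4_eff, c6_eff, c8_eff, c5_eff,
                         isomer_iC4 = g("i-butyrate"),
                         isomer_steps = isomer_steps)
  e_red <- max(g("butanol"), 0) + max(g("hexanol"), 0) + max(g("propanol"), 0)
  e_exp <- s / 5
  excess <- e_cons - s - e_red - e_exp
  alloc <- c(elongation = s, expected_oxidation = e_exp,
             reduction_exchange = e_red, excess = excess)
  list(eeo = 100 * excess / e_cons,
       allocation = alloc,
       allocation_cmol = 2 * alloc,   # ethanol is a C2 donor
       ethanol_consumption = e_cons)
}

#' Arithmetic mean of the last records of a phase
#'
#' End-of-phase averaging: phase-level values are the mean of the last
#' `n_last` interval records of the phase, i.e. the data points just before
#' the switch to the next phase. When the phase holds fewer records, all of
#' them are used with a warning.
#'
#' @param metrics a data frame of per-interval records containing a `phase`
#'   column (e.g. `interval_metrics` from [reactor_metrics()]).
#' @param phase phase label to average.
#' @param n_last number of trailing records to average.
#' @return A one-row data frame of column means (numeric columns only),
#'   with `phase` and `n_used` attached.
#' @export
phase_average <- function(metrics, phase, n_last = 5) {
  sel <- metrics[!is.na(metrics$phase) & metrics$phase == phase, , drop = FALSE]
  if (nrow(sel) == 0) stop("no records in phase '", phase, "'", call. = FALSE)
  if (nrow(sel) < n_last) {
    warning("phase '", phase, "' holds only ", nrow(sel), " record(s); ",
            "averaging all of them", call. = FALSE)
    n_last <- nrow(sel)
  }
  tail_sel <- utils::tail(sel, n_last)
  num <- vapply(tail_sel, is.numeric, logical(1))
  out <- as.data.frame(lapply(tail_sel[num], mean, na.rm = TRUE))
  out$phase <- phase
  out$n_used <- n_last
  out
}

# average a rates record over a set of interval indices, returning the
# pieces the balance/selectivity/EEO calculators need
.average_record <- function(rr, idx) {
  list(rates = colMeans(rr$rates[idx, , drop = FALSE]),
       influx = colMeans(rr$influx[idx, , drop = FALSE]),
       gas = as.list(colMeans(rr$interval[idx, c("co2_in", "co2_out_gas",
                                                 "co2_out_dissolved",
                                                 "co2_utilization", "h2_out",
                                                 "ch4_out", "hrt_h")])))
}

#' Per-interval and per-phase stoichiometric metrics for one reactor
#'
#' The main analysis entry point: computes conversion rates
#' ([reactor_rates()]), per-interval carbon/electron balances, EEO and CO2
#' utilisation, flags steady-state windows ([detect_steady_state()]), and
#' summarises each operating phase from its end-of-phase window. Phase
#' selectivities, balances and EEO are derived from the window-averaged
#' rates (not averages of per-interval ratios), which keeps the ratio
#' estimators well-behaved under measurement noise.
#'
#' @param ts a [reactor_timeseries()].
#' @param feed a [feed_definition()].
#' @param phases optional [phase_schedule()]; may also be pre-assigned on
#'   `ts` with [assign_phases()].
#' @param n_last intervals in the end-of-phase averaging window.
#' @param criteria a [steady_state_criteria()] for the steady flags.
#' @param isomer_steps see [excessive_ethanol_oxidation()].
#' @param ... passed on to [reactor_rates()] (method, dissolved-CO2
#'   constants, ...).
#' @return An object of class `ce_metrics`: list with `interval_metrics`
#'   (data frame, one row per interval), `selectivity` (intervals x
#'   products Cmol% matrix), `phase_summary` (one row per phase),
#'   `phase_selectivity`, the underlying `rates` record and the steady
#'   intervals.
#' @export
reactor_metrics <- function(ts, feed, phases = NULL, n_last = 5,
                            criteria = steady_state_criteria(),
                            isomer_steps = 0, ...) {
  if (!is.null(phases)) ts <- assign_phases(ts, phases)
  rr <- reactor_rates(ts, feed, ...)
  k <- nrow(rr$interval)
  registry <- compound_registry()

  cb <- carbon_balance(rr)
  eb <- electron_balance(rr)
  eeo <- vapply(seq_len(k), function(i) {
    excessive_ethanol_oxidation(rr$rates[i, ], isomer_steps, quiet = TRUE,
                                registry = registry)$eeo
  }, numeric(1))

  prod_set <- registry$name[registry$phase_hint == "liquid" &
                              registry$n_C >= 1 &
                              !(registry$name %in% c("ethanol", .NON_PRODUCTS))]
  prod_set <- intersect(prod_set, colnames(rr$rates))
  sel <- matrix(0, k, length(prod_set), dimnames = list(NULL, prod_set))
  for (i in seq_len(k)) {
    s <- suppressWarnings(
      product_selectivity(rr$rates[i, prod_set, drop = TRUE],
                          fed = "ethanol", registry = registry))
    sel[i, names(s)] <- s
  }

  ss <- detect_steady_state(ts, criteria)
  im <- data.frame(
    time = rr$interval$time,
    phase = if ("phase" %in% names(rr$interval)) rr$interval$phase else NA,
    hrt_h = rr$interval$hrt_h,
    carbon_balance = cb, electron_balance = eb, eeo = eeo,
    co2_utilization = rr$interval$co2_utilization,
    h2_out = rr$interval$h2_out,
    steady = ss$flags[-1])   # flag of the interval's right endpoint

  phase_summary <- NULL
  phase_selectivity <- NULL
  if ("phase" %in% names(rr$interval)) {
    for (ph in unique(rr$interval$phase)) {
      idx <- which(rr$interval$phase == ph)
      idx <- utils::tail(idx, min(n_last, length(idx)))
      avg <- .average_record(rr, idx)
      psel <- suppressWarnings(
        product_selectivity(avg$rates[prod_set], registry = registry))
      peeo <- excessive_ethanol_oxidation(avg$rates, isomer_steps,
                                          quiet = TRUE, registry = registry)
      pcb <- .balance_one(avg$rates, avg$influx, avg$gas, registry, "carbon")
      peb <- .balance_one(avg$rates, avg$influx, avg$gas, registry, "electron")
      getr <- function(nm) if (nm %in% names(avg$rates)) avg$rates[[nm]] else NA_real_
      row <- data.frame(
        reactor = rr$reactor_id, phase = ph, n_used = length(idx),
        t_start = rr$interval$t_prev[idx[1]],
        t_end = rr$interval$time[idx[length(idx)]],
        hrt_h = avg$gas$hrt_h,
        carbon_balance_pct = pcb, electron_balance_pct = peb,
        eeo_pct = peeo$eeo,
        co2_utilization_mCmol_L_d = avg$gas$co2_utilization,
        h2_out_mmol_L_d = avg$gas$h2_out,
        ethanol_rate_mCmol_L_d = getr("ethanol"),
        acetate_rate_mCmol_L_d = getr("acetate"),
        butyrate_rate_mCmol_L_d = getr("n-butyrate"),
        caproate_rate_mCmol_L_d = getr("n-caproate"),
        steady_fraction = mean(im$steady[idx]))
      phase_summary <- rbind(phase_summary, row)
      srow <- stats::setNames(numeric(length(prod_set)), prod_set)
      srow[names(psel)] <- psel
      phase_selectivity <- rbind(phase_selectivity, srow)
    }
    rownames(phase_selectivity) <- phase_summary$phase
  }

  structure(list(interval_metrics = im, selectivity = sel,
                 phase_summary = phase_summary,
                 phase_selectivity = phase_selectivity,
                 rates = rr, steady_intervals = ss$intervals,
                 n_last = n_last),
            class = "ce_metrics")
}

#' @export
print.ce_metrics <- function(x, ...) {
  cat("Chain-elongation metrics for reactor '", x$rates$reactor_id, "'\n",
      sep = "")
  cat(sprintf("  %d intervals; mean carbon balance %.1f%%, electron balance %.1f%%\n",
              nrow(x$interval_metrics),
              mean(x$interval_metrics$carbon_balance, na.rm = TRUE),
              mean(x$interval_metrics$electron_balance, na.rm = TRUE)))
  if (!is.null(x$phase_summary)) {
    cat("  phase summary (end-of-phase windows):\n")
    print(x$phase_summary[, c("phase", "n_used", "hrt_h", "carbon_balance_pct",
                              "electron_balance_pct", "eeo_pct",
                              "co2_utilization_mCmol_L_d")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' @export
summary.ce_metrics <- function(object, ...) {
  print(object)
  if (!is.null(object$phase_selectivity)) {
    cat("  phase product selectivities (Cmol%):\n")
    keep <- colSums(object$phase_selectivity) > 0
    print(round(object$phase_selectivity[, keep, drop = FALSE], 1))
  }
  invisible(object)
}

#' @export
plot.ce_metrics <- function(x, ...) {
  im <- x$interval_metrics
  old <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(old))
  graphics::plot(im$time, im$eeo, type = "b", xlab = "time (d)",
                 ylab = "EEO (%)", main = "excessive ethanol oxidation", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::plot(im$time, im$carbon_balance, type = "b", xlab = "time (d)",
                 ylab = "closure (%)", main = "carbon / electron balance",
                 ylim = range(c(im$carbon_balance, im$electron_balance, 100),
                              na.rm = TRUE))
  graphics::lines(im$time, im$electron_balance, type = "b", col = 2)
  graphics::abline(h = 100, lty = 3)
  invisible(x)
}
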