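# Stoichiometric CSTR simulator with exact ground truth.
#
# Liquid species follow dC_i/dt = (Q_in C_feed,i - Q_out C_i)/V + sum_j
# S_ij r_j(t) with prescribed (piecewise constant or logistic) reaction
# rate profiles; there is no microbial kinetic model, which keeps the
# ground truth exact. Gas species use a quasi-steady headspace: the off-gas
# is the instantaneous source mix (sampling cadence of days is far longer
# than the gas residence time). Dissolved CO2 leaves with the effluent
# following the same equilibrium speciation model the rate engine uses, so
# the analysis pipeline closes carbon balances on simulator output exactly.

#' Default reaction set
#'
#' The conversions of an ethanol/carboxylate chain-elongation microbiome:
#' reverse beta-oxidation elongation steps (CE1: ethanol + acetate ->
#' butyrate; CE2: ethanol + butyrate -> caproate), hydrogenogenic ethanol
#' oxidation (EO: ethanol + H2O -> acetate + 2 H2), homoacetogenesis (HAC:
#' 4 H2 + 2 CO2 -> acetate + 2 H2O), carboxyl-hydroxyl exchange (REDX4/
#' REDX6: ethanol + acid -> acetate + alcohol), direct hydrogenotrophic
#' butyrate reduction (H2RED4) and butyrate isomerisation (ISO). Each
#' reaction carries its elongation-step count for EEO ground truth.
#'
#' @return Named list of reactions, each `list(stoich = <named mol
#'   coefficients, negative = consumed>, steps = <elongation events>)`.
#' @export
default_reactions <- function() {
  list(
    CE1 = list(stoich = c(ethanol = -1, acetate = -1, "n-butyrate" = 1,
                          h2o = 1), steps = 1),
    CE2 = list(stoich = c(ethanol = -1, "n-butyrate" = -1, "n-caproate" = 1,
                          h2o = 1), steps = 1),
    EO = list(stoich = c(ethanol = -1, h2o = -1, acetate = 1, h2 = 2),
              steps = 0),
    HAC = list(stoich = c(h2 = -4, co2 = -2, acetate = 1, h2o = 2),
               steps = 0),
    REDX4 = list(stoich = c(ethanol = -1, "n-butyrate" = -1, acetate = 1,
                            butanol = 1), steps = 0),
    REDX6 = list(stoich = c(ethanol = -1, "n-caproate" = -1, acetate = 1,
                            hexanol = 1), steps = 0),
    H2RED4 = list(stoich = c("n-butyrate" = -1, h2 = -2, butanol = 1,
                             h2o = 1), steps = 0),
    ISO = list(stoich = c("n-butyrate" = -1, "i-butyrate" = 1), steps = 0)
  )
}

#' Validated reaction set and stoichiometric matrix
#'
#' Checks that every reaction closes its C, H, O and N element balances
#' exactly (available-electron closure follows automatically, being a fixed
#' linear combination of the four).
#'
#' @param reactions a list shaped like [default_reactions()].
#' @param registry a [compound_registry()].
#' @return An object of class `reaction_set`: list with `reactions`, the
#'   species x reactions `stoich` matrix and the per-reaction
#'   elongation-step vector `steps`.
#' @export
reaction_set <- function(reactions = default_reactions(),
                         registry = compound_registry()) {
  species <- unique(unlist(lapply(reactions, function(r) names(r$stoich))))
  species <- resolve_compound(species, registry)
  S <- matrix(0, length(species), length(reactions),
              dimnames = list(species, names(reactions)))
  for (j in seq_along(reactions)) {
    st <- reactions[[j]]$stoich
    S[resolve_compound(names(st), registry), j] <- st
  }
  rows <- registry[match(species, registry$name), ]
  for (el in c("n_C", "n_H", "n_O", "n_N")) {
    resid <- as.vector(rows[[el]] %*% S)
    bad <- abs(resid) > 1e-9
    if (any(bad)) {
      stop("reaction(s) violate the ", sub("n_", "", el), " balance: ",
           paste(colnames(S)[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(reactions = reactions, stoich = S,
                 steps = vapply(reactions, function(r) r$steps %||% 0,
                                numeric(1)),
                 species = species),
            class = "reaction_set")
}

#' Reaction-rate schedule
#'
#' Prescribes each reaction's volumetric rate per operating phase, either
#' constant or as a logistic ingrowth
#' `r(t) = rate0 + (rate - rate0) / (1 + exp(-k_rate (t - t_mid)))`
#' (mimicking the slow, accumulating ingrowth of acetogenic activity).
#' Unlisted reaction/phase pairs run at zero.
#'
#' @param reaction,phase,rate vectors defining constant rates
#'   (mmol L^-1 d^-1).
#' @param type `"constant"` or `"logistic"`.
#' @param rate0,t_mid,k_rate logistic parameters (start rate, midpoint day,
#'   steepness per day); ignored for constant rows.
#' @return A data frame of class `rate_schedule`.
#' @export
rate_schedule <- function(reaction, phase, rate, type = "constant",
                          rate0 = 0, t_mid = NA, k_rate = NA) {
  out <- data.frame(reaction = reaction, phase = phase, rate = rate,
                    type = rep_len(type, length(reaction)),
                    rate0 = rep_len(rate0, length(reaction)),
                    t_mid = rep_len(t_mid, length(reaction)),
                    k_rate = rep_len(k_rate, length(reaction)),
                    stringsAsFactors = FALSE)
  if (any(out$rate < 0) || any(out$rate0 < 0)) {
    stop("reaction rates must be non-negative", call. = FALSE)
  }
  class(out) <- c("rate_schedule", "data.frame")
  out
}

# prescribed rate vector at time t (before feasibility capping)
.prescribed_rates <- function(t, schedule, phases, rxn_names) {
  ph <- phases$name[findInterval(t, phases$start_day)]
  if (t >= max(phases$end_day)) ph <- phases$name[nrow(phases)]
  r <- stats::setNames(numeric(length(rxn_names)), rxn_names)
  rows <- schedule[schedule$phase == ph, , drop = FALSE]
  for (i in seq_len(nrow(rows))) {
    if (rows$type[i] == "constant") {
      r[rows$reaction[i]] <- rows$rate[i]
    } else {
      r[rows$reaction[i]] <- rows$rate0[i] +
        (rows$rate[i] - rows$rate0[i]) /
        (1 + exp(-rows$k_rate[i] * (t - rows$t_mid[i])))
    }
  }
  r
}

# cap gas-consuming reactions at their instantaneous gas supply; returns
# list(rates, underpressure). Two passes cover the HAC-after-EO coupling.
.effective_rates <- function(r, S, co2_supply) {
  under <- FALSE
  for (pass in 1:2) {
    co2_row <- if ("co2" %in% rownames(S)) S["co2", ] else numeric(ncol(S))
    cons <- -sum(pmin(co2_row, 0) * r)
    prod <- sum(pmax(co2_row, 0) * r)
    if (cons > co2_supply + prod + 1e-12) {
      f <- (co2_supply + prod) / cons
      r[co2_row < 0] <- r[co2_row < 0] * f
      under <- TRUE
    }
    if ("h2" %in% rownames(S)) {
      h2_row <- S["h2", ]
      h2_cons <- -sum(pmin(h2_row, 0) * r)
      h2_prod <- sum(pmax(h2_row, 0) * r)
      if (h2_cons > h2_prod + 1e-12) {
        r[h2_row < 0] <- r[h2_row < 0] * (h2_prod / max(h2_cons, 1e-300))
      }
    }
  }
  list(rates = r, underpressure = under)
}

# dissolved/gaseous split of the CO2 leaving the reactor. A = total CO2 to
# dispose (mmol/L/d), B = other off-gas (mmol/L/d), kdis = dissolved-CO2
# coefficient (mmol/L/d per unit mole fraction). Solves
# g + kdis * g/(g+B) = A for the gaseous part g >= 0.
.split_co2_out <- function(A, B, kdis) {
  if (A <= 0) return(c(gas = 0, dissolved = 0))
  b <- B + kdis - A
  g <- (-b + sqrt(b^2 + 4 * A * B)) / 2
  g <- max(g, 0)
  c(gas = g, dissolved = A - g)
}

#' Simulate a chain-elongation retentostat
#'
#' Integrates the constant-volume CSTR balances for the liquid species
#' under a prescribed reaction-rate schedule, books the gas phase
#' quasi-steadily (off-gas = dosing + net production; CO2-consuming
#' reactions are capped at their supply, raising an `underpressure` flag),
#' splits outgoing CO2 between off-gas and effluent-dissolved carbon with
#' the equilibrium speciation model, simulates pH-control base dosing
#' proportional to net acid formation, samples on the reactor check-up
#' schedule and optionally applies multiplicative measurement noise.
#'
#' @param feed a [feed_definition()].
#' @param phases a [phase_schedule()] (gas dosing set-points and bounds).
#' @param schedule a [rate_schedule()].
#' @param volume working volume, L.
#' @param feed_flow medium inflow, mL/d.
#' @param seed RNG seed for the measurement noise.
#' @param noise_cv multiplicative measurement CV (0 = noiseless).
#' @param replicates analytical replicates averaged per reported value
#'   (broth sampled in duplicate -> 2).
#' @param sample_every repeating day-gap pattern of the sampling schedule;
#'   the default `c(2, 2, 3)` is three check-ups per week.
#' @param init `"feed"` (reactor starts filled with medium), `"empty"`, or
#'   a named vector of start concentrations in mCmol/L.
#' @param reactions a [reaction_set()].
#' @param base_gain fraction of net acid formation neutralised by base.
#' @param base_molarity_schedule data frame `from_day`, `molarity` for the
#'   KOH strength (default 1 M, switched to 2 M on day 55).
#' @param ph,temperature controlled set-points.
#' @param kh,pka1,total_pressure,speciation dissolved-CO2 constants as in
#'   [dissolved_co2_effluent()].
#' @param molar_volume NmL/mmol at the gas reference conditions.
#' @param reactor_id identifier stamped on the series.
#' @return An object of class `ce_simulation`: list with `timeseries` (a
#'   [reactor_timeseries()], noised when `noise_cv > 0`) and `truth` (class
#'   `ce_ground_truth`: clean concentrations, effective reaction rates,
#'   exact interval-averaged net conversion rates, per-phase true EEO and
#'   selectivities, underpressure flags, seed and noise model).
#' @export
simulate_reactor <- function(feed, phases, schedule, volume = 1,
                             feed_flow = 522, seed = NULL, noise_cv = 0,
                             replicates = 1, sample_every = c(2, 2, 3),
                             init = "feed", reactions = reaction_set(),
                             base_gain = 1,
                             base_molarity_schedule =
                               data.frame(from_day = c(0, 55),
                                          molarity = c(1, 2)),
                             ph = 6.5, temperature = 35, kh = 0.026,
                             pka1 = 6.31, total_pressure = 1,
                             speciation = TRUE,
                             molar_volume = .MOLAR_VOLUME_NORMAL,
                             reactor_id = "SIM") {
  registry <- compound_registry()
  S <- reactions$stoich
  rxn <- colnames(S)
  bad <- setdiff(schedule$reaction, rxn)
  if (length(bad)) stop("schedule names unknown reaction(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(schedule$phase, phases$name)
  if (length(bad)) stop("schedule names unknown phase(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)

  # liquid state: measurable organics (acids, alcohols) incl. feed compounds
  rows <- registry[match(rownames(S), registry$name), ]
  state_sp <- union(rownames(S)[rows$phase_hint == "liquid" & rows$n_C >= 1 &
                                  rownames(S) != "biomass"],
                    names(feed$composition))
  nC <- registry$n_C[match(state_sp, registry$name)]
  cfeed_mmol <- stats::setNames(numeric(length(state_sp)), state_sp)
  cfeed_mmol[names(feed$composition)] <-
    feed$composition / registry$n_C[match(names(feed$composition),
                                          registry$name)]
  S_liq <- matrix(0, length(state_sp), length(rxn),
                  dimnames = list(state_sp, rxn))
  common <- intersect(state_sp, rownames(S))
  S_liq[common, ] <- S[common, ]

  acid_sp <- intersect(rownames(S),
                       c("acetate", "propionate", "n-butyrate", "i-butyrate",
                         "n-valerate", "n-caproate", "n-caprylate"))

  t_end <- max(phases$end_day)
  times <- 0
  while (max(times) < t_end) {
    times <- c(times, max(times) +
                 sample_every[(length(times) - 1) %% length(sample_every) + 1])
  }
  times <- times[times <= t_end]
  if (max(times) < t_end) times <- c(times, t_end)

  co2_supply_at <- function(t) {
    i <- findInterval(t, phases$start_day)
    if (t >= t_end) i <- nrow(phases)
    gas_volume_to_moles(phases$co2_load[i] * 1440, molar_volume)
  }
  n2_supply_at <- function(t) {
    i <- findInterval(t, phases$start_day)
    if (t >= t_end) i <- nrow(phases)
    gas_volume_to_moles(phases$n2_load[i] * 1440, molar_volume)
  }
  r_eff_at <- function(t) {
    r <- .prescribed_rates(t, schedule, phases, rxn)
    .effective_rates(r, S, co2_supply_at(t))$rates
  }
  base_molarity_at <- function(t) {
    base_molarity_schedule$molarity[findInterval(
      t, base_molarity_schedule$from_day)]
  }
  base_flow_at <- function(t, r) {
    acid_net <- sum(pmax(S[acid_sp, , drop = FALSE] %*% r, 0))  # mmol/L/d
    base_gain * acid_net * volume / base_molarity_at(t)          # mL/d
  }

  deriv <- function(t, y, parms) {
    r <- r_eff_at(t)
    qb <- base_flow_at(t, r) / 1000
    qf <- feed_flow / 1000
    dy <- (qf * cfeed_mmol - (qf + qb) * y) / volume +
      as.vector(S_liq %*% r)
    list(dy)
  }

  y0 <- if (identical(init, "feed")) {
    cfeed_mmol
  } else if (identical(init, "empty")) {
    stats::setNames(numeric(length(state_sp)), state_sp)
  } else {
    y <- stats::setNames(numeric(length(state_sp)), state_sp)
    nm <- resolve_compound(names(init), registry)
    y[nm] <- init / registry$n_C[match(nm, registry$name)]
    y
  }

  # integrate piecewise between phase boundaries (rate discontinuities)
  bounds <- sort(unique(c(phases$start_day, phases$end_day, times)))
  seg_edges <- sort(unique(c(phases$start_day, t_end)))
  sol_t <- 0
  sol_y <- matrix(y0, 1, dimnames = list(NULL, state_sp))
  y <- y0
  for (s in seq_len(length(seg_edges) - 1)) {
    seg <- bounds[bounds >= seg_edges[s] & bounds <= seg_edges[s + 1]]
    if (length(seg) < 2) seg <- c(seg_edges[s], seg_edges[s + 1])
    out <- deSolve::ode(y = y, times = seg, func = deriv, parms = NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-8)
    y <- out[nrow(out), -1]
    sol_t <- c(sol_t, out[-1, 1])
    sol_y <- rbind(sol_y, out[-1, -1, drop = FALSE])
  }
  if (any(sol_y < -1e-6)) {
    worst <- which(sol_y < -1e-6, arr.ind = TRUE)[1, ]
    stop("rate profile infeasible: '", state_sp[worst[2]],
         "' driven negative near day ", round(sol_t[worst[1]], 2),
         call. = FALSE)
  }
  sol_y[sol_y < 0] <- 0
  conc <- sol_y[match(times, sol_t), , drop = FALSE]   # mmol/L at samples

  # per-sample gas bookkeeping and base flow
  n <- length(times)
  gas_out_flow <- base_flow <- numeric(n)
  hs <- matrix(0, n, length(.HEADSPACE_SPECIES),
               dimnames = list(NULL, .HEADSPACE_SPECIES))
  underpressure <- logical(n)
  r_samples <- matrix(0, n, length(rxn), dimnames = list(NULL, rxn))
  spec_factor <- if (speciation) 1 + 10^(ph - pka1) else 1
  for (i in seq_len(n)) {
    t <- times[i]
    r0 <- .prescribed_rates(t, schedule, phases, rxn)
    eff <- .effective_rates(r0, S, co2_supply_at(t))
    r <- eff$rates
    underpressure[i] <- eff$underpressure
    r_samples[i, ] <- r
    base_flow[i] <- base_flow_at(t, r)
    net <- as.vector(S %*% r)
    names(net) <- rownames(S)
    g <- function(nm) if (nm %in% names(net)) net[[nm]] else 0
    A <- co2_supply_at(t) + g("co2")               # CO2 to dispose, mmol/L/d
    A <- max(A, 0)
    B <- n2_supply_at(t) + max(g("h2"), 0) + max(g("ch4"), 0)
    q_out <- feed_flow + base_flow[i]              # mL/d
    kdis <- kh * total_pressure * spec_factor * q_out / 1000 / volume * 1000
    split <- .split_co2_out(A, B, kdis)
    total_out <- split[["gas"]] + B                # mmol/L/d
    gas_out_flow[i] <- moles_to_gas_volume(total_out, molar_volume) *
      volume / 1440                                # NmL/min
    if (total_out > 0) {
      hs[i, "co2"] <- split[["gas"]] / total_out
      hs[i, "h2"] <- max(g("h2"), 0) / total_out
      hs[i, "n2"] <- n2_supply_at(t) / total_out
      hs[i, "ch4"] <- max(g("ch4"), 0) / total_out
    }
  }

  broth <- data.frame(time = times, sweep(conc, 2, nC, `*`),
                      check.names = FALSE)
  gas_in <- data.frame(
    time = times,
    co2 = vapply(times, function(t) {
      i <- findInterval(t, phases$start_day); if (t >= t_end) i <- nrow(phases)
      phases$co2_load[i]
    }, numeric(1)),
    n2 = vapply(times, function(t) {
      i <- findInterval(t, phases$start_day); if (t >= t_end) i <- nrow(phases)
      phases$n2_load[i]
    }, numeric(1)))
  scalars <- data.frame(
    time = times, gas_out_flow = gas_out_flow, feed_flow = feed_flow,
    base_flow = base_flow,
    base_molarity = vapply(times, base_molarity_at, numeric(1)),
    ph = ph, temperature = temperature)
  ts <- reactor_timeseries(broth, scalars,
                           gas_in, data.frame(time = times, hs,
                                              check.names = FALSE),
                           volume = volume, reactor_id = reactor_id)
  ts <- assign_phases(ts, phases)

  truth <- structure(list(
    schedule = schedule, reactions = reactions, phases = phases,
    sample_times = times, clean_broth = broth,
    reaction_rates = r_samples,
    interval_reaction_rates = .interval_reaction_rates(times, schedule,
                                                       phases, rxn, S,
                                                       co2_supply_at),
    underpressure = underpressure, seed = seed,
    noise = list(cv = noise_cv, replicates = replicates),
    feed = feed, volume = volume, feed_flow = feed_flow),
    class = "ce_ground_truth")
  truth$interval_net_cmol <- .net_cmol(truth$interval_reaction_rates, S,
                                       state_sp, nC)
  truth$phase_metrics <- do.call(rbind, lapply(seq_len(nrow(phases)),
    function(i) {
      tm <- true_phase_metrics_at(phases$end_day[i] - 1e-9, schedule, phases,
                                  reactions, registry, co2_supply_at)
      data.frame(phase = phases$name[i], eeo_true = tm$eeo,
                 c6_selectivity_true = tm$selectivity[["n-caproate"]] %||% NA,
                 alcohol_selectivity_true = tm$alcohol_selectivity)
    }))
  truth$phase_selectivity <- lapply(stats::setNames(seq_len(nrow(phases)),
                                                    phases$name),
    function(i) true_phase_metrics_at(phases$end_day[i] - 1e-9, schedule,
                                      phases, reactions, registry,
                                      co2_supply_at)$selectivity)

  if (noise_cv > 0) {
    ts <- apply_measurement_noise(ts, cv = noise_cv, seed = seed,
                                  replicates = replicates)
  }
  structure(list(timeseries = ts, truth = truth), class = "ce_simulation")
}

# exact interval averages of the effective reaction rates (Simpson rule on
# each between-boundary segment; exact for the piecewise-constant case)
.interval_reaction_rates <- function(times, schedule, phases, rxn, S,
                                     co2_supply_at) {
  k <- length(times) - 1
  out <- matrix(0, k, length(rxn), dimnames = list(NULL, rxn))
  edges <- sort(unique(c(phases$start_day, phases$end_day)))
  for (i in seq_len(k)) {
    t1 <- times[i]; t2 <- times[i + 1]
    cuts <- sort(unique(c(t1, t2, edges[edges > t1 & edges < t2])))
    acc <- stats::setNames(numeric(length(rxn)), rxn)
    for (s in seq_len(length(cuts) - 1)) {
      a <- cuts[s]; b <- cuts[s + 1]
      # open Simpson nodes keep evaluations off the discontinuities
      xs <- a + (b - a) * (seq(0.5, 20.5) / 21)
      vals <- vapply(xs, function(t) {
        .effective_rates(.prescribed_rates(t, schedule, phases, rxn), S,
                         co2_supply_at(t))$rates
      }, numeric(length(rxn)))
      acc <- acc + rowMeans(vals) * (b - a)
    }
    out[i, ] <- acc / (t2 - t1)
  }
  out
}

.net_cmol <- function(rate_mat, S, state_sp, nC) {
  S_liq <- matrix(0, length(state_sp), ncol(S),
                  dimnames = list(state_sp, colnames(S)))
  common <- intersect(state_sp, rownames(S))
  S_liq[common, ] <- S[common, ]
  net <- rate_mat %*% t(S_liq)          # intervals x species, mmol/L/d
  sweep(net, 2, nC, `*`)                # mCmol/L/d
}

# true metrics from the effective reaction rates at one instant
true_phase_metrics_at <- function(t, schedule, phases, reactions, registry,
                                  co2_supply_at) {
  S <- reactions$stoich
  r <- .effective_rates(.prescribed_rates(t, schedule, phases, colnames(S)),
                        S, co2_supply_at(t))$rates
  net <- stats::setNames(as.vector(S %*% r), rownames(S))
  rows <- registry[match(names(net), registry$name), ]
  is_prod <- rows$phase_hint == "liquid" & rows$n_C >= 1 &
    !(names(net) %in% c("ethanol", .NON_PRODUCTS)) & net > 0
  cmol <- net[is_prod] * rows$n_C[is_prod]
  selectivity <- if (sum(cmol) > 0) 100 * cmol / sum(cmol) else cmol
  alcohols <- intersect(c("propanol", "butanol", "hexanol"),
                        names(selectivity))
  s_steps <- sum(reactions$steps * r)
  e_cons <- -if ("ethanol" %in% names(net)) {
    sum(S["ethanol", ] * r)
  } else 0
  # ethanol-coupled carboxylate reductions: consume ethanol, make an alcohol
  redx <- vapply(seq_len(ncol(S)), function(j) {
    S["ethanol", j] < 0 &&
      any(S[intersect(c("propanol", "butanol", "hexanol"), rownames(S)), j] > 0)
  }, logical(1))
  e_red <- sum(r[redx])
  eeo <- if (e_cons > 0) {
    100 * (e_cons - s_steps - e_red - s_steps / 5) / e_cons
  } else NA_real_
  list(selectivity = as.list(selectivity),
       alcohol_selectivity = sum(unlist(selectivity[alcohols])),
       eeo = eeo, elongation_steps = s_steps,
       ethanol_consumption = e_cons)
}

#' True end-of-phase metrics of a simulation
#'
#' Ground-truth EEO and Cmol% selectivities computed directly from the
#' simulator's effective reaction rates (stoichiometry plus per-reaction
#' elongation-step annotation) at the end of a phase — an oracle
#' independent of the concentration-based analysis pipeline.
#'
#' @param sim a `ce_simulation` from [simulate_reactor()].
#' @param phase phase name; default the last phase.
#' @return List with `selectivity` (Cmol% by product),
#'   `alcohol_selectivity`, `eeo`, `elongation_steps` and
#'   `ethanol_consumption` (mmol L^-1 d^-1).
#' @export
true_phase_metrics <- function(sim, phase = NULL) {
  tr <- sim$truth
  phases <- tr$phases
  if (is.null(phase)) phase <- phases$name[nrow(phases)]
  i <- match(phase, phases$name)
  if (is.na(i)) stop("unknown phase '", phase, "'", call. = FALSE)
  co2_supply_at <- function(t) {
    j <- findInterval(t, phases$start_day)
    if (t >= max(phases$end_day)) j <- nrow(phases)
    gas_volume_to_moles(phases$co2_load[j] * 1440)
  }
  true_phase_metrics_at(phases$end_day[i] - 1e-9, tr$schedule, phases,
                        tr$reactions, compound_registry(), co2_supply_at)
}

#' @export
print.ce_simulation <- function(x, ...) {
  tr <- x$truth
  cat("Simulated chain-elongation reactor (", length(tr$sample_times),
      " samples, days ", min(tr$sample_times), "-", max(tr$sample_times),
      ")\n", sep = "")
  cat("  phases:", paste(tr$phases$name, collapse = ", "),
      "| noise cv", tr$noise$cv,
      if (any(tr$underpressure)) "| UNDERPRESSURE flagged" else "", "\n")
  print(tr$phase_metrics, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Apply multiplicative measurement noise to a reactor time series
#'
#' Emulates GC measurement error: every broth concentration, headspace
#' fraction and off-gas flow is multiplied by `1 + cv * z`, `z` standard
#' normal, truncated at zero; with `replicates > 1` the reported value is
#' the mean of that many analytical replicates. Headspace fractions are
#' renormalised to their original sum (GC compositions are reported
#' normalised). Deterministic under a fixed seed.
#'
#' @param ts a [reactor_timeseries()].
#' @param cv relative standard deviation per replicate (>= 0).
#' @param seed RNG seed; `NULL` uses the current RNG state.
#' @param replicates analytical replicates averaged per reported value.
#' @return The noised [reactor_timeseries()].
#' @export
apply_measurement_noise <- function(ts, cv, seed = NULL, replicates = 1) {
  if (cv < 0) stop("cv must be non-negative", call. = FALSE)
  if (cv == 0) return(ts)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  noisy <- function(x) {
    reps <- vapply(seq_len(replicates), function(r) {
      pmax(0, x * (1 + cv * stats::rnorm(length(x))))
    }, numeric(length(x)))
    if (length(x) == 1) mean(reps) else rowMeans(reps)
  }
  for (cc in setdiff(names(ts$broth), "time")) {
    ts$broth[[cc]] <- noisy(ts$broth[[cc]])
  }
  hs_cols <- setdiff(names(ts$headspace), "time")
  hs <- as.matrix(ts$headspace[hs_cols])
  target <- rowSums(hs)
  hs_noisy <- apply(hs, 2, noisy)
  if (length(target) == 1) hs_noisy <- matrix(hs_noisy, 1)
  sums <- rowSums(hs_noisy)
  scale <- ifelse(sums > 0, target / sums, 1)
  ts$headspace[hs_cols] <- hs_noisy * scale
  ts$scalars$gas_out_flow <- noisy(ts$scalars$gas_out_flow)
  validate_timeseries(ts)
  ts
}
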