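# Compound registry and unit conversions.
#
# All balances in this package run on two consistent scales:
#   carbon:    mCmol (millimoles of carbon), the "mMC" convention of
#              chain-elongation practice;
#   electrons: "available electron equivalents" per mol, gamma * n_C for
#              carbon compounds, where gamma is the degree of reduction per
#              Cmol relative to CO2/H2O/NH3. H2 carries 2 equivalents per
#              mol (H2 -> 2 H+ + 2 e-), O2 -4, and CO2/H2O/N2/NH3 zero.

# standard atomic masses (g/mol)
.ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999, N = 14.007)

# molar volume of an ideal gas at the default "normal" reference conditions,
# 273.15 K and 101.325 kPa, in NmL/mmol (= L/mol)
.MOLAR_VOLUME_NORMAL <- 22.414

.ce_cache <- new.env(parent = emptyenv())

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Degree of reduction per carbon mole
#'
#' Electron equivalents per Cmol relative to CO2, H2O and NH3:
#' `(4 n_C + n_H - 2 n_O - 3 n_N) / n_C`. Ethanol is 6, acetic acid 4,
#' CO2 0, methane 8; the generic biomass formula CH1.8O0.5N0.2 gives 4.2.
#'
#' @param n_C,n_H,n_O,n_N atom counts of the (undissociated) molecule.
#'   `n_C` must be at least 1; carbon-free species (H2, N2, ...) carry their
#'   electron content as a per-mol constant instead (see
#'   [electrons_per_mol()]).
#' @return Degree of reduction per Cmol (dimensionless).
#' @examples
#' degree_of_reduction(2, 6, 1)  # ethanol: 6
#' degree_of_reduction(6, 12, 2) # caproic acid: 5.333...
#' @export
degree_of_reduction <- function(n_C, n_H, n_O, n_N = 0) {
  if (any(n_C < 1)) {
    stop("degree_of_reduction() is undefined for carbon-free species (n_C < 1); ",
         "use electrons_per_mol() for H2 and other gases", call. = FALSE)
  }
  (4 * n_C + n_H - 2 * n_O - 3 * n_N) / n_C
}

#' Compound registry
#'
#' Elemental composition, molar mass, degree of reduction and electron
#' content for every species tracked by the package: linear and branched
#' C2-C8 acids, C2-C6 primary alcohols, the gases CO2/H2/N2/CH4/O2, water,
#' ammonia and a generic biomass (CH1.8O0.5N0.2). Shipped as a
#' human-editable CSV (`inst/extdata/compounds.csv`); acids are listed in
#' their undissociated form so that elemental balances stay charge-free.
#'
#' @param path optional path to an alternative registry CSV with columns
#'   `name, n_C, n_H, n_O, n_N, molar_mass, phase_hint, synonyms`
#'   (synonyms separated by `;`).
#' @return A data frame with one row per compound and derived columns
#'   `gamma` (degree of reduction per Cmol, `NA` for carbon-free species)
#'   and `electrons_per_mol`.
#' @examples
#' reg <- compound_registry()
#' reg[reg$name == "n-caproate", c("n_C", "molar_mass", "gamma")]
#' @export
compound_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.ce_cache$registry)) return(.ce_cache$registry)
    path <- system.file("extdata", "compounds.csv", package = "chainelong",
                        mustWork = TRUE)
    cache <- TRUE
  } else {
    cache <- FALSE
  }
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("name", "n_C", "n_H", "n_O", "n_N", "molar_mass",
              "phase_hint", "synonyms")
  missing <- setdiff(needed, names(reg))
  if (length(missing)) {
    stop("compound registry at '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mw <- reg$n_C * .ATOMIC_MASS[["C"]] + reg$n_H * .ATOMIC_MASS[["H"]] +
    reg$n_O * .ATOMIC_MASS[["O"]] + reg$n_N * .ATOMIC_MASS[["N"]]
  off <- abs(mw - reg$molar_mass) > 0.01
  if (any(off)) {
    stop("registry molar mass disagrees with atom counts (> 0.01 g/mol) for: ",
         paste(reg$name[off], collapse = ", "), call. = FALSE)
  }
  reg$carbon_number <- reg$n_C
  reg$gamma <- ifelse(reg$n_C >= 1,
                      (4 * reg$n_C + reg$n_H - 2 * reg$n_O - 3 * reg$n_N) / reg$n_C,
                      NA_real_)
  reg$electrons_per_mol <- ifelse(reg$n_C >= 1, reg$gamma * reg$n_C, 0)
  reg$electrons_per_mol[reg$name == "h2"] <- 2
  reg$electrons_per_mol[reg$name == "o2"] <- -4
  if (cache) .ce_cache$registry <- reg
  reg
}

# lookup table canonical-or-synonym -> canonical name (lower-cased keys)
.registry_alias_map <- function(registry) {
  syn <- strsplit(registry$synonyms, ";", fixed = TRUE)
  keys <- c(registry$name, unlist(syn))
  vals <- c(registry$name, rep(registry$name, lengths(syn)))
  keep <- nzchar(keys)
  stats::setNames(vals[keep], tolower(trimws(keys[keep])))
}

#' Resolve compound names (including synonyms) to registry names
#'
#' @param names character vector of compound names or synonyms
#'   (case-insensitive; e.g. `"n-C6"`, `"EtOH"`, `"caproate"`).
#' @param registry a [compound_registry()] data frame.
#' @return Canonical registry names.
#' @export
resolve_compound <- function(names, registry = compound_registry()) {
  map <- .registry_alias_map(registry)
  out <- map[tolower(trimws(names))]
  if (anyNA(out)) {
    stop("unknown compound name(s): ",
         paste(unique(names[is.na(out)]), collapse = ", "),
         " (not in registry or its synonyms)", call. = FALSE)
  }
  unname(out)
}

.compound_row <- function(name, registry = compound_registry()) {
  registry[match(resolve_compound(name, registry), registry$name), , drop = FALSE]
}

#' Electron equivalents per mol of a compound
#'
#' @inheritParams resolve_compound
#' @param names compound names or synonyms.
#' @return Available electron equivalents per mol (gamma * n_C for carbon
#'   compounds, 2 for H2, -4 for O2, 0 for CO2/H2O/N2/NH3).
#' @export
electrons_per_mol <- function(names, registry = compound_registry()) {
  .compound_row(names, registry)$electrons_per_mol
}

#' Convert a carbon-molar rate to a mass rate
#'
#' `rate [mCmol/L/d] * molar_mass / carbon_number` gives mg/L/d; e.g. a CO2
#' utilisation of 163 mCmol/L/d is 7.17 g/L/d.
#'
#' @param rate numeric, mCmol L^-1 d^-1 (or any mCmol-based quantity; the
#'   conversion is per-Cmol and unit-shape preserving).
#' @param compound a single compound name or synonym.
#' @param registry a [compound_registry()] data frame.
#' @return Rate in mg L^-1 d^-1.
#' @export
cmol_rate_to_mass_rate <- function(rate, compound, registry = compound_registry()) {
  row <- .compound_row(compound, registry)
  if (row$carbon_number < 1) {
    stop("'", compound, "' carries no carbon; a Cmol rate is undefined for it",
         call. = FALSE)
  }
  rate * row$molar_mass / row$carbon_number
}

#' Convert a mass rate to a carbon-molar rate
#'
#' Inverse of [cmol_rate_to_mass_rate()].
#'
#' @param rate numeric, mg L^-1 d^-1.
#' @inheritParams cmol_rate_to_mass_rate
#' @return Rate in mCmol L^-1 d^-1.
#' @export
mass_rate_to_cmol_rate <- function(rate, compound, registry = compound_registry()) {
  row <- .compound_row(compound, registry)
  if (row$carbon_number < 1) {
    stop("'", compound, "' carries no carbon; a Cmol rate is undefined for it",
         call. = FALSE)
  }
  rate * row$carbon_number / row$molar_mass
}

#' Convert a "normal" gas volume to moles
#'
#' Gas dosing and off-gas flows are metered in NmL, i.e. volumes at a fixed
#' reference state. The reference is not universal; the default molar volume
#' of 22.414 NmL/mmol corresponds to 273.15 K and 101.325 kPa and can be
#' overridden wherever a different convention applies.
#'
#' @param volume gas volume in NmL (non-negative).
#' @param molar_volume molar volume at the reference conditions, NmL/mmol.
#' @return Amount in mmol.
#' @examples
#' gas_volume_to_moles(22.414) # 1 mmol
#' @export
gas_volume_to_moles <- function(volume, molar_volume = .MOLAR_VOLUME_NORMAL) {
  if (any(volume < 0)) stop("gas volume must be non-negative", call. = FALSE)
  volume / molar_volume
}

#' Convert moles of gas to a "normal" volume
#'
#' @param moles amount in mmol.
#' @inheritParams gas_volume_to_moles
#' @return Volume in NmL.
#' @export
moles_to_gas_volume <- function(moles, molar_volume = .MOLAR_VOLUME_NORMAL) {
  moles * molar_volume
}
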