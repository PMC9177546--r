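#' Kinetic and stoichiometric parameter registry
#'
#' Builds the bundled 68-entry parameter registry of the reduced IFAS
#' biokinetic model. Seven headline parameters carry their field names and
#' software defaults (aerobic/anoxic heterotrophic yields, heterotrophic
#' decay rate, reduction factor for denitrification on nitrite-N, oxygen
#' inhibition coefficient for denitrification, unbiodegradable fraction from
#' cell decay, maximum growth rate of the nitrite oxidizer). The remaining
#' entries are standard activated-sludge constants: those consumed by the
#' reduced model are marked `active = TRUE`; the rest are documented
#' placeholders that pad the registry to the full screening size of a
#' comprehensive biokinetic model and take no part in the reduced kinetics.
#'
#' Screening/decomposition ranges default to +/-50% of each default value
#' (`low`, `high`). Literature-derived uncertainty ranges for the headline
#' parameters live in a separate fixture (see [read_pdf_specs()]).
#'
#' @param k total number of registry entries (default 68). Values smaller
#'   than 68 truncate inactive padding only; active entries are always kept.
#' @return A `parameter_registry` data frame with columns `code`, `name`,
#'   `units`, `kind` (kinetic/stoichiometric), `role` (short identifier used
#'   by the model engine, `NA` for inactive padding), `default`, `low`,
#'   `high`, `pdf`, `active`.
#' @export
#' @examples
#' reg <- ifas_registry()
#' nrow(reg)                      # 68
#' reg[reg$code == "X52", ]       # aerobic heterotrophic yield, default 0.666
ifas_registry <- function(k = 68) {
  row <- function(code, name, units, kind, role, default, active = TRUE)
    data.frame(code = code, name = name, units = units, kind = kind,
               role = role, default = default, active = active,
               stringsAsFactors = FALSE)

  active <- rbind(
    row("X10", "Maximum specific growth rate of heterotrophs", "1/d", "kinetic", "mu_H", 6.0),
    row("X12", "Reduction factor for denitrification on nitrite-N", "-", "kinetic", "eta_NO2", 0.48),
    row("X13", "Half-saturation of readily biodegradable substrate", "mgCOD/L", "kinetic", "K_S", 20),
    row("X14", "Oxygen half-saturation for heterotrophic growth", "mgO2/L", "kinetic", "K_OH", 0.2),
    row("X15", "Oxygen inhibition coefficient for denitrification", "mgO2/L", "kinetic", "K_O_den", 0.2),
    row("X16", "Aerobic heterotrophic decay rate", "1/d", "kinetic", "b_H", 0.62),
    row("X17", "Nitrate half-saturation for anoxic growth", "mgN/L", "kinetic", "K_NO3", 0.5),
    row("X18", "Nitrite half-saturation for anoxic growth", "mgN/L", "kinetic", "K_NO2", 0.5),
    row("X20", "Maximum growth rate for ammonia oxidizer", "1/d", "kinetic", "mu_AOB", 0.9),
    row("X21", "Ammonia half-saturation for ammonia oxidizer", "mgN/L", "kinetic", "K_NH", 0.7),
    row("X22", "Oxygen half-saturation for autotrophic growth", "mgO2/L", "kinetic", "K_OA", 0.4),
    row("X23", "Autotrophic decay rate", "1/d", "kinetic", "b_A", 0.17),
    row("X27", "Maximum growth rate for nitrite oxidizer", "1/d", "kinetic", "mu_NOB", 0.7),
    row("X28", "Nitrite half-saturation for nitrite oxidizer", "mgN/L", "kinetic", "K_NO2_NOB", 0.5),
    row("X30", "Maximum specific hydrolysis rate", "1/d", "kinetic", "k_h", 3.0),
    row("X31", "Hydrolysis half-saturation coefficient", "gCOD/gCOD", "kinetic", "K_X", 0.03),
    row("X32", "Ammonification rate coefficient", "m3/(gCOD.d)", "kinetic", "k_a", 0.08),
    row("X33", "Biomass attachment rate onto media", "1/d", "kinetic", "k_att", 0.4),
    row("X34", "Biofilm detachment rate", "1/d", "kinetic", "k_det", 0.05),
    row("X52", "Aerobic heterotrophic yield on soluble substrate", "mgCOD/mgCOD", "stoichiometric", "Y_H_aer", 0.666),
    row("X53", "Anoxic heterotrophic yield on soluble substrate", "mgCOD/mgCOD", "stoichiometric", "Y_H_anx", 0.533),
    row("X54", "Ammonia oxidizer yield", "gCOD/gN", "stoichiometric", "Y_AOB", 0.18),
    row("X55", "Nitrite oxidizer yield", "gCOD/gN", "stoichiometric", "Y_NOB", 0.06),
    row("X61", "Unbiodegradable fraction from cell decay", "-", "stoichiometric", "f_U", 0.08),
    row("X62", "Nitrogen content of active biomass", "gN/gCOD", "stoichiometric", "i_XB", 0.086)
  )

  pad_names <- c(
    X1 = "Maximum specific fermentation rate|1/d|kinetic|3",
    X2 = "Fermentation half-saturation coefficient|mgCOD/L|kinetic|4",
    X3 = "Fermentable substrate half-saturation for heterotrophs|mgCOD/L|kinetic|4",
    X4 = "Alkalinity half-saturation coefficient|mmolHCO3/L|kinetic|0.1",
    X5 = "Anaerobic hydrolysis reduction factor|-|kinetic|0.1",
    X6 = "Anoxic hydrolysis reduction factor|-|kinetic|0.6",
    X7 = "Ammonia half-saturation for heterotrophic synthesis|mgN/L|kinetic|0.05",
    X8 = "Phosphorus half-saturation for growth|mgP/L|kinetic|0.01",
    X9 = "Colloidal substrate flocculation rate|1/d|kinetic|0.15",
    X11 = "Reduction factor for denitrification on nitrate-N|-|kinetic|0.48",
    X19 = "Oxygen half-saturation for hydrolysis inhibition|mgO2/L|kinetic|0.2",
    X24 = "Maximum acetate uptake rate for phosphorus accumulators|1/d|kinetic|3",
    X25 = "Storage-polymer half-saturation for phosphorus accumulators|gCOD/gCOD|kinetic|0.01",
    X26 = "Phosphorus accumulator lysis rate|1/d|kinetic|0.2",
    X29 = "Anoxic reduction factor for autotrophic decay|-|kinetic|0.5",
    X35 = "Maximum growth rate of fermenting organisms|1/d|kinetic|3",
    X36 = "Volatile fatty acid half-saturation|mgCOD/L|kinetic|4",
    X37 = "Maximum growth rate of methylotrophs|1/d|kinetic|1.3",
    X38 = "Methanol half-saturation|mgCOD/L|kinetic|0.5",
    X39 = "Nitrous-oxide reduction rate coefficient|1/d|kinetic|0.5",
    X40 = "Free-ammonia inhibition coefficient for nitrite oxidation|mgN/L|kinetic|1",
    X41 = "Free-nitrous-acid inhibition coefficient|mgN/L|kinetic|0.2",
    X42 = "Assimilative nitrate reduction rate|1/d|kinetic|0.1",
    X43 = "Maximum specific colloid adsorption rate|1/d|kinetic|0.8",
    X44 = "Adsorbed substrate hydrolysis rate|1/d|kinetic|2",
    X45 = "Endogenous respiration rate under anoxia|1/d|kinetic|0.3",
    X46 = "Maximum specific denitrification rate on storage products|1/d|kinetic|0.7",
    X47 = "Storage yield under aerobic conditions|gCOD/gCOD|kinetic|0.85",
    X48 = "Storage yield under anoxic conditions|gCOD/gCOD|kinetic|0.8",
    X49 = "Half-saturation of storage products|gCOD/gCOD|kinetic|1",
    X50 = "Maximum specific storage rate|1/d|kinetic|5",
    X51 = "Oxygen half-saturation for storage|mgO2/L|kinetic|0.2",
    X56 = "Fermentation yield|gCOD/gCOD|stoichiometric|0.18",
    X57 = "Yield of phosphorus accumulators|gCOD/gCOD|stoichiometric|0.639",
    X58 = "Polyphosphate storage yield|gP/gCOD|stoichiometric|0.4",
    X59 = "Yield of methylotrophs|gCOD/gCOD|stoichiometric|0.45",
    X60 = "Fraction of inert COD in slowly biodegradable substrate|-|stoichiometric|0.05",
    X63 = "Nitrogen content of particulate inert products|gN/gCOD|stoichiometric|0.06",
    X64 = "Nitrogen content of soluble inerts|gN/gCOD|stoichiometric|0.01",
    X65 = "Phosphorus content of active biomass|gP/gCOD|stoichiometric|0.02",
    X66 = "Phosphorus content of inert products|gP/gCOD|stoichiometric|0.01",
    X67 = "COD of colloidal influent fraction|gCOD/gCOD|stoichiometric|0.15",
    X68 = "Soluble fraction of decay products|-|stoichiometric|0.05"
  )
  pad <- do.call(rbind, lapply(names(pad_names), function(code) {
    parts <- strsplit(pad_names[[code]], "|", fixed = TRUE)[[1]]
    n <- length(parts)
    row(code, parts[1], parts[2], parts[n - 1], NA_character_,
        as.numeric(parts[n]), active = FALSE)
  }))

  reg <- rbind(active, pad)
  ord <- order(as.integer(sub("^X", "", reg$code)))
  reg <- reg[ord, , drop = FALSE]
  if (k < nrow(reg)) {
    keep_inactive <- which(!reg$active)
    drop <- utils::tail(keep_inactive, nrow(reg) - k)
    if (length(drop) < nrow(reg) - k)
      stop_ifas("cannot truncate registry below its active entry count")
    reg <- reg[-drop, , drop = FALSE]
  }
  reg$low <- 0.5 * reg$default
  reg$high <- 1.5 * reg$default
  reg$pdf <- "uniform"
  rownames(reg) <- NULL
  reg <- reg[, c("code", "name", "units", "kind", "role", "default",
                 "low", "high", "pdf", "active")]
  class(reg) <- c("parameter_registry", "data.frame")
  validate_registry(reg)
  reg
}

validate_registry <- function(reg) {
  stopifnot(is.data.frame(reg))
  need <- c("code", "name", "units", "kind", "default", "low", "high")
  miss <- setdiff(need, names(reg))
  if (length(miss))
    stop_ifas("registry is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(reg$code))
    stop_ifas("registry codes must be unique")
  bad <- which(!(reg$low <= reg$default & reg$default <= reg$high))
  if (length(bad))
    stop_ifas("registry rows violate low <= default <= high: ",
              paste(reg$code[bad], collapse = ", "))
  if (any(reg$high - reg$low <= 0))
    stop_ifas("registry ranges must have positive width")
  invisible(reg)
}

#' Default parameter vector from a registry
#'
#' @param registry a [ifas_registry()] data frame.
#' @return Named numeric vector (codes -> default values) covering the full
#'   registry, i.e. a complete point in parameter space.
#' @export
default_params <- function(registry = ifas_registry()) {
  validate_registry(registry)
  stats::setNames(registry$default, registry$code)
}

#' Validate a parameter vector against its registry
#'
#' Checks completeness (every registry code present) and range membership.
#'
#' @param params named numeric vector (code -> value).
#' @param registry parameter registry.
#' @param clip if `TRUE`, values are clipped into `[low, high]` instead of
#'   failing.
#' @return The (possibly clipped) parameter vector, invisibly valid.
#' @export
as_parameter_vector <- function(params, registry = ifas_registry(), clip = FALSE) {
  validate_registry(registry)
  miss <- setdiff(registry$code, names(params))
  if (length(miss))
    stop_ifas("parameter vector is missing codes: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(params), registry$code)
  if (length(extra))
    stop_ifas("unknown parameter codes: ", paste(extra, collapse = ", "))
  p <- params[registry$code]
  if (clip) {
    p <- pmin(pmax(p, registry$low), registry$high)
  } else {
    bad <- which(p < registry$low | p > registry$high)
    if (length(bad))
      stop_ifas("parameter values out of range: ",
                paste(registry$code[bad], collapse = ", "))
  }
  p
}

# Extract the role-named list of constants the model engine consumes.
model_constants <- function(params, registry = ifas_registry()) {
  act <- registry[registry$active, ]
  miss <- setdiff(act$code, names(params))
  if (length(miss))
    stop_ifas("missing parameter code(s): ", paste(miss, collapse = ", "))
  stats::setNames(as.list(as.numeric(params[act$code])), act$role)
}

#' Read / write a parameter registry CSV
#'
#' Plain-text interchange format: one row per parameter with the same columns
#' as [ifas_registry()].
#'
#' @param path CSV file path.
#' @export
read_registry <- function(path) {
  reg <- utils::read.csv(path, stringsAsFactors = FALSE)
  reg$active <- as.logical(reg$active)
  reg$role[!is.na(reg$role) & reg$role == ""] <- NA_character_
  class(reg) <- c("parameter_registry", "data.frame")
  validate_registry(reg)
  reg
}

#' @rdname read_registry
#' @param registry registry to write.
#' @export
write_registry <- function(registry, path) {
  validate_registry(registry)
  utils::write.csv(registry, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.parameter_registry <- function(x, ...) {
  cat(sprintf("<parameter_registry> %d parameters (%d active in the reduced model)\n",
              nrow(x), sum(x$active)))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...", nrow(x) - 8, "more rows\n")
  invisible(x)
}
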