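#' Parameter registry
#'
#' The fixed registry of quantitative readouts computed from an aortic-ring
#' explant network, grouped into the four subindex categories used by the
#' angiogenic activity index: explant, pattern, network properties and
#' sprouting. Twelve parameters are scored by default; the remainder
#' (circumference, raw counts whose normalized forms are scored, and per-hour
#' speed variants) are measured and reported but excluded from the default
#' index so that no quantity enters the score twice.
#'
#' @return A data frame with columns `parameter`, `category`, `units` and
#'   `scored` (logical, member of the default 12-parameter index).
#' @export
#' @examples
#' parameter_registry()
parameter_registry <- function() {
  reg <- rbind(
    data.frame(parameter = "migration",                  category = "explant",            units = "%",        scored = TRUE),
    data.frame(parameter = "ring_circumference",         category = "explant",            units = "um",       scored = FALSE),
    data.frame(parameter = "vessel_structure_pct",       category = "pattern",            units = "%",        scored = TRUE),
    data.frame(parameter = "n_loops",                    category = "pattern",            units = "count",    scored = TRUE),
    data.frame(parameter = "max_radial_outgrowth",       category = "network_properties", units = "um",       scored = TRUE),
    data.frame(parameter = "max_initial_vessel_length",  category = "network_properties", units = "um",       scored = TRUE),
    data.frame(parameter = "total_vessel_length",        category = "network_properties", units = "um",       scored = TRUE),
    data.frame(parameter = "mean_vessel_length",         category = "network_properties", units = "um",       scored = TRUE),
    data.frame(parameter = "speed_mean_initial_length",  category = "network_properties", units = "um/day",   scored = TRUE),
    data.frame(parameter = "speed_max_initial_length",   category = "network_properties", units = "um/day",   scored = FALSE),
    data.frame(parameter = "speed_mean_initial_length_per_h", category = "network_properties", units = "um/h", scored = FALSE),
    data.frame(parameter = "speed_max_initial_length_per_h",  category = "network_properties", units = "um/h", scored = FALSE),
    data.frame(parameter = "vessel_count",               category = "sprouting",          units = "count",    scored = FALSE),
    data.frame(parameter = "vessel_density",             category = "sprouting",          units = "count/mm", scored = TRUE),
    data.frame(parameter = "n_branches",                 category = "sprouting",          units = "count",    scored = TRUE),
    data.frame(parameter = "mean_branch_length",         category = "sprouting",          units = "um",       scored = TRUE),
    data.frame(parameter = "n_junctions",                category = "sprouting",          units = "count",    scored = FALSE),
    data.frame(parameter = "junctions_per_vessel",       category = "sprouting",          units = "count",    scored = TRUE)
  )
  rownames(reg) <- NULL
  reg
}

#' Names of the twelve default scored parameters
#' @return Character vector in registry order.
#' @export
scored_parameters <- function() {
  reg <- parameter_registry()
  reg$parameter[reg$scored]
}

#' Subindex category of registry parameters
#' @param parameters Character vector of registry parameter names.
#' @return Character vector of categories.
#' @export
parameter_category <- function(parameters) {
  reg <- parameter_registry()
  idx <- match(parameters, reg$parameter)
  if (anyNA(idx)) {
    stop_angioring("unknown_parameter",
                   paste("unknown parameter(s):",
                         paste(parameters[is.na(idx)], collapse = ", ")))
  }
  reg$category[idx]
}

# Fixed ordering of the subindex categories (also the radar-profile order).
subindex_categories <- function() {
  c("explant", "pattern", "network_properties", "sprouting")
}

parameter_units <- function(parameters) {
  reg <- parameter_registry()
  reg$units[match(parameters, reg$parameter)]
}
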