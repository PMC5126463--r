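#' The 22-mediator plasma cytokine/chemokine panel
#'
#' Names of the circulating inflammatory mediators measured by the
#' multiplex bead immunoassay panel this package analyses: interleukins,
#' soluble receptors, chemokines and TNF, all in pg/mL plasma.
#' Greek letters are transliterated (`IL-1b` for IL-1beta, `IFN-g` for
#' IFN-gamma, ...) so the names survive CSV round trips.
#'
#' @return Character vector of 22 unique mediator names.
#' @export
#' @examples
#' mediator_panel()
mediator_panel <- function() {
  c("IL-1b", "IL-1RA", "IL-2", "sIL-2Ra", "IL-4", "IL-5", "IL-6", "IL-7",
    "IL-8", "IL-10", "IL-13", "IL-15", "IL-17A", "IFN-g", "IP-10", "MIG",
    "MIP-1a", "MIP-1b", "MCP-1", "GM-CSF", "Eotaxin", "TNF-a")
}

# Mediators reported as differentially elevated in the high-BD stratum,
# with the log10 group effect implied by the published 0-24 h / day-7
# fold changes (log10 of fold, AUC-scale).  Mediators absent from this
# table get no group effect.
.default_group_effects <- c(
  "IL-1RA"  = log10(3.1),
  "IL-7"    = log10(2.2),
  "IL-8"    = log10(2.1),
  "sIL-2Ra" = log10(1.9),
  "MCP-1"   = log10(1.6),
  "IL-6"    = log10(1.6),
  "IL-5"    = log10(1.8),
  "IFN-g"   = log10(1.5),
  "IL-13"   = log10(1.4),
  "IL-4"    = log10(1.4),
  "IL-2"    = log10(1.3),
  "MIP-1b"  = log10(1.3),
  "TNF-a"   = log10(1.2)
)

# Baseline log10 pg/mL at the first draw for the low-BD stratum, chosen
# to give AUC magnitudes on the scale of the published tables (e.g.
# MCP-1 and IL-1RA in the tens of pg/mL, IL-7/IL-8 in single digits).
.default_baseline_log10 <- c(
  "IL-1b" = 0.5, "IL-1RA" = 1.65, "IL-2" = 0.70, "sIL-2Ra" = 1.35,
  "IL-4" = 1.30, "IL-5" = 0.95, "IL-6" = 1.60, "IL-7" = 0.80,
  "IL-8" = 0.85, "IL-10" = 1.10, "IL-13" = 1.00, "IL-15" = 0.60,
  "IL-17A" = 0.70, "IFN-g" = 1.30, "IP-10" = 2.30, "MIG" = 2.40,
  "MIP-1a" = 1.30, "MIP-1b" = 1.75, "MCP-1" = 1.95, "GM-CSF" = 0.90,
  "Eotaxin" = 1.90, "TNF-a" = 0.80
)

#' Default per-cell mean log10 concentrations
#'
#' Builds the mediator x group x time array of mean log10(pg/mL)
#' concentrations used by [simulation_config()]. Each mediator starts
#' from a baseline at the first draw and decays slowly towards day 7
#' (an acute-phase profile); the high-BD stratum (`BD_GE`) is shifted
#' upward for the mediators known to respond to metabolic acidosis, by
#' the log10 of their published fold change.
#'
#' @param mediators Character vector of mediator names.
#' @param times_h Numeric vector of nominal draw times in hours.
#' @return Numeric array with `dim = c(mediators, 2 groups, times)` and
#'   dimnames `(mediator, c("BD_LT", "BD_GE"), time)`.
#' @export
default_log_means <- function(mediators = mediator_panel(),
                              times_h = c(4, 12, 20, 48, 72, 96, 120, 144, 168)) {
  base <- .default_baseline_log10[mediators]
  base[is.na(base)] <- 1.0
  eff <- .default_group_effects[mediators]
  eff[is.na(eff)] <- 0
  # acute-phase decay: flat over day 1, then -0.4 log10 by day 7
  decay <- vapply(times_h, function(t) -0.4 * max(0, t - 24) / 144, numeric(1))
  arr <- array(NA_real_,
               dim = c(length(mediators), 2L, length(times_h)),
               dimnames = list(mediators, c("BD_LT", "BD_GE"),
                               as.character(times_h)))
  for (k in seq_along(times_h)) {
    arr[, "BD_LT", k] <- base + decay[k]
    arr[, "BD_GE", k] <- base + eff + decay[k]
  }
  arr
}
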