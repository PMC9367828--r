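# Suspended / dissolved / settled partition of total silver from instrument
# readouts. Unit conversions (mg/L vs ug/L) are centralised here.

ug_per_mg <- 1000

#' Dissolution percentage
#'
#' 100 * dissolved (ug/L) / total (mg/L converted to ug/L).
#'
#' @param dissolved_ug_L Dissolved Ag from AAS, ug/L (>= 0).
#' @param total_mg_L Total initial nanoparticle Ag, mg/L (> 0).
#' @return Percent dissolved (full precision; display rounding is the
#'   caller's choice).
#' @export
#' @examples
#' round(dissolution_percent(156.7, 1.68), 1)  # 9.3
dissolution_percent <- function(dissolved_ug_L, total_mg_L) {
  if (any(total_mg_L <= 0)) abort("total_mg_L must be > 0")
  if (any(dissolved_ug_L < 0)) abort("dissolved_ug_L must be >= 0")
  if (any(dissolved_ug_L > total_mg_L * ug_per_mg)) {
    abort("dissolved Ag exceeds total Ag")
  }
  100 * dissolved_ug_L / (total_mg_L * ug_per_mg)
}

#' Suspended fraction from NTA number concentrations
#'
#' 100 * sample / control, capped at 100. Assumes the control's
#' number-to-mass mapping (a documented limitation once aggregates form).
#'
#' @param sample_number_conc Particle number concentration of the sample,
#'   particles/mL (>= 0).
#' @param control_number_conc Control concentration, particles/mL (> 0).
#' @return Percent suspended.
#' @export
suspended_fraction <- function(sample_number_conc, control_number_conc) {
  if (any(control_number_conc <= 0)) abort("control concentration must be > 0")
  if (any(sample_number_conc < 0)) abort("sample concentration must be >= 0")
  pmin(100 * sample_number_conc / control_number_conc, 100)
}

#' Close the silver mass balance
#'
#' The settled (plus container-adsorbed) share is the closure term:
#' settled = 100 - suspended - dissolved. The three fractions must sum to
#' 100 within a 0.5 percentage-point closure tolerance; physically
#' impossible inputs (settled below -0.5) raise an error.
#'
#' @param total_mg_L Total Ag, mg/L.
#' @param dissolved_ug_L Dissolved Ag, ug/L.
#' @param suspended_pct Suspended share, percent in `[0, 100]`.
#' @return A one-row tibble (`total_mg_L`, `dissolved_ug_L`,
#'   `suspended_pct`, `dissolved_pct`, `settled_pct`).
#' @export
#' @examples
#' close_balance(1.68, 156.7, 10.7)  # SW condition: settled 80.0
close_balance <- function(total_mg_L, dissolved_ug_L, suspended_pct) {
  if (suspended_pct < 0 || suspended_pct > 100) {
    abort("suspended_pct must be in [0, 100]")
  }
  dis <- dissolution_percent(dissolved_ug_L, total_mg_L)
  settled <- 100 - suspended_pct - dis
  if (settled < -0.5) {
    abort(paste0("inconsistent balance: suspended + dissolved = ",
                 signif(suspended_pct + dis, 4), "% exceeds 100%"))
  }
  settled <- max(settled, 0)
  tibble(total_mg_L = total_mg_L, dissolved_ug_L = dissolved_ug_L,
         suspended_pct = suspended_pct, dissolved_pct = dis,
         settled_pct = settled)
}

#' Mass-balance table for several conditions
#'
#' Vectorised [close_balance()] over a conditions table, mirroring a
#' partition-figure layout (percentages displayed to 1 decimal).
#'
#' @param conditions Data frame with columns `condition`, `total_mg_L`,
#'   `dissolved_ug_L` and either `suspended_pct` or the pair
#'   `number_conc` + `control_number_conc`.
#' @return A tibble with one row per condition and columns `condition`,
#'   `suspended_pct`, `dissolved_pct`, `settled_pct` (rounded to 1 decimal).
#' @export
mass_balance_table <- function(conditions) {
  conditions <- as_tibble(conditions)
  if (!"suspended_pct" %in% names(conditions)) {
    conditions$suspended_pct <- suspended_fraction(
      conditions$number_conc, conditions$control_number_conc)
  }
  rows <- purrr::pmap_dfr(
    conditions[, c("total_mg_L", "dissolved_ug_L", "suspended_pct")],
    close_balance)
  out <- dplyr::bind_cols(condition = conditions$condition, rows)
  out$suspended_pct <- round(out$suspended_pct, 1)
  out$dissolved_pct <- round(out$dissolved_pct, 1)
  out$settled_pct <- round(out$settled_pct, 1)
  out[, c("condition", "suspended_pct", "dissolved_pct", "settled_pct")]
}
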