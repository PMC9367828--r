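# Seeded generators of instrument-like datasets with the measurement
# structure of the four exposure conditions: logistic size growth to a
# plateau, a fast step change in zeta-potential, time-stable dissolved
# silver, and dilution series with an NTA detection floor.

scenario_defaults <- function() {
  tibble(
    label = c("DI", "SW", "DI+sludge", "SW+sludge"),
    d0_nm = 21.5,
    d_plateau_nm = c(21.5, 388.8, 220.1, 313.4),
    rate_const_min = c(0, 0.07, 0.07, 0.07),
    zeta_initial_mV = -37.4,
    zeta_final_mV = c(-37.4, -18.4, -42.0, -22.2),
    zeta_step_min = 5,
    dissolved_ug_L = c(4.3, 156.7, 30.0, 577.5),
    suspended_pct = c(90, 10.7, 60, 20),
    pH = c(7.0, 7.7, 8.7, 8.7),
    ionic_strength_M = c(3.98e-5, 0.1, NA, NA),
    total_mg_L = 1.68)
}

#' Scenario specification for the synthetic-data generators
#'
#' Defaults encode the four study conditions: initial hydrodynamic size
#' 21.5 nm; plateau sizes 21.5 (DI), 388.8 (SW), 220.1 (DI+sludge) and
#' 313.4 nm (SW+sludge); zeta-potential stepping from -37.4 mV to the
#' condition value within 5 min; time-stable dissolved Ag at 4.3, 156.7,
#' 30.0 and 577.5 ug/L; nanoparticle dose 1.68 mg/L. The logistic rate
#' constant (0.07/min for aggregating conditions) places the fastest growth
#' near 40 min and the plateau within ~100 min.
#'
#' @param label One of `"DI"`, `"SW"`, `"DI+sludge"`, `"SW+sludge"`.
#' @param seed Integer seed; all generator noise flows from it.
#' @param noise_sd_size_nm,noise_sd_zeta_mV,noise_sd_dissolved_ug_L Gaussian
#'   measurement-noise standard deviations (defaults 5 nm, 1 mV, 5 ug/L).
#' @param ... Named overrides of any default field (e.g. `d_plateau_nm`).
#' @return A list of class `nf_scenario`.
#' @export
#' @examples
#' scenario_spec("SW", seed = 7)
scenario_spec <- function(label = c("DI", "SW", "DI+sludge", "SW+sludge"),
                          seed = 1L, noise_sd_size_nm = 5,
                          noise_sd_zeta_mV = 1,
                          noise_sd_dissolved_ug_L = 5, ...) {
  label <- match.arg(label)
  row <- as.list(scenario_defaults()[scenario_defaults()$label == label, ])
  over <- list(...)
  bad <- setdiff(names(over), names(row))
  if (length(bad) > 0) abort(paste0("unknown scenario field(s): ",
                                    paste(bad, collapse = ", ")))
  row[names(over)] <- over
  spec <- c(row, list(seed = as.integer(seed),
                      noise_sd_size_nm = noise_sd_size_nm,
                      noise_sd_zeta_mV = noise_sd_zeta_mV,
                      noise_sd_dissolved_ug_L = noise_sd_dissolved_ug_L))
  if (!(spec$d_plateau_nm >= spec$d0_nm) || spec$d0_nm <= 0) {
    abort("need d_plateau_nm >= d0_nm > 0")
  }
  if (spec$zeta_step_min < 0) abort("zeta_step_min must be >= 0")
  structure(spec, class = "nf_scenario")
}

#' @export
print.nf_scenario <- function(x, ...) {
  cat("<scenario ", x$label, "> size ", x$d0_nm, " -> ", x$d_plateau_nm,
      " nm (r = ", x$rate_const_min, "/min); zeta ", x$zeta_initial_mV,
      " -> ", x$zeta_final_mV, " mV by ", x$zeta_step_min,
      " min; dissolved ", x$dissolved_ug_L, " ug/L; seed ", x$seed,
      "\n", sep = "")
  invisible(x)
}

logistic_size <- function(spec, t) {
  d0 <- spec$d0_nm
  K <- spec$d_plateau_nm
  if (K == d0 || spec$rate_const_min == 0) return(rep(d0, length(t)))
  K / (1 + ((K - d0) / d0) * exp(-spec$rate_const_min * t))
}

#' Generate a hydrodynamic-size time series
#'
#' Logistic growth D(t) = K / (1 + ((K - d0)/d0) exp(-r t)) plus i.i.d.
#' Gaussian noise; with zero noise the deterministic curve is reproduced
#' exactly. Sizes are floored at 0.1 nm.
#'
#' @param spec An `nf_scenario`.
#' @param times_min Sampling times in minutes.
#' @return Tibble `time_min`, `size_nm`.
#' @export
gen_size_series <- function(spec, times_min = seq(0, 210, by = 10)) {
  stopifnot(inherits(spec, "nf_scenario"))
  d <- logistic_size(spec, times_min)
  if (spec$noise_sd_size_nm > 0) {
    d <- withr::with_seed(spec$seed, {
      d + rnorm(length(d), 0, spec$noise_sd_size_nm)
    })
  }
  tibble(time_min = times_min, size_nm = pmax(d, 0.1))
}

#' Generate a zeta-potential time series
#'
#' Linear ramp from `zeta_initial_mV` to `zeta_final_mV` completed by
#' `zeta_step_min`, flat thereafter, plus seeded Gaussian noise.
#'
#' @inheritParams gen_size_series
#' @return Tibble `time_min`, `zeta_mV`.
#' @export
gen_zeta_series <- function(spec, times_min = seq(0, 50, by = 10)) {
  stopifnot(inherits(spec, "nf_scenario"))
  z <- if (spec$zeta_step_min == 0) {
    rep(spec$zeta_final_mV, length(times_min))
  } else {
    frac <- pmin(times_min / spec$zeta_step_min, 1)
    spec$zeta_initial_mV + frac * (spec$zeta_final_mV - spec$zeta_initial_mV)
  }
  if (spec$noise_sd_zeta_mV > 0) {
    z <- withr::with_seed(spec$seed + 1L, {
      z + rnorm(length(z), 0, spec$noise_sd_zeta_mV)
    })
  }
  tibble(time_min = times_min, zeta_mV = z)
}

#' Generate a dissolved-silver time series
#'
#' Constant level plus seeded Gaussian noise, floored at 0 (dissolved Ag is
#' stable over the experiment).
#'
#' @inheritParams gen_size_series
#' @return Tibble `time_min`, `dissolved_ug_L`.
#' @export
gen_dissolution_series <- function(spec, times_min = seq(0, 210, by = 30)) {
  stopifnot(inherits(spec, "nf_scenario"))
  y <- rep(spec$dissolved_ug_L, length(times_min))
  if (spec$noise_sd_dissolved_ug_L > 0) {
    y <- withr::with_seed(spec$seed + 2L, {
      y + rnorm(length(y), 0, spec$noise_sd_dissolved_ug_L)
    })
  }
  tibble(time_min = times_min, dissolved_ug_L = pmax(y, 0))
}

#' Generate an NTA dilution series
#'
#' In `"linear"` mode the measured concentration is `start_conc / factor`
#' (pure dilution); in `"exponential"` mode it is `start_conc * factor^-beta`
#' with `beta > 1`, emulating loss to aggregation and settling on top of the
#' dilution. Readings below the NTA detection floor (about 1e7-1e8
#' particles/mL) are clamped to the floor and flagged as censored.
#'
#' @param mode `"linear"` or `"exponential"`.
#' @param start_conc Undiluted number concentration, particles/mL.
#' @param factors Dilution factors (>= 1).
#' @param beta Exponential decay exponent (> 1; default 1.5).
#' @param detection_floor Detection floor, particles/mL (default 1e8).
#' @return Tibble `factor`, `true_conc`, `measured_conc`, `censored`.
#' @export
#' @examples
#' gen_dilution_series("linear", 8.5e11, c(1, 50, 500))
gen_dilution_series <- function(mode = c("linear", "exponential"),
                                start_conc = 8.5e11,
                                factors = c(1, 10, 20, 50, 100, 500),
                                beta = 1.5, detection_floor = 1e8) {
  mode <- match.arg(mode)
  if (any(factors < 1)) abort("dilution factors must be >= 1")
  if (mode == "exponential" && beta <= 1) abort("beta must be > 1")
  true <- switch(mode,
                 linear = start_conc / factors,
                 exponential = start_conc * factors^(-beta))
  censored <- true < detection_floor
  tibble(factor = factors, true_conc = true,
         measured_conc = pmax(true, detection_floor), censored = censored)
}

#' Write the four synthetic CSVs for a scenario
#'
#' Writes `size.csv`, `zeta.csv`, `dissolved.csv` and `dilution.csv` in the
#' schemas the analysis readers expect.
#'
#' @param spec An `nf_scenario`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
simulate_scenario <- function(spec, dir) {
  stopifnot(inherits(spec, "nf_scenario"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("size.csv", "zeta.csv", "dissolved.csv",
                            "dilution.csv"))
  readr::write_csv(gen_size_series(spec), paths[1])
  readr::write_csv(gen_zeta_series(spec), paths[2])
  readr::write_csv(gen_dissolution_series(spec), paths[3])
  mode <- if (spec$label %in% c("SW", "SW+sludge")) "exponential" else "linear"
  readr::write_csv(gen_dilution_series(mode), paths[4])
  invisible(paths)
}
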