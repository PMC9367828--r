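# File I/O and the full four-condition analysis pipeline.

ts_schemas <- list(
  size = c("time_min", "size_nm"),
  zeta = c("time_min", "zeta_mV"),
  dissolved = c("time_min", "dissolved_ug_L"))

#' Read an instrument time-series CSV
#'
#' Recognises three schemas by their headers (unit suffixes are part of the
#' schema): `time_min,size_nm[,sd_nm]`, `time_min,zeta_mV`, and
#' `time_min,dissolved_ug_L`. Times must be strictly increasing.
#'
#' @param path CSV path.
#' @return A tibble with attribute `"kind"` set to `"size"`, `"zeta"` or
#'   `"dissolved"`.
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- readr::read_csv(path, show_col_types = FALSE)
  kind <- NULL
  for (k in names(ts_schemas)) {
    want <- ts_schemas[[k]]
    if (all(want %in% names(x)) &&
        all(names(x) %in% c(want, "sd_nm"))) {
      kind <- k
      break
    }
  }
  if (is.null(kind)) {
    abort(paste0("unknown time-series schema: ", paste(names(x), collapse = ",")),
          class = "nf_schema_error")
  }
  if (anyDuplicated(x$time_min) || is.unsorted(x$time_min, strictly = TRUE)) {
    abort("times must be strictly increasing", class = "nf_schema_error")
  }
  out <- as_tibble(x)
  attr(out, "kind") <- kind
  out
}

#' Write a speciation table in the per-component layout
#'
#' Long CSV mirroring a speciation-table layout: one row per (component,
#' ranked species) pair with the percent of the component total
#' (2 decimals).
#'
#' @param result An `nf_speciation`.
#' @param path Output CSV path.
#' @param top Number of ranked species to keep per component (default 2).
#' @return Invisibly, the written tibble.
#' @export
write_speciation_csv <- function(result, path, top = 2) {
  stopifnot(inherits(result, "nf_speciation"))
  comps <- result$problem$components
  tab <- purrr::map_dfr(comps$name, function(nm) {
    pd <- head(percent_distribution(result, nm), top)
    tibble(component = nm,
           total_mM = comps$total_mM[comps$name == nm],
           rank = seq_len(nrow(pd)), species = pd$species,
           percent = round(pd$percent, 2))
  })
  readr::write_csv(tab, path)
  invisible(tab)
}

#' Run the full four-condition analysis
#'
#' Orchestrates every stage for each requested exposure condition: medium
#' speciation (ionic media only), dissolved-Ag distribution at the
#' condition's measured dissolved level (with humic ligands for sludge
#' conditions), the DLVO profile and energy barrier (conditions without
#' sludge only -- sludge systems are outside DLVO's assumptions),
#' aggregation-rate statistics on a generated size series, and the
#' suspended/dissolved/settled partition. All randomness flows from the
#' single seed; outputs embed the thermodynamic-database checksum.
#'
#' @param out_dir Output directory for CSVs and the JSON manifest.
#' @param scenarios Condition labels (default all four).
#' @param seed Integer seed for the synthetic series.
#' @param db_path Thermodynamic database path.
#' @param radius_convention Passed to [dlvo_profile()].
#' @param ha_mg_L Humic acid for sludge conditions, mg/L (default 42).
#' @return Invisibly, a list of per-condition bundles plus the manifest.
#' @export
run_full_analysis <- function(out_dir,
                              scenarios = c("DI", "SW", "DI+sludge", "SW+sludge"),
                              seed = 1L, db_path = nf_default_db_path(),
                              radius_convention = "half-size",
                              ha_mg_L = 42) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  db <- read_thermo_db(db_path)
  check_db_charges(db)
  bundles <- list()
  for (label in scenarios) {
    spec <- scenario_spec(label, seed = seed)
    tag <- gsub("[^A-Za-z0-9]", "_", label)
    cond_dir <- file.path(out_dir, tag)
    if (!dir.exists(cond_dir)) dir.create(cond_dir)

    is_sw <- grepl("^SW", label)
    has_sludge <- grepl("sludge", label)

    # medium: SW recipe for SW conditions, silver-only blank for DI
    medium <- if (is_sw) {
      pr <- sw_problem(sludge = has_sludge, species = db)
      pr
    } else {
      speciation_problem(
        tibble(name = c("Na+", "NO2-"), charge = c(1, -1),
               total_mM = c(1e-3, 1e-3)),
        species = db, pH = spec$pH)
    }
    spec_tbl <- NULL
    if (is_sw) {
      med_res <- solve_equilibrium(medium)
      spec_tbl <- write_speciation_csv(med_res, file.path(cond_dir, "speciation.csv"))
    }

    ag_medium <- if (has_sludge) bind_humic(medium, ha_mg_L) else medium
    ag_dist <- speciate_dissolved_silver(ag_medium, spec$dissolved_ug_L)
    readr::write_csv(
      mutate(as_tibble(ag_dist), percent = round(.data$percent, 2)),
      file.path(cond_dir, "silver_speciation.csv"))

    barrier <- NULL
    if (!has_sludge) {
      prof <- dlvo_profile(spec$d0_nm, spec$zeta_final_mV,
                           spec$ionic_strength_M,
                           radius_convention = radius_convention)
      readr::write_csv(as_tibble(prof), file.path(cond_dir, "dlvo_profile.csv"))
      barrier <- energy_barrier(prof)
      readr::write_csv(barrier, file.path(cond_dir, "dlvo_barrier.csv"))
    }

    sizes <- gen_size_series(spec)
    readr::write_csv(sizes, file.path(cond_dir, "size.csv"))
    rates <- aggregation_rates(sizes)
    readr::write_csv(glance(rates), file.path(cond_dir, "rate_summary.csv"))

    dis <- gen_dissolution_series(spec)
    bal <- close_balance(spec$total_mg_L, mean(dis$dissolved_ug_L),
                         spec$suspended_pct)
    readr::write_csv(bal, file.path(cond_dir, "mass_balance.csv"))

    bundles[[label]] <- list(scenario = spec, speciation = spec_tbl,
                             silver = ag_dist, barrier = barrier,
                             rates = rates, balance = bal)
  }
  manifest <- list(
    package = "nanofate",
    version = as.character(utils::packageVersion("nanofate")),
    seed = seed,
    db_path = db_path,
    db_md5 = unname(tools::md5sum(db_path)),
    conditions = lapply(bundles, function(b) list(
      label = b$scenario$label,
      barrier_kBT = if (!is.null(b$barrier)) b$barrier$height_kBT else NA,
      dissolved_pct = b$balance$dissolved_pct,
      settled_pct = b$balance$settled_pct)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(bundles, list(manifest = manifest)))
}
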