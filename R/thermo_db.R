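# Thermodynamic database: TSV of aqueous species defined by component
# stoichiometry and a base-10 formation constant at 25 C / zero ionic strength.

#' Read a thermodynamic database
#'
#' Parses a TSV database of aqueous species. Expected columns:
#' `species`, `charge`, `log_k`, `ref_temp_C`, `stoichiometry`, where
#' `stoichiometry` holds `component:coefficient` pairs separated by
#' semicolons (e.g. `"Ag+:1;Cl-:2"`). Lines starting with `#` are comments.
#'
#' @param path Path to the TSV file. Defaults to the database shipped with
#'   the package (MINTEQ/NIST-family constants for the ammonium, carbonate,
#'   sulfate, chloride and silver chloro/ammine systems).
#' @return A tibble with columns `species`, `charge`, `log_k`, `ref_temp_C`
#'   and a list-column `stoich` of named numeric coefficient vectors.
#' @export
#' @examples
#' db <- read_thermo_db()
#' db[db$species == "AgCl2-", ]
read_thermo_db <- function(path = nf_default_db_path()) {
  if (!file.exists(path)) {
    abort(paste0("thermodynamic database not found: ", path))
  }
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           species = readr::col_character(),
                           charge = readr::col_double(),
                           log_k = readr::col_double(),
                           ref_temp_C = readr::col_double(),
                           stoichiometry = readr::col_character()
                         ))
  required <- c("species", "charge", "log_k", "ref_temp_C", "stoichiometry")
  if (!all(required %in% names(raw))) {
    abort("database must have columns species, charge, log_k, ref_temp_C, stoichiometry")
  }
  if (anyDuplicated(raw$species)) {
    abort("duplicate species names in database")
  }
  if (any(!is.finite(raw$log_k))) {
    abort("non-finite log_k in database")
  }
  db <- as_tibble(raw)
  db$stoich <- lapply(db$stoichiometry, parse_stoich)
  db$stoichiometry <- NULL
  db
}

#' Path to the shipped thermodynamic database
#' @return File path of the packaged TSV database.
#' @export
nf_default_db_path <- function() {
  system.file("extdata", "thermo_db.tsv", package = "nanofate", mustWork = TRUE)
}

parse_stoich <- function(s) {
  pairs <- strsplit(trimws(s), ";", fixed = TRUE)[[1]]
  parts <- strsplit(pairs, ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1)) != 2
  if (any(bad)) abort(paste0("malformed stoichiometry string: ", s))
  coefs <- vapply(parts, function(p) as.numeric(p[[2]]), numeric(1))
  names(coefs) <- vapply(parts, function(p) trimws(p[[1]]), character(1))
  if (any(is.na(coefs))) abort(paste0("non-numeric coefficient in: ", s))
  coefs
}

#' Check database species charges against component stoichiometry
#'
#' Every species charge must equal the stoichiometry-weighted sum of its
#' component charges. Components not listed in `component_charges` cause an
#' error.
#'
#' @param db A database tibble from [read_thermo_db()].
#' @param component_charges Named numeric vector of component charges
#'   (defaults to the built-in component registry [nf_component_charges()]).
#' @return Invisibly `TRUE`; aborts with the offending species otherwise.
#' @export
check_db_charges <- function(db, component_charges = nf_component_charges()) {
  for (i in seq_len(nrow(db))) {
    st <- db$stoich[[i]]
    unknown <- setdiff(names(st), names(component_charges))
    if (length(unknown) > 0) {
      abort(paste0("species ", db$species[i], " references unknown component(s): ",
                   paste(unknown, collapse = ", ")))
    }
    implied <- sum(st * component_charges[names(st)])
    if (abs(implied - db$charge[i]) > 1e-9) {
      abort(paste0("charge mismatch for species ", db$species[i],
                   ": declared ", db$charge[i], ", stoichiometric ", implied))
    }
  }
  invisible(TRUE)
}

#' Built-in component charge registry
#'
#' Charges of the conserved components the shipped database is written over.
#'
#' @return Named numeric vector of signed charges.
#' @export
nf_component_charges <- function() {
  c("H+" = 1, "NH4+" = 1, "Na+" = 1, "K+" = 1, "Ca+2" = 2, "Mg+2" = 2,
    "Cl-" = -1, "NO2-" = -1, "SO4-2" = -2, "CO3-2" = -2, "Ag+" = 1,
    "HA1-" = -1, "HA2-" = -1)
}
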