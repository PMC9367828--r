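# Aqueous equilibrium speciation: components (conserved totals) + species
# (stoichiometric combinations with formation constants), solved by Newton
# iteration on log10 free concentrations with Davies activity corrections.

#' Ionic strength of a solution
#'
#' I = 1/2 * sum(c_i * z_i^2) over all charged species.
#'
#' @param concentrations Numeric vector of species concentrations (mol/L).
#' @param charges Numeric vector of signed species charges, same length.
#' @return Ionic strength in mol/L.
#' @export
#' @examples
#' ionic_strength(c(0.1, 0.1), c(1, -1))    # 0.1 M NaCl -> 0.1
#' ionic_strength(c(0.01, 0.01), c(2, -2))  # 0.01 M MgSO4 -> 0.04
ionic_strength <- function(concentrations, charges) {
  if (length(concentrations) != length(charges)) {
    abort("concentrations and charges must have the same length")
  }
  if (any(concentrations < 0)) abort("negative concentration")
  sum(concentrations * charges^2) / 2
}

# Debye-Huckel A coefficient (base-10) at temperature T (K), from the
# dielectric constant of water (Malmberg-Maryott polynomial). ~0.51 at 25 C.
davies_A <- function(temperature_K) {
  tC <- temperature_K - 273.15
  eps_r <- 87.740 - 0.40008 * tC + 9.398e-4 * tC^2 - 1.410e-6 * tC^3
  1.824829e6 / (eps_r * temperature_K)^1.5
}

#' Davies log activity coefficient
#'
#' log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I), the empirical
#' Debye-Huckel extension valid to roughly 0.5 M ionic strength. Neutral
#' species get log10(gamma) = 0.
#'
#' @param charge Signed integer charge (vectorised).
#' @param ionic_strength Ionic strength, mol/L (>= 0).
#' @param temperature_K Absolute temperature; sets the Debye-Huckel A
#'   coefficient (~0.51 at 298.15 K).
#' @return Base-10 log activity coefficient(s).
#' @export
#' @examples
#' davies_log_gamma(1, 0.1)   # about -0.107
#' davies_log_gamma(0, 0.1)   # exactly 0
davies_log_gamma <- function(charge, ionic_strength, temperature_K = 298.15) {
  if (any(ionic_strength < 0)) abort("ionic strength must be >= 0")
  A <- davies_A(temperature_K)
  sI <- sqrt(ionic_strength)
  -A * charge^2 * (sI / (1 + sI) - 0.3 * ionic_strength)
}

#' Define a speciation problem
#'
#' Assembles conserved components, candidate species and solution conditions
#' into a problem object for [solve_equilibrium()]. The proton is handled as
#' a fixed-activity component at the given pH (pH is an input, never
#' predicted), and every component's free ion is automatically included as a
#' species.
#'
#' @param components A data frame with columns `name`, `charge` and
#'   `total_mM` (component totals in mmol/L).
#' @param species Database tibble from [read_thermo_db()]; species whose
#'   stoichiometry references undeclared components are ignored at solve
#'   time.
#' @param pH Fixed pH in `[0, 14]`.
#' @param temperature_C Temperature in Celsius (reference constants are
#'   25 C; no enthalpy correction is applied).
#' @param activity_model `"davies"` or `"none"`.
#' @param ionic_strength Optional fixed ionic strength override (mol/L); the
#'   default `NULL` solves the activity model self-consistently.
#' @return An object of class `nf_problem`.
#' @export
#' @examples
#' pr <- speciation_problem(
#'   tibble::tibble(name = c("Na+", "Cl-"), charge = c(1, -1),
#'                  total_mM = c(10, 10)),
#'   pH = 7)
#' solve_equilibrium(pr)
speciation_problem <- function(components, species = read_thermo_db(),
                               pH, temperature_C = 25,
                               activity_model = c("davies", "none"),
                               ionic_strength = NULL) {
  activity_model <- match.arg(activity_model)
  components <- as_tibble(components)
  if (!all(c("name", "charge", "total_mM") %in% names(components))) {
    abort("components needs columns name, charge, total_mM")
  }
  if (anyDuplicated(components$name)) abort("component names must be unique")
  if ("H+" %in% components$name) {
    abort("the proton is fixed by pH; do not declare H+ as a component")
  }
  if (any(components$total_mM < 0)) abort("component totals must be >= 0")
  if (!is.numeric(pH) || length(pH) != 1 || pH < 0 || pH > 14) {
    abort("pH must be a single value in [0, 14]")
  }
  if (!is.null(ionic_strength) && ionic_strength <= 0) {
    abort("fixed ionic strength override must be > 0")
  }
  dropped <- components$name[components$total_mM == 0]
  if (length(dropped) > 0) {
    components <- components[components$total_mM > 0, ]
  }
  if (nrow(components) == 0) abort("at least one component with positive total is required")
  structure(
    list(components = components, species = species, pH = pH,
         temperature_C = temperature_C, activity_model = activity_model,
         ionic_strength = ionic_strength),
    class = "nf_problem")
}

#' @export
print.nf_problem <- function(x, ...) {
  cat("<speciation problem> ", nrow(x$components), " components, pH ", x$pH,
      ", ", x$temperature_C, " C, activity model: ", x$activity_model,
      if (!is.null(x$ionic_strength)) paste0(", fixed I = ", x$ionic_strength, " M"),
      "\n", sep = "")
  print(x$components)
  invisible(x)
}

#' Read a medium recipe from YAML
#'
#' The YAML holds `components: {name: {total_mM, charge}}`, `pH`,
#' `temperature_C` and `activity_model`.
#'
#' @param path Path to the recipe YAML.
#' @param species Thermodynamic database tibble.
#' @return An `nf_problem`.
#' @export
read_medium <- function(path, species = read_thermo_db()) {
  y <- yaml::read_yaml(path)
  comps <- purrr::imap_dfr(y$components, function(v, nm) {
    tibble(name = nm, charge = as.numeric(v$charge),
           total_mM = as.numeric(v$total_mM))
  })
  speciation_problem(comps, species = species, pH = y$pH,
                     temperature_C = y$temperature_C %||% 25,
                     activity_model = y$activity_model %||% "davies")
}

#' Built-in synthetic wastewater recipe
#'
#' The high-ammonia synthetic wastewater major-ion totals (mM): NH4+ 18.10,
#' Na+ 22.84, K+ 12.42, Ca2+ 0.01, Mg2+ 2.10, Cl- 18.50, NO2- 23.19,
#' SO4^2- 2.03, CO3^2- 0.05. Measured pH is 7.7 without sludge and 8.7 with
#' sludge.
#'
#' @param sludge If `TRUE`, use the sludge-amended condition (pH 8.7).
#' @param species Thermodynamic database tibble.
#' @return An `nf_problem`.
#' @export
sw_problem <- function(sludge = FALSE, species = read_thermo_db()) {
  f <- if (sludge) "sw_sludge_medium.yaml" else "sw_medium.yaml"
  read_medium(system.file("extdata", f, package = "nanofate", mustWork = TRUE),
              species = species)
}

# Filter database species to those expressible over the declared components
# (plus the fixed-activity proton).
usable_species <- function(species, comp_names) {
  keep <- vapply(species$stoich, function(st) {
    all(names(st) %in% c(comp_names, "H+"))
  }, logical(1))
  species[keep, ]
}

#' Solve a speciation problem
#'
#' Newton iteration on the log10 free component concentrations (damped to at
#' most one log unit per step), wrapped in an outer fixed-point loop that
#' makes the Davies activity coefficients consistent with the solved ionic
#' strength. Mass-action holds in activities for every species; mass balance
#' is enforced for every non-fixed component.
#'
#' @param problem An `nf_problem` from [speciation_problem()].
#' @param tol Convergence tolerance on the maximum relative mass-balance
#'   residual (default 1e-8).
#' @param max_iter Newton iteration cap per activity pass (default 200).
#' @param max_outer Activity fixed-point iteration cap (default 50).
#' @return An object of class `nf_speciation`: solved species concentrations,
#'   free component concentrations, activity coefficients per charge, ionic
#'   strength, residuals and convergence flag. Use [tidy()] for the species
#'   table, [glance()] for a one-row summary and [percent_distribution()]
#'   for per-component percentages.
#' @export
solve_equilibrium <- function(problem, tol = 1e-8, max_iter = 200,
                              max_outer = 50) {
  stopifnot(inherits(problem, "nf_problem"))
  comps <- problem$components
  temp_K <- problem$temperature_C + 273.15
  db <- usable_species(problem$species, comps$name)

  # tableau: database species + the free ion of every component
  sp_names <- c(comps$name, db$species)
  sp_charge <- c(comps$charge, db$charge)
  sp_logk <- c(rep(0, nrow(comps)), db$log_k)
  n_c <- nrow(comps)
  n_s <- length(sp_names)
  # stoichiometry matrix over (components, H+)
  S <- matrix(0, n_s, n_c + 1,
              dimnames = list(sp_names, c(comps$name, "H+")))
  S[seq_len(n_c), seq_len(n_c)] <- diag(n_c)
  for (i in seq_len(nrow(db))) {
    st <- db$stoich[[i]]
    S[n_c + i, names(st)] <- st
  }
  S_free <- S[, seq_len(n_c), drop = FALSE]

  totals <- comps$total_mM / 1000
  la_H <- -problem$pH
  # log10 gamma per species/component, updated by the outer loop
  I_fixed <- problem$ionic_strength
  I_cur <- if (!is.null(I_fixed)) I_fixed else ionic_strength(totals, comps$charge)
  use_davies <- problem$activity_model == "davies"

  lg_of <- function(charge, I) {
    if (!use_davies) return(rep(0, length(charge)))
    davies_log_gamma(charge, I, temp_K)
  }

  x <- pmax(log10(totals), -20)
  converged <- FALSE
  inner_total <- 0L
  outer <- 0L
  conc <- numeric(n_s)

  repeat {
    outer <- outer + 1L
    lg_comp <- lg_of(comps$charge, I_cur)
    lg_sp <- lg_of(sp_charge, I_cur)
    for (it in seq_len(max_iter)) {
      inner_total <- inner_total + 1L
      la <- c(x + lg_comp, la_H)
      logc <- sp_logk + as.vector(S %*% la) - lg_sp
      conc <- 10^pmin(logc, 30)
      resid <- as.vector(t(S_free) %*% conc) - totals
      rel <- abs(resid) / totals
      if (max(rel) < tol) break
      W <- conc * log(10)
      J <- t(S_free) %*% (S_free * W)
      dx <- tryCatch(solve(J, -resid), error = function(e) {
        qr.solve(J + diag(1e-12 * max(diag(J)), n_c), -resid)
      })
      dx <- pmax(pmin(dx, 1), -1)
      x <- pmax(x + dx, -300)
    }
    inner_ok <- max(abs(resid) / totals) < tol
    if (!use_davies || !is.null(I_fixed)) {
      converged <- inner_ok
      break
    }
    I_new <- ionic_strength(conc, sp_charge)
    if (inner_ok && abs(I_new - I_cur) <= 1e-8 * max(I_new, 1e-12)) {
      converged <- TRUE
      I_cur <- I_new
      break
    }
    I_cur <- I_new
    if (outer >= max_outer) break
  }

  residuals <- setNames(abs(as.vector(t(S_free) %*% conc) - totals) / totals,
                        comps$name)
  if (!converged) {
    msg <- paste0("speciation did not converge; max relative residual ",
                  format(max(residuals), digits = 3))
    abort(msg, class = "nf_convergence_error",
          residuals = residuals)
  }

  lg_sp <- lg_of(sp_charge, I_cur)
  species_tbl <- tibble(
    species = sp_names, charge = sp_charge,
    conc_mol = conc, log_activity = log10(conc) + lg_sp)
  charges_seen <- sort(unique(c(sp_charge, comps$charge, 1, -1)))
  gamma_tbl <- tibble(charge = charges_seen,
                      gamma = 10^lg_of(charges_seen, I_cur))
  structure(
    list(problem = problem,
         species = species_tbl,
         free_conc = setNames(conc[seq_len(n_c)], comps$name),
         gamma = gamma_tbl,
         ionic_strength = I_cur,
         residuals = residuals,
         converged = converged,
         iterations = c(newton = inner_total, activity = outer),
         stoich = S),
    class = "nf_speciation")
}

#' @export
print.nf_speciation <- function(x, ...) {
  cat("<speciation result> ", nrow(x$species), " species, I = ",
      signif(x$ionic_strength * 1000, 4), " mM, ",
      if (x$converged) "converged" else "NOT converged",
      " (", x$iterations[["newton"]], " Newton / ",
      x$iterations[["activity"]], " activity iterations)\n", sep = "")
  print(dplyr::arrange(x$species, desc(.data$conc_mol)), n = 10)
  invisible(x)
}

#' @method tidy nf_speciation
#' @export
tidy.nf_speciation <- function(x, ...) {
  dplyr::arrange(x$species, desc(.data$conc_mol))
}

#' @method glance nf_speciation
#' @export
glance.nf_speciation <- function(x, ...) {
  tibble(n_components = nrow(x$problem$components),
         n_species = nrow(x$species),
         ionic_strength_M = x$ionic_strength,
         max_rel_residual = max(x$residuals),
         converged = x$converged,
         newton_iterations = unname(x$iterations["newton"]))
}

#' Percent distribution of a component over its species
#'
#' For each species containing the component, 100 * coefficient *
#' concentration / component total, ranked descending. Sums to 100 within
#' rounding of the mass-balance tolerance.
#'
#' @param result An `nf_speciation` from [solve_equilibrium()].
#' @param component Component name (e.g. `"Cl-"`).
#' @return A tibble with columns `species`, `conc_mol`, `percent`.
#' @export
percent_distribution <- function(result, component) {
  stopifnot(inherits(result, "nf_speciation"))
  comps <- result$problem$components
  if (!component %in% comps$name) {
    abort(paste0("unknown component: ", component))
  }
  total <- comps$total_mM[comps$name == component] / 1000
  nu <- result$stoich[, component]
  keep <- which(nu > 0)
  tibble(species = rownames(result$stoich)[keep],
         conc_mol = unname(result$species$conc_mol[keep]),
         percent = unname(100 * nu[keep] *
                            result$species$conc_mol[keep] / total)) |>
    arrange(desc(.data$percent))
}

#' Speciate dissolved silver in a medium
#'
#' Adds a silver component at the measured dissolved-Ag total to an existing
#' medium problem, re-solves the equilibrium, and returns the ranked percent
#' distribution of dissolved Ag over its species (chloro complexes, ammine
#' complexes, free ion, and humic-bound forms if present).
#'
#' @param medium An `nf_problem` (e.g. [sw_problem()]).
#' @param total_ag_ug_L Total dissolved silver in micrograms/L (> 0).
#' @param ... Passed to [solve_equilibrium()].
#' @return A tibble `species`, `conc_mol`, `percent` (attribute `"result"`
#'   carries the full `nf_speciation`).
#' @export
#' @examples
#' speciate_dissolved_silver(sw_problem(), 156.7)
speciate_dissolved_silver <- function(medium, total_ag_ug_L, ...) {
  stopifnot(inherits(medium, "nf_problem"))
  if (total_ag_ug_L <= 0) abort("total dissolved Ag must be > 0")
  ag_umol_L <- total_ag_ug_L / .nf_const$ag_molar_mass
  pr <- medium
  if ("Ag+" %in% pr$components$name) abort("medium already contains Ag+")
  pr$components <- bind_rows(pr$components,
                             tibble(name = "Ag+", charge = 1,
                                    total_mM = ag_umol_L / 1000))
  res <- solve_equilibrium(pr, ...)
  out <- percent_distribution(res, "Ag+")
  attr(out, "result") <- res
  out
}

#' Discrete two-site humic-acid ligand model
#'
#' Default site densities and constants for a carboxylic-type and a
#' phenolic-type binding site. These are stated model assumptions, not
#' measured properties of the study sludge.
#'
#' @param density_mol_g Site densities in mol sites per g HA.
#' @param pKa Proton dissociation constants of the sites.
#' @param log_k_ag log10 formation constants of the 1:1 Ag-site complexes.
#' @return A tibble with one row per site.
#' @export
ha_two_site <- function(density_mol_g = c(3e-3, 5e-4),
                        pKa = c(4.5, 9.0),
                        log_k_ag = c(5.0, 7.5)) {
  if (any(density_mol_g < 0)) abort("site densities must be >= 0")
  tibble(site = c("HA1-", "HA2-"),
         density_mol_g = density_mol_g, pKa = pKa, log_k_ag = log_k_ag)
}

#' Add humic-acid binding sites to a medium
#'
#' Augments a speciation problem with discrete humic ligand components and
#' their protonated and silver-bound species. With `ha_mg_L = 0` the problem
#' is returned unchanged.
#'
#' @param medium An `nf_problem`.
#' @param ha_mg_L Humic acid concentration, mg/L (>= 0).
#' @param site_model Site table from [ha_two_site()].
#' @return An `nf_problem` with the ligands added.
#' @export
bind_humic <- function(medium, ha_mg_L, site_model = ha_two_site()) {
  stopifnot(inherits(medium, "nf_problem"))
  if (ha_mg_L < 0) abort("ha_mg_L must be >= 0")
  if (any(site_model$density_mol_g < 0)) abort("site densities must be >= 0")
  if (ha_mg_L == 0) return(medium)
  site_model <- site_model[site_model$density_mol_g > 0, ]
  if (nrow(site_model) == 0) return(medium)
  pr <- medium
  totals_mM <- ha_mg_L / 1000 * site_model$density_mol_g * 1000
  pr$components <- bind_rows(
    pr$components,
    tibble(name = site_model$site, charge = -1, total_mM = totals_mM))
  new_sp <- tibble(
    species = c(paste0("H", sub("-$", "", site_model$site)),
                paste0("Ag", sub("-$", "", site_model$site))),
    charge = rep(0, 2 * nrow(site_model)),
    log_k = c(site_model$pKa, site_model$log_k_ag),
    ref_temp_C = 25,
    stoich = c(lapply(site_model$site, function(s) setNames(c(1, 1), c(s, "H+"))),
               lapply(site_model$site, function(s) setNames(c(1, 1), c(s, "Ag+")))))
  pr$species <- bind_rows(pr$species, new_sp)
  pr
}
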