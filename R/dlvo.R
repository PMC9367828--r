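# Sphere-sphere DLVO interaction energies: retarded van der Waals attraction
# (Gregory form) plus electrical double-layer repulsion in the
# constant-potential, zeta-for-surface-potential approximation.

#' Debye screening parameter
#'
#' kappa = sqrt(2 N_A I e^2 / (eps_r eps_0 k_B T)) with I converted from
#' mol/L to mol/m^3. The Debye length kappa^-1 shrinks as sqrt(I) grows;
#' at 0.1 M and 298.15 K it is about 0.96 nm.
#'
#' @param ionic_strength_M Ionic strength, mol/L (> 0).
#' @param temperature_K Absolute temperature (> 0).
#' @param epsilon_r Relative dielectric constant of the medium (water: 78.5).
#' @return A tibble with columns `kappa_m` (1/m) and `debye_length_m` (m).
#' @export
#' @examples
#' debye_kappa(0.1)$debye_length_m * 1e9   # ~0.96 nm
debye_kappa <- function(ionic_strength_M, temperature_K = 298.15,
                        epsilon_r = 78.5) {
  if (any(ionic_strength_M <= 0)) {
    abort("ionic strength must be > 0 (infinite screening length is not representable)")
  }
  if (any(temperature_K <= 0)) abort("temperature must be > 0")
  cst <- .nf_const
  I_m3 <- ionic_strength_M * 1000
  kappa <- sqrt(2 * cst$N_A * I_m3 * cst$e^2 /
                  (epsilon_r * cst$epsilon_0 * cst$k_B * temperature_K))
  tibble(kappa_m = kappa, debye_length_m = 1 / kappa)
}

#' Particle pair geometry and potentials
#'
#' @param radius1_m,radius2_m Particle radii in metres (> 0).
#' @param zeta1_V,zeta2_V Signed zeta-potentials in volts.
#' @return A list of class `nf_pair`.
#' @export
particle_pair <- function(radius1_m, radius2_m = radius1_m,
                          zeta1_V = 0, zeta2_V = zeta1_V) {
  if (radius1_m <= 0 || radius2_m <= 0) abort("radii must be > 0")
  structure(list(a1 = radius1_m, a2 = radius2_m, z1 = zeta1_V, z2 = zeta2_V),
            class = "nf_pair")
}

#' Retarded van der Waals sphere-sphere attraction
#'
#' Gregory's retarded expression
#' V = -A131 a1 a2 / (6 D (a1 + a2)) * (1 - (5.32 D / lambda) *
#' log(1 + lambda / (5.32 D))). Strictly attractive (<= 0) and decaying to
#' zero at large separation; the bracket tends to 1 in the unretarded
#' (small D / lambda) limit.
#'
#' @param D Surface-to-surface separation in metres (> 0); vectorised.
#' @param pair An `nf_pair` from [particle_pair()].
#' @param hamaker_J Hamaker constant A131 of the particles across the
#'   medium, J (default 3.7e-20 for citrate-coated AgNPs in water).
#' @param lambda_m Characteristic retardation wavelength, m (default 1e-7).
#' @return Interaction energy in joules (vector).
#' @export
v_vdw <- function(D, pair, hamaker_J = 3.7e-20, lambda_m = 1e-7) {
  if (any(D <= 0)) abort("separation D must be > 0")
  if (hamaker_J < 0 || lambda_m <= 0) abort("hamaker_J >= 0 and lambda_m > 0 required")
  bracket <- 1 - (5.32 * D / lambda_m) * log1p(lambda_m / (5.32 * D))
  -hamaker_J * pair$a1 * pair$a2 / (6 * D * (pair$a1 + pair$a2)) * bracket
}

#' Electrical double-layer repulsion between two spheres
#'
#' Hogg-Healy-Fuerstenau constant-potential expression
#' V = pi eps_r eps_0 (a1 a2 / (a1 + a2)) *
#' \{2 z1 z2 ln((1 + e^-kD)/(1 - e^-kD)) + (z1^2 + z2^2) ln(1 - e^-2kD)\},
#' with the zeta-potentials standing in for the surface potentials. For
#' equal particles this collapses to
#' pi eps_r eps_0 (a/2) zeta^2 * 4 ln(1 + e^-kD).
#'
#' @param D Separation in metres (> 0); vectorised.
#' @param pair An `nf_pair`.
#' @param kappa_m Debye parameter, 1/m (from [debye_kappa()]).
#' @param epsilon_r Relative dielectric constant (default 78.5).
#' @return Interaction energy in joules (vector).
#' @export
v_edl <- function(D, pair, kappa_m, epsilon_r = 78.5) {
  if (any(D <= 0)) abort("separation D must be > 0")
  cst <- .nf_const
  x <- exp(-kappa_m * D)
  pref <- pi * epsilon_r * cst$epsilon_0 * pair$a1 * pair$a2 / (pair$a1 + pair$a2)
  pref * (2 * pair$z1 * pair$z2 * log((1 + x) / (1 - x)) +
            (pair$z1^2 + pair$z2^2) * log1p(-x^2))
}

#' Total DLVO interaction-energy profile
#'
#' Pointwise sum of the van der Waals and double-layer terms on a log-spaced
#' separation grid, reported in joules and in k_B T units at the medium
#' temperature.
#'
#' @param radius_nm Hydrodynamic size of the particles, nm. Interpreted per
#'   `radius_convention`.
#' @param zeta_mV Zeta-potential, mV (signed).
#' @param ionic_strength_M Ionic strength, mol/L.
#' @param temperature_K Absolute temperature (default 298.15 K).
#' @param hamaker_J,lambda_m Van der Waals parameters (see [v_vdw()]).
#' @param epsilon_r Relative dielectric constant.
#' @param d_min_nm,d_max_nm,n_points Separation grid: log-spaced from
#'   `d_min_nm` to `d_max_nm` (default 0.1-100 nm, 2000 points).
#' @param radius_convention `"half-size"` treats `radius_nm` as a diameter
#'   and halves it (default); `"size"` uses it directly as the radius.
#' @return A tibble of class `nf_dlvo_profile` with columns `D_nm`,
#'   `v_vdw_J`, `v_edl_J`, `v_total_J`, `v_total_kBT` and parameter
#'   attributes.
#' @export
#' @examples
#' prof <- dlvo_profile(21.5, -37.4, 3.98e-5)
#' energy_barrier(prof)
dlvo_profile <- function(radius_nm, zeta_mV, ionic_strength_M,
                         temperature_K = 298.15, hamaker_J = 3.7e-20,
                         lambda_m = 1e-7, epsilon_r = 78.5,
                         d_min_nm = 0.1, d_max_nm = 100, n_points = 2000,
                         radius_convention = c("half-size", "size")) {
  radius_convention <- match.arg(radius_convention)
  if (!(d_min_nm > 0 && d_min_nm < d_max_nm)) abort("need 0 < d_min < d_max")
  a_m <- radius_nm * 1e-9 / if (radius_convention == "half-size") 2 else 1
  pair <- particle_pair(a_m, a_m, zeta_mV * 1e-3, zeta_mV * 1e-3)
  kappa <- debye_kappa(ionic_strength_M, temperature_K, epsilon_r)$kappa_m
  D <- 10^seq(log10(d_min_nm), log10(d_max_nm), length.out = n_points) * 1e-9
  vdw <- v_vdw(D, pair, hamaker_J, lambda_m)
  edl <- v_edl(D, pair, kappa, epsilon_r)
  tot <- vdw + edl
  out <- tibble(D_nm = D * 1e9, v_vdw_J = vdw, v_edl_J = edl,
                v_total_J = tot,
                v_total_kBT = tot / (.nf_const$k_B * temperature_K))
  structure(out,
            class = c("nf_dlvo_profile", class(out)),
            params = list(radius_nm = radius_nm, zeta_mV = zeta_mV,
                          ionic_strength_M = ionic_strength_M,
                          temperature_K = temperature_K,
                          hamaker_J = hamaker_J, lambda_m = lambda_m,
                          epsilon_r = epsilon_r, kappa_m = kappa,
                          radius_convention = radius_convention))
}

#' Energy barrier of a DLVO profile
#'
#' The positive maximum of the total interaction energy, refined by local
#' quadratic interpolation around the grid maximum. A profile that is
#' attractive everywhere has no barrier.
#'
#' @param profile An `nf_dlvo_profile`.
#' @return One-row tibble: `has_barrier`, `height_kBT` (0 when no barrier),
#'   `position_nm` (NA when no barrier).
#' @export
energy_barrier <- function(profile) {
  stopifnot(inherits(profile, "nf_dlvo_profile"), nrow(profile) > 0)
  v <- profile$v_total_kBT
  i <- which.max(v)
  if (v[i] <= 0) {
    return(tibble(has_barrier = FALSE, height_kBT = 0, position_nm = NA_real_))
  }
  if (i > 1 && i < length(v)) {
    # quadratic through the three points around the grid maximum
    x <- profile$D_nm[(i - 1):(i + 1)]
    y <- v[(i - 1):(i + 1)]
    fit <- coef(lm(y ~ poly(x, 2, raw = TRUE)))
    if (is.finite(fit[[3]]) && fit[[3]] < 0) {
      xv <- -fit[[2]] / (2 * fit[[3]])
      if (xv >= x[1] && xv <= x[3]) {
        yv <- fit[[1]] + fit[[2]] * xv + fit[[3]] * xv^2
        return(tibble(has_barrier = TRUE, height_kBT = yv, position_nm = xv))
      }
    }
  }
  tibble(has_barrier = TRUE, height_kBT = v[i], position_nm = profile$D_nm[i])
}

#' Energy barrier as a function of ionic strength
#'
#' Recomputes the DLVO profile over a grid of ionic strengths at fixed
#' zeta-potential (no charge regulation) and reports the barrier height at
#' each, together with the first ionic strength at which the barrier
#' vanishes -- a fixed-potential proxy for the critical coagulation
#' concentration.
#'
#' @param is_grid_M Increasing vector of ionic strengths, mol/L.
#' @inheritParams dlvo_profile
#' @param ... Further arguments passed to [dlvo_profile()].
#' @return A tibble `ionic_strength_M`, `barrier_kBT`, `has_barrier`, with
#'   attribute `ccc_proxy_M` (NA if the barrier never vanishes on the grid).
#' @export
barrier_vs_ionic_strength <- function(is_grid_M, radius_nm, zeta_mV, ...) {
  rows <- purrr::map_dfr(is_grid_M, function(I) {
    b <- energy_barrier(dlvo_profile(radius_nm, zeta_mV, I, ...))
    tibble(ionic_strength_M = I, barrier_kBT = b$height_kBT,
           has_barrier = b$has_barrier)
  })
  gone <- which(!rows$has_barrier)
  attr(rows, "ccc_proxy_M") <- if (length(gone) > 0) {
    rows$ionic_strength_M[min(gone)]
  } else NA_real_
  rows
}
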