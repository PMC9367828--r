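# Independent oracles and small fixture builders used across the suite.

# Build a database tibble in code (no files) from a list of
# name = list(charge, log_k, stoich) entries.
make_db <- function(...) {
  entries <- list(...)
  tibble::tibble(
    species = names(entries),
    charge = vapply(entries, function(e) e$charge, numeric(1)),
    log_k = vapply(entries, function(e) e$log_k, numeric(1)),
    ref_temp_C = 25,
    stoich = lapply(entries, function(e) e$stoich))
}

empty_db <- function() {
  tibble::tibble(species = character(), charge = numeric(),
                 log_k = numeric(), ref_temp_C = numeric(),
                 stoich = list())
}

# Brute-force oracle for a two-component metal/ligand system with species
# ML (log b1) and optionally ML2 (log b2), no activity corrections:
# 1-D bisection on the free ligand concentration.
bisect_ml_oracle <- function(total_m, total_l, log_b1, log_b2 = NULL,
                             tol = 1e-14) {
  b1 <- 10^log_b1
  b2 <- if (is.null(log_b2)) 0 else 10^log_b2
  g <- function(l) {
    m <- total_m / (1 + b1 * l + b2 * l^2)
    l + b1 * m * l + 2 * b2 * m * l^2 - total_l
  }
  lo <- total_l * 1e-15
  hi <- total_l
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if ((hi - lo) / hi < tol) break
  }
  l <- (lo + hi) / 2
  m <- total_m / (1 + b1 * l + b2 * l^2)
  list(free_m = m, free_l = l,
       ml = b1 * m * l, ml2 = b2 * m * l^2)
}

# Equal-sphere double-layer closed form used as an independent check:
# pi eps_r eps0 (a/2) zeta^2 * 4 ln(1 + exp(-kappa D)).
edl_closed_form <- function(D, a, zeta, kappa, epsilon_r = 78.5) {
  eps0 <- 8.8541878128e-12
  pi * epsilon_r * eps0 * (a / 2) * zeta^2 * 4 * log1p(exp(-kappa * D))
}

logistic_curve <- function(t, d0, K, r) {
  K / (1 + ((K - d0) / d0) * exp(-r * t))
}
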