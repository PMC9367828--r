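test_that("ionic strength is the half charge-weighted sum", {
  expect_equal(ionic_strength(c(0.1, 0.1), c(1, -1)), 0.1)
  expect_equal(ionic_strength(c(0.01, 0.01), c(2, -2)), 0.04)
  expect_equal(ionic_strength(c(0.5, 0), c(0, 3)), 0)
  expect_error(ionic_strength(c(-1e-9), c(1)), "negative")
  expect_error(ionic_strength(c(1, 2), c(1)), "length")
})

test_that("solved SW ionic strength matches the frozen brute-force sum", {
  res <- solve_equilibrium(sw_problem())
  # regression value: brute-force 0.5 * sum(c z^2) over the solved species
  brute <- sum(res$species$conc_mol * res$species$charge^2) / 2
  expect_equal(res$ionic_strength, brute, tolerance = 1e-10)
  expect_equal(res$ionic_strength, 0.05423223519, tolerance = 1e-6)
})

test_that("Davies coefficients behave and match a hand evaluation", {
  expect_identical(davies_log_gamma(0, 0.3), 0)
  expect_equal(davies_log_gamma(1, 0.1), davies_log_gamma(-1, 0.1))
  # hand evaluation: -A (sqrt(.1)/(1+sqrt(.1)) - 0.03), A ~ 0.51 at 25 C
  expect_equal(davies_log_gamma(1, 0.1), -0.107, tolerance = 0.01)
  expect_equal(davies_log_gamma(2, 0.1), 4 * davies_log_gamma(1, 0.1))
  expect_error(davies_log_gamma(1, -0.1), ">= 0")
})

test_that("identity system returns the totals as free concentrations", {
  pr <- speciation_problem(
    tibble::tibble(name = c("Na+", "NO2-"), charge = c(1, -1),
                   total_mM = c(5, 5)),
    species = empty_db(), pH = 7, activity_model = "none")
  res <- solve_equilibrium(pr)
  expect_equal(unname(res$free_conc), c(5e-3, 5e-3), tolerance = 1e-10)
  pd <- percent_distribution(res, "Na+")
  expect_equal(nrow(pd), 1)
  expect_equal(pd$percent, 100, tolerance = 1e-6)
})

test_that("monoprotic acid with pK at the fixed pH splits 50/50", {
  db <- make_db(HA = list(charge = 0, log_k = 6.5,
                          stoich = c("A-" = 1, "H+" = 1)))
  pr <- speciation_problem(
    tibble::tibble(name = "A-", charge = -1, total_mM = 1),
    species = db, pH = 6.5, activity_model = "none")
  pd <- percent_distribution(solve_equilibrium(pr), "A-")
  expect_equal(sort(pd$percent), c(50, 50), tolerance = 1e-8)
})

test_that("Newton solution matches 1-D bisection on small metal-ligand systems", {
  cases <- list(
    list(tm = 1e-3, tl = 2e-3, b1 = 3.2, b2 = NULL),
    list(tm = 1e-5, tl = 1e-2, b1 = 3.31, b2 = 5.25),
    list(tm = 5e-4, tl = 5e-4, b1 = 4.0, b2 = 7.0),
    list(tm = 1e-6, tl = 1e-1, b1 = 2.0, b2 = 3.5))
  for (cs in cases) {
    sp <- list(ML = list(charge = 0, log_k = cs$b1,
                         stoich = c("M+" = 1, "L-" = 1)))
    if (!is.null(cs$b2)) {
      sp$ML2 <- list(charge = -1, log_k = cs$b2,
                     stoich = c("M+" = 1, "L-" = 2))
    }
    db <- do.call(make_db, sp)
    pr <- speciation_problem(
      tibble::tibble(name = c("M+", "L-"), charge = c(1, -1),
                     total_mM = 1000 * c(cs$tm, cs$tl)),
      species = db, pH = 7, activity_model = "none")
    res <- solve_equilibrium(pr)
    orc <- bisect_ml_oracle(cs$tm, cs$tl, cs$b1, cs$b2)
    expect_equal(unname(res$free_conc[["M+"]]), orc$free_m,
                 tolerance = 1e-8)
    expect_equal(unname(res$free_conc[["L-"]]), orc$free_l,
                 tolerance = 1e-8)
  }
})

test_that("Davies and activity-free solutions coincide as I -> 0", {
  db <- read_thermo_db()
  comps <- tibble::tibble(name = c("Ag+", "Cl-"), charge = c(1, -1),
                          total_mM = c(1e-6, 1e-5))
  r_dav <- solve_equilibrium(
    speciation_problem(comps, db, pH = 7, activity_model = "davies"))
  r_non <- solve_equilibrium(
    speciation_problem(comps, db, pH = 7, activity_model = "none"))
  expect_equal(unname(r_dav$free_conc), unname(r_non$free_conc),
               tolerance = 1e-4)
})

test_that("a symmetric two-species ladder splits 50/50", {
  # free ligand pinned at b1/b2 by a large-excess ligand pool makes the
  # 1:1 and 1:2 complexes exactly equal
  db <- make_db(
    ML = list(charge = 0, log_k = 8, stoich = c("M+" = 1, "L-" = 1)),
    ML2 = list(charge = -1, log_k = 10, stoich = c("M+" = 1, "L-" = 2)))
  pr <- speciation_problem(
    tibble::tibble(name = c("M+", "L-"), charge = c(1, -1),
                   total_mM = c(1e-3, 10.002)),
    species = db, pH = 7, activity_model = "none")
  pd <- percent_distribution(solve_equilibrium(pr), "M+")
  p <- pd$percent[pd$species %in% c("ML", "ML2")]
  expect_equal(p[1], p[2], tolerance = 1e-3)
  expect_equal(sum(pd$percent), 100, tolerance = 1e-6)
})

test_that("mass balance closes to 1e-6 and percents sum to 100 on varied problems", {
  db <- read_thermo_db()
  base <- sw_problem()$components
  for (seed in 1:5) {
    comps <- withr::with_seed(seed, {
      k <- sample(nrow(base), 5)
      out <- base[k, ]
      out$total_mM <- out$total_mM * stats::runif(5, 0.2, 3)
      out
    })
    pr <- speciation_problem(comps, db, pH = withr::with_seed(seed, stats::runif(1, 6, 9)))
    res <- solve_equilibrium(pr)
    expect_true(all(res$species$conc_mol >= 0))
    expect_lt(max(res$residuals), 1e-6)
    for (nm in comps$name) {
      s <- sum(percent_distribution(res, nm)$percent)
      expect_lt(s, 100.1)
      expect_equal(s, 100, tolerance = 1e-4)
    }
  }
})

test_that("the AgCl2-/AgCl ratio is independent of total dissolved Ag", {
  pr <- sw_problem()
  ratios <- vapply(c(0.36, 3.6, 36, 360), function(ug) {
    pd <- speciate_dissolved_silver(pr, ug)
    pd$percent[pd$species == "AgCl2-"] / pd$percent[pd$species == "AgCl"]
  }, numeric(1))
  expect_lt(max(abs(ratios / ratios[1] - 1)), 1e-2)
})

test_that("the printed ammonium split pins SW pH at 7.7, not 8.7", {
  res77 <- solve_equilibrium(sw_problem())
  nh <- percent_distribution(res77, "NH4+")
  expect_equal(unname(nh$percent[nh$species == "NH4+"]), 96.85, tolerance = 1)
  expect_equal(unname(nh$percent[nh$species == "NH3"]), 2.26, tolerance = 0.5)
  res87 <- solve_equilibrium(sw_problem(sludge = TRUE))
  nh87 <- percent_distribution(res87, "NH4+")
  expect_lt(unname(nh87$percent[nh87$species == "NH4+"]), 90)
})

test_that("a ligand-free medium leaves silver fully free", {
  medium <- speciation_problem(
    tibble::tibble(name = "Na+", charge = 1, total_mM = 1),
    species = empty_db(), pH = 7, activity_model = "none")
  pd <- speciate_dissolved_silver(medium, 30)
  expect_equal(pd$species, "Ag+")
  expect_equal(unname(pd$percent), 100, tolerance = 1e-6)
})

test_that("a fixed ionic-strength override is honoured", {
  pr <- speciation_problem(sw_problem()$components, read_thermo_db(),
                           pH = 7.7, ionic_strength = 0.1)
  res <- solve_equilibrium(pr)
  expect_equal(res$ionic_strength, 0.1)
  g1 <- res$gamma$gamma[res$gamma$charge == 1]
  expect_equal(log10(g1), davies_log_gamma(1, 0.1), tolerance = 1e-12)
})

test_that("humic binding augments the problem and captures trace silver", {
  pr <- sw_problem()
  expect_identical(bind_humic(pr, 0), pr)
  expect_error(ha_two_site(density_mol_g = c(-1, 1)), ">= 0")

  # deionised water + 42 mg/L HA + 30 ug/L Ag: bound forms dominate
  blank <- speciation_problem(
    tibble::tibble(name = "Na+", charge = 1, total_mM = 1e-3),
    species = read_thermo_db(), pH = 7)
  pd <- speciate_dissolved_silver(bind_humic(blank, 42), 30)
  bound <- sum(pd$percent[grepl("^AgHA", pd$species)])
  expect_gt(bound, 90)

  # ligand-excess limit with a single strong site: bound fraction -> 100%
  one_site <- ha_two_site(density_mol_g = c(1e-3, 0), pKa = c(3, 9),
                          log_k_ag = c(12, 0))
  pd2 <- speciate_dissolved_silver(bind_humic(blank, 42, one_site), 1e-3)
  expect_equal(sum(pd2$percent[grepl("^AgHA", pd2$species)]), 100,
               tolerance = 1e-4)
})

test_that("problem validation rejects bad inputs", {
  comps <- tibble::tibble(name = "Na+", charge = 1, total_mM = 1)
  expect_error(speciation_problem(comps, empty_db(), pH = 15), "pH")
  expect_error(speciation_problem(
    tibble::tibble(name = c("Na+", "Na+"), charge = 1, total_mM = 1),
    empty_db(), pH = 7), "unique")
  expect_error(speciation_problem(
    tibble::tibble(name = "H+", charge = 1, total_mM = 1),
    empty_db(), pH = 7), "proton")
  res <- solve_equilibrium(speciation_problem(comps, empty_db(), pH = 7))
  expect_error(percent_distribution(res, "K+"), "unknown component")
})
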