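test_that("Debye parameter has the right magnitude and sqrt(I) scaling", {
  dl <- debye_kappa(0.1)$debye_length_m
  expect_equal(dl * 1e9, 0.96, tolerance = 0.01)
  # quadrupling I halves the screening length
  expect_equal(debye_kappa(0.4)$debye_length_m, dl / 2, tolerance = 1e-12)
  # the near-deionised condition screens over tens of nm
  expect_equal(debye_kappa(3.98e-5)$debye_length_m * 1e9, 48, tolerance = 0.01)
  expect_error(debye_kappa(0), "> 0")
  expect_error(debye_kappa(-1), "> 0")
})

test_that("retarded van der Waals term is attractive, decaying, and matches the frozen oracle", {
  pair <- particle_pair(10.75e-9)
  D <- 10^seq(-11, -6, length.out = 50)
  v <- v_vdw(D, pair)
  expect_true(all(v <= 0))
  expect_true(all(diff(v) > 0))          # monotone toward 0
  expect_lt(abs(v_vdw(1e-3, pair)), 1e-30)
  # unretarded Hamaker limit -A a / (12 D) recovered within 1% at D = 1e-11
  unret <- -3.7e-20 * 10.75e-9 / (12 * 1e-11)
  expect_equal(v_vdw(1e-11, pair) / unret, 1, tolerance = 0.01)
  # frozen value from an independent step-by-step evaluation at D = 1 nm
  expect_equal(v_vdw(1e-9, pair), -2.788127407327e-20, tolerance = 1e-10)
  expect_error(v_vdw(0, pair), "> 0")
})

test_that("double-layer term matches the equal-sphere closed form to 1e-12", {
  set.seed(42)
  for (i in 1:25) {
    a <- runif(1, 5, 100) * 1e-9
    zeta <- runif(1, -0.06, 0.06)
    kappa <- 1 / (runif(1, 0.5, 50) * 1e-9)
    D <- runif(1, 0.1, 50) * 1e-9
    pair <- particle_pair(a, a, zeta, zeta)
    expect_equal(v_edl(D, pair, kappa),
                 edl_closed_form(D, a, zeta, kappa),
                 tolerance = 1e-12)
  }
  # zero potential gives exactly zero
  expect_equal(v_edl(1e-9, particle_pair(1e-8, 1e-8, 0, 0), 1e9), 0)
  # kappa D = ln 3 makes the equal-sphere bracket equal 4 ln(4/3)
  a <- 2e-8; zeta <- -0.02
  pair <- particle_pair(a, a, zeta, zeta)
  pref <- pi * 78.5 * 8.8541878128e-12 * (a / 2) * zeta^2
  expect_equal(v_edl(log(3) * 1e-9, pair, 1e9),
               pref * 4 * log(4 / 3), tolerance = 1e-12)
})

test_that("total profile is the pointwise sum and decays to zero", {
  prof <- dlvo_profile(21.5, -37.4, 3.98e-5)
  expect_equal(prof$v_total_J, prof$v_vdw_J + prof$v_edl_J)
  expect_true(all(prof$v_vdw_J <= 0))
  expect_lt(abs(dlvo_profile(21.5, -37.4, 3.98e-5,
                             d_max_nm = 1000)$v_total_kBT[2000]), 0.01)
  # zero zeta collapses onto the attraction term
  p0 <- dlvo_profile(21.5, 0, 0.1)
  expect_equal(p0$v_total_J, p0$v_vdw_J)
})

test_that("energy barrier detection handles flat, repulsive and constructed cases", {
  # all-attractive: no barrier
  b0 <- energy_barrier(dlvo_profile(21.5, 0, 0.1))
  expect_false(b0$has_barrier)
  expect_equal(b0$height_kBT, 0)
  # pure repulsion (zero Hamaker): monotone decay, maximum at the d_min end
  brep <- energy_barrier(dlvo_profile(21.5, -30, 0.01, hamaker_J = 0))
  expect_true(brep$has_barrier)
  expect_equal(brep$position_nm, 0.1, tolerance = 1e-6)
  # constructed profile with a known inserted maximum
  D <- seq(0.5, 50, length.out = 500)
  v <- 5 - (D - 12.34)^2 / 10
  fake <- tibble::tibble(D_nm = D, v_vdw_J = 0, v_edl_J = 0,
                         v_total_J = v, v_total_kBT = v)
  class(fake) <- c("nf_dlvo_profile", class(tibble::tibble()))
  b <- energy_barrier(fake)
  expect_equal(b$position_nm, 12.34, tolerance = 0.01)
  expect_equal(b$height_kBT, 5, tolerance = 1e-4)
})

test_that("barrier is monotone in |zeta|, ionic strength and Hamaker constant", {
  h_z <- vapply(c(10, 20, 30, 40), function(z)
    energy_barrier(dlvo_profile(21.5, -z, 1e-3))$height_kBT, numeric(1))
  expect_true(all(diff(h_z) >= 0))
  h_I <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(I)
    energy_barrier(dlvo_profile(21.5, -30, I))$height_kBT, numeric(1))
  expect_true(all(diff(h_I) <= 0))
  h_A <- vapply(c(1, 2, 4, 8) * 1e-20, function(A)
    energy_barrier(dlvo_profile(21.5, -30, 1e-2, hamaker_J = A))$height_kBT,
    numeric(1))
  expect_true(all(diff(h_A) <= 0))
})

test_that("temperature only rescales the kBT axis at fixed kappa", {
  kappa <- debye_kappa(0.01, 298.15)$kappa_m
  pair <- particle_pair(1e-8, 1e-8, -0.03, -0.03)
  # v_edl carries no explicit temperature once kappa is fixed
  expect_equal(v_edl(1e-9, pair, kappa), v_edl(1e-9, pair, kappa))
  p1 <- dlvo_profile(21.5, -30, 0.01, temperature_K = 298.15)
  expect_equal(p1$v_total_kBT * (1.380649e-23 * 298.15), p1$v_total_J)
})

test_that("barrier-vs-ionic-strength scan is monotone and finds the vanishing point", {
  grid <- 10^seq(-4, 0, length.out = 30)
  scan <- barrier_vs_ionic_strength(grid, 21.5, -30)
  expect_true(all(diff(scan$barrier_kBT) <= 1e-9))
  ccc <- attr(scan, "ccc_proxy_M")
  expect_true(is.finite(ccc))
  # bisection oracle on the barrier sign brackets the same crossing
  lo <- 1e-4; hi <- 1
  for (i in 1:40) {
    mid <- sqrt(lo * hi)
    b <- energy_barrier(dlvo_profile(21.5, -30, mid))
    if (b$has_barrier) lo <- mid else hi <- mid
  }
  below <- max(grid[grid < lo], -Inf)
  expect_gte(ccc, below)
  expect_lte(ccc, min(grid[grid >= hi]))
  # zero Hamaker constant: the barrier never vanishes
  scan0 <- barrier_vs_ionic_strength(grid, 21.5, -30, hamaker_J = 0)
  expect_true(all(scan0$has_barrier))
  expect_true(is.na(attr(scan0, "ccc_proxy_M")))
})
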