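test_that("a zero potential gives zero classical term and zero corrections", {
  flat <- dissociation_curve(seq(0.5, 30, by = 0.1), rep(0, 296), "X", "X")
  res <- b2_semiclassical(flat, c(50, 300), 20.18, spacing = 0)
  # the analytic core below the first sample contributes the tiny hard-core term
  core <- 2 * pi / 3 * vdw_constants$N_A * 0.5^3 * 1e-24
  expect_equal(res$B_classical, rep(core, 2), tolerance = 1e-6)
  expect_equal(res$B_qc1, c(0, 0), tolerance = 1e-10)
  expect_equal(res$B_qc2, c(0, 0), tolerance = 1e-10)
  expect_equal(res$B_qc3, c(0, 0), tolerance = 1e-10)
})

test_that("hard-sphere B2 equals the closed form (2 pi/3) N_A d^3", {
  d <- 3
  hs <- dissociation_curve(seq(d, 30, by = 0.1), rep(0, 271), "X", "X")
  res <- b2_semiclassical(hs, 150, 39.948)
  expect_equal(res$B_classical, 2 * pi / 3 * vdw_constants$N_A * d^3 * 1e-24,
               tolerance = 1e-9)
  expect_equal(res$B_total, res$B_classical, tolerance = 1e-9)
})

test_that("classical LJ B2 matches an independent high-resolution quadrature", {
  lj <- ar_like_lj()
  for (Tk in c(100, 273.15, 600)) {
    res <- b2_semiclassical(lj, Tk, 39.948)
    RT <- vdw_constants$R_kJ * Tk
    f <- function(r) (exp(-pmin(evaluate_energy(lj, r) / RT, 700)) - 1) * r^2
    oracle <- -2 * pi * vdw_constants$N_A * 1e-24 *
      pracma::integral(f, 1e-6, 50 * 3.405, reltol = 1e-12)
    expect_lt(abs(res$B_classical - oracle) / abs(oracle), 1e-3)
  }
})

test_that("the first quantum correction equals its classic single-term form", {
  # independent cross-check: the fully parts-reduced first-order expression
  # +2 pi N_A lambda/24 Int e^{-v} v'^2 r^2 dr computed with pracma
  lj <- ar_like_lj()
  Tk <- 150
  RT <- vdw_constants$R_kJ * Tk
  mu <- 39.948 / 2 * vdw_constants$amu
  lam <- vdw_constants$hbar^2 / (mu * vdw_constants$k_B * Tk) * 1e20
  g <- function(r) {
    exp(-pmin(evaluate_energy(lj, r) / RT, 700)) *
      (evaluate_derivative(lj, r, 1) / RT)^2 * r^2
  }
  oracle <- 2 * pi * vdw_constants$N_A * 1e-24 * lam / 24 *
    pracma::integral(g, 0.5, 170, reltol = 1e-11)
  res <- b2_semiclassical(lj, Tk, 39.948)
  expect_equal(res$B_qc1, oracle, tolerance = 1e-6)
  expect_gt(res$B_qc1, 0) # repulsive quantum effect
})

test_that("quantum corrections scale with inverse powers of the mass", {
  lj <- potential_model("LJ12-6", c(epsilon = 0.36, sigma = 2.75)) # neon-like
  r1 <- b2_semiclassical(lj, 80, 20.18)
  r2 <- b2_semiclassical(lj, 80, 40.36)
  expect_equal(r2$B_qc1 / r1$B_qc1, 1 / 2, tolerance = 1e-6)
  expect_equal(r2$B_qc2 / r1$B_qc2, 1 / 4, tolerance = 1e-6)
  expect_equal(r2$B_qc3 / r1$B_qc3, 1 / 8, tolerance = 1e-6)
  # corrections vanish relative to the classical term at high temperature
  lo <- b2_semiclassical(lj, 60, 20.18)
  hi <- b2_semiclassical(lj, 1200, 20.18)
  expect_lt(abs(hi$B_qc1 / hi$B_classical), abs(lo$B_qc1 / lo$B_classical))
  # heterodimer masses enter through twice the reduced mass: for equal masses
  # this is the atom mass itself
  het <- b2_semiclassical(lj, 80, 20.18, 20.18)
  expect_equal(het$B_qc1, r1$B_qc1, tolerance = 1e-10)
})

test_that("B2 has the expected sign structure and a Boyle point", {
  lj <- ar_like_lj()
  res <- b2_semiclassical(lj, c(80, 1500), 39.948)
  expect_lt(res$B_classical[1], 0)
  expect_gt(res$B_classical[2], 0)
  # purely repulsive potential: positive and decreasing with T
  rep_curve <- dissociation_curve(seq(1, 30, by = 0.1),
                                  5 * exp(-(seq(1, 30, by = 0.1) - 1)), "X", "X")
  rr <- b2_semiclassical(rep_curve, c(100, 400), 39.948)
  expect_true(all(rr$B_classical > 0))
  expect_lt(rr$B_classical[2], rr$B_classical[1])
})

test_that("splined-curve and analytic routes agree", {
  lj <- ar_like_lj()
  cv <- generate_synthetic_curve(lj, 2.0, 30, 0.1, element_a = "Ar", element_b = "Ar")
  for (Tk in c(120, 300)) {
    ra <- b2_semiclassical(lj, Tk, 39.948, r_max = 30)
    rc <- b2_semiclassical(cv, Tk, 39.948)
    expect_gt(abs(ra$B_total), 10)
    expect_lt(abs(ra$B_total - rc$B_total) / abs(ra$B_total), 5e-3)
  }
})

test_that("experimental comparison reports per-T deltas and their RMSE", {
  lj <- ar_like_lj()
  Ts <- c(150, 250, 400)
  model_vals <- b2_semiclassical(lj, Ts, 39.948)$B_total
  exact <- b2_table(Ts, model_vals, "Ar", "Ar")
  dev <- b2_vs_experiment(lj, exact, 39.948)
  expect_lt(b2_rmse(dev), 1e-6)

  offset <- b2_table(Ts, model_vals + 3.5, "Ar", "Ar")
  dev2 <- b2_vs_experiment(lj, offset, 39.948)
  expect_equal(b2_rmse(dev2), 3.5, tolerance = 1e-6)
  expect_equal(dev2$delta, rep(-3.5, 3), tolerance = 1e-6)
})

test_that("the He-He pair is rejected for semiclassical B2", {
  he <- b2_table(c(100, 200), c(-1, 5), "He", "He")
  lj <- ar_like_lj()
  expect_error(b2_vs_experiment(lj, he, 4.0026), "He-He|quantum")
  # a mixed pair involving He is fine
  hx <- b2_table(c(100, 200), c(-1, 5), "He", "Xe")
  expect_s3_class(b2_vs_experiment(lj, hx, 4.0026, 131.29), "b2_deviation")
})

test_that("virial preconditions are enforced", {
  lj <- ar_like_lj()
  expect_error(b2_semiclassical(lj, -5, 39.948), "temperatures")
  expect_error(b2_semiclassical(lj, 100, -1), "masses")
  cv <- generate_synthetic_curve(lj, 2, 10, 0.1, element_a = "Ar", element_b = "Ar")
  expect_error(b2_semiclassical(cv, 100, 39.948, r_max = 40), "extent")
  # curve truncated before the attractive branch turns back up
  trunc <- dissociation_curve(seq(2, 3, by = 0.1), 10 - 4 * seq(2, 3, by = 0.1),
                              "X", "X")
  expect_error(b2_semiclassical(trunc, 100, 39.948), "too short")
})
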