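# double-entry transcription pins: expected values computed from independently
# typed formulas (second transcription), frozen here; relative tolerance 1e-12
transcription_pins <- list(
  "LJ12-6" = c(15.5655930404418, 0.491892104802665, -1.18999981377575,
               -0.746572952925062, -0.139832534046093),
  "LJ8-6"  = c(5.89696128186462, -0.274284742666942, -1.19,
               -0.838413072504551, -0.203377553207839),
  "WBH"    = c(4.23239367331799, -0.358331236835385, -1.19,
               -0.82007693843985, -0.172596253767189),
  "MBH"    = c(9.69327420220778, 0.190197876582215, -1.19,
               -0.746852224390462, -0.132567607942093),
  "MRS"    = c(13.1663776308772, 0.605969574321123, -1.19,
               -0.652535333513785, -0.0475878424087709),
  "BHA"    = c(24.7748201208157, 3.94871838793323, -0.429069183070396,
               -0.664100691251033, -0.132160825540979),
  "GBH"    = c(10.0922642228744, 0.236295853599596, -1.19,
               -0.737562465441196, -0.12418612414861),
  "LJ14-7" = c(12.6002702429264, 0.415329588530578, -1.19,
               -0.695071255451257, -0.105127669084041),
  "TT"     = c(10.9544508683816, 0.320312795410286, -1.19000000003308,
               -0.726112577998495, -0.118217850498652)
)
pin_grid <- c(2.9, 3.3, 3.76, 4.4, 6.0)

test_that("all nine families reproduce independently transcribed grid values", {
  models <- example_models()
  for (fam in names(transcription_pins)) {
    got <- evaluate_energy(models[[fam]], pin_grid)
    expect_equal(got, transcription_pins[[fam]], tolerance = 1e-12,
                 info = fam)
  }
})

test_that("well conventions hold where sigma is the minimum position", {
  e <- 0.8; s <- 3.9
  expect_equal(evaluate_energy(potential_model("LJ8-6", c(epsilon = e, sigma = s)), s), -e)
  expect_equal(evaluate_energy(potential_model("MRS", c(epsilon = e, sigma = s, gamma = 7)), s), -e)
  expect_equal(evaluate_energy(potential_model("MBH", c(epsilon = e, sigma = s, gamma = 14)), s), -e)
  expect_equal(evaluate_energy(potential_model("WBH", c(epsilon = e, sigma = s, gamma = 10)), s), -e)
  expect_equal(evaluate_energy(potential_model("GBH", c(epsilon = e, sigma = s, gamma = 14, delta = 7)), s), -e)
  # LJ12-6 zero-crossing convention: E(sigma) = 0, minimum at 2^(1/6) sigma
  lj <- potential_model("LJ12-6", c(epsilon = e, sigma = s))
  expect_equal(evaluate_energy(lj, s), 0)
  expect_equal(evaluate_energy(lj, 2^(1 / 6) * s), -e)
  # minimum-position variant
  ljm <- potential_model("LJ12-6", c(epsilon = e, sigma = s), lj126_sigma = "minimum")
  expect_equal(evaluate_energy(ljm, s), -e)
})

test_that("energies decay to zero at long range", {
  for (m in example_models()) {
    eps_scale <- if (m$family == "TT") m$constants[["De"]] else {
      if ("epsilon" %in% names(m$params)) m$params[["epsilon"]] else 1
    }
    expect_lt(abs(evaluate_energy(m, 30 * 3.76)), 1e-3 * eps_scale)
  }
})

test_that("BHA limiting forms and core behaviour", {
  m <- potential_model("BHA", c(A = 5, C6 = 0, b = 2))
  expect_equal(evaluate_energy(m, 1 / 2), 5 * exp(-1))
  # with dispersion the potential dives to -Inf towards the origin
  m2 <- potential_model("BHA", c(A = 5, C6 = 100, b = 2))
  expect_lt(evaluate_energy(m2, 0.05), -1e6)
})

test_that("WBH is finite at r = 0", {
  m <- potential_model("WBH", c(epsilon = 1.1, sigma = 4, gamma = 11))
  v0 <- evaluate_energy(m, 0)
  expect_true(is.finite(v0))
  expect_gt(v0, 0)
})

test_that("TT with zero dispersion reduces to pure exponential repulsion", {
  m <- potential_model("TT", c(A = 4e5, b = 13.1, C6 = 0, C8 = 0, C10 = 0),
                       constants = list(Re = 3.7, De = 1.3))
  r <- c(1.2, 2.5, 3.7, 6)
  expect_equal(evaluate_energy(m, r), 4e5 * 1.3 * exp(-13.1 * r / 3.7),
               tolerance = 1e-13)
})

test_that("MBH and BHA parameter interconversion gives identical energies", {
  mb <- potential_model("MBH", c(epsilon = 1.66, sigma = 4.01, gamma = 13.4))
  ba <- mbh_to_bha(mb)
  r <- seq(1.2, 16, by = 0.01)
  expect_lt(max(abs(evaluate_energy(mb, r) - evaluate_energy(ba, r))), 1e-10)
  # round trip through the inverse map
  mb2 <- bha_to_mbh(ba)
  expect_equal(mb2$params, mb$params, tolerance = 1e-9)
  # relative agreement holds even deep on the repulsive wall
  r_wall <- seq(0.4, 1.2, by = 0.01)
  rel <- abs(evaluate_energy(mb, r_wall) - evaluate_energy(ba, r_wall)) /
    abs(evaluate_energy(mb, r_wall))
  expect_lt(max(rel), 1e-12)
})

test_that("derivatives match an independent central difference", {
  for (m in example_models()) {
    # grid avoids the stationary point, where a relative check is meaningless
    r <- c(3.1, 3.5, 4.6, 7.5)
    h <- 1e-4
    f <- function(x) evaluate_energy(m, x)
    fd1 <- (f(r + h) - f(r - h)) / (2 * h)
    d1 <- evaluate_derivative(m, r, 1)
    expect_lt(max(abs(d1 - fd1) / pmax(abs(fd1), 1e-3 * max(abs(fd1)))), 1e-5)
    fd2 <- (f(r + h) - 2 * f(r) + f(r - h)) / h^2
    expect_lt(max(abs(evaluate_derivative(m, r, 2) - fd2) /
                    pmax(abs(fd2), 1e-3 * max(abs(fd2)))), 1e-4)
  }
})

test_that("first derivative vanishes at the analytic minimum", {
  lj <- potential_model("LJ12-6", c(epsilon = 2, sigma = 3.1))
  expect_lt(abs(evaluate_derivative(lj, 2^(1 / 6) * 3.1, 1)), 1e-9)
  mrs <- potential_model("MRS", c(epsilon = 1.3, sigma = 4.2, gamma = 6))
  expect_lt(abs(evaluate_derivative(mrs, 4.2, 1)), 1e-9)
})

test_that("locate_well matches closed forms and a dense grid scan", {
  lj <- potential_model("LJ12-6", c(epsilon = 0.7, sigma = 3.2))
  w <- locate_well(lj)
  expect_equal(w[["r_min"]], 2^(1 / 6) * 3.2, tolerance = 1e-8)
  expect_equal(w[["depth"]], 0.7, tolerance = 1e-10)

  mrs <- potential_model("MRS", c(epsilon = 1.4, sigma = 3.8, gamma = 7))
  w <- locate_well(mrs)
  expect_equal(w[["r_min"]], 3.8, tolerance = 1e-8)
  expect_equal(w[["depth"]], 1.4, tolerance = 1e-10)

  gbh <- potential_model("GBH", c(epsilon = 1.2, sigma = 3.9, gamma = 12.5, delta = 6.5))
  w <- locate_well(gbh)
  grid <- seq(2, 8, by = 1e-4)
  e <- evaluate_energy(gbh, grid)
  expect_lt(abs(w[["r_min"]] - grid[which.min(e)]), 1e-3)

  # every family parameterised by its own well reproduces (r_min, depth)
  for (fam in c("LJ8-6", "WBH", "MBH", "MRS", "GBH")) {
    m <- example_models()[[fam]]
    w <- locate_well(m)
    expect_equal(w[["r_min"]], 3.76, tolerance = 1e-7, info = fam)
    expect_equal(w[["depth"]], 1.19, tolerance = 1e-8, info = fam)
  }
  wtt <- locate_well(example_models()[["TT"]])
  expect_equal(wtt[["r_min"]], 3.76, tolerance = 1e-7)
  expect_equal(wtt[["depth"]], 1.19, tolerance = 1e-8)
})

test_that("purely repulsive models raise a no-minimum error", {
  m <- potential_model("BHA", c(A = 1e5, C6 = 0, b = 3))
  expect_error(locate_well(m), "no attractive minimum")
})

test_that("model validation rejects unphysical parameters and domains", {
  expect_error(potential_model("MBH", c(epsilon = 1, sigma = 3, gamma = 5)), "gamma > 6")
  expect_error(potential_model("GBH", c(epsilon = 1, sigma = 3, gamma = 5, delta = 7)),
               "gamma > delta")
  expect_error(potential_model("LJ12-6", c(epsilon = -1, sigma = 3)), "epsilon")
  expect_error(potential_model("LJ12-6", c(epsilon = 1, sig = 3)), "parameters")
  expect_error(potential_model("TT", c(A = 1, b = 1, C6 = 0, C8 = 0, C10 = 0)), "Re")
  m <- potential_model("LJ12-6", c(epsilon = 1, sigma = 3))
  expect_error(evaluate_energy(m, c(2, -1)), "r must be")
})
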