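#' Semiclassical second virial coefficient with quantum corrections
#'
#' Computes `B2(T)` for a pair potential by direct numerical integration of
#' the classical expression
#' `B_cl = -2 pi N_A Int (exp(-V/kT) - 1) R^2 dR`
#' plus semiclassical (Wigner-Kirkwood) quantum corrections of first, second
#' and third order.  The corrections are successive powers of
#' `lambda = hbar^2/(mu kT)` (`mu` the reduced mass of the pair, so that for
#' a like pair the usual atom-mass expressions are recovered) times integrals
#' over the first, second and third radial derivatives of the potential:
#'
#' `B_qc,k = -2 pi N_A Int exp(-v) Q_k(v', v'', v''', r) dr`,  `v = V/kT`,
#'
#' with `Q_1 = lambda (v'^2 r^2/24 - v' r/6 - v'' r^2/12)` and the
#' corresponding second- and third-order brackets (see the methods
#' vignette for the full expressions and their validation against the exact
#' harmonic-oscillator partition function).
#'
#' Tabulated curves are interpolated with a natural cubic spline on an
#' effective 0.025 Angstrom grid and the derivatives are taken from the
#' spline; below the first tabulated point the Boltzmann factor is taken as
#' zero (the quantum-chemistry wall at the first sample already exceeds
#' `10^3 kT` at relevant temperatures), which contributes the analytic core
#' term `+2 pi N_A r_first^3/3`.  For analytic models the derivatives of
#' [evaluate_derivative()] are used directly and integration extends to
#' `50` length scales unless `r_max` is given.
#'
#' @param potential A [potential_model()] or a [dissociation_curve()].
#' @param T Temperature(s) in kelvin.
#' @param mass_a,mass_b Atomic masses in u.
#' @param r_max Integration extent in Angstrom; defaults to the data extent
#'   for curves and 50 length scales for analytic models.
#' @param spacing Effective spline grid spacing for tabulated curves
#'   (Angstrom).
#' @param abs_tol Absolute quadrature tolerance in cm^3/mol.
#' @return A tibble of class `virial_result`, one row per temperature, with
#'   the classical term, the three quantum corrections, their sum `B_total`
#'   (all cm^3/mol), an estimate of the truncated `-C6/r^6` tail beyond
#'   `r_max`, and the inputs.
#' @export
b2_semiclassical <- function(potential, T, mass_a, mass_b = mass_a,
                             r_max = NULL, spacing = 0.025, abs_tol = 1e-4) {
  if (any(T <= 0)) abort("temperatures must be > 0")
  if (mass_a <= 0 || mass_b <= 0) abort("masses must be > 0")

  if (inherits(potential, "dissociation_curve")) {
    curve <- if (nrow(potential) >= 4 && spacing > 0) {
      resample_spline(potential, spacing)
    } else {
      potential
    }
    f <- splinefun(curve$r, curve$E, method = "natural")
    r_lo <- min(curve$r)
    r_hi <- r_max %||% max(curve$r)
    if (r_hi > max(curve$r) + 1e-9) abort("r_max exceeds the data extent")
    i_min <- which.min(curve$E)
    if (curve$E[i_min] < 0) {
      if (i_min == nrow(curve)) abort("curve too short to contain the well")
      r_well <- curve$r[i_min]
      if (r_hi <= r_well) abort("r_max must exceed the well position")
    } else {
      r_well <- NA_real_ # purely repulsive: no well to split the quadrature at
    }
    Vfun <- function(r) f(r)
    Dfun <- function(r, k) f(r, deriv = k)
    core_r <- r_lo
  } else if (inherits(potential, "potential_model")) {
    s <- length_scale(potential)
    r_hi <- r_max %||% (50 * s)
    # hard core below the top of the repulsive wall: BHA, MBH and GBH dive to
    # -Inf towards the origin, and for every family the Boltzmann factor is
    # numerically zero there anyway
    grid <- s * seq(0.01, 1.2, by = 1e-3)
    e <- evaluate_energy(potential, grid)
    r_lo <- grid[which.max(e)]
    Vfun <- function(r) evaluate_energy(potential, r)
    Dfun <- function(r, k) evaluate_derivative(potential, r, k)
    well <- tryCatch(locate_well(potential), error = function(e) NULL)
    r_well <- if (is.null(well)) NA_real_ else well[["r_min"]]
    core_r <- r_lo
  } else {
    abort("potential must be a potential_model or a dissociation_curve")
  }

  mu <- mass_a * mass_b / (mass_a + mass_b) * vdw_constants$amu
  pref <- 2 * pi * vdw_constants$N_A * 1e-24 # A^3 -> cm^3/mol

  one_T <- function(Tk) {
    RT <- vdw_constants$R_kJ * Tk
    lam <- vdw_constants$hbar^2 / (mu * vdw_constants$k_B * Tk) * 1e20 # A^2
    v <- function(r) Vfun(r) / RT
    v1 <- function(r) Dfun(r, 1) / RT
    v2 <- function(r) Dfun(r, 2) / RT
    v3 <- function(r) Dfun(r, 3) / RT

    splits <- c(core_r, r_hi)
    if (is.finite(r_well) && r_well > core_r && r_well < r_hi) {
      splits <- c(core_r, r_well, r_hi)
    }
    quad <- function(g, atol) {
      tot <- 0
      for (i in seq_len(length(splits) - 1)) {
        tot <- tot + integrate(g, splits[i], splits[i + 1],
                               subdivisions = 2000L,
                               rel.tol = 1e-10, abs.tol = atol / pref,
                               stop.on.error = FALSE)$value
      }
      tot
    }

    B_cl <- pref * core_r^3 / 3 -
      pref * quad(function(r) expm1(-v(r)) * r^2, abs_tol)

    q1 <- function(r) {
      a1 <- v1(r)
      lam * (a1^2 * r^2 / 24 - a1 * r / 6 - v2(r) * r^2 / 12)
    }
    q2 <- function(r) {
      a1 <- v1(r); a2 <- v2(r); a3 <- v3(r)
      lam^2 * (a1^4 * r^2 / 1152 - a1^3 * r / 144 - 11 * a1^2 * a2 * r^2 / 1440 +
                 a1^2 / 360 + 11 * a1 * a2 * r / 360 + a1 * a3 * r^2 / 240 +
                 a2^2 * r^2 / 160 - a3 * r / 120)
    }
    q3 <- function(r) {
      a1 <- v1(r); a2 <- v2(r); a3 <- v3(r)
      lam^3 * (a1^6 * r^2 / 82944 - a1^5 * r / 6912 -
                 17 * a1^4 * a2 * r^2 / 69120 + a1^4 / 8640 +
                 17 * a1^3 * a2 * r / 8640 + a1^3 * a3 * r^2 / 5760 +
                 83 * a1^2 * a2^2 * r^2 / 80640 + a1^3 / (7560 * r) -
                 11 * a1^2 * a2 / 15120 - a1^2 * a3 * r / 960 -
                 83 * a1 * a2^2 * r / 20160 - 17 * a1 * a2 * a3 * r^2 / 20160 -
                 61 * a2^3 * r^2 / 120960 + a1^2 / (5040 * r^2) -
                 a1 * a2 / (2520 * r) - a1 * a3 / 5040 + a2^2 / 5040 +
                 17 * a2 * a3 * r / 10080 - a3^2 * r^2 / 13440)
    }
    # the corrections can be orders of magnitude below the classical term, so
    # they get a much tighter absolute tolerance than the headline abs_tol
    wq <- function(g) function(r) exp(-v(r)) * g(r)
    B1 <- -pref * quad(wq(q1), 1e-12)
    B2c <- -pref * quad(wq(q2), 1e-12)
    B3 <- -pref * quad(wq(q3), 1e-12)

    # truncated-tail estimate from the -C6/r^6 asymptote at r_max
    C6_eff <- -Vfun(r_hi) * r_hi^6
    tail_est <- if (C6_eff > 0) pref * C6_eff / (RT * 3 * r_hi^3) else 0

    tibble::tibble(T = Tk, B_classical = B_cl, B_qc1 = B1, B_qc2 = B2c,
                   B_qc3 = B3, B_total = B_cl + B1 + B2c + B3,
                   tail_est = tail_est, r_max = r_hi,
                   mass_a = mass_a, mass_b = mass_b)
  }

  out <- dplyr::bind_rows(lapply(T, one_T))
  class(out) <- c("virial_result", class(out))
  out
}

#' Compare computed second virial coefficients with an experimental table
#'
#' Computes the semiclassical `B2` at every temperature of the experimental
#' table and reports per-temperature deviations and their RMSE.  The He-He
#' pair is rejected: the semiclassical expansion is unreliable for the
#' helium dimer and a fully quantum treatment is required.
#'
#' @param potential A [potential_model()] or [dissociation_curve()].
#' @param exp_table A [b2_table()] with the experimental values.
#' @param mass_a,mass_b Atomic masses in u.
#' @param r_max Integration extent, see [b2_semiclassical()].
#' @return A tibble of class `b2_deviation` with columns `T`, `B2_model`,
#'   `B2_exp`, `delta` (cm^3/mol) and attribute `rmse` (see [b2_rmse()]).
#' @export
b2_vs_experiment <- function(potential, exp_table, mass_a, mass_b = mass_a,
                             r_max = NULL) {
  stopifnot(inherits(exp_table, "b2_table"))
  if (nrow(exp_table) == 0) abort("experimental table is empty")
  el <- c(attr(exp_table, "element_a"), attr(exp_table, "element_b"))
  if (all(el == "He")) {
    abort(paste("the He-He pair is outside the validity of the semiclassical",
                "expansion; a fully quantum treatment is required"))
  }
  res <- b2_semiclassical(potential, exp_table$T, mass_a, mass_b, r_max = r_max)
  out <- tibble::tibble(T = exp_table$T, B2_model = res$B_total,
                        B2_exp = exp_table$B2,
                        delta = res$B_total - exp_table$B2)
  class(out) <- c("b2_deviation", class(out))
  attr(out, "rmse") <- sqrt(mean(out$delta^2))
  attr(out, "pair") <- el
  out
}

#' RMSE of a B2 comparison
#'
#' @param deviation A `b2_deviation` from [b2_vs_experiment()].
#' @return RMSE of (model - experiment) in cm^3/mol.
#' @export
b2_rmse <- function(deviation) {
  stopifnot(inherits(deviation, "b2_deviation"))
  attr(deviation, "rmse")
}
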