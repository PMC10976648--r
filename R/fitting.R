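#' Energy window for fitting and scoring
#'
#' Points enter the fit when their energy does not exceed `upper_cut` on the
#' repulsive side and their magnitude is at least `lower_frac` times the well
#' depth on the long-range side.  The conventional window is 20 kJ/mol and
#' 10% of the well depth.
#'
#' @param upper_cut Repulsive inclusion limit in kJ/mol (> 0).
#' @param lower_frac Fraction of the well depth below which tail points are
#'   dropped (in (0, 1)).
#' @return An object of class `energy_window`.
#' @export
energy_window <- function(upper_cut = 20, lower_frac = 0.10) {
  if (upper_cut <= 0) abort("upper_cut must be > 0")
  if (lower_frac <= 0 || lower_frac >= 1) abort("lower_frac must be in (0, 1)")
  structure(list(upper_cut = upper_cut, lower_frac = lower_frac),
            class = "energy_window")
}

# Spline-refined well of a tabulated curve: coarse grids (0.1 A) misplace
# shallow minima, so the depth used by the window is re-estimated from the
# natural-spline interpolant around the grid minimum.
curve_well <- function(curve) {
  i <- which.min(curve$E)
  if (curve$E[i] >= 0) abort("curve has no negative minimum")
  n <- nrow(curve)
  if (n >= 4) {
    f <- splinefun(curve$r, curve$E, method = "natural")
    lo <- curve$r[max(1, i - 1)]
    hi <- curve$r[min(n, i + 1)]
    opt <- optimize(f, c(lo, hi), tol = 1e-10)
    if (opt$objective < 0) {
      return(c(r_min = opt$minimum, depth = -opt$objective))
    }
  }
  c(r_min = curve$r[i], depth = -curve$E[i])
}

#' Select the windowed subset of a curve
#'
#' Retains the points with `E <= upper_cut` and `|E| >= lower_frac * depth`,
#' where the depth is the magnitude of the curve minimum refined by spline
#' interpolation.  Retained points keep their original grid values.
#'
#' @param curve A [dissociation_curve()] with a negative minimum.
#' @param window An [energy_window()].
#' @return The windowed [dissociation_curve()] subset.
#' @export
select_window <- function(curve, window = energy_window()) {
  stopifnot(inherits(window, "energy_window"))
  depth <- curve_well(curve)[["depth"]]
  keep <- curve$E <= window$upper_cut & abs(curve$E) >= window$lower_frac * depth
  if (!any(keep)) abort("energy window selects no points")
  el <- curve_elements(curve)
  dissociation_curve(curve$r[keep], curve$E[keep], el[1], el[2], curve_source(curve))
}

#' RMSE of a model against a curve subset
#'
#' @param model A [potential_model()].
#' @param curve_subset A non-empty [dissociation_curve()] (typically the
#'   output of [select_window()]).
#' @return Root mean squared energy deviation in kJ/mol.
#' @export
curve_rmse <- function(model, curve_subset) {
  if (nrow(curve_subset) == 0) abort("empty curve subset")
  sqrt(mean((evaluate_energy(model, curve_subset$r) - curve_subset$E)^2))
}

# Internal fitting parametrisation.  Most families fit their natural
# parameters inside a box; GBH fits (epsilon, sigma, delta, dgap) with
# gamma = delta + dgap so the gamma > delta constraint becomes a box bound.
fit_spec <- function(family, well, bounds = NULL) {
  r_w <- well[["r_min"]]; d <- well[["depth"]]
  spec <- switch(family,
    "LJ12-6" = list(
      names = c("epsilon", "sigma"),
      lower = c(0.1 * d, 0.5 * r_w), upper = c(10 * d, 2 * r_w),
      start = c(d, r_w / 2^(1 / 6)), log = c(FALSE, FALSE),
      map = function(th) th),
    "LJ8-6" = list(
      names = c("epsilon", "sigma"),
      lower = c(0.1 * d, 0.5 * r_w), upper = c(10 * d, 2 * r_w),
      start = c(d, r_w), log = c(FALSE, FALSE),
      map = function(th) th),
    "WBH" = list(
      names = c("epsilon", "sigma", "gamma"),
      lower = c(0.1 * d, 0.5 * r_w, 0.5), upper = c(10 * d, 2 * r_w, 50),
      start = c(d, r_w, 10), log = c(FALSE, FALSE, FALSE),
      map = function(th) th),
    "MBH" = list(
      names = c("epsilon", "sigma", "gamma"),
      lower = c(0.1 * d, 0.5 * r_w, 6.2), upper = c(10 * d, 2 * r_w, 50),
      start = c(d, r_w, 12), log = c(FALSE, FALSE, FALSE),
      map = function(th) th),
    "MRS" = list(
      names = c("epsilon", "sigma", "gamma"),
      lower = c(0.1 * d, 0.5 * r_w, 0.5), upper = c(10 * d, 2 * r_w, 50),
      start = c(d, r_w, 6), log = c(FALSE, FALSE, FALSE),
      map = function(th) th),
    "BHA" = list(
      names = c("A", "C6", "b"),
      lower = c(1e-2 * d, 1e-3 * d * r_w^6, 0.5),
      upper = c(1e9 * d, 1e3 * d * r_w^6, 10),
      start = c(d * exp(12) / 1, 2 * d * r_w^6, 12 / r_w),
      log = c(TRUE, TRUE, FALSE),
      map = function(th) th),
    "GBH" = list(
      names = c("epsilon", "sigma", "delta", "dgap"),
      lower = c(0.1 * d, 0.5 * r_w, 0.5, 0.2),
      upper = c(10 * d, 2 * r_w, 45, 45),
      start = c(d, r_w, 6, 6), log = c(FALSE, FALSE, FALSE, FALSE),
      map = function(th) c(epsilon = th[[1]], sigma = th[[2]],
                           gamma = th[[3]] + th[[4]], delta = th[[3]])),
    "LJ14-7" = list(
      names = c("epsilon", "sigma", "gamma", "delta"),
      lower = c(0.1 * d, 0.5 * r_w, 1e-3, 1e-3),
      upper = c(10 * d, 2 * r_w, 50, 50),
      start = c(d, r_w, 0.12, 0.07), log = c(FALSE, FALSE, TRUE, TRUE),
      map = function(th) th),
    "TT" = list(
      names = c("A", "b", "C6", "C8", "C10"),
      lower = c(1, 2, 0, 0, 0), upper = c(1e9, 40, 20, 20, 20),
      start = c(exp(13) * 0.9, 13, 1.3, 0.4, 0.2),
      log = c(TRUE, FALSE, FALSE, FALSE, FALSE),
      map = function(th) th),
    abort(paste0("no fit specification for family ", family))
  )
  if (!is.null(bounds)) {
    for (nm in names(bounds)) {
      tgt <- nm
      if (family == "GBH" && nm == "gamma") next # handled below via dgap
      i <- match(tgt, spec$names)
      if (is.na(i)) next
      spec$lower[i] <- bounds[[nm]][1]
      spec$upper[i] <- bounds[[nm]][2]
    }
    if (family == "GBH" && !is.null(bounds$gamma)) {
      dlo <- spec$lower[match("delta", spec$names)]
      dhi <- spec$upper[match("delta", spec$names)]
      spec$lower[4] <- max(0.05, bounds$gamma[1] - dhi)
      spec$upper[4] <- max(spec$lower[4] + 1e-6, bounds$gamma[2] - dlo)
    }
    spec$start <- pmin(pmax(spec$start, spec$lower), spec$upper)
  }
  names(spec$lower) <- names(spec$upper) <- names(spec$start) <- spec$names
  spec
}

#' Fit a potential family to a dissociation curve
#'
#' Bounded least-squares fit of the chosen family to the windowed points of
#' the curve, minimising the unweighted sum of squared energy residuals with
#' a Levenberg-Marquardt solver and seeded Latin-hypercube multistart.
#' Default parameter bounds are adapted to the curve (the well position and
#' depth set the scale); loose bounds are known to trap optimisers, so the
#' bounds actually used are always reported.  For the Tang-Toennies family
#' the well constants `Re` and `De` are held fixed (taken from the
#' spline-refined curve minimum unless supplied) and only the five
#' dimensionless parameters are adjusted.
#'
#' @param family Potential family identifier.
#' @param curve A [dissociation_curve()].
#' @param window An [energy_window()].
#' @param bounds Optional named list parameter -> `c(lower, upper)`
#'   overriding the curve-adaptive defaults.
#' @param seed Integer seed for the multistart sampling.
#' @param n_starts Number of optimisation starts (1 physics-informed start
#'   plus `n_starts - 1` Latin-hypercube draws).
#' @param tt_constants For `TT`: `list(Re=, De=)` to hold fixed.
#' @return An object of class `vdw_fit`: the fitted [potential_model()], the
#'   window, the number of fitted points, per-point residuals, the RMSE over
#'   the windowed points (kJ/mol), the bounds used and a convergence flag.
#' @export
fit_potential <- function(family, curve, window = energy_window(),
                          bounds = NULL, seed = 1L, n_starts = 16L,
                          tt_constants = NULL) {
  family <- match_family(family)
  sub <- select_window(curve, window)
  well <- curve_well(curve)
  spec <- fit_spec(family, well, bounds)
  k <- length(spec$names)
  if (nrow(sub) < k) abort("windowed subset has fewer points than free parameters")

  constants <- NULL
  if (family == "TT") {
    constants <- tt_constants %||% list(Re = well[["r_min"]], De = well[["depth"]])
  }
  efn <- energy_fn(family, constants)
  resid_fn <- function(th) {
    p <- spec$map(setNames(th, spec$names))
    e <- efn(p, sub$r)
    bad <- !is.finite(e)
    if (any(bad)) e[bad] <- 1e8
    e - sub$E
  }

  # start points: informed start + seeded LHS over the (log-scaled) box
  lo <- spec$lower; hi <- spec$upper
  slo <- ifelse(spec$log, log(pmax(lo, 1e-12)), lo)
  shi <- ifelse(spec$log, log(hi), hi)
  starts <- list(pmin(pmax(spec$start, lo), hi))
  if (n_starts > 1) {
    u <- withr::with_seed(as.integer(seed), lhs::randomLHS(n_starts - 1, k))
    for (i in seq_len(n_starts - 1)) {
      th <- slo + u[i, ] * (shi - slo)
      th <- ifelse(spec$log, exp(th), th)
      starts[[i + 1]] <- pmin(pmax(th, lo), hi)
    }
  }

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lo, upper = hi, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 400, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(resid_fn(fit$par)^2)
    if (is.null(best) || obj < best$obj) {
      best <- list(fit = fit, obj = obj, par = fit$par)
    }
  }
  if (is.null(best)) abort("all optimisation starts failed")

  params <- spec$map(setNames(best$par, spec$names))
  model <- potential_model(family, params, constants = constants)
  res <- evaluate_energy(model, sub$r) - sub$E
  structure(list(
    model = model,
    family = family,
    window = window,
    n_points = nrow(sub),
    data = tibble::tibble(r = sub$r, E = sub$E,
                          E_fit = sub$E + res, resid = res),
    rmse = sqrt(mean(res^2)),
    bounds_used = tibble::tibble(param = spec$names,
                                 lower = unname(lo), upper = unname(hi)),
    converged = best$fit$info %in% 1:4,
    seed = as.integer(seed),
    n_starts = as.integer(n_starts)
  ), class = "vdw_fit")
}

#' @export
print.vdw_fit <- function(x, ...) {
  cat("<vdw_fit> ", x$family, ": rmse = ", signif(x$rmse, 5), " kJ/mol over ",
      x$n_points, " windowed points\n", sep = "")
  print(x$model)
  invisible(x)
}
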