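#' @importFrom rlang abort warn %||%
#' @importFrom stats optimize pgamma rnorm runif setNames splinefun uniroot integrate
#' @importFrom utils head tail modifyList
NULL

# Canonical family order used in all reports (mirrors the usual workbench layout:
# two-parameter Lennard-Jones forms first, Buckingham variants, then the
# four/five-parameter potentials).
.vdw_family_order <- c("LJ12-6", "LJ8-6", "WBH", "MBH", "MRS", "BHA", "GBH", "LJ14-7", "TT")

.vdw_param_names <- list(
  "LJ12-6" = c("epsilon", "sigma"),
  "LJ8-6"  = c("epsilon", "sigma"),
  "WBH"    = c("epsilon", "sigma", "gamma"),
  "MBH"    = c("epsilon", "sigma", "gamma"),
  "MRS"    = c("epsilon", "sigma", "gamma"),
  "BHA"    = c("A", "C6", "b"),
  "GBH"    = c("epsilon", "sigma", "gamma", "delta"),
  "LJ14-7" = c("epsilon", "sigma", "gamma", "delta"),
  "TT"     = c("A", "b", "C6", "C8", "C10")
)

#' Supported pair-potential families
#'
#' @return Character vector of family identifiers in canonical report order:
#'   Lennard-Jones 12-6 and 8-6, Wang-Buckingham (`WBH`), modified (exp-6)
#'   Buckingham (`MBH`), Morse (`MRS`), original Buckingham (`BHA`),
#'   generalized four-parameter Buckingham (`GBH`), buffered Lennard-Jones
#'   14-7 (`LJ14-7`) and the dimensionless Tang-Toennies form (`TT`).
#' @export
vdw_families <- function() .vdw_family_order

#' Parameter names of a potential family
#'
#' @param family Family identifier, see [vdw_families()].
#' @return Character vector of parameter names in canonical order (the order
#'   used in rule-set notation, e.g. `"10 20 14 10"` maps onto it).
#' @export
vdw_param_names <- function(family) {
  family <- match_family(family)
  .vdw_param_names[[family]]
}

match_family <- function(family) {
  idx <- match(toupper(gsub("[_ ]", "-", family)), toupper(.vdw_family_order))
  if (is.na(idx)) {
    abort(paste0("unknown potential family '", family, "'; expected one of ",
                 paste(.vdw_family_order, collapse = ", ")))
  }
  .vdw_family_order[idx]
}

#' Construct a pair-potential model
#'
#' A potential model bundles a family identifier with its named parameter
#' vector (Angstrom / kJ/mol units; `gamma`, `delta` and all Tang-Toennies
#' parameters are dimensionless).  The Tang-Toennies family additionally
#' carries the fixed well constants `Re` (Angstrom) and `De` (kJ/mol): its
#' five free parameters are dimensionless and only meaningful relative to a
#' known well.
#'
#' @param family Family identifier, see [vdw_families()].
#' @param params Named numeric vector or list of parameters; names must match
#'   [vdw_param_names()] for the family.
#' @param constants For `TT` only: named list/vector with `Re` and `De`.
#' @param lj126_sigma For `LJ12-6` only: whether `sigma` is the zero-crossing
#'   of the potential (the conventional 4-epsilon form, default) or the
#'   position of the minimum.
#' @return An object of class `potential_model`.
#' @export
#' @examples
#' m <- potential_model("LJ12-6", c(epsilon = 1, sigma = 3.4))
#' evaluate_energy(m, 2^(1 / 6) * 3.4) # the well bottom: -epsilon
potential_model <- function(family, params, constants = NULL,
                            lj126_sigma = c("zero-crossing", "minimum")) {
  family <- match_family(family)
  lj126_sigma <- match.arg(lj126_sigma)
  params <- unlist(params)
  wanted <- .vdw_param_names[[family]]
  if (!setequal(names(params), wanted)) {
    abort(paste0("family ", family, " needs parameters {",
                 paste(wanted, collapse = ", "), "}, got {",
                 paste(names(params), collapse = ", "), "}"))
  }
  params <- params[wanted]
  if (any(!is.finite(params))) abort("all parameters must be finite")
  check_pos <- function(nm) {
    if (nm %in% wanted && params[[nm]] <= 0) {
      abort(paste0("parameter '", nm, "' must be > 0 for family ", family))
    }
  }
  for (nm in c("epsilon", "sigma", "gamma", "delta", "A", "b")) check_pos(nm)
  if (family == "MBH" && params[["gamma"]] <= 6) {
    abort("MBH requires gamma > 6 (the exp-6 form is unbound otherwise)")
  }
  if (family == "GBH" && params[["gamma"]] <= params[["delta"]]) {
    abort("GBH requires gamma > delta for a bound well")
  }
  if (family == "BHA" && params[["C6"]] < 0) abort("BHA requires C6 >= 0")
  if (family == "TT") {
    constants <- unlist(constants)
    if (is.null(constants) || !all(c("Re", "De") %in% names(constants))) {
      abort("TT models need constants = list(Re = ..., De = ...)")
    }
    if (constants[["Re"]] <= 0 || constants[["De"]] <= 0) {
      abort("TT constants Re and De must be > 0")
    }
    if (any(params[c("C6", "C8", "C10")] < 0)) {
      abort("TT dispersion coefficients must be >= 0")
    }
    constants <- constants[c("Re", "De")]
  } else if (!is.null(constants)) {
    constants <- NULL
  }
  structure(
    list(family = family, params = params, constants = constants,
         lj126_sigma = if (family == "LJ12-6") lj126_sigma else NULL),
    class = "potential_model"
  )
}

#' @export
print.potential_model <- function(x, ...) {
  cat("<potential_model> ", x$family, "\n", sep = "")
  cat("  ", paste(names(x$params), signif(x$params, 6), sep = " = ", collapse = ", "), "\n", sep = "")
  if (!is.null(x$constants)) {
    cat("  constants: ", paste(names(x$constants), signif(x$constants, 6),
                               sep = " = ", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Tang-Toennies damping f_{2n}(y) = 1 - e^{-y} sum_{k=0}^{2n} y^k/k!,
# evaluated through the regularized lower incomplete gamma function
# P(2n+1, y) = pgamma(y, 2n+1), which is free of the catastrophic
# cancellation of the naive subtraction at small y.
tt_damping <- function(y, two_n) pgamma(y, two_n + 1)

# Fast internal evaluator: function(params, r) for a family. The exported
# evaluate_energy() wraps this with validation.
energy_fn <- function(family, constants = NULL, lj126_sigma = "zero-crossing") {
  switch(family,
    "LJ12-6" = if (identical(lj126_sigma, "minimum")) {
      function(p, r) {
        x6 <- (p[["sigma"]] / r)^6
        p[["epsilon"]] * (x6 * x6 - 2 * x6)
      }
    } else {
      function(p, r) {
        x6 <- (p[["sigma"]] / r)^6
        4 * p[["epsilon"]] * (x6 * x6 - x6)
      }
    },
    "LJ8-6" = function(p, r) {
      x2 <- (p[["sigma"]] / r)^2
      x6 <- x2 * x2 * x2
      p[["epsilon"]] * (3 * x6 * x2 - 4 * x6)
    },
    "WBH" = function(p, r) {
      e <- p[["epsilon"]]; s <- p[["sigma"]]; g <- p[["gamma"]]
      s6 <- s^6
      2 * e * (g + 3) / g * s6 / (s6 + r^6) *
        (3 / (g + 3) * exp(g * (1 - r / s)) - 1)
    },
    "MBH" = function(p, r) {
      e <- p[["epsilon"]]; s <- p[["sigma"]]; g <- p[["gamma"]]
      e * g / (g - 6) * (6 / g * exp(g * (1 - r / s)) - (s / r)^6)
    },
    "MRS" = function(p, r) {
      e <- p[["epsilon"]]; s <- p[["sigma"]]; g <- p[["gamma"]]
      u <- exp(g * (1 - r / s))
      e * (u * u - 2 * u)
    },
    "BHA" = function(p, r) {
      p[["A"]] * exp(-p[["b"]] * r) - p[["C6"]] / r^6
    },
    "GBH" = function(p, r) {
      e <- p[["epsilon"]]; s <- p[["sigma"]]; g <- p[["gamma"]]; d <- p[["delta"]]
      e * g / (g - d) * (d / g * exp(g * (1 - r / s)) - (s / r)^d)
    },
    "LJ14-7" = function(p, r) {
      e <- p[["epsilon"]]; s <- p[["sigma"]]; g <- p[["gamma"]]; d <- p[["delta"]]
      x <- r / s
      e * ((1 + d) / (x + d))^7 * ((1 + g) / (x^7 + g) - 2)
    },
    "TT" = {
      Re <- constants[["Re"]]; De <- constants[["De"]]
      function(p, r) {
        x <- r / Re
        y <- p[["b"]] * x
        disp <- tt_damping(y, 6) * p[["C6"]] / x^6 +
          tt_damping(y, 8) * p[["C8"]] / x^8 +
          tt_damping(y, 10) * p[["C10"]] / x^10
        De * (p[["A"]] * exp(-y) - disp)
      }
    },
    abort(paste0("no energy function for family ", family))
  )
}

#' Evaluate the pair interaction energy
#'
#' Computes the interaction energy of the model at one or more interatomic
#' separations.  All families require `r > 0` except the Wang-Buckingham
#' form, which is finite at `r = 0` by construction.
#'
#' @param model A [potential_model()].
#' @param r Separation(s) in Angstrom.
#' @return Energy in kJ/mol, same length as `r`.
#' @export
evaluate_energy <- function(model, r) {
  stopifnot(inherits(model, "potential_model"))
  if (model$family != "WBH" && any(r <= 0)) {
    abort(paste0("r must be > 0 for family ", model$family))
  }
  if (model$family == "WBH" && any(r < 0)) abort("r must be >= 0")
  f <- energy_fn(model$family, model$constants, model$lj126_sigma %||% "zero-crossing")
  e <- f(model$params, r)
  if (any(!is.finite(e))) {
    bad <- r[!is.finite(e)][1]
    abort(paste0("non-finite energy for family ", model$family, " at r = ", bad))
  }
  e
}

# Analytic radial derivatives where simple; NULL marks finite-difference fallback.
deriv_fn <- function(family) {
  switch(family,
    "LJ12-6" = function(p, r, k, lj126_sigma = "zero-crossing") {
      s <- p[["sigma"]]; e <- p[["epsilon"]]
      if (identical(lj126_sigma, "minimum")) {
        c12 <- e * s^12; c6 <- 2 * e * s^6
      } else {
        c12 <- 4 * e * s^12; c6 <- 4 * e * s^6
      }
      switch(k,
        -12 * c12 * r^-13 + 6 * c6 * r^-7,
        156 * c12 * r^-14 - 42 * c6 * r^-8,
        -2184 * c12 * r^-15 + 336 * c6 * r^-9)
    },
    "LJ8-6" = function(p, r, k, ...) {
      s <- p[["sigma"]]; e <- p[["epsilon"]]
      c8 <- 3 * e * s^8; c6 <- 4 * e * s^6
      switch(k,
        -8 * c8 * r^-9 + 6 * c6 * r^-7,
        72 * c8 * r^-10 - 42 * c6 * r^-8,
        -720 * c8 * r^-11 + 336 * c6 * r^-9)
    },
    "MRS" = function(p, r, k, ...) {
      e <- p[["epsilon"]]; s <- p[["sigma"]]; g <- p[["gamma"]]
      u <- exp(g * (1 - r / s))
      a <- g / s
      switch(k,
        e * (-2 * a * u * u + 2 * a * u),
        e * (4 * a^2 * u * u - 2 * a^2 * u),
        e * (-8 * a^3 * u * u + 2 * a^3 * u))
    },
    "BHA" = function(p, r, k, ...) {
      A <- p[["A"]]; b <- p[["b"]]; C6 <- p[["C6"]]
      switch(k,
        -A * b * exp(-b * r) + 6 * C6 * r^-7,
        A * b^2 * exp(-b * r) - 42 * C6 * r^-8,
        -A * b^3 * exp(-b * r) + 336 * C6 * r^-9)
    },
    "MBH" = function(p, r, k, ...) {
      e <- p[["epsilon"]]; s <- p[["sigma"]]; g <- p[["gamma"]]
      pref <- e * g / (g - 6)
      u <- exp(g * (1 - r / s))
      switch(k,
        pref * (-6 / s * u + 6 * s^6 * r^-7),
        pref * (6 * g / s^2 * u - 42 * s^6 * r^-8),
        pref * (-6 * g^2 / s^3 * u + 336 * s^6 * r^-9))
    },
    "GBH" = function(p, r, k, ...) {
      e <- p[["epsilon"]]; s <- p[["sigma"]]; g <- p[["gamma"]]; d <- p[["delta"]]
      pref <- e * g / (g - d)
      u <- exp(g * (1 - r / s))
      sd <- s^d
      switch(k,
        pref * (-d / s * u + d * sd * r^(-d - 1)),
        pref * (d * g / s^2 * u - d * (d + 1) * sd * r^(-d - 2)),
        pref * (-d * g^2 / s^3 * u + d * (d + 1) * (d + 2) * sd * r^(-d - 3)))
    },
    NULL
  )
}

#' Evaluate radial derivatives of the pair energy
#'
#' First, second and third derivatives with respect to the separation, as
#' needed by the semiclassical quantum corrections of the second virial
#' coefficient.  Analytic expressions are used for the Lennard-Jones 12-6 and
#' 8-6, Morse, Buckingham, modified Buckingham and generalized Buckingham
#' families; the remaining families (Wang-Buckingham, buffered 14-7,
#' Tang-Toennies) use high-order central finite differences with a step
#' scaled to `r`.
#'
#' @inheritParams evaluate_energy
#' @param order Derivative order, 1, 2 or 3.
#' @return Derivative in kJ/mol/Angstrom^order, same length as `r`.
#' @export
evaluate_derivative <- function(model, r, order = 1) {
  stopifnot(inherits(model, "potential_model"))
  if (!order %in% 1:3) abort("order must be 1, 2 or 3")
  an <- deriv_fn(model$family)
  if (!is.null(an)) {
    return(an(model$params, r, order, lj126_sigma = model$lj126_sigma %||% "zero-crossing"))
  }
  f <- function(x) evaluate_energy(model, x)
  h <- pmax(abs(r), 0.5) * switch(order, 2e-3, 3e-3, 8e-3)
  if (order == 1) {
    (8 * (f(r + h) - f(r - h)) - (f(r + 2 * h) - f(r - 2 * h))) / (12 * h)
  } else if (order == 2) {
    (-f(r + 2 * h) + 16 * f(r + h) - 30 * f(r) + 16 * f(r - h) - f(r - 2 * h)) / (12 * h^2)
  } else {
    (-f(r - 3 * h) + 8 * f(r - 2 * h) - 13 * f(r - h) +
       13 * f(r + h) - 8 * f(r + 2 * h) + f(r + 3 * h)) / (8 * h^3)
  }
}

# characteristic length used to bracket the well
length_scale <- function(model) {
  p <- model$params
  switch(model$family,
    "BHA" = 12 / p[["b"]],
    "TT"  = model$constants[["Re"]],
    p[["sigma"]]
  )
}

#' Locate the potential well
#'
#' Finds the position and depth of the attractive minimum by a dense grid
#' scan followed by golden-section refinement.  For the Buckingham `A e^{-br}
#' - C6/r^6` form, which dives to minus infinity at the origin, the physical
#' well beyond the repulsive wall is returned.
#'
#' @inheritParams evaluate_energy
#' @return Named numeric vector `c(r_min = ..., depth = ...)`; `depth` is the
#'   positive well depth `-E(r_min)` in kJ/mol.
#' @export
locate_well <- function(model) {
  stopifnot(inherits(model, "potential_model"))
  s <- length_scale(model)
  grid <- s * seq(0.25, 8, by = 5e-4)
  e <- evaluate_energy(model, grid)
  # several families (BHA, MBH, GBH) dive to -Inf at the origin; the physical
  # well is always beyond the repulsive wall, i.e. past the global maximum
  imax <- which.max(e)
  grid <- grid[imax:length(grid)]
  e <- e[imax:length(e)]
  i <- which.min(e)
  if (e[i] >= 0) abort(paste0("family ", model$family, ": no attractive minimum found"))
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(function(x) evaluate_energy(model, x), c(lo, hi), tol = 1e-12)
  r_min <- opt$minimum
  # polish to ~1e-9 A with a root find on the first derivative
  g <- function(x) evaluate_derivative(model, x, 1)
  if (g(lo) < 0 && g(hi) > 0) {
    r_min <- uniroot(g, c(lo, hi), tol = 1e-12)$root
  }
  c(r_min = r_min, depth = -evaluate_energy(model, r_min))
}

#' Interconvert modified Buckingham and Buckingham parameters
#'
#' The exp-6 (`MBH`) and `A e^{-br} - C6/r^6` (`BHA`) potentials are the same
#' function under the parameter map `A = 6 eps e^gamma/(gamma-6)`,
#' `b = gamma/sigma`, `C6 = eps gamma sigma^6/(gamma-6)`.  `mbh_to_bha()`
#' applies the map; `bha_to_mbh()` inverts it (solving `6 e^g / g^7 =
#' A b^-6 / C6` for `gamma > 6` by bisection).
#'
#' @param model A `potential_model` of the source family.
#' @return A `potential_model` of the target family describing the identical
#'   energy function.
#' @export
mbh_to_bha <- function(model) {
  stopifnot(model$family == "MBH")
  p <- model$params
  e <- p[["epsilon"]]; s <- p[["sigma"]]; g <- p[["gamma"]]
  potential_model("BHA", c(
    A = 6 * e * exp(g) / (g - 6),
    C6 = e * g * s^6 / (g - 6),
    b = g / s
  ))
}

#' @rdname mbh_to_bha
#' @export
bha_to_mbh <- function(model) {
  stopifnot(model$family == "BHA")
  p <- model$params
  A <- p[["A"]]; b <- p[["b"]]; C6 <- p[["C6"]]
  if (C6 <= 0) abort("BHA with C6 = 0 has no exp-6 equivalent")
  target <- A / (C6 * b^6)
  f <- function(g) 6 * exp(g) / g^7 - target
  # 6 e^g/g^7 is increasing for g > 7; bracket in (6, 500)
  lo <- 6 + 1e-9; hi <- 500
  if (f(lo) > 0 || f(hi) < 0) abort("BHA parameters have no gamma > 6 exp-6 equivalent")
  g <- uniroot(f, c(lo, hi), tol = 1e-14)$root
  s <- g / b
  e <- A * (g - 6) / (6 * exp(g))
  potential_model("MBH", c(epsilon = e, sigma = s, gamma = g))
}
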