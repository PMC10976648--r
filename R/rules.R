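#' Combination relations for van der Waals parameters
#'
#' Applies one of the twelve combination relations (identified by the
#' equation numbers 10-21 conventionally used for them) to a pair of
#' homodimer parameter values.  All relations are symmetric and idempotent:
#' `apply_rule(e, x, x) == x`.
#'
#' Single-input relations (usable for any positive parameter):
#' \describe{
#'   \item{10}{geometric mean `sqrt(x1 x2)`}
#'   \item{11}{arithmetic mean `(x1 + x2)/2`}
#'   \item{12}{harmonic mean `2 x1 x2/(x1 + x2)` (Hogervorst's well-depth
#'     rule; ill-behaved when both inputs are zero)}
#'   \item{14}{`x1 x2 (x1 + x2)/(x1^2 + x2^2)` (Morse-potential rule)}
#'   \item{15}{contraharmonic mean `(x1^2 + x2^2)/(x1 + x2)` (Mason's
#'     steepness rule, conventionally used for gamma of exp-6 forms)}
#'   \item{17}{sixth-power mean `((x1^6 + x2^6)/2)^(1/6)` (Waldman-Hagler
#'     radius rule)}
#'   \item{18}{cubic mean `(x1^3 + x2^3)/(x1^2 + x2^2)` (Halgren's buffered
#'     14-7 radius rule)}
#'   \item{19}{HHG mean `4 x1 x2/(sqrt(x1) + sqrt(x2))^2` (Halgren's
#'     harmonic-mean well-depth rule)}
#'   \item{20}{cube mean `((x1^3 + x2^3)/2)^(1/3)`, an atomic-volume average
#'     for van der Waals radii}
#'   \item{21}{power mean of order -3, `((x1^-3 + x2^-3)/2)^(-1/3)`; strictly
#'     smaller than the geometric mean for unequal inputs, intended for
#'     well depths}
#' }
#'
#' Multi-input relations (admissible only for the parameter they were
#' designed for):
#' \describe{
#'   \item{13}{Hogervorst's sigma rule for exponential-repulsion forms.  The
#'     dispersion-like product `eps * gamma * sigma^6` is combined
#'     geometrically and solved for the mixed sigma using the already
#'     combined well depth and steepness:
#'     `sigma12 = (sqrt(e1 g1 s1^6 * e2 g2 s2^6)/(e12 g12))^(1/6)`.
#'     Requires `context` entries `epsilon1`, `epsilon2`, `gamma1`, `gamma2`,
#'     `epsilon12`, `gamma12`; ill-behaved when `epsilon12` or `gamma12` is
#'     zero.  `x1`, `x2` are the homodimer sigmas.}
#'   \item{16}{Waldman-Hagler well-depth rule
#'     `eps12 = sqrt(e1 e2) * 2 (s1 s2)^3/(s1^6 + s2^6)`.  Requires `context`
#'     entries `sigma1`, `sigma2`; `x1`, `x2` are the homodimer well depths.}
#' }
#'
#' @param eq_id Integer relation identifier in 10:21.
#' @param x1,x2 Homodimer parameter values (positive).
#' @param context Named list with the auxiliary values needed by relations
#'   13 and 16 (see above); ignored otherwise.
#' @return The combined heterodimer parameter value.
#' @export
#' @examples
#' apply_rule(10, 4, 9) # geometric: 6
#' apply_rule(20, 1, 2) # cube mean: 1.650964
apply_rule <- function(eq_id, x1, x2, context = NULL) {
  if (!is.finite(x1) || !is.finite(x2)) abort("rule inputs must be finite")
  if (x1 < 0 || x2 < 0) abort("rule inputs must be non-negative")
  eq_id <- as.integer(eq_id)
  switch(as.character(eq_id),
    "10" = sqrt(x1 * x2),
    "11" = (x1 + x2) / 2,
    "12" = {
      if (x1 + x2 == 0) abort("rule 12 is singular when both inputs are zero")
      2 * x1 * x2 / (x1 + x2)
    },
    "13" = {
      need <- c("epsilon1", "epsilon2", "gamma1", "gamma2", "epsilon12", "gamma12")
      if (is.null(context) || !all(need %in% names(context))) {
        abort("rule 13 needs context epsilon1/2, gamma1/2 and combined epsilon12, gamma12")
      }
      ct <- context
      if (ct$epsilon12 == 0 || ct$gamma12 == 0) {
        abort("rule 13 is singular when the combined epsilon or gamma is zero")
      }
      (sqrt(ct$epsilon1 * ct$gamma1 * x1^6 * ct$epsilon2 * ct$gamma2 * x2^6) /
         (ct$epsilon12 * ct$gamma12))^(1 / 6)
    },
    "14" = {
      if (x1 + x2 == 0) abort("rule 14 is singular when both inputs are zero")
      x1 * x2 * (x1 + x2) / (x1^2 + x2^2)
    },
    "15" = {
      if (x1 + x2 == 0) abort("rule 15 is singular when both inputs are zero")
      (x1^2 + x2^2) / (x1 + x2)
    },
    "16" = {
      if (is.null(context) || !all(c("sigma1", "sigma2") %in% names(context))) {
        abort("rule 16 needs context sigma1 and sigma2")
      }
      s1 <- context$sigma1; s2 <- context$sigma2
      sqrt(x1 * x2) * 2 * (s1 * s2)^3 / (s1^6 + s2^6)
    },
    "17" = ((x1^6 + x2^6) / 2)^(1 / 6),
    "18" = {
      if (x1 + x2 == 0) abort("rule 18 is singular when both inputs are zero")
      (x1^3 + x2^3) / (x1^2 + x2^2)
    },
    "19" = {
      if (x1 + x2 == 0) abort("rule 19 is singular when both inputs are zero")
      4 * x1 * x2 / (sqrt(x1) + sqrt(x2))^2
    },
    "20" = ((x1^3 + x2^3) / 2)^(1 / 3),
    "21" = {
      if (x1 == 0 || x2 == 0) abort("rule 21 is singular when an input is zero")
      ((x1^-3 + x2^-3) / 2)^(-1 / 3)
    },
    abort(paste0("unknown combination relation ", eq_id))
  )
}

#' Construct a rule set
#'
#' A rule set assigns one combination relation to each parameter of a
#' potential family, in the family's canonical parameter order (see
#' [vdw_param_names()]).  Multi-input relations are admissible only for the
#' parameter they depend on: relation 13 only for `sigma` (it consumes the
#' combined `epsilon` and `gamma`), relation 16 only for `epsilon` (it
#' consumes the homodimer sigmas), relation 15 only for `gamma`.
#'
#' @param family Potential family identifier.
#' @param assignment Named integer vector mapping parameter names to relation
#'   identifiers, or an unnamed vector in canonical parameter order, or a
#'   string such as `"10 20 14 10"`.
#' @return An object of class `vdw_ruleset`.
#' @export
#' @examples
#' ruleset("MBH", "10 20 14")
#' ruleset("LJ12-6", c(epsilon = 10, sigma = 10))
ruleset <- function(family, assignment) {
  family <- match_family(family)
  pnames <- .vdw_param_names[[family]]
  if (is.character(assignment) && length(assignment) == 1) {
    assignment <- as.integer(strsplit(trimws(assignment), "[ \t]+")[[1]])
  }
  if (is.null(names(assignment))) {
    if (length(assignment) != length(pnames)) {
      abort(paste0("family ", family, " needs ", length(pnames), " rules"))
    }
    assignment <- setNames(as.integer(assignment), pnames)
  } else {
    if (!setequal(names(assignment), pnames)) {
      abort(paste0("assignment names must be {", paste(pnames, collapse = ", "), "}"))
    }
    assignment <- setNames(as.integer(assignment[pnames]), pnames)
  }
  if (!all(assignment %in% 10:21)) abort("relation identifiers must be in 10:21")
  for (pn in pnames) {
    eq <- assignment[[pn]]
    if (eq == 13 && pn != "sigma") abort("relation 13 is admissible only for sigma")
    if (eq == 16 && pn != "epsilon") abort("relation 16 is admissible only for epsilon")
    if (eq == 15 && pn != "gamma") abort("relation 15 is admissible only for gamma")
  }
  if (any(assignment == 13) && !all(c("epsilon", "gamma") %in% pnames)) {
    abort("relation 13 needs a family with epsilon and gamma parameters")
  }
  if (any(assignment == 16) && !("sigma" %in% pnames)) {
    abort("relation 16 needs a family with a sigma parameter")
  }
  structure(list(family = family, assignment = assignment), class = "vdw_ruleset")
}

#' @export
print.vdw_ruleset <- function(x, ...) {
  cat("<vdw_ruleset> ", x$family, ": ", ruleset_label(x), "\n", sep = "")
  invisible(x)
}

#' Rule-set notation
#'
#' @param rs A [ruleset()].
#' @return Space-separated relation identifiers in canonical parameter order,
#'   e.g. `"10 20 14 10"`.
#' @export
ruleset_label <- function(rs) paste(rs$assignment, collapse = " ")

#' Combine homodimer parameters into a heterodimer model
#'
#' Applies a rule set parameter-by-parameter to two homodimer models of the
#' same family.  Dependency order is respected: `epsilon` and `gamma` are
#' combined before relation 13 is used for `sigma`.  For the Tang-Toennies
#' family the heterodimer well constants `Re` and `De` must be supplied —
#' the dimensionless parametrisation presumes the mixed well is known.
#'
#' @param rs A [ruleset()].
#' @param m1,m2 Homodimer [potential_model()]s of the rule set's family.
#' @param constants Heterodimer `list(Re=, De=)`, required for `TT`.
#' @return The combined heterodimer [potential_model()].
#' @export
combine_params <- function(rs, m1, m2, constants = NULL) {
  stopifnot(inherits(rs, "vdw_ruleset"))
  if (m1$family != rs$family || m2$family != rs$family) {
    abort("homodimer models must match the rule set family")
  }
  pnames <- names(rs$assignment)
  p1 <- m1$params; p2 <- m2$params
  out <- setNames(numeric(length(pnames)), pnames)
  first <- setdiff(pnames, "sigma")
  for (pn in first) {
    ctx <- if (rs$assignment[[pn]] == 16) {
      list(sigma1 = p1[["sigma"]], sigma2 = p2[["sigma"]])
    }
    out[[pn]] <- apply_rule(rs$assignment[[pn]], p1[[pn]], p2[[pn]], ctx)
  }
  if ("sigma" %in% pnames) {
    ctx <- if (rs$assignment[["sigma"]] == 13) {
      list(epsilon1 = p1[["epsilon"]], epsilon2 = p2[["epsilon"]],
           gamma1 = p1[["gamma"]], gamma2 = p2[["gamma"]],
           epsilon12 = out[["epsilon"]], gamma12 = out[["gamma"]])
    }
    out[["sigma"]] <- apply_rule(rs$assignment[["sigma"]], p1[["sigma"]], p2[["sigma"]], ctx)
  }
  if (rs$family == "TT" && is.null(constants)) {
    abort("TT heterodimers need constants = list(Re, De): the mixed well must be known")
  }
  potential_model(rs$family, out, constants = constants)
}

#' Default admissibility of combination relations per parameter
#'
#' All nine single-input relations (10, 11, 12, 14, 17, 18, 19, 20, 21) are
#' admissible for every parameter; relation 15 is added for `gamma`,
#' relation 13 for `sigma` (when the family has `epsilon` and `gamma`), and
#' relation 16 for `epsilon` (when the family has `sigma`).
#'
#' @param family Potential family identifier.
#' @return Named list mapping parameter names to admissible relation ids.
#' @export
default_admissibility <- function(family) {
  family <- match_family(family)
  pnames <- .vdw_param_names[[family]]
  single <- c(10L, 11L, 12L, 14L, 17L, 18L, 19L, 20L, 21L)
  adm <- lapply(pnames, function(pn) {
    ids <- single
    if (pn == "gamma") ids <- c(ids, 15L)
    if (pn == "sigma" && all(c("epsilon", "gamma") %in% pnames)) ids <- c(ids, 13L)
    if (pn == "epsilon" && "sigma" %in% pnames) ids <- c(ids, 16L)
    sort(ids)
  })
  setNames(adm, pnames)
}

#' Enumerate all admissible rule sets of a family
#'
#' Forms the Cartesian product of the admissible relation identifiers over
#' the family's parameters, in deterministic order (sorted by the
#' equation-id tuple in canonical parameter order).
#'
#' @param family Potential family identifier.
#' @param admissibility Named list parameter -> admissible relation ids;
#'   defaults to [default_admissibility()].
#' @return A tibble with one integer column per parameter (canonical order)
#'   and one row per rule set.
#' @export
enumerate_rulesets <- function(family, admissibility = default_admissibility(family)) {
  family <- match_family(family)
  pnames <- .vdw_param_names[[family]]
  if (!all(pnames %in% names(admissibility))) {
    abort("admissibility must cover every parameter of the family")
  }
  if (any(vapply(admissibility[pnames], length, 1L) == 0)) {
    abort("empty admissible relation set for a parameter")
  }
  grid <- expand.grid(rev(lapply(admissibility[pnames], sort)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, rev(seq_along(pnames)), drop = FALSE]
  names(grid) <- pnames
  grid <- grid[do.call(order, grid), , drop = FALSE]
  rownames(grid) <- NULL
  tibble::as_tibble(grid)
}

#' Rank rule sets against heterodimer reference curves
#'
#' For every rule set, combines the fitted homodimer parameters into each
#' heterodimer model, evaluates it on the windowed points of the heterodimer
#' reference curve, and scores the rule set by the unweighted mean RMSE over
#' the pairs.  Rule sets that raise a singularity on any pair score `Inf`
#' and sort last; ties are broken by the sorted equation-id tuple, so the
#' ranking is deterministic and invariant under permutation of the input
#' curve list.
#'
#' @param homodimer_fits Named list element -> [potential_model()] (all the
#'   same family).
#' @param hetero_curves List of heterodimer [dissociation_curve()]s; every
#'   element appearing must have a homodimer fit.
#' @param window An [energy_window()]; the windowed subset of each reference
#'   curve (computed on the reference's own grid) defines the scored points.
#' @param family Potential family; defaults to the family of the fits.
#' @param admissibility See [enumerate_rulesets()].
#' @param tt_constants For `TT` only: named list `"A-B"` -> `list(Re=, De=)`
#'   per heterodimer pair (element names sorted alphabetically).
#' @return A tibble, one row per rule set, sorted by `mean_rmse`: columns
#'   `rule` (notation string), one `rmse_<A>.<B>` column per pair, and
#'   `mean_rmse` (kJ/mol).
#' @export
rank_rulesets <- function(homodimer_fits, hetero_curves,
                          window = energy_window(),
                          family = NULL,
                          admissibility = NULL,
                          tt_constants = NULL) {
  if (length(hetero_curves) == 0) abort("no heterodimer curves supplied")
  family <- match_family(family %||% homodimer_fits[[1]]$family)
  if (!all(vapply(homodimer_fits, function(m) m$family, "") == family)) {
    abort("all homodimer fits must share one family")
  }
  admissibility <- admissibility %||% default_admissibility(family)
  sets <- enumerate_rulesets(family, admissibility)
  pnames <- .vdw_param_names[[family]]

  pairs <- lapply(hetero_curves, function(cv) {
    el <- curve_elements(cv)
    for (e in el) {
      if (!e %in% names(homodimer_fits)) {
        abort(paste0("no homodimer fit for element ", e))
      }
    }
    sub <- select_window(cv, window)
    key <- paste(sort(el), collapse = "-")
    consts <- NULL
    if (family == "TT") {
      if (is.null(tt_constants) || is.null(tt_constants[[key]])) {
        abort(paste0("TT ranking needs tt_constants for pair ", key))
      }
      consts <- tt_constants[[key]]
    }
    list(key = key, el = el, r = sub$r, E = sub$E, constants = consts)
  })
  # order pairs deterministically by pair key
  pairs <- pairs[order(vapply(pairs, function(p) p$key, ""))]

  efn_cache <- list()
  rmse_mat <- matrix(NA_real_, nrow(sets), length(pairs))
  colnames(rmse_mat) <- vapply(pairs, function(p) p$key, "")
  set_mat <- as.matrix(sets)
  for (j in seq_along(pairs)) {
    pr <- pairs[[j]]
    m1 <- homodimer_fits[[pr$el[1]]]
    m2 <- homodimer_fits[[pr$el[2]]]
    efn <- energy_fn(family, pr$constants)
    for (i in seq_len(nrow(set_mat))) {
      rs <- structure(list(family = family,
                           assignment = setNames(set_mat[i, ], pnames)),
                      class = "vdw_ruleset")
      rmse_mat[i, j] <- tryCatch({
        cm <- combine_params_fast(rs, m1, m2)
        e <- efn(cm, pr$r)
        if (any(!is.finite(e))) Inf else sqrt(mean((e - pr$E)^2))
      }, error = function(e) Inf)
    }
  }
  mean_rmse <- rowMeans(rmse_mat)
  lab <- apply(set_mat, 1, paste, collapse = " ")
  out <- tibble::as_tibble(sets)
  out$rule <- lab
  score <- tibble::as_tibble(as.data.frame(rmse_mat))
  names(score) <- paste0("rmse_", gsub("-", ".", colnames(rmse_mat), fixed = TRUE))
  out <- dplyr::bind_cols(out[, "rule", drop = FALSE], out[, pnames], score)
  out$mean_rmse <- mean_rmse
  ord <- do.call(order, c(list(mean_rmse), as.list(sets)))
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "rank")
}

# combine without re-validating through potential_model(); returns the raw
# parameter vector for the fast energy path
combine_params_fast <- function(rs, m1, m2) {
  pnames <- names(rs$assignment)
  p1 <- m1$params; p2 <- m2$params
  out <- setNames(numeric(length(pnames)), pnames)
  for (pn in setdiff(pnames, "sigma")) {
    ctx <- if (rs$assignment[[pn]] == 16) {
      list(sigma1 = p1[["sigma"]], sigma2 = p2[["sigma"]])
    }
    out[[pn]] <- apply_rule(rs$assignment[[pn]], p1[[pn]], p2[[pn]], ctx)
  }
  if ("sigma" %in% pnames) {
    ctx <- if (rs$assignment[["sigma"]] == 13) {
      list(epsilon1 = p1[["epsilon"]], epsilon2 = p2[["epsilon"]],
           gamma1 = p1[["gamma"]], gamma2 = p2[["gamma"]],
           epsilon12 = out[["epsilon"]], gamma12 = out[["gamma"]])
    }
    out[["sigma"]] <- apply_rule(rs$assignment[["sigma"]], p1[["sigma"]], p2[["sigma"]], ctx)
  }
  out
}
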