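#' Fit every family to a set of curves and tabulate mean windowed RMSE
#'
#' The table-shaped driver of the workbench: every curve in the set is
#' fitted with every requested family, and the mean windowed RMSE is
#' reported per (family, source tag).  Per-curve fits, seeds and bounds are
#' kept in the `details` component so any number in the summary can be
#' traced back.
#'
#' @param curves A list of [dissociation_curve()]s, or a directory of curve
#'   files readable by [read_curve()].
#' @param families Families to fit; defaults to all nine.
#' @param window An [energy_window()].
#' @param seed Base integer seed; curve/family fits use offsets from it.
#' @param n_starts Multistart count per fit.
#' @return An object of class `fit_study`: a list with `summary` (tibble
#'   family x source_tag with `mean_rmse`, `n_curves`) and `details` (tibble
#'   with one row per fit: elements, source tag, rmse, n_points, seed and
#'   the fitted model in a list column).
#' @export
run_fit_study <- function(curves, families = vdw_families(),
                          window = energy_window(), seed = 1L, n_starts = 16L) {
  curves <- load_curves(curves)
  if (length(families) == 0) abort("no families requested")
  families <- vapply(families, match_family, "")
  rows <- list()
  for (fi in seq_along(families)) {
    fam <- families[fi]
    for (ci in seq_along(curves)) {
      cv <- curves[[ci]]
      fit <- fit_potential(fam, cv, window = window,
                           seed = as.integer(seed) + 1000L * fi + ci,
                           n_starts = n_starts)
      el <- curve_elements(cv)
      rows[[length(rows) + 1]] <- tibble::tibble(
        family = fam, element_a = el[1], element_b = el[2],
        source_tag = curve_source(cv), rmse = fit$rmse,
        n_points = fit$n_points, converged = fit$converged,
        seed = fit$seed, model = list(fit$model))
    }
  }
  details <- dplyr::bind_rows(rows)
  summary <- details |>
    dplyr::group_by(.data$family, .data$source_tag) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse),
                     n_curves = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(match(.data$family, .vdw_family_order), .data$source_tag)
  structure(list(summary = summary, details = details,
                 window = window, seed = as.integer(seed)),
            class = "fit_study")
}

#' @export
print.fit_study <- function(x, ...) {
  cat("<fit_study> ", nrow(x$details), " fits\n", sep = "")
  print(tidyr::pivot_wider(x$summary, names_from = "family",
                           values_from = "mean_rmse", id_cols = "source_tag"))
  invisible(x)
}

#' Fit homodimers, scan combination rules, and report the best rule set
#'
#' The rule-study driver: fits the requested family to every homodimer
#' curve, ranks all admissible rule sets against the heterodimer reference
#' curves, and reports the best rule set in the conventional space-separated
#' notation together with its mean RMSE.  For comparison, the heterodimer
#' curves are also fitted directly, giving the fit-RMSE floor that combined
#' potentials cannot beat.
#'
#' @param homodimer_curves List of homodimer [dissociation_curve()]s (one
#'   per element).
#' @param hetero_curves List of heterodimer [dissociation_curve()]s.
#' @param family Potential family to study.
#' @param window An [energy_window()].
#' @param admissibility See [enumerate_rulesets()].
#' @param seed Base seed for the fits.
#' @param n_starts Multistart count per fit.
#' @param tt_constants For `TT`: per-pair well constants, see
#'   [rank_rulesets()].
#' @return An object of class `rule_study`: list with `best_rule` (notation
#'   string), `best_mean_rmse`, `fit_mean_rmse` (direct heterodimer fits),
#'   `ranking` (full tibble from [rank_rulesets()]), `homodimer_fits`.
#' @export
run_rule_study <- function(homodimer_curves, hetero_curves, family,
                           window = energy_window(),
                           admissibility = NULL, seed = 1L, n_starts = 16L,
                           tt_constants = NULL) {
  family <- match_family(family)
  homodimer_curves <- load_curves(homodimer_curves)
  hetero_curves <- load_curves(hetero_curves)
  if (length(hetero_curves) == 0) abort("no heterodimer curves")
  hetero_el <- unique(unlist(lapply(hetero_curves, curve_elements)))
  homo_el <- vapply(homodimer_curves, function(cv) curve_elements(cv)[1], "")
  missing <- setdiff(hetero_el, homo_el)
  if (length(missing)) {
    abort(paste0("heterodimer elements without a homodimer curve: ",
                 paste(missing, collapse = ", ")))
  }
  fits <- list()
  for (i in seq_along(homodimer_curves)) {
    cv <- homodimer_curves[[i]]
    el <- curve_elements(cv)[1]
    tc <- if (family == "TT") {
      w <- curve_well(cv)
      list(Re = w[["r_min"]], De = w[["depth"]])
    }
    fits[[el]] <- fit_potential(family, cv, window = window,
                                seed = as.integer(seed) + i,
                                n_starts = n_starts,
                                tt_constants = tc)$model
  }
  ranking <- rank_rulesets(fits, hetero_curves, window = window,
                           family = family, admissibility = admissibility,
                           tt_constants = tt_constants)
  direct <- vapply(seq_along(hetero_curves), function(i) {
    cv <- hetero_curves[[i]]
    tc <- if (family == "TT") {
      w <- curve_well(cv)
      list(Re = w[["r_min"]], De = w[["depth"]])
    }
    fit_potential(family, cv, window = window,
                  seed = as.integer(seed) + 100L + i,
                  n_starts = n_starts, tt_constants = tc)$rmse
  }, 0)
  structure(list(
    family = family,
    best_rule = ranking$rule[1],
    best_mean_rmse = ranking$mean_rmse[1],
    fit_mean_rmse = mean(direct),
    ranking = ranking,
    homodimer_fits = fits,
    window = window, seed = as.integer(seed)
  ), class = "rule_study")
}

#' @export
print.rule_study <- function(x, ...) {
  cat("<rule_study> ", x$family, "\n", sep = "")
  cat("  best rule:     ", x$best_rule, "\n", sep = "")
  cat("  RMSE comb:     ", signif(x$best_mean_rmse, 4), " kJ/mol\n", sep = "")
  cat("  RMSE fit:      ", signif(x$fit_mean_rmse, 4), " kJ/mol (direct heterodimer fits)\n", sep = "")
  invisible(x)
}

load_curves <- function(curves) {
  if (is.character(curves) && length(curves) == 1 && dir.exists(curves)) {
    files <- sort(list.files(curves, pattern = "\\.(tsv|csv|txt)$", full.names = TRUE))
    if (length(files) == 0) abort(paste0("no curve files in ", curves))
    curves <- lapply(files, read_curve)
  }
  if (inherits(curves, "dissociation_curve")) curves <- list(curves)
  if (!all(vapply(curves, inherits, TRUE, "dissociation_curve"))) {
    abort("curves must be dissociation_curve objects or a directory path")
  }
  curves
}
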