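#' @importFrom generics tidy glance
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted potential
#'
#' @param x A `vdw_fit` from [fit_potential()].
#' @param ... Unused.
#' @return One row per parameter: `term`, `estimate`, and the bounds the
#'   optimiser was allowed to roam.
#' @export
tidy.vdw_fit <- function(x, ...) {
  p <- x$model$params
  out <- tibble::tibble(term = names(p), estimate = unname(p))
  # bounds are reported in the fitted parametrisation; map back by name
  b <- x$bounds_used
  out$lower <- b$lower[match(out$term, b$param)]
  out$upper <- b$upper[match(out$term, b$param)]
  out
}

#' @rdname tidy.vdw_fit
#' @return `glance()`: a one-row summary with the family, windowed RMSE
#'   (kJ/mol), point count and convergence flag.
#' @export
glance.vdw_fit <- function(x, ...) {
  tibble::tibble(family = x$family, rmse = x$rmse, n_points = x$n_points,
                 converged = x$converged, seed = x$seed)
}

#' @export
tidy.rule_study <- function(x, ...) {
  out <- x$ranking
  out
}

#' @export
glance.rule_study <- function(x, ...) {
  tibble::tibble(family = x$family, best_rule = x$best_rule,
                 best_mean_rmse = x$best_mean_rmse,
                 fit_mean_rmse = x$fit_mean_rmse,
                 n_rulesets = nrow(x$ranking))
}

#' @export
glance.fit_study <- function(x, ...) {
  tidyr::pivot_wider(x$summary, names_from = "family",
                     values_from = "mean_rmse", id_cols = "source_tag")
}
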