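#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_hline labs
#'   autoplot theme_minimal facet_wrap scale_y_log10
NULL

#' @export
ggplot2::autoplot

#' Plot a dissociation curve
#'
#' @param object A [dissociation_curve()].
#' @param models Optional named list of [potential_model()]s to overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dissociation_curve <- function(object, models = NULL, ...) {
  df <- tibble::tibble(r = object$r, E = object$E)
  p <- ggplot(df, aes(x = .data$r, y = .data$E)) +
    geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    geom_point(size = 0.8) +
    labs(x = "separation r (Å)", y = "E (kJ/mol)",
         title = paste(curve_elements(object), collapse = "-"),
         subtitle = curve_source(object)) +
    theme_minimal()
  if (!is.null(models)) {
    grid <- seq(min(object$r), max(object$r), length.out = 400)
    md <- purrr::imap_dfr(models, function(m, nm) {
      tibble::tibble(r = grid, E = evaluate_energy(m, grid), model = nm)
    })
    p <- p + geom_line(data = md, aes(colour = .data$model))
  }
  p
}

#' Plot a fitted potential against its windowed data
#'
#' @param object A `vdw_fit`.
#' @param ... Unused.
#' @return A ggplot with the windowed reference points and the fitted curve.
#' @export
autoplot.vdw_fit <- function(object, ...) {
  grid <- seq(min(object$data$r), max(object$data$r), length.out = 400)
  fitline <- tibble::tibble(r = grid, E = evaluate_energy(object$model, grid))
  ggplot(object$data, aes(x = .data$r, y = .data$E)) +
    geom_hline(yintercept = 0, linetype = "dotted", colour = "grey50") +
    geom_point(size = 0.8) +
    geom_line(data = fitline, colour = "firebrick") +
    labs(x = "separation r (Å)", y = "E (kJ/mol)",
         title = paste0(object$family, " fit, RMSE = ",
                        signif(object$rmse, 3), " kJ/mol")) +
    theme_minimal()
}

#' Plot second virial coefficients against temperature
#'
#' @param object A `virial_result` from [b2_semiclassical()].
#' @param ... Unused.
#' @return A ggplot of the classical, corrected and total B2 versus T.
#' @export
autoplot.virial_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("B_classical", "B_qc1", "B_qc2", "B_qc3", "B_total"),
                              names_to = "component", values_to = "B")
  ggplot(long, aes(x = .data$T, y = .data$B, colour = .data$component)) +
    geom_line() + geom_point(size = 0.7) +
    labs(x = "T (K)", y = expression(B[2] ~ (cm^3 / mol))) +
    theme_minimal()
}

#' Plot a rule-set ranking
#'
#' @param object A `rule_study` from [run_rule_study()].
#' @param top Number of leading rule sets to label.
#' @param ... Unused.
#' @return A ggplot of mean RMSE versus rank (log scale), with the best
#'   rule sets highlighted.
#' @export
autoplot.rule_study <- function(object, top = 10, ...) {
  rk <- object$ranking
  rk <- rk[is.finite(rk$mean_rmse), ]
  ggplot(rk, aes(x = .data$rank, y = .data$mean_rmse)) +
    geom_point(size = 0.5, alpha = 0.5) +
    geom_point(data = utils::head(rk, top), colour = "firebrick") +
    scale_y_log10() +
    labs(x = "rank", y = "mean RMSE (kJ/mol)",
         title = paste0(object$family, ": best rule ", object$best_rule)) +
    theme_minimal()
}
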