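#' Synthetic five-element study world
#'
#' A reproducible stand-in for the noble-gas dimer study: five synthetic
#' elements whose well positions, depths and masses span the helium-to-xenon
#' range, with per-element shape parameters for every potential family.
#' Homodimer ground truths are built directly from the element table;
#' heterodimer ground truths are built by applying a chosen (planted)
#' combination rule set to the homodimer parameters.  Curves follow the
#' standard scan convention: 0.1 Angstrom steps up to 30 Angstrom, starting
#' above the short-range region where a quantum-chemistry scan would fail.
#'
#' @return `synthetic_elements()`: a tibble with one row per element:
#'   `element`, `r_min` (well position, Angstrom), `depth` (kJ/mol), `mass`
#'   (u), and the family shape parameters `gamma_exp` (exponential-form
#'   steepness), `delta_gbh`, `gamma_buf`, `delta_buf` (buffered 14-7
#'   constants).
#' @export
synthetic_elements <- function() {
  tibble::tibble(
    element = c("Hs", "Ns", "As", "Ks", "Xs"),
    r_min   = c(2.97, 3.09, 3.76, 4.01, 4.36),
    depth   = c(0.091, 0.354, 1.19, 1.66, 2.35),
    mass    = c(4.0026, 20.180, 39.948, 83.798, 131.29),
    gamma_exp = c(12.0, 12.6, 13.1, 13.4, 13.0),
    delta_gbh = c(5.6, 5.9, 6.2, 6.4, 6.1),
    gamma_buf = c(0.10, 0.11, 0.12, 0.13, 0.125),
    delta_buf = c(0.055, 0.065, 0.07, 0.08, 0.075)
  )
}

# Frozen dimensionless Tang-Toennies shape whose minimum sits exactly at
# (x, V*) = (1, -1): A and C6 solved from V*(1) = -1, dV*/dx(1) = 0 with
# b = 13.1, C8 = 0.41, C10 = 0.17.
.tt_shape <- c(A = 451676.4713957143, b = 13.1,
               C6 = 1.4598240220, C8 = 0.41, C10 = 0.17)

#' Ground-truth homodimer model of a synthetic element
#'
#' @param family Potential family identifier.
#' @param element Element label from [synthetic_elements()].
#' @return A [potential_model()] whose well position and depth equal the
#'   element's `r_min` and `depth` (exactly for families parameterised by
#'   their own well; by construction for the others).
#' @export
synthetic_truth <- function(family, element) {
  family <- match_family(family)
  tab <- synthetic_elements()
  row <- tab[tab$element == element, ]
  if (nrow(row) != 1) abort(paste0("unknown synthetic element ", element))
  r_w <- row$r_min; d <- row$depth; g <- row$gamma_exp
  switch(family,
    "LJ12-6" = potential_model(family, c(epsilon = d, sigma = r_w / 2^(1 / 6))),
    "LJ8-6"  = potential_model(family, c(epsilon = d, sigma = r_w)),
    "WBH"    = potential_model(family, c(epsilon = d, sigma = r_w, gamma = g - 2)),
    "MBH"    = potential_model(family, c(epsilon = d, sigma = r_w, gamma = g)),
    "MRS"    = potential_model(family, c(epsilon = d, sigma = r_w, gamma = g / 2)),
    "BHA"    = mbh_to_bha(potential_model("MBH", c(epsilon = d, sigma = r_w, gamma = g))),
    "GBH"    = potential_model(family, c(epsilon = d, sigma = r_w, gamma = g,
                                         delta = row$delta_gbh)),
    "LJ14-7" = potential_model(family, c(epsilon = d, sigma = r_w,
                                         gamma = row$gamma_buf, delta = row$delta_buf)),
    "TT"     = potential_model(family, .tt_shape, constants = list(Re = r_w, De = d))
  )
}

#' Generate the synthetic study curves
#'
#' Homodimer curves are generated from [synthetic_truth()] for each element;
#' heterodimer curves from the model obtained by applying `planted_rule` to
#' each element pair.  The scan grid is 0.1 Angstrom up to 30 Angstrom,
#' starting at 60% of the combined well position (the short-range points a
#' real scan would discard are never generated).
#'
#' @param family Potential family identifier.
#' @param planted_rule A [ruleset()] (or notation string) used as the
#'   ground-truth combination rule for heterodimers; `NULL` generates
#'   homodimers only.
#' @param noise_sd Gaussian noise SD in kJ/mol.
#' @param seed Integer base seed.
#' @param step Grid step in Angstrom.
#' @return List with `homodimers` and `heterodimers`: named lists of
#'   [dissociation_curve()]s (names `"A-B"`), plus `truths`, the generating
#'   models, and `tt_constants` (per-pair well constants, `TT` only).
#' @export
synthetic_world_curves <- function(family, planted_rule = NULL, noise_sd = 0,
                                   seed = 1L, step = 0.1) {
  family <- match_family(family)
  tab <- synthetic_elements()
  if (!is.null(planted_rule) && !inherits(planted_rule, "vdw_ruleset")) {
    planted_rule <- ruleset(family, planted_rule)
  }
  tag <- paste0("synthetic/", family, if (noise_sd > 0) paste0("/noise", noise_sd))
  homo <- list(); truths <- list(); tt_consts <- list()
  for (i in seq_len(nrow(tab))) {
    el <- tab$element[i]
    m <- synthetic_truth(family, el)
    truths[[paste(el, el, sep = "-")]] <- m
    w <- locate_well(m)
    cv <- generate_synthetic_curve(
      m, r_start = 0.6 * w[["r_min"]], r_stop = 30, step = step,
      noise_sd = noise_sd, seed = as.integer(seed) + i,
      element_a = el, element_b = el)
    attr(cv, "source_tag") <- tag
    homo[[paste(el, el, sep = "-")]] <- cv
  }
  hetero <- list()
  if (!is.null(planted_rule)) {
    for (i in seq_len(nrow(tab) - 1)) {
      for (j in (i + 1):nrow(tab)) {
        ei <- tab$element[i]; ej <- tab$element[j]
        key <- paste(ei, ej, sep = "-")
        consts <- NULL
        if (family == "TT") {
          # the mixed well must be known beforehand for the dimensionless form
          consts <- list(Re = apply_rule(11, tab$r_min[i], tab$r_min[j]),
                         De = apply_rule(10, tab$depth[i], tab$depth[j]))
          tt_consts[[key]] <- consts
        }
        m12 <- combine_params(planted_rule,
                              synthetic_truth(family, ei),
                              synthetic_truth(family, ej),
                              constants = consts)
        truths[[key]] <- m12
        w <- locate_well(m12)
        cv <- generate_synthetic_curve(
          m12, r_start = 0.6 * w[["r_min"]], r_stop = 30, step = step,
          noise_sd = noise_sd, seed = as.integer(seed) + 100L + 10L * i + j,
          element_a = ei, element_b = ej)
        attr(cv, "source_tag") <- tag
        hetero[[key]] <- cv
      }
    }
  }
  list(homodimers = homo, heterodimers = hetero, truths = truths,
       tt_constants = if (family == "TT") tt_consts else NULL)
}
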