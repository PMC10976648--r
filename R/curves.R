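#' Construct a dimer dissociation curve
#'
#' A dissociation curve is a tibble of ordered `(r, E)` samples — separation
#' in Angstrom, interaction energy in kJ/mol — for one element pair, plus
#' provenance metadata.  Rows are sorted by `r`; duplicated separations are
#' rejected.
#'
#' @param r Separations in Angstrom (positive, distinct).
#' @param E Interaction energies in kJ/mol (finite).
#' @param element_a,element_b Element symbols (or synthetic labels).
#' @param source_tag Free-text provenance, e.g. a level-of-theory tag or
#'   `"synthetic"`.
#' @return A tibble of class `dissociation_curve` with columns `r` and `E`
#'   and attributes `element_a`, `element_b`, `source_tag`.
#' @export
#' @examples
#' dissociation_curve(c(3, 3.5, 4), c(1.2, -0.9, -0.4), "Ar", "Ar", "demo")
dissociation_curve <- function(r, E, element_a, element_b, source_tag = "unknown") {
  if (length(r) != length(E)) abort("r and E must have the same length")
  if (length(r) < 2) abort("a curve needs at least 2 points")
  if (any(!is.finite(r)) || any(!is.finite(E))) abort("r and E must be finite")
  if (any(r <= 0)) abort("all separations must be > 0")
  ord <- order(r)
  r <- r[ord]; E <- E[ord]
  if (any(diff(r) == 0)) {
    abort(paste0("duplicated separation r = ", r[which(diff(r) == 0)[1]]))
  }
  out <- tibble::tibble(r = r, E = E)
  class(out) <- c("dissociation_curve", class(out))
  attr(out, "element_a") <- as.character(element_a)
  attr(out, "element_b") <- as.character(element_b)
  attr(out, "source_tag") <- as.character(source_tag)
  out
}

#' Curve metadata accessors
#'
#' @param curve A [dissociation_curve()].
#' @return `curve_elements()`: character vector of the two element labels;
#'   `curve_source()`: the provenance tag.
#' @export
curve_elements <- function(curve) {
  c(attr(curve, "element_a"), attr(curve, "element_b"))
}

#' @rdname curve_elements
#' @export
curve_source <- function(curve) attr(curve, "source_tag")

parse_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (grepl(":", body, fixed = TRUE)) {
      key <- trimws(sub(":.*$", "", body))
      val <- trimws(sub("^[^:]*:", "", body))
      meta[[tolower(key)]] <- val
    }
  }
  meta
}

read_two_columns <- function(path, n_cols = 2) {
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  blank <- !nzchar(trimws(lines))
  meta <- parse_meta(lines[is_meta])
  data_idx <- which(!is_meta & !blank)
  if (length(data_idx) == 0) abort(paste0("no data rows in ", path))
  vals <- matrix(NA_real_, length(data_idx), n_cols)
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    fields <- strsplit(trimws(lines[i]), "[,\t ]+")[[1]]
    if (length(fields) < n_cols) {
      abort(paste0(path, " line ", i, ": expected ", n_cols, " columns"))
    }
    v <- suppressWarnings(as.numeric(fields[seq_len(n_cols)]))
    if (any(is.na(v))) {
      abort(paste0(path, " line ", i, ": malformed numeric field '",
                   fields[which(is.na(v))[1]], "'"))
    }
    vals[k, ] <- v
  }
  list(values = vals, meta = meta)
}

#' Read a dissociation curve from a TSV/CSV file
#'
#' The file format is two numeric columns (separation in Angstrom, energy in
#' kJ/mol) separated by tabs, commas or spaces, preceded by `#`-prefixed
#' metadata lines of the form `# pair: He Xe` and `# source: CCSD(T)/CBS`.
#' Rows may appear in any order; they are sorted by separation.  Duplicated
#' separations and malformed numeric fields are errors.
#'
#' @param path Path to the curve file.
#' @return A [dissociation_curve()].
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  parsed <- read_two_columns(path, 2)
  pair <- strsplit(trimws(parsed$meta[["pair"]] %||% "X X"), "[ \t]+")[[1]]
  if (length(pair) < 2) pair <- c(pair, pair)
  dissociation_curve(parsed$values[, 1], parsed$values[, 2],
                     element_a = pair[1], element_b = pair[2],
                     source_tag = parsed$meta[["source"]] %||% "unknown")
}

#' Write a dissociation curve to a TSV file
#'
#' @param curve A [dissociation_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  el <- curve_elements(curve)
  hdr <- c(paste("# pair:", el[1], el[2]),
           paste("# source:", curve_source(curve)))
  rows <- sprintf("%.12g\t%.12g", curve$r, curve$E)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Construct / read / write experimental second-virial tables
#'
#' A B2 table holds ordered `(T, B2)` rows — temperature in kelvin, second
#' virial coefficient in cm^3/mol — for one element pair.  The file format
#' mirrors the curve format: two numeric columns `T_K`, `B2_cm3_per_mol`
#' with `#`-prefixed metadata.
#'
#' @param T Temperatures in kelvin (positive, strictly increasing after sort).
#' @param B2 Second virial coefficients in cm^3/mol.
#' @param element_a,element_b Element symbols.
#' @return A tibble of class `b2_table` with columns `T` and `B2`.
#' @export
b2_table <- function(T, B2, element_a, element_b) {
  if (length(T) != length(B2)) abort("T and B2 must have the same length")
  if (any(!is.finite(T)) || any(!is.finite(B2))) abort("T and B2 must be finite")
  if (any(T <= 0)) abort("temperatures must be > 0")
  ord <- order(T)
  T <- T[ord]; B2 <- B2[ord]
  if (any(diff(T) == 0)) abort("duplicated temperature")
  out <- tibble::tibble(T = T, B2 = B2)
  class(out) <- c("b2_table", class(out))
  attr(out, "element_a") <- as.character(element_a)
  attr(out, "element_b") <- as.character(element_b)
  out
}

#' @rdname b2_table
#' @param path File path.
#' @export
read_b2_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  parsed <- read_two_columns(path, 2)
  pair <- strsplit(trimws(parsed$meta[["pair"]] %||% "X X"), "[ \t]+")[[1]]
  if (length(pair) < 2) pair <- c(pair, pair)
  b2_table(parsed$values[, 1], parsed$values[, 2], pair[1], pair[2])
}

#' @rdname b2_table
#' @param table A `b2_table`.
#' @export
write_b2_table <- function(table, path) {
  el <- c(attr(table, "element_a"), attr(table, "element_b"))
  hdr <- c(paste("# pair:", el[1], el[2]), "# columns: T_K B2_cm3_per_mol")
  writeLines(c(hdr, sprintf("%.10g\t%.10g", table$T, table$B2)), path)
  invisible(path)
}

#' Resample a curve on a uniform grid with a natural cubic spline
#'
#' Interpolates the curve with a natural cubic spline and evaluates it on a
#' uniform grid of the requested spacing spanning the original range.  Knot
#' energies are reproduced exactly where grid points coincide with knots.
#'
#' @param curve A [dissociation_curve()] with at least 4 points.
#' @param spacing Grid spacing in Angstrom; must be positive and no larger
#'   than the span of the curve.
#' @return A resampled [dissociation_curve()].
#' @export
resample_spline <- function(curve, spacing) {
  if (nrow(curve) < 4) abort("resampling needs at least 4 points")
  if (spacing <= 0) abort("spacing must be > 0")
  span <- max(curve$r) - min(curve$r)
  if (spacing > span) abort("spacing exceeds the span of the curve")
  f <- splinefun(curve$r, curve$E, method = "natural")
  grid <- seq(min(curve$r), max(curve$r), by = spacing)
  el <- curve_elements(curve)
  dissociation_curve(grid, f(grid), el[1], el[2], curve_source(curve))
}

#' Two-point complete-basis-set extrapolation of the correlation energy
#'
#' The Helgaker two-point scheme extrapolates correlation energies obtained
#' with consecutive basis-set cardinal numbers `n-1` and `n` as
#' `E_CBS = (n^3 E_n - (n-1)^3 E_{n-1}) / (n^3 - (n-1)^3)`.  Only the
#' correlation component should be extrapolated; the SCF component converges
#' much faster and is conventionally taken from the larger basis unchanged.
#'
#' @param E_small Correlation energy at cardinal number `n - 1` (kJ/mol).
#' @param E_large Correlation energy at cardinal number `n` (kJ/mol).
#' @param n Cardinal number of the larger basis (integer, at least 3:
#'   extrapolation below triple-zeta is not meaningful).
#' @return Extrapolated correlation energy in kJ/mol.
#' @export
#' @examples
#' cbs_extrapolate(-0.9, -1.0, n = 4)
cbs_extrapolate <- function(E_small, E_large, n) {
  if (length(n) != 1 || n != round(n) || n < 3) {
    abort("n must be an integer >= 3 (triple-zeta or larger basis)")
  }
  (n^3 * E_large - (n - 1)^3 * E_small) / (n^3 - (n - 1)^3)
}

#' Generate a synthetic dissociation curve from a ground-truth potential
#'
#' Emulates a quantum-chemical dissociation scan: the ground-truth model is
#' evaluated on a uniform grid (conventionally 0.1 Angstrom steps up to
#' 30 Angstrom) and optional Gaussian noise of known standard deviation is
#' added.  The generator is seeded and fully reproducible; the source tag
#' records the truth family, its parameters and the seed.
#'
#' @param truth A [potential_model()] used as ground truth.
#' @param r_start,r_stop Grid limits in Angstrom (`0 < r_start < r_stop`).
#'   Short-range points where a real scan would fail are simply not requested:
#'   no extrapolation below `r_start` is ever performed.
#' @param step Grid step in Angstrom.
#' @param noise_sd Standard deviation of additive Gaussian noise in kJ/mol.
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @param element_a,element_b Labels for the synthetic pair.
#' @return A [dissociation_curve()].
#' @export
generate_synthetic_curve <- function(truth, r_start, r_stop, step = 0.1,
                                     noise_sd = 0, seed = 1L,
                                     element_a = "S1", element_b = "S2") {
  stopifnot(inherits(truth, "potential_model"))
  if (!(r_start > 0 && r_stop > r_start)) abort("need 0 < r_start < r_stop")
  if (step <= 0) abort("step must be > 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  grid <- seq(r_start, r_stop, by = step)
  E <- tryCatch(evaluate_energy(truth, grid), error = function(e) {
    abort(paste0("truth potential not finite on grid: ", conditionMessage(e)))
  })
  if (noise_sd > 0) {
    E <- E + withr::with_seed(as.integer(seed), rnorm(length(grid), 0, noise_sd))
  }
  tag <- paste0("synthetic ", truth$family, " [",
                paste(names(truth$params), signif(truth$params, 8),
                      sep = "=", collapse = ", "),
                "] noise_sd=", noise_sd, " seed=", as.integer(seed))
  dissociation_curve(grid, E, element_a, element_b, tag)
}
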