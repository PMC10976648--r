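#' Axilrod-Teller triple-dipole three-body energy
#'
#' The leading three-body dispersion term for a triplet of atoms A, B, C:
#' `E = V_ABC (1 + 3 cos(theta_A) cos(theta_B) cos(theta_C)) /
#' (r_AB r_BC r_CA)^3`, where the thetas are the internal angles of the
#' triangle.  The term is repulsive for near-equilateral geometries and
#' attractive for near-linear ones, and is invariant under any permutation
#' of the three atoms and under rigid motions.
#'
#' @param pos_a,pos_b,pos_c Cartesian coordinates in Angstrom (length-3).
#' @param V_abc Triple-dipole coefficient in kJ mol^-1 Angstrom^9 (invariant
#'   under permutation of the triple; positive for noble gases).
#' @return Energy in kJ/mol.
#' @export
#' @examples
#' d <- 4
#' tri <- rbind(c(0, 0, 0), c(d, 0, 0), c(d / 2, d * sqrt(3) / 2, 0))
#' axilrod_teller_energy(tri[1, ], tri[2, ], tri[3, ], V_abc = 1e3)
#' 1.375 * 1e3 / d^9 # equilateral closed form
axilrod_teller_energy <- function(pos_a, pos_b, pos_c, V_abc) {
  ab <- pos_b - pos_a; ac <- pos_c - pos_a; bc <- pos_c - pos_b
  r_ab <- sqrt(sum(ab^2)); r_ac <- sqrt(sum(ac^2)); r_bc <- sqrt(sum(bc^2))
  if (min(r_ab, r_ac, r_bc) == 0) abort("coincident atoms in a triplet")
  cos_a <- sum(ab * ac) / (r_ab * r_ac)
  cos_b <- sum(-ab * bc) / (r_ab * r_bc)
  cos_c <- sum(-ac * -bc) / (r_ac * r_bc)
  V_abc * (1 + 3 * cos_a * cos_b * cos_c) / (r_ab * r_bc * r_ac)^3
}

#' Atomic configuration for three-body evaluation
#'
#' @param elements Character vector of element symbols.
#' @param x,y,z Cartesian coordinates in Angstrom.
#' @param box Optional periodic box lengths `c(Lx, Ly, Lz)` in Angstrom.
#' @return A tibble of class `atomic_config`.
#' @export
atomic_config <- function(elements, x, y, z, box = NULL) {
  n <- length(elements)
  if (length(x) != n || length(y) != n || length(z) != n) {
    abort("elements, x, y, z must have equal length")
  }
  if (any(!is.finite(c(x, y, z)))) abort("coordinates must be finite")
  if (!is.null(box)) {
    if (length(box) != 3 || any(box <= 0)) abort("box must be 3 positive lengths")
  }
  out <- tibble::tibble(element = as.character(elements), x = x, y = y, z = z)
  class(out) <- c("atomic_config", class(out))
  attr(out, "box") <- box
  out
}

#' Read an XYZ configuration file
#'
#' Standard XYZ layout: atom count, comment line (which may carry
#' `box: Lx Ly Lz`), then one `element x y z` row per atom.
#'
#' @param path Path to the XYZ file.
#' @return An [atomic_config()].
#' @export
read_xyz <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) abort("first line of an XYZ file must be the atom count")
  box <- NULL
  if (grepl("box:", lines[2])) {
    box <- as.numeric(strsplit(trimws(sub(".*box:", "", lines[2])), "[ \t]+")[[1]])
  }
  rows <- lines[3:(2 + n)]
  fields <- strsplit(trimws(rows), "[ \t]+")
  el <- vapply(fields, `[[`, "", 1)
  co <- t(vapply(fields, function(f) as.numeric(f[2:4]), numeric(3)))
  atomic_config(el, co[, 1], co[, 2], co[, 3], box = box)
}

# minimum-image displacement table
pair_distances <- function(config) {
  co <- cbind(config$x, config$y, config$z)
  n <- nrow(co)
  box <- attr(config, "box")
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    dx <- t(co[(i + 1):n, , drop = FALSE]) - co[i, ]
    if (!is.null(box)) dx <- dx - box * round(dx / box)
    dist <- sqrt(colSums(dx^2))
    d[i, (i + 1):n] <- dist
    d[(i + 1):n, i] <- dist
  }
  d
}

# minimum-image position of atom j relative to atom i
rel_pos <- function(co, i, j, box) {
  dx <- co[j, ] - co[i, ]
  if (!is.null(box)) dx <- dx - box * round(dx / box)
  dx
}

#' Total Axilrod-Teller energy of a configuration
#'
#' Sums the triple-dipole energy over all unordered atom triplets whose
#' three pair distances (minimum-image when a periodic box is present) are
#' all within the cutoff.  With a periodic box the cutoff must not exceed
#' half the shortest box length, so that no triplet spans more than half
#' the box.
#'
#' @param config An [atomic_config()] with at least 3 atoms.
#' @param coefficients Named numeric vector of triple-dipole coefficients,
#'   keyed by the alphabetically sorted element triple joined with dashes,
#'   e.g. `c("Ar-Ar-Ar" = 518.3)`, in kJ mol^-1 Angstrom^9.
#' @param cutoff Cutoff in Angstrom (conventionally 10); a triplet enters
#'   the sum only if all three legs are within it.
#' @return Total three-body energy in kJ/mol.
#' @export
three_body_total <- function(config, coefficients, cutoff = 10) {
  stopifnot(inherits(config, "atomic_config"))
  if (cutoff <= 0) abort("cutoff must be > 0")
  n <- nrow(config)
  if (n < 3) abort("three-body evaluation needs at least 3 atoms")
  box <- attr(config, "box")
  if (!is.null(box) && cutoff > min(box) / 2) {
    abort("cutoff exceeds half the box: the minimum-image convention breaks")
  }
  d <- pair_distances(config)
  co <- cbind(config$x, config$y, config$z)
  el <- config$element
  total <- 0
  for (i in seq_len(n - 2)) {
    js <- which(d[i, ] <= cutoff & seq_len(n) > i)
    for (j in js) {
      ks <- which(d[i, ] <= cutoff & d[j, ] <= cutoff & seq_len(n) > j)
      for (k in ks) {
        key <- paste(sort(el[c(i, j, k)]), collapse = "-")
        if (!key %in% names(coefficients) || is.na(coefficients[[key]])) {
          abort(paste0("no triple-dipole coefficient for triple ", key))
        }
        V <- coefficients[[key]]
        # place the triplet in a consistent minimum image relative to atom i
        pa <- c(0, 0, 0)
        pb <- rel_pos(co, i, j, box)
        pc <- rel_pos(co, i, k, box)
        total <- total + axilrod_teller_energy(pa, pb, pc, V)
      }
    }
  }
  total
}

#' Enthalpy of vaporization from the liquid potential energy
#'
#' `Delta_vap H = E_pot(gas) - E_pot(liquid) + R T` with the gas-phase
#' potential energy taken as zero, as appropriate for models whose isolated
#' atoms are the energy reference.  `R T` is the molar-gas-constant term
#' (per-mole convention; all package energies are molar).
#'
#' @param E_pot_liquid Average liquid potential energy per atom in kJ/mol.
#' @param T Temperature in kelvin (>= 0).
#' @return Enthalpy of vaporization in kJ/mol.
#' @export
#' @examples
#' enthalpy_of_vaporization(-2.0, 100) # 2 + R*100 = 2.83145
enthalpy_of_vaporization <- function(E_pot_liquid, T) {
  if (any(T < 0)) abort("T must be >= 0")
  0 - E_pot_liquid + vdw_constants$R_kJ * T
}
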