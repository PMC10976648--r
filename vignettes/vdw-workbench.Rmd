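---
title: "Methods: pair potentials, combination rules, and semiclassical virial coefficients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pair potentials, combination rules, and semiclassical virial coefficients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdwcomb)
```

# The problem

Noble-gas dimers are the cleanest laboratory for van der Waals modelling:
their interaction is pure Pauli repulsion plus dispersion, so the quality of
an analytic pair potential and of the *combination rules* that build
unlike-pair (heterodimer) parameters from like-pair (homodimer) parameters
can be judged directly against dimer dissociation curves and gas-phase
observables.  `vdwcomb` packages that whole workflow: windowed least-squares
fitting of nine analytic families to dissociation curves, exhaustive
permutation of combination relations with RMSE ranking, semiclassical second
virial coefficients $B_2(T)$ with quantum corrections to third order, and
the Axilrod–Teller triple-dipole three-body term.

Throughout the package separations are in Å, energies in kJ/mol,
temperatures in K, $B_2$ in cm³/mol and masses in u; all physical constants
are CODATA values centralised in `vdw_constants`.

# Potential families

Nine families are implemented (`vdw_families()`), with $\varepsilon$ the
well depth, $\sigma$ a length parameter, and $\gamma,\delta$ dimensionless
shape parameters:

* **LJ12-6** $E = 4\varepsilon[(\sigma/r)^{12}-(\sigma/r)^6]$, with $\sigma$
  the zero crossing (minimum at $2^{1/6}\sigma$).  A minimum-position
  convention is available behind the `lj126_sigma` flag; the zero-crossing
  form is the default because it is the form in which the potential is
  almost universally quoted.
* **LJ8-6** $E = \varepsilon[3(\sigma/r)^8 - 4(\sigma/r)^6]$, $\sigma$ the
  minimum position.
* **MRS** (Morse, dimensionless steepness)
  $E = \varepsilon[e^{2\gamma(1-r/\sigma)} - 2e^{\gamma(1-r/\sigma)}]$.
  The dimensionless $\gamma$ makes all three parameters combinable by
  dimension-agnostic rules.
* **BHA** (Buckingham) $E = A e^{-br} - C_6/r^6$.
* **MBH** (modified Buckingham, exp-6)
  $E = \frac{\varepsilon}{1-6/\gamma}\left[\frac{6}{\gamma}
  e^{\gamma(1-r/\sigma)} - (\sigma/r)^6\right]$, $\gamma > 6$.  MBH and BHA
  are the same function under
  $A = 6\varepsilon e^\gamma/(\gamma-6)$, $b=\gamma/\sigma$,
  $C_6 = \varepsilon\gamma\sigma^6/(\gamma-6)$ (`mbh_to_bha()`,
  `bha_to_mbh()`); the package treats the interconversion identity as a
  structural test of both transcriptions.
* **WBH** (Wang-regularised Buckingham)
  $E = \frac{2\varepsilon(\gamma+3)}{\gamma}\,
  \frac{\sigma^6}{\sigma^6+r^6}\left[\frac{3}{\gamma+3}
  e^{\gamma(1-r/\sigma)} - 1\right]$.  Unlike exp-6 it is finite at $r=0$
  while keeping the minimum exactly at $(\sigma, -\varepsilon)$ and a
  $-1/r^6$ tail.
* **GBH** (generalised four-parameter Buckingham)
  $E = \frac{\varepsilon}{1-\delta/\gamma}\left[\frac{\delta}{\gamma}
  e^{\gamma(1-r/\sigma)} - (\sigma/r)^\delta\right]$, $\gamma>\delta$; the
  long-range exponent $\delta$ is adjustable and $\delta = 6$ recovers MBH
  exactly, which gives the nesting property used in the tests (a GBH fit can
  never be worse than an MBH fit).
* **LJ14-7** (buffered 14-7)
  $E = \varepsilon\left(\frac{1+\delta}{x+\delta}\right)^7
  \left(\frac{1+\gamma}{x^7+\gamma} - 2\right)$, $x=r/\sigma$, with
  $\gamma,\delta$ treated as free per-atom parameters rather than the
  historical shared constants.
* **TT** (Tang–Toennies, dimensionless)
  $E = D_e\big[A^* e^{-bx} - \sum_{n=3,4,5} f_{2n}(bx)\,C^*_{2n}/x^{2n}\big]$,
  $x = r/R_e$, with damping
  $f_{2n}(y) = 1 - e^{-y}\sum_{k=0}^{2n} y^k/k!$.  The well constants
  $(R_e, D_e)$ are fixed inputs: the dimensionless parametrisation is only
  meaningful when the well of the target pair is known beforehand, which
  also restricts the family's use with combination rules.

The damping functions are evaluated through the regularised lower
incomplete gamma function, $f_{2n}(y) = P(2n{+}1, y)$ (`stats::pgamma`),
which avoids the catastrophic cancellation of the naive
$1 - e^{-y}\sum\ldots$ at small $y$; this is equivalent to summing the
Taylor remainder but delegates the numerics to a well-tested special
function.

Several of these algebraic forms circulate in more than one convention.
Each form implemented here was pinned by double-entry transcription: the
formula was typed twice independently and five grid values per family are
frozen in the test suite, so a transcription slip in either copy fails
structurally.  The conventions above (minimum positions, depths, finiteness
of WBH at the origin, the damping structure of TT) are the acceptance
surface of the transcription.

Derivatives up to third order (`evaluate_derivative()`) are analytic for
LJ12-6, LJ8-6, MRS, BHA, MBH and GBH, and high-order central finite
differences with an $r$-scaled step for WBH, LJ14-7 and TT; every analytic
path is tested against an independent central difference.

# Fitting protocol

`fit_potential()` minimises the unweighted sum of squared energy residuals
over the *windowed* points of a curve.  The window
(`energy_window(20, 0.10)` by default) keeps points with
$E \le 20$ kJ/mol on the repulsive side and $|E| \ge 0.10\,\varepsilon$ on
the tail side, where the depth is re-estimated per curve by natural-spline
refinement of the grid minimum — a 0.1 Å grid misplaces shallow wells
(helium-like pairs) by enough to matter.  No weighting is applied; because
RMSE values are only comparable between curves with similar point
densities, every result reports `n_points` alongside.

The optimiser is bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with a
physics-informed start (well position and depth of the curve set the scale)
plus seeded Latin-hypercube restarts (16 by default).  Default bounds are
curve-adaptive — $\sigma$ within a factor 2 of the well position,
$\varepsilon$ within a factor 10 of the depth, $\gamma,\delta \in (0, 50]$,
log-scaled sampling for amplitude-like parameters — because loose bounds
demonstrably trap the optimiser in suboptimal basins.  The GBH constraint
$\gamma > \delta$ is handled by fitting $(\delta, \gamma-\delta)$ so it
becomes a box bound.  All randomness is seeded; a fit is reproducible from
`(curve, family, window, bounds, seed, n_starts)`.

# Combination rules

Twelve combination relations are implemented in `apply_rule()` under their
conventional equation identifiers 10–21: geometric (10), arithmetic (11),
harmonic (12), the Morse-potential rule $x_1x_2(x_1{+}x_2)/(x_1^2{+}x_2^2)$
(14), the contraharmonic steepness rule (15), the Waldman–Hagler pair
(16, 17), the cubic-mean radius rule (18), the HHG well-depth rule (19),
an atomic-volume cube mean (20), a power mean of order $-3$ (21, provably
below the geometric mean for unequal inputs and therefore suited to well
depths), and the dispersion-matching $\sigma$ rule (13) that consumes the
already-combined $\varepsilon_{12}$ and $\gamma_{12}$
($\sigma_{12}^6 = \sqrt{\varepsilon_1\gamma_1\sigma_1^6\,
\varepsilon_2\gamma_2\sigma_2^6}/(\varepsilon_{12}\gamma_{12})$).
All relations are symmetric and idempotent — the homodimer-consistency
requirement — and those properties are property-tested over $10^4$ random
inputs, together with the mean ordering
harmonic $\le$ geometric $\le$ arithmetic $\le$ power means.

A *rule set* assigns one relation per parameter, written in the canonical
parameter order as e.g. `"10 20 14 10"`.  Multi-input relations are
admissible only for the parameter they were designed for (13 for $\sigma$,
16 for $\varepsilon$, 15 for $\gamma$); all nine single-input relations are
admissible everywhere, including for $\gamma$ and $\delta$.
`enumerate_rulesets()` forms the Cartesian product in deterministic sorted
order, and `rank_rulesets()` scores every rule set by the unweighted mean
windowed RMSE over the heterodimer reference curves (ten pairs for a
five-element world), with ties broken by the sorted equation-id tuple.
Rule sets that raise singularities (relation 12 with two zeros, relation 13
with a vanishing combined parameter, a relation used where its context
cannot be built) score $+\infty$ and sort last rather than aborting the
scan — an exhaustive permutation search must survive individual
pathological rules.

# Semiclassical second virial coefficients

The classical term is
$B_\mathrm{cl}(T) = -2\pi N_A \int_0^{r_\mathrm{max}}
\left(e^{-V(R)/k_BT} - 1\right) R^2\,\mathrm{d}R$,
and nuclear quantum effects are added as Wigner–Kirkwood corrections in
successive powers of $\lambda = \hbar^2/(\mu k_B T)$, with $\mu$ the
reduced mass of the pair (equivalently, twice the reduced mass substitutes
the atom mass of the like-pair formulas; for equal masses the two
conventions coincide).  Writing $v = V/k_BT$ and $v_k$ for its radial
derivatives, each correction is
$B_{\mathrm{qc},k} = -2\pi N_A \int e^{-v}\, Q_k\,\mathrm{d}r$ with

$$Q_1 = \lambda\left(\tfrac{v_1^2 r^2}{24} - \tfrac{v_1 r}{6}
  - \tfrac{v_2 r^2}{12}\right),$$

$$Q_2 = \lambda^2\Big(\tfrac{v_1^4 r^2}{1152} - \tfrac{v_1^3 r}{144}
  - \tfrac{11 v_1^2 v_2 r^2}{1440} + \tfrac{v_1^2}{360}
  + \tfrac{11 v_1 v_2 r}{360} + \tfrac{v_1 v_3 r^2}{240}
  + \tfrac{v_2^2 r^2}{160} - \tfrac{v_3 r}{120}\Big),$$

and the corresponding third-order bracket in $v_1, v_2, v_3$ (see the
source of `b2_semiclassical()`).  These integrands were derived
symbolically from the Moyal–Bloch recursion for the Weyl symbol of
$e^{-\beta H}$, integrated by parts until no derivative beyond the third
remains (so that spline-differentiated tabulated curves suffice), and
validated three ways: the first-order term reproduces the classic
Wigner–Kirkwood result analytically; the full recursion reproduces the
exact quantum partition function of the 3D harmonic oscillator through
$O(\hbar^6)$; and the parts-reduced integrands agree with the raw
expansion to machine precision under numerical quadrature.  The package's
tests additionally cross-check the first-order term against its fully
reduced single-term form computed with an independent quadrature library,
and check the $\mu^{-1},\mu^{-2},\mu^{-3}$ mass scaling numerically.

Tabulated curves are interpolated with a natural cubic spline at an
effective 0.025 Å spacing and $v_1,v_2,v_3$ are taken from the spline.
Below the first tabulated point the Boltzmann factor is set to zero
(integrand $-1$), contributing the analytic core term
$+\tfrac{2\pi}{3} N_A r_\mathrm{first}^3$: the wall at the first retained
sample of a realistic scan already exceeds $10^3\,k_BT$.  The same
construction makes a flat zero-energy curve starting at $d$ an exact hard
sphere, reproducing $B_2 = \tfrac{2\pi}{3}N_A d^3$ — one of the package's
closed-form checks.  Integration is adaptive quadrature split at the well
position, with a 1e-4 cm³/mol absolute tolerance for the classical term
and a much tighter one for the corrections (which can be orders of
magnitude smaller).  `r_max` defaults to the data extent for curves and to
50 length scales for analytic models; the truncated $-C_6/r^6$ tail beyond
`r_max` is estimated and reported (`tail_est`).

The helium–helium pair is refused in `b2_vs_experiment()`: at helium
masses and temperatures the semiclassical expansion is no longer reliable
and a fully quantum treatment is required.  The expansion's validity for
heavier pairs is visible in the package's own numbers: the corrections
are small, positive at first order (the repulsive quantum effect), and
vanish with rising temperature and mass.

# Three-body dispersion

`axilrod_teller_energy()` implements the triple-dipole term
$E = V_{ABC}\,(1 + 3\cos\theta_A\cos\theta_B\cos\theta_C)/
(r_{AB} r_{BC} r_{CA})^3$; `three_body_total()` sums it over all unordered
triplets whose three legs are within a cutoff (conventionally 10 Å),
minimum-image in periodic boxes, with the cutoff capped at half the box.
The all-legs inclusion criterion was chosen because a single cutoff is the
stated convention for the dispersion terms; centre-based criteria would
need an arbitrary triplet centre.  Closed forms for equilateral
($1.375\,V/d^9$, repulsive) and collinear ($-V/(4d^9)$, attractive)
geometries and brute-force triplet enumeration are the tests.  No
numerical $V_{ABC}$ values ship with the package: the literature
coefficients are not reproduced here, so the coefficient table is a
user-supplied YAML/named vector keyed by the sorted element triple (a
synthetic-labelled schema example is in `inst/extdata/`).
`enthalpy_of_vaporization()` is the companion helper
$\Delta_\mathrm{vap}H = -E_\mathrm{pot}(l) + RT$ with a per-mole gas
constant, since all package energies are molar.

# The synthetic world

`synthetic_elements()` defines five synthetic elements whose well
positions (2.97–4.36 Å), depths (0.091–2.35 kJ/mol) and masses
(4–131 u) span the helium-to-xenon range; the values are realistic
noble-gas-scale choices fixed once so that every study condition is
reproducible.  `synthetic_world_curves()` generates homodimer curves from
per-family ground truths and heterodimer curves from a *planted*
combination rule, on the standard 0.1 Å grid to 30 Å, starting at 60% of
the well position (short-range points a real scan would discard are never
generated), with optional seeded Gaussian noise.  The default noise level
used in the study drivers is 0.01 kJ/mol, a realistic magnitude for
converged coupled-cluster energies near the well.

What the generator emulates: grid convention, noise, well-depth range,
mass range, and heterodimers that are *exactly* consistent with a known
rule.  What it does not emulate: systematic level-of-theory bias (real
curves from different electronic-structure methods differ coherently, not
white-noisily), ill-behaved long-range tails, and heterodimers that no
single rule set reproduces exactly.  Passing the planted-truth tests
therefore shows the machinery is correct and self-consistent — it does not
show that any rule set describes real heterodimers to a given accuracy.

Problem sizes in the shipped tests and acceptance script were chosen to
keep a desk-scale run comfortable: 15-curve fit studies, a 9000-rule-set
scan for the four-parameter family, 50-seed noise replicates, 20-atom
three-body configurations.

# Numerical choices and degenerate inputs

* Natural spline boundary conditions everywhere a spline appears, so all
  derivative-based results are deterministic and platform-stable.
* `locate_well()` scans a dense grid *beyond the global maximum* of the
  energy — BHA, MBH and GBH dive to $-\infty$ at the origin, and the
  physical well is always past the repulsive wall — then polishes the
  minimum with a root find on the first derivative (≈1e-9 Å).
* Curves must have strictly increasing positive $r$ and finite energies;
  duplicated separations and malformed numeric fields are parse-time
  errors naming the offending line.  Two-point curves are accepted for
  bookkeeping, but spline-based operations require at least four points.
* Rule-set ranking treats any evaluation failure as an infinite score, and
  its ordering is invariant under permutation of the input curves.
* Fit results always carry seeds, bounds, residuals and point counts, so
  any aggregate number can be audited.

# Limitations

* Electronic-structure generation of curves, molecular-dynamics protocols
  and melting-point determination are outside the package's scope; the
  three-body module computes energies only (no forces or virials).
* The semiclassical $B_2$ is an asymptotic expansion: for helium-like
  masses at low temperature it is refused rather than silently degraded.
* The TT family is only applicable where the pair's well constants are
  known beforehand, which excludes it from blind heterodimer prediction.
* RMSE comparisons across curve sets with different point densities are
  not meaningful; the reported `n_points` must be checked first.
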