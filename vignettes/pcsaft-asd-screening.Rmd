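---
title: "PC-SAFT phase equilibria for API-polymer compatibility screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PC-SAFT phase equilibria for API-polymer compatibility screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saftscreen)
```

## The problem

Amorphous solid dispersions (ASDs) improve the bioavailability of poorly
water-soluble drugs by dispersing the active pharmaceutical ingredient (API)
molecularly in a polymer carrier.  Whether a carrier is suitable depends on
two phase-behavior properties of the binary API-polymer system:

* **solubility** of the crystalline API in the amorphous polymer
  (solid-liquid equilibrium, SLE), and
* **miscibility** of API and polymer in the amorphous state; limited
  miscibility produces an amorphous-amorphous phase separation (AAPS,
  thermodynamically a liquid-liquid equilibrium, LLE) that destabilizes the
  dispersion.

`saftscreen` computes both from the PC-SAFT equation of state in a *purely
predictive* regime: every binary interaction parameter is zero
(`kij = 0`), so predictions use only pure-component parameters and the
API's experimental fusion properties.  This simulates the screening
situation where a new API-polymer pair has no binary data at all.

## The model

### PC-SAFT residual Helmholtz energy

Molecules are chains of `m` spherical segments of diameter `sigma`
(Angstrom) with a dispersion energy `u/kB` (K).  Hydrogen bonding is
described by an association energy `eps_hb/kB` (K), an association volume
`kappa_hb` (dimensionless) and a site scheme "Z (X, Y)" (X donors, Y
acceptors per molecule).  The reduced residual Helmholtz energy is a sum of
hard-chain, dispersion and association contributions,

    a_res = a_hc + a_disp + a_assoc,

each implemented in compiled code with analytic density and composition
derivatives.  The compressibility factor is `Z = 1 + rho (d a_res/d rho)`,
and fugacity coefficients follow from the composition derivatives of
`a_res` and `Z`.  Copolymers are heterosegmented chains: each monomer type
keeps the parameters of its homopolymer, segment numbers are
`m_alpha = (m/M)_alpha * w_alpha * M` with `w_alpha` the mass fraction of
the chain made of type alpha, and bond fractions between segment types
default to the random (composition-proportional) convention, with an
`alternating` option for strictly alternating two-monomer chains.  The
choice matters little for the systems tested (bond terms enter only through
`ln g` at contact) but is exposed because the sequence statistics of a real
copolymer are rarely known.

Cross parameters use the conventional combining rules: arithmetic mean for
`sigma`, geometric mean for `u` corrected by `(1 - kij)`, arithmetic mean
for `eps_hb` and a Wolbach-Sandler volume term for `kappa_hb`.  A
consequence worth spelling out: a polymer with acceptor sites but
`eps_hb = 0` (PVP-like carriers) gets a cross-association energy of half
the API's self-association energy -- the *induced cross-association*
mechanism -- without any extra parameter.

### Association solver

Site fractions solve the mass-action equations by damped successive
substitution (damping 0.5, tolerance 1e-12, at most 1000 iterations),
warm-started across neighboring density evaluations.  Derivatives of
`a_assoc` use the stationarity of the underlying Q function, so the site
fractions can be held fixed during differentiation; the correctness of this
shortcut is guarded by finite-difference oracle tests.

### Density solver

States at given (T, p) are found on the packing fraction
`eta in (0, 0.7404)`: a directional scan brackets the liquid root from the
close-packing end (or the vapor root from the ideal-gas end), followed by
safeguarded secant/bisection refinement to a relative pressure residual
below 1e-9.  With no phase hint, all roots are refined and the lowest-Gibbs
root wins.  All equilibrium work in this package uses the liquid branch --
amorphous phases are (supercooled) liquids.

### Solubility (SLE)

The solubility of the crystalline API satisfies

    ln(x_API * gamma_API(T, p, x)) = -dG_fus(T) / (R T),

where `dG_fus` is the Gibbs energy difference between pure supercooled
liquid and crystal, computed from the melting temperature, the enthalpy of
fusion and a linear `dCp(T) = a + b T` whose two integrals are evaluated in
closed form (several APIs in the built-in table have temperature-dependent
`dCp`; the constant-`dCp` shortcut is measurably wrong for them and is not
used).  The solver is damped successive substitution on
`x <- exp(-dG_fus/RT)/gamma(x)` with a bracketed root-finding fallback;
inside a demixing region the equation can have several roots, in which case
the smallest is reported and all roots are available from the diagnostics
mode.  Activity coefficients are `gamma_i = phi_i / phi_i_pure` at equal
(T, p) on the liquid branch.

### Miscibility (LLE / AAPS)

Binodal points satisfy equal activities of both components across the two
amorphous phases.  They are found by an alternating-tangent style iteration
that searches for one phase at a time: the API-activity equation is solved
for the API-lean phase at fixed API-rich composition, then the
polymer-activity equation for the API-rich phase, and so on until both
ln-activities match within 1e-8.  Starting values come from a spinodal
pre-check (sign changes of the second composition derivative of the Gibbs
energy of mixing on a coarse grid) and a convex-hull bridge of that grid;
a detected spinodal whose iteration fails raises an error, which keeps
"no split" answers honest.  Phase compositions are iterated in log space
(`ln x_API` for the lean phase, `ln x_poly` for the rich phase) because
strongly immiscible API-polymer systems partition the polymer below the
resolution of `1 - x` in double precision; the rich-phase polymer fraction
is reported separately as `x2_poly`.  An AAPS scan repeats this over
200-600 K (default step 2 K) and an empty curve means "no AAPS predicted".

### Error statistics and ranking

Prediction error is quantified as percent average absolute relative
deviation and its signed counterpart,

    AARD = 100/N sum |w_calc - w_exp| / w_exp,
    ARD  = 100/N sum (w_calc - w_exp) / w_exp,

with negative ARD meaning systematic underestimation.  Aggregated grids
(polymer rows, API columns) carry "ALL" margins; the margins *pool the
underlying points* of the group by default, because averaging per-system
statistics would weight a two-point system like a ten-point one.  Both
conventions are implemented (`mode = "system_mean"`) since the pooling
convention in the field is often left unstated.

Polymers are ranked per API by predicted weight-fraction solubility at the
lowest experimental temperature common to all of that API's systems
(automated as max over systems of the per-system minimum temperature).
Any polymer whose system shows a predicted AAPS is demoted exactly one
position below its unpenalized slot; ties are resolved with unflagged
entries first and demotion past the end of the list is clamped.  For
systems with a single experimental point, the experimental reference order
at the ranking temperature is built by adjusting a temperature-independent
`kij` to that point and extrapolating.

### Parameter estimation

API parameters are routinely regressed from solubility data in low-molar-
mass solvents.  `fit_api_parameters()` reproduces that procedure: four free
parameters (`m`, `sigma`, `u`, `eps_hb`), `kappa_hb` fixed at 0.01, a
six-site scheme by default, and simulated annealing with Metropolis
acceptance, geometric cooling (factor 0.95) and 50 moves per level.  The
loss is the mean squared deviation in `ln x_API` over all (solvent, T)
points with the model solubility obtained by fully solving the SLE equation
per datum (a cheaper equation-residual loss is available).  The objective
function, schedule endpoints and bounds are not dictated by any reference,
so they are explicit configuration with the defaults above.  A
deterministic Nelder-Mead polish from the annealing best (on by default)
sharpens the answer: annealing explores, the polish converges -- on
noise-free synthetic data the combination recovers all four parameters to
better than 0.3%, comfortably inside the 2% gate the test suite enforces.
Everything is bit-reproducible under a fixed seed.

## Synthetic data: what it emulates, and what a green test means

No experimental datasets ship with the package.  The generators emulate
the *structure* of calorimetric (DSC-derived) solubility data:

* **sparsity**: 4 points per system by default, clustered in a 60 K window
  below the melting point -- where dissolution endpoints are measurable;
* **noise**: multiplicative lognormal noise on the weight fraction
  (`w_obs = w exp(eps)`, `eps ~ N(0, cv^2)`, default cv 0.05), because
  solubilities span orders of magnitude and additive noise would be
  nonsensical at small `w`; truncations into (0, 1) are counted;
* **component archetypes**: three toy APIs (2-, 4- and 6-site schemes) and
  four toy polymers -- self-associating, induced-cross-associating,
  nonassociating, and a two-monomer copolymer -- drawn inside the parameter
  envelope of the built-in API table, with fusion properties inside the
  built-in fusion table ranges.

A green synthetic test therefore establishes internal consistency (the
pipeline inverts its own forward model, statistics close at their ideal
values, rankings are recovered exactly) -- it does *not* establish
agreement with laboratory data, which requires user-supplied polymer
parameters and measurements.  Real DSC data also carry method biases and
polymer polydispersity that the generator deliberately does not simulate.

## Numerical choices

* Units: `sigma` in Angstrom, energies over `kB` in K, densities internally
  in molecules per cubic Angstrom, pressure in Pa (default 0.1 MPa
  everywhere), `dH_fus` stored in kJ/mol exactly as tabulated.
* Temperature grids: 1 K steps for solubility curves (298 K up to the
  melting point), 2 K for AAPS scans; both configurable.  The boolean AAPS
  flag in the synthetic study uses a 10 K step since only the presence of a
  split matters there.
* Polymers are monodisperse at their stated molar mass.
* Degenerate inputs: a one-segment-type "copolymer" reproduces the
  homopolymer path to better than 1e-12 relative; identical components give
  `gamma = 1` to 1e-8; `T = T_m` gives `x = 1` exactly.
* Tie-break on multiple SLE roots: smallest root in (0, 1], all roots
  reported on request.

## Limitations

* Intramolecular hydrogen bonding is not modeled; carriers that form strong
  intra-chain HB networks (poly(vinyl alcohol)-like) are exactly the
  systems where this model family is known to err.
* No dipolar/quadrupolar terms, no ternary (API-polymer-water) systems,
  no temperature-dependent `kij` correlation, no polydispersity.
* Pure prediction is quantitatively rough by construction; the intended use
  is relative screening (ranking), not numeric solubility forecasts.

## A minimal session

```{r example, eval = FALSE}
library(saftscreen)

# components from the built-in API table and a user polymer file
lib <- parameter_library("polymers.dcf")
api <- build_component(lib, "NPX", strategy = "REF")
poly <- build_component(lib, "PVPtoy")

# phase diagram: solubility curve + AAPS scan, pure prediction
pd <- build_phase_diagram(api, poly)
write_phase_diagram(pd, "NPX_PVPtoy.tsv")

# score against experimental data and rank carriers
run_screen(list(data_file = "solubility.tsv", parameter_file = "polymers.dcf",
                out_dir = "screen_out"))
```
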