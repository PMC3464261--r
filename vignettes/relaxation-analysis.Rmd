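---
title: "Backbone relaxation analysis with relaxkit: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Backbone relaxation analysis with relaxkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxkit)
```

# The scientific problem

¹⁵N spin relaxation reports on protein backbone motion at two very
different time scales. Fast (ps–ns) reorientation of each amide N–H bond
vector is summarized by the Lipari–Szabo order parameter S² (1 = rigid,
0 = unrestricted) and an effective internal correlation time τe, while
slower (µs–ms) conformational exchange adds a contribution Rex to the
transverse relaxation rate. `relaxkit` implements the full chain from
peak-intensity decay series to per-residue (S², τe, Rex), plus the
companion structural analyses such studies lean on: localization of a
paramagnetic metal center from bleached resonances, bead-model
hydrodynamics, solvent accessibility and protease cleavage mapping.

# The relaxation model

All relaxation observables derive from the model-free spectral density
on an isotropically tumbling molecule,

$$J(\omega) = \frac{2}{5}\left[\frac{S^2\tau_m}{1+(\omega\tau_m)^2} +
\frac{(1-S^2)\tau'}{1+(\omega\tau')^2}\right],\qquad
\frac{1}{\tau'}=\frac{1}{\tau_m}+\frac{1}{\tau_e},$$

entering the standard dipolar + CSA single-field expressions for R1, R2
and the heteronuclear NOE (see `forward_rates()`). Two relaxation
mechanisms are modelled: the ¹H–¹⁵N dipolar interaction and the ¹⁵N
chemical-shift anisotropy. Cross-correlated relaxation is not modelled,
matching the level of theory of classical single-field model-free
software.

Physical constants are user-visible in `spin_constants()` and default
to the values conventional for that software generation: N–H bond
length 1.02 Å, ¹⁵N CSA −160 ppm, CODATA gyromagnetic ratios. Changing
any of them propagates consistently through the whole chain. The
degenerate parameter point S² = 0, τe = 0 makes every rate vanish; the
NOE (a 0/0 there) is defined as 1 so bounded optimizers can traverse
that corner of the box.

## Observables from decays

* `fit_exponential()` fits `I(t) = I₀ e^{−Rt}` by profiled least
  squares: for fixed R the amplitude is available in closed form, so
  the fit is a one-dimensional minimization in R (Brent search on a
  bracket around a log-linear starting slope). Rate errors are the
  standard deviation of rates refitted on `n_mc` replicates built from
  the best-fit curve plus Gaussian noise of sd σ; replicates are
  refitted on a vectorized rate grid with parabolic refinement, which
  keeps 500 replicates per residue cheap. When a series carries no σ,
  the rms residual of the initial fit is used. Replicates in which
  noise makes a volume non-positive are redrawn and counted. Negative
  fitted rates are reported with a flag, never clamped. Duplicate delay
  points are independent observations; they are not pre-averaged.
* `r2_from_r1rho()` inverts the tilted-frame relation
  `R1ρ = R1 cos²θ + R2eff sin²θ`. θ is computed from the magnitudes of
  the spin-lock strength and resonance offset (`θ = π/2` on
  resonance). `R2eff` keeps any exchange contribution folded in — the
  separation happens in the model-free stage.
* `hetero_noe()` is the saturated/unsaturated intensity ratio with
  first-order error propagation.
* `integrate_ellipse()` sums the grid points inside an elliptical
  crest footprint (default 8 × 4 Hz semi-axes in ¹H × ¹⁵N); no baseline
  correction is applied.

## Overall tumbling time

`estimate_tau_m()` returns the τm at which a rigid rotor reproduces the
observed R2/R1 ratio — equivalent to the classical square-root-of-T1/T2
estimate — found by monotone root search on [0.5, 50] ns. Because both
R1 and R2 scale identically with S² when τe = 0, this inversion is
unbiased for rigid residues regardless of their S².

`select_tumbling_subset()` guards the average against residues that
violate the rigid assumption: residues with NOE < 0.65 (fast internal
motion) are dropped, then residues whose T1/T2 deviates from the subset
median by more than 1.5 sd are trimmed, and the trimming is *iterated*
until stable (max 10 rounds, with a relative floor that stops once the
surviving cluster is tight). Iterating is a deliberate design choice:
with exchange residues present, a single trimming round leaves the sd
inflated by the very outliers it is meant to catch, while iteration
collapses the subset onto the rigid-ratio cluster — in the noiseless
limit, exactly. The cost is aggressiveness under noise (the subset can
shrink to a few dozen residues), which is harmless for the average
because the retained ratios are the most exchange-free ones. Both
thresholds are exposed as arguments.

## Per-residue fitting and model selection

Three nested models compete per residue, at fixed τm: M1 (S² only, 2
residual dof with three observables), M2 (S² + τe, 1 dof) and M3
(S² + Rex, 1 dof). Each χ² is minimized by a deterministic coarse grid
(S² step 0.01; τe log-spaced 1 ps–1 ns plus 0; Rex 0–15 s⁻¹ step 0.25)
followed by L-BFGS-B and a Nelder–Mead polish; evaluations outside the
parameter box are clamped with a smooth quadratic penalty so
finite-difference gradients behave at the bounds. Reproducibility is
preferred over speed throughout.

Model selection follows the classical two-stage protocol: M1 is kept
only when (a) its χ² passes a goodness-of-fit adequacy test at level α
(default 0.05) and (b) no extension improves it significantly by an
F-test at α. Otherwise the best-fitting extension is selected, with
F-significance breaking ties first and χ² second. The pure F-test
alone was considered and rejected: with three observables the F(1,1)
95% critical value is ≈161, so a residue with a perfectly fitted Rex of
several s⁻¹ and an M1 misfit of hundreds of χ² units can still fail a
pure F criterion on denominator luck. The adequacy test restores the
behaviour practitioners expect from the era's model-free software,
which used exactly this χ²-plus-F-test combination.

Zero or missing observable errors get a floor before fitting: relative
(2% of the value) for R1 and R2, absolute (0.02) for the NOE. The NOE
floor must be absolute because the NOE passes through zero for flexible
residues, where a relative floor makes χ² explode.

`model_free()` packages all of this behind a single fitting call
returning a classed object with `print`, `summary`, `coef`, `predict`,
`residuals`, `plot` and `simulate` methods, in the style of base R
modelling functions.

# The synthetic-data generator

`generate_profile()` encodes the study conditions as defaults: a
114-residue chain tumbling at τm = 7.9 ns observed at 600.13 MHz ¹H
(60.85 MHz ¹⁵N) with the published delay lists (R1: 10*, 150, 300, 450,
600*, 700, 900, 1200 ms; R1ρ: 10*, 50, 80, 100*, 120, 150, 170, 190 ms;
starred delays duplicated), a 1560 Hz on-resonance spin lock, and
Gaussian intensity noise of 1% of I₀. The per-residue classes mimic the
dynamics profile of a small disulfide-stabilized helical protein:

| class | residues | S² | τe (ps) | Rex (s⁻¹) |
|---|---|---|---|---|
| core | remainder | U(0.75, 0.9) | 0 | 0 |
| terminus | first/last 3 | U(0.2, 0.6) | U(300, 800) | 0 |
| mobile loop | ~29–33% of chain | U(0.2, 0.6) | U(300, 800) | 0 |
| moderate loop | ~72–79% of chain | U(0.55, 0.75) | U(200, 500) | 0 |
| exchange | 15% of chain, from core | core-like | 0 | U(1, 5) |

Core residues carry τe = 0 — internal motion too fast to detect — which
is also what makes the rigid-ratio τm inversion exact in the noiseless
limit. Loop τe values of hundreds of ps push the forward-model NOE well
below the 0.65 exclusion threshold, so flexible residues self-exclude
from the tumbling average as they should. The noise model is additive
Gaussian on peak volumes with sd proportional to I₀, the standard
assumption for volume integrals; per-residue resonance offsets default
to on-resonance because the R1ρ experiment's offsets are
study-specific.

What the generator does *not* emulate: spectral processing artifacts
(apodization, linear prediction, baseline), peak overlap and
assignment errors, cross-correlated relaxation, anisotropic tumbling,
field-dependent exchange, and glycosylation-type site-specific
perturbations. Green tests therefore certify the inference machinery
under its own forward model, not robustness to every pathology of real
spectra.

Toy structures (`generate_toy_structure()`) place backbone N, H, CA, C,
O with ideal covalent geometry by internal-coordinate chaining (helix
φ = −57°, ψ = −47°; extended φ = ψ = 180°). The
`synthetic_bundle_structure()` fixture packs four short ideal helices
as an antiparallel bundle with connecting loops and pseudo side-chain
beads matching each residue's heavy-atom count — entirely synthetic,
but with the size and atom density of a real 114-residue globular
protein, which is what its consumers (hydrodynamics, SASA) care about.

# Metal-site localization

`predict_bleached()` is the forward model of paramagnetic bleaching: at
the default 8 Å radius it returns every backbone amide N/H (optionally
side-chain amide) within range of a center. `locate_center()` solves
the inverse problem: each bleached amide contributes a flat-bottom
quadratic penalty (zero inside the 1.8–8 Å restraint window, squared
excursion outside), minimized over the center coordinates from the
restrained-atom centroid plus six deterministic ±5 Å axis offsets. The
contract is feasibility, not uniqueness: a zero penalty certifies that
all restraints can be satisfied simultaneously; an irreducible penalty
sets an `unsatisfiable` flag instead of erroring. Restraints attach to
the amide H when present, else to N. No steric term keeps the center
out of the protein interior — buried sites are legitimate. Rigid
rotations and translations of the structure change the returned
position covariantly and the penalty not at all (tested to 1e-3).

# Structure annotation

* **SASA** (`shrake_rupley_sasa()`): Shrake–Rupley sphere-point
  sampling with a deterministic Fibonacci point set (default 960
  points, probe 1.4 Å), heavy atoms only by default. Van der Waals
  radii ship as data (C 1.70, N 1.55, O 1.52, S 1.80, H 1.20 Å);
  unknown elements fall back to 1.70 Å with a warning. An isolated
  atom reproduces 4π(r+p)² to quadrature accuracy.
* **Pepsin mapping** (`pepsin_sites()`): implements the PeptideCutter
  specificity model for pepsin at pH 1.3 (hydrophobic F/L at P1 or P1′)
  and pH > 2 (adds W/Y), with the documented blocking rules (P at P2 or
  P2′, H/K/R at P3, R at P1 for the P1′-driven variant); a site needs a
  full P3–P2′ window. The rule matrix is vendored data; the test suite
  pins the engine to captured reference outputs for fixed sequences.
  `exposed_cleavage_sites()` intersects a cleavage map with backbone
  amide accessibility at a user-supplied threshold — deliberately a
  required argument, because no principled default exists.
* **Hydrodynamics** (`bead_diffusion()`): one bead per heavy atom
  (default radius 3.4 Å, chosen so heavy-atom beads absorb the
  unmodelled hydration shell), Rotne–Prager–Yamakawa pairwise mobility
  with the overlap form for r < 2a, inverted to a friction supermatrix
  and projected onto rigid-body motions. The rotational block of the
  inverted 6×6 tensor is origin-independent, so no center-of-diffusion
  search is needed; the two blocks are rescaled by a characteristic
  length before inversion because translation (∝ηa) and rotation
  (∝ηa³) otherwise make the matrix numerically singular in SI units.
  The bead-spin ("volume") correction of 8πηa³ per bead is weighted by
  each bead's solvent-exposed surface fraction: exact for one bead
  (Stokes–Einstein–Debye) and for separated beads, while buried beads
  of an overlapping filled model contribute nothing — unweighted
  per-bead corrections overcount rotational friction by an order of
  magnitude for densely overlapping models (measured on a filled test
  sphere against the closed form). Defaults: 303 K, water viscosity
  0.797 mPa·s at that temperature. Outputs: sorted rotational
  eigenvalues, τm,iso = 1/(6D_iso), Δ = 2Dzz/(Dxx+Dyy) ≥ 1 by the
  sorting convention.
* **Stoichiometry** (`stoichiometry_ratio()`): the protein:metal molar
  ratio plus the smallest convincing integer label — the smallest
  denominator q ≤ 10 whose rounded numerator lands within 1% relative
  error, falling back to the error-minimizing pair. The 1% acceptance
  rule (rather than global error minimization over q ≤ 10) is what
  turns 65.17 into the conventional "65:1" instead of a spuriously
  precise "391:6", while still resolving 1.333 to "4:3".
* **Restraint taxonomy** (`classify_restraints()`): the four standard
  sequence-separation classes; disjoint and exhaustive by construction.

# Numerical choices and problem sizes

Seeded randomness everywhere: every generator and Monte-Carlo routine
takes a seed and restores the caller's RNG state, so library calls
never perturb user code and regeneration is bit-identical. The test
suite and the acceptance script run the full pipeline at the study's
own size — 114 residues, 10 delays per decay (duplicates included), 500
Monte-Carlo error replicates, 930 hydrodynamic beads — which keeps a
complete run in tens of seconds on one core. Optimizer tolerances
(Brent 1e-12 on rates; `factr = 10` / `reltol = 1e-14` in the
model-free polish) are set so the noiseless round trip recovers
(S², τe, Rex, τm) to better than 1e-6 relative, comfortably inside the
1e-4 contract asserted in the tests.

# Known limitations

* Isotropic tumbling only: no axially-symmetric or fully anisotropic
  diffusion-tensor fitting of the relaxation data (the bead model
  reports tensor anisotropy, but the model-free stage does not consume
  it).
* Single-field data: Rex is not field-separated, and the M2/M3
  competition leaves only one residual dof per residue, so model
  selection has limited power at low exchange amplitudes.
* S² uncertainties are χ²-based only; no Monte-Carlo parameter error
  propagation in the model-free stage.
* PRE is binary (bleached / not bleached); no Γ₂-versus-distance
  fitting and no coordination-geometry modelling of the metal site.
* The hydrodynamic bead model's handling of overlapping beads is the
  package's own (exposure-weighted spin correction); published bead
  codes differ in undocumented internals, so agreement between
  implementations should only be expected at the 10–15% level.
* The pepsin rule engine reproduces the PeptideCutter specificity
  table; experimentally observed cleavage also depends on pH history,
  denaturation state and disulfide topology, none of which are
  modelled.
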