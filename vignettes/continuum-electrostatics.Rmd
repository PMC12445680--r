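---
title: "Continuum electrostatics of protonation and redox equilibria: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuum electrostatics of protonation and redox equilibria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(redoxpb)
```

## The physical model

A titratable site is a group of atoms with two or more charge states that
differ by exactly one proton (acids, bases, the three-state His tautomer
site) or one electron (redox couples such as Trp/Trp•⁺).  Its behaviour in
a protein is predicted from continuum electrostatics in three layers:

1. **The linearized Poisson–Boltzmann equation.**
   ∇·(ε∇φ) − ε κ² φ = −4πCρ with ε = 4 in the protein interior, 80 in
   water, κ from the Debye length at 100 mM and 300 K (≈ 9.7 Å), and κ = 0
   inside the protein and a 2 Å Stern shell.  Potentials are carried in
   kcal/mol/e and exported in mV (43.364 mV per kcal/mol).

2. **The thermodynamic cycle.**  The intrinsic pKa/Em of a site is its
   reference value (Asp 4.0, Glu 4.4, Cys 9.5, Tyr 9.6, Lys 10.4, Arg 12.0;
   His Nε 7.0 / Nδ 6.6; Trp/Trp•⁺ 1070 mV in water) plus the shift in
   charging free energy between the protein and the model compound — the
   site's own atoms transferred to water.  The shift has a reaction-field
   part (solvation) and a background part (interaction with all
   non-titrating charges, other sites clamped in their reference states).

3. **Coupled titration.**  Microstates are weighted by
   G(s) = Σ g_i + ½ Σ W_ij, with g anchored at each site's reference state
   (deprotonated for acids and bases, the Nε-H tautomer for His, reduced
   for redox sites) and W the pairwise couplings of the state-difference
   charge sets.  Populations come from Metropolis Monte Carlo or, up to 20
   sites, from the exact sum that the sampler is validated against.
   pKa is the Henderson–Hasselbalch half-protonation pH; Em is the bias
   potential equalizing the redox populations, found by bisection.

## Numerical choices

* **Discretization.**  Seven-point finite differences with face-centred
  dielectrics.  The dielectric boundary is the van der Waals union of the
  atoms; boundary-crossing edges get a fraction-weighted harmonic mean,
  with the crossing located by linear interpolation of the signed distance
  function.  A solvent-excluded surface (probe-rolled) is a documented
  alternative we do not implement; it is the main source of divergence
  from solvers that use one.
* **Focusing.**  Three levels at 2.5 / 1.0 / 0.3 Å by default; the coarsest
  grid covers the whole structure with Debye–Hückel monopole boundary
  values, each finer grid takes Dirichlet values interpolated from its
  parent, and only charges inside a level are spread on it.  Nesting
  margins shrink with depth so a child grid can never clip its parent.
* **Self-energy cancellation.**  Every reaction-field term subtracts a
  uniform-dielectric solve on the identical finest grid with analytic
  Coulomb boundary values, so the (spacing-dependent) self-energy of the
  spread charges cancels exactly; raw grid self-energies are never
  reported.  This is also why an isolated site returns its reference value
  to machine precision: the protein and model legs are the same grids.
* **Solver.**  Jacobi-preconditioned conjugate gradients on the symmetric
  system, relative residual 1e−6, iteration cap 10⁴ with the residual
  history attached to any failure.
* **Monte Carlo.**  Single-site moves plus joint moves for pairs with
  |W| > 2.5 kcal/mol; 10³ burn-in and 10⁵ production sweeps by default;
  ties (ΔG ≤ 0) accepted with probability 1; occupancies and block-wise
  standard errors; fully reproducible per seed.  This is the smallest
  protocol that holds the ≤ 0.01 occupancy agreement with exact
  enumeration on all our ≤ 15-site fixtures.
* **Midpoint search.**  Bisection to |⟨ox⟩ − 0.5| ≤ 0.005 and a 0.02 mV
  interval on the exact backend.  In Em profiles the other redox sites are
  clamped reduced (one hole at a time); without that convention,
  neighbouring probes half-oxidize near the shared midpoint and their
  mutual repulsion contaminates per-site values.
* **Degenerate inputs.**  Zero ionic strength gives κ = 0; zero charges
  give identically zero fields; single-member hopping chains have zero
  transfer time; a site alone in a "protein" equal to its model compound
  closes the cycle exactly.

## The Em-shift decomposition

Em − Em_ref = solvation_shift + charge_shift + residual, exact by
construction: the solvation term is the reaction-field shift with all
protein charges zeroed (the operational definition of "solvation loss");
the charge term is the interaction of the ox-minus-red charges with the
background plus the equilibrium-average charges of the other titratable
sites; the residual collects what coupled titration relaxes away and stays
below a millivolt on weakly coupled fixtures.  Per-residue contributions
are read off the same state-difference potential, so they sum to the
charge term identically.  Both a relaxed variant (equilibrium-average
site charges, the default) and a frozen variant (reference states) are
available, since either convention appears in the literature.

## What the synthetic fixtures emulate — and what they do not

* `make_born_ion`, and the Kirkwood sphere built from it, give the two
  closed forms (−81.96 kcal/mol for q = 1 e, a = 2 Å, ε 1→80; the
  off-centre image series) that pin the solver's absolute accuracy.
* `make_layered_protein` is a watertight FCC-packed slab (2 Å pseudo-atoms,
  3.5 Å cube edge) spanning a 40 Å membrane with unit charges in 5 Å
  surface slabs — negative toward one side, positive toward the other —
  and 9-atom pseudo-indole redox probes along the normal.  Probe depths are
  lattice-commensurate so every probe sees an identical packing shell;
  with the slab charges removed, the probes' Em values agree within ~1 mV,
  so the Em gradient in the charged fixture is attributable entirely to
  the layered charges.
* `make_coupled_redox_proton` buries a probe and a proton-release site
  3.2 Å apart in a 12 Å pseudo-protein sphere.  The repulsive coupling
  (~31 kcal/mol, ~23 pH units) makes oxidation strictly expel the proton.
  The proton site's model-compound reference pKa (26.5) is a fixture
  design constant: the burial penalty of its +1 state (~−15.5 pH units in
  this geometry) lands the intrinsic pKa near 11, midway between the
  reduced-state and oxidized-state titration windows, leaving ≥ 2 pH units
  of margin around the pH 6–9 range where the Nernstian −59.5 mV/pH slope
  is measured.
* `make_site_cluster` places single-atom acids/bases in water with
  nearest-neighbour distances tuned so the screened-Coulomb couplings
  reach a requested scale; in uniform water the PB problem has the exact
  closed form used for its energetics, which the grid solver is checked
  against separately.

None of these fixtures has conformational flexibility, explicit waters,
hydrogen placement, or cofactor charge sets; passing tests demonstrate the
correctness of the electrostatic and statistical machinery, not the
accuracy of any particular force field or structure preparation.  Real
structures bring their own uncertainties (charge models, the vdW-union
versus molecular-surface choice, crystal-water handling) that the fixtures
deliberately exclude.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| ε protein / water | 4 / 80 | — | dielectric contrast; the solvation loss scales with 1/ε_in − 1/ε_out |
| ionic strength | 0.1 | mol/L | Debye screening (λ_D ≈ 9.7 Å); negligible below ~15 Å separations |
| temperature | 300 | K | RT ln10 = 1.373 kcal/mol = 59.5 mV per pH/pKa unit |
| Stern width | 2.0 | Å | ion-exclusion shell; weakly influential on fixtures |
| focusing levels | 2.5/1.0/0.3 | Å | absolute solvation accuracy; 2-level (…/1.0) suffices for shifts and couplings |
| MC sweeps | 10⁵ (10³ burn) | — | occupancy error ≲ 10⁻³ on 15-site systems |
| pair-move cutoff | 2.5 | kcal/mol | mixing for strongly coupled pairs |
| ruler coefficients | 15, 0.6, 3.1 | — | generic (distance in Å, energies in eV); configurable |

Problem sizes in the shipped analyses — fixtures of 10–2000 atoms, finest
grids ≤ ~85³ nodes, 10⁵ MC sweeps, chains of ≤ 8 members — were chosen so
each driver completes in seconds to tens of seconds on one core while
leaving the closed-form checks inside 0.5 % (Born) and 0.1 % (Kirkwood).

## Membrane conventions and the field map

The membrane normal is +z, toward the cytoplasmic analogue; interface
planes are user-declared (automatic membrane assignment is out of scope).
The field map solves the plain Poisson equation (no screening) in a fixed
120 Å box with ~4.4 × 10⁵ nodes, Gaussian-smeared charges (σ = 1 Å,
renormalized per atom so total charge is conserved exactly), ε = 4 for
protein plus the declared membrane slab, and 0 V on the z = ±60 Å planes.
The lateral faces are also held at 0 V — a symmetric closure we quantify
on the capacitor fixture (interior field within 5 % of the grounded-plane
1D closed form); absolute potentials near the lateral walls are therefore
less trustworthy than the field direction, which is the quantity the
layered-charge analysis relies on.

## Hole-hopping kinetics

Step free energies for hole transfer are ΔG° = e(Em_acceptor − Em_donor):
the hole runs downhill toward lower Em.  Forward rates follow the
Moser–Dutton ruler; backward rates are set by exact detailed balance,
k_b = k_f exp(ΔG°/kT) at the physical temperature.  (Evaluating the ruler
with the sign of ΔG° flipped would imply an effective temperature of
1/(4·3.1·ln10) ≈ 0.035 eV and distort equilibrium populations; we preferred
thermodynamic consistency and document the choice here.)  Total transfer
times are exact mean first-passage times of the linear master equation,
cross-checked against matrix-exponential survival integration in the test
suite.  ΔG° carries no entropic correction, and the packing-factor variant
of the ruler is not implemented; both are documented dials for future work.

## Known limitations

* van der Waals union instead of a solvent-excluded surface; small water-
  sized crevices in real proteins are treated as solvent.
* Em calculations use no low-dielectric membrane slab by default (the slab
  is available, and used, in the field mapper); for deeply buried sites in
  real membranes this underestimates burial slightly.
* The bundled amino-acid charge library is a deliberately simple synthetic
  model-compound set (formal charges on the titrating group, element-based
  radii), and the Trp/Trp•⁺ charge distribution is a labelled stand-in;
  quantitative work on real structures should supply PQR files from a
  proper force field.
* Conformational sampling is limited to externally supplied conformer
  ensembles (`ensemble_em`); there is no pH-adapted conformer generation.
* Exact enumeration is capped at 2²⁰ microstates; larger systems rely on
  the sampler alone.
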