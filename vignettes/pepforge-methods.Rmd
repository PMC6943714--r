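---
title: "Models, parameters and numerical choices in pepforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and numerical choices in pepforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pepforge implements a desk-scale stack for structure-based peptide design
on protein–peptide systems of the MDM2/MDMX–p53 type. This vignette is the
package's own account of the science: the models, their assumptions, the
tunable parameters and their defaults, the numerical decisions, what the
synthetic fixtures emulate, and where the limits are. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## Interface descriptors and the empirical score

A complex is scored from four interface descriptors. Hydrophobic burial
ΔX_H sums the interface-buried solvent-accessible area of carbon and
sulfur atoms; charged-group burial ΔX_C does the same over nitrogen and
oxygen atoms of Asp/Glu/Lys/Arg side chains (and of ionized free termini
when the peptide is uncapped — capped peptides contribute no terminal
charges). X_HB counts conventional hydrogen bonds across the interface and
ΔX_SB is the *net* salt-bridge count: favorable opposite-charge group
pairs minus repulsive like-charge pairs, each group pair counted once when
any of its N/O atoms approach within the cutoff. The affinity estimate is
the fixed linear combination with intercept −1.94 kcal/mol and weights
+0.16, −0.68, −0.52, −0.41 on ΔX_H, ΔX_C, X_HB, ΔX_SB; the coefficients
are applied to raw descriptor values and are never refit. More negative
scores mean stronger predicted binding; that orientation is recorded
explicitly on every score vector so consensus scoring can normalize
correctly.

Choices a user should know about:

* **Burial units.** Whether the original burial descriptors were areas,
  atom counts or calibrated free energies is not derivable from their
  published description. The package computes areas (Å²) and converts with
  a configurable scale, default 0.025 kcal/(mol·Å²), a common
  hydrophobic-effect value. Only the intercept of the scoring equation is
  unit-independent, and only that intercept is used as an exact reference
  value.
* **Hydrogen bonds.** Structures of this class are X-ray models without
  hydrogens, so donors are inferred from heavy-atom connectivity
  (residue-template tables) and an ideal hydrogen is placed opposite the
  mean direction of the donor's bonded neighbors. Criteria: donor–acceptor
  ≤ 3.5 Å and D–H···A ≥ 120°, both configurable; each donor pairs with at
  most its best acceptor. Pairs in which both atoms belong to charged
  groups are *excluded* from X_HB — those are salt bridges, and counting
  them in both descriptors would double-weight ionic contacts.
* **"Net" salt bridges.** The net convention (favorable − repulsive) is a
  documented reading of an underspecified term; it is what the toy-complex
  generator and the tests pin down.

SASA is computed by deterministic sphere-point sampling (spherical
Fibonacci lattice, 960 points/atom by default; radii C 1.70, N 1.55,
O 1.52, S 1.80, H 1.20 Å; probe 1.4 Å). The test suite checks it against
an independent Monte-Carlo rejection oracle to 1% on random ≤20-atom
clusters. Burial is the per-atom SASA difference between the isolated
component and the complex, floored at zero.

## Packing metrics

The knowledge-based packing-quality potentials that motivate the weighted
combiner are proprietary-database artifacts; pepforge therefore treats
packing metrics as a pluggable input and ships only simple surrogates
(dihedral normality from a coarse torsion-region score, packing normality
from interface contact-count Z-scores). The combiner itself is
bit-specified: weights 0.145 (dihedral), 0.390 (1D distance), 0.465 (3D
direction), asserted to sum to 1. Consensus scoring min–max normalizes
each method (best → 1, worst → 0, orientation-aware) and averages;
constant score vectors are rejected rather than silently mapped to a
midpoint, because silent midpoints corrupt consensus ranks.

## The force field

The energy model is deliberately small and fully shipped as versioned CSV
data: 12-6 Lennard-Jones with Amber-style r_min/ε per coarse atom type;
Coulomb with distance-dependent dielectric ε(d) = 4d (pair energy
k·q_iq_j/4d², k = 332.0636 kcal·Å/(mol·e²)); a Gaussian-exclusion
continuum solvation term (Lazaridis–Karplus functional form: a fully
exposed atom contributes its reference ΔG, neighbors subtract
Gaussian-weighted volume exclusions, 9 Å cutoff); and a nonpolar surface
term 0.65 kcal/(mol·Å²) × SASA where a flavor requests solvation. Totals
are always the plain component sum — no reweighting. Partial charges are a
bundled per-residue template table with implicit hydrogens folded into
heavy atoms (charged side chains sum to ±1 e, neutral residues to 0);
quantum-chemical charge derivation is out of scope by design, and the
charge table is data, not code. Non-natural residues map to their nearest
aliphatic templates (cyclobutylalanine as a cyclobutyl side chain, staple
residues as four-carbon arms closed by an explicit inter-residue bond).
Nonbonded exclusions are 1-2/1-3 with 1-4 scaling 0.5. No cutoffs are
applied to the pair terms by default; the systems are small.

Heavy-atom-only modeling has a visible consequence in torsion space: much
of the exclusion of positive φ in real Ramachandran maps comes from amide
hydrogen clashes, which a hydrogen-free model cannot see. Reference runs
with this model place 68–78% of low-energy tetra-alanine φ values in the
broadly allowed regions (φ < 0 or |φ| > 150°); the regression test pins
that behavior at ≥ 60%, and users should not expect the near-total
exclusion a polar-hydrogen force field would give.

## Binding-energy flavors and minimization

Four rigid-body flavors: *simple* is E(complex) − E(protein) − E(peptide)
with both components extracted in exactly their bound conformations;
*strain* minimizes the extracted peptide first, so a strained bound
conformation pays a non-negative penalty (the inequality strain ≥ simple
is asserted property-style); *neutralized* zeroes all charged-group
charges, side chains and termini both — the uncharged-termini question is
resolved as "yes, both", noted here; *solvated* adds the polar
Gaussian-exclusion term plus the 0.65·SASA nonpolar term inside every
Energy(). The solvated flavor is explicitly a surrogate: it keeps the
intent (polar + nonpolar solvation) and the printed nonpolar scale of a
PBSA treatment without a Poisson–Boltzmann solver, which is out of scope.

Cartesian minimization (used by the strain flavor and the two-round
protocol) optimizes movable atoms by L-BFGS-B with analytic gradients.
Because sampling geometry lives in internal coordinates, the Cartesian
objective adds harmonic restraints of bonded (k = 300) and geminal
1-3 (k = 50 kcal/(mol·Å²)) distances to a reference geometry — by default
the input itself, so the restraint energy is exactly zero at the start
point. That anchoring preserves the strain inequality exactly: the
minimizer only accepts points whose restrained total is below the start,
so the reported nonbonded energy of the minimized peptide can never
exceed its starting value. It also means re-minimizing a result while
re-anchoring at that result lets geometry creep; callers who need a fixed
point pass the original reference (`restraint_ref`). Convergence is
declared at max gradient < 0.05 kcal/(mol·Å) or the iteration cap, with a
warning and best-so-far on cap exit. The two-round protocol mobilizes, in
round 1, all peptide side chains plus protein side chains with any atom
within 4 Å of the peptide (backbones fixed); round 2 frees the whole
peptide against a fixed protein.

## Conformational sampling (MCSAM)

Sampling is in dihedral space with fixed template bond lengths and angles:
per-residue (φ, ψ) with ω held trans; side chains beyond Cβ are not built
by the generator. Each run seeds a stack with random minimized
conformations, then iterates Monte-Carlo-with-minimization: pick a random
stack member, perturb one position (probability 0.8: redraw (φ, ψ) from
the position's Ramachandran map; otherwise a local Gaussian move, σ = 30°),
minimize in torsion space (numerical-gradient BFGS), and apply a
Metropolis test along a geometric annealing ladder (1000 → 300 K — the
schedule is a free choice, as is the move mix). Stack maintenance rules,
also a documented free choice standing in for externally referenced ones:
a candidate within the diversity radius (0.5 Å backbone+Cβ RMSD) of a
member replaces that member only if lower in energy; otherwise it enters
if the stack is below capacity or beats the worst member; stacks stay
energy-sorted and capped (published scale: 100 initial, 200 capacity).

Ramachandran maps are computed per position from the flanking-residue
tripeptide on a 10° grid, Boltzmann-weighted at a 600 K bias temperature
(hot enough to keep minor basins populated; configurable) and cached.
Deriving maps from the energy model rather than database statistics keeps
D- and non-natural residues on an equal footing; because the model is
mirror-symmetric, a D-residue's map is the exact point reflection of its
L counterpart's, and glycine maps are exactly centro-symmetric — both
asserted to 1e-12.

Analysis follows the published protocol shape: 15 kcal/mol energy-window
filtering, leader clustering in energy order at 1.0 Å backbone+Cβ RMSD
(so representatives are energy-ranked; "ranked clusters" is read as
energy-ranked, the open alternative readings being size- or
combination-ranked), and best-RMSD-in-top-k evaluation (k = 25/100/500 at
published scale; k beyond the cluster count uses all clusters). RMSD is
Kabsch superposition over N, CA, C, O, Cβ, cross-checked against an
independent implementation and against bio3d.

Problem sizes: the package preserves the published profile (500 runs ×
10,000 steps; 100 × 2,000 for constrained binding runs) as the `paper`
config profile, and the tests and examples run the same code paths at
desk scale (single-digit runs, tens of steps, 3–4 residue peptides) —
chosen as the smallest sizes at which every contract under test (seed
determinism, stack caps, window compliance, limit behavior) is exercised
meaningfully.

## Constrained Boltzmann affinity

Around a given bound backbone, the peptide samples torsions plus a
rigid-body placement (Rodrigues rotation + translation residual on a
template aligned to the pose) in the field of a rigid receptor. Each
non-terminal backbone heavy atom carries a flat-bottom harmonic
constraint: zero penalty within 1.0 Å of its reference position,
k·(d − 1)² beyond (k = 10 kcal/(mol·Å²) — the force constant is not
derivable from the published description and is configurable).
"Excluding the 2 terminal residues" is read as one residue at each end,
matching the stated full flexibility of the N- and C-terminal residues;
a two-per-end alternative is available through the constraint settings.
Per run, the minimum total-energy pose (constraint + internal +
interaction) is recorded with its protein–peptide interaction energy; the
affinity is the Boltzmann-weighted average of the interaction energies
using the total energies at 300 K (temperature configurable; the T → 0
and T → ∞ limits — argmin and plain mean — are asserted). Intra-peptide
strain deliberately never enters the affinity itself, only the weights.
Receptor side-chain flexibility is off by default. Selectivity between
two receptors is the paired difference of affinities at shared seeds and
settings. Mutation support is template-based: a mutated residue keeps its
backbone and receives the new side chain's Cβ stub (mirrored for D
targets), refined by minimization or sampling.

## SAR statistics and the bundled tables

Two fixtures ship as plain CSV transcriptions of printed tables, guarded
by checksum tests: the conformational-sampling summary (16 systems) and
the prospective Ala/D-scan of a stapled ATSP-7041 analog (10 + 12 mutant
rows plus wild type). Statistics are recomputed from the fixtures at test
time: mean minimum RMSD 1.12 Å, best-in-top-25/500 means 2.38/1.48 Å,
length–RMSD correlation r = 0.46, and a two-term OLS (length + staple
indicator) R² ≈ 0.68. One internal inconsistency is surfaced rather than
resolved: the printed best-in-top-100 column averages to 1.93 Å while the
printed average row says 2.16 Å; the package reports the value recomputed
from the rows. Scan correlations are computed over mutant rows only (the
wild type has no ΔΔG in the calculated columns; a flag can include it at
(0, 0)): Ala-scan r² = 0.84 and 0.82 for the force-field and
ensemble methods, D-scan 0.09 and 0.38. The four-descriptor empirical
score's Ala-scan column recomputes to r² = 0.66 from the printed
(rounded) values where the source reports 0.67 from unrounded data; the
tests treat ±0.01 around 0.66 as agreement.

Unit notes: ΔΔG = RT·ln(Kd/Kd_ref). The experimental ΔΔG column of the
prospective table is internally consistent with RT ≈ 0.815 kcal/mol for
the MDM2 data but RT = 0.593 (298 K) for the MDMX data; both constants are
exported (`rt_standard`, `rt_table4_mdm2_effective`) and the discrepancy
is documented, not resolved — Pearson correlations are invariant under
positive affine maps, so no r² depends on the choice. The inactive-peptide
floor (−2.0 kcal/mol) is applied to the binding-energy axis although the
source wording conflates it with a Kd; that reading is the only
dimensionally consistent one.

## Anisotropy models

The direct 1:1 model uses the exact quadratic bound-fraction solution;
the competitive model uses the exact cubic closed form (the printed d, e,
f, θ quantities; the published rendering of the final fraction contains a
typographical corruption, and the d/e/f/θ definitions uniquely identify
the intended root). Numerically, the trigonometric root loses precision
for extreme parameter ratios (arccos argument near ±1), so the closed
form's value seeds a few safeguarded Newton steps on the equivalent
monotone free-protein mass balance; the tests verify both closed forms
against independent brute-force bisection solvers to 1e-9 over 10⁴ random
valid parameter sets, including the mass balances and both Kd definitions
of the implied species concentrations.

Fitting is Levenberg–Marquardt (minpack.lm) with Kd on the log scale and
replicate-variance weights when replicates exist; degenerate designs
(< 5 distinct concentrations direct, < 6 competitive) are rejected.
Assay-control diagnostics mirror laboratory practice for this assay: the
pt > lst assumption is flagged when violated; a final baseline below the
independently measured free-peptide anisotropy (`r0_free`) is flagged as
an unintended competitor–tracer interaction; an essentially flat
displacement curve is flagged as an unidentifiable competitor Kd. The
simulator evaluates the chosen model over a dilution series (assay
defaults: protein 250 nM, labeled peptide 50 nM, triplicate) and adds
Gaussian noise per point; σ = 0.005 anisotropy units is the default noise
scale at which the recovery study in the test suite measures a median
|log10 Kd error| below 0.1 over 200 simulated curves. The published
13.0 nM tracer Kd ships as a constant for competitive fits, never as a
validation value.

## The toy-complex generator

Synthetic fixtures make the descriptor stack testable without any
external structure downloads. Each requested interaction is built on an
isolated "station" 25 Å from its neighbors (beyond every cutoff), rigidly
rotated by a seeded random rotation: carbonyl-acceptor/amide-donor pairs
at 2.9 Å with aligned geometry for hydrogen bonds; Lys-NZ/Glu-OE1 at
3.2 Å for salt bridges; NZ/NZ at 3.5 Å for like-charge contacts; an
icosahedral cage of methyl carbons at 4.0 Å for complete burial of a
central atom. Counts are exact by construction, verified against the
descriptor module before returning (bounded retries, then a placement
error), and deterministic per seed. What the toys deliberately do not
emulate: crowded interfaces where contacts overlap, solvent-mediated
interactions, and real side-chain rotamer context — so exact-count tests
validate the counting logic, not descriptor behavior on dense real
interfaces.

## Known limitations

* Heavy-atom energetics (no explicit hydrogens): weaker φ-region
  discrimination, no directional hydrogen-bond energetics in the force
  field (the descriptor module handles directionality separately).
* The solvated flavor is a Gaussian-exclusion + surface-area surrogate,
  not a Poisson–Boltzmann treatment.
* The builder generates backbone + Cβ only; full side-chain conformations
  enter via PDB input.
* Packing metrics are surrogates behind a stable interface.
* Affinities from the Boltzmann module are relative interaction-energy
  scores, not absolute Kd predictions.
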