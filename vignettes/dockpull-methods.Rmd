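---
title: "Models and methods behind dockpull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dockpull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dockpull)
```

dockpull re-implements the computational downstream of a
structure–activity study of indirubin-3′-oxime derivatives against
GSK-3β: thermodynamic conversions around docking scores, drug-likeness
descriptors, protein–ligand interaction fingerprints, and a
coarse-grained steered-unbinding estimator. This vignette explains each
model, the parameters that matter, the design choices that were
genuinely open, and what the synthetic generators do and do not emulate.

## Thermodynamic conversions and temperature conventions

All conversions rest on two relations:

* K_i = exp(ΔG / RT), between a binding free energy and an inhibition
  constant, and
* ΔG_exp = R·T·ln(IC50), with the cellular IC50 (converted µM → mol/L)
  taken as equal to K_i.

Two temperature conventions coexist and are both fields of
`thermo_constants()`, never hard-coded. The experimental conversion uses
T = 300 K with R = 1.987×10⁻³ kcal K⁻¹ mol⁻¹, as the study states. The
predicted inhibition constants of the docking table, however, round-trip
to their printed dock scores only at T = 298.15 K (the docking-engine
convention): at 298.15 K the printed pairs agree to ≤ 0.006 kcal/mol,
while at 300 K they disagree by ~0.05 kcal/mol — far above print
rounding. `validate_dock_consistency()` therefore back-converts at
`T_dock`; with the packaged table it flags exactly one row (compound 6b,
printed K_i,pred equivalent to −7.99 kcal/mol against a printed score of
−9.34). The row is flagged, not corrected: the table is the source of
record.

Because the printed K_i values derive from two-decimal dock scores,
forward agreement in concentration space is only ~1%; consistency checks
run in ΔG space, where rounding contributes ≤ 0.01 kcal/mol.

## The correlation model and the censoring rule

`fit_dock_correlation()` joins the cytotoxicity and docking tables per
cell line, converts IC50 to ΔG_exp and fits ΔG_exp = a + b·ΔG_dock by
ordinary least squares, reporting Pearson r and the RMS residual. The
model object follows the base-R fitting idiom (coef, predict, residuals,
plot, simulate), and `simulate()` draws parametric-bootstrap datasets
through the synthetic affinity generator.

The one genuinely open choice is what to do with IC50 entries reported
only as "> 20 µM". Two rules are implemented:

* `censored = "at-bound"` (default): censored entries enter at the 20 µM
  ceiling, n = 19 per cell line. Under this rule the computed
  correlations are 0.9030, 0.9344, 0.9329 and 0.9014 on HepG2, LU-1,
  SW480 and HL-60 — the published 0.90/0.93/0.93/0.90 to two decimals —
  so this is demonstrably the rule under which the published figure was
  produced.
* `censored = "drop"`: censored entries are excluded (n = 15–16), the
  statistically cleaner treatment since a censored assay carries no
  point estimate. It yields r = 0.84–0.91.

The default reproduces the published analysis; the alternative
quantifies how much the bound-imputed points (which sit at both extremes
of the dock-score axis) inflate the correlation. Users doing inference
rather than reproduction should prefer `"drop"` or a proper censored
regression (out of scope here).

## Descriptors: typing is the contract

`ertl_tpsa()` sums Ertl's published fragment contributions over N/O
(and, for completeness, S/P) atoms, matched on element, aromaticity,
formal charge, hydrogen count, bond-order environment and
three-membered-ring membership. An unmatched polar atom is an error, not
a zero: silent omissions are the classic TPSA bug.

Aromaticity perception is deliberately **not** performed: the molecular
graph, including aromatic flags and explicit hydrogen counts, is the
input contract, and the certified fixtures for compounds 1–4 encode the
convention under which the published values were computed — the
five-membered indole-type rings are aromatic, so their N–H atoms match
the aromatic nH fragment (15.79 Å²) rather than the larger aliphatic
value. Under this typing, compound 1 reproduces 65.72 Å² exactly, and
the oxime-bearing rows agree to 0.01 Å² (81.24 vs 81.25, 54.86 vs 54.87,
70.38 vs 70.39) — the residual being last-digit rounding in the source
descriptor server. Molar masses use IUPAC conventional atomic weights
frozen in a constants table and match all four published values to 0.01
g/mol. Only compounds 1–4 have certified graphs; the conjugate series
6a–6p has no authoritative structures to type, and miLogP and predicted
LD50 are third-party model outputs that are loaded, never computed.

## Interaction fingerprints

The study never states its hydrogen-bond criteria (its tables come from
a visualisation tool), so defaults were chosen once from common
geometric practice: donor–acceptor heavy-atom distance ≤ 3.5 Å, and a
D–H⋯A angle ≥ 120° whenever the donor carries explicit hydrogens;
distance-only otherwise (receptor structures usually lack hydrogens).
Both are arguments everywhere. Donor/acceptor typing on the receptor
side uses a rule table over the 20 standard residues (backbone N except
proline donates; backbone O/OXT accepts; side chains per their
chemistry); on the ligand side, N/O atoms accept and donate when a
hydrogen sits within 1.25 Å. Waters and monoatomic ions are excluded,
altlocs resolve to the highest occupancy (ties → "A"), and contacts
count any residue with a heavy atom within the 5 Å radius the study
uses.

Because the study's docked poses were never deposited, its per-compound
H-bond counts are treated as a format reference only. Correctness is
instead established constructively: `synthetic_complex()` plants
hydrogen bonds on orthogonal directions (2.75–3.05 Å, collinear D–H⋯A),
contact residues with nearest carbons at 4.2–4.7 Å, and decoys beyond
6.2 Å — every planted feature satisfies or violates the default criteria
with a margin of at least 0.2 Å, so float noise cannot flip a detection
— and the detectors must recover the planted fingerprint exactly, and
agree with exhaustive O(n²) oracles, across seeds.

## The coarse-grained FPL engine

The study's explicit-solvent GROMACS setup (PME, ~26,000 waters,
restrained backbone) is replaced by the smallest model that preserves
the estimator and protocol: a single ligand bead (the ligand's centre of
mass; mass 300 amu by default) moving by Langevin dynamics in a field of
rigidly fixed Lennard-Jones + Coulomb sites, with a plain 0.9 nm cutoff
on both terms — no periodicity, so cutoff Coulomb stands in for PME, and
fixed sites stand in for the study's 1,000 kJ/mol·nm² backbone
restraints. The protocol parameters are the study's: spring constant
k = 600 kJ/mol/nm², pulling speed v = 0.005 nm/ps, force recorded every
0.1 ps, other metrics every 10 ps, 8 replicas, pull along +Z. Internal
units are GROMACS-style (kJ/mol, nm, ps, amu); reported affinities are
kcal/mol at exactly 4.184 kJ/kcal.

Numerical choices: BAOAB splitting (stable and accurate for
configurational averages at large friction), friction 10 ps⁻¹ and
timestep 0.002 ps — a relaxation time of 0.1 ps, 50 steps per relaxation
— with divergence detection at |coordinate| > 50 nm. The integrator's
inner loop is compiled (Rcpp); randomness comes from R's seeded
Mersenne-Twister stream, so trajectories are bitwise reproducible.

The estimator is the study's interaction-energy difference
ΔE = ΔE_cou + ΔE_vdW, each term E^bound − E^unbound. The study does not
define its bound/unbound windows; here the bound state averages over the
100 ps pre-pull equilibration window (mirroring the study's short
NVT/NPT stage) and the unbound state over the last 10% of the
trajectory, where both terms are exactly zero once the ligand has
cleared the cutoff — so ΔE equals the (negative) bound-state interaction
energy, favorable pockets give negative ΔE, and the decomposition
identity holds to machine precision by construction. Replicas that end
inside the cutoff raise an error rather than contaminating the average.
Spread is reported as the SD across replicas, and the work series is the
trapezoidal integral of the recorded spring force times the anchor
speed; whether "work" should use spring or total force is ambiguous in
the source — spring force was chosen because it is what a cantilever
measures.

One subtlety the tests document: pulling work converges to the
potential-energy difference only in the slow **and stiff** limit. At the
protocol spring constant, the spring stores ~F²/2k at rupture and that
energy is dissipated after the ligand breaks free regardless of pulling
speed; the quasi-static check therefore uses k = 5000 kJ/mol/nm² and
v = 2.5×10⁻⁴ nm/ps, where the recorded work matches the potential
profile within 1%.

## Synthetic data: what it does and does not show

The generators emulate *interface statistics* (planted H-bond
geometries, contact shells, linear dock-vs-affinity structure with
Gaussian ΔG-space noise, LJ/Coulomb pockets of controlled depth and
charge), not real GSK-3β geometry, chemistry or force fields. Passing
tests therefore demonstrate that the detectors, conversions, regressions
and the estimator are correct and internally consistent — they do not
validate docking accuracy, H-bond counts of real poses, or the
FPL-versus-experiment correlation (R = 0.88, RMSE = 0.8 kcal/mol in the
study), which would require the undeposited complexes and trajectories.
Affinity noise is applied in ΔG space because assay error is
multiplicative in concentration; `noise_sd_for_r()` converts a target
population correlation into a noise level for uniform dock scores.

Problem sizes used by the default test suite and the acceptance script
were chosen to keep every stochastic check comfortably inside its
tolerance: 20 seeded complexes for exact fingerprint recovery, 50 seeds
× 200 compounds for correlation recovery (mean within 0.03 of the
target), 4 well depths × 8 replicas of 400–500 ps for depth
monotonicity, and a single 4.8 ns deterministic trajectory for the
quasi-static limit. The full suite runs in well under a minute on one
CPU.

## Known limitations

* The censored-at-bound default reproduces the published correlations
  but is not a defensible inferential treatment of censoring.
* TPSA certification covers compounds 1–4 only; the conjugates' rows are
  consumed as data.
* The H-bond detector has no π-stacking, salt-bridge or halogen-bond
  notions, and angle criteria apply only where hydrogens exist.
* The FPL model has one bead, no solvent, no conformational
  flexibility; its numbers are estimator properties, not predictions of
  GSK-3β binding.
* The pipeline's per-stage seeds derive from the global seed by a fixed
  integer hash of the stage name; changing stage names reshuffles
  stochastic stages.
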