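---
title: "Methods: interaction fingerprints and kinetics for protease characterization"
author: "SIFtKit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interaction fingerprints and kinetics for protease characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SIFtKit)
```

# Scope

SIFtKit characterizes a protease from two directions: structurally,
by reducing docked ligand pose ensembles against a receptor to
per-residue interaction-frequency profiles (structural interaction
fingerprints, SIFt), and kinetically, by fitting saturation assay data
to the Hill equation and deriving kcat, Km, kcat/Km, fold changes and
the accounting tables (purification, relative activity) that
accompany an enzyme characterization.  The package does not dock,
score or minimize anything: it starts from a receptor structure (PDB),
pose files (AutoDock PDBQT), assay tables (delimited text) and
sequences (FASTA).

# The fingerprint model

## Bits and their geometric criteria

Each (residue, pose) pair is summarized by nine Boolean bits: any,
backbone, sidechain, polar, hydrophobic, H-bond acceptor, H-bond
donor, aromatic, charged.  "H-bond acceptor" is receptor-centric: the
*receptor* atom accepts from a ligand donor; "H-bond donor" is the
converse.  The defining thresholds live in one object,
`interactionParams()`, so every cutoff is visible and overridable:

| parameter | default | role |
|---|---|---|
| `contact` | 4.5 Å | heavy-atom contact envelope: any/backbone/sidechain/hydrophobic |
| `hbondDA` | 3.5 Å | donor–acceptor distance for hydrogen bonds |
| `hbondAngle` | 120° | minimum angle at H between H→donor and H→acceptor |
| `aromaticCentroid` | 5.0 Å | ring-centroid separation for aromatic contacts |
| `charged` | 4.0 Å | cation–anion (salt-bridge) distance |
| `polar` | 3.8 Å | N/O/S pair distance |

These numbers are not dictated by the fingerprint formalism — it only
requires *some* distance/type/angle rule per bit — so we chose
mid-range values from the conventional interaction-geometry literature
(hydrogen bonds 2.5–3.5 Å donor–acceptor; salt bridges up to ~4 Å;
π-stacking centroids 3.5–5.5 Å; generic "contact" 4–5 Å).  They are
deliberately conservative defaults, not tuned to reproduce any
particular published table.

Two pragmatic rules deal with incomplete chemistry in real inputs:

* **Hydrogens are optional.**  Crystallographic receptor files rarely
  contain hydrogens, yet hydrogen bonds must still be reported.  When
  a donor has an explicit hydrogen the angular criterion is enforced;
  when it does not, detection degrades to distance-only.  This is the
  standard fallback in fingerprinting practice, and it means adding
  hydrogens can only *remove* H-bond bits, never add them.
* **The charged bit demands opposite formal charges.**  Mere proximity
  of two charged residues is not a salt bridge; the bit fires only for
  cation–anion pairs.  This keeps the bit sparse and interpretable.

The `any` bit is defined to dominate: it is set whenever any other bit
is set, even when the triggering geometry (e.g. a 4.9 Å ring-centroid
contact) involves no atom pair inside the contact cutoff.  This
hierarchy is enforced as a class invariant, so averaged profiles can
never show a sub-bit frequency above the `any` frequency.  (Published
fingerprint tables occasionally violate this by rounding; we treat the
hierarchy as exact.)

## Atom typing

Receptor roles are assigned from residue and atom names: backbone
N (except proline) and the usual sidechain N/O donors; carbonyl,
carboxylate, hydroxyl and His-ring acceptors; Lys/Arg cations;
Asp/Glu/C-terminal anions; Phe/Tyr/His rings and both Trp rings, each
carrying a centroid and a best-fit-plane normal (smallest singular
vector of the centered ring coordinates).  Residue *classes* (polar,
hydrophobic, aromatic, charged) are multi-label on purpose: a tyrosine
legitimately makes polar (OH), hydrophobic (ring CH) and aromatic
contacts, so it belongs to all three classes.  Classes describe
residues; the bits themselves are decided per interaction.

Ligands arrive untyped (PDBQT carries AutoDock atom types, which we
map to elements via the published AutoDock4 table: A→C, OA→O, NA→N,
SA→S, HD→H, …).  Roles are perceived from a covalent-radius bond
graph: N/O are acceptors; N/O are donors when they carry an explicit
hydrogen, or unconditionally when the molecule has no hydrogens;
amine-like nitrogens (bonded only to C/H, no adjacent carbonyl
carbon) are cations; carboxylate-pattern oxygens are anions.  Rings
are 5- and 6-cycles of C/N/O/S that are planar within 0.2 Å — a
tolerance that accepts aromatic rings and rejects chair-puckered
saturated ones.  This perception is intentionally minimal; exotic
charged groups (tetrazoles, phosphates) would need explicit support.

## Ensemble statistics

`computeSIFt()` finds contacts with a spatial-binning neighbor search
(cubic cells of the cutoff size, 27-cell lookup) whose output is
verified in the test suite against an all-pairs oracle.
`averageSIFt()` pools fingerprints over poses — and, if desired, over
receptor conformations, matching residues by chain and number — into
per-residue frequencies; residues never contacted are omitted, rows
are ordered by residue number, and frequency × n is always an integer
count.  `bindingSiteResidues()` thresholds the `any` frequency (default
0.3, i.e. residues contacted by at least 30 % of the population).
`tanimoto()` compares two fingerprints as bit sets; two empty
fingerprints are defined maximally similar (1.0).

Poses are clustered by the greedy leader algorithm in file order: a
pose joins the first cluster whose *founding* pose is within the RMSD
cutoff (default 1.0 Å), else founds a new cluster.  This is the
convention used by docking packages themselves; it is deterministic,
order-dependent by design (the representative is always the
lowest-index pose), and O(n·k).  RMSD is computed over heavy atoms in
file order without superposition, because docked poses share the
receptor coordinate frame and rigid-body displacement is real signal.

# The kinetic model

Velocities are fitted to v = Vmax·S^h/(Km^h + S^h).  With h = 1 this
is Michaelis–Menten; the Hill exponent accommodates the cooperativity
that oligomeric enzymes can show.  Because a table of kcat and Km
alone cannot distinguish h ≈ 1 from fixed h = 1, `fitHill()` offers
`fixH = 1`, and the test suite verifies that this reduction agrees
with an independent direct Michaelis–Menten fit to better than one
part in 10⁶.

Numerical choices:

* **Positivity by log-parameterization.**  The optimizer works on
  (log Vmax, log Km, log h), so estimates are positive by
  construction and no constrained solver is needed.  Standard errors
  are mapped back by the delta method; the kcat/Km standard error uses
  the full covariance of (log Vmax, log Km).
* **Levenberg–Marquardt** (via `minpack.lm::nls.lm`) with tight
  tolerances (ftol = ptol = 10⁻¹⁵, ≤ 500 iterations) and four
  deterministic starts around (max v, concentration nearest
  half-maximal velocity, h = 1); the best converged solution wins.
  Multiple starts guard against poor initial curvature on sparse
  concentration grids, not against multimodality — the Hill RSS
  surface in these data is effectively unimodal.
* **Degenerate data are refused, not fitted.**  Flat velocity vectors
  (range below 10⁻⁸ of scale) return `converged = FALSE` with `NA`
  estimates; fewer than four distinct concentrations, negative
  concentrations, or a missing enzyme concentration are errors.
  Downstream fold changes require converged fits on both sides.
* **Replicates are fitted pooled**, not averaged first, so the
  residual scatter that feeds the standard errors reflects the actual
  replicate noise.

kcat = Vmax/[E]₀ requires the enzyme concentration as an explicit user
input — assay write-ups frequently omit it, and silently assuming a
value would corrupt every derived constant.  Synthetic tests set
[E]₀ = 1 µM so Vmax and kcat coincide numerically.

## Accounting tables

`purificationSummary()` derives specific activity (U/mg), yield (%)
and fold purification from step totals.  Both normalizations are
designated explicitly because published tables are not consistent
about them: yield is anchored at a chosen step (typically the first
with a measured activity), and the fold baseline may be either a step
label or a *numeric* specific activity — the latter matters when the
true crude-extract baseline was never tabulated and is known only
through a printed, rounded value.  `relativeActivity()` normalizes an
activity panel to a reference condition defined as 100 %, optionally
within concentration groups, and propagates not-determinable (`ND`)
entries as `NA` rather than dropping or zeroing them.

# Sequence identity

`globalAlign()` is Needleman–Wunsch with affine gaps, delegated to
`Biostrings::pairwiseAlignment` (BLOSUM62, gap opening 10, extension
0.5 — a conventional default when the original alignment protocol is
unstated).  The dynamic program's optimum is verified in the tests
against exhaustive enumeration of all alignments for short sequences.
Percent identity defaults to identical columns over aligned columns;
a shorter-sequence denominator is available since homology figures in
the literature use both conventions.  Reported identities are rounded
to one decimal.  Ties among co-optimal alignments are broken by the
underlying DP implementation deterministically; identity percentages
of co-optimal alignments can differ in principle, which is one reason
identity comparisons against published figures should carry a
tolerance of a percentage point or two.

# The synthetic-data module

The generator exists so that every pipeline stage can be tested
end-to-end, offline, against known ground truth.

* `makeComplex()` places one minimal pseudo-residue per planted
  interaction on a line with 20 Å spacing (≥ 15 Å guarantees that a
  probe can only register against its own residue) and realizes each
  interaction at its exact stated geometry: a carbon probe for
  contacts, N/O probes for polar and hydrogen bonds (optionally with
  an explicit hydrogen placed to realize a stated D–H⋯A angle), a
  carboxylate or ammonium group for salt bridges, a parallel benzene
  ring at a stated centroid distance for aromatic contacts.
  Distances beyond the cutoff plant deliberate violations; these
  leave the residue perpendicular to the template plane so a probe on
  its way out cannot graze the residue's own sidechain.
* `sampleEnsemble()` toggles each planted geometry between satisfying
  and violating values independently per pose with probability f
  (or with exact counts, for fixtures that must average to an exact
  fraction).  All randomness flows through a single seed and the
  caller's RNG state is restored afterwards.
* `simulateKinetics()` applies multiplicative Gaussian noise
  (truncated at −0.99) to Hill-equation velocities on a 10-point
  log-spaced grid spanning 0.5–400 µM in triplicate by default — the
  concentration design of a typical fluorogenic protease assay — with
  a default 3 % coefficient of variation, a realistic plate-reader
  noise level.

What the generator does *not* emulate matters for interpreting green
tests: real docked poses have correlated, physically constrained
geometries rather than independent per-bit coin flips; real receptors
have packed, flexible sidechains rather than isolated rigid templates;
real assay noise has outliers and systematic drifts beyond i.i.d.
multiplicative Gaussian.  Passing the recovery tests therefore
demonstrates that the *computation* is correct (bits fire exactly when
their geometry holds, frequencies estimate planted probabilities
within binomial error, fits recover generating parameters within the
noise-implied uncertainty) — not that any particular docking run or
assay will be as well-behaved.

# Problem sizes used in the tests

The suite exercises: planted-bit round trips over all nine bit types;
frequency recovery on ensembles of 1000 poses at f ∈ {0, 0.25, 0.5,
0.75, 1} against 99 % binomial intervals; a 29-pose fixture whose
hydrogen-bond frequency averages to 12/29; parameter recovery over
200 simulated triplicate assays at 3 % noise (median Km error and
2·SE coverage); and brute-force cross-checks of the neighbor search
and the alignment DP at small instance sizes where exhaustive oracles
are feasible.  These sizes were chosen to make the statistical
assertions sharp while keeping the whole suite comfortably fast.

# Known limitations

* No docking, scoring, pose generation, protonation or structure
  repair; inputs are taken as given.  No mmCIF reader.
* Aromatic contacts are distance-only; no stacking-angle filter, so
  parallel and T-shaped geometries are not distinguished.
* Ligand role perception covers amines, carboxylates and neutral N/O
  donors/acceptors; unusual charged warheads need manual annotation.
* Residue identity is (chain, number); oligomer-specific renumbering
  schemes (e.g. counting residues of a neighboring protomer with an
  offset) must be resolved to chain+number before input, and no
  symmetry expansion is performed.
* The Hill fit assumes homoscedastic additive residuals on the
  velocity scale; strongly heteroscedastic data would warrant
  weighting that the current interface does not expose.
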