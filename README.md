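# SIFtKit

Structural interaction fingerprints and steady-state kinetics for
protease characterization.

## What this package is for

When a protease is characterized computationally, two kinds of evidence
are usually combined: *where* substrates bind (from docked pose
ensembles against the receptor structure) and *how well* they are
turned over (from saturation kinetics of fluorogenic substrates).
SIFtKit implements both analysis tracks for people doing this kind of
enzyme work — structural bioinformaticians post-processing AutoDock
output, and enzymologists reducing assay plates to kcat/Km tables —
plus the bookkeeping that surrounds them (purification accounting,
relative-activity tables, homolog percent identity).

### The structural interaction fingerprint (SIFt)

For every receptor residue contacted by a docked pose, a nine-bit
vector records which interaction types occur:

| bit | fires when |
|---|---|
| any            | any heavy-atom pair within the contact cutoff (4.5 Å) |
| backbone       | a contact involves a backbone atom (N, CA, C, O, OXT) |
| sidechain      | a contact involves a sidechain atom |
| polar          | an N/O/S pair within 3.8 Å |
| hydrophobic    | a C/S pair within 4.5 Å |
| H-bond acceptor| a receptor acceptor within 3.5 Å of a ligand donor (angle ≥ 120° at H when hydrogens exist) |
| H-bond donor   | the converse |
| aromatic       | ring centroids within 5.0 Å |
| charged        | opposite formal charges within 4.0 Å (salt bridge) |

Averaging the fingerprints over a pose population gives per-residue
interaction *frequencies* — e.g. "41 % of ligands hydrogen-bond to
Arg71" — from which binding-site residues are extracted by
thresholding the `any` bit.  Poses are grouped by greedy leader
clustering at a 1.0 Å heavy-atom RMSD cutoff (no superposition; docked
poses share the receptor frame).

### Steady-state kinetics

Initial velocities v at substrate concentration S are fitted to the
Hill equation

    v = Vmax · S^h / (Km^h + S^h)

by Levenberg–Marquardt least squares on log-parameters (h = 1 recovers
Michaelis–Menten, available via `fixH = 1`).  kcat = Vmax/[E]₀ and the
specificity constant kcat/Km are derived with standard errors from the
fit covariance.  `foldChange()` forms mutant-versus-wild-type ratios,
`relativeActivity()` normalizes inhibitor/ion panels to a control
defined as 100 %, and `purificationSummary()` derives specific
activity (U/mg), yield (%) and fold purification from step totals.

Every stage is testable without downloads: the synthetic-data module
builds receptor–ligand complexes with interactions planted at exact
geometries, pose ensembles realizing prescribed bit frequencies, and
noisy saturation datasets from stated Hill parameters.

## Worked example

Plant a Tyr120 π-stack in every pose and an Arg71 hydrogen bond in 12
of 29 poses, then fingerprint and average:

```r
library(SIFtKit)
ens <- sampleEnsemble(list(
    list(bit = "aromatic",       residue = "TYR", resno = 120, f = 1),
    list(bit = "hbond_acceptor", residue = "ARG", resno = 71,  f = 12/29)),
  nPoses = 29, seed = 7, exact = TRUE)
avg <- averageSIFt(lapply(poses(ens), computeSIFt, receptor = receptor(ens)))
avg
#> AveragedSIFt over 29 fingerprints, 2 residues
#>       any backbone sidechain polar hydrophobic hbond_acceptor hbond_donor
#> R71  0.41     0.41         0  0.41           0           0.41           0
#> Y120 1.00     0.00         1  0.00           1           0.00           0
#>      aromatic charged
#> R71         0       0
#> Y120        1       0
```

Y120 stacks in all poses (frequency 1.00); R71 accepts a hydrogen bond
in 12/29 = 0.41 of them.  (Arg has no sidechain acceptor, so the
planted bond lands on its backbone carbonyl — hence the matching
backbone/polar frequencies.)

Kinetics: simulate triplicate assays at wild-type (kcat 0.646 min⁻¹,
Km 12 µM) and mutant (4.37 min⁻¹, 11.3 µM) parameters with 3 % noise,
fit, and compare:

```r
wt  <- fitHill(simulateKinetics(kcat = 0.646, Km = 12,   cv = 0.03, seed = 1),
               enzymeConc = 1, fixH = 1)
mut <- fitHill(simulateKinetics(kcat = 4.37,  Km = 11.3, cv = 0.03, seed = 2),
               enzymeConc = 1, fixH = 1)
wt
#> KineticFit: kcat 0.651 +/- 0.0036 min^-1, Km 12.2 +/- 0.28 uM, h 1 (fixed)
#>   kcat/Km 0.0532 +/- 0.001 min^-1 uM^-1 (RSS 0.00219, n = 30)
round(foldChange(mut, wt), 2)
#>         kcat           Km kcat_over_Km
#>         6.82         0.97         7.05
```

The mutant turns over ~7× faster with essentially unchanged substrate
affinity.  Purification accounting from step totals:

```r
steps <- data.frame(
  label          = c("Crude extract", "Heat incubation", "Sephacryl S-200"),
  total_protein  = c(3048.9, 672.5, 50.2),
  total_activity = c(NA, 1670.4, 997.474))
purificationSummary(steps, yieldRef = "Heat incubation", foldRef = 2.48)
#>             label total_protein total_activity specific_activity yield_pct  fold
#> 1   Crude extract        3048.9             NA                NA        NA    NA
#> 2 Heat incubation         672.5         1670.4             2.484    100.00 1.002
#> 3 Sephacryl S-200          50.2          997.474           19.870     59.71 8.012
```

See `vignettes/protease-characterization.Rmd` for the full account of
the methods, parameter choices and limitations.

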