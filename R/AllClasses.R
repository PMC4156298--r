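#' @import methods
NULL

#' Geometric criteria for interaction detection
#'
#' Container for the distance/angle cutoffs that define when each of the
#' nine fingerprint bits fires.  All distances are in Angstrom, the
#' hydrogen-bond angle in degrees.  Defaults follow conventional
#' interaction-geometry ranges used in binding-site analysis:
#' a 4.5 A heavy-atom contact envelope, 3.5 A donor--acceptor distance with
#' a minimum 120 degree angle at the hydrogen (when hydrogens are present),
#' 5.0 A ring-centroid distance for aromatic contacts, 4.0 A for salt
#' bridges and 3.8 A for polar atom pairs.
#'
#' @slot contact heavy-atom contact cutoff (A) driving the "any",
#'   backbone/sidechain and hydrophobic bits.
#' @slot hbondDA maximum donor--acceptor distance (A) for hydrogen bonds.
#' @slot hbondAngle minimum angle (degrees) at the hydrogen between the
#'   H-to-donor and H-to-acceptor vectors; only enforced when an explicit
#'   hydrogen is available.
#' @slot aromaticCentroid maximum ring-centroid separation (A).
#' @slot charged maximum cation--anion distance (A).
#' @slot polar maximum distance (A) between two polar (N/O/S) atoms.
#' @seealso [interactionParams()]
#' @exportClass InteractionParams
setClass("InteractionParams", representation(
  contact = "numeric", hbondDA = "numeric", hbondAngle = "numeric",
  aromaticCentroid = "numeric", charged = "numeric", polar = "numeric"
))

setValidity("InteractionParams", function(object) {
  v <- c(object@contact, object@hbondDA, object@hbondAngle,
         object@aromaticCentroid, object@charged, object@polar)
  if (any(!is.finite(v)) || any(v <= 0))
    return("all cutoffs must be finite and positive")
  if (object@hbondDA > object@contact)
    return("hbondDA must not exceed the contact cutoff")
  if (object@contact > object@aromaticCentroid + 1)
    return("contact cutoff must not exceed aromaticCentroid + 1")
  TRUE
})

#' Construct interaction-geometry parameters
#'
#' @param contact,hbondDA,hbondAngle,aromaticCentroid,charged,polar see
#'   [InteractionParams-class] for meanings, units and defaults.
#' @return an `InteractionParams` object.
#' @examples
#' interactionParams()
#' interactionParams(contact = 4.0)
#' @export
interactionParams <- function(contact = 4.5, hbondDA = 3.5, hbondAngle = 120,
                              aromaticCentroid = 5.0, charged = 4.0,
                              polar = 3.8) {
  new("InteractionParams", contact = contact, hbondDA = hbondDA,
      hbondAngle = hbondAngle, aromaticCentroid = aromaticCentroid,
      charged = charged, polar = polar)
}

#' Receptor structure with atom chemistry annotations
#'
#' Holds the receptor atoms (one row per atom, PDB-style fields plus
#' logical role flags) and the perceived aromatic rings.  Roles (donor,
#' acceptor, cation, anion, aromatic-ring member, backbone) are assigned by
#' [assignAtomRoles()]; the `typed` flag records whether that has happened.
#'
#' @slot atoms data.frame of atoms; see [atoms()].
#' @slot rings list of rings, each a list with elements `atoms` (integer
#'   row indices into the atom table), `centroid` and `normal`
#'   (numeric 3-vectors) and `label` (residue label such as `"Y120"`).
#' @slot typed logical; `TRUE` once atom roles have been assigned.
#' @exportClass TypedStructure
setClass("TypedStructure", representation(
  atoms = "data.frame", rings = "list", typed = "logical"
))

setValidity("TypedStructure", function(object) {
  assertAtomTable(object@atoms, "TypedStructure atoms")
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) && any(!is.finite(xyz)))
    return("atom coordinates must be finite")
  if (nrow(object@atoms) && any(!nzchar(object@atoms$element)))
    return("every atom needs a non-empty element symbol")
  for (r in object@rings) {
    if (length(r$atoms) < 5L) return("every ring must have >= 5 atoms")
  }
  key <- unique(object@atoms[, c("chain", "resno", "resname")])
  if (anyDuplicated(key[, c("chain", "resno")]))
    return("residue keys (chain, resno) must be unique")
  TRUE
})

#' One docked conformation of a ligand
#'
#' @slot ligandId character identifier of the ligand.
#' @slot poseIndex integer >= 0, order of appearance in the pose file.
#' @slot atoms atom table (same schema as [TypedStructure-class]).
#' @slot rings perceived aromatic rings (see [perceiveLigandRings()]).
#' @exportClass LigandPose
setClass("LigandPose", representation(
  ligandId = "character", poseIndex = "integer",
  atoms = "data.frame", rings = "list"
))

setValidity("LigandPose", function(object) {
  assertAtomTable(object@atoms, "LigandPose atoms")
  if (length(object@poseIndex) != 1L || object@poseIndex < 0L)
    return("poseIndex must be a single non-negative integer")
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (nrow(xyz) && any(!is.finite(xyz)))
    return("atom coordinates must be finite")
  TRUE
})

#' A receptor together with an ordered collection of docked poses
#'
#' @slot receptor a [TypedStructure-class].
#' @slot poses non-empty list of [LigandPose-class] objects.
#' @exportClass PoseEnsemble
setClass("PoseEnsemble", representation(
  receptor = "TypedStructure", poses = "list"
))

setValidity("PoseEnsemble", function(object) {
  if (!length(object@poses))
    return("a PoseEnsemble needs at least one pose")
  ok <- vapply(object@poses, is, logical(1), "LigandPose")
  if (!all(ok)) return("all poses must be LigandPose objects")
  TRUE
})

#' Per-residue nine-bit interaction fingerprint of one pose
#'
#' Rows of `bits` are the residues that make at least one interaction with
#' the pose; columns are the nine bits in fixed order: any, backbone,
#' sidechain, polar, hydrophobic, H-bond acceptor, H-bond donor, aromatic,
#' charged.  Residues absent from the matrix are implicitly all-zero.
#' "H-bond acceptor" means the receptor atom accepts a hydrogen bond from
#' a ligand donor; "H-bond donor" the converse.
#'
#' @slot ligandId,poseIndex identity of the pose the fingerprint describes.
#' @slot bits logical matrix, one row per interacting residue (rownames are
#'   residue labels such as `"R71"`), nine named columns.
#' @slot residues data.frame with `chain`, `resno`, `resname`, `label` for
#'   each fingerprint row, used for ordering and comparisons.
#' @slot receptorTag character fingerprint of the receptor's residue
#'   complement; two SIFts are only comparable when tags agree.
#' @exportClass SIFt
setClass("SIFt", representation(
  ligandId = "character", poseIndex = "integer",
  bits = "matrix", residues = "data.frame", receptorTag = "character"
))

setValidity("SIFt", function(object) {
  b <- object@bits
  if (ncol(b) != 9L || !identical(colnames(b), BIT_NAMES))
    return("bits must have the nine canonical columns")
  if (!is.logical(b)) return("bits must be logical")
  if (nrow(b) && any(rowSums(b) == 0))
    return("stored fingerprints must have at least one set bit")
  if (nrow(b) && any(!b[, "any"] & rowSums(b[, -1L, drop = FALSE]) > 0))
    return("'any' must be set whenever any other bit is set")
  if (nrow(b) != nrow(object@residues))
    return("residues table must parallel the bit matrix")
  TRUE
})

#' Ensemble-averaged interaction fingerprint
#'
#' Per-residue per-bit frequencies over a population of fingerprints:
#' entry (r, b) is the fraction of fingerprints in which residue r sets
#' bit b.  Residues never contacted are omitted.
#'
#' @slot freq numeric matrix in `[0, 1]`, residues x nine bits.
#' @slot residues data.frame as in [SIFt-class].
#' @slot nFingerprints number of fingerprints averaged.
#' @exportClass AveragedSIFt
setClass("AveragedSIFt", representation(
  freq = "matrix", residues = "data.frame", nFingerprints = "integer"
))

setValidity("AveragedSIFt", function(object) {
  f <- object@freq
  if (ncol(f) != 9L || !identical(colnames(f), BIT_NAMES))
    return("freq must have the nine canonical columns")
  if (nrow(f) && (any(f < 0) || any(f > 1)))
    return("frequencies must lie in [0, 1]")
  if (object@nFingerprints < 1L)
    return("nFingerprints must be >= 1")
  counts <- f * object@nFingerprints
  if (nrow(f) && any(abs(counts - round(counts)) > 1e-9))
    return("frequency x nFingerprints must be integral")
  if (nrow(f) && any(f[, "any"] + 1e-12 < apply(f[, -1L, drop = FALSE], 1, max)))
    return("frequency('any') must dominate every other bit")
  TRUE
})

#' Pose-clustering parameters
#'
#' @slot rmsdCutoff RMSD cutoff (A) for greedy leader clustering;
#'   default 1.0 A, the conventional criterion for docked-pose families.
#' @exportClass ClusterParams
setClass("ClusterParams", representation(rmsdCutoff = "numeric"))

setValidity("ClusterParams", function(object) {
  if (length(object@rmsdCutoff) != 1L || !is.finite(object@rmsdCutoff) ||
      object@rmsdCutoff <= 0)
    return("rmsdCutoff must be a single positive number")
  TRUE
})

#' @rdname ClusterParams-class
#' @param rmsdCutoff RMSD cutoff in Angstrom.
#' @return a `ClusterParams` object.
#' @export
clusterParams <- function(rmsdCutoff = 1.0) {
  new("ClusterParams", rmsdCutoff = rmsdCutoff)
}

#' Result of fitting the Hill equation to saturation data
#'
#' Estimates of Vmax, Km and the Hill coefficient h from nonlinear least
#' squares on v = Vmax * S^h / (Km^h + S^h), with derived kcat = Vmax /
#' [E]0 and specificity constant kcat/Km.  Standard errors come from the
#' covariance of the fit (delta method on the internal log scale).
#'
#' @slot estimates named numeric: Vmax, Km, h.
#' @slot se named numeric standard errors of the estimates.
#' @slot enzymeConc total enzyme concentration (same concentration units
#'   as the substrate axis) used to convert Vmax to kcat.
#' @slot kcat,kcatSe turnover number and its standard error.
#' @slot kcatOverKm,kcatOverKmSe specificity constant and standard error.
#' @slot rss residual sum of squares.
#' @slot nobs number of data points fitted.
#' @slot fixedH logical; `TRUE` when h was held fixed (Michaelis--Menten
#'   when fixed at 1).
#' @slot converged logical convergence flag; when `FALSE` the estimates
#'   are `NA` and must not be interpreted.
#' @exportClass KineticFit
setClass("KineticFit", representation(
  estimates = "numeric", se = "numeric", enzymeConc = "numeric",
  kcat = "numeric", kcatSe = "numeric",
  kcatOverKm = "numeric", kcatOverKmSe = "numeric",
  rss = "numeric", nobs = "integer", fixedH = "logical",
  converged = "logical"
))

setValidity("KineticFit", function(object) {
  if (object@converged) {
    if (any(!is.finite(object@estimates))) return("converged fit has NA estimates")
    if (any(object@estimates <= 0)) return("Vmax, Km and h must be positive")
    expected <- object@kcat / object@estimates[["Km"]]
    if (abs(object@kcatOverKm - expected) > 1e-9 * max(1, abs(expected)))
      return("kcatOverKm must equal kcat / Km")
    if (any(stats::na.omit(object@se) < 0)) return("standard errors must be >= 0")
  }
  TRUE
})

#' Pairwise global alignment with percent identity
#'
#' @slot idA,idB sequence identifiers.
#' @slot alignedA,alignedB equal-length aligned strings with `-` gaps.
#' @slot score alignment score.
#' @slot identityPct percent identity under the default denominator
#'   (aligned columns, excluding none since double gaps cannot occur in a
#'   pairwise alignment).
#' @exportClass AlignmentResult
setClass("AlignmentResult", representation(
  idA = "character", idB = "character",
  alignedA = "character", alignedB = "character",
  score = "numeric", identityPct = "numeric"
))

setValidity("AlignmentResult", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings must have equal length")
  if (object@identityPct < 0 || object@identityPct > 100)
    return("identityPct must lie in [0, 100]")
  TRUE
})
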