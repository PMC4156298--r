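# Accessors and show methods.

#' Atom table of a structure or pose
#'
#' One row per atom with PDB-style identity fields (`serial`, `name`,
#' `resname`, `chain`, `resno`), coordinates (`x`, `y`, `z`, Angstrom),
#' `element`, and logical flags: `het`, `water`, `hydrogen`, `backbone`,
#' and the chemistry roles `donor`, `acceptor`, `cation`, `anion`,
#' `aromatic` (ring membership).
#'
#' @param x a [TypedStructure-class] or [LigandPose-class].
#' @return a data.frame of atoms.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "TypedStructure", function(x) x@atoms)

#' @rdname atoms
#' @export
setMethod("atoms", "LigandPose", function(x) x@atoms)

#' Aromatic rings of a structure or pose
#'
#' @param x a [TypedStructure-class] or [LigandPose-class].
#' @return list of rings (`atoms` indices, `centroid`, `normal`, `label`).
#' @export
setGeneric("rings", function(x) standardGeneric("rings"))

#' @rdname rings
#' @export
setMethod("rings", "TypedStructure", function(x) x@rings)

#' @rdname rings
#' @export
setMethod("rings", "LigandPose", function(x) x@rings)

#' Poses and receptor of an ensemble
#'
#' @param x a [PoseEnsemble-class].
#' @return `poses()`: list of [LigandPose-class]; `receptor()`: the
#'   [TypedStructure-class].
#' @export
setGeneric("poses", function(x) standardGeneric("poses"))

#' @rdname poses
#' @export
setMethod("poses", "PoseEnsemble", function(x) x@poses)

#' @rdname poses
#' @export
setGeneric("receptor", function(x) standardGeneric("receptor"))

#' @rdname poses
#' @export
setMethod("receptor", "PoseEnsemble", function(x) x@receptor)

#' Fingerprint bit matrix
#'
#' @param x a [SIFt-class].
#' @return logical residues-by-nine-bits matrix.
#' @export
setGeneric("fingerprintBits", function(x) standardGeneric("fingerprintBits"))

#' @rdname fingerprintBits
#' @export
setMethod("fingerprintBits", "SIFt", function(x) x@bits)

#' Per-residue bit frequencies of an averaged fingerprint
#'
#' @param x an [AveragedSIFt-class].
#' @return numeric residues-by-nine-bits matrix in `[0, 1]`.
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname frequencies
#' @export
setMethod("frequencies", "AveragedSIFt", function(x) x@freq)

#' Number of fingerprints behind an average
#'
#' @param x an [AveragedSIFt-class].
#' @return integer count.
#' @export
setGeneric("nFingerprints", function(x) standardGeneric("nFingerprints"))

#' @rdname nFingerprints
#' @export
setMethod("nFingerprints", "AveragedSIFt", function(x) x@nFingerprints)

#' Kinetic-fit accessors
#'
#' `kcat()`, `km()`, `hillCoefficient()` and `kcatOverKm()` return point
#' estimates; `standardErrors()` the named SE vector (Vmax, Km, h, kcat,
#' kcat_over_Km); `converged()` the convergence flag.
#'
#' @param x a [KineticFit-class].
#' @return numeric scalar (or named vector for `standardErrors`).
#' @name kineticfit-accessors
NULL

#' @rdname kineticfit-accessors
#' @export
setGeneric("kcat", function(x) standardGeneric("kcat"))

#' @rdname kineticfit-accessors
#' @export
setMethod("kcat", "KineticFit", function(x) x@kcat)

#' @rdname kineticfit-accessors
#' @export
setGeneric("km", function(x) standardGeneric("km"))

#' @rdname kineticfit-accessors
#' @export
setMethod("km", "KineticFit", function(x) unname(x@estimates["Km"]))

#' @rdname kineticfit-accessors
#' @export
setGeneric("hillCoefficient", function(x) standardGeneric("hillCoefficient"))

#' @rdname kineticfit-accessors
#' @export
setMethod("hillCoefficient", "KineticFit",
          function(x) unname(x@estimates["h"]))

#' @rdname kineticfit-accessors
#' @export
setGeneric("kcatOverKm", function(x) standardGeneric("kcatOverKm"))

#' @rdname kineticfit-accessors
#' @export
setMethod("kcatOverKm", "KineticFit", function(x) x@kcatOverKm)

#' @rdname kineticfit-accessors
#' @export
setGeneric("standardErrors", function(x) standardGeneric("standardErrors"))

#' @rdname kineticfit-accessors
#' @export
setMethod("standardErrors", "KineticFit", function(x) {
  c(x@se, kcat = unname(x@kcatSe), kcat_over_Km = unname(x@kcatOverKmSe))
})

#' @rdname kineticfit-accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname kineticfit-accessors
#' @export
setMethod("converged", "KineticFit", function(x) x@converged)

#' Percent identity of an alignment
#'
#' @param result an [AlignmentResult-class].
#' @param denominator `"aligned_columns"` (default) divides matches by the
#'   number of alignment columns; `"shorter_sequence"` by the length of
#'   the shorter unaligned sequence.
#' @return percent identity, rounded to one decimal.
#' @export
setGeneric("percentIdentity",
           function(result, denominator = c("aligned_columns",
                                            "shorter_sequence"))
             standardGeneric("percentIdentity"))

setMethod("show", "InteractionParams", function(object) {
  cat("InteractionParams:",
      sprintf("contact %.2f A, H-bond D-A %.2f A / angle >= %.0f deg,",
              object@contact, object@hbondDA, object@hbondAngle),
      sprintf("aromatic centroid %.2f A, charged %.2f A, polar %.2f A\n",
              object@aromaticCentroid, object@charged, object@polar))
})

setMethod("show", "TypedStructure", function(object) {
  a <- object@atoms
  nres <- nrow(unique(a[!a$het & !a$water, c("chain", "resno")]))
  cat(sprintf(
    "TypedStructure: %d atoms, %d protein residues, %d aromatic rings%s\n",
    nrow(a), nres, length(object@rings),
    if (object@typed) " (roles assigned)" else " (roles NOT assigned)"))
})

setMethod("show", "LigandPose", function(object) {
  cat(sprintf("LigandPose '%s' #%d: %d atoms, %d rings\n",
              object@ligandId, object@poseIndex, nrow(object@atoms),
              length(object@rings)))
})

setMethod("show", "PoseEnsemble", function(object) {
  cat(sprintf("PoseEnsemble: %d poses\n", length(object@poses)))
  show(object@receptor)
})

setMethod("show", "SIFt", function(object) {
  cat(sprintf("SIFt of '%s' pose %d: %d interacting residues\n",
              object@ligandId, object@poseIndex, nrow(object@bits)))
  if (nrow(object@bits)) print(object@bits * 1L)
})

setMethod("show", "AveragedSIFt", function(object) {
  cat(sprintf("AveragedSIFt over %d fingerprints, %d residues\n",
              object@nFingerprints, nrow(object@freq)))
  if (nrow(object@freq)) print(round(object@freq, 2))
})

setMethod("show", "KineticFit", function(object) {
  if (!object@converged) {
    cat("KineticFit: NOT converged\n")
    return(invisible(NULL))
  }
  est <- object@estimates
  cat(sprintf(
    "KineticFit: kcat %.3g +/- %.2g min^-1, Km %.3g +/- %.2g uM, h %.3g%s\n",
    object@kcat, object@kcatSe, est["Km"], object@se["Km"], est["h"],
    if (object@fixedH) " (fixed)" else ""))
  cat(sprintf("  kcat/Km %.3g +/- %.2g min^-1 uM^-1 (RSS %.3g, n = %d)\n",
              object@kcatOverKm, object@kcatOverKmSe, object@rss,
              object@nobs))
})

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("Global alignment %s vs %s: score %.1f, identity %.1f%%\n",
              object@idA, object@idB, object@score, object@identityPct))
})
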