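# The nine-bit structural interaction fingerprint (SIFt) engine:
# contact detection, per-pose fingerprints, ensemble averaging,
# fingerprint comparison, pose RMSD clustering and binding-site
# extraction.

H_COVALENT_MAX <- 1.25  # A, distance for "H attached to donor"

residueTag <- function(atoms) {
  prot <- !atoms$het & !atoms$water
  key <- unique(paste(atoms$chain[prot], atoms$resno[prot],
                      atoms$resname[prot], sep = "|"))
  paste(key, collapse = ";")
}

# All (receptor atom, ligand atom) pairs within `cutoff`, via spatial
# binning of the receptor atoms into cubic cells of edge `cutoff` and a
# 27-cell neighborhood lookup per ligand atom.
neighborPairs <- function(rxyz, lxyz, cutoff) {
  if (!nrow(rxyz) || !nrow(lxyz))
    return(data.frame(i = integer(0), j = integer(0), d = numeric(0)))
  cellOf <- function(xyz) floor(xyz / cutoff)
  rcell <- cellOf(rxyz)
  keys <- paste(rcell[, 1], rcell[, 2], rcell[, 3])
  bins <- split(seq_len(nrow(rxyz)), keys)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  iOut <- jOut <- integer(0); dOut <- numeric(0)
  lcell <- cellOf(lxyz)
  for (j in seq_len(nrow(lxyz))) {
    cand <- integer(0)
    for (k in seq_len(nrow(offs))) {
      key <- paste(lcell[j, 1] + offs[k, 1], lcell[j, 2] + offs[k, 2],
                   lcell[j, 3] + offs[k, 3])
      hit <- bins[[key]]
      if (!is.null(hit)) cand <- c(cand, hit)
    }
    if (!length(cand)) next
    dv <- sweep(rxyz[cand, , drop = FALSE], 2, lxyz[j, ])
    dd <- sqrt(rowSums(dv * dv))
    ok <- dd <= cutoff
    if (any(ok)) {
      iOut <- c(iOut, cand[ok]); jOut <- c(jOut, rep.int(j, sum(ok)))
      dOut <- c(dOut, dd[ok])
    }
  }
  data.frame(i = iOut, j = jOut, d = dOut)
}

#' Heavy-atom contacts between a receptor and a pose
#'
#' All receptor/ligand heavy-atom pairs within the contact cutoff, found
#' with a spatial-binning neighbor search (equivalent to, but faster
#' than, the all-pairs scan).  Waters and hydrogens are excluded.
#'
#' @param receptor a [TypedStructure-class].
#' @param pose a [LigandPose-class].
#' @param params an [InteractionParams-class]; `params@contact` is the
#'   cutoff unless `cutoff` overrides it.
#' @param cutoff optional explicit cutoff (A).
#' @return data.frame with columns `chain`, `resno`, `resname`, `label`,
#'   `receptorAtom` and `ligandAtom` (row indices into the respective
#'   atom tables) and `distance`, sorted by residue then distance.
#' @export
residueContacts <- function(receptor, pose, params = interactionParams(),
                            cutoff = NULL) {
  cutoff <- cutoff %||% params@contact
  ra <- receptor@atoms
  la <- pose@atoms
  rIdx <- which(!ra$hydrogen & !ra$water)
  lIdx <- which(!la$hydrogen & !la$water)
  pairs <- neighborPairs(as.matrix(ra[rIdx, c("x", "y", "z")]),
                         as.matrix(la[lIdx, c("x", "y", "z")]), cutoff)
  out <- data.frame(
    chain = ra$chain[rIdx[pairs$i]], resno = ra$resno[rIdx[pairs$i]],
    resname = ra$resname[rIdx[pairs$i]],
    label = residueLabel(ra$resname[rIdx[pairs$i]], ra$resno[rIdx[pairs$i]]),
    receptorAtom = rIdx[pairs$i], ligandAtom = lIdx[pairs$j],
    distance = pairs$d, stringsAsFactors = FALSE
  )
  out[order(out$chain, out$resno, out$distance), , drop = FALSE]
}

#' Hydrogen-bond geometric test
#'
#' True when the donor--acceptor distance is within `params@hbondDA` and,
#' if an explicit hydrogen position is supplied, the angle at the
#' hydrogen between the H-to-donor and H-to-acceptor vectors is at least
#' `params@hbondAngle` (near-linear D-H...A arrangements approach 180
#' degrees).  Without a hydrogen the test is distance-only, the fallback
#' for structures deposited without hydrogens.
#'
#' @param donor,acceptor numeric xyz coordinates (A) of the donor and
#'   acceptor heavy atoms.
#' @param h optional xyz of the donor-attached hydrogen.
#' @param params an [InteractionParams-class].
#' @return logical scalar.
#' @examples
#' p <- interactionParams()
#' detectHBond(c(0, 0, 0), c(2.9, 0, 0), h = c(1, 0, 0), params = p)  # TRUE
#' detectHBond(c(0, 0, 0), c(4.0, 0, 0), params = p)                  # FALSE
#' @export
detectHBond <- function(donor, acceptor, h = NULL,
                        params = interactionParams()) {
  d <- vnorm(acceptor - donor)
  if (d > params@hbondDA) return(FALSE)
  if (is.null(h)) return(TRUE)
  hd <- donor - h
  ha <- acceptor - h
  ang <- acos(pmin(1, pmax(-1, sum(hd * ha) / (vnorm(hd) * vnorm(ha))))) *
    180 / pi
  ang >= params@hbondAngle
}

#' Aromatic ring--ring contact test
#'
#' Distance-only criterion: true when the ring centroids are within
#' `params@aromaticCentroid`.  No stacking-angle filter is applied, so
#' parallel and T-shaped arrangements are both accepted.
#'
#' @param ringA,ringB ring objects (lists with a `centroid` element) as
#'   produced by [assignAtomRoles()] / [perceiveLigandRings()].
#' @param params an [InteractionParams-class].
#' @return logical scalar.
#' @export
detectAromaticContact <- function(ringA, ringB,
                                  params = interactionParams()) {
  vnorm(ringA$centroid - ringB$centroid) <= params@aromaticCentroid
}

attachedHydrogens <- function(atoms, heavyIdx) {
  hIdx <- which(atoms$hydrogen)
  if (!length(hIdx)) return(integer(0))
  xyz <- unlist(atoms[heavyIdx, c("x", "y", "z")])
  hxyz <- as.matrix(atoms[hIdx, c("x", "y", "z")])
  dv <- sweep(hxyz, 2, xyz)
  hIdx[sqrt(rowSums(dv * dv)) <= H_COVALENT_MAX]
}

hbondWithH <- function(atoms, donorIdx, acceptorXYZ, params) {
  dXYZ <- unlist(atoms[donorIdx, c("x", "y", "z")])
  hIdx <- attachedHydrogens(atoms, donorIdx)
  if (!length(hIdx)) return(detectHBond(dXYZ, acceptorXYZ, params = params))
  any(vapply(hIdx, function(hi)
    detectHBond(dXYZ, acceptorXYZ,
                h = unlist(atoms[hi, c("x", "y", "z")]), params = params),
    logical(1)))
}

#' Compute the nine-bit fingerprint of one pose
#'
#' For each receptor residue in contact with the pose, sets: `any` (at
#' least one heavy-atom pair within the contact cutoff, or any other bit
#' fired), `backbone`/`sidechain` (contacts partitioned by receptor-atom
#' role), `polar` (N/O/S pair within the polar cutoff), `hydrophobic`
#' (C/S pair within the contact cutoff), `hbond_acceptor` (receptor
#' acceptor within H-bond range of a ligand donor), `hbond_donor`
#' (receptor donor to ligand acceptor), `aromatic` (residue ring within
#' centroid range of a ligand ring) and `charged` (opposite formal
#' charges within the salt-bridge cutoff).  Hydrogen-bond tests use the
#' angle criterion whenever the donor has an explicit hydrogen.
#'
#' @param receptor a [TypedStructure-class] with roles assigned.
#' @param pose a [LigandPose-class].
#' @param params an [InteractionParams-class].
#' @return a [SIFt-class]; residues with no set bit are omitted.
#' @export
computeSIFt <- function(receptor, pose, params = interactionParams()) {
  if (!receptor@typed)
    stop("receptor atoms have no chemistry roles; ",
         "run assignAtomRoles() on the structure first")
  ra <- receptor@atoms
  la <- pose@atoms
  maxcut <- max(params@contact, params@polar, params@charged,
                params@hbondDA)
  contacts <- residueContacts(receptor, pose, params, cutoff = maxcut)

  resKey <- paste(contacts$chain, contacts$resno, sep = "|")
  bitRows <- list()
  resInfo <- list()
  setBits <- function(key, chain, resno, resname, bits) {
    prev <- bitRows[[key]] %||% stats::setNames(rep(FALSE, 9L), BIT_NAMES)
    bitRows[[key]] <<- prev | bits
    resInfo[[key]] <<- data.frame(chain = chain, resno = resno,
                                  resname = resname,
                                  label = residueLabel(resname, resno),
                                  stringsAsFactors = FALSE)
  }

  for (key in unique(resKey)) {
    rows <- contacts[resKey == key, , drop = FALSE]
    ri <- rows$receptorAtom
    lj <- rows$ligandAtom
    d <- rows$distance
    bits <- stats::setNames(rep(FALSE, 9L), BIT_NAMES)
    inContact <- d <= params@contact
    bits["any"] <- any(inContact)
    bits["backbone"] <- any(inContact & ra$backbone[ri])
    bits["sidechain"] <- any(inContact & !ra$backbone[ri] & !ra$het[ri])
    bits["hydrophobic"] <- any(inContact &
                                 ra$element[ri] %in% c("C", "S") &
                                 la$element[lj] %in% c("C", "S"))
    bits["polar"] <- any(d <= params@polar &
                           ra$element[ri] %in% c("N", "O", "S") &
                           la$element[lj] %in% c("N", "O", "S"))
    bits["charged"] <- any(d <= params@charged &
                             ((ra$cation[ri] & la$anion[lj]) |
                                (ra$anion[ri] & la$cation[lj])))
    hbAcc <- which(d <= params@hbondDA & ra$acceptor[ri] & la$donor[lj])
    for (p in hbAcc) {
      if (hbondWithH(la, lj[p], unlist(ra[ri[p], c("x", "y", "z")]),
                     params)) {
        bits["hbond_acceptor"] <- TRUE
        break
      }
    }
    hbDon <- which(d <= params@hbondDA & ra$donor[ri] & la$acceptor[lj])
    for (p in hbDon) {
      if (hbondWithH(ra, ri[p], unlist(la[lj[p], c("x", "y", "z")]),
                     params)) {
        bits["hbond_donor"] <- TRUE
        break
      }
    }
    setBits(key, rows$chain[1L], rows$resno[1L], rows$resname[1L], bits)
  }

  # aromatic: receptor residue rings vs ligand rings (centroid criterion);
  # may involve residues beyond the atom-contact cutoff.
  if (length(pose@rings)) {
    for (rring in receptor@rings) {
      at <- rring$atoms[1L]
      hit <- any(vapply(pose@rings, detectAromaticContact, logical(1),
                        ringA = rring, params = params))
      if (hit) {
        bits <- stats::setNames(rep(FALSE, 9L), BIT_NAMES)
        bits["aromatic"] <- TRUE
        setBits(paste(ra$chain[at], ra$resno[at], sep = "|"),
                ra$chain[at], ra$resno[at], ra$resname[at], bits)
      }
    }
  }

  if (!length(bitRows)) {
    return(new("SIFt", ligandId = pose@ligandId, poseIndex = pose@poseIndex,
               bits = matrix(logical(0), 0, 9,
                             dimnames = list(NULL, BIT_NAMES)),
               residues = data.frame(chain = character(0),
                                     resno = integer(0),
                                     resname = character(0),
                                     label = character(0)),
               receptorTag = residueTag(ra)))
  }

  bits <- do.call(rbind, bitRows)
  bits[, "any"] <- bits[, "any"] | rowSums(bits[, -1L, drop = FALSE]) > 0
  res <- do.call(rbind, resInfo[rownames(bits)])
  keep <- rowSums(bits) > 0
  bits <- bits[keep, , drop = FALSE]
  res <- res[keep, , drop = FALSE]
  ord <- order(res$chain, res$resno)
  bits <- bits[ord, , drop = FALSE]
  res <- res[ord, , drop = FALSE]
  rownames(bits) <- res$label
  rownames(res) <- NULL
  new("SIFt", ligandId = pose@ligandId, poseIndex = pose@poseIndex,
      bits = bits, residues = res, receptorTag = residueTag(ra))
}

#' Average fingerprints over a pose population
#'
#' Per residue and per bit, the frequency is the fraction of fingerprints
#' in which that bit is set.  Residues never contacted by any pose are
#' omitted; rows are sorted by chain and residue number.  Fingerprints
#' from different receptor conformations may be pooled (residues are
#' matched by chain and number), mirroring population averaging over
#' ligands and receptors.
#'
#' @param sifts non-empty list of [SIFt-class] objects.
#' @return an [AveragedSIFt-class].
#' @export
averageSIFt <- function(sifts) {
  if (!length(sifts)) stop("cannot average an empty fingerprint list")
  n <- length(sifts)
  counts <- list()
  resInfo <- list()
  for (s in sifts) {
    for (k in seq_len(nrow(s@bits))) {
      key <- paste(s@residues$chain[k], s@residues$resno[k], sep = "|")
      counts[[key]] <- (counts[[key]] %||%
                          stats::setNames(rep(0, 9L), BIT_NAMES)) + s@bits[k, ]
      resInfo[[key]] <- s@residues[k, , drop = FALSE]
    }
  }
  if (!length(counts)) {
    return(new("AveragedSIFt",
               freq = matrix(numeric(0), 0, 9,
                             dimnames = list(NULL, BIT_NAMES)),
               residues = data.frame(chain = character(0),
                                     resno = integer(0),
                                     resname = character(0),
                                     label = character(0)),
               nFingerprints = as.integer(n)))
  }
  freq <- do.call(rbind, counts) / n
  res <- do.call(rbind, resInfo[rownames(freq)])
  ord <- order(res$chain, res$resno)
  freq <- freq[ord, , drop = FALSE]
  res <- res[ord, , drop = FALSE]
  rownames(freq) <- res$label
  rownames(res) <- NULL
  new("AveragedSIFt", freq = freq, residues = res,
      nFingerprints = as.integer(n))
}

#' Tanimoto similarity of two fingerprints
#'
#' The number of (residue, bit) positions set in both fingerprints
#' divided by the number set in either; 1 when both are empty.
#'
#' @param a,b [SIFt-class] objects computed against the same receptor.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (!identical(a@receptorTag, b@receptorTag))
    stop("fingerprints come from different receptors")
  setOf <- function(s) {
    if (!nrow(s@bits)) return(character(0))
    idx <- which(s@bits, arr.ind = TRUE)
    paste(s@residues$chain[idx[, 1L]], s@residues$resno[idx[, 1L]],
          colnames(s@bits)[idx[, 2L]], sep = "|")
  }
  sa <- setOf(a)
  sb <- setOf(b)
  u <- union(sa, sb)
  if (!length(u)) return(1.0)
  length(intersect(sa, sb)) / length(u)
}

#' Heavy-atom RMSD between two poses of the same ligand
#'
#' Root-mean-square deviation over paired heavy atoms in file order, with
#' no superposition: docked poses share the receptor frame, so rigid-body
#' differences are part of the deviation.
#'
#' @param a,b [LigandPose-class] objects with identical atom layouts.
#' @return RMSD in Angstrom.
#' @export
poseRMSD <- function(a, b) {
  ia <- which(!a@atoms$hydrogen)
  ib <- which(!b@atoms$hydrogen)
  if (length(ia) != length(ib))
    stop("poses have different heavy-atom counts (",
         length(ia), " vs ", length(ib), ")")
  A <- as.matrix(a@atoms[ia, c("x", "y", "z")])
  B <- as.matrix(b@atoms[ib, c("x", "y", "z")])
  sqrt(mean(rowSums((A - B)^2)))
}

#' Cluster poses by RMSD (greedy leader algorithm)
#'
#' Poses are visited in order; each joins the first existing cluster
#' whose representative (the founding, lowest-index pose) lies within
#' the RMSD cutoff, otherwise it founds a new cluster.  Deterministic
#' given the pose order.
#'
#' @param posesList list of [LigandPose-class] of one ligand.
#' @param params a [ClusterParams-class] (default 1.0 A cutoff).
#' @return list of clusters, each a list with `representative` (pose
#'   index of the leader) and `members` (pose indices, leader first).
#' @export
clusterPoses <- function(posesList, params = clusterParams()) {
  if (!length(posesList)) stop("no poses to cluster")
  leaders <- integer(0)     # positions in posesList
  clusters <- list()
  for (k in seq_along(posesList)) {
    placed <- FALSE
    for (ci in seq_along(leaders)) {
      if (poseRMSD(posesList[[k]], posesList[[leaders[ci]]]) <=
          params@rmsdCutoff) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members,
                                    posesList[[k]]@poseIndex)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      leaders <- c(leaders, k)
      clusters[[length(clusters) + 1L]] <-
        list(representative = posesList[[k]]@poseIndex,
             members = posesList[[k]]@poseIndex)
    }
  }
  clusters
}

#' Extract binding-site residues from an averaged fingerprint
#'
#' Residues whose `any`-bit frequency reaches the threshold, in sequence
#' order, i.e. the residues contacted by at least that fraction of the
#' pose population.
#'
#' @param avg an [AveragedSIFt-class].
#' @param threshold frequency threshold in `[0, 1]` on the `any` bit.
#' @return character vector of residue labels (e.g. `"R71"`).
#' @export
bindingSiteResidues <- function(avg, threshold = 0.3) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (!nrow(avg@freq)) return(character(0))
  keep <- avg@freq[, "any"] >= threshold
  res <- avg@residues[keep, , drop = FALSE]
  res$label[order(res$chain, res$resno)]
}

#' @describeIn averageSIFt Tabular view of an averaged fingerprint
#'   (column order: amino acid then the nine bits).
#' @param x an [AveragedSIFt-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.AveragedSIFt <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(amino_acid = x@residues$label,
             as.data.frame(x@freq, row.names = NULL),
             check.names = FALSE, stringsAsFactors = FALSE)
}

#' @describeIn computeSIFt Long-format view of one fingerprint
#'   (residue, bit, value).
#' @param x a [SIFt-class].
#' @param row.names,optional,... ignored (S3 compatibility).
#' @export
as.data.frame.SIFt <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (!nrow(x@bits)) {
    return(data.frame(ligand = character(0), pose = integer(0),
                      residue = character(0), bit = character(0),
                      value = integer(0)))
  }
  data.frame(
    ligand = x@ligandId, pose = x@poseIndex,
    residue = rep(x@residues$label, each = 9L),
    bit = rep(BIT_NAMES, nrow(x@bits)),
    value = as.integer(t(x@bits)), stringsAsFactors = FALSE
  )
}

#' Write an averaged fingerprint as TSV
#'
#' Columns: amino acid then the nine bits in canonical order, values to
#' two decimals.
#'
#' @param avg an [AveragedSIFt-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAveragedSIFt <- function(avg, path) {
  df <- as.data.frame(avg)
  df[, -1L] <- lapply(df[, -1L, drop = FALSE],
                      function(v) sprintf("%.2f", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Compact bitstring of one fingerprint
#'
#' Concatenates the nine bits of every interacting residue (residue order
#' as stored) into a 0/1 string, a convenient per-pose signature.
#'
#' @param sift a [SIFt-class].
#' @return character scalar.
#' @export
siftBitstring <- function(sift) {
  paste(as.integer(t(sift@bits)), collapse = "")
}
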