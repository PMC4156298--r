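# Residue classification, receptor atom roles and aromatic-ring perception.

# Residue class membership.  Multi-label on purpose: fingerprint bits are
# per-interaction, and a residue such as Tyr legitimately makes polar,
# hydrophobic and aromatic contacts.
RESIDUE_CLASSES <- list(
  polar = c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "HIS",
            "LYS", "ARG", "ASP", "GLU"),
  hydrophobic = c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP",
                  "PRO", "GLY", "TYR"),
  aromatic = c("PHE", "TYR", "TRP", "HIS"),
  charged = c("ASP", "GLU", "LYS", "ARG", "HIS")
)

# Sidechain hydrogen-bond donors / acceptors / formal charges by residue.
SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
  ASN = "ND2", GLN = "NE2", HIS = c("ND1", "NE2"),
  LYS = "NZ", ARG = c("NE", "NH1", "NH2"), TRP = "NE1"
)
SIDECHAIN_ACCEPTORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH",
  ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), MET = "SD"
)
SIDECHAIN_CATIONS <- list(
  LYS = "NZ", ARG = c("NE", "NH1", "NH2")
)
SIDECHAIN_ANIONS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2")
)

# Aromatic ring atom names, in ring order, per residue (TRP has two).
RING_ATOMS <- list(
  PHE = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  TYR = list(c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")),
  HIS = list(c("CG", "ND1", "CE1", "NE2", "CD2")),
  TRP = list(c("CG", "CD1", "NE1", "CE2", "CD2"),
             c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"))
)

RING_PLANARITY_TOL <- 0.2  # A, max out-of-plane deviation for aromaticity

#' Classify a residue into interaction classes
#'
#' Residues are grouped into four (overlapping) classes: polar,
#' hydrophobic, aromatic and charged.  Membership is fixed by a standard
#' chemistry table; e.g. Tyr is polar, hydrophobic and aromatic, Lys is
#' polar and charged, Val is hydrophobic.
#'
#' @param name three-letter residue code (case-insensitive).
#' @return character vector of classes (subset of `"polar"`,
#'   `"hydrophobic"`, `"aromatic"`, `"charged"`); empty with a warning for
#'   unknown codes.
#' @examples
#' classifyResidue("TYR")
#' classifyResidue("val")
#' @export
classifyResidue <- function(name) {
  nm <- toupper(name)
  if (!nm %in% unlist(RESIDUE_CLASSES)) {
    if (!nm %in% names(AA_3TO1))
      warning("unknown residue code: ", name)
    return(character(0))
  }
  names(RESIDUE_CLASSES)[vapply(RESIDUE_CLASSES, function(m) nm %in% m,
                                logical(1))]
}

buildRing <- function(xyz, atomIdx, label) {
  list(atoms = atomIdx, centroid = colMeans(xyz),
       normal = planeNormal(xyz), label = label)
}

#' Assign chemistry roles to receptor atoms
#'
#' Flags hydrogen-bond donors (backbone N, sidechain N/O donors such as
#' Lys NZ or Arg NH1/NH2), acceptors (carbonyl and carboxylate O, hydroxyl
#' O, His ring N), cations (Lys NZ, Arg guanidinium N), anions (Asp/Glu
#' carboxylate O and the C-terminal OXT) and aromatic-ring members
#' (Phe/Tyr/Trp/His ring atoms), and builds one ring object per complete
#' aromatic ring (centroid plus best-fit plane normal).  Unknown atoms are
#' left role-free.  Backbone N of proline is not a donor (no amide H).
#'
#' @param structure a [TypedStructure-class].
#' @return the structure with roles, rings and `typed = TRUE`.
#' @export
assignAtomRoles <- function(structure) {
  a <- structure@atoms
  prot <- !a$het & !a$water & !a$hydrogen
  resn <- toupper(a$resname)

  a$donor <- prot & ((a$name == "N" & resn != "PRO") |
    mapply(function(r, nm) nm %in% (SIDECHAIN_DONORS[[r]] %||% character(0)),
           resn, a$name))
  a$acceptor <- prot & (a$name %in% c("O", "OXT") |
    mapply(function(r, nm) nm %in% (SIDECHAIN_ACCEPTORS[[r]] %||% character(0)),
           resn, a$name))
  a$cation <- prot &
    mapply(function(r, nm) nm %in% (SIDECHAIN_CATIONS[[r]] %||% character(0)),
           resn, a$name)
  a$anion <- prot & (a$name == "OXT" |
    mapply(function(r, nm) nm %in% (SIDECHAIN_ANIONS[[r]] %||% character(0)),
           resn, a$name))

  ringList <- list()
  a$aromatic <- FALSE
  resKey <- paste(a$chain, a$resno, sep = "|")
  for (key in unique(resKey[prot & resn %in% names(RING_ATOMS)])) {
    rows <- which(resKey == key & prot)
    rname <- toupper(a$resname[rows[1L]])
    for (ringNames in RING_ATOMS[[rname]]) {
      idx <- rows[match(ringNames, a$name[rows])]
      if (anyNA(idx)) next  # incomplete sidechain
      xyz <- as.matrix(a[idx, c("x", "y", "z")])
      if (planarity(xyz) > RING_PLANARITY_TOL) next
      a$aromatic[idx] <- TRUE
      ringList[[length(ringList) + 1L]] <-
        buildRing(xyz, idx, residueLabel(rname, a$resno[idx[1L]]))
    }
  }
  new("TypedStructure", atoms = a, rings = ringList, typed = TRUE)
}

# ---- ligand perception -----------------------------------------------------

# Heavy-atom (plus H) bond graph from covalent radii: bonded when the
# distance is below r1 + r2 + 0.45 A.  Returns an adjacency list.
bondGraph <- function(atoms) {
  n <- nrow(atoms)
  adj <- vector("list", n)
  if (n < 2L) return(adj)
  radii <- COVALENT_RADII[atoms$element]
  radii[is.na(radii)] <- 0.77
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  thr <- outer(radii, radii, "+") + 0.45
  bonded <- d > 0.1 & d <= thr
  for (i in seq_len(n)) adj[[i]] <- which(bonded[i, ])
  adj
}

# All unique simple cycles of length 5 or 6 in an adjacency list,
# by bounded DFS from each vertex with canonical deduplication.
findSmallCycles <- function(adj) {
  n <- length(adj)
  seen <- new.env(parent = emptyenv())
  cycles <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == path[1L] && length(path) >= 5L) {
        key <- paste(sort(path), collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          cycles[[length(cycles) + 1L]] <<- path
        }
      } else if (!(nb %in% path) && length(path) < 6L && nb > path[1L]) {
        recurse(c(path, nb))
      }
    }
  }
  for (v in seq_len(n)) recurse(v)
  cycles
}

#' Perceive aromatic rings in a ligand pose
#'
#' Builds a bond graph from a covalent-radius distance rule, detects
#' 5- and 6-membered cycles, and flags a cycle as an aromatic ring when
#' all members are C/N/O/S and the ring is planar (out-of-plane deviation
#' below 0.2 A, which excludes chair-puckered saturated rings).
#'
#' @param pose a [LigandPose-class].
#' @return list of rings (`atoms` indices, `centroid`, `normal`,
#'   `label`); empty for acyclic ligands.
#' @export
perceiveLigandRings <- function(pose) {
  a <- pose@atoms
  heavy <- which(!a$hydrogen)
  if (length(heavy) < 5L) return(list())
  adj <- bondGraph(a[heavy, , drop = FALSE])
  cycles <- findSmallCycles(adj)
  out <- list()
  for (cyc in cycles) {
    idx <- heavy[cyc]
    if (!all(a$element[idx] %in% c("C", "N", "O", "S"))) next
    xyz <- as.matrix(a[idx, c("x", "y", "z")])
    if (planarity(xyz) > RING_PLANARITY_TOL) next
    out[[length(out) + 1L]] <- buildRing(xyz, idx, pose@ligandId)
  }
  out
}

# Generic ligand role perception used by readPDBQT and the synthetic
# complex builder.  Donors: N/O carrying an explicit hydrogen, or any N/O
# when the pose has no hydrogens (distance-only fallback).  Acceptors:
# all N/O.  Cations: N bonded only to C/H and not adjacent to a carbonyl
# carbon (amine/guanidinium-like).  Anions: carboxylate-pattern O
# (terminal O on a carbon bearing two terminal oxygens).
annotateLigand <- function(pose) {
  a <- pose@atoms
  adj <- bondGraph(a)
  hasH <- any(a$hydrogen)
  isNO <- a$element %in% c("N", "O")
  a$acceptor <- isNO
  if (hasH) {
    a$donor <- isNO & vapply(seq_len(nrow(a)), function(i)
      any(a$hydrogen[adj[[i]]]), logical(1))
  } else {
    a$donor <- isNO
  }
  carbonyl <- function(ci) {
    any(a$element[adj[[ci]]] == "O" &
          vapply(adj[[ci]], function(j) {
            a$element[j] == "O" &&
              vnorm(unlist(a[ci, c("x", "y", "z")]) -
                      unlist(a[j, c("x", "y", "z")])) <= 1.32
          }, logical(1)))
  }
  a$cation <- vapply(seq_len(nrow(a)), function(i) {
    if (a$element[i] != "N") return(FALSE)
    nbr <- adj[[i]]
    if (length(nbr) && !all(a$element[nbr] %in% c("C", "H"))) return(FALSE)
    cNbr <- nbr[a$element[nbr] == "C"]
    !any(vapply(cNbr, carbonyl, logical(1)))
  }, logical(1))
  a$anion <- vapply(seq_len(nrow(a)), function(i) {
    if (a$element[i] != "O") return(FALSE)
    nbr <- adj[[i]][!a$hydrogen[adj[[i]]]]
    if (length(nbr) != 1L || a$element[nbr] != "C") return(FALSE)
    cNbr <- adj[[nbr]]
    oTerm <- cNbr[a$element[cNbr] == "O" &
                    vapply(cNbr, function(j)
                      sum(!a$hydrogen[adj[[j]]]) == 1L, logical(1))]
    length(oTerm) >= 2L
  }, logical(1))
  pose@atoms <- a
  pose@rings <- perceiveLigandRings(pose)
  ringIdx <- unlist(lapply(pose@rings, `[[`, "atoms"))
  pose@atoms$aromatic <- seq_len(nrow(a)) %in% ringIdx
  pose
}
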