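# Synthetic-fixture generators: receptor/pose complexes with planted
# interactions at exact geometries, pose ensembles with prescribed
# per-residue bit frequencies, and noisy saturation-kinetics datasets.
#
# The receptor scaffold places one residue per planted interaction on a
# widely spaced grid (default 20 A), so each probe can only register
# against its own residue and every bit is isolated for testing.  Each
# amino acid has one minimal pseudo-residue template carrying just the
# atoms its roles need (e.g. Tyr = backbone + ring + OH), not a rotamer
# library.

# ---- residue templates -----------------------------------------------------

# Regular n-gon of circumradius r in the z = z0 plane, centered at (cx, cy).
ringCoords <- function(n, r, cx, cy, z0, phase = pi / 2) {
  ang <- phase + 2 * pi * (seq_len(n) - 1L) / n
  cbind(x = cx + r * cos(ang), y = cy + r * sin(ang), z = z0)
}

# Remaining vertices of a regular n-gon that has A and B (2D, adjacent,
# in cyclic order A -> ... -> B) as one edge; returns the n - 2 vertices
# between A and B going the long way round.
polygonFromEdge <- function(A, B, n) {
  s <- vnorm(B - A)
  apo <- s / (2 * tan(pi / n))
  mid <- (A + B) / 2
  u <- c(-(B - A)[2L], (B - A)[1L]) / s   # perpendicular to AB
  for (center in list(mid + apo * u, mid - apo * u)) {
    thA <- atan2(A[2L] - center[2L], A[1L] - center[1L])
    thB <- atan2(B[2L] - center[2L], B[1L] - center[1L])
    delta <- -((thB - thA + pi) %% (2 * pi) - pi)  # step away from B
    R <- vnorm(A - center)
    verts <- t(vapply(seq_len(n - 2L), function(k)
      center + R * c(cos(thA + k * delta), sin(thA + k * delta)),
      numeric(2)))
    # both centers give congruent polygons; first is fine
    return(verts)
  }
}

templateAtoms <- function(resname) {
  resname <- toupper(resname)
  rows <- list()
  addAtom <- function(name, element, x, y, z) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, element = element, x = x, y = y, z = z,
      stringsAsFactors = FALSE)
  }
  addRingAtoms <- function(names, xyz) {
    for (k in seq_along(names))
      addAtom(names[k], substr(names[k], 1, 1), xyz[k, 1], xyz[k, 2],
              xyz[k, 3])
  }
  # backbone
  addAtom("N", "N", 0, 0, 0)
  addAtom("CA", "C", 1.46, 0, 0)
  addAtom("C", "C", 2.00, 1.25, 0)
  addAtom("O", "O", 1.45, 2.35, 0)
  cb <- c(1.20, -1.40, 0.60)
  if (resname != "GLY") addAtom("CB", "C", cb[1], cb[2], cb[3])

  hexNames <- c("CG", "CD1", "CE1", "CZ", "CE2", "CD2")
  switch(resname,
    GLY = , ALA = NULL,
    VAL = {
      addAtom("CG1", "C", cb[1] + 0.95, cb[2] - 1.10, cb[3] + 0.45)
      addAtom("CG2", "C", cb[1] + 1.35, cb[2] + 0.40, cb[3] - 0.55)
    },
    LEU = {
      addAtom("CG", "C", cb[1] + 0.85, cb[2] - 1.20, cb[3] + 0.30)
      addAtom("CD1", "C", cb[1] + 2.10, cb[2] - 1.10, cb[3] + 1.05)
      addAtom("CD2", "C", cb[1] + 0.80, cb[2] - 2.55, cb[3] - 0.25)
    },
    ILE = {
      addAtom("CG1", "C", cb[1] + 0.85, cb[2] - 1.20, cb[3] + 0.30)
      addAtom("CG2", "C", cb[1] + 1.35, cb[2] + 0.40, cb[3] - 0.55)
      addAtom("CD1", "C", cb[1] + 2.10, cb[2] - 2.05, cb[3] + 0.70)
    },
    PRO = {
      addAtom("CG", "C", cb[1] + 0.35, cb[2] - 1.15, cb[3] + 0.85)
      addAtom("CD", "C", -0.45, -1.25, 0.55)
    },
    SER = addAtom("OG", "O", cb[1] + 0.85, cb[2] - 1.05, cb[3] + 0.35),
    THR = {
      addAtom("OG1", "O", cb[1] + 0.85, cb[2] - 1.05, cb[3] + 0.35)
      addAtom("CG2", "C", cb[1] + 1.30, cb[2] + 0.50, cb[3] - 0.45)
    },
    CYS = addAtom("SG", "S", cb[1] + 1.00, cb[2] - 1.35, cb[3] + 0.45),
    MET = {
      addAtom("CG", "C", cb[1] + 0.85, cb[2] - 1.20, cb[3] + 0.30)
      addAtom("SD", "S", cb[1] + 2.05, cb[2] - 2.20, cb[3] + 0.70)
      addAtom("CE", "C", cb[1] + 3.45, cb[2] - 1.55, cb[3] + 1.25)
    },
    ASN = {
      addAtom("CG", "C", cb[1] + 0.90, cb[2] - 1.10, cb[3])
      addAtom("OD1", "O", cb[1] + 0.90, cb[2] - 2.33, cb[3])
      addAtom("ND2", "N", cb[1] + 2.07, cb[2] - 0.50, cb[3])
    },
    GLN = {
      addAtom("CG", "C", cb[1] + 0.85, cb[2] - 1.20, cb[3] + 0.30)
      addAtom("CD", "C", cb[1] + 2.05, cb[2] - 2.00, cb[3] + 0.30)
      addAtom("OE1", "O", cb[1] + 2.05, cb[2] - 3.23, cb[3] + 0.30)
      addAtom("NE2", "N", cb[1] + 3.22, cb[2] - 1.40, cb[3] + 0.30)
    },
    ASP = {
      addAtom("CG", "C", cb[1] + 0.90, cb[2] - 1.10, cb[3])
      addAtom("OD1", "O", cb[1] + 0.90, cb[2] - 2.35, cb[3])
      addAtom("OD2", "O", cb[1] + 1.91, cb[2] - 0.37, cb[3])
    },
    GLU = {
      addAtom("CG", "C", cb[1] + 0.85, cb[2] - 1.20, cb[3] + 0.30)
      addAtom("CD", "C", cb[1] + 2.05, cb[2] - 2.00, cb[3] + 0.30)
      addAtom("OE1", "O", cb[1] + 2.05, cb[2] - 3.25, cb[3] + 0.30)
      addAtom("OE2", "O", cb[1] + 3.06, cb[2] - 1.27, cb[3] + 0.30)
    },
    LYS = {
      addAtom("CG", "C", cb[1] + 0.85, cb[2] - 1.20, cb[3] + 0.25)
      addAtom("CD", "C", cb[1] + 1.70, cb[2] - 2.40, cb[3] + 0.50)
      addAtom("CE", "C", cb[1] + 2.55, cb[2] - 3.60, cb[3] + 0.75)
      addAtom("NZ", "N", cb[1] + 3.40, cb[2] - 4.80, cb[3] + 1.00)
    },
    ARG = {
      addAtom("CG", "C", cb[1] + 0.85, cb[2] - 1.20, cb[3] + 0.25)
      addAtom("CD", "C", cb[1] + 1.70, cb[2] - 2.40, cb[3] + 0.50)
      addAtom("NE", "N", cb[1] + 2.55, cb[2] - 3.55, cb[3] + 0.75)
      addAtom("CZ", "C", cb[1] + 3.75, cb[2] - 4.10, cb[3] + 0.75)
      addAtom("NH1", "N", cb[1] + 3.95, cb[2] - 5.42, cb[3] + 0.75)
      addAtom("NH2", "N", cb[1] + 4.80, cb[2] - 3.30, cb[3] + 0.75)
    },
    HIS = {
      xyz <- ringCoords(5, 1.37 / (2 * sin(pi / 5)), cb[1] + 1.2,
                        cb[2] - 2.0, cb[3])
      addRingAtoms(c("CG", "ND1", "CE1", "NE2", "CD2"), xyz)
    },
    PHE = , TYR = {
      xyz <- ringCoords(6, 1.39, cb[1] + 1.5, cb[2] - 2.3, cb[3])
      addRingAtoms(hexNames, xyz)
      if (resname == "TYR") {
        cz <- xyz[4L, ]
        ctr <- c(cb[1] + 1.5, cb[2] - 2.3, cb[3])
        dir <- (cz - ctr) / vnorm(cz - ctr)
        addAtom("OH", "O", cz[1] + 1.38 * dir[1], cz[2] + 1.38 * dir[2],
                cz[3] + 1.38 * dir[3])
      }
    },
    TRP = {
      hx <- ringCoords(6, 1.39, cb[1] + 2.8, cb[2] - 2.6, cb[3])
      addRingAtoms(c("CD2", "CE2", "CZ2", "CH2", "CZ3", "CE3"), hx)
      penta <- polygonFromEdge(hx[1L, 1:2], hx[2L, 1:2], 5L)
      addRingAtoms(c("CG", "CD1", "NE1"),
                   cbind(penta, cb[3]))
    },
    stop("no template for residue ", resname)
  )
  do.call(rbind, rows)
}

# ---- receptor scaffold -----------------------------------------------------

# Build a synthetic receptor with the given residues placed along x at
# `spacing` Angstrom; returns an untyped TypedStructure.
buildScaffold <- function(resnames, resnos, spacing = 20, chain = "A") {
  stopifnot(length(resnames) == length(resnos),
            !anyDuplicated(resnos), spacing >= 15)
  parts <- vector("list", length(resnames))
  for (i in seq_along(resnames)) {
    t <- templateAtoms(resnames[i])
    t$x <- t$x + spacing * (i - 1L)
    parts[[i]] <- data.frame(
      serial = 0L, name = t$name, resname = toupper(resnames[i]),
      chain = chain, resno = as.integer(resnos[i]),
      x = t$x, y = t$y, z = t$z, element = t$element,
      het = FALSE, water = FALSE, hydrogen = FALSE,
      backbone = t$name %in% c("N", "CA", "C", "O", "OXT"),
      donor = FALSE, acceptor = FALSE, cation = FALSE, anion = FALSE,
      aromatic = FALSE, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, parts)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  new("TypedStructure", atoms = atoms, rings = list(), typed = FALSE)
}

# ---- planted probes --------------------------------------------------------

DEFAULT_PROBE_RESIDUE <- c(
  any = "GLY", backbone = "GLY", sidechain = "VAL", hydrophobic = "VAL",
  polar = "SER", hbond_acceptor = "ASN", hbond_donor = "ARG",
  aromatic = "TYR", charged = "LYS"
)

# Distances (A) that satisfy each bit under the default parameters.
DEFAULT_SATISFY <- c(
  any = 3.5, backbone = 3.5, sidechain = 3.5, hydrophobic = 3.5,
  polar = 3.6, hbond_acceptor = 2.9, hbond_donor = 2.9,
  aromatic = 4.0, charged = 3.5
)
VIOLATE_DISTANCE <- 9.0

# Receptor atom name targeted by a planted bit on a given residue.
targetAtomFor <- function(bit, resname) {
  resname <- toupper(resname)
  firstOf <- function(tab, fallback = NULL) {
    v <- tab[[resname]]
    if (!is.null(v)) v[1L] else fallback
  }
  switch(bit,
    backbone = "N",
    any = if (resname == "GLY") "CA" else "CB",
    sidechain = , hydrophobic = {
      if (resname == "GLY")
        stop("glycine has no sidechain atom to plant a ", bit, " contact")
      "CB"
    },
    polar = firstOf(SIDECHAIN_ACCEPTORS, firstOf(SIDECHAIN_DONORS, "O")),
    hbond_acceptor = firstOf(SIDECHAIN_ACCEPTORS, "O"),
    hbond_donor = firstOf(SIDECHAIN_DONORS, "N"),
    charged = {
      at <- firstOf(SIDECHAIN_CATIONS, firstOf(SIDECHAIN_ANIONS))
      if (is.null(at))
        stop(resname, " carries no formal charge for a charged contact")
      at
    },
    aromatic = {
      if (!resname %in% names(RING_ATOMS))
        stop(resname, " is not aromatic")
      NA_character_  # ring-level target
    },
    stop("unknown bit: ", bit)
  )
}

# Ligand probe atoms realizing one planted interaction at distance `d`
# from the receptor target.  Near-range (satisfying) probes leave the
# residue outward along `outDir` (centroid-to-target direction), so the
# measured distance is to the intended atom; long-range (violating)
# probes leave along -z, perpendicular to the flat residue templates,
# so they cannot graze the residue's own sidechain on the way out.
# Returns a data.frame of atoms.
probeAtoms <- function(bit, resname, targetXYZ, ringNormal, d,
                       hAngle = NULL, tag = "", outDir = c(0, -1, 0)) {
  resname <- toupper(resname)
  atom <- function(name, element, xyz) {
    data.frame(name = paste0(name, tag), element = element,
               x = xyz[1], y = xyz[2], z = xyz[3],
               stringsAsFactors = FALSE)
  }
  u <- if (d <= 5) outDir else c(0, 0, -1)        # probe direction
  # any unit vector perpendicular to u
  p <- c(-u[2L], u[1L], 0)
  if (vnorm(p) < 1e-6) p <- c(1, 0, 0)
  p <- p / vnorm(p)
  below <- function(dd) targetXYZ + dd * u
  switch(bit,
    any = , backbone = , sidechain = , hydrophobic =
      atom("C", "C", below(d)),
    polar = atom("O", "O", below(d)),
    hbond_acceptor = {
      D <- below(d)
      out <- atom("N", "N", D)
      if (!is.null(hAngle)) {
        # place H 1.0 A from the donor so the angle at H between
        # H->donor and H->acceptor equals hAngle (degrees)
        e <- (targetXYZ - D) / d
        angleAt <- function(phi) {
          H <- D + cos(phi) * e + sin(phi) * p
          hd <- D - H; ha <- targetXYZ - H
          acos(pmin(1, pmax(-1, sum(hd * ha) /
                              (vnorm(hd) * vnorm(ha))))) * 180 / pi
        }
        phi <- stats::uniroot(function(x) angleAt(x) - hAngle,
                              c(1e-6, pi - 1e-6))$root
        H <- D + cos(phi) * e + sin(phi) * p
        out <- rbind(out, atom("H", "H", H))
      }
      out
    },
    hbond_donor = atom("O", "O", below(d)),
    charged = {
      if (resname %in% names(SIDECHAIN_CATIONS)) {
        # carboxylate anion probe: O1 at distance d, then C and O2 with
        # an O-C-O angle of 126 degrees (C->O1 points back at the
        # target, C->O2 splays off it)
        O1 <- below(d)
        C <- O1 + 1.25 * u
        O2 <- C + 1.25 * (sin(126 * pi / 180) * p -
                            cos(126 * pi / 180) * u)
        rbind(atom("O1", "O", O1), atom("C", "C", C), atom("O2", "O", O2))
      } else {
        atom("N", "N", below(d))  # ammonium-like cation probe
      }
    },
    aromatic = {
      # parallel benzene ring with centroid at distance d along the
      # receptor-ring normal
      ctr <- targetXYZ + d * ringNormal
      xyz <- ringCoords(6, 1.39, ctr[1], ctr[2], ctr[3])
      do.call(rbind, lapply(seq_len(6), function(k)
        atom(paste0("C", k), "C", xyz[k, ])))
    },
    stop("unknown bit: ", bit)
  )
}

normalizeInteractions <- function(interactions) {
  out <- vector("list", length(interactions))
  for (i in seq_along(interactions)) {
    it <- interactions[[i]]
    if (is.null(it$bit) || !it$bit %in% BIT_NAMES[-1L] && it$bit != "any")
      stop("interaction ", i, " needs a valid 'bit'")
    it$residue <- toupper(it$residue %||% DEFAULT_PROBE_RESIDUE[[it$bit]])
    it$resno <- it$resno %||% (10L * i)
    it$distance <- it$distance %||% DEFAULT_SATISFY[[it$bit]]
    out[[i]] <- it
  }
  resnos <- vapply(out, `[[`, numeric(1), "resno")
  if (anyDuplicated(resnos))
    stop("planted interactions must use distinct residue numbers")
  out
}

buildPlantedPose <- function(receptor, specs, distances, ligandId,
                             poseIndex) {
  ra <- receptor@atoms
  parts <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    it <- specs[[i]]
    if (it$bit == "aromatic") {
      lab <- residueLabel(it$residue, it$resno)
      ring <- Filter(function(r) r$label == lab, receptor@rings)
      if (!length(ring))
        stop("no aromatic ring on residue ", lab, " to target")
      parts[[i]] <- probeAtoms(it$bit, it$residue, ring[[1L]]$centroid,
                               ring[[1L]]$normal, distances[i],
                               tag = as.character(i))
    } else {
      atName <- targetAtomFor(it$bit, it$residue)
      row <- which(ra$resno == it$resno & ra$name == atName)
      if (!length(row))
        stop("target atom ", atName, " not found on residue ", it$resno)
      target <- unlist(ra[row[1L], c("x", "y", "z")])
      resRows <- which(ra$resno == it$resno)
      outDir <- target - colMeans(ra[resRows, c("x", "y", "z")])
      outDir <- if (vnorm(outDir) < 1e-6) c(0, -1, 0)
                else outDir / vnorm(outDir)
      parts[[i]] <- probeAtoms(it$bit, it$residue, target,
                               NULL, distances[i], hAngle = it$hAngle,
                               tag = as.character(i), outDir = outDir)
    }
  }
  atoms <- do.call(rbind, parts)
  if (anyDuplicated(round(atoms[, c("x", "y", "z")], 6)))
    stop("contradictory spec: two ligand atoms forced to one position")
  n <- nrow(atoms)
  full <- data.frame(
    serial = seq_len(n), name = atoms$name, resname = "LIG",
    chain = "X", resno = 1L, x = atoms$x, y = atoms$y, z = atoms$z,
    element = atoms$element, het = TRUE, water = FALSE,
    hydrogen = atoms$element == "H", backbone = FALSE,
    donor = FALSE, acceptor = FALSE, cation = FALSE, anion = FALSE,
    aromatic = FALSE, stringsAsFactors = FALSE)
  annotateLigand(new("LigandPose", ligandId = ligandId,
                     poseIndex = as.integer(poseIndex), atoms = full,
                     rings = list()))
}

#' Build a synthetic receptor-ligand complex with planted interactions
#'
#' Each planted interaction gets its own scaffold residue and a minimal
#' ligand probe placed at the exact stated geometry: a carbon for
#' contact/hydrophobic bits, an oxygen or nitrogen for polar and
#' hydrogen-bond bits, a carboxylate or ammonium group for salt bridges,
#' and a parallel benzene ring for aromatic contacts.  Distances beyond
#' the corresponding cutoff plant a deliberate violation.
#'
#' @param interactions list of interactions; each a list with `bit`
#'   (one of the nine bit names), optional `residue` (three-letter code;
#'   a sensible default per bit), optional `resno`, optional `distance`
#'   (A; defaults to a geometry satisfying the bit under default
#'   parameters) and optional `hAngle` (degrees, for
#'   `bit = "hbond_acceptor"`: plants an explicit hydrogen realizing
#'   that D-H...A angle).
#' @param spacing scaffold spacing in A (>= 15 so that only planted
#'   interactions register).
#' @param ligandId identifier for the synthetic ligand.
#' @return a [PoseEnsemble-class] with one pose.
#' @examples
#' cx <- makeComplex(list(list(bit = "hydrophobic", distance = 3.5)))
#' computeSIFt(receptor(cx), poses(cx)[[1]])
#' @export
makeComplex <- function(interactions, spacing = 20,
                        ligandId = "synthetic-ligand") {
  specs <- normalizeInteractions(interactions)
  rec <- assignAtomRoles(buildScaffold(
    vapply(specs, `[[`, character(1), "residue"),
    vapply(specs, `[[`, numeric(1), "resno"), spacing = spacing))
  pose <- buildPlantedPose(rec, specs,
                           vapply(specs, `[[`, numeric(1), "distance"),
                           ligandId, 0L)
  new("PoseEnsemble", receptor = rec, poses = list(pose))
}

#' Sample a pose ensemble with prescribed bit frequencies
#'
#' Generates `nPoses` poses over one scaffold receptor; each pose
#' independently realizes each planted bit with probability `f` by
#' toggling the probe between a satisfying and a violating geometry
#' (with `exact = TRUE`, exactly `round(f * nPoses)` poses satisfy each
#' bit, assigned by a seeded shuffle).  Deterministic given `seed`.
#'
#' @param targets list of targets; each a list with `bit`, `f` in
#'   `[0, 1]`, and optional `residue`/`resno` as in [makeComplex()].
#' @param nPoses number of poses (>= 1).
#' @param seed integer seed for the generator.
#' @param exact realize exact counts instead of independent Bernoulli
#'   draws.
#' @param spacing scaffold spacing in A.
#' @param ligandId ligand identifier.
#' @return a [PoseEnsemble-class] with `nPoses` poses.
#' @examples
#' ens <- sampleEnsemble(list(list(bit = "aromatic", f = 1)), nPoses = 5,
#'                       seed = 1)
#' @export
sampleEnsemble <- function(targets, nPoses, seed, exact = FALSE,
                           spacing = 20, ligandId = "synthetic-ligand") {
  stopifnot(nPoses >= 1)
  specs <- normalizeInteractions(targets)
  f <- vapply(specs, function(t) t$f %||% 1.0, numeric(1))
  stopifnot(all(f >= 0), all(f <= 1))
  rec <- assignAtomRoles(buildScaffold(
    vapply(specs, `[[`, character(1), "residue"),
    vapply(specs, `[[`, numeric(1), "resno"), spacing = spacing))
  satisfyD <- vapply(specs, `[[`, numeric(1), "distance")
  sat <- withSeed(seed, {
    if (exact) {
      vapply(f, function(fi) {
        k <- round(fi * nPoses)
        s <- logical(nPoses)
        s[sample.int(nPoses, k)] <- TRUE
        s
      }, logical(nPoses))
    } else {
      vapply(f, function(fi) stats::runif(nPoses) < fi, logical(nPoses))
    }
  })
  sat <- matrix(sat, nrow = nPoses)
  posesList <- lapply(seq_len(nPoses), function(p) {
    d <- ifelse(sat[p, ], satisfyD, VIOLATE_DISTANCE)
    buildPlantedPose(rec, specs, d, ligandId, p - 1L)
  })
  new("PoseEnsemble", receptor = rec, poses = posesList)
}

#' Simulate a noisy saturation-kinetics dataset
#'
#' Velocities follow the Hill equation with multiplicative Gaussian
#' noise: v = Vmax * S^h / (Km^h + S^h) * (1 + eps), eps ~ N(0, cv)
#' truncated at -0.99 so velocities stay positive.  Deterministic given
#' `seed`.  Defaults emulate a fluorogenic protease assay read in
#' triplicate over 10 substrate concentrations log-spaced across
#' 0.5--400 uM.
#'
#' @param kcat turnover number, min^-1.
#' @param Km half-saturation constant, uM.
#' @param h Hill coefficient.
#' @param enzymeConc enzyme concentration, uM (Vmax = kcat x
#'   `enzymeConc`).
#' @param conc substrate grid, uM.
#' @param replicates replicate count per concentration.
#' @param cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @return data.frame with `substrate_conc_uM`, `velocity`, `replicate`.
#' @examples
#' head(simulateKinetics(kcat = 0.646, Km = 12, seed = 42))
#' @export
simulateKinetics <- function(kcat, Km, h = 1, enzymeConc = 1,
                             conc = logSpace(0.5, 400, 10),
                             replicates = 3, cv = 0.03, seed) {
  stopifnot(cv >= 0, replicates >= 1, all(conc >= 0))
  Vmax <- kcat * enzymeConc
  S <- rep(conc, times = replicates)
  mu <- hillVelocity(S, Vmax, Km, h)
  eps <- withSeed(seed, stats::rnorm(length(S), 0, cv))
  eps <- pmax(eps, -0.99)
  data.frame(substrate_conc_uM = S, velocity = mu * (1 + eps),
             replicate = rep(seq_len(replicates), each = length(conc)))
}
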