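# Shared fixture builders and independent oracles for the test suite.

BITS9 <- c("any", "backbone", "sidechain", "polar", "hydrophobic",
           "hbond_acceptor", "hbond_donor", "aromatic", "charged")

# Build a TypedStructure from a minimal atom spec (name, resname, chain,
# resno, x, y, z, element), with roles assigned.
makeStructure <- function(df, assignRoles = TRUE) {
  n <- nrow(df)
  atoms <- data.frame(
    serial = seq_len(n), name = df$name, resname = toupper(df$resname),
    chain = df$chain %||% "A", resno = as.integer(df$resno),
    x = df$x, y = df$y, z = df$z, element = df$element,
    het = FALSE, water = FALSE, hydrogen = df$element == "H",
    backbone = df$name %in% c("N", "CA", "C", "O", "OXT"),
    donor = FALSE, acceptor = FALSE, cation = FALSE, anion = FALSE,
    aromatic = FALSE, stringsAsFactors = FALSE)
  s <- new("TypedStructure", atoms = atoms, rings = list(), typed = FALSE)
  if (assignRoles) assignAtomRoles(s) else s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a bare LigandPose from name/element/xyz rows (roles perceived).
makePose <- function(df, ligandId = "lig", poseIndex = 0L) {
  n <- nrow(df)
  atoms <- data.frame(
    serial = seq_len(n), name = df$name, resname = "LIG", chain = "X",
    resno = 1L, x = df$x, y = df$y, z = df$z, element = df$element,
    het = TRUE, water = FALSE, hydrogen = df$element == "H",
    backbone = FALSE, donor = FALSE, acceptor = FALSE, cation = FALSE,
    anion = FALSE, aromatic = FALSE, stringsAsFactors = FALSE)
  SIFtKit:::annotateLigand(new("LigandPose", ligandId = ligandId,
                               poseIndex = as.integer(poseIndex),
                               atoms = atoms, rings = list()))
}

translatePose <- function(pose, dx = 0, dy = 0, dz = 0, poseIndex = NULL) {
  pose@atoms$x <- pose@atoms$x + dx
  pose@atoms$y <- pose@atoms$y + dy
  pose@atoms$z <- pose@atoms$z + dz
  for (i in seq_along(pose@rings))
    pose@rings[[i]]$centroid <- pose@rings[[i]]$centroid + c(dx, dy, dz)
  if (!is.null(poseIndex)) pose@poseIndex <- as.integer(poseIndex)
  pose
}

# Regular hexagon (benzene-like) coordinates in the z = z0 plane.
hexagonXYZ <- function(cx = 0, cy = 0, z0 = 0, r = 1.39, phase = 0) {
  ang <- phase + 2 * pi * (0:5) / 6
  data.frame(name = paste0("C", 1:6), element = "C",
             x = cx + r * cos(ang), y = cy + r * sin(ang), z = z0,
             stringsAsFactors = FALSE)
}

# ---- oracles ---------------------------------------------------------------

# All-pairs brute-force contact oracle (no spatial binning).
bruteContacts <- function(receptor, pose, cutoff) {
  ra <- atoms(receptor)
  la <- atoms(pose)
  out <- data.frame(receptorAtom = integer(0), ligandAtom = integer(0),
                    distance = numeric(0))
  for (i in which(!ra$hydrogen & !ra$water)) {
    for (j in which(!la$hydrogen & !la$water)) {
      d <- sqrt((ra$x[i] - la$x[j])^2 + (ra$y[i] - la$y[j])^2 +
                  (ra$z[i] - la$z[j])^2)
      if (d <= cutoff)
        out <- rbind(out, data.frame(receptorAtom = i, ligandAtom = j,
                                     distance = d))
    }
  }
  out
}

# Independent all-pairs re-derivation of the nine bits (loops, no
# neighbor search), returning a residue-label -> bit matrix.
bruteSIFt <- function(receptor, pose, params = interactionParams()) {
  ra <- atoms(receptor)
  la <- atoms(pose)
  xyzR <- as.matrix(ra[, c("x", "y", "z")])
  xyzL <- as.matrix(la[, c("x", "y", "z")])
  attachedH <- function(tab, xyz, k) {
    which(tab$hydrogen &
            sqrt(colSums((t(xyz) - xyz[k, ])^2)) <= 1.25 &
            seq_len(nrow(tab)) != k)
  }
  hbOK <- function(dTab, dXyz, dIdx, aXyz) {
    hs <- attachedH(dTab, dXyz, dIdx)
    if (!length(hs)) return(TRUE)
    for (h in hs) {
      hd <- dXyz[dIdx, ] - dXyz[h, ]
      ha <- aXyz - dXyz[h, ]
      ang <- acos(min(1, max(-1, sum(hd * ha) /
                               (sqrt(sum(hd^2)) * sqrt(sum(ha^2)))))) *
        180 / pi
      if (ang >= params@hbondAngle) return(TRUE)
    }
    FALSE
  }
  keyOf <- function(i) paste(ra$chain[i], ra$resno[i], sep = "|")
  bits <- list()
  labs <- list()
  ensure <- function(key, i) {
    if (is.null(bits[[key]])) {
      bits[[key]] <<- setNames(rep(FALSE, 9), BITS9)
      labs[[key]] <<- list(label = SIFtKit:::residueLabel(ra$resname[i],
                                                          ra$resno[i]),
                           resno = ra$resno[i], chain = ra$chain[i])
    }
  }
  for (i in which(!ra$hydrogen & !ra$water)) {
    for (j in which(!la$hydrogen & !la$water)) {
      d <- sqrt(sum((xyzR[i, ] - xyzL[j, ])^2))
      key <- keyOf(i)
      if (d <= params@contact) {
        ensure(key, i)
        bits[[key]]["any"] <- TRUE
        if (ra$backbone[i]) bits[[key]]["backbone"] <- TRUE
        if (!ra$backbone[i] && !ra$het[i]) bits[[key]]["sidechain"] <- TRUE
        if (ra$element[i] %in% c("C", "S") &&
            la$element[j] %in% c("C", "S"))
          bits[[key]]["hydrophobic"] <- TRUE
      }
      if (d <= params@polar && ra$element[i] %in% c("N", "O", "S") &&
          la$element[j] %in% c("N", "O", "S")) {
        ensure(key, i)
        bits[[key]]["polar"] <- TRUE
      }
      if (d <= params@charged &&
          ((ra$cation[i] && la$anion[j]) || (ra$anion[i] && la$cation[j]))) {
        ensure(key, i)
        bits[[key]]["charged"] <- TRUE
      }
      if (d <= params@hbondDA) {
        if (ra$acceptor[i] && la$donor[j] &&
            hbOK(la, xyzL, j, xyzR[i, ])) {
          ensure(key, i)
          bits[[key]]["hbond_acceptor"] <- TRUE
        }
        if (ra$donor[i] && la$acceptor[j] &&
            hbOK(ra, xyzR, i, xyzL[j, ])) {
          ensure(key, i)
          bits[[key]]["hbond_donor"] <- TRUE
        }
      }
    }
  }
  for (rr in rings(receptor)) {
    for (lr in rings(pose)) {
      if (sqrt(sum((rr$centroid - lr$centroid)^2)) <=
          params@aromaticCentroid) {
        i <- rr$atoms[1]
        key <- keyOf(i)
        ensure(key, i)
        bits[[key]]["aromatic"] <- TRUE
      }
    }
  }
  if (!length(bits))
    return(matrix(FALSE, 0, 9, dimnames = list(NULL, BITS9)))
  m <- do.call(rbind, bits)
  m[, "any"] <- m[, "any"] | rowSums(m[, -1, drop = FALSE]) > 0
  ord <- order(vapply(labs, function(l) l$chain, character(1)),
               vapply(labs, function(l) l$resno, numeric(1)))
  m <- m[ord, , drop = FALSE]
  rownames(m) <- unname(vapply(labs, function(l) l$label,
                               character(1))[ord])
  m
}

# Exhaustive enumeration of global alignments with affine gaps
# (gap of length L costs opening + L * extension); returns the optimal
# score.  Only feasible for short sequences.
enumAlignScore <- function(a, b, mat, opening, extension) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  la <- length(ca)
  lb <- length(cb)
  best <- -Inf
  rec <- function(i, j, state, sc) {
    if (i > la && j > lb) {
      best <<- max(best, sc)
      return(invisible(NULL))
    }
    if (i <= la && j <= lb)
      rec(i + 1, j + 1, "m", sc + mat[ca[i], cb[j]])
    if (i <= la)
      rec(i + 1, j, "d",
          sc - extension - if (state == "d") 0 else opening)
    if (j <= lb)
      rec(i, j + 1, "i",
          sc - extension - if (state == "i") 0 else opening)
  }
  rec(1, 1, "start", 0)
  best
}

# Direct Michaelis-Menten fit (independent of fitHill's implementation).
directMMFit <- function(data) {
  fit <- stats::nls(velocity ~ Vmax * substrate_conc_uM /
                      (Km + substrate_conc_uM),
                    data = data, algorithm = "port",
                    lower = c(Vmax = 1e-9, Km = 1e-9),
                    start = list(Vmax = max(data$velocity) * 1.2,
                                 Km = stats::median(data$substrate_conc_uM)),
                    control = stats::nls.control(maxiter = 500,
                                                 tol = 1e-12))
  stats::coef(fit)
}
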