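test_that("contact detection matches distances and cutoffs exactly", {
  s <- makeStructure(data.frame(name = "CB", resname = "VAL", resno = 10,
                                x = 0, y = 0, z = 0, element = "C"))
  p <- makePose(data.frame(name = "C1", element = "C", x = 3, y = 0, z = 0))
  cc <- residueContacts(s, p)
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$distance, 3.0)
  expect_equal(cc$label, "V10")

  far <- makePose(data.frame(name = "C1", element = "C",
                             x = 30, y = 0, z = 0))
  expect_equal(nrow(residueContacts(s, far)), 0L)
})

test_that("the neighbor search equals the all-pairs oracle on random atoms", {
  set.seed(91)
  for (rep in 1:3) {
    rdf <- data.frame(
      name = paste0("C", 1:50), resname = "ALA",
      resno = rep(1:10, each = 5),
      x = runif(50, 0, 18), y = runif(50, 0, 18), z = runif(50, 0, 18),
      element = sample(c("C", "N", "O"), 50, replace = TRUE))
    # keep residue keys unique per resno but allow arbitrary names
    s <- makeStructure(rdf, assignRoles = FALSE)
    s@typed <- TRUE
    p <- makePose(data.frame(
      name = paste0("L", 1:20), element = "C",
      x = runif(20, 0, 18), y = runif(20, 0, 18), z = runif(20, 0, 18)))
    got <- residueContacts(s, p, cutoff = 4.5)
    want <- bruteContacts(s, p, cutoff = 4.5)
    keyG <- sort(paste(got$receptorAtom, got$ligandAtom))
    keyW <- sort(paste(want$receptorAtom, want$ligandAtom))
    expect_identical(keyG, keyW)
    expect_equal(sort(got$distance), sort(want$distance), tolerance = 1e-12)
  }
})

test_that("hydrogen-bond geometry obeys distance and angle criteria", {
  p <- interactionParams()
  # collinear D-H...A at 2.9 A
  expect_true(detectHBond(c(0, 0, 0), c(2.9, 0, 0), h = c(1, 0, 0),
                          params = p))
  # beyond the donor-acceptor cutoff
  expect_false(detectHBond(c(0, 0, 0), c(4.0, 0, 0), params = p))
  # D...A ~2.97 A but the angle at H is 90 degrees
  expect_false(detectHBond(c(0, 0, 0), c(1, 2.8, 0), h = c(1, 0, 0),
                           params = p))
  # same geometry without an H: distance-only fallback accepts
  expect_true(detectHBond(c(0, 0, 0), c(1, 2.8, 0), params = p))
})

test_that("aromatic contacts use the centroid-distance criterion only", {
  p <- interactionParams()
  mkring <- function(ctr, normal)
    list(atoms = 1:6, centroid = ctr, normal = normal, label = "ring")
  expect_true(detectAromaticContact(mkring(c(0, 0, 0), c(0, 0, 1)),
                                    mkring(c(0, 0, 4), c(0, 0, 1)), p))
  expect_false(detectAromaticContact(mkring(c(0, 0, 0), c(0, 0, 1)),
                                     mkring(c(8, 0, 0), c(0, 0, 1)), p))
  # T-shaped at 4.8 A: still a contact
  expect_true(detectAromaticContact(mkring(c(0, 0, 0), c(0, 0, 1)),
                                    mkring(c(4.8, 0, 0), c(1, 0, 0)), p))
})

test_that("an isolated Val sidechain contact sets exactly three bits", {
  cx <- makeComplex(list(list(bit = "hydrophobic", distance = 3.5)))
  s <- computeSIFt(receptor(cx), poses(cx)[[1]])
  expect_equal(nrow(fingerprintBits(s)), 1L)
  b <- fingerprintBits(s)[1, ]
  expect_true(all(b[c("any", "sidechain", "hydrophobic")]))
  expect_false(any(b[setdiff(BITS9, c("any", "sidechain", "hydrophobic"))]))
})

test_that("a ligand beyond every cutoff yields an empty fingerprint", {
  cx <- makeComplex(list(list(bit = "hydrophobic", distance = 9)))
  s <- computeSIFt(receptor(cx), poses(cx)[[1]])
  expect_equal(nrow(fingerprintBits(s)), 0L)
})

test_that("a benzene ring near a Tyr ring sets the aromatic bit", {
  cx <- makeComplex(list(list(bit = "aromatic", residue = "TYR",
                              resno = 120, distance = 4)))
  s <- computeSIFt(receptor(cx), poses(cx)[[1]])
  b <- fingerprintBits(s)
  expect_true("Y120" %in% rownames(b))
  expect_true(b["Y120", "aromatic"])
  # ring carbons also make hydrophobic sidechain contacts
  expect_true(b["Y120", "hydrophobic"])
  expect_true(b["Y120", "any"])
})

test_that("fingerprints agree with the brute-force all-pairs oracle", {
  params <- interactionParams()
  fixtures <- list(
    makeComplex(lapply(BITS9, function(b) list(bit = b))),
    makeComplex(list(list(bit = "hbond_acceptor", hAngle = 150),
                     list(bit = "charged"),
                     list(bit = "aromatic", distance = 4.9))),
    makeComplex(lapply(BITS9, function(b)
      list(bit = b, distance = SIFtKit:::DEFAULT_SATISFY[[b]] + 0.3)))
  )
  for (cx in fixtures) {
    n <- nrow(atoms(receptor(cx))) + nrow(atoms(poses(cx)[[1]]))
    expect_lte(nrow(atoms(poses(cx)[[1]])), 100L)
    got <- fingerprintBits(computeSIFt(receptor(cx), poses(cx)[[1]],
                                       params))
    want <- bruteSIFt(receptor(cx), poses(cx)[[1]], params)
    expect_identical(got, want)
  }
})

test_that("averaging a single fingerprint reproduces its bits", {
  cx <- makeComplex(list(list(bit = "charged"), list(bit = "polar")))
  s <- computeSIFt(receptor(cx), poses(cx)[[1]])
  avg <- averageSIFt(list(s))
  expect_equal(frequencies(avg), fingerprintBits(s) * 1,
               ignore_attr = FALSE)
  expect_equal(nFingerprints(avg), 1L)
})

test_that("ensemble averages equal the arithmetic mean of bit vectors", {
  ens <- sampleEnsemble(list(list(bit = "hbond_acceptor", f = 0.4,
                                  resno = 10),
                             list(bit = "aromatic", f = 0.7, resno = 20)),
                        nPoses = 40, seed = 5)
  sifts <- lapply(poses(ens), computeSIFt, receptor = receptor(ens))
  avg <- averageSIFt(sifts)
  # oracle: accumulate indicator matrices over the union of residues
  labs <- sort(unique(unlist(lapply(sifts, function(s)
    rownames(fingerprintBits(s))))))
  acc <- matrix(0, length(labs), 9, dimnames = list(labs, BITS9))
  for (s in sifts) {
    b <- fingerprintBits(s)
    if (nrow(b)) acc[rownames(b), ] <- acc[rownames(b), ] + b
  }
  acc <- acc / length(sifts)
  f <- frequencies(avg)
  expect_setequal(rownames(f), labs)
  expect_equal(f[labs, ], acc, tolerance = 1e-12)
  # frequencies times n are integral counts
  counts <- f * nFingerprints(avg)
  expect_equal(counts, round(counts), tolerance = 1e-9)
})

test_that("the bit hierarchy holds for every fingerprint and average", {
  ens <- sampleEnsemble(list(list(bit = "polar", f = 0.5, resno = 10),
                             list(bit = "charged", f = 0.3, resno = 20),
                             list(bit = "aromatic", f = 0.8, resno = 30)),
                        nPoses = 30, seed = 17)
  sifts <- lapply(poses(ens), computeSIFt, receptor = receptor(ens))
  for (s in sifts) {
    b <- fingerprintBits(s)
    if (!nrow(b)) next
    expect_true(all(b[, "any"] >= b[, -1, drop = FALSE]))
  }
  f <- frequencies(averageSIFt(sifts))
  expect_true(all(f[, "any"] + 1e-12 >=
                    apply(f[, -1, drop = FALSE], 1, max)))
})

test_that("tanimoto similarity counts shared set bits over the union", {
  cx <- makeComplex(list(list(bit = "hydrophobic")))
  s <- computeSIFt(receptor(cx), poses(cx)[[1]])
  expect_equal(tanimoto(s, s), 1.0)

  empty <- computeSIFt(receptor(cx),
                       translatePose(poses(cx)[[1]], dy = -50))
  expect_equal(tanimoto(empty, empty), 1.0)  # both empty
  # a has 3 set bits (any, sidechain, hydrophobic); b shares 2 plus 2 more
  b <- s
  m <- fingerprintBits(s)
  m[1, "hydrophobic"] <- FALSE
  m[1, c("polar", "hbond_donor")] <- TRUE
  b@bits <- m
  expect_equal(tanimoto(s, b), 2 / 5)
  expect_equal(tanimoto(s, b), tanimoto(b, s))

  other <- makeComplex(list(list(bit = "polar")))
  s2 <- computeSIFt(receptor(other), poses(other)[[1]])
  expect_error(tanimoto(s, s2), "different receptors")
})

test_that("pose RMSD follows the direct formula and is a metric", {
  benz <- makePose(hexagonXYZ())
  expect_equal(poseRMSD(benz, benz), 0)
  expect_equal(poseRMSD(benz, translatePose(benz, dx = 1)), 1)

  set.seed(3)
  mk <- function() makePose(data.frame(
    name = paste0("C", 1:7), element = "C",
    x = runif(7, 0, 5), y = runif(7, 0, 5), z = runif(7, 0, 5)))
  for (k in 1:5) {
    a <- mk(); b <- mk(); c <- mk()
    A <- as.matrix(atoms(a)[, c("x", "y", "z")])
    B <- as.matrix(atoms(b)[, c("x", "y", "z")])
    expect_equal(poseRMSD(a, b), sqrt(mean(rowSums((A - B)^2))),
                 tolerance = 1e-12)
    expect_equal(poseRMSD(a, b), poseRMSD(b, a))
    expect_lte(poseRMSD(a, c), poseRMSD(a, b) + poseRMSD(b, c) + 1e-12)
  }
  short <- makePose(data.frame(name = "C1", element = "C",
                               x = 0, y = 0, z = 0))
  expect_error(poseRMSD(benz, short), "heavy-atom counts")
})

test_that("greedy leader clustering separates pose families", {
  benz <- makePose(hexagonXYZ())
  same <- lapply(0:3, function(i) translatePose(benz, poseIndex = i))
  expect_length(clusterPoses(same), 1L)

  set.seed(7)
  jitterPose <- function(base, idx, mag) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2)) * mag
    translatePose(base, u[1], u[2], u[3], poseIndex = idx)
  }
  g1 <- lapply(0:4, function(i) jitterPose(benz, i, 0.3))
  g2 <- lapply(5:9, function(i)
    jitterPose(translatePose(benz, dx = 5), i, 0.3))
  cl <- clusterPoses(c(g1, g2), clusterParams(1.0))
  expect_length(cl, 2L)
  expect_setequal(cl[[1]]$members, 0:4)
  expect_setequal(cl[[2]]$members, 5:9)
  expect_equal(cl[[1]]$representative, 0L)
  expect_equal(cl[[2]]$representative, 5L)
  # deterministic on re-run
  expect_identical(cl, clusterPoses(c(g1, g2), clusterParams(1.0)))
})

test_that("binding-site extraction thresholds the any-bit frequency", {
  ens <- sampleEnsemble(list(list(bit = "polar", f = 0.9, resno = 10),
                             list(bit = "charged", f = 0.1, resno = 20)),
                        nPoses = 20, seed = 2, exact = TRUE)
  avg <- averageSIFt(lapply(poses(ens), computeSIFt,
                            receptor = receptor(ens)))
  expect_equal(bindingSiteResidues(avg, 0.5), "S10")
  expect_setequal(bindingSiteResidues(avg, 0), c("S10", "K20"))
  emptyAvg <- averageSIFt(list(computeSIFt(
    receptor(ens), translatePose(poses(ens)[[1]], dy = -60))))
  expect_length(bindingSiteResidues(emptyAvg, 0.3), 0L)
})

test_that("averaged fingerprints export in canonical table order", {
  cx <- makeComplex(list(list(bit = "aromatic", residue = "TYR",
                              resno = 120)))
  avg <- averageSIFt(list(computeSIFt(receptor(cx), poses(cx)[[1]])))
  df <- as.data.frame(avg)
  expect_equal(names(df), c("amino_acid", BITS9))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeAveragedSIFt(avg, tsv)
  back <- read.delim(tsv, check.names = FALSE)
  expect_equal(back$amino_acid, "Y120")
  expect_equal(back$aromatic, 1)
})
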