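test_that("a minimal ATOM record maps to one residue with a backbone N", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    paste0("ATOM      1  N   VAL A 150      11.000  12.000  13.000",
           "  1.00  0.00           N"),
    "END"), pdb)
  s <- readPDB(pdb)
  a <- atoms(s)
  expect_equal(nrow(a), 1L)
  expect_equal(a$resname, "VAL")
  expect_equal(a$chain, "A")
  expect_equal(a$resno, 150L)
  expect_equal(c(a$x, a$y, a$z), c(11, 12, 13))
  expect_true(a$backbone)
  expect_true(a$donor)  # backbone amide N
})

test_that("two chains with the same numbering give distinct residue keys", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  rec <- function(serial, chain, x)
    sprintf("ATOM  %5d  CA  GLY %s  10    %8.3f%8.3f%8.3f  1.00  0.00           C",
            serial, chain, x, 0, 0)
  writeLines(c(rec(1, "A", 0), rec(2, "B", 30), "END"), pdb)
  s <- readPDB(pdb)
  a <- atoms(s)
  expect_equal(nrow(a), 2L)
  expect_equal(sort(unique(paste(a$chain, a$resno))), c("A 10", "B 10"))
})

test_that("PDB write-then-read round-trips coordinates, names and order", {
  cx <- makeComplex(list(list(bit = "aromatic"), list(bit = "charged"),
                         list(bit = "polar")))
  rec <- receptor(cx)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writePDB(rec, pdb)
  back <- readPDB(pdb)
  a0 <- atoms(rec)
  a1 <- atoms(back)
  expect_equal(nrow(a1), nrow(a0))
  expect_equal(a1$name, a0$name)
  expect_equal(a1$resname, a0$resname)
  expect_equal(a1$resno, a0$resno)
  expect_equal(a1$x, a0$x, tolerance = 5e-4)
  expect_equal(a1$y, a0$y, tolerance = 5e-4)
  expect_equal(a1$z, a0$z, tolerance = 5e-4)
})

test_that("an independent PDB reader agrees on the written coordinates", {
  cx <- makeComplex(list(list(bit = "hydrophobic"), list(bit = "aromatic")))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writePDB(receptor(cx), pdb)
  ref <- bio3d::read.pdb(pdb)
  a <- atoms(receptor(cx))
  expect_equal(ref$atom$x, round(a$x, 3))
  expect_equal(ref$atom$y, round(a$y, 3))
  expect_equal(ref$atom$z, round(a$z, 3))
  expect_equal(ref$atom$elety, a$name)
  expect_equal(ref$atom$resno, a$resno)
})

test_that("malformed coordinate fields are reported with their line number", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "REMARK header",
    paste0("ATOM      1  CA  GLY A  10      10.000  10.000  10.000",
           "  1.00  0.00           C"),
    paste0("ATOM      2  CA  GLY A  11      10.0XX  10.000  10.000",
           "  1.00  0.00           C")), pdb)
  expect_error(readPDB(pdb), "line 3")
  expect_error(readPDB(withr::local_tempfile(fileext = ".pdb")),
               "file not found")
})

test_that("PDBQT MODEL blocks become ordered poses with mapped elements", {
  qt <- withr::local_tempfile(fileext = ".pdbqt")
  mkatom <- function(serial, name, x, type)
    sprintf("%-6s%5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
            "ATOM", serial, name, "LIG", "X", 1, x, 0, 0, 1, 0, 0, type)
  writeLines(c(
    "MODEL        1",
    mkatom(1, "C1", 0, "A"), mkatom(2, "O1", 1.4, "OA"),
    mkatom(3, "N1", 2.8, "NA"), mkatom(4, "S1", 4.2, "SA"),
    mkatom(5, "H1", 5.0, "HD"),
    "ENDMDL",
    "MODEL        2",
    mkatom(1, "C1", 10, "A"), mkatom(2, "O1", 11.4, "OA"),
    mkatom(3, "N1", 12.8, "NA"), mkatom(4, "S1", 14.2, "SA"),
    mkatom(5, "H1", 15.0, "HD"),
    "ENDMDL"), qt)
  ps <- readPDBQT(qt, ligandId = "probe")
  expect_length(ps, 2L)
  expect_equal(vapply(ps, function(p) p@poseIndex, integer(1)), 0:1)
  expect_equal(nrow(atoms(ps[[1]])), 5L)
  expect_equal(atoms(ps[[1]])$element, c("C", "O", "N", "S", "H"))
  expect_equal(atoms(ps[[2]])$x, c(10, 11.4, 12.8, 14.2, 15.0))
})

test_that("PDBQT poses round-trip through write and read", {
  ens <- sampleEnsemble(list(list(bit = "aromatic", f = 1),
                             list(bit = "charged", f = 1)),
                        nPoses = 3, seed = 11)
  qt <- withr::local_tempfile(fileext = ".pdbqt")
  writePDBQT(poses(ens), qt)
  back <- readPDBQT(qt)
  expect_length(back, 3L)
  for (k in 1:3) {
    expect_equal(atoms(back[[k]])$x, atoms(poses(ens)[[k]])$x,
                 tolerance = 5e-4)
    expect_equal(atoms(back[[k]])$element, atoms(poses(ens)[[k]])$element)
  }
})

test_that("differing atom counts across MODEL blocks are rejected", {
  qt <- withr::local_tempfile(fileext = ".pdbqt")
  mkatom <- function(serial, x)
    sprintf("ATOM  %5d  C%d  LIG X   1    %8.3f%8.3f%8.3f  1.00  0.00     0.000 C",
            serial, serial, x, 0, 0)
  writeLines(c("MODEL 1", mkatom(1, 0), mkatom(2, 1.5), "ENDMDL",
               "MODEL 2", mkatom(1, 0), "ENDMDL"), qt)
  expect_error(readPDBQT(qt), "differing atom counts")
})

test_that("residue classification is fixed, multi-label and total", {
  expect_setequal(classifyResidue("TYR"),
                  c("polar", "hydrophobic", "aromatic"))
  expect_setequal(classifyResidue("LYS"), c("polar", "charged"))
  expect_equal(classifyResidue("VAL"), "hydrophobic")
  expect_setequal(classifyResidue("HIS"),
                  c("polar", "aromatic", "charged"))
  # total over the 20 standard residues, case-insensitive, pure
  for (aa in names(SIFtKit:::AA_3TO1)) {
    c1 <- classifyResidue(aa)
    expect_gt(length(c1), 0)
    expect_identical(c1, classifyResidue(tolower(aa)))
    expect_identical(c1, classifyResidue(aa))
  }
  expect_warning(res <- classifyResidue("XYZ"), "unknown residue")
  expect_length(res, 0L)
})

test_that("atom roles follow the chemistry table", {
  cx <- makeComplex(list(list(bit = "charged", residue = "LYS"),
                         list(bit = "hbond_donor", residue = "ARG"),
                         list(bit = "hbond_acceptor", residue = "ASN")))
  a <- atoms(receptor(cx))
  nz <- a[a$name == "NZ", ]
  expect_true(nz$donor && nz$cation)
  nh1 <- a[a$name == "NH1", ]
  expect_true(nh1$donor && nh1$cation && !nh1$acceptor)
  od1 <- a[a$name == "OD1", ]
  expect_true(od1$acceptor && !od1$donor)
  expect_true(all(a$donor[a$name == "N"]))       # backbone amide donors
  expect_true(all(a$acceptor[a$name == "O"]))    # carbonyl acceptors
})

test_that("aromatic residues yield one ring each and Trp yields two", {
  s <- SIFtKit:::buildScaffold(c("PHE", "TYR", "HIS", "TRP", "VAL"),
                               c(1, 2, 3, 4, 5))
  s <- assignAtomRoles(s)
  labs <- vapply(rings(s), `[[`, character(1), "label")
  expect_equal(sum(labs == "F1"), 1L)
  expect_equal(sum(labs == "Y2"), 1L)
  expect_equal(sum(labs == "H3"), 1L)
  expect_equal(sum(labs == "W4"), 2L)
  expect_length(rings(s), 5L)
})

test_that("ring centroid and normal match a best-fit-plane oracle", {
  s <- assignAtomRoles(SIFtKit:::buildScaffold("TYR", 120))
  r <- rings(s)[[1]]
  a <- atoms(s)
  xyz <- as.matrix(a[r$atoms, c("x", "y", "z")])
  expect_equal(r$centroid, colMeans(xyz), tolerance = 1e-10,
               ignore_attr = TRUE)
  # oracle: smallest principal component of the centered ring coords
  pc <- prcomp(xyz)
  oracleN <- pc$rotation[, 3]
  expect_equal(abs(sum(r$normal * oracleN)), 1, tolerance = 1e-8)
  expect_equal(sqrt(sum(r$normal^2)), 1, tolerance = 1e-10)
})

test_that("ligand ring perception finds aromatic and fused rings only", {
  benz <- makePose(hexagonXYZ())
  expect_length(rings(benz), 1L)
  expect_length(rings(benz)[[1]]$atoms, 6L)

  chain4 <- makePose(data.frame(
    name = paste0("C", 1:4), element = "C",
    x = 1.5 * (0:3), y = 0, z = 0))
  expect_length(rings(chain4), 0L)

  # naphthalene-like fused bicyclic: two hexagons sharing one edge
  h1 <- hexagonXYZ(0, 0)
  apo <- 1.39 * cos(pi / 6)
  mid <- c(mean(h1$x[1:2]), mean(h1$y[1:2]))
  ctr2 <- 2 * mid
  h2 <- hexagonXYZ(ctr2[1], ctr2[2])
  both <- rbind(h1, h2)
  dup <- duplicated(round(both[, c("x", "y", "z")], 4))
  both <- both[!dup, ]
  both$name <- paste0("C", seq_len(nrow(both)))
  expect_equal(nrow(both), 10L)
  fused <- makePose(both)
  expect_length(rings(fused), 2L)
  shared <- intersect(rings(fused)[[1]]$atoms, rings(fused)[[2]]$atoms)
  expect_length(shared, 2L)

  # puckered (chair) six-ring is not aromatic
  chair <- hexagonXYZ(r = 1.53)
  chair$z <- rep(c(0.25, -0.25), 3)
  expect_length(rings(makePose(chair)), 0L)
})

test_that("computing a fingerprint demands an annotated receptor", {
  s <- SIFtKit:::buildScaffold("VAL", 10)  # roles not assigned
  p <- makePose(data.frame(name = "C1", element = "C",
                           x = 1.2, y = -4.9, z = 0.6))
  expect_error(computeSIFt(s, p), "assignAtomRoles")
})
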