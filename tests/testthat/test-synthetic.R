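test_that("every planted bit is detected and every violation is not", {
  for (bit in BITS9) {
    sat <- makeComplex(list(list(bit = bit)))
    s <- computeSIFt(receptor(sat), poses(sat)[[1]])
    b <- fingerprintBits(s)
    expect_equal(nrow(b), 1L, info = bit)
    expect_true(b[1, bit], info = bit)
    expect_true(b[1, "any"], info = bit)

    vio <- makeComplex(list(list(bit = bit, distance = 9)))
    sv <- computeSIFt(receptor(vio), poses(vio)[[1]])
    bv <- fingerprintBits(sv)
    expect_false(nrow(bv) > 0 && bv[1, bit],
                 info = paste("violated", bit))
  }
})

test_that("a hydrogen bond planted beyond its cutoff is not detected", {
  cx <- makeComplex(list(list(bit = "hbond_acceptor", distance = 3.9)))
  b <- fingerprintBits(computeSIFt(receptor(cx), poses(cx)[[1]]))
  expect_false(b[1, "hbond_acceptor"])
  expect_true(b[1, "any"])  # still an atom contact at 3.9 < 4.5
})

test_that("planted donor hydrogens enforce the angle criterion", {
  bent <- makeComplex(list(list(bit = "hbond_acceptor", distance = 2.9,
                                hAngle = 90)))
  b <- fingerprintBits(computeSIFt(receptor(bent), poses(bent)[[1]]))
  expect_false(b[1, "hbond_acceptor"])
  straight <- makeComplex(list(list(bit = "hbond_acceptor",
                                    distance = 2.9, hAngle = 165)))
  b2 <- fingerprintBits(computeSIFt(receptor(straight),
                                    poses(straight)[[1]]))
  expect_true(b2[1, "hbond_acceptor"])
})

test_that("a twelve-residue planted site is recovered in full", {
  site <- list(
    list(bit = "any", residue = "GLU", resno = 12),
    list(bit = "any", residue = "GLU", resno = 15),
    list(bit = "any", residue = "LYS", resno = 43),
    list(bit = "any", residue = "GLY", resno = 70),
    list(bit = "hbond_donor", residue = "ARG", resno = 71),
    list(bit = "any", residue = "CYS", resno = 100),
    list(bit = "any", residue = "HIS", resno = 101),
    list(bit = "aromatic", residue = "TYR", resno = 120),
    list(bit = "hydrophobic", residue = "VAL", resno = 150),
    list(bit = "any", residue = "ARG", resno = 471),
    list(bit = "charged", residue = "GLU", resno = 474),
    list(bit = "any", residue = "ARG", resno = 475))
  cx <- makeComplex(site)
  avg <- averageSIFt(list(computeSIFt(receptor(cx), poses(cx)[[1]])))
  got <- bindingSiteResidues(avg, 0.3)
  expect_length(got, 12L)
  expect_equal(got, c("E12", "E15", "K43", "G70", "R71", "C100", "H101",
                      "Y120", "V150", "R471", "E474", "R475"))
})

test_that("contradictory complex specs are refused", {
  expect_error(makeComplex(list(list(bit = "polar", resno = 10),
                                list(bit = "polar", resno = 10))),
               "distinct residue numbers")
  expect_error(makeComplex(list(list(bit = "aromatic", residue = "VAL"))),
               "aromatic ring")
  expect_error(makeComplex(list(list(bit = "sidechain",
                                     residue = "GLY"))),
               "sidechain")
})

test_that("ensembles realize planted bit frequencies", {
  # certain frequency: all poses satisfy
  ens1 <- sampleEnsemble(list(list(bit = "aromatic", residue = "TYR",
                                   resno = 120, f = 1)),
                         nPoses = 29, seed = 4)
  avg1 <- averageSIFt(lapply(poses(ens1), computeSIFt,
                             receptor = receptor(ens1)))
  expect_equal(frequencies(avg1)["Y120", "aromatic"], 1.0)

  # f = 0.5, large n: inside the 99 percent binomial interval
  ens2 <- sampleEnsemble(list(list(bit = "hbond_acceptor", f = 0.5)),
                         nPoses = 1000, seed = 9)
  avg2 <- averageSIFt(lapply(poses(ens2), computeSIFt,
                             receptor = receptor(ens2)))
  k <- frequencies(avg2)["N10", "hbond_acceptor"] * 1000
  expect_gte(k, qbinom(0.005, 1000, 0.5))
  expect_lte(k, qbinom(0.995, 1000, 0.5))
})

test_that("ensemble generation is deterministic given the seed", {
  e1 <- sampleEnsemble(list(list(bit = "charged", f = 0.5)),
                       nPoses = 10, seed = 33)
  e2 <- sampleEnsemble(list(list(bit = "charged", f = 0.5)),
                       nPoses = 10, seed = 33)
  for (k in 1:10)
    expect_identical(atoms(poses(e1)[[k]]), atoms(poses(e2)[[k]]))
  e3 <- sampleEnsemble(list(list(bit = "charged", f = 0.5)),
                       nPoses = 10, seed = 34)
  same <- vapply(1:10, function(k)
    isTRUE(all.equal(atoms(poses(e1)[[k]])$y, atoms(poses(e3)[[k]])$y)),
    logical(1))
  expect_false(all(same))
})

test_that("exact-count sampling hits the requested counts exactly", {
  ens <- sampleEnsemble(list(list(bit = "polar", f = 0.3)),
                        nPoses = 20, seed = 5, exact = TRUE)
  avg <- averageSIFt(lapply(poses(ens), computeSIFt,
                            receptor = receptor(ens)))
  expect_equal(frequencies(avg)["S10", "polar"], 6 / 20)
})

test_that("simulated kinetics honor noise level, seed and the mean law", {
  exact <- simulateKinetics(kcat = 0.646, Km = 12, cv = 0, seed = 1)
  expect_equal(exact$velocity,
               hillVelocity(exact$substrate_conc_uM, 0.646, 12),
               tolerance = 1e-12)
  a <- simulateKinetics(kcat = 1, Km = 10, cv = 0.05, seed = 8)
  b <- simulateKinetics(kcat = 1, Km = 10, cv = 0.05, seed = 8)
  expect_identical(a, b)

  big <- simulateKinetics(kcat = 1, Km = 10, cv = 0.1, conc = 20,
                          replicates = 1e4, seed = 10)
  mu <- hillVelocity(20, 1, 10)
  se <- mu * 0.1 / sqrt(1e4)
  expect_lt(abs(mean(big$velocity) - mu), 3 * se)
})

test_that("the generator leaves the caller's RNG state untouched", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulateKinetics(kcat = 1, Km = 10, cv = 0.1, seed = 3))
  invisible(sampleEnsemble(list(list(bit = "polar", f = 0.5)),
                           nPoses = 2, seed = 3))
  expect_equal(runif(1), before)
})
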