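# Internal helpers shared across modules.

# Canonical bit order for the nine-bit fingerprint (Table-style column order).
BIT_NAMES <- c("any", "backbone", "sidechain", "polar", "hydrophobic",
               "hbond_acceptor", "hbond_donor", "aromatic", "charged")

AA_3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Covalent radii (Angstrom) for bond perception on small molecules.
COVALENT_RADII <- c(
  H = 0.31, C = 0.77, N = 0.75, O = 0.73, S = 1.03, P = 1.06,
  F = 0.71, Cl = 0.99, Br = 1.14, I = 1.33
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Logarithmically spaced sequence
#'
#' @param from,to positive range endpoints.
#' @param length.out number of points.
#' @return numeric vector of `length.out` points log-spaced in `[from, to]`.
#' @keywords internal
logSpace <- function(from, to, length.out) {
  stopifnot(from > 0, to > 0)
  exp(seq(log(from), log(to), length.out = length.out))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

vnorm <- function(x) sqrt(sum(x * x))

# Unit normal of the best-fit plane through >= 3 points (rows of `xyz`),
# i.e. the singular vector of the centered coordinates with smallest
# singular value.
planeNormal <- function(xyz) {
  centered <- sweep(xyz, 2, colMeans(xyz))
  sv <- svd(centered)
  n <- sv$v[, 3L]
  n / vnorm(n)
}

# Maximum out-of-plane deviation of points from their best-fit plane.
planarity <- function(xyz) {
  n <- planeNormal(xyz)
  centered <- sweep(xyz, 2, colMeans(xyz))
  max(abs(centered %*% n))
}

# Empty atom table with the schema used by TypedStructure and LigandPose.
emptyAtomTable <- function() {
  data.frame(
    serial = integer(0), name = character(0), resname = character(0),
    chain = character(0), resno = integer(0),
    x = numeric(0), y = numeric(0), z = numeric(0),
    element = character(0), het = logical(0), water = logical(0),
    hydrogen = logical(0), backbone = logical(0),
    donor = logical(0), acceptor = logical(0),
    cation = logical(0), anion = logical(0), aromatic = logical(0),
    stringsAsFactors = FALSE
  )
}

# One-letter residue label, e.g. "Y120"; unknown residues use "X".
residueLabel <- function(resname, resno) {
  one <- AA_3TO1[toupper(resname)]
  one[is.na(one)] <- "X"
  paste0(one, resno)
}

assertAtomTable <- function(atoms, what = "atoms") {
  need <- names(emptyAtomTable())
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop(what, " table is missing columns: ", paste(miss, collapse = ", "))
  invisible(TRUE)
}
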