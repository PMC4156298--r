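# Readers and writers for PDB and AutoDock PDBQT files.
#
# Both readers work on the fixed-column ATOM/HETATM layout, tolerate
# trailing junk lines, and report malformed coordinate fields with the
# offending line number.  PDBQT adds the AutoDock atom-type column, which
# is mapped to an element via the AutoDock4 atom-type table.

# AutoDock4 atom type -> element.
ADTYPE_TO_ELEMENT <- c(
  A = "C", C = "C", N = "N", NA. = "N", NS = "N", OA = "O", OS = "O",
  S = "S", SA = "S", H = "H", HD = "H", HS = "H", P = "P",
  F = "F", CL = "Cl", BR = "Br", I = "I", MG = "Mg", MN = "Mn",
  ZN = "Zn", CA = "Ca", FE = "Fe", W = "O"
)

mapADType <- function(type) {
  key <- toupper(type)
  key[key == "NA"] <- "NA."
  el <- ADTYPE_TO_ELEMENT[key]
  unknown <- is.na(el)
  if (any(unknown)) {
    # fall back to the leading letters of the type symbol
    el[unknown] <- sub("[0-9].*$", "", type[unknown])
  }
  unname(el)
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

# Derive an element symbol from a PDB atom name when columns 77-78 are
# blank.  Strips digits; treats names beginning with a digit or with
# H/1H/2H patterns as hydrogen.
elementFromName <- function(name) {
  vapply(name, function(nm) {
    s <- gsub("[0-9']", "", trimws(nm))
    if (!nzchar(s)) return("X")
    if (grepl("^H", s)) return("H")
    two <- toupper(substr(s, 1, 2))
    if (two %in% c("CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE"))
      return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
    substr(s, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

# Parse ATOM/HETATM records (fixed columns) from a character vector of
# lines.  `lineno` carries the original line numbers for error messages.
parseAtomRecords <- function(lines, lineno, pdbqt = FALSE) {
  n <- length(lines)
  if (!n) return(emptyAtomTable())
  num <- function(txt, what) {
    out <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(out) & nzchar(trimws(txt)) | !nzchar(trimws(txt)))
    if (length(bad))
      stop(sprintf("malformed %s field at line %d: '%s'",
                   what, lineno[bad[1L]], trimws(txt[bad[1L]])),
           call. = FALSE)
    out
  }
  serial <- suppressWarnings(as.integer(trimws(substr(lines, 7, 11))))
  serial[is.na(serial)] <- seq_len(n)[is.na(serial)]
  name <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  chain <- substr(lines, 22, 22)
  chain[!nzchar(trimws(chain))] <- " "
  resno <- suppressWarnings(as.integer(trimws(substr(lines, 23, 26))))
  bad <- which(is.na(resno))
  if (length(bad))
    stop(sprintf("malformed residue number at line %d", lineno[bad[1L]]),
         call. = FALSE)
  x <- num(substr(lines, 31, 38), "x coordinate")
  y <- num(substr(lines, 39, 46), "y coordinate")
  z <- num(substr(lines, 47, 54), "z coordinate")
  het <- startsWith(lines, "HETATM")
  if (pdbqt) {
    # AutoDock writes the atom type as the final whitespace token.
    toks <- strsplit(trimws(substr(lines, 67, nchar(lines))), "[[:space:]]+")
    adtype <- vapply(toks, function(t) if (length(t)) t[length(t)] else "",
                     character(1))
    element <- mapADType(adtype)
  } else {
    element <- trimws(substr(lines, 77, 78))
    miss <- !nzchar(element)
    if (any(miss)) element[miss] <- elementFromName(name[miss])
    element <- paste0(toupper(substr(element, 1, 1)),
                      tolower(substr(element, 2, 2)))
  }
  water <- resname %in% WATER_RESNAMES
  hydrogen <- element == "H"
  backbone <- !het & !water &
    name %in% c("N", "CA", "C", "O", "OXT")
  data.frame(
    serial = serial, name = name, resname = resname, chain = chain,
    resno = resno, x = x, y = y, z = z, element = element,
    het = het, water = water, hydrogen = hydrogen, backbone = backbone,
    donor = FALSE, acceptor = FALSE, cation = FALSE, anion = FALSE,
    aromatic = FALSE, stringsAsFactors = FALSE
  )
}

#' Read a receptor structure from a PDB file
#'
#' Parses ATOM/HETATM records in the fixed-column PDB layout.  Waters and
#' hydrogens are retained but flagged (`water`, `hydrogen` columns) and
#' excluded from interaction detection downstream.  Unrecognized lines are
#' skipped silently; malformed coordinate fields raise an error naming the
#' line number.
#'
#' @param path path to a PDB file.
#' @param assignRoles assign donor/acceptor/charge/aromatic roles and
#'   perceive sidechain rings via [assignAtomRoles()] (default `TRUE`).
#' @return a [TypedStructure-class] with residues in file order.
#' @examples
#' pdb <- tempfile(fileext = ".pdb")
#' writeLines(c(
#'   "ATOM      1  N   VAL A 150      10.000  10.000  10.000  1.00  0.00           N",
#'   "END"), pdb)
#' readPDB(pdb)
#' @export
readPDB <- function(path, assignRoles = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PDB file: ", path)
  keep <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  if (!any(keep)) stop("no ATOM/HETATM records in ", path)
  atoms <- parseAtomRecords(lines[keep], which(keep), pdbqt = FALSE)
  structure <- new("TypedStructure", atoms = atoms, rings = list(),
                   typed = FALSE)
  if (assignRoles) structure <- assignAtomRoles(structure)
  structure
}

#' Read docked ligand poses from a PDBQT file
#'
#' One pose per MODEL/ENDMDL block (a file without MODEL records yields a
#' single pose).  The AutoDock atom-type column is mapped to an element
#' via the AutoDock4 type table (A -> C, OA -> O, NA -> N, SA -> S,
#' HD -> H, ...).  Atom order is preserved and must be identical across
#' models of one ligand, as required for pose RMSD.
#'
#' Ligand donor/acceptor/charge roles and aromatic rings are perceived on
#' the first pose's connectivity and applied to all poses.
#'
#' @param path path to a PDBQT file.
#' @param ligandId ligand identifier; defaults to the file name without
#'   extension.
#' @return list of [LigandPose-class], `poseIndex` 0-based in file order.
#' @export
readPDBQT <- function(path, ligandId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty PDBQT file: ", path)
  ligandId <- ligandId %||% sub("\\.[^.]*$", "", basename(path))
  starts <- which(startsWith(lines, "MODEL"))
  if (!length(starts)) {
    blocks <- list(seq_along(lines))
  } else {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) < length(starts))
      ends <- c(ends, length(lines))
    blocks <- Map(function(s, e) seq(s, e), starts, ends)
  }
  posesList <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    idx <- blocks[[i]]
    keep <- idx[startsWith(lines[idx], "ATOM") |
                  startsWith(lines[idx], "HETATM")]
    if (!length(keep))
      stop("MODEL block ", i, " of ", path, " has no atoms")
    atoms <- parseAtomRecords(lines[keep], keep, pdbqt = TRUE)
    posesList[[i]] <- new("LigandPose", ligandId = ligandId,
                          poseIndex = i - 1L, atoms = atoms, rings = list())
  }
  counts <- vapply(posesList, function(p) nrow(p@atoms), integer(1))
  if (length(unique(counts)) > 1L)
    stop("differing atom counts across MODEL blocks of '", ligandId,
         "' (", paste(counts, collapse = ", "),
         "); poses of one ligand must share the same atoms")
  nm0 <- posesList[[1L]]@atoms$name
  for (p in posesList[-1L]) {
    if (!identical(p@atoms$name, nm0))
      stop("atom order differs across MODEL blocks of '", ligandId, "'")
  }
  lapply(posesList, annotateLigand)
}

formatAtomName <- function(name, element) {
  # Element symbols of one letter start in column 14.
  ifelse(nchar(name) >= 4L, substr(name, 1, 4),
         ifelse(nchar(element) == 1L,
                sprintf(" %-3s", name), sprintf("%-4s", name)))
}

atomRecordLines <- function(atoms, pdbqt = FALSE) {
  rec <- ifelse(atoms$het, "HETATM", "ATOM  ")
  nm <- formatAtomName(atoms$name, atoms$element)
  base <- sprintf("%s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
                  rec, atoms$serial %% 100000L, nm, " ",
                  atoms$resname, atoms$chain, atoms$resno,
                  atoms$x, atoms$y, atoms$z, 1.0, 0.0)
  if (pdbqt) {
    type <- toupper(atoms$element)
    type[type == "CL"] <- "Cl"
    paste0(base, sprintf("    %6.3f %-2s", 0, type))
  } else {
    paste0(base, sprintf("          %2s", toupper(atoms$element)))
  }
}

#' Write a structure or pose as a PDB file
#'
#' @param x a [TypedStructure-class] or [LigandPose-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(x, path) {
  a <- atoms(x)
  writeLines(c(atomRecordLines(a, pdbqt = FALSE), "END"), path)
  invisible(path)
}

#' Write ligand poses as a multi-MODEL PDBQT file
#'
#' @param posesList list of [LigandPose-class] sharing one atom layout.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDBQT <- function(posesList, path) {
  if (is(posesList, "LigandPose")) posesList <- list(posesList)
  out <- character(0)
  for (i in seq_along(posesList)) {
    a <- atoms(posesList[[i]])
    out <- c(out, sprintf("MODEL %8d", i),
             atomRecordLines(a, pdbqt = TRUE), "ENDMDL")
  }
  writeLines(out, path)
  invisible(path)
}
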