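# Pairwise global alignment and percent identity for homolog comparison.

AA_ALPHABET_RE <- "[^ACDEFGHIKLMNPQRSTVWYX]"

checkProteinSequence <- function(seq, id) {
  if (!nchar(seq)) stop("sequence '", id, "' is empty")
  bad <- regexpr(AA_ALPHABET_RE, toupper(seq))
  if (bad > 0)
    stop("illegal character '", substr(seq, bad, bad), "' at position ",
         bad, " of sequence '", id, "'")
  invisible(TRUE)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file path.
#' @return a [Biostrings::AAStringSet].
#' @export
readSequences <- function(path) {
  Biostrings::readAAStringSet(path)
}

#' Global pairwise alignment of two protein sequences
#'
#' Needleman--Wunsch global alignment with affine gap penalties
#' (dynamic programming via [Biostrings::pairwiseAlignment]).  The
#' default scoring is BLOSUM62 with gap opening 10 and gap extension
#' 0.5, a conventional choice when the original alignment protocol is
#' unknown.  Percent identity (identical columns over aligned columns)
#' is computed on the optimal alignment.
#'
#' @param a,b sequences: character strings, named character vectors, or
#'   `AAString`/length-1 `AAStringSet` objects.  Names (or FASTA headers)
#'   become sequence ids.
#' @param substitutionMatrix scoring matrix name or matrix (default
#'   `"BLOSUM62"`).
#' @param gapOpening,gapExtension affine gap penalties (positive costs).
#' @return an [AlignmentResult-class].
#' @examples
#' globalAlign(c(A = "ACDE"), c(B = "ACDF"))
#' @export
globalAlign <- function(a, b, substitutionMatrix = "BLOSUM62",
                        gapOpening = 10, gapExtension = 0.5) {
  asSeq <- function(x, fallback) {
    if (is(x, "AAStringSet")) {
      id <- names(x)[1L] %||% fallback
      return(list(id = id, seq = as.character(x[[1L]])))
    }
    if (is(x, "AAString")) return(list(id = fallback, seq = as.character(x)))
    id <- names(x)[1L] %||% fallback
    list(id = if (is.null(id) || is.na(id)) fallback else id,
         seq = toupper(as.character(x)[1L]))
  }
  A <- asSeq(a, "seqA")
  B <- asSeq(b, "seqB")
  checkProteinSequence(A$seq, A$id)
  checkProteinSequence(B$seq, B$id)
  if (is.character(substitutionMatrix) && length(substitutionMatrix) == 1L) {
    env <- new.env()
    utils::data(list = substitutionMatrix, package = "Biostrings",
                envir = env)
    substitutionMatrix <- get(substitutionMatrix, envir = env)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(A$seq), Biostrings::AAString(B$seq),
    substitutionMatrix = substitutionMatrix,
    gapOpening = gapOpening, gapExtension = gapExtension,
    type = "global")
  alnA <- as.character(Biostrings::alignedPattern(pa))
  alnB <- as.character(Biostrings::alignedSubject(pa))
  res <- new("AlignmentResult", idA = A$id, idB = B$id,
             alignedA = alnA, alignedB = alnB,
             score = Biostrings::score(pa), identityPct = 0)
  res@identityPct <- percentIdentity(res)
  validObject(res)
  res
}

#' @rdname percentIdentity
#' @export
setMethod("percentIdentity", "AlignmentResult",
          function(result, denominator = c("aligned_columns",
                                           "shorter_sequence")) {
  denominator <- match.arg(denominator)
  ca <- strsplit(result@alignedA, "")[[1L]]
  cb <- strsplit(result@alignedB, "")[[1L]]
  matches <- sum(ca == cb & ca != "-")
  denom <- switch(denominator,
    aligned_columns = sum(!(ca == "-" & cb == "-")),
    shorter_sequence = min(sum(ca != "-"), sum(cb != "-")))
  round(100 * matches / denom, 1)
})

#' Pairwise identity matrix for a set of sequences
#'
#' @param seqs named character vector or `AAStringSet`.
#' @param ... passed to [globalAlign()].
#' @return symmetric numeric matrix of percent identities (diagonal 100).
#' @export
identityMatrix <- function(seqs, ...) {
  if (is(seqs, "AAStringSet")) {
    nm <- names(seqs) %||% paste0("seq", seq_along(seqs))
    seqs <- stats::setNames(as.character(seqs), nm)
  }
  n <- length(seqs)
  nm <- names(seqs) %||% paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(nm, nm))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      r <- globalAlign(stats::setNames(seqs[i], nm[i]),
                       stats::setNames(seqs[j], nm[j]), ...)
      m[i, j] <- m[j, i] <- r@identityPct
    }
  }
  m
}
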