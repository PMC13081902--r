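#' Substitution matrix for protein alignment
#'
#' Returns a square scoring matrix over the 20 standard amino acids plus
#' ambiguity codes and the stop symbol \code{*}. BLOSUM62 is taken from
#' \pkg{Biostrings}; following the package convention, \code{X} (unknown
#' residue) scores 0 against every letter so that ambiguous translated
#' codons neither reward nor punish an alignment.
#'
#' @param name matrix name; currently \code{"BLOSUM62"}
#' @param xZero if TRUE (default), zero out the \code{X} row/column
#' @return numeric matrix with identical row and column names
#' @export
substitutionMatrix <- function(name = "BLOSUM62", xZero = TRUE) {
  e <- new.env()
  data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  m <- m + 0 # numeric copy
  if (xZero && "X" %in% rownames(m)) {
    m["X", ] <- 0
    m[, "X"] <- 0
  }
  stopifnot(identical(rownames(m), colnames(m)), isSymmetric(unname(m)))
  m
}

.check_protein <- function(seq, alphabet) {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq) || nchar(seq) == 0L)
    stop("sequence must be a single non-empty string", call. = FALSE)
  letters <- unique(strsplit(seq, "")[[1]])
  bad <- setdiff(letters, alphabet)
  if (length(bad))
    stop("invalid residue(s) in sequence: ", paste(bad, collapse = ", "),
         call. = FALSE)
  invisible(seq)
}

.as_seq <- function(x) {
  if (inherits(x, "AAString") || inherits(x, "AAStringSet")) as.character(x)[1]
  else as.character(x)[1]
}

.make_alignment_result <- function(al, mode, denominator, lenA, lenB) {
  denom <- switch(denominator,
    columns = al$aln_len,
    shorter = min(lenA, lenB),
    stop("denominator must be 'columns' or 'shorter'")
  )
  ident <- if (denom > 0) 100 * al$n_identical / denom else 0
  new("AlignmentResult",
    alignedA = al$aligned_a, alignedB = al$aligned_b,
    score = al$score, nIdentical = as.integer(al$n_identical),
    alnLen = as.integer(al$aln_len), identityPct = ident, mode = mode,
    coords = c(startA = al$start_a, endA = al$end_a,
               startB = al$start_b, endB = al$end_b)
  )
}

#' Global (Needleman-Wunsch) protein alignment
#'
#' Optimal end-to-end alignment under affine gap penalties: a gap of length
#' L costs \code{gapOpen + L * gapExt}. Percent identity is reported over
#' all alignment columns by default, i.e. gap columns count in the
#' denominator; set \code{denominator = "shorter"} to divide by the shorter
#' sequence length instead (reporting conventions differ between tools and
#' neither is canonical).
#'
#' @param a,b protein sequences (strings or \code{AAString})
#' @param matrix substitution matrix, see [substitutionMatrix()]
#' @param gapOpen,gapExt affine gap penalties (positive numbers)
#' @param denominator identity denominator: \code{"columns"} (default) or
#'   \code{"shorter"}
#' @return an [AlignmentResult-class]
#' @examples
#' al <- globalAlign("HEAGAWGHEE", "PAWHEAE")
#' identityPct(al)
#' @export
globalAlign <- function(a, b, matrix = substitutionMatrix(), gapOpen = 10,
                        gapExt = 0.5, denominator = c("columns", "shorter")) {
  denominator <- match.arg(denominator)
  a <- .as_seq(a); b <- .as_seq(b)
  .check_protein(a, rownames(matrix))
  .check_protein(b, rownames(matrix))
  al <- cpp_pair_align(a, b, matrix, rownames(matrix), gapOpen, gapExt, FALSE)
  .make_alignment_result(al, "global", denominator, nchar(a), nchar(b))
}

#' Local (Smith-Waterman) protein alignment
#'
#' Optimal local alignment under affine gap penalties; the score is never
#' negative and an empty alignment (score 0) is returned when no residue
#' pair scores positively.
#'
#' @inheritParams globalAlign
#' @return an [AlignmentResult-class]
#' @export
localAlign <- function(a, b, matrix = substitutionMatrix(), gapOpen = 11,
                       gapExt = 1, denominator = c("columns", "shorter")) {
  denominator <- match.arg(denominator)
  a <- .as_seq(a); b <- .as_seq(b)
  .check_protein(a, rownames(matrix))
  .check_protein(b, rownames(matrix))
  al <- cpp_pair_align(a, b, matrix, rownames(matrix), gapOpen, gapExt, TRUE)
  .make_alignment_result(al, "local", denominator, nchar(a), nchar(b))
}

#' @describeIn AlignmentResult-class alignment score
#' @param object,x an \code{AlignmentResult}
#' @export
setGeneric("alignmentScore", function(x) standardGeneric("alignmentScore"))
#' @export
setMethod("alignmentScore", "AlignmentResult", function(x) x@score)

#' @describeIn AlignmentResult-class percent identity
#' @export
setGeneric("identityPct", function(x) standardGeneric("identityPct"))
#' @export
setMethod("identityPct", "AlignmentResult", function(x) x@identityPct)

#' @describeIn AlignmentResult-class gapped aligned strings
#' @export
setGeneric("alignedStrings", function(x) standardGeneric("alignedStrings"))
#' @export
setMethod("alignedStrings", "AlignmentResult",
          function(x) c(a = x@alignedA, b = x@alignedB))

setMethod("show", "AlignmentResult", function(object) {
  cat(sprintf("%s alignment: score %.1f, identity %.1f%% (%d/%d columns)\n",
              object@mode, object@score, object@identityPct,
              object@nIdentical, object@alnLen))
  w <- 60L
  n <- object@alnLen
  for (s in seq(1L, max(n, 1L), by = w)) {
    e <- min(s + w - 1L, n)
    cat(" a: ", substr(object@alignedA, s, e), "\n",
        " b: ", substr(object@alignedB, s, e), "\n", sep = "")
  }
  invisible(object)
})

#' Read / write protein FASTA
#'
#' Thin wrappers around \pkg{Biostrings}. On reading, the record id is the
#' first whitespace-delimited token of the header; on writing, sequences
#' wrap at 60 columns.
#'
#' @param path file path
#' @return \code{readProteinFasta}: an \code{AAStringSet} with ids as names
#' @export
readProteinFasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname readProteinFasta
#' @param seqs named character vector or \code{AAStringSet}
#' @export
writeProteinFasta <- function(seqs, path) {
  if (!inherits(seqs, "AAStringSet"))
    seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}
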