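#' Six-frame translation of a nucleotide read
#'
#' Translates the read in frames +1..+3 and its reverse complement in
#' frames -1..-3 under the standard genetic code. Stop codons are emitted
#' as \code{*}, codons containing \code{N} as \code{X}; trailing partial
#' codons are dropped. Reads shorter than 3 nt yield six empty frames with
#' a warning.
#'
#' @param read nucleotide string (ACGTN; U accepted as T)
#' @return named character vector of six peptides ("+1".."-3")
#' @export
sixFrameTranslate <- function(read) {
  read <- .as_seq(read)
  if (nchar(read) < 3L) {
    warning("read shorter than 3 nt: all frames empty")
    return(stats::setNames(rep("", 6), c("+1", "+2", "+3", "-1", "-2", "-3")))
  }
  bad <- setdiff(unique(strsplit(toupper(read), "")[[1]]),
                 c("A", "C", "G", "T", "U", "N"))
  if (length(bad)) stop("invalid nucleotide(s): ", paste(bad, collapse = ", "))
  cpp_six_frames(read)
}

#' Translated search of reads against a protein reference database
#'
#' Each read is translated in six frames; frames sharing at least one
#' amino-acid k-mer with a database entry (the prefilter) are locally
#' aligned to it, and alignments with score at or above \code{minScore}
#' are reported as hits. Alignment columns holding \code{*} or \code{X}
#' never count as identical. Reporting is score-based: no E-value is
#' computed (the downstream quantification depends on the identity filter
#' and best-hit rule, not on E-value calibration).
#'
#' @param reads named character vector, \code{DNAStringSet}, or
#'   \code{QualityScaledDNAStringSet} of nucleotide reads
#' @param db a [ReferenceDB-class]
#' @param k k-mer length of the shared-k-mer prefilter (default 4);
#'   \code{prefilter = FALSE} aligns every frame against every entry
#' @param minScore minimal reported local alignment score (default 50, high
#'   enough that short spurious alignments arising from chance k-mer
#'   collisions are not reported)
#' @param prefilter logical; disable to obtain exhaustive search
#' @inheritParams globalAlign
#' @return data.frame of hits: read_id, target_id, frame, identity_pct,
#'   score, aln_len, n_identical, mismatch, gapopen, qstart, qend, sstart,
#'   send, is_decoy
#' @export
searchReads <- function(reads, db, k = 4L, minScore = 50,
                        matrix = substitutionMatrix(), gapOpen = 11,
                        gapExt = 1, prefilter = TRUE) {
  stopifnot(is(db, "ReferenceDB"))
  if (length(db) == 0L) stop("empty reference database")
  if (inherits(reads, "XStringSet")) reads <- as.character(reads)
  if (is.null(names(reads)))
    names(reads) <- paste0("read_", seq_along(reads))
  dbseq <- as.character(db@sequences)
  hits <- cpp_search_reads(unname(reads), unname(dbseq), matrix,
                           rownames(matrix), gapOpen, gapExt, as.integer(k),
                           minScore, prefilter)
  data.frame(
    read_id = names(reads)[hits$read],
    target_id = names(dbseq)[hits$target],
    frame = hits$frame,
    identity_pct = hits$identity_pct,
    score = hits$score,
    aln_len = hits$aln_len,
    n_identical = hits$n_identical,
    mismatch = hits$mismatch,
    gapopen = hits$gapopen,
    qstart = hits$qstart, qend = hits$qend,
    sstart = hits$sstart, send = hits$send,
    is_decoy = db@isDecoy[hits$target],
    stringsAsFactors = FALSE
  )
}

#' Resolve hits to best-hit read assignments
#'
#' Applies the quantification rules: hits with identity at or below
#' \code{minIdentity} are dropped (strict \code{>}); among a read's
#' surviving hits the highest identity wins (ties broken by score, then by
#' lexicographically smallest target id); a read whose winning hit is a
#' decoy is discarded and counted in \code{nDecoyBest}.
#'
#' @param hits data.frame from [searchReads()]
#' @param minIdentity percent identity cutoff, strict (default 90)
#' @param nReadsTotal total number of reads searched (defaults to the
#'   number of distinct read ids in \code{hits})
#' @return a [MappingResult-class]
#' @export
assignBest <- function(hits, minIdentity = 90,
                       nReadsTotal = length(unique(hits$read_id))) {
  need <- c("read_id", "target_id", "identity_pct", "score", "is_decoy")
  stopifnot(all(need %in% colnames(hits)))
  for (cc in c("frame", "aln_len"))
    if (!cc %in% colnames(hits)) hits[[cc]] <- rep(NA_integer_, nrow(hits))
  withHits <- unique(hits$read_id)
  surv <- hits[hits$identity_pct > minIdentity, , drop = FALSE]
  nFiltered <- length(setdiff(withHits, unique(surv$read_id)))
  if (nrow(surv)) {
    # deterministic winner per read: identity desc, score desc, id asc
    o <- order(surv$read_id, -surv$identity_pct, -surv$score, surv$target_id)
    surv <- surv[o, , drop = FALSE]
    best <- surv[!duplicated(surv$read_id), , drop = FALSE]
  } else {
    best <- surv
  }
  nDecoy <- sum(best$is_decoy)
  assigned <- best[!best$is_decoy,
                   c("read_id", "target_id", "frame", "identity_pct",
                     "score", "aln_len"), drop = FALSE]
  rownames(assigned) <- NULL
  new("MappingResult",
      assigned = S4Vectors::DataFrame(assigned),
      nReadsTotal = as.integer(nReadsTotal),
      nFilteredIdentity = as.integer(nFiltered),
      nDecoyBest = as.integer(nDecoy),
      minIdentity = minIdentity)
}

#' @rdname assignBest
#' @param x a \code{MappingResult}
#' @export
setGeneric("assignedHits", function(x) standardGeneric("assignedHits"))
#' @export
setMethod("assignedHits", "MappingResult", function(x) x@assigned)

#' @rdname assignBest
#' @export
setGeneric("nDecoyBest", function(x) standardGeneric("nDecoyBest"))
#' @export
setMethod("nDecoyBest", "MappingResult", function(x) x@nDecoyBest)

setMethod("show", "MappingResult", function(object) {
  cat(sprintf(
    "MappingResult: %d/%d reads assigned (identity > %g%%); %d decoy-best discarded, %d below identity\n",
    nrow(object@assigned), object@nReadsTotal, object@minIdentity,
    object@nDecoyBest, object@nFilteredIdentity))
  invisible(object)
})

#' Write hits as a 12-column BLAST-like tab-separated table
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore. No E-value is computed; the evalue column is
#' emitted as \code{NA} and the raw alignment score stands in the bitscore
#' column.
#'
#' @param hits data.frame from [searchReads()]
#' @param path output file
#' @export
writeHitsTable <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$read_id, sseqid = hits$target_id,
    pident = sprintf("%.2f", hits$identity_pct), length = hits$aln_len,
    mismatch = hits$mismatch, gapopen = hits$gapopen,
    qstart = hits$qstart, qend = hits$qend, sstart = hits$sstart,
    send = hits$send, evalue = "NA", bitscore = hits$score,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read FASTQ / FASTA reads
#'
#' @param path reads file (FASTQ when the extension contains "fastq" or
#'   "fq", FASTA otherwise)
#' @return named character vector of nucleotide sequences
#' @export
readReads <- function(path) {
  fq <- grepl("f(ast)?q($|\\.)", tolower(path))
  x <- if (fq) Biostrings::readDNAStringSet(path, format = "fastq")
       else Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  as.character(x)
}
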