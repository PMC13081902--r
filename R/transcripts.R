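#' Transcripts per million (TPM)
#'
#' Per column: \code{rate_g = count_g / length_g}; \code{tpm_g = 1e6 *
#' rate_g / sum(rate)}. Each column therefore sums to 1e6 and is invariant
#' to rescaling all counts in a replicate by a constant. Lengths follow
#' the same convention as [rpkm()] (coding nucleotides derived from the
#' protein length, or amino acids; only the relative lengths matter).
#'
#' @param counts non-negative count matrix (genes x replicates) or vector
#' @param lengths per-gene lengths (> 0)
#' @return matrix (or vector) of TPM values
#' @export
tpm <- function(counts, lengths) {
  vec <- !is.matrix(counts)
  m <- as.matrix(counts)
  if (length(lengths) != nrow(m)) stop("one length per gene required")
  if (any(lengths <= 0)) stop("lengths must be positive")
  if (any(m < 0)) stop("counts must be non-negative")
  if (any(colSums(m) == 0)) stop("a replicate has all-zero counts")
  rate <- m / lengths
  out <- sweep(rate, 2, colSums(rate), "/") * 1e6
  if (vec) out <- drop(out)
  out
}

#' Rank genes by median log-transformed expression
#'
#' Per gene, the median of log10(TPM + 1) across replicates; genes are
#' sorted descending (ties broken by gene id) and flagged when their rank
#' falls within the top decile (rank <= ceil(0.10 n)) or the top centile
#' (rank <= ceil(0.01 n)). \code{medianOrder = "median_first"} instead
#' takes the median of the raw TPM and transforms it afterwards - with an
#' odd number of replicates both orders agree.
#'
#' @param tpmMat TPM matrix, genes x replicates, rownames = gene ids
#' @param medianOrder \code{"transform_first"} (default) or
#'   \code{"median_first"}
#' @return data.frame sorted by rank: gene, median_log_tpm, rank, top10,
#'   top1
#' @export
rankGenes <- function(tpmMat,
                      medianOrder = c("transform_first", "median_first")) {
  medianOrder <- match.arg(medianOrder)
  tpmMat <- as.matrix(tpmMat)
  if (is.null(rownames(tpmMat)))
    rownames(tpmMat) <- paste0("gene_", seq_len(nrow(tpmMat)))
  med <- if (medianOrder == "transform_first")
    apply(log10(tpmMat + 1), 1, stats::median)
  else
    log10(apply(tpmMat, 1, stats::median) + 1)
  ids <- rownames(tpmMat)
  o <- order(-med, ids)
  n <- length(med)
  out <- data.frame(gene = ids[o], median_log_tpm = med[o],
                    rank = seq_len(n), stringsAsFactors = FALSE)
  out$top10 <- out$rank <= ceiling(0.10 * n)
  out$top1 <- out$rank <= ceiling(0.01 * n)
  rownames(out) <- NULL
  out
}
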