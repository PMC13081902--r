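#' Tally assigned reads per target
#'
#' @param mapping a [MappingResult-class]
#' @param targetIds targets to report (zero-filled when unobserved);
#'   defaults to the targets present in the mapping
#' @return named integer vector of raw counts
#' @export
tallyCounts <- function(mapping, targetIds = NULL) {
  stopifnot(is(mapping, "MappingResult"))
  a <- mapping@assigned
  if (is.null(targetIds)) targetIds <- sort(unique(a$target_id))
  counts <- table(factor(a$target_id, levels = targetIds))
  stats::setNames(as.integer(counts), targetIds)
}

#' Reads per kilobase per million (RPKM)
#'
#' \code{rpkm = count / ((3 * lengthAA / 1000) * (totalReads / 1e6))}:
#' counts are normalized per kilobase of coding nucleotides (amino acids
#' times 3) and per million total reads. \code{lengthUnit = "aa"} instead
#' treats the protein length itself as the kilobase unit (the convention
#' differs between pipelines; coding-nucleotide kilobases is the default).
#'
#' @param count non-negative read count (vectorized)
#' @param lengthAA protein length in amino acids (> 0)
#' @param totalReads total reads in the sample (> 0)
#' @param lengthUnit \code{"coding_nt"} (default) or \code{"aa"}
#' @return RPKM value(s)
#' @export
rpkm <- function(count, lengthAA, totalReads,
                 lengthUnit = c("coding_nt", "aa")) {
  lengthUnit <- match.arg(lengthUnit)
  if (any(lengthAA <= 0)) stop("protein length must be positive")
  if (any(totalReads <= 0)) stop("total read count must be positive")
  if (any(count < 0)) stop("counts must be non-negative")
  kb <- if (lengthUnit == "coding_nt") 3 * lengthAA / 1000 else lengthAA / 1000
  count / (kb * (totalReads / 1e6))
}

#' Average-genome-size normalization
#'
#' Divides RPKM by the sample's average genome size expressed in Mb,
#' correcting cross-sample comparisons for community genome-size
#' differences. Any consistent AGS unit works for the rank-based
#' statistics downstream.
#'
#' @param rpkmValue RPKM value(s)
#' @param agsBp average genome size of the sample in base pairs (> 0)
#' @return AGS-normalized abundance
#' @export
agsNormalize <- function(rpkmValue, agsBp) {
  if (any(agsBp <= 0)) stop("average genome size must be positive")
  rpkmValue / (agsBp / 1e6)
}

#' Presence call from AGS-normalized abundance
#'
#' A gene is "present" in a sample when its AGS-normalized abundance
#' strictly exceeds the threshold (default 1e-4); a value exactly at the
#' threshold is absent.
#'
#' @param agsNorm AGS-normalized abundance value(s)
#' @param threshold presence threshold (default \code{1e-4})
#' @return logical
#' @export
callPresence <- function(agsNorm, threshold = 1e-4) {
  agsNorm > threshold
}

#' Build a per-sample abundance table from mappings
#'
#' Combines per-sample [MappingResult-class]s with per-sample sequencing
#' statistics into a \code{SummarizedExperiment} with assays
#' \code{raw_count}, \code{rpkm}, \code{ags_norm} and \code{presence}
#' (genes in rows, samples in columns). \code{sampleStats} supplies the
#' post-QC total read count and the externally estimated average genome
#' size per sample.
#'
#' @param mappings named list of \code{MappingResult}, one per sample
#' @param db the [ReferenceDB-class] searched (provides target ids and
#'   protein lengths)
#' @param sampleStats data.frame with columns sample_id, total_reads,
#'   ags_bp
#' @param threshold presence threshold on the AGS-normalized layer
#' @param lengthUnit passed to [rpkm()]
#' @return \code{SummarizedExperiment}
#' @export
abundanceTable <- function(mappings, db, sampleStats, threshold = 1e-4,
                           lengthUnit = c("coding_nt", "aa")) {
  lengthUnit <- match.arg(lengthUnit)
  stopifnot(is(db, "ReferenceDB"),
            all(c("sample_id", "total_reads", "ags_bp") %in%
                  colnames(sampleStats)))
  if (any(sampleStats$total_reads <= 0) || any(sampleStats$ags_bp <= 0))
    stop("sample stats must have positive total_reads and ags_bp")
  samples <- sampleStats$sample_id
  if (!all(samples %in% names(mappings)))
    stop("every sample in sampleStats needs a mapping")
  tids <- targetIds(db)
  lens <- Biostrings::width(db@sequences)[match(tids, names(db@sequences))]
  counts <- vapply(samples, function(s) tallyCounts(mappings[[s]], tids),
                   integer(length(tids)))
  counts <- matrix(counts, nrow = length(tids),
                   dimnames = list(tids, samples))
  rp <- counts
  an <- counts * 0
  for (j in seq_along(samples)) {
    rp[, j] <- rpkm(counts[, j], lens, sampleStats$total_reads[j],
                    lengthUnit)
    an[, j] <- agsNormalize(rp[, j], sampleStats$ags_bp[j])
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(raw_count = counts, rpkm = rp, ags_norm = an,
                  presence = callPresence(an, threshold)),
    rowData = S4Vectors::DataFrame(length_aa = lens, row.names = tids),
    colData = S4Vectors::DataFrame(sampleStats, row.names = samples),
    metadata = list(presence_threshold = threshold,
                    length_unit = lengthUnit)
  )
}

#' Summed family abundance per sample
#'
#' Sums a layer of the abundance table over all targets (the whole gene
#' family), the quantity correlated against metabolite panels.
#'
#' @param se \code{SummarizedExperiment} from [abundanceTable()]
#' @param assay layer to sum (default \code{"ags_norm"})
#' @return named numeric vector, one value per sample
#' @export
familyAbundance <- function(se, assay = "ags_norm") {
  colSums(SummarizedExperiment::assay(se, assay))
}

#' Write an abundance layer as TSV (samples x genes)
#'
#' @param se \code{SummarizedExperiment} from [abundanceTable()]
#' @param assay layer name
#' @param path output file
#' @export
writeAbundanceLayer <- function(se, assay, path) {
  m <- t(SummarizedExperiment::assay(se, assay))
  utils::write.table(
    data.frame(sample_id = rownames(m), m, check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
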