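#' Run the quantification pipeline on a simulated community study
#'
#' Maps every sample's reads against the study's target + decoy database,
#' applies the strict identity filter and best-hit assignment, builds the
#' per-sample abundance table (raw counts, RPKM, AGS-normalized, presence),
#' and correlates the summed family abundance with the metabolite panel
#' (Spearman, Benjamini-Hochberg across the panel).
#'
#' @param study a \code{SimTruth} list from [simulateCommunityStudy()]
#' @param minIdentity strict percent-identity cutoff (default 90)
#' @param k prefilter k-mer size (default 4)
#' @param minScore minimal reported alignment score (default 50)
#' @param presenceThreshold presence cutoff on AGS-normalized abundance
#' @return list: \code{mappings} (per sample), \code{abundance}
#'   (SummarizedExperiment), \code{familyAbundance}, \code{associations}
#' @export
runCommunityPipeline <- function(study, minIdentity = 90, k = 4L,
                                 minScore = 50, presenceThreshold = 1e-4) {
  stopifnot(inherits(study, "SimTruth"))
  mat <- substitutionMatrix()
  samples <- study$sampleStats$sample_id
  mappings <- lapply(samples, function(s) {
    hits <- searchReads(study$reads[[s]], study$db, k = k,
                        minScore = minScore, matrix = mat)
    assignBest(hits, minIdentity = minIdentity,
               nReadsTotal = length(study$reads[[s]]))
  })
  names(mappings) <- samples
  se <- abundanceTable(mappings, study$db, study$sampleStats,
                       threshold = presenceThreshold)
  fam <- familyAbundance(se)
  assoc <- correlateMultiomics(fam, study$metabolites)
  list(mappings = mappings, abundance = se, familyAbundance = fam,
       associations = assoc)
}

#' Estimated family-metabolite correlation from one simulated study
#'
#' Convenience wrapper: simulate a study at the given seed, run the
#' pipeline, and return the Spearman rho estimated for the coupled
#' metabolite (plus the truth for comparison).
#'
#' @param seed integer seed
#' @param ... passed to [simulateCommunityStudy()]
#' @param pipelineArgs list of arguments for [runCommunityPipeline()]
#' @return list: rho_est, rho_target, p_adj, n
#' @export
estimateCouplingRho <- function(seed, ..., pipelineArgs = list()) {
  study <- simulateCommunityStudy(seed, ...)
  res <- do.call(runCommunityPipeline, c(list(study), pipelineArgs))
  a <- res$associations
  row <- a[a$metabolite_id == "coupled", ]
  list(rho_est = row$rho, rho_target = study$params$rhoTarget,
       p_adj = row$p_adj, n = row$n)
}
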