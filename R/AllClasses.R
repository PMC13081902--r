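#' @useDynLib metaBSH, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

#' AlignmentResult: a scored pairwise protein alignment
#'
#' Holds the gapped alignment of two protein sequences together with its
#' score and percent identity. Identity is the number of identical,
#' non-ambiguous columns divided by the chosen denominator (all alignment
#' columns by default, including gap columns).
#'
#' @slot alignedA,alignedB gapped strings of equal length
#' @slot score alignment score under the substitution matrix and affine gaps
#' @slot nIdentical number of identical columns (gap, \code{X} and \code{*}
#'   columns never count as identical)
#' @slot alnLen number of alignment columns
#' @slot identityPct percent identity
#' @slot mode \code{"global"} or \code{"local"}
#' @slot coords 1-based start/end of the aligned region on each input
#'   (named numeric: startA, endA, startB, endB)
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(
    alignedA = "character", alignedB = "character",
    score = "numeric", nIdentical = "integer", alnLen = "integer",
    identityPct = "numeric", mode = "character", coords = "numeric"
  )
)

setValidity("AlignmentResult", function(object) {
  msg <- NULL
  if (nchar(object@alignedA) != nchar(object@alignedB))
    msg <- c(msg, "aligned strings differ in length")
  if (nchar(object@alignedA) != object@alnLen)
    msg <- c(msg, "alnLen does not match the aligned strings")
  if (object@nIdentical < 0L || object@nIdentical > object@alnLen)
    msg <- c(msg, "nIdentical outside [0, alnLen]")
  if (!object@mode %in% c("global", "local"))
    msg <- c(msg, "mode must be 'global' or 'local'")
  if (is.null(msg)) TRUE else msg
})

#' SSNGraph: a sequence similarity network
#'
#' Undirected graph over sequence ids in which an edge records a pairwise
#' alignment that passed both the score cutoff and the minimum identity.
#' Connected components approximate isofunctional families.
#'
#' @slot graph an \code{igraph} object; edge attributes \code{score} and
#'   \code{identity}
#' @slot scoreCutoff,minIdentity the thresholds the edges satisfy
#' @exportClass SSNGraph
setClass("SSNGraph",
  representation(graph = "ANY", scoreCutoff = "numeric", minIdentity = "numeric")
)

setValidity("SSNGraph", function(object) {
  g <- object@graph
  if (!inherits(g, "igraph")) return("graph slot must be an igraph object")
  if (igraph::ecount(g) > 0) {
    sc <- igraph::edge_attr(g, "score")
    id <- igraph::edge_attr(g, "identity")
    if (is.null(sc) || is.null(id))
      return("edges must carry 'score' and 'identity' attributes")
    if (any(sc < object@scoreCutoff)) return("edge below score cutoff")
    if (any(id < object@minIdentity)) return("edge below identity cutoff")
    el <- igraph::as_edgelist(g)
    if (any(el[, 1] == el[, 2])) return("self-edges are not allowed")
  }
  TRUE
})

#' ReferenceDB: target + decoy protein search database
#'
#' The curated family members ("targets") together with every non-family
#' sequence retained as a decoy, so that reads more similar to a non-family
#' protein can be excluded from family counts.
#'
#' @slot sequences an \code{AAStringSet} of all entries
#' @slot isDecoy logical, one per entry
#' @slot provenance \code{DataFrame} with one row per entry (cluster
#'   membership, residue-filter outcome)
#' @exportClass ReferenceDB
setClass("ReferenceDB",
  representation(sequences = "ANY", isDecoy = "logical", provenance = "ANY")
)

setValidity("ReferenceDB", function(object) {
  msg <- NULL
  if (!inherits(object@sequences, "AAStringSet"))
    msg <- c(msg, "sequences must be an AAStringSet")
  if (length(object@isDecoy) != length(object@sequences))
    msg <- c(msg, "isDecoy must have one flag per sequence")
  nm <- names(object@sequences)
  if (is.null(nm) || anyDuplicated(nm))
    msg <- c(msg, "sequences must carry unique names")
  if (is.null(msg)) TRUE else msg
})

#' MappingResult: best-hit read assignments against a ReferenceDB
#'
#' One row per assigned read after the strict identity filter and the
#' highest-identity multi-mapping rule; reads whose best surviving hit is a
#' decoy are discarded and only counted.
#'
#' @slot assigned \code{DataFrame} (read_id, target_id, frame, identity_pct,
#'   score, aln_len)
#' @slot nReadsTotal number of reads searched
#' @slot nFilteredIdentity reads with hits but none above the identity cutoff
#' @slot nDecoyBest reads discarded because a decoy won the best-hit rule
#' @slot minIdentity the identity cutoff applied (strict \code{>})
#' @exportClass MappingResult
setClass("MappingResult",
  representation(
    assigned = "ANY", nReadsTotal = "integer", nFilteredIdentity = "integer",
    nDecoyBest = "integer", minIdentity = "numeric"
  )
)

setValidity("MappingResult", function(object) {
  a <- object@assigned
  msg <- NULL
  need <- c("read_id", "target_id", "frame", "identity_pct", "score", "aln_len")
  if (!all(need %in% colnames(a)))
    msg <- c(msg, paste("assigned must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(a) && any(a$identity_pct <= object@minIdentity))
      msg <- c(msg, "assigned hit at or below the identity cutoff")
    if (anyDuplicated(a$read_id)) msg <- c(msg, "a read is assigned twice")
  }
  if (object@nDecoyBest < 0L || object@nReadsTotal < 0L)
    msg <- c(msg, "negative counters")
  if (is.null(msg)) TRUE else msg
})

#' MMFit: Michaelis-Menten kinetic parameters
#'
#' @slot Vmax maximal rate (same unit as the observed rates, e.g. uM/s)
#' @slot Km Michaelis constant (same unit as substrate concentrations, uM)
#' @slot kcat turnover number (1/s), \code{Vmax / [E]}
#' @slot kcatOverKm catalytic efficiency in 1/(M s)
#' @slot se standard errors for Vmax and Km
#' @slot converged logical convergence flag
#' @slot fit the underlying \code{nls} object (or NULL on failure)
#' @exportClass MMFit
setClass("MMFit",
  representation(
    Vmax = "numeric", Km = "numeric", kcat = "numeric",
    kcatOverKm = "numeric", se = "numeric", converged = "logical",
    fit = "ANY"
  )
)

setValidity("MMFit", function(object) {
  if (isTRUE(object@converged) && (object@Vmax <= 0 || object@Km <= 0))
    return("converged fit must have positive Vmax and Km")
  TRUE
})
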