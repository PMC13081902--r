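#' All-vs-all pairwise alignment statistics
#'
#' Global-aligns every unordered pair of sequences and returns one row per
#' pair with the score and percent identity. Used by [buildSSN()] and
#' [greedyCluster()].
#'
#' @param seqs named character vector or \code{AAStringSet} with unique ids
#' @inheritParams globalAlign
#' @return data.frame with columns id_a, id_b, score, identity
#' @export
allPairsAlign <- function(seqs, matrix = substitutionMatrix(), gapOpen = 10,
                          gapExt = 0.5) {
  seqs <- .named_seqs(seqs)
  ids <- names(seqs)
  n <- length(seqs)
  if (n < 2L) stop("need at least two sequences")
  pairs <- utils::combn(n, 2L)
  res <- apply(pairs, 2L, function(p) {
    al <- globalAlign(seqs[[p[1]]], seqs[[p[2]]], matrix, gapOpen, gapExt)
    c(score = alignmentScore(al), identity = identityPct(al))
  })
  data.frame(
    id_a = ids[pairs[1L, ]], id_b = ids[pairs[2L, ]],
    score = res["score", ], identity = res["identity", ],
    stringsAsFactors = FALSE
  )
}

.named_seqs <- function(seqs) {
  if (inherits(seqs, "AAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs)) || any(names(seqs) == "") || anyDuplicated(names(seqs)))
    stop("sequences must carry unique non-empty ids", call. = FALSE)
  seqs
}

#' Build a sequence similarity network
#'
#' All-vs-all global alignment; an undirected edge joins two sequences when
#' the alignment score reaches \code{scoreCutoff} and the percent identity
#' reaches \code{minIdentity}. Connected components of the resulting graph
#' approximate isofunctional enzyme families.
#'
#' The score cutoff is expressed on the raw substitution-matrix score scale
#' of this package's aligner; it is a free parameter to be calibrated so
#' that within-family pairs connect and unrelated pairs do not (alignment
#' score scales are tool-specific and not portable between aligners).
#'
#' @param seqs named character vector or \code{AAStringSet}, >= 2 entries
#' @param minIdentity minimum percent identity for an edge (default 31)
#' @param scoreCutoff minimum alignment score for an edge
#' @inheritParams globalAlign
#' @return an [SSNGraph-class]
#' @export
buildSSN <- function(seqs, minIdentity = 31, scoreCutoff = 0,
                     matrix = substitutionMatrix(), gapOpen = 10,
                     gapExt = 0.5) {
  seqs <- .named_seqs(seqs)
  pw <- allPairsAlign(seqs, matrix, gapOpen, gapExt)
  keep <- pw$score >= scoreCutoff & pw$identity >= minIdentity
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(seqs), name = names(seqs))
  if (any(keep)) {
    el <- rbind(pw$id_a[keep], pw$id_b[keep])
    g <- igraph::add_edges(g, as.vector(el),
                           score = pw$score[keep], identity = pw$identity[keep])
  }
  new("SSNGraph", graph = g, scoreCutoff = scoreCutoff,
      minIdentity = minIdentity)
}

#' @rdname buildSSN
#' @param x an \code{SSNGraph}
#' @export
setGeneric("ssnEdges", function(x) standardGeneric("ssnEdges"))
#' @export
setMethod("ssnEdges", "SSNGraph", function(x) {
  g <- x@graph
  if (igraph::ecount(g) == 0)
    return(data.frame(id_a = character(), id_b = character(),
                      score = numeric(), identity = numeric()))
  el <- igraph::as_edgelist(g)
  data.frame(id_a = el[, 1], id_b = el[, 2],
             score = igraph::edge_attr(g, "score"),
             identity = igraph::edge_attr(g, "identity"),
             stringsAsFactors = FALSE)
})

#' @rdname buildSSN
#' @export
setGeneric("ssnNodes", function(x) standardGeneric("ssnNodes"))
#' @export
setMethod("ssnNodes", "SSNGraph",
          function(x) igraph::vertex_attr(x@graph, "name"))

setMethod("show", "SSNGraph", function(object) {
  g <- object@graph
  cat(sprintf(
    "SSNGraph: %d nodes, %d edges (score >= %g, identity >= %g%%), %d components\n",
    igraph::vcount(g), igraph::ecount(g), object@scoreCutoff,
    object@minIdentity, igraph::count_components(g)))
  invisible(object)
})

#' Extract the connected component containing a seed sequence
#'
#' @param ssn an [SSNGraph-class]
#' @param seedId node id of the seed (e.g. the characterised family member)
#' @return character vector of node ids in the seed's component
#' @export
extractCluster <- function(ssn, seedId) {
  stopifnot(is(ssn, "SSNGraph"))
  g <- ssn@graph
  nodes <- igraph::vertex_attr(g, "name")
  if (!seedId %in% nodes) stop("seed id not found in the network: ", seedId)
  comp <- igraph::components(g)
  nodes[comp$membership == comp$membership[match(seedId, nodes)]]
}

#' Greedy identity clustering with representative selection
#'
#' Sequences are visited in order of decreasing length (ties: lexicographic
#' id); each joins the first existing cluster whose current representative
#' it matches at >= \code{identityThreshold} percent global identity,
#' otherwise it founds a new cluster. After all assignments, each cluster's
#' representative is the member with the highest total alignment score to
#' its co-members (ties: longest, then lexicographically smallest id).
#'
#' @param seqs named character vector or \code{AAStringSet}
#' @param identityThreshold percent identity for cluster membership
#'   (default 65)
#' @inheritParams globalAlign
#' @return named list of clusters, each \code{list(members, representative)}
#' @export
greedyCluster <- function(seqs, identityThreshold = 65,
                          matrix = substitutionMatrix(), gapOpen = 10,
                          gapExt = 0.5) {
  seqs <- .named_seqs(seqs)
  ids <- names(seqs)
  ord <- order(-nchar(seqs), ids)
  clusters <- list() # each: list(rep = id, members = ids)
  for (i in ord) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_id <- clusters[[ci]]$rep
      al <- globalAlign(seqs[[i]], seqs[[rep_id]], matrix, gapOpen, gapExt)
      if (identityPct(al) >= identityThreshold) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, ids[i])
        placed <- TRUE
        break
      }
    }
    if (!placed)
      clusters[[length(clusters) + 1L]] <- list(rep = ids[i], members = ids[i])
  }
  # final representative: arg-max of summed pairwise scores within cluster
  out <- lapply(clusters, function(cl) {
    m <- cl$members
    if (length(m) == 1L)
      return(list(members = m, representative = m))
    tot <- vapply(m, function(a) {
      sum(vapply(setdiff(m, a), function(b)
        alignmentScore(globalAlign(seqs[[a]], seqs[[b]], matrix,
                                   gapOpen, gapExt)), numeric(1)))
    }, numeric(1))
    best <- m[order(-tot, -nchar(seqs[m]), m)][1L]
    list(members = m, representative = best)
  })
  names(out) <- paste0("cluster_", seq_along(out))
  out
}

#' Key active-site residue profile
#'
#' Positions (1-based on the full-length reference enzyme) of the conserved
#' dinuclear-metal-binding ligands and of the substrate-recognition
#' residues of the metal-dependent bile salt hydrolase family. KCX
#' (carboxylated lysine) is matched as K because carboxylation is a
#' post-translational modification invisible in primary sequence.
#'
#' @param referenceId id of the full-length reference sequence
#' @param metal named character vector: expected residue per position
#' @param substrate named character vector for the substrate-binding set
#' @return list with elements referenceId, metal, substrate
#' @export
keyResidueProfile <- function(
    referenceId = "BwBSH1",
    metal = c(`110` = "H", `112` = "H", `373` = "K", `441` = "H",
              `474` = "H", `583` = "D"),
    substrate = c(`194` = "S", `196` = "H", `381` = "Q", `443` = "N",
                  `544` = "H")) {
  for (set in list(metal, substrate)) {
    pos <- as.integer(names(set))
    if (any(is.na(pos)) || is.unsorted(pos, strictly = TRUE))
      stop("profile positions must be strictly increasing integers")
    if (!all(set %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
      stop("expected residues must be single standard amino acids")
  }
  list(referenceId = referenceId, metal = metal, substrate = substrate)
}

#' Check conservation of key active-site residues
#'
#' Globally aligns a candidate to the full-length reference and asks, for
#' every profile position, whether the candidate residue in the alignment
#' column of that reference position equals the expected amino acid (a gap
#' means absent). A candidate passes when the complete metal-ligand set is
#' present and, if \code{requireSubstrate}, the substrate-recognition set
#' too. Truncated sequences lacking part of the dinuclear metal centre
#' therefore fail.
#'
#' @param candidate,reference protein sequences (strings); \code{reference}
#'   must be the full-length sequence the profile positions refer to
#' @param profile from [keyResidueProfile()]
#' @param requireSubstrate also require the substrate set (default TRUE)
#' @inheritParams globalAlign
#' @return list: \code{pass} flag and \code{report} data.frame
#'   (position, set, expected, observed, present)
#' @export
checkKeyResidues <- function(candidate, reference, profile = keyResidueProfile(),
                             requireSubstrate = TRUE,
                             matrix = substitutionMatrix(), gapOpen = 10,
                             gapExt = 0.5) {
  candidate <- .as_seq(candidate); reference <- .as_seq(reference)
  allpos <- c(as.integer(names(profile$metal)),
              as.integer(names(profile$substrate)))
  if (max(allpos) > nchar(reference))
    stop("profile position beyond reference length")
  al <- globalAlign(candidate, reference, matrix, gapOpen, gapExt)
  ca <- strsplit(al@alignedA, "")[[1]]
  cr <- strsplit(al@alignedB, "")[[1]]
  # column index of each reference position
  refpos <- cumsum(cr != "-")
  colOf <- match(seq_len(nchar(reference)), refpos)
  rows <- lapply(c("metal", "substrate"), function(set) {
    exp <- profile[[set]]
    pos <- as.integer(names(exp))
    obs <- ca[colOf[pos]]
    data.frame(position = pos, set = set, expected = unname(exp),
               observed = obs, present = obs == unname(exp),
               stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  pass <- all(report$present[report$set == "metal"]) &&
    (!requireSubstrate || all(report$present[report$set == "substrate"]))
  list(pass = pass, report = report)
}

#' Assemble the target + decoy reference database
#'
#' Cluster members that pass the key-residue filter become targets; every
#' other input sequence (outside the cluster, or inside it but failing the
#' filter) is kept as a decoy so that reads closer to a non-family protein
#' are excluded from family counts downstream.
#'
#' @param clusterMembers character vector of ids in the family cluster
#' @param allSeqs named character vector or \code{AAStringSet} of every
#'   sequence in the network
#' @param filterReports named list of [checkKeyResidues()] results, one per
#'   cluster member
#' @return a [ReferenceDB-class]
#' @export
assembleReferenceDB <- function(clusterMembers, allSeqs, filterReports) {
  allSeqs <- .named_seqs(allSeqs)
  ids <- names(allSeqs)
  if (!all(clusterMembers %in% ids))
    stop("cluster members must be a subset of the sequence ids")
  passed <- vapply(clusterMembers, function(id) {
    fr <- filterReports[[id]]
    !is.null(fr) && isTRUE(fr$pass)
  }, logical(1))
  targets <- clusterMembers[passed]
  if (!length(targets)) warning("no cluster member passed the residue filter")
  isDecoy <- !(ids %in% targets)
  prov <- S4Vectors::DataFrame(
    id = ids,
    in_cluster = ids %in% clusterMembers,
    passed_filter = ids %in% targets,
    row.names = ids
  )
  new("ReferenceDB",
      sequences = Biostrings::AAStringSet(allSeqs[c(targets, ids[isDecoy])]),
      isDecoy = c(rep(FALSE, length(targets)), rep(TRUE, sum(isDecoy))),
      provenance = prov[c(targets, ids[isDecoy]), ])
}

#' Construct a ReferenceDB directly from targets and decoys
#'
#' Convenience constructor used when the family delineation has already been
#' done (e.g. in simulations with known truth).
#'
#' @param targets,decoys named character vectors or \code{AAStringSet}s
#' @return a [ReferenceDB-class]
#' @export
referenceDB <- function(targets, decoys = character()) {
  targets <- if (length(targets)) .named_seqs(targets) else character()
  decoys <- if (length(decoys)) .named_seqs(decoys) else character()
  ids <- c(names(targets), names(decoys))
  if (anyDuplicated(ids)) stop("target and decoy ids must be disjoint")
  prov <- S4Vectors::DataFrame(
    id = ids, in_cluster = c(rep(TRUE, length(targets)),
                             rep(FALSE, length(decoys))),
    passed_filter = c(rep(TRUE, length(targets)), rep(FALSE, length(decoys))),
    row.names = ids)
  new("ReferenceDB",
      sequences = Biostrings::AAStringSet(c(targets, decoys)),
      isDecoy = c(rep(FALSE, length(targets)), rep(TRUE, length(decoys))),
      provenance = prov)
}

#' @rdname referenceDB
#' @param x a \code{ReferenceDB}
#' @export
setGeneric("targetIds", function(x) standardGeneric("targetIds"))
#' @export
setMethod("targetIds", "ReferenceDB",
          function(x) names(x@sequences)[!x@isDecoy])

#' @rdname referenceDB
#' @export
setGeneric("decoyIds", function(x) standardGeneric("decoyIds"))
#' @export
setMethod("decoyIds", "ReferenceDB",
          function(x) names(x@sequences)[x@isDecoy])

#' @rdname referenceDB
#' @export
setGeneric("dbSequences", function(x) standardGeneric("dbSequences"))
#' @export
setMethod("dbSequences", "ReferenceDB", function(x) x@sequences)

#' @rdname referenceDB
#' @export
setGeneric("isDecoy", function(x) standardGeneric("isDecoy"))
#' @export
setMethod("isDecoy", "ReferenceDB",
          function(x) stats::setNames(x@isDecoy, names(x@sequences)))

setMethod("show", "ReferenceDB", function(object) {
  cat(sprintf("ReferenceDB: %d targets, %d decoys\n",
              sum(!object@isDecoy), sum(object@isDecoy)))
  invisible(object)
})

setMethod("length", "ReferenceDB", function(x) length(x@sequences))
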