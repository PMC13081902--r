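#' @importFrom stats rnorm runif rbinom rnbinom qnorm setNames
NULL

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# most-frequent E. coli codon per amino acid; deterministic, so that
# six-frame translation of a reverse-translated protein round-trips exactly
.CODON_OF <- c(
  A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT", G = "GGC",
  H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
  P = "CCG", Q = "CAG", R = "CGC", S = "AGC", T = "ACC", V = "GTG",
  W = "TGG", Y = "TAT", X = "NNN"
)

#' Random protein sequence
#'
#' Uniform over the 20 standard amino acids; uses the current R RNG state
#' (seed with \code{set.seed} for reproducibility).
#'
#' @param n length in residues
#' @return protein string
#' @export
randomProtein <- function(n) {
  paste(sample(.AA20, n, replace = TRUE), collapse = "")
}

#' Mutate a protein toward a target percent identity
#'
#' Applies random substitutions (and, optionally, a small fraction of
#' indels) and re-measures global identity to the source until it falls
#' within +/- \code{window} points of \code{targetIdentity}. Positions in
#' \code{protect} (1-based on the source) are never touched, which keeps
#' key active-site residues intact in simulated homolog families.
#'
#' @param seq source protein string
#' @param targetIdentity desired percent identity in (0, 100]
#' @param protect integer positions never mutated
#' @param indelRate fraction of edits made as single-residue indels
#'   (default 0; capped at 0.05)
#' @param window acceptance half-width in identity points (default 2)
#' @param maxAttempts attempts before giving up (default 60)
#' @inheritParams globalAlign
#' @return mutated protein string
#' @export
mutateToIdentity <- function(seq, targetIdentity, protect = integer(),
                             indelRate = 0, window = 2, maxAttempts = 60,
                             matrix = substitutionMatrix(), gapOpen = 10,
                             gapExt = 0.5) {
  if (targetIdentity <= 0 || targetIdentity > 100)
    stop("targetIdentity must lie in (0, 100]")
  if (targetIdentity == 100) return(seq)
  indelRate <- min(indelRate, 0.05)
  L <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  free <- setdiff(seq_len(L), protect)
  k <- max(1L, round(L * (1 - targetIdentity / 100)))
  for (attempt in seq_len(maxAttempts)) {
    k <- min(k, length(free))
    mut <- chars
    pos <- sample(free, k)
    nIndel <- min(round(k * indelRate), floor(0.05 * L))
    subPos <- pos[seq_len(k - nIndel)]
    for (p in subPos)
      mut[p] <- sample(setdiff(.AA20, chars[p]), 1)
    if (nIndel > 0) {
      delPos <- pos[seq(k - nIndel + 1L, k)]
      mut[delPos] <- "" # deletions; insertions would shift protected columns
    }
    cand <- paste(mut, collapse = "")
    al <- globalAlign(cand, seq, matrix, gapOpen, gapExt)
    d <- identityPct(al) - targetIdentity
    if (abs(d) <= window) return(cand)
    # adjust the edit load proportionally and retry
    k <- max(1L, k + as.integer(round(d / 100 * L * 0.8)))
  }
  stop("could not reach ", targetIdentity, "% identity in ", maxAttempts,
       " attempts")
}

#' Deterministic reverse translation
#'
#' Encodes each residue with the most frequent E. coli codon, so that
#' translating frame +1 of the result returns the input exactly.
#'
#' @param protein protein string (standard residues plus X)
#' @return nucleotide coding sequence
#' @export
reverseTranslate <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  bad <- setdiff(unique(chars), names(.CODON_OF))
  if (length(bad)) stop("cannot encode residue(s): ", paste(bad, collapse = ", "))
  paste(.CODON_OF[chars], collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Simulate short metagenomic reads with known provenance
#'
#' Reads are drawn from the supplied coding sequences with probability
#' proportional to abundance times length, start positions uniform along
#' the gene, strand uniform, and independent per-base substitution errors
#' at \code{errorRate}. Every read's true source, position, strand and
#' error count are recorded in the returned truth table.
#'
#' @param cds named character vector of nucleotide coding sequences (all
#'   at least \code{readLen} long)
#' @param abundance named non-negative vector over the same genes, summing
#'   to 1 (relative community abundance)
#' @param nReads number of reads to draw
#' @param readLen read length in nt (default 150)
#' @param errorRate per-base substitution probability (default 0)
#' @return list: \code{reads} (named character vector) and \code{truth}
#'   (data.frame read_id, gene, start, strand, n_errors)
#' @export
simulateMetagenome <- function(cds, abundance, nReads, readLen = 150,
                               errorRate = 0) {
  stopifnot(length(cds) == length(abundance),
            all(names(abundance) %in% names(cds)))
  abundance <- abundance[names(cds)]
  if (abs(sum(abundance) - 1) > 1e-8)
    stop("abundances must sum to 1")
  lens <- nchar(cds)
  if (any(lens < readLen)) stop("every CDS must be at least readLen long")
  w <- abundance * lens
  gene <- sample(names(cds), nReads, replace = TRUE, prob = w / sum(w))
  start <- 1L + floor(runif(nReads) * (lens[gene] - readLen + 1L))
  strand <- sample(c("+", "-"), nReads, replace = TRUE)
  reads <- substring(cds[gene], start, start + readLen - 1L)
  minus <- strand == "-"
  if (any(minus))
    reads[minus] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reads[minus])))
  nerr <- integer(nReads)
  if (errorRate > 0) {
    nt <- c("A", "C", "G", "T")
    nerr <- rbinom(nReads, readLen, errorRate)
    for (i in which(nerr > 0L)) {
      pos <- sample.int(readLen, nerr[i])
      for (p in pos) {
        old <- substr(reads[i], p, p)
        substr(reads[i], p, p) <- sample(setdiff(nt, old), 1L)
      }
    }
  }
  ids <- sprintf("read_%06d", seq_len(nReads))
  names(reads) <- ids
  list(reads = reads,
       truth = data.frame(read_id = ids, gene = unname(gene),
                          start = unname(start), strand = strand,
                          n_errors = nerr, stringsAsFactors = FALSE))
}

#' Simulate a metabolite panel coupled to gene abundance
#'
#' The coupled metabolite is built through a Gaussian copula: normal
#' scores of the abundance ranks receive independent Gaussian noise whose
#' variance is calibrated in closed form so that the population Spearman
#' correlation equals \code{rhoTarget} (via the bivariate-normal identity
#' \code{rho_S = (6 / pi) asin(rho_P / 2)}), then mapped to a log-normal
#' concentration scale (a monotone transform, which leaves Spearman
#' untouched). Independent null metabolites are appended.
#'
#' @param geneAbundance named numeric vector, one value per sample
#' @param rhoTarget signed target Spearman correlation, |rho| < 1
#' @param direction +1 or -1; overrides the sign of \code{rhoTarget}
#' @param noiseSd if supplied, used directly as the noise standard
#'   deviation instead of the calibrated value (0 gives |rho| = 1)
#' @param nNull number of independent null metabolites (default 3)
#' @return list: \code{metabolites} (matrix samples x metabolites, the
#'   coupled one named \code{"coupled"}) and \code{params}
#' @export
simulateMetabolome <- function(geneAbundance, rhoTarget = -0.45,
                               direction = sign(rhoTarget), noiseSd = NULL,
                               nNull = 3) {
  n <- length(geneAbundance)
  if (n < 4L) stop("need at least 4 samples")
  if (abs(rhoTarget) >= 1) stop("|rhoTarget| must be < 1")
  z <- qnorm((rank(geneAbundance, ties.method = "average") - 0.5) / n)
  if (is.null(noiseSd)) {
    rhoP <- 2 * sin(pi * abs(rhoTarget) / 6)
    noiseSd <- sqrt(1 / rhoP^2 - 1)
  }
  y <- direction * z + noiseSd * rnorm(n)
  mets <- matrix(NA_real_, n, 1 + nNull,
                 dimnames = list(names(geneAbundance),
                                 c("coupled", if (nNull > 0)
                                   paste0("null_", seq_len(nNull)))))
  mets[, "coupled"] <- exp(2 + 0.8 * y) # log-normal concentration scale
  for (k in seq_len(nNull))
    mets[, 1 + k] <- exp(rnorm(n, mean = 2, sd = 1))
  list(metabolites = mets,
       params = list(rho_target = rhoTarget, direction = direction,
                     noise_sd = noiseSd, n = n))
}

#' Simulate replicate transcript counts with planted expression ranks
#'
#' Negative-binomial counts around a log-normal expected-TPM profile in
#' which designated genes are boosted by \code{foldChange}. Gene lengths
#' are drawn uniformly; expected counts are proportional to TPM times
#' length.
#'
#' @param nGenes,nReps dimensions (defaults 1000 genes, 4 replicates)
#' @param hotGenes indices (or count) of boosted genes (default 3 genes)
#' @param foldChange expression boost of the hot genes (default 10)
#' @param libSize expected reads per replicate (default 2e5)
#' @param dispersion NB dispersion (default 0.1)
#' @return list: counts (genes x reps), lengths, tpm_truth, hot (ids)
#' @export
simulateTranscripts <- function(nGenes = 1000, nReps = 4, hotGenes = 3,
                                foldChange = 10, libSize = 2e5,
                                dispersion = 0.1) {
  if (length(hotGenes) == 1L && hotGenes == round(hotGenes) && hotGenes < nGenes)
    hotGenes <- sample.int(nGenes, hotGenes)
  ids <- sprintf("gene_%04d", seq_len(nGenes))
  lengths <- sample(300:3000, nGenes, replace = TRUE)
  base <- exp(rnorm(nGenes, mean = 0, sd = 1))
  base[hotGenes] <- foldChange # fold times the unit base rate
  tpmTruth <- 1e6 * base / sum(base)
  mu <- tpmTruth / 1e6 * lengths
  mu <- mu / sum(mu) * libSize
  counts <- matrix(rnbinom(nGenes * nReps, mu = rep(mu, nReps),
                           size = 1 / dispersion),
                   nrow = nGenes,
                   dimnames = list(ids, paste0("rep_", seq_len(nReps))))
  list(counts = counts, lengths = setNames(lengths, ids),
       tpm_truth = setNames(tpmTruth, ids), hot = ids[hotGenes])
}

#' Simulate an initial-rate kinetics dataset
#'
#' Rates follow \code{v = Vmax S / (Km + S)} with multiplicative Gaussian
#' noise, over log-spaced substrate concentrations spanning the
#' assay-typical window.
#'
#' @param Vmax,Km true parameters (uM/s and uM)
#' @param S substrate levels in uM (default 12 log-spaced in 10..20000)
#' @param noiseSd multiplicative noise sd (default 0)
#' @param nRep replicates per level (default 1)
#' @return data.frame (S, v) with the truth in attributes Vmax, Km
#' @export
simulateKinetics <- function(Vmax, Km,
                             S = 10^seq(log10(10), log10(20000),
                                        length.out = 12),
                             noiseSd = 0, nRep = 1) {
  S <- rep(S, each = nRep)
  v <- Vmax * S / (Km + S) * (1 + noiseSd * rnorm(length(S)))
  out <- data.frame(S = S, v = v)
  attr(out, "Vmax") <- Vmax
  attr(out, "Km") <- Km
  out
}

#' Simulate a complete multi-omic community study with known truth
#'
#' Generates everything the quantification pipeline consumes: a target
#' gene family (homologs of one ancestral protein with key residues
#' protected) plus unrelated decoy proteins, their coding sequences,
#' per-sample short-read sets drawn at a log-normally varying family
#' abundance, per-sample sequencing statistics (total reads, average
#' genome size), and a metabolite panel negatively coupled to the
#' AGS-normalized family abundance. All randomness flows from
#' \code{seed}, so the same seed regenerates the study byte-identically.
#'
#' @param seed integer seed
#' @param nSamples number of samples (default 10)
#' @param nReads reads per sample (default 10000)
#' @param readLen read length in nt (default 150)
#' @param errorRate per-base substitution error (default 0.01)
#' @param nTargets family size (default 10)
#' @param nDecoys decoy count (default 50)
#' @param targetLen family protein length in aa (default 240)
#' @param decoyLenRange decoy protein length range (default 180..300)
#' @param familyIdentity identity band of family homologs to the ancestor,
#'   percent (default c(60, 85))
#' @param rhoTarget target Spearman coupling of the coupled metabolite
#'   (default -0.45)
#' @param meanLogAbundance,sdLogAbundance log-scale location/spread of the
#'   per-sample family relative abundance (defaults -2.3, 0.7: median
#'   about 10 percent of the community)
#' @param nNullMetabolites independent null metabolites (default 3)
#' @return a \code{SimTruth}-style list: db, cds, sampleStats, reads (per
#'   sample), readTruth, familyRelAbundance, familyAgsNorm, metabolites,
#'   params
#' @export
simulateCommunityStudy <- function(seed, nSamples = 10, nReads = 10000,
                                   readLen = 150, errorRate = 0.01,
                                   nTargets = 10, nDecoys = 50,
                                   targetLen = 240,
                                   decoyLenRange = c(180, 300),
                                   familyIdentity = c(60, 85),
                                   rhoTarget = -0.45,
                                   meanLogAbundance = -2.3,
                                   sdLogAbundance = 0.7,
                                   nNullMetabolites = 3) {
  set.seed(seed)
  profile <- keyResidueProfile()
  protect <- c(as.integer(names(profile$metal)),
               as.integer(names(profile$substrate)))
  protect <- protect[protect <= targetLen]
  # ancestor and homolog family
  anc <- randomProtein(targetLen)
  targets <- c(anc, vapply(seq_len(nTargets - 1L), function(i) {
    mutateToIdentity(anc, runif(1, familyIdentity[1], familyIdentity[2]),
                     protect = protect)
  }, character(1)))
  names(targets) <- sprintf("target_%02d", seq_len(nTargets))
  decoys <- vapply(seq_len(nDecoys), function(i)
    randomProtein(sample(decoyLenRange[1]:decoyLenRange[2], 1)), character(1))
  names(decoys) <- sprintf("decoy_%02d", seq_len(nDecoys))
  db <- referenceDB(targets, decoys)
  cds <- vapply(c(targets, decoys), reverseTranslate, character(1))
  # per-sample community composition and sequencing stats
  sampleIds <- sprintf("sample_%03d", seq_len(nSamples))
  famRel <- pmin(exp(rnorm(nSamples, meanLogAbundance, sdLogAbundance)), 0.6)
  names(famRel) <- sampleIds
  ags <- runif(nSamples, 2.5e6, 5.5e6)
  sampleStats <- data.frame(sample_id = sampleIds,
                            total_reads = rep(nReads, nSamples),
                            ags_bp = ags, stringsAsFactors = FALSE)
  # family genes split the family share unevenly but consistently
  famSplit <- runif(nTargets, 0.5, 1.5)
  famSplit <- famSplit / sum(famSplit)
  reads <- vector("list", nSamples)
  readTruth <- vector("list", nSamples)
  names(reads) <- names(readTruth) <- sampleIds
  for (s in seq_len(nSamples)) {
    ab <- c(famRel[s] * famSplit,
            rep((1 - famRel[s]) / nDecoys, nDecoys))
    names(ab) <- names(cds)
    sim <- simulateMetagenome(cds, ab, nReads, readLen, errorRate)
    names(sim$reads) <- paste0(sampleIds[s], "_", names(sim$reads))
    sim$truth$read_id <- names(sim$reads)
    sim$truth$sample_id <- sampleIds[s]
    reads[[s]] <- sim$reads
    readTruth[[s]] <- sim$truth
  }
  famAgsNorm <- famRel / (ags / 1e6)
  met <- simulateMetabolome(famAgsNorm, rhoTarget = rhoTarget,
                            nNull = nNullMetabolites)
  structure(list(
    db = db, cds = cds, sampleStats = sampleStats, reads = reads,
    readTruth = do.call(rbind, readTruth),
    familyRelAbundance = famRel, familyAgsNorm = famAgsNorm,
    metabolites = met$metabolites,
    params = list(seed = seed, nSamples = nSamples, nReads = nReads,
                  readLen = readLen, errorRate = errorRate,
                  nTargets = nTargets, nDecoys = nDecoys,
                  rhoTarget = rhoTarget,
                  metabolome = met$params)
  ), class = "SimTruth")
}

#' Write the ground truth of a simulated study as JSON
#'
#' Serializes the scalar/tabular truth (abundances, coupling parameters,
#' read provenance, sample statistics) - not the sequence data, which
#' travels as FASTA/FASTQ.
#'
#' @param truth a \code{SimTruth} list from [simulateCommunityStudy()]
#' @param path output JSON file
#' @export
writeSimTruth <- function(truth, path) {
  payload <- list(
    params = truth$params,
    sample_stats = truth$sampleStats,
    family_rel_abundance = as.list(truth$familyRelAbundance),
    family_ags_norm = as.list(truth$familyAgsNorm),
    read_truth = truth$readTruth
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
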