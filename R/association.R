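#' Spearman rank correlation with t-approximation p-value
#'
#' Pairs with a missing value in either vector are dropped. The
#' coefficient is the Pearson correlation of average-ranked data (average
#' ranks for ties); the p-value uses the t approximation
#' \code{t = rho * sqrt((n - 2) / (1 - rho^2))} on n - 2 degrees of
#' freedom, adequate for the sample sizes this package targets (tens to
#' hundreds). For n < 10 an exact permutation p-value is available.
#'
#' @param x,y numeric vectors of equal length
#' @param exact compute the exact permutation p-value (only for n < 10)
#' @return list: rho, p, n; for a constant input, \code{rho} and \code{p}
#'   are NA with \code{degenerate = TRUE} (no error is thrown)
#' @export
spearmanTest <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(list(rho = NA_real_, p = NA_real_, n = n, degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact && n < 10L) {
    perms <- .permutations(n)
    obs <- abs(rho)
    cnt <- 0L
    for (i in seq_len(nrow(perms))) {
      if (abs(stats::cor(rx, ry[perms[i, ]])) >= obs - 1e-12) cnt <- cnt + 1L
    }
    p <- cnt / nrow(perms)
  } else {
    if (abs(rho) >= 1) {
      p <- .Machine$double.xmin # perfect monotone association
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- max(2 * stats::pt(-abs(tstat), df = n - 2), .Machine$double.xmin)
    }
  }
  list(rho = rho, p = p, n = n, degenerate = FALSE)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment: with m p-values sorted ascending,
#' \code{p_adj(i) = min over j >= i of m * p(j) / j}, clipped at 1 and
#' returned in the input order.
#'
#' @param p numeric vector of raw p-values in (0, 1]
#' @return adjusted p-values
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Chi-square test of equal detection proportions
#'
#' Pearson chi-square on the groups x {detected, not detected} contingency
#' table, df = groups - 1. No continuity correction by default; set
#' \code{yates = TRUE} for the corrected 2-group version.
#'
#' @param nDetected per-group number of samples with the gene detected
#' @param nSamples per-group total number of samples
#' @param yates apply Yates continuity correction (2 groups only)
#' @return list: chi2, p, df, proportions
#' @export
chiSquareProportions <- function(nDetected, nSamples, yates = FALSE) {
  if (length(nDetected) != length(nSamples) || length(nDetected) < 2L)
    stop("need >= 2 groups with matching vectors")
  if (any(nDetected < 0) || any(nDetected > nSamples))
    stop("0 <= nDetected <= nSamples violated")
  tab <- rbind(detected = nDetected, not_detected = nSamples - nDetected)
  exp0 <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(exp0 == 0)) stop("degenerate table: zero expected count")
  ht <- suppressWarnings(stats::chisq.test(t(tab), correct = yates))
  list(chi2 = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter),
       proportions = nDetected / nSamples)
}

#' Half-minimum pseudo-count and log transform
#'
#' Computes one pseudo-count for the whole matrix - half of its minimum
#' non-zero value - adds it uniformly, and (optionally) log-transforms.
#' This is the zero-handling used for visualizing gene abundances (log2)
#' and metabolite concentrations (log10); association statistics run on
#' untransformed values (rank-based statistics are invariant to the
#' monotone transform anyway). \code{scope = "column"} computes a
#' pseudo-count per column instead.
#'
#' @param values numeric matrix (or vector) with at least one non-zero
#'   entry; NAs are carried through
#' @param logBase 2, 10, or NA for no transform
#' @param scope \code{"matrix"} (default) or \code{"column"}
#' @return list: transformed matrix and the pseudo-count(s) used
#' @export
halfMinPseudocount <- function(values, logBase = NA,
                               scope = c("matrix", "column")) {
  scope <- match.arg(scope)
  vec <- !is.matrix(values)
  m <- as.matrix(values)
  pcOf <- function(v) {
    nz <- v[!is.na(v) & v > 0]
    if (!length(nz)) stop("no non-zero value to derive the pseudo-count from")
    min(nz) / 2
  }
  if (scope == "matrix") {
    pc <- pcOf(m)
    out <- m + pc
  } else {
    pc <- apply(m, 2, pcOf)
    out <- sweep(m, 2, pc, "+")
  }
  if (!is.na(logBase)) out <- log(out, base = logBase)
  if (vec) out <- drop(out)
  list(values = out, pseudocount = pc)
}

#' Gene family vs metabolite panel association
#'
#' Restricts to samples present in both tables (paired design), computes
#' the Spearman correlation of the summed family abundance against each
#' metabolite on untransformed values, and adjusts p-values across the
#' panel by Benjamini-Hochberg. Missing metabolite values are dropped
#' pairwise.
#'
#' @param abundance named numeric vector of per-sample family abundance
#'   (e.g. [familyAbundance()]), names = sample ids
#' @param metabolites numeric matrix samples x metabolites with sample ids
#'   as rownames (blanks/NA = missing)
#' @param geneSetId label for the gene set (default "family")
#' @param minPairs minimum paired samples required per metabolite
#' @return data.frame: gene_set_id, metabolite_id, n, rho, p_raw, p_adj
#' @export
correlateMultiomics <- function(abundance, metabolites,
                                geneSetId = "family", minPairs = 4L) {
  metabolites <- as.matrix(metabolites)
  shared <- intersect(names(abundance), rownames(metabolites))
  if (length(shared) < minPairs) {
    warning("fewer than ", minPairs, " paired samples; empty result")
    return(data.frame(gene_set_id = character(), metabolite_id = character(),
                      n = integer(), rho = numeric(), p_raw = numeric(),
                      p_adj = numeric()))
  }
  ab <- abundance[shared]
  res <- lapply(colnames(metabolites), function(met) {
    y <- metabolites[shared, met]
    st <- spearmanTest(ab, y)
    data.frame(gene_set_id = geneSetId, metabolite_id = met, n = st$n,
               rho = st$rho, p_raw = st$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$p_raw)
  out$p_adj <- NA_real_
  if (any(ok)) out$p_adj[ok] <- bhAdjust(out$p_raw[ok])
  out
}

#' Per-group prevalence with chi-square test
#'
#' @param presence named logical vector of per-sample presence calls
#' @param groups named character/factor vector of group labels (same
#'   sample ids)
#' @param yates see [chiSquareProportions()]
#' @return list: table (group, n_samples, n_detected, prevalence), chi2,
#'   p, df
#' @export
prevalenceTest <- function(presence, groups, yates = FALSE) {
  shared <- intersect(names(presence), names(groups))
  if (!length(shared)) stop("no shared sample ids")
  g <- factor(groups[shared])
  pr <- presence[shared]
  nS <- as.integer(table(g))
  nD <- as.integer(tapply(pr, g, sum))
  ht <- chiSquareProportions(nD, nS, yates = yates)
  list(table = data.frame(group = levels(g), n_samples = nS,
                          n_detected = nD, prevalence = nD / nS),
       chi2 = ht$chi2, p = ht$p, df = ht$df)
}
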