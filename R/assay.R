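#' Fit the Michaelis-Menten equation to initial-rate data
#'
#' Unweighted nonlinear least squares of \code{v = Vmax * S / (Km + S)}
#' via Levenberg-Marquardt (\pkg{minpack.lm}), initialized at
#' \code{Vmax0 = max(v)} and \code{Km0 = S} at half-maximal rate. When an
#' enzyme concentration is supplied, \code{kcat = Vmax / [E]} and the
#' catalytic efficiency \code{kcat / Km} are reported in 1/(M s) (with S
#' in uM and rates in uM/s). Non-convergence yields a flagged result, not
#' an error.
#'
#' @param S substrate concentrations (uM), >= 5 levels
#' @param v initial rates (uM/s), same length
#' @param enzymeNM enzyme concentration in nM (optional; enables kcat)
#' @param maxIter maximum iterations (default 500)
#' @param tol relative tolerance on the parameter change (default 1e-10)
#' @return an [MMFit-class]
#' @export
fitMM <- function(S, v, enzymeNM = NA_real_, maxIter = 500, tol = 1e-10) {
  if (length(S) != length(v)) stop("S and v must have equal length")
  if (length(S) < 5L) stop("need at least 5 substrate levels")
  if (any(S <= 0)) stop("substrate concentrations must be positive")
  vmax0 <- max(v)
  km0 <- S[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(S)
  dat <- data.frame(S = S, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = dat,
                      start = list(Vmax = vmax0, Km = km0),
                      lower = c(Vmax = 0, Km = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = maxIter, ptol = tol, ftol = tol)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new("MMFit", Vmax = NA_real_, Km = NA_real_, kcat = NA_real_,
               kcatOverKm = NA_real_, se = c(Vmax = NA_real_, Km = NA_real_),
               converged = FALSE, fit = NULL))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  kcat <- if (is.na(enzymeNM)) NA_real_ else unname(cf["Vmax"]) /
    (enzymeNM / 1000) # uM/s over uM -> 1/s
  kOverKm <- if (is.na(kcat)) NA_real_ else kcat / (unname(cf["Km"]) * 1e-6)
  new("MMFit", Vmax = unname(cf["Vmax"]), Km = unname(cf["Km"]),
      kcat = kcat, kcatOverKm = kOverKm,
      se = c(Vmax = unname(se[1]), Km = unname(se[2])),
      converged = TRUE, fit = fit)
}

setMethod("show", "MMFit", function(object) {
  if (!object@converged) {
    cat("MMFit: did not converge\n")
    return(invisible(object))
  }
  cat(sprintf("MMFit: Vmax = %.4g, Km = %.4g", object@Vmax, object@Km))
  if (!is.na(object@kcat))
    cat(sprintf(", kcat = %.4g 1/s, kcat/Km = %.3g 1/(M s)",
                object@kcat, object@kcatOverKm))
  cat("\n")
  invisible(object)
})

#' @rdname fitMM
#' @param x an \code{MMFit}
#' @export
setGeneric("mmParameters", function(x) standardGeneric("mmParameters"))
#' @export
setMethod("mmParameters", "MMFit", function(x)
  c(Vmax = x@Vmax, Km = x@Km, kcat = x@kcat, kcat_over_Km = x@kcatOverKm))

#' End-point activity percentages
#'
#' \code{relativeActivity}: product in the test condition as a percentage
#' of the product in the control under initial-rate conditions.
#' \code{conversionRate}: product generated by a variant as a percentage
#' of the wild-type product after extended incubation. Both are
#' \code{100 * x / reference} and require a positive reference.
#'
#' @param test,control,variant,wildtype product concentrations (>= 0;
#'   reference > 0)
#' @return percent
#' @export
relativeActivity <- function(test, control) {
  if (any(control <= 0)) stop("control product must be positive")
  if (any(test < 0)) stop("test product must be non-negative")
  100 * test / control
}

#' @rdname relativeActivity
#' @export
conversionRate <- function(variant, wildtype) {
  if (any(wildtype <= 0)) stop("wild-type product must be positive")
  if (any(variant < 0)) stop("variant product must be non-negative")
  100 * variant / wildtype
}

# CODATA/IUPAC monoisotopic masses (u), 6+ decimals; electron included in
# ion m/z so that calculated adducts match high-resolution MS conventions.
.MONO_MASS <- c(
  C = 12.000000, H = 1.00782503, N = 14.00307401, O = 15.99491462,
  Na = 22.98976928, S = 31.97207069, P = 30.97376151, K = 38.96370690,
  Cl = 34.96885271
)
.ELECTRON_MASS <- 0.00054858

#' Parse a molecular formula
#'
#' @param formula e.g. \code{"C24H41NO5"}
#' @return named integer vector element -> count
#' @export
parseFormula <- function(formula) {
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", formula))
    stop("malformed formula: ", formula)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  ct <- as.integer(ifelse(grepl("[0-9]$", toks),
                          sub("^[A-Z][a-z]?", "", toks), "1"))
  counts <- tapply(ct, el, sum)
  out <- stats::setNames(as.integer(counts), names(counts))
  bad <- setdiff(names(out), names(.MONO_MASS))
  if (length(bad))
    stop("element(s) without a monoisotopic mass: ", paste(bad, collapse = ", "))
  out
}

#' Exact adduct m/z from a neutral formula
#'
#' Monoisotopic m/z of common electrospray adducts:
#' \code{(sum of atomic masses - charge * electron mass) / |charge|},
#' with the neutral formula doubled for dimeric adducts before the
#' charge carrier is added.
#'
#' @param formula neutral molecular formula, e.g. \code{"C24H41NO5"}
#' @param adduct one of \code{"M+H"}, \code{"2M+H"}, \code{"2M+Na"},
#'   \code{"M-H"}, \code{"M+Na"}
#' @return m/z
#' @examples
#' adductMz("C24H41NO5", "M+H") # taurine-conjugate standard, [M+H]+
#' @export
adductMz <- function(formula, adduct = c("M+H", "2M+H", "2M+Na", "M-H",
                                         "M+Na")) {
  adduct <- match.arg(adduct)
  counts <- parseFormula(formula)
  neutral <- sum(.MONO_MASS[names(counts)] * counts)
  switch(adduct,
    "M+H" = neutral + .MONO_MASS["H"] - .ELECTRON_MASS,
    "M+Na" = neutral + .MONO_MASS["Na"] - .ELECTRON_MASS,
    "2M+H" = 2 * neutral + .MONO_MASS["H"] - .ELECTRON_MASS,
    "2M+Na" = 2 * neutral + .MONO_MASS["Na"] - .ELECTRON_MASS,
    "M-H" = neutral - .MONO_MASS["H"] + .ELECTRON_MASS
  ) |> unname()
}

#' Exact m/z of an ion formula as printed
#'
#' For calculated values quoted directly as ion formulas (e.g.
#' \code{C24H42NO5+}): subtracts \code{charge} electron masses and divides
#' by \code{|charge|}.
#'
#' @param formula ion formula without the charge sign
#' @param charge integer charge (non-zero)
#' @return m/z
#' @export
ionMz <- function(formula, charge = 1L) {
  if (charge == 0) stop("charge must be non-zero")
  counts <- parseFormula(formula)
  msum <- sum(.MONO_MASS[names(counts)] * counts)
  unname((msum - charge * .ELECTRON_MASS) / abs(charge))
}

#' Distance between the two metal atoms of a dinuclear site
#'
#' Reads ATOM/HETATM records (via \pkg{bio3d}) and reports the Euclidean
#' distance between the closest pair of distinct atoms of the requested
#' element, preferring pairs within a single chain. Coordinates may also
#' be given directly as a matrix.
#'
#' @param x path to a PDB file, a \code{bio3d} pdb object, or a numeric
#'   matrix of coordinates (rows = atoms of the element, columns x,y,z)
#' @param element element symbol to search for (default \code{"ZN"})
#' @return distance in Angstrom
#' @export
metalPairDistance <- function(x, element = "ZN") {
  if (is.matrix(x)) {
    xyz <- x
    chain <- rep("A", nrow(xyz))
  } else {
    pdb <- if (inherits(x, "pdb")) x else bio3d::read.pdb(x)
    sel <- toupper(trimws(pdb$atom$elesy)) == toupper(element)
    if (!any(sel)) # fall back on atom names when the element column is blank
      sel <- toupper(trimws(pdb$atom$elety)) == toupper(element)
    xyz <- as.matrix(pdb$atom[sel, c("x", "y", "z")])
    chain <- pdb$atom$chain[sel]
  }
  if (nrow(xyz) < 2L)
    stop("fewer than two ", element, " atoms found")
  best <- Inf
  bestSame <- Inf
  for (i in seq_len(nrow(xyz) - 1L)) {
    for (j in seq(i + 1L, nrow(xyz))) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= 0) next # the same position listed twice is not a pair
      if (d < best) best <- d
      if (!is.na(chain[i]) && !is.na(chain[j]) && chain[i] == chain[j] &&
          d < bestSame) bestSame <- d
    }
  }
  out <- if (is.finite(bestSame)) bestSame else best
  if (!is.finite(out)) stop("no distinct atom pair found")
  out
}
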