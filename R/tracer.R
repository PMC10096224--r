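# Stable-isotope tracer arithmetic: natural-abundance correction matrices,
# non-negative least-squares correction, and the relative-enrichment
# statistic for labeled-vs-unlabeled experiments.

# Natural isotope compositions (atom fractions by mass shift relative to the
# lightest isotope), NIST standard atomic weights compilation. Fluorine and
# phosphorus are monoisotopic.
ISOTOPE_ABUNDANCE <- list(
  C  = c(0.9893, 0.0107),
  H  = c(0.999885, 0.000115),
  N  = c(0.99636, 0.00364),
  O  = c(0.99757, 0.00038, 0.00205),
  Si = c(0.92223, 0.04685, 0.03092),
  S  = c(0.9499, 0.0075, 0.0425, 0.0000, 0.0001),
  P  = 1,
  F  = 1
)

polyConvolve <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

elementDistribution <- function(element, count) {
  if (!element %in% names(ISOTOPE_ABUNDANCE))
    stop("unknown element symbol: '", element, "'", call. = FALSE)
  if (count == 0) return(1)
  Reduce(polyConvolve, rep(list(ISOTOPE_ABUNDANCE[[element]]), count))
}

#' Parse a molecular formula string
#'
#' @param formula e.g. `"C6H14N2O2"`; element symbols with optional counts.
#' @return named numeric vector, element -> atom count.
#' @examples
#' parseFormula("C6H14N2O2")
#' @export
parseFormula <- function(formula) {
  if (is.numeric(formula)) return(formula)  # already parsed
  if (!length(formula) || !nzchar(formula)) return(numeric())
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!length(parts) || paste(parts, collapse = "") != formula)
    stop("cannot parse formula: '", formula, "'", call. = FALSE)
  counts <- numeric()
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    k <- sub("^[A-Z][a-z]?", "", p)
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0) +
      (if (nzchar(k)) as.numeric(k) else 1)
  }
  counts
}

#' Natural-abundance correction matrix
#'
#' Column `j` (0-based) is the isotopologue distribution that a species with
#' exactly `j` tracer-labeled atoms is predicted to produce at the detector:
#' the convolution of the natural isotope distributions of all non-label
#' atoms with that of the `n - j` unlabeled atoms of the label element,
#' shifted up by `j` mass units. Each column sums to at most 1 (mass shifts
#' beyond the measured window M+0..M+n are truncated). Tracer isotopic
#' purity is assumed to be 1.
#'
#' @param formula elemental composition of the quantified fragment
#'   (string or named count vector), including derivatisation-added atoms.
#' @param labelElement element carrying the tracer label (default `"C"`).
#' @param nLabelPositions number of label positions `n`; the measured
#'   vector has length `n + 1`.
#' @return an `(n+1) x (n+1)` matrix, columns `M0..Mn`.
#' @export
correctionMatrix <- function(formula, labelElement = "C",
                             nLabelPositions) {
  counts <- parseFormula(formula)
  nLabelAtoms <- if (labelElement %in% names(counts))
    counts[[labelElement]] else 0
  if (nLabelAtoms < nLabelPositions)
    stop("formula has ", nLabelAtoms, " atom(s) of ", labelElement,
         " but ", nLabelPositions, " label positions were requested",
         call. = FALSE)
  # label-element atoms are handled per column below
  otherDist <- 1
  for (el in setdiff(names(counts), labelElement))
    otherDist <- polyConvolve(otherDist,
                              elementDistribution(el, counts[[el]]))
  nOut <- nLabelPositions + 1L
  M <- matrix(0, nOut, nOut,
              dimnames = list(paste0("M", 0:(nOut - 1L)),
                              paste0("M", 0:(nOut - 1L))))
  for (j in 0:nLabelPositions) {
    unlabeled <- elementDistribution(labelElement, nLabelAtoms - j)
    dist <- polyConvolve(otherDist, unlabeled)
    for (i in j:nLabelPositions) {
      shift <- i - j
      if (shift + 1L <= length(dist)) M[i + 1L, j + 1L] <- dist[shift + 1L]
    }
  }
  M
}

#' Correct an isotopologue vector for natural abundance
#'
#' Solves `matrix %*% x = intensities` by non-negative least squares
#' (Lawson-Hanson, via [pracma::lsqnonneg()]) and renormalises the solution
#' to fractions. The relative residual is reported for noisy inputs whose
#' negative components were clipped at zero by the NNLS constraint.
#'
#' @param x an [IsotopologueVector-class] or plain non-negative numeric
#'   vector (M+0 first).
#' @param cmat correction matrix from [correctionMatrix()]; dimensions must
#'   match.
#' @return for vector input, a list with `fractions` and `residual`;
#'   for an `IsotopologueVector`, the corrected object (fractions, flag
#'   set) with the residual in attribute `"residual"`.
#' @export
correctNaturalAbundance <- function(x, cmat) {
  vec <- if (is(x, "IsotopologueVector")) x@intensities else x
  if (is(x, "IsotopologueVector") && x@corrected)
    stop("vector is already corrected", call. = FALSE)
  if (all(vec == 0)) stop("all-zero isotopologue vector", call. = FALSE)
  if (length(vec) != nrow(cmat))
    stop("intensity vector length ", length(vec),
         " does not match correction matrix dimension ", nrow(cmat),
         call. = FALSE)
  fit <- pracma::lsqnonneg(cmat, as.numeric(vec))
  sol <- fit$x
  if (sum(sol) <= 0) stop("degenerate NNLS solution", call. = FALSE)
  fractions <- sol / sum(sol)
  residual <- sqrt(sum((cmat %*% sol - vec)^2)) / sqrt(sum(vec^2))
  if (is(x, "IsotopologueVector")) {
    out <- new("IsotopologueVector", compound = x@compound,
               formula = x@formula, intensities = fractions,
               corrected = TRUE)
    attr(out, "residual") <- residual
    out
  } else {
    list(fractions = fractions, residual = residual)
  }
}

#' Relative isotopic enrichment of labeled vs unlabeled samples
#'
#' For each isotopologue `i`, `R_i` is the difference between the M+0
#' normalised abundances in the labeled and unlabeled samples,
#' `R_i = labeled_i / labeled_0 - unlabeled_i / unlabeled_0`, and the
#' relative enrichment is `R_i / (R_i + 1) * 100` percent. Comparing
#' against the paired unlabeled sample subtracts the natural-abundance
#' contribution without requiring a correction matrix, which is why this
#' statistic is applied to uncorrected intensities.
#'
#' A zero M+0 intensity makes the statistic undefined: the result is `NA`
#' (never 0). `R_i <= -1` likewise yields `NA`.
#'
#' @param labeled,unlabeled [IsotopologueVector-class] objects or plain
#'   intensity vectors of equal length (same compound and fragment).
#' @return data.frame with columns `isotopologue`, `R`,
#'   `enrichment_pct`.
#' @examples
#' relativeEnrichment(c(100, 100), c(100, 0))   # R = 1  -> 50 %
#' relativeEnrichment(c(100, 50), c(100, 25))   # R = 0.25 -> 20 %
#' @export
relativeEnrichment <- function(labeled, unlabeled) {
  lab <- if (is(labeled, "IsotopologueVector")) labeled@intensities
         else labeled
  unl <- if (is(unlabeled, "IsotopologueVector")) unlabeled@intensities
         else unlabeled
  if (is(labeled, "IsotopologueVector") &&
      is(unlabeled, "IsotopologueVector") &&
      !identical(labeled@compound, unlabeled@compound))
    stop("labeled and unlabeled vectors are for different compounds",
         call. = FALSE)
  if (length(lab) != length(unl))
    stop("labeled and unlabeled vectors differ in length", call. = FALSE)
  n <- length(lab) - 1L
  if (lab[1] <= 0 || unl[1] <= 0) {
    warning("zero M+0 intensity: enrichment undefined, reported as NA",
            call. = FALSE)
    return(data.frame(isotopologue = paste0("M+", 0:n),
                      R = NA_real_, enrichment_pct = NA_real_))
  }
  R <- lab / lab[1] - unl / unl[1]
  enr <- ifelse(R > -1, R / (R + 1) * 100, NA_real_)
  data.frame(isotopologue = paste0("M+", 0:n), R = R,
             enrichment_pct = enr)
}

#' Construct an IsotopologueVector
#'
#' @param compound compound label.
#' @param intensities non-negative M+0..M+n vector.
#' @param formula fragment elemental composition (string or named counts),
#'   including derivatisation atoms; optional when no matrix correction is
#'   intended.
#' @param corrected logical flag.
#' @return an [IsotopologueVector-class].
#' @export
isotopologueVector <- function(compound, intensities, formula = numeric(),
                               corrected = FALSE) {
  new("IsotopologueVector", compound = compound,
      formula = parseFormula(formula), intensities = as.numeric(intensities),
      corrected = corrected)
}
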