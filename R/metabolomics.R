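# Targeted metabolomics preprocessing (blank subtraction, normalisation to
# total quantified metabolites) and pairwise differential abundance with
# Benjamini-Hochberg adjustment.

#' Construct an AbundanceExperiment
#'
#' @param values metabolite x sample numeric matrix of peak areas
#'   (instrument units); rownames are metabolite ids, colnames sample ids.
#' @param group character vector of group labels per sample (e.g. `"WT"`,
#'   `"dhgd-1"`); blanks may use any label.
#' @param replicate optional replicate index per sample.
#' @param isBlank logical vector flagging extraction/solvent blank samples.
#' @return an [AbundanceExperiment-class].
#' @export
AbundanceExperiment <- function(values, group,
                                replicate = seq_len(ncol(values)),
                                isBlank = rep(FALSE, ncol(values))) {
  values <- as.matrix(values)
  stopifnot(length(group) == ncol(values),
            length(isBlank) == ncol(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = values),
    colData = S4Vectors::DataFrame(group = as.character(group),
                                   replicate = replicate,
                                   is_blank = as.logical(isBlank)))
  out <- new("AbundanceExperiment", se)
  S4Vectors::metadata(out)$normalized <- FALSE
  S4Vectors::metadata(out)$blank_subtracted <- FALSE
  validObject(out)
  out
}

#' Blank-subtract and total-normalise an abundance table
#'
#' Subtracts the mean blank value per metabolite from every non-blank
#' sample, flooring negative differences at zero (floored cells are flagged
#' in the `"floored"` assay), then divides each sample by its own total over
#' all quantified metabolites, so every normalised sample sums to 1. Blank
#' columns are dropped from the result. Calling it on an already-normalised
#' object is a guarded no-op.
#'
#' @param x an [AbundanceExperiment-class].
#' @param subtractBlanks set `FALSE` to skip blank subtraction (only the
#'   normalisation is applied, e.g. when no blanks were acquired).
#' @return a normalised [AbundanceExperiment-class] without blank columns;
#'   metadata records `blank_means` and `sample_totals`.
#' @examples
#' ae <- AbundanceExperiment(
#'   cbind(s1 = c(m1 = 4, m2 = 6), blank = c(1, 1)),
#'   group = c("WT", "blank"), isBlank = c(FALSE, TRUE))
#' SummarizedExperiment::assay(preprocessAbundance(ae))  # 0.375, 0.625
#' @export
preprocessAbundance <- function(x, subtractBlanks = TRUE) {
  stopifnot(is(x, "AbundanceExperiment"))
  if (isTRUE(S4Vectors::metadata(x)$normalized)) {
    message("abundance table already normalised; returning unchanged")
    return(x)
  }
  blank <- SummarizedExperiment::colData(x)$is_blank
  if (all(blank)) stop("all samples are blanks", call. = FALSE)
  vals <- SummarizedExperiment::assay(x, "abundance")[, !blank,
                                                      drop = FALSE]
  blankMeans <- rep(0, nrow(vals))
  didSubtract <- FALSE
  if (subtractBlanks && any(blank)) {
    blankMeans <- rowMeans(
      SummarizedExperiment::assay(x, "abundance")[, blank, drop = FALSE])
    vals <- vals - blankMeans
    didSubtract <- TRUE
  }
  floored <- vals < 0
  vals[floored] <- 0
  totals <- colSums(vals)
  if (any(totals <= 0))
    stop("zero total quantified signal in sample(s): ",
         paste(colnames(vals)[totals <= 0], collapse = ", "), call. = FALSE)
  vals <- sweep(vals, 2, totals, "/")
  cd <- SummarizedExperiment::colData(x)[!blank, , drop = FALSE]
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(abundance = vals, floored = floored), colData = cd)
  out <- new("AbundanceExperiment", se)
  S4Vectors::metadata(out)$normalized <- TRUE
  S4Vectors::metadata(out)$blank_subtracted <- didSubtract
  S4Vectors::metadata(out)$blank_means <- blankMeans
  S4Vectors::metadata(out)$sample_totals <- totals
  out
}

welchP <- function(a, b, varEqual) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: constant groups; identical means are maximally
    # consistent with the null, unequal ones maximally inconsistent
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  tryCatch(stats::t.test(a, b, var.equal = varEqual)$p.value,
           error = function(e) NA_real_)
}

#' Per-metabolite differential abundance between two groups
#'
#' Two-sample t test (Welch unequal-variance by default) per metabolite on
#' the normalised values, fold change `mean(groupB) / mean(groupA)`
#' reported as log2, and Benjamini-Hochberg step-up adjustment across all
#' metabolites.
#'
#' @param x a normalised [AbundanceExperiment-class] (see
#'   [preprocessAbundance()]).
#' @param groupA,groupB group labels to compare (fold change is B over A).
#' @param varEqual use the pooled-variance t test instead of Welch.
#' @return data.frame with columns `metabolite`, `mean_a`, `mean_b`,
#'   `log2fc`, `pvalue`, `padj`, ordered as in the input.
#' @export
differentialAbundance <- function(x, groupA, groupB, varEqual = FALSE) {
  stopifnot(is(x, "AbundanceExperiment"))
  if (!isTRUE(S4Vectors::metadata(x)$normalized))
    stop("normalise the table first with preprocessAbundance()",
         call. = FALSE)
  grp <- SummarizedExperiment::colData(x)$group
  ia <- which(grp == groupA)
  ib <- which(grp == groupB)
  if (length(ia) < 2 || length(ib) < 2)
    stop("need >= 2 replicates per group (", groupA, ": ", length(ia),
         ", ", groupB, ": ", length(ib), ")", call. = FALSE)
  vals <- SummarizedExperiment::assay(x, "abundance")
  res <- data.frame(metabolite = rownames(vals),
                    mean_a = rowMeans(vals[, ia, drop = FALSE]),
                    mean_b = rowMeans(vals[, ib, drop = FALSE]),
                    stringsAsFactors = FALSE, row.names = NULL)
  res$log2fc <- log2(res$mean_b / res$mean_a)
  res$pvalue <- vapply(seq_len(nrow(vals)), function(i)
    welchP(vals[i, ia], vals[i, ib], varEqual), numeric(1))
  res$padj <- stats::p.adjust(res$pvalue, method = "BH")
  res
}
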