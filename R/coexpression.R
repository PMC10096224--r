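# Coexpression compendium construction and correlation ranking.

#' Build a z-normalised multi-dataset expression compendium
#'
#' Datasets with fewer than `minConditions` conditions are dropped. Within
#' every retained dataset each gene row is z-normalised (mean 0, sd 1);
#' constant rows, whose z-score is undefined, are dropped and logged. The
#' normalised datasets are concatenated column-wise over the union of
#' genes; a gene absent from a dataset carries `NA` in its columns.
#' Z-normalisation preserves within-dataset Pearson correlations exactly.
#'
#' @param datasets named list of genes x conditions numeric matrices (gene
#'   ids as rownames).
#' @param minConditions minimum number of conditions for a dataset to enter
#'   the compendium (default 10).
#' @return an [ExpressionCompendium-class].
#' @export
buildCompendium <- function(datasets, minConditions = 10) {
  if (!length(datasets)) stop("no datasets supplied", call. = FALSE)
  if (is.null(names(datasets)))
    names(datasets) <- paste0("dataset", seq_along(datasets))
  info <- data.frame(id = names(datasets),
                     n_conditions = vapply(datasets, ncol, integer(1)),
                     retained = vapply(datasets, ncol, integer(1)) >=
                       minConditions,
                     stringsAsFactors = FALSE, row.names = NULL)
  kept <- datasets[info$retained]
  if (!length(kept))
    stop("no dataset has at least ", minConditions, " conditions",
         call. = FALSE)
  dropped <- list()
  znorm <- lapply(names(kept), function(id) {
    m <- as.matrix(kept[[id]])
    sds <- apply(m, 1, stats::sd)
    constant <- is.na(sds) | sds == 0
    dropped[[id]] <<- rownames(m)[constant]
    m <- m[!constant, , drop = FALSE]
    z <- t(scale(t(m)))
    colnames(z) <- paste(id, seq_len(ncol(z)), sep = ".")
    z
  })
  names(znorm) <- names(kept)
  genes <- sort(unique(unlist(lapply(znorm, rownames))))
  big <- matrix(NA_real_, length(genes),
                sum(vapply(znorm, ncol, integer(1))),
                dimnames = list(genes, unlist(lapply(znorm, colnames))))
  at <- 0L
  for (z in znorm) {
    big[rownames(z), at + seq_len(ncol(z))] <- z
    at <- at + ncol(z)
  }
  new("ExpressionCompendium", exprs = big, datasets = info,
      droppedGenes = dropped)
}

#' Rank genes by Pearson correlation with a query gene
#'
#' Pairwise-complete Pearson correlation of every gene with the query
#' across the pooled compendium conditions. Gene pairs sharing fewer than
#' `minShared` non-missing conditions are excluded from the list (their
#' correlation is considered undefined). Ties are broken by lexicographic
#' gene id; the query is excluded from its own list.
#'
#' @param compendium an [ExpressionCompendium-class].
#' @param query query gene id (at least 3 non-missing values required).
#' @param minShared minimum shared non-missing conditions per pair
#'   (default 10).
#' @return data.frame with columns `gene`, `r`, `n_shared`, sorted by
#'   decreasing `r`; attribute `"query"` carries the query id.
#' @export
rankByCorrelation <- function(compendium, query, minShared = 10) {
  M <- compendiumMatrix(compendium)
  if (!query %in% rownames(M))
    stop("query gene '", query, "' absent from compendium", call. = FALSE)
  q <- M[query, ]
  if (sum(!is.na(q)) < 3)
    stop("query gene has fewer than 3 non-missing values", call. = FALSE)
  others <- setdiff(rownames(M), query)
  r <- suppressWarnings(
    as.vector(stats::cor(t(M[others, , drop = FALSE]), q,
                         use = "pairwise.complete.obs")))
  shared <- as.vector((!is.na(M[others, , drop = FALSE])) %*%
                        as.numeric(!is.na(q)))
  keep <- !is.na(r) & shared >= minShared
  out <- data.frame(gene = others[keep], r = r[keep],
                    n_shared = shared[keep], stringsAsFactors = FALSE)
  out <- out[order(-out$r, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "query") <- query
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member gene ids, tab
#' separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[`, "", 1L))
}
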