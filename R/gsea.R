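# Preranked gene set enrichment analysis, classic weighted
# Kolmogorov-Smirnov running-sum form with a gene-label permutation null.
#
# Conventions: hit increments are |r|^p (weight exponent p, default 1)
# normalised to the set total; miss decrements are 1/(N - k); the
# enrichment score is the running-sum extreme of larger magnitude. The
# normalised enrichment score divides the observed ES by the mean |null ES|
# of the same sign, and the false discovery rate follows the
# positive/negative-tail convention: for a set with NES*, the ratio of the
# fraction of pooled same-sign null NES at least as extreme to the fraction
# of observed same-sign NES at least as extreme, clipped to [0, 1].

# ES from sorted hit positions only: the running sum attains its extremes
# immediately after a hit (maxima) or immediately before one (minima), so
# the full N-step walk is not needed.
esFromPositions <- function(positions, weights, N) {
  k <- length(positions)
  pos <- sort(positions)
  w <- weights[pos]
  sw <- sum(w)
  hitCum <- if (sw > 0) cumsum(w) / sw else seq_len(k) / k
  missBefore <- (pos - seq_len(k)) / (N - k)
  devAfter <- hitCum - missBefore
  devBefore <- c(0, hitCum[-k]) - missBefore
  up <- max(devAfter)
  down <- min(devBefore)
  if (up >= -down) up else down
}

#' Preranked gene set enrichment analysis
#'
#' Runs the weighted running-sum enrichment statistic over a ranked gene
#' list for every gene set, with a gene-label permutation null (the only
#' null available for an externally ranked list). Sets overlapping the
#' ranked universe in fewer than `minSize` genes are skipped and reported
#' via the `"skipped"` attribute. Results are bit-for-bit reproducible for
#' a fixed `seed` and permutation count.
#'
#' @param ranked data.frame with columns `gene` and `r` (output of
#'   [rankByCorrelation()]), or a named numeric vector of ranking scores.
#' @param geneSets named list of character vectors (e.g. from [readGMT()]).
#' @param nPermutations permutation count for the null (default 1000).
#' @param seed RNG seed for the permutations.
#' @param weightExponent running-sum weight exponent `p` on `|r|`
#'   (default 1, the classic weighted statistic).
#' @param minSize minimum overlap with the ranked universe (default 2).
#' @return data.frame with columns `pathway`, `size`, `ES`, `NES`,
#'   `pval`, `FDR`; attribute `"skipped"` lists skipped sets.
#' @export
prerankedGSEA <- function(ranked, geneSets, nPermutations = 1000,
                          seed = 1, weightExponent = 1, minSize = 2) {
  if (is.data.frame(ranked)) {
    ord <- order(-ranked$r, ranked$gene)
    stats_ <- stats::setNames(ranked$r[ord], ranked$gene[ord])
  } else {
    stats_ <- sort(ranked, decreasing = TRUE)
  }
  if (!length(geneSets)) stop("empty gene-set collection", call. = FALSE)
  genes <- names(stats_)
  N <- length(stats_)
  w <- abs(stats_)^weightExponent

  overlap <- lapply(geneSets, function(s) which(genes %in% s))
  sizes <- lengths(overlap)
  skipped <- names(geneSets)[sizes < minSize]
  keep <- names(geneSets)[sizes >= minSize]
  if (!length(keep))
    stop("no gene set overlaps the ranked universe in at least ",
         minSize, " genes", call. = FALSE)

  esObs <- vapply(keep, function(nm)
    esFromPositions(overlap[[nm]], w, N), numeric(1))

  # size-matched permutation null per set, one RNG stream for the lot
  runif(1)  # force RNG initialisation before seeding
  old <- .Random.seed
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  uniqueSizes <- sort(unique(sizes[keep]))
  nullBySize <- list()
  for (k in uniqueSizes) {
    nullBySize[[as.character(k)]] <- vapply(seq_len(nPermutations),
      function(b) esFromPositions(sample.int(N, k), w, N), numeric(1))
  }

  res <- data.frame(pathway = keep, size = sizes[keep], ES = esObs,
                    NES = NA_real_, pval = NA_real_, FDR = NA_real_,
                    stringsAsFactors = FALSE, row.names = NULL)
  nesNullAll <- numeric()
  for (i in seq_len(nrow(res))) {
    nullES <- nullBySize[[as.character(res$size[i])]]
    same <- if (res$ES[i] >= 0) nullES[nullES >= 0] else nullES[nullES < 0]
    if (length(same)) {
      res$NES[i] <- res$ES[i] / mean(abs(same))
      res$pval[i] <- (sum(abs(same) >= abs(res$ES[i])) + 1) /
        (length(same) + 1)
    }
  }
  # pooled null NES for the FDR (each set's null normalised like the set)
  nullNES <- unlist(lapply(seq_len(nrow(res)), function(i) {
    nullES <- nullBySize[[as.character(res$size[i])]]
    pos <- nullES[nullES >= 0]
    neg <- nullES[nullES < 0]
    c(if (length(pos)) pos / mean(abs(pos)) else numeric(),
      if (length(neg)) neg / mean(abs(neg)) else numeric())
  }))
  for (i in seq_len(nrow(res))) {
    nes <- res$NES[i]
    if (is.na(nes)) next
    if (nes >= 0) {
      nullTail <- nullNES[nullNES >= 0]
      pNull <- if (length(nullTail)) mean(nullTail >= nes) else 0
      obsTail <- res$NES[!is.na(res$NES) & res$NES >= 0]
      pObs <- mean(obsTail >= nes)
    } else {
      nullTail <- nullNES[nullNES < 0]
      pNull <- if (length(nullTail)) mean(nullTail <= nes) else 0
      obsTail <- res$NES[!is.na(res$NES) & res$NES < 0]
      pObs <- mean(obsTail <= nes)
    }
    res$FDR[i] <- min(1, pNull / max(pObs, 1 / nrow(res)))
  }
  attr(res, "skipped") <- skipped
  res[order(res$FDR, res$pval), , drop = FALSE]
}
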