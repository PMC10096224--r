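test_that("z-normalisation gives mean 0, sd 1 within each dataset", {
  set.seed(1)
  ds <- list(d1 = matrix(rnorm(60, mean = 5, sd = 3), 5, 12,
                         dimnames = list(paste0("g", 1:5), NULL)))
  comp <- buildCompendium(ds)
  M <- compendiumMatrix(comp)
  expect_equal(unname(rowMeans(M)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(M, 1, sd)), rep(1, 5), tolerance = 1e-12)
})

test_that("datasets below the condition filter are excluded", {
  set.seed(2)
  g <- paste0("g", 1:4)
  ds <- list(big = matrix(rnorm(48), 4, 12, dimnames = list(g, NULL)),
             small = matrix(rnorm(36), 4, 9, dimnames = list(g, NULL)))
  comp <- buildCompendium(ds)
  expect_identical(datasetInfo(comp)$retained, c(TRUE, FALSE))
  expect_equal(ncol(compendiumMatrix(comp)), 12)
  expect_error(buildCompendium(ds["small"]), "at least 10 conditions")
})

test_that("partially shared genes merge with missing values", {
  set.seed(3)
  d1 <- matrix(rnorm(40), 4, 10,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  d2 <- matrix(rnorm(40), 4, 10,
               dimnames = list(c("c", "d", "e", "f"), NULL))
  comp <- buildCompendium(list(x = d1, y = d2))
  M <- compendiumMatrix(comp)
  expect_equal(dim(M), c(6, 20))
  expect_true(all(is.na(M["a", 11:20])))
  expect_true(all(is.na(M["e", 1:10])))
  expect_true(all(!is.na(M["c", ])))
})

test_that("constant gene rows are dropped and logged", {
  set.seed(4)
  d <- matrix(rnorm(30), 3, 10, dimnames = list(c("g1", "g2", "g3"), NULL))
  d["g2", ] <- 7
  comp <- buildCompendium(list(d = d))
  expect_false("g2" %in% rownames(compendiumMatrix(comp)))
  expect_identical(comp@droppedGenes$d, "g2")
})

test_that("z-normalisation preserves within-dataset Pearson correlations", {
  set.seed(5)
  d <- matrix(rnorm(100), 10, 10, dimnames = list(paste0("g", 1:10), NULL))
  d <- d * runif(10, 1, 10) + runif(10, -5, 5)   # arbitrary scale per row
  comp <- buildCompendium(list(d = d))
  M <- compendiumMatrix(comp)
  expect_equal(cor(t(M)), cor(t(d[rownames(M), ])), tolerance = 1e-12)
})

test_that("correlation ranking is exact for perfect and anti correlation", {
  set.seed(6)
  base <- rnorm(15)
  d <- rbind(query = base, twin = base, anti = -base,
             noise1 = rnorm(15), noise2 = rnorm(15))
  comp <- buildCompendium(list(d = d))
  ranked <- rankByCorrelation(comp, "query")
  expect_false("query" %in% ranked$gene)
  expect_identical(ranked$gene[1], "twin")
  expect_equal(ranked$r[1], 1, tolerance = 1e-12)
  expect_identical(ranked$gene[nrow(ranked)], "anti")
  expect_equal(ranked$r[nrow(ranked)], -1, tolerance = 1e-12)
  expect_error(rankByCorrelation(comp, "absent"), "absent")
})

test_that("pairs with too few shared conditions are excluded", {
  set.seed(7)
  d1 <- matrix(rnorm(30), 3, 10,
               dimnames = list(c("q", "a", "b"), NULL))
  d2 <- matrix(rnorm(20), 2, 10, dimnames = list(c("q", "c"), NULL))
  comp <- buildCompendium(list(d1 = d1, d2 = d2))
  ranked <- rankByCorrelation(comp, "q", minShared = 15)
  expect_false(any(c("a", "b", "c") %in% ranked$gene))  # 10 shared < 15
  ranked2 <- rankByCorrelation(comp, "q", minShared = 10)
  expect_setequal(ranked2$gene, c("a", "b", "c"))
})

test_that("rank ties break lexicographically by gene id", {
  d <- rbind(q = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             zz = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             aa = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  comp <- buildCompendium(list(d = d))
  ranked <- rankByCorrelation(comp, "q")
  expect_identical(ranked$gene, c("aa", "zz"))
})

test_that("the running-sum ES matches the brute-force walk and fgsea", {
  set.seed(8)
  for (i in 1:25) {
    N <- sample(10:50, 1)
    k <- sample(2:min(8, N - 2), 1)
    stats_ <- sort(rnorm(N), decreasing = TRUE)
    names(stats_) <- paste0("g", seq_len(N))
    hits <- sort(sample(N, k))
    esPkg <- b12flux:::esFromPositions(hits, abs(stats_), N)
    esBrute <- bruteForceES(stats_, seq_len(N) %in% hits, p = 1)
    expect_equal(esPkg, esBrute, tolerance = 1e-12)
    esFgsea <- fgsea::calcGseaStat(stats_, selectedStats = hits,
                                   gseaParam = 1)
    expect_equal(esPkg, esFgsea, tolerance = 1e-9)
  }
})

test_that("a set of the top-ranked genes is maximally enriched", {
  set.seed(9)
  stats_ <- sort(abs(rnorm(200, sd = 2)), decreasing = TRUE)
  names(stats_) <- paste0("g", 1:200)
  res <- prerankedGSEA(stats_, list(top = names(stats_)[1:15]),
                       nPermutations = 500, seed = 1)
  expect_gt(res$ES[1], 0.9)
  expect_lt(res$FDR[1], 0.01)
})

test_that("undersized sets are skipped and logged; empty collections error", {
  set.seed(10)
  stats_ <- sort(rnorm(50), decreasing = TRUE)
  names(stats_) <- paste0("g", 1:50)
  res <- prerankedGSEA(stats_, list(ok = c("g1", "g5", "g9"),
                                    tiny = "g2",
                                    gone = c("zz1", "zz2")),
                       nPermutations = 100, seed = 2)
  expect_identical(sort(attr(res, "skipped")), c("gone", "tiny"))
  expect_identical(res$pathway, "ok")
  expect_error(prerankedGSEA(stats_, list()), "empty gene-set")
})

test_that("permutation results are bit-for-bit reproducible given a seed", {
  set.seed(11)
  stats_ <- sort(rnorm(100), decreasing = TRUE)
  names(stats_) <- paste0("g", 1:100)
  sets <- list(s1 = paste0("g", c(1, 4, 9, 16, 25)),
               s2 = paste0("g", c(90, 91, 95)))
  a <- prerankedGSEA(stats_, sets, nPermutations = 300, seed = 7)
  b <- prerankedGSEA(stats_, sets, nPermutations = 300, seed = 7)
  expect_identical(a, b)
  c_ <- prerankedGSEA(stats_, sets, nPermutations = 300, seed = 8)
  expect_false(identical(a$FDR, c_$FDR))
})

test_that("a planted coexpression module is recovered by rank and by GSEA", {
  hitsTop20 <- 0
  fdrHits <- 0
  nrep <- 15
  for (s in seq_len(nrep)) {
    sim <- makeCompendium(seed = 500 + s)
    comp <- buildCompendium(sim$datasets)
    query <- sim$truth$module[1]
    ranked <- rankByCorrelation(comp, query)
    others <- setdiff(sim$truth$module, query)
    if (all(match(others, ranked$gene) <= 20))
      hitsTop20 <- hitsTop20 + 1
    sets <- list(module = sim$truth$module,
                 random = sample(rownames(compendiumMatrix(comp)), 6))
    res <- prerankedGSEA(ranked, sets, nPermutations = 200,
                         seed = s)
    if (res$FDR[res$pathway == "module"] <= 0.05)
      fdrHits <- fdrHits + 1
  }
  expect_gte(hitsTop20, nrep - 1)
  expect_gte(fdrHits, nrep - 1)
})

test_that("GMT files round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tanother\tg9\tg2"), path)
  sets <- readGMT(path)
  expect_identical(sets, list(setA = c("g1", "g2", "g3"),
                              setB = c("g9", "g2")))
})
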