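test_that("monoisotopic fragments give an identity correction matrix", {
  M <- correctionMatrix("P4", labelElement = "P", nLabelPositions = 3)
  expect_equal(M, diag(4), ignore_attr = TRUE)
})

test_that("CO2 correction matrix matches the hand-computed binomial", {
  a13C <- 0.0107
  aO <- c(0.99757, 0.00038, 0.00205)
  M <- correctionMatrix("CO2", labelElement = "C", nLabelPositions = 1)
  # column 0: unlabeled CO2; M+0 = 12C * (16O)^2, M+1 adds one mass unit
  # from either 13C or one 17O
  expect_equal(M[1, 1], (1 - a13C) * aO[1]^2)
  expect_equal(M[2, 1], a13C * aO[1]^2 + (1 - a13C) * 2 * aO[1] * aO[2])
  # column 1: the single carbon is labeled; no unlabeled carbon remains
  expect_equal(M[1, 2], 0)
  expect_equal(M[2, 2], aO[1]^2)
})

test_that("a fully labeled fragment contributes nothing below M+n", {
  M <- correctionMatrix("C6H12O6", labelElement = "C", nLabelPositions = 6)
  expect_true(all(M[1:6, 7] == 0))
  expect_gt(M[7, 7], 0.9)
  # every column is a (truncated) probability distribution
  expect_true(all(colSums(M) <= 1 + 1e-12))
  expect_true(all(M >= 0))
})

test_that("an unlabeled measurement corrects to pure M+0", {
  M <- correctionMatrix("C6H14N2O2", "C", 3)
  res <- correctNaturalAbundance(M[, 1], M)
  expect_equal(res$fractions, c(1, 0, 0, 0), tolerance = 1e-10)
  expect_lt(res$residual, 1e-12)
})

test_that("natural-abundance round-trip recovers planted fractions", {
  truth <- c(0.7, 0, 0.3)
  M <- correctionMatrix("C6H14N2O2", "C", 2)
  measured <- as.vector(M %*% truth)
  res <- correctNaturalAbundance(measured, M)
  expect_equal(res$fractions, truth, tolerance = 1e-6)
})

test_that("noisy inputs are clipped at zero with a reported residual", {
  M <- correctionMatrix("C3H6O3", "C", 2)
  measured <- as.vector(M %*% c(0.9, 0.1, 0)) + c(-0.03, 0.002, 0.001)
  measured <- pmax(measured, 0)
  res <- correctNaturalAbundance(measured, M)
  expect_true(all(res$fractions >= 0))
  expect_equal(sum(res$fractions), 1)
  expect_gt(res$residual, 0)
})

test_that("correction guards: corrected flag, zero input, size mismatch", {
  M <- correctionMatrix("C3H6O3", "C", 2)
  v <- isotopologueVector("lactate", c(100, 10, 1), "C3H6O3")
  corr <- correctNaturalAbundance(v, M)
  expect_true(isCorrected(corr))
  expect_error(correctNaturalAbundance(corr, M), "already corrected")
  expect_error(correctNaturalAbundance(c(0, 0, 0), M), "all-zero")
  expect_error(correctNaturalAbundance(c(1, 2), M), "does not match")
})

test_that("relative enrichment reproduces the closed-form values", {
  # R = 1 -> 50 %
  e1 <- relativeEnrichment(c(100, 100), c(100, 0))
  expect_equal(e1$enrichment_pct[2], 50)
  # R = 0.25 -> 20 %
  e2 <- relativeEnrichment(c(100, 50), c(100, 25))
  expect_equal(e2$R[2], 0.25)
  expect_equal(e2$enrichment_pct[2], 20)
  # identical samples -> 0 % everywhere
  e3 <- relativeEnrichment(c(80, 40, 10), c(80, 40, 10))
  expect_equal(e3$enrichment_pct, c(0, 0, 0))
})

test_that("enrichment is scale invariant and monotone in the labeled ratio", {
  set.seed(11)
  for (i in 1:20) {
    lab <- runif(4, 1, 100)
    unl <- runif(4, 1, 100)
    base <- relativeEnrichment(lab, unl)
    scaled <- relativeEnrichment(lab * runif(1, 0.1, 50),
                                 unl * runif(1, 0.1, 50))
    expect_equal(scaled$enrichment_pct, base$enrichment_pct,
                 tolerance = 1e-10)
  }
  ratios <- seq(0.1, 2, by = 0.1)
  enr <- vapply(ratios, function(r)
    relativeEnrichment(c(100, 100 * r), c(100, 5))$enrichment_pct[2],
    numeric(1))
  expect_true(all(diff(enr) > 0))
})

test_that("zero M+0 yields NA, never zero", {
  expect_warning(res <- relativeEnrichment(c(0, 10), c(100, 5)),
                 "undefined")
  expect_true(all(is.na(res$enrichment_pct)))
})

test_that("isotopologue fixtures: noiseless unlabeled equals column 0", {
  fix <- makeIsotopologueFixtures(c(0.7, 0, 0.3), noiseCV = 0,
                                  nReplicates = 1, seed = 5)
  unl <- intensities(fix$unlabeled[[1]])
  expect_equal(unl / sum(unl) * sum(fix$matrix[, 1]),
               unname(fix$matrix[, 1]), tolerance = 1e-10)
  # round-trip through the correction recovers the planted labeling
  lab <- correctNaturalAbundance(intensities(fix$labeled[[1]]),
                                 fix$matrix)
  expect_equal(lab$fractions, c(0.7, 0, 0.3), tolerance = 1e-6)
})

test_that("fixture generation is a pure function of its seed", {
  a <- makeIsotopologueFixtures(c(0.5, 0.5), seed = 9)
  b <- makeIsotopologueFixtures(c(0.5, 0.5), seed = 9)
  expect_identical(lapply(a$labeled, intensities),
                   lapply(b$labeled, intensities))
  c_ <- makeIsotopologueFixtures(c(0.5, 0.5), seed = 10)
  expect_false(identical(intensities(a$labeled[[1]]),
                         intensities(c_$labeled[[1]])))
})

test_that("noisy round-trip stays within noise bounds over replicates", {
  errs <- vapply(1:200, function(s) {
    fix <- makeIsotopologueFixtures(c(0.6, 0.1, 0.3), noiseCV = 0.05,
                                    nReplicates = 1, seed = 1000 + s)
    got <- correctNaturalAbundance(intensities(fix$labeled[[1]]),
                                   fix$matrix)$fractions
    max(abs(got - c(0.6, 0.1, 0.3)))
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
  expect_lt(max(errs), 0.2)
})

test_that("fraction guards reject bad labeling vectors", {
  expect_error(makeIsotopologueFixtures(c(0.5, 0.6)), "sum to 1")
  expect_error(makeIsotopologueFixtures(c(1.2, -0.2)), "negative")
  expect_error(correctionMatrix("C2H4", "C", 3), "2 atom")
  expect_error(correctionMatrix("C2Zz4", "C", 2), "unknown element|parse")
})
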