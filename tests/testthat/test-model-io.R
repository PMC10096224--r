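test_that("the bundled toy-network file loads and matches the generator", {
  path <- system.file("extdata", "toy_network.json", package = "b12flux")
  m <- readNetworkModel(path)
  toy <- makeToyNetwork()$model
  expect_equal(nReactions(m), nReactions(toy))
  expect_identical(m@reactions, toy@reactions)
  expect_equal(stoichMatrix(m), stoichMatrix(toy))
})

test_that("JSON write/read round-trips a model field by field", {
  toy <- makeToyNetwork()$model
  path <- withr::local_tempfile(fileext = ".json")
  writeNetworkModel(toy, path)
  back <- readNetworkModel(path)
  expect_identical(back@metabolites, toy@metabolites)
  expect_identical(back@reactions, toy@reactions)
  expect_equal(stoichMatrix(back), stoichMatrix(toy))
})

test_that("validation flags exactly the seeded defects", {
  toy <- makeToyNetwork()$model
  path <- withr::local_tempfile(fileext = ".json")
  writeNetworkModel(toy, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)

  # duplicate reaction id
  d1 <- doc
  d1$reactions[[2]]$id <- d1$reactions[[1]]$id
  p1 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(d1, p1, auto_unbox = TRUE, digits = NA)
  expect_error(readNetworkModel(p1), "duplicate reaction id.*R_EX_FOOD")

  # stoichiometry referencing an unknown metabolite, named in the error
  d2 <- doc
  d2$reactions[[3]]$metabolites <- list(X_missing = -1)
  p2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(d2, p2, auto_unbox = TRUE, digits = NA)
  expect_error(readNetworkModel(p2), "R_DIGEST_ALT.*X_missing")

  # inverted bounds
  d3 <- doc
  d3$reactions[[1]]$lower_bound <- 5
  d3$reactions[[1]]$upper_bound <- 3
  p3 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(d3, p3, auto_unbox = TRUE, digits = NA)
  expect_error(readNetworkModel(p3), "lower_bound > upper_bound.*R_EX_FOOD")

  # the pristine file still validates
  expect_s4_class(validateNetworkModel(readNetworkModel(path)),
                  "MetabolicNetwork")
})

test_that("huge or non-finite bounds map to the +/-1000 sentinel", {
  toy <- makeToyNetwork()$model
  path <- withr::local_tempfile(fileext = ".json")
  writeNetworkModel(toy, path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$reactions[[2]]$lower_bound <- -1e7
  doc$reactions[[2]]$upper_bound <- 1e22
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  m <- readNetworkModel(path)
  expect_equal(reactionBounds(m)$lower_bound[2], -1000)
  expect_equal(reactionBounds(m)$upper_bound[2], 1000)
})

test_that("setReactionBounds edits one reaction and rejects inversions", {
  toy <- makeToyNetwork()$model
  m <- setReactionBounds(toy, "R_GLYX", lower = 0)
  expect_equal(reactionBounds(m)$lower_bound[match("R_GLYX",
                                                   reactionIds(m))], 0)
  m2 <- setReactionBounds(m, "R_EX_PROPSEC", upper = 0)
  i <- match("R_EX_PROPSEC", reactionIds(m2))
  expect_equal(reactionBounds(m2)$upper_bound[i], 0)
  untouched <- setdiff(seq_len(nReactions(toy)),
                       match(c("R_GLYX", "R_EX_PROPSEC"),
                             reactionIds(toy)))
  expect_identical(m2@reactions[untouched, ], toy@reactions[untouched, ])
  expect_error(setReactionBounds(toy, "R_EX_FOOD", lower = 5, upper = 3),
               "lower bound.*exceeds upper")
  expect_error(setReactionBounds(toy, "nope", lower = 0),
               "unknown reaction")
})

test_that("knockoutReactions zeroes bounds, is idempotent, no-op on empty", {
  toy <- makeToyNetwork()$model
  expect_identical(knockoutReactions(toy, character()), toy)
  k1 <- knockoutReactions(toy, "R_AASS")
  i <- match("R_AASS", reactionIds(k1))
  expect_equal(unlist(reactionBounds(k1)[i, 2:3], use.names = FALSE),
               c(0, 0))
  expect_identical(knockoutReactions(k1, "R_AASS"), k1)
  # knocked-out lysine entry carries zero flux in any optimal solution
  sol <- maximizeFlux(knockoutReactions(toy, "R_AASS"), "R_ATPM")
  expect_equal(unname(sol@fluxes["R_AASS"]), 0)
})

test_that("restrictGeneToReactions prunes rules, never touches stoichiometry", {
  toy <- makeToyNetwork()$model
  expect_match(geneRules(toy)[["R_MSA"]], "hphd-1")
  m <- restrictGeneToReactions(toy, "hphd-1", "R_HPHD")
  expect_identical(geneRules(m)[["R_MSA"]], "alh-8")
  expect_identical(geneRules(m)[["R_HPHD"]], "hphd-1")
  expect_equal(stoichMatrix(m), stoichMatrix(toy))
  expect_identical(reactionBounds(m), reactionBounds(toy))
  expect_identical(attr(m, "emptiedRules"), character())

  # keeping every carrier leaves the model unchanged
  carriers <- names(geneRules(toy))[vapply(
    geneRules(toy), function(r) "alh-8" %in% b12flux:::ruleGenes(r),
    logical(1))]
  m2 <- restrictGeneToReactions(toy, "alh-8", carriers)
  expect_identical(geneRules(m2), geneRules(toy))

  # a rule made empty is reported
  m3 <- restrictGeneToReactions(toy, "dhgd-1", character())
  expect_identical(attr(m3, "emptiedRules"), "R_DHGD")
  expect_identical(geneRules(m3)[["R_DHGD"]], "")

  expect_error(restrictGeneToReactions(toy, "nosuchgene", "R_HPHD"),
               "absent from model.*aass-1")
})

test_that("boolean gene rules parse, simplify and deparse", {
  expect_identical(b12flux:::ruleGenes("(a and b) or (c and d)"),
                   c("a", "b", "c", "d"))
  tree <- b12flux:::parseGeneRule("(a and b) or c")
  expect_identical(b12flux:::deparseGeneRule(tree), "a and b or c")
  pruned <- b12flux:::dropGeneFromTree(tree, "a")
  expect_identical(b12flux:::deparseGeneRule(pruned), "b or c")
  expect_error(b12flux:::parseGeneRule("a and (b or"), "parenthes|malformed")
})

test_that("the SBML FBC reader recovers species, bounds and gene rules", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(tinySBML(), path)
  m <- readNetworkModel(path)
  # boundary species B is outside the balanced system
  expect_identical(metaboliteIds(m), "A")
  expect_identical(reactionIds(m), c("up", "conv"))
  expect_equal(reactionBounds(m)$upper_bound, c(10, 1000))  # big -> sentinel
  expect_identical(geneRules(m)[["conv"]], "gene1 and gene2")
  expect_equal(stoichMatrix(m)["A", "conv"], -1)
  sol <- maximizeFlux(m, "conv")
  expect_equal(sol@objectiveValue, 10)
})
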