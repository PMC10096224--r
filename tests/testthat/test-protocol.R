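toy <- makeToyNetwork()
ppt <- runB12Protocol(toy$model, toyIdMap())
tab <- potentialTable(ppt)

test_that("every production potential equals the closed-form truth", {
  cmp <- merge(tab, toy$truth$table,
               by = c("scenario", "b12", "objective"),
               suffixes = c("", "_truth"))
  expect_equal(nrow(cmp), 24)
  expect_identical(cmp$status, cmp$status_truth)
  expect_equal(cmp$value, cmp$value_truth, tolerance = 1e-8)
  expect_equal(ppt@baseline, toy$truth$baseline, tolerance = 1e-8)
  expect_equal(ppt@lowB12Baseline, toy$truth$lowB12Baseline,
               tolerance = 1e-8)
})

test_that("single perturbations are neutral: low B12 alone and dhgd KO alone", {
  wt <- tab[tab$scenario == "WT" & tab$b12 == "replete", ]
  for (cell in list(tab[tab$scenario == "WT" & tab$b12 == "low", ],
                    tab[tab$scenario == "dhgd-1 KO" &
                          tab$b12 == "replete", ])) {
    m <- merge(wt, cell, by = "objective")
    expect_equal(m$value.x, m$value.y, tolerance = 1e-9)
  }
})

test_that("low B12 plus dhgd KO strictly reduces all three potentials", {
  wtLow <- tab[tab$scenario == "WT" & tab$b12 == "low", ]
  dhgdLow <- tab[tab$scenario == "dhgd-1 KO" & tab$b12 == "low", ]
  m <- merge(wtLow, dhgdLow, by = "objective")
  expect_true(all(m$value.y < m$value.x - 1e-9))
})

test_that("cumulative knockouts are non-increasing within each condition", {
  for (b12 in c("replete", "low")) {
    for (ob in unique(tab$objective)) {
      v <- tab$value[tab$b12 == b12 & tab$objective == ob]
      v <- v[order(tab$scenario[tab$b12 == b12 & tab$objective == ob])]
      v <- v[!is.na(v)]
      expect_true(all(diff(v) <= 1e-9))
    }
  }
})

test_that("applyBaseConstraints applies both edits and is idempotent", {
  m1 <- applyBaseConstraints(toy$model, toyIdMap())
  i <- match(c("R_GLYX", "R_EX_PROPSEC"), reactionIds(m1))
  expect_equal(reactionBounds(m1)$lower_bound[i[1]], 0)
  expect_equal(reactionBounds(m1)$upper_bound[i[2]], 0)
  expect_identical(applyBaseConstraints(m1, toyIdMap()), m1)
  noSec <- toy$model
  noSec@reactions <- noSec@reactions[noSec@reactions$id != "R_EX_PROPSEC", ]
  noSec@stoichiometry <-
    noSec@stoichiometry[, colnames(noSec@stoichiometry) != "R_EX_PROPSEC"]
  expect_error(applyBaseConstraints(noSec, toyIdMap()),
               "R_EX_PROPSEC \\(propionate_secretion\\)")
})

test_that("background activity: B12-independent biomass gives ratio 1", {
  m <- applyBaseConstraints(toy$model, toyIdMap())
  bg <- computeBackgroundActivity(m, toyIdMap())
  expect_equal(bg$lowB12Baseline, bg$baseline)
  i <- match("R_BIO", reactionIds(bg$model))
  expect_equal(reactionBounds(bg$model)$lower_bound[i], bg$lowB12Baseline)
  # MS cap removed from the returned model
  j <- match("R_MS", reactionIds(bg$model))
  expect_equal(reactionBounds(bg$model)$upper_bound[j],
               reactionBounds(m)$upper_bound[j])
})

test_that("background activity: MS-coupled biomass drops by half the cap", {
  v <- makeToyNetwork(toyNetworkSpec(biomassRequiresMet = TRUE))
  m <- applyBaseConstraints(v$model, toyIdMap())
  bg <- computeBackgroundActivity(m, toyIdMap())
  expect_equal(bg$baseline, v$truth$baseline, tolerance = 1e-8)
  expect_equal(bg$lowB12Baseline, v$truth$lowB12Baseline, tolerance = 1e-8)
  expect_equal(bg$msCap, v$truth$msCap, tolerance = 1e-8)
})

test_that("a prior MS knockout gives a zero cap, biomass still feasible", {
  m <- applyBaseConstraints(knockoutReactions(toy$model, "R_MS"),
                            toyIdMap())
  bg <- computeBackgroundActivity(m, toyIdMap())
  expect_equal(bg$msCap, 0)
  expect_equal(bg$lowB12Baseline, bg$baseline)  # biomass is MS-independent
})

test_that("applyLowB12 closes the canonical route, leaves the shunt open", {
  m <- applyBaseConstraints(toy$model, toyIdMap())
  bg <- computeBackgroundActivity(m, toyIdMap())
  low <- applyLowB12(bg$model, toyIdMap(), bg$msCap)
  i <- match("R_MUT", reactionIds(low))
  expect_equal(unlist(reactionBounds(low)[i, 2:3], use.names = FALSE),
               c(0, 0))
  expect_identical(applyLowB12(low, toyIdMap(), bg$msCap), low)
  # propionate can still be disposed of through the shunt
  sol <- maximizeFlux(low, "R_ATPM")
  expect_identical(sol@status, "optimal")
  expect_gt(unname(sol@fluxes["R_HPHD"]), 0)
})

test_that("infeasible scenario cells are reported as such, not as zero", {
  iv <- makeToyNetwork(toyNetworkSpec(maintenance = 6))
  tab2 <- potentialTable(runB12Protocol(iv$model, toyIdMap()))
  cmp <- merge(tab2, iv$truth$table,
               by = c("scenario", "b12", "objective"),
               suffixes = c("", "_truth"))
  expect_identical(cmp$status, cmp$status_truth)
  inf <- cmp[cmp$status == "infeasible", ]
  expect_gt(nrow(inf), 0)
  expect_true(all(is.na(inf$value)))
  # zero-valued optimal cells coexist and are distinct from infeasible ones
  zero <- tab[tab$value == 0 & tab$status == "optimal", ]
  expect_gt(nrow(zero), 0)
  expect_equal(cmp$value, cmp$value_truth, tolerance = 1e-8)
})

test_that("an incomplete id map is rejected before any computation", {
  expect_error(runB12Protocol(toy$model, toyIdMap()[-1]),
               "missing role\\(s\\): biomass")
  wrong <- toyIdMap()
  wrong[["dhgd"]] <- "R_NOPE"
  expect_error(runB12Protocol(toy$model, wrong), "R_NOPE \\(dhgd\\)")
})

test_that("the constraint log records the ordered edits", {
  expect_match(constraintLog(ppt)[1], "R_GLYX")
  expect_match(constraintLog(ppt)[2], "R_EX_PROPSEC")
  expect_true(any(grepl("background metabolic activity",
                        constraintLog(ppt))))
  expect_true(any(grepl("low B12", constraintLog(ppt))))
})
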