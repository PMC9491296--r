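test_that("bhFdr matches the literal step-up definition", {
  r <- bhFdr(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(r$mask))
  r <- bhFdr(0.5)
  expect_equal(r$adjusted, 0.5)
  expect_false(r$mask)
  expect_error(bhFdr(c(0.2, 1.4)), "\\[0, 1\\]")
  expect_error(bhFdr(0.5, alpha = 1.2), "alpha")

  set.seed(41)
  for (trial in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhFdr(p)$adjusted, oracle_bh(p), tolerance = 1e-15)
  }
})

test_that("minCellTest excludes the minimum cell and flags identical input", {
  set.seed(42)
  base <- matrix(runif(16, 0.1, 0.4), 4)
  base <- (base + t(base)) / 2
  diag(base) <- 0
  same <- lapply(1:5, function(i) make_fnc(base, "enmi"))
  cmp <- minCellTest(same)
  expect_true(all(is.na(cmp@pMap[upper.tri(cmp@pMap)])))
  expect_false(any(cmp@mask))
  expect_error(minCellTest(same[1:2]), "at least 3")
})

test_that("minCellTest detects a cell inflated above the matrix minimum", {
  set.seed(43)
  nil <- data.frame(i = integer(), j = integer(), weight = numeric())
  coh <- simulateCohort(nPerGroup = 15, nComponents = 5, linearPairs = nil,
                        nonlinearPairs = data.frame(i = 1, j = 2,
                                                    weight = 1.6),
                        seed = 43)
  mats <- cohortFnc(coh, "enmi")
  cmp <- minCellTest(mats)
  expect_true(cmp@mask[1, 2])
  minCell <- attr(cmp, "minCell")
  expect_true(is.na(cmp@pMap[minCell[1], minCell[2]]))
  ## maps symmetric, diagonal excluded
  expect_equal(cmp@pMap, t(cmp@pMap))
  expect_true(all(is.na(diag(cmp@pMap))))
  expect_false(any(diag(cmp@mask)))
})

test_that("twoSampleCompare reports A - B with exact nulls for identical groups", {
  set.seed(44)
  mats <- cohortFnc(simulateCohort(nPerGroup = 3, nComponents = 4,
                                   nTimepoints = 60, seed = 44), "pearson")
  cmp <- twoSampleCompare(mats[1:3], mats[1:3])
  ut <- upper.tri(cmp@tMap)
  expect_equal(cmp@tMap[ut], rep(0, sum(ut)))
  expect_equal(cmp@pMap[ut], rep(1, sum(ut)))
  expect_false(any(cmp@mask))

  ## orientation: group A values shifted up => positive t
  up <- lapply(mats[1:3], function(m)
    make_fnc(pmin(connValues(m) + 0.3, 1), "pearson"))
  cmp2 <- twoSampleCompare(up, mats[1:3])
  expect_true(all(cmp2@tMap[ut] > 0))
  expect_equal(cmp2@signedLogP[ut], -log10(cmp2@pMap[ut]) * sign(cmp2@tMap[ut]))

  e <- cohortFnc(simulateCohort(nPerGroup = 2, nComponents = 4,
                                nTimepoints = 60, seed = 45), "enmi")
  expect_error(twoSampleCompare(mats[1:3], e), "metric mismatch")
  expect_error(twoSampleCompare(mats[1], mats[2:3]), "at least 2")
})

test_that("Welch and pooled variants agree in direction, differ in df", {
  set.seed(46)
  coh <- simulateCohort(nPerGroup = 8, nComponents = 4, nTimepoints = 80,
                        seed = 46)
  mats <- cohortFnc(coh, "pearson")
  g <- subjectGroups(coh)
  pooled <- twoSampleCompare(mats[g == "A"], mats[g == "B"])
  welch <- twoSampleCompare(mats[g == "A"], mats[g == "B"], welch = TRUE)
  ut <- upper.tri(pooled@tMap)
  expect_equal(sign(pooled@tMap[ut]), sign(welch@tMap[ut]))
  expect_false(identical(pooled@pMap[ut], welch@pMap[ut]))
  fz <- twoSampleCompare(mats[g == "A"], mats[g == "B"], fisherZ = TRUE)
  expect_equal(sign(fz@tMap[ut]), sign(pooled@tMap[ut]))
})

test_that("selectTopPairs ranks by p, then |t|, then lexicographic order", {
  set.seed(47)
  mats <- cohortFnc(simulateCohort(nPerGroup = 5, nComponents = 5,
                                   nTimepoints = 60, seed = 47), "pearson")
  cmp <- twoSampleCompare(mats[1:5], mats[6:10])
  top1 <- selectTopPairs(cmp, 1)
  ut <- upper.tri(cmp@pMap)
  expect_equal(top1$p, min(cmp@pMap[ut]))
  topAll <- selectTopPairs(cmp, sum(ut))
  expect_equal(sort(topAll$p), unname(sort(cmp@pMap[ut])))
  expect_error(selectTopPairs(cmp, 0), "out of range")
  expect_error(selectTopPairs(cmp, sum(ut) + 1), "out of range")

  ## all-ties case: lexicographically first pairs win
  tied <- cmp
  tied@pMap[] <- 0.5
  tied@tMap[] <- 1
  top3 <- selectTopPairs(tied, 3)
  expect_equal(top3$i, c(1, 1, 1))
  expect_equal(top3$j, c(2, 3, 4))
})

test_that("significantEdges carries labels, sign and optional domains", {
  set.seed(48)
  nil <- data.frame(i = integer(), j = integer(), weight = numeric())
  coh <- simulateCohort(nPerGroup = 20, nComponents = 4, linearPairs = nil,
                        nonlinearPairs = data.frame(i = 1, j = 2,
                                                    weight = 0.3),
                        groupDelta = 1.3, seed = 48)
  g <- subjectGroups(coh)
  mats <- cohortFnc(coh, "enmi")
  cmp <- twoSampleCompare(mats[g == "A"], mats[g == "B"])
  edges <- significantEdges(cmp, domains = domains(coh))
  expect_true(nrow(edges) >= 1)
  expect_true(all(c("label_i", "label_j", "domain_i", "domain_j", "sign")
                  %in% colnames(edges)))
  injected <- edges[edges$i == 1 & edges$j == 2, ]
  expect_equal(nrow(injected), 1)
  expect_equal(injected$sign, -1)  # group B has the stronger coupling
})
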