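# Manipulation algebra and the qualitative outcome classifiers.

test_that("deletions conserve Kbp bookkeeping", {
  m <- hoxFixture("mouse_hoxd")
  d810 <- applyManipulation(m, deletionOf(8, 10))
  expect_equal(clusterSpan(d810), 94 - 16)          # d(8,9)+d(9,10)
  expect_equal(geneNumbers(d810), c(1L, 3L, 4L, 11L, 12L, 13L))
  expect_equal(distancesKbp(d810), c(15, 16, 36, 5, 6))  # 26+10 merged

  di810 <- applyManipulation(m, deletionOf(8, 10, includeI = TRUE))
  expect_equal(clusterSpan(di810), 94 - 26)

  di <- applyManipulation(m, deletionOf(NULL, includeI = TRUE))
  expect_equal(nGenes(di), 9L)
  expect_equal(clusterSpan(di), 84)
  expect_equal(distancesKbp(di)[3], 16)   # d(4,8) loses the 10 Kbp of "i"

  expect_error(applyManipulation(m, deletionOfInterval(-5, 10)),
               "crosses the cluster boundary")
  expect_error(applyManipulation(m, deletionOfInterval(50, 200)),
               "crosses the cluster boundary")
})

test_that("duplications add the copied fiber and a junction spacer", {
  m <- hoxFixture("mouse_hoxd")
  dup <- applyManipulation(m, duplicationOf(12, 13))
  # copied region d(12,13)=6 plus junction = anterior flank d(11,12)=5
  expect_equal(clusterSpan(dup), 94 + 6 + 5)
  expect_equal(nGenes(dup), 11L)
  expect_equal(geneNumbers(dup)[10:11], c(12L, 13L))
  # duplicate then delete the inserted interval restores the original
  x2 <- genePositions(m)[["Hoxd13"]]
  restored <- applyManipulation(dup, deletionOfInterval(x2, x2 + 11))
  expect_equal(distancesKbp(restored), distancesKbp(m))
  expect_equal(geneNumbers(restored), geneNumbers(m))
})

test_that("splittings toggle the anchor and keep distances", {
  m <- hoxFixture("mouse_hoxd")
  sp <- applyManipulation(m, splitInversion(removesFixedEnd = TRUE))
  expect_false(fixedPosteriorEnd(sp))
  expect_equal(clusterSpan(sp), 94)
  expect_equal(distancesKbp(sp), distancesKbp(m))
  keep <- applyManipulation(m, splitInversion(removesFixedEnd = FALSE))
  expect_true(fixedPosteriorEnd(keep))
})

test_that("anterior-deletion cases follow the E versus L-D comparison", {
  m <- hoxFixture("mouse_hoxd")
  profs <- scenarioProfiles()

  o1 <- classifyAnteriorDeletion(m, deletionOf(8, 10), 11)
  expect_equal(o1@verdict, "UNCHANGED")
  expect_equal(o1@caseLabel, "case1")

  o2 <- classifyAnteriorDeletion(m, deletionOf(8, 10, includeI = TRUE), 11,
                                 profile = profs$stiff_del_i_8_10)
  expect_equal(o2@verdict, "ANTERIORIZED_WITH_GAIN")
  expect_equal(o2@caseLabel, "case2")

  o3 <- classifyAnteriorDeletion(m, deletionOf(10, 12), 13)
  expect_equal(o3@verdict, "UNCHANGED")

  o4 <- classifyAnteriorDeletion(m, deletionOf(9, 12), 13,
                                 profile = profs$soft_del_9_12)
  expect_equal(o4@verdict, "SILENCED")
  expect_equal(o4@caseLabel, "case3")

  # intergenic-only deletion anteriorizes without the gain
  o5 <- classifyAnteriorDeletion(m, deletionOf(NULL, includeI = TRUE), 11,
                                 profile = profs$stiff_i)
  expect_equal(o5@verdict, "ANTERIORIZED")

  expect_error(classifyAnteriorDeletion(m, deletionOf(12, 13), 11),
               "not entirely anterior")
  expect_error(classifyAnteriorDeletion(m, duplicationOf(8, 10), 11),
               "must be a deletion")
  expect_match(o4@rationale, "E=")
})

test_that("posterior edits follow the charge rule", {
  m <- hoxFixture("mouse_hoxd")
  od <- classifyPosteriorEdit(m, deletionOf(12, 13), 11)
  expect_equal(od@verdict, "POSTERIORIZED_DELAYED")
  expect_false(od@downregulated)

  ou <- classifyPosteriorEdit(m, duplicationOf(12, 13), 11)
  expect_equal(ou@verdict, "ANTERIORIZED")
  expect_true(ou@downregulated)

  expect_equal(classifyPosteriorEdit(m, NULL, 11)@verdict, "UNCHANGED")
  expect_error(classifyPosteriorEdit(m, deletionOf(8, 10), 11),
               "not posterior")
})

test_that("splitting verdicts depend only on the anchor", {
  m <- hoxFixture("mouse_hoxd")
  res <- classifySplit(m, splitInversion(removesFixedEnd = TRUE), c(9, 11))
  expect_equal(sapply(res, slot, "verdict"),
               rep("ANTERIORIZED", 2))
  res2 <- classifySplit(m, splitInversion(removesFixedEnd = FALSE,
                                          includesEvx2Boundary = FALSE),
                        11)
  expect_equal(res2[[1]]@verdict, "UNCHANGED")
  # inversion that carries the Evx2 boundary away = anchor removed
  res3 <- classifySplit(m, splitInversion(removesFixedEnd = FALSE,
                                          includesEvx2Boundary = TRUE), 11)
  expect_equal(res3[[1]]@verdict, "ANTERIORIZED")
  expect_error(classifySplit(m, deletionOf(8, 10), 11), "split_inversion")
})

test_that("the case partition is exhaustive, exclusive and monotone in E", {
  L <- 83; D <- 26; eta <- 0.05
  Es <- seq(0, 120, by = 0.5)
  verdictOrder <- c(SILENCED = 1, UNCHANGED = 2, ANTERIORIZED = 3,
                    ANTERIORIZED_WITH_GAIN = 3)
  v <- sapply(Es, function(E)
    hoxphys:::.anteriorCaseVerdict(E, L, D, eta)[["verdict"]])
  expect_true(all(v %in% names(verdictOrder)))          # exhaustive
  steps <- diff(verdictOrder[v])
  expect_true(all(steps >= 0))                          # monotone
  # boundary ties fall to case 1
  band <- eta * L
  expect_equal(
    hoxphys:::.anteriorCaseVerdict((L - D) + band, L, D, eta)[["verdict"]],
    "UNCHANGED")
  expect_equal(
    hoxphys:::.anteriorCaseVerdict((L - D) - band, L, D, eta)[["verdict"]],
    "UNCHANGED")
  # exclusivity across tolerance choices
  for (eta2 in c(0.01, 0.05, 0.2)) {
    v2 <- sapply(Es, function(E)
      hoxphys:::.anteriorCaseVerdict(E, L, D, eta2)[["caseLabel"]])
    expect_true(all(table(v2) > 0) && length(unique(v2)) == 3)
  }
})

test_that("enlarging a posterior deletion never flips the verdict", {
  m <- hoxFixture("mouse_hoxd")
  for (fromGene in c(13, 12)) {
    o <- classifyPosteriorEdit(m, deletionOf(fromGene, 13), 11)
    expect_equal(o@verdict, "POSTERIORIZED_DELAYED")
  }
})

test_that("preset scenarios all reproduce their expected verdicts", {
  res <- suppressWarnings(runScenarios())
  expect_equal(nrow(res), 9L)
  expect_true(all(res$match))
  # determinism: identical rerun
  res2 <- suppressWarnings(runScenarios())
  expect_identical(res$computed_verdict, res2$computed_verdict)
})

test_that("malformed scenario rows are skipped with a warning", {
  sc <- presetScenarios()
  sc$region[4] <- "99-98"
  expect_warning(res <- runScenarios(scenarios = sc), "row 4")
  expect_equal(sum(is.na(res$computed_verdict)), 1L)
  expect_equal(sum(res$match), 8L)
})
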