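test_that("ViewScoreMatrix construction validates its invariants", {
  s <- matrix(c(0.7, 0.2, 0.1, 0.6, 0.3, 0.1), ncol = 2)
  vm <- ViewScoreMatrix(s, classLabels = c("a", "b", "c"))
  expect_s4_class(vm, "ViewScoreMatrix")
  expect_equal(classLabels(vm), c("a", "b", "c"))
  expect_equal(nViews(vm), 2L)

  expect_error(ViewScoreMatrix(matrix(0.5, 1, 2)), "C >= 2")
  expect_error(ViewScoreMatrix(matrix(c(0.5, 0.7), 2, 1)), "sums to")
  expect_warning(
    ViewScoreMatrix(matrix(c(0.5, 0.7), 2, 1), colSumCheck = "warn"),
    "sums to")
  expect_silent(
    ViewScoreMatrix(matrix(c(0.5, 0.7), 2, 1), colSumCheck = "none"))
  expect_error(ViewScoreMatrix(matrix(c(1.2, -0.2, 0.5, 0.5), 2, 2),
                               colSumCheck = "none"), "out of range")
  expect_error(ViewScoreMatrix(s, classLabels = c("a", "a", "c")),
               "distinct")
})

test_that("select_class takes the maximum response with lowest-index ties", {
  expect_equal(selectClass(c(0.1, 0.9, 0.05))$index, 2L)
  expect_false(selectClass(c(0.1, 0.9, 0.05))$tieBroken)
  tie <- selectClass(c(0.5, 0.5))
  expect_equal(tie$index, 1L)
  expect_true(tie$tieBroken)
  # ties within 1e-12 count as ties; beyond, they do not
  expect_true(selectClass(c(0.5, 0.5 - 1e-13))$tieBroken)
  expect_false(selectClass(c(0.5, 0.5 - 1e-9))$tieBroken)
  expect_equal(selectClass(0.3)$index, 1L)
  expect_error(selectClass(numeric(0)), "non-empty")
})

test_that("fusing identical columns returns the common column (idempotency)", {
  col <- c(0.5, 0.3, 0.2)
  vm <- ViewScoreMatrix(matrix(col, 3, 4), classLabels = c("a", "b", "c"))
  for (q in c(0.5, 1, 3)) {
    f <- fuseViews(vm, powerMeasure(q, 4))
    expect_equal(unname(fusedScores(f)), col)
    expect_equal(decidedClass(f), 1L)
    expect_equal(decidedLabel(f), "a")
  }
})

test_that("two-class worked examples fuse as hand-computed", {
  # q = 1 is the row mean; symmetric rows tie, broken to the lowest index
  vm <- ViewScoreMatrix(matrix(c(0.2, 0.8, 0.8, 0.2), 2, 2),
                        classLabels = c("A", "B"))
  f <- fuseViews(vm, powerMeasure(1, 2))
  expect_equal(unname(fusedScores(f)), c(0.5, 0.5))
  expect_true(tieBroken(f))
  expect_equal(decidedClass(f), 1L)

  # q = 2: each row gives 0.1 * 1 + 0.8 * 0.25 = 0.3
  vm2 <- ViewScoreMatrix(matrix(c(0.1, 0.9, 0.9, 0.1), 2, 2),
                         classLabels = c("A", "B"))
  m <- powerMeasure(2, 2)
  f2 <- fuseViews(vm2, m)
  expect_equal(unname(fusedScores(f2)), c(0.3, 0.3))
  expect_equal(unname(fusedScores(f2)),
               c(choquetOracle(c(0.1, 0.9), m), choquetOracle(c(0.9, 0.1), m)))
})

test_that("fused scores obey per-class internality and view-order invariance", {
  set.seed(201)
  for (rep in 1:50) {
    vm <- randomScoreMatrix(C = 6, K = 4)
    m <- powerMeasure(sample(c(0.5, 1, 2, 5), 1L), 4)
    f <- fusedScores(fuseViews(vm, m))
    s <- scoreMatrix(vm)
    expect_true(all(f >= apply(s, 1, min) - 1e-12))
    expect_true(all(f <= apply(s, 1, max) + 1e-12))
    perm <- sample(4)
    vmP <- ViewScoreMatrix(s[, perm], classLabels = classLabels(vm),
                           colSumCheck = "none")
    expect_identical(unname(fusedScores(fuseViews(vmP, m))), unname(f))
  }
})

test_that("measure/view-count mismatch is rejected", {
  vm <- randomScoreMatrix(C = 4, K = 3)
  expect_error(fuseViews(vm, powerMeasure(1, 4)), "does not match view count")
})

test_that("predictBatch modes: single view, baselines and q=1 equivalence", {
  set.seed(202)
  mats <- lapply(1:20, function(i)
    randomScoreMatrix(C = 5, K = 3, captureId = sprintf("cap%02d", i)))

  # single_view:k reproduces the per-capture argmax of column k
  preds1 <- predictBatch(mats, mode = "single_view:1")
  expect_equal(vapply(preds1, decidedClass, integer(1)),
               vapply(mats, function(m) which.max(scoreMatrix(m)[, 1]),
                      integer(1)))

  # choquet with q = 1 is the mean on every capture
  pm <- predictBatch(mats, powerMeasure(1, 3), "choquet")
  pmean <- predictBatch(mats, mode = "mean")
  expect_equal(lapply(pm, fusedScores), lapply(pmean, fusedScores))

  # choquet with K = 1 is the single-view identity
  one <- lapply(mats, function(m)
    ViewScoreMatrix(scoreMatrix(m)[, 1, drop = FALSE],
                    classLabels = classLabels(m), captureId = captureId(m),
                    colSumCheck = "none"))
  pK1 <- predictBatch(one, powerMeasure(2, 1), "choquet")
  p1 <- predictBatch(one, mode = "single_view:1")
  expect_equal(lapply(pK1, fusedScores), lapply(p1, fusedScores))

  expect_error(predictBatch(mats, mode = "single_view:9"), "out of range")
  expect_error(predictBatch(mats, mode = "sum"), "unknown fusion mode")

  # inconsistent class labels across captures are rejected
  bad <- c(mats[1:2], list(ViewScoreMatrix(scoreMatrix(mats[[3]]),
                                           classLabels = letters[1:5],
                                           colSumCheck = "none")))
  expect_error(predictBatch(bad, mode = "mean"), "share the same class")
})

test_that("fusion is deterministic: identical inputs, bit-identical outputs", {
  set.seed(203)
  vm <- randomScoreMatrix(C = 10, K = 4)
  m <- powerMeasure(1.7, 4)
  f1 <- fuseViews(vm, m)
  f2 <- fuseViews(vm, m)
  expect_identical(fusedScores(f1), fusedScores(f2))
  expect_identical(decidedClass(f1), decidedClass(f2))
})
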