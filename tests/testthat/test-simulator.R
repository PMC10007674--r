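test_that("simulation config applies regime defaults and validates", {
  clean <- simulationConfig("clean")
  expect_equal(clean@nClasses, 38L)
  expect_equal(clean@nViews, 4L)
  expect_equal(clean@alphaSignal, 20)
  expect_equal(clean@pCorrupt, 0.05)
  degraded <- simulationConfig("degraded")
  expect_equal(degraded@alphaSignal, 8)
  expect_equal(degraded@pCorrupt, 0.35)

  expect_error(simulationConfig("clean", C = 1), "C >= 2")
  expect_error(simulationConfig("clean", K = 0), "K >= 1")
  expect_error(simulationConfig("clean", pCorrupt = 1.5), "pCorrupt")
  expect_error(simulationConfig("clean", alphaSignal = -1), "alphaSignal")
  expect_error(simulationConfig("foggy"))
})

test_that("simulated batches are well-formed softmax-like outputs", {
  cfg <- simulationConfig("degraded", C = 7, K = 3, nCaptures = 40, seed = 9)
  b <- simulateBatch(cfg)
  expect_s4_class(b, "LabeledBatch")
  expect_length(b@matrices, 40L)
  expect_length(trueLabels(b), 40L)
  expect_true(all(trueLabels(b) %in% classLabels(b)))
  for (m in b@matrices) {
    s <- scoreMatrix(m)
    expect_equal(dim(s), c(7L, 3L))
    expect_true(all(s >= 0 & s <= 1))
    expect_equal(unname(colSums(s)), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("the same seed reproduces a bit-identical batch", {
  cfg <- simulationConfig("clean", C = 5, K = 2, nCaptures = 25, seed = 77)
  b1 <- simulateBatch(cfg)
  b2 <- simulateBatch(cfg)
  expect_identical(trueLabels(b1), trueLabels(b2))
  for (i in seq_along(b1@matrices))
    expect_identical(b1@matrices[[i]]@scores, b2@matrices[[i]]@scores)
  b3 <- simulateBatch(simulationConfig("clean", C = 5, K = 2,
                                       nCaptures = 25, seed = 78))
  expect_false(identical(trueLabels(b1), trueLabels(b3)) &&
               identical(b1@matrices[[1]]@scores, b3@matrices[[1]]@scores))
})

test_that("noise-free strong-signal limit gives perfect decisions", {
  cfg <- simulationConfig("clean", C = 10, K = 3, nCaptures = 60,
                          alphaSignal = 1e6, pCorrupt = 0, seed = 5)
  b <- simulateBatch(cfg)
  for (mode in c("choquet", "single_view:1", "mean", "min", "max")) {
    preds <- predictBatch(b, powerMeasure(1, 3), mode)
    expect_identical(vapply(preds, decidedLabel, character(1)),
                     trueLabels(b))
  }
})

test_that("fully corrupted views put every mode at chance level", {
  C <- 10
  n <- 2000
  cfg <- simulationConfig("degraded", C = C, K = 4, nCaptures = n,
                          pCorrupt = 1, seed = 11)
  b <- simulateBatch(cfg)
  se <- sqrt((1 / C) * (1 - 1 / C) / n)
  for (mode in c("choquet", "single_view:2")) {
    preds <- predictBatch(b, powerMeasure(1, 4), mode)
    acc <- mean(vapply(preds, decidedLabel, character(1)) == trueLabels(b))
    expect_lt(abs(acc - 1 / C), 3 * se)
  }
})

test_that("experiment report has the expected shape and equivalences", {
  cfg <- simulationConfig("degraded", C = 6, K = 3, nCaptures = 150,
                          seed = 21)
  suppressMessages(
    rep_ <- runExperiment(cfg, qValues = c(1, 2),
                          modes = c("choquet", "single_view", "mean")))
  expect_setequal(
    rep_$mode,
    c("choquet", "single_view:1", "single_view:2", "single_view:3",
      "single_view:avg", "mean"))
  expect_equal(sum(rep_$mode == "choquet"), 2L)
  expect_named(rep_, c("mode", "q", "Prec", "Rec", "F0.5", "F1", "accuracy"))
  expect_true(all(rep_[, c("Prec", "Rec", "F0.5", "F1", "accuracy")] >= 0 &
                  rep_[, c("Prec", "Rec", "F0.5", "F1", "accuracy")] <= 1))

  # single_view:avg row is the mean of the per-view rows
  per <- rep_[grepl("^single_view:[0-9]", rep_$mode), -(1:2)]
  avg <- rep_[rep_$mode == "single_view:avg", -(1:2)]
  expect_equal(unlist(avg), colMeans(per), tolerance = 1e-12)

  # mean mode and choquet q=1 coincide end to end
  expect_equal(unlist(rep_[rep_$mode == "choquet" & rep_$q == 1, -(1:2)]),
               unlist(rep_[rep_$mode == "mean", -(1:2)]), tolerance = 1e-12)

  # reproducibility of the whole report
  suppressMessages(
    rep2 <- runExperiment(cfg, qValues = c(1, 2),
                          modes = c("choquet", "single_view", "mean")))
  expect_identical(rep_, rep2)
})

test_that("Dirichlet columns are simplex points with the right mean", {
  set.seed(401)
  a <- c(5, 1, 1, 1)
  d <- ChoquetFusion:::rdirichletCols(4000, a)
  expect_equal(unname(colSums(d)), rep(1, 4000), tolerance = 1e-12)
  expect_true(all(d >= 0))
  expect_equal(rowMeans(d), a / sum(a), tolerance = 0.02)
})
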