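test_that("stratified folds balance both classes to within one sample", {
  y <- rep(c(-1L, 1L), c(40, 22))
  fold <- stratifiedKFold(y, k = 10, seed = 7)
  expect_length(fold, 62L)
  expect_setequal(unique(fold), 0:9)
  tab <- table(fold, y)
  expect_true(all(tab[, "-1"] == 4L))            # 40 majority over 10 folds
  expect_true(all(tab[, "1"] %in% 2:3))          # 22 minority: 2 or 3
  sizes <- as.integer(table(fold))
  expect_true(all(sizes %in% 6:7))
})

test_that("k = m gives leave-one-out and seeds make folds reproducible", {
  y <- c(-1L, -1L, 1L, 1L)
  fold <- stratifiedKFold(y, k = 4, seed = 1)
  expect_setequal(fold, 0:3)                     # exactly one sample per fold
  expect_identical(stratifiedKFold(y, k = 2, seed = 9),
                   stratifiedKFold(y, k = 2, seed = 9))
  expect_warning(stratifiedKFold(rep(c(-1L, 1L), c(12, 3)), k = 5, seed = 1),
                 "approximate")
  expect_warning(stratifiedKFold(y, k = 9, seed = 1), "reduced")
})

test_that("cross-validation is perfect on well-separated data and honest on null data", {
  out <- generateExpression(syntheticSpec(
    m = 60, n = 3, nInformative = 3, effect = 3, classBalance = 0.5,
    seed = 5))
  ds <- zscoreNormalize(out$dataset)
  cv <- crossValidate(ds, geneIds(ds), k = 10, seed = 1)
  expect_gte(cvAccuracy(cv), 95)
  expect_valid(cv)
  # accuracy equals a brute-force recount of per-fold predictions
  expect_equal(cvAccuracy(cv),
               100 * sum(perFoldCounts(cv)[, "correct"]) / nSamples(ds))
  expect_equal(sum(perFoldCounts(cv)[, "total"]), nSamples(ds))

  # permuted labels: near-chance mean accuracy
  x <- exprMatrix(ds)
  accs <- vapply(1:10, function(s) {
    yPerm <- withr::with_seed(s, sample(unname(classLabels(ds))))
    dsPerm <- toyDataset(x, ifelse(yPerm == 1, "pos", "neg"),
                         geneIds = rownames(x))
    cvAccuracy(crossValidate(dsPerm, geneIds(dsPerm), k = 10, seed = s))
  }, numeric(1))
  expect_gt(mean(accs), 30)
  expect_lt(mean(accs), 70)
})

test_that("leave-one-out predictions match per-fold QP oracle models", {
  set.seed(40)
  x <- matrix(rnorm(8), nrow = 2)
  x[1, ] <- c(-2, -1.5, 1.5, 2)
  y <- c(-1L, -1L, 1L, 1L)
  ds <- toyDataset(x, ifelse(y == 1, "pos", "neg"))
  cv <- crossValidate(ds, geneIds(ds), k = 4, C = 1, seed = 2)
  fold <- foldAssignment(cv)
  correct <- integer(4)
  for (f in 0:3) {
    test <- fold == f
    orc <- qpOracle(t(x)[!test, , drop = FALSE], y[!test], C = 1,
                    kernel = "rbf", gamma = 1 / 2)
    K <- exp(-0.5 * as.matrix(dist(rbind(t(x)[test, , drop = FALSE],
                                         t(x)[!test, , drop = FALSE])))^2)
    f0 <- sum(orc$alpha * y[!test] * K[1, -1]) + orc$b
    correct[f + 1L] <- as.integer((f0 >= 0) == (y[test] == 1L))
  }
  expect_equal(perFoldCounts(cv)[, "correct"], correct)
})

test_that("within-fold normalization shields training from test outliers", {
  # leak canary: an extreme outlier confined to a test fold must not reach
  # the training-side statistics. The implementation's counts are compared
  # with an independent recount that trains on strictly-training-derived
  # z-scores; if test-fold values leaked into the normalization, the +500
  # outlier would make the two disagree.
  out <- generateExpression(syntheticSpec(
    m = 30, n = 5, nInformative = 2, effect = 2.5, classBalance = 0.5,
    seed = 6))
  noLeakCounts <- function(ds, fold) {
    x <- t(exprMatrix(ds)); y <- unname(classLabels(ds))
    t(vapply(sort(unique(fold)), function(f) {
      test <- fold == f
      mu <- colMeans(x[!test, , drop = FALSE])
      sdv <- sqrt(colMeans(sweep(x[!test, , drop = FALSE], 2, mu)^2))
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(x[!test, , drop = FALSE], 2, mu), 2, sdv, "/")
      xte <- sweep(sweep(x[test, , drop = FALSE], 2, mu), 2, sdv, "/")
      fit <- trainSvm(xtr, y[!test], kernel = "rbf", gamma = 1 / ncol(x))
      c(sum(predict(fit, xte) == y[test]), sum(test))
    }, numeric(2)))
  }
  fold <- stratifiedKFold(classLabels(out$dataset), k = 5, seed = 3)
  victim <- which(fold == 0L)[1L]
  for (shift in c(0, 500)) {
    x2 <- exprMatrix(out$dataset)
    x2[, victim] <- x2[, victim] + shift
    ds <- toyDataset(x2, names(classMap(out$dataset))[
      (unname(classLabels(out$dataset)) + 3L) / 2L],
      geneIds = rownames(x2))
    cv <- crossValidate(ds, geneIds(ds), k = 5, seed = 3,
                        normalizeWithinFold = TRUE)
    expect_equal(unname(perFoldCounts(cv)),
                 unname(noLeakCounts(ds, fold)),
                 info = sprintf("outlier shift %g", shift))
  }
})

test_that("accuracy is invariant to sample order under a fixed fold map", {
  out <- plantedDataset(m = 24, nNoise = 8, nSignal = 2, seed = 14)
  ds <- zscoreNormalize(out$dataset)
  cv <- crossValidate(ds, geneIds(ds), k = 6, seed = 11)
  fold <- foldAssignment(cv)
  x <- t(exprMatrix(ds)); y <- unname(classLabels(ds))
  correct <- 0L
  for (f in sort(unique(fold))) {
    test <- fold == f
    fit <- trainSvm(x[!test, ], y[!test], kernel = "rbf",
                    gamma = 1 / ncol(x))
    correct <- correct + sum(predict(fit, x[test, , drop = FALSE]) == y[test])
  }
  expect_equal(cvAccuracy(cv), 100 * correct / length(y))
})

test_that("benchmarkHybrids reports one accuracy column per method", {
  out <- generateExpression(syntheticSpec(
    m = 40, n = 120, nInformative = 3, effect = 3, classBalance = 0.5,
    seed = 10))
  ds <- zscoreNormalize(out$dataset)
  tab <- benchmarkHybrids(ds, methods = c("ig", "correlation"),
                          nFilter = 30, kFinal = 3, seed = 1)
  expect_equal(names(tab), c("ig", "correlation"))
  expect_true(all(tab >= 0 & tab <= 100))
  expect_gte(tab$ig, 90)
  genes <- attr(tab, "genes")
  expect_setequal(genes$ig, out$informative)
  one <- benchmarkHybrids(ds, methods = "ig", nFilter = 30, kFinal = 3,
                          seed = 1)
  expect_equal(names(one), "ig")
})

test_that("within-fold selection removes the selection bias visible on null data", {
  biased <- honest <- numeric(4)
  for (seed in 1:4) {
    out <- generateExpression(syntheticSpec(
      m = 40, n = 300, nInformative = 1, effect = 0, classBalance = 0.5,
      seed = seed))
    ds <- zscoreNormalize(out$dataset)
    biased[seed] <- benchmarkHybrids(ds, methods = "ig", nFilter = 30,
                                     kFinal = 3, k = 5, seed = seed)$ig
    honest[seed] <- benchmarkHybrids(ds, methods = "ig", nFilter = 30,
                                     kFinal = 3, k = 5, seed = seed,
                                     selectWithinFold = TRUE)$ig
  }
  # honest accuracy sits near chance; full-data selection inflates it
  expect_gt(mean(honest), 30)
  expect_lt(mean(honest), 70)
  expect_gt(mean(biased), mean(honest) + 10)
})

test_that("the accuracy curve plateaus once the planted genes are included", {
  out <- generateExpression(syntheticSpec(
    m = 50, n = 200, nInformative = 5, effect = 3, classBalance = 0.5,
    seed = 18))
  ds <- zscoreNormalize(out$dataset)
  grid <- c(1, 3, 5, 10, 30, 60)
  curve <- accuracyCurve(ds, "ig", nGrid = grid, seed = 2)
  expect_equal(curve$n, grid)
  expect_equal(nrow(curve), length(grid))
  at5 <- curve$accuracy[curve$n == 5]
  expect_gte(at5, 90)
  expect_true(all(curve$accuracy[curve$n > 5] >= at5 - 5))
  expect_error(accuracyCurve(ds, "ig", nGrid = c(0, 5)), "nGrid")
})
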