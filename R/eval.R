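#' Stratified k-fold assignment
#'
#' Assigns samples to `k` folds class by class: within each class the
#' samples are shuffled under `seed` and dealt round-robin, with the fold
#' counter carried over between classes so that total fold sizes also
#' differ by at most one. Per-class fold counts differ by at most one, so
#' each fold's class proportions are within one sample of the global
#' proportions. `k = m` yields leave-one-out. If `k` exceeds the smaller
#' class, stratification is necessarily approximate and a warning is
#' raised; `k > m` is reduced to `m`.
#'
#' @param labels -1/+1 labels, length m >= 2.
#' @param k number of folds (default 10).
#' @param seed integer seed for the within-class shuffle.
#' @return integer fold ids in `0..k-1`, one per sample.
#' @export
stratifiedKFold <- function(labels, k = 10L, seed = 1L) {
  m <- length(labels)
  if (m < 2L) stop("need at least 2 samples")
  stopIfNot01Labels(labels)
  if (k > m) {
    warning("k reduced from ", k, " to m = ", m)
    k <- m
  }
  if (k < 2L) stop("k must be >= 2")
  sizes <- table(labels)
  if (min(sizes) < k && k < m)
    warning("a class has fewer than k = ", k,
            " samples; stratification is approximate")
  k <- as.integer(k)
  fold <- integer(m)
  offset <- 0L
  withSeed(seed, {
    for (cls in c(-1L, 1L)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- as.integer((offset + seq_along(idx) - 1L) %% k)
      offset <- as.integer((offset + length(idx)) %% k)
    }
  })
  fold
}

#' Cross-validated RBF-SVM accuracy of a gene subset
#'
#' Evaluates a selected gene set the way small-sample expression studies
#' do: stratified k-fold cross-validation (default 10-fold) of an
#' RBF-kernel soft-margin SVM trained on the training folds and scored on
#' the held-out fold, with pooled accuracy reported as a percentage.
#' Defaults follow LIBSVM: `C = 1`, `gamma = 1/p` with `p` the number of
#' genes evaluated. With `normalizeWithinFold = TRUE` the per-gene z-score
#' statistics are recomputed on each training fold only and applied to its
#' test fold, so no test-fold information reaches training.
#'
#' @param ds a [GeneExpressionSet-class].
#' @param genes gene ids to evaluate (subset of `geneIds(ds)`).
#' @param k folds (default 10).
#' @param C box constraint.
#' @param gamma `"auto"` (`1/length(genes)`) or a number.
#' @param seed seed for the fold assignment.
#' @param normalizeWithinFold recompute z-scores inside each training fold.
#' @return a [CvResult-class].
#' @export
crossValidate <- function(ds, genes, k = 10L, C = 1, gamma = "auto",
                          seed = 1L, normalizeWithinFold = FALSE) {
  sub <- subsetGenes(ds, genes)
  x <- t(exprMatrix(sub))            # samples x genes
  y <- classLabels(ds)
  g <- if (identical(gamma, "auto")) 1 / length(genes) else as.numeric(gamma)
  fold <- stratifiedKFold(y, k = k, seed = seed)
  kEff <- max(fold) + 1L
  perFold <- matrix(0L, nrow = kEff, ncol = 2L,
                    dimnames = list(NULL, c("correct", "total")))
  for (f in seq_len(kEff) - 1L) {
    test <- fold == f
    xtr <- x[!test, , drop = FALSE]
    xte <- x[test, , drop = FALSE]
    if (normalizeWithinFold) {
      mu <- colMeans(xtr)
      sdv <- sqrt(colMeans(sweep(xtr, 2L, mu)^2))
      sdv[sdv == 0] <- 1
      xtr <- sweep(sweep(xtr, 2L, mu), 2L, sdv, "/")
      xte <- sweep(sweep(xte, 2L, mu), 2L, sdv, "/")
    }
    fit <- trainSvm(xtr, y[!test], C = C, kernel = "rbf", gamma = g)
    pred <- predict(fit, xte)
    perFold[f + 1L, ] <- c(sum(pred == y[test]), sum(test))
  }
  methods::new("CvResult", foldAssignment = fold, perFold = perFold,
               accuracy = 100 * sum(perFold[, "correct"]) / length(y))
}

#' @describeIn crossValidate per-sample fold ids of a result.
#' @param x a [CvResult-class].
#' @export
foldAssignment <- function(x) x@foldAssignment

#' @describeIn crossValidate k-by-2 matrix of per-fold correct/total counts.
#' @export
perFoldCounts <- function(x) x@perFold

#' @describeIn crossValidate pooled accuracy in percent.
#' @export
cvAccuracy <- function(x) x@accuracy

setMethod("show", "CvResult", function(object) {
  cat("CvResult: ", nrow(object@perFold), "-fold, accuracy ",
      sprintf("%.2f", object@accuracy), "%\n", sep = "")
})

#' Cross-validation with selection re-run inside each training fold
#'
#' The unbiased counterpart of select-then-cross-validate: within every
#' fold, the full hybrid pipeline ([hybridSelect()]) is re-run on the
#' training samples only, and the genes it picks there are used to
#' classify the held-out fold. Slower by a factor of `k`, but the test
#' folds never influence selection, so the accuracy is an honest estimate.
#'
#' @inheritParams hybridSelect
#' @param k CV folds.
#' @param seed seed for the fold assignment.
#' @return a [CvResult-class].
#' @export
crossValidateHybrid <- function(ds, method = "ig", nFilter = 150L,
                                kFinal = 3L, k = 10L, C = 1, seed = 1L,
                                ...) {
  y <- classLabels(ds)
  fold <- stratifiedKFold(y, k = k, seed = seed)
  kEff <- max(fold) + 1L
  perFold <- matrix(0L, nrow = kEff, ncol = 2L,
                    dimnames = list(NULL, c("correct", "total")))
  for (f in seq_len(kEff) - 1L) {
    test <- fold == f
    dsTrain <- ds[, !test]
    sel <- hybridSelect(dsTrain, method, nFilter = nFilter,
                        kFinal = kFinal, C = C, ...)
    xtr <- t(exprMatrix(dsTrain)[sel, , drop = FALSE])
    xte <- t(exprMatrix(ds)[sel, test, drop = FALSE])
    fit <- trainSvm(xtr, y[!test], C = C, kernel = "rbf",
                    gamma = 1 / length(sel))
    pred <- predict(fit, xte)
    perFold[f + 1L, ] <- c(sum(pred == y[test]), sum(test))
  }
  methods::new("CvResult", foldAssignment = fold, perFold = perFold,
               accuracy = 100 * sum(perFold[, "correct"]) / length(y))
}

#' Benchmark the four hybrid pipelines
#'
#' Runs [hybridSelect()] with each requested filter and cross-validates the
#' selected genes, producing a one-row accuracy table (methods as columns,
#' percent) of the kind used to compare IG-SVM against the gain-ratio,
#' reliefF and correlation hybrids. By default selection happens once on
#' the full dataset (the conventional, optimistically biased protocol);
#' `selectWithinFold = TRUE` switches to [crossValidateHybrid()].
#'
#' @inheritParams hybridSelect
#' @param methods filters to run (default all four).
#' @param k CV folds.
#' @param seed seed for folds (and reliefF sampling, if enabled).
#' @param selectWithinFold redo selection inside each training fold.
#' @return `data.frame` with one accuracy column per method and an
#'   attribute `"genes"` (the per-method selections; `NULL` per method
#'   when selection is per-fold).
#' @export
benchmarkHybrids <- function(ds, methods = c("ig", "gain_ratio", "relieff",
                                             "correlation"),
                             nFilter = 150L, kFinal = 3L, k = 10L, C = 1,
                             seed = 1L, selectWithinFold = FALSE, ...) {
  acc <- numeric(0)
  genes <- list()
  for (mth in methods) {
    if (selectWithinFold) {
      cv <- crossValidateHybrid(ds, mth, nFilter = nFilter,
                                kFinal = kFinal, k = k, C = C,
                                seed = seed, ...)
      genes[mth] <- list(NULL)
    } else {
      sel <- hybridSelect(ds, mth, nFilter = nFilter, kFinal = kFinal,
                          C = C, seed = seed, ...)
      cv <- crossValidate(ds, sel, k = k, C = C, seed = seed)
      genes[[mth]] <- sel
    }
    acc[mth] <- cvAccuracy(cv)
  }
  out <- as.data.frame(as.list(round(acc, 2)))
  attr(out, "genes") <- genes
  out
}

#' Accuracy as a function of the number of filtered genes
#'
#' The filter-sweep benchmark: rank once with `method`, then for each `n`
#' in `nGrid` evaluate the top-`n` genes (filter stage only, no RFE) by
#' cross-validated RBF-SVM accuracy. Reproduces the accuracy-vs-gene-count
#' curves used to show that a few dozen genes saturate performance.
#'
#' @inheritParams crossValidate
#' @param method filter to rank with.
#' @param nGrid integer gene counts, each in `1..nGenes(ds)`.
#' @param ... passed to [rankFeatures()].
#' @return `data.frame` with columns `n` and `accuracy` (percent).
#' @export
accuracyCurve <- function(ds, method = "ig", nGrid = c(1:10, seq(20, 200, 10)),
                          k = 10L, C = 1, seed = 1L, ...) {
  if (any(nGrid < 1L) || max(nGrid) > nGenes(ds))
    stop("nGrid values must lie in 1..", nGenes(ds))
  ranking <- rankFeatures(ds, method, ...)
  acc <- vapply(nGrid, function(n) {
    cvAccuracy(crossValidate(ds, selectTop(ranking, n), k = k, C = C,
                             seed = seed))
  }, numeric(1))
  data.frame(n = as.integer(nGrid), accuracy = round(acc, 2))
}
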