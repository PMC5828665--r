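#' Entropy, conditional entropy and information gain (bits)
#'
#' Filter-stage scoring primitives. `entropyBits` is the Shannon entropy
#' \eqn{H(Y) = -\sum_y p(y) \log_2 p(y)} of a discrete label vector (with
#' \eqn{0 \log 0 := 0}); `conditionalEntropy` is
#' \eqn{H(Y|X) = \sum_x p(x) H(Y|X=x)} for discretized gene codes `codes`;
#' `infoGain` is the reduction in class uncertainty
#' \eqn{g(Y,X) = H(Y) - H(Y|X)}, clipped at zero against floating-point
#' round-off; `gainRatio` divides the gain by the split information
#' (the entropy of the code distribution), the C4.5 correction for
#' many-valued features, with the convention that a constant feature
#' scores 0.
#'
#' @param labels discrete class labels (typically -1/+1), length m >= 1.
#' @param codes integer bin codes for one gene, same length as `labels`.
#' @return a numeric scalar in bits (`gainRatio` is unitless in `[0, 1]`).
#' @examples
#' entropyBits(c(1, 1, -1, -1))                     # 1
#' infoGain(c(0, 0, 0, 1), c(-1, -1, 1, 1))         # 0.311278
#' gainRatio(c(0, 0, 0, 1), c(-1, -1, 1, 1))        # 0.383688
#' @export
entropyBits <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  entropyFromCounts(as.numeric(table(labels)))
}

#' @rdname entropyBits
#' @export
conditionalEntropy <- function(codes, labels) {
  if (length(codes) != length(labels))
    stop("codes and labels must have the same length")
  m <- length(labels)
  h <- 0
  for (x in unique(codes)) {
    sel <- codes == x
    h <- h + sum(sel) / m * entropyFromCounts(as.numeric(table(labels[sel])))
  }
  h
}

#' @rdname entropyBits
#' @export
infoGain <- function(codes, labels) {
  g <- entropyBits(labels) - conditionalEntropy(codes, labels)
  max(g, 0)
}

#' @rdname entropyBits
#' @export
gainRatio <- function(codes, labels) {
  split <- entropyBits(codes)
  if (split == 0) return(0)
  infoGain(codes, labels) / split
}

#' Point-biserial correlation score
#'
#' Absolute Pearson correlation between a gene's continuous expression and
#' the -1/+1 class labels; a higher value flags a more class-associated
#' gene. A constant gene scores 0 by convention (not `NaN`).
#'
#' @param values numeric expression values, length m >= 2.
#' @param labels class labels, -1/+1.
#' @return `|r|` in `[0, 1]`.
#' @export
pearsonScore <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 2L)
  if (popSd(values) == 0 || popSd(labels) == 0) return(0)
  abs(stats::cor(values, as.numeric(labels)))
}

#' ReliefF feature weights
#'
#' Instance-based feature weighting: for each (sampled) instance, the k
#' nearest same-class neighbours (hits) decrease and the k nearest
#' other-class neighbours (misses) increase the weight of every gene by its
#' normalized per-gene difference `|a_j - b_j| / (max_j - min_j)`. Neighbour
#' search uses Euclidean distance over all genes on min–max-scaled values;
#' in the two-class case the miss-class prior factor reduces to 1. With
#' `mIter = NULL` (all instances, the default) the result is
#' seed-independent; otherwise `mIter` instances are sampled without
#' replacement under `seed`. If a class has fewer than `k + 1` members its
#' neighbour count is reduced with a warning.
#'
#' @param ds a [GeneExpressionSet-class].
#' @param k neighbours per class (default 10).
#' @param mIter number of instances to sample, or `NULL` for all.
#' @param seed integer seed (used only when `mIter` is given).
#' @return named numeric weights in `[-1, 1]`, one per gene.
#' @export
relieffWeights <- function(ds, k = 10L, mIter = NULL, seed = 1L) {
  x <- t(exprMatrix(ds))                 # samples x genes
  y <- classLabels(ds)
  m <- nrow(x)
  rng <- apply(x, 2L, function(col) diff(range(col)))
  zeroRng <- rng == 0
  rng[zeroRng] <- 1
  xs <- sweep(sweep(x, 2L, apply(x, 2L, min)), 2L, rng, "/")
  xs[, zeroRng] <- 0
  dmat <- as.matrix(stats::dist(xs))

  idx <- seq_len(m)
  if (!is.null(mIter)) {
    mIter <- min(mIter, m)
    idx <- withSeed(seed, sample.int(m, mIter))
  }
  nIter <- length(idx)
  classes <- c(-1L, 1L)
  sizes <- table(factor(y, levels = classes))
  kUse <- stats::setNames(pmin(k, as.integer(sizes) - 1L), classes)
  if (any(kUse < k))
    warning("class with fewer than k+1 samples; k reduced to ",
            paste(kUse, collapse = "/"), " per class")

  w <- numeric(ncol(x))
  for (i in idx) {
    for (cls in classes) {
      same <- cls == y[i]
      pool <- which(y == cls & seq_len(m) != i)
      kk <- if (same) kUse[as.character(cls)]
            else min(k, length(pool))
      if (kk < 1L) next
      nb <- pool[order(dmat[i, pool], pool)][seq_len(kk)]
      diffs <- abs(sweep(x[nb, , drop = FALSE], 2L, x[i, ])) /
        matrix(rng, nrow = kk, ncol = ncol(x), byrow = TRUE)
      diffs[, zeroRng] <- 0
      contrib <- colSums(diffs) / (nIter * kk)
      w <- if (same) w - contrib else w + contrib
    }
  }
  stats::setNames(w, rownames(exprMatrix(ds)))
}

#' Rank all genes with one filter
#'
#' Scores every gene with the requested filter and returns a complete
#' [FeatureRanking-class] ordered by score (descending); ties keep the
#' canonical gene order, so rankings are stable and reproducible. For the
#' entropy-based filters (`"ig"`, `"gain_ratio"`) each gene is first
#' discretized with [mdlDiscretize()]; a gene with no accepted cuts scores
#' exactly 0.
#'
#' @param ds a [GeneExpressionSet-class] (normalize first; see
#'   [zscoreNormalize()]).
#' @param method `"ig"`, `"gain_ratio"`, `"relieff"` or `"correlation"`.
#' @param discretization `"mdlp"` or `"eqfreq"`, for the entropy filters.
#' @param bins bins for `"eqfreq"`.
#' @param k,mIter,seed reliefF parameters, see [relieffWeights()].
#' @return A [FeatureRanking-class] covering all genes.
#' @export
rankFeatures <- function(ds, method = c("ig", "gain_ratio", "relieff",
                                        "correlation"),
                         discretization = c("mdlp", "eqfreq"), bins = 10L,
                         k = 10L, mIter = NULL, seed = 1L) {
  method <- match.arg(method)
  discretization <- match.arg(discretization)
  x <- exprMatrix(ds)
  y <- classLabels(ds)
  scores <- switch(method,
    ig = apply(x, 1L, function(v)
      infoGain(binCodes(mdlDiscretize(v, y, discretization, bins)), y)),
    gain_ratio = apply(x, 1L, function(v)
      gainRatio(binCodes(mdlDiscretize(v, y, discretization, bins)), y)),
    correlation = apply(x, 1L, function(v) pearsonScore(v, y)),
    relieff = relieffWeights(ds, k = k, mIter = mIter, seed = seed))
  ord <- order(-scores, seq_along(scores))
  methods::new("FeatureRanking", method = method,
               records = data.frame(gene_id = rownames(x)[ord],
                                    score = as.numeric(scores[ord]),
                                    rank = seq_along(ord)))
}

#' @describeIn rankFeatures the ranking table (`gene_id`, `score`, `rank`).
#' @param ranking a [FeatureRanking-class].
#' @export
rankingTable <- function(ranking) ranking@records

#' @describeIn rankFeatures the filter that produced a ranking.
#' @export
rankingMethod <- function(ranking) ranking@method

#' @describeIn rankFeatures the `nKeep` top-ranked gene ids.
#' @param nKeep how many genes to keep, `1..n`.
#' @export
selectTop <- function(ranking, nKeep) {
  n <- nrow(ranking@records)
  if (nKeep < 1L || nKeep > n)
    stop("nKeep must be in 1..", n)
  ranking@records$gene_id[seq_len(nKeep)]
}

setMethod("show", "FeatureRanking", function(object) {
  r <- object@records
  cat("FeatureRanking (", object@method, "): ", nrow(r), " genes\n",
      sep = "")
  print(utils::head(r, 5L), row.names = FALSE)
  if (nrow(r) > 5L) cat("  ...\n")
})
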