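#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' Two-class gene expression container
#'
#' `GeneExpressionSet` extends [SummarizedExperiment::SummarizedExperiment]
#' for the binary-classification setting: a genes-by-samples matrix of
#' continuous expression values plus a two-level class factor on the samples.
#' The class labels are mapped internally to \eqn{-1/+1}; the
#' lexicographically smaller class name becomes \eqn{-1} so that the mapping
#' is deterministic across runs. Row (gene) order is the canonical order used
#' for every downstream tie-break.
#'
#' @slot .ignored inherited slots only; see `SummarizedExperiment`.
#' @seealso [GeneExpressionSet()] for construction, [classLabels()],
#'   [geneIds()], [zscoreNormalize()].
#' @export
setClass("GeneExpressionSet", contains = "SummarizedExperiment")

setValidity("GeneExpressionSet", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    x <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(x)) msg <- c(msg, "expression values must be numeric")
    if (anyNA(x)) msg <- c(msg, "expression values contain missing entries")
  }
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("class", "y") %in% colnames(cd))) {
    msg <- c(msg, "colData must carry 'class' and 'y'")
  } else {
    if (nlevels(factor(cd$class)) != 2L)
      msg <- c(msg, "not a binary problem: exactly two classes required")
    if (!all(cd$y %in% c(-1L, 1L)))
      msg <- c(msg, "numeric labels must be -1/+1")
  }
  if (length(msg)) msg else TRUE
})

#' Supervised discretization of one gene
#'
#' Holds the accepted cut points and the per-sample integer bin codes for a
#' single gene. Bins are half-open: code `b` covers values in
#' `[cut_b, cut_(b+1))`, i.e. the code of a value is the number of cut points
#' strictly below it. An empty cut set codes every sample as 0.
#'
#' @slot cutPoints ascending numeric thresholds (possibly empty).
#' @slot codes integer bin codes, one per sample, in `0..length(cutPoints)`.
#' @export
setClass("Discretization",
  representation(cutPoints = "numeric", codes = "integer"))

setValidity("Discretization", function(object) {
  msg <- character()
  if (is.unsorted(object@cutPoints, strictly = TRUE) && length(object@cutPoints) > 1L)
    msg <- c(msg, "cut points must be strictly ascending")
  if (length(object@codes) &&
      (min(object@codes) < 0L || max(object@codes) > length(object@cutPoints)))
    msg <- c(msg, "codes out of range 0..#cuts")
  if (length(msg)) msg else TRUE
})

#' Filter-stage feature ranking
#'
#' Result of scoring every gene with one filter (information gain, gain
#' ratio, reliefF or point-biserial correlation) and ordering by score.
#' Ties are broken by the canonical (on-disk / row) gene order, so rankings
#' are reproducible.
#'
#' @slot method one of `"ig"`, `"gain_ratio"`, `"relieff"`, `"correlation"`.
#' @slot records `data.frame` with columns `gene_id`, `score`, `rank`
#'   (ranks `1..n` with no gaps, scores non-increasing).
#' @export
setClass("FeatureRanking",
  representation(method = "character", records = "data.frame"))

setValidity("FeatureRanking", function(object) {
  msg <- character()
  r <- object@records
  if (!all(c("gene_id", "score", "rank") %in% names(r)))
    msg <- c(msg, "records needs gene_id, score, rank columns")
  else {
    if (nrow(r) && !identical(as.integer(r$rank), seq_len(nrow(r))))
      msg <- c(msg, "ranks must be 1..n in order")
    if (nrow(r) > 1L && any(diff(r$score) > 1e-12))
      msg <- c(msg, "scores must be non-increasing with rank")
    if (anyNA(r$score) || any(!is.finite(r$score)))
      msg <- c(msg, "scores must be finite")
  }
  if (!object@method %in% c("ig", "gain_ratio", "relieff", "correlation"))
    msg <- c(msg, "unknown method")
  if (object@method %in% c("ig", "gain_ratio") && nrow(r) && min(r$score) < 0)
    msg <- c(msg, "ig / gain_ratio scores must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Trained soft-margin support vector machine
#'
#' A fitted two-class SVM in dual form. `dualCoefs` holds
#' \eqn{\alpha_i y_i} for every training sample (zero off the support set),
#' so the dual constraints \eqn{0 \le \alpha_i \le C} and
#' \eqn{\sum_i \alpha_i y_i = 0} can be checked directly. For the linear
#' kernel the primal weight vector \eqn{\omega = \sum_i \alpha_i y_i x_i}
#' is materialized in `weights`; it is what recursive feature elimination
#' ranks genes by.
#'
#' @slot dualCoefs numeric, \eqn{\alpha_i y_i} per training sample.
#' @slot bias intercept \eqn{b} of the decision function
#'   \eqn{f(x)=\sum_i \alpha_i y_i K(x_i,x)+b}.
#' @slot kernel `"linear"` or `"rbf"`.
#' @slot gamma RBF width \eqn{\gamma \ge 0} (ignored for linear).
#' @slot cost box constraint \eqn{C > 0}.
#' @slot supportIdx integer indices of training samples with
#'   \eqn{\alpha_i > 0}.
#' @slot SV matrix of support vectors (rows of the training matrix).
#' @slot weights per-feature linear weights, length-0 for RBF.
#' @slot yTrain training labels (-1/+1), kept for diagnostics.
#' @export
setClass("SvmModel",
  representation(dualCoefs = "numeric", bias = "numeric", kernel = "character",
                 gamma = "numeric", cost = "numeric", supportIdx = "integer",
                 SV = "matrix", weights = "numeric", yTrain = "integer"))

setValidity("SvmModel", function(object) {
  msg <- character()
  alpha <- object@dualCoefs * object@yTrain
  if (any(alpha < -1e-8) || any(alpha > object@cost + 1e-8))
    msg <- c(msg, "dual coefficients violate 0 <= alpha <= C")
  if (abs(sum(object@dualCoefs)) > 1e-6)
    msg <- c(msg, "sum(alpha_i y_i) != 0")
  if (!object@kernel %in% c("linear", "rbf"))
    msg <- c(msg, "kernel must be linear or rbf")
  if (length(msg)) msg else TRUE
})

#' Trace of recursive feature elimination
#'
#' Records, for an SVM-RFE run, the order in which genes were discarded,
#' the surviving set after each round, and the squared linear weight of each
#' removed gene at the time of removal.
#'
#' @slot eliminationOrder gene ids, first-removed first.
#' @slot survivingSets list of id vectors, one per round, strictly nested.
#' @slot criterionValues squared weights \eqn{\omega_j^2} of removed genes.
#' @export
setClass("RfeTrace",
  representation(eliminationOrder = "character", survivingSets = "list",
                 criterionValues = "numeric"))

#' Cross-validation result
#'
#' Fold assignment and per-fold correct/total counts from a stratified
#' k-fold evaluation; pooled accuracy is reported as a percentage.
#'
#' @slot foldAssignment integer fold index in `0..k-1` per sample.
#' @slot perFold k-by-2 matrix, columns `correct`, `total`.
#' @slot accuracy pooled accuracy in percent, `100 * sum(correct) / m`.
#' @export
setClass("CvResult",
  representation(foldAssignment = "integer", perFold = "matrix",
                 accuracy = "numeric"))

setValidity("CvResult", function(object) {
  msg <- character()
  if (!identical(colnames(object@perFold), c("correct", "total")))
    msg <- c(msg, "perFold needs columns correct, total")
  else {
    if (sum(object@perFold[, "total"]) != length(object@foldAssignment))
      msg <- c(msg, "fold totals do not sum to m")
    acc <- 100 * sum(object@perFold[, "correct"]) / sum(object@perFold[, "total"])
    if (abs(acc - object@accuracy) > 1e-9)
      msg <- c(msg, "accuracy inconsistent with per-fold counts")
  }
  if (length(msg)) msg else TRUE
})

#' Specification of a synthetic two-class expression dataset
#'
#' Parameters of the Gaussian class-shift generator used to emulate
#' microarray studies (thousands of genes, tens of samples, a small planted
#' set of class-informative genes against noise).
#'
#' @slot m number of samples.
#' @slot n number of genes.
#' @slot nInformative number of planted class-informative genes.
#' @slot effect between-class mean shift, in pooled-standard-deviation units.
#' @slot classBalance fraction of positive-class samples, in (0, 1).
#' @slot noiseSd within-class standard deviation (> 0).
#' @slot correlatedBlock `NULL`, or `c(size, rho)`: a block of genes cloned
#'   from the first informative gene at correlation `rho` (redundancy model).
#' @slot logNormal exponentiate values to mimic heavy-tailed intensities.
#' @slot seed integer seed; generation is fully reproducible.
#' @export
setClass("SyntheticSpec",
  representation(m = "integer", n = "integer", nInformative = "integer",
                 effect = "numeric", classBalance = "numeric",
                 noiseSd = "numeric", correlatedBlock = "ANY",
                 logNormal = "logical", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  if (object@nInformative > object@n)
    msg <- c(msg, "nInformative must not exceed n")
  if (object@classBalance <= 0 || object@classBalance >= 1)
    msg <- c(msg, "classBalance must lie strictly between 0 and 1")
  if (object@effect < 0) msg <- c(msg, "effect must be >= 0")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be > 0")
  if (!is.null(object@correlatedBlock)) {
    cb <- object@correlatedBlock
    if (length(cb) != 2L || cb[1] < 1 || abs(cb[2]) > 1)
      msg <- c(msg, "correlatedBlock must be c(size >= 1, |rho| <= 1)")
    if (object@nInformative < 1L)
      msg <- c(msg, "correlatedBlock requires at least one informative gene")
  }
  if (length(msg)) msg else TRUE
})
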