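#' SVM recursive feature elimination
#'
#' Guyon-style wrapper selection: a linear-kernel soft-margin SVM is
#' trained on the surviving genes and, at each round, the `step` genes with
#' the smallest squared weight \eqn{\omega_j^2} are discarded, until
#' `kFinal` genes remain. Exact weight ties are broken by the canonical
#' gene order (the later gene is removed first). The linear kernel is used
#' here even though final classification uses the RBF kernel, because only
#' the linear kernel yields per-gene weights; the linear kernel is itself
#' the limiting special case of the RBF family. Survivors are returned in
#' descending final-model \eqn{\omega_j^2} order.
#'
#' @param ds a (normalized) [GeneExpressionSet-class].
#' @param candidateGenes gene ids to start from (e.g. a filter's top 150).
#' @param kFinal how many genes to keep (default 3).
#' @param C linear-SVM box constraint (default 1, the LIBSVM default).
#' @param step genes removed per round (default 1).
#' @return `list(genes = <kFinal ids>, trace = <RfeTrace>)`.
#' @export
svmRfe <- function(ds, candidateGenes, kFinal = 3L, C = 1, step = 1L) {
  if (length(candidateGenes) < kFinal)
    stop("candidate list smaller than kFinal")
  canon <- match(candidateGenes, geneIds(ds))
  if (anyNA(canon))
    stop("unknown gene id(s): ",
         paste(candidateGenes[is.na(canon)], collapse = ", "))
  x <- t(exprMatrix(ds))[, candidateGenes, drop = FALSE]
  y <- classLabels(ds)

  surviving <- candidateGenes
  elimOrder <- character()
  critVals <- numeric()
  sets <- list(surviving)
  w2 <- NULL
  repeat {
    fit <- trainSvm(x[, surviving, drop = FALSE], y, C = C,
                    kernel = "linear")
    w2 <- stats::setNames(modelWeights(fit)^2, surviving)
    if (length(surviving) == kFinal) break
    nDrop <- min(step, length(surviving) - kFinal)
    # smallest w^2 first; on exact ties drop the later canonical gene first
    ord <- order(w2, -match(surviving, geneIds(ds)))
    drop <- surviving[ord[seq_len(nDrop)]]
    elimOrder <- c(elimOrder, drop)
    critVals <- c(critVals, w2[drop])
    surviving <- setdiff(surviving, drop)
    sets <- c(sets, list(surviving))
    if (length(surviving) == kFinal) {
      fit <- trainSvm(x[, surviving, drop = FALSE], y, C = C,
                      kernel = "linear")
      w2 <- stats::setNames(modelWeights(fit)^2, surviving)
      break
    }
  }
  genes <- surviving[order(-w2[surviving],
                           match(surviving, geneIds(ds)))]
  trace <- methods::new("RfeTrace", eliminationOrder = elimOrder,
                        survivingSets = sets,
                        criterionValues = as.numeric(critVals))
  list(genes = genes, trace = trace)
}

#' @describeIn svmRfe gene ids in removal order (first-removed first).
#' @param trace an [RfeTrace-class].
#' @export
eliminationOrder <- function(trace) trace@eliminationOrder

#' @describeIn svmRfe the nested surviving sets, one per round.
#' @export
survivingSets <- function(trace) trace@survivingSets

#' @describeIn svmRfe squared weights of the removed genes.
#' @export
criterionValues <- function(trace) trace@criterionValues

setMethod("show", "RfeTrace", function(object) {
  cat("RfeTrace: ", length(object@eliminationOrder), " genes removed, ",
      length(object@survivingSets[[length(object@survivingSets)]]),
      " surviving\n", sep = "")
})

#' Two-stage hybrid gene selection (filter + SVM-RFE)
#'
#' The headline pipeline: rank all genes with a filter
#' ([rankFeatures()]), keep the top `nFilter` (default 150), then refine to
#' `kFinal` genes (default 3) with linear SVM-RFE ([svmRfe()]). Equivalent
#' to composing the three stages explicitly.
#'
#' @inheritParams rankFeatures
#' @param nFilter genes kept by the filter stage (default 150).
#' @param kFinal genes returned by the wrapper stage (default 3).
#' @param C linear-SVM box constraint for the RFE stage.
#' @param details return the intermediate ranking and RFE trace too.
#' @return the `kFinal` selected gene ids, or (with `details = TRUE`) a
#'   list with `genes`, `ranking`, `trace`.
#' @examples
#' \donttest{
#' fx <- makeFixture("colon-like", seed = 1)
#' ds <- zscoreNormalize(fx$dataset)
#' hybridSelect(ds, "ig")
#' }
#' @export
hybridSelect <- function(ds, method = c("ig", "gain_ratio", "relieff",
                                        "correlation"),
                         nFilter = 150L, kFinal = 3L, C = 1,
                         discretization = c("mdlp", "eqfreq"), bins = 10L,
                         k = 10L, mIter = NULL, seed = 1L,
                         details = FALSE) {
  method <- match.arg(method)
  if (nFilter > nGenes(ds)) stop("nFilter exceeds the number of genes")
  if (kFinal > nFilter) stop("kFinal exceeds nFilter")
  ranking <- rankFeatures(ds, method, discretization = discretization,
                          bins = bins, k = k, mIter = mIter, seed = seed)
  candidates <- selectTop(ranking, nFilter)
  rfe <- svmRfe(ds, candidates, kFinal = kFinal, C = C)
  if (details)
    list(genes = rfe$genes, ranking = ranking, trace = rfe$trace)
  else rfe$genes
}
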