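#' Construct a GeneExpressionSet
#'
#' Builds the package's central container from a genes-by-samples matrix and
#' a two-level label vector. Labels may be any two distinct values
#' (character, factor or numeric); the lexicographically smaller class name
#' is mapped to \eqn{-1}, the larger to \eqn{+1}, and the mapping is stored
#' in the object metadata so reports can echo it.
#'
#' @param values numeric matrix, genes in rows, samples in columns.
#' @param geneIds unique gene identifiers (default: rownames).
#' @param sampleIds unique sample identifiers (default: colnames, or
#'   `S1..Sm` when absent).
#' @param labels per-sample class labels, exactly two distinct values.
#' @return A [GeneExpressionSet-class] object.
#' @examples
#' x <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' ds <- GeneExpressionSet(x, labels = c("tumor", "normal", "tumor", "tumor"))
#' classLabels(ds)
#' @export
GeneExpressionSet <- function(values, geneIds = rownames(values),
                              sampleIds = colnames(values), labels) {
  values <- as.matrix(values)
  m <- ncol(values)
  if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(m))
  if (is.null(geneIds)) stop("gene ids are required")
  if (length(labels) != m)
    stop("labels must have one value per sample (", m, ")")
  if (anyNA(labels)) stop("labels contain missing values")
  lab <- as.character(labels)
  classes <- sort(unique(lab))
  if (length(classes) != 2L)
    stop("not a binary problem: found ", length(classes),
         " classes (", paste(classes, collapse = ", "), ")")
  y <- ifelse(lab == classes[1L], -1L, 1L)
  dup <- geneIds[duplicated(geneIds)]
  if (length(dup))
    stop("duplicate gene ids: ", paste(unique(dup), collapse = ", "))
  dimnames(values) <- list(geneIds, sampleIds)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values),
    colData = S4Vectors::DataFrame(class = factor(lab, levels = classes),
                                   y = as.integer(y), row.names = sampleIds),
    rowData = S4Vectors::DataFrame(constant = logical(nrow(values)),
                                   row.names = geneIds))
  obj <- methods::new("GeneExpressionSet", se)
  S4Vectors::metadata(obj)$classMap <-
    stats::setNames(c(-1L, 1L), classes)
  S4Vectors::metadata(obj)$normalized <- FALSE
  obj
}

#' @describeIn GeneExpressionSet genes-by-samples expression matrix.
#' @param x a `GeneExpressionSet`.
#' @export
exprMatrix <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn GeneExpressionSet gene identifiers in canonical order.
#' @export
geneIds <- function(x) rownames(x)

#' @describeIn GeneExpressionSet sample identifiers.
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn GeneExpressionSet per-sample labels coded -1/+1.
#' @export
classLabels <- function(x)
  stats::setNames(as.integer(SummarizedExperiment::colData(x)$y), colnames(x))

#' @describeIn GeneExpressionSet named map from class names to -1/+1.
#' @export
classMap <- function(x) S4Vectors::metadata(x)$classMap

#' @describeIn GeneExpressionSet number of genes.
#' @export
nGenes <- function(x) nrow(x)

#' @describeIn GeneExpressionSet number of samples.
#' @export
nSamples <- function(x) ncol(x)

#' @describeIn GeneExpressionSet `TRUE` after [zscoreNormalize()].
#' @export
isNormalized <- function(x) isTRUE(S4Vectors::metadata(x)$normalized)

#' @describeIn GeneExpressionSet ids of genes flagged constant during
#'   normalization.
#' @export
constantGenes <- function(x)
  rownames(x)[SummarizedExperiment::rowData(x)$constant]

setMethod("show", "GeneExpressionSet", function(object) {
  cm <- classMap(object)
  tab <- table(SummarizedExperiment::colData(object)$class)
  cat("GeneExpressionSet: ", nrow(object), " genes x ", ncol(object),
      " samples\n", sep = "")
  cat("  classes: ", paste0(names(cm), " -> ", cm, " (n=", as.integer(tab),
                            ")", collapse = ", "), "\n", sep = "")
  cat("  normalized: ", isNormalized(object),
      if (length(constantGenes(object)))
        paste0(" (", length(constantGenes(object)), " constant genes flagged)"),
      "\n", sep = "")
})

# subset a dataset to a gene id vector, preserving order of `genes`
subsetGenes <- function(ds, genes) {
  missing <- setdiff(genes, rownames(ds))
  if (length(missing))
    stop("unknown gene id(s): ", paste(missing, collapse = ", "))
  ds[genes, ]
}
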