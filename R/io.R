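#' Read a delimited or ARFF expression table
#'
#' Loads a samples-by-genes (or genes-by-samples) expression table with a
#' binary class label and validates it into a [GeneExpressionSet-class].
#' For delimited files the first row is a header; with
#' `orientation = "genes-as-columns"` each remaining row is a sample and one
#' column named by `labelSource` carries the class, while with
#' `"genes-as-rows"` each row is a gene (gene id in the first column) and the
#' labels come either from a row whose id equals `labelSource` or from a
#' sidecar file (one label per line) if `labelSource` is an existing path.
#' ARFF files are read with [foreign::read.arff()]; the nominal class
#' attribute is `labelSource`.
#'
#' Non-numeric cells and missing values are rejected with their coordinates
#' (set `impute = "mean"` to replace missing values by the per-gene mean);
#' duplicate gene ids and problems with more than two classes are rejected.
#'
#' @param path file to read.
#' @param orientation `"genes-as-columns"` (default) or `"genes-as-rows"`.
#' @param labelSource label column/row name, or path to a sidecar label file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"arff"`.
#' @param impute `"reject"` (default) or `"mean"` for missing cells.
#' @return A [GeneExpressionSet-class]; the class-to--1/+1 mapping is
#'   reported via `message()` and retrievable with [classMap()].
#' @export
readExpressionTable <- function(path,
                                orientation = c("genes-as-columns",
                                                "genes-as-rows"),
                                labelSource = "label",
                                format = c("auto", "tsv", "csv", "arff"),
                                impute = c("reject", "mean")) {
  orientation <- match.arg(orientation)
  format <- match.arg(format)
  impute <- match.arg(impute)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", arff = "arff", "tsv")
  }

  if (format == "arff") {
    df <- foreign::read.arff(path)
    if (!labelSource %in% names(df))
      stop("label attribute '", labelSource, "' not found in ARFF file")
    labels <- as.character(df[[labelSource]])
    vals <- df[, setdiff(names(df), labelSource), drop = FALSE]
    mat <- t(checkNumericTable(vals, impute))
    ds <- GeneExpressionSet(mat, labels = labels)
    reportMapping(ds)
    return(ds)
  }

  sep <- if (format == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"",
                           row.names = NULL, stringsAsFactors = FALSE)

  sidecar <- !is.null(labelSource) && file.exists(labelSource)
  if (orientation == "genes-as-columns") {
    if (!sidecar && !labelSource %in% names(raw))
      stop("label column '", labelSource, "' not found")
    idCol <- detectIdColumn(raw, labelSource)
    sampleIds <- if (is.na(idCol)) paste0("S", seq_len(nrow(raw)))
                 else raw[[idCol]]
    labels <- if (sidecar) readLines(labelSource)
              else raw[[labelSource]]
    geneCols <- setdiff(names(raw),
                        c(if (!sidecar) labelSource,
                          if (!is.na(idCol)) names(raw)[idCol]))
    vals <- raw[, geneCols, drop = FALSE]
    mat <- t(checkNumericTable(vals, impute))    # -> genes x samples
    colnames(mat) <- sampleIds
  } else {
    geneIds <- raw[[1L]]
    body <- raw[, -1L, drop = FALSE]
    labRow <- which(geneIds == labelSource)
    if (sidecar) {
      labels <- readLines(labelSource)
    } else if (length(labRow) == 1L) {
      labels <- as.character(unlist(body[labRow, ], use.names = FALSE))
      body <- body[-labRow, , drop = FALSE]
      geneIds <- geneIds[-labRow]
    } else {
      stop("label row '", labelSource, "' not found and no sidecar file")
    }
    rownames(body) <- NULL
    mat <- as.matrix(checkNumericTable(body, impute, rowIds = geneIds))
    rownames(mat) <- geneIds
    colnames(mat) <- names(body)
  }
  if (length(labels) != ncol(mat))
    stop("label count (", length(labels), ") does not match sample count (",
         ncol(mat), ")")
  ds <- GeneExpressionSet(mat, labels = labels)
  reportMapping(ds)
  ds
}

# coerce a character data.frame to numeric, rejecting (or mean-imputing)
# bad cells with their coordinates
checkNumericTable <- function(df, impute, rowIds = NULL) {
  out <- matrix(NA_real_, nrow = nrow(df), ncol = ncol(df),
                dimnames = list(rowIds, names(df)))
  bad <- character()
  for (j in seq_along(df)) {
    col <- trimws(as.character(df[[j]]))
    col[col %in% c("", "NA", "?")] <- NA
    v <- suppressWarnings(as.numeric(col))
    nonNum <- which(!is.na(col) & is.na(v))
    if (length(nonNum))
      bad <- c(bad, paste0("row ", nonNum, ", column '", names(df)[j],
                           "' (value '", col[nonNum], "')"))
    out[, j] <- v
  }
  if (length(bad))
    stop("non-numeric cell(s): ", paste(bad, collapse = "; "))
  if (anyNA(out)) {
    if (impute == "reject") {
      idx <- which(is.na(out), arr.ind = TRUE)
      stop("missing value(s) at: ",
           paste0("row ", idx[, 1], ", column '", colnames(out)[idx[, 2]],
                  "'", collapse = "; "))
    }
    # per-gene mean imputation; genes are columns here for
    # genes-as-columns input, rows when rowIds were supplied
    if (is.null(rowIds)) {
      for (j in seq_len(ncol(out))) {
        nas <- is.na(out[, j])
        if (any(nas)) out[nas, j] <- mean(out[, j], na.rm = TRUE)
      }
    } else {
      for (i in seq_len(nrow(out))) {
        nas <- is.na(out[i, ])
        if (any(nas)) out[i, nas] <- mean(out[i, ], na.rm = TRUE)
      }
    }
  }
  out
}

detectIdColumn <- function(raw, labelSource) {
  first <- names(raw)[1L]
  if (first %in% c("", "id", "sample", "sample_id", "Sample", "ID") &&
      first != labelSource && anyNA(suppressWarnings(as.numeric(raw[[1L]]))))
    1L
  else NA_integer_
}

reportMapping <- function(ds) {
  cm <- classMap(ds)
  message("class mapping: ", paste0(names(cm), " -> ",
                                    sprintf("%+d", cm), collapse = ", "))
}

#' Per-gene z-score normalization
#'
#' Centers every gene to mean zero and scales it to unit population
#' variance (the 1/m form), the usual preprocessing before filter scoring
#' so that expression differences between genes do not dominate. Genes with
#' zero variance are set to all-zeros and flagged (see [constantGenes()])
#' rather than producing NaNs. The operation is idempotent and depends only
#' on per-gene statistics, so it is invariant to sample order.
#'
#' @param ds a [GeneExpressionSet-class].
#' @return The normalized dataset, with `isNormalized(ds)` set.
#' @export
zscoreNormalize <- function(ds) {
  x <- exprMatrix(ds)
  if (ncol(x) < 2L) stop("need at least 2 samples per gene")
  mu <- rowMeans(x)
  cx <- x - mu
  sdv <- sqrt(rowMeans(cx^2))
  const <- sdv == 0
  sdv[const] <- 1
  z <- cx / sdv
  z[const, ] <- 0
  SummarizedExperiment::assay(ds, "exprs") <- z
  SummarizedExperiment::rowData(ds)$constant <-
    SummarizedExperiment::rowData(ds)$constant | const
  S4Vectors::metadata(ds)$normalized <- TRUE
  methods::validObject(ds)
  ds
}

#' Write / read a feature ranking as TSV
#'
#' Serializes a [FeatureRanking-class] to a three-column TSV
#' (`gene_id`, `score`, `rank`); scores are written with six significant
#' digits and round-trip losslessly at that precision.
#'
#' @param ranking a `FeatureRanking` (or its `records` data.frame).
#' @param path output file.
#' @export
writeRanking <- function(ranking, path) {
  rec <- if (methods::is(ranking, "FeatureRanking")) ranking@records
         else ranking
  out <- data.frame(gene_id = rec$gene_id,
                    score = sprintf("%.6g", rec$score),
                    rank = rec$rank)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname writeRanking
#' @param method filter name recorded in the reconstructed object.
#' @return `readRanking` returns a [FeatureRanking-class].
#' @export
readRanking <- function(path, method = "ig") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "numeric", "integer"))
  methods::new("FeatureRanking", method = method,
               records = data.frame(gene_id = df$gene_id, score = df$score,
                                    rank = df$rank))
}
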