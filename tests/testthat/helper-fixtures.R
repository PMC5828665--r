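# fixture builders shared across test files

# small GeneExpressionSet straight from a genes x samples matrix
toyDataset <- function(values, labels, geneIds = NULL) {
  if (is.null(geneIds)) geneIds <- paste0("G", seq_len(nrow(values)))
  rownames(values) <- geneIds
  colnames(values) <- paste0("S", seq_len(ncol(values)))
  suppressMessages(GeneExpressionSet(values, labels = labels))
}

# write the canonical 4-sample x 3-gene samples-as-rows TSV
writeToyTsv <- function(path, sep = "\t", labels = c("tumor", "normal",
                                                     "tumor", "normal")) {
  df <- data.frame(GA = c(1.5, 2.5, 3.5, 4.5),
                   GB = c(0.1, 0.2, 0.3, 0.4),
                   GC = c(9, 8, 7, 6),
                   label = labels)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  df
}

# dataset with planted informative genes plus Gaussian noise genes
plantedDataset <- function(m = 40, nNoise = 20, nSignal = 1, effect = 3,
                           seed = 42) {
  out <- generateExpression(syntheticSpec(
    m = m, n = nNoise + nSignal, nInformative = nSignal, effect = effect,
    classBalance = 0.5, seed = seed))
  out
}

expect_valid <- function(object) {
  testthat::expect_true(isTRUE(methods::validObject(object, test = TRUE)))
}
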