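#' Candidate cut points for one gene
#'
#' Sorts the samples by expression value, groups tied values, and returns
#' the midpoints between consecutive distinct values that are class
#' boundaries: a midpoint is a candidate unless both adjacent value-groups
#' are pure and of the same class (the boundary-point argument guarantees
#' entropy-optimal cuts lie at such points, so the others can be skipped).
#'
#' @param values numeric expression values for one gene (length m >= 2).
#' @param labels class labels, -1/+1, same length.
#' @return ascending numeric vector of candidate thresholds (possibly empty).
#' @examples
#' candidateCuts(c(1, 2, 3, 4), c(-1, -1, 1, 1))  # 2.5
#' @export
candidateCuts <- function(values, labels) {
  stopifnot(length(values) == length(labels), length(values) >= 2L)
  stopIfNot01Labels(labels)
  ord <- order(values)
  v <- values[ord]
  y <- labels[ord]
  uv <- unique(v)
  if (length(uv) < 2L) return(numeric())
  # per distinct value: does the group contain -1 / +1 samples?
  hasNeg <- vapply(uv, function(u) any(y[v == u] == -1L), logical(1))
  hasPos <- vapply(uv, function(u) any(y[v == u] == 1L), logical(1))
  k <- length(uv)
  keep <- logical(k - 1L)
  for (i in seq_len(k - 1L)) {
    purerSame <- (!hasNeg[i] && !hasNeg[i + 1L]) ||
                 (!hasPos[i] && !hasPos[i + 1L])
    keep[i] <- !purerSame
  }
  (uv[-k][keep] + uv[-1L][keep]) / 2
}

# info gain and MDLP bookkeeping for a sorted interval -------------------

# counts: c(#neg, #pos)
intervalEntropy <- function(counts) entropyFromCounts(counts)

# Fayyad–Irani MDLP acceptance threshold for a split of N samples with
# k classes overall and k1/k2 classes in the two halves; entropies in bits.
mdlpThreshold <- function(N, k, k1, k2, hS, hS1, hS2) {
  delta <- log2(3^k - 2) - (k * hS - k1 * hS1 - k2 * hS2)
  (log2(N - 1) + delta) / N
}

#' Entropy-based (MDLP) discretization of one gene
#'
#' Recursive binary discretization in the Fayyad–Irani style: within each
#' interval the candidate cut with the largest class-information gain is
#' taken (leftmost on ties) and accepted only if the gain clears the
#' minimum-description-length threshold
#' \deqn{gain > \frac{\log_2(N-1) + \log_2(3^k-2) - [k H(S) - k_1 H(S_1) - k_2 H(S_2)]}{N}}
#' with \eqn{N} the interval size and \eqn{k, k_1, k_2} the number of
#' classes present in the interval and its two halves; accepted cuts are
#' recursed on both sides. Genes whose labels carry no signal get no cuts,
#' and therefore zero information gain downstream. `method = "eqfreq"`
#' substitutes unsupervised equal-frequency binning.
#'
#' @inheritParams candidateCuts
#' @param method `"mdlp"` (default) or `"eqfreq"`.
#' @param bins number of bins for `"eqfreq"`.
#' @return A [Discretization-class] with the accepted cut points and the
#'   per-sample bin codes (number of cuts strictly below each value).
#' @examples
#' d <- mdlDiscretize(c(0.1, 0.2, 0.9, 1.0), c(-1, -1, 1, 1))
#' cutPoints(d); binCodes(d)
#' @export
mdlDiscretize <- function(values, labels, method = c("mdlp", "eqfreq"),
                          bins = 10L) {
  method <- match.arg(method)
  stopifnot(length(values) == length(labels), length(values) >= 2L)
  stopIfNot01Labels(labels)
  if (method == "eqfreq") {
    qs <- stats::quantile(values, probs = seq_len(bins - 1L) / bins,
                          names = FALSE, type = 7)
    cuts <- sort(unique(qs))
    cuts <- cuts[cuts > min(values) & cuts <= max(values)]
    return(newDiscretization(cuts, values))
  }
  ord <- order(values)
  v <- values[ord]
  y01 <- as.integer(labels[ord] == 1L)   # 0 = negative class, 1 = positive
  cuts <- mdlpRecurse(v, y01)
  newDiscretization(sort(cuts), values)
}

newDiscretization <- function(cuts, values) {
  codes <- vapply(values, function(x) sum(cuts < x), integer(1))
  methods::new("Discretization", cutPoints = as.numeric(cuts),
               codes = codes)
}

# v sorted ascending, y01 in {0,1}; returns accepted cut values
mdlpRecurse <- function(v, y01) {
  N <- length(v)
  if (N < 2L) return(numeric())
  cntNeg <- sum(y01 == 0L)
  cntPos <- N - cntNeg
  if (cntNeg == 0L || cntPos == 0L) return(numeric())

  # candidate boundaries between distinct values, Fayyad boundary rule
  grpEnd <- which(diff(v) > 0)             # last index of each value group
  if (!length(grpEnd)) return(numeric())
  cumPos <- cumsum(y01)
  cumNeg <- seq_len(N) - cumPos
  starts <- c(1L, grpEnd + 1L)             # group start indices
  ends <- c(grpEnd, N)
  gPos <- cumPos[ends] - c(0L, cumPos[ends[-length(ends)]])
  gNeg <- cumNeg[ends] - c(0L, cumNeg[ends[-length(ends)]])
  ng <- length(ends)
  bnd <- logical(ng - 1L)
  for (i in seq_len(ng - 1L)) {
    pureSame <- (gPos[i] == 0L && gPos[i + 1L] == 0L) ||
                (gNeg[i] == 0L && gNeg[i + 1L] == 0L)
    bnd[i] <- !pureSame
  }
  candEnd <- ends[-ng][bnd]                # split after these indices
  if (!length(candEnd)) return(numeric())

  hS <- entropyFromCounts(c(cntNeg, cntPos))
  leftPos <- cumPos[candEnd]; leftNeg <- cumNeg[candEnd]
  rightPos <- cntPos - leftPos; rightNeg <- cntNeg - leftNeg
  hL <- vapply(seq_along(candEnd),
               function(i) entropyFromCounts(c(leftNeg[i], leftPos[i])),
               numeric(1))
  hR <- vapply(seq_along(candEnd),
               function(i) entropyFromCounts(c(rightNeg[i], rightPos[i])),
               numeric(1))
  nL <- candEnd
  gain <- hS - (nL * hL + (N - nL) * hR) / N
  best <- which.max(gain)                  # leftmost maximum
  k1 <- sum(c(leftNeg[best], leftPos[best]) > 0L)
  k2 <- sum(c(rightNeg[best], rightPos[best]) > 0L)
  thr <- mdlpThreshold(N, 2L, k1, k2, hS, hL[best], hR[best])
  if (gain[best] <= thr) return(numeric())
  i <- candEnd[best]
  cut <- (v[i] + v[i + 1L]) / 2
  c(mdlpRecurse(v[seq_len(i)], y01[seq_len(i)]),
    cut,
    mdlpRecurse(v[(i + 1L):N], y01[(i + 1L):N]))
}

#' @describeIn mdlDiscretize accepted cut points of a `Discretization`.
#' @param d a [Discretization-class].
#' @export
cutPoints <- function(d) d@cutPoints

#' @describeIn mdlDiscretize integer bin codes of a `Discretization`.
#' @export
binCodes <- function(d) d@codes

setMethod("show", "Discretization", function(object) {
  cat("Discretization: ", length(object@cutPoints), " cut(s), ",
      length(object@codes), " samples\n", sep = "")
  if (length(object@cutPoints))
    cat("  cuts: ", paste(signif(object@cutPoints, 6), collapse = ", "),
        "\n", sep = "")
})
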