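#' RBF kernel
#'
#' \eqn{K(a,b) = \exp(-\gamma \|a-b\|^2)}; equals 1 when `a == b` or when
#' `gamma == 0` (the flat limit).
#'
#' @param a,b numeric vectors of equal length.
#' @param gamma width parameter, `>= 0`.
#' @return kernel value in `(0, 1]`.
#' @examples
#' rbfKernel(c(0, 0), c(1, 1), 0.5)  # exp(-1)
#' @export
rbfKernel <- function(a, b, gamma) {
  if (length(a) != length(b)) stop("length mismatch")
  if (gamma < 0) stop("gamma must be >= 0")
  exp(-gamma * sum((a - b)^2))
}

# kernel matrix between row-sets A and B
kernelMat <- function(A, B, kernel, gamma) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (kernel == "linear") return(A %*% t(B))
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  exp(-gamma * pmax(d2, 0))
}

#' Train a soft-margin SVM
#'
#' Solves the two-class soft-margin dual
#' \deqn{\max_\alpha \sum_i \alpha_i - \tfrac12 \sum_{ij} \alpha_i \alpha_j
#'       y_i y_j K(x_i, x_j), \quad 0 \le \alpha_i \le C,\;
#'       \sum_i \alpha_i y_i = 0}
#' via LIBSVM ([e1071::svm()], `scale = FALSE`) and repackages the solution
#' as an [SvmModel-class] with full-length dual coefficients
#' \eqn{\alpha_i y_i}, the bias of
#' \eqn{f(x) = \sum_i \alpha_i y_i K(x_i, x) + b}, and (for the linear
#' kernel) the primal weights \eqn{\omega = \sum_i \alpha_i y_i x_i}. The
#' sign convention is normalized so that positive decision values predict
#' the +1 class regardless of sample order.
#'
#' @param X m-by-p training matrix.
#' @param y training labels, -1/+1, both classes present.
#' @param C box constraint (> 0), default 1 (the LIBSVM default).
#' @param kernel `"linear"` or `"rbf"`.
#' @param gamma RBF width; default `1/p` (the LIBSVM default).
#' @param tol KKT termination tolerance (default `1e-3`).
#' @return an [SvmModel-class].
#' @examples
#' X <- rbind(c(-1, 0), c(-1, 1), c(1, 0), c(1, 1))
#' fit <- trainSvm(X, c(-1, -1, 1, 1), C = 1, kernel = "linear")
#' modelWeights(fit)
#' @export
trainSvm <- function(X, y, C = 1, kernel = c("linear", "rbf"),
                     gamma = 1 / ncol(X), tol = 1e-3) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.integer(y)
  stopIfNot01Labels(y)
  if (length(unique(y)) < 2L)
    stop("single-class input: both classes are required to train an SVM")
  yf <- factor(y, levels = c(-1L, 1L))
  fit <- e1071::svm(x = X, y = yf, scale = FALSE,
                    kernel = if (kernel == "rbf") "radial" else "linear",
                    cost = C, gamma = gamma, tolerance = tol)
  coefs <- as.numeric(fit$coefs)
  b <- -fit$rho
  # libsvm's decision sign follows its internal label order; normalize so
  # positive decision values mean class +1
  if (fit$labels[1L] == 1L) {    # internal first label is factor code 1 = "-1"
    coefs <- -coefs
    b <- -b
  }
  dual <- numeric(nrow(X))
  dual[fit$index] <- coefs
  w <- if (kernel == "linear") as.numeric(crossprod(X, dual)) else numeric()
  methods::new("SvmModel",
               dualCoefs = dual, bias = b, kernel = kernel,
               gamma = if (kernel == "rbf") gamma else 0,
               cost = C, supportIdx = sort(as.integer(fit$index)),
               SV = X[sort(as.integer(fit$index)), , drop = FALSE],
               weights = w, yTrain = y)
}

#' @describeIn trainSvm decision values \eqn{f(x)} for new rows.
#' @param model an `SvmModel`.
#' @param newX matrix of observations (rows).
#' @export
decisionValues <- function(model, newX) {
  newX <- as.matrix(newX)
  K <- kernelMat(newX, model@SV, model@kernel, model@gamma)
  as.numeric(K %*% model@dualCoefs[model@supportIdx] + model@bias)
}

#' @describeIn trainSvm full-length dual coefficients \eqn{\alpha_i y_i}.
#' @export
dualCoefs <- function(model) model@dualCoefs

#' @describeIn trainSvm indices of the support vectors.
#' @export
supportIndices <- function(model) model@supportIdx

#' @describeIn trainSvm linear primal weights (length 0 for RBF).
#' @export
modelWeights <- function(model) model@weights

#' @describeIn trainSvm dual objective value
#'   \eqn{\sum_i \alpha_i - \frac12 (\alpha y)^\top K (\alpha y)} of the
#'   trained solution.
#' @export
dualObjective <- function(model) {
  ay <- model@dualCoefs[model@supportIdx]
  K <- kernelMat(model@SV, model@SV, model@kernel, model@gamma)
  sum(abs(ay)) - 0.5 * as.numeric(t(ay) %*% K %*% ay)
}

#' @rdname trainSvm
#' @param object an `SvmModel`.
#' @param ... ignored.
#' @return `predict` returns -1/+1 labels (`sign(f)`, with 0 mapped to +1).
#' @export
setMethod("predict", "SvmModel", function(object, newX, ...) {
  f <- decisionValues(object, newX)
  ifelse(f >= 0, 1L, -1L)
})

setMethod("show", "SvmModel", function(object) {
  cat("SvmModel: ", object@kernel, " kernel, C = ", object@cost,
      if (object@kernel == "rbf") paste0(", gamma = ", signif(object@gamma, 4)),
      "\n  ", length(object@supportIdx), "/", length(object@dualCoefs),
      " support vectors, bias = ", signif(object@bias, 6), "\n", sep = "")
})
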