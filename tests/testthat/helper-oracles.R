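# Independent oracles used to cross-check the implementation. These are
# deliberately written on different principles than the package code
# (joint-count tables, exhaustive enumeration) and kept brute-force slow.

# Information gain via the joint distribution: I(X;Y) = H(X) + H(Y) - H(X,Y)
igJointOracle <- function(codes, labels) {
  jt <- table(codes, labels)
  hxy <- entropyOfCounts(as.numeric(jt))
  hx <- entropyOfCounts(as.numeric(rowSums(jt)))
  hy <- entropyOfCounts(as.numeric(colSums(jt)))
  hx + hy - hxy
}

entropyOfCounts <- function(cnt) {
  cnt <- cnt[cnt > 0]
  p <- cnt / sum(cnt)
  -sum(p * log2(p))
}

# Exhaustive recursive MDLP: enumerate every candidate boundary midpoint,
# evaluate its gain from scratch with table() counts, apply the
# Fayyad-Irani acceptance inequality, recurse.  No shared code with the
# package implementation beyond the inequality itself.
mdlpOracle <- function(values, labels) {
  rec <- function(v, y) {
    o <- order(v); v <- v[o]; y <- y[o]
    N <- length(v)
    if (N < 2L || length(unique(y)) < 2L) return(numeric())
    uv <- unique(v)
    if (length(uv) < 2L) return(numeric())
    cand <- c()
    for (i in seq_len(length(uv) - 1L)) {
      gl <- y[v == uv[i]]; gr <- y[v == uv[i + 1L]]
      if (length(unique(c(gl, gr))) > 1L)
        cand <- c(cand, (uv[i] + uv[i + 1L]) / 2)
    }
    if (!length(cand)) return(numeric())
    hS <- entropyOfCounts(as.numeric(table(y)))
    gains <- sapply(cand, function(ct) {
      l <- y[v < ct]; r <- y[v >= ct]
      hS - (length(l) * entropyOfCounts(as.numeric(table(l))) +
            length(r) * entropyOfCounts(as.numeric(table(r)))) / N
    })
    best <- which.max(gains)
    ct <- cand[best]
    l <- y[v < ct]; r <- y[v >= ct]
    k  <- length(unique(y))
    k1 <- length(unique(l)); k2 <- length(unique(r))
    hS1 <- entropyOfCounts(as.numeric(table(l)))
    hS2 <- entropyOfCounts(as.numeric(table(r)))
    delta <- log2(3^k - 2) - (k * hS - k1 * hS1 - k2 * hS2)
    if (gains[best] <= (log2(N - 1) + delta) / N) return(numeric())
    c(rec(v[v < ct], y[v < ct]), ct, rec(v[v >= ct], y[v >= ct]))
  }
  sort(rec(values, labels))
}

# Brute-force soft-margin dual solver by exhaustive KKT-pattern
# enumeration: every sample is either inactive (alpha = 0), free
# (0 < alpha < C, on the margin) or at the box bound (alpha = C).  For
# each of the 3^m patterns the equality KKT system is solved and the
# inequality conditions verified; KKT points of the concave dual are
# global optima.  Returns alpha, bias and the dual objective.
qpOracle <- function(X, y, C = 1, kernel = "linear", gamma = 0) {
  m <- length(y)
  K <- if (kernel == "linear") X %*% t(X)
       else exp(-gamma * as.matrix(dist(X))^2)
  Q <- K * outer(y, y)
  tol <- 1e-7
  bestObj <- -Inf; best <- NULL
  grid <- as.matrix(expand.grid(rep(list(0:2), m)))
  for (s in seq_len(nrow(grid))) {
    st <- grid[s, ]
    fr <- which(st == 1L); bd <- which(st == 2L); ze <- which(st == 0L)
    alpha <- numeric(m); alpha[bd] <- C
    if (length(fr)) {
      A <- rbind(cbind(Q[fr, fr, drop = FALSE], y[fr]), c(y[fr], 0))
      rhs <- c(1 - if (length(bd))
                 as.numeric(Q[fr, bd, drop = FALSE] %*% alpha[bd])
               else rep(0, length(fr)),
               -sum(alpha[bd] * y[bd]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      alpha[fr] <- sol[seq_along(fr)]
      b <- sol[length(sol)]
      if (any(alpha < -tol) || any(alpha > C + tol)) next
      alpha <- pmin(pmax(alpha, 0), C)
      f <- as.numeric(K %*% (alpha * y)) + b
      if (length(ze) && any(y[ze] * f[ze] < 1 - 1e-6)) next
      if (length(bd) && any(y[bd] * f[bd] > 1 + 1e-6)) next
    } else {
      if (abs(sum(alpha * y)) > tol) next
      f0 <- as.numeric(K %*% (alpha * y))
      lo <- -Inf; hi <- Inf
      for (i in seq_len(m)) {
        if (st[i] == 0L) {
          if (y[i] > 0) lo <- max(lo, 1 - f0[i]) else hi <- min(hi, -1 - f0[i])
        } else {
          if (y[i] > 0) hi <- min(hi, 1 - f0[i]) else lo <- max(lo, -1 - f0[i])
        }
      }
      if (lo > hi + 1e-6) next
      b <- mean(c(max(lo, -1e3), min(hi, 1e3)))
    }
    obj <- sum(alpha) - 0.5 * sum((alpha * y) * as.numeric(K %*% (alpha * y)))
    if (obj > bestObj) { bestObj <- obj; best <- list(alpha = alpha, b = b) }
  }
  c(best, list(objective = bestObj))
}

# Plain-loop reliefF (all instances, two classes) for cross-checking
# relieffWeights on tiny fixtures.
relieffOracle <- function(x, y, k) {
  m <- nrow(x); p <- ncol(x)
  rng <- apply(x, 2, function(c) max(c) - min(c))
  rng[rng == 0] <- 1
  xs <- scale(x, center = apply(x, 2, min), scale = rng)
  xs[, apply(x, 2, function(c) max(c) == min(c))] <- 0
  w <- numeric(p)
  for (i in seq_len(m)) {
    d <- sqrt(colSums((t(xs) - xs[i, ])^2))
    for (cls in c(-1, 1)) {
      pool <- setdiff(which(y == cls), i)
      kk <- min(k, length(pool))
      if (kk < 1) next
      nb <- pool[order(d[pool], pool)][1:kk]
      for (j in seq_len(p)) {
        dj <- sum(abs(x[nb, j] - x[i, j]) / rng[j]) / (m * kk)
        if (max(x[, j]) == min(x[, j])) dj <- 0
        w[j] <- if (cls == y[i]) w[j] - dj else w[j] + dj
      }
    }
  }
  w
}
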