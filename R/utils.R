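# internal helpers shared across modules

# Evaluate `code` under set.seed(seed) without disturbing the caller's RNG
# stream. All user-facing randomness in the package funnels through here.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Shannon entropy (bits) of a vector of counts; 0 log 0 := 0.
entropyFromCounts <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

# population (1/m) standard deviation
popSd <- function(x) sqrt(mean((x - mean(x))^2))

stopIfNot01Labels <- function(y) {
  if (!all(y %in% c(-1L, 1L)))
    stop("labels must be coded -1/+1", call. = FALSE)
}
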