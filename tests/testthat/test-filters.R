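test_that("entropy, conditional entropy and information gain match hand values", {
  expect_equal(entropyBits(c(1, 1, -1, -1)), 1)
  expect_equal(entropyBits(rep(1, 4)), 0)
  expect_equal(entropyBits(c(rep(1, 3), rep(-1, 5))), 0.954434,
               tolerance = 1e-6)
  expect_error(entropyBits(integer()), "empty")

  expect_equal(conditionalEntropy(c(0, 0, 1, 1), c(-1, -1, 1, 1)), 0)
  expect_equal(conditionalEntropy(rep(0, 4), c(1, -1, 1, 1)),
               entropyBits(c(1, -1, 1, 1)))
  expect_equal(conditionalEntropy(c(0, 0, 1, 1), c(1, -1, 1, -1)), 1)
  expect_error(conditionalEntropy(c(0, 1), c(1, 1, -1)), "length")

  expect_equal(infoGain(c(0, 0, 1, 1), c(-1, -1, 1, 1)), 1)
  expect_equal(infoGain(rep(0, 4), c(-1, -1, 1, 1)), 0)
  expect_equal(infoGain(c(0, 0, 0, 1), c(-1, -1, 1, 1)), 0.311278,
               tolerance = 1e-6)
})

test_that("gain ratio normalizes by split information", {
  expect_equal(gainRatio(c(0, 0, 1, 1), c(-1, -1, 1, 1)), 1)
  expect_equal(gainRatio(rep(0, 4), c(-1, -1, 1, 1)), 0)  # constant feature
  expect_equal(gainRatio(c(0, 0, 0, 1), c(-1, -1, 1, 1)),
               0.311278 / 0.811278, tolerance = 1e-6)
})

test_that("information gain matches the joint-distribution oracle", {
  set.seed(11)
  for (rep in 1:80) {
    m <- sample(2:10, 1)
    codes <- sample(0:3, m, replace = TRUE)
    labels <- sample(c(-1L, 1L), m, replace = TRUE)
    expect_equal(infoGain(codes, labels), igJointOracle(codes, labels),
                 tolerance = 1e-12)
    # bounds: 0 <= IG <= min(H(Y), split info)
    expect_gte(infoGain(codes, labels), 0)
    expect_lte(infoGain(codes, labels),
               min(entropyBits(labels), entropyBits(codes)) + 1e-12)
    gr <- gainRatio(codes, labels)
    expect_gte(gr, 0); expect_lte(gr, 1 + 1e-12)
    # symmetry under class and code relabeling
    expect_equal(infoGain(codes, -labels), infoGain(codes, labels))
    expect_equal(infoGain(max(codes) - codes, labels),
                 infoGain(codes, labels))
  }
})

test_that("point-biserial correlation scores match the direct formula", {
  expect_equal(pearsonScore(c(-1, -1, 1, 1), c(-1, -1, 1, 1)), 1)
  expect_equal(pearsonScore(c(1, 1, -1, -1), c(-1, -1, 1, 1)), 1)
  expect_equal(pearsonScore(c(1, 2, 3, 4), c(-1, -1, 1, 1)), 0.894427,
               tolerance = 1e-6)
  expect_equal(pearsonScore(rep(2, 5), c(-1, -1, 1, 1, 1)), 0)
})

test_that("reliefF separates signal from noise and matches the loop oracle", {
  out <- plantedDataset(m = 20, nNoise = 1, nSignal = 1, effect = 4,
                        seed = 12)
  ds <- out$dataset
  w <- relieffWeights(ds, k = 3)
  expect_gt(w[out$informative], w[setdiff(names(w), out$informative)])
  expect_true(all(w >= -1 & w <= 1))

  # plain-loop oracle on the same fixture
  wo <- relieffOracle(t(exprMatrix(ds)), unname(classLabels(ds)), k = 3)
  expect_equal(unname(w), wo, tolerance = 1e-10)

  # constant gene gets weight exactly 0
  x <- exprMatrix(ds)
  x <- rbind(x, CONST = rep(5, ncol(x)))
  dsc <- toyDataset(x, names(classMap(ds))[
    (unname(classLabels(ds)) + 3L) / 2L], geneIds = rownames(x))
  expect_identical(unname(relieffWeights(dsc, k = 3)["CONST"]), 0)

  # deterministic for a fixed seed, with and without sampling
  expect_identical(relieffWeights(ds, k = 3), relieffWeights(ds, k = 3))
  expect_identical(relieffWeights(ds, k = 3, mIter = 10, seed = 4),
                   relieffWeights(ds, k = 3, mIter = 10, seed = 4))
})

test_that("a perfectly separating gene ranks first under all four filters", {
  set.seed(30)
  m <- 24
  y <- rep(c(-1L, 1L), each = m / 2)
  x <- matrix(rnorm(10 * m, sd = 1), nrow = 10)
  x[4, ] <- y * 2 + rnorm(m, sd = 0.05)   # near-perfect separator
  ds <- toyDataset(x, ifelse(y == 1, "pos", "neg"))
  for (mth in c("ig", "gain_ratio", "relieff", "correlation")) {
    rk <- rankFeatures(ds, mth, k = 5)
    expect_equal(rankingTable(rk)$gene_id[1], "G4", info = mth)
    expect_valid(rk)
  }
})

test_that("ties keep canonical gene order and rankings ignore sample order", {
  set.seed(31)
  x <- matrix(rnorm(5 * 12), nrow = 5)
  x[3, ] <- x[2, ]                        # identical pair G2, G3
  y <- rep(c(-1L, 1L), 6)
  ds <- toyDataset(x, ifelse(y == 1, "pos", "neg"))
  tab <- rankingTable(rankFeatures(ds, "correlation"))
  pos <- match(c("G2", "G3"), tab$gene_id)
  expect_equal(pos[2], pos[1] + 1L)       # adjacent, canonical order

  perm <- sample(12)
  for (mth in c("ig", "gain_ratio", "correlation")) {
    s1 <- rankingTable(rankFeatures(ds, mth))
    s2 <- rankingTable(rankFeatures(ds[, perm], mth))
    expect_equal(s2, s1, info = mth)
  }
})

test_that("adding a pure-noise gene leaves existing filter scores unchanged", {
  out <- plantedDataset(m = 16, nNoise = 6, seed = 8)
  ds <- out$dataset
  x2 <- rbind(exprMatrix(ds), NEW = rnorm(16, sd = 3))
  ds2 <- toyDataset(x2, names(classMap(ds))[
    (unname(classLabels(ds)) + 3L) / 2L], geneIds = rownames(x2))
  for (mth in c("ig", "gain_ratio", "correlation")) {
    s1 <- rankingTable(rankFeatures(ds, mth))
    s2 <- rankingTable(rankFeatures(ds2, mth))
    keep <- s2$gene_id != "NEW"
    expect_equal(stats::setNames(s2$score[keep], s2$gene_id[keep]),
                 stats::setNames(s1$score, s1$gene_id), info = mth)
  }
})

test_that("selectTop returns the leading gene ids and validates bounds", {
  out <- plantedDataset(m = 14, nNoise = 9, seed = 21)
  rk <- rankFeatures(out$dataset, "correlation")
  expect_equal(selectTop(rk, nGenes(out$dataset)),
               rankingTable(rk)$gene_id)
  expect_equal(selectTop(rk, 1), rankingTable(rk)$gene_id[1])
  expect_error(selectTop(rk, 0), "nKeep")
  expect_error(selectTop(rk, 11), "nKeep")
})
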