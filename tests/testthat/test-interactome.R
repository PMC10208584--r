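test_that("Bonferroni rho threshold matches grid-search inversion", {
  # independent oracle: brute-force inversion of the p-value formula on a
  # rho grid with step 1e-5 (frozen value 0.70632 for n=20, 100 tests)
  thr <- bonferroniRhoThreshold(20, 100, 0.05)
  expect_equal(thr, 0.70632, tolerance = 1e-5)
  # no correction, alpha -> 1: no evidence needed
  expect_lt(bonferroniRhoThreshold(231, 1, 0.999999), 1e-2)
})

test_that("rho threshold is monotone in test count and participants", {
  t1 <- bonferroniRhoThreshold(100, 10)
  t2 <- bonferroniRhoThreshold(100, 1000)
  t3 <- bonferroniRhoThreshold(400, 10)
  expect_gt(t2, t1)   # more tests, stricter
  expect_lt(t3, t1)   # more participants, easier
})

test_that("all-pairs Spearman agrees with a brute-force oracle", {
  # oracle: explicit midrank transform + product-moment formula per pair
  m <- randomOmics(n = 12, f = 8, seed = 101)
  vals <- featureMatrix(m)
  vals[, 3] <- round(vals[, 3]) # inject ties
  m <- OmicsMatrix(vals, "proteome")
  cs <- spearmanAllPairs(m)
  p <- correlationPairs(cs)
  expect_equal(nrow(p), 28)
  for (k in seq_len(nrow(p))) {
    x <- vals[, p$feature_a[k]]; y <- vals[, p$feature_b[k]]
    rx <- rank(x); ry <- rank(y)
    rho_o <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_equal(p$rho[k], rho_o, tolerance = 1e-12)
    t_o <- rho_o * sqrt((12 - 2) / (1 - rho_o^2))
    expect_equal(p$p_raw[k], 2 * pt(-abs(t_o), 10), tolerance = 1e-12)
    expect_equal(p$p_adj[k], min(1, p$p_raw[k] * 28), tolerance = 1e-12)
  }
})

test_that("ties are handled by midranks (hand-enumerated case)", {
  vals <- cbind(a = c(1, 2, 2, 3, 4), b = c(2, 1, 3, 3, 5),
                c = rnorm(5))
  rownames(vals) <- paste0("P", 1:5)
  cs <- spearmanAllPairs(OmicsMatrix(vals, "proteome"))
  p <- correlationPairs(cs)
  # hand computation with midranks: 0.763157894736842
  expect_equal(p$rho[p$feature_a == "a" & p$feature_b == "b"],
               0.763157894736842, tolerance = 1e-12)
})

test_that("monotone transforms leave rho at 1 and classification intact", {
  set.seed(2)
  x <- rnorm(20)
  vals <- cbind(f1 = x, f2 = exp(x), f3 = rnorm(20))
  rownames(vals) <- sprintf("P%02d", 1:20)
  cs <- spearmanAllPairs(OmicsMatrix(vals, c("proteome", "metabolome", "lipidome")))
  p <- correlationPairs(cs)
  expect_equal(p$rho[p$feature_a == "f1" & p$feature_b == "f2"], 1)
  expect_identical(p$class[p$feature_a == "f1" & p$feature_b == "f2"], "inter")
  expect_identical(p$omic_pair[p$feature_a == "f1" & p$feature_b == "f2"],
                   "proteome-metabolome")
})

test_that("significance flag coincides exactly with the rho threshold", {
  dat <- tinyDataset()
  cs <- spearmanAllPairs(dat$combined)
  p <- correlationPairs(cs)
  expect_identical(p$significant, abs(p$rho) > cs@rho_threshold)
  # and with the adjusted-p criterion away from the boundary
  expect_identical(p$significant, p$p_adj < cs@alpha)
})

test_that("constant features are flagged undefined and excluded", {
  vals <- cbind(f1 = rnorm(10), f2 = rep(1, 10), f3 = rnorm(10))
  rownames(vals) <- sprintf("P%02d", 1:10)
  expect_warning(cs <- spearmanAllPairs(OmicsMatrix(vals, "proteome")), "f2")
  p <- correlationPairs(cs)
  expect_true(all(is.na(p$rho[p$feature_a == "f2" | p$feature_b == "f2"])))
  expect_false(any(p$significant[is.na(p$rho)]))
  expect_equal(cs@n_tests, 3) # denominator still counts all pairs
})

test_that("strength bins partition pairs and are order-invariant", {
  dat <- tinyDataset()
  cs <- spearmanAllPairs(dat$combined)
  p <- correlationPairs(cs)
  expect_false(anyNA(p$bin))
  expect_identical(p$significant, p$bin != "none")
  s <- summarizeInteractome(cs)
  expect_equal(sum(s$per_pair$weak + s$per_pair$moderate + s$per_pair$strong),
               s$total_significant)
  # permuting feature order leaves counts unchanged
  vals <- featureMatrix(dat$combined)
  set.seed(4)
  perm <- sample(ncol(vals))
  cs2 <- spearmanAllPairs(OmicsMatrix(vals[, perm], omicOf(dat$combined)[perm]))
  s2 <- summarizeInteractome(cs2)
  expect_equal(s2$per_pair[order(s2$per_pair$omic_pair), ],
               s$per_pair[order(s$per_pair$omic_pair), ],
               ignore_attr = TRUE)
})

test_that("a planted cross-omic block fills only its omic pair's strong bin", {
  set.seed(8)
  base <- rnorm(40)
  vals <- cbind(
    sapply(1:4, function(i) base + rnorm(40, sd = 0.05)), # metabolome block
    sapply(1:4, function(i) base + rnorm(40, sd = 0.05)), # proteome copies
    matrix(rnorm(40 * 4), 40)                             # lipidome noise
  )
  colnames(vals) <- c(sprintf("met_%04d", 1:4), sprintf("prot_%03d", 1:4),
                      sprintf("lip_%03d", 1:4))
  rownames(vals) <- sprintf("P%02d", 1:40)
  cs <- spearmanAllPairs(OmicsMatrix(vals, rep(c("metabolome", "proteome",
                                                 "lipidome"), each = 4)))
  s <- summarizeInteractome(cs)$per_pair
  strong_inter <- s[s$class == "inter" & s$strong > 0, "omic_pair"]
  expect_identical(strong_inter, "proteome-metabolome")
  expect_equal(s$strong[s$omic_pair == "proteome-metabolome"], 16)
})

test_that("normalized link weights use per-omic-pair possible counts", {
  dat <- tinyDataset()
  cs <- spearmanAllPairs(dat$combined)
  s <- summarizeInteractome(cs)$per_pair
  sizes <- cs@omic_sizes
  expect_equal(s$possible[s$omic_pair == "proteome-proteome"],
               choose(sizes[["proteome"]], 2))
  expect_equal(s$possible[s$omic_pair == "proteome-metabolome"],
               sizes[["proteome"]] * sizes[["metabolome"]])
  expect_equal(s$normalized_weight, s$significant / s$possible)
})

test_that("bootstrap null destroys coupling and is seed-reproducible", {
  dat <- tinyDataset()
  real <- summarizeInteractome(spearmanAllPairs(dat$combined))$significant_fraction
  null1 <- bootstrapNull(dat$combined, n_sets = 3, seed = 77)
  null2 <- bootstrapNull(dat$combined, n_sets = 3, seed = 77)
  expect_identical(null1, null2)
  expect_length(bootstrapNull(dat$combined, n_sets = 0), 0)
  expect_gt(real, 10 * max(null1))
})

test_that("modularity counts components to 90% variance like an eigen oracle", {
  # identical features collapse to one component
  same <- matrix(rep(rnorm(10), 5), nrow = 10,
                 dimnames = list(sprintf("P%02d", 1:10), sprintf("prot_%03d", 1:5)))
  expect_equal(suppressWarnings(modularityPC90(OmicsMatrix(same + 0, "proteome"))), 1)

  # independent oracle: eigendecomposition of the correlation matrix
  set.seed(31)
  vals <- matrix(rnorm(20 * 10), nrow = 20,
                 dimnames = list(sprintf("P%02d", 1:20), sprintf("prot_%03d", 1:10)))
  ev <- eigen(cor(vals), symmetric = TRUE, only.values = TRUE)$values
  k_oracle <- which(cumsum(ev) / sum(ev) >= 0.9)[1]
  expect_equal(modularityPC90(OmicsMatrix(vals, "proteome")), k_oracle)

  # two equal orthogonal perfect blocks need exactly 2 components
  u <- rnorm(30); v <- rnorm(30)
  blocks <- cbind(u, u, u, v, v, v)
  dimnames(blocks) <- list(sprintf("P%02d", 1:30), sprintf("lip_%03d", 1:6))
  expect_equal(modularityPC90(OmicsMatrix(blocks, "lipidome")), 2)
})

test_that("correlation-space embedding separates planted blocks", {
  set.seed(12)
  u <- rnorm(30); v <- rnorm(30)
  vals <- cbind(sapply(1:5, function(i) u + rnorm(30, sd = 0.1)),
                sapply(1:5, function(i) v + rnorm(30, sd = 0.1)))
  colnames(vals) <- sprintf("prot_%03d", 1:10)
  rownames(vals) <- sprintf("P%02d", 1:30)
  cs <- spearmanAllPairs(OmicsMatrix(vals, "proteome"))
  xy <- embedCorrelationSpace(cs)
  expect_identical(xy, embedCorrelationSpace(cs)) # deterministic
  d <- as.matrix(dist(xy))
  block <- rep(1:2, each = 5)
  within <- mean(d[outer(block, block, "==") & upper.tri(d)])
  between <- mean(d[outer(block, block, "!=") & upper.tri(d)])
  expect_lt(within, between)
})

test_that("pair counting follows the handshake formula", {
  expect_equal(pairCount(5), 10)
  expect_equal(pairCount(2), 1)
})
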