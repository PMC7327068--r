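test_that("CPM columns sum to one million and are scale-invariant", {
  m <- matrix(c(50, 50, 10, 30), 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cpm <- normalizeCPM(m)
  expect_equal(colSums(cpm), c(s1 = 1e6, s2 = 1e6))
  expect_equal(cpm[, "s1"], c(a = 5e5, b = 5e5))
  # single feature: always 10^6
  one <- matrix(c(7, 3000), 1, dimnames = list("a", c("s1", "s2")))
  expect_equal(as.numeric(normalizeCPM(one)), c(1e6, 1e6))
  # doubling a sample's counts leaves its CPM unchanged
  m2 <- m; m2[, 1] <- m2[, 1] * 2
  expect_equal(normalizeCPM(m2), cpm)
  m3 <- m; m3[, 2] <- 0
  expect_error(normalizeCPM(m3), class = "cernaTriad_zero_library")
})

test_that("identical groups yield fold change 1 and no calls", {
  base <- matrix(rpois(40, 100), 10, 4,
                 dimnames = list(sprintf("f%02d", 1:10), NULL))
  dup <- cbind(base, base)
  colnames(dup) <- paste0("s", 1:8)
  le <- makeLayer(dup, rep(c("NC", "OC"), each = 4))
  tab <- callDegs(le, "NC", "OC")
  expect_equal(tab$fold_change, rep(1, 10))
  expect_true(all(tab$call == "ns"))
})

test_that("the fold-change gate is strict and overrides significance", {
  # two-feature design with equal library sizes so CPM equals count scale
  f1a <- c(100000, 100000, 100000); f1b <- c(120000, 120000, 120000)
  m <- rbind(f1 = c(f1a, f1b),
             f2 = c(1e6 - f1a, 1e6 - f1b))
  le <- makeLayer(m, rep(c("NC", "OC"), each = 3))
  tab <- callDegs(le, "NC", "OC")
  r1 <- tab[tab$feature == "f1", ]
  expect_lt(r1$p, 0.001)               # zero within-group variance
  expect_equal(r1$fold_change, (120000 + 1) / (100000 + 1))
  expect_equal(r1$call, "ns")          # FC 1.2 fails the 1.5 bound
  # fold change exactly 1.5 (pseudocount-exact) is ns under strict >
  m2 <- rbind(f1 = c(999, 999, 999, 1499, 1499, 1499),
              f2 = c(1e6 - 999, 1e6 - 999, 1e6 - 999,
                     1e6 - 1499, 1e6 - 1499, 1e6 - 1499))
  le2 <- makeLayer(m2, rep(c("NC", "OC"), each = 3))
  tab2 <- callDegs(le2, "NC", "OC")
  expect_equal(tab2$fold_change[tab2$feature == "f1"], 1.5)
  expect_equal(tab2$call[tab2$feature == "f1"], "ns")
})

test_that("fold changes are reciprocal under contrast reversal", {
  sim <- simulateDataset(tinyConfig(seed = 12))
  ab <- callDegs(sim@mrna, "NC", "OC")
  ba <- callDegs(sim@mrna, "OC", "NC")
  expect_equal(ab$fold_change, 1 / ba$fold_change, tolerance = 1e-12)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
})

test_that("p-values are invariant to feature and sample order", {
  sim <- simulateDataset(tinyConfig(seed = 13))
  tab <- callDegs(sim@mrna, "NC", "OC")
  perm <- sample(nrow(sim@mrna))
  tabP <- callDegs(sim@mrna[perm, ], "NC", "OC")
  expect_equal(tabP$p[match(tab$feature, tabP$feature)], tab$p)
  scramble <- sample(ncol(sim@mrna))
  tabS <- callDegs(sim@mrna[, scramble], "NC", "OC")
  expect_equal(tabS$p, tab$p)
})

test_that("row-wise Welch matches stats::t.test", {
  sim <- simulateDataset(tinyConfig(seed = 14))
  tab <- callDegs(sim@mrna, "NC", "OC")
  lcpm <- normalizeCPM(sim@mrna, log = TRUE)
  g <- sampleGroups(sim@mrna)
  for (f in sample(tab$feature, 8)) {
    ref <- t.test(lcpm[f, g == "OC"], lcpm[f, g == "NC"])$p.value
    expect_equal(tab$p[tab$feature == f], ref, tolerance = 1e-12)
  }
})

test_that("DEG count tables are symmetric and need all groups", {
  sim <- simulateDataset(tinyConfig(seed = 15))
  d <- degCounts(sim@mrna)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0L))
  sub <- sim@mrna[, sampleGroups(sim@mrna) != "LOS"]
  expect_error(degCounts(sub), class = "cernaTriad_missing_group")
})

test_that("Ward clustering merges duplicates first and is deterministic", {
  m <- matrix(c(10, 20, 30, 10, 20, 30, 200, 40, 80), 3,
              dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  hc <- wardCluster(m)
  expect_equal(hc$height[1], 0)   # duplicate samples merge at height 0
  two <- m[, 1:2]
  hc2 <- wardCluster(two)
  lcpm <- normalizeCPM(two, log = TRUE)
  expect_equal(hc2$height, as.numeric(dist(t(lcpm))))
  expect_error(wardCluster(m[, 1, drop = FALSE]),
               class = "cernaTriad_too_few_values")
})

test_that("Ward clustering recovers the five arms on simulated data", {
  aris <- vapply(1:20, function(s) {
    sim <- simulateDataset(SimConfig(seed = s))
    le <- expressionLayer(sim, "mRNA")
    k5 <- cutree(wardCluster(le), 5)
    adjustedRand(k5, sampleGroups(le)[names(k5)])
  }, 0)
  expect_true(all(aris >= 0.8))
})

test_that("PC1 correlates exactly with scores proportional to itself", {
  sim <- simulateDataset(tinyConfig(seed = 16))
  le <- sim@mrna
  base <- pc1Pathology(le, setNames(seq_len(ncol(le)), colnames(le)))
  self <- pc1Pathology(le, base$pc1)
  expect_equal(self$r, 1)
  neg <- pc1Pathology(le, -base$pc1)
  expect_equal(neg$r, -1)
  expect_gt(mean(base$pc1[sampleGroups(le) == "OC"]), 0)  # sign convention
  expect_error(pc1Pathology(le, setNames(rep(1, ncol(le)), colnames(le))),
               class = "cernaTriad_constant_scores")
})
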