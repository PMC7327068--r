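# direct two-pass covariance oracle, independent of stats::cor
pearsonOracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxy / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

test_that("perfectly collinear profiles give r of +1 and -1, and t-p of 0/1", {
  m <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(6, 4, 2))
  cr <- correlate(m)
  expect_equal(corValues(cr)["a", "b"], 1)
  expect_equal(corValues(cr)["a", "c"], -1)
  expect_equal(corPvalues(cr)["a", "b"], 0)
  # exactly orthogonal profiles: r = 0, p = 1
  o <- rbind(x = c(1, 1, -1, -1), y = c(1, -1, 1, -1))
  cro <- correlate(o)
  expect_equal(corValues(cro)["x", "y"], 0)
  expect_equal(corPvalues(cro)["x", "y"], 1)
})

test_that("correlations agree with a direct covariance oracle", {
  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(rnorm(100), 10, 10,
                dimnames = list(paste0("f", 1:10), paste0("s", 1:10)))
    cr <- correlate(m)
    for (i in 1:9) for (j in (i + 1):10)
      expect_equal(corValues(cr)[i, j], pearsonOracle(m[i, ], m[j, ]),
                   tolerance = 1e-12)
    expect_equal(corValues(cr), t(corValues(cr)))
    expect_true(all(corAdjPvalues(cr) >= corPvalues(cr) - 1e-15))
  }
})

test_that("constant features are excluded with a warning, few samples error", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(5, 5, 5, 5), c = c(2, 1, 4, 3))
  colnames(m) <- paste0("s", 1:4)
  expect_warning(cr <- correlate(m), "constant")
  expect_equal(rownames(corValues(cr)), c("a", "c"))
  expect_error(correlate(m[, 1:2]), class = "cernaTriad_too_few_samples")
  expect_error(suppressWarnings(correlate(m[2, , drop = FALSE])),
               class = "cernaTriad_all_constant")
})

test_that("the 0.8 coexpression rule is inclusive at the boundary", {
  r <- matrix(c(1, 0.8, 0.79, 0.8, 1, -0.85, 0.79, -0.85, 1), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  p <- matrix(1e-3, 3, 3, dimnames = dimnames(r)); diag(p) <- 0
  cr <- new("CorrelationResult", r = r, p = p, padj = p,
            nSamples = 15L, symmetric = TRUE)
  edges <- coexpressionEdges(cr, threshold = 0.8)
  key <- paste(edges$source, edges$target)
  expect_true("a b" %in% key)        # r = 0.8 exactly: kept
  expect_true("b c" %in% key)        # |r| = 0.85: kept, sign retained
  expect_false("a c" %in% key)       # r = 0.79: below threshold
  expect_equal(edges$sign[key == "b c"], -1)
  expect_equal(edges$adjacency, abs(edges$r))   # beta = 1
  e2 <- coexpressionEdges(cr, threshold = 0.8, beta = 2)
  expect_equal(e2$adjacency, abs(e2$r)^2)
  expect_error(coexpressionEdges(cr, threshold = 1.01),
               class = "cernaTriad_invalid_threshold")
})

test_that("null coexpression edge counts follow the t-tail mass", {
  # independent features: expected |r| >= 0.8 edges per simulation equal
  # the two-sided t-tail times the number of pairs
  edges <- vapply(1:50, function(s) {
    sim <- simulateDataset(nullConfig(seed = s, nMrna = 50))
    nrow(coexpressionEdges(correlate(expressionLayer(sim, "mRNA")), 0.8))
  }, 0)
  n <- 15
  tail2 <- 2 * pt(0.8 * sqrt((n - 2) / (1 - 0.64)), n - 2,
                  lower.tail = FALSE)
  expected <- 50 * choose(50, 2) * tail2
  expect_lt(abs(sum(edges) - expected), 4 * sqrt(expected))
})

test_that("miRNA edges require both the map and the -0.8 correlation", {
  sim <- simulateDataset(tinyConfig(seed = 21))
  edges <- mirnaTargetEdges(sim@mirna, sim@mrna, sim@targetMap)
  # oracle: brute-force filter on the log2-CPM correlations
  lm <- normalizeCPM(sim@mirna, log = TRUE)
  lg <- normalizeCPM(sim@mrna, log = TRUE)
  pairs <- targetPairs(sim@targetMap)
  rAll <- mapply(function(a, b) cor(lm[a, ], lg[b, ]),
                 pairs$mirna_id, pairs$target_id)
  keep <- pairs[rAll <= -0.8, c("mirna_id", "target_id")]
  expect_setequal(paste(edges$mirna_id, edges$target_id),
                  paste(keep$mirna_id, keep$target_id))
  # planted pairs are all kept; a strongly negative pair NOT in the map
  # contributes no edge
  tp <- groundTruth(sim)@mirnaPairs
  expect_true(all(paste(tp$mirna_id, tp$target_id) %in%
                  paste(edges$mirna_id, edges$target_id)))
  inMap <- paste(pairs$mirna_id, pairs$target_id)
  expect_false(any(!paste(edges$mirna_id, edges$target_id) %in% inMap))
  # empty overlap warns and returns an empty frame
  offMap <- TargetMap(data.frame(mirna_id = "nope", target_id = "nada",
                                 target_layer = "mRNA"))
  expect_warning(none <- mirnaTargetEdges(sim@mirna, sim@mrna, offMap),
                 "no target-map pair")
  expect_equal(nrow(none), 0L)
})

test_that("sponge triads are recovered and respect the sign pattern", {
  sim <- simulateDataset(tinyConfig(seed = 22))
  net <- buildCerna(sim@lncrna, sim@mirna, sim@mrna, sim@targetMap)
  tr <- networkTriads(net)
  gt <- groundTruth(sim)@spongeTriads
  expect_true(all(paste(gt$lncrna_id, gt$mirna_id, gt$mrna_id) %in%
                  paste(tr$lncrna, tr$mirna, tr$mrna)))
  expect_true(all(tr$r_lm <= -0.8))
  expect_true(all(tr$r_mg <= -0.8))
  expect_true(all(tr$r_lg >= 0.8))
  expect_true(all(networkEdges(net)$weight >= 0))
  # empty target map: no triads whatever the correlations
  emptyMap <- TargetMap(data.frame(mirna_id = character(),
                                   target_id = character(),
                                   target_layer = character()))
  net0 <- suppressWarnings(
    buildCerna(sim@lncrna, sim@mirna, sim@mrna, emptyMap))
  expect_equal(nrow(networkTriads(net0)), 0L)
  # mismatched samples are rejected
  expect_error(buildCerna(sim@lncrna[, 1:10], sim@mirna, sim@mrna,
                          sim@targetMap),
               class = "cernaTriad_sample_mismatch")
})

test_that("triad counts are monotone nonincreasing in the threshold", {
  sim <- simulateDataset(tinyConfig(seed = 23))
  counts <- vapply(c(0.5, 0.7, 0.8, 0.9, 0.99), function(th)
    nrow(networkTriads(buildCerna(sim@lncrna, sim@mirna, sim@mrna,
                                  sim@targetMap, threshold = th))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("uncoupled simulations yield essentially no triads", {
  nTriads <- vapply(1:20, function(s) {
    sim <- simulateDataset(nullConfig(seed = s, nMrna = 50))
    nrow(networkTriads(buildCerna(sim@lncrna, sim@mirna, sim@mrna,
                                  sim@targetMap)))
  }, 0L)
  expect_gte(mean(nTriads == 0L), 0.95)
})

test_that("edge sets are invariant to feature and sample reordering", {
  sim <- simulateDataset(tinyConfig(seed = 24))
  net <- buildCerna(sim@lncrna, sim@mirna, sim@mrna, sim@targetMap)
  perm <- sample(ncol(sim@mrna))
  fperm <- sample(nrow(sim@mrna))
  net2 <- buildCerna(sim@lncrna[, perm], sim@mirna[, perm],
                     sim@mrna[fperm, perm], sim@targetMap)
  canon <- function(n) {
    e <- networkEdges(n)
    e <- e[order(e$source, e$target), ]
    rownames(e) <- NULL
    e
  }
  expect_equal(canon(net), canon(net2), tolerance = 1e-12)
})

test_that("BH adjustment matches a brute-force step-up oracle", {
  bhOracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(adj, 1)[order(o)]
  }
  set.seed(9)
  for (rep in 1:5) {
    p <- runif(100)^2
    expect_equal(p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-12)
  }
  # and the package's correlation BH uses the same machinery
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  cr <- correlate(m)
  up <- upper.tri(corPvalues(cr))
  expect_equal(corAdjPvalues(cr)[up], bhOracle(corPvalues(cr)[up]),
               tolerance = 1e-12)
})

test_that("the adjusted-p filter prunes edges, triads and orphan nodes", {
  sim <- simulateDataset(tinyConfig(seed = 25))
  net <- buildCerna(sim@lncrna, sim@mirna, sim@mrna, sim@targetMap)
  f <- filterByAdjustedP(net, alpha = 0.05)
  expect_true(all(networkEdges(f)$p_adj < 0.05))
  expect_lte(nrow(networkEdges(f)), nrow(networkEdges(net)))
  ids <- c(networkEdges(f)$source, networkEdges(f)$target)
  expect_setequal(networkNodes(f)$id, unique(ids))
  strict <- filterByAdjustedP(net, alpha = 1e-30)
  expect_equal(nrow(networkEdges(strict)), 0L)
  expect_equal(nrow(networkTriads(strict)), 0L)
})
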