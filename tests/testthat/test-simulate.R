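test_that("identical config and seed give byte-identical output", {
  a <- simulateDataset(tinyConfig(seed = 42))
  b <- simulateDataset(tinyConfig(seed = 42))
  expect_identical(counts(a@mrna), counts(b@mrna))
  expect_identical(counts(a@mirna), counts(b@mirna))
  expect_identical(counts(a@lncrna), counts(b@lncrna))
  expect_identical(targetPairs(a@targetMap), targetPairs(b@targetMap))
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  f1 <- writeDataset(a, d1); f2 <- writeDataset(b, d2)
  for (nm in names(f1))
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]),
                     info = nm)
  c3 <- simulateDataset(tinyConfig(seed = 43))
  expect_false(identical(counts(a@mrna), counts(c3@mrna)))
})

test_that("manifest ids exist in the matrices and true pairs are mapped", {
  sim <- simulateDataset(tinyConfig(seed = 3))
  tr <- groundTruth(sim)
  expect_true(all(tr@deFeatures$feature_id %in% rownames(sim@mrna)))
  expect_true(all(tr@spongeTriads$lncrna_id %in% rownames(sim@lncrna)))
  mk <- paste(targetPairs(sim@targetMap)$mirna_id,
              targetPairs(sim@targetMap)$target_id)
  expect_true(all(paste(tr@mirnaPairs$mirna_id,
                        tr@mirnaPairs$target_id) %in% mk))
  # decoys are present and disjoint from planted structure
  expect_gt(length(sim@targetMap), nrow(tr@mirnaPairs))
})

test_that("configs with planted sets exceeding feature counts are rejected", {
  expect_error(SimConfig(nMrna = 10, nDeMrna = 20), "exceed")
  expect_error(SimConfig(nMirna = 3, nTrueMirnaPairs = 5,
                         nSpongeTriads = 0), "exceed")
  expect_error(SimConfig(repressionCoupling = 1.5), "repressionCoupling")
  expect_error(SimConfig(doseProfile = c(NC = 0.1, OC = 1, LK = 0.7,
                                         HK = 0.2, LOS = 0.4)), "NC")
})

test_that("null features match negative-binomial moments", {
  cfg <- nullConfig(seed = 9, nMrna = 400)
  sim <- simulateDataset(cfg)
  m <- counts(sim@mrna)
  mu <- groundTruth(sim)@groupMeans$mRNA[, "NC"]  # flat across groups
  disp <- 0.05
  meanRatio <- rowMeans(m) / mu
  varRatio <- apply(m, 1, var) / (mu + disp * mu^2)
  # each ratio has mean 1; averaging over 400 features shrinks the MC error
  expect_lt(abs(mean(meanRatio) - 1), 0.05)
  expect_lt(abs(mean(varRatio) - 1), 0.15)
})

test_that("planted pairs at coupling 0.95 concentrate below r = -0.8", {
  hits <- unlist(lapply(1:20, function(s) {
    sim <- simulateDataset(tinyConfig(seed = s,
                                      repressionCoupling = 0.95))
    tp <- groundTruth(sim)@mirnaPairs
    lm <- normalizeCPM(sim@mirna, log = TRUE)
    lg <- normalizeCPM(sim@mrna, log = TRUE)
    mapply(function(a, b) cor(lm[a, ], lg[b, ]) <= -0.8,
           tp$mirna_id, tp$target_id)
  }))
  expect_gte(mean(hits), 0.9)
})

test_that("histology respects point-mass and mixed grade profiles", {
  probs <- matrix(0, 5, 5, dimnames = list(TREATMENT_GROUPS,
                                           paste0("grade", 0:4)))
  probs["NC", 1] <- 1           # all grade 0
  probs["OC", 5] <- 1           # all grade 4
  probs[c("LK", "HK", "LOS"), 2:5] <- 1 / 4  # quarter on grades 1..4
  cfg <- tinyConfig(seed = 5, glomProbs = probs, nPerGroup = 60)
  h <- simulateHistology(cfg)
  gcols <- grep("^g\\d+$", colnames(h$glomeruli))
  gsis <- apply(h$glomeruli[, gcols], 1, function(g) gsi(as.integer(g)))
  expect_true(all(gsis[h$glomeruli$group == "NC"] == 0))
  expect_true(all(gsis[h$glomeruli$group == "OC"] == 4))
  # E[GSI] for the quarter profile is 2.5; 60 animals x 40 glomeruli
  expect_lt(abs(mean(gsis[h$glomeruli$group == "LK"]) - 2.5), 0.1)
  expect_equal(ncol(h$glomeruli[, gcols]), 40L)
  expect_error(SimConfig(glomProbs = probs * 2), "summing to 1")
})

test_that("PC1 group-centroid distances follow the planted dose ordering", {
  ok <- vapply(1:10, function(s) {
    sim <- simulateDataset(SimConfig(seed = s))
    le <- expressionLayer(sim, "mRNA")
    lcpm <- normalizeCPM(le, log = TRUE)
    pc1 <- stats::prcomp(t(lcpm), center = TRUE)$x[, 1]
    cent <- tapply(pc1, sampleGroups(le), mean)
    d <- abs(cent - cent["NC"])
    d["HK"] < d["LK"] && d["LK"] < d["OC"]
  }, NA)
  expect_gte(mean(ok), 0.9)
})
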