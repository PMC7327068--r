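test_that("GSI evaluates the weighted-grade formula", {
  for (g in 0:4) expect_equal(gsi(rep(g, 40)), g)
  expect_equal(gsi(counts = c(0, 10, 10, 10, 10)), 2.5)
  expect_equal(gsi(c(rep(1, 10), rep(2, 10), rep(3, 10), rep(4, 10))), 2.5)
  expect_error(gsi(rep(0, 39)), class = "cernaTriad_invalid_grades")
  expect_error(gsi(c(rep(0, 39), 5)), class = "cernaTriad_invalid_grades")
  expect_error(gsi(counts = c(0, 10, 10, 10, 11)),
               class = "cernaTriad_invalid_grades")
})

test_that("GSI is permutation-invariant and monotone in any grade", {
  set.seed(101)
  for (i in 1:20) {
    g <- sample(0:4, 40, replace = TRUE)
    expect_equal(gsi(sample(g)), gsi(g))
    j <- sample.int(40, 1)
    if (g[j] < 4) {
      g2 <- g; g2[j] <- g2[j] + 1L
      expect_gt(gsi(g2), gsi(g))
    }
  }
})

test_that("TII reproduces the printed grade bins", {
  expect_equal(tii(0), 0L)      # no morphological deformity
  expect_equal(tii(5), 1L)      # < 10
  expect_equal(tii(15), 2L)     # < 25
  expect_equal(tii(30), 3L)     # < 50
  expect_equal(tii(60), 4L)     # < 75
  expect_equal(tii(80), 5L)     # 75 and higher
  # bin edges belong to the higher grade
  expect_equal(tii(c(10, 25, 50, 75)), c(2L, 3L, 4L, 5L))
  expect_error(tii(101), class = "cernaTriad_invalid_percent")
  expect_error(tii(-1), class = "cernaTriad_invalid_percent")
})

test_that("TII is a nondecreasing step function", {
  x <- seq(0, 100, by = 0.25)
  expect_true(all(diff(tii(x)) >= 0))
  expect_setequal(unique(tii(x)), 0:5)
})

test_that("ddct returns 1 at the calibrator mean and halves per unit", {
  ct <- rbind(
    data.frame(sample = c("a", "b", "c", "d"),
               group = c("NC", "NC", "OC", "OC"),
               gene = "T1", ct = c(24, 24, 25, 22)),
    data.frame(sample = c("a", "b", "c", "d"),
               group = c("NC", "NC", "OC", "OC"),
               gene = "Gapdh", ct = c(18, 18, 18, 18)))
  out <- ddct(ct, "Gapdh", "NC")
  # calibrator samples sit exactly at the calibrator mean dCt of 6
  expect_equal(out$rel_expr[out$sample %in% c("a", "b")], c(1, 1))
  expect_equal(out$rel_expr[out$sample == "c"], 0.5)  # ddCt = +1
  expect_equal(out$rel_expr[out$sample == "d"], 4)    # ddCt = -2
  expect_error(ddct(ct[ct$sample != "a" | ct$gene != "Gapdh", ],
                    "Gapdh", "NC"),
               class = "cernaTriad_missing_reference")
})

test_that("ddct relative expressions are path-consistent across calibrators", {
  sim <- simulateDataset(tinyConfig(seed = 8))
  viaNC <- ddct(sim@ct, "Gapdh", "NC")
  viaOC <- ddct(sim@ct, "Gapdh", "OC")
  # switching calibrator rescales every gene by one constant
  ratio <- viaNC$rel_expr / viaOC$rel_expr
  for (g in unique(viaNC$gene))
    expect_equal(diff(range(ratio[viaNC$gene == g])), 0, tolerance = 1e-12)
})

test_that("group summaries report mean, sample SD and tiered marks", {
  vals <- c(1, 2, 3,                 # NC
            1, 2, 3,                 # OC identical to NC
            101, 100.5, 99.5, 100, 99)  # HK far away
  grp <- c(rep("NC", 3), rep("OC", 3), rep("HK", 5))
  out <- groupSummary(vals, grp)
  nc <- out[out$group == "NC", ]
  expect_equal(nc$mean, 2)
  expect_equal(nc$sd, 1)           # sample (n-1) SD
  expect_equal(nc$mark_vs_OC, "")  # identical distributions: no mark
  hk <- out[out$group == "HK", ]
  expect_equal(hk$mark_vs_OC, "***")
  expect_equal(hk$mark_vs_NC, "###")
  expect_error(groupSummary(c(1, 1, 2), c("NC", "OC", "OC")),
               class = "cernaTriad_too_few_values")
})

test_that("summary p-values agree with stats::t.test (Welch)", {
  set.seed(77)
  vals <- c(rnorm(4, 0), rnorm(5, 1), rnorm(6, 3))
  grp <- c(rep("NC", 4), rep("OC", 5), rep("HK", 6))
  out <- groupSummary(vals, grp)
  expect_equal(out$p_vs_NC[out$group == "HK"],
               t.test(vals[grp == "HK"], vals[grp == "NC"])$p.value)
  expect_equal(out$p_vs_OC[out$group == "NC"],
               t.test(vals[grp == "NC"], vals[grp == "OC"])$p.value)
})
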