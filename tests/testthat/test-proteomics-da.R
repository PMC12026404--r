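test_that("detection filter keeps proteins at the inclusive 90% boundary", {
  m <- rbind(p1 = c(1:9, NA),      # 9/10 detected
             p2 = c(1:8, NA, NA),  # 8/10
             p3 = 1:10)
  kept <- detectionFilter(m, minFrac = 0.90)
  expect_equal(rownames(kept), c("p1", "p3"))
  # minFrac near zero keeps everything with at least one detection
  m2 <- rbind(m, p4 = rep(NA_real_, 10))
  expect_equal(rownames(detectionFilter(m2, minFrac = 1e-9)),
               c("p1", "p2", "p3"))
  expect_warning(detectionFilter(matrix(NA_real_, 1, 10), minFrac = 0.5),
                 "no protein")
})

test_that("detection filter honours the below-LOD flag in SummarizedExperiment input", {
  npx <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("p", 1:4), paste0("s", 1:10)))
  lod <- matrix(FALSE, 4, 10)
  lod[2, 1:3] <- TRUE   # p2 detected in only 7/10
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = npx, belowLOD = lod))
  expect_equal(rownames(detectionFilter(se, 0.9)), c("p1", "p3", "p4"))
})

test_that("Welch statistics match the textbook formulas and stats::t.test", {
  m <- rbind(pA = c(10, 11, 12, 13, 0, 1, 2, 3),
             pB = c(1, 2, 3, 1, 2, 3, NA, NA))
  groups <- rep(c("A", "B"), each = 4)
  res <- welchTest(m, groups, c("A", "B"))

  # hand-computed Welch for pA: means 11.5 / 1.5, both variances 5/3, n = 4
  expect_equal(res$estimate[1], 10)
  se2 <- (5 / 3) / 4
  expect_equal(res$t[1], 10 / sqrt(2 * se2))
  expect_equal(res$df[1], (2 * se2)^2 / (2 * se2^2 / 3))

  # and against the independent t.test implementation (incl. NA dropping)
  for (i in 1:2) {
    a <- m[i, 1:4]; b <- m[i, 5:8]
    tt <- t.test(a[!is.na(a)], b[!is.na(b)])
    expect_equal(res$estimate[i], unname(diff(rev(tt$estimate))))
    expect_equal(res$t[i], unname(tt$statistic))
    expect_equal(res$df[i], unname(tt$parameter))
    expect_equal(res$p[i], tt$p.value)
  }
})

test_that("identical groups give zero estimate and p = 1", {
  m <- rbind(p = c(1, 2, 3, 1, 2, 3))
  res <- welchTest(m, rep(c("A", "B"), each = 3), c("A", "B"))
  expect_equal(res$estimate, 0)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
})

test_that("swapping the contrast negates estimate and t and preserves p", {
  set.seed(42)
  m <- matrix(rnorm(200), 10, 20)
  groups <- rep(c("A", "B"), each = 10)
  ab <- welchTest(m, groups, c("A", "B"))
  ba <- welchTest(m, groups, c("B", "A"))
  expect_equal(ab$estimate, -ba$estimate)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
})

test_that("untestable proteins are flagged and excluded from the BH family", {
  m <- rbind(p1 = c(1, 2, 3, 4, 5, 6),
             p2 = c(1, NA, NA, 4, 5, 6),   # one A observation
             p3 = c(2, 1, 4, 3, 7, 5))
  res <- welchTest(m, rep(c("A", "B"), each = 3), c("A", "B"))
  expect_equal(res$testable, c(TRUE, FALSE, TRUE))
  expect_true(is.na(res$adj_p[2]))
  expect_equal(res$adj_p[res$testable],
               p.adjust(res$p[res$testable], "BH"))
})

test_that("BH adjustment equals the exhaustive step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.5), 0.5)
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  for (i in 1:50) {
    p <- runif(sample(1:30, 1))
    expect_equal(bhAdjust(p), bhOracle(p))
  }
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bhAdjust(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("signature derivation applies the strict FDR threshold and sign rule", {
  da <- data.frame(protein = paste0("p", 1:5),
                   estimate = c(2, -2, 1, 0.5, 3),
                   t = 1, df = 10,
                   p = c(1e-5, 1e-5, 0.2, 1e-4, 0.04),
                   adj_p = c(1e-4, 1e-4, 0.3, 5e-4, 0.06),
                   testable = TRUE)
  sig <- deriveIpss(da, fdrThreshold = 0.05, name = "UC-IPSS")
  expect_s4_class(sig, "SignatureSet")
  expect_equal(signatureFeatures(sig), c("p1", "p4"))  # p2 fails sign rule
  expect_equal(signatureMetadata(sig)$fdr_threshold, 0.05)
  expect_warning(empty <- deriveIpss(da, fdrThreshold = 0), "empty")
  expect_equal(length(empty), 0L)
  down <- deriveIpss(da, direction = "down")
  expect_equal(signatureFeatures(down), "p2")
})

test_that("overlap counts match exhaustive membership enumeration", {
  sets <- list(x = c("A", "B", "C"), y = c("B", "C", "D"), z = "C")
  ov <- setOverlapCounts(sets)
  expect_equal(ov$intersection[ov$region == "x&y&z"], 1L)
  expect_equal(ov$exclusive[ov$region == "x"], 1L)       # A only
  expect_equal(ov$intersection[ov$region == "x&y"], 2L)  # B, C

  disj <- setOverlapCounts(list(a = c("1", "2"), b = c("3", "4")))
  expect_equal(disj$intersection[disj$region == "a&b"], 0L)

  # random sets against brute-force enumeration over the universe
  set.seed(7)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i) sample(letters, sample(5:15, 1)))
    names(sets) <- c("A", "B", "C")
    ov <- setOverlapCounts(sets)
    for (r in seq_len(nrow(ov))) {
      idx <- strsplit(ov$region[r], "&")[[1]]
      manual <- Reduce(intersect, sets[idx])
      expect_equal(ov$intersection[r], length(manual))
      others <- setdiff(names(sets), idx)
      excl <- setdiff(manual, unique(unlist(sets[others])))
      expect_equal(ov$exclusive[r], length(excl))
    }
  }
})

test_that("the long-format NPX table round-trips into the matrix container", {
  sim <- simulateCohort(tinyConfig(seed = 30))
  dir <- withr::local_tempdir()
  ibdatlas:::writeSimulatedBundle(sim, dir)
  long <- readCohortBundle(dir)$npx
  se <- npxFromLong(long)
  orig <- SummarizedExperiment::assay(sim$npx, "npx")
  back <- SummarizedExperiment::assay(se, "npx")[rownames(orig), colnames(orig)]
  expect_equal(unname(back), unname(orig))
  expect_equal(
    unname(SummarizedExperiment::assay(se, "belowLOD")[rownames(orig), colnames(orig)]),
    unname(SummarizedExperiment::assay(sim$npx, "belowLOD")))
})
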