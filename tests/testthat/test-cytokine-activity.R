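test_that("differential profiles are log2(TPM+1) differences, centered", {
  tpm <- c(g1 = 3, g2 = 7, g3 = 0, g4 = 1, g5 = 15)
  ref <- c(g1 = 3, g2 = 7, g3 = 0, g4 = 1, g5 = 15)
  expect_equal(unname(prepareProfile(tpm, ref)), rep(0, 5))

  ref2 <- ref
  tpm2 <- ref
  tpm2["g2"] <- 14  # doubled
  y <- log2(tpm2 + 1) - log2(ref2 + 1)
  expect_equal(prepareProfile(tpm2, ref2), y - mean(y))

  # disjoint gene sets fail loudly
  expect_error(prepareProfile(c(a = 1), c(b = 2)), "no shared")
})

test_that("ridge solutions match closed forms", {
  # identity design, no penalty: coefficients are the data
  y <- c(0.5, -1, 2, 0.25)
  expect_equal(unname(ridgeFit(diag(4), y, alpha = 0, center = FALSE)), y)

  # orthonormal columns with penalty a: beta = S'y / (1 + a)
  Q <- qr.Q(qr(matrix(rnorm(18), 6, 3)))
  y2 <- rnorm(6)
  for (a in c(0.5, 2)) {
    expect_equal(unname(ridgeFit(Q, y2, alpha = a, center = FALSE)),
                 as.numeric(crossprod(Q, y2)) / (1 + a))
  }

  # exact linear recovery as alpha -> 0
  set.seed(8)
  S <- matrix(rnorm(250), 50, 5)
  bstar <- rnorm(5)
  yS <- as.numeric(S %*% bstar)
  expect_equal(unname(ridgeFit(S, yS, alpha = 1e-10, center = FALSE)), bstar,
               tolerance = 1e-8)

  # collinear design without penalty is rejected with advice
  Sc <- cbind(1:4, 1:4)
  expect_error(ridgeFit(Sc, rnorm(4), alpha = 0, center = FALSE), "alpha > 0")
})

test_that("ridge coefficients scale linearly in y and z-scores are scale invariant", {
  set.seed(9)
  S <- matrix(rnorm(400), 100, 4, dimnames = list(paste0("g", 1:100), NULL))
  y <- setNames(rnorm(100), rownames(S))
  b1 <- ridgeFit(S, y, alpha = 10)
  b2 <- ridgeFit(S, 3 * y, alpha = 10)
  expect_equal(b2, 3 * b1)
  r1 <- permutationZ(S, y, alpha = 10, nPerm = 200, seed = 4)
  r2 <- permutationZ(S, 3 * y, alpha = 10, nPerm = 200, seed = 4)
  expect_equal(r1$z, r2$z)   # same seed: permutations scale identically
  expect_equal(r1$p, r2$p)
})

test_that("permutation inference is deterministic and handles the null profile", {
  set.seed(10)
  S <- matrix(rnorm(300), 100, 3, dimnames = list(paste0("g", 1:100), c("c1", "c2", "c3")))
  y <- setNames(rnorm(100), rownames(S))
  a <- permutationZ(S, y, nPerm = 300, seed = 11)
  b <- permutationZ(S, y, nPerm = 300, seed = 11)
  expect_identical(a, b)
  expect_true(all(a$p >= 1 / 301))   # add-one correction floors p

  z0 <- permutationZ(S, setNames(rep(0, 100), rownames(S)), nPerm = 100,
                     seed = 1)
  expect_equal(z0$beta, rep(0, 3))
  expect_equal(z0$z, rep(0, 3))
  expect_error(permutationZ(S, y, nPerm = 10), "seed")
})

test_that("the t-test fallback at zero permutations gives finite calibrated stats", {
  set.seed(12)
  S <- matrix(rnorm(500), 100, 5, dimnames = list(paste0("g", 1:100), NULL))
  y <- setNames(rnorm(100), rownames(S))
  res <- permutationZ(S, y, alpha = 1, nPerm = 0)
  expect_true(all(is.finite(res$z)))
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_equal(res$z, res$beta / res$se)
})

test_that("group activity assigns star tiers at the stated FDR cutoffs", {
  expect_equal(ibdatlas:::activityTier(c(0.005, 0.04, 0.09, 0.2, NA)),
               c("***", "**", "*", "", ""))
})

test_that("group-vs-reference activity is zero when the groups coincide", {
  set.seed(13)
  tpm <- matrix(rexp(200 * 8, 0.1), 200, 8,
                dimnames = list(paste0("g", 1:200), paste0("s", 1:8)))
  S <- matrix(rnorm(600), 200, 3,
              dimnames = list(paste0("g", 1:200), c("c1", "c2", "c3")))
  groups <- rep(c("inf", "ctrl"), each = 4)
  # duplicate the reference samples into the test group: profile is zero
  tpm[, 1:4] <- tpm[, 5:8]
  res <- groupActivity(tpm, groups, c(inf = "ctrl"), S, nPerm = 50, seed = 2)
  expect_equal(res$beta, rep(0, 3))
  expect_equal(res$z, rep(0, 3))
  expect_true(all(res$tier == ""))
  expect_warning(
    groupActivity(tpm, groups, c(missing = "ctrl"), S, nPerm = 10, seed = 2),
    "skipped")
})

test_that("weighted-mean activities match hand arithmetic and normalize nulls", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("cell1", paste0("g", 1:6)))
  net <- data.frame(cytokine = "TNFA",
                    gene = c("g1", "g2", "g3", "g6"),
                    weight = c(2, -1, 0.5, 1))
  res <- wmeanActivity(X, net, nPerm = 10, seed = 3)
  raw <- (2 * 1 - 1 * 2 + 0.5 * 3 + 1 * 6) / (2 + 1 + 0.5 + 1)
  expect_equal(unname(res$raw[1, "TNFA"]), raw)

  # constant expression: every permutation gives the same raw score
  Xc <- matrix(5, 3, 6, dimnames = list(NULL, paste0("g", 1:6)))
  netu <- data.frame(cytokine = "c", gene = paste0("g", 1:6), weight = 1)
  resc <- wmeanActivity(Xc, netu, nPerm = 20, seed = 4)
  expect_equal(unname(resc$raw[, "c"]), rep(5, 3))
  expect_equal(unname(resc$normalized[, "c"]), rep(0, 3))

  expect_warning(
    wmeanActivity(X, data.frame(cytokine = "solo", gene = "g1", weight = 1),
                  nPerm = 5, seed = 1), "fewer than 2")
})

test_that("weighted-mean scores separate a planted high-activity population", {
  set.seed(14)
  genes <- paste0("g", 1:50)
  net <- data.frame(cytokine = "IL6", gene = genes[1:10], weight = runif(10, 0.5, 2))
  hot <- matrix(rnorm(40 * 50), 40, 50, dimnames = list(NULL, genes))
  hot[, 1:10] <- hot[, 1:10] + 2
  cold <- matrix(rnorm(40 * 50), 40, 50, dimnames = list(NULL, genes))
  res <- wmeanActivity(rbind(hot, cold), net, nPerm = 50, seed = 5)
  auc <- aucOracle(res$normalized[, "IL6"], rep(c(TRUE, FALSE), each = 40))
  expect_gte(auc, 0.9)
})
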