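test_that("disease allocation follows deterministic largest-remainder apportionment", {
  cfg <- CohortConfig(nPatients = 100L, seed = 7,
                      diseaseMix = c(CD = 0.5, UC = 0.3, nonIBD = 0.2))
  coh <- generateCohort(cfg)
  tb <- table(cohortPatients(coh)$disease)
  expect_equal(as.integer(tb[c("CD", "UC", "nonIBD")]), c(50L, 30L, 20L))

  # remainder case recomputed from the allocation rule: 101 * (1/3,1/3,1/3)
  # gives base (33,33,33); the two leftover units go to the tied largest
  # remainders in category order
  cfg2 <- CohortConfig(nPatients = 101L, seed = 7,
                       diseaseMix = c(CD = 1/3, UC = 1/3, nonIBD = 1/3))
  tb2 <- table(cohortPatients(generateCohort(cfg2))$disease)
  expect_equal(as.integer(tb2[c("CD", "UC", "nonIBD")]), c(34L, 34L, 33L))
})

test_that("nonIBD severities are exactly zero and IBD severities fill (0,1)", {
  coh <- generateCohort(CohortConfig(nPatients = 30L, seed = 2,
                                     diseaseMix = c(CD = 0, UC = 0, nonIBD = 1)))
  expect_true(all(cohortContexts(coh)$severity == 0))

  coh2 <- generateCohort(CohortConfig(nPatients = 200L, seed = 2,
                                      diseaseMix = c(CD = 0.5, UC = 0.5, nonIBD = 0)))
  sev <- cohortContexts(coh2)$severity
  expect_true(all(sev > 0 & sev < 1))
  # Beta(2,2): mean 0.5, sd sqrt(1/20); check mean within 4 SE
  expect_lt(abs(mean(sev) - 0.5), 4 * sqrt(0.05) / sqrt(length(sev)))
})

test_that("identical config and seed reproduce the cohort field-for-field", {
  a <- simulateCohort(tinyConfig(seed = 9))
  b <- simulateCohort(tinyConfig(seed = 9))
  expect_identical(cohortContexts(a$cohort), cohortContexts(b$cohort))
  expect_identical(a$histo, b$histo)
  expect_identical(SummarizedExperiment::assay(a$npx, "npx"),
                   SummarizedExperiment::assay(b$npx, "npx"))
  expect_identical(SummarizedExperiment::assay(a$expression, "counts"),
                   SummarizedExperiment::assay(b$expression, "counts"))
  expect_identical(a$bags$bags[[3]]$features, b$bags$bags[[3]]$features)
  expect_identical(a$clinical, b$clinical)
})

test_that("histopathology scores are Binomial(max, severity) in the endpoints and mean", {
  coh0 <- generateCohort(CohortConfig(nPatients = 20L, seed = 3,
                                      diseaseMix = c(CD = 0, UC = 0, nonIBD = 1)))
  h0 <- simulateHisto(coh0)
  expect_true(all(h0$raw == 0))

  # all-CD cohort forced to severity 1: raw must equal the context maximum
  coh1 <- generateCohort(CohortConfig(nPatients = 20L, seed = 3,
                                      diseaseMix = c(CD = 1, UC = 0, nonIBD = 0)))
  coh1@contexts$severity <- 1
  h1 <- simulateHisto(coh1)
  expect_true(all(h1$normalized == 1))

  # severity 0.5: mean of raw/max is 0.5 within 3 SE of the binomial average
  cohH <- generateCohort(CohortConfig(nPatients = 400L, seed = 3,
                                      diseaseMix = c(CD = 1, UC = 0, nonIBD = 0)))
  cohH@contexts$severity <- 0.5
  hH <- simulateHisto(cohH)
  mx <- maxScore(hH$system, hH$tissue_group, hH$method)
  se <- sqrt(mean(0.5 * 0.5 / mx) / nrow(hH))
  expect_lt(abs(mean(hH$normalized) - 0.5), 3 * se)
})

test_that("NPX simulation plants exact shifts in the noise-free limit", {
  cfg <- tinyConfig(seed = 4, npxSd = 0)
  coh <- generateCohort(cfg)
  npx <- simulateNpx(coh, lodOffset = Inf)   # no censoring
  mat <- SummarizedExperiment::assay(npx, "npx")
  rd <- SummarizedExperiment::rowData(npx)
  sev <- SummarizedExperiment::colData(npx)$severity
  for (i in which(rd$planted)) {
    expect_equal(unname(mat[i, ] - rd$baseline_mean[i]), cfg@npxDelta * sev)
  }
  for (i in which(!rd$planted)) {
    expect_equal(unname(mat[i, ]), rep(rd$baseline_mean[i], ncol(mat)))
  }
})

test_that("a detection limit at the baseline mean censors about half the null draws", {
  coh <- generateCohort(CohortConfig(nPatients = 200L, seed = 5,
                                     diseaseMix = c(CD = 0, UC = 0, nonIBD = 1)))
  npx <- simulateNpx(coh, lodOffset = 0)
  frac <- mean(SummarizedExperiment::assay(npx, "belowLOD"))
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("TPM columns sum to one million", {
  sim <- simulateExpression(generateCohort(tinyConfig(seed = 6)))
  cs <- colSums(SummarizedExperiment::assay(sim, "tpm"))
  expect_true(all(abs(cs - 1e6) < 1e-3))
})

test_that("bags carry lesion fractions tracking severity with targets from histology", {
  coh <- generateCohort(tinyConfig(seed = 8))
  bags <- simulateBags(coh)
  ctx <- cohortContexts(coh)
  lesFrac <- vapply(bags$bags, function(b) mean(b$lesion), numeric(1))
  expect_equal(bags$index$context_id, ctx$context_id)
  # severity 0 contexts have no lesion tiles
  expect_true(all(lesFrac[ctx$severity == 0] == 0))
  expect_gt(cor(lesFrac, ctx$severity), 0.8)
  expect_true(all(bags$index$target >= 0 & bags$index$target <= 1))
})

test_that("clinical indices are monotone in severity and hit the minimum at zero", {
  coh <- generateCohort(CohortConfig(nPatients = 150L, seed = 10,
                                     clinicalSd = 0))
  cl <- simulateClinical(coh)
  uc <- cl[cl$disease == "UC", ]
  ord <- order(uc$severity)
  expect_true(all(diff(uc$UCEIS[ord]) >= 0))
  expect_true(all(diff(uc$PMS[ord]) >= 0))
  cd <- cl[cl$disease == "CD", ]
  ordcd <- order(cd$severity)
  expect_true(all(diff(cd$SES_CD[ordcd]) >= 0))
  expect_true(all(cl$bristol[cl$severity == 0] == 1))

  # with default noise the endoscopic index still tracks matched histology
  cohN <- generateCohort(CohortConfig(nPatients = 300L, seed = 11))
  clN <- simulateClinical(cohN)
  hN <- simulateHisto(cohN)
  riley <- hN[hN$system == "Riley", ]
  rileyByVisit <- tapply(riley$normalized, riley$visit_id, max)
  ucN <- clN[clN$disease == "UC", ]
  ct <- cor.test(ucN$UCEIS, rileyByVisit[ucN$visit_id])
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("invalid configurations are rejected", {
  expect_error(CohortConfig(nPatients = 10, seed = 1,
                            diseaseMix = c(CD = 0.6, UC = 0.6, nonIBD = 0.2)),
               "sum to 1")
  expect_error(CohortConfig(nPatients = 10), "seed")
  expect_error(CohortConfig(nPatients = 10, seed = 1, tilesPerBag = c(9L, 2L)),
               "tilesPerBag")
})
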