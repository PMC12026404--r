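#' Generate a synthetic IBD cohort with a shared latent severity
#'
#' Builds the patient / visit / tissue-context backbone of the synthetic
#' cohort. Disease and center labels are allocated by deterministic
#' largest-remainder apportionment of the configured proportions (no
#' multinomial jitter), so the composition is exact and reproducible. Each
#' patient contributes one visit; each visit carries two tissue contexts, one
#' from the colonic group and one from the ileal group, each with its own
#' latent inflammation severity: Beta(2,2) draws for IBD patients, exactly 0
#' for nonIBD controls. Severity is per (visit, tissue context), so an
#' inflamed ileum can coexist with a quiescent colon in the same patient.
#'
#' @param config a \linkS4class{CohortConfig}.
#' @return a \linkS4class{LatentCohort}.
#' @examples
#' coh <- generateCohort(CohortConfig(nPatients = 30, seed = 42))
#' coh
#' @export
generateCohort <- function(config) {
  validObject(config)
  n <- config@nPatients
  nDis <- largestRemainder(n, config@diseaseMix)
  nCen <- largestRemainder(n, config@centerMix)
  disease <- rep(names(nDis), nDis)
  center <- rep(names(nCen), nCen)

  colonTissues <- c("colon", "rectum", "caecum")
  ileumTissues <- c("ileum", "ileocecal valve", "small intestine",
                    "anastomosis", "pouch")

  withSeed(modalitySeed(config@seed, "cohort"), {
    patients <- data.frame(
      patient_id = sprintf("P%04d", seq_len(n)),
      disease = disease,
      sex = sample(c("female", "male"), n, replace = TRUE),
      age = pmin(pmax(round(stats::rnorm(n, 42, 14)), 18), 85),
      center = sample(center),   # decouple center from disease ordering
      stringsAsFactors = FALSE
    )
    visits <- data.frame(
      visit_id = sprintf("V%04d", seq_len(n)),
      patient_id = patients$patient_id,
      date = as.Date("2020-01-01") + sample.int(730, n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    ctxTissue <- c(sample(colonTissues, n, replace = TRUE),
                   sample(ileumTissues, n, replace = TRUE))
    contexts <- data.frame(
      context_id = sprintf("C%04d", seq_len(2L * n)),
      visit_id = rep(visits$visit_id, 2L),
      patient_id = rep(patients$patient_id, 2L),
      tissue = ctxTissue,
      method = sample(c("biopsy", "resection"), 2L * n, replace = TRUE,
                      prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE
    )
    contexts$tissue_group <- tissueGrouping(contexts$tissue)
    sev <- stats::rbeta(nrow(contexts), 2, 2)
    isIBD <- patients$disease[match(contexts$patient_id,
                                    patients$patient_id)] != "nonIBD"
    contexts$severity <- ifelse(isIBD, sev, 0)
    contexts <- contexts[, c("context_id", "visit_id", "patient_id", "tissue",
                             "tissue_group", "method", "severity")]
    new("LatentCohort", patients = patients, visits = visits,
        contexts = contexts, config = config, truth = list())
  })
}

# Visit-level severity: systemic readouts (serum, clinical indices) reflect
# the most inflamed sampled site of the visit.
visitSeverity <- function(cohort) {
  ctx <- cohort@contexts
  sev <- tapply(ctx$severity, ctx$visit_id, max)
  data.frame(visit_id = names(sev), severity = as.numeric(sev),
             stringsAsFactors = FALSE)
}
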