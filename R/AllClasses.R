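#' @import methods
NULL

#' Configuration for the synthetic IBD cohort generator
#'
#' Holds every knob of the synthetic multi-modal cohort: cohort composition,
#' planted effect sizes, per-modality noise scales and panel sizes. All
#' downstream modalities (histopathology, serum NPX, bulk expression,
#' tile-feature bags, clinical indices) are driven by one latent inflammation
#' severity per (visit, tissue context), so the config fully determines the
#' joint distribution of the simulated cohort.
#'
#' @slot nPatients number of patients.
#' @slot diseaseMix named proportions over \code{CD}, \code{UC}, \code{nonIBD}
#'   (must sum to 1).
#' @slot centerMix named proportions over study centers \code{A}, \code{B}.
#' @slot seed master RNG seed; each modality derives its own sub-stream.
#' @slot npxDelta NPX units of shift per unit severity for planted proteins.
#' @slot nPlantedProteins,nPlantedGenes numbers of planted severity-responsive
#'   features in the proteomic / transcriptomic panels.
#' @slot lesionShift feature-space displacement magnitude of lesion tiles.
#' @slot lfcPerSeverity log2 fold change per unit severity for planted genes.
#' @slot npxSd residual NPX standard deviation per protein.
#' @slot exprDispersion negative-binomial size parameter for counts.
#' @slot clinicalSd additive noise (index units) on clinical/endoscopic scores.
#' @slot bagNoiseSd standard deviation of background tile features.
#' @slot nProteins,nGenes,nCytokines panel sizes.
#' @slot featureDim tile feature dimension d.
#' @slot tilesPerBag integer range (min, max) of tiles per slide.
#' @slot activityScale magnitude of planted cytokine activities.
#' @export
setClass("CohortConfig",
  representation(
    nPatients = "integer",
    diseaseMix = "numeric",
    centerMix = "numeric",
    seed = "integer",
    npxDelta = "numeric",
    nPlantedProteins = "integer",
    nPlantedGenes = "integer",
    lesionShift = "numeric",
    lfcPerSeverity = "numeric",
    npxSd = "numeric",
    exprDispersion = "numeric",
    clinicalSd = "numeric",
    bagNoiseSd = "numeric",
    nProteins = "integer",
    nGenes = "integer",
    nCytokines = "integer",
    featureDim = "integer",
    tilesPerBag = "integer",
    activityScale = "numeric"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (length(object@nPatients) != 1L || object@nPatients < 1L)
    msgs <- c(msgs, "nPatients must be a positive integer")
  if (!setequal(names(object@diseaseMix), c("CD", "UC", "nonIBD")))
    msgs <- c(msgs, "diseaseMix must be named over CD, UC, nonIBD")
  if (abs(sum(object@diseaseMix) - 1) > 1e-9)
    msgs <- c(msgs, "diseaseMix proportions must sum to 1 (tol 1e-9)")
  if (any(object@diseaseMix < 0)) msgs <- c(msgs, "diseaseMix must be non-negative")
  if (abs(sum(object@centerMix) - 1) > 1e-9)
    msgs <- c(msgs, "centerMix proportions must sum to 1 (tol 1e-9)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "seed is mandatory")
  counts <- c(object@nPlantedProteins, object@nPlantedGenes, object@nProteins,
              object@nGenes, object@nCytokines, object@featureDim)
  if (any(counts < 0L)) msgs <- c(msgs, "panel counts must be non-negative")
  if (object@nPlantedProteins > object@nProteins)
    msgs <- c(msgs, "nPlantedProteins exceeds nProteins")
  if (object@nPlantedGenes > object@nGenes)
    msgs <- c(msgs, "nPlantedGenes exceeds nGenes")
  if (length(object@tilesPerBag) != 2L || any(object@tilesPerBag < 1L) ||
      object@tilesPerBag[1] > object@tilesPerBag[2])
    msgs <- c(msgs, "tilesPerBag must be an increasing positive range (min, max)")
  if (any(c(object@npxSd, object@exprDispersion, object@clinicalSd,
            object@bagNoiseSd) < 0))
    msgs <- c(msgs, "noise scales must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic cohort with a shared latent inflammation severity
#'
#' The generated cohort: patient, visit and tissue-context tables plus
#' ground-truth records for every planted effect. The \code{contexts} table
#' carries the latent severity in [0,1] per (visit, tissue context) that every
#' modality simulator reads; nonIBD contexts have severity exactly 0.
#'
#' @slot patients data.frame: patient_id, disease, sex, age, center.
#' @slot visits data.frame: visit_id, patient_id, date.
#' @slot contexts data.frame: context_id, visit_id, patient_id, tissue,
#'   tissue_group, method, severity.
#' @slot config the \linkS4class{CohortConfig} used.
#' @slot truth list of ground-truth tables filled in by the modality
#'   simulators (planted protein/gene ids, planted cytokine activities,
#'   lesion-tile indicators).
#' @export
setClass("LatentCohort",
  representation(
    patients = "data.frame",
    visits = "data.frame",
    contexts = "data.frame",
    config = "CohortConfig",
    truth = "list"
  )
)

setValidity("LatentCohort", function(object) {
  msgs <- character()
  ctx <- object@contexts
  if (nrow(ctx)) {
    if (any(ctx$severity < 0 | ctx$severity > 1))
      msgs <- c(msgs, "severity must lie in [0,1]")
    dis <- object@patients$disease[match(ctx$patient_id, object@patients$patient_id)]
    if (any(dis == "nonIBD" & ctx$severity != 0))
      msgs <- c(msgs, "nonIBD contexts must have severity 0")
    if (!all(ctx$visit_id %in% object@visits$visit_id))
      msgs <- c(msgs, "every context must link to a visit")
  }
  if (length(msgs)) msgs else TRUE
})

#' A derived protein/gene signature
#'
#' An ordered, duplicate-free feature list together with the derivation
#' metadata (contrast, FDR threshold, direction), e.g. the inflammatory
#' protein severity signatures IBD-IPSS / UC-IPSS / CD-IPSS.
#'
#' @slot name signature name.
#' @slot features ordered character vector of member features.
#' @slot metadata list recording how the signature was derived.
#' @export
setClass("SignatureSet",
  representation(name = "character", features = "character", metadata = "list")
)

setValidity("SignatureSet", function(object) {
  msgs <- character()
  if (length(object@name) != 1L) msgs <- c(msgs, "name must be a single string")
  if (anyDuplicated(object@features))
    msgs <- c(msgs, "signature features must be duplicate-free")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn SignatureSet number of member features
#' @param x a \code{SignatureSet}
#' @export
setMethod("length", "SignatureSet", function(x) length(x@features))

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nPatients, "patients, seed", object@seed, "\n")
  cat("  disease mix:", paste(sprintf("%s=%.2f", names(object@diseaseMix),
                                      object@diseaseMix), collapse = " "), "\n")
  cat("  panels:", object@nProteins, "proteins /", object@nGenes, "genes /",
      object@nCytokines, "cytokines; d =", object@featureDim, "\n")
  cat("  effects: npxDelta", object@npxDelta, "| lfcPerSeverity",
      object@lfcPerSeverity, "| lesionShift", object@lesionShift, "\n")
})

setMethod("show", "LatentCohort", function(object) {
  cat("LatentCohort:", nrow(object@patients), "patients,",
      nrow(object@visits), "visits,", nrow(object@contexts),
      "tissue contexts\n")
  tb <- table(object@patients$disease)
  cat("  ", paste(sprintf("%s=%d", names(tb), tb), collapse = " "), "\n")
  if (length(object@truth))
    cat("  truth tables:", paste(names(object@truth), collapse = ", "), "\n")
})

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet", object@name, "with", length(object@features),
      "features\n")
  if (length(object@features))
    cat("  ", paste(utils::head(object@features, 8), collapse = ", "),
        if (length(object@features) > 8) "..." else "", "\n")
})

#' Accessors for LatentCohort components
#'
#' @param x a \linkS4class{LatentCohort}
#' @return the corresponding table (data.frame) or list.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
cohortPatients <- function(x) x@patients

#' @rdname cohort-accessors
#' @export
cohortVisits <- function(x) x@visits

#' @rdname cohort-accessors
#' @export
cohortContexts <- function(x) x@contexts

#' @rdname cohort-accessors
#' @export
cohortTruth <- function(x) x@truth

#' @rdname cohort-accessors
#' @export
cohortConfig <- function(x) x@config

#' Signature accessors
#' @param x a \linkS4class{SignatureSet}
#' @return character vector of members / list of metadata.
#' @export
signatureFeatures <- function(x) x@features

#' @rdname signatureFeatures
#' @export
signatureMetadata <- function(x) x@metadata
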