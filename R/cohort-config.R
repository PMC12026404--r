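#' Build a cohort generator configuration
#'
#' Defaults describe a mid-sized two-center IBD cohort with moderate planted
#' effects: 1 NPX unit of protein shift per unit severity, 100 planted
#' inflammation genes with 2 log2 units of fold change per unit severity, and
#' lesion tiles displaced 2 standard deviations from the tile background.
#'
#' @param nPatients number of patients (default 100).
#' @param diseaseMix named proportions over CD/UC/nonIBD summing to 1.
#' @param centerMix named proportions over centers A/B summing to 1.
#' @param seed master seed (mandatory).
#' @param npxDelta NPX shift per unit severity for planted proteins.
#' @param nPlantedProteins,nPlantedGenes planted feature counts.
#' @param lesionShift displacement of lesion tiles along the lesion axis.
#' @param lfcPerSeverity log2 fold change per unit severity (planted genes).
#' @param npxSd,exprDispersion,clinicalSd,bagNoiseSd per-modality noise scales.
#' @param nProteins,nGenes,nCytokines,featureDim,tilesPerBag panel sizes.
#' @param activityScale magnitude of planted cytokine activities.
#' @return a validated \linkS4class{CohortConfig}.
#' @examples
#' cfg <- CohortConfig(nPatients = 20, seed = 1)
#' cfg
#' @export
CohortConfig <- function(nPatients = 100L,
                         diseaseMix = c(CD = 0.4, UC = 0.4, nonIBD = 0.2),
                         centerMix = c(A = 0.7, B = 0.3),
                         seed,
                         npxDelta = 1.0,
                         nPlantedProteins = 20L,
                         nPlantedGenes = 100L,
                         lesionShift = 2.0,
                         lfcPerSeverity = 2.0,
                         npxSd = 0.5,
                         exprDispersion = 10,
                         clinicalSd = 1.0,
                         bagNoiseSd = 1.0,
                         nProteins = 200L,
                         nGenes = 2000L,
                         nCytokines = 8L,
                         featureDim = 64L,
                         tilesPerBag = c(30L, 80L),
                         activityScale = 1.0) {
  if (missing(seed)) stop("CohortConfig: 'seed' is mandatory")
  new("CohortConfig",
      nPatients = as.integer(nPatients),
      diseaseMix = diseaseMix[c("CD", "UC", "nonIBD")],
      centerMix = centerMix,
      seed = as.integer(seed),
      npxDelta = npxDelta,
      nPlantedProteins = as.integer(nPlantedProteins),
      nPlantedGenes = as.integer(nPlantedGenes),
      lesionShift = lesionShift,
      lfcPerSeverity = lfcPerSeverity,
      npxSd = npxSd,
      exprDispersion = exprDispersion,
      clinicalSd = clinicalSd,
      bagNoiseSd = bagNoiseSd,
      nProteins = as.integer(nProteins),
      nGenes = as.integer(nGenes),
      nCytokines = as.integer(nCytokines),
      featureDim = as.integer(featureDim),
      tilesPerBag = as.integer(tilesPerBag),
      activityScale = activityScale)
}

# Largest-remainder (Hamilton) apportionment of n units over proportions.
# Deterministic: ties in remainders broken by category order.
largestRemainder <- function(n, props) {
  quota <- n * props
  base <- floor(quota)
  rem <- quota - base
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

# Per-modality RNG sub-stream: a deterministic 32-bit seed derived from the
# master seed and a modality tag, so regenerating one modality never disturbs
# the draws of another.
modalitySeed <- function(seed, modality) {
  tag <- sum(utf8ToInt(modality) * seq_along(utf8ToInt(modality)))
  as.integer((as.double(seed) * 1009 + tag * 9176) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
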