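#' Simulate histopathology scoring records
#'
#' Each tissue context yields raw scores drawn as Binomial(max_score,
#' severity), where the maximum comes from the normalization table for the
#' record's (system, tissue group, sampling method). Disease entity selects
#' the scoring system — modified Naini Cortina for CD, modified Riley for UC —
#' while nonIBD controls are scored with both systems.
#'
#' @param cohort a \linkS4class{LatentCohort}.
#' @param normTable normalization table (default \code{\link{defaultNormTable}}).
#' @return data.frame of scoring records with raw and normalized scores.
#' @export
simulateHisto <- function(cohort, normTable = defaultNormTable()) {
  ctx <- cohort@contexts
  pat <- cohort@patients
  vis <- cohort@visits
  disease <- pat$disease[match(ctx$patient_id, pat$patient_id)]
  system <- lapply(disease, function(d) switch(d,
    CD = "NainiCortina", UC = "Riley", nonIBD = c("NainiCortina", "Riley")))
  reps <- lengths(system)
  rec <- ctx[rep(seq_len(nrow(ctx)), reps), ]
  rec$system <- unlist(system)
  rec$date <- vis$date[match(rec$visit_id, vis$visit_id)]
  mx <- maxScore(rec$system, rec$tissue_group, rec$method, normTable)
  withSeed(modalitySeed(cohort@config@seed, "histo"), {
    rec$raw <- stats::rbinom(nrow(rec), mx, rec$severity)
  })
  rec$normalized <- rec$raw / mx
  rec$sample_id <- sprintf("HIS%04d", seq_len(nrow(rec)))
  rownames(rec) <- NULL
  rec[, c("sample_id", "patient_id", "visit_id", "context_id", "date",
          "tissue", "tissue_group", "method", "system", "raw", "normalized",
          "severity")]
}

#' Simulate a serum proteomics (NPX) panel
#'
#' One serum draw per visit, dated with the visit. Per-protein baselines are
#' Normal(mu_p, npxSd) on the log2 NPX scale; planted proteins gain
#' \code{npxDelta * severity}, where a visit's severity is the maximum across
#' its tissue contexts (systemic markers track the worst inflamed site).
#' Values below a per-protein detection limit (set two baseline standard
#' deviations under the baseline mean) are recorded as missing and flagged
#' below-LOD.
#'
#' @param cohort a \linkS4class{LatentCohort}.
#' @param lodOffset detection limit in baseline SDs below the baseline mean
#'   (default 2).
#' @return a \code{SummarizedExperiment} (proteins x samples) with assays
#'   \code{npx} and \code{belowLOD}; planted proteins flagged in
#'   \code{rowData}, latent severity in \code{colData}.
#' @export
simulateNpx <- function(cohort, lodOffset = 2) {
  cfg <- cohort@config
  vs <- visitSeverity(cohort)
  vis <- cohort@visits[match(vs$visit_id, cohort@visits$visit_id), ]
  pat <- cohort@patients
  nS <- nrow(vs)
  nP <- cfg@nProteins
  proteins <- sprintf("PROT%04d", seq_len(nP))
  planted <- proteins[seq_len(cfg@nPlantedProteins)]

  withSeed(modalitySeed(cfg@seed, "npx"), {
    mu <- stats::rnorm(nP, 5, 1.5)
    base <- matrix(stats::rnorm(nP * nS, mu, cfg@npxSd), nrow = nP)
    shift <- matrix(0, nP, nS)
    shift[seq_len(cfg@nPlantedProteins), ] <-
      cfg@npxDelta * matrix(vs$severity, cfg@nPlantedProteins, nS, byrow = TRUE)
    npx <- base + shift
  })
  lod <- mu - lodOffset * cfg@npxSd
  belowLOD <- npx < lod
  npx[belowLOD] <- NA_real_

  dimnames(npx) <- dimnames(belowLOD) <- list(proteins,
                                              sprintf("SER%04d", seq_len(nS)))
  cd <- S4Vectors::DataFrame(
    sample_id = colnames(npx),
    patient_id = vis$patient_id,
    visit_id = vis$visit_id,
    disease = pat$disease[match(vis$patient_id, pat$patient_id)],
    date = vis$date,
    severity = vs$severity)
  rd <- S4Vectors::DataFrame(protein = proteins, baseline_mean = mu,
                             lod = lod, planted = proteins %in% planted)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = npx, belowLOD = belowLOD),
    rowData = rd, colData = cd,
    metadata = list(planted_proteins = planted, npxDelta = cfg@npxDelta))
}

#' Simulate a sparse cytokine response-signature matrix
#'
#' Genes x cytokines weight matrix: each cytokine drives a random subset of
#' genes with Normal(0,1) weights (zero elsewhere). Used both to embed
#' cytokine-driven structure into simulated expression and as the signature
#' matrix for activity inference.
#'
#' @param genes character vector of gene ids.
#' @param cytokines character vector of cytokine ids.
#' @param genesPerCytokine responsive genes per cytokine (default 50).
#' @param seed RNG seed.
#' @return numeric matrix (genes x cytokines) with no all-zero column.
#' @export
simulateResponseMatrix <- function(genes, cytokines, genesPerCytokine = 50L,
                                   seed) {
  withSeed(seed, {
    S <- matrix(0, length(genes), length(cytokines),
                dimnames = list(genes, cytokines))
    for (j in seq_along(cytokines)) {
      idx <- sample.int(length(genes), min(genesPerCytokine, length(genes)))
      S[idx, j] <- stats::rnorm(length(idx))
    }
    S
  })
}

#' Simulate bulk RNA expression (counts and TPM)
#'
#' One RNA sample per tissue context. Expected expression on the log2 scale
#' is a per-gene baseline plus \code{lfcPerSeverity * severity} for planted
#' inflammation genes plus a cytokine-driven term \code{(S a) * severity} for
#' the planted cytokine activities, so that downstream activity inference has
#' a recoverable ground truth. Counts are negative binomial with the
#' configured dispersion; TPM is computed from counts and gene lengths and
#' sums to 1e6 per sample.
#'
#' @param cohort a \linkS4class{LatentCohort}.
#' @param responseMatrix optional genes x cytokines matrix; simulated when
#'   absent.
#' @param libSize expected library size (default 2e6).
#' @return a \code{SummarizedExperiment} (genes x samples) with assays
#'   \code{counts} and \code{tpm}; metadata holds the response matrix and the
#'   planted activity vector.
#' @export
simulateExpression <- function(cohort, responseMatrix = NULL, libSize = 2e6) {
  cfg <- cohort@config
  ctx <- cohort@contexts
  pat <- cohort@patients
  nG <- cfg@nGenes
  nS <- nrow(ctx)
  genes <- sprintf("G%05d", seq_len(nG))
  cytokines <- c("TNFA", "IFNG", "IL6", "IL1B", "IL17A", "IL10", "TGFB1",
                 "IL12B", sprintf("CYT%02d", seq_len(max(0, cfg@nCytokines - 8L))))
  cytokines <- cytokines[seq_len(cfg@nCytokines)]
  if (is.null(responseMatrix))
    responseMatrix <- simulateResponseMatrix(genes, cytokines,
                                             seed = modalitySeed(cfg@seed, "response"))
  activities <- stats::setNames(rep(0, length(cytokines)), cytokines)
  activities[1] <- cfg@activityScale   # TNFA-like planted activity

  planted <- genes[seq_len(cfg@nPlantedGenes)]
  withSeed(modalitySeed(cfg@seed, "expression"), {
    len <- round(stats::rlnorm(nG, log(1500), 0.4))
    b <- stats::rnorm(nG, 4, 1.5)
    lfc <- numeric(nG)
    lfc[seq_len(cfg@nPlantedGenes)] <- cfg@lfcPerSeverity
    cytoEffect <- as.numeric(responseMatrix %*% activities)
    counts <- matrix(0L, nG, nS)
    for (s in seq_len(nS)) {
      log2x <- b + (lfc + cytoEffect) * ctx$severity[s]
      relAbund <- 2^log2x * len
      mu <- relAbund / sum(relAbund) * libSize
      counts[, s] <- stats::rnbinom(nG, mu = mu, size = cfg@exprDispersion)
    }
  })
  rate <- counts / len
  tpm <- sweep(rate, 2, colSums(rate), "/") * 1e6
  dimnames(counts) <- dimnames(tpm) <- list(genes,
                                            sprintf("RNA%04d", seq_len(nS)))
  cd <- S4Vectors::DataFrame(
    sample_id = colnames(counts),
    patient_id = ctx$patient_id, visit_id = ctx$visit_id,
    context_id = ctx$context_id, tissue = ctx$tissue,
    tissue_group = ctx$tissue_group,
    disease = pat$disease[match(ctx$patient_id, pat$patient_id)],
    date = cohort@visits$date[match(ctx$visit_id, cohort@visits$visit_id)],
    severity = ctx$severity)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts, tpm = tpm),
    rowData = S4Vectors::DataFrame(gene = genes, length = len,
                                   planted = genes %in% planted),
    colData = cd,
    metadata = list(response_matrix = responseMatrix,
                    planted_activities = activities,
                    planted_genes = planted))
}

#' Simulate per-slide tile-feature bags
#'
#' One slide per tissue context. Tiles are background Gaussian feature
#' vectors; a Binomial(n_tiles, severity) number of tiles are lesion tiles,
#' displaced by \code{lesionShift} along a fixed unit direction (the first
#' feature axis). The bag target is the normalized histopathology score of
#' the matching scoring record (the record whose system matches the disease
#' entity; modified Naini Cortina for nonIBD controls).
#'
#' @param cohort a \linkS4class{LatentCohort}.
#' @param histo histopathology record table from \code{\link{simulateHisto}};
#'   simulated on the fly when absent.
#' @return list with \code{bags} (each: slide_id, context_id, features
#'   (n x d), target, lesion logical vector) and \code{index} data.frame.
#' @export
simulateBags <- function(cohort, histo = NULL) {
  cfg <- cohort@config
  if (is.null(histo)) histo <- simulateHisto(cohort)
  ctx <- cohort@contexts
  pat <- cohort@patients
  disease <- pat$disease[match(ctx$patient_id, pat$patient_id)]
  system <- ifelse(disease == "UC", "Riley", "NainiCortina")
  key <- paste(ctx$context_id, system)
  hkey <- paste(histo$context_id, histo$system)
  target <- histo$normalized[match(key, hkey)]
  d <- cfg@featureDim
  withSeed(modalitySeed(cfg@seed, "bags"), {
    bags <- lapply(seq_len(nrow(ctx)), function(i) {
      n <- sample(seq(cfg@tilesPerBag[1], cfg@tilesPerBag[2]), 1)
      x <- matrix(stats::rnorm(n * d, 0, cfg@bagNoiseSd), n, d)
      nLesion <- stats::rbinom(1, n, ctx$severity[i])
      lesion <- rep(FALSE, n)
      if (nLesion > 0) {
        idx <- sample.int(n, nLesion)
        lesion[idx] <- TRUE
        x[idx, 1] <- x[idx, 1] + cfg@lesionShift
      }
      list(slide_id = sprintf("SLD%04d", i), context_id = ctx$context_id[i],
           features = x, target = target[i], lesion = lesion)
    })
  })
  index <- data.frame(
    slide_id = vapply(bags, `[[`, "", "slide_id"),
    context_id = ctx$context_id,
    patient_id = ctx$patient_id,
    n_tiles = vapply(bags, function(b) nrow(b$features), 1L),
    target = target,
    severity = ctx$severity,
    stringsAsFactors = FALSE)
  list(bags = bags, index = index)
}

#' Simulate clinical and endoscopic disease-activity indices
#'
#' Each index is a monotone map of the visit-level severity (maximum across
#' the visit's tissue contexts) onto its integer range, plus Gaussian noise,
#' rounded and clipped. UC indices (UCEIS 0-8, partial Mayo 0-9) are reported
#' only for UC patients, CD indices (SES-CD 0-56, HBI 0-16) only for CD; the
#' Bristol stool score (1-7) is reported for everyone.
#'
#' @param cohort a \linkS4class{LatentCohort}.
#' @return data.frame, one row per visit, NA for non-applicable indices.
#' @export
simulateClinical <- function(cohort) {
  cfg <- cohort@config
  vs <- visitSeverity(cohort)
  vis <- cohort@visits[match(vs$visit_id, cohort@visits$visit_id), ]
  disease <- cohort@patients$disease[match(vis$patient_id,
                                           cohort@patients$patient_id)]
  n <- nrow(vs)
  mapIndex <- function(sev, lo, hi, sd) {
    pmin(pmax(round(lo + sev * (hi - lo) + stats::rnorm(n, 0, sd)), lo), hi)
  }
  withSeed(modalitySeed(cfg@seed, "clinical"), {
    out <- data.frame(
      visit_id = vis$visit_id, patient_id = vis$patient_id,
      disease = disease, date = vis$date, severity = vs$severity,
      UCEIS = mapIndex(vs$severity, 0, 8, cfg@clinicalSd),
      PMS = mapIndex(vs$severity, 0, 9, cfg@clinicalSd),
      SES_CD = mapIndex(vs$severity, 0, 56, 4 * cfg@clinicalSd),
      HBI = mapIndex(vs$severity, 0, 16, 1.5 * cfg@clinicalSd),
      bristol = mapIndex(vs$severity, 1, 7, cfg@clinicalSd),
      stringsAsFactors = FALSE)
  })
  out$UCEIS[disease != "UC"] <- NA_integer_
  out$PMS[disease != "UC"] <- NA_integer_
  out$SES_CD[disease != "CD"] <- NA_integer_
  out$HBI[disease != "CD"] <- NA_integer_
  out
}

#' Simulate the full multi-modal cohort in one call
#'
#' Convenience wrapper running every modality simulator off one latent
#' cohort. With \code{dir} given, also writes the tabular bundle
#' (patients.tsv, samples.tsv, histo.tsv, clinical.tsv, long-format npx.tsv,
#' counts.tsv / tpm.tsv, per-slide feature TSVs plus bags_index.tsv, and
#' truth tables).
#'
#' @param config a \linkS4class{CohortConfig}.
#' @param dir optional output directory for the TSV bundle.
#' @return list: cohort, histo, npx (SummarizedExperiment), expression
#'   (SummarizedExperiment), bags, clinical.
#' @export
simulateCohort <- function(config, dir = NULL) {
  cohort <- generateCohort(config)
  histo <- simulateHisto(cohort)
  npx <- simulateNpx(cohort)
  expr <- simulateExpression(cohort)
  bags <- simulateBags(cohort, histo)
  clinical <- simulateClinical(cohort)
  out <- list(cohort = cohort, histo = histo, npx = npx, expression = expr,
              bags = bags, clinical = clinical)
  if (!is.null(dir)) writeSimulatedBundle(out, dir)
  out
}

# Serialize the simulated modalities as the tabular bundle consumed by
# assembleAtlas (and by downstream file-based workflows).
writeSimulatedBundle <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  npxMat <- SummarizedExperiment::assay(sim$npx, "npx")
  lodMat <- SummarizedExperiment::assay(sim$npx, "belowLOD")
  cd <- as.data.frame(SummarizedExperiment::colData(sim$npx))
  npxLong <- data.frame(
    sample_id = rep(colnames(npxMat), each = nrow(npxMat)),
    protein = rep(rownames(npxMat), ncol(npxMat)),
    NPX = as.vector(npxMat),
    below_LOD = as.vector(lodMat), stringsAsFactors = FALSE)
  ecd <- as.data.frame(SummarizedExperiment::colData(sim$expression))
  samples <- rbind(
    data.frame(sample_id = cd$sample_id, patient_id = cd$patient_id,
               modality = "serum", tissue = NA, tissue_group = NA,
               date = as.character(cd$date), stringsAsFactors = FALSE),
    data.frame(sample_id = ecd$sample_id, patient_id = ecd$patient_id,
               modality = "rna", tissue = ecd$tissue,
               tissue_group = ecd$tissue_group, date = as.character(ecd$date),
               stringsAsFactors = FALSE),
    data.frame(sample_id = sim$histo$sample_id,
               patient_id = sim$histo$patient_id, modality = "histo",
               tissue = sim$histo$tissue, tissue_group = sim$histo$tissue_group,
               date = as.character(sim$histo$date), stringsAsFactors = FALSE))
  writeCohortBundle(list(
    patients = sim$cohort@patients,
    samples = samples,
    histo = sim$histo,
    clinical = sim$clinical,
    npx = npxLong,
    bags_index = sim$bags$index), dir)
  utils::write.table(
    data.frame(gene = rownames(sim$expression),
               as.data.frame(SummarizedExperiment::assay(sim$expression, "counts"))),
    file.path(dir, "counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene = rownames(sim$expression),
               as.data.frame(SummarizedExperiment::assay(sim$expression, "tpm"))),
    file.path(dir, "tpm.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  slideDir <- file.path(dir, "slides")
  dir.create(slideDir, showWarnings = FALSE)
  for (b in sim$bags$bags)
    utils::write.table(b$features,
                       file.path(slideDir, paste0(b$slide_id, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  truthDir <- file.path(dir, "truth")
  dir.create(truthDir, showWarnings = FALSE)
  utils::write.table(
    data.frame(protein = S4Vectors::metadata(sim$npx)$planted_proteins),
    file.path(truthDir, "planted_proteins.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(gene = S4Vectors::metadata(sim$expression)$planted_genes),
    file.path(truthDir, "planted_genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  act <- S4Vectors::metadata(sim$expression)$planted_activities
  utils::write.table(
    data.frame(cytokine = names(act), activity = as.numeric(act)),
    file.path(truthDir, "planted_activities.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  lesions <- do.call(rbind, lapply(sim$bags$bags, function(b)
    data.frame(slide_id = b$slide_id, tile = seq_along(b$lesion),
               lesion = b$lesion, stringsAsFactors = FALSE)))
  utils::write.table(lesions, file.path(truthDir, "lesion_tiles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
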