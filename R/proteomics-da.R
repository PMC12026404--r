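#' Filter a protein panel by detection rate
#'
#' Keeps proteins detected in at least \code{minFrac} of the samples
#' (inclusive boundary, so 9/10 passes at 0.90). "Detected" means measured
#' and not below the limit of detection. Protein ordering is preserved.
#'
#' @param npx proteins x samples numeric matrix (NA = not detected), or a
#'   \code{SummarizedExperiment} with assays \code{npx} and (optionally)
#'   \code{belowLOD}.
#' @param minFrac minimum detected fraction, default 0.90.
#' @return filtered object of the same kind as the input.
#' @export
detectionFilter <- function(npx, minFrac = 0.90) {
  stopifnot(minFrac > 0, minFrac <= 1)
  mat <- npxAssay(npx)
  detected <- !is.na(mat)
  if (methods::is(npx, "SummarizedExperiment") &&
      "belowLOD" %in% SummarizedExperiment::assayNames(npx))
    detected <- detected & !SummarizedExperiment::assay(npx, "belowLOD")
  keep <- rowMeans(detected) >= minFrac
  if (!any(keep)) warning("detectionFilter: no protein passes the filter")
  npx[keep, , drop = FALSE]
}

npxAssay <- function(npx) {
  if (methods::is(npx, "SummarizedExperiment"))
    SummarizedExperiment::assay(npx, "npx")
  else as.matrix(npx)
}

#' Rebuild the NPX container from the long-format bundle table
#'
#' Inverse of the bundle serialization: pivots the long table
#' (sample_id, protein, NPX, below_LOD) back into a proteins x samples
#' \code{SummarizedExperiment} with assays \code{npx} and \code{belowLOD}.
#'
#' @param long data.frame with columns sample_id, protein, NPX, below_LOD.
#' @return a \code{SummarizedExperiment}.
#' @export
npxFromLong <- function(long) {
  need <- c("sample_id", "protein", "NPX", "below_LOD")
  if (!all(need %in% names(long)))
    stop("npxFromLong: table must have columns ", paste(need, collapse = ", "))
  proteins <- unique(long$protein)
  samples <- unique(long$sample_id)
  npx <- matrix(NA_real_, length(proteins), length(samples),
                dimnames = list(proteins, samples))
  lod <- matrix(FALSE, length(proteins), length(samples),
                dimnames = list(proteins, samples))
  idx <- cbind(match(long$protein, proteins), match(long$sample_id, samples))
  npx[idx] <- long$NPX
  lod[idx] <- long$below_LOD
  SummarizedExperiment::SummarizedExperiment(
    assays = list(npx = npx, belowLOD = lod))
}

#' Welch two-sample t-tests across a protein panel
#'
#' Per-protein Welch (unequal-variance) t-test between two sample groups on
#' the NPX scale, with Benjamini-Hochberg correction across the testable
#' proteins. Missing values are dropped per protein (complete observations,
#' no imputation); a protein with fewer than two observations in either
#' group is flagged untestable and excluded from the BH family.
#'
#' @param npx proteins x samples matrix or SummarizedExperiment.
#' @param groups character/factor of sample group labels (length = ncol).
#' @param contrast length-2 character: (groupA, groupB); the estimate is
#'   mean(A) - mean(B).
#' @return data.frame: protein, estimate, t, df, p, adj_p, testable.
#' @export
welchTest <- function(npx, groups, contrast) {
  stopifnot(length(contrast) == 2)
  mat <- npxAssay(npx)
  stopifnot(length(groups) == ncol(mat))
  A <- mat[, groups == contrast[1], drop = FALSE]
  B <- mat[, groups == contrast[2], drop = FALSE]

  welchStats <- function(X) {
    n <- rowSums(!is.na(X))
    m <- rowMeans(X, na.rm = TRUE)
    v <- rowSums((X - m)^2, na.rm = TRUE) / pmax(n - 1, 1)
    list(n = n, mean = m, var = v)
  }
  a <- welchStats(A); b <- welchStats(B)
  testable <- a$n >= 2 & b$n >= 2
  se2a <- a$var / a$n
  se2b <- b$var / b$n
  estimate <- a$mean - b$mean
  tstat <- estimate / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 /
    (se2a^2 / pmax(a$n - 1, 1) + se2b^2 / pmax(b$n - 1, 1))
  # identical groups give 0/0; the two-sided p of a zero effect is 1
  tstat[testable & is.nan(tstat)] <- 0
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero pooled variance: df is degenerate; p follows the sign of the effect
  p[testable & is.na(p) & tstat == 0] <- 1
  p[testable & is.na(p) & is.infinite(tstat)] <- 0
  out <- data.frame(protein = rownames(mat) %||% seq_len(nrow(mat)),
                    estimate = estimate, t = tstat, df = df, p = p,
                    adj_p = NA_real_, testable = testable,
                    stringsAsFactors = FALSE)
  out$estimate[!testable] <- NA_real_
  out$t[!testable] <- NA_real_
  out$df[!testable] <- NA_real_
  out$p[!testable] <- NA_real_
  out$adj_p[testable] <- bhAdjust(out$p[testable])
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg step-up adjustment
#'
#' Validating wrapper around \code{stats::p.adjust(method = "BH")}: inputs
#' must be probabilities; outputs are capped at 1 and monotone in the ranks.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("bhAdjust: p-values must lie in [0, 1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Derive an inflammatory protein severity signature (IPSS)
#'
#' Selects the proteins significantly upregulated in the inflamed vs
#' non-inflamed contrast: BH-adjusted p strictly below \code{fdrThreshold}
#' and positive estimate (for \code{direction = "up"}). The returned
#' \linkS4class{SignatureSet} records contrast, threshold and direction.
#'
#' @param da data.frame from \code{\link{welchTest}} on the inflamed (A) vs
#'   non-inflamed (B) contrast.
#' @param fdrThreshold FDR cutoff, default 0.05.
#' @param direction \code{"up"} (estimate > 0) or \code{"down"}.
#' @param name signature name, e.g. \code{"IBD-IPSS"}.
#' @return a \linkS4class{SignatureSet}.
#' @export
deriveIpss <- function(da, fdrThreshold = 0.05, direction = c("up", "down"),
                       name = "IBD-IPSS") {
  direction <- match.arg(direction)
  keep <- !is.na(da$adj_p) & da$adj_p < fdrThreshold &
    (if (direction == "up") da$estimate > 0 else da$estimate < 0)
  feats <- da$protein[keep]
  if (!length(feats)) warning("deriveIpss: empty signature at threshold ",
                              fdrThreshold)
  new("SignatureSet", name = name, features = as.character(feats),
      metadata = list(fdr_threshold = fdrThreshold, direction = direction,
                      n_tested = sum(da$testable)))
}

#' Venn region counts over a list of feature sets
#'
#' Exact counts of every region of the Venn partition (exclusive regions)
#' together with all intersection counts, in deterministic subset order.
#'
#' @param sets named list of character vectors or
#'   \linkS4class{SignatureSet}s (at least 2).
#' @return data.frame: region (e.g. \code{"A&B"}), n_sets, exclusive (count
#'   of elements in exactly these sets), intersection (count in at least
#'   these sets).
#' @examples
#' setOverlapCounts(list(x = c("A","B","C"), y = c("B","C","D"), z = "C"))
#' @export
setOverlapCounts <- function(sets) {
  stopifnot(length(sets) >= 2)
  sets <- lapply(sets, function(s)
    if (methods::is(s, "SignatureSet")) signatureFeatures(s) else unique(as.character(s)))
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_along(sets)]
  universe <- unique(unlist(sets))
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (!is.matrix(membership)) membership <- matrix(membership, nrow = length(universe))
  k <- length(sets)
  combos <- unlist(lapply(seq_len(k), function(m)
    utils::combn(seq_len(k), m, simplify = FALSE)), recursive = FALSE)
  do.call(rbind, lapply(combos, function(idx) {
    inThese <- rowSums(membership[, idx, drop = FALSE]) == length(idx)
    onlyThese <- inThese & rowSums(membership) == length(idx)
    data.frame(region = paste(names(sets)[idx], collapse = "&"),
               n_sets = length(idx),
               exclusive = sum(onlyThese),
               intersection = sum(inThese),
               stringsAsFactors = FALSE)
  }))
}

#' @rdname setOverlapCounts
#' @export
signatureOverlap <- setOverlapCounts
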