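#' Kernel-CDF transform of an expression matrix
#'
#' First stage of single-sample gene-set variation scoring: each feature's
#' values are re-expressed as their estimated cumulative distribution across
#' samples. The gaussian kernel estimate is
#' \deqn{z_{ij} = \frac{1}{n}\sum_k \Phi\!\left(\frac{x_{ij}-x_{ik}}{h_i}\right)}
#' with per-feature bandwidth \eqn{h_i = s_i/4} (a quarter of the feature's
#' standard deviation); the \code{ecdf} option uses the empirical CDF
#' (proportion of samples at or below the value), which makes the whole
#' pipeline invariant under any strictly increasing per-feature transform.
#'
#' @param X features x samples numeric matrix (log2(TPM+1) for RNA, NPX for
#'   proteins); needs at least 3 samples of cross-sample spread.
#' @param kernel \code{"gaussian"} (default) or \code{"ecdf"}.
#' @return matrix of the same shape with values in (0, 1].
#' @export
kcdfTransform <- function(X, kernel = c("gaussian", "ecdf")) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  if (ncol(X) < 3) stop("kcdfTransform: at least 3 samples required")
  Z <- X
  if (kernel == "gaussian") {
    s <- apply(X, 1, stats::sd)
    if (any(s == 0)) {
      stop("kcdfTransform: zero-variance feature(s) with gaussian kernel: ",
           paste(utils::head(rownames(X)[s == 0] %||% which(s == 0), 5),
                 collapse = ", "))
    }
    h <- s / 4
    n <- ncol(X)
    for (i in seq_len(nrow(X))) {
      d <- outer(X[i, ], X[i, ], "-") / h[i]
      Z[i, ] <- rowMeans(stats::pnorm(d))
    }
  } else {
    for (i in seq_len(nrow(X))) {
      Z[i, ] <- stats::ecdf(X[i, ])(X[i, ])
    }
  }
  Z
}

#' Enrichment score of one feature set in one sample
#'
#' Second stage of the single-sample scoring: features are ordered by their
#' kernel-CDF value (descending, ties broken by stable feature order) and a
#' weighted Kolmogorov-Smirnov-like random walk is run down the list. The
#' walk steps up by the normalized symmetric rank weight
#' \eqn{|p/2 - \mathrm{rank}|^\tau} at set members and down by
#' \eqn{1/(p - m)} elsewhere. In \code{difference} mode the score is the
#' maximum positive excursion plus the minimum negative excursion (each 0 if
#' the walk never leaves that side); \code{max_deviation} returns the single
#' largest-magnitude excursion.
#'
#' @param z numeric vector: one sample's kernel-CDF column.
#' @param setIdx indices (or logical mask) of the feature set; must be a
#'   proper nonempty subset of the features.
#' @param tau rank-weight exponent (default 1).
#' @param mode \code{"difference"} (default) or \code{"max_deviation"}.
#' @return a single enrichment score; bounded by [-1, 1] for any tau.
#' @export
enrichmentScore <- function(z, setIdx, tau = 1,
                            mode = c("difference", "max_deviation")) {
  mode <- match.arg(mode)
  stopifnot(tau >= 0)
  p <- length(z)
  inSet <- logical(p)
  inSet[setIdx] <- TRUE
  m <- sum(inSet)
  if (m == 0 || m == p)
    stop("enrichmentScore: the set must be a proper nonempty subset")
  ord <- order(z, decreasing = TRUE)   # stable: ties keep feature order
  r <- abs(p / 2 - seq_len(p))         # symmetric rank statistic
  member <- inSet[ord]
  w <- numeric(p)
  setWeight <- r[member]^tau
  # a lone set member exactly at rank p/2 has zero rank weight; fall back to
  # equal up-steps so the walk still integrates to 1
  w[member] <- if (sum(setWeight) > 0) setWeight / sum(setWeight) else 1 / m
  w[!member] <- -1 / (p - m)
  walk <- cumsum(w)
  maxPos <- max(c(walk, 0))
  minNeg <- min(c(walk, 0))
  if (mode == "difference") maxPos + minNeg
  else if (maxPos >= -minNeg) maxPos else minNeg
}

#' Score feature sets across all samples
#'
#' Runs the kernel-CDF transform once and evaluates the enrichment walk for
#' every (sample, set) pair. Set members missing from the matrix are dropped
#' (with a message reporting the count); sets with fewer than \code{minSize}
#' surviving members are skipped with a warning.
#'
#' @param X features x samples matrix (or SummarizedExperiment assay).
#' @param sets named list of character vectors of feature ids.
#' @param kernel,tau,mode passed to \code{\link{kcdfTransform}} /
#'   \code{\link{enrichmentScore}}.
#' @param minSize minimum surviving set size (default 2).
#' @return samples x sets numeric matrix of scores in [-1, 1].
#' @export
scoreSets <- function(X, sets, kernel = c("gaussian", "ecdf"), tau = 1,
                      mode = c("difference", "max_deviation"), minSize = 2L) {
  kernel <- match.arg(kernel)
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(names(sets)))
    names(sets) <- paste0("set", seq_along(sets))
  Z <- kcdfTransform(X, kernel)
  feats <- rownames(X) %||% as.character(seq_len(nrow(X)))
  out <- matrix(NA_real_, ncol(X), length(sets),
                dimnames = list(colnames(X), names(sets)))
  for (s in names(sets)) {
    idx <- match(intersect(sets[[s]], feats), feats)
    dropped <- length(sets[[s]]) - length(idx)
    if (dropped > 0)
      message("scoreSets: set '", s, "': ", dropped,
              " feature(s) absent from the matrix, dropped")
    if (length(idx) < minSize) {
      warning("scoreSets: set '", s, "' has fewer than ", minSize,
              " surviving features; skipped")
      next
    }
    for (j in seq_len(ncol(X)))
      out[j, s] <- enrichmentScore(Z[, j], idx, tau = tau, mode = mode)
  }
  out
}

#' Biopsy molecular inflammation score (bMIS)
#'
#' Single-sample enrichment of an inflammation gene signature on expression
#' (log2(TPM+1)). With an optional down-regulated set the score is
#' score(up) - score(down); with only an up set it is the plain set score.
#' The signature gene lists are inputs (externally derived).
#'
#' @param X genes x samples expression matrix (log2(TPM+1)).
#' @param upSet character vector of up-regulated signature genes.
#' @param downSet optional down-regulated set.
#' @param ... passed to \code{\link{scoreSets}}.
#' @return named numeric vector, one bMIS per sample.
#' @export
bmis <- function(X, upSet, downSet = NULL, ...) {
  sets <- list(up = upSet)
  if (!is.null(downSet)) sets$down <- downSet
  sc <- scoreSets(X, sets, ...)
  if (is.null(downSet)) sc[, "up"] else sc[, "up"] - sc[, "down"]
}

#' Per-sample IPSS score
#'
#' Scores an inflammatory protein severity signature on the (detection
#' filtered) NPX matrix with the same single-sample enrichment machinery used
#' for the bMIS, treating the signature proteins as the feature set.
#'
#' @param npx proteins x samples NPX matrix or SummarizedExperiment.
#' @param signature a \linkS4class{SignatureSet} or character vector.
#' @param censored how to treat missing (below-LOD) values before the rank
#'   transform: \code{"floor"} (default) substitutes each protein's observed
#'   minimum — a below-detection measurement is a low abundance, so it ranks
#'   at the bottom — while \code{"drop"} removes any protein with a missing
#'   value.
#' @param ... passed to \code{\link{scoreSets}}.
#' @return named numeric vector, one score per sample.
#' @export
ipssScore <- function(npx, signature, censored = c("floor", "drop"), ...) {
  censored <- match.arg(censored)
  mat <- npxAssay(npx)
  feats <- if (methods::is(signature, "SignatureSet"))
    signatureFeatures(signature) else as.character(signature)
  if (censored == "floor") {
    for (i in which(rowSums(is.na(mat)) > 0)) {
      obs <- mat[i, ][!is.na(mat[i, ])]
      if (!length(obs)) next
      mat[i, is.na(mat[i, ])] <- min(obs)
    }
    mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  } else {
    mat <- mat[rowSums(is.na(mat)) == 0, , drop = FALSE]
  }
  scoreSets(mat, list(IPSS = feats), ...)[, "IPSS"]
}

#' Read / write gene-set GMT files
#'
#' Standard GMT layout: one set per line, tab-separated
#' \code{name <tab> description <tab> member...}.
#'
#' @param path file path.
#' @return \code{readGmt}: named list of character vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(x) x[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[[`, "", 1L)
  sets
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @param description per-set description column (recycled).
#' @export
writeGmt <- function(sets, path, description = "") {
  lines <- mapply(function(nm, s, d) paste(c(nm, d, s), collapse = "\t"),
                  names(sets), sets, rep_len(description, length(sets)))
  writeLines(lines, path)
  invisible(path)
}
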