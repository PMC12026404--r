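#' Differential expression profile on the log2(TPM+1) scale
#'
#' The input to cytokine activity inference: per-gene difference of
#' log2(TPM+1) between a case and a reference profile, computed on the
#' intersection of gene ids and mean-centered.
#'
#' @param tpmCase,tpmReference named numeric vectors of TPM (or matrices
#'   whose rows are genes; column means are taken).
#' @return named numeric vector y, centered.
#' @export
prepareProfile <- function(tpmCase, tpmReference) {
  toVec <- function(x) if (is.matrix(x)) rowMeans(x) else x
  a <- toVec(tpmCase); b <- toVec(tpmReference)
  genes <- intersect(names(a), names(b))
  if (!length(genes)) stop("prepareProfile: no shared gene ids")
  y <- log2(a[genes] + 1) - log2(b[genes] + 1)
  y - mean(y)
}

#' Ridge regression of a profile on a response-signature matrix
#'
#' Solves \eqn{\beta = (S^\top S + \alpha I)^{-1} S^\top y} after centering
#' the columns of S and y, giving one coefficient per cytokine: the inferred
#' signaling activity.
#'
#' @param S genes x cytokines response matrix.
#' @param y named per-gene differential profile; intersected with the rows
#'   of S (the intersection size is reported via message).
#' @param alpha ridge penalty (default 1e4).
#' @param center center S columns and y before fitting (default TRUE).
#' @return named numeric vector of coefficients, one per cytokine.
#' @export
ridgeFit <- function(S, y, alpha = 1e4, center = TRUE) {
  stopifnot(alpha >= 0)
  S <- as.matrix(S)
  if (!is.null(names(y)) && !is.null(rownames(S))) {
    genes <- intersect(rownames(S), names(y))
    if (!length(genes)) stop("ridgeFit: no shared gene ids")
    if (length(genes) < length(y))
      message("ridgeFit: using ", length(genes), " of ", length(y), " genes")
    S <- S[genes, , drop = FALSE]
    y <- y[genes]
  }
  if (center) {
    S <- sweep(S, 2, colMeans(S))
    y <- y - mean(y)
  }
  G <- crossprod(S) + diag(alpha, ncol(S))
  beta <- tryCatch(solve(G, crossprod(S, y)),
                   error = function(e)
                     stop("ridgeFit: singular system; use alpha > 0 ",
                          "(collinear signature columns)"))
  stats::setNames(as.numeric(beta), colnames(S))
}

#' Cytokine activities with permutation z-scores
#'
#' Ridge coefficients plus permutation-based significance: the standard error
#' of each coefficient is the standard deviation of its value over
#' \code{nPerm} gene-label permutations of y, the z-score is
#' coefficient / SE, and the two-sided p-value is
#' \eqn{(1 + \#\{|\beta_{perm}| \ge |\beta|\})/(1 + n_{perm})} (add-one
#' correction, so p is never 0). With \code{nPerm = 0} the classical
#' linear-model t formulation is used instead. BH adjustment across
#' cytokines.
#'
#' @param S genes x cytokines response matrix.
#' @param y per-gene differential profile.
#' @param alpha ridge penalty (default 1e4).
#' @param nPerm number of permutations (default 1000); 0 selects the t-test.
#' @param seed RNG seed, mandatory when nPerm > 0.
#' @return data.frame: cytokine, beta, se, z, p, adj_p, n_perm.
#' @export
permutationZ <- function(S, y, alpha = 1e4, nPerm = 1000L, seed = NULL) {
  S <- as.matrix(S)
  if (!is.null(names(y)) && !is.null(rownames(S))) {
    genes <- intersect(rownames(S), names(y))
    S <- S[genes, , drop = FALSE]
    y <- y[genes]
  }
  Sc <- sweep(S, 2, colMeans(S))
  yc <- y - mean(y)
  n <- length(yc)
  M <- solve(crossprod(Sc) + diag(alpha, ncol(Sc)))
  beta <- as.numeric(M %*% crossprod(Sc, yc))

  if (nPerm > 0) {
    if (is.null(seed)) stop("permutationZ: seed is mandatory when nPerm > 0")
    withSeed(seed, {
      P <- vapply(seq_len(nPerm), function(i) sample(yc), numeric(n))
    })
    Bperm <- M %*% crossprod(Sc, P)           # cytokines x nPerm
    se <- apply(Bperm, 1, stats::sd)
    # degenerate permutations: a zero coefficient is simply inactive (z = 0);
    # a nonzero one with zero SE is flagged undefined
    z <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, NA_real_))
    pv <- vapply(seq_along(beta), function(j)
      (1 + sum(abs(Bperm[j, ]) >= abs(beta[j]))) / (1 + nPerm), numeric(1))
    pv[is.na(z)] <- NA_real_
  } else {
    fitted <- as.numeric(Sc %*% beta)
    H <- Sc %*% M %*% t(Sc)
    dfres <- n - sum(diag(H))
    sigma2 <- sum((yc - fitted)^2) / dfres
    covB <- sigma2 * M %*% crossprod(Sc) %*% M
    se <- sqrt(diag(covB))
    z <- ifelse(se > 0, beta / se, NA_real_)
    pv <- 2 * stats::pt(abs(z), dfres, lower.tail = FALSE)
  }
  adj <- rep(NA_real_, length(pv))
  ok <- !is.na(pv)
  adj[ok] <- bhAdjust(pv[ok])
  data.frame(cytokine = colnames(S) %||% seq_along(beta),
             beta = beta, se = se, z = z, p = pv, adj_p = adj,
             n_perm = nPerm, stringsAsFactors = FALSE)
}

#' Group-level cytokine activity with significance tiers
#'
#' For each sample group, builds the differential profile against its
#' designated reference group (mean log2(TPM+1) difference), infers
#' activities with \code{\link{permutationZ}}, and assigns star tiers on the
#' BH-adjusted p: \code{*} below 0.1, \code{**} below 0.05, \code{***}
#' below 0.01.
#'
#' @param tpm genes x samples TPM matrix.
#' @param groups character vector of group labels per sample.
#' @param referenceMap named character: for each tested group, its reference
#'   group (e.g. the non-IBD group of the matching tissue). Groups without a
#'   reference are skipped with a warning.
#' @param S response matrix; \code{alpha}, \code{nPerm}, \code{seed} as in
#'   \code{\link{permutationZ}}.
#' @inheritParams permutationZ
#' @return data.frame with one row per (group, cytokine) and a \code{tier}
#'   column.
#' @export
groupActivity <- function(tpm, groups, referenceMap, S, alpha = 1e4,
                          nPerm = 1000L, seed = NULL) {
  out <- list()
  for (g in names(referenceMap)) {
    ref <- referenceMap[[g]]
    if (!any(groups == g) || !any(groups == ref)) {
      warning("groupActivity: group '", g, "' or its reference '", ref,
              "' has no samples; skipped")
      next
    }
    y <- prepareProfile(rowMeans(tpm[, groups == g, drop = FALSE]),
                        rowMeans(tpm[, groups == ref, drop = FALSE]))
    res <- permutationZ(S, y, alpha = alpha, nPerm = nPerm,
                        seed = if (is.null(seed)) NULL else
                          seed + match(g, names(referenceMap)))
    res$group <- g
    res$reference <- ref
    out[[g]] <- res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$tier <- activityTier(res$adj_p)
  res
}

activityTier <- function(adjP) {
  ifelse(is.na(adjP), "",
         ifelse(adjP < 0.01, "***",
                ifelse(adjP < 0.05, "**",
                       ifelse(adjP < 0.1, "*", ""))))
}

#' Normalized weighted-mean activity scores (single-cell style)
#'
#' Per cell and cytokine: raw score
#' \eqn{\sum_g w_g x_g / \sum_g |w_g|} over the cytokine's network genes,
#' normalized against \code{nPerm} gene-label permutations:
#' (raw - mean(permuted raws)) / sd(permuted raws). Cytokines with fewer
#' than 2 network genes present in the matrix are skipped.
#'
#' @param X cells x genes expression matrix.
#' @param network data.frame with columns \code{cytokine}, \code{gene},
#'   \code{weight}.
#' @param nPerm number of permutations (default 100, must be >= 1).
#' @param seed RNG seed.
#' @return list with matrices \code{raw} and \code{normalized}
#'   (cells x cytokines).
#' @export
wmeanActivity <- function(X, network, nPerm = 100L, seed = 1L) {
  stopifnot(nPerm >= 1)
  X <- as.matrix(X)
  genes <- colnames(X)
  cytos <- unique(network$cytokine)
  raw <- norm <- matrix(NA_real_, nrow(X), length(cytos),
                        dimnames = list(rownames(X), cytos))
  withSeed(seed, {
    perms <- lapply(seq_len(nPerm), function(i) sample(ncol(X)))
  })
  for (cy in cytos) {
    net <- network[network$cytokine == cy & network$gene %in% genes, ]
    if (nrow(net) < 2) {
      warning("wmeanActivity: cytokine '", cy,
              "' has fewer than 2 network genes present; skipped")
      next
    }
    w <- numeric(ncol(X))
    w[match(net$gene, genes)] <- net$weight
    denom <- sum(abs(w))
    raw[, cy] <- as.numeric(X %*% w) / denom
    permRaw <- matrix(vapply(perms, function(p) as.numeric(X %*% w[p]) / denom,
                             numeric(nrow(X))), nrow = nrow(X))
    mu <- rowMeans(permRaw)
    sdev <- apply(permRaw, 1, stats::sd)
    norm[, cy] <- ifelse(sdev > 0, (raw[, cy] - mu) / sdev, 0)
  }
  list(raw = raw, normalized = norm)
}
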