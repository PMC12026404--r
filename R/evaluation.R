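#' Pearson correlation on pairwise-complete observations
#'
#' Correlation of two score vectors using only the positions where both are
#' observed, with the two-sided p-value from the t transform. Fewer than 3
#' complete pairs gives an undefined (flagged) result instead of an error.
#'
#' @param x,y numeric vectors of equal length, NA allowed.
#' @return one-row data.frame: n, r, p, defined.
#' @export
pearsonPairwise <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  n <- sum(ok)
  if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
    return(data.frame(n = n, r = NA_real_, p = NA_real_, defined = FALSE))
  }
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  data.frame(n = n, r = unname(ct$estimate), p = ct$p.value, defined = TRUE)
}

#' All-pairs correlation matrix with significance tiers
#'
#' Pairwise-complete Pearson correlations between every pair of score
#' columns, with star tiers on the raw p-value (\code{*} < 0.05,
#' \code{**} < 0.01, \code{***} < 0.001, strict inequalities) and an
#' optional BH-adjusted tier column for matrices with many pairs.
#'
#' @param scores data.frame or matrix, one row per sample, one column per
#'   named score; missing values allowed.
#' @param adjust also report BH-adjusted p over the upper-triangle family
#'   (default TRUE).
#' @return list: \code{r}, \code{p}, \code{n} matrices (symmetric, diagonal
#'   r = 1) and \code{pairs} long data.frame with tiers.
#' @export
correlationMatrix <- function(scores, adjust = TRUE) {
  scores <- as.data.frame(scores)
  stopifnot(ncol(scores) >= 2)
  nm <- colnames(scores)
  k <- length(nm)
  R <- P <- N <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(R) <- 1
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    pp <- pearsonPairwise(scores[[i]], scores[[j]])
    R[i, j] <- R[j, i] <- pp$r
    P[i, j] <- P[j, i] <- pp$p
    N[i, j] <- N[j, i] <- pp$n
    pairs[[length(pairs) + 1L]] <-
      data.frame(score1 = nm[i], score2 = nm[j], n = pp$n, r = pp$r,
                 p = pp$p, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  pairs$tier <- correlationTier(pairs$p)
  if (adjust) {
    ok <- !is.na(pairs$p)
    pairs$adj_p <- NA_real_
    pairs$adj_p[ok] <- bhAdjust(pairs$p[ok])
    pairs$adj_tier <- correlationTier(pairs$adj_p)
  }
  list(r = R, p = P, n = N, pairs = pairs)
}

correlationTier <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Filter a differential-expression table into up/down gene sets
#'
#' Strict thresholds: adjusted p strictly below \code{alpha} and |log2 fold
#' change| strictly above \code{lfcThreshold} (so a gene at exactly the
#' threshold is excluded).
#'
#' @param de data.frame with columns \code{gene} (or rownames),
#'   \code{log2FoldChange}, \code{padj}.
#' @param lfcThreshold log2 fold-change threshold (default 1).
#' @param alpha adjusted-p threshold (default 0.05).
#' @return list: \code{up}, \code{down} character vectors.
#' @export
deFilter <- function(de, lfcThreshold = 1, alpha = 0.05) {
  need <- c("log2FoldChange", "padj")
  if (!all(need %in% colnames(de)))
    stop("deFilter: table must have columns ", paste(need, collapse = ", "))
  genes <- if ("gene" %in% colnames(de)) de$gene else rownames(de)
  sig <- !is.na(de$padj) & de$padj < alpha
  list(up = genes[sig & de$log2FoldChange > lfcThreshold],
       down = genes[sig & de$log2FoldChange < -lfcThreshold])
}

#' Over-representation analysis with fold enrichment
#'
#' For each annotation term, the hypergeometric upper-tail probability of
#' observing at least the realized overlap between the query set and the
#' term's annotated genes within the universe, plus the fold enrichment
#' \eqn{(k/m)/(K/N)}. BH adjustment across terms.
#'
#' @param query character vector, must be a subset of \code{universe}.
#' @param universe character vector of all considered features.
#' @param annotations named list: term -> character vector of annotated
#'   features (intersected with the universe).
#' @return data.frame: term, N, K, m, k, fold_enrichment, p, adj_p.
#' @export
ora <- function(query, universe, annotations) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("ora: query must be a subset of the universe")
  N <- length(universe)
  m <- length(query)
  rows <- lapply(names(annotations), function(term) {
    ann <- intersect(annotations[[term]], universe)
    K <- length(ann)
    k <- length(intersect(ann, query))
    fe <- if (m == 0 || K == 0) 0 else (k / m) / (K / N)
    p <- if (m == 0) 1 else stats::phyper(k - 1, K, N - K, m, lower.tail = FALSE)
    data.frame(term = term, N = N, K = K, m = m, k = k,
               fold_enrichment = fe, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bhAdjust(out$p)
  out
}
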