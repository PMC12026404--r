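# Shared fixtures and independent oracles used across test files.

tinyConfig <- function(seed = 1L, ...) {
  CohortConfig(nPatients = 20L, seed = seed, nProteins = 50L, nGenes = 200L,
               nPlantedProteins = 5L, nPlantedGenes = 20L, featureDim = 8L,
               tilesPerBag = c(5L, 15L), ...)
}

# Independent step-up BH oracle: sort, apply (m/i) p_(i), cumulative minimum
# from the largest rank down, cap at 1, undo the sort.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  stepped <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(stepped)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Independent enrichment-walk oracle: explicit data-frame sort and
# step-by-step loop, no shared code with enrichmentScore.
walkOracle <- function(z, setIdx, tau = 1, mode = "difference") {
  p <- length(z)
  df <- data.frame(i = seq_len(p), z = z, member = seq_len(p) %in% setIdx)
  df <- df[order(-df$z, df$i), ]
  df$r <- abs(p / 2 - seq_len(p))
  m <- sum(df$member)
  denom <- sum(df$r[df$member]^tau)
  level <- 0
  maxPos <- 0
  minNeg <- 0
  for (row in seq_len(p)) {
    if (df$member[row]) {
      level <- level + (if (denom > 0) df$r[row]^tau / denom else 1 / m)
    } else level <- level - 1 / (p - m)
    if (level > maxPos) maxPos <- level
    if (level < minNeg) minNeg <- level
  }
  if (mode == "difference") maxPos + minNeg
  else if (maxPos >= -minNeg) maxPos else minNeg
}

# Rank-based AUC of scores for a binary label.
aucOracle <- function(score, label) {
  r <- rank(score)
  n1 <- sum(label)
  n0 <- sum(!label)
  (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# A degenerate MIL model predicting a constant, for ensemble arithmetic.
constantModel <- function(value, d = 4L) {
  m <- attMILInit(d, attMILParams(embedDim = 2L, attnDim = 2L, seed = 1L))
  m$W1[] <- 0
  m$b1[] <- 0
  m$w2[] <- 0
  m$b2 <- value
  m
}

# Small signal bags without going through the cohort generator: target is
# the lesion fraction, lesions displaced along the first axis.
makeSignalBags <- function(n, d = 16L, shift = 2, seed = 1L, tiles = 20L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    sev <- runif(1)
    x <- matrix(rnorm(tiles * d), tiles, d)
    lesion <- seq_len(tiles) <= round(sev * tiles)
    x[lesion, 1] <- x[lesion, 1] + shift
    list(slide_id = sprintf("S%03d", i), features = x,
         target = mean(lesion), lesion = lesion)
  })
}
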