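#' Hyperparameters for attention-MIL regression
#'
#' Defaults follow the weakly supervised regression setting: learning rate
#' 1e-4, decoupled weight decay 0.01, batch size 1. The epoch count defaults
#' to 25 (no early stopping) and everything is configurable.
#'
#' @param embedDim tile embedding width (default 32).
#' @param attnDim attention hidden width (default 16).
#' @param gated use gated attention (tanh branch modulated by a sigmoid
#'   branch; default TRUE).
#' @param learningRate,weightDecay,batchSize,epochs optimizer settings.
#' @param seed RNG seed controlling initialization and epoch shuffling.
#' @return list of class \code{"attMILParams"}.
#' @export
attMILParams <- function(embedDim = 32L, attnDim = 16L, gated = TRUE,
                         learningRate = 1e-4, weightDecay = 0.01,
                         batchSize = 1L, epochs = 25L, seed = 1L) {
  stopifnot(learningRate > 0, batchSize >= 1)
  structure(list(embedDim = as.integer(embedDim), attnDim = as.integer(attnDim),
                 gated = isTRUE(gated), learningRate = learningRate,
                 weightDecay = weightDecay, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "attMILParams")
}

# Uniform Glorot-style initialization of all weight tensors.
attMILInit <- function(d, params) {
  m <- params$embedDim; k <- params$attnDim
  gl <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  model <- list(
    W1 = gl(d, m), b1 = numeric(m),
    V = gl(m, k), w = as.numeric(gl(k, 1)),
    U = if (params$gated) gl(m, k) else NULL,
    w2 = as.numeric(gl(m, 1)), b2 = 0,
    d = d, params = params)
  class(model) <- "attMILModel"
  model
}

#' @export
print.attMILModel <- function(x, ...) {
  cat("attMILModel: d =", x$d, "-> embed", ncol(x$W1), "-> attn",
      ncol(x$V), if (!is.null(x$U)) "(gated)" else "", "\n")
  invisible(x)
}

#' Forward pass of the attention-MIL regressor
#'
#' Embeds each tile (linear + tanh), scores it with (optionally gated)
#' additive attention, pools the embeddings by the softmax attention weights
#' and maps the bag vector to a scalar prediction:
#' \deqn{h_i = \tanh(W_1^\top x_i + b_1),\quad
#'       u_i = w^\top(\tanh(V^\top h_i) \odot \sigma(U^\top h_i)),\quad
#'       a = \mathrm{softmax}(u),\quad
#'       \hat y = w_2^\top \textstyle\sum_i a_i h_i + b_2.}
#' The prediction is permutation invariant in the tiles and the attention
#' weights sum to 1.
#'
#' @param model a trained (or initialized) \code{attMILModel}.
#' @param x tile feature matrix (n_tiles x d) or a bag list with a
#'   \code{features} element.
#' @return list: \code{prediction} (scalar), \code{attention}
#'   (length-n, sums to 1), plus cached intermediates for the backward pass.
#' @export
attmilForward <- function(model, x) {
  if (is.list(x) && !is.null(x$features)) x <- x$features
  x <- as.matrix(x)
  if (ncol(x) != model$d)
    stop("attmilForward: feature dimension ", ncol(x),
         " does not match model d = ", model$d)
  H <- tanh(sweep(x %*% model$W1, 2, model$b1, "+"))
  Tm <- tanh(H %*% model$V)
  if (!is.null(model$U)) {
    G <- 1 / (1 + exp(-(H %*% model$U)))
    A <- Tm * G
  } else {
    G <- NULL
    A <- Tm
  }
  u <- as.numeric(A %*% model$w)
  a <- exp(u - max(u))
  a <- a / sum(a)
  z <- as.numeric(crossprod(H, a))
  pred <- sum(model$w2 * z) + model$b2
  list(prediction = pred, attention = a,
       cache = list(x = x, H = H, Tm = Tm, G = G, u = u, a = a, z = z))
}

# Gradient of the squared error (pred - y)^2 w.r.t. every parameter.
attmilBackward <- function(model, fw, y) {
  c2 <- fw$cache
  g <- 2 * (fw$prediction - y)
  H <- c2$H; a <- c2$a
  dw2 <- g * c2$z
  db2 <- g
  dz <- g * model$w2                        # m
  da <- as.numeric(H %*% dz)                # n
  dH <- outer(a, dz)                        # n x m
  du <- a * (da - sum(a * da))              # softmax backward
  dA <- outer(du, model$w)                  # n x k
  Aact <- if (is.null(c2$G)) c2$Tm else c2$Tm * c2$G
  dw <- as.numeric(crossprod(Aact, du))     # k
  if (!is.null(model$U)) {
    dT <- dA * c2$G
    dG <- dA * c2$Tm
    dPreG <- dG * c2$G * (1 - c2$G)
    dU <- crossprod(H, dPreG)
    dH <- dH + dPreG %*% t(model$U)
  } else {
    dT <- dA
    dU <- NULL
  }
  dPreT <- dT * (1 - c2$Tm^2)
  dV <- crossprod(H, dPreT)
  dH <- dH + dPreT %*% t(model$V)
  dPreH <- dH * (1 - H^2)
  list(W1 = crossprod(c2$x, dPreH), b1 = colSums(dPreH),
       V = dV, w = dw, U = dU, w2 = dw2, b2 = db2)
}

# One AdamW update of the flat parameter list.
adamwStep <- function(model, grads, state, lr, wd, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    if (is.null(grads[[nm]])) next
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    decay <- if (nm %in% c("b1", "b2")) 0 else wd   # no decay on biases
    model[[nm]] <- model[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                       decay * model[[nm]])
  }
  list(model = model, state = state)
}

#' Train one attention-MIL model
#'
#' Minimizes the mean squared error between bag predictions and targets with
#' AdamW (decoupled weight decay), batch size 1, iterating the bags in a
#' seed-determined shuffled order each epoch. Deterministic given seed and
#' bag order.
#'
#' @param bags list of bags (each with \code{features} n x d and
#'   \code{target} in [0, 1]).
#' @param params an \code{\link{attMILParams}} list.
#' @return trained \code{attMILModel} with a \code{log} data.frame of
#'   per-epoch mean training loss.
#' @export
trainFold <- function(bags, params = attMILParams()) {
  stopifnot(length(bags) >= 1)
  d <- ncol(bags[[1]]$features)
  withSeed(params$seed, {
    model <- attMILInit(d, params)
    zeroLike <- lapply(model[c("W1", "b1", "V", "w", "U", "w2", "b2")],
                       function(p) if (is.null(p)) NULL else p * 0)
    state <- list(t = 0, m = zeroLike, v = zeroLike)
    log <- data.frame(epoch = integer(), loss = numeric())
    for (ep in seq_len(params$epochs)) {
      ord <- sample(length(bags))
      losses <- numeric(length(bags))
      for (ii in seq_along(ord)) {
        b <- bags[[ord[ii]]]
        fw <- attmilForward(model, b$features)
        if (!is.finite(fw$prediction))
          stop("trainFold: non-finite prediction at epoch ", ep,
               " (bag ", b$slide_id %||% ord[ii], ")")
        losses[ii] <- (fw$prediction - b$target)^2
        grads <- attmilBackward(model, fw, b$target)
        upd <- adamwStep(model, grads, state, params$learningRate,
                         params$weightDecay)
        model <- upd$model
        state <- upd$state
      }
      log <- rbind(log, data.frame(epoch = ep, loss = mean(losses)))
    }
    model$log <- log
    model
  })
}

#' Score-stratified k-fold plan
#'
#' Bins the bag targets into \code{nBins} quantile bins and deals each bin's
#' bags (shuffled within bin by the seed) cyclically across the k folds, so
#' the score distribution is consistent across folds: per-bin fold counts
#' differ by at most 1.
#'
#' @param targets numeric vector of bag targets.
#' @param k number of folds (default 5).
#' @param nBins number of quantile bins (default 4).
#' @param seed RNG seed for the within-bin shuffles.
#' @return integer vector of fold assignments in 1..k.
#' @export
stratifiedKfold <- function(targets, k = 5L, nBins = 4L, seed = 1L) {
  n <- length(targets)
  if (n < k) stop("stratifiedKfold: fewer bags than folds")
  brk <- unique(stats::quantile(targets, probs = seq(0, 1, length.out = nBins + 1)))
  bins <- if (length(brk) < 3) rep(1L, n) else
    cut(targets, breaks = brk, include.lowest = TRUE, labels = FALSE)
  fold <- integer(n)
  withSeed(seed, {
    pos <- 0L
    for (bn in sort(unique(bins))) {
      idx <- which(bins == bn)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((pos + seq_along(idx) - 1L) %% k) + 1L
      pos <- pos + length(idx)
    }
  })
  fold
}

#' Cross-validated out-of-fold MIL predictions
#'
#' Trains one model per fold on the complement and predicts the held-out
#' bags, so each bag is predicted exactly once by a model that never saw it.
#'
#' @param bags list of bags.
#' @param params an \code{\link{attMILParams}}; the per-fold training seed is
#'   offset by the fold index.
#' @param plan fold assignment from \code{\link{stratifiedKfold}} (computed
#'   from the targets when absent).
#' @return list: \code{predictions} data.frame (slide_id, fold, target,
#'   prediction), \code{foldR} per-fold Pearson R, \code{pooledR}, and the
#'   per-fold \code{models}.
#' @export
crossValidate <- function(bags, params = attMILParams(), plan = NULL) {
  targets <- vapply(bags, `[[`, numeric(1), "target")
  if (is.null(plan))
    plan <- stratifiedKfold(targets, seed = params$seed)
  k <- max(plan)
  preds <- rep(NA_real_, length(bags))
  models <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- which(plan != f)
    teIdx <- which(plan == f)
    pf <- params
    pf$seed <- params$seed + f
    models[[f]] <- trainFold(bags[trIdx], pf)
    preds[teIdx] <- vapply(bags[teIdx], function(b)
      attmilForward(models[[f]], b$features)$prediction, numeric(1))
  }
  foldR <- vapply(seq_len(k), function(f) {
    idx <- plan == f
    if (stats::sd(targets[idx]) == 0 || stats::sd(preds[idx]) == 0) NA_real_
    else stats::cor(targets[idx], preds[idx])
  }, numeric(1))
  data <- data.frame(
    slide_id = vapply(bags, function(b) b$slide_id %||% NA_character_,
                      character(1)),
    fold = plan, target = targets, prediction = preds,
    stringsAsFactors = FALSE)
  list(predictions = data, foldR = foldR,
       pooledR = stats::cor(targets, preds), models = models)
}

#' Ensemble prediction by arithmetic fold averaging
#'
#' Each model predicts every bag; the slide-level score is the arithmetic
#' mean across models, clipped to [0, 1] for reporting.
#'
#' @param models list of trained \code{attMILModel}s.
#' @param bags list of bags.
#' @param clip clip the averaged predictions to [0, 1] (default TRUE).
#' @return data.frame: slide_id, prediction, plus one column per model.
#' @export
ensemblePredict <- function(models, bags, clip = TRUE) {
  stopifnot(length(models) >= 1)
  per <- vapply(models, function(m)
    vapply(bags, function(b) attmilForward(m, b$features)$prediction,
           numeric(1)), numeric(length(bags)))
  per <- matrix(per, nrow = length(bags))
  avg <- rowMeans(per)
  if (clip) avg <- pmin(pmax(avg, 0), 1)
  out <- data.frame(
    slide_id = vapply(bags, function(b) b$slide_id %||% NA_character_,
                      character(1)),
    prediction = avg, stringsAsFactors = FALSE)
  colnames(per) <- paste0("model", seq_along(models))
  cbind(out, per)
}

#' Attention map of one bag
#'
#' Extracts the per-tile attention of a trained model, min-max rescales it to
#' [0, 1] for display, and flags tiles at or above the display threshold
#' (default 0.4). Bags whose attention is constant (e.g. uniform features)
#' are flagged uninformative.
#'
#' @param model trained \code{attMILModel}.
#' @param bag a bag (list with \code{features}).
#' @param threshold display threshold on the rescaled attention (default 0.4).
#' @param topK number of top-attention tile indices to return (default 10).
#' @return list: attention (softmax weights, sum 1), rescaled, flagged
#'   (logical), topTiles (indices), uninformative (logical).
#' @export
attentionMap <- function(model, bag, threshold = 0.4, topK = 10L) {
  fw <- attmilForward(model, bag)
  a <- fw$attention
  rng <- range(a)
  uninformative <- diff(rng) < .Machine$double.eps * length(a)
  rescaled <- if (uninformative) rep(0, length(a)) else
    (a - rng[1]) / diff(rng)
  if (uninformative)
    warning("attentionMap: attention is (near-)uniform; map uninformative")
  list(attention = a, rescaled = rescaled,
       flagged = rescaled >= threshold,
       topTiles = order(a, decreasing = TRUE)[seq_len(min(topK, length(a)))],
       uninformative = uninformative,
       prediction = fw$prediction)
}
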