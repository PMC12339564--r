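#' Bundle aligned multi-sensor feature channels
#'
#' @param ... named numeric arrays, each `T x J x C` (conventionally
#'   `vision`, `imu`, `pressure`). Matrices (`T x C`) are promoted to
#'   `T x 1 x C`. A modality that was not recorded is simply omitted.
#' @param lambda optional named static mixing coefficients (`>= 0`);
#'   defaults to equal weights.
#' @return A [ModalityBundle-class].
#' @export
modalityBundle <- function(..., lambda = NULL) {
  mods <- list(...)
  if (length(mods) == 1L && is.list(mods[[1L]]) &&
      !is.array(mods[[1L]])) {
    mods <- mods[[1L]]
  }
  mods <- lapply(mods, function(m) {
    if (length(dim(m)) == 2L) array(m, c(nrow(m), 1L, ncol(m)))
    else if (length(dim(m)) == 3L) m
    else stop("modality arrays must be T x C or T x J x C")
  })
  if (is.null(lambda)) {
    lambda <- rep(1 / length(mods), length(mods))
    names(lambda) <- names(mods)
  }
  new("ModalityBundle", modalities = mods, lambda = lambda)
}

#' Modality names present in a bundle
#' @param bundle a [ModalityBundle-class].
#' @return Character vector.
#' @export
modalityNames <- function(bundle) names(bundle@modalities)

#' Static weighted modality mix
#'
#' The fixed-coefficient baseline combination
#' `X_total = sum_i lambda_i X_i`. All modalities must share one shape.
#' All-zero coefficients produce a zero tensor with a warning.
#'
#' @param bundle a [ModalityBundle-class].
#' @param lambda named or positional coefficients; defaults to the
#'   bundle's.
#' @return Combined array with the common modality shape.
#' @export
staticMix <- function(bundle, lambda = NULL) {
  if (is.null(lambda)) lambda <- bundle@lambda
  mods <- bundle@modalities
  if (!is.null(names(lambda)) && all(names(lambda) %in% names(mods))) {
    lambda <- lambda[names(mods)]
  }
  if (length(lambda) != length(mods))
    stop("need one coefficient per modality")
  if (any(lambda < 0)) stop("lambda coefficients must be >= 0")
  dims <- lapply(mods, dim)
  if (length(unique(dims)) != 1L)
    stop("static mixing needs dimension-compatible modalities")
  if (all(lambda == 0)) {
    warning("all static coefficients are zero; returning a zero tensor")
  }
  out <- array(0, dims[[1L]])
  for (i in seq_along(mods)) out <- out + lambda[[i]] * mods[[i]]
  out
}

#' Fusion parameters
#'
#' Per-modality linear projections into a shared embedding space of
#' dimension `d_s`, plus the shared soft scoring function
#' `s_i = w_s' tanh(W_s [x_i, c_t] + b_s)` and the temporal-context window.
#' `W_s` always spans the concatenated `[embedding, context]` input; when
#' no context is supplied the context half sees zeros, which makes the
#' context-free and context-aware scores one formula.
#'
#' @param inputDims named integer vector: channel count per modality.
#' @param sharedDim shared embedding dimension `d_s`, default 8.
#' @param attnDim hidden width of the scoring tanh, default 8.
#' @param contextWindow trailing-mean window `W_c` for the temporal context
#'   vector, in frames; default 10.
#' @param seed RNG seed for all weight draws.
#' @return Object of class `FusionParams`.
#' @export
fusionParams <- function(inputDims, sharedDim = 8L, attnDim = 8L,
                         contextWindow = 10L, seed = 1L) {
  stopifnot(!is.null(names(inputDims)))
  p <- withSeed(seed, {
    proj <- lapply(inputDims, function(d) {
      list(W = glorotUniform(as.integer(d), sharedDim),
           b = rep(0, sharedDim))
    })
    list(projections = proj,
         Ws = glorotUniform(2L * sharedDim, attnDim),
         bs = rep(0, attnDim),
         ws = as.vector(glorotUniform(attnDim, 1L)))
  })
  structure(c(p, list(sharedDim = as.integer(sharedDim),
                      attnDim = as.integer(attnDim),
                      contextWindow = as.integer(contextWindow),
                      inputDims = inputDims, seed = as.integer(seed))),
            class = "FusionParams")
}

#' Project modality features into the shared embedding space
#'
#' Applies each modality's learnable affine map `W x + b` along the channel
#' axis: a `T x J x C_i` array becomes `T x J x d_s`; a plain vector or
#' matrix of channel rows is mapped row-wise.
#'
#' @param bundle a [ModalityBundle-class], or a named list of arrays.
#' @param params a [fusionParams()].
#' @return Named list of embeddings (same leading shape, `d_s` channels).
#' @export
projectModalities <- function(bundle, params) {
  mods <- if (is(bundle, "ModalityBundle")) bundle@modalities else bundle
  out <- lapply(names(mods), function(nm) {
    pr <- params$projections[[nm]]
    if (is.null(pr)) stop("no projection for modality '", nm, "'")
    x <- mods[[nm]]
    if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
    if (length(dim(x)) == 2L) {
      return(sweep(as.matrix(x) %*% pr$W, 2L, pr$b, "+"))
    }
    d <- dim(x)
    flat <- matrix(x, d[1L] * d[2L], d[3L])
    emb <- sweep(flat %*% pr$W, 2L, pr$b, "+")
    array(emb, c(d[1L], d[2L], ncol(pr$W)))
  })
  names(out) <- names(mods)
  out
}

## Scoring core: one embedding vector (d_s) + optional context (d_s) -> scalar.
scoreEmbedding <- function(x, params, context = NULL) {
  if (is.null(context)) context <- rep(0, params$sharedDim)
  h <- tanh(drop(crossprod(params$Ws, c(x, context))) + params$bs)
  sum(params$ws * h)
}

#' Adaptive modality attention weights
#'
#' Soft scoring of each modality's embedding,
#' `s_i = w_s' tanh(W_s [x_i, c_t] + b_s)`, normalized by softmax so the
#' weights are strictly positive and sum to one. A modality marked missing
#' has its score masked to `-Inf` before the softmax, renormalizing over
#' the present modalities.
#'
#' @param embeddings named list of per-modality embedding vectors (length
#'   `d_s`), or an `M x d_s` matrix.
#' @param params a [fusionParams()].
#' @param context optional temporal context vector `c_t` (length `d_s`).
#' @param missing character vector of modality names to mask out.
#' @return Named weight vector `alpha` (sums to 1).
#' @export
modalityWeights <- function(embeddings, params, context = NULL,
                            missing = character(0)) {
  if (is.matrix(embeddings)) {
    embeddings <- split(embeddings, row(embeddings))
  }
  s <- vapply(embeddings, scoreEmbedding, numeric(1),
              params = params, context = context)
  if (length(missing) > 0L) s[names(s) %in% missing] <- -Inf
  if (all(!is.finite(s))) stop("no modality left after masking")
  alpha <- softmaxRows(s)
  names(alpha) <- names(embeddings)
  alpha
}

#' Attention-weighted modality fusion
#'
#' Weighted summation of the modality embeddings,
#' `X_fused = sum_i alpha_i X_i`. With weights on the simplex every fused
#' coordinate stays inside the per-coordinate range of the inputs, and the
#' result is invariant to permuting modalities together with their
#' weights.
#'
#' @param embeddings list of co-shaped arrays (one per modality).
#' @param alpha weight vector, `sum(alpha) = 1`.
#' @return Fused array of the common shape.
#' @export
fuse <- function(embeddings, alpha) {
  if (length(embeddings) != length(alpha))
    stop("need one weight per modality")
  if (!is.null(names(alpha)) && !is.null(names(embeddings)))
    alpha <- alpha[names(embeddings)]
  out <- embeddings[[1L]] * 0
  for (i in seq_along(embeddings)) out <- out + alpha[[i]] * embeddings[[i]]
  out
}

#' Temporal context vector
#'
#' Causal summary of the fusion history: the mean of the previous
#' `min(t - 1, W_c)` fused frame vectors, and the zero vector at the first
#' frame (no history).
#'
#' @param history matrix of fused frame vectors so far (rows = frames
#'   `1..t-1`), or `NULL` at the first frame.
#' @param contextWindow trailing window `W_c` in frames.
#' @param dim embedding dimension (used when `history` is empty).
#' @return Context vector `c_t` of length `d_s`.
#' @export
temporalContext <- function(history, contextWindow, dim = NULL) {
  if (is.null(history) || nrow(as.matrix(history)) == 0L) {
    if (is.null(dim)) stop("need dim when history is empty")
    return(rep(0, dim))
  }
  history <- as.matrix(history)
  n <- nrow(history)
  idx <- seq.int(max(1L, n - contextWindow + 1L), n)
  colMeans(history[idx, , drop = FALSE])
}

#' Adaptive multi-modal fusion over a sequence
#'
#' The full per-frame fusion pass: project each modality into the shared
#' space, score them against the running temporal context, softmax into
#' adaptive weights, and fuse per joint. Weights are shared across frames;
#' only the context changes over time.
#'
#' @param bundle a [ModalityBundle-class] with `T x J x C` modalities.
#' @param params a [fusionParams()].
#' @param useContext include the temporal context vector in scoring
#'   (default `TRUE`).
#' @param missing modality names to mask out at inference.
#' @return List with `fused` (`T x J x d_s`), `alpha` (`T x M` per-frame
#'   weights), `context` (`T x d_s` contexts used).
#' @export
adaptiveFuse <- function(bundle, params, useContext = TRUE,
                     missing = character(0)) {
  emb <- projectModalities(bundle, params)
  fuseEmbeddings(emb, params, useContext = useContext, missing = missing)
}

## Fusion pass over precomputed embeddings (shared by adaptiveFuse and the
## scoring-head fitting loop, where projections are fixed).
fuseEmbeddings <- function(emb, params, useContext = TRUE,
                           missing = character(0)) {
  T <- dim(emb[[1L]])[1L]; Jn <- dim(emb[[1L]])[2L]
  ds <- params$sharedDim
  M <- length(emb)
  fused <- array(0, c(T, Jn, ds))
  alphaMat <- matrix(0, T, M, dimnames = list(NULL, names(emb)))
  ctxMat <- matrix(0, T, ds)
  pooledHistory <- matrix(0, 0, ds)
  for (t in seq_len(T)) {
    ctx <- if (useContext) {
      temporalContext(pooledHistory, params$contextWindow, dim = ds)
    } else NULL
    ## frame-pooled embedding per modality feeds the scalar scoring
    frameEmb <- lapply(emb, function(e) colMeans(matrix(e[t, , ], Jn, ds)))
    alpha <- modalityWeights(frameEmb, params, context = ctx,
                             missing = missing)
    frameFused <- matrix(0, Jn, ds)
    for (i in seq_along(emb)) {
      frameFused <- frameFused + alpha[[i]] * matrix(emb[[i]][t, , ], Jn, ds)
    }
    fused[t, , ] <- frameFused
    alphaMat[t, ] <- alpha
    if (useContext) ctxMat[t, ] <- ctx
    pooledHistory <- rbind(pooledHistory,
                           colMeans(matrix(fused[t, , ], Jn, ds)))
  }
  list(fused = fused, alpha = alphaMat, context = ctxMat)
}

#' Fit the fusion scoring function to favor reliable modalities
#'
#' Trains the shared scoring parameters (`w_s`, `W_s`, `b_s`) by gradient
#' descent on the mean squared error between the fused embedding and a
#' clean target embedding, using central finite-difference gradients (the
#' scoring head has only a handful of parameters). Projections stay fixed.
#' After fitting on a corpus where one modality is noisier than the rest,
#' that modality's average attention weight drops — the adaptive behavior
#' the fusion strategy exists for.
#'
#' @param bundle a [ModalityBundle-class].
#' @param target clean target array, `T x J x d_s` (same shape as the
#'   fused output).
#' @param params a [fusionParams()]; returned updated.
#' @param epochs gradient steps, default 40.
#' @param lr learning rate, default 0.5.
#' @param useContext score with the temporal context, default `FALSE`
#'   (context-free fitting is cheaper and the weights are shared anyway).
#' @return List with `params` (updated), `loss` (per-epoch), `alpha`
#'   (final mean weights per modality).
#' @export
trainFusionWeights <- function(bundle, target, params, epochs = 40,
                               lr = 0.5, useContext = FALSE) {
  packScore <- function(p) c(p$ws, as.vector(p$Ws), p$bs)
  unpackScore <- function(p, theta) {
    nw <- length(p$ws); nW <- length(p$Ws)
    p$ws <- theta[seq_len(nw)]
    p$Ws <- matrix(theta[nw + seq_len(nW)], nrow(p$Ws), ncol(p$Ws))
    p$bs <- theta[nw + nW + seq_along(p$bs)]
    p
  }
  emb <- projectModalities(bundle, params)
  objective <- function(theta) {
    p <- unpackScore(params, theta)
    out <- fuseEmbeddings(emb, p, useContext = useContext)
    mean((out$fused - target)^2)
  }
  theta <- packScore(params)
  losses <- numeric(epochs)
  h <- 1e-4
  for (e in seq_len(epochs)) {
    g <- vapply(seq_along(theta), function(i) {
      tp <- theta; tm <- theta
      tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      (objective(tp) - objective(tm)) / (2 * h)
    }, numeric(1))
    theta <- theta - lr * g
    losses[e] <- objective(theta)
  }
  params <- unpackScore(params, theta)
  out <- adaptiveFuse(bundle, params, useContext = useContext)
  list(params = params, loss = losses, alpha = colMeans(out$alpha))
}
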