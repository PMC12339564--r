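#' Sinusoidal positional encoding
#'
#' The fixed sine/cosine encoding that stamps absolute temporal order onto
#' per-frame features: `PE[t, 2i-1] = sin(t / base^{2(i-1)/d})` and
#' `PE[t, 2i] = cos(t / base^{2(i-1)/d})` with frame index `t` running from
#' 0. Every entry lies in `[-1, 1]`. Odd `d` is handled by computing one
#' extra column internally and dropping it.
#'
#' @param T number of frames.
#' @param d feature dimension.
#' @param base frequency base, default 10000.
#' @return `T x d` matrix.
#' @export
positionalEncoding <- function(T, d, base = 10000) {
  dEff <- if (d %% 2L == 1L) d + 1L else d
  nPairs <- dEff %/% 2L
  tIdx <- seq_len(T) - 1L
  freq <- base^(-(2 * (seq_len(nPairs) - 1L)) / dEff)
  angles <- outer(tIdx, freq)           # T x nPairs
  PE <- matrix(0, T, dEff)
  PE[, 2L * seq_len(nPairs) - 1L] <- sin(angles)
  PE[, 2L * seq_len(nPairs)] <- cos(angles)
  PE[, seq_len(d), drop = FALSE]
}

#' Add positional encoding to a feature sequence
#'
#' @param X `T x d` per-frame features.
#' @param base frequency base, default 10000.
#' @return `X + PE`, same shape.
#' @export
addPositionalEncoding <- function(X, base = 10000) {
  X <- as.matrix(X)
  X + positionalEncoding(nrow(X), ncol(X), base)
}

#' Temporal attention parameters
#'
#' Learnable projections `W_Q, W_K, W_V` from the frame-feature dimension
#' `d` to a shared latent dimension `d'`, Glorot-initialized under a seed,
#' plus the stride `k` used by the contrastive loss.
#'
#' @param d input feature dimension.
#' @param dPrime latent dimension `d'`, default 64.
#' @param k contrastive temporal stride (frames), default 5.
#' @param seed RNG seed.
#' @return Object of class `TemporalAttentionParams`.
#' @export
temporalAttentionParams <- function(d, dPrime = 64L, k = 5L, seed = 1L) {
  stopifnot(dPrime >= 1L, k >= 1L)
  W <- withSeed(seed, list(
    WQ = glorotUniform(d, dPrime),
    WK = glorotUniform(d, dPrime),
    WV = glorotUniform(d, dPrime)
  ))
  structure(c(W, list(d = as.integer(d), dPrime = as.integer(dPrime),
                      k = as.integer(k), seed = as.integer(seed))),
            class = "TemporalAttentionParams")
}

#' Scaled dot-product temporal self-attention
#'
#' Projects the frame sequence into queries, keys and values, forms the
#' row-stochastic attention matrix `A = softmax(Q K' / sqrt(d'))`, and
#' returns the contextually mixed representation `Z = A V`. Every frame
#' attends over the whole sequence (no causal mask; sequences here are
#' short).
#'
#' @param X `T x d` frame features (positional encoding should already be
#'   added if order matters).
#' @param params a [temporalAttentionParams()].
#' @return List with `A` (`T x T`, rows sum to 1, strictly positive) and
#'   `Z` (`T x d'`).
#' @export
temporalAttention <- function(X, params) {
  X <- as.matrix(X)
  stopIfNotFinite(X, "attention input")
  if (ncol(X) != params$d)
    stop("input has ", ncol(X), " channels, params expect ", params$d)
  Q <- X %*% params$WQ
  K <- X %*% params$WK
  V <- X %*% params$WV
  A <- softmaxRows(Q %*% t(K) / sqrt(params$dPrime))
  list(A = A, Z = A %*% V)
}

#' Temporal smoothness loss on attention features
#'
#' Sum of squared frame-to-frame feature differences,
#' `sum_t ||Z_t - Z_{t+1}||^2`: zero for a constant sequence, growing with
#' high-frequency fluctuation. Nonnegative by construction.
#'
#' @param Z `T x d'` feature sequence.
#' @return Scalar `>= 0`.
#' @export
temporalSmoothnessLoss <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 2L) return(0)
  d <- Z[-1L, , drop = FALSE] - Z[-nrow(Z), , drop = FALSE]
  sum(d * d)
}

#' Temporal contrastive loss at stride k
#'
#' `sum_{t=1}^{T-k} (1 - cos(Z_t, Z_{t+k}))`: rewards representations that
#' stay directionally aligned across a lag of `k` frames (zero when the
#' sequence is periodic with period `k`), bounded by `2 (T - k)`.
#'
#' @param Z `T x d'` feature sequence with no zero-norm rows.
#' @param k temporal stride, `1 <= k < T`.
#' @return Scalar in `[0, 2(T - k)]`.
#' @export
temporalContrastiveLoss <- function(Z, k) {
  Z <- as.matrix(Z)
  T <- nrow(Z)
  stopifnot(k >= 1L)
  if (T <= k) stop("need T > k (T = ", T, ", k = ", k, ")")
  nrm <- sqrt(rowSums(Z * Z))
  zero <- which(nrm == 0)
  if (length(zero) > 0L)
    stop("zero-norm feature row at frame ", zero[1L],
         "; cosine similarity undefined")
  idx <- seq_len(T - k)
  cosSim <- rowSums(Z[idx, , drop = FALSE] * Z[idx + k, , drop = FALSE]) /
    (nrm[idx] * nrm[idx + k])
  ## clamp against floating-point overshoot so aligned rows cost exactly 0
  cosSim <- pmin(pmax(cosSim, -1), 1)
  sum(1 - cosSim)
}

#' Frame-pool joint features
#'
#' Collapses the joint axis of a `T x J x F` tensor to one vector per frame
#' for the temporal module, by mean over joints (default) or concatenation.
#'
#' @param H `T x J x F` array.
#' @param method `"mean"` (default) or `"concat"`.
#' @return `T x F` (mean) or `T x (J*F)` (concat) matrix.
#' @export
poolJoints <- function(H, method = c("mean", "concat")) {
  method <- match.arg(method)
  stopifnot(length(dim(H)) == 3L)
  if (method == "mean") {
    apply(H, c(1L, 3L), mean)
  } else {
    matrix(aperm(H, c(1L, 3L, 2L)), nrow = dim(H)[1L])
  }
}
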