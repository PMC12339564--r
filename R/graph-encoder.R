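#' Construct a stack of graph-convolution layers
#'
#' Seeded Glorot-uniform weight matrices chaining the given dimensions,
#' with a named activation (ReLU by default; identity available so tests
#' can check the bare linear operator).
#'
#' @param dims integer vector of layer widths, length `nLayers + 1`:
#'   `dims[1]` is the input feature dimension.
#' @param activation `"relu"` (default), `"identity"` or `"tanh"`.
#' @param seed RNG seed for the weight draws.
#' @return An object of class `GCNStack` (list of weights + activation).
#' @export
gcnStack <- function(dims, activation = "relu", seed = 1L) {
  stopifnot(length(dims) >= 2L)
  weights <- withSeed(seed, {
    lapply(seq_len(length(dims) - 1L), function(l) {
      glorotUniform(dims[l], dims[l + 1L])
    })
  })
  structure(list(weights = weights, activation = activation,
                 dims = as.integer(dims), seed = as.integer(seed)),
            class = "GCNStack")
}

#' Graph-convolution forward pass
#'
#' Applies `H <- act(Ahat %*% H %*% W)` layer by layer, where `Ahat` is the
#' degree-normalized (optionally self-looped) skeleton adjacency. Each node
#' aggregates its neighbors' features through the shared weights, so the
#' operator is equivariant to joint relabeling. A `T x J x F` tensor is
#' processed frame by frame with the same weights (no cross-frame mixing;
#' temporal structure is the attention module's job).
#'
#' @param H node features, `J x F` matrix or `T x J x F` array.
#' @param Ahat `J x J` normalized adjacency (or a [SkeletonGraph-class]).
#' @param stack a [gcnStack()].
#' @return Features with the final layer width, same leading shape as `H`.
#' @export
gcnForward <- function(H, Ahat, stack) {
  if (is(Ahat, "SkeletonGraph")) Ahat <- Ahat@normAdjacency
  act <- getActivation(stack$activation)
  forwardFrame <- function(h) {
    for (l in seq_along(stack$weights)) {
      W <- stack$weights[[l]]
      if (ncol(h) != nrow(W))
        stop("layer ", l, ": features have ", ncol(h),
             " channels but weights expect ", nrow(W))
      h <- act(Ahat %*% h %*% W)
    }
    h
  }
  if (length(dim(H)) == 3L) {
    T <- dim(H)[1L]
    outDim <- ncol(stack$weights[[length(stack$weights)]])
    out <- array(0, c(T, dim(H)[2L], outDim))
    for (t in seq_len(T)) out[t, , ] <- forwardFrame(H[t, , , drop = TRUE])
    return(out)
  }
  forwardFrame(as.matrix(H))
}

#' Spatial attention parameters
#'
#' The two learnable linear maps (`phi`, `psi`) from node-feature dimension
#' to a shared attention dimension, initialized Glorot-uniform under a seed.
#'
#' @param featureDim node feature width.
#' @param attnDim shared attention dimension `d_a`.
#' @param seed RNG seed.
#' @return Object of class `SpatialAttentionParams`.
#' @export
spatialAttentionParams <- function(featureDim, attnDim = 8L, seed = 1L) {
  maps <- withSeed(seed, list(
    phi = glorotUniform(featureDim, attnDim),
    psi = glorotUniform(featureDim, attnDim)
  ))
  structure(c(maps, list(featureDim = as.integer(featureDim),
                         attnDim = as.integer(attnDim),
                         seed = as.integer(seed))),
            class = "SpatialAttentionParams")
}

#' Joint-level spatial attention over the skeleton
#'
#' Assigns each joint a softmax-normalized weight over its anatomical
#' neighborhood (neighbors plus the joint itself) from the bilinear logit
#' `phi(F_i)' psi(F_j)`, then aggregates the neighbors' raw features with
#' those weights. Rows of the attention matrix sum to one, and a joint's
#' output depends only on features inside its neighborhood.
#'
#' @param F node features, `J x F` matrix.
#' @param graph a [SkeletonGraph-class] (defines the neighborhoods).
#' @param params a [spatialAttentionParams()].
#' @param temperature divides the logits; default 1 (the raw bilinear
#'   form).
#' @return List with `alpha` (`J x J`, zero outside neighborhoods, rows sum
#'   to 1) and `H` (`J x F` aggregated features).
#' @export
spatialAttention <- function(F, graph, params, temperature = 1) {
  F <- as.matrix(F)
  J <- graph@nJoints
  if (nrow(F) != J) stop("features must have one row per joint")
  phiF <- F %*% params$phi
  psiF <- F %*% params$psi
  logits <- (phiF %*% t(psiF)) / temperature
  nb <- neighborhoods(graph)
  alpha <- matrix(0, J, J)
  H <- matrix(0, J, ncol(F))
  for (i in seq_len(J)) {
    idx <- nb[[i]]
    w <- softmaxRows(logits[i, idx])
    alpha[i, idx] <- w
    H[i, ] <- crossprod(F[idx, , drop = FALSE], w)
  }
  list(alpha = alpha, H = H)
}
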