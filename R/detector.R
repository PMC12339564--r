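#' Static biomechanical threshold detector
#'
#' The classical baseline: a sigmoid over a weighted sum of per-joint
#' acceleration magnitudes, `p = sigmoid(sum_j w_j ||A_j||)`, with
#' `||A_j||` the time-mean of the per-frame acceleration norms of joint
#' `j` (the norm carries no time index, so the time average is the natural
#' reading). Monotone nondecreasing in any acceleration scale-up when the
#' weights are nonnegative.
#'
#' @param A `T x J x D` acceleration tensor (or a
#'   [KinematicFeatures-class]).
#' @param w length-J joint importance weights.
#' @return Injury probability in (0, 1).
#' @export
baselineThresholdDetector <- function(A, w) {
  if (is(A, "KinematicFeatures")) A <- A@acceleration
  stopifnot(length(dim(A)) == 3L)
  meanNorm <- colMeans(normTJ(A))
  if (length(w) != length(meanNorm))
    stop("need one weight per joint")
  sigmoid(sum(w * meanNorm))
}

#' Two-layer classifier head parameters
#'
#' A single-hidden-layer perceptron with ReLU hidden units and a sigmoid
#' output: the injury classification function applied per frame to the
#' concatenation of refined temporal features and anomaly scores.
#'
#' @param inputDim input feature width.
#' @param hiddenDim hidden width, default 16; forced to `2 * inputDim`
#'   for the `"linear-pairs"` init.
#' @param seed RNG seed for Glorot initialization.
#' @param init `"glorot"` (random) or `"linear-pairs"`: the hidden layer
#'   is the fixed signed rectification basis `W1 = [I, -I]` with zero
#'   output weights, so `relu(x) - relu(-x) = x` lets the output layer
#'   express any linear frame scorer exactly (plus rectified magnitude
#'   terms), and fitting the output layer alone is convex.
#' @return Object of class `ClassifierHead`.
#' @export
classifierHead <- function(inputDim, hiddenDim = 16L, seed = 1L,
                           init = c("glorot", "linear-pairs")) {
  init <- match.arg(init)
  inputDim <- as.integer(inputDim)
  if (init == "linear-pairs") {
    hiddenDim <- 2L * inputDim
    p <- list(W1 = cbind(diag(inputDim), -diag(inputDim)),
              b1 = rep(0, hiddenDim),
              w2 = rep(0, hiddenDim),
              b2 = 0)
  } else {
    p <- withSeed(seed, list(
      W1 = glorotUniform(inputDim, as.integer(hiddenDim)),
      b1 = rep(0, hiddenDim),
      w2 = as.vector(glorotUniform(as.integer(hiddenDim), 1L)),
      b2 = 0
    ))
  }
  structure(c(p, list(inputDim = inputDim,
                      hiddenDim = as.integer(hiddenDim),
                      seed = as.integer(seed), init = init)),
            class = "ClassifierHead")
}

## Forward pass of the head on a T x F feature matrix.
## Returns frame probabilities plus the intermediates backprop needs.
headForward <- function(X, head) {
  H <- X %*% head$W1
  H <- sweep(H, 2L, head$b1, "+")
  Hr <- pmax(H, 0)
  a <- drop(Hr %*% head$w2) + head$b2
  P <- sigmoid(a)
  list(P = P, Hr = Hr, mask = H > 0)
}

#' Classify a sequence from per-frame features
#'
#' Runs the two-layer perceptron on each frame's feature vector, producing
#' per-frame injury probabilities; the sequence-level probability is the
#' temporal mean and the binary label is its comparison with the decision
#' threshold.
#'
#' @param features `T x F` matrix (refined temporal embedding concatenated
#'   with the per-joint anomaly scores).
#' @param head a [classifierHead()].
#' @param threshold sequence decision threshold, default 0.5.
#' @return A [Predictions-class].
#' @export
classify <- function(features, head, threshold = 0.5) {
  features <- as.matrix(features)
  if (ncol(features) != head$inputDim)
    stop("features have ", ncol(features), " channels but the head expects ",
         head$inputDim)
  P <- headForward(features, head)$P
  sp <- mean(P)
  new("Predictions", frameProb = as.numeric(P), seqProb = sp,
      label = as.integer(sp >= threshold), threshold = threshold)
}

## Clipped binary cross-entropy (natural log), safe at p in {0, 1}.
crossEntropy <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Energy-regularized classification loss
#'
#' Cross-entropy plus a penalty on total energy deviation,
#' `L = CE(p, y) + lambda * sum_{t,j} S[t, j]` — discouraging solutions
#' that tolerate large unexplained energy excursions.
#'
#' @param p predicted probability (sequence-level or per-frame vector with
#'   matching `y`).
#' @param y 0/1 label(s).
#' @param S `T x J` anomaly score matrix.
#' @param lambda regularization strength `>= 0`.
#' @return Scalar loss.
#' @export
lossRegularized <- function(p, y, S, lambda) {
  stopifnot(lambda >= 0)
  crossEntropy(p, y) + lambda * sum(S)
}

#' Temporal consistency loss
#'
#' Squared frame-to-frame prediction differences,
#' `sum_t (P_t - P_{t+1})^2`: pushes the detector towards sustained,
#' stable injury probabilities rather than one-frame spikes.
#'
#' @param P per-frame probability vector.
#' @return Scalar `>= 0`.
#' @export
consistencyLoss <- function(P) {
  if (length(P) < 2L) return(0)
  sum(diff(P)^2)
}

#' Deviation-weighted consistency loss
#'
#' The consistency loss with each term scaled by
#' `alpha_t = 1 + gamma * |P_t - P_{t+1}|`, growing with the deviation so
#' large prediction jumps are penalized more than proportionally. At
#' `gamma = 0` it reduces exactly to [consistencyLoss()].
#'
#' @param P per-frame probability vector.
#' @param gamma weighting slope `>= 0`, default 1.
#' @return Scalar `>= 0`.
#' @export
weightedConsistencyLoss <- function(P, gamma = 1) {
  stopifnot(gamma >= 0)
  if (length(P) < 2L) return(0)
  d <- diff(P)
  sum((1 + gamma * abs(d)) * d^2)
}

#' L1 temporal smoothing loss
#'
#' `sum_t |P_t - P_{t-1}|`: the total variation of the prediction
#' sequence. A monotone ramp from 0 to 1 costs exactly 1 regardless of how
#' many steps it takes.
#'
#' @param P per-frame probability vector.
#' @return Scalar `>= 0`.
#' @export
smoothingLoss <- function(P) {
  if (length(P) < 2L) return(0)
  sum(abs(diff(P)))
}

#' Lag-k temporal regularization loss
#'
#' `sum_{t=1}^{T-k} (P_t - P_{t+k})^2`: consistency across a longer
#' horizon of `k` frames, aligning predictions with sustained injury
#' dynamics. An empty sum (`k >= T`) returns 0 with a warning.
#'
#' @param P per-frame probability vector.
#' @param k lag in frames, `>= 1`.
#' @return Scalar `>= 0`.
#' @export
temporalRegLoss <- function(P, k) {
  stopifnot(k >= 1L)
  T <- length(P)
  if (k >= T) {
    warning("lag k = ", k, " >= T = ", T, "; empty sum, returning 0")
    return(0)
  }
  idx <- seq_len(T - k)
  sum((P[idx] - P[idx + k])^2)
}

#' Loss weights for detector training
#'
#' @param lambda energy-regularizer weight (on `sum S`), default 0.
#' @param lambda1 consistency weight, default 0.
#' @param lambda2 smoothing weight, default 0.
#' @param lambda3 lag-k regularization weight, default 0.
#' @param k lag for the regularization term, default 5.
#' @param gamma slope of the deviation weighting (0 = unweighted
#'   consistency), default 0.
#' @return Object of class `LossWeights`.
#' @export
lossWeights <- function(lambda = 0, lambda1 = 0, lambda2 = 0, lambda3 = 0,
                        k = 5L, gamma = 0) {
  vals <- c(lambda, lambda1, lambda2, lambda3, gamma)
  if (any(vals < 0)) stop("loss weights must be >= 0")
  structure(list(lambda = lambda, lambda1 = lambda1, lambda2 = lambda2,
                 lambda3 = lambda3, k = as.integer(k), gamma = gamma),
            class = "LossWeights")
}

#' Combined training loss with per-term breakdown
#'
#' `L_total = L_class + lambda1 L_consistency + lambda2 L_smoothing +
#' lambda3 L_reg`, where the classification term is cross-entropy
#' optionally augmented with the energy-deviation regularizer (weight
#' `lambda`), the consistency term uses the deviation weighting when
#' `gamma > 0`, and the regularization term compares predictions `k`
#' frames apart. Linear in each weight; always `>= L_class`.
#'
#' @param P per-frame probability vector.
#' @param y 0/1 sequence label.
#' @param weights a [lossWeights()].
#' @param S optional `T x J` anomaly scores for the energy regularizer.
#' @param classification `"sequence"` (cross-entropy on the pooled mean
#'   probability, the default) or `"frame"` (mean per-frame cross-entropy
#'   against the sequence label).
#' @return List with `total` and `breakdown` (named per-term values).
#' @export
totalLoss <- function(P, y, weights, S = NULL,
                      classification = c("sequence", "frame")) {
  classification <- match.arg(classification)
  cls <- if (classification == "sequence") {
    crossEntropy(mean(P), y)
  } else {
    crossEntropy(P, rep(y, length(P)))
  }
  if (weights$lambda > 0) {
    if (is.null(S)) stop("lambda > 0 requires anomaly scores S")
    cls <- cls + weights$lambda * sum(S)
  }
  cons <- if (weights$gamma > 0) {
    weightedConsistencyLoss(P, weights$gamma)
  } else {
    consistencyLoss(P)
  }
  smo <- smoothingLoss(P)
  reg <- if (weights$lambda3 > 0) temporalRegLoss(P, weights$k) else {
    if (weights$k < length(P)) temporalRegLoss(P, weights$k) else 0
  }
  total <- cls + weights$lambda1 * cons + weights$lambda2 * smo +
    weights$lambda3 * reg
  list(total = total,
       breakdown = c(classification = cls, consistency = cons,
                     smoothing = smo, reg = reg))
}

## ---- gradients ----

## dL/dP for the temporal terms (consistency, weighted consistency,
## smoothing, lag-k), all differentiable a.e.; smoothing uses the sign
## subgradient.
temporalLossGrad <- function(P, weights) {
  T <- length(P)
  g <- numeric(T)
  if (T >= 2L) {
    d <- P[seq_len(T - 1L)] - P[2L:T]     # P_t - P_{t+1}
    if (weights$lambda1 > 0) {
      gd <- if (weights$gamma > 0) {
        2 * d + 3 * weights$gamma * abs(d) * d
      } else {
        2 * d
      }
      gd <- weights$lambda1 * gd
      g[seq_len(T - 1L)] <- g[seq_len(T - 1L)] + gd
      g[2L:T] <- g[2L:T] - gd
    }
    if (weights$lambda2 > 0) {
      gs <- weights$lambda2 * sign(d)
      g[seq_len(T - 1L)] <- g[seq_len(T - 1L)] + gs
      g[2L:T] <- g[2L:T] - gs
    }
  }
  if (weights$lambda3 > 0 && weights$k < T) {
    idx <- seq_len(T - weights$k)
    dk <- P[idx] - P[idx + weights$k]
    g[idx] <- g[idx] + weights$lambda3 * 2 * dk
    g[idx + weights$k] <- g[idx + weights$k] - weights$lambda3 * 2 * dk
  }
  g
}

## Analytic gradient of the sequence loss w.r.t. head parameters.
## classification = "sequence": cross-entropy on the pooled (mean) frame
## probability; "frame": mean per-frame cross-entropy against the sequence
## label (the weak-label reading of a per-frame injury probability).
headGradient <- function(X, y, head, weights,
                         classification = c("frame", "sequence")) {
  classification <- match.arg(classification)
  fw <- headForward(X, head)
  P <- fw$P
  T <- length(P)
  eps <- 1e-12
  if (classification == "sequence") {
    pbar <- min(max(mean(P), eps), 1 - eps)
    gP <- rep((pbar - y) / (pbar * (1 - pbar)) / T, T)
  } else {
    Pc <- pmin(pmax(P, eps), 1 - eps)
    gP <- (Pc - y) / (Pc * (1 - Pc)) / T
  }
  gP <- gP + temporalLossGrad(P, weights)
  delta <- gP * P * (1 - P)                       # dL/da_t
  gW2 <- drop(crossprod(fw$Hr, delta))
  gb2 <- sum(delta)
  gH <- (delta %*% t(head$w2)) * fw$mask          # T x hidden
  gW1 <- crossprod(X, gH)
  gb1 <- colSums(gH)
  loss <- totalLoss(P, y, weights, classification = classification)
  list(gW1 = gW1, gb1 = gb1, gW2 = gW2, gb2 = gb2,
       loss = loss$total, breakdown = loss$breakdown, P = P)
}

## Minimal Adam optimizer state and step.
adamInit <- function(shapes) {
  list(m = lapply(shapes, function(s) s * 0),
       v = lapply(shapes, function(s) s * 0), t = 0L)
}

## weightDecay is decoupled (applied directly to the parameters, not fed
## through the adaptive normalizer), so the decay strength is not distorted
## by the per-parameter gradient scale.
adamStep <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, clipNorm = 10, weightDecay = 0) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
  if (gnorm > clipNorm) grads <- lapply(grads, function(g) g * clipNorm / gnorm)
  state$t <- state$t + 1L
  for (i in seq_along(params)) {
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * grads[[i]]
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * grads[[i]]^2
    mhat <- state$m[[i]] / (1 - beta1^state$t)
    vhat <- state$v[[i]] / (1 - beta2^state$t)
    params[[i]] <- params[[i]] -
      lr * (mhat / (sqrt(vhat) + eps) + weightDecay * params[[i]])
  }
  list(state = state, params = params)
}

#' Binary classification metrics
#'
#' Accuracy, recall, F1 and AUC for 0/1 labels. AUC is the rank statistic:
#' the probability that a random positive scores above a random negative,
#' ties counted half (equivalent to the Mann-Whitney U normalization).
#'
#' @param scores numeric predicted scores or probabilities.
#' @param labels 0/1 true labels.
#' @param threshold decision threshold on the scores, default 0.5.
#' @return Named list: `accuracy`, `recall`, `f1`, `auc`.
#' @export
evaluateDetector <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  acc <- (tp + tn) / length(labels)
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0) {
    2 * prec * rec / (prec + rec)
  } else NA_real_
  auc <- rankAUC(scores, labels)
  list(accuracy = acc, recall = rec, f1 = f1, auc = auc)
}

#' Rank-statistic AUC
#'
#' @param scores numeric scores.
#' @param labels 0/1 labels (needs at least one of each class).
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
rankAUC <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}
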