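#' Detector configuration
#'
#' Hyperparameters of the end-to-end detector: encoder widths, attention
#' latent size, loss weights, fitting settings and thresholds. The head is
#' fitted by a convex validation-selected warm start followed by optional
#' Adam fine-tuning (learning rate halved after a 3-epoch validation
#' stall, gradient clipping at norm 10, batches scaled to desk-size
#' corpora); see [trainDetector()].
#'
#' @param gcnDims GCN layer widths (input width is inferred), default
#'   `c(16, 16)`.
#' @param dPrime temporal attention latent dimension, default 16.
#' @param includeJerk append jerk channels to the node features, default
#'   `TRUE`.
#' @param hiddenDim classifier hidden width, default 32.
#' @param weights a [lossWeights()].
#' @param classification `"frame"` (default; mean per-frame cross-entropy
#'   against the sequence label, the weak-label reading of a per-frame
#'   injury probability) or `"sequence"` (cross-entropy on the pooled
#'   mean probability).
#' @param zThreshold anomaly flag cutoff, default 2.5.
#' @param decisionThreshold sequence decision cutoff, default 0.5.
#' @param lr initial fine-tuning learning rate, default 1e-4 (the
#'   fine-tune polishes a warm-started head whose weights are themselves
#'   small; the step size is scaled accordingly).
#' @param epochs fine-tuning epochs after the convex warm start, default
#'   15 (0 skips fine-tuning entirely).
#' @param batchSize sequences per gradient step, default 32.
#' @param clipNorm gradient clipping norm, default 10.
#' @param weightDecay decoupled L2 decay during fine-tuning, default 0.
#' @param ridgeGrid ridge penalties searched by the warm start, selected
#'   on the validation split.
#' @param scaleGrid frame-score scales searched when installing the
#'   pooled fit into the per-frame head (small scales keep the sigmoid
#'   near-linear so pooling preserves the fitted ranking).
#' @param neutralRescale pass to [refineFeatures()], default `FALSE`.
#' @return Object of class `DetectorConfig`.
#' @export
detectorConfig <- function(gcnDims = c(16L, 16L), dPrime = 16L,
                           includeJerk = TRUE, hiddenDim = 32L,
                           weights = lossWeights(),
                           classification = c("frame", "sequence"),
                           zThreshold = 2.5,
                           decisionThreshold = 0.5, lr = 1e-4,
                           epochs = 15L, batchSize = 32L, clipNorm = 10,
                           weightDecay = 0,
                           ridgeGrid = c(0.003, 0.01, 0.03, 0.1),
                           scaleGrid = c(0.02, 0.05, 0.1),
                           neutralRescale = FALSE) {
  classification <- match.arg(classification)
  structure(list(gcnDims = as.integer(gcnDims), dPrime = as.integer(dPrime),
                 includeJerk = includeJerk, hiddenDim = as.integer(hiddenDim),
                 weights = weights, classification = classification,
                 zThreshold = zThreshold,
                 decisionThreshold = decisionThreshold, lr = lr,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 clipNorm = clipNorm, weightDecay = weightDecay,
                 ridgeGrid = ridgeGrid, scaleGrid = scaleGrid,
                 neutralRescale = neutralRescale),
            class = "DetectorConfig")
}

applyFeatNorm <- function(f, norm) {
  sweep(sweep(f, 2L, norm$mu), 2L, norm$sd, "/")
}

## Build the fixed (seeded) encoder for a given skeleton/config.
buildEncoder <- function(graph, config, seed) {
  D <- 3L
  fDim <- if (config$includeJerk) 4L * D else 3L * D
  stack <- gcnStack(c(fDim, config$gcnDims), activation = "relu",
                    seed = seed)
  tParams <- temporalAttentionParams(
    d = config$gcnDims[length(config$gcnDims)],
    dPrime = config$dPrime, seed = seed + 1L)
  list(stack = stack, tParams = tParams)
}

#' Per-frame feature matrix for one sequence
#'
#' The full feature path of the detector: composite kinematic node
#' features -> graph convolution over the skeleton -> confidence-weighted
#' refinement from the energy z-scores -> mean pooling over joints ->
#' positional encoding and temporal self-attention -> concatenation of the
#' attended embedding with the per-joint anomaly z-scores.
#'
#' @param seq a [MotionSequence-class].
#' @param graph the skeleton.
#' @param encoder result of the internal encoder builder (a GCN stack +
#'   temporal attention parameters).
#' @param stats corpus energy statistics (`mu`, `sigma`).
#' @param config a [detectorConfig()].
#' @return List with `features` (`T x (dPrime + 3 J + 2)`; the attended
#'   embedding, the per-joint z-scores and deviation scores S, the
#'   per-joint anomaly flags, and two bounded frame summaries the
#'   flagging rule induces: the flagged-joint count and the largest
#'   absolute z of the frame), `scores` (the [AnomalyScores-class]) and
#'   `energy` (the profile).
#' @export
featurizeSequence <- function(seq, graph, encoder, stats, config) {
  kin <- computeKinematics(seq)
  E <- totalEnergy(kin, seq, graph)
  sc <- scoreSequence(E, stats, threshold = config$zThreshold)
  X <- compositeFeatures(seq, kin, includeJerk = config$includeJerk)
  H <- gcnForward(X, graph, encoder$stack)
  H <- refineFeatures(H, sc@beta, neutralRescale = config$neutralRescale)
  pooled <- poolJoints(H, "mean")
  pooled <- addPositionalEncoding(pooled)
  Z <- temporalAttention(pooled, encoder$tParams)$Z
  fl <- sc@flags + 0
  feat <- cbind(Z, sc@z, sc@S, fl, rowSums(fl), apply(abs(sc@z), 1L, max))
  list(features = feat, scores = sc, energy = E)
}

## Corpus-level energy statistics from the *normal* training sequences.
corpusEnergyStats <- function(corpus, trainIdx, graph) {
  normals <- trainIdx[corpus$labels[trainIdx] == 0L]
  if (length(normals) == 0L) stop("no normal sequences to calibrate on")
  energies <- lapply(corpus$sequences[normals], function(s) {
    totalEnergy(computeKinematics(s), s, graph)
  })
  energyStats(energies, perJoint = TRUE)
}

#' Train the injury detector on a labeled corpus
#'
#' End-to-end training under a fixed seed: the corpus is split by a
#' stratified seeded shuffle, energy statistics are calibrated on the
#' normal training sequences, and every sequence is featurized through
#' the seeded graph/temporal encoder. The classifier head is then fitted
#' in two phases. First a convex warm start: penalized logistic
#' regression on the frame-pooled features (deterministic BFGS), with
#' the ridge penalty and frame-score scale grid-searched and selected on
#' the validation split, installed exactly in the signed-rectification
#' two-layer head. Then mini-batch Adam fine-tuning on the combined loss
#' (classification plus the temporal-consistency family), with the
#' learning rate halved after a three-epoch validation stall and
#' gradients clipped at the configured norm. Identical seed and
#' configuration give identical parameters and logs.
#'
#' @param corpus a [makeCorpus()] result.
#' @param config a [detectorConfig()].
#' @param seed master seed for split, initialization and batch order.
#' @return Object of class `DetectorModel`: encoder, head, energy stats,
#'   split, config, seed and the per-epoch training `log`.
#' @export
trainDetector <- function(corpus, config = detectorConfig(), seed = 1L) {
  graph <- corpus$graph
  split <- splitCorpus(corpus, seed = seed)
  stats <- corpusEnergyStats(corpus, split$train, graph)
  encoder <- buildEncoder(graph, config, seed = seed)
  feats <- lapply(corpus$sequences, function(s) {
    featurizeSequence(s, graph, encoder, stats, config)$features
  })
  ## column standardization fitted on the training split only
  trainMat <- do.call(rbind, feats[split$train])
  featNorm <- list(mu = colMeans(trainMat),
                   sd = pmax(apply(trainMat, 2L, stats::sd), 1e-6))
  feats <- lapply(feats, applyFeatNorm, norm = featNorm)
  labels <- corpus$labels

  warm <- pooledWarmStart(feats, labels, split, config)
  head <- warm$head
  ## the convex phase is exact for the pure classification objective;
  ## gradient fine-tuning exists to incorporate the temporal loss terms
  hasTemporal <- with(config$weights,
                      lambda1 > 0 || lambda2 > 0 || lambda3 > 0 || lambda > 0)
  fineEpochs <- if (hasTemporal) config$epochs else 0L
  log <- adamFineTune(feats, labels, split, head, config, seed,
                      epochs = fineEpochs)
  structure(list(encoder = encoder, head = log$head, stats = stats,
                 featNorm = featNorm, warmStart = warm$selection,
                 split = split, config = config, seed = as.integer(seed),
                 graph = graph,
                 log = log$log),
            class = "DetectorModel")
}

## Convex warm start: penalized logistic regression on the frame-pooled
## feature means (deterministic BFGS), with the ridge penalty and the
## score scale chosen on the validation split, then installed in the
## signed-rectification head so the frame-wise forward pass reproduces
## the fitted scorer. Grid selection on validation follows the training
## protocol (grid search over regularization weights, best validation
## performance wins).
pooledWarmStart <- function(feats, labels, split, config) {
  Fd <- ncol(feats[[1L]])
  Xb <- t(vapply(feats, colMeans, numeric(Fd)))
  ytr <- labels[split$train]
  Xtr <- Xb[split$train, , drop = FALSE]
  fitOne <- function(lam) {
    obj <- function(th) {
      p <- sigmoid(th[1L] + Xtr %*% th[-1L])
      crossEntropy(as.vector(p), ytr) + lam / 2 * sum(th[-1L]^2)
    }
    grd <- function(th) {
      p <- as.vector(sigmoid(th[1L] + Xtr %*% th[-1L]))
      r <- p - ytr
      c(mean(r), as.vector(crossprod(Xtr, r)) / length(ytr) + lam * th[-1L])
    }
    stats::optim(rep(0, Fd + 1L), obj, grd, method = "BFGS",
                 control = list(maxit = 300L, reltol = 1e-12))$par
  }
  best <- NULL
  for (lam in config$ridgeGrid) {
    th <- fitOne(lam)
    for (scl in config$scaleGrid) {
      pv <- vapply(split$val, function(i) {
        mean(sigmoid(scl * (th[1L] + feats[[i]] %*% th[-1L])))
      }, numeric(1))
      vacc <- mean((pv >= config$decisionThreshold) ==
                     (labels[split$val] == 1L))
      vloss <- crossEntropy(pv, labels[split$val])
      if (is.null(best) || vacc > best$vacc + 1e-9 ||
          (abs(vacc - best$vacc) <= 1e-9 && vloss < best$vloss - 1e-12)) {
        best <- list(lambda = lam, scale = scl, vacc = vacc, vloss = vloss,
                     theta = th)
      }
    }
  }
  head <- classifierHead(Fd, init = "linear-pairs")
  th <- best$theta
  head$w2 <- best$scale * c(th[-1L], -th[-1L])
  head$b2 <- best$scale * th[1L]
  list(head = head,
       selection = list(lambda = best$lambda, scale = best$scale,
                        val_accuracy = best$vacc, val_loss = best$vloss))
}

## Mini-batch Adam fine-tuning of the warm-started head on the combined
## loss (classification plus the temporal-consistency family), with the
## learning rate halved after a three-epoch validation stall and
## gradients clipped at the configured norm.
adamFineTune <- function(feats, labels, split, head, config, seed,
                         epochs = config$epochs) {
  pnames <- c("W1", "b1", "w2", "b2")
  opt <- adamInit(head[pnames])
  lr <- config$lr
  stall <- 0L; bestVal <- Inf
  log <- vector("list", epochs)
  if (epochs == 0L) {
    return(list(head = head, log = NULL))
  }
  batchSeeds <- deriveSeeds(seed + 3L, epochs)
  for (epoch in seq_len(epochs)) {
    order <- withSeed(batchSeeds[epoch], sample(split$train))
    batches <- split(order, ceiling(seq_along(order) / config$batchSize))
    epochLoss <- 0; epochBreak <- NULL
    for (b in batches) {
      grads <- NULL
      for (i in b) {
        g <- headGradient(feats[[i]], labels[i], head, config$weights,
                          classification = config$classification)
        if (!is.finite(g$loss))
          stop("non-finite loss at sequence ", i, "; aborting")
        gi <- list(W1 = g$gW1, b1 = g$gb1, w2 = g$gW2, b2 = g$gb2)
        grads <- if (is.null(grads)) gi else Map(`+`, grads, gi)
        epochLoss <- epochLoss + g$loss
        epochBreak <- if (is.null(epochBreak)) g$breakdown else {
          epochBreak + g$breakdown
        }
      }
      grads <- lapply(grads, function(g) g / length(b))
      step <- adamStep(opt, head[pnames], grads, lr,
                       clipNorm = config$clipNorm,
                       weightDecay = config$weightDecay)
      opt <- step$state
      head[pnames] <- step$params
    }
    valLoss <- mean(vapply(split$val, function(i) {
      P <- headForward(feats[[i]], head)$P
      totalLoss(P, labels[i], config$weights,
                classification = config$classification)$total
    }, numeric(1)))
    if (valLoss < bestVal - 1e-9) {
      bestVal <- valLoss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= 3L) {                  # halve on a 3-epoch stall
        lr <- lr / 2; stall <- 0L
      }
    }
    log[[epoch]] <- c(epoch = epoch,
                      train_loss = epochLoss / length(split$train),
                      val_loss = valLoss, lr = lr,
                      epochBreak / length(split$train))
  }
  list(head = head, log = do.call(rbind, log))
}

#' Predict injury probabilities with a trained detector
#'
#' @param model a [trainDetector()] result.
#' @param seq a [MotionSequence-class] (or a corpus, in which case a list
#'   of predictions is returned).
#' @return A [Predictions-class], or a list of them for a corpus.
#' @export
predictDetector <- function(model, seq) {
  if (is(seq, "MotionSequence")) {
    f <- featurizeSequence(seq, model$graph, model$encoder, model$stats,
                           model$config)
    feat <- applyFeatNorm(f$features, model$featNorm)
    return(classify(feat, model$head,
                    threshold = model$config$decisionThreshold))
  }
  if (inherits(seq, "LabeledCorpus")) {
    return(lapply(seq$sequences, predictDetector, model = model))
  }
  stop("seq must be a MotionSequence or LabeledCorpus")
}

#' Evaluate a trained detector on corpus indices
#'
#' @param model a [trainDetector()] result.
#' @param corpus the corpus to score.
#' @param idx sequence indices (default: the model's validation split).
#' @return List with the metric set of [evaluateDetector()] plus
#'   `jitter`, the mean frame-to-frame probability change, and the raw
#'   `seqProb` scores.
#' @export
evaluateOnCorpus <- function(model, corpus, idx = model$split$val) {
  preds <- lapply(corpus$sequences[idx], predictDetector, model = model)
  scores <- vapply(preds, function(p) p@seqProb, numeric(1))
  jitter <- mean(vapply(preds, function(p) {
    if (length(p@frameProb) < 2L) 0 else mean(abs(diff(p@frameProb)))
  }, numeric(1)))
  m <- evaluateDetector(scores, corpus$labels[idx],
                        threshold = model$config$decisionThreshold)
  c(m, list(jitter = jitter, seqProb = scores))
}

#' Rank sequences by their maximum absolute energy z-score
#'
#' The unsupervised screening statistic: the largest `|z|` over all
#' (frame, joint) cells of a sequence's energy profile, against energy
#' statistics calibrated on normal motion. Injured sequences rank high.
#'
#' @param corpus a [makeCorpus()] result.
#' @param statsIdx indices used to calibrate the energy statistics
#'   (default: all normal sequences).
#' @return Numeric vector of max-`|z|` scores, one per sequence.
#' @export
maxAbsZScores <- function(corpus, statsIdx = which(corpus$labels == 0L)) {
  graph <- corpus$graph
  energies <- lapply(corpus$sequences, function(s) {
    totalEnergy(computeKinematics(s), s, graph)
  })
  stats <- energyStats(energies[statsIdx], perJoint = TRUE)
  vapply(energies, function(E) {
    max(abs(zscoreEnergy(E, stats)))
  }, numeric(1))
}
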