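test_that("the static threshold baseline follows the sigmoid arithmetic", {
  A <- array(0, c(4, 2, 3))
  ## zero weights -> sigma(0) = 0.5
  expect_equal(baselineThresholdDetector(A, c(0, 0)), 0.5)
  ## hand case: single joint with time-mean norm log 3 and unit weight
  A1 <- array(0, c(3, 1, 3)); A1[, 1, 1] <- log(3)
  expect_equal(baselineThresholdDetector(A1, 1), 0.75)
  ## monotone in an acceleration scale-up under nonnegative weights
  set.seed(81)
  A2 <- array(abs(rnorm(24)), c(4, 2, 3))
  w <- c(0.5, 1.5)
  expect_gte(baselineThresholdDetector(2 * A2, w),
             baselineThresholdDetector(A2, w))
})

test_that("classification head produces calibrated per-frame probabilities", {
  ## zero-weight head -> every frame at 0.5
  h <- classifierHead(3, 4, seed = 1)
  h$W1[] <- 0; h$w2[] <- 0; h$b2 <- 0
  pred <- classify(matrix(rnorm(15), 5, 3), h)
  expect_equal(pred@frameProb, rep(0.5, 5))
  expect_equal(pred@seqProb, 0.5)
  expect_equal(pred@label, 1L)     # 0.5 >= threshold, inclusive
  ## probabilities always in [0, 1]
  h2 <- classifierHead(3, 4, seed = 2)
  p2 <- classify(matrix(rnorm(30, sd = 5), 10, 3), h2)
  expect_true(all(p2@frameProb >= 0 & p2@frameProb <= 1))
  ## fixed tiny weights against a hand forward pass
  h3 <- classifierHead(2, 2, seed = 3)
  h3$W1 <- matrix(c(1, 0, 0, 1), 2, 2); h3$b1 <- c(0, -1)
  h3$w2 <- c(1, 2); h3$b2 <- 0.5
  x <- matrix(c(0.3, 2), 1, 2)
  hid <- pmax(c(0.3, 2 - 1), 0)
  expect_equal(classify(x, h3)@frameProb,
               1 / (1 + exp(-(sum(c(1, 2) * hid) + 0.5))))
  expect_error(classify(matrix(0, 2, 5), h3), "expects")
})

test_that("the signed-rectification head reproduces a linear scorer exactly", {
  set.seed(82)
  h <- classifierHead(4, init = "linear-pairs")
  w <- rnorm(4); b <- 0.3; scl <- 0.05
  h$w2 <- scl * c(w, -w); h$b2 <- scl * b
  X <- matrix(rnorm(24), 6, 4)
  pred <- classify(X, h)
  expect_equal(pred@frameProb,
               as.vector(1 / (1 + exp(-scl * (X %*% w + b)))))
})

test_that("loss family matches its closed forms and degenerate zeros", {
  P <- rep(0.3, 6)
  expect_equal(consistencyLoss(P), 0)
  expect_equal(weightedConsistencyLoss(P, 2), 0)
  expect_equal(smoothingLoss(P), 0)
  expect_equal(temporalRegLoss(P, 2), 0)

  ## single jumps
  expect_equal(consistencyLoss(c(0, 1)), 1)
  expect_equal(weightedConsistencyLoss(c(0, 1), gamma = 0.7), 1.7)
  expect_equal(weightedConsistencyLoss(c(0, 1), gamma = 0), 1)
  expect_equal(smoothingLoss(c(0.2, 0.5)), 0.3)
  expect_equal(temporalRegLoss(c(0, 0, 1), 2), 1)

  ## telescoping: a monotone ramp costs exactly its total rise in l1
  ramp <- seq(0, 1, length.out = 11)
  expect_equal(smoothingLoss(ramp), 1)

  ## period-k oscillation is invisible to the lag-k regularizer
  osc <- rep(c(0.2, 0.8), 5)
  expect_equal(temporalRegLoss(osc, 2), 0)
  expect_warning(out <- temporalRegLoss(c(0.1, 0.9), 5), "empty")
  expect_equal(out, 0)

  ## energy-regularized classification
  S <- matrix(1, 2, 1)
  expect_equal(lossRegularized(1, 1, S, 0), crossEntropy(1, 1))
  expect_equal(lossRegularized(1, 1, matrix(0, 2, 2), 0.7),
               crossEntropy(1, 1))
  expect_equal(lossRegularized(1, 1, S, 0.5), 0.5 * 2, tolerance = 1e-9)
})

test_that("total loss is linear in each weight and bounded below by classification", {
  set.seed(83)
  P <- runif(10, 0.1, 0.9); y <- 1
  w0 <- lossWeights()
  base <- totalLoss(P, y, w0)
  expect_equal(base$total, base$breakdown[["classification"]])
  for (nm in c("lambda1", "lambda2", "lambda3")) {
    args1 <- list(); args1[[nm]] <- 1
    args2 <- list(); args2[[nm]] <- 2
    l1 <- do.call(lossWeights, args1)
    l2 <- do.call(lossWeights, args2)
    t1 <- totalLoss(P, y, l1)$total - base$total
    t2 <- totalLoss(P, y, l2)$total - base$total
    expect_equal(t2, 2 * t1, tolerance = 1e-9)
    expect_gte(totalLoss(P, y, l1)$total, base$total)
  }
  expect_error(lossWeights(lambda1 = -1), ">= 0")
})

test_that("analytic head gradients match central finite differences", {
  set.seed(84)
  T <- 9; F <- 5
  X <- matrix(rnorm(T * F), T, F)
  head <- classifierHead(F, 4, seed = 2)
  ## perturbing W1[, j] moves the whole hidden column j: check a column
  ## whose pre-activations sit well away from the ReLU kink, where the
  ## analytic subgradient and the finite difference agree
  H <- sweep(X %*% head$W1, 2, head$b1, "+")
  jSafe <- which.max(apply(abs(H), 2, min))
  w <- lossWeights(lambda1 = 0.7, lambda2 = 0.3, lambda3 = 0.4,
                   k = 3, gamma = 0.5)
  for (mode in c("frame", "sequence")) {
    g <- kinedetect:::headGradient(X, 1, head, w, classification = mode)
    lossAt <- function(h) {
      P <- kinedetect:::headForward(X, h)$P
      totalLoss(P, 1, w, classification = mode)$total
    }
    num <- function(slot, i, j = NULL) {
      h <- head; eps <- 1e-6
      bump <- function(h, d) {
        if (is.null(j)) h[[slot]][i] <- h[[slot]][i] + d
        else h[[slot]][i, j] <- h[[slot]][i, j] + d
        h
      }
      (lossAt(bump(h, eps)) - lossAt(bump(h, -eps))) / (2 * eps)
    }
    expect_equal(g$gW1[2, jSafe], num("W1", 2, jSafe), tolerance = 1e-5)
    expect_equal(g$gb1[jSafe], num("b1", jSafe), tolerance = 1e-5)
    expect_equal(g$gW2[2], num("w2", 2), tolerance = 1e-5)
    expect_equal(g$gb2, num("b2", 1), tolerance = 1e-5)
  }
})

test_that("evaluation metrics follow the confusion-table arithmetic", {
  ## perfect predictions
  m <- evaluateDetector(c(0.9, 0.1, 0.8, 0.2), c(1, 0, 1, 0))
  expect_equal(unlist(m[c("accuracy", "recall", "f1", "auc")]),
               c(accuracy = 1, recall = 1, f1 = 1, auc = 1))
  ## all-positive predictor on balanced labels
  m <- evaluateDetector(rep(0.9, 4), c(1, 0, 1, 0))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$recall, 1)
  ## random scores have AUC near one half
  set.seed(85)
  aucs <- replicate(200, rankAUC(runif(40), rep(c(0, 1), 20)))
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  ## degenerate single-class labels give NA AUC
  expect_true(is.na(rankAUC(runif(5), rep(1, 5))))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(86)
  for (rep in 1:5) {
    y <- rbinom(50, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- rnorm(50) + y
    ref <- suppressMessages(as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
    expect_equal(rankAUC(s, y), ref, tolerance = 1e-12)
  }
})

test_that("training is seeded, deterministic and improves the loss", {
  spec <- syntheticSpec(nSequences = 24, nFrames = 30, nJoints = 6, seed = 9)
  corpus <- makeCorpus(spec)
  cfg <- detectorConfig(weights = lossWeights(lambda1 = 0.5), epochs = 6)
  m1 <- trainDetector(corpus, cfg, seed = 4)
  m2 <- trainDetector(corpus, cfg, seed = 4)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$head$w2, m2$head$w2)
  ## the fine-tune loss decreases from its first epoch
  log <- as.data.frame(m1$log)
  expect_lt(log$train_loss[6], log$train_loss[1])
  ## a different seed changes the split
  m3 <- trainDetector(corpus, cfg, seed = 5)
  expect_false(identical(m1$split$train, m3$split$train))
})

test_that("one-epoch training on a tiny corpus runs end to end", {
  spec <- syntheticSpec(nSequences = 8, nFrames = 20, nJoints = 5, seed = 3)
  corpus <- makeCorpus(spec)
  m <- trainDetector(corpus,
                     detectorConfig(weights = lossWeights(lambda1 = 1),
                                    epochs = 1), seed = 1)
  pred <- predictDetector(m, corpus$sequences[[1]])
  expect_s4_class(pred, "Predictions")
  expect_true(all(pred@frameProb >= 0 & pred@frameProb <= 1))
  ev <- evaluateOnCorpus(m, corpus, idx = seq_along(corpus$labels))
  expect_true(is.finite(ev$accuracy))
})
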