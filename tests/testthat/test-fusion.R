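test_that("static mixing is the coefficient-weighted sum", {
  T <- 4; J <- 2; C <- 3
  v <- array(rnorm(T * J * C), c(T, J, C))
  i <- array(rnorm(T * J * C), c(T, J, C))
  p <- array(rnorm(T * J * C), c(T, J, C))
  b <- modalityBundle(vision = v, imu = i, pressure = p)
  ## one-hot returns the selected channel unchanged
  expect_equal(staticMix(b, c(vision = 1, imu = 0, pressure = 0)), v)
  ## convexity over identical channels
  b2 <- modalityBundle(vision = v, imu = v, pressure = p)
  expect_equal(staticMix(b2, c(vision = 0.5, imu = 0.5, pressure = 0)), v)
  ## all-zero coefficients: zero tensor with a warning
  expect_warning(out <- staticMix(b, c(vision = 0, imu = 0, pressure = 0)),
                 "zero")
  expect_equal(max(abs(out)), 0)
  expect_error(staticMix(b, c(-1, 1, 1)), ">= 0")
})

test_that("modality projection is the affine channel map", {
  prm <- fusionParams(c(a = 3, b = 3), sharedDim = 3, seed = 1)
  ## identity weights, zero bias -> passthrough
  prm$projections$a$W <- diag(3)
  x <- matrix(rnorm(12), 4, 3)
  out <- projectModalities(list(a = x), prm)
  expect_equal(out$a, x)
  ## zero weights -> bias rows
  prm$projections$b$W <- matrix(0, 3, 3)
  prm$projections$b$b <- c(1, 2, 3)
  out <- projectModalities(list(b = x), prm)
  expect_equal(out$b, matrix(c(1, 2, 3), 4, 3, byrow = TRUE))
  ## random case against a hand matrix product, T x J x C arrays
  prm2 <- fusionParams(c(a = 2), sharedDim = 4, seed = 2)
  arr <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  emb <- projectModalities(list(a = arr), prm2)$a
  expect_equal(emb[2, 1, ],
               as.vector(arr[2, 1, ] %*% prm2$projections$a$W +
                           prm2$projections$a$b))
})

test_that("modality weights softmax the scores and honor masking", {
  prm <- fusionParams(c(a = 1, b = 1), sharedDim = 1, attnDim = 1, seed = 1)
  ## identical embeddings -> uniform
  a <- modalityWeights(list(a = 0.4, b = 0.4), prm)
  expect_equal(unname(a), c(0.5, 0.5))
  ## engineered scores (0, log 3) -> (0.25, 0.75): tanh saturates at +-1
  prm$Ws <- matrix(c(1000, 0), 2, 1)    # rows: embedding, context
  prm$bs <- 0
  prm$ws <- log(3)
  a <- modalityWeights(list(a = 0, b = 1), prm)
  expect_equal(unname(a), c(0.25, 0.75), tolerance = 1e-9)
  ## masking a modality renormalizes over the rest
  a <- modalityWeights(list(a = 0, b = 1), prm, missing = "b")
  expect_equal(unname(a), c(1, 0))
  expect_error(modalityWeights(list(a = 0, b = 1), prm,
                               missing = c("a", "b")), "no modality")
  ## fuzz: weights always normalize
  set.seed(71)
  prm2 <- fusionParams(c(x = 2, y = 2, z = 2), sharedDim = 2, seed = 3)
  for (rep in 1:10) {
    emb <- list(x = rnorm(2), y = rnorm(2), z = rnorm(2))
    a <- modalityWeights(emb, prm2, context = rnorm(2))
    expect_lt(abs(sum(a) - 1), 1e-9)
    expect_true(all(a > 0))
  }
})

test_that("fusion is a convex combination and permutation-invariant", {
  e <- list(a = c(1, 2), b = c(3, -2), c = c(0, 0))
  ## one-hot picks that embedding
  expect_equal(fuse(e, c(a = 0, b = 1, c = 0)), e$b)
  ## uniform over opposite vectors cancels
  expect_equal(fuse(list(u = c(1, -1), v = c(-1, 1)), c(u = 0.5, v = 0.5)),
               c(0, 0))
  ## hand 3-modality sum
  alpha <- c(a = 0.2, b = 0.3, c = 0.5)
  expect_equal(fuse(e, alpha), 0.2 * e$a + 0.3 * e$b + 0.5 * e$c)
  ## coordinates stay inside the per-coordinate range
  f <- fuse(e, alpha)
  rng <- sapply(1:2, function(k) range(sapply(e, `[`, k)))
  expect_true(all(f >= rng[1, ] & f <= rng[2, ]))
  ## permuting modalities with their weights changes nothing
  expect_equal(fuse(e[c(3, 1, 2)], alpha[c(3, 1, 2)]), f)
})

test_that("temporal context is the trailing mean with zero start", {
  expect_equal(temporalContext(NULL, 10, dim = 3), c(0, 0, 0))
  h <- matrix(2, 5, 3)
  expect_equal(temporalContext(h, 10), c(2, 2, 2))
  ## ramp history with window 2 -> midpoint of the last two rows
  h <- matrix(c(1, 2, 3, 4), 4, 1)
  expect_equal(temporalContext(h, 2), 3.5)
})

test_that("sequence-level fusion returns normalized per-frame weights", {
  set.seed(72)
  T <- 6; J <- 3
  v <- array(rnorm(T * J * 2), c(T, J, 2))
  b <- modalityBundle(vision = v, imu = v + 0.1, pressure = v - 0.1)
  prm <- fusionParams(c(vision = 2, imu = 2, pressure = 2),
                      sharedDim = 3, seed = 4)
  out <- adaptiveFuse(b, prm)
  expect_equal(dim(out$fused), c(T, J, 3))
  expect_lt(max(abs(rowSums(out$alpha) - 1)), 1e-9)
  ## missing modality is excluded for every frame
  out2 <- adaptiveFuse(b, prm, missing = "pressure")
  expect_equal(max(out2$alpha[, "pressure"]), 0)
})

test_that("fitting the scoring head downweights a corrupted modality", {
  spec <- syntheticSpec(nFrames = 20, nJoints = 4, noiseSd = 0, seed = 5)
  graph <- makeSkeleton(4)
  clean <- positions(simulateNormalMotion(spec, graph = graph))
  res <- sapply(1:5, function(r) {
    mk <- function(imuNoise) {
      set.seed(100 + r)
      modalityBundle(
        vision = clean + array(rnorm(length(clean), 0, 0.005), dim(clean)),
        imu = clean + array(rnorm(length(clean), 0, imuNoise), dim(clean)),
        pressure = clean + array(rnorm(length(clean), 0, 0.005), dim(clean)))
    }
    p <- fusionParams(c(vision = 3, imu = 3, pressure = 3),
                      sharedDim = 3, attnDim = 3, seed = r)
    target <- projectModalities(list(vision = clean), p)$vision
    cl <- trainFusionWeights(mk(0.005), target, p, epochs = 40, lr = 1)
    no <- trainFusionWeights(mk(1.0), target, p, epochs = 40, lr = 1)
    c(cl$alpha["imu"], no$alpha["imu"])
  })
  ## corrupting the inertial channel lowers its average learned weight
  expect_lt(mean(res[2, ]), mean(res[1, ]))
  ## and the fitting loss itself decreases
  p <- fusionParams(c(vision = 3, imu = 3, pressure = 3),
                    sharedDim = 3, attnDim = 3, seed = 1)
  target <- projectModalities(list(vision = clean), p)$vision
  set.seed(101)
  fit <- trainFusionWeights(
    modalityBundle(vision = clean, imu = clean +
                     array(rnorm(length(clean), 0, 1), dim(clean)),
                   pressure = clean),
    target, p, epochs = 15, lr = 1)
  expect_lt(fit$loss[15], fit$loss[1])
})
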