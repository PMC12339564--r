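test_that("the default skeleton is a connected anatomical tree", {
  g <- makeSkeleton(15)
  expect_equal(nJoints(g), 15L)
  expect_equal(nrow(g@edges), 14L)           # tree: J - 1 edges
  expect_equal(adjacency(g), t(adjacency(g)))
  ## connectivity by breadth-first search from the root
  A <- adjacency(g)
  seen <- c(1L); frontier <- c(1L)
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(lapply(frontier, function(i)
      which(A[i, ] > 0)))), seen)
    seen <- c(seen, nxt); frontier <- nxt
  }
  expect_setequal(seen, 1:15)
  expect_equal(sum(masses(g)), 70)
  ## pressure sensors sit at the ankles
  expect_setequal(jointNames(g)[g@sensorMap$pressure],
                  c("l_ankle", "r_ankle"))
})

test_that("noiseless gait is exactly periodic with the gait period", {
  spec <- syntheticSpec(nFrames = 75, nJoints = 15, noiseSd = 0, seed = 2)
  seq <- simulateNormalMotion(spec, gaitFreq = 1)
  pos <- positions(seq)
  ## 1 Hz at 25 Hz sampling: period 25 frames
  expect_equal(pos[1:25, , ], pos[26:50, , ], tolerance = 1e-12)
  expect_equal(pos[1:25, , ], pos[51:75, , ], tolerance = 1e-12)
})

test_that("the simulator is seed-deterministic and amplitude-linear", {
  spec <- syntheticSpec(nFrames = 30, seed = 7)
  s1 <- simulateNormalMotion(spec)
  s2 <- simulateNormalMotion(spec)
  expect_identical(positions(s1), positions(s2))
  ## doubling the amplitude doubles the peak joint speed (noiseless)
  spec0 <- syntheticSpec(nFrames = 50, noiseSd = 0, seed = 7)
  peakSpeed <- function(amp) {
    s <- simulateNormalMotion(spec0, amplitude = amp)
    max(abs(velocity(computeKinematics(s))))
  }
  expect_equal(peakSpeed(0.30), 2 * peakSpeed(0.15), tolerance = 1e-9)
})

test_that("injury injection is local, transient and energy-raising", {
  spec <- syntheticSpec(nFrames = 50, noiseSd = 0, seed = 11)
  graph <- makeSkeleton(15)
  seq <- simulateNormalMotion(spec, graph = graph)
  ## zero magnitude leaves the sequence unchanged
  inj0 <- injectInjury(seq, joint = 5, onset = 20, duration = 8,
                       magnitude = 0)
  expect_equal(positions(inj0$seq), positions(seq))
  inj <- injectInjury(seq, joint = 5, onset = 20, duration = 8,
                      magnitude = 1.5)
  p0 <- positions(seq); p1 <- positions(inj$seq)
  ## all other joints untouched
  expect_equal(p1[, -5, ], p0[, -5, ])
  ## outside the event window the target joint is untouched too
  expect_equal(p1[c(1:19, 28:50), 5, ], p0[c(1:19, 28:50), 5, ])
  ## strictly higher peak energy at the target joint
  E0 <- energyMatrix(totalEnergy(computeKinematics(seq), seq, graph))
  E1 <- energyMatrix(totalEnergy(computeKinematics(inj$seq), inj$seq, graph))
  expect_gt(max(E1[, 5]), max(E0[, 5]))
  ## annotation carries the event geometry
  expect_equal(inj$annotation[c("joint", "onset", "duration")],
               list(joint = 5L, onset = 20L, duration = 8L))
})

test_that("modality simulation respects its degradation limits", {
  spec <- syntheticSpec(nFrames = 30, nJoints = 6, noiseSd = 0, seed = 13)
  graph <- makeSkeleton(6)
  seq <- simulateNormalMotion(spec, graph = graph)
  ## zero degradation: vision equals positions exactly
  b0 <- simulateModalities(seq, graph, seed = 1, visionNoiseSd = 0,
                           occlusionProb = 0, imuNoiseSd = 0, driftRate = 0)
  expect_equal(b0@modalities$vision, positions(seq),
               ignore_attr = TRUE)
  ## zero drift and noise: imu equals the accelerations
  expect_equal(b0@modalities$imu,
               acceleration(computeKinematics(seq)), ignore_attr = TRUE)
  ## full occlusion masks every frame after the first
  b1 <- simulateModalities(seq, graph, seed = 1, occlusionProb = 1)
  occ <- attr(b1@modalities$vision, "occluded")
  expect_false(occ[1])
  expect_true(all(occ[-1]))
})

test_that("corpora have the prescribed label balance and stratified splits", {
  spec <- syntheticSpec(nSequences = 20, nFrames = 20, nJoints = 5,
                        injuryRate = 0.5, seed = 17)
  corpus <- makeCorpus(spec)
  expect_equal(sum(corpus$labels), 10L)
  ## annotations present exactly for positives
  hasAnn <- !vapply(corpus$annotations, is.null, logical(1))
  expect_equal(hasAnn, corpus$labels == 1L)
  ## disjoint seeds give different corpora
  corpus2 <- makeCorpus(syntheticSpec(nSequences = 20, nFrames = 20,
                                      nJoints = 5, seed = 18))
  expect_false(identical(positions(corpus$sequences[[1]]),
                         positions(corpus2$sequences[[1]])))
  ## stratified split preserves balance
  sp <- splitCorpus(corpus, trainFrac = 0.7, seed = 1)
  expect_equal(sum(corpus$labels[sp$train]), 7L)
  expect_equal(sum(corpus$labels[sp$val]), 3L)
  expect_setequal(c(sp$train, sp$val), 1:20)
})

test_that("noiseless localization recovers the injected joint and window", {
  spec <- syntheticSpec(nSequences = 16, nFrames = 50, nJoints = 15,
                        noiseSd = 0, seed = 23)
  corpus <- makeCorpus(spec)
  graph <- corpus$graph
  normals <- which(corpus$labels == 0L)
  stats <- energyStats(lapply(corpus$sequences[normals], function(s) {
    totalEnergy(computeKinematics(s), s, graph)
  }))
  for (i in which(corpus$labels == 1L)[1:3]) {
    ann <- corpus$annotations[[i]]
    s <- corpus$sequences[[i]]
    z <- zscoreEnergy(totalEnergy(computeKinematics(s), s, graph), stats)
    am <- which(abs(z) == max(abs(z)), arr.ind = TRUE)
    expect_equal(unname(am[1, 2]), ann$joint)
    expect_gte(unname(am[1, 1]), ann$onset)
    expect_lte(unname(am[1, 1]), ann$onset + ann$duration)
  }
})
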