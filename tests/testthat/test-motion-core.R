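test_that("kinematic differentiation matches hand finite differences", {
  ## constant positions: every derivative vanishes
  kin <- computeKinematics(constSeq(T = 6, value = 3))
  expect_equal(max(abs(velocity(kin))), 0)
  expect_equal(max(abs(acceleration(kin))), 0)
  expect_equal(max(abs(jerk(kin))), 0)

  ## linear motion x = t at dt = 1: unit velocity from frame 2 on
  kin <- computeKinematics(movingSeq(function(t) t))
  expect_equal(velocity(kin)[2:6, 1, 1], rep(1, 5))
  expect_equal(velocity(kin)[1, 1, 1], 0)
  expect_equal(acceleration(kin)[3:6, 1, 1], rep(0, 4))

  ## quadratic motion x = t^2: V_t = 2t - 1, A_t = 2 for t >= 2
  kin <- computeKinematics(movingSeq(function(t) t^2))
  expect_equal(velocity(kin)[, 1, 1], c(0, 1, 3, 5, 7, 9))
  expect_equal(acceleration(kin)[3:6, 1, 1], rep(2, 4))
  expect_equal(jerk(kin)[4:6, 1, 1], rep(0, 3))
})

test_that("kinematics is linear in the positions", {
  set.seed(11)
  X <- array(rnorm(8 * 3 * 3), c(8, 3, 3))
  Y <- array(rnorm(8 * 3 * 3), c(8, 3, 3))
  a <- 1.7; b <- -0.4
  kXY <- computeKinematics(motionSequence(a * X + b * Y, frameRate = 25))
  kX <- computeKinematics(motionSequence(X, frameRate = 25))
  kY <- computeKinematics(motionSequence(Y, frameRate = 25))
  expect_equal(velocity(kXY), a * velocity(kX) + b * velocity(kY))
  expect_equal(jerk(kXY), a * jerk(kX) + b * jerk(kY))
})

test_that("non-uniform sampling is rejected with the offending frame", {
  pos <- array(0, c(4, 1, 3))
  expect_error(
    motionSequence(pos, frameRate = 25, times = c(0, 0.04, 0.09, 0.13)),
    "frame 3")
})

test_that("composite features concatenate position, velocity, acceleration, jerk", {
  seq <- movingSeq(function(t) t^2, T = 5)
  kin <- computeKinematics(seq)
  f3 <- compositeFeatures(seq, kin)
  f4 <- compositeFeatures(seq, kin, includeJerk = TRUE)
  expect_equal(dim(f3)[3], 9)
  expect_equal(dim(f4)[3], 12)
  ## constant sequence: rows equal [x, 0, 0, 0]
  cseq <- constSeq(T = 4, J = 1, value = 2)
  fc <- compositeFeatures(cseq, includeJerk = TRUE)
  expect_equal(fc[3, 1, ], c(2, 2, 2, rep(0, 9)))
  ## mismatched kinematics are rejected
  expect_error(compositeFeatures(cseq, computeKinematics(constSeq(T = 7))),
               "does not match")
})

test_that("normalized adjacency matches the closed forms", {
  g <- skeletonGraph(rbind(c(1, 2)), 2, selfLoops = FALSE)
  expect_equal(normAdjacency(g), matrix(c(0, 1, 1, 0), 2))
  g <- skeletonGraph(rbind(c(1, 2)), 2, selfLoops = TRUE)
  expect_equal(normAdjacency(g), matrix(0.5, 2, 2))
  ## duplicate edges collapse to one
  g2 <- skeletonGraph(rbind(c(1, 2), c(2, 1), c(1, 2)), 2, selfLoops = TRUE)
  expect_equal(normAdjacency(g2), matrix(0.5, 2, 2))
})

test_that("self-looped normalization of regular graphs is row-stochastic (K4)", {
  k4 <- skeletonGraph(t(combn(4, 2)), 4, selfLoops = TRUE)
  expect_equal(rowSums(normAdjacency(k4)), rep(1, 4))
})

test_that("normalized adjacency matches the element-wise loop oracle", {
  set.seed(21)
  for (rep in 1:5) {
    J <- sample(3:6, 1)
    g <- randomGraph(J)
    Aeff <- adjacency(g) + diag(J)
    deg <- rowSums(Aeff)
    oracle <- matrix(0, J, J)
    for (i in seq_len(J)) for (j in seq_len(J)) {
      oracle[i, j] <- Aeff[i, j] / sqrt(deg[i] * deg[j])
    }
    expect_lt(max(abs(normAdjacency(g) - oracle)), 1e-12)
  }
})

test_that("isolated joints without self-loops are rejected", {
  expect_error(skeletonGraph(rbind(c(1, 2)), 3, selfLoops = FALSE),
               "isolated")
})

test_that("mechanical energy follows the kinetic + potential decomposition", {
  ## pure kinetic: m = 2 kg, |V| = 5 m/s, flat ground -> 25 J
  pos <- array(0, c(3, 1, 3))
  pos[, 1, 1] <- c(0, 5, 10)           # 5 m per 1 s frame
  seq <- motionSequence(pos, frameRate = 1)
  g2 <- loneGraph(mass = 2)
  E <- totalEnergy(computeKinematics(seq), seq, g2, groundRef = "fixed")
  expect_equal(energyMatrix(E)[2, 1], 25)

  ## pure potential: m = 1 kg at height 1 m -> 9.81 J
  pos <- array(0, c(3, 1, 3)); pos[, 1, 3] <- 1
  seq <- motionSequence(pos)
  E <- totalEnergy(computeKinematics(seq), seq, loneGraph(1),
                   groundRef = "fixed", groundLevel = 0)
  expect_equal(energyMatrix(E)[1, 1], 9.81)

  ## V = 0, h = 0 -> E = 0
  seq0 <- constSeq(T = 4, J = 1)
  E0 <- totalEnergy(computeKinematics(seq0), seq0, loneGraph(1))
  expect_equal(max(abs(energyMatrix(E0))), 0)
})

test_that("energy decomposes: g = 0 leaves kinetic, V = 0 leaves potential", {
  set.seed(3)
  pos <- array(rnorm(10 * 2 * 3), c(10, 2, 3))
  seq <- motionSequence(pos, frameRate = 25)
  graph <- skeletonGraph(rbind(c(1, 2)), 2)
  kin <- computeKinematics(seq)
  Ek <- energyMatrix(totalEnergy(kin, seq, graph, g = 0))
  m <- matrix(masses(graph), 10, 2, byrow = TRUE)
  speed2 <- apply(velocity(kin)^2, c(1, 2), sum)
  expect_equal(Ek, 0.5 * m * speed2)

  cseq <- motionSequence(array(1, c(10, 2, 3)), frameRate = 25)
  Ep <- totalEnergy(computeKinematics(cseq), cseq, graph,
                    groundRef = "fixed", groundLevel = 0)
  expect_equal(energyMatrix(Ep), m * 9.81 * 1)
})

test_that("baseline-min ground reference keeps heights and energy nonnegative", {
  set.seed(5)
  pos <- array(rnorm(20 * 3 * 3, sd = 0.5) - 2, c(20, 3, 3))
  seq <- motionSequence(pos, frameRate = 25)
  graph <- chainGraph()
  E <- totalEnergy(computeKinematics(seq), seq, graph)
  expect_gte(min(E@heights), 0)
  expect_gte(min(energyMatrix(E)), 0)
})

test_that("non-positive masses are rejected", {
  expect_error(skeletonGraph(rbind(c(1, 2)), 2, masses = c(1, 0)),
               "positive")
})
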