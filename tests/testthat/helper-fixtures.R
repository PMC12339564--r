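## Shared fixtures, all built in code.

## A constant-position sequence: every kinematic quantity is zero.
constSeq <- function(T = 5, J = 2, D = 3, value = 0, frameRate = 25) {
  motionSequence(array(value, c(T, J, D)), frameRate = frameRate)
}

## One joint moving along x as a supplied function of the frame index
## (0-based), dt = 1 s.
movingSeq <- function(fun, T = 6, D = 3) {
  pos <- array(0, c(T, 1, D))
  pos[, 1, 1] <- fun(seq_len(T) - 1)
  motionSequence(pos, frameRate = 1)
}

## Single-joint graph (self-loops give it a defined degree).
loneGraph <- function(mass = 1) {
  skeletonGraph(matrix(integer(0), 0, 2), 1, masses = mass)
}

## A 3-joint chain 1-2-3.
chainGraph <- function(selfLoops = TRUE) {
  skeletonGraph(rbind(c(1, 2), c(2, 3)), 3, selfLoops = selfLoops)
}

## Random small graph with at least one edge, every node connected when
## selfLoops are off is not guaranteed -- used with selfLoops on.
randomGraph <- function(J, p = 0.5) {
  A <- matrix(0, J, J)
  for (i in seq_len(J - 1)) for (j in (i + 1):J) {
    if (runif(1) < p) A[i, j] <- A[j, i] <- 1
  }
  edges <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  if (nrow(edges) == 0) edges <- rbind(c(1L, 2L))
  skeletonGraph(edges, J)
}
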