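#' Kinematic differentiation of a motion sequence
#'
#' Computes joint velocity, acceleration and jerk by repeated backward
#' finite differences: `V[t] = (X[t] - X[t-1]) / dt` for `t >= 2`,
#' acceleration as the same difference of velocity, and jerk as the
#' difference of acceleration. The leading frame of each derivative (where
#' the difference is undefined) is zero-filled so all tensors keep length
#' `T` and downstream shapes stay uniform.
#'
#' @param seq a [MotionSequence-class].
#' @return A [KinematicFeatures-class] with slots `velocity` (m/s),
#'   `acceleration` (m/s^2) and `jerk` (m/s^3), each `T x J x D`.
#' @examples
#' pos <- array(rep((0:9)^2, 2 * 3), c(10, 2, 3))
#' kin <- computeKinematics(motionSequence(pos, frameRate = 1))
#' velocity(kin)[3, 1, 1]   # (4 - 1) / 1 = 3
#' @export
computeKinematics <- function(seq) {
  stopifnot(is(seq, "MotionSequence"))
  validObject(seq)
  dt <- 1 / seq@frameRate
  diffFill <- function(arr) {
    out <- array(0, dim(arr))
    T <- dim(arr)[1L]
    if (T >= 2L) {
      out[-1L, , ] <- (arr[-1L, , , drop = FALSE] -
                       arr[-T, , , drop = FALSE]) / dt
    }
    out
  }
  V <- diffFill(seq@positions)
  A <- diffFill(V)
  Jk <- diffFill(A)
  new("KinematicFeatures", velocity = V, acceleration = A, jerk = Jk)
}

#' Composite per-joint node features
#'
#' Concatenates position, velocity and acceleration (and optionally jerk)
#' along the channel axis, giving the `T x J x 3D` (or `T x J x 4D`) node
#' feature tensor consumed by the graph encoder.
#'
#' @param seq a [MotionSequence-class].
#' @param kin matching [KinematicFeatures-class]; computed if missing.
#' @param includeJerk append the jerk channels for higher-order motion
#'   encoding. Default `FALSE`.
#' @return Numeric array `T x J x D_f` with `D_f = 3D` or `4D`.
#' @export
compositeFeatures <- function(seq, kin = NULL, includeJerk = FALSE) {
  stopifnot(is(seq, "MotionSequence"))
  if (is.null(kin)) kin <- computeKinematics(seq)
  d <- dim(seq@positions)
  if (!identical(d, dim(kin@velocity)))
    stop("kinematics shape ", paste(dim(kin@velocity), collapse = "x"),
         " does not match positions ", paste(d, collapse = "x"))
  parts <- list(seq@positions, kin@velocity, kin@acceleration)
  if (includeJerk) parts <- c(parts, list(kin@jerk))
  out <- array(0, c(d[1L], d[2L], d[3L] * length(parts)))
  for (i in seq_along(parts)) {
    out[, , (i - 1L) * d[3L] + seq_len(d[3L])] <- parts[[i]]
  }
  out
}

#' Build a skeleton graph with degree-normalized adjacency
#'
#' Assembles the binary symmetric adjacency from an undirected edge list
#' (duplicate edges collapse) and computes the symmetric normalization
#' `D^{-1/2} A D^{-1/2}`. With `selfLoops = TRUE` (default) the identity is
#' added before normalizing — the renormalization that keeps every node's
#' own features in the aggregation and keeps isolated-node degrees defined.
#' With `selfLoops = FALSE` the literal normalization of the bare adjacency
#' is used, and an isolated joint is an error (its degree would be zero).
#'
#' @param edges two-column matrix (or list of pairs) of 1-based joint
#'   indices, one undirected edge per row.
#' @param nJoints number of joints `J`.
#' @param massTotal total body mass in kg, split uniformly across joints
#'   when `masses` is not given. Default 70.
#' @param masses optional per-joint masses (kg), overriding the uniform
#'   default.
#' @param selfLoops add self-loops before normalization. Default `TRUE`.
#' @param jointNames optional joint identifiers.
#' @param sensorMap optional named list mapping modalities to joint indices.
#' @return A [SkeletonGraph-class].
#' @examples
#' g <- skeletonGraph(rbind(c(1, 2)), nJoints = 2, selfLoops = FALSE)
#' normAdjacency(g)   # antidiagonal 1s: D = I for the single edge
#' @export
skeletonGraph <- function(edges, nJoints, massTotal = 70, masses = NULL,
                          selfLoops = TRUE, jointNames = NULL,
                          sensorMap = list()) {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- do.call(rbind, edges)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  J <- as.integer(nJoints)
  if (nrow(edges) > 0L && (any(edges < 1L) || any(edges > J)))
    stop("edge indices must lie in [1, ", J, "]")
  if (any(edges[, 1L] == edges[, 2L]))
    stop("explicit self-edges are not allowed; use selfLoops")
  A <- matrix(0, J, J)
  A[edges] <- 1
  A[edges[, 2:1, drop = FALSE]] <- 1
  Aeff <- if (selfLoops) A + diag(J) else A
  deg <- rowSums(Aeff)
  if (any(deg == 0))
    stop("joint ", which(deg == 0)[1L],
         " is isolated; degree 0 makes D^{-1/2} undefined (enable selfLoops)")
  dInv <- 1 / sqrt(deg)
  Ahat <- Aeff * outer(dInv, dInv)
  if (is.null(masses)) masses <- rep(massTotal / J, J)
  if (length(masses) != J) stop("need one mass per joint")
  if (any(masses <= 0)) stop("joint masses must be positive")
  if (is.null(jointNames)) jointNames <- paste0("j", seq_len(J))
  new("SkeletonGraph",
      nJoints = J, edges = edges, adjacency = A, normAdjacency = Ahat,
      selfLoops = isTRUE(selfLoops), masses = as.numeric(masses),
      jointNames = as.character(jointNames), sensorMap = sensorMap)
}

#' Neighborhoods of a skeleton graph
#'
#' Returns, for each joint, its anatomical neighbors plus the joint itself
#' (a node always retains access to its own features in attention).
#'
#' @param graph a [SkeletonGraph-class].
#' @return List of integer index vectors, one per joint.
#' @export
neighborhoods <- function(graph) {
  lapply(seq_len(graph@nJoints), function(i) {
    sort(unique(c(i, which(graph@adjacency[i, ] != 0))))
  })
}

#' Per-joint mechanical energy
#'
#' Total mechanical energy of every joint at every frame:
#' `E = 1/2 m ||v||^2 + m g h`, the kinetic term from the finite-difference
#' velocity and the gravitational potential term from the joint's height
#' above a ground reference. By default the reference is chosen per
#' sequence so the minimum vertical coordinate over the baseline window is
#' zero, which guarantees `h >= 0` and hence `E >= 0`; a fixed ground plane
#' can be supplied instead.
#'
#' @param kin a [KinematicFeatures-class].
#' @param seq the source [MotionSequence-class].
#' @param graph a [SkeletonGraph-class] providing joint masses.
#' @param g gravitational acceleration, m/s^2. Default 9.81.
#' @param groundRef `"baseline-min"` (default) or `"fixed"`.
#' @param groundLevel the fixed plane height when `groundRef = "fixed"`.
#' @param baselineWindow frame indices over which the minimum is taken for
#'   `"baseline-min"`; defaults to the first `min(T, 50)` frames (about 2 s
#'   at 25 Hz).
#' @return An [EnergyProfile-class] (`T x J` joules plus the heights used).
#' @examples
#' pos <- array(0, c(5, 1, 3))
#' seq <- motionSequence(pos)
#' g <- skeletonGraph(matrix(integer(0), 0, 2), 1, masses = 2)
#' energyMatrix(totalEnergy(computeKinematics(seq), seq, g))  # all zero
#' @export
totalEnergy <- function(kin, seq, graph, g = 9.81,
                        groundRef = c("baseline-min", "fixed"),
                        groundLevel = 0, baselineWindow = NULL) {
  groundRef <- match.arg(groundRef)
  stopifnot(is(kin, "KinematicFeatures"), is(seq, "MotionSequence"),
            is(graph, "SkeletonGraph"))
  if (any(graph@masses <= 0)) stop("joint masses must be positive")
  T <- nFrames(seq); J <- nJoints(seq)
  if (graph@nJoints != J)
    stop("graph has ", graph@nJoints, " joints but sequence has ", J)
  heights <- seq@positions[, , seq@verticalAxis, drop = TRUE]
  heights <- matrix(heights, T, J)
  if (groundRef == "baseline-min") {
    if (is.null(baselineWindow)) baselineWindow <- seq_len(min(T, 50L))
    heights <- heights - min(heights[baselineWindow, , drop = FALSE])
  } else {
    heights <- heights - groundLevel
  }
  speed2 <- apply(kin@velocity^2, c(1L, 2L), sum)
  m <- matrix(graph@masses, T, J, byrow = TRUE)
  E <- 0.5 * m * speed2 + m * g * heights
  new("EnergyProfile", energy = E, heights = heights, g = g)
}
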