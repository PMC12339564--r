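#' MotionSequence: uniformly sampled skeletal motion
#'
#' Container for a motion-capture sequence: joint positions over time as a
#' `T x J x D` array (meters), the sampling times (seconds, strictly
#' increasing, uniform spacing), joint names, and the index of the vertical
#' (height) coordinate. The universal input object of the package.
#'
#' @slot times numeric vector of length `T`, seconds, uniform spacing.
#' @slot positions numeric array `T x J x D`, meters, no missing values.
#' @slot jointNames character vector of length `J`.
#' @slot verticalAxis integer in `[1, D]`: which coordinate is height.
#' @slot frameRate sampling rate in Hz (`1 / dt`).
#'
#' @seealso [motionSequence()], [computeKinematics()], [totalEnergy()]
#' @export
setClass("MotionSequence",
  representation(
    times = "numeric",
    positions = "array",
    jointNames = "character",
    verticalAxis = "integer",
    frameRate = "numeric"
  )
)

setValidity("MotionSequence", function(object) {
  d <- dim(object@positions)
  if (length(d) != 3L) return("positions must be a T x J x D array")
  T <- d[1L]; J <- d[2L]; D <- d[3L]
  if (T < 1L) return("need at least one frame")
  if (length(object@times) != T) return("times length must equal nrow(positions)")
  if (anyNA(object@positions)) return("positions contain missing values")
  if (length(object@jointNames) != J) return("jointNames length must equal J")
  if (object@verticalAxis < 1L || object@verticalAxis > D)
    return("verticalAxis out of range")
  if (T >= 2L) {
    dt <- 1 / object@frameRate
    gaps <- diff(object@times)
    bad <- which(abs(gaps - dt) > 1e-9)
    if (length(bad) > 0L)
      return(sprintf("non-uniform sampling at frame %d (gap %.12g s, expected %.12g s)",
                     bad[1L] + 1L, gaps[bad[1L]], dt))
  }
  TRUE
})

#' Construct a MotionSequence
#'
#' @param positions numeric `T x J x D` array of joint positions (meters).
#' @param frameRate sampling rate in Hz. Default 25, the rate at which a
#'   2-3 s reference window spans 50-75 frames.
#' @param times optional explicit time stamps (seconds); defaults to
#'   `(0:(T-1)) / frameRate`.
#' @param jointNames optional joint identifiers; defaults to `j1..jJ`.
#' @param verticalAxis 1-based index of the height coordinate; defaults to
#'   the last coordinate.
#' @return A [MotionSequence-class] object.
#' @examples
#' pos <- array(0, c(10, 2, 3))
#' seq <- motionSequence(pos, frameRate = 25)
#' nFrames(seq)
#' @export
motionSequence <- function(positions, frameRate = 25, times = NULL,
                           jointNames = NULL, verticalAxis = NULL) {
  if (length(dim(positions)) != 3L)
    stop("positions must be a T x J x D array")
  T <- dim(positions)[1L]; J <- dim(positions)[2L]; D <- dim(positions)[3L]
  if (is.null(times)) times <- (seq_len(T) - 1L) / frameRate
  if (is.null(jointNames)) jointNames <- paste0("j", seq_len(J))
  if (is.null(verticalAxis)) verticalAxis <- D
  new("MotionSequence",
      times = as.numeric(times), positions = positions,
      jointNames = as.character(jointNames),
      verticalAxis = as.integer(verticalAxis),
      frameRate = as.numeric(frameRate))
}

#' KinematicFeatures: velocity, acceleration and jerk
#'
#' First, second and third discrete time derivatives of joint positions,
#' all shaped like the source positions (`T x J x D`). Frames preceding the
#' first computable difference are zero-filled so every tensor keeps
#' length `T`.
#'
#' @slot velocity `T x J x D`, m/s.
#' @slot acceleration `T x J x D`, m/s^2.
#' @slot jerk `T x J x D`, m/s^3.
#' @seealso [computeKinematics()]
#' @export
setClass("KinematicFeatures",
  representation(velocity = "array", acceleration = "array", jerk = "array")
)

setValidity("KinematicFeatures", function(object) {
  dv <- dim(object@velocity)
  if (!identical(dv, dim(object@acceleration)) ||
      !identical(dv, dim(object@jerk)))
    return("velocity, acceleration and jerk must share one shape")
  TRUE
})

#' SkeletonGraph: anatomical joint connectivity
#'
#' The skeleton as an undirected graph: binary symmetric adjacency over `J`
#' joints, its symmetric degree normalization `D^{-1/2} A D^{-1/2}`
#' (optionally with self-loops added before normalizing), and per-joint
#' effective masses (kg) for mechanical-energy computation.
#'
#' @slot nJoints number of joints `J`.
#' @slot edges integer matrix, one row per undirected edge, 1-based indices.
#' @slot adjacency binary symmetric `J x J`, zero diagonal.
#' @slot normAdjacency `J x J` degree-normalized operator.
#' @slot selfLoops whether self-loops were added before normalization.
#' @slot masses positive per-joint masses, kg.
#' @slot jointNames joint identifiers.
#' @slot sensorMap named list mapping sensor modalities to joint indices.
#' @seealso [skeletonGraph()], [makeSkeleton()]
#' @export
setClass("SkeletonGraph",
  representation(
    nJoints = "integer",
    edges = "matrix",
    adjacency = "matrix",
    normAdjacency = "matrix",
    selfLoops = "logical",
    masses = "numeric",
    jointNames = "character",
    sensorMap = "list"
  )
)

setValidity("SkeletonGraph", function(object) {
  J <- object@nJoints
  A <- object@adjacency
  if (!identical(dim(A), c(J, J))) return("adjacency must be J x J")
  if (!isTRUE(all.equal(A, t(A)))) return("adjacency must be symmetric")
  if (any(diag(A) != 0)) return("adjacency diagonal must be zero")
  if (length(object@masses) != J) return("need one mass per joint")
  if (any(object@masses <= 0)) return("joint masses must be positive")
  TRUE
})

#' EnergyProfile: per-joint mechanical energy over time
#'
#' Total mechanical energy `E[t, j] = 1/2 m_j ||v||^2 + m_j g h` for every
#' joint and frame, with the heights (relative to the ground reference) that
#' entered the potential term.
#'
#' @slot energy `T x J` matrix, joules.
#' @slot heights `T x J` matrix, meters above the ground reference.
#' @slot g gravitational acceleration, m/s^2.
#' @seealso [totalEnergy()]
#' @export
setClass("EnergyProfile",
  representation(energy = "matrix", heights = "matrix", g = "numeric")
)

setValidity("EnergyProfile", function(object) {
  if (!identical(dim(object@energy), dim(object@heights)))
    return("energy and heights must share one shape")
  if (object@g < 0) return("g must be nonnegative")
  TRUE
})

#' AnomalyScores: energy deviations, z-scores and confidence weights
#'
#' Per-frame, per-joint anomaly quantities: the absolute energy deviation
#' `S` from a reference-window baseline, the z-score against corpus-level
#' energy statistics, the sigmoid confidence weight `beta = 1/(1+exp(-z))`,
#' and the boolean flags `|z| >= threshold`.
#'
#' @slot S `T x J` nonnegative deviations, joules.
#' @slot z `T x J` z-scores.
#' @slot beta `T x J` confidence weights in (0, 1).
#' @slot flags `T x J` logical anomaly flags.
#' @slot threshold the z threshold used for flagging (default 2.5).
#' @seealso [scoreSequence()], [flagAnomalies()]
#' @export
setClass("AnomalyScores",
  representation(
    S = "matrix", z = "matrix", beta = "matrix",
    flags = "matrix", threshold = "numeric"
  )
)

setValidity("AnomalyScores", function(object) {
  if (any(object@S < 0)) return("S must be nonnegative")
  if (any(object@beta <= 0 | object@beta >= 1))
    return("beta must lie strictly inside (0, 1)")
  if (!identical(dim(object@S), dim(object@z)) ||
      !identical(dim(object@z), dim(object@beta)) ||
      !identical(dim(object@beta), dim(object@flags)))
    return("S, z, beta, flags must share one shape")
  TRUE
})

#' ModalityBundle: aligned multi-sensor feature channels
#'
#' Named per-modality feature arrays (conventionally `vision`, `imu`,
#' `pressure`, extensible), all aligned to the same number of frames `T`
#' and, where joint-indexed, to the same `J`. A modality that was not
#' recorded is simply absent from the list; it is never silently zero.
#'
#' @slot modalities named list of numeric arrays, each `T x J x C`.
#' @slot lambda named nonnegative static mixing coefficients.
#' @seealso [modalityBundle()], [staticMix()], [adaptiveFuse()]
#' @export
setClass("ModalityBundle",
  representation(modalities = "list", lambda = "numeric")
)

setValidity("ModalityBundle", function(object) {
  mods <- object@modalities
  if (length(mods) == 0L) return("bundle needs at least one modality")
  if (is.null(names(mods)) || any(names(mods) == ""))
    return("every modality must be named")
  Ts <- vapply(mods, function(m) dim(m)[1L], integer(1))
  if (length(unique(Ts)) != 1L) return("all modalities must share T")
  if (any(object@lambda < 0)) return("lambda coefficients must be >= 0")
  TRUE
})

#' Predictions: per-frame and sequence-level injury output
#'
#' @slot frameProb per-frame injury probabilities, in `[0, 1]`.
#' @slot seqProb pooled sequence probability (temporal mean).
#' @slot label 0/1 sequence decision (`seqProb >= threshold`).
#' @slot threshold decision threshold, default 0.5.
#' @seealso [classify()], [evaluateDetector()]
#' @export
setClass("Predictions",
  representation(
    frameProb = "numeric", seqProb = "numeric",
    label = "integer", threshold = "numeric"
  )
)

setValidity("Predictions", function(object) {
  if (any(object@frameProb < 0 | object@frameProb > 1))
    return("frame probabilities must lie in [0, 1]")
  if ((object@label == 1L) != (object@seqProb >= object@threshold))
    return("label must equal (seqProb >= threshold)")
  TRUE
})

## ---- accessors ----

#' Basic accessors for motion objects
#'
#' `nFrames`, `nJoints`, `nDims` return the tensor extents; `positions`,
#' `frameTimes`, `jointNames` the corresponding slots; `velocity`,
#' `acceleration`, `jerk` the kinematic tensors; `energyMatrix` the `T x J`
#' energy; `adjacency` and `normAdjacency` the graph operators; `masses`
#' the per-joint masses.
#'
#' @param x a package object.
#' @return The requested slot or extent.
#' @name accessors
#' @aliases nFrames nJoints nDims positions frameTimes jointNames velocity
#'   acceleration jerk energyMatrix adjacency normAdjacency masses
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("nJoints", function(x) standardGeneric("nJoints"))
#' @rdname accessors
#' @export
setGeneric("nDims", function(x) standardGeneric("nDims"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("jointNames", function(x) standardGeneric("jointNames"))
#' @rdname accessors
#' @export
setGeneric("velocity", function(x) standardGeneric("velocity"))
#' @rdname accessors
#' @export
setGeneric("acceleration", function(x) standardGeneric("acceleration"))
#' @rdname accessors
#' @export
setGeneric("jerk", function(x) standardGeneric("jerk"))
#' @rdname accessors
#' @export
setGeneric("energyMatrix", function(x) standardGeneric("energyMatrix"))
#' @rdname accessors
#' @export
setGeneric("adjacency", function(x) standardGeneric("adjacency"))
#' @rdname accessors
#' @export
setGeneric("normAdjacency", function(x) standardGeneric("normAdjacency"))
#' @rdname accessors
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))

#' @rdname accessors
setMethod("nFrames", "MotionSequence", function(x) dim(x@positions)[1L])
#' @rdname accessors
setMethod("nJoints", "MotionSequence", function(x) dim(x@positions)[2L])
#' @rdname accessors
setMethod("nDims", "MotionSequence", function(x) dim(x@positions)[3L])
#' @rdname accessors
setMethod("positions", "MotionSequence", function(x) x@positions)
#' @rdname accessors
setMethod("frameTimes", "MotionSequence", function(x) x@times)
#' @rdname accessors
setMethod("jointNames", "MotionSequence", function(x) x@jointNames)
#' @rdname accessors
setMethod("nJoints", "SkeletonGraph", function(x) x@nJoints)
#' @rdname accessors
setMethod("jointNames", "SkeletonGraph", function(x) x@jointNames)
#' @rdname accessors
setMethod("adjacency", "SkeletonGraph", function(x) x@adjacency)
#' @rdname accessors
setMethod("normAdjacency", "SkeletonGraph", function(x) x@normAdjacency)
#' @rdname accessors
setMethod("masses", "SkeletonGraph", function(x) x@masses)
#' @rdname accessors
setMethod("velocity", "KinematicFeatures", function(x) x@velocity)
#' @rdname accessors
setMethod("acceleration", "KinematicFeatures", function(x) x@acceleration)
#' @rdname accessors
setMethod("jerk", "KinematicFeatures", function(x) x@jerk)
#' @rdname accessors
setMethod("energyMatrix", "EnergyProfile", function(x) x@energy)

## ---- show methods ----

setMethod("show", "MotionSequence", function(object) {
  d <- dim(object@positions)
  cat(sprintf("MotionSequence: %d frames x %d joints x %dD, %.6g Hz (%.3g s)\n",
              d[1L], d[2L], d[3L], object@frameRate,
              d[1L] / object@frameRate))
  cat("  joints:", paste(utils::head(object@jointNames, 6L), collapse = ", "),
      if (d[2L] > 6L) "..." else "", "\n")
})

setMethod("show", "SkeletonGraph", function(object) {
  cat(sprintf("SkeletonGraph: %d joints, %d edges, self-loops %s\n",
              object@nJoints, nrow(object@edges),
              if (object@selfLoops) "on" else "off"))
  cat(sprintf("  total mass %.3g kg\n", sum(object@masses)))
})

setMethod("show", "EnergyProfile", function(object) {
  cat(sprintf("EnergyProfile: %d frames x %d joints, g = %.4g m/s^2\n",
              nrow(object@energy), ncol(object@energy), object@g))
  cat(sprintf("  energy range [%.4g, %.4g] J\n",
              min(object@energy), max(object@energy)))
})

setMethod("show", "AnomalyScores", function(object) {
  cat(sprintf("AnomalyScores: %d frames x %d joints, |z| >= %.3g\n",
              nrow(object@z), ncol(object@z), object@threshold))
  cat(sprintf("  %d flagged cells, max |z| = %.4g\n",
              sum(object@flags), max(abs(object@z))))
})

setMethod("show", "ModalityBundle", function(object) {
  cat(sprintf("ModalityBundle: %s (%d frames)\n",
              paste(names(object@modalities), collapse = ", "),
              dim(object@modalities[[1L]])[1L]))
})

setMethod("show", "Predictions", function(object) {
  cat(sprintf("Predictions: %d frames, sequence p = %.4f, label %d (threshold %.2f)\n",
              length(object@frameProb), object@seqProb,
              object@label, object@threshold))
})
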