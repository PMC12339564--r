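#' Baseline energy statistics
#'
#' Bundles the two reference quantities anomaly scoring needs: the
#' per-joint expected energy over a reference window of normal motion
#' (used by the deviation score `S`), and the population-level mean and
#' standard deviation of joint energy over a corpus of normal motion (used
#' by the z-score). Keeping both honors the method's two distinct
#' baselines: the window mean localizes, the corpus statistics calibrate.
#'
#' @param window integer frame indices of the reference window (length
#'   `>= 2`).
#' @param expected per-joint mean energy over the window (J vector),
#'   joules.
#' @param mu,sigma corpus-level mean and standard deviation of energy,
#'   either scalars (pooled) or per-joint J vectors (default layout).
#' @param sigmaFloor smallest admissible sigma, default `1e-6` J; a corpus
#'   so degenerate that sigma falls below it is rejected.
#' @return Object of class `BaselineStats`.
#' @export
baselineStats <- function(window, expected, mu, sigma, sigmaFloor = 1e-6) {
  if (length(window) < 2L) stop("reference window must span >= 2 frames")
  if (any(sigma < sigmaFloor))
    stop("energy standard deviation below the ", sigmaFloor,
         " J floor; the reference corpus is degenerate")
  structure(list(window = as.integer(window), expected = expected,
                 mu = mu, sigma = sigma, sigmaFloor = sigmaFloor),
            class = "BaselineStats")
}

#' Expected joint energy over a reference window
#'
#' Per-joint mean of the energy profile over a window of normal-motion
#' frames (2-3 s, i.e. 50-75 frames at 25 Hz, by convention).
#'
#' @param E an [EnergyProfile-class] or `T x J` energy matrix.
#' @param window integer frame indices, all within `[1, T]`, length `>= 2`.
#' @return Numeric J vector of expected energies (joules).
#' @export
expectedEnergy <- function(E, window) {
  E <- if (is(E, "EnergyProfile")) E@energy else as.matrix(E)
  window <- as.integer(window)
  if (length(window) < 2L) stop("reference window must span >= 2 frames")
  if (any(window < 1L) || any(window > nrow(E)))
    stop("window indices outside [1, ", nrow(E), "]")
  colMeans(E[window, , drop = FALSE])
}

#' Energy deviation (anomaly score)
#'
#' Absolute deviation of each joint's energy from its expected baseline,
#' `S[t, j] = |E[t, j] - baseline_j|`. Symmetric in the sign of the
#' deviation and always nonnegative.
#'
#' @param E an [EnergyProfile-class] or `T x J` matrix.
#' @param baseline per-joint expected energy (J vector).
#' @return `T x J` nonnegative matrix, joules.
#' @export
anomalyScore <- function(E, baseline) {
  E <- if (is(E, "EnergyProfile")) E@energy else as.matrix(E)
  if (length(baseline) != ncol(E))
    stop("baseline length must equal the number of joints")
  abs(sweep(E, 2L, baseline))
}

#' Corpus-level energy statistics
#'
#' Mean and standard deviation of joint energy over a corpus of normal
#' motion, per joint by default (each joint's energy scale differs with
#' mass and height) or pooled across joints.
#'
#' @param energies list of `T x J` energy matrices (or [EnergyProfile-class]
#'   objects) from normal sequences.
#' @param perJoint estimate per joint (default) or pooled.
#' @return List with `mu` and `sigma` (J vectors, or scalars if pooled).
#' @export
energyStats <- function(energies, perJoint = TRUE) {
  mats <- lapply(energies, function(e)
    if (is(e, "EnergyProfile")) e@energy else as.matrix(e))
  all <- do.call(rbind, mats)
  if (perJoint) {
    list(mu = colMeans(all), sigma = apply(all, 2L, stats::sd))
  } else {
    list(mu = mean(all), sigma = stats::sd(as.vector(all)))
  }
}

#' Z-score energy against corpus statistics
#'
#' Standard z-transformation `z = (E - mu) / sigma` using the
#' population-level statistics of normal motion, putting joint energies on
#' a comparable scale regardless of joint mass or motion intensity.
#' Invariant under common positive rescaling of `E`, `mu`, `sigma`.
#'
#' @param E an [EnergyProfile-class] or `T x J` matrix.
#' @param stats a [baselineStats()] or a list with `mu`, `sigma` (scalars
#'   or per-joint vectors).
#' @param sigmaFloor reject sigma below this (default `1e-6` J).
#' @return `T x J` matrix of z-scores.
#' @export
zscoreEnergy <- function(E, stats, sigmaFloor = 1e-6) {
  E <- if (is(E, "EnergyProfile")) E@energy else as.matrix(E)
  if (any(stats$sigma < sigmaFloor))
    stop("energy standard deviation below the ", sigmaFloor,
         " J floor; the reference corpus is degenerate")
  if (length(stats$mu) == 1L) {
    (E - stats$mu) / stats$sigma
  } else {
    sweep(sweep(E, 2L, stats$mu), 2L, stats$sigma, "/")
  }
}

#' Sigmoid confidence weight
#'
#' Maps a z-score into the open interval (0, 1) through the logistic
#' function `beta = 1 / (1 + exp(-z))`: 0.5 at zero deviation (typical
#' behavior), approaching the extremes as the deviation grows. A strictly
#' increasing bijection with `beta(z) + beta(-z) = 1`.
#'
#' @param z numeric z-scores (any shape).
#' @return Confidence weights, same shape, strictly inside (0, 1).
#' @examples
#' confidenceWeight(0)        # 0.5
#' confidenceWeight(log(3))   # 0.75
#' @export
confidenceWeight <- function(z) {
  b <- sigmoid(z)
  dim(b) <- dim(z)
  b
}

#' Two-sided standard-normal coverage of a z threshold
#'
#' The probability mass of the standard normal inside `|z| <= threshold`,
#' as a percentage: the confidence level a symmetric z cutoff corresponds
#' to under a Gaussian assumption (about 98.8% at the default 2.5).
#'
#' @param threshold z cutoff, default 2.5.
#' @return Percent coverage in `[0, 100]`.
#' @export
gaussianCoverage <- function(threshold = 2.5) {
  100 * (2 * stats::pnorm(threshold) - 1)
}

#' Flag anomalous (frame, joint) cells
#'
#' Marks every cell with `|z| >= threshold` (inclusive, matching the
#' printed cutoff) and returns a ranked summary of the flagged cells,
#' sorted by `|z|` descending with ties broken by (frame, joint) ascending.
#'
#' @param z `T x J` z-score matrix.
#' @param threshold z cutoff, default 2.5 (98.8% Gaussian coverage).
#' @return List with `flags` (`T x J` logical) and `summary` (data.frame
#'   `frame`, `joint`, `z` of flagged cells in rank order).
#' @export
flagAnomalies <- function(z, threshold = 2.5) {
  z <- as.matrix(z)
  flags <- abs(z) >= threshold
  idx <- which(flags, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    df <- data.frame(frame = idx[, 1L], joint = idx[, 2L],
                     z = z[idx])
    df <- df[order(-abs(df$z), df$frame, df$joint), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(frame = integer(0), joint = integer(0), z = numeric(0))
  }
  list(flags = flags, summary = df)
}

#' Score a sequence end to end
#'
#' Convenience wrapper: energy profile -> window baseline -> deviation `S`,
#' corpus z-score, sigmoid confidence and threshold flags, bundled into an
#' [AnomalyScores-class].
#'
#' @param E an [EnergyProfile-class] or `T x J` matrix.
#' @param stats corpus statistics (list with `mu`, `sigma` or
#'   [baselineStats()]).
#' @param window reference window indices; defaults to the first
#'   `min(T, 50)` frames.
#' @param threshold z flag cutoff, default 2.5.
#' @return An [AnomalyScores-class].
#' @export
scoreSequence <- function(E, stats, window = NULL, threshold = 2.5) {
  Em <- if (is(E, "EnergyProfile")) E@energy else as.matrix(E)
  if (is.null(window)) window <- seq_len(min(nrow(Em), 50L))
  base <- expectedEnergy(Em, window)
  S <- anomalyScore(Em, base)
  z <- zscoreEnergy(Em, stats)
  beta <- confidenceWeight(z)
  fl <- flagAnomalies(z, threshold)
  new("AnomalyScores", S = S, z = z, beta = beta,
      flags = fl$flags, threshold = threshold)
}

#' Confidence-weighted feature refinement
#'
#' Attenuates the channels of each (frame, joint) by that joint's sigmoid
#' confidence weight: `X_refined[t, j, ] = beta[t, j] * X[t, j, ]`,
#' suppressing joints with statistically unlikely energy. With
#' `neutralRescale = TRUE` the factor is `2 beta`, so a joint at zero
#' deviation (`beta = 0.5`) passes through unchanged; by default the
#' literal product is used and the uniform 0.5 scale of neutral joints is
#' absorbed by downstream linear layers.
#'
#' @param X `T x J x F` fused feature tensor.
#' @param beta `T x J` confidence weights.
#' @param neutralRescale multiply by `2 beta` instead of `beta`.
#' @return Refined `T x J x F` tensor.
#' @export
refineFeatures <- function(X, beta, neutralRescale = FALSE) {
  stopifnot(length(dim(X)) == 3L)
  beta <- as.matrix(beta)
  if (!identical(dim(beta), dim(X)[1:2]))
    stop("beta must be T x J matching the feature tensor")
  fac <- if (neutralRescale) 2 * beta else beta
  X * array(fac, dim(X))
}

#' Energy smoothness regularizer
#'
#' Sum over joints of squared frame-to-frame energy changes,
#' `sum_t sum_j (E[t, j] - E[t+1, j])^2` — penalizes high-frequency energy
#' fluctuations from sensor noise or transient artifacts. Homogeneous of
#' degree 2 in the energy scale.
#'
#' @param E an [EnergyProfile-class] or `T x J` matrix.
#' @return Scalar `>= 0`.
#' @export
energySmoothnessReg <- function(E) {
  E <- if (is(E, "EnergyProfile")) E@energy else as.matrix(E)
  if (nrow(E) < 2L) return(0)
  d <- E[-1L, , drop = FALSE] - E[-nrow(E), , drop = FALSE]
  sum(d * d)
}
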