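#' Specification for the synthetic motion corpus
#'
#' All study conditions of the bundled gait simulator in one object:
#' corpus size, sequence length and rate, skeleton size, pose noise,
#' injury prevalence and magnitude, and the mandatory master seed.
#'
#' @param nSequences corpus size, default 200.
#' @param nFrames frames per sequence, default 50 (2 s at 25 Hz).
#' @param nJoints joints, default 15.
#' @param dt frame interval in seconds, default 0.04 (25 Hz).
#' @param noiseSd additive Gaussian pose noise, meters; default 0.002
#'   (marker-based capture jitter; white noise of sd s becomes velocity
#'   noise sqrt(2) s / dt under differentiation, so millimeter-level is
#'   what raw unfiltered differencing tolerates).
#' @param injuryRate fraction of injured sequences, default 0.5.
#' @param injuryMagnitude peak velocity excursion of an injury event, m/s;
#'   default 1.5 (a violent transient - about 1.5 g of added peak
#'   acceleration over 0.32 s - superimposed on normal limb motion).
#' @param injuryDuration event length in frames, default 8 (0.32 s).
#' @param seed master RNG seed (mandatory).
#' @return Object of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nSequences = 200L, nFrames = 50L, nJoints = 15L,
                          dt = 0.04, noiseSd = 0.002, injuryRate = 0.5,
                          injuryMagnitude = 1.5, injuryDuration = 8L,
                          seed) {
  if (missing(seed)) stop("a seed is mandatory for the synthetic corpus")
  stopifnot(nSequences >= 1L, nFrames >= 2L, nJoints >= 2L, dt > 0,
            noiseSd >= 0, injuryRate >= 0, injuryRate <= 1,
            injuryMagnitude >= 0, injuryDuration >= 1L)
  structure(list(nSequences = as.integer(nSequences),
                 nFrames = as.integer(nFrames),
                 nJoints = as.integer(nJoints), dt = dt,
                 noiseSd = noiseSd, injuryRate = injuryRate,
                 injuryMagnitude = injuryMagnitude,
                 injuryDuration = as.integer(injuryDuration),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

## The 15-joint human skeleton: name, parent, rest position (x lateral,
## y walking direction, z vertical, meters).
skeletonTable15 <- function() {
  data.frame(
    name = c("pelvis", "spine", "head",
             "l_shoulder", "l_elbow", "l_wrist",
             "r_shoulder", "r_elbow", "r_wrist",
             "l_hip", "l_knee", "l_ankle",
             "r_hip", "r_knee", "r_ankle"),
    parent = c(NA, "pelvis", "spine",
               "spine", "l_shoulder", "l_elbow",
               "spine", "r_shoulder", "r_elbow",
               "pelvis", "l_hip", "l_knee",
               "pelvis", "r_hip", "r_knee"),
    x = c(0, 0, 0, -0.20, -0.25, -0.28, 0.20, 0.25, 0.28,
          -0.10, -0.10, -0.10, 0.10, 0.10, 0.10),
    y = rep(0, 15),
    z = c(1.00, 1.35, 1.70, 1.45, 1.10, 0.85, 1.45, 1.10, 0.85,
          0.95, 0.50, 0.10, 0.95, 0.50, 0.10),
    stringsAsFactors = FALSE
  )
}

#' Human-like skeleton graph
#'
#' A fixed anatomical tree: pelvis root, spine and head, two arms
#' (shoulder-elbow-wrist) and two legs (hip-knee-ankle). `J = 15` gives
#' exactly this skeleton (14 edges); other sizes truncate or extend the
#' joint list along a chain, preserving the tree property. Masses default
#' to a uniform split of 70 kg. The sensor map routes the IMU channels to
#' every joint and the pressure channels to the two ankles.
#'
#' @param J joint count, default 15.
#' @param massTotal total body mass (kg), default 70.
#' @param selfLoops passed to [skeletonGraph()], default `TRUE`.
#' @return A [SkeletonGraph-class].
#' @export
makeSkeleton <- function(J = 15L, massTotal = 70, selfLoops = TRUE) {
  tab <- skeletonTable15()
  if (J <= 15L) {
    tab <- tab[seq_len(J), , drop = FALSE]
    tab$parent[!(tab$parent %in% tab$name)] <- NA
  } else {
    extra <- J - 15L
    add <- data.frame(
      name = paste0("aux", seq_len(extra)),
      parent = c("head", paste0("aux", seq_len(extra - 1L)))[seq_len(extra)],
      x = 0, y = 0, z = 1.7 + 0.05 * seq_len(extra),
      stringsAsFactors = FALSE)
    tab <- rbind(tab, add)
  }
  ## connect any orphan (after truncation) to the first joint to keep a tree
  orphan <- which(is.na(tab$parent))
  if (length(orphan) > 1L) tab$parent[orphan[-1L]] <- tab$name[1L]
  idx <- seq_len(nrow(tab))
  names(idx) <- tab$name
  edges <- cbind(idx[tab$parent[!is.na(tab$parent)]],
                 idx[tab$name[!is.na(tab$parent)]])
  g <- skeletonGraph(edges, nrow(tab), massTotal = massTotal,
                     selfLoops = selfLoops, jointNames = tab$name,
                     sensorMap = list(
                       imu = unname(idx),
                       pressure = unname(idx[names(idx) %in%
                                             c("l_ankle", "r_ankle")])))
  attr(g, "restPose") <- as.matrix(tab[, c("x", "y", "z")])
  g
}

#' Rest pose of a generated skeleton
#' @param graph a skeleton built by [makeSkeleton()].
#' @return `J x 3` matrix of rest positions (meters).
#' @export
restPose <- function(graph) {
  rp <- attr(graph, "restPose")
  if (is.null(rp)) stop("graph carries no rest pose")
  rp
}

#' Simulate normal (injury-free) gait
#'
#' Each joint oscillates around its rest pose as the sum of two seeded
#' sinusoids — the gait fundamental (default 1 Hz) and its first harmonic
#' — mostly along the walking direction with a smaller vertical bob.
#' Left- and right-side joints move in phase opposition, and distal joints
#' (wrists, ankles) swing with larger amplitude, as in human gait.
#' Gaussian noise of standard deviation `noiseSd` is added to every
#' coordinate. With `noiseSd = 0` the output is exactly periodic with the
#' gait period.
#'
#' @param spec a [syntheticSpec()] (fields `nFrames`, `nJoints`, `dt`,
#'   `noiseSd` are used).
#' @param seed RNG seed for this sequence (defaults to the spec's).
#' @param gaitFreq fundamental frequency, Hz; default 1.
#' @param amplitude base swing amplitude, meters; default 0.15.
#' @param graph optional skeleton from [makeSkeleton()] (built from the
#'   spec otherwise).
#' @return A [MotionSequence-class].
#' @export
simulateNormalMotion <- function(spec, seed = spec$seed, gaitFreq = 1,
                                 amplitude = 0.15, graph = NULL) {
  if (is.null(graph)) graph <- makeSkeleton(spec$nJoints)
  rp <- restPose(graph)
  T <- spec$nFrames; J <- nrow(rp)
  tt <- (seq_len(T) - 1L) * spec$dt
  nm <- jointNames(graph)
  side <- ifelse(startsWith(nm, "l_"), 1, ifelse(startsWith(nm, "r_"), -1, 0))
  distal <- ifelse(grepl("wrist|ankle", nm), 1.3,
                   ifelse(grepl("elbow|knee", nm), 1.0, 0.45))
  pos <- array(0, c(T, J, 3L))
  withSeed(seed, {
    phase2 <- stats::runif(J, 0, 2 * pi)
    for (j in seq_len(J)) {
      amp <- amplitude * distal[j]
      ph <- if (side[j] == 0) 0 else (side[j] + 1) / 2 * pi  # 0 or pi
      swing <- amp * sin(2 * pi * gaitFreq * tt + ph) +
        0.3 * amp * sin(4 * pi * gaitFreq * tt + phase2[j])
      bob <- 0.2 * amp * sin(4 * pi * gaitFreq * tt + ph)
      pos[, j, 1L] <- rp[j, 1L]
      pos[, j, 2L] <- rp[j, 2L] + swing
      pos[, j, 3L] <- rp[j, 3L] + bob
    }
    if (spec$noiseSd > 0) {
      pos <- pos + array(stats::rnorm(length(pos), 0, spec$noiseSd), dim(pos))
    }
  })
  motionSequence(pos, frameRate = 1 / spec$dt, jointNames = nm,
                 verticalAxis = 3L)
}

#' Inject a localized injury event
#'
#' Adds a smooth raised-cosine displacement pulse to one joint over the
#' frames `[onset, onset + duration)`, directed mostly along the walking
#' axis with a vertical component, scaled so the peak added *velocity*
#' equals `magnitude` (m/s). The pulse returns to zero displacement at the
#' end of the window, so only a transient velocity/height excursion — an
#' abnormal mechanical-energy pattern — remains; all other joints are
#' untouched. The raised-cosine envelope keeps the perturbation spectrally
#' tame so smoothness penalties respond to the event itself, not to an
#' injected discontinuity.
#'
#' @param seq a [MotionSequence-class].
#' @param joint target joint index (1-based).
#' @param onset first affected frame (1-based).
#' @param duration event length in frames (`>= 2` within the sequence).
#' @param magnitude peak velocity excursion, m/s.
#' @return List with `seq` (perturbed copy) and `annotation`
#'   (`joint`, `onset`, `duration`, `magnitude`).
#' @export
injectInjury <- function(seq, joint, onset, duration, magnitude) {
  T <- nFrames(seq)
  stopifnot(joint >= 1L, joint <= nJoints(seq),
            onset >= 1L, duration >= 2L, onset + duration - 1L <= T)
  dt <- 1 / seq@frameRate
  pos <- seq@positions
  tau <- seq_len(duration) - 1L
  ## displacement envelope 0 -> A -> 0; peak velocity = A * pi / (duration*dt)
  A <- magnitude * duration * dt / pi
  env <- A * 0.5 * (1 - cos(2 * pi * tau / (duration - 1L)))
  ## the excursion rides along the joint's instantaneous movement direction
  ## (plus an upward component), so the kinetic term grows by construction
  ## instead of partially cancelling against the ongoing gait velocity
  vAtOnset <- if (onset > 1L) {
    pos[onset, joint, 2L] - pos[onset - 1L, joint, 2L]
  } else {
    pos[min(onset + 1L, T), joint, 2L] - pos[onset, joint, 2L]
  }
  ySign <- if (vAtOnset < 0) -1 else 1
  dir <- c(0, 0.8 * ySign, 0.6)       # walking + vertical excursion
  rows <- onset:(onset + duration - 1L)
  for (d in 1:3) pos[rows, joint, d] <- pos[rows, joint, d] + dir[d] * env
  out <- motionSequence(pos, frameRate = seq@frameRate,
                        times = seq@times, jointNames = seq@jointNames,
                        verticalAxis = seq@verticalAxis)
  list(seq = out,
       annotation = list(joint = as.integer(joint),
                         onset = as.integer(onset),
                         duration = as.integer(duration),
                         magnitude = magnitude))
}

#' Simulate co-registered sensor modalities
#'
#' Builds the three-sensor bundle a capture session would produce, each
#' with its characteristic degradation:
#' * `vision` — joint positions plus Gaussian pose noise; seeded occlusion
#'   replaces whole frames with the last observed pose (zero-order hold)
#'   and records a frame mask.
#' * `imu` — per-joint finite-difference accelerations plus a constant
#'   bias drift ramp and Gaussian noise.
#' * `pressure` — a smoothed vertical-force proxy per foot joint
#'   (`m (g + a_z)`, clamped at zero, 3-frame moving average), broadcast
#'   to the ankle joints via the skeleton's sensor map and zero elsewhere.
#'
#' @param seq a [MotionSequence-class].
#' @param graph the matching skeleton (provides masses and the sensor
#'   map).
#' @param seed RNG seed.
#' @param visionNoiseSd vision noise sd (m), default 0.01.
#' @param occlusionProb per-frame occlusion probability, default 0.05.
#' @param imuNoiseSd IMU noise sd (m/s^2), default 0.2.
#' @param driftRate IMU bias ramp rate (m/s^2 per second), default 0.05.
#' @return A [ModalityBundle-class]; the vision array carries the logical
#'   occlusion mask as attribute `"occluded"`.
#' @export
simulateModalities <- function(seq, graph, seed,
                               visionNoiseSd = 0.01, occlusionProb = 0.05,
                               imuNoiseSd = 0.2, driftRate = 0.05) {
  kin <- computeKinematics(seq)
  T <- nFrames(seq); J <- nJoints(seq); D <- nDims(seq)
  g <- 9.81
  withSeed(seed, {
    vision <- seq@positions
    if (visionNoiseSd > 0) {
      vision <- vision + array(stats::rnorm(length(vision), 0, visionNoiseSd),
                               dim(vision))
    }
    occluded <- stats::runif(T) < occlusionProb
    occluded[1L] <- FALSE                     # need one observed frame
    for (t in which(occluded)) vision[t, , ] <- vision[t - 1L, , ]
    attr(vision, "occluded") <- occluded

    imu <- kin@acceleration
    if (imuNoiseSd > 0) {
      imu <- imu + array(stats::rnorm(length(imu), 0, imuNoiseSd), dim(imu))
    }
    tt <- (seq_len(T) - 1L) / seq@frameRate
    bias <- array(stats::rnorm(J * D, 0, 1), c(J, D))
    for (t in seq_len(T)) imu[t, , ] <- imu[t, , ] + driftRate * tt[t] * bias

    pressure <- array(0, c(T, J, 1L))
    feet <- graph@sensorMap$pressure
    if (is.null(feet)) feet <- integer(0)
    for (j in feet) {
      force <- graph@masses[j] *
        pmax(g + kin@acceleration[, j, seq@verticalAxis], 0)
      pressure[, j, 1L] <- stats::filter(force, rep(1 / 3, 3), sides = 2L) |>
        (\(x) ifelse(is.na(x), force, x))()
    }
  })
  modalityBundle(vision = vision, imu = imu, pressure = pressure)
}

#' Generate a labeled synthetic corpus
#'
#' Draws `n` gait sequences under the spec's conditions; a seeded subset
#' of size `round(injuryRate * n)` receives an injected injury at a
#' uniformly drawn joint and onset. Per-sequence seeds are derived from
#' the master seed, so the corpus is fully determined by the spec.
#'
#' @param spec a [syntheticSpec()].
#' @param modalities also simulate the sensor bundle per sequence
#'   (default `FALSE`; the motion sequence alone is enough for most
#'   analyses and much faster).
#' @return Object of class `LabeledCorpus`: a list with `sequences`,
#'   `bundles` (or `NULL`s), integer `labels`, `annotations` (per-sequence
#'   list or `NULL`), `graph`, and the `spec`.
#' @export
makeCorpus <- function(spec, modalities = FALSE) {
  graph <- makeSkeleton(spec$nJoints)
  n <- spec$nSequences
  seeds <- deriveSeeds(spec$seed, 3L * n)
  seqSeeds <- seeds[seq_len(n)]
  injSeeds <- seeds[n + seq_len(n)]
  modSeeds <- seeds[2L * n + seq_len(n)]
  nInjured <- round(spec$injuryRate * n)
  injured <- withSeed(spec$seed + 1L, sample.int(n, nInjured))
  sequences <- vector("list", n)
  bundles <- vector("list", n)
  annotations <- vector("list", n)
  labels <- integer(n)
  for (i in seq_len(n)) {
    s <- simulateNormalMotion(spec, seed = seqSeeds[i], graph = graph)
    if (i %in% injured) {
      ann <- withSeed(injSeeds[i], {
        maxOnset <- spec$nFrames - spec$injuryDuration + 1L
        list(joint = sample.int(spec$nJoints, 1L),
             onset = sample.int(maxOnset, 1L))
      })
      inj <- injectInjury(s, ann$joint, ann$onset,
                          spec$injuryDuration, spec$injuryMagnitude)
      s <- inj$seq
      annotations[[i]] <- inj$annotation
      labels[i] <- 1L
    }
    if (modalities) {
      bundles[[i]] <- simulateModalities(s, graph, seed = modSeeds[i])
    }
    sequences[[i]] <- s
  }
  structure(list(sequences = sequences, bundles = bundles,
                 labels = labels, annotations = annotations,
                 graph = graph, spec = spec),
            class = "LabeledCorpus")
}

#' Stratified train/validation split of a corpus
#'
#' @param corpus a [makeCorpus()] result.
#' @param trainFrac fraction assigned to training, default 0.7.
#' @param seed shuffle seed.
#' @return List with integer index vectors `train` and `val`, label
#'   proportions preserved per stratum.
#' @export
splitCorpus <- function(corpus, trainFrac = 0.7, seed = 1L) {
  labels <- corpus$labels
  withSeed(seed, {
    train <- integer(0)
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      take <- round(trainFrac * length(idx))
      train <- c(train, sample(idx, take))
    }
    train <- sort(train)
    list(train = train, val = setdiff(seq_along(labels), train))
  })
}
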