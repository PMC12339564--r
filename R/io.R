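#' Read a motion CSV
#'
#' Long-format dialect: header `time,joint,x,y,z` (or `time,joint,x,y`
#' for planar data), rows sorted by time then joint, decimal points,
#' UTF-8. Every timestamp must list every joint. Interior runs of missing
#' coordinate values up to 5 frames long are linearly interpolated;
#' longer gaps (or leading/trailing gaps) reject the sequence. Sampling
#' must be uniform.
#'
#' @param path CSV file path.
#' @param verticalAxis 1-based height coordinate; defaults to the last.
#' @param maxGap longest interpolatable interior gap, frames; default 5.
#' @return A [MotionSequence-class].
#' @export
readMotionCsv <- function(path, verticalAxis = NULL, maxGap = 5L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coordCols <- intersect(c("x", "y", "z"), names(df))
  if (!all(c("time", "joint") %in% names(df)) || length(coordCols) < 2L)
    stop("motion CSV needs columns time, joint, x, y[, z]: ", path)
  D <- length(coordCols)
  joints <- unique(df$joint)
  times <- unique(df$time)
  if (is.unsorted(df$time)) {
    bad <- which(diff(df$time) < 0)[1L]
    stop("rows not sorted by time at line ", bad + 2L, " of ", path)
  }
  T <- length(times); J <- length(joints)
  if (nrow(df) != T * J) {
    counts <- table(df$time)
    bad <- names(counts)[counts != J][1L]
    stop("timestamp ", bad, " does not list all ", J, " joints in ", path)
  }
  if (T >= 2L) {
    gaps <- diff(times)
    if (any(abs(gaps - gaps[1L]) > 1e-9)) {
      bad <- which(abs(gaps - gaps[1L]) > 1e-9)[1L]
      stop("non-uniform sampling between frames ", bad, " and ", bad + 1L,
           " of ", path)
    }
  }
  pos <- array(NA_real_, c(T, J, D))
  jIdx <- match(df$joint, joints)
  tIdx <- match(df$time, times)
  for (d in seq_len(D)) {
    pos[cbind(tIdx, jIdx, d)] <- df[[coordCols[d]]]
  }
  pos <- imputeGaps(pos, maxGap = maxGap, path = path)
  frameRate <- if (T >= 2L) 1 / (times[2L] - times[1L]) else 25
  motionSequence(pos, frameRate = frameRate, times = times,
                 jointNames = joints,
                 verticalAxis = if (is.null(verticalAxis)) D else verticalAxis)
}

## Linear interpolation of interior NA runs of length <= maxGap;
## anything longer, or a gap touching either end, rejects the sequence.
imputeGaps <- function(pos, maxGap, path = "<input>") {
  if (!anyNA(pos)) return(pos)
  d <- dim(pos)
  for (j in seq_len(d[2L])) for (k in seq_len(d[3L])) {
    v <- pos[, j, k]
    if (!anyNA(v)) next
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      if (r$lengths[i] > maxGap)
        stop("missing-data gap of ", r$lengths[i], " frames (> ", maxGap,
             ") at joint ", j, " in ", path)
      if (starts[i] == 1L || ends[i] == d[1L])
        stop("missing data at the sequence boundary (joint ", j, ") in ",
             path)
      lo <- starts[i] - 1L; hi <- ends[i] + 1L
      v[starts[i]:ends[i]] <- v[lo] +
        (v[hi] - v[lo]) * (starts[i]:ends[i] - lo) / (hi - lo)
    }
    pos[, j, k] <- v
  }
  pos
}

#' Write a motion CSV
#'
#' Inverse of [readMotionCsv()]: long format sorted by time then joint,
#' full precision (round-trips to at least 1e-9 m).
#'
#' @param seq a [MotionSequence-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotionCsv <- function(seq, path) {
  T <- nFrames(seq); J <- nJoints(seq); D <- nDims(seq)
  coordCols <- c("x", "y", "z")[seq_len(D)]
  df <- data.frame(
    time = rep(seq@times, each = J),
    joint = rep(seq@jointNames, T)
  )
  for (d in seq_len(D)) {
    df[[coordCols[d]]] <- as.vector(t(seq@positions[, , d]))
  }
  utils::write.csv(format(df, digits = 17, scientific = FALSE, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a skeleton JSON
#'
#' Schema: `{"joints": [names], "edges": [[i,j],...] (0-based),
#' "masses": [kg], "vertical_axis": k (0-based), "sensor_map":
#' {modality: [0-based joint indices]}}`. Indices are converted to R's
#' 1-based convention on read.
#'
#' @param path JSON file path.
#' @param selfLoops passed to [skeletonGraph()].
#' @return A [SkeletonGraph-class].
#' @export
readSkeletonJson <- function(path, selfLoops = TRUE) {
  js <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(js$joints) || is.null(js$edges))
    stop("skeleton JSON needs 'joints' and 'edges': ", path)
  edges <- matrix(as.integer(js$edges), ncol = 2L) + 1L
  J <- length(js$joints)
  masses <- if (!is.null(js$masses)) as.numeric(js$masses) else NULL
  sensorMap <- if (!is.null(js$sensor_map)) {
    lapply(js$sensor_map, function(v) as.integer(v) + 1L)
  } else list()
  skeletonGraph(edges, J, masses = masses, selfLoops = selfLoops,
                jointNames = js$joints, sensorMap = sensorMap)
}

#' @rdname readSkeletonJson
#' @param graph a [SkeletonGraph-class] to serialize.
#' @param verticalAxis 0-based vertical axis recorded in the file,
#'   default 2 (the z coordinate).
#' @export
writeSkeletonJson <- function(graph, path, verticalAxis = 2L) {
  js <- list(
    joints = graph@jointNames,
    edges = unname(lapply(seq_len(nrow(graph@edges)), function(i) {
      as.integer(graph@edges[i, ] - 1L)
    })),
    masses = graph@masses,
    vertical_axis = as.integer(verticalAxis),
    sensor_map = lapply(graph@sensorMap, function(v) as.integer(v) - 1L)
  )
  writeLines(as.character(jsonlite::toJSON(js, auto_unbox = FALSE,
                                           digits = NA)), path)
  invisible(path)
}

#' Read a long-format modality CSV
#'
#' Dialect `time,channel,value`; returns a `T x C` matrix with channels
#' as columns in first-appearance order.
#'
#' @param path CSV path.
#' @return Numeric matrix with `dimnames` channel names and attribute
#'   `"times"`.
#' @export
readModalityCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time", "channel", "value") %in% names(df)))
    stop("modality CSV needs columns time, channel, value: ", path)
  times <- unique(df$time)
  channels <- unique(df$channel)
  m <- matrix(NA_real_, length(times), length(channels),
              dimnames = list(NULL, channels))
  m[cbind(match(df$time, times), match(df$channel, channels))] <- df$value
  attr(m, "times") <- times
  m
}

#' Read / write sequence labels CSV
#'
#' Dialect `sequence,label` with 0/1 labels.
#' @param path CSV path.
#' @return Integer label vector named by sequence id.
#' @export
readLabelsCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("sequence", "label") %in% names(df)))
    stop("labels CSV needs columns sequence, label: ", path)
  stats::setNames(as.integer(df$label), df$sequence)
}

#' @rdname readLabelsCsv
#' @param labels integer 0/1 vector (names used as sequence ids).
#' @export
writeLabelsCsv <- function(labels, path) {
  ids <- names(labels)
  if (is.null(ids)) ids <- sprintf("seq%03d", seq_along(labels))
  utils::write.csv(data.frame(sequence = ids, label = as.integer(labels)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Recognized configuration keys and their defaults (YAML surface).
configDefaults <- function() {
  list(
    motion = NULL, skeleton = NULL, modalities = NULL, labels = NULL,
    output_dir = ".",
    gcn_dims = c(16L, 16L), d_prime = 16L, include_jerk = TRUE,
    hidden_dim = 32L, context_window = 10L, k = 5L,
    lambda = 0, lambda1 = 0, lambda2 = 0, lambda3 = 0, gamma = 0,
    z_threshold = 2.5, decision_threshold = 0.5,
    lr = 1e-4, epochs = 15L, batch_size = 32L, clip_norm = 10,
    n_sequences = 200L, n_frames = 50L, n_joints = 15L, dt = 0.04,
    noise_sd = 0.002, injury_rate = 0.5, injury_magnitude = 1.5,
    injury_duration = 8L,
    seed = 1L, verbose = FALSE
  )
}

#' Read a YAML run configuration
#'
#' Validates against the known key set (unknown keys are an error, not a
#' silent ignore), fills defaults, and records an MD5 provenance hash of
#' the resolved configuration.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @param overrides named list applied after the file.
#' @return Named list of class `RunConfig` with attribute `"hash"`.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- configDefaults()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, user)
  structure(cfg, class = "RunConfig", hash = hashObject(cfg))
}

## RunConfig -> the typed objects the pipeline consumes.
configToDetector <- function(cfg) {
  detectorConfig(
    gcnDims = cfg$gcn_dims, dPrime = cfg$d_prime,
    includeJerk = cfg$include_jerk, hiddenDim = cfg$hidden_dim,
    weights = lossWeights(lambda = cfg$lambda, lambda1 = cfg$lambda1,
                          lambda2 = cfg$lambda2, lambda3 = cfg$lambda3,
                          k = cfg$k, gamma = cfg$gamma),
    zThreshold = cfg$z_threshold,
    decisionThreshold = cfg$decision_threshold,
    lr = cfg$lr, epochs = cfg$epochs, batchSize = cfg$batch_size,
    clipNorm = cfg$clip_norm)
}

configToSpec <- function(cfg) {
  syntheticSpec(nSequences = cfg$n_sequences, nFrames = cfg$n_frames,
                nJoints = cfg$n_joints, dt = cfg$dt,
                noiseSd = cfg$noise_sd, injuryRate = cfg$injury_rate,
                injuryMagnitude = cfg$injury_magnitude,
                injuryDuration = cfg$injury_duration, seed = cfg$seed)
}

#' Write a run manifest
#'
#' Every CLI run emits a manifest recording the schema version, the
#' resolved configuration and its hash, the seed, and the files written.
#' Timestamps go to the log, not the manifest, so identical runs produce
#' byte-identical manifests.
#'
#' @param path output JSON path.
#' @param config the `RunConfig` used.
#' @param outputs named list/vector of files written.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(path, config, outputs = list()) {
  man <- list(schema = 1L,
              config = unclass(config),
              config_hash = attr(config, "hash"),
              seed = config$seed,
              outputs = outputs)
  writeLines(as.character(jsonlite::toJSON(man, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             path)
  invisible(path)
}
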