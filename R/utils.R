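#' @importFrom methods new validObject is slot slotNames
#' @importFrom stats rnorm runif plogis pnorm sd
#' @importFrom utils read.csv write.csv head modifyList
NULL

## Row-wise softmax with the usual max-shift for overflow safety.
## Works on a matrix (each row normalized) or a plain vector.
softmaxRows <- function(x) {
  if (is.null(dim(x))) {
    z <- exp(x - max(x))
    return(z / sum(z))
  }
  m <- apply(x, 1L, max)
  z <- exp(x - m)
  z / rowSums(z)
}

sigmoid <- function(x) stats::plogis(x)

reluAct <- function(x) pmax(x, 0)

## Named activation registry; identity is kept for oracle tests.
getActivation <- function(name) {
  switch(name,
    relu = reluAct,
    identity = identity,
    tanh = tanh,
    stop("unknown activation: ", name)
  )
}

## Glorot/Xavier uniform initialization: uniform(-a, a),
## a = sqrt(6 / (fan_in + fan_out)). Draws consume the current RNG stream.
glorotUniform <- function(fanIn, fanOut) {
  a <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(fanIn * fanOut, -a, a), fanIn, fanOut)
}

## Deterministic child seeds derived from one master seed, each < 2^31,
## so parallel or out-of-order generation stays reproducible.
deriveSeeds <- function(seed, n) {
  old <- globalenv()$.Random.seed
  on.exit(restoreSeed(old), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

restoreSeed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

withSeed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit(restoreSeed(old), add = TRUE)
  set.seed(seed)
  expr
}

## L2 norm along the last margin of a T x J x D array -> T x J matrix.
normTJ <- function(arr) {
  d <- dim(arr)
  sqrt(apply(arr * arr, c(1L, 2L), sum))
}

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(TRUE)
}

## Canonical MD5 of an R object via its JSON rendering (used for config
## provenance hashes in manifests).
hashObject <- function(x) {
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  writeLines(as.character(js), tf)
  unname(tools::md5sum(tf))
}
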