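.log_state <- new.env(parent = emptyenv())
.log_state$verbose <- FALSE

setVerbose <- function(on = TRUE) {
  old <- .log_state$verbose
  .log_state$verbose <- isTRUE(on)
  invisible(old)
}

logInfo <- function(...) {
  if (.log_state$verbose) message("INFO  ", sprintf(...))
  invisible(NULL)
}

logWarn <- function(...) {
  warning(sprintf(...), call. = FALSE)
  invisible(NULL)
}

# 0-based voxel indices of all nonzero entries of an array, as an N x 3 matrix
nonzeroIndices <- function(arr) {
  idx <- which(arr != 0)
  arrayInd(idx, dim(arr)) - 1L
}

# per-row L2 norm
rowNorms <- function(m) sqrt(rowSums(m^2))

# affine helper: world voxel spacing along each axis
voxelSpacing <- function(affine) sqrt(colSums(affine[1:3, 1:3, drop = FALSE]^2))

# nearest known name by edit distance (<= maxDist), or NA
nearestName <- function(name, known, maxDist = 3L) {
  d <- utils::adist(name, known)[1L, ]
  i <- which.min(d)
  if (d[i] <= maxDist) known[i] else NA_character_
}

# world x coordinate of every voxel of a grid (0-based indices), as an array
worldXGrid <- function(dims, affine) {
  i <- seq_len(dims[1]) - 1
  j <- seq_len(dims[2]) - 1
  k <- seq_len(dims[3]) - 1
  outer(outer(affine[1, 1] * i, affine[1, 2] * j, `+`),
        affine[1, 3] * k, `+`) + affine[1, 4]
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
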