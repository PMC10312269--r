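# Template rendering styles: glass, surface, filled, cloudy.
#
# Each style converts a BrainVolume into renderable geometry: a Mesh
# (surface) or a PointCloud (glass/cloudy/filled). Default alphas: surface
# 1.0, glass 0.01 per point, cloudy 0.05, filled 0.2.

.templateStyleAlphas <- c(surface = 1.0, glass = 0.01, cloudy = 0.05,
                          filled = 0.2)

#' Binarize a volume
#'
#' @param v a \linkS4class{BrainVolume}.
#' @param level threshold; the mask is `grid > level` (default 0).
#' @return a \linkS4class{BrainVolume} whose grid is 0/1.
#' @export
binarizeVolume <- function(v, level = 0) {
  stopifnot(is(v, "BrainVolume"))
  new("BrainVolume", grid = (v@grid > level) * 1.0, affine = v@affine,
      spaceName = v@spaceName)
}

# logical array of mask voxels with >= 1 background 6-neighbor
# (the grid boundary counts as background)
.surfaceVoxels <- function(mask) {
  d <- dim(mask)
  hasBg <- array(FALSE, d)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    nb <- array(FALSE, d)   # neighbor-in-mask indicator; FALSE off-grid
    xs <- max(1, 1 + sh[1]):min(d[1], d[1] + sh[1])
    ys <- max(1, 1 + sh[2]):min(d[2], d[2] + sh[2])
    zs <- max(1, 1 + sh[3]):min(d[3], d[3] + sh[3])
    nb[xs - sh[1], ys - sh[2], zs - sh[3]] <- mask[xs, ys, zs]
    hasBg <- hasBg | !nb
  }
  mask & hasBg
}

#' Cloudy template geometry
#'
#' A semi-transparent cloud of the mask's surface-adjacent voxels: mask
#' voxels with at least one background 6-neighbor (the grid boundary counts
#' as background).
#'
#' @param v a \linkS4class{BrainVolume}.
#' @param level binarization threshold (default 0).
#' @param alpha per-point opacity (default 0.05).
#' @return a \linkS4class{PointCloud}.
#' @export
cloudyGeometry <- function(v, level = 0, alpha = 0.05) {
  mask <- v@grid > level
  if (!any(mask)) stopf("volume is empty after binarization")
  vox <- which(.surfaceVoxels(mask))
  idx <- arrayInd(vox, dim(mask)) - 1L
  new("PointCloud", points = voxelToWorld(idx, v@affine), alpha = alpha,
      size = 1)
}

#' Filled template geometry
#'
#' Plots each mask voxel as one point at its world-mm center. An optional
#' `voxelsize` routes through [downsampleVolume()] first — the documented
#' performance lever for this memory-heavy style.
#'
#' @param v a \linkS4class{BrainVolume}.
#' @param voxelsize optional coarser voxel size in mm.
#' @param level binarization threshold (default 0).
#' @param alpha per-point opacity (default 0.2).
#' @return a \linkS4class{PointCloud}.
#' @export
filledGeometry <- function(v, voxelsize = NULL, level = 0, alpha = 0.2) {
  if (!is.null(voxelsize)) v <- downsampleVolume(v, voxelsize)
  mask <- v@grid > level
  if (!any(mask)) stopf("volume is empty after binarization")
  idx <- arrayInd(which(mask), dim(mask)) - 1L
  new("PointCloud", points = voxelToWorld(idx, v@affine), alpha = alpha,
      size = 1)
}

# SLIC-style supervoxel segmentation of the masked volume: seeds on a
# regular grid inside the mask, then k-means-like refinement under the
# combined intensity/spatial distance D^2 = d_int^2 + (compactness * d_s/S)^2.
# Returns an integer label per mask voxel (vector parallel to `which(mask)`).
.superVoxels <- function(grid, mask, segments, compactness, iters = 5L) {
  vox <- arrayInd(which(mask), dim(mask))
  n <- nrow(vox)
  intens <- grid[mask]
  rng <- range(intens)
  if (diff(rng) > 0) intens <- (intens - rng[1]) / diff(rng)
  S <- max(1, (n / segments)^(1 / 3))
  lo <- apply(vox, 2, min)
  hi <- apply(vox, 2, max)
  gridAxes <- lapply(1:3, function(k) seq(lo[k] + S / 2, hi[k], by = S))
  cand <- round(as.matrix(expand.grid(gridAxes[[1]], gridAxes[[2]],
                                      gridAxes[[3]])))
  cand <- cand[mask[cand], , drop = FALSE]       # keep grid seeds in-mask
  if (!nrow(cand)) cand <- vox[1, , drop = FALSE]
  look <- array(NA_real_, dim(mask))
  look[mask] <- intens
  seeds <- unique(cbind(cand, look[cand]))
  lab <- integer(n)
  for (it in seq_len(iters)) {
    best <- rep(Inf, n)
    for (s in seq_len(nrow(seeds))) {
      ds2 <- (vox[, 1] - seeds[s, 1])^2 + (vox[, 2] - seeds[s, 2])^2 +
        (vox[, 3] - seeds[s, 3])^2
      D2 <- (intens - seeds[s, 4])^2 + (compactness / S)^2 * ds2
      upd <- D2 < best
      best[upd] <- D2[upd]
      lab[upd] <- s
    }
    seeds <- cbind(rowsum(vox, lab), rowsum(intens, lab)) /
      as.vector(table(lab))
  }
  lab
}

#' Glass template geometry
#'
#' The translucent "glass brain" outline: the volume is segmented into
#' supervoxels (SLIC-style, grid-seeded and deterministic) and the voxels on
#' segment borders — internal intensity borders and the external mask border
#' — are returned as a sparse, low-alpha point cloud.
#'
#' @param v a \linkS4class{BrainVolume}.
#' @param segments target supervoxel count (default 500).
#' @param compactness spatial/intensity weighting; higher values favor
#'   compact, evenly sized segments (default 0.05).
#' @param level binarization threshold for the mask (default 0).
#' @param alpha per-point opacity (default 0.01).
#' @param mergeTol adjacent supervoxels whose mean (normalized) intensities
#'   differ by less than this are merged before border extraction, so
#'   borders trace intensity structure rather than the arbitrary supervoxel
#'   tiling; a uniform solid therefore yields only its outer shell.
#' @return a \linkS4class{PointCloud}.
#' @export
glassGeometry <- function(v, segments = 500, compactness = 0.05, level = 0,
                          alpha = 0.01, mergeTol = 0.02) {
  mask <- v@grid > level
  if (!any(mask)) stopf("volume is empty after binarization")
  lab <- .superVoxels(v@grid, mask, segments, compactness)
  lab <- .mergeFlatSegments(v@grid, mask, lab, mergeTol)
  labGrid <- array(0L, dim(mask))
  labGrid[mask] <- lab
  # border voxels: any 6-neighbor with a different label (incl. background)
  d <- dim(mask)
  border <- array(FALSE, d)
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                  c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (s in seq_len(nrow(shifts))) {
    sh <- shifts[s, ]
    nb <- array(0L, d)      # 0 = off-grid/background
    xs <- max(1, 1 + sh[1]):min(d[1], d[1] + sh[1])
    ys <- max(1, 1 + sh[2]):min(d[2], d[2] + sh[2])
    zs <- max(1, 1 + sh[3]):min(d[3], d[3] + sh[3])
    nb[xs - sh[1], ys - sh[2], zs - sh[3]] <- labGrid[xs, ys, zs]
    border <- border | (nb != labGrid)
  }
  border <- border & mask
  idx <- arrayInd(which(border), d) - 1L
  new("PointCloud", points = voxelToWorld(idx, v@affine), alpha = alpha,
      size = 0.7)
}

# union adjacent segments whose mean normalized intensities are within tol
.mergeFlatSegments <- function(grid, mask, lab, tol) {
  if (tol <= 0) return(lab)
  intens <- grid[mask]
  rng <- range(intens)
  if (diff(rng) > 0) intens <- (intens - rng[1]) / diff(rng)
  means <- as.vector(rowsum(intens, lab) / as.vector(table(lab)))
  labGrid <- array(0L, dim(mask))
  labGrid[mask] <- lab
  d <- dim(mask)
  pairs <- matrix(integer(0), 0, 2)
  for (ax in 1:3) {
    idxA <- lapply(seq_along(d), function(k)
      if (k == ax) seq_len(d[k] - 1L) else seq_len(d[k]))
    idxB <- lapply(seq_along(d), function(k)
      if (k == ax) 1L + seq_len(d[k] - 1L) else seq_len(d[k]))
    a <- labGrid[idxA[[1]], idxA[[2]], idxA[[3]]]
    b <- labGrid[idxB[[1]], idxB[[2]], idxB[[3]]]
    touch <- a != 0L & b != 0L & a != b
    if (any(touch))
      pairs <- rbind(pairs, unique(cbind(a[touch], b[touch])))
  }
  if (!nrow(pairs)) return(lab)
  parent <- seq_along(means)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    if (abs(means[a] - means[b]) < tol) {
      ra <- find(a); rb <- find(b)
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(means), find, integer(1))
  roots[lab]
}

#' Dispatch a template style to its geometry
#'
#' Routes the `template_style` option to the matching geometry operation:
#' `glass`, `surface`, `filled`, `cloudy`, or `none` (no template layer).
#'
#' @param style style name.
#' @param v a \linkS4class{BrainVolume} (ignored for `none`).
#' @param options template option list as resolved by [resolveOptions()]
#'   (alpha, level, voxelsize, segments, compactness, color).
#' @return a list layer (`kind`, `geometry`, `alpha`, `color`), or `NULL`
#'   for `none`.
#' @export
styleDispatch <- function(style, v, options = list()) {
  valid <- c("glass", "surface", "filled", "cloudy")
  if (!is.character(style) || length(style) != 1L ||
      !style %in% c(valid, "none"))
    stopf("unknown template style '%s'; valid styles: %s", style,
          paste(sQuote(valid), collapse = ", "))
  if (style == "none") return(NULL)
  level <- options$level %||% 0
  alpha <- options$alpha %||% unname(.templateStyleAlphas[style])
  color <- options$color %||% "lightgray"
  geom <- switch(style,
    surface = extractSurface(binarizeVolume(v, level)),
    glass = glassGeometry(v, segments = options$segments %||% 500,
                          compactness = options$compactness %||% 0.05,
                          level = level, alpha = alpha),
    cloudy = cloudyGeometry(v, level = level, alpha = alpha),
    filled = filledGeometry(v, voxelsize = options$voxelsize, level = level,
                            alpha = alpha))
  list(kind = if (is(geom, "Mesh")) "mesh" else "points",
       geometry = geom, alpha = alpha, color = color, style = style)
}
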