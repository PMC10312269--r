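# Volumetric I/O and voxel/world geometry.
#
# Volumes are NIfTI-1 files (.nii, optionally gzipped); the affine is taken
# from the file header and every volume is reoriented to RAS on load so that
# world x increases to the subject's right (the hemisphere logic and the
# anatomical view letters rely on this convention).

#' Load a 3D NIfTI volume
#'
#' Reads a NIfTI-1 image (optionally gzip-compressed), reorients it to RAS
#' and returns it as a \linkS4class{BrainVolume}. 4D inputs with a singleton
#' trailing dimension are squeezed; anything with more than three
#' non-singleton dimensions is rejected.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a \linkS4class{BrainVolume}.
#' @export
loadVolume <- function(path) {
  if (!is.character(path) || length(path) != 1L)
    stopf("path must be a single file path")
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L) {
    keep <- d > 1L
    if (sum(keep) > 3L)
      stopf("volume has %d non-singleton dimensions; only 3D is supported",
            sum(keep))
    img <- RNifti::asNifti(array(as.numeric(img), dim = d[keep]),
                           reference = img)
    d <- dim(img)
  }
  if (length(d) < 3L)
    stopf("volume is %dD; a 3D image is required", length(d))
  hasXform <- isTRUE(attr(RNifti::xform(img), "code") > 0)
  if (hasXform) RNifti::orientation(img) <- "RAS"   # else affine is pixdim
  aff <- RNifti::xform(img)
  grid <- array(as.numeric(img), dim = dim(img))
  new("BrainVolume", grid = grid, affine = matrix(as.numeric(aff), 4, 4))
}

#' Write a BrainVolume to a NIfTI file
#'
#' @param v a \linkS4class{BrainVolume}.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
writeVolume <- function(v, path) {
  stopifnot(is(v, "BrainVolume"))
  img <- RNifti::asNifti(v@grid)
  RNifti::pixdim(img) <- voxelSpacing(v@affine)   # qform encodes spacing here
  RNifti::sform(img) <- structure(v@affine, code = 2L)
  RNifti::qform(img) <- structure(v@affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Coerce a BrainVolume to a Parcellation
#'
#' @param v a \linkS4class{BrainVolume} whose grid holds non-negative integer
#'   labels (0 = background).
#' @return a \linkS4class{Parcellation}.
#' @export
asParcellation <- function(v) {
  if (is(v, "Parcellation")) return(v)
  stopifnot(is(v, "BrainVolume"))
  g <- v@grid
  if (any(g < 0) || max(abs(g - round(g))) > 0)
    stopf("volume is not a parcellation: values must be non-negative integers")
  g <- round(g)
  labs <- sort(unique(as.integer(g[g != 0])))
  new("Parcellation", grid = g, affine = v@affine, spaceName = v@spaceName,
      labels = labs)
}

#' Map voxel indices to world coordinates
#'
#' Applies the affine to 0-based voxel indices: the world position of voxel
#' `(i, j, k)` is the first three components of `affine %*% c(i, j, k, 1)`.
#'
#' @param indices length-3 vector or N x 3 matrix of 0-based voxel indices
#'   (fractional indices are allowed; centroids live in continuous index
#'   space).
#' @param affine 4x4 voxel-to-world matrix.
#' @return world coordinates, same shape as the input (N x 3 or length 3).
#' @export
voxelToWorld <- function(indices, affine) {
  single <- is.null(dim(indices))
  m <- if (single) matrix(indices, 1, 3) else as.matrix(indices)
  out <- m %*% t(affine[1:3, 1:3]) +
    matrix(affine[1:3, 4], nrow(m), 3, byrow = TRUE)
  if (single) drop(out) else out
}

#' @rdname voxelToWorld
#' @param coords world-mm coordinates (length-3 vector or N x 3 matrix).
#' @export
worldToVoxel <- function(coords, affine) {
  voxelToWorld(coords, solve(affine))
}

#' Extract per-label centroids from a parcellation
#'
#' One node per nonzero label, in ascending integer-label order. A label's
#' centroid is the mean of its voxel indices (continuous, 0-based) mapped
#' through the affine into world mm — the location edges are drawn between.
#'
#' @param p a \linkS4class{Parcellation} with at least one label.
#' @return canonical node table with columns `node_id`, `x`, `y`, `z` and a
#'   `label` metadata column.
#' @export
computeCentroids <- function(p) {
  stopifnot(is(p, "Parcellation"))
  g <- p@grid
  idx <- which(g != 0)
  if (!length(idx))
    stopf("parcellation is empty (all background)")
  labs <- as.integer(g[idx])
  vox <- arrayInd(idx, dim(g)) - 1L
  sums <- rowsum(vox, labs)                     # groups sorted numerically
  counts <- as.vector(table(labs))
  centroids <- sums / counts
  world <- voxelToWorld(centroids, p@affine)
  data.frame(node_id = seq_len(nrow(world)) - 1L,
             x = world[, 1], y = world[, 2], z = world[, 3],
             label = sort(unique(labs)))
}

#' Downsample a volume to a coarser voxel size
#'
#' Resamples to (approximately) the requested isotropic voxel size by
#' aggregating whole blocks of voxels: block-mean for intensity volumes,
#' modal label (background excluded from the vote unless the block is all
#' background) for \linkS4class{Parcellation}s. The affine is updated so each
#' output voxel sits at the world-space center of its block; world extent is
#' preserved within one output voxel. This is the documented performance
#' lever for the `filled` template style.
#'
#' @param v a \linkS4class{BrainVolume} or \linkS4class{Parcellation}.
#' @param voxelsize requested voxel size in mm; must be at least the native
#'   voxel size (upsampling is unsupported).
#' @return volume of the same class, resampled.
#' @export
downsampleVolume <- function(v, voxelsize) {
  stopifnot(is(v, "BrainVolume"))
  if (!is.numeric(voxelsize) || length(voxelsize) != 1L || voxelsize <= 0)
    stopf("voxelsize must be a positive number (mm)")
  spacing <- voxelSpacing(v@affine)
  if (voxelsize < min(spacing) - 1e-9)
    stopf("voxelsize %g mm is below the native voxel size %g mm; %s",
          voxelsize, min(spacing), "upsampling is unsupported")
  f <- pmax(1L, as.integer(round(voxelsize / spacing)))
  if (all(f == 1L)) return(v)
  d <- dim(v@grid)
  nout <- as.integer(ceiling(d / f))
  pad <- array(NA_real_, dim = nout * f)
  pad[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- v@grid
  blocks <- array(pad, dim = c(f[1], nout[1], f[2], nout[2], f[3], nout[3]))
  blocks <- aperm(blocks, c(1, 3, 5, 2, 4, 6))
  bm <- matrix(blocks, nrow = prod(f), ncol = prod(nout))

  isParc <- is(v, "Parcellation")
  if (isParc) {
    vals <- apply(bm, 2L, function(col) {
      col <- col[!is.na(col)]
      nz <- col[col != 0]
      if (!length(nz)) return(0)
      tab <- table(nz)
      as.numeric(names(tab)[which.max(tab)])   # ties: lowest label
    })
  } else {
    vals <- colMeans(bm, na.rm = TRUE)
  }
  grid <- array(vals, dim = nout)

  aff <- v@affine
  aff[1:3, 1:3] <- v@affine[1:3, 1:3] %*% diag(f)
  aff[1:3, 4] <- v@affine[1:3, 1:3] %*% ((f - 1) / 2) + v@affine[1:3, 4]
  if (isParc) {
    labs <- sort(unique(as.integer(grid[grid != 0])))
    new("Parcellation", grid = grid, affine = aff, spaceName = v@spaceName,
        labels = labs)
  } else {
    new("BrainVolume", grid = grid, affine = aff, spaceName = v@spaceName)
  }
}

#' Restrict a volume or a node/edge set to one hemisphere
#'
#' Under the RAS convention the left hemisphere is world `x <= 0` and the
#' right is `x >= 0`; elements exactly on the midline (`x == 0`) belong to
#' both sides. For volumes, voxels strictly on the other side are zeroed.
#' For node tables, nodes on the other side are dropped and, when an edge
#' table is supplied, any edge losing an endpoint is removed — only the
#' connections within the hemisphere are shown.
#'
#' @param x a \linkS4class{BrainVolume} or a canonical node table.
#' @param side `'L'` or `'R'`.
#' @param edges optional edge table accompanying a node table.
#' @return the restricted volume, or `list(nodes=, edges=)` for tables.
#' @export
hemisphereRestrict <- function(x, side, edges = NULL) {
  if (!is.character(side) || length(side) != 1L || !side %in% c("L", "R"))
    stopf("side must be 'L' or 'R'")
  if (is(x, "BrainVolume")) {
    wx <- worldXGrid(dim(x@grid), x@affine)
    drop <- if (side == "L") wx > 0 else wx < 0
    g <- x@grid
    g[drop] <- 0
    if (is(x, "Parcellation")) {
      labs <- sort(unique(as.integer(g[g != 0])))
      return(new("Parcellation", grid = g, affine = x@affine,
                 spaceName = x@spaceName, labels = labs))
    }
    return(new("BrainVolume", grid = g, affine = x@affine,
               spaceName = x@spaceName))
  }
  nodes <- validateNodeTable(x)
  keep <- if (side == "L") nodes$x <= 0 else nodes$x >= 0
  kept <- nodes[keep, , drop = FALSE]
  rownames(kept) <- NULL
  if (is.null(edges)) return(list(nodes = kept, edges = NULL))
  ids <- kept$node_id
  ekeep <- edges$i %in% ids & edges$j %in% ids
  keptEdges <- edges[ekeep, , drop = FALSE]
  rownames(keptEdges) <- NULL
  logInfo("hemisphere %s: kept %d/%d nodes, %d/%d edges", side,
          nrow(kept), nrow(nodes), nrow(keptEdges), nrow(edges))
  list(nodes = kept, edges = keptEdges)
}

#' Resolve a template identifier to a volume
#'
#' Paths and in-memory volumes pass straight through [loadVolume()]. A bare
#' space-name string is resolved through the supplied `fetcher`: a segmented
#' anatomical (T1w) image is sought first and, when the space provides none,
#' the binary brain mask is used instead; the chosen variant is recorded in
#' the volume's `spaceName` as `"<space>/<variant>"`.
#'
#' @param identifier a \linkS4class{BrainVolume}, a NIfTI path, or a
#'   template-space name.
#' @param fetcher resolver `function(space, query)` returning a path or
#'   `NULL`; required for space-name identifiers (see [localFetcher()]).
#' @return a \linkS4class{BrainVolume}.
#' @export
selectTemplateImage <- function(identifier, fetcher = NULL) {
  if (is(identifier, "BrainVolume")) return(identifier)
  if (!is.character(identifier) || length(identifier) != 1L)
    stopf("template must be a volume, a file path or a space name")
  if (file.exists(identifier) || grepl("\\.nii(\\.gz)?$", identifier))
    return(loadVolume(identifier))
  if (is.null(fetcher))
    stopf("template space name '%s' requires a fetcher to resolve it",
          identifier)
  queried <- character()
  p <- .queryFetcher(fetcher, list(space = identifier),
                     suffix = "T1w", desc = "brain")
  variant <- "T1w"
  queried <- c(queried, "suffix=T1w desc=brain")
  if (is.null(p)) {
    p <- .queryFetcher(fetcher, list(space = identifier),
                       suffix = "mask", desc = "brain")
    variant <- "mask"
    queried <- c(queried, "suffix=mask desc=brain")
    if (!is.null(p))
      logInfo("template %s: no segmented T1w image; using the brain mask",
              identifier)
  }
  if (is.null(p))
    stopf("template space '%s' could not be resolved; queried: %s",
          identifier, paste(queried, collapse = "; "))
  v <- loadVolume(p)
  v@spaceName <- paste0(identifier, "/", variant)
  v
}

# normalize a descriptor + extras into a fetcher call
.queryFetcher <- function(fetcher, spec, ...) {
  extras <- list(...)
  space <- spec$space %||% spec$template
  query <- spec[setdiff(names(spec), c("space", "template"))]
  for (nm in names(extras))
    if (is.null(query[[nm]])) query[[nm]] <- extras[[nm]]
  fetcher(space, query)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Offline resolver over a TemplateFlow-style directory tree
#'
#' Returns a fetcher `function(space, query)` that searches `dir`
#' (recursively) for NIfTI files following the template-repository naming
#' scheme (`tpl-<space>_..._<suffix>.nii[.gz]`, with `atlas-`, `desc-` and
#' `res-` entities). All query keys present must match; `NULL` is returned
#' when nothing does.
#'
#' @param dir root directory of the local template tree.
#' @return a fetcher function usable with [selectTemplateImage()] and
#'   [parseNodes()].
#' @export
localFetcher <- function(dir) {
  force(dir)
  function(space, query = list()) {
    files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", recursive = TRUE,
                        full.names = TRUE)
    if (!length(files) || is.null(space)) return(NULL)
    base <- basename(files)
    ok <- grepl(paste0("^(tpl-)?", space, "_"), base)
    if (!is.null(query$suffix))
      ok <- ok & grepl(paste0("_", query$suffix, "\\.nii(\\.gz)?$"), base)
    for (key in c("atlas", "desc")) {
      if (!is.null(query[[key]]))
        ok <- ok & grepl(paste0(key, "-", query[[key]], "(_|\\.)"), base)
    }
    if (!is.null(query$resolution))
      ok <- ok & grepl(sprintf("res-0*%s(_|\\.)", query$resolution), base)
    hits <- sort(files[ok])
    if (length(hits)) hits[1] else NULL
  }
}
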