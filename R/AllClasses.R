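#' @import methods
NULL

#' BrainVolume: a 3D intensity grid in world (mm) space
#'
#' Container for a volumetric image: a 3D array of intensities plus the 4x4
#' affine matrix mapping homogeneous 0-based voxel indices to world
#' millimetres (RAS orientation: x increases to the subject's right).
#'
#' @slot grid 3D numeric array of intensities.
#' @slot affine 4x4 numeric matrix; \code{affine \%*\% c(i, j, k, 1)} gives the
#'   world-mm position of voxel \code{(i, j, k)} (0-based).
#' @slot spaceName optional identifier of the template space this volume lives
#'   in (e.g. a standard-space name); \code{NA_character_} when unknown.
#' @export
setClass("BrainVolume",
  representation(grid = "array", affine = "matrix", spaceName = "character"),
  prototype(spaceName = NA_character_))

setValidity("BrainVolume", function(object) {
  msg <- character()
  if (length(dim(object@grid)) != 3L)
    msg <- c(msg, "grid must be a 3D array")
  if (any(dim(object@grid) < 1L))
    msg <- c(msg, "all grid dimensions must be >= 1")
  if (!all(dim(object@affine) == c(4L, 4L)))
    msg <- c(msg, "affine must be a 4x4 matrix")
  else if (abs(det(object@affine)) < 1e-12)
    msg <- c(msg, "affine must be invertible")
  if (length(object@spaceName) != 1L)
    msg <- c(msg, "spaceName must be a single string")
  if (length(msg)) msg else TRUE
})

#' Parcellation: an integer-labeled BrainVolume
#'
#' A \linkS4class{BrainVolume} whose voxel values are non-negative integer
#' region labels; 0 is background and each nonzero label defines one network
#' node.
#'
#' @slot labels sorted integer vector of the nonzero labels present.
#' @export
setClass("Parcellation", contains = "BrainVolume",
  representation(labels = "integer"))

setValidity("Parcellation", function(object) {
  g <- object@grid
  if (any(g < 0) || any(g != round(g)))
    return("parcellation grid values must be non-negative integers")
  present <- sort(unique(as.integer(g[g != 0])))
  if (!identical(present, object@labels))
    return("labels slot must equal the sorted nonzero labels present in grid")
  TRUE
})

#' Triangle mesh in world coordinates
#'
#' @slot vertices V x 3 numeric matrix of world-mm positions.
#' @slot faces F x 3 integer matrix of 1-based vertex indices.
#' @export
setClass("Mesh", representation(vertices = "matrix", faces = "matrix"))

setValidity("Mesh", function(object) {
  msg <- character()
  if (ncol(object@vertices) != 3L) msg <- c(msg, "vertices must be V x 3")
  if (ncol(object@faces) != 3L) msg <- c(msg, "faces must be F x 3")
  if (nrow(object@faces) > 0 &&
      (min(object@faces) < 1L || max(object@faces) > nrow(object@vertices)))
    msg <- c(msg, "face indices out of range")
  if (length(msg)) msg else TRUE
})

#' Point cloud in world coordinates
#'
#' @slot points N x 3 numeric matrix of world-mm positions.
#' @slot alpha per-point (or scalar) opacity in [0, 1].
#' @slot size per-point (or scalar) marker size.
#' @export
setClass("PointCloud",
  representation(points = "matrix", alpha = "numeric", size = "numeric"),
  prototype(alpha = 1, size = 1))

setValidity("PointCloud", function(object) {
  msg <- character()
  if (ncol(object@points) != 3L) msg <- c(msg, "points must be N x 3")
  if (nrow(object@points) > 0 && !all(is.finite(object@points)))
    msg <- c(msg, "point coordinates must be finite")
  if (any(object@alpha < 0 | object@alpha > 1))
    msg <- c(msg, "alpha must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Resolved style options for the four figure components
#'
#' Produced by [resolveOptions()]; one fully-defaulted named list per
#' component (template, node, edge, figure).
#'
#' @slot template template-layer options (style, alpha, voxelsize, ...).
#' @slot node node-layer options (style, color, size, scale, ...).
#' @slot edge edge-layer options (columnnames, weights, threshold, ...).
#' @slot figure figure-level options (view, frames, savename, ...).
#' @export
setClass("StyleOptions",
  representation(template = "list", node = "list", edge = "list",
                 figure = "list"))

#' A grid of view panels
#'
#' Each panel is either a camera angle (azimuth/elevation in degrees) or the
#' spring-layout marker. Rows need not have equal length; the grid is padded
#' when rendered.
#'
#' @slot rows list of rows; each row a list of panels. A panel is a list with
#'   \code{type} ("angle" or "spring") and, for angles, \code{azimuth} and
#'   \code{elevation}.
#' @export
setClass("ViewSpec", representation(rows = "list"))

setValidity("ViewSpec", function(object) {
  if (length(object@rows) < 1L) return("at least one row required")
  for (row in object@rows) {
    if (length(row) < 1L) return("every row needs at least one panel")
    for (p in row) {
      if (!is.list(p) || is.null(p$type) ||
          !p$type %in% c("angle", "spring"))
        return("panels must be angle or spring markers")
      if (p$type == "angle" &&
          (!is.finite(p$azimuth) || !is.finite(p$elevation)))
        return("camera angles must be finite")
    }
  }
  TRUE
})

#' Result of a high-level plot call
#'
#' @slot panels ordered list of panel handles, one per subplot; each records
#'   the panel's camera angle (or spring marker), its grid position and its
#'   resolved scene layers.
#' @slot scene shared scene layers (template geometry, node geometry, edge
#'   segments) reused across panels.
#' @slot legend legend specification built from the active aesthetic
#'   mappings, or an empty list.
#' @slot provenance serializable record of resolved options, input element
#'   counts, chosen template variant and seeds.
#' @slot viewspec the parsed \linkS4class{ViewSpec}.
#' @export
setClass("FigureResult",
  representation(panels = "list", scene = "list", legend = "list",
                 provenance = "list", viewspec = "ViewSpec"))

setValidity("FigureResult", function(object) {
  if (length(object@panels) != viewTotal(object@viewspec))
    return("panel count must equal the ViewSpec's total panel count")
  TRUE
})
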