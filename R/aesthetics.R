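# Declarative aesthetics: table columns -> colors, sizes, highlighting,
# plus node/edge geometry and automatic legend construction.

#' Map a metadata column to colors
#'
#' Implements the high-level color interface: pass a column of values and
#' get one color per element plus legend entries. Non-numeric columns, and
#' integer-valued numeric columns with at most `maxLevels` distinct values
#' (e.g. community labels), are treated as categorical and assigned one
#' distinct palette color per category. Anything else is continuous and maps
#' linearly onto the colormap between the observed min and max.
#'
#' @param values vector of values (one per node/edge).
#' @param palette categorical palette name for [grDevices::hcl.colors()].
#' @param cmap continuous colormap name for [grDevices::hcl.colors()].
#' @param maxLevels categorical-inference cutoff for integer-valued columns.
#' @param kind force `"categorical"` or `"continuous"` instead of inferring.
#' @return an `AestheticMapping`: list with `column` (filled by callers),
#'   `kind`, `values` (colors per element) and `legend` entries.
#' @examples
#' m <- mapColor(c(1, 1, 2))   # 2 communities -> 2 distinct colors
#' m$values[1] == m$values[2]
#' @export
mapColor <- function(values, palette = "Dark 3", cmap = "viridis",
                     maxLevels = 12, kind = NULL) {
  if (!length(values)) stopf("cannot map colors over an empty column")
  if (is.list(values)) stopf("color column has un-coercible mixed types")
  if (is.null(kind)) {
    kind <- if (!is.numeric(values)) "categorical"
    else if (all(is.finite(values)) && all(values == round(values)) &&
             length(unique(values)) <= maxLevels) "categorical"
    else "continuous"
  }
  if (kind == "categorical") {
    lev <- sort(unique(values))
    cols <- grDevices::hcl.colors(max(length(lev), 2L), palette)[
      seq_along(lev)]
    resolved <- cols[match(values, lev)]
    legend <- lapply(seq_along(lev), function(k)
      list(label = as.character(lev[k]), color = cols[k]))
  } else {
    if (!is.numeric(values)) stopf("continuous color column must be numeric")
    if (!all(is.finite(values)))
      stopf("color column contains non-finite values")
    ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, cmap))
    rng <- range(values)
    t <- if (diff(rng) > 0)
      pmin(1, pmax(0, (values - rng[1]) / diff(rng)))
    else rep(0.5, length(values))
    resolved <- grDevices::rgb(ramp(t), maxColorValue = 255)
    at <- if (diff(rng) > 0) c(0, 0.5, 1) else 0.5
    labs <- if (diff(rng) > 0)
      c(rng[1], mean(rng), rng[2]) else rng[1]
    legend <- lapply(seq_along(at), function(k)
      list(label = format(labs[k], digits = 3),
           color = grDevices::rgb(ramp(at[k]), maxColorValue = 255)))
  }
  structure(list(column = NULL, kind = kind, values = resolved,
                 legend = legend, aesthetic = "color"),
            class = "AestheticMapping")
}

#' Map a numeric column to sizes
#'
#' Affine map of `[min(values), max(values)]` onto `[bounds[1], bounds[2]]`;
#' a constant column maps to the midpoint. The legend carries representative
#' min/mid/max entries.
#'
#' @param values numeric vector.
#' @param bounds length-2 `(min_size, max_size)`.
#' @return an `AestheticMapping` with per-element sizes.
#' @examples
#' mapSize(c(0.5, 0.2, 0.8), bounds = c(10, 50))$values  # 25 10 50
#' @export
mapSize <- function(values, bounds = c(2, 6)) {
  if (!is.numeric(values)) stopf("size column must be numeric")
  if (!length(values)) stopf("cannot map sizes over an empty column")
  if (!all(is.finite(values)))
    stopf("size column contains non-finite values")
  rng <- range(values)
  sizes <- if (diff(rng) > 0)
    bounds[1] + (values - rng[1]) / diff(rng) * (bounds[2] - bounds[1])
  else rep(mean(bounds), length(values))
  reps <- if (diff(rng) > 0)
    list(c(rng[1], bounds[1]), c(mean(rng), mean(bounds)),
         c(rng[2], bounds[2]))
  else list(c(rng[1], mean(bounds)))
  legend <- lapply(reps, function(p)
    list(label = format(p[1], digits = 3), size = p[2]))
  structure(list(column = NULL, kind = "continuous", values = sizes,
                 legend = legend, aesthetic = "size"),
            class = "AestheticMapping")
}

#' Resolve a highlight specification to per-element emphasis
#'
#' Selected elements keep their full alpha; unselected ones are dimmed to
#' `dimAlpha`. The selector may be the name of a logical column of
#' `elements`, a vector of ids (node ids for node tables, 1-based row
#' numbers for edge tables), or — for edges — a binary N x N matrix marking
#' node pairs, as produced by network-based-statistics implementations.
#'
#' @param elements node or edge table.
#' @param spec selector, or list with `selector` and `dimAlpha`.
#' @param nNodes node count (required to validate a matrix selector).
#' @param baseAlpha alpha of emphasized elements (default 1).
#' @return list with `selected` (logical), `alpha` (numeric per element)
#'   and `count` of selected elements.
#' @export
applyHighlight <- function(elements, spec, nNodes = NULL, baseAlpha = 1) {
  if (is.list(spec) && !is.data.frame(spec) && !is.null(spec$selector)) {
    dimAlpha <- spec$dimAlpha %||% 0.15
    selector <- spec$selector
  } else {
    dimAlpha <- 0.15
    selector <- spec
  }
  n <- nrow(elements)
  isEdges <- all(c("i", "j") %in% names(elements))
  if (is.matrix(selector)) {
    if (!isEdges) stopf("a matrix selector only applies to edges")
    if (is.null(nNodes)) nNodes <- max(elements$i, elements$j) + 1L
    if (!all(dim(selector) == c(nNodes, nNodes)))
      stopf("highlight matrix is %d x %d but there are %d nodes",
            nrow(selector), ncol(selector), nNodes)
    sel <- selector[cbind(elements$i + 1L, elements$j + 1L)] != 0 |
      selector[cbind(elements$j + 1L, elements$i + 1L)] != 0
  } else if (is.character(selector) && length(selector) == 1L) {
    if (!selector %in% names(elements))
      stopf("highlight column '%s' not found", selector)
    sel <- as.logical(elements[[selector]])
    if (any(is.na(sel))) stopf("highlight column '%s' is not boolean",
                               selector)
  } else if (is.logical(selector)) {
    if (length(selector) != n)
      stopf("logical selector has length %d but there are %d elements",
            length(selector), n)
    sel <- selector
  } else if (is.numeric(selector)) {
    sel <- if (isEdges) seq_len(n) %in% selector
    else elements$node_id %in% selector
  } else {
    stopf("unsupported highlight selector")
  }
  alpha <- ifelse(sel, baseAlpha, dimAlpha)
  logInfo("highlight: %d of %d element(s) emphasized", sum(sel), n)
  list(selected = sel, alpha = alpha, count = sum(sel))
}

#' Build node geometry for a node style
#'
#' `circles` places a 2D marker billboard at each node coordinate; `spheres`
#' tessellates a 3D sphere per node with radius proportional to size;
#' `parcels` meshes each label of the accompanying parcellation — for that
#' style the nodes need to be specified using a NIfTI image (a
#' parcellation), not bare coordinates.
#'
#' @param nodes canonical node table.
#' @param style `"circles"`, `"spheres"` or `"parcels"`.
#' @param sizes per-node sizes (marker cex for circles, radius in mm for
#'   spheres); recycled.
#' @param parcellation the \linkS4class{Parcellation} behind the nodes
#'   (required for `parcels`).
#' @param sphereRes sphere tessellation resolution.
#' @return list layer: `kind` (`"markers"` or `"meshes"`), plus coordinates
#'   and sizes, or one mesh per node in node order.
#' @export
nodeGeometry <- function(nodes, style = "circles", sizes = NULL,
                         parcellation = NULL, sphereRes = 20) {
  validateNodeTable(nodes)
  if (!style %in% c("circles", "spheres", "parcels"))
    stopf("node_style must be one of 'circles', 'spheres', 'parcels'")
  if (is.null(sizes)) sizes <- if (style == "spheres") 4 else 1.5
  sizes <- rep_len(sizes, nrow(nodes))
  coords <- as.matrix(nodes[c("x", "y", "z")])
  if (style == "circles")
    return(list(kind = "markers", coords = coords, sizes = sizes))
  if (style == "spheres") {
    meshes <- lapply(seq_len(nrow(nodes)), function(k)
      sphereMesh(coords[k, ], radius = sizes[k], res = sphereRes))
    return(list(kind = "meshes", meshes = meshes, coords = coords,
                sizes = sizes))
  }
  if (is.null(parcellation))
    stopf(paste("node_style 'parcels' requires label-based input:",
                "the nodes need to be specified using a NIfTI image"))
  labs <- parcelLabels(parcellation)
  if (!"label" %in% names(nodes))
    stopf("'parcels' requires nodes derived from the parcellation")
  meshes <- lapply(nodes$label, function(lb) {
    m <- (parcellation@grid == lb) * 1.0
    tryCatch(extractSurface(m, parcellation@affine),
             error = function(e) extractSurface(m, parcellation@affine,
                                                smoothing = 0))
  })
  list(kind = "meshes", meshes = meshes, coords = coords, sizes = sizes)
}

#' Build edge line segments
#'
#' One straight 3D segment per surviving edge, drawn between the endpoints'
#' node coordinates (label centroids for parcellation-derived nodes). When
#' `threshold` is given, edges with weight below it are removed before any
#' width scaling (`thresholdAbs` switches the comparison to |weight|). When
#' `weightScaling` is given, widths follow [mapSize()] on that column.
#'
#' @param nodes canonical node table.
#' @param edges canonical edge table.
#' @param weightScaling optional list `(column, bounds)` for width mapping.
#' @param threshold optional minimum weight.
#' @param thresholdAbs threshold on absolute weight instead (default FALSE).
#' @return data.frame of segments (`i`, `j`, endpoint coordinates,
#'   `width`, `weight`).
#' @export
edgeSegments <- function(nodes, edges, weightScaling = NULL,
                         threshold = NULL, thresholdAbs = FALSE) {
  validateNodeTable(nodes)
  validateEdgeTable(edges, max(c(nodes$node_id, -1)) + 1L)
  w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
  if (!is.null(threshold)) {
    keep <- if (thresholdAbs) abs(w) >= threshold else w >= threshold
    edges <- edges[keep, , drop = FALSE]
    w <- w[keep]
  }
  ii <- match(edges$i, nodes$node_id)
  jj <- match(edges$j, nodes$node_id)
  widths <- if (!is.null(weightScaling)) {
    col <- weightScaling$column %||% "weight"
    vals <- if (col == "weight") w else edges[[col]]
    if (is.null(vals)) stopf("edge width column '%s' not found", col)
    if (nrow(edges)) mapSize(vals, weightScaling$bounds %||% c(0.5, 3))$values
    else numeric(0)
  } else rep(1, nrow(edges))
  out <- data.frame(i = edges$i, j = edges$j,
                    x0 = nodes$x[ii], y0 = nodes$y[ii], z0 = nodes$z[ii],
                    x1 = nodes$x[jj], y1 = nodes$y[jj], z1 = nodes$z[jj],
                    width = widths, weight = w)
  rownames(out) <- NULL
  out
}

#' Assemble legend blocks from aesthetic mappings
#'
#' One legend block per mapping, in declaration order; categorical color
#' blocks list every category, size blocks list min/mid/max. An empty
#' mapping list yields no legend.
#'
#' @param mappings list of `AestheticMapping` objects (NULLs are dropped).
#' @return list of legend blocks (`title`, `aesthetic`, `entries`).
#' @export
buildLegend <- function(mappings) {
  mappings <- Filter(Negate(is.null), mappings)
  lapply(mappings, function(m)
    list(title = m$column %||% m$aesthetic, aesthetic = m$aesthetic,
         kind = m$kind, entries = m$legend))
}
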