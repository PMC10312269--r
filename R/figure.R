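# High-level figure assembly: the single plot entry point, the multi-panel
# renderer and PNG/SVG export.

#' Plot a brain network
#'
#' The single high-level entry point. Composes up to three independently
#' specifiable components — an anatomical `template` volume, a `nodes` set
#' and an `edges` set — into a multi-panel 3D figure. All three are
#' optional: a template can be plotted by itself, and so can bare nodes; if
#' edges are specified, the `nodes` argument must be specified. A
#' node-attributed igraph object can supply nodes and edges simultaneously
#' through `network` (mutually exclusive with `nodes`/`edges`).
#'
#' Styling is driven by keyword options following the
#' `<component>_<option>` convention (see [resolveOptions()]): e.g.
#' `node_color = "community"` colors nodes by that metadata column,
#' `node_size = "degree"` sizes them by another, `view = "LSR"` draws
#' three panels, `highlight_edges` dims all but a selected edge cluster.
#' Legends for active aesthetic mappings are generated automatically. With
#' `savename` set the figure is also written to PNG or SVG.
#'
#' There is deliberately no default template: the template is drawn only
#' when explicitly identified, so a figure can never silently acquire a
#' reference space the nodes were not defined in.
#'
#' @param template optional \linkS4class{BrainVolume}, NIfTI path, or
#'   template-space name (resolved through `fetcher`).
#' @param nodes optional node specification (see [parseNodes()]).
#' @param edges optional adjacency matrix, edge table or path (see
#'   [parseEdges()]).
#' @param network optional igraph object with x/y/z vertex attributes.
#' @param nodesDf,edgesDf optional extra metadata tables merged onto the
#'   nodes/edges (row order; ascending-label order for atlas-derived nodes).
#' @param fetcher optional resolver for space names and atlas descriptors.
#' @param ... style options routed by [resolveOptions()].
#' @return a \linkS4class{FigureResult}; its `panels` list has one handle
#'   per subplot of the view grid.
#' @examples
#' net <- makeNetwork(10, fixtureConfig(seed = 1))
#' fig <- plotBrainNetwork(nodes = net$nodes, edges = net$edges,
#'                         view = "LSR", node_color = "community")
#' length(panels(fig))   # 3
#' @export
plotBrainNetwork <- function(template = NULL, nodes = NULL, edges = NULL,
                             network = NULL, nodesDf = NULL, edgesDf = NULL,
                             fetcher = NULL, ...) {
  opts <- resolveOptions(list(...))
  if (!is.null(edges) && is.null(nodes) && is.null(network))
    stopf("if edges are specified, the 'nodes' argument must be specified")
  if (!is.null(network) && (!is.null(nodes) || !is.null(edges)))
    stopf("'network' is mutually exclusive with 'nodes' and 'edges'")
  if (is.null(template) && is.null(nodes) && is.null(network))
    stopf("nothing to draw: supply a template, nodes, or a network")

  nodeTab <- NULL; edgeTab <- NULL; parc <- NULL
  if (!is.null(network)) {
    ing <- ingestGraph(network, columnnames = opts@node$columnnames)
    nodeTab <- ing$nodes
    edgeTab <- ing$edges
    if (!is.null(nodesDf)) nodeTab <- mergeNodeMetadata(nodeTab, nodesDf)
    logInfo("network: ingested graph with %d nodes, %d edges",
            nrow(nodeTab), nrow(edgeTab))
  } else if (!is.null(nodes)) {
    pn <- parseNodes(nodes, columnnames = opts@node$columnnames,
                     metadata = nodesDf, fetcher = fetcher)
    nodeTab <- pn$nodes
    parc <- pn$parcellation
    logInfo("nodes: %d node(s)%s", nrow(nodeTab),
            if (!is.null(parc)) " (from parcellation)" else "")
    if (!is.null(edges)) {
      wcol <- if (identical(opts@edge$weights, "weight")) NULL else
        opts@edge$weights
      ccol <- if (identical(opts@edge$columnnames, c("i", "j"))) NULL else
        opts@edge$columnnames
      edgeTab <- parseEdges(edges, columnnames = ccol, weightsColumn = wcol,
                            nNodes = nrow(nodeTab))
      logInfo("edges: %d edge(s)", nrow(edgeTab))
    }
  }
  if (!is.null(edgesDf) && !is.null(edgeTab)) {
    if (nrow(edgesDf) != nrow(edgeTab))
      stopf("edges_df has %d rows but there are %d edges", nrow(edgesDf),
            nrow(edgeTab))
    edgeTab <- cbind(edgeTab,
                     edgesDf[setdiff(names(edgesDf), names(edgeTab))])
  }

  tvol <- NULL; templateVariant <- NA_character_
  if (!is.null(template)) {
    tvol <- selectTemplateImage(template, fetcher)
    templateVariant <- if (is.na(spaceName(tvol))) "local" else
      spaceName(tvol)
    logInfo("template: %s, %s", templateVariant,
            paste(dim(tvol), collapse = "x"))
  }

  hemi <- opts@template$hemisphere
  if (!is.null(hemi)) {
    if (!is.null(tvol)) tvol <- hemisphereRestrict(tvol, hemi)
    if (!is.null(nodeTab)) {
      hr <- hemisphereRestrict(nodeTab, hemi, edgeTab)
      nodeTab <- hr$nodes
      edgeTab <- hr$edges
    }
  }

  templateLayer <- if (!is.null(tvol))
    styleDispatch(opts@template$style, tvol, opts@template) else NULL

  # --- declarative aesthetics ----------------------------------------------
  mappings <- list()
  nodeColors <- NULL; nodeSizes <- NULL
  if (!is.null(nodeTab) && nrow(nodeTab)) {
    colOpt <- opts@node$color
    if (is.character(colOpt) && length(colOpt) == 1L &&
        colOpt %in% names(nodeTab)) {
      cm <- mapColor(nodeTab[[colOpt]], palette = opts@node$palette,
                     cmap = opts@node$cmap)
      cm$column <- colOpt
      nodeColors <- cm$values
      mappings <- c(mappings, list(cm))
    } else {
      nodeColors <- rep(colOpt %||% "steelblue", nrow(nodeTab))
    }
    sizeOpt <- opts@node$size
    if (is.character(sizeOpt) && length(sizeOpt) == 1L &&
        sizeOpt %in% names(nodeTab)) {
      sm <- mapSize(nodeTab[[sizeOpt]], bounds = opts@node$scale)
      sm$column <- sizeOpt
      nodeSizes <- sm$values
      mappings <- c(mappings, list(sm))
    } else if (is.numeric(sizeOpt)) {
      nodeSizes <- rep(sizeOpt, nrow(nodeTab))
    }
  }
  nodeAlpha <- if (!is.null(nodeTab))
    rep(opts@node$alpha, nrow(nodeTab)) else NULL
  if (!is.null(opts@node$highlight) && !is.null(nodeTab)) {
    hl <- applyHighlight(nodeTab,
                         list(selector = opts@node$highlight,
                              dimAlpha = opts@node$dimalpha),
                         baseAlpha = opts@node$alpha)
    nodeAlpha <- hl$alpha
  }

  segs <- NULL; edgeColors <- NULL; edgeAlpha <- NULL
  if (!is.null(edgeTab) && !is.null(nodeTab)) {
    ws <- if (!is.null(opts@edge$widthscale))
      list(column = "weight", bounds = opts@edge$widthscale) else NULL
    segs <- edgeSegments(nodeTab, edgeTab, weightScaling = ws,
                         threshold = opts@edge$threshold,
                         thresholdAbs = isTRUE(opts@edge$thresholdabs))
    ecol <- opts@edge$color
    if (is.character(ecol) && length(ecol) == 1L &&
        ecol %in% names(edgeTab)) {
      kept <- match(paste(segs$i, segs$j), paste(edgeTab$i, edgeTab$j))
      em <- mapColor(edgeTab[[ecol]][kept], cmap = opts@node$cmap)
      em$column <- ecol
      edgeColors <- em$values
      mappings <- c(mappings, list(em))
    } else {
      edgeColors <- rep(ecol %||% "black", nrow(segs))
    }
    edgeAlpha <- rep(opts@edge$alpha, nrow(segs))
    if (!is.null(opts@edge$highlight)) {
      segTab <- segs
      hl <- applyHighlight(segTab,
                           list(selector = opts@edge$highlight,
                                dimAlpha = opts@edge$dimalpha),
                           nNodes = nrow(nodeTab),
                           baseAlpha = opts@edge$alpha)
      edgeAlpha <- hl$alpha
    }
  }

  nodeLayer <- if (!is.null(nodeTab) && nrow(nodeTab))
    nodeGeometry(nodeTab, style = opts@node$style, sizes = nodeSizes,
                 parcellation = parc, sphereRes = opts@node$sphereres)
    else NULL

  viewspec <- parseView(opts@figure$view, frames = opts@figure$frames)
  hasSpring <- any(vapply(unlist(viewspec@rows, recursive = FALSE),
                          function(p) p$type == "spring", logical(1)))
  springPos <- NULL
  if (hasSpring) {
    if (is.null(nodeTab) || !nrow(nodeTab))
      stopf("a spring-layout panel ('s') requires nodes")
    springPos <- springLayout(nodeTab, edgeTab, seed = opts@figure$seed)
  }

  legend <- if (isTRUE(opts@figure$legend)) buildLegend(mappings) else
    list()

  scene <- list(template = templateLayer, nodes = nodeLayer,
                nodeTable = nodeTab, edgeTable = edgeTab,
                segments = segs, nodeColors = nodeColors,
                nodeAlpha = nodeAlpha, edgeColors = edgeColors,
                edgeAlpha = edgeAlpha, springPositions = springPos,
                background = opts@figure$background,
                panelsize = opts@figure$panelsize, dpi = opts@figure$dpi,
                options = opts)

  panelHandles <- list()
  idx <- 0L
  for (r in seq_along(viewspec@rows)) {
    row <- viewspec@rows[[r]]
    for (cc in seq_along(row)) {
      idx <- idx + 1L
      p <- row[[cc]]
      panelHandles[[idx]] <- c(p, list(index = idx, gridRow = r,
                                       gridCol = cc))
    }
  }

  provenance <- list(
    options = list(template = opts@template, node = opts@node,
                   edge = opts@edge, figure = opts@figure),
    template_variant = templateVariant,
    n_nodes = if (is.null(nodeTab)) 0L else nrow(nodeTab),
    n_edges = if (is.null(edgeTab)) 0L else nrow(edgeTab),
    n_segments = if (is.null(segs)) 0L else nrow(segs),
    seed = opts@figure$seed,
    panel_count = length(panelHandles))

  result <- new("FigureResult", panels = panelHandles, scene = scene,
                legend = legend, provenance = provenance,
                viewspec = viewspec)
  if (!is.null(opts@figure$savename))
    saveFigure(result, opts@figure$savename)
  result
}

# orthographic projection basis for an (azimuth, elevation) camera, degrees
.projectionBasis <- function(az, el) {
  a <- az * pi / 180
  e <- el * pi / 180
  list(right = c(-sin(a), cos(a), 0),
       up = c(-sin(e) * cos(a), -sin(e) * sin(a), cos(e)),
       depth = c(cos(e) * cos(a), cos(e) * sin(a), sin(e)))
}

.project <- function(coords, basis) {
  cbind(x = coords %*% basis$right, y = coords %*% basis$up,
        d = coords %*% basis$depth)
}

.withAlpha <- function(col, alpha) {
  rgbm <- grDevices::col2rgb(col) / 255
  grDevices::rgb(rgbm[1, ], rgbm[2, ], rgbm[3, ], alpha = alpha)
}

# world-space bounding box of everything in the scene
.sceneBBox <- function(scene) {
  pts <- NULL
  tl <- scene$template
  if (!is.null(tl)) {
    g <- tl$geometry
    pts <- rbind(pts, if (is(g, "Mesh")) g@vertices else g@points)
  }
  if (!is.null(scene$nodeTable) && nrow(scene$nodeTable))
    pts <- rbind(pts, as.matrix(scene$nodeTable[c("x", "y", "z")]))
  if (is.null(pts)) pts <- matrix(c(-1, -1, -1, 1, 1, 1), 2, byrow = TRUE)
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  pad <- pmax(0.05 * (hi - lo), 1)
  rbind(lo - pad, hi + pad)
}

.drawMesh <- function(mesh, basis, color, alpha, shade = TRUE) {
  pv <- .project(mesh@vertices, basis)
  f <- mesh@faces
  if (!nrow(f)) return(invisible())
  depth <- (pv[f[, 1], 3] + pv[f[, 2], 3] + pv[f[, 3], 3]) / 3
  ord <- order(depth)                       # painter: back to front
  f <- f[ord, , drop = FALSE]
  if (shade) {
    a <- mesh@vertices[f[, 2], , drop = FALSE] -
      mesh@vertices[f[, 1], , drop = FALSE]
    b <- mesh@vertices[f[, 3], , drop = FALSE] -
      mesh@vertices[f[, 1], , drop = FALSE]
    nrm <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                 a[, 3] * b[, 1] - a[, 1] * b[, 3],
                 a[, 1] * b[, 2] - a[, 2] * b[, 1])
    nn <- rowNorms(nrm)
    nn[nn == 0] <- 1
    lambert <- abs((nrm / nn) %*% basis$depth)
    shadeCol <- grDevices::col2rgb(color) / 255
    cols <- grDevices::rgb(shadeCol[1] * (0.35 + 0.65 * lambert),
                           shadeCol[2] * (0.35 + 0.65 * lambert),
                           shadeCol[3] * (0.35 + 0.65 * lambert),
                           alpha = alpha)
  } else {
    cols <- rep(.withAlpha(color, alpha), nrow(f))
  }
  n <- nrow(f)
  xs <- rbind(pv[f[, 1], 1], pv[f[, 2], 1], pv[f[, 3], 1], NA)
  ys <- rbind(pv[f[, 1], 2], pv[f[, 2], 2], pv[f[, 3], 2], NA)
  graphics::polygon(as.vector(xs), as.vector(ys), col = cols, border = NA)
}

.drawPanel3D <- function(scene, az, el) {
  basis <- .projectionBasis(az, el)
  bb <- .sceneBBox(scene)
  corners <- as.matrix(expand.grid(bb[, 1], bb[, 2], bb[, 3]))
  pc <- .project(corners, basis)
  graphics::plot.new()
  graphics::plot.window(xlim = range(pc[, 1]), ylim = range(pc[, 2]),
                        asp = 1)
  tl <- scene$template
  if (!is.null(tl)) {
    if (tl$kind == "mesh") {
      .drawMesh(tl$geometry, basis, tl$color, tl$alpha)
    } else {
      pts <- .project(tl$geometry@points, basis)
      ord <- order(pts[, 3])
      graphics::points(pts[ord, 1], pts[ord, 2], pch = 16,
                       cex = 0.3 * mean(tl$geometry@size),
                       col = .withAlpha(tl$color, tl$alpha))
    }
  }
  if (!is.null(scene$segments) && nrow(scene$segments)) {
    s <- scene$segments
    p0 <- .project(as.matrix(s[c("x0", "y0", "z0")]), basis)
    p1 <- .project(as.matrix(s[c("x1", "y1", "z1")]), basis)
    graphics::segments(p0[, 1], p0[, 2], p1[, 1], p1[, 2],
                       lwd = s$width,
                       col = .withAlpha(scene$edgeColors, scene$edgeAlpha))
  }
  nl <- scene$nodes
  if (!is.null(nl)) {
    if (nl$kind == "markers") {
      pn <- .project(nl$coords, basis)
      ord <- order(pn[, 3])
      graphics::points(pn[ord, 1], pn[ord, 2], pch = 16,
                       cex = nl$sizes[ord],
                       col = .withAlpha(scene$nodeColors[ord],
                                        scene$nodeAlpha[ord]))
    } else {
      for (k in seq_along(nl$meshes))
        .drawMesh(nl$meshes[[k]], basis, scene$nodeColors[k],
                  scene$nodeAlpha[k])
    }
  }
}

.drawPanelSpring <- function(scene) {
  pos <- scene$springPositions
  graphics::plot.new()
  rx <- range(pos[, 1]); ry <- range(pos[, 2])
  pad <- pmax(c(diff(rx), diff(ry)) * 0.1, 0.1)
  graphics::plot.window(xlim = rx + c(-pad[1], pad[1]),
                        ylim = ry + c(-pad[2], pad[2]), asp = 1)
  if (!is.null(scene$segments) && nrow(scene$segments)) {
    s <- scene$segments
    nodeIdx <- scene$nodeTable$node_id
    i0 <- match(s$i, nodeIdx)
    i1 <- match(s$j, nodeIdx)
    graphics::segments(pos[i0, 1], pos[i0, 2], pos[i1, 1], pos[i1, 2],
                       lwd = s$width,
                       col = .withAlpha(scene$edgeColors, scene$edgeAlpha))
  }
  sizes <- if (!is.null(scene$nodes)) scene$nodes$sizes else 1.5
  graphics::points(pos[, 1], pos[, 2], pch = 16, cex = sizes,
                   col = .withAlpha(scene$nodeColors, scene$nodeAlpha))
  graphics::title(main = "spring layout", cex.main = 0.8)
}

.drawLegend <- function(legend) {
  labs <- character(); cols <- character(); cexs <- numeric()
  for (block in legend) {
    for (e in block$entries) {
      labs <- c(labs, paste0(block$title, ": ", e$label))
      cols <- c(cols, e$color %||% "grey30")
      cexs <- c(cexs, if (!is.null(e$size)) 0.3 * e$size + 0.5 else 1)
    }
  }
  if (!length(labs)) return(invisible())
  op <- graphics::par(fig = c(0, 1, 0, 1), oma = c(0, 0, 0, 0),
                      mar = c(0, 0, 0, 0), new = TRUE)
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::legend("bottom", legend = labs, col = cols, pch = 16,
                   pt.cex = cexs, horiz = length(labs) <= 4, bty = "n",
                   cex = 0.8, xpd = NA)
}

#' Render a FigureResult to the active graphics device
#'
#' @param result a \linkS4class{FigureResult}.
#' @return the result, invisibly.
#' @export
renderFigure <- function(result) {
  stopifnot(is(result, "FigureResult"))
  rows <- result@viewspec@rows
  nrow <- length(rows)
  ncol <- max(vapply(rows, length, integer(1)))
  scene <- result@scene
  hasLegend <- length(result@legend) > 0
  graphics::par(mfrow = c(nrow, ncol),
                mar = c(0.2, 0.2, 1.0, 0.2),
                oma = c(if (hasLegend) 4 else 0, 0, 0, 0),
                bg = scene$background)
  for (r in seq_len(nrow)) {
    row <- rows[[r]]
    for (cc in seq_len(ncol)) {
      if (cc > length(row)) { graphics::plot.new(); next }
      p <- row[[cc]]
      if (p$type == "spring") .drawPanelSpring(scene)
      else .drawPanel3D(scene, p$azimuth, p$elevation)
    }
  }
  if (hasLegend) .drawLegend(result@legend)
  invisible(result)
}

#' Export a figure to PNG or SVG
#'
#' Writes the rendered multi-panel figure. The format follows the file
#' extension; a path without an extension gets `.png` appended. Identical
#' inputs, options and seeds produce structurally identical vector output.
#'
#' @param result a \linkS4class{FigureResult} from [plotBrainNetwork()].
#' @param path output path ending in `.png` or `.svg`.
#' @return the written path, invisibly.
#' @export
saveFigure <- function(result, path) {
  stopifnot(is(result, "FigureResult"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "") {
    path <- paste0(path, ".png")
    ext <- "png"
  }
  if (!ext %in% c("png", "svg"))
    stopf("unsupported figure format '.%s'; supported formats: .png, .svg",
          ext)
  rows <- result@viewspec@rows
  nrow <- length(rows)
  ncol <- max(vapply(rows, length, integer(1)))
  ps <- result@scene$panelsize %||% 3
  h <- nrow * ps + if (length(result@legend)) 0.8 else 0
  if (ext == "png") {
    grDevices::png(path, width = ncol * ps, height = h, units = "in",
                   res = result@scene$dpi %||% 150)
  } else {
    grDevices::svg(path, width = ncol * ps, height = h)
  }
  ok <- FALSE
  tryCatch({ renderFigure(result); ok <- TRUE },
           finally = grDevices::dev.off())
  if (!ok) stopf("rendering failed while writing %s", path)
  if (!file.exists(path) || file.size(path) == 0)
    stopf("figure file %s was not written", path)
  logInfo("figure: wrote %s (%d panel(s))", path, length(result@panels))
  invisible(path)
}
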