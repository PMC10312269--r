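# Registry of recognized options per component, with package defaults.
# Option names follow the "<component>_<option>" calling convention; figure-
# level options (view, frames, savename, ...) are also accepted unprefixed.

.optionRegistry <- function() {
  list(
    template = list(
      style = "glass",        # glass | surface | filled | cloudy | none
      alpha = NULL,           # NULL = per-style default
      color = "lightgray",
      voxelsize = NULL,       # mm; downsampling lever for filled/cloudy
      hemisphere = NULL,      # 'L' or 'R'
      level = 0,              # binarization threshold
      segments = 500,         # glass: supervoxel count
      compactness = 0.05      # glass: spatial/intensity trade-off
    ),
    node = list(
      style = "circles",      # circles | spheres | parcels
      color = "steelblue",    # constant color or a metadata column name
      size = NULL,            # constant size, or a metadata column name
      columnnames = NULL,     # coordinate column remapping, length 3
      alpha = 1,
      scale = c(2, 6),        # size bounds for column-driven sizes
      cmap = "viridis",       # continuous colormap name (hcl.colors)
      palette = "Dark 3",     # categorical palette name (hcl.colors)
      highlight = NULL,       # boolean column name or id vector
      dimalpha = 0.15,        # alpha applied to non-highlighted elements
      sphereres = 20          # sphere tessellation resolution
    ),
    edge = list(
      columnnames = c("i", "j"),
      weights = "weight",     # weight column name
      color = "black",
      alpha = 1,
      width = 1,              # constant width when weights not scaled
      widthscale = NULL,      # c(min, max) line widths mapped from weights
      threshold = NULL,       # drop edges with weight < threshold
      thresholdabs = FALSE,   # threshold |weight| instead of raw weight
      highlight = NULL,       # boolean column, id list, or binary N x N matrix
      dimalpha = 0.15
    ),
    figure = list(
      view = "L",
      frames = NULL,          # rotation frames for a 2-letter view
      savename = NULL,
      panelsize = 3,          # inches per panel
      background = "white",
      seed = 42,              # spring-layout seed
      legend = TRUE,
      title = NULL,
      dpi = 150
    )
  )
}

# figure-level options are accepted without a prefix (view=..., savename=...)
.bareFigureNames <- c("view", "frames", "savename", "panelsize", "background",
                      "seed", "legend", "title", "dpi")
# documented top-level aliases routed into a component
.aliasMap <- list(
  hemisphere = c("template", "hemisphere"),
  highlight_edges = c("edge", "highlight"),
  highlight_nodes = c("node", "highlight")
)

.knownOptionNames <- function() {
  reg <- .optionRegistry()
  prefixed <- unlist(lapply(c("template", "node", "edge", "fig"), function(p) {
    comp <- if (p == "fig") "figure" else p
    paste0(p, "_", names(reg[[comp]]))
  }))
  c(prefixed, .bareFigureNames, names(.aliasMap))
}

#' Route raw keyword options to their components
#'
#' Options are named following the `<component>_<option>` convention: e.g.
#' `template_alpha`, `node_color`, `edge_threshold` address the transparency,
#' color and thresholding of the respective layer. Figure-level options
#' (`view`, `frames`, `savename`, `panelsize`, `background`, `seed`,
#' `legend`, `title`, `dpi`) may be given bare or prefixed with `fig_`.
#' Unrecognized names are rejected; when a known option is within edit
#' distance 3, the error suggests it.
#'
#' @param raw named list of raw option values (possibly empty), or an
#'   already-resolved \linkS4class{StyleOptions} (returned unchanged).
#' @return a \linkS4class{StyleOptions} with every option present (defaults
#'   filled for anything unset).
#' @examples
#' so <- resolveOptions(list(template_alpha = 0.2, view = "LSR"))
#' so@template$alpha
#' @export
resolveOptions <- function(raw = list()) {
  if (is(raw, "StyleOptions")) return(raw)
  if (!is.list(raw)) stopf("options must be a named list")
  if (length(raw) && (is.null(names(raw)) || any(names(raw) == "")))
    stopf("every option must be named")

  reg <- .optionRegistry()
  for (nm in names(raw)) {
    routed <- .routeOption(nm)
    reg[[routed[1]]][[routed[2]]] <- raw[[nm]]
  }
  .validateOptionValues(reg)
  new("StyleOptions", template = reg$template, node = reg$node,
      edge = reg$edge, figure = reg$figure)
}

# name -> c(component, option) or error
.routeOption <- function(nm) {
  reg <- .optionRegistry()
  if (nm %in% names(.aliasMap)) return(.aliasMap[[nm]])
  if (nm %in% .bareFigureNames) return(c("figure", nm))
  if (grepl("_", nm, fixed = TRUE)) {
    prefix <- sub("_.*$", "", nm)
    option <- sub("^[^_]*_", "", nm)
    comp <- switch(prefix, template = "template", node = "node",
                   edge = "edge", fig = "figure", NULL)
    if (is.null(comp)) {
      hint <- nearestName(nm, .knownOptionNames())
      stopf(paste0("unknown option '%s': component prefix '%s' is not one of ",
                   "template, node, edge, fig%s"), nm, prefix,
            if (!is.na(hint)) sprintf("; did you mean '%s'?", hint) else "")
    }
    if (!option %in% names(reg[[comp]])) {
      hint <- nearestName(option, names(reg[[comp]]))
      stopf("unknown %s option '%s'%s", comp, nm,
            if (!is.na(hint)) sprintf("; did you mean '%s_%s'?",
                                      prefix, hint) else "")
    }
    return(c(comp, option))
  }
  hint <- nearestName(nm, .knownOptionNames())
  stopf("unknown option '%s'%s", nm,
        if (!is.na(hint)) sprintf("; did you mean '%s'?", hint) else "")
}

.validateOptionValues <- function(reg) {
  tplStyles <- c("glass", "surface", "filled", "cloudy", "none")
  if (!is.null(reg$template$style) && !reg$template$style %in% tplStyles)
    stopf("template_style must be one of %s",
          paste(sQuote(tplStyles), collapse = ", "))
  nodeStyles <- c("circles", "spheres", "parcels")
  if (!reg$node$style %in% nodeStyles)
    stopf("node_style must be one of %s",
          paste(sQuote(nodeStyles), collapse = ", "))
  for (comp in c("template", "node", "edge")) {
    a <- reg[[comp]]$alpha
    if (!is.null(a) && (!is.numeric(a) || any(a < 0 | a > 1)))
      stopf("%s_alpha must lie in [0, 1]", comp)
  }
  if (!is.null(reg$template$hemisphere) &&
      !reg$template$hemisphere %in% c("L", "R"))
    stopf("hemisphere must be 'L' or 'R'")
  if (!is.null(reg$figure$frames) &&
      (!is.numeric(reg$figure$frames) || reg$figure$frames < 1))
    stopf("frames must be a positive integer")
  invisible(TRUE)
}
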