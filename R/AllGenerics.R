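#' @rdname BrainVolume-class
#' @param object,x a \linkS4class{BrainVolume} (or subclass).
#' @export
setGeneric("volumeData", function(object) standardGeneric("volumeData"))
#' @rdname BrainVolume-class
#' @export
setGeneric("volumeAffine", function(object) standardGeneric("volumeAffine"))
#' @rdname BrainVolume-class
#' @export
setGeneric("spaceName", function(object) standardGeneric("spaceName"))
#' @rdname Parcellation-class
#' @param object a \linkS4class{Parcellation}.
#' @export
setGeneric("parcelLabels", function(object) standardGeneric("parcelLabels"))
#' @rdname Mesh-class
#' @param object a \linkS4class{Mesh}.
#' @export
setGeneric("meshVertices", function(object) standardGeneric("meshVertices"))
#' @rdname Mesh-class
#' @export
setGeneric("meshFaces", function(object) standardGeneric("meshFaces"))
#' @rdname FigureResult-class
#' @param object a \linkS4class{FigureResult}.
#' @export
setGeneric("panels", function(object) standardGeneric("panels"))
#' @rdname FigureResult-class
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @rdname ViewSpec-class
#' @param object a \linkS4class{ViewSpec}.
#' @export
setGeneric("viewTotal", function(object) standardGeneric("viewTotal"))

#' @rdname BrainVolume-class
setMethod("volumeData", "BrainVolume", function(object) object@grid)
#' @rdname BrainVolume-class
setMethod("volumeAffine", "BrainVolume", function(object) object@affine)
#' @rdname BrainVolume-class
setMethod("spaceName", "BrainVolume", function(object) object@spaceName)
#' @rdname Parcellation-class
setMethod("parcelLabels", "Parcellation", function(object) object@labels)
#' @rdname Mesh-class
setMethod("meshVertices", "Mesh", function(object) object@vertices)
#' @rdname Mesh-class
setMethod("meshFaces", "Mesh", function(object) object@faces)
#' @rdname FigureResult-class
setMethod("panels", "FigureResult", function(object) object@panels)
#' @rdname FigureResult-class
setMethod("provenance", "FigureResult", function(object) object@provenance)

#' @rdname ViewSpec-class
setMethod("viewTotal", "ViewSpec", function(object)
  sum(vapply(object@rows, length, integer(1))))

#' @rdname BrainVolume-class
setMethod("dim", "BrainVolume", function(x) dim(x@grid))

setMethod("show", "BrainVolume", function(object) {
  d <- dim(object@grid)
  vs <- sqrt(colSums(object@affine[1:3, 1:3]^2))
  cat(sprintf("%s of dimension %d x %d x %d (voxels %.3g x %.3g x %.3g mm)\n",
              class(object), d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  if (!is.na(object@spaceName))
    cat("  space:", object@spaceName, "\n")
  if (is(object, "Parcellation"))
    cat("  labels:", length(object@labels), "nonzero region labels\n")
})

setMethod("show", "Mesh", function(object) {
  cat(sprintf("Mesh: %d vertices, %d faces\n",
              nrow(object@vertices), nrow(object@faces)))
})

setMethod("show", "PointCloud", function(object) {
  cat(sprintf("PointCloud: %d points (alpha %s)\n", nrow(object@points),
              paste(format(range(object@alpha)), collapse = "-")))
})

setMethod("show", "StyleOptions", function(object) {
  cat("StyleOptions\n")
  for (comp in c("template", "node", "edge", "figure")) {
    opts <- slot(object, comp)
    set <- vapply(opts, function(v) !is.null(v), logical(1))
    cat(sprintf("  %s: %d options (%d set)\n", comp, length(opts), sum(set)))
  }
})

setMethod("show", "ViewSpec", function(object) {
  nr <- length(object@rows)
  cat(sprintf("ViewSpec: %d panel(s) in %d row(s)\n", viewTotal(object), nr))
  for (row in object@rows) {
    lab <- vapply(row, function(p) {
      if (p$type == "spring") "spring"
      else sprintf("(%g, %g)", p$azimuth, p$elevation)
    }, character(1))
    cat("   ", paste(lab, collapse = "  "), "\n")
  }
})

setMethod("show", "FigureResult", function(object) {
  cat(sprintf("FigureResult: %d panel(s)\n", length(object@panels)))
  pv <- object@provenance
  if (!is.null(pv$n_nodes)) cat("  nodes:", pv$n_nodes, "\n")
  if (!is.null(pv$n_edges)) cat("  edges:", pv$n_edges, "\n")
  if (!is.null(pv$template_variant))
    cat("  template:", pv$template_variant, "\n")
  if (length(object@legend)) cat("  legend:", length(object@legend), "block(s)\n")
})
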