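# Node and edge table parsing/normalization.
#
# Node tables are plain data.frames with a dense 0-based integer `node_id`,
# world-mm coordinate columns `x`, `y`, `z`, and open-ended metadata columns.
# Edge tables are data.frames with node-id columns `i`, `j` (referencing
# node_id), a numeric `weight` (default 1.0) and optional metadata columns.

validateNodeTable <- function(nodes) {
  if (!is.data.frame(nodes)) stopf("node table must be a data.frame")
  need <- c("node_id", "x", "y", "z")
  miss <- setdiff(need, names(nodes))
  if (length(miss))
    stopf("node table lacks column(s): %s", paste(miss, collapse = ", "))
  for (cc in c("x", "y", "z")) {
    if (!is.numeric(nodes[[cc]]))
      stopf("node coordinate column '%s' is not numeric", cc)
    if (nrow(nodes) && !all(is.finite(nodes[[cc]])))
      stopf("node coordinate column '%s' contains non-finite values", cc)
  }
  if (anyDuplicated(nodes$node_id))
    stopf("node_id values must be unique")
  invisible(nodes)
}

validateEdgeTable <- function(edges, nNodes) {
  if (!is.data.frame(edges)) stopf("edge table must be a data.frame")
  miss <- setdiff(c("i", "j"), names(edges))
  if (length(miss))
    stopf("edge table lacks column(s): %s", paste(miss, collapse = ", "))
  bad <- which(edges$i < 0 | edges$i >= nNodes |
               edges$j < 0 | edges$j >= nNodes)
  if (length(bad))
    stopf("edge rows reference node ids outside 0..%d: row(s) %s",
          nNodes - 1L, paste(utils::head(bad, 5L), collapse = ", "))
  invisible(edges)
}

#' Parse node input into a canonical node table
#'
#' Accepts any of the supported node specifications: a delimited file path
#' (TSV/CSV) or data.frame with coordinate columns `x`, `y`, `z` (remappable
#' via `columnnames`); a NIfTI path or \linkS4class{Parcellation} whose
#' integer labels define nodes at their label centroids; or an atlas
#' descriptor (a named list with at least `atlas`) resolved through a
#' `fetcher`.
#'
#' @param source node specification (see Details).
#' @param columnnames optional length-3 character vector naming the
#'   coordinate columns to use instead of `x`, `y`, `z`.
#' @param metadata optional data.frame of extra per-node columns, merged via
#'   [mergeNodeMetadata()].
#' @param fetcher optional resolver used for atlas descriptors (see
#'   [localFetcher()]).
#' @return list with `nodes` (the canonical node table) and `parcellation`
#'   (the \linkS4class{Parcellation} when the source was label-based, else
#'   `NULL`; required by the `parcels` node style).
#' @export
parseNodes <- function(source, columnnames = NULL, metadata = NULL,
                       fetcher = NULL) {
  parc <- NULL
  if (is.character(source) && length(source) == 1L) {
    if (grepl("\\.nii(\\.gz)?$", source)) {
      parc <- asParcellation(loadVolume(source))
      nodes <- computeCentroids(parc)
    } else {
      nodes <- .readDelimited(source)
      nodes <- .canonicalizeCoords(nodes, columnnames)
    }
  } else if (is(source, "Parcellation")) {
    parc <- source
    nodes <- computeCentroids(parc)
  } else if (is(source, "BrainVolume")) {
    parc <- asParcellation(source)
    nodes <- computeCentroids(parc)
  } else if (is.data.frame(source)) {
    nodes <- .canonicalizeCoords(source, columnnames)
  } else if (is.list(source)) {
    if (is.null(source$atlas))
      stopf("an atlas descriptor must contain an 'atlas' entry")
    if (is.null(fetcher))
      stopf("an atlas descriptor requires a fetcher to resolve it")
    path <- .queryFetcher(fetcher, source, suffix = "dseg")
    if (is.null(path))
      stopf("fetcher could not resolve atlas descriptor (queried: %s)",
            paste(sprintf("%s=%s", names(source), unlist(source)),
                  collapse = ", "))
    parc <- asParcellation(loadVolume(path))
    nodes <- computeCentroids(parc)
    logInfo("nodes: atlas '%s' resolved to %d parcels", source$atlas,
            nrow(nodes))
  } else {
    stopf("unsupported node specification of class '%s'", class(source)[1])
  }
  if (!"node_id" %in% names(nodes))
    nodes <- cbind(data.frame(node_id = seq_len(nrow(nodes)) - 1L), nodes)
  validateNodeTable(nodes)
  if (!is.null(metadata))
    nodes <- mergeNodeMetadata(nodes, metadata)
  list(nodes = nodes, parcellation = parc)
}

.canonicalizeCoords <- function(df, columnnames = NULL) {
  df <- as.data.frame(df)
  if (!is.null(columnnames)) {
    if (length(columnnames) != 3L)
      stopf("columnnames must name three coordinate columns")
    miss <- setdiff(columnnames, names(df))
    if (length(miss))
      stopf("coordinate column(s) %s not found; available: %s",
            paste(sQuote(miss), collapse = ", "),
            paste(names(df), collapse = ", "))
    names(df)[match(columnnames, names(df))] <- c("x", "y", "z")
  }
  miss <- setdiff(c("x", "y", "z"), names(df))
  if (length(miss))
    stopf("node table lacks coordinate column(s) %s; available: %s",
          paste(sQuote(miss), collapse = ", "),
          paste(names(df), collapse = ", "))
  for (cc in c("x", "y", "z"))
    if (!is.numeric(df[[cc]]))
      stopf("coordinate column '%s' is not numeric", cc)
  df
}

.readDelimited <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Parse edge input into a canonical edge table
#'
#' Accepts an N x N numeric adjacency matrix (converted through
#' [adjacencyToEdgeList()]) or an edge-list data.frame/file with node-id
#' columns `i`, `j` (remappable via `columnnames`) and an optional weight
#' column (default name `weight`; weights default to 1.0 when absent).
#' Self-loops are dropped with a warning; duplicate unordered pairs are
#' collapsed to their first occurrence.
#'
#' @param source adjacency matrix, data.frame, or delimited file path.
#' @param columnnames optional length-2 character vector naming the node-id
#'   columns.
#' @param weightsColumn optional name of the weight column.
#' @param nNodes number of nodes in the companion node table; edge ids must
#'   lie in `0..nNodes-1`.
#' @return canonical edge table (`i`, `j`, `weight`, metadata columns), with
#'   `i < j` for every row.
#' @export
parseEdges <- function(source, columnnames = NULL, weightsColumn = NULL,
                       nNodes) {
  if (is.character(source) && length(source) == 1L) {
    source <- .readEdgeFile(source)
  }
  if (is.matrix(source)) {
    edges <- adjacencyToEdgeList(source)
    if (nrow(source) != nNodes)
      stopf("adjacency matrix is %d x %d but there are %d nodes",
            nrow(source), ncol(source), nNodes)
  } else if (is.data.frame(source)) {
    edges <- as.data.frame(source)
    if (!is.null(columnnames)) {
      if (length(columnnames) != 2L)
        stopf("edge columnnames must name two columns")
      miss <- setdiff(columnnames, names(edges))
      if (length(miss))
        stopf("edge column(s) %s not found; available: %s",
              paste(sQuote(miss), collapse = ", "),
              paste(names(edges), collapse = ", "))
      names(edges)[match(columnnames, names(edges))] <- c("i", "j")
    }
    if (!is.null(weightsColumn)) {
      if (!weightsColumn %in% names(edges))
        stopf("weight column '%s' not found", weightsColumn)
      names(edges)[match(weightsColumn, names(edges))] <- "weight"
    }
    if (!"weight" %in% names(edges)) edges$weight <- 1.0
    edges <- .normalizeEdges(edges)
  } else {
    stopf("unsupported edge specification of class '%s'", class(source)[1])
  }
  validateEdgeTable(edges, nNodes)
  edges
}

# drop self-loops, canonicalize i < j, collapse duplicate unordered pairs
.normalizeEdges <- function(edges) {
  loops <- edges$i == edges$j
  if (any(loops)) {
    logWarn("dropped %d self-loop edge(s)", sum(loops))
    edges <- edges[!loops, , drop = FALSE]
  }
  swap <- edges$i > edges$j
  if (any(swap)) {
    tmp <- edges$i[swap]
    edges$i[swap] <- edges$j[swap]
    edges$j[swap] <- tmp
  }
  dup <- duplicated(edges[c("i", "j")])
  if (any(dup)) {
    logWarn("collapsed %d duplicate edge record(s)", sum(dup))
    edges <- edges[!dup, , drop = FALSE]
  }
  rownames(edges) <- NULL
  edges
}

# edge file: header containing non-numeric tokens -> edge list, else matrix
.readEdgeFile <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  tokens <- strsplit(trimws(first), "[,\t ]+")[[1]]
  isHeader <- any(is.na(suppressWarnings(as.numeric(tokens))))
  if (isHeader) {
    .readDelimited(path)
  } else {
    as.matrix(utils::read.table(path, header = FALSE))
  }
}

#' Convert an adjacency matrix to an edge list
#'
#' The matrix is interpreted as undirected: it must be symmetric within
#' `1e-9`. One edge record is emitted per unordered pair `i < j` with a
#' nonzero value; the diagonal is ignored.
#'
#' @param m square numeric matrix (node ids are row/column positions,
#'   0-based in the output).
#' @return edge table with columns `i`, `j`, `weight`.
#' @examples
#' m <- matrix(0, 3, 3); m[1, 3] <- m[3, 1] <- 1.5
#' adjacencyToEdgeList(m)   # one edge: (0, 2, 1.5)
#' @export
adjacencyToEdgeList <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stopf("adjacency must be a numeric matrix")
  if (nrow(m) != ncol(m))
    stopf("adjacency matrix must be square; got %d x %d", nrow(m), ncol(m))
  asym <- max(abs(m - t(m)))
  if (asym > 1e-9)
    stopf(paste0("adjacency matrix must be symmetric for undirected ",
                 "plotting; max |m[i,j] - m[j,i]| = %g"), asym)
  up <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  data.frame(i = as.integer(up[, 1] - 1L), j = as.integer(up[, 2] - 1L),
             weight = m[up])
}

#' Reconstruct an adjacency matrix from an edge table
#'
#' Inverse of [adjacencyToEdgeList()] (zero diagonal, symmetric output).
#'
#' @param edges canonical edge table.
#' @param nNodes matrix dimension.
#' @return symmetric `nNodes` x `nNodes` numeric matrix.
#' @export
edgeListToAdjacency <- function(edges, nNodes) {
  m <- matrix(0, nNodes, nNodes)
  if (nrow(edges)) {
    w <- if ("weight" %in% names(edges)) edges$weight else rep(1, nrow(edges))
    m[cbind(edges$i + 1L, edges$j + 1L)] <- w
    m[cbind(edges$j + 1L, edges$i + 1L)] <- w
  }
  m
}

#' Append per-node metadata columns
#'
#' `extra` must have one row per node. When the nodes came from a
#' parcellation, row `k` of `extra` attaches to the `k`-th label in ascending
#' integer-label order (the order [computeCentroids()] emits).
#'
#' @param nodes canonical node table.
#' @param extra data.frame of additional columns.
#' @return node table with `extra`'s columns appended.
#' @export
mergeNodeMetadata <- function(nodes, extra) {
  extra <- as.data.frame(extra)
  if (nrow(extra) != nrow(nodes))
    stopf("metadata has %d rows but there are %d nodes",
          nrow(extra), nrow(nodes))
  clash <- intersect(names(extra), c("x", "y", "z"))
  if (length(clash))
    stopf("metadata column(s) %s collide with the coordinate columns",
          paste(sQuote(clash), collapse = ", "))
  dupe <- intersect(names(extra), names(nodes))
  if (length(dupe))
    nodes <- nodes[setdiff(names(nodes), dupe)]
  cbind(nodes, extra)
}

#' Ingest a node-attributed graph
#'
#' Converts an undirected igraph object whose vertices carry `x`, `y`, `z`
#' attributes (world mm; remappable via `columnnames`) into canonical node
#' and edge tables. All other vertex attributes become node metadata columns
#' usable by the high-level aesthetics; edge attributes (including `weight`)
#' become edge columns. Vertex identifiers are remapped to dense 0-based ids;
#' original names are kept in a `name` column when present.
#'
#' @param g an \code{igraph} graph.
#' @param columnnames optional length-3 names of the coordinate attributes.
#' @return list with `nodes` and `edges` tables.
#' @export
ingestGraph <- function(g, columnnames = NULL) {
  if (!igraph::is_igraph(g)) stopf("'network' must be an igraph object")
  coordNames <- if (is.null(columnnames)) c("x", "y", "z") else columnnames
  n <- igraph::vcount(g)
  vattrs <- igraph::vertex_attr_names(g)
  nodes <- data.frame(node_id = seq_len(n) - 1L)
  for (k in seq_along(coordNames)) {
    a <- coordNames[k]
    if (!a %in% vattrs) {
      if (n == 0L) { nodes[[c("x", "y", "z")[k]]] <- numeric(0); next }
      stopf("graph vertices lack coordinate attribute '%s'", a)
    }
    vals <- igraph::vertex_attr(g, a)
    bad <- which(!is.finite(as.numeric(vals)))
    if (length(bad))
      stopf("vertex %d is missing coordinate attribute '%s'", bad[1], a)
    nodes[[c("x", "y", "z")[k]]] <- as.numeric(vals)
  }
  for (a in setdiff(vattrs, coordNames))
    nodes[[a]] <- igraph::vertex_attr(g, a)
  validateNodeTable(nodes)

  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- data.frame(i = as.integer(el[, 1] - 1L),
                      j = as.integer(el[, 2] - 1L))
  for (a in igraph::edge_attr_names(g))
    edges[[a]] <- igraph::edge_attr(g, a)
  if (!"weight" %in% names(edges)) edges$weight <- rep(1.0, nrow(edges))
  if (nrow(edges)) edges <- .normalizeEdges(edges)
  list(nodes = nodes, edges = edges)
}
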