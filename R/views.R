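# View grammar: anatomical letters, panel grids, rotation frames and the
# spring-layout companion panel.

.viewLetters <- c("S", "I", "P", "A", "L", "R")

# preset panel grids; compositions are a fixed package convention
.viewPresets <- list(
  "preset-3" = "LSR",
  "preset-4" = "LPRA",
  "preset-6" = c("LRA", "PSI"),
  "preset-9" = c("LRA", "PSI", "_oblique")   # marker row, see below
)
.obliqueAngles <- list(c(45, 20), c(-45, 20), c(135, 20))

#' Camera angle for an anatomical view letter
#'
#' Fixed azimuth/elevation (degrees) under the RAS convention:
#' `L` (180, 0), `R` (0, 0), `A` (90, 0), `P` (-90, 0), `S` (-90, 90),
#' `I` (-90, -90).
#'
#' @param letter one of `S`, `I`, `P`, `A`, `L`, `R` (uppercase).
#' @return numeric `c(azimuth, elevation)` in degrees.
#' @export
letterToAngle <- function(letter) {
  angles <- list(L = c(180, 0), R = c(0, 0), A = c(90, 0), P = c(-90, 0),
                 S = c(-90, 90), I = c(-90, -90))
  if (!is.character(letter) || length(letter) != 1L ||
      is.null(angles[[letter]]))
    stopf("unknown view letter '%s'; valid letters: %s plus 's' (spring)",
          letter, paste(.viewLetters, collapse = ", "))
  angles[[letter]]
}

.anglePanel <- function(az, el)
  list(type = "angle", azimuth = .normAz(az), elevation = el)
.springPanel <- function() list(type = "spring")

# normalize azimuth into (-180, 180]
.normAz <- function(az) {
  az <- az %% 360
  ifelse(az > 180, az - 360, az)
}

.lettersToRow <- function(str) {
  chars <- strsplit(str, "")[[1]]
  bad <- setdiff(chars, c(.viewLetters, "s"))
  if (length(bad))
    stopf("unknown view letter '%s'; valid letters: %s plus 's' (spring)",
          bad[1], paste(.viewLetters, collapse = ", "))
  lapply(chars, function(ch) {
    if (ch == "s") .springPanel()
    else do.call(.anglePanel, as.list(letterToAngle(ch)))
  })
}

#' Parse a view specification into a panel grid
#'
#' The accepted grammar mirrors the documented viewing options:
#' a single letter (1 panel), a multi-letter string (one row of panels, in
#' letter order), a character vector / list of strings (one row per string),
#' a `"preset-N"` string (N in 3, 4, 6, 9), a numeric
#' `(azimuth, elevation)` 2-tuple, or a two-letter string plus `frames = F`
#' (a 1 x F row rotating between the two views). A lowercase `'s'` anywhere
#' marks a spring-layout panel at that grid position.
#'
#' @param view view specification (see Details).
#' @param frames optional frame count; only valid with a two-letter view.
#' @return a \linkS4class{ViewSpec}.
#' @examples
#' viewTotal(parseView("LSR"))              # 3
#' viewTotal(parseView(c("LSR", "AIP")))    # 6, two rows
#' viewTotal(parseView("AP", frames = 4))   # 4 rotating frames
#' @export
parseView <- function(view, frames = NULL) {
  if (is.numeric(view)) {
    if (length(view) != 2L || !all(is.finite(view)))
      stopf("a numeric view must be an (azimuth, elevation) 2-tuple")
    if (!is.null(frames))
      stopf("frames requires a two-letter view string (e.g. 'AP')")
    return(new("ViewSpec", rows = list(list(.anglePanel(view[1], view[2])))))
  }
  if (is.list(view)) view <- unlist(view)
  if (!is.character(view) || !length(view))
    stopf("view must be a letter string, a list of strings, %s",
          "a 'preset-N' string, or an (azimuth, elevation) 2-tuple")
  if (length(view) > 1L) {
    if (!is.null(frames))
      stopf("frames cannot be combined with a multi-row view")
    return(new("ViewSpec", rows = lapply(view, .lettersToRow)))
  }
  if (grepl("^preset-", view)) {
    if (!is.null(frames))
      stopf("frames cannot be combined with a preset view")
    preset <- .viewPresets[[view]]
    if (is.null(preset))
      stopf("unknown preset '%s'; available presets: %s", view,
            paste(names(.viewPresets), collapse = ", "))
    rows <- lapply(preset, function(rowSpec) {
      if (rowSpec == "_oblique")
        lapply(.obliqueAngles, function(a) .anglePanel(a[1], a[2]))
      else .lettersToRow(rowSpec)
    })
    return(new("ViewSpec", rows = rows))
  }
  if (!is.null(frames)) {
    frames <- as.integer(frames)
    if (nchar(view) != 2L)
      stopf("frames requires exactly two view letters; got '%s'", view)
    a <- letterToAngle(substr(view, 1, 1))
    b <- letterToAngle(substr(view, 2, 2))
    angles <- interpolateAngles(a, b, frames)
    return(new("ViewSpec",
               rows = list(lapply(angles, function(x)
                 .anglePanel(x[1], x[2])))))
  }
  new("ViewSpec", rows = list(.lettersToRow(view)))
}

#' Interpolate camera angles between two views
#'
#' `frames` angles including both endpoints; azimuth and elevation are each
#' linearly interpolated, the azimuth along the shorter angular arc. An
#' exact 180-degree azimuth separation is a tie, broken toward decreasing
#' azimuth.
#'
#' @param a,b numeric `c(azimuth, elevation)` in degrees.
#' @param frames integer >= 2.
#' @return list of `frames` angle vectors, endpoints equal to the inputs.
#' @export
interpolateAngles <- function(a, b, frames) {
  if (!is.numeric(frames) || frames < 2)
    stopf("frames must be an integer >= 2")
  frames <- as.integer(frames)
  az0 <- .normAz(a[1])
  daz <- .normAz(b[1] - a[1])
  if (abs(abs(daz) - 180) < 1e-12) daz <- -180   # tie: decreasing azimuth
  t <- seq(0, 1, length.out = frames)
  lapply(seq_len(frames), function(k)
    c(.normAz(az0 + t[k] * daz), a[2] + t[k] * (b[2] - a[2])))
}

#' Force-directed 2D layout for the spring panel
#'
#' Deterministic Fruchterman-Reingold embedding of the network topology
#' (seeded), used for the `'s'` spring-layout panel; the node aesthetics
#' (color, size, highlight) computed for the anatomical panels are reused
#' unchanged there.
#'
#' @param nodes canonical node table.
#' @param edges canonical edge table (may be empty).
#' @param seed RNG seed fixing the embedding (default 42).
#' @return N x 2 matrix of positions in node order.
#' @export
springLayout <- function(nodes, edges = NULL, seed = 42) {
  validateNodeTable(nodes)
  n <- nrow(nodes)
  if (n < 1L) stopf("spring layout needs at least one node")
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (!is.null(edges) && nrow(edges)) {
    idx <- rbind(match(edges$i, nodes$node_id),
                 match(edges$j, nodes$node_id))
    g <- igraph::add_edges(g, as.vector(idx))
  }
  wts <- if (!is.null(edges) && nrow(edges) && "weight" %in% names(edges) &&
             all(edges$weight > 0)) edges$weight else NULL
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pos <- igraph::layout_with_fr(g, weights = wts)
  pos[, 1:2, drop = FALSE]
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
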