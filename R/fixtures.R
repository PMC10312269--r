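# Synthetic fixtures: every input form the engine accepts, generated
# offline and deterministically — an ellipsoidal "brain" template, a
# Voronoi parcellation of it, community-structured random networks and
# NBS-style binary highlight matrices.

#' Fixture generation settings
#'
#' Defaults describe a small standard-space-like volume: a 64x64x64 grid of
#' 2 mm voxels (world origin at the grid center) holding an ellipsoidal
#' brain of semi-axes 45 x 55 x 40 mm, and community-structured random
#' networks in the style of the package's worked examples (3 communities,
#' denser within than between).
#'
#' @param shape grid dimensions (voxels).
#' @param voxmm isotropic voxel size (mm).
#' @param semiAxes ellipsoid semi-axes (mm), x/y/z.
#' @param falloff border softness as a fraction of the normalized ellipsoid
#'   radius (0 = hard binary edge).
#' @param nLabels number of parcellation labels.
#' @param nNodes number of network nodes.
#' @param nCommunities number of communities.
#' @param pWithin,pBetween within/between-community edge probabilities.
#' @param seed RNG seed fixing every random draw.
#' @return a `FixtureConfig` (named list).
#' @export
fixtureConfig <- function(shape = c(64, 64, 64), voxmm = 2,
                          semiAxes = c(45, 55, 40), falloff = 0.1,
                          nLabels = 20, nNodes = 100, nCommunities = 3,
                          pWithin = 0.3, pBetween = 0.05, seed = 42) {
  stopifnot(length(shape) == 3, all(shape >= 1), voxmm > 0,
            length(semiAxes) == 3, all(semiAxes > 0), falloff >= 0,
            nLabels >= 1, nNodes >= 1, nCommunities >= 1,
            pWithin >= 0, pWithin <= 1, pBetween >= 0, pBetween <= 1)
  structure(list(shape = as.integer(shape), voxmm = voxmm,
                 semiAxes = semiAxes, falloff = falloff,
                 nLabels = as.integer(nLabels), nNodes = as.integer(nNodes),
                 nCommunities = as.integer(nCommunities),
                 pWithin = pWithin, pBetween = pBetween,
                 seed = as.integer(seed)),
            class = "FixtureConfig")
}

#' Synthetic ellipsoidal brain template
#'
#' A smooth ellipsoid: intensity 1 inside, falling linearly to 0 across the
#' border band controlled by `falloff` (a zero falloff gives a strictly
#' binary volume). The RAS affine centers the world origin on the ellipsoid.
#'
#' @param cfg a [fixtureConfig()].
#' @return a \linkS4class{BrainVolume}.
#' @export
makeTemplate <- function(cfg = fixtureConfig()) {
  halfExtent <- cfg$voxmm * (cfg$shape - 1) / 2
  if (any(cfg$semiAxes > halfExtent))
    stopf("ellipsoid semi-axes (%s mm) exceed the grid half-extent (%s mm)",
          paste(cfg$semiAxes, collapse = ", "),
          paste(halfExtent, collapse = ", "))
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(rep(cfg$voxmm, 3))
  aff[1:3, 4] <- -halfExtent
  ax <- lapply(1:3, function(k)
    ((seq_len(cfg$shape[k]) - 1) * cfg$voxmm - halfExtent[k]) /
      cfg$semiAxes[k])
  rho2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  rho <- sqrt(rho2)
  g <- if (cfg$falloff > 0)
    pmin(1, pmax(0, (1 - rho) / cfg$falloff)) else (rho <= 1) * 1.0
  g <- array(g, dim = cfg$shape)
  new("BrainVolume", grid = g, affine = aff, spaceName = "synthetic")
}

#' Voronoi parcellation of a synthetic template
#'
#' Draws `nLabels` seed voxels uniformly inside the template's mask and
#' labels every mask voxel by its nearest seed (voxel-space Euclidean
#' distance). Labels are 1..nLabels and each is nonempty.
#'
#' @param template a \linkS4class{BrainVolume} (mask = nonzero voxels).
#' @param nLabels number of labels.
#' @param seed RNG seed.
#' @return a \linkS4class{Parcellation}.
#' @export
makeParcellation <- function(template, nLabels = 20, seed = 42) {
  mask <- template@grid > 0
  vox <- which(mask)
  if (nLabels > length(vox))
    stopf("nLabels (%d) exceeds the mask voxel count (%d)", nLabels,
          length(vox))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  seeds <- arrayInd(sample(vox, nLabels), dim(mask))
  coords <- arrayInd(vox, dim(mask))
  lab <- integer(length(vox))
  best <- rep(Inf, length(vox))
  for (s in seq_len(nLabels)) {
    d2 <- (coords[, 1] - seeds[s, 1])^2 + (coords[, 2] - seeds[s, 2])^2 +
      (coords[, 3] - seeds[s, 3])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    lab[upd] <- s
  }
  g <- array(0, dim(mask))
  g[vox] <- lab
  new("Parcellation", grid = g, affine = template@affine,
      spaceName = template@spaceName, labels = sort(unique(lab)))
}

#' Community-structured random network inside the template ellipsoid
#'
#' Node coordinates are sampled uniformly inside the fixture ellipsoid;
#' communities are assigned in equal contiguous blocks; undirected edges are
#' drawn independently with probability `pWithin` inside a community and
#' `pBetween` across, with uniform(0,1] weights. The node table carries the
#' metadata columns `community`, `measure1` and `measure2` used by the
#' high-level aesthetics examples.
#'
#' @param nNodes number of nodes (defaults to the config's).
#' @param cfg a [fixtureConfig()].
#' @return list with `nodes` and `edges` tables.
#' @export
makeNetwork <- function(nNodes = NULL, cfg = fixtureConfig()) {
  n <- nNodes %||% cfg$nNodes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(cfg$seed)
  coords <- matrix(NA_real_, n, 3)
  filled <- 0L
  while (filled < n) {
    m <- 2L * (n - filled)
    cand <- cbind(stats::runif(m, -1, 1), stats::runif(m, -1, 1),
                  stats::runif(m, -1, 1))
    keep <- rowSums(cand^2) <= 0.9^2
    take <- utils::head(which(keep), n - filled)
    if (length(take)) {
      coords[filled + seq_along(take), ] <- cand[take, , drop = FALSE] *
        matrix(cfg$semiAxes, length(take), 3, byrow = TRUE)
      filled <- filled + length(take)
    }
  }
  community <- sort(rep_len(seq_len(cfg$nCommunities), n))
  nodes <- data.frame(node_id = seq_len(n) - 1L,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      community = community,
                      measure1 = stats::runif(n),
                      measure2 = stats::runif(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  sameCom <- community[pairs[, 1]] == community[pairs[, 2]]
  p <- ifelse(sameCom, cfg$pWithin, cfg$pBetween)
  draw <- stats::runif(nrow(pairs)) < p
  edges <- data.frame(i = as.integer(pairs[draw, 1] - 1L),
                      j = as.integer(pairs[draw, 2] - 1L),
                      weight = stats::runif(sum(draw)))
  list(nodes = nodes, edges = edges)
}

#' NBS-style binary highlight matrix
#'
#' Marks `nSelect` randomly chosen existing edges in a symmetric binary
#' N x N matrix — the shape network-based-statistics implementations emit
#' for their significant cluster, consumable by the `highlight_edges`
#' option.
#'
#' @param edges canonical edge table.
#' @param nSelect number of edges to mark (must not exceed the edge count).
#' @param nNodes matrix dimension.
#' @param seed RNG seed.
#' @return binary `nNodes` x `nNodes` symmetric matrix.
#' @export
makeHighlightMatrix <- function(edges, nSelect, nNodes, seed = 42) {
  if (nSelect > nrow(edges))
    stopf("nSelect (%d) exceeds the number of edges (%d)", nSelect,
          nrow(edges))
  m <- matrix(0, nNodes, nNodes)
  if (nSelect > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    pick <- sample(nrow(edges), nSelect)
    m[cbind(edges$i[pick] + 1L, edges$j[pick] + 1L)] <- 1
    m[cbind(edges$j[pick] + 1L, edges$i[pick] + 1L)] <- 1
  }
  m
}

#' Write fixture tables and matrices in the formats the engine reads
#'
#' @param x node/edge data.frame (TSV with header) or numeric matrix
#'   (whitespace-delimited text, no header).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFixtureTable <- function(x, path) {
  if (is.matrix(x)) {
    utils::write.table(x, path, row.names = FALSE, col.names = FALSE)
  } else {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    utils::write.table(x, path, row.names = FALSE, sep = sep,
                       quote = FALSE)
  }
  invisible(path)
}
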