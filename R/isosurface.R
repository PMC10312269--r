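# Isosurface extraction by marching tetrahedra.
#
# Each grid cell is split into six tetrahedra sharing the main diagonal;
# every tetrahedron crossed by the iso-level contributes one or two
# triangles whose vertices are linear interpolations along the crossing
# edges. Shared cell faces and edges interpolate identically, so the
# resulting surface is watertight for solid (zero-padded) masks, and the
# construction is fully deterministic.

# cube corner offsets, order v0..v7 (bit patterns of (x, y, z))
.mtOffsets <- rbind(
  c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
  c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))

# six tetrahedra around the v0-v6 diagonal (1-based corner ids)
.mtTets <- rbind(
  c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))

# triangle soup (n x 9: three xyz triples) for one scalar field
marchingTetrahedra <- function(vol, level = 0.5) {
  d <- dim(vol)
  nc <- d - 1L
  if (any(nc < 1L)) return(matrix(numeric(0), 0, 9))
  cornerVals <- vector("list", 8L)
  for (cc in 1:8) {
    o <- .mtOffsets[cc, ]
    cornerVals[[cc]] <- as.vector(
      vol[o[1] + seq_len(nc[1]), o[2] + seq_len(nc[2]),
          o[3] + seq_len(nc[3])])
  }
  ins <- vapply(cornerVals, function(v) v > level,
                logical(length(cornerVals[[1]])))
  nin <- rowSums(ins)
  act <- which(nin > 0L & nin < 8L)
  if (!length(act)) return(matrix(numeric(0), 0, 9))
  base <- arrayInd(act, nc) - 1L               # 0-based cell corner
  vals <- vapply(cornerVals, function(v) v[act], numeric(length(act)))
  insA <- vals > level

  # interpolated crossing point on the edge u -> w, for selected cells
  interp <- function(sel, u, w) {
    pu <- base[sel, , drop = FALSE] +
      matrix(.mtOffsets[u, ], length(sel), 3, byrow = TRUE)
    pw <- base[sel, , drop = FALSE] +
      matrix(.mtOffsets[w, ], length(sel), 3, byrow = TRUE)
    t <- (level - vals[sel, u]) / (vals[sel, w] - vals[sel, u])
    pu + t * (pw - pu)
  }

  tris <- list()
  for (ti in seq_len(nrow(.mtTets))) {
    tet <- .mtTets[ti, ]
    bits <- insA[, tet[1]] + 2L * insA[, tet[2]] +
      4L * insA[, tet[3]] + 8L * insA[, tet[4]]
    for (B in 1:14) {
      sel <- which(bits == B)
      if (!length(sel)) next
      inside <- tet[bitwAnd(B, c(1L, 2L, 4L, 8L)) > 0L]
      outside <- setdiff(tet, inside)
      if (length(inside) == 1L) {
        tris[[length(tris) + 1L]] <- cbind(
          interp(sel, inside, outside[1]),
          interp(sel, inside, outside[2]),
          interp(sel, inside, outside[3]))
      } else if (length(inside) == 3L) {
        tris[[length(tris) + 1L]] <- cbind(
          interp(sel, inside[1], outside[1]),
          interp(sel, inside[2], outside[1]),
          interp(sel, inside[3], outside[1]))
      } else {                                  # 2 in / 2 out -> quad
        a <- inside[1]; b <- inside[2]
        cc <- outside[1]; dd <- outside[2]
        q1 <- interp(sel, a, cc); q2 <- interp(sel, a, dd)
        q3 <- interp(sel, b, dd); q4 <- interp(sel, b, cc)
        tris[[length(tris) + 1L]] <- cbind(q1, q2, q3)
        tris[[length(tris) + 1L]] <- cbind(q1, q3, q4)
      }
    }
  }
  do.call(rbind, tris)
}

# triangle soup (voxel space) -> Mesh with deduplicated vertices
.soupToMesh <- function(soup, affine, shift = 0) {
  if (!nrow(soup)) stopf("isosurface is empty")
  verts <- rbind(soup[, 1:3, drop = FALSE], soup[, 4:6, drop = FALSE],
                 soup[, 7:9, drop = FALSE]) + shift
  key <- paste(round(verts[, 1], 6), round(verts[, 2], 6),
               round(verts[, 3], 6))
  uid <- match(key, unique(key))
  uverts <- verts[!duplicated(key), , drop = FALSE]
  n <- nrow(soup)
  faces <- cbind(uid[seq_len(n)], uid[n + seq_len(n)], uid[2L * n + seq_len(n)])
  keep <- faces[, 1] != faces[, 2] & faces[, 2] != faces[, 3] &
    faces[, 1] != faces[, 3]
  world <- voxelToWorld(uverts, affine)
  new("Mesh", vertices = world,
      faces = matrix(as.integer(faces[keep, , drop = FALSE]), ncol = 3))
}

# separately-normalized 3x3x3 Gaussian smoothing (edge-aware normalization)
gaussSmooth3 <- function(a, sigma) {
  d <- dim(a)
  out <- array(0, d)
  tot <- array(0, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    w <- exp(-(dx^2 + dy^2 + dz^2) / (2 * sigma^2))
    xs <- max(1, 1 + dx):min(d[1], d[1] + dx)
    ys <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
    xs0 <- xs - dx; ys0 <- ys - dy; zs0 <- zs - dz
    out[xs0, ys0, zs0] <- out[xs0, ys0, zs0] + w * a[xs, ys, zs]
    tot[xs0, ys0, zs0] <- tot[xs0, ys0, zs0] + w
  }
  out / tot
}

#' Extract the bounding isosurface of a binary mask
#'
#' Meshes the 0.5 iso-level of a binary mask (marching-tetrahedra
#' tessellation with linear edge interpolation). The mask is zero-padded by
#' one voxel first, so solid masks yield closed, watertight surfaces.
#' Vertices are returned in world mm via the affine.
#'
#' Before meshing, the binary mask is lightly Gaussian-smoothed
#' (`smoothing` is the kernel sigma in voxels); interpolating the smoothed
#' field suppresses the staircase facets a raw binary field produces and
#' brings the surface area of voxelized solids close to the analytic value.
#' Masks too small to survive smoothing (no voxel above the iso-level) fall
#' back to the raw binary field. `smoothing = 0` disables smoothing.
#'
#' @param mask a \linkS4class{BrainVolume} (binarized with [binarizeVolume()]
#'   first if needed) or a 3D array; nonzero voxels are inside.
#' @param affine 4x4 voxel-to-world matrix; defaults to the volume's own.
#' @param smoothing Gaussian sigma in voxels (default 0.55).
#' @return a \linkS4class{Mesh}.
#' @export
extractSurface <- function(mask, affine = NULL, smoothing = 0.55) {
  if (is(mask, "BrainVolume")) {
    if (is.null(affine)) affine <- mask@affine
    mask <- mask@grid
  }
  if (is.null(affine)) affine <- diag(4)
  m <- (mask != 0) * 1.0
  if (!any(m > 0)) stopf("mask is empty; no surface to extract")
  field <- if (smoothing > 0) gaussSmooth3(m, smoothing) else m
  if (!any(field > 0.5)) field <- m              # tiny mask: binary fallback
  d <- dim(m)
  padded <- array(0, d + 2L)
  padded[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <-
    field
  soup <- marchingTetrahedra(padded, 0.5)
  .soupToMesh(soup, affine, shift = -1)
}

#' Total surface area of a mesh
#'
#' @param mesh a \linkS4class{Mesh}.
#' @return sum of triangle areas (mm^2 for world-space meshes).
#' @export
meshArea <- function(mesh) {
  v <- mesh@vertices
  f <- mesh@faces
  if (!nrow(f)) return(0)
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Connected components of a mesh
#'
#' Components are maximal sets of faces connected through shared vertices.
#'
#' @param mesh a \linkS4class{Mesh}.
#' @return number of connected components.
#' @export
meshComponents <- function(mesh) {
  f <- mesh@faces
  if (!nrow(f)) return(0L)
  parent <- seq_len(nrow(mesh@vertices))
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  for (r in seq_len(nrow(f))) {
    union2(f[r, 1], f[r, 2])
    union2(f[r, 1], f[r, 3])
  }
  used <- unique(as.vector(f))
  length(unique(vapply(used, find, integer(1))))
}

#' Euler characteristic of a mesh
#'
#' `V - E + F` over the vertices used by at least one face; 2 for a single
#' closed surface of genus 0 (e.g. the boundary of a convex solid).
#'
#' @param mesh a \linkS4class{Mesh}.
#' @return integer Euler characteristic.
#' @export
meshEuler <- function(mesh) {
  f <- mesh@faces
  if (!nrow(f)) return(0L)
  V <- length(unique(as.vector(f)))
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  E <- nrow(unique(e))
  V - E + nrow(f)
}

# TRUE when every edge borders exactly two faces (closed surface)
meshWatertight <- function(mesh) {
  f <- mesh@faces
  if (!nrow(f)) return(FALSE)
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(1, 3)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

# UV-sphere mesh (used by the 'spheres' node style)
sphereMesh <- function(center, radius, res = 20L) {
  res <- max(4L, as.integer(res))
  theta <- seq(0, pi, length.out = res)          # polar
  phi <- seq(0, 2 * pi, length.out = res + 1L)[-(res + 1L)]
  verts <- cbind(
    as.vector(outer(sin(theta), cos(phi))),
    as.vector(outer(sin(theta), sin(phi))),
    as.vector(outer(cos(theta), rep(1, length(phi)))))
  verts <- verts * radius +
    matrix(center, nrow(verts), 3, byrow = TRUE)
  idx <- function(i, j) (j - 1L) * res + i       # i: theta row, j: phi col
  faces <- list()
  for (j in seq_len(res)) {
    jn <- if (j == res) 1L else j + 1L
    for (i in seq_len(res - 1L)) {
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, j), idx(i + 1L, jn))
      faces[[length(faces) + 1L]] <- c(idx(i, j), idx(i + 1L, jn), idx(i, jn))
    }
  }
  new("Mesh", vertices = verts,
      faces = matrix(as.integer(unlist(faces)), ncol = 3, byrow = TRUE))
}
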