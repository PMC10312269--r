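# Shared in-code fixtures: everything is generated, nothing is stored.

# compact fixture settings for fast tests
smallCfg <- function(seed = 1, ...) {
  fixtureConfig(shape = c(20, 20, 20), voxmm = 2, semiAxes = c(14, 16, 12),
                nLabels = 6, nNodes = 10, seed = seed, ...)
}

# solid ball mask (array) of radius r voxels centered in an n^3 grid
ballArray <- function(n, r, center = (n - 1) / 2) {
  co <- seq(0, n - 1)
  d2 <- outer(outer((co - center)^2, (co - center)^2, `+`),
              (co - center)^2, `+`)
  (d2 <= r^2) * 1.0
}

asVolume <- function(arr, affine = diag(4)) {
  new("BrainVolume", grid = arr, affine = affine)
}

asParc <- function(arr, affine = diag(4)) {
  labs <- sort(unique(as.integer(arr[arr != 0])))
  new("Parcellation", grid = arr, affine = affine, labels = labs)
}

# independent brute-force centroid oracle: per-label voxel-index mean
# mapped through the affine, one label at a time
bruteCentroids <- function(p) {
  g <- p@grid
  labs <- sort(unique(as.integer(g[g != 0])))
  t(vapply(labs, function(lb) {
    vox <- which(g == lb, arr.ind = TRUE) - 1
    voxelToWorld(colMeans(vox), p@affine)
  }, numeric(3)))
}

# random parcellation with a random diagonal affine
randomParcellation <- function(seed, shape = c(12, 12, 12), nLab = 4) {
  set.seed(seed)
  aff <- diag(4)
  aff[1:3, 1:3] <- diag(runif(3, 0.5, 3))
  aff[1:3, 4] <- runif(3, -20, 20)
  g <- array(sample(0:nLab, prod(shape), replace = TRUE), shape)
  if (!any(g != 0)) g[1] <- 1L
  asParc(g * 1.0, aff)
}

tinyNodes <- function() {
  data.frame(x = c(-10, 0, 10), y = c(5, -5, 0), z = c(0, 3, -3))
}

# small connected node/edge pair with metadata
tinyNetwork <- function() {
  nodes <- data.frame(node_id = 0:2, x = c(-10, 0, 10), y = c(5, -5, 0),
                      z = c(0, 3, -3), community = c(1, 1, 2))
  edges <- data.frame(i = c(0L, 0L, 1L), j = c(1L, 2L, 2L),
                      weight = c(1, 2, 3))
  list(nodes = nodes, edges = edges)
}
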