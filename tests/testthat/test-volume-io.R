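test_that("NIfTI volumes round-trip through write/load", {
  g <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -10, -10)
  v <- new("BrainVolume", grid = g, affine = aff)

  p1 <- tempfile(fileext = ".nii.gz")
  writeVolume(v, p1)
  v1 <- loadVolume(p1)
  expect_equal(v1@grid, g, tolerance = 1e-6)
  expect_equal(v1@affine, aff, tolerance = 1e-6)

  p2 <- tempfile(fileext = ".nii")       # uncompressed route
  writeVolume(v, p2)
  v2 <- loadVolume(p2)
  expect_equal(v2@grid, v1@grid, tolerance = 1e-6)
  expect_equal(v2@affine, v1@affine, tolerance = 1e-6)

  expect_error(loadVolume(tempfile()), "not found")
})

test_that("singleton 4th dimensions are squeezed; 2D inputs are rejected", {
  p <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4, 1))), p)
  expect_equal(dim(loadVolume(p)@grid), c(4, 4, 4))

  p2 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(matrix(1, 4, 4)), p2)
  expect_error(loadVolume(p2), "3D")
})

test_that("voxel/world mapping follows the affine and vectorizes", {
  expect_equal(voxelToWorld(c(0, 0, 0), diag(4)), c(0, 0, 0))

  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-10, -10, -10)
  expect_equal(voxelToWorld(c(1, 2, 3), aff), c(-8, -6, -4))

  set.seed(2)
  idx <- matrix(runif(30, 0, 9), 10, 3)
  w <- voxelToWorld(idx, aff)
  expect_equal(nrow(w), 10)
  expect_equal(w[4, ], voxelToWorld(idx[4, ], aff))
  # inverse composition is the identity
  expect_equal(worldToVoxel(w, aff), idx, tolerance = 1e-9)
})

test_that("centroids are affine-mapped per-label voxel means", {
  g <- array(0, c(4, 4, 4))
  g[c(1, 3), 1, 1] <- 1                  # voxels (0,0,0) and (2,0,0)
  ct <- computeCentroids(asParc(g))
  expect_equal(unlist(ct[1, c("x", "y", "z")], use.names = FALSE),
               c(1, 0, 0))

  ct2 <- computeCentroids(asParc(g, diag(c(2, 2, 2, 1))))
  expect_equal(unlist(ct2[1, c("x", "y", "z")], use.names = FALSE),
               c(2, 0, 0))

  g[4, 4, 4] <- 2
  ct3 <- computeCentroids(asParc(g))
  expect_equal(ct3$label, c(1, 2))
  expect_equal(ct3$node_id, 0:1)

  empty <- new("Parcellation", grid = array(0, c(2, 2, 2)),
               affine = diag(4), labels = integer(0))
  expect_error(computeCentroids(empty), "empty")
})

test_that("centroids agree with the brute-force oracle on random inputs", {
  for (seed in 1:10) {
    p <- randomParcellation(seed)
    got <- as.matrix(computeCentroids(p)[c("x", "y", "z")])
    expect_lt(max(abs(got - bruteCentroids(p))), 1e-9)
  }
})

test_that("downsampling block-averages and preserves world placement", {
  v <- asVolume(array(1:64 * 1.0, c(4, 4, 4)))
  expect_identical(downsampleVolume(v, 1), v)      # native size: unchanged

  vc <- asVolume(array(3.5, c(4, 4, 4)))
  expect_true(all(downsampleVolume(vc, 2)@grid == 3.5))

  dv <- downsampleVolume(v, 2)
  expect_equal(dim(dv@grid), c(2, 2, 2))
  # oracle: brute-force mean over each 2x2x2 block
  for (i in 0:1) for (j in 0:1) for (k in 0:1) {
    block <- v@grid[i * 2 + 1:2, j * 2 + 1:2, k * 2 + 1:2]
    expect_equal(dv@grid[i + 1, j + 1, k + 1], mean(block))
  }
  # output voxel centers sit at the world mean of their block
  expect_equal(voxelToWorld(c(0, 0, 0), dv@affine), c(0.5, 0.5, 0.5))

  expect_error(downsampleVolume(v, 0.5), "unsupported")
})

test_that("downsampling conserves the global mean and labels stay modal", {
  set.seed(3)
  v <- asVolume(array(runif(8^3), c(8, 8, 8)))
  dv <- downsampleVolume(v, 2)
  expect_equal(mean(dv@grid), mean(v@grid), tolerance = 1e-6)

  g <- array(0, c(4, 4, 4))
  g[1:2, 1:2, 1:2] <- 1                  # block is 8 voxels of label 1
  g[3:4, 1:2, 1:2] <- c(2, 2, 2, 0, 2, 0, 0, 0)  # 4 of 8 are label 2
  dp <- downsampleVolume(asParc(g), 2)
  expect_s4_class(dp, "Parcellation")
  expect_equal(dp@grid[1, 1, 1], 1)      # unanimous block
  expect_equal(dp@grid[2, 1, 1], 2)      # background excluded from vote
  expect_equal(dp@grid[2, 2, 2], 0)      # all-background block stays 0
})

test_that("hemisphere restriction keeps within-hemisphere connections only", {
  nodes <- data.frame(node_id = 0:1, x = c(-10, 10), y = 0, z = 0)
  edges <- data.frame(i = 0L, j = 1L, weight = 1)
  left <- hemisphereRestrict(nodes, "L", edges)
  expect_equal(nrow(left$nodes), 1)
  expect_equal(left$nodes$x, -10)
  expect_equal(nrow(left$edges), 0)

  allLeft <- data.frame(node_id = 0:2, x = c(-1, -2, -3), y = 0, z = 0)
  e2 <- data.frame(i = c(0L, 1L), j = c(1L, 2L), weight = 1)
  res <- hemisphereRestrict(allLeft, "L", e2)
  expect_equal(nrow(res$nodes), 3)
  expect_equal(nrow(res$edges), 2)

  expect_error(hemisphereRestrict(nodes, "left"), "'L' or 'R'")
})

test_that("midline voxels and nodes belong to both hemispheres", {
  # 3 voxels along x at world x = -2, 0, 2
  aff <- diag(4); aff[1, 4] <- -2; aff[1, 1] <- 2
  g <- array(1, c(3, 1, 1))
  v <- new("BrainVolume", grid = g, affine = aff)
  L <- hemisphereRestrict(v, "L")@grid
  R <- hemisphereRestrict(v, "R")@grid
  expect_equal(as.vector(L), c(1, 1, 0))
  expect_equal(as.vector(R), c(0, 1, 1))

  nodes <- data.frame(node_id = 0:2, x = c(-5, 0, 5), y = 0, z = 0)
  nl <- hemisphereRestrict(nodes, "L")$nodes
  nr <- hemisphereRestrict(nodes, "R")$nodes
  expect_true(0 %in% nl$x && 0 %in% nr$x)
  # union recovers every node, midline counted on both sides
  expect_setequal(union(nl$node_id, nr$node_id), nodes$node_id)
})

test_that("template selection prefers T1w and falls back to the mask", {
  cfg <- smallCfg()
  tpl <- makeTemplate(cfg)
  dir <- tempfile(); dir.create(dir)
  writeVolume(tpl, file.path(dir, "tpl-TESTSPACE_desc-brain_mask.nii.gz"))

  maskOnly <- localFetcher(dir)
  v <- selectTemplateImage("TESTSPACE", maskOnly)
  expect_match(spaceName(v), "mask")

  writeVolume(tpl, file.path(dir, "tpl-TESTSPACE_desc-brain_T1w.nii.gz"))
  v2 <- selectTemplateImage("TESTSPACE", localFetcher(dir))
  expect_match(spaceName(v2), "T1w")

  # pass-through for local paths and in-memory volumes
  p <- file.path(dir, "tpl-TESTSPACE_desc-brain_T1w.nii.gz")
  expect_s4_class(selectTemplateImage(p), "BrainVolume")
  expect_identical(selectTemplateImage(tpl), tpl)

  expect_error(selectTemplateImage("NOSPACE", localFetcher(dir)),
               "queried")
  expect_error(selectTemplateImage("TESTSPACE"), "fetcher")
})

test_that("atlas descriptors resolve to parcellation centroids", {
  cfg <- smallCfg()
  parc <- makeParcellation(makeTemplate(cfg), nLabels = 4, seed = 2)
  dir <- tempfile(); dir.create(dir)
  writeVolume(parc,
    file.path(dir, "tpl-TESTSPACE_atlas-Toy_desc-4Parcels_dseg.nii.gz"))
  out <- parseNodes(list(template = "TESTSPACE", atlas = "Toy",
                         desc = "4Parcels"),
                    fetcher = localFetcher(dir))
  expect_equal(nrow(out$nodes), 4)
  expect_s4_class(out$parcellation, "Parcellation")
  expect_error(parseNodes(list(atlas = "Toy")), "fetcher")
})
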