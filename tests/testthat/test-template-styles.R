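test_that("binarization thresholds the grid", {
  z <- asVolume(array(0, c(3, 3, 3)))
  expect_true(all(binarizeVolume(z)@grid == 0))
  one <- asVolume(array(1, c(3, 3, 3)))
  expect_true(all(binarizeVolume(one)@grid == 1))
  mix <- asVolume(array(c(0, 2), c(4, 4, 4)))
  bm <- binarizeVolume(mix, level = 1)
  expect_equal(sum(bm@grid), sum(mix@grid == 2))
})

test_that("surface meshes match analytic areas of voxelized solids", {
  # solid cube, 10 voxels a side: iso surface area ~ 6 * 10^2
  g <- array(0, c(16, 16, 16)); g[4:13, 4:13, 4:13] <- 1
  m <- extractSurface(g)
  expect_lt(abs(meshArea(m) / 600 - 1), 0.10)
  expect_equal(meshComponents(m), 1)
  expect_equal(meshEuler(m), 2)         # single closed genus-0 surface

  # solid ball of radius 10 voxels: area within 15% of 4*pi*r^2
  ball <- ballArray(25, 10, center = 12)
  mb <- extractSurface(ball)
  expect_lt(abs(meshArea(mb) / (4 * pi * 100) - 1), 0.15)
  expect_equal(meshComponents(mb), 1)

  # two disjoint blobs -> two connected components
  g2 <- array(0, c(14, 8, 8))
  g2[2:4, 3:5, 3:5] <- 1
  g2[10:12, 3:5, 3:5] <- 1
  expect_equal(meshComponents(extractSurface(g2)), 2)

  expect_error(extractSurface(array(0, c(4, 4, 4))), "empty")
})

test_that("surface vertices land in world space through the affine", {
  g <- array(0, c(8, 8, 8)); g[3:6, 3:6, 3:6] <- 1
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- -7
  m <- extractSurface(asVolume(g, aff))
  vr <- apply(meshVertices(m), 2, range)
  # cube of voxels 2..5 -> world centers -3..3, surface within one voxel
  expect_true(all(vr[1, ] > -6 & vr[2, ] < 6))
  expect_true(all(vr[1, ] < -2 & vr[2, ] > 2))
})

test_that("glass borders trace intensity structure, not the tiling", {
  n <- 31; r <- 12; c0 <- 15
  co <- seq(0, n - 1)
  rho <- sqrt(outer(outer((co - c0)^2, (co - c0)^2, `+`),
                    (co - c0)^2, `+`))
  # uniform solid ball: every border point within 1 voxel of the shell
  v <- asVolume((rho <= r) * 1.0)
  g <- glassGeometry(v, segments = 200)
  shellDist <- abs(sqrt(rowSums((g@points - c0)^2)) - r)
  expect_lt(max(shellDist), 1)
  expect_true(all(g@alpha <= 0.05))

  # nested intensity regions: points adjacent to the internal boundary
  ph <- ifelse(rho <= 6, 0.4, ifelse(rho <= r, 1.0, 0))
  g2 <- glassGeometry(asVolume(array(ph, dim(rho))), segments = 200)
  dists <- sqrt(rowSums((g2@points - c0)^2))
  expect_gt(sum(abs(dists - 6) <= 1.5), 0)

  # raising the segment count never reduces the border point count
  grad <- ifelse(rho <= r, rho / r, 0)
  vg <- asVolume(array(grad, dim(rho)))
  n1 <- nrow(glassGeometry(vg, segments = 50)@points)
  n2 <- nrow(glassGeometry(vg, segments = 200)@points)
  expect_gte(n2, n1)

  expect_error(glassGeometry(asVolume(array(0, c(3, 3, 3)))), "empty")
})

test_that("cloudy returns exactly the background-adjacent mask voxels", {
  cube <- asVolume(array(1, c(3, 3, 3)))
  expect_equal(nrow(cloudyGeometry(cube)@points), 26)   # all but center

  single <- array(0, c(3, 3, 3)); single[2, 2, 2] <- 1
  expect_equal(nrow(cloudyGeometry(asVolume(single))@points), 1)

  # one-voxel-thick hollow box: every mask voxel borders background
  shell <- array(1, c(7, 7, 7)); shell[2:6, 2:6, 2:6] <- 0
  pad <- array(0, c(9, 9, 9)); pad[2:8, 2:8, 2:8] <- shell
  pc <- cloudyGeometry(asVolume(pad))
  expect_equal(nrow(pc@points), sum(pad))

  expect_error(cloudyGeometry(asVolume(array(0, c(2, 2, 2)))), "empty")
})

test_that("filled plots one point per mask voxel, with the voxelsize lever", {
  g <- array(0, c(4, 4, 4)); g[sample(64, 7)] <- 1
  pc <- filledGeometry(asVolume(g))
  expect_equal(nrow(pc@points), 7)

  solid <- asVolume(array(1, c(4, 4, 4)))
  expect_equal(nrow(filledGeometry(solid, voxelsize = 2)@points), 8)

  # point coordinates are the affine-mapped voxel indices
  aff <- diag(c(3, 3, 3, 1))
  one <- array(0, c(3, 3, 3)); one[2, 3, 1] <- 1
  pt <- filledGeometry(asVolume(one, aff))@points
  expect_equal(as.vector(pt), voxelToWorld(c(1, 2, 0), aff))
})

test_that("style dispatch routes the four styles and rejects typos", {
  v <- asVolume(ballArray(12, 4, 5.5))
  expect_s4_class(styleDispatch("surface", v, list())$geometry, "Mesh")
  expect_s4_class(styleDispatch("cloudy", v, list())$geometry,
                  "PointCloud")
  expect_null(styleDispatch("none", v, list()))
  err <- tryCatch(styleDispatch("glas", v, list()),
                  error = conditionMessage)
  expect_match(err, "glass")
  expect_match(err, "surface")
  expect_match(err, "filled")
  expect_match(err, "cloudy")
})

test_that("styles are deterministic and stay inside the inflated bbox", {
  cfg <- smallCfg()
  tpl <- makeTemplate(cfg)
  a <- glassGeometry(tpl, segments = 100)
  b <- glassGeometry(tpl, segments = 100)
  expect_identical(a@points, b@points)

  d <- dim(tpl@grid)
  lo <- voxelToWorld(c(0, 0, 0), tpl@affine) - voxelSpacing(tpl@affine)
  hi <- voxelToWorld(d - 1, tpl@affine) + voxelSpacing(tpl@affine)
  for (style in c("glass", "surface", "filled", "cloudy")) {
    layer <- styleDispatch(style, tpl, list())
    pts <- if (layer$kind == "mesh") meshVertices(layer$geometry) else
      layer$geometry@points
    expect_true(all(t(pts) >= lo - 1e-9 & t(pts) <= hi + 1e-9),
                label = paste(style, "bbox"))
  }
})
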