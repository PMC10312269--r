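test_that("node styles produce markers, spheres, and per-label meshes", {
  nodes <- parseNodes(tinyNodes())$nodes
  mk <- nodeGeometry(nodes, "circles")
  expect_equal(mk$kind, "markers")
  expect_equal(nrow(mk$coords), 3)
  expect_equal(mk$coords[, 1], nodes$x)

  sp <- nodeGeometry(nodes[1, ], "spheres", sizes = 5)
  v <- meshVertices(sp$meshes[[1]])
  ctr <- matrix(unlist(nodes[1, c("x", "y", "z")]), nrow(v), 3,
                byrow = TRUE)
  radii <- sqrt(rowSums((v - ctr)^2))
  expect_true(all(radii <= 5 * (1 + 1e-9)))
  big <- nodeGeometry(nodes[1, ], "spheres", sizes = 8)
  vb <- meshVertices(big$meshes[[1]])
  expect_gt(max(sqrt(rowSums((vb - ctr)^2))), max(radii))

  g <- array(0, c(10, 6, 6))
  g[2:4, 2:5, 2:5] <- 1; g[7:9, 2:5, 2:5] <- 2
  parc <- asParc(g)
  pn <- parseNodes(parc)
  pg <- nodeGeometry(pn$nodes, "parcels", parcellation = parc)
  expect_length(pg$meshes, 2)
  expect_equal(meshComponents(pg$meshes[[1]]), 1)
  # the two parcel meshes occupy disjoint x-ranges
  r1 <- range(meshVertices(pg$meshes[[1]])[, 1])
  r2 <- range(meshVertices(pg$meshes[[2]])[, 1])
  expect_lt(r1[2], r2[1])

  expect_error(nodeGeometry(pn$nodes, "parcels"), "NIfTI")
})

test_that("color mapping infers categorical vs continuous as documented", {
  m <- mapColor(c(1, 1, 2))
  expect_equal(m$kind, "categorical")
  expect_equal(m$values[1], m$values[2])
  expect_false(m$values[1] == m$values[3])
  expect_length(unique(m$values), 2)
  expect_length(m$legend, 2)

  const <- mapColor(rep(3, 4))
  expect_length(unique(const$values), 1)
  expect_length(const$legend, 1)

  vals <- c(0.5, 0.2, 0.8)
  cont <- mapColor(vals)
  expect_equal(cont$kind, "continuous")
  # color order follows value order under the colormap
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, "viridis"))
  t <- pmin(1, (vals - min(vals)) / diff(range(vals)))
  expect_equal(cont$values, grDevices::rgb(ramp(t), maxColorValue = 255))

  expect_error(mapColor(list(1, "a")), "mixed")
})

test_that("size mapping is the affine map of the observed range", {
  expect_equal(mapSize(c(0.5, 0.2, 0.8), bounds = c(10, 50))$values,
               c(30, 10, 50))
  expect_equal(mapSize(rep(2, 5), bounds = c(10, 50))$values, rep(30, 5))
  expect_equal(mapSize(c(1, 9), bounds = c(4, 8))$values, c(4, 8))
  expect_error(mapSize(letters[1:3]), "numeric")

  set.seed(5)
  for (k in 1:10) {
    vals <- rnorm(7)
    s <- mapSize(vals, bounds = c(1, 11))$values
    a <- vals[1]; b <- vals[2]; cc <- vals[3]
    expect_lt(abs((s[2] - s[1]) / (s[3] - s[1]) - (b - a) / (cc - a)),
              1e-9)
  }
})

test_that("highlighting dims the unselected and reports the count", {
  net <- makeNetwork(10, smallCfg(seed = 4, pWithin = 0.9, pBetween = 0.5))
  edges <- net$edges
  expect_gte(nrow(edges), 10)
  hm <- makeHighlightMatrix(edges, 2, nNodes = 10, seed = 1)
  hl <- applyHighlight(edges, list(selector = hm, dimAlpha = 0.15),
                       nNodes = 10)
  expect_equal(hl$count, 2)
  expect_equal(sum(hl$alpha == 0.15), nrow(edges) - 2)

  allTrue <- applyHighlight(edges, rep(TRUE, nrow(edges)))
  expect_equal(allTrue$count, nrow(edges))
  expect_true(all(allTrue$alpha == 1))

  allFalse <- applyHighlight(edges, rep(FALSE, nrow(edges)))
  expect_equal(allFalse$count, 0)
  expect_true(all(allFalse$alpha == 0.15))

  expect_error(applyHighlight(edges, "nope"), "not found")
  expect_error(applyHighlight(edges, matrix(0, 3, 3), nNodes = 10),
               "3 x 3")
})

test_that("edge segments join node coordinates and honor the threshold", {
  nodes <- data.frame(node_id = 0:1, x = c(-10, 10), y = c(0, 1),
                      z = c(2, 3))
  edges <- data.frame(i = 0L, j = 1L, weight = 1)
  s <- edgeSegments(nodes, edges)
  expect_equal(nrow(s), 1)
  expect_equal(unlist(s[1, c("x0", "y0", "z0")], use.names = FALSE),
               c(-10, 0, 2))
  expect_equal(unlist(s[1, c("x1", "y1", "z1")], use.names = FALSE),
               c(10, 1, 3))

  net <- tinyNetwork()
  s2 <- edgeSegments(net$nodes, net$edges, threshold = 2)
  expect_equal(nrow(s2), 2)            # weights 1,2,3 -> keep >= 2
  expect_true(all(s2$weight >= 2))

  sEq <- edgeSegments(net$nodes,
                      data.frame(i = c(0L, 0L), j = c(1L, 2L),
                                 weight = c(4, 4)),
                      weightScaling = list(column = "weight",
                                           bounds = c(1, 3)))
  expect_equal(sEq$width[1], sEq$width[2])   # equal weights, equal widths
})

test_that("legends enumerate categories and keep declaration order", {
  cm <- mapColor(c(1, 1, 2)); cm$column <- "community"
  sm <- mapSize(c(0.1, 0.5, 0.9)); sm$column <- "strength"
  lg <- buildLegend(list(cm, sm))
  expect_length(lg, 2)
  expect_equal(lg[[1]]$title, "community")
  expect_length(lg[[1]]$entries, 2)
  expect_equal(lg[[2]]$title, "strength")
  expect_length(lg[[2]]$entries, 3)    # min / mid / max

  expect_length(buildLegend(list()), 0)
  expect_length(buildLegend(list(NULL, cm)), 1)
})

test_that("aesthetics are order-independent and highlighting is geometry-neutral", {
  set.seed(9)
  vals <- c(3, 1, 2, 1, 3, 2)
  perm <- sample(length(vals))
  m1 <- mapColor(vals)$values
  m2 <- mapColor(vals[perm])$values
  expect_equal(m2, m1[perm])
  s1 <- mapSize(vals)$values
  expect_equal(mapSize(vals[perm])$values, s1[perm])

  net <- tinyNetwork()
  base <- edgeSegments(net$nodes, net$edges)
  hl <- applyHighlight(net$edges, c(1))
  expect_equal(base[c("x0", "y0", "z0", "x1", "y1", "z1")],
               edgeSegments(net$nodes, net$edges)[
                 c("x0", "y0", "z0", "x1", "y1", "z1")])
  expect_length(hl$alpha, nrow(net$edges))
})
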