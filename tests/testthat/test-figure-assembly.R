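test_that("each component can be plotted by itself and composes freely", {
  cfg <- smallCfg()
  tpl <- makeTemplate(cfg)

  tOnly <- plotBrainNetwork(template = tpl, template_style = "cloudy")
  expect_s4_class(tOnly, "FigureResult")
  expect_length(panels(tOnly), 1)
  expect_null(tOnly@scene$nodes)

  net <- makeNetwork(3, cfg)
  nOnly <- plotBrainNetwork(nodes = net$nodes, view = "LSR")
  expect_length(panels(nOnly), 3)
  expect_equal(nrow(nOnly@scene$nodes$coords), 3)

  full <- plotBrainNetwork(template = tpl, nodes = net$nodes,
                           edges = net$edges, template_style = "cloudy",
                           view = "S")
  expect_length(panels(full), 1)
  expect_equal(provenance(full)$n_nodes, 3)
})

test_that("input preconditions are enforced with the documented errors", {
  net <- makeNetwork(3, smallCfg())
  expect_error(plotBrainNetwork(edges = net$edges),
               "'nodes' argument must be specified")
  g <- igraph::make_empty_graph(0, directed = FALSE)
  expect_error(plotBrainNetwork(network = g, nodes = net$nodes),
               "mutually exclusive")
  expect_error(plotBrainNetwork(), "nothing to draw")
})

test_that("a network graph input matches the equivalent nodes+edges call", {
  net <- makeNetwork(5, smallCfg(seed = 8))
  g <- igraph::make_empty_graph(5, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(rbind(net$edges$i + 1,
                                            net$edges$j + 1)))
  igraph::V(g)$x <- net$nodes$x
  igraph::V(g)$y <- net$nodes$y
  igraph::V(g)$z <- net$nodes$z
  igraph::E(g)$weight <- net$edges$weight

  a <- plotBrainNetwork(network = g, view = "A")
  b <- plotBrainNetwork(nodes = net$nodes, edges = net$edges, view = "A")
  expect_equal(a@scene$nodes$coords, b@scene$nodes$coords)
  expect_equal(a@scene$segments[c("x0", "x1", "width")],
               b@scene$segments[c("x0", "x1", "width")])
  expect_equal(provenance(a)$n_edges, provenance(b)$n_edges)
})

test_that("panel count always equals the view specification total", {
  net <- makeNetwork(4, smallCfg())
  set.seed(21)
  for (k in 1:8) {
    letters6 <- c("S", "I", "P", "A", "L", "R")
    view <- paste(sample(letters6, sample(1:4, 1), replace = TRUE),
                  collapse = "")
    fig <- plotBrainNetwork(nodes = net$nodes, view = view)
    expect_length(panels(fig), nchar(view))
  }
  fig2 <- plotBrainNetwork(nodes = net$nodes, edges = net$edges,
                           view = c("LR", "As"))
  expect_length(panels(fig2), 4)
})

test_that("layers are independent: adding one never moves another", {
  cfg <- smallCfg()
  tpl <- makeTemplate(cfg)
  net <- makeNetwork(6, cfg)

  nodesAlone <- plotBrainNetwork(nodes = net$nodes, view = "A")
  withEdges <- plotBrainNetwork(nodes = net$nodes, edges = net$edges,
                                view = "A")
  withTpl <- plotBrainNetwork(template = tpl, nodes = net$nodes,
                              edges = net$edges, view = "A",
                              template_style = "cloudy")
  expect_equal(withEdges@scene$nodes$coords, nodesAlone@scene$nodes$coords)
  expect_equal(withTpl@scene$nodes$coords, nodesAlone@scene$nodes$coords)
  expect_equal(withTpl@scene$segments, withEdges@scene$segments)
})

test_that("high-level aesthetics drive colors, sizes and the legend", {
  net <- makeNetwork(8, smallCfg(seed = 3))
  fig <- plotBrainNetwork(nodes = net$nodes, edges = net$edges,
                          node_color = "community",
                          node_size = "measure1", view = "L")
  expect_length(unique(fig@scene$nodeColors),
                length(unique(net$nodes$community)))
  expect_length(fig@legend, 2)
  titles <- vapply(fig@legend, `[[`, "", "title")
  expect_equal(titles, c("community", "measure1"))

  # community categories all enumerated in the legend
  expect_length(fig@legend[[1]]$entries,
                length(unique(net$nodes$community)))
})

test_that("hemisphere and highlight options reach the scene", {
  nodes <- data.frame(node_id = 0:1, x = c(-10, 10), y = 0, z = 0)
  edges <- data.frame(i = 0L, j = 1L, weight = 1)
  fig <- plotBrainNetwork(nodes = nodes, edges = edges, hemisphere = "L",
                          view = "L")
  expect_equal(provenance(fig)$n_nodes, 1)
  expect_equal(provenance(fig)$n_segments, 0)

  net <- makeNetwork(10, smallCfg(seed = 5, pWithin = 0.9))
  hm <- makeHighlightMatrix(net$edges, 2, nNodes = 10, seed = 2)
  fh <- plotBrainNetwork(nodes = net$nodes, edges = net$edges,
                         highlight_edges = hm, view = "A")
  expect_equal(sum(fh@scene$edgeAlpha == 1), 2)
})

test_that("figures export to valid PNG and SVG, and only those", {
  net <- makeNetwork(4, smallCfg())
  fig <- plotBrainNetwork(nodes = net$nodes, edges = net$edges,
                          view = "LS")

  png <- tempfile(fileext = ".png")
  saveFigure(fig, png)
  expect_true(file.size(png) > 0)
  sig <- readBin(png, "raw", 8)
  expect_equal(as.integer(sig[1:4]), c(137L, 80L, 78L, 71L))  # \x89PNG

  svgf <- tempfile(fileext = ".svg")
  saveFigure(fig, svgf)
  expect_true(file.size(svgf) > 0)
  doc <- xml2::read_xml(svgf)            # well-formed XML
  expect_equal(xml2::xml_name(doc), "svg")

  noext <- tempfile()
  saveFigure(fig, noext)
  expect_true(file.exists(paste0(noext, ".png")))

  expect_error(saveFigure(fig, tempfile(fileext = ".bmp")),
               "\\.png, \\.svg")
})

test_that("identical seeded calls are fully deterministic", {
  run <- function() {
    net <- makeNetwork(6, smallCfg(seed = 12))
    plotBrainNetwork(nodes = net$nodes, edges = net$edges,
                     node_color = "community", view = "LSs", seed = 5)
  }
  a <- run(); b <- run()
  expect_identical(provenance(a), provenance(b))
  expect_identical(a@scene$springPositions, b@scene$springPositions)

  fa <- tempfile(fileext = ".svg"); fb <- tempfile(fileext = ".svg")
  saveFigure(a, fa); saveFigure(b, fb)
  expect_identical(readLines(fa), readLines(fb))
})

test_that("provenance is serializable and records the resolved call", {
  net <- makeNetwork(4, smallCfg())
  fig <- plotBrainNetwork(nodes = net$nodes, view = "LR", seed = 9)
  pv <- provenance(fig)
  expect_equal(pv$panel_count, 2)
  expect_equal(pv$seed, 9)
  js <- jsonlite::toJSON(pv, auto_unbox = TRUE, null = "null",
                         force = TRUE)
  expect_gt(nchar(js), 50)
})

test_that("the spring panel reuses the anatomical panels' aesthetics", {
  net <- makeNetwork(6, smallCfg(seed = 2))
  fig <- plotBrainNetwork(nodes = net$nodes, edges = net$edges,
                          node_color = "community", view = "Ls", seed = 4)
  expect_false(is.null(fig@scene$springPositions))
  expect_equal(nrow(fig@scene$springPositions), 6)
  # one shared color vector feeds both panel kinds
  expect_length(fig@scene$nodeColors, 6)
  expect_error(plotBrainNetwork(template = makeTemplate(smallCfg()),
                                view = "s"),
               "requires nodes")
})
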