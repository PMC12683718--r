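test_that("region generation echoes its configuration and is deterministic", {
  r <- generate_region(seed = 1)
  expect_equal(r$width, 15.5)
  expect_equal(r$height, 11.25)
  expect_equal(nrow(r$kernels), 3L)
  expect_equal(r$width * r$height, 174.375, tolerance = 0.01)
  expect_true(all(r$kernels$x >= 0 & r$kernels$x <= r$width))
  expect_true(all(r$kernels$y >= 0 & r$kernels$y <= r$height))
  expect_identical(r, generate_region(seed = 1))
  expect_false(identical(r$kernels, generate_region(seed = 2)$kernels))
  expect_error(generate_region(list(width = -1)), "positive")
  expect_error(generate_region(list(n_kernels = 0)), "kernel")
})

test_that("density sampling stays in the region and centres on its kernel", {
  reg <- tiny_region()
  expect_equal(nrow(sample_points(reg, 0)), 0L)
  pts <- sample_points(reg, 200, seed = 7)
  expect_equal(nrow(pts), 200L)
  expect_true(all(pts$x >= 0 & pts$x <= 10 & pts$y >= 0 & pts$y <= 10))
  # law of large numbers: tight single kernel -> sample mean near the centre
  tight <- tiny_region(spread = 0.1)
  p <- sample_points(tight, 2000, seed = 3)
  se <- 0.1 / sqrt(2000)
  expect_lt(abs(mean(p$x) - 5), 3 * se)
  expect_lt(abs(mean(p$y) - 5), 3 * se)
  expect_identical(sample_points(reg, 50, seed = 9), sample_points(reg, 50, seed = 9))
})

test_that("facility generation honours per-type counts exactly", {
  reg <- tiny_region()
  fac <- generate_facilities(reg, seed = 4)
  expect_equal(nrow(fac), 100L)
  expect_equal(unname(table(fac$type)[c("prevention", "treatment", "care")]),
               c(40L, 40L, 20L), ignore_attr = TRUE)
  expect_false(any(duplicated(fac$id)))
  expect_true(all(fac$education_host == (fac$type == "prevention")))
  expect_identical(fac, generate_facilities(reg, seed = 4))
  expect_equal(nrow(generate_facilities(reg, counts = c(prevention = 0L))), 0L)
  f3 <- generate_facilities(reg, counts = c(prevention = 3L), seed = 2)
  expect_equal(nrow(f3), 3L)
  expect_error(generate_facilities(reg, counts = c(prevention = -1L)), "non-negative")
})

test_that("euclidean distances behave like a metric", {
  expect_equal(travel_distance(eu, c(0, 0), c(3, 4)), 5)
  expect_equal(travel_distance(eu, c(2, 2), c(2, 2)), 0)
  a <- matrix(runif(20), ncol = 2)
  D <- distance_matrix(eu, a, a)
  expect_true(all(D >= 0))
  expect_equal(D, t(D))
  expect_equal(diag(D), rep(0, 10))
})

test_that("network distance follows shortest paths and dominates euclidean", {
  # 2x2 unit grid, unit edge weights: opposite corners are 2 km apart
  g <- igraph::add_edges(igraph::make_empty_graph(4, directed = FALSE),
                         c(1, 2, 1, 3, 2, 4, 3, 4))
  igraph::E(g)$weight <- 1
  nodes <- data.frame(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1))
  dm <- distance_model("network", graph = g, nodes = nodes)
  expect_equal(travel_distance(dm, c(0, 0), c(1, 1)), 2)
  expect_equal(travel_distance(dm, c(0, 0), c(0, 0)), 0)

  reg <- tiny_region()
  dmg <- distance_model("network", region = reg, grid_spacing = 1, seed = 5)
  pts <- sample_points(reg, 30, seed = 11)
  Dn <- distance_matrix(dmg, pts, pts)
  De <- distance_matrix(eu, pts, pts)
  expect_true(all(Dn - De >= -1e-12))
  expect_equal(Dn, t(Dn))

  # disconnected pair -> unreachable (Inf)
  g2 <- igraph::add_edges(igraph::make_empty_graph(4, directed = FALSE), c(1, 2, 3, 4))
  igraph::E(g2)$weight <- 1
  dm2 <- suppressWarnings(distance_model("network", graph = g2, nodes = nodes))
  expect_identical(travel_distance(dm2, c(0, 0), c(1, 1)), Inf)
})

test_that("facility and road-network files round-trip", {
  fac <- toy_facilities(c(1, 2, 3), c(1, 1, 2),
                        c("prevention", "treatment", "care"))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_facilities_csv(fac, csv)
  back <- read_facilities_csv(csv)
  expect_equal(back[, c("id", "x", "y", "type")], fac[, c("id", "x", "y", "type")])
  expect_equal(back$gain, unname(default_facility_gains()[fac$type]))

  gj <- withr::local_tempfile(fileext = ".geojson")
  write_facilities_geojson(fac, gj)
  back2 <- read_facilities_geojson(gj)
  expect_equal(back2[, c("id", "x", "y", "type")], fac[, c("id", "x", "y", "type")])

  net <- list(graph = igraph::add_edges(igraph::make_empty_graph(3, directed = FALSE),
                                        c(1, 2, 2, 3)),
              nodes = cbind(x = c(0, 1, 2), y = c(0, 0, 1)))
  igraph::E(net$graph)$weight <- c(1, 1.5)
  e <- withr::local_tempfile(fileext = ".csv")
  n <- withr::local_tempfile(fileext = ".csv")
  write_road_network(net, e, n)
  back3 <- read_road_network(e, n)
  expect_equal(igraph::E(back3$graph)$weight, c(1, 1.5))
  expect_equal(back3$nodes[, "x"], c(0, 1, 2))
})
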