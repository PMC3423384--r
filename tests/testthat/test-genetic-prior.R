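write_lines_tmp <- function(lines, ext) {
  f <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("CSV Q matrices parse, renormalize and reject bad rows by line", {
  f <- write_lines_tmp(c("id,q1,q2", "A,1.0,0.0", "B,0.25,0.75"), ".csv")
  qt <- read_q_matrix(f, "csv")
  expect_equal(attr(qt, "K"), 2)
  expect_equal(qt$q[[1]], c(1, 0))
  expect_equal(qt$q[[2]], c(0.25, 0.75))

  # rounding within the 0.02 tolerance is absorbed and renormalized
  f2 <- write_lines_tmp(
    c("id,q1,q2,q3,q4,q5", "A,0.199,0.201,0.2,0.2,0.2"), ".csv"
  )
  qt2 <- read_q_matrix(f2, "csv")
  expect_equal(attr(qt2, "K"), 5)
  expect_equal(sum(qt2$q[[1]]), 1, tolerance = 1e-15)
  expect_equal(qt2$q[[1]], c(0.199, 0.201, 0.2, 0.2, 0.2), tolerance = 1e-12)

  # K = 1 forces unity
  f3 <- write_lines_tmp(c("id,q1", "A,1", "B,1.0"), ".csv")
  expect_true(all(vapply(read_q_matrix(f3, "csv")$q, identical, TRUE, 1)))

  # violations are reported with their line numbers
  f4 <- write_lines_tmp(c("id,q1,q2", "A,0.5,0.5", "B,0.7,0.6"), ".csv")
  expect_error(read_q_matrix(f4, "csv"), "line 3")
  f5 <- write_lines_tmp(c("id,q1,q2", "A,oops,0.5"), ".csv")
  expect_error(read_q_matrix(f5, "csv"), "line 2")
})

test_that("STRUCTURE-style whitespace tables parse with label offsets", {
  f <- write_lines_tmp(
    c("ind1  1  0.90 0.05 0.05",
      "ind2  1  0.10 0.80 0.10"), ".txt"
  )
  qt <- read_q_matrix(f, "structure_whitespace", label_cols = 2)
  expect_equal(attr(qt, "K"), 3)
  expect_equal(qt$sample_id, c("ind1", "ind2"))
  expect_equal(qt$q[[2]], c(0.1, 0.8, 0.1))
  # inconsistent K across rows is a shape error
  f2 <- write_lines_tmp(c("a 0.5 0.5", "b 0.2 0.4 0.4"), ".txt")
  expect_error(read_q_matrix(f2, "structure_whitespace"), "inconsistent")
})

test_that("Q matrices round-trip through CSV", {
  qt <- tibble::tibble(sample_id = c("A", "B"),
                       q = list(c(0.7, 0.3), c(0.2, 0.8)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_q_matrix(qt, f)
  back <- read_q_matrix(f, "csv")
  expect_equal(back$sample_id, qt$sample_id)
  expect_equal(back$q, qt$q, tolerance = 1e-12)
})

two_cluster_strip <- function() {
  # 1 x 5 strip: cluster 1 = cells 1:2, cluster 2 = cells 3:5
  cluster_map(strip_grid(5), c(1, 1, 2, 2, 2))
}

test_that("prior surfaces spread cluster mass uniformly within clusters", {
  cm <- two_cluster_strip()
  # hand division of cluster mass by cell counts
  pr <- build_prior_surface(c(0.8, 0.2), cm, floor_eps = 0)
  expect_equal(surface_values(pr), c(0.4, 0.4, 0.2 / 3, 0.2 / 3, 0.2 / 3),
               tolerance = 1e-12)
  # zero coefficient zeroes the cluster (no floor)
  pr0 <- build_prior_surface(c(1, 0), cm, floor_eps = 0)
  expect_equal(surface_values(pr0)[3:5], c(0, 0, 0))
  # single cluster covering the range: uniform whatever the floor
  k1 <- cluster_map(strip_grid(4), rep(1, 4))
  for (eps in c(0, 0.01, 0.5)) {
    expect_equal(surface_values(build_prior_surface(1, k1, eps)),
                 rep(0.25, 4), tolerance = 1e-12)
  }
  expect_error(build_prior_surface(c(0.5, 0.3, 0.2), cm), "K = 2")
})

test_that("prior mass accounting holds for fuzzed inputs", {
  cm <- cluster_map(
    grid_spec(6, 8, 0, 0, 1),
    matrix(rep(c(1, 1, 1, 2, 2, 3, 4, 4), each = 6), 6, 8)
  )
  counts <- tabulate(cm$labels, 4)
  n_in <- sum(cm$range_mask)
  withr::with_seed(33, {
    for (i in 1:50) {
      q <- as.numeric(rmultinom(1, 1000, runif(4))) / 1000
      eps <- runif(1, 0, 0.2)
      pr <- build_prior_surface(q, cm, eps)
      v <- surface_values(pr)
      expect_lt(abs(sum(v) - 1), 1e-12)
      for (k in 1:4) {
        in_k <- sum(v[dualorigin:::cluster_labels_vector(cm) == k])
        expect_lt(abs(in_k - ((1 - eps) * q[k] + eps * counts[k] / n_in)),
                  1e-12)
      }
    }
  })
})

test_that("prior construction is invariant to cell enumeration order", {
  g <- grid_spec(4, 5, 0, 0, 1)
  labs <- sample(rep(1:3, length.out = 20))
  a <- build_prior_surface(c(0.5, 0.3, 0.2),
                           cluster_map(g, labs), 0.05)
  b <- build_prior_surface(c(0.5, 0.3, 0.2),
                           cluster_map(g, matrix(labs, 4, 5, byrow = TRUE)),
                           0.05)
  expect_equal(a$values, b$values, tolerance = 1e-15)
})

test_that("hard genetic assignment takes the argmax with a deterministic tie rule", {
  expect_equal(genetic_cluster_assignment(c(1, 0, 0)),
               list(cluster = 1, ambiguous = FALSE))
  # low-confidence regime: a plurality still assigns
  expect_equal(genetic_cluster_assignment(c(0.37, 0.33, 0.30))$cluster, 1)
  tie <- genetic_cluster_assignment(c(0.5, 0.5))
  expect_equal(tie$cluster, 1)
  expect_true(tie$ambiguous)
})

test_that("cluster maps validate their partition", {
  g <- strip_grid(4)
  expect_error(cluster_map(g, c(1, 1, 3, 3), K = 3), "missing: 2")
  expect_error(cluster_map(g, c(0, 1, 1, 1), K = 1), "1..K")
  cm <- cluster_map(g, c(1, NA, 2, 2), K = 2)
  expect_equal(sum(cm$range_mask), 3)
})

test_that("labelled rasters and GeoJSON polygons rasterize to the same bands", {
  world <- tiny_world(n_rows = 6, n_cols = 8, K = 2)
  dir <- withr::local_tempdir()
  asc <- file.path(dir, "clusters.asc")
  gj <- file.path(dir, "clusters.geojson")
  write_cluster_map(world$clusters, asc)
  write_cluster_geojson(world$clusters, gj)
  from_asc <- read_cluster_map(asc)
  from_gj <- read_cluster_map(gj, grid = world$clusters$grid)
  expect_equal(from_asc$labels, world$clusters$labels)
  expect_equal(from_gj$labels, world$clusters$labels)
  expect_equal(from_gj$K, 2)
})

test_that("cells outside every polygon join the nearest cluster", {
  g <- grid_spec(1, 4, lon_origin = 0, lat_origin = 0, cell_size_deg = 1)
  # polygons cover only cells 1 and 4; cells 2-3 are orphans
  gj <- list(
    type = "FeatureCollection",
    features = list(
      list(type = "Feature", properties = list(cluster = 1),
           geometry = list(type = "Polygon", coordinates = list(list(
             list(-0.4, -0.4), list(0.4, -0.4), list(0.4, 0.4),
             list(-0.4, 0.4), list(-0.4, -0.4))))),
      list(type = "Feature", properties = list(cluster = 2),
           geometry = list(type = "Polygon", coordinates = list(list(
             list(2.6, -0.4), list(3.4, -0.4), list(3.4, 0.4),
             list(2.6, 0.4), list(2.6, -0.4)))))
    )
  )
  f <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, f, auto_unbox = TRUE, digits = NA)
  cm <- read_cluster_map(f, grid = g)
  expect_equal(as.vector(t(cm$labels)), c(1L, 1L, 2L, 2L))
})
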