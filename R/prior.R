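#' Construct a cluster map
#'
#' Partitions the in-range cells of a grid among K genetic clusters: each
#' in-range cell carries exactly one label in `1..K`, and every label occupies
#' at least one cell. The map carries the geography over which an
#' individual's admixture coefficients are spread into a spatial prior.
#'
#' @param grid A `grid_spec`.
#' @param labels Integer matrix/vector (row-major): cluster label per cell;
#'   `NA` outside the range.
#' @param K Number of clusters; default `max(labels)`.
#' @return A `cluster_map` with fields `grid`, `K`, `labels` (matrix),
#'   `range_mask`.
#' @export
cluster_map <- function(grid, labels, K = NULL) {
  grid <- as_grid_spec(grid)
  labels <- shape_to_matrix(grid, labels, "labels")
  storage.mode(labels) <- "integer"
  mask <- !is.na(labels)
  if (!any(mask)) stop("cluster map labels no cells", call. = FALSE)
  if (is.null(K)) K <- max(labels, na.rm = TRUE)
  K <- as.integer(K)
  present <- sort(unique(labels[mask]))
  if (any(present < 1L | present > K)) {
    stop("cluster labels must lie in 1..K", call. = FALSE)
  }
  if (!all(seq_len(K) %in% present)) {
    stop("every cluster in 1..K must occupy >= 1 cell; missing: ",
         paste(setdiff(seq_len(K), present), collapse = ", "), call. = FALSE)
  }
  structure(list(grid = grid, K = K, labels = labels, range_mask = mask),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat(sprintf("<cluster_map> K = %d over %d in-range cells (%d x %d grid)\n",
              x$K, sum(x$range_mask), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}

cluster_labels_vector <- function(clusters) as.vector(t(clusters$labels))

#' Read a cluster geography
#'
#' Either a labelled integer raster (ESRI ASCII grid, value = cluster label,
#' NODATA outside the range) or a GeoJSON FeatureCollection of polygons with
#' an integer `cluster` property. Polygons are rasterized by cell-center
#' containment (even-odd ray casting); in-range cells whose centers fall in no
#' polygon are assigned to the nearest polygon by great-circle distance to its
#' boundary vertices, so the partition is exhaustive.
#'
#' @param path `.asc` or `.geojson`/`.json` file.
#' @param grid Required for GeoJSON input: the `grid_spec` to rasterize onto.
#' @param range_mask Optional logical matrix restricting the GeoJSON
#'   rasterization; default all cells.
#' @return A [cluster_map()].
#' @export
read_cluster_map <- function(path, grid = NULL, range_mask = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.(geojson|json)$", path, ignore.case = TRUE)) {
    if (is.null(grid)) stop("GeoJSON cluster input needs a grid", call. = FALSE)
    rasterize_cluster_geojson(path, grid, range_mask)
  } else {
    surf <- read_ascii_grid(path)
    labs <- surf$values
    if (any(abs(labs - round(labs)) > 1e-6, na.rm = TRUE)) {
      stop("labelled cluster raster has non-integer values", call. = FALSE)
    }
    cluster_map(surf$grid, round(labs))
  }
}

rasterize_cluster_geojson <- function(path, grid, range_mask = NULL) {
  grid <- as_grid_spec(grid)
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection",
                                 call. = FALSE)
  polys <- list() # per cluster: list of rings (matrices lon,lat)
  for (f in gj$features) {
    k <- f$properties$cluster
    if (is.null(k)) stop("feature lacks integer 'cluster' property",
                         call. = FALSE)
    k <- as.integer(k)
    geom <- f$geometry
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1]]),
      MultiPolygon = lapply(geom$coordinates, `[[`, 1),
      stop("unsupported geometry type: ", geom$type, call. = FALSE)
    )
    rings <- lapply(rings, function(r) {
      do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
    })
    polys[[as.character(k)]] <- c(polys[[as.character(k)]] %||% list(), rings)
  }
  ks <- sort(as.integer(names(polys)))
  centers <- cell_centers(grid)
  if (is.null(range_mask)) range_mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  in_range <- as.vector(t(range_mask))
  lab <- rep(NA_integer_, nrow(centers))
  for (k in ks) {
    inside <- rep(FALSE, nrow(centers))
    for (ring in polys[[as.character(k)]]) {
      inside <- xor(inside, point_in_ring(centers$lon, centers$lat, ring))
    }
    hit <- inside & in_range & is.na(lab) # first polygon wins on overlap
    lab[hit] <- k
  }
  # exhaustive partition: orphan in-range cells go to the nearest polygon
  orphan <- in_range & is.na(lab)
  if (any(orphan)) {
    verts <- do.call(rbind, lapply(ks, function(k) {
      v <- do.call(rbind, polys[[as.character(k)]])
      cbind(v, k)
    }))
    for (i in which(orphan)) {
      d <- haversine_km(centers$lon[i], centers$lat[i], verts[, 1], verts[, 2])
      lab[i] <- as.integer(verts[which.min(d), 3])
    }
  }
  lab[!in_range] <- NA_integer_
  cluster_map(grid, lab, K = max(ks))
}

# even-odd rule; points exactly on an edge count as inside for at most one
# adjacent ring, which the first-polygon-wins rule above makes deterministic
point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Write a cluster map as a labelled ASCII raster
#'
#' @param clusters A [cluster_map()].
#' @param path Output `.asc` path.
#' @return `path`, invisibly.
#' @export
write_cluster_map <- function(clusters, path) {
  surf <- raster_surface(clusters$grid, clusters$labels + 0,
                         clusters$range_mask)
  write_ascii_grid(surf, path, digits = 12)
}

#' Write a cluster map as GeoJSON band polygons
#'
#' Emits one rectangular polygon per cluster, the bounding box of its cells
#' expanded to cell edges. Intended for the synthetic world's contiguous
#' longitudinal bands, where the bounding box is exact.
#'
#' @param clusters A [cluster_map()].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_cluster_geojson <- function(clusters, path) {
  g <- clusters$grid
  h <- g$cell_size_deg / 2
  cc <- cell_centers(g)
  lab <- cluster_labels_vector(clusters)
  feats <- lapply(seq_len(clusters$K), function(k) {
    sel <- which(lab == k)
    lo_lon <- min(cc$lon[sel]) - h; hi_lon <- max(cc$lon[sel]) + h
    lo_lat <- min(cc$lat[sel]) - h; hi_lat <- max(cc$lat[sel]) + h
    ring <- list(
      list(lo_lon, lo_lat), list(hi_lon, lo_lat),
      list(hi_lon, hi_lat), list(lo_lon, hi_lat), list(lo_lon, lo_lat)
    )
    list(
      type = "Feature",
      properties = list(cluster = k),
      geometry = list(type = "Polygon", coordinates = list(ring))
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = feats), path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Spatial prior from an individual's admixture coefficients
#'
#' Converts a Q vector into a prior probability surface over the range: the
#' probability that the individual came from genetic cluster k is its
#' admixture coefficient `q[k]`, and that cluster-level mass is spread
#' uniformly over the cluster's cells (the maximum-entropy completion, since
#' the genetic marker says nothing about location *within* a cluster). Note
#' the consequence: a large cluster gets a *lower* per-cell prior than a
#' small cluster with the same coefficient.
#'
#' A small uniform floor `floor_eps` is mixed in over the whole range so that
#' no in-range cell has exactly zero prior; without it, a dispersing bird
#' whose feather signal lies outside its genetic cluster would receive an
#' identically zero posterior.
#'
#' @param q Numeric K-vector of admixture coefficients (sums to 1), or a
#'   one-row slice of a [read_q_matrix()] table.
#' @param clusters A [cluster_map()] with the same K.
#' @param floor_eps Uniform floor mass in `[0, 1)`; default 0.01.
#' @return A `probability_surface` summing to 1 over the range mask.
#' @export
build_prior_surface <- function(q, clusters, floor_eps = 0.01) {
  if (is.list(q) && !is.null(q$q)) q <- q$q[[1]]
  q <- as.numeric(q)
  stopifnot(inherits(clusters, "cluster_map"),
            floor_eps >= 0, floor_eps < 1)
  if (length(q) != clusters$K) {
    stop(sprintf("Q vector has %d entries, cluster map has K = %d",
                 length(q), clusters$K), call. = FALSE)
  }
  if (any(q < 0) || abs(sum(q) - 1) > 1e-6) {
    stop("q must be nonnegative and sum to 1 (renormalize on read)",
         call. = FALSE)
  }
  lab <- clusters$labels
  n_in <- sum(clusters$range_mask)
  counts <- tabulate(lab[clusters$range_mask], nbins = clusters$K)
  p <- matrix(0, clusters$grid$n_rows, clusters$grid$n_cols)
  per_cell <- (1 - floor_eps) * q / counts
  p[clusters$range_mask] <- per_cell[lab[clusters$range_mask]] +
    floor_eps / n_in
  probability_surface(clusters$grid, p, clusters$range_mask)
}

#' Hard genetic cluster assignment
#'
#' The cluster with the largest admixture coefficient. Exact ties resolve to
#' the lowest-index tied cluster and are flagged as ambiguous.
#'
#' @param q Numeric K-vector of admixture coefficients.
#' @return A list with `cluster` (integer label) and `ambiguous` (logical).
#' @export
genetic_cluster_assignment <- function(q) {
  q <- as.numeric(q)
  stopifnot(length(q) >= 1, all(is.finite(q)))
  top <- which(q == max(q))
  list(cluster = top[1], ambiguous = length(top) > 1)
}
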