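#' Configuration for a synthetic world
#'
#' The generator emulates the geographic complementarity the dual-marker
#' method exploits: feather-deuterium isoscapes in North America follow broad
#' *latitudinal* clines, while population genetic structure is predominantly
#' *longitudinal*. The synthetic world therefore interpolates precipitation
#' deuterium linearly in latitude between two endpoints and partitions the
#' range into K contiguous longitudinal cluster bands.
#'
#' Defaults describe a realistic mid-continental study system: precipitation
#' deuterium from -140 permil at the northern edge to -30 permil at the
#' southern edge; ASY calibration d2Hf = -20 + 0.9 d2Hp with 8 permil
#' residual SD, SY calibration -25 + 0.95 d2Hp with 10 permil SD; Dirichlet
#' concentration 10 on the home cluster (mean home-cluster admixture ~0.71
#' at K = 5, the mid range of published Q values); no dispersal.
#'
#' @param grid A `grid_spec`; default 100 x 120 cells of 0.2 degrees with NW
#'   cell center at (-110, 55).
#' @param K Number of genetic clusters (longitudinal bands).
#' @param precip_north_permil,precip_south_permil Endpoints of the
#'   latitudinal precipitation-deuterium gradient (row 1 / row `n_rows`).
#' @param calib Named list (`ASY`, `SY`) of `list(intercept, slope, sigma)`
#'   generating feather values from precipitation values.
#' @param q_concentration Dirichlet concentration on the natal cluster
#'   (others get 1); larger values give cleaner genetic assignment.
#' @param dispersal_fraction Fraction of birds captured in a cluster other
#'   than their natal one, in `[0, 1)`. Dispersers keep their natal-cell
#'   feather value and natal-cluster-centred Q vector: the genetic and
#'   isotopic signals are of natal origin, only the capture location moves.
#' @param seed Integer seed; all randomness in [simulate_birds()] flows
#'   through it.
#' @return A `world_config` list.
#' @export
world_config <- function(grid = grid_spec(100, 120, lon_origin = -110,
                                          lat_origin = 55,
                                          cell_size_deg = 0.2),
                         K = 5,
                         precip_north_permil = -140,
                         precip_south_permil = -30,
                         calib = list(
                           ASY = list(intercept = -20, slope = 0.9, sigma = 8),
                           SY = list(intercept = -25, slope = 0.95, sigma = 10)
                         ),
                         q_concentration = 10,
                         dispersal_fraction = 0,
                         seed = 1L) {
  grid <- as_grid_spec(grid)
  stopifnot(K >= 1, q_concentration > 0,
            dispersal_fraction >= 0, dispersal_fraction < 1,
            all(c("ASY", "SY") %in% names(calib)))
  for (a in c("ASY", "SY")) {
    stopifnot(all(c("intercept", "slope", "sigma") %in% names(calib[[a]])),
              calib[[a]]$sigma > 0)
  }
  structure(
    list(grid = grid, K = as.integer(K),
         precip_north_permil = precip_north_permil,
         precip_south_permil = precip_south_permil,
         calib = calib, q_concentration = q_concentration,
         dispersal_fraction = dispersal_fraction, seed = as.integer(seed)),
    class = "world_config"
  )
}

#' Build the synthetic isoscape and cluster geography
#'
#' Precipitation deuterium interpolates linearly in latitude between the two
#' configured endpoints (constant along rows); genetic clusters are K
#' contiguous longitudinal bands of near-equal width partitioning the range.
#'
#' @param config A [world_config()].
#' @return A `synthetic_world`: list with `precip` ([raster_surface()]),
#'   `clusters` ([cluster_map()]) and `config`.
#' @export
make_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  g <- config$grid
  if (config$K > g$n_cols) {
    stop(sprintf("K = %d exceeds n_cols = %d: bands would be empty",
                 config$K, g$n_cols), call. = FALSE)
  }
  frac <- if (g$n_rows == 1) 0 else (seq_len(g$n_rows) - 1) / (g$n_rows - 1)
  row_vals <- config$precip_north_permil +
    frac * (config$precip_south_permil - config$precip_north_permil)
  precip <- raster_surface(g, matrix(row_vals, g$n_rows, g$n_cols))
  band <- ceiling(seq_len(g$n_cols) * config$K / g$n_cols)
  clusters <- cluster_map(g, matrix(band, g$n_rows, g$n_cols, byrow = TRUE),
                          K = config$K)
  structure(list(precip = precip, clusters = clusters, config = config),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(
    "<synthetic_world> %d x %d grid, K = %d bands, precip %.0f..%.0f permil, seed %d\n",
    x$config$grid$n_rows, x$config$grid$n_cols, x$config$K,
    x$config$precip_north_permil, x$config$precip_south_permil,
    x$config$seed
  ))
  invisible(x)
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  x / sum(x)
}

#' Simulate a seeded cohort of birds
#'
#' Each bird draws a natal cluster (cycled evenly: `n_per_cluster` birds per
#' cluster) and a uniform true natal cell within it. With probability
#' `dispersal_fraction` the capture cluster is a different, uniformly chosen
#' cluster and the capture cell is uniform within it; otherwise capture cell
#' = natal cell. Capture coordinates are the capture cell's center. The
#' feather value is drawn from the generative model at the *natal* cell,
#' `d2hf ~ Normal(b0 + b1 * precip(true_cell), sigma)` with the age-specific
#' calibration parameters, and the Q vector is Dirichlet with concentration
#' `q_concentration` on the natal cluster and 1 elsewhere — dispersers'
#' markers stay natal, reproducing the marker discordance dispersal causes.
#'
#' The same `config$seed` always yields an identical cohort; no global random
#' state leaks.
#'
#' @param world A [make_world()] result.
#' @param n_per_cluster Birds per cluster.
#' @param age_class `"ASY"` or `"SY"`.
#' @param prefix Sample-id prefix.
#' @return A tibble of `simulated_bird` rows: `sample_id`, `age_class`,
#'   `lon`, `lat` (capture), `d2hf`, `locale` (capture cluster name),
#'   `true_cell`, `true_row`, `true_col`, `natal_cluster`,
#'   `capture_cluster`, and list-column `q`.
#' @export
simulate_birds <- function(world, n_per_cluster, age_class = c("ASY", "SY"),
                           prefix = "bird") {
  stopifnot(inherits(world, "synthetic_world"), n_per_cluster >= 1)
  age_class <- match.arg(age_class)
  cfg <- world$config
  g <- cfg$grid
  lab <- cluster_labels_vector(world$clusters)
  cells_by_k <- lapply(seq_len(cfg$K), function(k) which(lab == k))
  if (any(lengths(cells_by_k) == 0)) {
    stop("a cluster has no cells", call. = FALSE)
  }
  cal <- cfg$calib[[age_class]]
  centers <- cell_centers(g)
  precip_v <- surface_values(world$precip)

  with_seed(cfg$seed, {
    natal <- rep(seq_len(cfg$K), each = n_per_cluster)
    n <- length(natal)
    true_cell <- vapply(natal, function(k) {
      cells <- cells_by_k[[k]]
      cells[sample.int(length(cells), 1)]
    }, integer(1))
    disperses <- stats::runif(n) < cfg$dispersal_fraction
    capture_cluster <- natal
    capture_cell <- true_cell
    for (i in which(disperses)) {
      others <- setdiff(seq_len(cfg$K), natal[i])
      if (length(others) == 0) { disperses[i] <- FALSE; next }
      k2 <- others[sample.int(length(others), 1)]
      capture_cluster[i] <- k2
      cells <- cells_by_k[[k2]]
      capture_cell[i] <- cells[sample.int(length(cells), 1)]
    }
    d2hf <- stats::rnorm(n, mean = cal$intercept +
                           cal$slope * precip_v[true_cell],
                         sd = cal$sigma)
    q <- lapply(seq_len(n), function(i) {
      alpha <- rep(1, cfg$K)
      alpha[natal[i]] <- cfg$q_concentration
      rdirichlet1(alpha)
    })
    tibble::tibble(
      sample_id = sprintf("%s_%s_%04d", prefix, age_class, seq_len(n)),
      age_class = age_class,
      lon = centers$lon[capture_cell],
      lat = centers$lat[capture_cell],
      d2hf = d2hf,
      locale = sprintf("cluster%d", capture_cluster),
      true_cell = true_cell,
      true_row = centers$row[true_cell],
      true_col = centers$col[true_cell],
      natal_cluster = natal,
      capture_cluster = capture_cluster,
      q = q
    )
  })
}

#' Write a synthetic world and cohort to disk
#'
#' Emits exactly the file formats the rest of the pipeline consumes, so the
#' command-line workflow runs unmodified on synthetic data: `precip.asc`
#' (precipitation isoscape), `clusters.asc` (labelled cluster raster),
#' `clusters.geojson` (cluster band polygons), `calibration.csv` /
#' `query.csv` (sample tables), `qmatrix.csv` (admixture matrix), and
#' `truth.csv` (natal cells and clusters, for validation).
#'
#' @param world A [make_world()] result.
#' @param birds Cohort tibble from [simulate_birds()] (may bind several age
#'   classes).
#' @param dir Output directory (created if needed).
#' @param calibration_birds Optional second cohort written as
#'   `calibration.csv`; when `NULL`, `birds` doubles as the calibration set.
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, birds, dir, calibration_birds = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ascii_grid(world$precip, file.path(dir, "precip.asc"))
  write_cluster_map(world$clusters, file.path(dir, "clusters.asc"))
  write_cluster_geojson(world$clusters, file.path(dir, "clusters.geojson"))
  cal <- calibration_birds %||% birds
  sample_cols <- c("sample_id", "age_class", "lon", "lat", "d2hf", "locale")
  write_samples(cal[, sample_cols], file.path(dir, "calibration.csv"))
  write_samples(birds[, sample_cols], file.path(dir, "query.csv"))
  write_q_matrix(birds[, c("sample_id", "q")], file.path(dir, "qmatrix.csv"))
  utils::write.csv(
    birds[, c("sample_id", "true_cell", "true_row", "true_col",
              "natal_cluster", "capture_cluster")],
    file.path(dir, "truth.csv"), row.names = FALSE, quote = FALSE
  )
  invisible(dir)
}
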