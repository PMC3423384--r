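# Small fixture builders shared across test files. Everything is generated
# in code; no stored data.

# a 1 x n strip grid: handy for hand-computable surfaces
strip_grid <- function(n, cell_size = 1) {
  grid_spec(1, n, lon_origin = 0, lat_origin = 0, cell_size_deg = cell_size)
}

strip_prob <- function(p) {
  probability_surface(strip_grid(length(p)), matrix(p, 1), normalize = FALSE)
}

# random probability surface on an r x c grid with an optional random mask
random_prob_surface <- function(r, c, masked = FALSE) {
  g <- grid_spec(r, c, lon_origin = -100, lat_origin = 50, cell_size_deg = 1)
  mask <- matrix(TRUE, r, c)
  if (masked) {
    mask <- matrix(stats::runif(r * c) > 0.3, r, c)
    if (!any(mask)) mask[1, 1] <- TRUE
  }
  p <- matrix(stats::rexp(r * c), r, c)
  p[!mask] <- NA
  p[mask] <- p[mask] / sum(p[mask])
  probability_surface(g, p, mask)
}

# independent brute-force credible region: explicit greedy loops, re-sorting
# at every step; the oracle for threshold_region
brute_region_cells <- function(P, odds) {
  target <- odds / (odds + 1)
  p <- surface_values(P)
  remaining <- which(mask_vec <- as.vector(t(P$range_mask)))
  chosen <- integer(0)
  mass <- 0
  while (mass < target - 1e-12 && length(remaining) > 0) {
    top <- remaining[which.max(p[remaining])]
    chosen <- c(chosen, top)
    mass <- mass + p[top]
    remaining <- setdiff(remaining, top)
  }
  p_min <- min(p[chosen])
  sort(union(chosen, which(mask_vec)[p[which(mask_vec)] == p_min]))
}

selected_cells <- function(region) which(as.vector(t(region$selected)))

# a tiny two-band world for integration-style tests
tiny_world <- function(n_rows = 12, n_cols = 10, K = 2, seed = 7, ...) {
  make_world(world_config(
    grid = grid_spec(n_rows, n_cols, lon_origin = -100, lat_origin = 50,
                     cell_size_deg = 0.5),
    K = K, seed = seed, ...
  ))
}

# a calibration model with chosen coefficients (for map-only tests)
new_model_for_test <- function(intercept, slope, sigma = 1,
                               age_class = "ASY") {
  dualorigin:::new_calibration_model(
    age_class = age_class, intercept_permil = intercept, slope = slope,
    residual_sd_permil = sigma, n_samples = 3, r_squared = 1
  )
}

# deterministic calibration table lying exactly on a given line
exact_line_samples <- function(precip, cells, intercept, slope,
                               age_class = "ASY") {
  cc <- cell_centers(precip$grid)[cells, ]
  tibble::tibble(
    sample_id = sprintf("s%02d", seq_along(cells)),
    age_class = age_class,
    lon = cc$lon, lat = cc$lat,
    d2hf = intercept + slope * surface_values(precip, cells)
  )
}
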