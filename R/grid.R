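#' Define a raster grid
#'
#' A `grid_spec` describes the regular lon/lat lattice on which every surface
#' in the package lives: isoscapes, priors, posteriors and binary origin
#' regions. Registration follows the north-west convention: row 1 is the
#' northernmost row, and the center of cell (1, 1) sits at
#' (`lon_origin`, `lat_origin`). Cells are enumerated row-major, so cell id
#' `(row - 1) * n_cols + col`.
#'
#' Two surfaces may be combined (multiplied, compared, thresholded jointly)
#' only if their `grid_spec`s are identical; see [grids_identical()].
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param lon_origin,lat_origin Decimal-degree coordinates of the *center* of
#'   the north-west cell.
#' @param cell_size_deg Cell edge length in decimal degrees (> 0).
#' @param nominal_cell_area_km2 Reporting constant: the nominal area one cell
#'   stands for when region sizes are quoted in km^2. Cell counts, not this
#'   constant, are the primary area unit.
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(10, 12, lon_origin = -110, lat_origin = 55, cell_size_deg = 0.5)
#' @export
grid_spec <- function(n_rows, n_cols, lon_origin, lat_origin, cell_size_deg,
                      nominal_cell_area_km2 = 20) {
  stopifnot(
    length(n_rows) == 1, length(n_cols) == 1,
    n_rows >= 1, n_cols >= 1,
    n_rows == as.integer(n_rows), n_cols == as.integer(n_cols),
    is.finite(lon_origin), is.finite(lat_origin),
    cell_size_deg > 0, nominal_cell_area_km2 > 0
  )
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      lon_origin = as.numeric(lon_origin), lat_origin = as.numeric(lat_origin),
      cell_size_deg = as.numeric(cell_size_deg),
      nominal_cell_area_km2 = as.numeric(nominal_cell_area_km2)
    ),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "<grid_spec> %d x %d cells, %.4g deg/cell, NW cell center (%.4f, %.4f)\n",
    x$n_rows, x$n_cols, x$cell_size_deg, x$lon_origin, x$lat_origin
  ))
  invisible(x)
}

#' Are two grids combinable?
#'
#' @param a,b `grid_spec` objects (or objects carrying one in `$grid`).
#' @return `TRUE` if all registration fields agree.
#' @export
grids_identical <- function(a, b) {
  a <- as_grid_spec(a)
  b <- as_grid_spec(b)
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$lon_origin, b$lon_origin)) &&
    isTRUE(all.equal(a$lat_origin, b$lat_origin)) &&
    isTRUE(all.equal(a$cell_size_deg, b$cell_size_deg))
}

as_grid_spec <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (!is.null(x$grid) && inherits(x$grid, "grid_spec")) return(x$grid)
  stop("not a grid_spec", call. = FALSE)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_identical(a, b)) {
    ga <- as_grid_spec(a); gb <- as_grid_spec(b)
    stop(sprintf(
      "grid mismatch: %dx%d @ (%.4f, %.4f, %.4g deg) vs %dx%d @ (%.4f, %.4f, %.4g deg)",
      ga$n_rows, ga$n_cols, ga$lon_origin, ga$lat_origin, ga$cell_size_deg,
      gb$n_rows, gb$n_cols, gb$lon_origin, gb$lat_origin, gb$cell_size_deg
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Cell centers of a grid
#'
#' @param grid A `grid_spec`.
#' @return A tibble with one row per cell: `cell`, `row`, `col`, `lon`, `lat`,
#'   in row-major order.
#' @export
cell_centers <- function(grid) {
  grid <- as_grid_spec(grid)
  row <- rep(seq_len(grid$n_rows), each = grid$n_cols)
  col <- rep(seq_len(grid$n_cols), times = grid$n_rows)
  tibble::tibble(
    cell = seq_len(grid$n_rows * grid$n_cols),
    row = row,
    col = col,
    lon = grid$lon_origin + (col - 1) * grid$cell_size_deg,
    lat = grid$lat_origin - (row - 1) * grid$cell_size_deg
  )
}

#' Map capture coordinates to grid cells
#'
#' A coordinate maps to the cell whose center is nearest; a coordinate exactly
#' on a boundary between two cell centers resolves to the northern (for
#' latitude) or western (for longitude) cell, so the lookup is deterministic
#' and order-independent. Coordinates falling outside the grid extent map to
#' `NA`.
#'
#' @param grid A `grid_spec`.
#' @param lon,lat Numeric vectors of equal length, decimal degrees.
#' @return A tibble with columns `lon`, `lat`, `row`, `col`, `cell` (`NA` when
#'   off-grid).
#' @export
lonlat_to_cell <- function(grid, lon, lat) {
  grid <- as_grid_spec(grid)
  stopifnot(length(lon) == length(lat))
  # offsets in cell units from the NW cell center; ties round toward 0
  # (north / west)
  half_down <- function(x) ceiling(x - 0.5)
  ro <- half_down((grid$lat_origin - lat) / grid$cell_size_deg)
  co <- half_down((lon - grid$lon_origin) / grid$cell_size_deg)
  row <- ro + 1L
  col <- co + 1L
  off <- row < 1L | row > grid$n_rows | col < 1L | col > grid$n_cols
  row[off] <- NA_integer_
  col[off] <- NA_integer_
  tibble::tibble(
    lon = lon, lat = lat, row = row, col = col,
    cell = (row - 1L) * grid$n_cols + col
  )
}

#' Construct a raster surface
#'
#' The substrate for all gridded quantities: a value per cell (permil for
#' isoscapes, probability mass for assignment surfaces) plus a boolean range
#' mask. Cells outside the species range (`range_mask == FALSE`) carry `NA`
#' and are excluded from every sum, count and assignment.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix (`n_rows` x `n_cols`) or row-major vector.
#' @param range_mask Logical matrix/vector of the same shape; `TRUE` means the
#'   cell is inside the species range. Defaults to all `TRUE`.
#' @return A `raster_surface`.
#' @export
raster_surface <- function(grid, values, range_mask = NULL) {
  grid <- as_grid_spec(grid)
  values <- shape_to_matrix(grid, values, "values")
  if (is.null(range_mask)) {
    range_mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  } else {
    range_mask <- shape_to_matrix(grid, range_mask, "range_mask")
    storage.mode(range_mask) <- "logical"
  }
  if (!any(range_mask)) stop("range_mask excludes every cell", call. = FALSE)
  if (anyNA(values[range_mask])) {
    stop("values must be defined wherever range_mask is TRUE", call. = FALSE)
  }
  values[!range_mask] <- NA_real_
  structure(
    list(grid = grid, values = values, range_mask = range_mask),
    class = "raster_surface"
  )
}

shape_to_matrix <- function(grid, x, what) {
  if (is.matrix(x)) {
    if (nrow(x) != grid$n_rows || ncol(x) != grid$n_cols) {
      stop(sprintf("%s matrix is %dx%d, grid is %dx%d", what,
                   nrow(x), ncol(x), grid$n_rows, grid$n_cols), call. = FALSE)
    }
    return(x)
  }
  if (length(x) == 1) x <- rep(x, grid$n_rows * grid$n_cols)
  if (length(x) != grid$n_rows * grid$n_cols) {
    stop(sprintf("%s has length %d, grid has %d cells", what,
                 length(x), grid$n_rows * grid$n_cols), call. = FALSE)
  }
  matrix(x, grid$n_rows, grid$n_cols, byrow = TRUE)
}

#' @export
print.raster_surface <- function(x, ...) {
  v <- x$values[x$range_mask]
  cat(sprintf(
    "<%s> %d x %d (%d in range); values in [%.4g, %.4g]\n",
    class(x)[1], x$grid$n_rows, x$grid$n_cols, sum(x$range_mask),
    min(v), max(v)
  ))
  invisible(x)
}

#' Values of a surface at given cells, row-major
#'
#' @param surface A `raster_surface`.
#' @param cell Integer cell ids (row-major, 1-based); default all cells.
#' @return Numeric vector (`NA` outside the range mask).
#' @export
surface_values <- function(surface, cell = NULL) {
  v <- as.vector(t(surface$values)) # row-major
  if (is.null(cell)) v else v[cell]
}

mask_vector <- function(surface) as.vector(t(surface$range_mask))

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a raster surface into a cell table
#'
#' @param x A `raster_surface`.
#' @param ... Unused.
#' @return A tibble with one row per cell: `cell`, `row`, `col`, `lon`, `lat`,
#'   `in_range`, `value`.
#' @export
tidy.raster_surface <- function(x, ...) {
  out <- cell_centers(x$grid)
  out$in_range <- mask_vector(x)
  out$value <- surface_values(x)
  out
}

#' Plot a raster surface
#'
#' @param object A `raster_surface` (or `probability_surface`).
#' @param ... Unused.
#' @return A ggplot: cell-center tiles filled by value, out-of-range cells
#'   blank.
#' @export
autoplot.raster_surface <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$in_range)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  fill = if (inherits(object, "probability_surface"))
                    "P(origin)" else "value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
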