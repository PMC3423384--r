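#' Read an ESRI ASCII grid as a raster surface
#'
#' The standard six-line header (`ncols`, `nrows`, `xllcorner`/`xllcenter`,
#' `yllcorner`/`yllcenter`, `cellsize`, `nodata_value`) followed by rows of
#' values, northernmost row first. NODATA cells become the out-of-range part
#' of the mask.
#'
#' @param path Path to the `.asc` file.
#' @param nominal_cell_area_km2 Reporting constant attached to the grid.
#' @return A [raster_surface()].
#' @export
read_ascii_grid <- function(path, nominal_cell_area_km2 = 20) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[a-zA-Z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) {
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  }
  n_rows <- hdr$nrows; n_cols <- hdr$ncols; cs <- hdr$cellsize
  nodata <- hdr$nodata_value %||% -9999
  # lower-left corner or center -> NW cell center
  xll <- if (!is.null(hdr$xllcenter)) hdr$xllcenter else hdr$xllcorner + cs / 2
  yll <- if (!is.null(hdr$yllcenter)) hdr$yllcenter else hdr$yllcorner + cs / 2
  grid <- grid_spec(n_rows, n_cols, lon_origin = xll,
                    lat_origin = yll + (n_rows - 1) * cs, cell_size_deg = cs,
                    nominal_cell_area_km2 = nominal_cell_area_km2)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop(sprintf("ASCII grid body has %d values, expected %d",
                 length(vals), n_rows * n_cols), call. = FALSE)
  }
  m <- matrix(vals, n_rows, n_cols, byrow = TRUE)
  mask <- m != nodata
  m[!mask] <- NA_real_
  raster_surface(grid, m, mask)
}

#' Write a raster surface as an ESRI ASCII grid
#'
#' Out-of-range cells are written as the NODATA value, so the range mask
#' round-trips.
#'
#' @param surface A [raster_surface()].
#' @param path Output path.
#' @param nodata NODATA sentinel (must not collide with real values).
#' @param digits Significant digits to print.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(surface, path, nodata = -9999, digits = 10) {
  g <- surface$grid
  v <- surface$values
  if (any(abs(v - nodata) < 1e-12, na.rm = TRUE)) {
    stop("a real cell value equals the nodata sentinel; choose another",
         call. = FALSE)
  }
  v[!surface$range_mask] <- nodata
  hdr <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$lon_origin - g$cell_size_deg / 2),
    sprintf("yllcorner %.10g",
            g$lat_origin - (g$n_rows - 1) * g$cell_size_deg -
              g$cell_size_deg / 2),
    sprintf("cellsize %.10g", g$cell_size_deg),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a feather-sample table
#'
#' CSV with header `sample_id,age_class,lon,lat,d2hf` (an optional `locale`
#' column is carried through). `age_class` must be `SY` or `ASY`; `d2hf` is
#' the feather deuterium value in permil vs VSMOW.
#'
#' @param path CSV path.
#' @param role One of `"calibration"`, `"validation"`, `"query"`; recorded on
#'   each row.
#' @return A tibble of samples.
#' @export
read_samples <- function(path, role = c("calibration", "validation", "query")) {
  role <- match.arg(role)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "age_class", "lon", "lat", "d2hf")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("sample table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$age_class %in% c("SY", "ASY")
  if (any(bad)) {
    stop("unknown age_class on rows: ",
         paste(utils::head(which(bad), 5), collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(df$d2hf))) {
    stop("non-finite d2hf on rows: ",
         paste(utils::head(which(!is.finite(df$d2hf)), 5), collapse = ", "),
         call. = FALSE)
  }
  df$sample_id <- as.character(df$sample_id)
  df$role <- role
  tibble::as_tibble(df)
}

#' Write a feather-sample table
#'
#' @param samples Tibble with at least `sample_id,age_class,lon,lat,d2hf`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(samples, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse an admixture (Q) matrix
#'
#' Each row is one individual's membership fractions over the K genetic
#' clusters, as estimated by Bayesian clustering of microsatellite genotypes.
#' Two dialects are understood:
#' \describe{
#'   \item{`csv`}{header `id,q1,...,qK`.}
#'   \item{`structure_whitespace`}{whitespace-delimited rows with
#'     `label_cols` leading label columns (id first) before the K
#'     coefficients, as in STRUCTURE output tables.}
#' }
#' Coefficients must lie in \[0, 1\] and sum to 1 within `sum_tol` (absorbing
#' rounding in published tables); accepted rows are renormalized to sum
#' exactly 1. Rows failing the tolerance are rejected with their line numbers.
#'
#' @param path Input file.
#' @param dialect `"csv"` or `"structure_whitespace"`.
#' @param label_cols Leading non-numeric columns in the structure dialect.
#' @param sum_tol Allowed deviation of a row sum from 1.
#' @return A tibble with columns `sample_id` and `q` (list-column of numeric
#'   K-vectors, each summing to 1), plus attribute `K`.
#' @export
read_q_matrix <- function(path, dialect = c("csv", "structure_whitespace"),
                          label_cols = 1, sum_tol = 0.02) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (ncol(df) < 2) stop("Q matrix needs an id column plus >=1 cluster",
                           call. = FALSE)
    ids <- as.character(df[[1]])
    qm <- suppressWarnings(
      apply(as.matrix(df[, -1, drop = FALSE]), c(1, 2), as.numeric)
    )
    first_line <- 2L # header occupies line 1
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(trimws(lines), "\\s+")
    wid <- lengths(toks)
    if (length(unique(wid)) != 1) {
      stop("inconsistent column count across rows (K differs?); widths: ",
           paste(unique(wid), collapse = ", "), call. = FALSE)
    }
    if (wid[1] <= label_cols) stop("no coefficient columns after labels",
                                   call. = FALSE)
    ids <- vapply(toks, `[[`, "", 1)
    qm <- do.call(rbind, lapply(toks, function(t) {
      suppressWarnings(as.numeric(t[(label_cols + 1):length(t)]))
    }))
    first_line <- 1L
  }
  bad_parse <- apply(qm, 1, anyNA)
  if (any(bad_parse)) {
    stop("malformed Q row at line ",
         paste(which(bad_parse) + first_line - 1L, collapse = ", "),
         call. = FALSE)
  }
  out_of_range <- apply(qm, 1, function(q) any(q < 0 | q > 1))
  sums <- rowSums(qm)
  bad_sum <- abs(sums - 1) > sum_tol | out_of_range
  if (any(bad_sum)) {
    stop("Q rows violating the [0,1] / sum-to-1 (tol ", sum_tol,
         ") constraints at line ",
         paste(which(bad_sum) + first_line - 1L, collapse = ", "),
         call. = FALSE)
  }
  qm <- qm / sums
  out <- tibble::tibble(
    sample_id = ids,
    q = lapply(seq_len(nrow(qm)), function(i) unname(qm[i, ]))
  )
  attr(out, "K") <- ncol(qm)
  out
}

#' Write a Q matrix as CSV
#'
#' @param qtab Tibble as returned by [read_q_matrix()] (columns `sample_id`,
#'   list-column `q`).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(qtab, path) {
  K <- length(qtab$q[[1]])
  qm <- do.call(rbind, qtab$q)
  df <- data.frame(id = qtab$sample_id, qm)
  names(df) <- c("id", paste0("q", seq_len(K)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / read a calibration model as JSON
#'
#' @param model A `calibration_model`.
#' @param path JSON path.
#' @return `path` invisibly for write; a `calibration_model` for read.
#' @export
write_calibration_json <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration_model(
    age_class = x$age_class, intercept_permil = x$intercept_permil,
    slope = x$slope, residual_sd_permil = x$residual_sd_permil,
    n_samples = x$n_samples, r_squared = x$r_squared
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
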