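#' Fit an age-specific feather calibration
#'
#' Feather deuterium is offset from growing-season precipitation deuterium by
#' trophic and physiological fractionation, so the precipitation isoscape must
#' be rescaled into "feather space" before birds can be assigned. The
#' calibration is an ordinary-least-squares regression of known-origin feather
#' values on the precipitation isoscape value at each bird's capture cell,
#'
#' \deqn{\delta^2H_f = \beta_0 + \beta_1\,\delta^2H_p + \epsilon,\quad
#'       \epsilon \sim N(0, \sigma^2),}
#'
#' fitted independently per age class: second-year (SY) and after-second-year
#' (ASY) feathers integrate different molt histories and get separate
#' isoscapes. The residual standard deviation uses the unbiased n-2
#' denominator and is the default assignment sigma downstream.
#'
#' @param samples Tibble of known-origin samples with columns
#'   `sample_id, age_class, lon, lat, d2hf` (see [read_samples()]).
#' @param precip Precipitation isoscape, a [raster_surface()] in permil.
#' @param age_class `"SY"` or `"ASY"`; only samples of this class are used.
#' @return A `calibration_model` with fields `age_class`, `intercept_permil`,
#'   `slope`, `residual_sd_permil`, `n_samples`, `r_squared`.
#' @seealso [predict_feather_surface()], [tidy.calibration_model()]
#' @examples
#' g <- grid_spec(5, 5, -100, 50, 1)
#' precip <- raster_surface(g, matrix(seq(-140, -60, length.out = 25), 5, 5))
#' cal <- tibble::tibble(
#'   sample_id = letters[1:5], age_class = "ASY",
#'   lon = c(-100, -99, -98, -97, -96), lat = c(50, 49, 48, 47, 46),
#'   d2hf = -25 + 1.0 * surface_values(precip, c(1, 7, 13, 19, 25))
#' )
#' fit_calibration(cal, precip, "ASY")
#' @export
fit_calibration <- function(samples, precip, age_class = c("ASY", "SY")) {
  age_class <- match.arg(age_class)
  stopifnot(inherits(precip, "raster_surface"))
  sub <- dplyr::filter(samples, .data$age_class == !!age_class)
  if (nrow(sub) > 0) {
    cells <- lonlat_to_cell(precip$grid, sub$lon, sub$lat)$cell
    x <- surface_values(precip, cells) # NA off-grid or off-range
    usable <- !is.na(x)
  } else {
    x <- numeric(0)
    usable <- logical(0)
  }
  if (sum(usable) < 3) {
    stop(sprintf(
      "insufficient data: %d usable %s calibration samples inside the range (need >= 3)",
      sum(usable), age_class
    ), call. = FALSE)
  }
  x <- x[usable]
  y <- sub$d2hf[usable]
  if (stats::sd(x) == 0) {
    stop("degenerate fit: zero variance in the precipitation predictor",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  n <- length(y)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((y - mean(y))^2)
  new_calibration_model(
    age_class = age_class,
    intercept_permil = unname(stats::coef(fit)[1]),
    slope = unname(stats::coef(fit)[2]),
    residual_sd_permil = sqrt(rss / (n - 2)),
    n_samples = n,
    r_squared = if (tss > 0) 1 - rss / tss else 1
  )
}

new_calibration_model <- function(age_class, intercept_permil, slope,
                                  residual_sd_permil, n_samples, r_squared) {
  stopifnot(age_class %in% c("SY", "ASY"), residual_sd_permil >= 0,
            n_samples >= 3, r_squared >= 0, r_squared <= 1 + 1e-12)
  structure(
    list(
      age_class = age_class,
      intercept_permil = as.numeric(intercept_permil),
      slope = as.numeric(slope),
      residual_sd_permil = as.numeric(residual_sd_permil),
      n_samples = as.integer(n_samples),
      r_squared = as.numeric(min(r_squared, 1))
    ),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "<calibration_model %s> d2Hf = %.3f + %.4f * d2Hp, sigma = %.3f permil (n = %d, R2 = %.3f)\n",
    x$age_class, x$intercept_permil, x$slope, x$residual_sd_permil,
    x$n_samples, x$r_squared
  ))
  invisible(x)
}

#' Tidy / summarize a calibration model
#'
#' `tidy()` returns one row per regression coefficient; `glance()` one row of
#' fit summaries, broom-style.
#'
#' @param x A `calibration_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.calibration_model <- function(x, ...) {
  tibble::tibble(
    age_class = x$age_class,
    term = c("intercept_permil", "slope"),
    estimate = c(x$intercept_permil, x$slope)
  )
}

#' @rdname tidy.calibration_model
#' @export
glance.calibration_model <- function(x, ...) {
  tibble::tibble(
    age_class = x$age_class,
    intercept_permil = x$intercept_permil,
    slope = x$slope,
    residual_sd_permil = x$residual_sd_permil,
    n_samples = x$n_samples,
    r_squared = x$r_squared
  )
}

#' @importFrom generics glance
#' @export
generics::glance

#' Fit calibrations for every age class present
#'
#' @inheritParams fit_calibration
#' @return Named list of `calibration_model`s, one per age class with >= 3
#'   usable samples.
#' @export
fit_calibrations <- function(samples, precip) {
  classes <- intersect(c("SY", "ASY"), unique(samples$age_class))
  models <- lapply(classes, function(a) fit_calibration(samples, precip, a))
  stats::setNames(models, classes)
}

#' Rescale a precipitation isoscape into feather space
#'
#' Applies the calibration map cell-wise: expected feather value
#' `intercept + slope * d2Hp`. The range mask is unchanged.
#'
#' @param model A `calibration_model`.
#' @param precip Precipitation isoscape ([raster_surface()], permil).
#' @return A [raster_surface()] of expected feather deuterium (the
#'   age-specific feather isoscape).
#' @export
predict_feather_surface <- function(model, precip) {
  stopifnot(inherits(model, "calibration_model"),
            inherits(precip, "raster_surface"))
  raster_surface(precip$grid,
                 model$intercept_permil + model$slope * precip$values,
                 precip$range_mask)
}
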