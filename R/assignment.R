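#' Construct a probability surface
#'
#' A raster surface whose in-range cells hold nonnegative mass summing to 1:
#' the "probability of origin" substrate for likelihoods, priors and
#' posteriors.
#'
#' @param grid A `grid_spec`.
#' @param p Nonnegative matrix/vector of cell masses.
#' @param range_mask Logical mask; see [raster_surface()].
#' @param normalize If `TRUE`, rescale to sum 1 instead of insisting the
#'   input already does.
#' @return A `probability_surface` (also a `raster_surface`).
#' @export
probability_surface <- function(grid, p, range_mask = NULL, normalize = FALSE) {
  surf <- raster_surface(grid, p, range_mask)
  v <- surf$values[surf$range_mask]
  if (any(v < 0)) stop("probability surface has negative cells", call. = FALSE)
  tot <- sum(v)
  if (normalize) {
    if (tot <= 0) stop("cannot normalize: total mass is zero", call. = FALSE)
    surf$values <- surf$values / tot
  } else if (abs(tot - 1) > 1e-9) {
    stop(sprintf("probability surface sums to %.12g, not 1", tot),
         call. = FALSE)
  }
  class(surf) <- c("probability_surface", "raster_surface")
  surf
}

#' Isotope likelihood surface for one bird
#'
#' The probability of origin at each cell given the bird's feather value: a
#' normal density of the observed `d2hf` centered on the cell's expected
#' feather value with standard deviation `sigma`, renormalized to sum to 1
#' over the range. `sigma` defaults downstream to the age-specific
#' calibration residual SD; it can be overridden (e.g. inflated for isoscape
#' model error).
#'
#' Normalizing the likelihood makes the isotope-only workflow a literal
#' special case of the Bayesian one with a uniform prior; the posterior is
#' unaffected by the normalization.
#'
#' @param d2hf Observed feather deuterium, permil.
#' @param feather_isoscape Expected-feather surface from
#'   [predict_feather_surface()].
#' @param sigma Assignment standard deviation, permil (> 0).
#' @return A `probability_surface`.
#' @export
likelihood_surface <- function(d2hf, feather_isoscape, sigma) {
  stopifnot(inherits(feather_isoscape, "raster_surface"),
            is.finite(d2hf), length(d2hf) == 1)
  if (!is.finite(sigma) || sigma <= 0) {
    stop("sigma must be a positive number of permil", call. = FALSE)
  }
  # log-space normalization: far-off observations must not underflow to an
  # all-zero surface
  logd <- stats::dnorm(d2hf, mean = feather_isoscape$values, sd = sigma,
                       log = TRUE)
  dens <- exp(logd - max(logd[feather_isoscape$range_mask]))
  probability_surface(feather_isoscape$grid, dens,
                      feather_isoscape$range_mask, normalize = TRUE)
}

#' Combine likelihood and prior via Bayes' theorem
#'
#' The posterior probability that a cell is the bird's origin given its
#' feather value, conditional on the genetic prior: the cell-wise product of
#' likelihood and prior, renormalized to sum 1 over the range.
#'
#' @param likelihood,prior `probability_surface`s on identical grids/masks.
#' @param sample_id Optional id used in the incompatible-evidence error.
#' @return A `probability_surface`.
#' @export
posterior_surface <- function(likelihood, prior, sample_id = NULL) {
  stopifnot(inherits(likelihood, "probability_surface"),
            inherits(prior, "probability_surface"))
  stop_if_grid_mismatch(likelihood, prior)
  if (!identical(likelihood$range_mask, prior$range_mask)) {
    stop("likelihood and prior have different range masks", call. = FALSE)
  }
  prod <- likelihood$values * prior$values
  tot <- sum(prod[likelihood$range_mask])
  if (tot <= 0) {
    stop(sprintf(
      "incompatible evidence%s: likelihood x prior is identically zero over the range",
      if (is.null(sample_id)) "" else paste0(" for ", sample_id)
    ), call. = FALSE)
  }
  probability_surface(likelihood$grid, prod, likelihood$range_mask,
                      normalize = TRUE)
}

#' Uniform prior over the range
#'
#' @param grid A `grid_spec` or object carrying one.
#' @param range_mask Logical mask (default all in range).
#' @return A `probability_surface` with equal mass on every in-range cell.
#' @export
uniform_prior <- function(grid, range_mask = NULL) {
  grid <- as_grid_spec(grid)
  probability_surface(grid, 1, range_mask, normalize = TRUE)
}

#' Credible level implied by an odds ratio
#'
#' Odds of r:1 that the bird truly originated within the mapped region
#' correspond to capturing a fraction r/(r+1) of the probability mass:
#' 2:1 odds define the upper 67% of probabilities of origin, 3:1 odds the
#' upper 75%.
#'
#' @param odds Positive odds ratio (the r in r:1).
#' @return Fraction in (0, 1).
#' @export
odds_quantile <- function(odds) {
  if (!is.numeric(odds) || any(!is.finite(odds)) || any(odds <= 0)) {
    stop("odds must be positive", call. = FALSE)
  }
  odds / (odds + 1)
}

#' @rdname odds_quantile
#' @return `format_odds_percent()`: the level rounded to the nearest whole
#'   percent, e.g. `"67%"` for 2:1 odds.
#' @export
format_odds_percent <- function(odds) {
  sprintf("%d%%", as.integer(round(100 * odds_quantile(odds))))
}

#' Threshold a probability surface into a binary origin region
#'
#' Sorts in-range cells by descending probability and selects the smallest
#' prefix whose cumulative mass reaches `odds / (odds + 1)`; cells exactly
#' tied with the last included cell are also selected, so the region is
#' deterministic and independent of enumeration order. The slight overshoot
#' of captured mass that ties (or the final discrete step) cause is recorded
#' in `captured_mass` rather than hidden.
#'
#' @param P A `probability_surface`.
#' @param odds Positive odds ratio; 2 captures >= 2/3 of the mass.
#' @return An `origin_region`: fields `grid`, `selected` (logical matrix),
#'   `odds`, `captured_mass`, `n_cells`.
#' @export
threshold_region <- function(P, odds) {
  stopifnot(inherits(P, "probability_surface"))
  target <- odds_quantile(odds)
  p <- surface_values(P)
  in_range <- mask_vector(P)
  idx <- which(in_range)
  ord <- idx[order(p[idx], decreasing = TRUE)]
  cum <- cumsum(p[ord])
  k <- match(TRUE, cum >= target - 1e-12)
  if (is.na(k)) k <- length(ord) # guard fp shortfall at full mass
  p_last <- p[ord[k]]
  sel_cells <- c(ord[seq_len(k)], ord[-seq_len(k)][p[ord[-seq_len(k)]] == p_last])
  selected <- rep(FALSE, length(p))
  selected[sel_cells] <- TRUE
  new_origin_region(
    grid = P$grid,
    selected = matrix(selected, P$grid$n_rows, P$grid$n_cols, byrow = TRUE),
    odds = odds,
    captured_mass = sum(p[selected]),
    range_mask = P$range_mask
  )
}

new_origin_region <- function(grid, selected, odds, captured_mass,
                              range_mask) {
  structure(
    list(grid = grid, selected = selected, odds = odds,
         captured_mass = captured_mass, n_cells = sum(selected),
         range_mask = range_mask),
    class = "origin_region"
  )
}

#' @export
print.origin_region <- function(x, ...) {
  cat(sprintf(
    "<origin_region> %s:1 odds (%s): %d cells, %.4f mass captured\n",
    format(x$odds), format_odds_percent(x$odds), x$n_cells, x$captured_mass
  ))
  invisible(x)
}

#' Tidy an origin region into a cell table
#'
#' @param x An `origin_region`.
#' @param ... Unused.
#' @return Tibble of cells with `selected` logical.
#' @export
tidy.origin_region <- function(x, ...) {
  out <- cell_centers(x$grid)
  out$in_range <- as.vector(t(x$range_mask))
  out$selected <- as.vector(t(x$selected))
  out
}

#' Binary 0/1 surface of a region (for raster export)
#'
#' @param region An `origin_region`.
#' @return A [raster_surface()] with value 1 on selected cells, 0 elsewhere
#'   in range.
#' @export
region_surface <- function(region) {
  raster_surface(region$grid, region$selected + 0, region$range_mask)
}

#' Plot an origin region
#'
#' @param object An `origin_region`.
#' @param ... Unused.
#' @return A ggplot of the binary origin map.
#' @export
autoplot.origin_region <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$in_range)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$selected)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey85",
                                          `TRUE` = "#2166ac")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      x = "Longitude", y = "Latitude", fill = "Probable origin",
      title = sprintf("%s origin region (%s:1 odds, %d cells)",
                      format_odds_percent(object$odds),
                      format(object$odds), object$n_cells)
    ) +
    ggplot2::theme_minimal()
}
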