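#' Assign a table of birds to probable origins
#'
#' The full per-bird workflow, one call: for each bird, build the isotope
#' likelihood over the age-specific feather isoscape, optionally combine it
#' with the genetic prior implied by the bird's admixture coefficients, and
#' threshold the resulting surface into binary origin regions at each
#' requested odds ratio. The isotope-only route is the uniform-prior special
#' case of the same machinery.
#'
#' Birds with no row in `qtab` degrade gracefully to isotope-only assignment
#' with a warning; the method fails only when a bird has neither marker.
#'
#' @param samples Tibble of birds to assign: columns `sample_id`,
#'   `age_class`, `lon`, `lat` (capture coordinates), `d2hf`; optional
#'   `locale` carried through.
#' @param models Named list of `calibration_model`s keyed by age class (as
#'   from [fit_calibrations()]), or a single model applied to all rows.
#' @param precip Precipitation isoscape ([raster_surface()]).
#' @param qtab Optional admixture table from [read_q_matrix()] (columns
#'   `sample_id`, list-column `q`).
#' @param clusters Optional [cluster_map()]; required with `qtab`.
#' @param odds Numeric vector of odds ratios (default `c(2, 3)`).
#' @param sigma Optional assignment SD override (permil); default each age
#'   class's calibration residual SD.
#' @param floor_eps Uniform floor for the genetic prior; see
#'   [build_prior_surface()].
#' @param include_genetic_only Also emit hard argmax-Q assignments as
#'   `genetic_only` rows (no region). Default `TRUE` when `qtab` is given.
#' @return A tibble with one row per bird x method x odds ratio:
#'   `sample_id`, `locale`, `age_class`, `method` (`isotope_only`, `bayes`,
#'   `genetic_only`), `odds`, `n_cells`, `captured_mass`, `containment`
#'   (of the capture location, see [containment_class()]),
#'   `fold_vs_no_prior` (on `bayes` rows), `assigned_cluster` and
#'   `ambiguous` (on `genetic_only` rows).
#' @export
assign_birds <- function(samples, models, precip, qtab = NULL,
                         clusters = NULL, odds = c(2, 3), sigma = NULL,
                         floor_eps = 0.01,
                         include_genetic_only = !is.null(qtab)) {
  stopifnot(inherits(precip, "raster_surface"), length(odds) >= 1,
            all(odds > 0))
  if (inherits(models, "calibration_model")) {
    models <- stats::setNames(
      rep(list(models), length(unique(samples$age_class))),
      unique(samples$age_class)
    )
  }
  if (!is.null(qtab) && is.null(clusters)) {
    stop("a cluster_map is required to use Q priors", call. = FALSE)
  }
  if (!is.null(clusters)) stop_if_grid_mismatch(precip, clusters)
  missing_age <- setdiff(unique(samples$age_class), names(models))
  if (length(missing_age)) {
    stop("no calibration model for age class: ",
         paste(missing_age, collapse = ", "), call. = FALSE)
  }

  centers <- cell_centers(precip$grid)
  capture_cells <- lonlat_to_cell(precip$grid, samples$lon, samples$lat)$cell
  locale <- if ("locale" %in% names(samples)) samples$locale else
    rep(NA_character_, nrow(samples))
  q_lookup <- if (!is.null(qtab)) {
    stats::setNames(qtab$q, qtab$sample_id)
  } else NULL

  feather <- lapply(models, predict_feather_surface, precip = precip)
  priors_env <- new.env(parent = emptyenv()) # memoised genetic priors

  rows <- vector("list", nrow(samples))
  n_missing_q <- 0L
  for (i in seq_len(nrow(samples))) {
    a <- samples$age_class[i]
    s <- sigma %||% models[[a]]$residual_sd_permil
    lik <- likelihood_surface(samples$d2hf[i], feather[[a]], s)
    qv <- if (!is.null(q_lookup)) q_lookup[[samples$sample_id[i]]] else NULL
    if (!is.null(q_lookup) && is.null(qv)) n_missing_q <- n_missing_q + 1L

    surfaces <- list(isotope_only = lik)
    if (!is.null(qv)) {
      prior <- prior_cached(priors_env, qv, clusters, floor_eps)
      surfaces$bayes <- posterior_surface(lik, prior,
                                          sample_id = samples$sample_id[i])
    }

    recs <- list()
    for (m in names(surfaces)) {
      for (r in odds) {
        reg <- threshold_region(surfaces[[m]], r)
        recs[[length(recs) + 1L]] <- tibble::tibble(
          sample_id = samples$sample_id[i], locale = locale[i],
          age_class = a, method = m, odds = r,
          n_cells = reg$n_cells, captured_mass = reg$captured_mass,
          containment = containment_of_cell(reg, capture_cells[i],
                                            samples$lon[i], samples$lat[i],
                                            centers),
          assigned_cluster = NA_integer_, ambiguous = NA
        )
      }
    }
    if (include_genetic_only && !is.null(qv)) {
      ga <- genetic_cluster_assignment(qv)
      recs[[length(recs) + 1L]] <- tibble::tibble(
        sample_id = samples$sample_id[i], locale = locale[i], age_class = a,
        method = "genetic_only", odds = NA_real_, n_cells = NA_integer_,
        captured_mass = NA_real_, containment = NA_character_,
        assigned_cluster = as.integer(ga$cluster), ambiguous = ga$ambiguous
      )
    }
    rows[[i]] <- dplyr::bind_rows(recs)
  }
  if (n_missing_q > 0) {
    warning(sprintf(
      "%d bird(s) had no Q row; reported isotope-only for those",
      n_missing_q
    ), call. = FALSE)
  }
  out <- dplyr::bind_rows(rows)

  # per-bird fold change in assigned area, attached to the bayes rows
  iso <- out |>
    dplyr::filter(.data$method == "isotope_only") |>
    dplyr::select("sample_id", "odds", n_cells_no_prior = "n_cells")
  out |>
    dplyr::left_join(iso, by = c("sample_id", "odds")) |>
    dplyr::mutate(
      fold_vs_no_prior = dplyr::if_else(
        .data$method == "bayes",
        .data$n_cells_no_prior / .data$n_cells, NA_real_
      )
    ) |>
    dplyr::select(-"n_cells_no_prior")
}

prior_cached <- function(env, qv, clusters, floor_eps) {
  key <- paste(format(qv, digits = 15), collapse = ",")
  got <- get0(key, envir = env, inherits = FALSE)
  if (is.null(got)) {
    got <- build_prior_surface(qv, clusters, floor_eps)
    assign(key, got, envir = env)
  }
  got
}

# containment with precomputed centers (hot loop form of containment_class)
containment_of_cell <- function(region, capture_cell, lon, lat, centers) {
  sel <- as.vector(t(region$selected))
  if (!is.na(capture_cell) && sel[capture_cell]) return("inside")
  cc <- centers[sel, ]
  dmin <- min(haversine_km(lon, lat, cc$lon, cc$lat))
  if (dmin <= 200) "within_200km"
  else if (dmin <= 400) "within_400km"
  else "outside"
}

#' Validate assignments against known origins
#'
#' Rolls an assignment table from [assign_birds()] into the standard
#' validation report: per-method accuracy with cumulative buffer rates,
#' per-locale area summaries, and chi-square tests of observed containment
#' rates against each odds ratio's nominal coverage.
#'
#' @param records Assignment tibble from [assign_birds()].
#' @param truth Optional tibble `sample_id`, `true_cluster` (the genetic
#'   cluster of each bird's capture locale), needed to grade `genetic_only`
#'   rows.
#' @return A list of tibbles: `accuracy` (see [assignment_accuracy()]),
#'   `locale_summary` (see [summarize_locale()]), `coverage_tests`
#'   (chi-square per region method and odds ratio).
#' @export
validate_assignments <- function(records, truth = NULL) {
  has_gen <- any(records$method == "genetic_only")
  acc <- assignment_accuracy(
    if (has_gen && is.null(truth)) {
      warning("no truth table: genetic_only rows not graded", call. = FALSE)
      dplyr::filter(records, .data$method != "genetic_only")
    } else records,
    truth
  )
  region <- dplyr::filter(records, .data$method != "genetic_only")
  cov <- region |>
    dplyr::group_by(.data$method, .data$odds) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_inside = sum(.data$containment == "inside"),
      p_expected = odds_quantile(.data$odds[1]),
      .groups = "drop"
    )
  cov <- dplyr::bind_cols(
    cov,
    purrr::pmap_dfr(cov[, c("n_inside", "n", "p_expected")],
                    function(n_inside, n, p_expected) {
                      chi_square_coverage(n_inside, n, p_expected)
                    })
  )
  list(
    accuracy = acc,
    locale_summary = summarize_locale(region),
    coverage_tests = cov
  )
}
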