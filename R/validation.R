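#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km; the backbone for the
#' 200/400 km buffer classes in validation.
#'
#' @param lon1,lat1,lon2,lat2 Decimal degrees; vectors recycle.
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Containment class of a capture location relative to an origin region
#'
#' `inside` if the capture coordinate's cell is selected; otherwise the
#' minimum great-circle distance from the capture point to any selected cell
#' center is binned into `within_200km`, `within_400km` (both cutoffs
#' inclusive), or `outside`. These are the buffer classes used to grade
#' validation birds.
#'
#' @param region An `origin_region`.
#' @param capture_lon,capture_lat Capture coordinates, decimal degrees.
#' @return One of `"inside"`, `"within_200km"`, `"within_400km"`,
#'   `"outside"` (an ordered factor level name).
#' @export
containment_class <- function(region, capture_lon, capture_lat) {
  stopifnot(inherits(region, "origin_region"))
  if (region$n_cells == 0) stop("empty origin region", call. = FALSE)
  cell <- lonlat_to_cell(region$grid, capture_lon, capture_lat)
  sel <- as.vector(t(region$selected))
  if (!is.na(cell$cell) && sel[cell$cell]) return("inside")
  cc <- cell_centers(region$grid)[sel, ]
  dmin <- min(haversine_km(capture_lon, capture_lat, cc$lon, cc$lat))
  if (dmin <= 200) "within_200km"
  else if (dmin <= 400) "within_400km"
  else "outside"
}

containment_levels <- c("inside", "within_200km", "within_400km", "outside")

#' Fold-change in assigned area from using a prior
#'
#' The factor by which the genetic prior shrinks the probable area of origin:
#' the ratio of the no-prior region's cell count to the with-prior region's.
#' Values above 1 mean the prior improved spatial resolution.
#'
#' @param n_cells_no_prior,n_cells_prior Positive cell counts.
#' @return Ratio(s), vectorized.
#' @examples
#' fold_change(3538, 286) # 12.37
#' fold_change(7686, 1158) # 6.64
#' @export
fold_change <- function(n_cells_no_prior, n_cells_prior) {
  if (any(n_cells_no_prior < 1) || any(n_cells_prior < 1)) {
    stop("cell counts must be >= 1 (regions are non-empty by construction)",
         call. = FALSE)
  }
  n_cells_no_prior / n_cells_prior
}

#' Per-locale summary of assigned areas
#'
#' Mean and sample standard deviation (n-1 denominator) of origin-region cell
#' counts, grouped by locale, age class, method and odds ratio. The SD is
#' `NA` for single-bird groups.
#'
#' @param records Tibble of assignment records with columns `locale`,
#'   `age_class`, `method`, `odds`, `n_cells` (one row per bird x method x
#'   odds; see [assign_birds()]).
#' @return Tibble with `locale`, `age_class`, `method`, `odds`, `n`,
#'   `mean_cells`, `sd_cells`.
#' @export
summarize_locale <- function(records) {
  records |>
    dplyr::group_by(.data$locale, .data$age_class, .data$method, .data$odds) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cells = mean(.data$n_cells),
      sd_cells = ifelse(dplyr::n() > 1, stats::sd(.data$n_cells), NA_real_),
      .groups = "drop"
    )
}

#' Chi-square test of observed vs nominal coverage
#'
#' Did the odds-ratio regions contain the true origin as often as their
#' nominal level promises? Pearson chi-square on the 2-cell
#' (correct, incorrect) table against expected proportions
#' (`p_expected`, `1 - p_expected`), one degree of freedom, no continuity
#' correction.
#'
#' @param n_correct Observed number of correctly contained birds.
#' @param n_total Number of birds tested.
#' @param p_expected Nominal coverage in (0, 1), e.g. 2/3 at 2:1 odds.
#' @return Tibble with `chi2`, `df` (= 1), `p_value`.
#' @examples
#' chi_square_coverage(81, 100, 0.75) # chi2 = 1.92
#' @export
chi_square_coverage <- function(n_correct, n_total, p_expected) {
  stopifnot(p_expected > 0, p_expected < 1, n_total >= 1,
            n_correct >= 0, n_correct <= n_total)
  ht <- suppressWarnings(stats::chisq.test(
    c(n_correct, n_total - n_correct),
    p = c(p_expected, 1 - p_expected), correct = FALSE
  ))
  tibble::tibble(
    chi2 = unname(ht$statistic),
    df = 1L,
    p_value = unname(ht$p.value)
  )
}

#' Accuracy of assignment methods against known truth
#'
#' For region-producing methods (`isotope_only`, `bayes`), a bird is correct
#' when its containment class is `inside` — the capture cell itself was
#' selected; the buffer-relaxed rates (within 200 km, within 400 km,
#' cumulative) are reported alongside rather than folded into accuracy. For
#' `genetic_only`, a bird is correct when the argmax-Q cluster equals the
#' cluster of its capture locale.
#'
#' @param records Tibble with `sample_id`, `method`, `odds`, and either
#'   `containment` (region methods) or `assigned_cluster` (genetic).
#' @param truth Tibble keyed by `sample_id` with column `true_cluster`
#'   (needed for `genetic_only` rows; region rows carry their own
#'   containment).
#' @return Tibble with `method`, `odds`, `n`, `accuracy`, and cumulative
#'   buffer rates `rate_within_200km`, `rate_within_400km`.
#' @export
assignment_accuracy <- function(records, truth = NULL) {
  gen <- dplyr::filter(records, .data$method == "genetic_only")
  if (nrow(gen) > 0) {
    if (is.null(truth)) stop("genetic_only rows need a truth table",
                             call. = FALSE)
    missing_ids <- setdiff(gen$sample_id, truth$sample_id)
    if (length(missing_ids)) {
      stop("truth table lacks sample_id: ",
           paste(utils::head(missing_ids, 5), collapse = ", "), call. = FALSE)
    }
    gen <- dplyr::left_join(gen, truth, by = "sample_id")
    gen_sum <- gen |>
      dplyr::group_by(.data$method) |>
      dplyr::summarise(
        odds = NA_real_, n = dplyr::n(),
        accuracy = mean(.data$assigned_cluster == .data$true_cluster),
        rate_within_200km = NA_real_, rate_within_400km = NA_real_,
        .groups = "drop"
      )
  } else {
    gen_sum <- NULL
  }
  reg <- dplyr::filter(records, .data$method != "genetic_only")
  reg_sum <- NULL
  if (nrow(reg) > 0) {
    reg_sum <- reg |>
      dplyr::group_by(.data$method, .data$odds) |>
      dplyr::summarise(
        n = dplyr::n(),
        accuracy = mean(.data$containment == "inside"),
        rate_within_200km =
          mean(.data$containment %in% containment_levels[1:2]),
        rate_within_400km =
          mean(.data$containment %in% containment_levels[1:3]),
        .groups = "drop"
      )
  }
  dplyr::bind_rows(gen_sum, reg_sum)
}
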