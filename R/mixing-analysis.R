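# Temporal-mixing test: if eDNA detections younger than the fossil-based
# extinction estimate fall within the window during which bones could still
# have been shedding DNA on the landscape, they do not require living
# individuals. Three nested windows are built from the fossil extinction
# median: mean persistence (never-buried regression), its upper interval
# bound, and the upper bound of the broader potentially-never-buried
# regression.

STATUS_LEVELS <- c("within_mean", "within_upper", "within_upper_potential", "outside")

#' Build a bone-persistence window below an extinction estimate
#'
#' The window starts at the median of the fossil-informed extinction estimate
#' (`window_old`) and extends toward the present by the predicted persistence
#' duration (`window_young = window_old - persistence`). A persistence longer
#' than the extinction median gives a negative `window_young`: the window
#' extends past the modern day.
#'
#' @param fossil_estimate An `extinction_estimate` from fossil occurrences.
#' @param prediction A persistence duration in years, or a one-row prediction
#'   tibble from [predict_persistence()] (use `which` to pick the column).
#' @param which When `prediction` is a tibble: `"mean"` uses
#'   `mean_persistence`, `"upper"` uses `upper_ci`.
#' @return A one-row tibble with `window_old` and `window_young` (cal yr BP).
#' @export
build_window <- function(fossil_estimate, prediction, which = c("mean", "upper")) {
  which <- match.arg(which)
  stopifnot(inherits(fossil_estimate, "extinction_estimate"))
  persistence <- if (is.data.frame(prediction)) {
    stopifnot(nrow(prediction) == 1)
    if (which == "mean") prediction$mean_persistence else prediction$upper_ci
  } else {
    stopifnot(is.numeric(prediction), length(prediction) == 1, prediction >= 0)
    prediction
  }
  tibble(window_old = fossil_estimate$median,
         window_young = fossil_estimate$median - persistence)
}

#' Classify eDNA occurrences against nested persistence windows
#'
#' Each eDNA age is assigned the tightest window that contains it, with
#' inclusive bounds: ages at or older than `window_old` precede the extinction
#' estimate and are `within_mean`; otherwise `within_mean` down to
#' `window_young_mean`, `within_upper` down to `window_young_upper`,
#' `within_upper_potential` down to `window_young_upper_potential`, and
#' `outside` beyond that. Classification uses point ages only; dating error is
#' not propagated here.
#'
#' @param edna A validated occurrence tibble with `source == "edna"`.
#' @param windows A named list or vector with `window_old`,
#'   `window_young_mean`, `window_young_upper`, `window_young_upper_potential`
#'   (cal yr BP), which must be nested:
#'   `window_old >= mean >= upper >= upper_potential`.
#' @return A tibble `record_id`, `age`, `status` (factor with the four levels
#'   above); exactly one status per record.
#' @export
classify_edna <- function(edna, windows) {
  validate_occurrence_table(edna)
  if (any(edna$source != "edna")) {
    abort("classify_edna expects eDNA occurrences only", class = "bonechron_input_error")
  }
  w <- unlist(windows)
  needed <- c("window_old", "window_young_mean", "window_young_upper",
              "window_young_upper_potential")
  if (!all(needed %in% names(w))) {
    abort(sprintf("windows must supply: %s", paste(needed, collapse = ", ")),
          class = "bonechron_input_error")
  }
  w <- w[needed]
  if (is.unsorted(rev(unname(w)))) {
    abort("windows are not nested (need window_old >= mean >= upper >= upper_potential on the BP axis)",
          class = "bonechron_input_error")
  }
  status <- dplyr::case_when(
    edna$age >= w[["window_young_mean"]] ~ "within_mean",
    edna$age >= w[["window_young_upper"]] ~ "within_upper",
    edna$age >= w[["window_young_upper_potential"]] ~ "within_upper_potential",
    TRUE ~ "outside"
  )
  tibble(record_id = edna$record_id, age = edna$age,
         status = factor(status, levels = STATUS_LEVELS))
}

new_mixing_report <- function(region, fossil_estimate, edna_estimate, windows,
                              classifications) {
  structure(
    list(region = region,
         fossil_estimate = fossil_estimate,
         edna_estimate = edna_estimate,
         window_old = windows[["window_old"]],
         window_young_mean = windows[["window_young_mean"]],
         window_young_upper = windows[["window_young_upper"]],
         window_young_upper_potential = windows[["window_young_upper_potential"]],
         edna_classifications = classifications),
    class = "mixing_report"
  )
}

#' @export
print.mixing_report <- function(x, ...) {
  counts <- table(x$edna_classifications$status)
  cat(sprintf("Temporal-mixing report: %s\n", x$region))
  cat(sprintf("  fossil extinction median %.2f kyr BP; windows down to %.2f / %.2f / %.2f kyr BP\n",
              x$window_old / 1000, x$window_young_mean / 1000,
              x$window_young_upper / 1000, x$window_young_upper_potential / 1000))
  cat(sprintf("  eDNA: %s\n",
              paste(sprintf("%s = %d", names(counts), counts), collapse = ", ")))
  invisible(x)
}

#' Tidy a mixing report
#'
#' @param x A `mixing_report`.
#' @param ... Unused.
#' @return The per-record classification tibble with the region attached.
#' @export
tidy.mixing_report <- function(x, ...) {
  dplyr::mutate(x$edna_classifications, region = x$region, .before = 1)
}

#' One-row summary of a mixing report
#'
#' @param x A `mixing_report`.
#' @param ... Unused.
#' @return A one-row tibble: region, window bounds, extinction medians, and
#'   counts per classification status.
#' @export
glance.mixing_report <- function(x, ...) {
  counts <- table(x$edna_classifications$status)
  tibble(
    region = x$region,
    fossil_median = x$fossil_estimate$median,
    edna_median = if (is.null(x$edna_estimate)) NA_real_ else x$edna_estimate$median,
    window_old = x$window_old,
    window_young_mean = x$window_young_mean,
    window_young_upper = x$window_young_upper,
    window_young_upper_potential = x$window_young_upper_potential,
    n_within_mean = unname(counts[["within_mean"]]),
    n_within_upper = unname(counts[["within_upper"]]),
    n_within_upper_potential = unname(counts[["within_upper_potential"]]),
    n_outside = unname(counts[["outside"]])
  )
}

#' Plot a mixing report as a timeline
#'
#' @param object A `mixing_report`.
#' @param ... Unused.
#' @return A ggplot timeline: nested persistence windows as horizontal bars
#'   and eDNA ages as points coloured by classification.
#' @method autoplot mixing_report
#' @export
autoplot.mixing_report <- function(object, ...) {
  bars <- tibble(
    window = factor(c("mean", "upper", "upper_potential"),
                    levels = c("upper_potential", "upper", "mean")),
    old = object$window_old,
    young = c(object$window_young_mean, object$window_young_upper,
              object$window_young_upper_potential)
  )
  pts <- object$edna_classifications
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = bars,
                          ggplot2::aes(x = .data$old, xend = .data$young,
                                       y = .data$window, yend = .data$window,
                                       linewidth = .data$window),
                          colour = "grey60", show.legend = FALSE) +
    ggplot2::scale_linewidth_manual(values = c(mean = 4, upper = 2,
                                               upper_potential = 0.8)) +
    ggplot2::geom_point(data = pts,
                        ggplot2::aes(x = .data$age, y = "eDNA",
                                     colour = .data$status)) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Age (cal yr BP)", y = NULL, title = object$region) +
    ggplot2::theme_minimal()
}

derive_seed <- function(root, region_index, offset) {
  as.integer((root + 1013L * region_index + offset) %% .Machine$integer.max)
}

#' Run the full persistence / extinction / mixing pipeline
#'
#' Per region: fits the two persistence regressions globally from the bone
#' table (oldest bone per region, never-buried and potentially-never-buried
#' classes), estimates extinction separately from the region's fossil and eDNA
#' occurrence series, builds the three nested persistence windows below the
#' fossil extinction median using the region's site MAT, and classifies every
#' eDNA occurrence. Per-region estimator seeds are derived deterministically
#' from `config$seed`, so a fixed seed gives byte-identical serialized output.
#'
#' @param bones A bone tibble or a CSV path ([read_bone_table()]).
#' @param occurrences An occurrence tibble or CSV path, with both fossil and
#'   eDNA rows, possibly several regions.
#' @param sites A data frame or CSV path with columns `region` and `mat`: the
#'   MAT at which persistence is predicted for each region (e.g. the MAT of
#'   the most recent DNA-bearing site).
#' @param config An [estimator_config()].
#' @param ci_level,interval_kind Passed to [predict_persistence()].
#' @param consolidate If `TRUE` (default) the bone table is reduced to the
#'   oldest bone per region before fitting.
#' @return A list of `mixing_report` objects (class `mixing_report_set`), one
#'   per region present in `occurrences`, in alphabetical region order (so the
#'   result does not depend on input row order).
#' @export
#' @examples
#' study <- gen_mixing_study(seed = 3)
#' reports <- run_pipeline(study$bones, study$occurrences, study$sites,
#'                         config = estimator_config(n_resamples = 200, seed = 1))
#' glance(reports[[1]])
run_pipeline <- function(bones, occurrences, sites,
                         config = estimator_config(),
                         ci_level = 0.95,
                         interval_kind = "mean_confidence",
                         consolidate = TRUE) {
  if (is.character(bones)) bones <- read_bone_table(bones)
  if (is.character(occurrences)) occurrences <- read_occurrence_table(occurrences)
  if (is.character(sites)) {
    sites <- readr::read_csv(sites, col_types = readr::cols(
      region = readr::col_character(), mat = readr::col_double()), progress = FALSE)
  }
  require_columns(sites, c("region", "mat"), "site table")
  validate_bone_table(bones)
  validate_occurrence_table(occurrences)
  if (consolidate) bones <- consolidate_oldest_per_region(bones)
  fit_never <- fit_persistence(bones, "never_buried")
  fit_potential <- fit_persistence(bones, "potentially_never_buried")

  regions <- sort(unique(occurrences$region))  # stable order => row-order invariance
  reports <- lapply(seq_along(regions), function(ri) {
    region <- regions[ri]
    occ_r <- occurrences[occurrences$region == region, , drop = FALSE]
    occ_r <- occ_r[order(occ_r$record_id), , drop = FALSE]  # row-order invariance
    fossils <- occ_r[occ_r$source == "fossil", , drop = FALSE]
    edna <- occ_r[occ_r$source == "edna", , drop = FALSE]
    mat_r <- sites$mat[sites$region == region]
    if (length(mat_r) != 1) {
      abort(sprintf("region '%s': need exactly one site MAT, found %d",
                    region, length(mat_r)),
            class = "bonechron_input_error")
    }
    cfg_f <- config; cfg_f$seed <- derive_seed(config$seed, ri, 1L)
    cfg_e <- config; cfg_e$seed <- derive_seed(config$seed, ri, 2L)
    fossil_est <- tryCatch(
      estimate_extinction(fossils, cfg_f),
      error = function(e) {
        abort(sprintf("region '%s', stage fossil extinction: %s",
                      region, conditionMessage(e)),
              class = "bonechron_pipeline_error")
      })
    edna_est <- if (nrow(edna) >= config$min_sightings) {
      estimate_extinction(edna, cfg_e)
    } else {
      NULL
    }
    pred_never <- predict_persistence(fit_never, mat_r, ci_level, interval_kind)
    pred_potential <- predict_persistence(fit_potential, mat_r, ci_level, interval_kind)
    # The potential-class window is nested with the never-class one by
    # construction (the broader burial class can only lengthen the window);
    # when the broader fit happens to give a narrower upper bound, take the
    # union so the windows stay nested.
    wy_mean <- build_window(fossil_est, pred_never, "mean")$window_young
    wy_upper <- build_window(fossil_est, pred_never, "upper")$window_young
    wy_pot <- min(wy_upper,
                  build_window(fossil_est, pred_potential, "upper")$window_young)
    windows <- c(
      window_old = fossil_est$median,
      window_young_mean = wy_mean,
      window_young_upper = wy_upper,
      window_young_upper_potential = wy_pot
    )
    classifications <- classify_edna(edna, windows)
    new_mixing_report(region, fossil_est, edna_est, windows, classifications)
  })
  structure(reports, class = "mixing_report_set",
            persistence_fits = list(never = fit_never, potential = fit_potential))
}

#' Tidy a set of mixing reports
#'
#' @param x A `mixing_report_set` from [run_pipeline()].
#' @param ... Unused.
#' @return Row-bound [tidy.mixing_report()] tibbles across regions.
#' @export
tidy.mixing_report_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' Summarize a set of mixing reports
#'
#' @param x A `mixing_report_set`.
#' @param ... Unused.
#' @return Row-bound [glance.mixing_report()] tibbles across regions.
#' @export
glance.mixing_report_set <- function(x, ...) {
  purrr::map_dfr(unclass(x), glance)
}

#' Serialize mixing reports to JSON and CSV
#'
#' Writes a JSON document with windows, extinction summaries and per-record
#' classifications for every region, and optionally a CSV of the per-region
#' summary table. Output is byte-identical across runs with the same inputs
#' and seed.
#'
#' @param reports A `mixing_report_set`.
#' @param json_path Output path for the JSON document.
#' @param csv_path Optional output path for the [glance()] summary CSV.
#' @return `json_path`, invisibly.
#' @export
write_mixing_report <- function(reports, json_path, csv_path = NULL) {
  payload <- lapply(unclass(reports), function(r) {
    list(
      region = r$region,
      fossil_estimate = tidy(r$fossil_estimate),
      edna_estimate = if (is.null(r$edna_estimate)) NULL else tidy(r$edna_estimate),
      windows = list(window_old = r$window_old,
                     window_young_mean = r$window_young_mean,
                     window_young_upper = r$window_young_upper,
                     window_young_upper_potential = r$window_young_upper_potential),
      classifications = dplyr::mutate(r$edna_classifications,
                                      status = as.character(.data$status))
    )
  })
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  if (!is.null(csv_path)) readr::write_csv(glance(reports), csv_path, progress = FALSE)
  invisible(json_path)
}
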