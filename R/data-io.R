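# Tables come in two shapes: dated surface bones (with locality temperature and a
# burial-history class) and dated occurrences of a focal taxon (fossil or eDNA).
# Ages are calibrated years BP throughout; dating errors are stored as 2-sigma,
# exactly as reported on radiocarbon dates.

BONE_COLS <- c("record_id", "region", "taxon", "age", "age_2sigma", "mat",
               "burial_class")
OCC_COLS <- c("record_id", "region", "source", "age", "age_2sigma")

BURIAL_CLASSES <- c("never_buried", "potentially_never_buried")
OCC_SOURCES <- c("fossil", "edna")

# Rename file headers to canonical names. `col_map` maps canonical -> file header,
# e.g. c(age = "cal_age_bp"); columns not mentioned keep their names.
apply_col_map <- function(df, col_map) {
  if (is.null(col_map)) return(df)
  stopifnot(is.character(col_map), !is.null(names(col_map)))
  for (canonical in names(col_map)) {
    from <- col_map[[canonical]]
    if (!from %in% names(df)) {
      abort(sprintf("column mapping refers to '%s', which is not in the file", from),
            class = "bonechron_schema_error")
    }
    names(df)[names(df) == from] <- canonical
  }
  df
}

require_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s", what,
                  paste(missing, collapse = ", ")),
          class = "bonechron_schema_error")
  }
  invisible(df)
}

# Parse a character column to numeric, reporting 1-based row indices that fail.
parse_numeric_column <- function(x, column) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) | is.na(x))
  if (length(bad) > 0) {
    abort(sprintf("column '%s' has non-numeric or missing values at row(s): %s",
                  column, paste(utils::head(bad, 10), collapse = ", ")),
          class = "bonechron_row_error")
  }
  out
}

check_enum_column <- function(x, allowed, column) {
  bad <- which(!(x %in% allowed))
  if (length(bad) > 0) {
    abort(sprintf(
      "column '%s' has unknown label(s) %s at row(s): %s (allowed: %s)",
      column, paste(unique(x[bad]), collapse = ", "),
      paste(utils::head(bad, 10), collapse = ", "),
      paste(allowed, collapse = ", ")),
      class = "bonechron_row_error")
  }
  invisible(x)
}

#' Validate a table of dated surface bones
#'
#' Checks the schema and row-level invariants of a bone-persistence table:
#' required columns present, ages strictly positive, dating errors (2-sigma)
#' non-negative, mean annual temperature finite, and `burial_class` one of
#' `"never_buried"` / `"potentially_never_buried"`.
#'
#' @param bones A data frame with columns `record_id`, `region`, `taxon`,
#'   `age` (cal yr BP), `age_2sigma` (yr), `mat` (deg C), `burial_class`.
#' @return `bones`, invisibly, if valid; otherwise an error describing the
#'   offending column or rows.
#' @export
validate_bone_table <- function(bones) {
  require_columns(bones, BONE_COLS, "bone table")
  check_positive(bones$age, "age", strict = TRUE)
  check_positive(bones$age_2sigma, "age_2sigma", strict = FALSE)
  if (any(!is.finite(bones$mat))) {
    abort(sprintf("column 'mat' has non-finite values at row(s): %s",
                  paste(utils::head(which(!is.finite(bones$mat)), 10), collapse = ", ")),
          class = "bonechron_row_error")
  }
  check_enum_column(bones$burial_class, BURIAL_CLASSES, "burial_class")
  invisible(bones)
}

#' Validate a table of dated occurrences
#'
#' @param occurrences A data frame with columns `record_id`, `region`,
#'   `source` (`"fossil"` or `"edna"`), `age` (cal yr BP), `age_2sigma` (yr).
#' @return `occurrences`, invisibly, if valid.
#' @export
validate_occurrence_table <- function(occurrences) {
  require_columns(occurrences, OCC_COLS, "occurrence table")
  check_positive(occurrences$age, "age", strict = FALSE)
  check_positive(occurrences$age_2sigma, "age_2sigma", strict = FALSE)
  check_enum_column(occurrences$source, OCC_SOURCES, "source")
  invisible(occurrences)
}

check_positive <- function(x, column, strict) {
  if (any(!is.finite(x))) {
    abort(sprintf("column '%s' has non-finite values at row(s): %s",
                  column, paste(utils::head(which(!is.finite(x)), 10), collapse = ", ")),
          class = "bonechron_row_error")
  }
  bad <- if (strict) which(x <= 0) else which(x < 0)
  if (length(bad) > 0) {
    abort(sprintf("column '%s' must be %s; offending row(s): %s",
                  column, if (strict) "> 0" else ">= 0",
                  paste(utils::head(bad, 10), collapse = ", ")),
          class = "bonechron_row_error")
  }
  invisible(x)
}

read_table_impl <- function(path, col_map, required, numeric_cols, validator) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  df <- apply_col_map(df, col_map)
  require_columns(df, required, basename(path))
  for (column in numeric_cols) {
    df[[column]] <- parse_numeric_column(df[[column]], column)
  }
  df <- as_tibble(df[, union(required, names(df))])
  validator(df)
  df
}

#' Read a bone-persistence table from CSV
#'
#' Reads a comma-delimited table of radiocarbon-dated surface-collected bones,
#' one row per bone, validates it with [validate_bone_table()] and returns a
#' tibble in row order. Column headers that differ from the canonical names can
#' be adapted through `col_map` without editing the file.
#'
#' @param path Path to a CSV file with a header row.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's headers, e.g. `c(age = "cal_age_bp", mat = "MAT_C")`.
#' @return A tibble with columns `record_id`, `region`, `taxon`, `age`,
#'   `age_2sigma`, `mat`, `burial_class` (plus any extra columns in the file).
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' readr::write_csv(gen_bone_table(bone_gen_config(n = 5, seed = 1)), path)
#' read_bone_table(path)
read_bone_table <- function(path, col_map = NULL) {
  read_table_impl(path, col_map, BONE_COLS, c("age", "age_2sigma", "mat"),
                  validate_bone_table)
}

#' Read an occurrence series from CSV
#'
#' Reads a comma-delimited series of dated occurrences of a focal taxon
#' (body fossils and/or eDNA detections), validates it with
#' [validate_occurrence_table()] and returns a tibble in row order.
#'
#' @inheritParams read_bone_table
#' @return A tibble with columns `record_id`, `region`, `source`, `age`,
#'   `age_2sigma`.
#' @export
read_occurrence_table <- function(path, col_map = NULL) {
  read_table_impl(path, col_map, OCC_COLS, c("age", "age_2sigma"),
                  validate_occurrence_table)
}

#' Keep only the oldest bone from each region
#'
#' Surface-bone persistence is censored from below: any bone still lying on the
#' landscape gives only a minimum persistence time, and within a region the
#' oldest dated surface bone is the best available estimate of how long bones
#' persist there. This collapses a bone table to exactly one record per region,
#' the one with maximal age. Ties on age are broken by smaller dating error
#' (2-sigma), then lexicographic `record_id`, so output is deterministic.
#'
#' @param bones A validated bone table (see [read_bone_table()]).
#' @return A tibble with one row per distinct region, ordered by first
#'   appearance of each region in the input. Idempotent.
#' @export
consolidate_oldest_per_region <- function(bones) {
  if (nrow(bones) == 0) {
    abort("cannot consolidate an empty bone table", class = "bonechron_input_error")
  }
  validate_bone_table(bones)
  region_order <- unique(bones$region)
  out <- bones |>
    dplyr::arrange(dplyr::desc(.data$age), .data$age_2sigma, .data$record_id) |>
    dplyr::distinct(.data$region, .keep_all = TRUE) |>
    dplyr::arrange(match(.data$region, region_order))
  as_tibble(out)
}

#' Write a record table to CSV
#'
#' Plain UTF-8 comma-delimited output with a header row; a write followed by
#' [read_bone_table()] / [read_occurrence_table()] round-trips all fields.
#'
#' @param x A bone or occurrence tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_record_table <- function(x, path) {
  readr::write_csv(x, path, progress = FALSE)
  invisible(path)
}
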