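#' Read a column-mapping configuration
#'
#' A mapping adapts a foreign intake file to the canonical schema: each
#' source column is mapped to a canonical target column together with a
#' positive multiplicative unit-conversion factor (e.g. sodium reported in
#' grams maps to `sodium_mg` with factor 1000). A worked example for
#' NHANES-style total-nutrient exports ships as
#' `dq_example("nhanes_mapping.yaml")`.
#'
#' @param path Path to a YAML file with a top-level `columns` mapping:
#'   `SourceColumn: {target: canonical_column, factor: number}` (`factor`
#'   defaults to 1).
#' @return A tibble with columns `source`, `target`, `factor`.
#' @export
read_column_mapping <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$columns)) {
    abort("Mapping file must have a top-level `columns` key.",
          class = "dietscore_schema_error")
  }
  map <- dplyr::bind_rows(lapply(names(cfg$columns), function(src) {
    e <- cfg$columns[[src]]
    tibble::tibble(source = src, target = as.character(e$target),
                   factor = as.numeric(e$factor %||% 1))
  }))
  known <- c("subject_id", "day", "energy_kcal", unname(.NUTRIENT_COLS))
  bad <- setdiff(map$target, known)
  if (length(bad) > 0) {
    abort(sprintf("Mapping targets unknown canonical column(s): %s.",
                  paste(bad, collapse = ", ")),
          class = "dietscore_schema_error")
  }
  if (any(!is.finite(map$factor) | map$factor <= 0)) {
    abort("Mapping conversion factors must be positive.",
          class = "dietscore_schema_error")
  }
  map
}

#' Read an intake table
#'
#' Reads a delimited text file (comma or tab, header required) of per
#' subject-day nutrient totals into the canonical intake tibble. With a
#' column mapping, foreign headers are renamed and unit-converted first.
#' Unmapped, non-canonical columns are a schema error (the file's meaning
#' should never be guessed); negative amounts are a validation error naming
#' the row; missing values are handled per `policy` and every dropped row is
#' logged.
#'
#' @param path File path.
#' @param mapping Optional mapping tibble from [read_column_mapping()] (or a
#'   path to one).
#' @param policy Missing-data policy: `"strict"` (default; any missing value
#'   is an error), `"drop_row"` (drop incomplete rows, with a message), or
#'   `"keep"` (keep `NA`s for downstream handling, e.g.
#'   `score_intakes(allow_missing = TRUE)`).
#' @return A canonical intake tibble.
#' @export
read_intakes <- function(path, mapping = NULL,
                         policy = c("strict", "drop_row", "keep")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) {
    abort(sprintf("Intake file not found: '%s'", path),
          class = "dietscore_io_error")
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(mapping)) {
    if (is.character(mapping)) mapping <- read_column_mapping(mapping)
    for (i in seq_len(nrow(mapping))) {
      src <- mapping$source[i]
      if (!src %in% names(tab)) next
      vals <- tab[[src]]
      if (is.numeric(vals)) vals <- vals * mapping$factor[i]
      tab[[mapping$target[i]]] <- vals
      if (src != mapping$target[i]) tab[[src]] <- NULL
    }
  }
  known <- c("subject_id", "day", "energy_kcal", unname(.NUTRIENT_COLS))
  unknown <- setdiff(names(tab), known)
  if (length(unknown) > 0) {
    abort(sprintf(
      "Unknown column(s) %s; supply a column mapping to adapt foreign headers.",
      paste0("`", unknown, "`", collapse = ", ")
    ), class = "dietscore_schema_error")
  }
  if (!"energy_kcal" %in% names(tab)) {
    abort("Intake file must provide `energy_kcal`.",
          class = "dietscore_schema_error")
  }
  if (!"subject_id" %in% names(tab)) tab$subject_id <- "S1"
  tab$subject_id <- as.character(tab$subject_id)
  if (!"day" %in% names(tab)) {
    tab <- tab |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::mutate(day = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  num_cols <- intersect(c("energy_kcal", unname(.NUTRIENT_COLS)), names(tab))
  for (col in num_cols) {
    if (!is.numeric(tab[[col]])) {
      abort(sprintf("Column `%s` is not numeric; check the file format.", col),
            class = "dietscore_parse_error")
    }
    neg <- which(tab[[col]] < 0)
    if (length(neg) > 0) {
      abort(sprintf("Negative value in `%s` at data row %d.", col, neg[1]),
            class = "dietscore_validation_error")
    }
  }
  incomplete <- !stats::complete.cases(tab[num_cols])
  if (any(incomplete)) {
    if (policy == "strict") {
      abort(sprintf(
        "%d row(s) with missing values (first at data row %d); set `policy` to handle them.",
        sum(incomplete), which(incomplete)[1]
      ), class = "dietscore_missing_error")
    }
    if (policy == "drop_row") {
      inform(sprintf("read_intakes: dropped %d incomplete row(s), kept %d.",
                     sum(incomplete), sum(!incomplete)))
      tab <- tab[!incomplete, ]
    } else {
      inform(sprintf("read_intakes: kept %d row(s) with missing values.",
                     sum(incomplete)))
    }
  }
  dplyr::relocate(tab, "subject_id", "day", "energy_kcal")
}

#' Write an intake table
#'
#' Writes the canonical columns of an intake tibble as delimited text;
#' `read -> write -> read` round-trips value-identically.
#'
#' @param intakes A canonical intake tibble.
#' @param path Output path; a `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_intakes <- function(intakes, path) {
  cols <- intersect(c("subject_id", "day", "energy_kcal",
                      unname(.NUTRIENT_COLS)), names(intakes))
  out <- intakes[cols]
  if (grepl("\\.tsv$", path)) readr::write_tsv(out, path)
  else readr::write_csv(out, path)
  invisible(path)
}

#' Restrict intakes to an energy range
#'
#' Keeps subject-days whose energy lies in the closed interval
#' `[low_kcal, high_kcal]` (the restriction used to make diet-quality scores
#' comparable across subjects with similar energy intakes, e.g. 1700--2300
#' kcal) and logs kept/dropped counts.
#'
#' @param intakes A data frame with an `energy_kcal` column.
#' @param low_kcal,high_kcal Interval bounds, `low_kcal < high_kcal`.
#' @return The filtered tibble.
#' @export
#' @examples
#' tab <- tibble::tibble(energy_kcal = c(1600, 1700, 2300, 2400))
#' filter_energy_range(tab, 1700, 2300)
filter_energy_range <- function(intakes, low_kcal, high_kcal) {
  stopifnot(is.data.frame(intakes), low_kcal < high_kcal)
  keep <- intakes$energy_kcal >= low_kcal & intakes$energy_kcal <= high_kcal
  inform(sprintf("filter_energy_range [%g, %g]: kept %d, dropped %d.",
                 low_kcal, high_kcal, sum(keep), sum(!keep)))
  intakes[keep, , drop = FALSE]
}

#' Write and read score tables
#'
#' Score tables (per subject-day subscores and totals, or per-subject
#' summaries) are plain delimited text.
#'
#' @param scores A score tibble from [score_intakes()] or a summary from
#'   [score_period()].
#' @param path File path; `.tsv` selects tab delimiting.
#' @return `path` (write) or a tibble (read).
#' @export
write_scores <- function(scores, path) {
  if (grepl("\\.tsv$", path)) readr::write_tsv(scores, path)
  else readr::write_csv(scores, path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Score file not found: '%s'", path),
          class = "dietscore_io_error")
  }
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}
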