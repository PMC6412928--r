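#' Load a nutrient reference table
#'
#' Reads a YAML reference configuration into a tidy table with one row per
#' (gender, age band, nutrient). The configuration carries, per nutrient, the
#' reference semantics the scorer needs: an adequacy anchor (RDA or AI, or an
#' AMDR percent-of-energy range) or a moderation limit (WHO recommendation,
#' absolute or percent of energy), the healthy-range upper multiple
#' (default 2, i.e. 100--200% DRI; vitamin C ships with 3), and an optional
#' tolerable upper intake level (TUL) that caps the zero-score ceiling.
#'
#' Validation enforces: all sixteen canonical nutrients present in every
#' band, no unknown nutrient ids, non-overlapping half-open `[low, high)`
#' age bands, mode-appropriate fields, positive values, and ordered AMDR
#' bounds. Any violation raises a classed error naming the band and nutrient.
#'
#' @param path Path to a YAML reference configuration. The default is the
#'   table bundled with the package (adult IOM DRI/AMDR values and WHO
#'   limits, with provenance notes per entry).
#' @return A tibble of class `reference_table` with columns `gender`,
#'   `age_low`, `age_high`, `nutrient`, `mode`, `dri`, `amdr_low_pct`,
#'   `amdr_high_pct`, `who_limit`, `upper_multiple`, `tul`, `source`.
#' @seealso [lookup_reference()], [derive_breakpoints()]
#' @export
#' @examples
#' refs <- default_references()
#' dplyr::filter(refs, gender == "female", age_low == 31)
load_reference_table <- function(path = dq_example("references.yaml")) {
  if (!file.exists(path)) {
    abort(sprintf("Reference config not found: '%s'", path),
          class = "dietscore_io_error")
  }
  cfg <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      abort(sprintf("Failed to parse reference config '%s': %s", path,
                    conditionMessage(e)),
            class = "dietscore_schema_error")
    }
  )
  if (is.null(cfg$bands) || !is.list(cfg$bands)) {
    abort("Reference config must have a top-level `bands` mapping.",
          class = "dietscore_schema_error")
  }
  rows <- list()
  for (gender in names(cfg$bands)) {
    if (!gender %in% c("female", "male")) {
      abort(sprintf("Unknown gender '%s' in reference config.", gender),
            class = "dietscore_schema_error")
    }
    for (band in cfg$bands[[gender]]) {
      lo <- band$age_low
      hi <- band$age_high
      if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
        abort(sprintf("Band for %s must have numeric age_low < age_high.",
                      gender),
              class = "dietscore_schema_error")
      }
      band_lab <- sprintf("(%s, [%g,%g))", gender, lo, hi)
      nuts <- band$nutrients
      unknown <- setdiff(names(nuts), .NUTRIENTS)
      if (length(unknown) > 0) {
        abort(sprintf("Unknown nutrient id(s) %s in band %s.",
                      paste0("'", unknown, "'", collapse = ", "), band_lab),
              class = "dietscore_schema_error")
      }
      missing <- setdiff(.NUTRIENTS, names(nuts))
      if (length(missing) > 0) {
        abort(sprintf("Band %s is missing nutrient(s): %s.", band_lab,
                      paste(missing, collapse = ", ")),
              class = "dietscore_schema_error")
      }
      for (nut in .NUTRIENTS) {
        e <- nuts[[nut]]
        rows[[length(rows) + 1L]] <- tibble::tibble(
          gender = gender, age_low = as.numeric(lo), age_high = as.numeric(hi),
          nutrient = nut,
          mode = e$mode %||% NA_character_,
          dri = as.numeric(e$dri %||% NA_real_),
          amdr_low_pct = as.numeric(e$amdr_low_pct %||% NA_real_),
          amdr_high_pct = as.numeric(e$amdr_high_pct %||% NA_real_),
          who_limit = as.numeric(e$who_limit %||% NA_real_),
          upper_multiple = as.numeric(e$upper_multiple %||% 2),
          tul = as.numeric(e$tul %||% NA_real_),
          source = as.character(e$source %||% NA_character_)
        )
      }
    }
  }
  tab <- dplyr::bind_rows(rows)
  validate_reference_table(tab)
  class(tab) <- c("reference_table", class(tab))
  tab
}

#' @rdname load_reference_table
#' @export
default_references <- function() load_reference_table()

#' Path to a bundled example or configuration file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
dq_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "dietscore")))
  }
  path <- system.file("extdata", file, package = "dietscore")
  if (!nzchar(path)) {
    abort(sprintf("No bundled file '%s'.", file), class = "dietscore_io_error")
  }
  path
}

validate_reference_table <- function(tab) {
  req <- function(cond, msg) {
    if (!all(cond)) abort(msg, class = "dietscore_schema_error")
  }
  req(tab$mode %in% .MODES,
      "Every reference entry must have a valid `mode`.")
  bad_num <- function(x) !is.na(x) & (!is.finite(x) | x <= 0)
  for (col in c("dri", "who_limit", "tul")) {
    if (any(bad_num(tab[[col]]))) {
      i <- which(bad_num(tab[[col]]))[1]
      abort(sprintf("Non-positive %s for %s in band (%s, [%g,%g)).", col,
                    tab$nutrient[i], tab$gender[i], tab$age_low[i],
                    tab$age_high[i]),
            class = "dietscore_schema_error")
    }
  }
  req(is.na(tab$upper_multiple) | tab$upper_multiple >= 1,
      "`upper_multiple` must be >= 1.")
  # mode-specific required fields
  chk_mode <- function(mode, ok) {
    sel <- tab$mode == mode
    if (any(sel & !ok)) {
      i <- which(sel & !ok)[1]
      abort(sprintf(
        "Entry for %s in band (%s, [%g,%g)) lacks the fields required by mode '%s'.",
        tab$nutrient[i], tab$gender[i], tab$age_low[i], tab$age_high[i], mode
      ), class = "dietscore_schema_error")
    }
  }
  chk_mode("adequacy_absolute", !is.na(tab$dri))
  chk_mode("adequacy_amdr", !is.na(tab$amdr_low_pct) & !is.na(tab$amdr_high_pct))
  chk_mode("moderation_absolute", !is.na(tab$who_limit))
  chk_mode("moderation_pct_energy", !is.na(tab$who_limit))
  amdr <- tab$mode == "adequacy_amdr"
  if (any(amdr & tab$amdr_low_pct >= tab$amdr_high_pct)) {
    i <- which(amdr & tab$amdr_low_pct >= tab$amdr_high_pct)[1]
    abort(sprintf("AMDR bounds out of order for %s in band (%s, [%g,%g)).",
                  tab$nutrient[i], tab$gender[i], tab$age_low[i],
                  tab$age_high[i]),
          class = "dietscore_schema_error")
  }
  # band structure: one entry per nutrient per band; bands non-overlapping
  dup <- dplyr::count(tab, .data$gender, .data$age_low, .data$age_high,
                      .data$nutrient)
  if (any(dup$n > 1)) {
    abort("Duplicate nutrient entry within a band.",
          class = "dietscore_schema_error")
  }
  bands <- dplyr::distinct(tab, .data$gender, .data$age_low, .data$age_high)
  for (g in unique(bands$gender)) {
    b <- dplyr::arrange(dplyr::filter(bands, .data$gender == g), .data$age_low)
    if (nrow(b) > 1 && any(b$age_low[-1] < b$age_high[-nrow(b)])) {
      abort(sprintf("Overlapping age bands for gender '%s'.", g),
            class = "dietscore_schema_error")
    }
  }
  invisible(tab)
}

#' Serialize a reference table back to YAML
#'
#' Inverse of [load_reference_table()]; `load -> write -> load` round-trips
#' to an identical table.
#'
#' @param table A `reference_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reference_table <- function(table, path) {
  stopifnot(inherits(table, "reference_table"))
  bands <- list()
  for (g in unique(table$gender)) {
    gtab <- dplyr::filter(table, .data$gender == g)
    glist <- list()
    for (key in unique(paste(gtab$age_low, gtab$age_high))) {
      btab <- gtab[paste(gtab$age_low, gtab$age_high) == key, ]
      nuts <- list()
      for (i in seq_len(nrow(btab))) {
        e <- list(mode = btab$mode[i])
        if (!is.na(btab$dri[i])) e$dri <- btab$dri[i]
        if (!is.na(btab$amdr_low_pct[i])) e$amdr_low_pct <- btab$amdr_low_pct[i]
        if (!is.na(btab$amdr_high_pct[i])) e$amdr_high_pct <- btab$amdr_high_pct[i]
        if (!is.na(btab$who_limit[i])) e$who_limit <- btab$who_limit[i]
        if (btab$upper_multiple[i] != 2) e$upper_multiple <- btab$upper_multiple[i]
        if (!is.na(btab$tul[i])) e$tul <- btab$tul[i]
        if (!is.na(btab$source[i])) e$source <- btab$source[i]
        nuts[[btab$nutrient[i]]] <- e
      }
      glist[[length(glist) + 1L]] <- list(
        age_low = btab$age_low[1], age_high = btab$age_high[1],
        nutrients = nuts
      )
    }
    bands[[g]] <- glist
  }
  yaml::write_yaml(list(version = 1, bands = bands), path)
  invisible(path)
}

#' Look up the reference entries covering a profile
#'
#' Age bands are half-open `[low, high)`: a 31-year-old falls in the band
#' starting at 31, not the one ending there.
#'
#' @param table A `reference_table`.
#' @param profile A [person_profile()].
#' @param nutrient Optional nutrient id; with `NULL`, all sixteen entries of
#'   the covering band are returned.
#' @return A tibble with one row per requested nutrient.
#' @export
#' @examples
#' p <- person_profile(40, "female", fixed_eer_kcal = 2000)
#' lookup_reference(default_references(), p, "calcium")
lookup_reference <- function(table, profile, nutrient = NULL) {
  stopifnot(inherits(table, "reference_table"),
            inherits(profile, "person_profile"))
  if ((profile$pregnant || profile$lactating)) {
    abort(paste0(
      "The default reference bands cover non-pregnant, non-lactating adults; ",
      "scoring pregnant or lactating subjects requires an explicit reference ",
      "band for them."
    ), class = "dietscore_lookup_error")
  }
  hit <- dplyr::filter(
    table, .data$gender == profile$gender,
    .data$age_low <= profile$age_years, profile$age_years < .data$age_high
  )
  if (nrow(hit) == 0) {
    abort(sprintf("No reference band covers %s aged %g.", profile$gender,
                  profile$age_years),
          class = "dietscore_lookup_error")
  }
  if (!is.null(nutrient)) {
    if (!nutrient %in% .NUTRIENTS) {
      abort(sprintf("Unknown nutrient id '%s'.", nutrient),
            class = "dietscore_lookup_error")
    }
    hit <- dplyr::filter(hit, .data$nutrient == !!nutrient)
  }
  hit
}
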