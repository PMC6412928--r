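#' Score daily intakes
#'
#' The workhorse of the package: takes an intake table (one row per
#' subject-day, canonical columns, see [dq_intake_columns()]) and returns one
#' row per subject-day with the sixteen nutrient subscores, the energy score,
#' their combination, and the total:
#'
#' * each nutrient subscore is the piecewise-linear adequacy or moderation
#'   score of the day's amount against the profile's personalised
#'   breakpoints (percent-of-energy nutrients are converted with the day's
#'   own energy first);
#' * `nutrient_mean` is the unweighted arithmetic mean of the sixteen
#'   subscores (an optional `weights` hook exists but defaults to uniform);
#' * `energy_score` compares the day's energy to the profile's estimated
#'   energy requirement (plateau at +/-15%);
#' * `total = nutrient_mean * energy_score`, so a day outside the plausible
#'   energy range scores low no matter how balanced its nutrients are.
#'
#' Days with zero energy are degenerate: the energy score is 0 (so the total
#' is 0) and percent-of-energy subscores are reported as 0.
#'
#' @param intakes A data frame with columns `subject_id`, `day`,
#'   `energy_kcal` and the sixteen canonical nutrient columns.
#' @param profile A [person_profile()].
#' @param references A `reference_table`; default the bundled one.
#' @param allow_missing If `TRUE`, nutrients whose column is absent or `NA`
#'   are dropped from the mean (with a message) instead of raising an error.
#'   The default is strict: any missing nutrient is an error naming it.
#' @param weights Optional named numeric vector of per-nutrient weights
#'   (names from [dq_nutrients()]); defaults to uniform. Normalised to sum
#'   to 1 over the nutrients actually scored.
#' @param scale Output scale: 1 (scores in \[0, 1\], default) or 100.
#' @param ... Passed to [derive_breakpoints()] (`zero_floor`, `zero_ceiling`,
#'   `moderation_ceiling`).
#' @return A tibble with columns `subject_id`, `day`, `energy_kcal`, one
#'   subscore column per nutrient id, `energy_score`, `nutrient_mean`,
#'   `total`.
#' @seealso [score_day()], [score_period()], [percent_dri_profile()]
#' @export
#' @examples
#' p <- person_profile(40, "female", fixed_eer_kcal = 2000)
#' days <- sample_days(diet_archetype("plateau"), p, n_days = 3, seed = 1)
#' score_intakes(days, p)
score_intakes <- function(intakes, profile, references = default_references(),
                          allow_missing = FALSE, weights = NULL, scale = 1,
                          ...) {
  stopifnot(is.data.frame(intakes), inherits(profile, "person_profile"))
  stopifnot(scale %in% c(1, 100))
  if (!"energy_kcal" %in% names(intakes)) {
    abort("Intake table must have an `energy_kcal` column.",
          class = "dietscore_schema_error")
  }
  refs <- lookup_reference(references, profile)
  bps <- derive_breakpoints(refs, ...)
  eer <- compute_eer(profile)

  present <- .NUTRIENTS[.NUTRIENT_COLS[.NUTRIENTS] %in% names(intakes)]
  n <- nrow(intakes)
  has_value <- vapply(present, function(nut) {
    !anyNA(intakes[[.NUTRIENT_COLS[[nut]]]])
  }, logical(1))
  complete <- present[has_value]
  missing <- setdiff(.NUTRIENTS, complete)
  if (length(missing) > 0) {
    if (!allow_missing) {
      abort(sprintf(
        "Intake table is missing nutrient(s): %s. Use `allow_missing = TRUE` to drop them from the mean.",
        paste(missing, collapse = ", ")
      ), class = "dietscore_missing_error")
    }
    inform(sprintf("Dropping %d nutrient(s) from the mean: %s.",
                   length(missing), paste(missing, collapse = ", ")))
  }
  scored <- intersect(.NUTRIENTS, complete)
  if (length(scored) == 0) {
    abort("No scoreable nutrient columns in the intake table.",
          class = "dietscore_missing_error")
  }
  if (is.null(weights)) {
    w <- setNames(rep(1, length(scored)), scored)
  } else {
    stopifnot(is.numeric(weights), !is.null(names(weights)))
    if (!all(scored %in% names(weights))) {
      abort("`weights` must name every scored nutrient.",
            class = "dietscore_config_error")
    }
    w <- weights[scored]
  }
  w <- w / sum(w)

  energy <- intakes$energy_kcal
  if (any(!is.finite(energy) | energy < 0)) {
    abort("`energy_kcal` must be finite and non-negative.",
          class = "dietscore_schema_error")
  }
  zero_e <- energy == 0
  if (any(zero_e)) {
    inform(sprintf("%d day(s) with zero energy: scored 0 (degenerate).",
                   sum(zero_e)))
  }

  sub <- matrix(NA_real_, nrow = n, ncol = length(scored),
                dimnames = list(NULL, scored))
  for (nut in scored) {
    x <- intakes[[.NUTRIENT_COLS[[nut]]]]
    if (any(x < 0)) {
      abort(sprintf("Negative amounts in column `%s`.", .NUTRIENT_COLS[[nut]]),
            class = "dietscore_validation_error")
    }
    bp <- bps[bps$nutrient == nut, ]
    if (bp$pct_energy) {
      val <- numeric(n)
      ok <- !zero_e
      if (any(ok)) val[ok] <- pct_energy(x[ok], nut, energy[ok])
      s <- numeric(n)
      s[ok] <- if (bp$shape == "adequacy") score_adequacy(val[ok], bp)
               else score_moderation(val[ok], bp)
      # zero-energy days: percent-of-energy subscores reported as 0
      sub[, nut] <- s
    } else {
      sub[, nut] <- if (bp$shape == "adequacy") score_adequacy(x, bp)
                    else score_moderation(x, bp)
    }
  }
  nutrient_mean <- as.numeric(sub %*% w)
  energy_score <- score_energy(energy, eer)
  total <- nutrient_mean * energy_score

  out <- tibble::tibble(
    subject_id = if ("subject_id" %in% names(intakes)) intakes$subject_id
                 else rep(NA_character_, n),
    day = if ("day" %in% names(intakes)) intakes$day else seq_len(n),
    energy_kcal = energy
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(sub * scale))
  out$energy_score <- energy_score * scale
  out$nutrient_mean <- nutrient_mean * scale
  # on the 0-100 display scale the product is still taken on [0,1] first
  out$total <- total * scale
  out
}

#' Score a single day
#'
#' Convenience wrapper around [score_intakes()] for one intake record.
#'
#' @param intake A one-row data frame (or named list) with `energy_kcal` and
#'   the canonical nutrient columns.
#' @inheritParams score_intakes
#' @return A one-row tibble, as [score_intakes()].
#' @export
score_day <- function(intake, profile, references = default_references(),
                      ...) {
  if (!is.data.frame(intake)) intake <- tibble::as_tibble(intake)
  stopifnot(nrow(intake) == 1)
  score_intakes(intake, profile, references, ...)
}

#' Score a multi-day period and summarise per subject
#'
#' Scores every day and aggregates per subject as the arithmetic mean and
#' sample standard deviation (n - 1) of the daily totals. The aggregate is
#' the mean of daily totals, not the score of mean intakes.
#'
#' @inheritParams score_intakes
#' @return A list with `days` (the per-day score tibble) and `summary` (one
#'   row per subject: `n_days`, `mean_total`, `sd_total`; `sd_total` is `NA`
#'   for a single day).
#' @export
#' @examples
#' p <- person_profile(40, "female", fixed_eer_kcal = 2000)
#' days <- sample_days(diet_archetype("plateau"), p, n_days = 7, seed = 1)
#' score_period(days, p)$summary
score_period <- function(intakes, profile, references = default_references(),
                         ...) {
  stopifnot(is.data.frame(intakes))
  if (nrow(intakes) == 0) {
    abort("At least one day is required.", class = "dietscore_validation_error")
  }
  days <- score_intakes(intakes, profile, references, ...)
  summary <- days |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mean_total = mean(.data$total),
      sd_total = if (dplyr::n() > 1) sd(.data$total) else NA_real_,
      .groups = "drop"
    )
  list(days = days, summary = summary)
}

#' Percent-of-reference nutrient profile
#'
#' Expresses a period's mean daily intake of each nutrient as a percentage of
#' its reference anchor — the coordinates of the classic percent-DRI
#' scatterplot used to compare menu plans against healthy ranges. Anchors:
#' the DRI for absolute adequacy nutrients; the WHO limit for moderation
#' nutrients (so 100 means "at the limit"); the midpoint of the AMDR range
#' for macronutrients (percent of energy is averaged over days first).
#'
#' @inheritParams score_intakes
#' @return A tibble with `nutrient`, `mean_amount` (canonical unit, or mean
#'   percent of energy for percent-of-energy nutrients), `anchor`,
#'   `anchor_type`, `pct_of_reference`.
#' @export
percent_dri_profile <- function(intakes, profile,
                                references = default_references(), ...) {
  stopifnot(is.data.frame(intakes), nrow(intakes) >= 1)
  refs <- lookup_reference(references, profile)
  bps <- derive_breakpoints(refs, ...)
  energy <- intakes$energy_kcal
  rows <- lapply(.NUTRIENTS, function(nut) {
    col <- .NUTRIENT_COLS[[nut]]
    if (!col %in% names(intakes)) {
      abort(sprintf("Intake table is missing column `%s`.", col),
            class = "dietscore_missing_error")
    }
    x <- intakes[[col]]
    ref <- refs[refs$nutrient == nut, ]
    bp <- bps[bps$nutrient == nut, ]
    if (bp$pct_energy) {
      mean_amt <- mean(pct_energy(x, nut, energy))
    } else {
      mean_amt <- mean(x)
    }
    if (ref$mode == "adequacy_absolute") {
      anchor <- ref$dri; type <- "DRI"
    } else if (ref$mode == "adequacy_amdr") {
      anchor <- (ref$amdr_low_pct + ref$amdr_high_pct) / 2
      type <- "AMDR midpoint"
    } else {
      anchor <- ref$who_limit; type <- "WHO limit"
    }
    tibble::tibble(nutrient = nut, mean_amount = mean_amt, anchor = anchor,
                   anchor_type = type,
                   pct_of_reference = 100 * mean_amt / anchor)
  })
  dplyr::bind_rows(rows)
}
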