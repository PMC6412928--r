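#' Derive piecewise-score breakpoints from reference entries
#'
#' Each nutrient's subscore is a piecewise-linear function of intake, defined
#' by breakpoint abscissae:
#'
#' * **Adequacy** (trapezoid, points A < B <= C < D): zero at or below A,
#'   rising linearly to the full-score plateau on \[B, C\], falling linearly
#'   to zero at or above D. B is the DRI (or the AMDR lower bound), C is
#'   `upper_multiple` x DRI (default 2, i.e. 200% DRI; vitamin C 3) or the
#'   AMDR upper bound, A = `zero_floor` x B, and D = `zero_ceiling` x C,
#'   capped at the TUL when the personalised D would exceed it.
#' * **Moderation** (points B < C): full score from zero intake up to B (the
#'   WHO limit), falling linearly to zero at or above C =
#'   `moderation_ceiling` x B.
#'
#' AMDR and percent-of-energy moderation breakpoints are expressed in percent
#' of energy; `pct_energy` in the result tells the scorer to convert intake
#' via [pct_energy()] first.
#'
#' @param refs A `reference_table` (or any subset of its rows, e.g. from
#'   [lookup_reference()]).
#' @param eer_kcal Daily energy requirement in kcal; only needed so callers
#'   can carry it alongside (the breakpoints themselves are energy-free, as
#'   percent-of-energy nutrients stay on the percent scale).
#' @param zero_floor Multiple of B at which the adequacy score reaches zero
#'   from below (default 0.5, i.e. 50% DRI).
#' @param zero_ceiling Multiple of C at which the adequacy score reaches zero
#'   from above (default 1.5).
#' @param moderation_ceiling Multiple of the WHO limit at which the
#'   moderation score reaches zero (default 1.5).
#' @return A tibble with columns `nutrient`, `shape` (`"adequacy"` /
#'   `"moderation"`), `a`, `b`, `c`, `d` (`a`, `d` are `NA` for moderation)
#'   and `pct_energy` (logical).
#' @export
#' @examples
#' p <- person_profile(40, "female", fixed_eer_kcal = 2000)
#' derive_breakpoints(lookup_reference(default_references(), p))
derive_breakpoints <- function(refs, eer_kcal = NULL, zero_floor = 0.5,
                               zero_ceiling = 1.5, moderation_ceiling = 1.5) {
  stopifnot(is.data.frame(refs), nrow(refs) >= 1)
  stopifnot(zero_floor > 0, zero_floor < 1, zero_ceiling > 1,
            moderation_ceiling > 1)
  one <- function(i) {
    mode <- refs$mode[i]
    nut <- refs$nutrient[i]
    if (mode == "adequacy_absolute") {
      b <- refs$dri[i]
      c_ <- refs$upper_multiple[i] * b
      a <- zero_floor * b
      d <- zero_ceiling * c_
      tul <- refs$tul[i]
      if (!is.na(tul) && tul < d) {
        if (tul <= c_) {
          abort(sprintf(
            "TUL for %s (%g) is at or below the upper healthy range (%g); breakpoints would be degenerate.",
            nut, tul, c_
          ), class = "dietscore_breakpoint_error")
        }
        d <- tul
      }
      tibble::tibble(nutrient = nut, shape = "adequacy", a = a, b = b, c = c_,
                     d = d, pct_energy = FALSE)
    } else if (mode == "adequacy_amdr") {
      b <- refs$amdr_low_pct[i]
      c_ <- refs$amdr_high_pct[i]
      tibble::tibble(nutrient = nut, shape = "adequacy", a = zero_floor * b,
                     b = b, c = c_, d = zero_ceiling * c_, pct_energy = TRUE)
    } else {
      b <- refs$who_limit[i]
      tibble::tibble(nutrient = nut, shape = "moderation", a = NA_real_,
                     b = b, c = moderation_ceiling * b, d = NA_real_,
                     pct_energy = mode == "moderation_pct_energy")
    }
  }
  out <- dplyr::bind_rows(lapply(seq_len(nrow(refs)), one))
  bad <- out$shape == "adequacy" &
    !(out$a < out$b & out$b <= out$c & out$c < out$d)
  if (any(bad)) {
    abort(sprintf("Degenerate adequacy breakpoints for %s.",
                  paste(out$nutrient[bad], collapse = ", ")),
          class = "dietscore_breakpoint_error")
  }
  out
}

bp_as_list <- function(bp) {
  if (is.data.frame(bp)) {
    stopifnot(nrow(bp) == 1)
    as.list(bp)
  } else {
    as.list(bp)
  }
}

#' Piecewise adequacy score
#'
#' Trapezoid score over breakpoints A < B <= C < D: 0 for `x <= a` or
#' `x >= d`, 1 on `[b, c]`, linear in between; continuous everywhere.
#'
#' @param x Intake amount(s), same unit as the breakpoints; vectorized.
#' @param bp Breakpoints: a one-row data frame or named list/vector with
#'   `a`, `b`, `c`, `d`.
#' @return Score(s) in \[0, 1\].
#' @export
#' @examples
#' score_adequacy(c(500, 750, 1500, 2500, 3000), list(a = 500, b = 1000, c = 2000, d = 3000))
score_adequacy <- function(x, bp) {
  bp <- bp_as_list(bp)
  a <- bp$a; b <- bp$b; c_ <- bp$c; d <- bp$d
  stopifnot(is.finite(a), is.finite(b), is.finite(c_), is.finite(d),
            a < b, b <= c_, c_ < d)
  out <- numeric(length(x))
  rise <- x > a & x < b
  fall <- x > c_ & x < d
  out[x >= b & x <= c_] <- 1
  out[rise] <- (x[rise] - a) / (b - a)
  out[fall] <- (d - x[fall]) / (d - c_)
  out
}

#' Piecewise moderation score
#'
#' Full score up to the limit B, declining linearly to zero at or above C.
#'
#' @param x Intake amount(s); vectorized.
#' @param bp Breakpoints with `b` and `c`.
#' @return Score(s) in \[0, 1\].
#' @export
#' @examples
#' score_moderation(c(0, 2500, 3000), list(b = 2000, c = 3000))
score_moderation <- function(x, bp) {
  bp <- bp_as_list(bp)
  b <- bp$b; c_ <- bp$c
  stopifnot(is.finite(b), is.finite(c_), b >= 0, b < c_)
  out <- numeric(length(x))
  out[x <= b] <- 1
  mid <- x > b & x < c_
  out[mid] <- (c_ - x[mid]) / (c_ - b)
  out
}

#' Energy score
#'
#' Adequacy-shaped score around the estimated energy requirement: plateau on
#' `[0.85, 1.15] x EER` (a +/-15% tolerance), zero at or below `0.5 x EER`
#' (implausibly low) and at or above `1.5 x EER` (excessive).
#'
#' @param energy_kcal Daily energy intake(s), kcal; vectorized.
#' @param eer_kcal Estimated energy requirement, kcal (> 0).
#' @return Score(s) in \[0, 1\].
#' @export
#' @examples
#' score_energy(c(1000, 1350, 2000, 2300), eer_kcal = 2000)
score_energy <- function(energy_kcal, eer_kcal) {
  stopifnot(is.numeric(eer_kcal), length(eer_kcal) == 1, eer_kcal > 0)
  score_adequacy(energy_kcal, list(a = 0.5 * eer_kcal, b = 0.85 * eer_kcal,
                                   c = 1.15 * eer_kcal, d = 1.5 * eer_kcal))
}

#' Convert a macronutrient amount to percent of energy
#'
#' Uses the Atwater factors: 4 kcal/g for carbohydrate, protein and added
#' sugars; 9 kcal/g for total and saturated fat.
#'
#' @param amount_g Amount(s) in grams; vectorized.
#' @param nutrient One of `"carbohydrate"`, `"protein"`, `"added_sugar"`,
#'   `"fat_total"`, `"fat_sat"`.
#' @param energy_kcal Total energy of the day, kcal (> 0).
#' @return Percent of energy.
#' @export
#' @examples
#' pct_energy(250, "carbohydrate", 2000)  # 50
pct_energy <- function(amount_g, nutrient, energy_kcal) {
  if (!nutrient %in% names(.ATWATER)) {
    abort(sprintf("No Atwater factor for nutrient '%s'.", nutrient),
          class = "dietscore_config_error")
  }
  if (!is.numeric(energy_kcal) || any(energy_kcal <= 0)) {
    abort("Percent of energy is undefined when energy is zero.",
          class = "dietscore_zero_energy_error")
  }
  100 * amount_g * .ATWATER[[nutrient]] / energy_kcal
}
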