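#' Create a person profile
#'
#' A profile identifies who is being scored: age, gender, and either the
#' anthropometric inputs of the IOM adult estimated-energy-requirement (EER)
#' equations (weight, height, physical-activity coefficient) or a fixed
#' energy requirement that bypasses the equations. Pregnant or lactating
#' subjects are excluded from scoring with the default reference table, whose
#' bands cover non-pregnant, non-lactating adults only.
#'
#' @param age_years Age in years, > 0.
#' @param gender `"female"` or `"male"`.
#' @param weight_kg,height_m Body weight (kg) and height (m); required
#'   together with `pa_coefficient` unless `fixed_eer_kcal` is given.
#' @param pa_coefficient IOM physical-activity coefficient (dimensionless;
#'   1.0 sedentary up to ~1.45/1.48 very active).
#' @param fixed_eer_kcal Optional fixed daily energy requirement (kcal);
#'   overrides the EER equations when present.
#' @param pregnant,lactating Logical flags; default `FALSE`.
#'
#' @return An object of class `person_profile`.
#' @seealso [compute_eer()]
#' @export
#' @examples
#' person_profile(40, "female", fixed_eer_kcal = 2000)
#' person_profile(40, "female", weight_kg = 65, height_m = 1.63,
#'                pa_coefficient = 1.12)
person_profile <- function(age_years, gender = c("female", "male"),
                           weight_kg = NULL, height_m = NULL,
                           pa_coefficient = NULL, fixed_eer_kcal = NULL,
                           pregnant = FALSE, lactating = FALSE) {
  gender <- match.arg(gender)
  if (!is.numeric(age_years) || length(age_years) != 1L || is.na(age_years) ||
      age_years <= 0) {
    abort("`age_years` must be a single positive number.",
          class = "dietscore_profile_error")
  }
  chk_pos <- function(x, nm) {
    if (!is.null(x) && (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)) {
      abort(sprintf("`%s` must be a single positive number when supplied.", nm),
            class = "dietscore_profile_error")
    }
  }
  chk_pos(weight_kg, "weight_kg")
  chk_pos(height_m, "height_m")
  chk_pos(pa_coefficient, "pa_coefficient")
  chk_pos(fixed_eer_kcal, "fixed_eer_kcal")
  has_eq <- !is.null(weight_kg) && !is.null(height_m) && !is.null(pa_coefficient)
  if (is.null(fixed_eer_kcal) && !has_eq) {
    abort(paste0(
      "A profile needs either `fixed_eer_kcal` or all of `weight_kg`, ",
      "`height_m` and `pa_coefficient`."
    ), class = "dietscore_profile_error")
  }
  structure(
    list(
      age_years = as.numeric(age_years), gender = gender,
      weight_kg = weight_kg, height_m = height_m,
      pa_coefficient = pa_coefficient, fixed_eer_kcal = fixed_eer_kcal,
      pregnant = isTRUE(pregnant), lactating = isTRUE(lactating)
    ),
    class = "person_profile"
  )
}

#' @export
print.person_profile <- function(x, ...) {
  cat(sprintf("<person_profile> %s, %g y", x$gender, x$age_years))
  if (!is.null(x$fixed_eer_kcal)) {
    cat(sprintf(", fixed EER %g kcal", x$fixed_eer_kcal))
  } else {
    cat(sprintf(", %g kg, %g m, PA %g", x$weight_kg, x$height_m,
                x$pa_coefficient))
  }
  if (x$pregnant) cat(", pregnant")
  if (x$lactating) cat(", lactating")
  cat("\n")
  invisible(x)
}

#' Estimated energy requirement (EER)
#'
#' Returns the profile's fixed energy requirement when one is set; otherwise
#' evaluates the IOM (2002) adult EER equations:
#' \deqn{EER_{male} = 662 - 9.53\,age + PA\,(15.91\,wt + 539.6\,ht)}
#' \deqn{EER_{female} = 354 - 6.91\,age + PA\,(9.36\,wt + 726\,ht)}
#' with age in years, weight in kg, height in m. The adult equations are the
#' only ones bundled; any other age class can still be scored by supplying
#' `fixed_eer_kcal`.
#'
#' @param profile A [person_profile()].
#' @return Daily energy requirement in kcal (a single positive number).
#' @export
#' @examples
#' compute_eer(person_profile(40, "female", fixed_eer_kcal = 2000))
#' compute_eer(person_profile(40, "female", weight_kg = 65, height_m = 1.63,
#'                            pa_coefficient = 1.12))
compute_eer <- function(profile) {
  stopifnot(inherits(profile, "person_profile"))
  if (!is.null(profile$fixed_eer_kcal)) {
    return(profile$fixed_eer_kcal)
  }
  if (is.null(profile$weight_kg) || is.null(profile$height_m) ||
      is.null(profile$pa_coefficient)) {
    abort("EER equation inputs missing and no `fixed_eer_kcal` override set.",
          class = "dietscore_config_error")
  }
  eer <- if (profile$gender == "male") {
    662 - 9.53 * profile$age_years +
      profile$pa_coefficient * (15.91 * profile$weight_kg + 539.6 * profile$height_m)
  } else {
    354 - 6.91 * profile$age_years +
      profile$pa_coefficient * (9.36 * profile$weight_kg + 726 * profile$height_m)
  }
  if (!is.finite(eer) || eer <= 0) {
    abort("EER evaluated to a non-positive value; check the profile inputs.",
          class = "dietscore_config_error")
  }
  eer
}
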