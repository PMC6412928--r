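# Independent oracles: literal, pointwise translations of the verbal scoring
# rules and textbook statistic formulas, kept deliberately separate from the
# package's vectorised implementations.

# Trapezoid rule, stated case by case: zero at or below A and at or above D,
# full score from B to C, straight lines in between.
oracle_adequacy <- function(x, a, b, c, d) {
  vapply(x, function(xi) {
    if (xi <= a) return(0)
    if (xi >= d) return(0)
    if (xi >= b && xi <= c) return(1)
    if (xi < b) return((xi - a) / (b - a))
    (d - xi) / (d - c)
  }, numeric(1))
}

# Moderation rule: full score at or below B, zero at or above C.
oracle_moderation <- function(x, b, c) {
  vapply(x, function(xi) {
    if (xi <= b) return(1)
    if (xi >= c) return(0)
    (c - xi) / (c - b)
  }, numeric(1))
}

# Cronbach's alpha through the average-covariance route (standardized-item
# free form): alpha = k * cbar / (vbar + (k - 1) * cbar), a different
# algebraic path from the variance-ratio formula the package uses.
oracle_alpha <- function(m) {
  k <- ncol(m)
  S <- stats::cov(m)
  vbar <- mean(diag(S))
  cbar <- mean(S[upper.tri(S)])
  k * cbar / (vbar + (k - 1) * cbar)
}

default_profile <- function() {
  person_profile(40, "female", fixed_eer_kcal = 2000)
}

# Cache the bundled reference table across tests.
refs_cache <- new.env(parent = emptyenv())
test_refs <- function() {
  if (is.null(refs_cache$tab)) refs_cache$tab <- default_references()
  refs_cache$tab
}

atwater_of <- function(nut) {
  c(carbohydrate = 4, protein = 4, added_sugar = 4,
    fat_total = 9, fat_sat = 9)[[nut]]
}

# A day whose every nutrient sits at its plateau midpoint: by construction
# every nutrient subscore is 1. Percent-of-energy nutrients are laid out
# relative to `energy` (default: the EER), so choosing a different energy
# moves only the energy score.
perfect_day <- function(profile = default_profile(),
                        references = test_refs(),
                        energy = compute_eer(profile)) {
  bps <- derive_breakpoints(lookup_reference(references, profile))
  cols <- dq_intake_columns()
  day <- tibble::tibble(subject_id = "S1", day = 1L, energy_kcal = energy)
  for (i in seq_len(nrow(bps))) {
    nut <- bps$nutrient[i]
    mid <- if (bps$shape[i] == "adequacy") (bps$b[i] + bps$c[i]) / 2
           else bps$b[i] / 2
    amt <- if (bps$pct_energy[i]) mid / 100 * energy / atwater_of(nut)
           else mid
    day[[cols[[nut]]]] <- amt
  }
  day
}
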