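#' Diet archetypes for synthetic intake generation
#'
#' An archetype describes where a synthetic diet sits relative to each
#' nutrient's healthy range, in breakpoint-anchored coordinates: each
#' nutrient gets a sampling band `[lo, hi]` whose endpoints are expressions
#' like `"0.5*A"`, `"B"`, `"1.2*C"` over the anchors of its piecewise score
#' (`A`, `B`, `C`, `D` for adequacy; `B`, `C` for moderation), plus an
#' energy band in multiples of the EER, a lognormal day-to-day jitter
#' (`noise_cv`), and an optional between-nutrient correlation structure
#' (compound-symmetric clusters, applied through a Gaussian copula).
#'
#' Bundled archetypes (see `inst/extdata/archetypes.yaml`, all synthetic):
#' `"plateau"` (everything in range), `"deficient"`, `"excess"`,
#' `"nhanes_like"` (typical-US shortfall pattern with correlated
#' vegetable- and dairy-borne nutrient clusters), `"myplate_like"` and
#' `"dash_like"` (exemplary-menu-style high-quality weeks).
#'
#' @param name Name of a bundled archetype, or any name for a custom one
#'   when `bands`/`energy_band` are supplied.
#' @param bands Named list of `c(lo, hi)` anchor-expression bands per
#'   nutrient; nutrients not listed use `default_adequacy` /
#'   `default_moderation`.
#' @param energy_band Length-2 numeric (or string) vector, multiples of EER.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   day-to-day jitter (0 disables it).
#' @param correlation Either `NULL`, a full positive-definite correlation
#'   matrix with nutrient dimnames, or a list
#'   `list(clusters = list(list(nutrients = ..., rho = ...), ...))`.
#' @param default_adequacy,default_moderation Fallback bands by shape.
#' @param path Path of the archetype YAML config (bundled file by default).
#' @return An object of class `diet_archetype`.
#' @seealso [sample_days()], [sample_population()]
#' @export
#' @examples
#' diet_archetype("plateau")
#' diet_archetype("custom", bands = list(fiber = c("0", "A")),
#'                energy_band = c(1, 1), noise_cv = 0)
diet_archetype <- function(name, bands = NULL, energy_band = NULL,
                           noise_cv = NULL, correlation = NULL,
                           default_adequacy = c("B", "C"),
                           default_moderation = c("0", "B"),
                           path = dq_example("archetypes.yaml")) {
  cfg <- NULL
  if (is.null(bands) && is.null(energy_band)) {
    all_cfg <- yaml::read_yaml(path)$archetypes
    if (!name %in% names(all_cfg)) {
      abort(sprintf("Unknown archetype '%s'. Available: %s.", name,
                    paste(names(all_cfg), collapse = ", ")),
            class = "dietscore_archetype_error")
    }
    cfg <- all_cfg[[name]]
    bands <- cfg$bands %||% list()
    energy_band <- cfg$energy_band
    noise_cv <- noise_cv %||% cfg$noise_cv %||% 0
    correlation <- correlation %||% cfg$correlation
    if (!is.null(cfg$default)) {
      default_adequacy <- unlist(cfg$default$adequacy) %||% default_adequacy
      default_moderation <- unlist(cfg$default$moderation) %||% default_moderation
    }
  }
  noise_cv <- noise_cv %||% 0
  stopifnot(is.numeric(noise_cv), noise_cv >= 0)
  energy_band <- as.numeric(energy_band)
  if (length(energy_band) != 2 || anyNA(energy_band) ||
      energy_band[1] < 0 || energy_band[1] > energy_band[2]) {
    abort("`energy_band` must be two non-negative numbers lo <= hi.",
          class = "dietscore_archetype_error")
  }
  unknown <- setdiff(names(bands), .NUTRIENTS)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown nutrient(s) in archetype bands: %s.",
                  paste(unknown, collapse = ", ")),
          class = "dietscore_archetype_error")
  }
  structure(
    list(name = name, bands = bands, energy_band = energy_band,
         noise_cv = noise_cv, correlation = correlation,
         default_adequacy = default_adequacy,
         default_moderation = default_moderation,
         description = cfg$description %||% NA_character_),
    class = "diet_archetype"
  )
}

#' @export
print.diet_archetype <- function(x, ...) {
  cat(sprintf("<diet_archetype> %s (noise_cv %g, energy %g-%g x EER)\n",
              x$name, x$noise_cv, x$energy_band[1], x$energy_band[2]))
  invisible(x)
}

# Evaluate an "m*X" anchor expression against one nutrient's breakpoints.
anchor_value <- function(expr, bp) {
  expr <- trimws(as.character(expr))
  m <- regmatches(expr, regexec("^([0-9.]+\\*)?([ABCD])$|^([0-9.]+)$", expr))[[1]]
  if (length(m) == 0 || !nzchar(m[1])) {
    abort(sprintf("Cannot parse band expression '%s'.", expr),
          class = "dietscore_archetype_error")
  }
  if (nzchar(m[4])) return(as.numeric(m[4]))  # bare number (e.g. "0")
  coef <- if (nzchar(m[2])) as.numeric(sub("\\*$", "", m[2])) else 1
  anchors <- if (bp$shape == "adequacy") {
    c(A = bp$a, B = bp$b, C = bp$c, D = bp$d)
  } else {
    c(A = 0, B = bp$b, C = bp$c, D = 2 * bp$c)
  }
  coef * anchors[[m[3]]]
}

archetype_correlation <- function(correlation) {
  k <- length(.NUTRIENTS)
  R <- diag(k)
  dimnames(R) <- list(.NUTRIENTS, .NUTRIENTS)
  if (is.null(correlation)) return(R)
  if (is.matrix(correlation)) {
    stopifnot(identical(dim(correlation), dim(R)))
    R <- correlation
  } else {
    for (cl in correlation$clusters) {
      nuts <- unlist(cl$nutrients)
      bad <- setdiff(nuts, .NUTRIENTS)
      if (length(bad) > 0) {
        abort(sprintf("Unknown nutrient(s) in correlation cluster: %s.",
                      paste(bad, collapse = ", ")),
              class = "dietscore_archetype_error")
      }
      R[nuts, nuts] <- cl$rho
      diag(R) <- 1
    }
  }
  if (!isSymmetric(R) || min(eigen(R, symmetric = TRUE,
                                   only.values = TRUE)$values) <= 1e-10) {
    abort("Correlation matrix must be symmetric positive-definite.",
          class = "dietscore_archetype_error")
  }
  R
}

# Core sampler; uses the current RNG stream (callers own the seeding).
sample_days_impl <- function(archetype, profile, references, n_days,
                             subject_id) {
  refs <- lookup_reference(references, profile)
  bps <- derive_breakpoints(refs)
  eer <- compute_eer(profile)
  k <- length(.NUTRIENTS)

  lo <- hi <- setNames(numeric(k), .NUTRIENTS)
  for (nut in .NUTRIENTS) {
    bp <- bps[bps$nutrient == nut, ]
    band <- archetype$bands[[nut]] %||%
      (if (bp$shape == "adequacy") archetype$default_adequacy
       else archetype$default_moderation)
    lo[nut] <- anchor_value(band[[1]], bp)
    hi[nut] <- anchor_value(band[[2]], bp)
    if (!is.finite(lo[nut]) || !is.finite(hi[nut]) || lo[nut] > hi[nut] ||
        lo[nut] < 0) {
      abort(sprintf("Infeasible sampling band for %s in archetype '%s'.",
                    nut, archetype$name),
            class = "dietscore_generation_error")
    }
  }

  R <- archetype_correlation(archetype$correlation)
  z <- MASS::mvrnorm(n_days, mu = rep(0, k), Sigma = R)
  if (n_days == 1) z <- matrix(z, nrow = 1)
  u <- stats::pnorm(z)
  colnames(u) <- .NUTRIENTS

  energy <- eer * stats::runif(n_days, archetype$energy_band[1],
                               archetype$energy_band[2])

  sigma <- sqrt(log(1 + archetype$noise_cv^2))
  jitter <- function(n) {
    if (sigma == 0) rep(1, n) else stats::rlnorm(n, -sigma^2 / 2, sigma)
  }

  out <- tibble::tibble(subject_id = subject_id, day = seq_len(n_days),
                        energy_kcal = energy)
  for (nut in .NUTRIENTS) {
    val <- (lo[nut] + u[, nut] * (hi[nut] - lo[nut])) * jitter(n_days)
    bp <- bps[bps$nutrient == nut, ]
    if (bp$pct_energy) {
      # band sampled on the percent-of-energy scale; convert to grams
      val <- val / 100 * energy / .ATWATER[[nut]]
    }
    out[[.NUTRIENT_COLS[[nut]]]] <- val
  }
  out
}

#' Sample synthetic daily intakes for one subject
#'
#' Draws `n_days` 24-hour intake records from an archetype, relative to the
#' profile's personalised breakpoints: uniform draws inside each nutrient's
#' band (correlated across nutrients through a Gaussian copula when the
#' archetype specifies clusters), multiplied by lognormal day-to-day jitter
#' with mean 1, with energy drawn in `energy_band x EER`. Fully reproducible
#' given `(seed, archetype, profile)`.
#'
#' @param archetype A [diet_archetype()].
#' @param profile A [person_profile()].
#' @param references A `reference_table`.
#' @param n_days Number of days, >= 1.
#' @param seed Integer seed.
#' @param subject_id Subject identifier for the output table.
#' @return A canonical intake tibble (`subject_id`, `day`, `energy_kcal`,
#'   sixteen nutrient columns).
#' @export
#' @examples
#' p <- person_profile(40, "female", fixed_eer_kcal = 2000)
#' sample_days(diet_archetype("plateau"), p, n_days = 2, seed = 42)
sample_days <- function(archetype, profile,
                        references = default_references(), n_days, seed,
                        subject_id = "S1") {
  stopifnot(inherits(archetype, "diet_archetype"), n_days >= 1)
  withr::with_seed(as.integer(seed),
                   sample_days_impl(archetype, profile, references,
                                    as.integer(n_days), subject_id))
}

#' Sample a synthetic cohort from a mixture of archetypes
#'
#' Assigns each subject an archetype drawn from the (normalised) mixture
#' weights, then samples that subject's days. The assigned archetype name is
#' kept as an `archetype` column for ground-truth checks.
#'
#' @param archetypes A list of [diet_archetype()] objects (or a single one).
#' @param weights Positive mixture weights, one per archetype; normalised
#'   internally. Default equal weights.
#' @param profile,references As in [sample_days()].
#' @param n_subjects,n_days Cohort dimensions, >= 1.
#' @param seed Integer seed governing both the assignment and the sampling.
#' @return A canonical intake tibble with an extra `archetype` column.
#' @export
#' @examples
#' p <- person_profile(40, "female", fixed_eer_kcal = 2000)
#' mix <- list(diet_archetype("plateau"), diet_archetype("deficient"))
#' tab <- sample_population(mix, weights = c(1, 1), profile = p,
#'                          n_subjects = 4, n_days = 2, seed = 7)
#' table(tab$archetype) / 2
sample_population <- function(archetypes, weights = NULL, profile,
                              references = default_references(),
                              n_subjects, n_days, seed) {
  if (inherits(archetypes, "diet_archetype")) archetypes <- list(archetypes)
  if (length(archetypes) == 0) {
    abort("Empty archetype mixture.", class = "dietscore_generation_error")
  }
  stopifnot(all(vapply(archetypes, inherits, logical(1), "diet_archetype")))
  if (n_subjects < 1 || n_days < 1) {
    abort("`n_subjects` and `n_days` must be >= 1.",
          class = "dietscore_generation_error")
  }
  weights <- weights %||% rep(1, length(archetypes))
  if (length(weights) != length(archetypes) || any(weights <= 0)) {
    abort("`weights` must be positive, one per archetype.",
          class = "dietscore_generation_error")
  }
  weights <- weights / sum(weights)
  withr::with_seed(as.integer(seed), {
    pick <- sample.int(length(archetypes), n_subjects, replace = TRUE,
                       prob = weights)
    width <- nchar(as.character(n_subjects))
    tabs <- lapply(seq_len(n_subjects), function(i) {
      id <- sprintf(paste0("S%0", width, "d"), i)
      tab <- sample_days_impl(archetypes[[pick[i]]], profile, references,
                              as.integer(n_days), id)
      tab$archetype <- archetypes[[pick[i]]]$name
      tab
    })
    dplyr::bind_rows(tabs)
  })
}
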