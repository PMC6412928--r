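test_that("a day at every plateau midpoint with energy at the EER scores 1", {
  p <- default_profile()
  day <- perfect_day(p)
  sc <- score_day(day, p, test_refs())
  expect_equal(sc$total, 1)
  expect_equal(sc$nutrient_mean, 1)
  expect_equal(sc$energy_score, 1)
  expect_true(all(unlist(sc[dq_nutrients()]) == 1))
})

test_that("implausibly low energy forces the total to zero", {
  p <- default_profile()
  day <- perfect_day(p, energy = 0.5 * compute_eer(p))
  sc <- score_day(day, p, test_refs())
  expect_equal(sc$energy_score, 0)
  expect_equal(sc$total, 0)
  expect_equal(sc$nutrient_mean, 1)  # nutrient quality unaffected
})

test_that("the total is the unweighted mean of subscores times the energy score", {
  p <- default_profile()
  day <- perfect_day(p)
  # push 8 of the 16 nutrients to a zero subscore: the three moderation
  # nutrients past their ceilings and five adequacy nutrients below A
  bps <- derive_breakpoints(lookup_reference(test_refs(), p))
  cols <- dq_intake_columns()
  eer <- compute_eer(p)
  zero_mod <- c("sodium", "fat_sat", "added_sugar")
  zero_adq <- c("fiber", "potassium", "vit_d", "vit_e", "iron")
  for (nut in zero_mod) {
    bp <- bps[bps$nutrient == nut, ]
    val <- bp$c * 1.2
    if (bp$pct_energy) val <- val / 100 * eer / atwater_of(nut)
    day[[cols[[nut]]]] <- val
  }
  for (nut in zero_adq) {
    bp <- bps[bps$nutrient == nut, ]
    day[[cols[[nut]]]] <- bp$a * 0.5
  }
  sc <- score_day(day, p, test_refs())
  expect_equal(sc$nutrient_mean, 0.5, tolerance = 1e-12)
  expect_equal(sc$total, 0.5, tolerance = 1e-12)
  expect_equal(sc$total, sc$nutrient_mean * sc$energy_score,
               tolerance = 1e-12)
})

test_that("scoring is invariant to nutrient column order", {
  p <- default_profile()
  days <- sample_days(diet_archetype("nhanes_like"), p, test_refs(),
                      n_days = 4, seed = 11)
  shuffled <- days[, c(1:3, 3 + sample(16))]
  expect_equal(score_intakes(days, p, test_refs())$total,
               score_intakes(shuffled, p, test_refs())$total)
})

test_that("the 0-100 display scale multiplies all outputs by 100", {
  p <- default_profile()
  days <- sample_days(diet_archetype("nhanes_like"), p, test_refs(),
                      n_days = 3, seed = 5)
  s1 <- score_intakes(days, p, test_refs())
  s100 <- score_intakes(days, p, test_refs(), scale = 100)
  expect_equal(s100$total, s1$total * 100)
  expect_equal(s100$calcium, s1$calcium * 100)
})

test_that("missing nutrients error under the strict policy and can be dropped", {
  p <- default_profile()
  day <- perfect_day(p)
  day$fiber_g <- NULL
  expect_error(score_day(day, p, test_refs()), "fiber",
               class = "dietscore_missing_error")
  expect_message(
    sc <- score_day(day, p, test_refs(), allow_missing = TRUE),
    "fiber"
  )
  expect_equal(sc$total, 1)  # remaining 15 subscores are all 1
  expect_false("fiber" %in% names(sc))
})

test_that("zero-energy days are scored zero with percent-energy subscores zero", {
  p <- default_profile()
  day <- perfect_day(p)
  day$energy_kcal <- 0
  expect_message(sc <- score_day(day, p, test_refs()), "zero energy")
  expect_equal(sc$total, 0)
  expect_equal(sc$carbohydrate, 0)
  expect_equal(sc$fat_sat, 0)
  expect_equal(sc$calcium, 1)  # absolute-unit nutrients unaffected
})

test_that("period aggregation is the mean and sample SD of daily totals", {
  p <- default_profile()
  # engineer daily totals of 0.4 and 0.6 through the energy score: with all
  # subscores at 1, energy on the rising edge a=1000, b=1700 gives
  # total = (e - 1000)/700
  two <- dplyr::bind_rows(perfect_day(p, energy = 1000 + 0.4 * 700),
                          perfect_day(p, energy = 1000 + 0.6 * 700))
  two$day <- 1:2
  res <- score_period(two, p, test_refs())
  expect_equal(res$days$total, c(0.4, 0.6), tolerance = 1e-12)
  expect_equal(res$summary$mean_total, 0.5, tolerance = 1e-12)
  expect_equal(res$summary$sd_total, 0.1414214, tolerance = 1e-6)

  one <- score_period(perfect_day(p), p, test_refs())
  expect_equal(one$summary$mean_total, 1)
  expect_true(is.na(one$summary$sd_total))
  expect_error(score_period(perfect_day(p)[0, ], p, test_refs()),
               class = "dietscore_validation_error")
})

test_that("percent-of-reference anchors follow the mode", {
  p <- default_profile()
  day <- perfect_day(p)
  day$calcium_mg <- 1000
  day$vit_c_mg <- 225
  day$sodium_mg <- 2000
  prof <- percent_dri_profile(day, p, test_refs())
  get <- function(nut) prof$pct_of_reference[prof$nutrient == nut]
  expect_equal(get("calcium"), 100)
  expect_equal(get("vit_c"), 300)
  expect_equal(get("sodium"), 100)
  expect_equal(prof$anchor_type[prof$nutrient == "carbohydrate"],
               "AMDR midpoint")
})
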