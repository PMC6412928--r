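test_that("sampling is deterministic in the seed", {
  p <- default_profile()
  arch <- diet_archetype("nhanes_like")
  a <- sample_days(arch, p, test_refs(), n_days = 5, seed = 33)
  b <- sample_days(arch, p, test_refs(), n_days = 5, seed = 33)
  c <- sample_days(arch, p, test_refs(), n_days = 5, seed = 34)
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c)))
})

test_that("plateau days score exactly 1 and deficient adequacy nutrients 0", {
  p <- default_profile()
  plat <- sample_days(diet_archetype("plateau"), p, test_refs(),
                      n_days = 50, seed = 1)
  sc <- score_intakes(plat, p, test_refs())
  expect_true(all(sc$total == 1))

  def <- sample_days(diet_archetype("deficient"), p, test_refs(),
                     n_days = 20, seed = 2)
  scd <- score_intakes(def, p, test_refs())
  adequacy <- setdiff(dq_nutrients(), c("sodium", "fat_sat", "added_sugar"))
  expect_true(all(unlist(scd[adequacy]) == 0))
  expect_equal(scd$energy_score, rep(1, 20))  # energy pinned at the EER
})

test_that("infeasible or malformed bands are rejected", {
  p <- default_profile()
  upside_down <- diet_archetype("custom", bands = list(fiber = c("C", "B")),
                                energy_band = c(1, 1), noise_cv = 0)
  expect_error(sample_days(upside_down, p, test_refs(), n_days = 1, seed = 1),
               class = "dietscore_generation_error")
  expect_error(diet_archetype("no_such_archetype"),
               class = "dietscore_archetype_error")
  expect_error(diet_archetype("x", bands = list(unobtainium = c("B", "C")),
                              energy_band = c(1, 1)),
               class = "dietscore_archetype_error")
})

test_that("mixture cohorts carry labels and mix means as expected", {
  p <- default_profile()
  mix <- list(diet_archetype("plateau"), diet_archetype("deficient"))
  tab <- sample_population(mix, weights = c(1, 1), profile = p,
                           references = test_refs(), n_subjects = 60,
                           n_days = 1, seed = 17)
  expect_equal(nrow(tab), 60)
  labels <- dplyr::distinct(tab, subject_id, archetype)
  expect_equal(nrow(labels), 60)  # one archetype per subject
  expect_setequal(unique(labels$archetype), c("plateau", "deficient"))

  sc <- score_intakes(tab[setdiff(names(tab), "archetype")], p, test_refs())
  sc$archetype <- tab$archetype
  means <- tapply(sc$total, sc$archetype, mean)
  expect_equal(unname(means["plateau"]), 1)
  # deficient days keep only the three moderation subscores
  expect_equal(unname(means["deficient"]), 3 / 16, tolerance = 1e-9)
  # cohort mean sits between the two archetype means, near the mixture value
  frac <- mean(tab$archetype == "plateau")
  expect_equal(mean(sc$total), frac * 1 + (1 - frac) * 3 / 16,
               tolerance = 1e-9)
})

test_that("a single-archetype mixture degenerates to per-subject sampling", {
  p <- default_profile()
  tab <- sample_population(diet_archetype("plateau"), profile = p,
                           references = test_refs(), n_subjects = 3,
                           n_days = 2, seed = 4)
  expect_equal(unique(tab$archetype), "plateau")
  expect_equal(nrow(tab), 6)
  expect_error(sample_population(list(), profile = p, n_subjects = 1,
                                 n_days = 1, seed = 1),
               class = "dietscore_generation_error")
})

test_that("archetype quality ordering separates cohorts by more than 0.2", {
  p <- default_profile()
  mean_total <- function(name, seed) {
    tab <- sample_population(diet_archetype(name), profile = p,
                             references = test_refs(), n_subjects = 60,
                             n_days = 1, seed = seed)
    mean(score_intakes(tab[setdiff(names(tab), "archetype")], p,
                       test_refs())$total)
  }
  plat <- mean_total("plateau", 91)
  nh <- mean_total("nhanes_like", 92)
  def <- mean_total("deficient", 93)
  expect_gt(plat - nh, 0.2)
  expect_gt(nh - def, 0.2)
})

test_that("correlation clusters are recoverable from the subscores", {
  p <- default_profile()
  tab <- sample_population(diet_archetype("nhanes_like"), profile = p,
                           references = test_refs(), n_subjects = 150,
                           n_days = 1, seed = 55)
  sc <- score_intakes(tab[setdiff(names(tab), "archetype")], p, test_refs())
  cl <- c("potassium", "magnesium", "folate_food", "fiber")
  within <- stats::cor(as.matrix(sc[cl]))
  off <- within[upper.tri(within)]
  expect_gt(mean(off), 0.25)
  # an unrelated pair should correlate far less
  expect_lt(abs(stats::cor(sc$vit_c, sc$protein)), mean(off))
  # and the leading principal component concentrates more variance than
  # under independence
  pv <- pca_variance_explained(sc[dq_nutrients()])
  expect_gt(pv$proportions[1], 1.5 / 16)
})
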