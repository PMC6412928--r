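ref_row <- function(nutrient = "calcium", mode = "adequacy_absolute",
                    dri = NA, amdr_low = NA, amdr_high = NA, who = NA,
                    um = 2, tul = NA) {
  tibble::tibble(nutrient = nutrient, mode = mode, dri = dri,
                 amdr_low_pct = amdr_low, amdr_high_pct = amdr_high,
                 who_limit = who, upper_multiple = um, tul = tul)
}

test_that("breakpoint construction follows the healthy-range rules", {
  # calcium: plateau 100-200% DRI, D capped at the TUL (1.5*C would be 3000)
  ca <- derive_breakpoints(ref_row(dri = 1000, tul = 2500))
  expect_equal(unlist(ca[, c("a", "b", "c", "d")]),
               c(a = 500, b = 1000, c = 2000, d = 2500))
  # vitamin C: 100-300% plateau, then the 1.5x ceiling
  vc <- derive_breakpoints(ref_row("vit_c", dri = 75, um = 3))
  expect_equal(unlist(vc[, c("a", "b", "c", "d")]),
               c(a = 37.5, b = 75, c = 225, d = 337.5))
  # sodium: moderation shape, C = 1.5 x WHO limit, no A or D
  na <- derive_breakpoints(ref_row("sodium", "moderation_absolute",
                                   who = 2000))
  expect_equal(na$shape, "moderation")
  expect_equal(c(na$b, na$c), c(2000, 3000))
  expect_true(is.na(na$a) && is.na(na$d))
  # AMDR: percent-of-energy axis with mirrored floor/ceiling rules
  carb <- derive_breakpoints(ref_row("carbohydrate", "adequacy_amdr",
                                     amdr_low = 45, amdr_high = 65))
  expect_equal(unlist(carb[, c("a", "b", "c", "d")]),
               c(a = 22.5, b = 45, c = 65, d = 97.5))
  expect_true(carb$pct_energy)
})

test_that("a TUL at or below the upper healthy range is a derivation error", {
  expect_error(derive_breakpoints(ref_row(dri = 1200, tul = 2000)),
               class = "dietscore_breakpoint_error")
})

test_that("adequacy scoring matches hand-computed interpolation", {
  bp <- list(a = 500, b = 1000, c = 2000, d = 3000)
  expect_equal(score_adequacy(1500, bp), 1)
  expect_equal(score_adequacy(500, bp), 0)   # zero exactly at A
  expect_equal(score_adequacy(3000, bp), 0)  # zero exactly at D
  expect_equal(score_adequacy(750, bp), 0.5)
  expect_equal(score_adequacy(2500, bp), 0.5)
  expect_equal(score_adequacy(c(1000, 2000), bp), c(1, 1))  # full at B and C
})

test_that("moderation scoring is full up to the limit, zero at the ceiling", {
  bp <- list(b = 2000, c = 3000)
  expect_equal(score_moderation(0, bp), 1)
  expect_equal(score_moderation(2000, bp), 1)
  expect_equal(score_moderation(2500, bp), 0.5)
  expect_equal(score_moderation(3000, bp), 0)
})

test_that("energy score has its plateau at +/-15% of the EER", {
  expect_equal(score_energy(2000, 2000), 1)
  expect_equal(score_energy(c(1700, 2300), 2000), c(1, 1))
  expect_equal(score_energy(1000, 2000), 0)
  expect_equal(score_energy(3000, 2000), 0)
  expect_equal(score_energy(1350, 2000), 0.5)
})

test_that("percent-of-energy conversion uses the Atwater factors", {
  expect_equal(pct_energy(250, "carbohydrate", 2000), 50)
  expect_equal(pct_energy(0, "fat_total", 2000), 0)
  expect_equal(pct_energy(77.8, "fat_total", 2000), 35.01)
  expect_error(pct_energy(10, "fat_total", 0),
               class = "dietscore_zero_energy_error")
  expect_error(pct_energy(10, "sodium", 2000),
               class = "dietscore_config_error")
})

test_that("closed forms agree with the pointwise verbal-rule oracle on a grid", {
  profile <- default_profile()
  bps <- derive_breakpoints(lookup_reference(test_refs(), profile))
  for (i in seq_len(nrow(bps))) {
    bp <- bps[i, ]
    if (bp$shape == "adequacy") {
      x <- seq(0, bp$d * 1.2, length.out = 2001)
      expect_equal(score_adequacy(x, bp),
                   oracle_adequacy(x, bp$a, bp$b, bp$c, bp$d),
                   tolerance = 1e-15)
    } else {
      x <- seq(0, bp$c * 1.5, length.out = 2001)
      expect_equal(score_moderation(x, bp),
                   oracle_moderation(x, bp$b, bp$c),
                   tolerance = 1e-15)
    }
  }
})

test_that("piecewise scores are continuous at every breakpoint", {
  eps <- 1e-9
  bp <- list(a = 500, b = 1000, c = 2000, d = 3000)
  for (pt in unlist(bp)) {
    vals <- score_adequacy(c(pt - eps, pt, pt + eps), bp)
    expect_lt(max(abs(diff(vals))), 1e-6)
  }
  bpm <- list(b = 2000, c = 3000)
  for (pt in c(bpm$b, bpm$c)) {
    vals <- score_moderation(c(pt - eps, pt, pt + eps), bpm)
    expect_lt(max(abs(diff(vals))), 1e-6)
  }
})

test_that("adequacy is unimodal and moderation non-increasing", {
  bp <- list(a = 10, b = 20, c = 40, d = 70)
  x <- seq(0, 80, by = 0.25)
  s <- score_adequacy(x, bp)
  expect_true(all(diff(s[x <= 20]) >= 0))
  expect_true(all(s[x >= 20 & x <= 40] == 1))
  expect_true(all(diff(s[x >= 40]) <= 0))
  sm <- score_moderation(x, list(b = 20, c = 50))
  expect_true(all(diff(sm) <= 0))
})
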