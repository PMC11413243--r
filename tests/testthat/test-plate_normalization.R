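test_that("negative-control reference is the pooled DMSO/media median", {
  expect_equal(negative_control_reference(mini_plate(dmso = c(100, 102, 98),
                                                     media = c(99, 101))), 100)
  expect_equal(negative_control_reference(mini_plate(dmso = 80,
                                                     media = numeric())), 80)
  d <- mini_plate(dmso = numeric(), media = numeric(), compound = c(100, 90))
  expect_error(negative_control_reference(d), "negative-control")
})

test_that("toxic wells are flagged strictly below half the reference", {
  d <- mini_plate(dmso = c(100, 100, 100), media = c(100, 100),
                  compound = c(40, 50, 49.999, 120, 30))
  fl <- flag_toxic_wells(d)
  expect_equal(d$raw_count[fl], c(40, 49.999, 30))
  # the boundary well at exactly 50% of the reference is kept
  expect_false(fl[d$role == "compound" & d$raw_count == 50])
  # control wells are never flagged, even at low counts
  d2 <- mini_plate(dmso = c(100, 100, 10), compound = 200)
  expect_false(any(flag_toxic_wells(d2)[d2$role != "compound"]))
  # all compound wells at or above the reference -> none flagged
  d3 <- mini_plate(dmso = c(100, 100), compound = c(100, 150))
  expect_false(any(flag_toxic_wells(d3)))
})

test_that("smoothing is the identity on a spatially flat plate", {
  d <- build_plate(function(r, c) 1000)
  sm <- loess_correct(d)
  seeded <- sm$role != "empty"
  expect_true(all(abs(sm$smoothed_count[seeded] / d$raw_count[seeded] - 1)
                  < 1e-6))
})

test_that("a known multiplicative column gradient is corrected away from edges", {
  baseline <- 1000
  g <- function(c) 1 + 0.3 * (c - 12.5) / 23   # linear column trend, +-15%
  d <- build_plate(function(r, c) baseline * g(c))
  sm <- normalize_plate(loess_correct(d))
  interior <- sm$column >= 4 & sm$column <= 21 &
    match(sm$row, LETTERS) >= 3 & match(sm$row, LETTERS) <= 14
  # after correction and DMSO normalisation all interior wells sit at the
  # flat baseline (viability 1) to within 2%
  expect_true(all(abs(sm$normalized_count[interior] - 1) < 0.02))
})

test_that("excluded toxic wells are corrected but never influence the fit", {
  d <- build_plate(function(r, c) 100)
  i <- which(d$role == "compound")[100]
  d$raw_count[i] <- 5
  sm <- loess_correct(d)
  # the toxic well keeps its toxicity signal (correction factor ~ 1)
  expect_lt(abs(sm$smoothed_count[i] - 5), 0.05)
  # removing the flagged well entirely changes no other well's correction
  sm2 <- loess_correct(d[-i, ])
  expect_equal(sm2$smoothed_count, sm$smoothed_count[-i], tolerance = 1e-10)
})

test_that("plates with too few wells skip smoothing with a warning", {
  d <- mini_plate(dmso = c(100, 101, 99), media = c(98, 102),
                  compound = rep(100, 10))
  expect_warning(sm <- loess_correct(d), "skipped")
  expect_equal(sm$smoothed_count, d$raw_count)
})

test_that("DMSO-median normalisation fixes every plate's DMSO median at 1", {
  d <- mini_plate(dmso = c(190, 200, 210), media = c(180, 220),
                  compound = c(100, 400))
  d$smoothed_count <- d$raw_count
  nm <- normalize_plate(d)
  expect_equal(nm$normalized_count[nm$role == "compound"], c(0.5, 2.0))
  expect_equal(nm$normalized_count[nm$raw_count == 200], 1.0)
  # media wells are normalised by the same DMSO median
  expect_equal(sort(nm$normalized_count[nm$role == "media"]), c(0.9, 1.1))
  expect_equal(median(nm$normalized_count[nm$role == "dmso"]), 1.0)

  d$smoothed_count <- 0
  expect_error(normalize_plate(d), "degenerate")
  expect_error(normalize_plate(mini_plate(compound = 1,
                                          dmso = numeric(),
                                          media = 100)), "smoothed_count")
})

test_that("every simulated plate has DMSO normalised median exactly 1", {
  nd <- normalize_screen(small_sim()$wells)
  for (p in unique(nd$plate_id)) {
    dmso <- nd$normalized_count[nd$plate_id == p & nd$role == "dmso"]
    expect_equal(median(dmso), 1, tolerance = 1e-12)
  }
})

test_that("viability bins partition the non-negative line with the stated boundaries", {
  expect_equal(assign_viability_bin(c(1.20, 1.00, 0.50, 0.49)),
               c("high", "normal", "moderate", "low"))
  # exact boundary conventions: 0.5 and 0.8 to the bin above, 1.15 normal
  expect_equal(assign_viability_bin(c(0.5, 0.8, 1.15, 1.1500001)),
               c("moderate", "normal", "normal", "high"))
  expect_error(assign_viability_bin(-0.1), "non-negative")
  # totality: every value on a fine grid maps to exactly one bin
  grid <- seq(0, 3, by = 0.005)
  bins <- assign_viability_bin(grid)
  expect_false(anyNA(bins))
  expect_setequal(unique(bins), c("high", "normal", "moderate", "low"))
})
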