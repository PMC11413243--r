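test_that("hit calling applies inclusive robust-Z cutoffs per score", {
  s <- make_scores(list("A", "L1", 1, -4.634), list("B", "L1", 1, 1.758),
                   list("C", "L1", 1, -2.0), list("D", "L1", 1, 2.0),
                   list("E", "L1", 1, -0.249))
  called <- call_hits(s)
  expect_equal(called$category[match(c("A", "B", "C", "D", "E"),
                                     called$compound_id)],
               c("cytotoxic", "neutral", "cytotoxic", "proliferative",
                 "neutral"))
})

test_that("high-confidence filter keeps cancer-wide hits clean in the control line", {
  panel <- toy_panel(12)
  s <- rbind(
    # cobimetinib-like: cytotoxic in all 12 cancer lines, control clean
    panel_scores("cobi", panel, z_1uM = rep(-4, 12), control_z_1uM = -0.249),
    # docetaxel-like: cytotoxic everywhere including the control
    panel_scores("doce", panel, z_1uM = rep(-4.753, 12),
                 control_z_1uM = -4.634),
    # below the 50%-of-lines requirement (5/12), control clean
    panel_scores("few", panel, z_1uM = c(rep(-3, 5), rep(0, 7)),
                 control_z_1uM = 0.5),
    # exactly half of the lines: inclusive boundary
    panel_scores("half", panel, z_1uM = c(rep(-2, 6), rep(0, 6)),
                 control_z_1uM = 1.758))
  high <- high_confidence_filter(s, panel)
  expect_setequal(high, c("cobi", "half"))
  # without the counter-screen the pan-toxic compound re-enters
  expect_setequal(high_confidence_filter(s, panel, control_filter = FALSE),
                  c("cobi", "doce", "half"))
  # a compound with no control score cannot pass, and is logged
  s2 <- panel_scores("noctrl", panel, z_1uM = rep(-5, 12))
  h2 <- high_confidence_filter(rbind(s, s2), panel)
  expect_false("noctrl" %in% h2)
  expect_equal(attr(h2, "excluded_no_control"), "noctrl")
})

test_that("the line-fraction denominator is the scored lines only", {
  panel <- toy_panel(12)
  # scored in just 4 cancer lines, cytotoxic in 2 of them = 50%
  s <- rbind(panel_scores("pilot", panel, z_1uM = c(-3, -2.5, 0, 0),
                          control_z_1uM = 0))
  expect_setequal(as.character(high_confidence_filter(s, panel)), "pilot")
})

test_that("moderate tier recaptures low-dose hits vetoed by the control line", {
  panel <- toy_panel(12)
  s <- rbind(
    panel_scores("mod", panel, z_0p1uM = c(rep(-3, 7), rep(0, 5)),
                 z_1uM = rep(-3, 12), control_z_1uM = -2.5),
    panel_scores("neither", panel, z_0p1uM = c(rep(-3, 7), rep(0, 5)),
                 z_1uM = rep(0, 12), control_z_1uM = -1),
    panel_scores("highc", panel, z_1uM = rep(-3, 12), control_z_1uM = 0))
  high <- high_confidence_filter(s, panel)
  mod <- moderate_confidence_filter(s, panel, high)
  expect_setequal(as.character(high), "highc")
  expect_equal(mod, "mod")
  # tiers are exclusive: a compound in the high set is never returned
  expect_false("highc" %in%
                 moderate_confidence_filter(s, panel, c(high, "mod", "highc")))
})

test_that("low-dose advancement uses the mean cancer-line score", {
  panel <- toy_panel(3)
  s <- rbind(panel_scores("adv", panel, z_0p1uM = c(-3, -2.5, -1.7)),
             panel_scores("stay", panel, z_0p1uM = c(-2.1, -0.5)))
  expect_equal(low_dose_advancement_filter(c("adv", "stay"), s, panel), "adv")
  expect_equal(low_dose_advancement_filter(character(), s, panel), character())
})

test_that("secondary candidate lists are deduplicated and deterministically ordered", {
  out <- secondary_hit_list(c("B", "A"), c("C", "A"))
  expect_equal(out$compound_id, c("A", "B", "C"))
  expect_equal(out$tier, c("high_advanced", "high_advanced", "moderate"))
  expect_equal(nrow(secondary_hit_list(character(), character())), 0L)
})

test_that("tier assignment equals brute-force clause evaluation over all miniature matrices", {
  panel <- toy_panel(2)
  lg <- c("LG01", "LG02")
  vals <- c(-3, 0)
  grid <- expand.grid(l1d1 = vals, l2d1 = vals, l1d0 = vals, l2d0 = vals,
                      cd1 = vals, cd0 = vals)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    s <- make_scores(
      list("X", "LG01", 1, g$l1d1), list("X", "LG02", 1, g$l2d1),
      list("X", "LG01", 0.1, g$l1d0), list("X", "LG02", 0.1, g$l2d0),
      list("X", "CTRL", 1, g$cd1), list("X", "CTRL", 0.1, g$cd0))
    res <- select_hits(s, panel)
    # written clauses, evaluated directly
    frac1 <- mean(c(g$l1d1, g$l2d1) <= -2)
    frac0 <- mean(c(g$l1d0, g$l2d0) <= -2)
    exp_high <- frac1 >= 0.5 && g$cd1 > -2
    exp_adv <- exp_high && mean(c(g$l1d0, g$l2d0)) <= -2
    exp_mod <- !exp_high && frac0 >= 0.5 && g$cd1 <= -2
    exp_tier <- if (exp_adv) "high_advanced" else if (exp_high) "high"
    else if (exp_mod) "moderate" else "none"
    expect_equal(res$table$tier[res$table$compound_id == "X"], exp_tier,
                 info = paste(unlist(g), collapse = ","))
  }
})

test_that("tier invariants and filter monotonicity hold on random score matrices", {
  panel <- toy_panel(6)
  lines <- panel$name
  set.seed(99)
  for (rep in 1:15) {
    s <- expand.grid(compound_id = sprintf("C%02d", 1:10),
                     cell_line = lines, concentration = c(0.1, 1),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    s$robust_z <- rnorm(nrow(s), -1, 2)
    res <- select_hits(s, panel)
    # advancement refines the high tier; tiers are exclusive
    expect_true(all(res$high_advanced %in% res$high))
    expect_length(intersect(res$moderate, res$high), 0)
    expect_false(any(duplicated(res$table$compound_id)))

    high <- res$high
    # more negative cancer-line score at 1 uM never removes a compound
    j <- sample(which(s$cell_line != "CTRL" & s$concentration == 1), 1)
    s2 <- s; s2$robust_z[j] <- s2$robust_z[j] - 5
    expect_true(all(high %in% high_confidence_filter(s2, panel)))
    # more negative control score never adds one
    k <- sample(which(s$cell_line == "CTRL" & s$concentration == 1), 1)
    s3 <- s; s3$robust_z[k] <- s3$robust_z[k] - 5
    expect_true(all(high_confidence_filter(s3, panel) %in% high))
  }
})

test_that("target aggregation counts multi-valued annotations with a floor", {
  ann <- data.frame(compound_id = c("X", "Y", "Z"),
                    target = c("MEK1;MEK2", "MEK1", NA),
                    pathway = c("MAPK", "MAPK", "PI3K"),
                    stringsAsFactors = FALSE)
  t2 <- aggregate_targets(c("X", "Y"), ann)
  expect_equal(t2$value, "MEK1")
  expect_equal(t2$count, 2L)
  t1 <- aggregate_targets(c("X", "Y"), ann, min_occurrence = 1)
  expect_setequal(t1$value, c("MEK1", "MEK2"))
  expect_equal(nrow(aggregate_targets(character(), ann)), 0L)
  # unannotated compounds are tallied explicitly
  t3 <- aggregate_targets(c("X", "Z"), ann, min_occurrence = 1)
  expect_true("unannotated" %in% t3$value)
  # two hit sets side by side (with/without the counter-screen filter)
  t4 <- aggregate_targets(list(with = c("X", "Y"), without = c("X", "Y", "Z")),
                          ann, min_occurrence = 1)
  expect_true(all(t4$without >= t4$with))
})

test_that("secondary validation requires half death in enough lines, strictly", {
  mk <- function(id, viab) {
    d <- well_data(plate_id = "S1", row = LETTERS[seq_along(viab)],
                   column = match(id, c("p", "f", "b")),
                   cell_line = paste0("V", seq_along(viab)), role = "compound",
                   compound_id = id, concentration = 10)
    d$normalized_count <- viab
    d
  }
  d <- rbind(mk("p", c(0.4, 0.45, 0.3, 0.6)),
             mk("f", c(0.6, 0.7, 0.4, 0.55)),
             mk("b", c(0.5, 0.5, 0.5, 0.5)))
  res <- secondary_validation_assessment(d)
  expect_equal(res$passed[match(c("p", "f", "b"), res$compound_id)],
               c(TRUE, FALSE, FALSE))
  # a compound screened in fewer lines has the missing lines held against it
  d2 <- mk("m", c(0.2, 0.3))
  expect_message(res2 <- secondary_validation_assessment(d2), "fewer than")
  expect_false(res2$passed)
})
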