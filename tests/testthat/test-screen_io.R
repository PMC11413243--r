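test_that("screen CSVs parse, preserve row counts and round-trip byte-identically", {
  d <- mini_plate(dmso = c(100, 102), media = 99,
                  compound = c(250, 300, 150, 90))
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(d, f1)

  r <- read_screen_csv(f1)
  expect_equal(nrow(r), nrow(d))
  expect_equal(r$raw_count, d$raw_count)
  expect_equal(r$role, d$role)
  expect_equal(r$concentration, d$concentration)

  write_screen_csv(r, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("derived columns appear in output only once computed", {
  d <- mini_plate(compound = c(250, 300))
  f <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(d, f)
  expect_false("Robust_Z" %in% names(utils::read.csv(f, check.names = FALSE)))

  d$robust_z <- seq_len(nrow(d))
  write_screen_csv(d, f)
  expect_true("Robust_Z" %in% names(utils::read.csv(f, check.names = FALSE)))

  # empty dataset -> header-only file
  write_screen_csv(d[0, ], f)
  expect_length(readLines(f), 1L)
})

test_that("schema, parse and integrity errors are reported precisely", {
  d <- mini_plate(compound = c(250, 300))
  f <- withr::local_tempfile(fileext = ".csv")
  write_screen_csv(d, f)

  # header lacking the mapped count column
  tab <- utils::read.csv(f, check.names = FALSE)
  tab$Count_Cells <- NULL
  utils::write.csv(tab, f, row.names = FALSE)
  expect_error(read_screen_csv(f), "Count_Cells")

  # unparseable count: row dropped, line number reported, rows conserved
  write_screen_csv(d, f)
  lines <- readLines(f)
  lines[3] <- sub("102", "oops", lines[3])
  writeLines(lines, f)
  expect_warning(r <- read_screen_csv(f), "unparseable")
  errs <- attr(r, "row_errors")
  expect_equal(nrow(r) + nrow(errs), nrow(d))
  expect_equal(errs$line, 3L)

  # duplicate (plate, well) address
  dup <- rbind(d, d[1, ])
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(CellLine = dup$cell_line, Plate = dup$plate_id,
                              Well = sprintf("%s%02d", dup$row, dup$column),
                              Role = dup$role, Count_Cells = dup$raw_count),
                   f3, row.names = FALSE)
  expect_error(read_screen_csv(f3), "duplicate")
})

test_that("roles are inferred from compound and control columns when unlabelled", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(
    CellLine = "L1", Plate = "P1", Well = c("A01", "A02", "A03", "A04", "A05"),
    QCL_Sample_Number = c("Q1", NA, NA, NA, NA),
    Compound_Name = c("drug", "0.2% DMSO", "Media only", "Staurosporine", NA),
    Count_Cells = 100), f, row.names = FALSE)
  r <- read_screen_csv(f)
  expect_equal(r$role,
               c("compound", "dmso", "media", "positive_control", "empty"))
})

test_that("validate_dataset reports geometry, control-count and panel issues", {
  sim <- small_sim()
  rep0 <- validate_dataset(sim$wells, sim$config$layout, sim$config$panel)
  expect_equal(nrow(rep0), 0L)

  # drop one DMSO well from one plate -> control count mismatch
  wells <- sim$wells
  drop <- which(wells$role == "dmso" & wells$plate_id == wells$plate_id[1])[1]
  rep1 <- validate_dataset(wells[-drop, ], sim$config$layout, sim$config$panel)
  expect_true(any(rep1$type == "control_count" &
                    grepl("13 DMSO", rep1$message)))

  # column 25 -> geometry violation; unknown line flagged
  bad <- wells[1, ]
  bad$column <- 25L
  bad$cell_line <- "MYSTERY"
  rep2 <- validate_dataset(rbind(wells, bad), sim$config$layout,
                           sim$config$panel)
  expect_true(any(rep2$type == "geometry"))
  expect_true(any(rep2$type == "unknown_cell_line"))
})

test_that("the default layout carries the documented control complement", {
  lay <- default_plate_layout()
  expect_equal(sum(lay$role == "dmso"), 14)
  expect_equal(sum(lay$role == "media"), 12)
  counts <- table(lay$control_name[lay$role == "positive_control"])
  expect_equal(unname(counts[["Cisplatin"]]), 1L)
  expect_true(all(counts[setdiff(names(counts), "Cisplatin")] == 2L))
  expect_equal(sum(cell_line_panel()$is_control), 1L)
})
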