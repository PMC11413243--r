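# Shared fixtures: small plates and score tables built in code.

# A full 384-well plate with the default control layout; raw counts come
# from count_fun(row_index, column_index).
build_plate <- function(count_fun, plate_id = "P1", cell_line = "L1",
                        layout = default_plate_layout()) {
  all_wells <- expand.grid(row = LETTERS[1:16], column = 1:24,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(all_wells$row, all_wells$column)
  lay_key <- paste(layout$row, layout$column)
  role <- rep("compound", nrow(all_wells))
  role[match(lay_key, key)] <- layout$role
  cname <- rep(NA_character_, nrow(all_wells))
  cname[match(lay_key, key)] <- layout$control_name
  is_cpd <- role == "compound"
  cid <- rep(NA_character_, nrow(all_wells))
  cid[is_cpd] <- sprintf("C%03d", seq_len(sum(is_cpd)))
  d <- well_data(plate_id = plate_id, row = all_wells$row,
                 column = all_wells$column, cell_line = cell_line,
                 role = role, compound_id = cid, compound_name = cname,
                 concentration = ifelse(is_cpd, 1, NA_real_))
  d$raw_count <- mapply(count_fun, match(d$row, LETTERS), d$column)
  d
}

# A tiny negative-control-only plate for reference/flagging tests.
mini_plate <- function(dmso = c(100, 102, 98), media = c(99, 101),
                       compound = numeric(), plate_id = "P1") {
  n <- length(dmso) + length(media) + length(compound)
  d <- well_data(plate_id = plate_id, row = rep(LETTERS[1:16], 24)[seq_len(n)],
                 column = rep(1:24, each = 16)[seq_len(n)], cell_line = "L1",
                 role = c(rep("dmso", length(dmso)),
                          rep("media", length(media)),
                          rep("compound", length(compound))),
                 compound_id = c(rep(NA, length(dmso) + length(media)),
                                 sprintf("C%03d", seq_along(compound))),
                 concentration = c(rep(NA, length(dmso) + length(media)),
                                   rep(1, length(compound))))
  d$raw_count <- c(dmso, media, compound)
  d
}

# Long score table for hit-selection tests.
make_scores <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(compound_id = r[[1]], cell_line = r[[2]],
               concentration = as.numeric(r[[3]]),
               robust_z = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
}

# Panel of n cancer lines plus one control line.
toy_panel <- function(n_lgsoc = 12) {
  cell_line_panel(data.frame(
    name = c(sprintf("LG%02d", seq_len(n_lgsoc)), "CTRL"),
    is_control = c(rep(FALSE, n_lgsoc), TRUE),
    mutation_status = "NA",
    seeding_density = 1000, stringsAsFactors = FALSE))
}

# Scores for one compound across a panel: named doses -> vector over lines.
panel_scores <- function(compound, panel, z_1uM = NULL, z_0p1uM = NULL,
                         control_z_1uM = NA, control_z_0p1uM = NA) {
  lg <- panel$name[!panel$is_control]
  ctrl <- panel$name[panel$is_control]
  out <- list()
  if (!is.null(z_1uM))
    out[[length(out) + 1L]] <- data.frame(compound_id = compound,
                                          cell_line = lg[seq_along(z_1uM)],
                                          concentration = 1, robust_z = z_1uM,
                                          stringsAsFactors = FALSE)
  if (!is.null(z_0p1uM))
    out[[length(out) + 1L]] <- data.frame(compound_id = compound,
                                          cell_line = lg[seq_along(z_0p1uM)],
                                          concentration = 0.1,
                                          robust_z = z_0p1uM,
                                          stringsAsFactors = FALSE)
  if (!is.na(control_z_1uM))
    out[[length(out) + 1L]] <- data.frame(compound_id = compound,
                                          cell_line = ctrl, concentration = 1,
                                          robust_z = control_z_1uM,
                                          stringsAsFactors = FALSE)
  if (!is.na(control_z_0p1uM))
    out[[length(out) + 1L]] <- data.frame(compound_id = compound,
                                          cell_line = ctrl,
                                          concentration = 0.1,
                                          robust_z = control_z_0p1uM,
                                          stringsAsFactors = FALSE)
  do.call(rbind, out)
}

# Independent brute-force robust Z: sorting-based median and MAD, no calls
# into the package's scoring path.
bf_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}
bf_robust_z <- function(x, constant = 1) {
  m <- bf_median(x)
  (x - m) / (constant * bf_median(abs(x - m)))
}

# Small simulation shared by several tests (1 plate per line, 3 lines).
small_sim <- function(seed = 11, ...) {
  args <- list(...)
  panel <- cell_line_panel(data.frame(
    name = c("LG01", "LG02", "CTRL"), is_control = c(FALSE, FALSE, TRUE),
    mutation_status = "NA", seeding_density = c(1000, 800, 350),
    stringsAsFactors = FALSE))
  defaults <- list(n_compounds = 80, panel = panel, seed = seed)
  defaults[names(args)] <- args
  simulate_screen(do.call(simulation_config, defaults))
}
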