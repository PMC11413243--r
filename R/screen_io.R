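# Canonical column schema for screen record CSVs.  Keys are the internal
# field names; values are the default column headers (the names used by the
# deposited data records where the convention is known, e.g. Count_Cells_fit).
.default_schema <- c(
  cell_line        = "CellLine",
  plate_id         = "Plate",
  well             = "Well",
  role             = "Role",
  compound_id      = "QCL_Sample_Number",
  compound_name    = "Compound_Name",
  library          = "Library",
  concentration    = "Concentration_uM",
  pathway          = "Pathway",
  target           = "Target",
  raw_count        = "Count_Cells",
  smoothed_count   = "Count_Cells_fit",
  normalized_count = "Count_Cells_Norm_fit",
  viability_bin    = "Viability_Bin",
  robust_z         = "Robust_Z"
)

.roles <- c("compound", "dmso", "media", "positive_control", "empty")
.derived_cols <- c("smoothed_count", "normalized_count", "viability_bin", "robust_z")

#' Default column schema for screen CSV files
#'
#' Returns the mapping from internal field names to CSV column headers used
#' by [read_screen_csv()] and [write_screen_csv()].  Override individual
#' entries to ingest files with a different dialect, e.g.
#' `schema_map = screen_schema(raw_count = "Nuclei_Count")`.
#'
#' @param ... named overrides, `internal_field = "Column header"`.
#' @return Named character vector mapping internal fields to column names.
#' @export
screen_schema <- function(...) {
  over <- c(...)
  schema <- .default_schema
  if (length(over)) {
    bad <- setdiff(names(over), names(schema))
    if (length(bad))
      stop("unknown schema field(s): ", paste(bad, collapse = ", "))
    schema[names(over)] <- over
  }
  schema
}

#' Construct a well-record table
#'
#' Builds the canonical data frame of per-well screen records used by every
#' pipeline stage.  One row is one well of one plate: its address, cell line,
#' role, compound annotation, dose, and raw count.  Derived columns
#' (`smoothed_count`, `normalized_count`, `viability_bin`, `robust_z`) are
#' `NA` until the corresponding stage has run.
#'
#' @param plate_id character, plate identifier.
#' @param row character, plate row letter `A`--`P`.
#' @param column integer, plate column `1`--`24`.
#' @param cell_line character.
#' @param role one of `"compound"`, `"dmso"`, `"media"`,
#'   `"positive_control"`, `"empty"`.
#' @param compound_id,compound_name,library,pathway,target character or `NA`.
#'   `target`/`pathway` may hold several values separated by `";"`.
#' @param concentration dose in micromolar, `NA` for undosed control wells.
#' @param raw_count non-negative nuclei count.
#' @return A `data.frame` with class `well_data`.
#' @export
well_data <- function(plate_id, row, column, cell_line, role,
                      compound_id = NA_character_, compound_name = NA_character_,
                      library = NA_character_, concentration = NA_real_,
                      pathway = NA_character_, target = NA_character_,
                      raw_count = NA_real_) {
  n <- max(length(plate_id), length(row), length(column), length(cell_line),
           length(role))
  d <- data.frame(
    plate_id = as.character(plate_id), row = as.character(row),
    column = as.integer(column), cell_line = as.character(cell_line),
    role = as.character(role), compound_id = as.character(compound_id),
    compound_name = as.character(compound_name), library = as.character(library),
    concentration = as.numeric(concentration), pathway = as.character(pathway),
    target = as.character(target), raw_count = as.numeric(raw_count),
    smoothed_count = rep(NA_real_, n), normalized_count = rep(NA_real_, n),
    viability_bin = rep(NA_character_, n), robust_z = rep(NA_real_, n),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(unique(d$role), .roles)
  if (length(bad)) stop("unknown role(s): ", paste(bad, collapse = ", "))
  class(d) <- c("well_data", "data.frame")
  d
}

.well_string <- function(row, column) sprintf("%s%02d", row, column)

.split_well <- function(well) {
  m <- regmatches(well, regexec("^([A-Pa-p])0?([0-9]{1,2})$", well))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("unparseable well address(es): ", paste(unique(well[bad]), collapse = ", "))
  list(row = toupper(vapply(m, `[`, "", 2L)),
       column = as.integer(vapply(m, `[`, "", 3L)))
}

# Role inference for files without an explicit role column: a compound id
# means a compound well; otherwise the compound-name field is matched against
# the vehicle/media conventions and the positive-control panel.
.infer_role <- function(compound_id, compound_name) {
  role <- rep("empty", length(compound_id))
  nm <- tolower(ifelse(is.na(compound_name), "", compound_name))
  role[grepl("dmso", nm)] <- "dmso"
  role[grepl("^media", nm)] <- "media"
  role[nm %in% tolower(positive_control_names())] <- "positive_control"
  role[!is.na(compound_id) & compound_id != ""] <- "compound"
  role
}

#' Names of the positive-control agents
#'
#' The cytotoxic reference agents carried on every plate.  Cisplatin is run
#' as a single well per plate; all others in duplicate.
#' @return Character vector of control names.
#' @export
positive_control_names <- function() {
  c("Cisplatin", "Carboplatin", "Doxorubicin", "Mitomycin C",
    "Paclitaxel", "Staurosporine")
}

#' Read a screen record CSV
#'
#' Parses a per-well cell-count CSV into the canonical well-record table.
#' Column names are resolved through `schema_map`; the `role`, annotation and
#' derived-score columns are optional, everything else is required.  Rows
#' whose count fields fail to parse are dropped and reported in the
#' `row_errors` attribute (a data frame of line numbers and messages), so
#' `nrow(input) == nrow(result) + nrow(attr(result, "row_errors"))`.
#'
#' @param path file path of a comma-separated, UTF-8, headered file.
#' @param schema_map column mapping from [screen_schema()].
#' @return A `well_data` data frame.
#' @export
read_screen_csv <- function(path, schema_map = screen_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", na.strings = c("NA", ""))
  required <- c("cell_line", "plate_id", "well", "raw_count")
  miss <- required[!schema_map[required] %in% names(raw)]
  if (length(miss))
    stop("schema error: missing mapped column(s): ",
         paste(sprintf("%s (-> %s)", schema_map[miss], miss), collapse = ", "))

  pick <- function(field) {
    col <- schema_map[[field]]
    if (col %in% names(raw)) raw[[col]] else rep(NA_character_, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))

  wells <- .split_well(pick("well"))
  raw_chr <- pick("raw_count")
  raw_num <- num(raw_chr)
  bad <- which(!is.na(raw_chr) & is.na(raw_num))
  row_errors <- data.frame(line = integer(), message = character(),
                           stringsAsFactors = FALSE)
  if (length(bad)) {
    row_errors <- data.frame(
      line = bad + 1L,  # header is line 1
      message = sprintf("unparseable count '%s'", raw_chr[bad]),
      stringsAsFactors = FALSE)
    warning(sprintf("%d row(s) dropped with unparseable counts; see attr(x, 'row_errors')",
                    length(bad)))
  }

  role <- pick("role")
  if (all(is.na(role))) role <- .infer_role(pick("compound_id"), pick("compound_name"))

  d <- well_data(
    plate_id = pick("plate_id"), row = wells$row, column = wells$column,
    cell_line = pick("cell_line"), role = role,
    compound_id = pick("compound_id"), compound_name = pick("compound_name"),
    library = pick("library"), concentration = num(pick("concentration")),
    pathway = pick("pathway"), target = pick("target"), raw_count = raw_num
  )
  d$smoothed_count <- num(pick("smoothed_count"))
  d$normalized_count <- num(pick("normalized_count"))
  d$viability_bin <- pick("viability_bin")
  d$robust_z <- num(pick("robust_z"))

  if (length(bad)) d <- d[-bad, , drop = FALSE]
  key <- paste(d$plate_id, d$row, d$column)
  if (anyDuplicated(key))
    stop("integrity error: duplicate (plate, well) address(es): ",
         paste(utils::head(unique(key[duplicated(key)]), 5), collapse = "; "))
  rownames(d) <- NULL
  attr(d, "row_errors") <- row_errors
  d
}

#' Write a screen record CSV
#'
#' Writes the canonical schema in fixed column order (UTF-8, comma-separated,
#' header row).  Derived columns are included only when at least one value is
#' present, so a freshly simulated dataset writes raw counts only.
#' Writing then re-reading is the identity on the canonical schema.
#'
#' @param dataset a `well_data` data frame.
#' @param path output file path.
#' @param schema_map column mapping from [screen_schema()].
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(dataset, path, schema_map = screen_schema()) {
  out <- data.frame(
    a = dataset$cell_line, b = dataset$plate_id,
  c = .well_string(dataset$row, dataset$column),
    d = dataset$role, e = dataset$compound_id, f = dataset$compound_name,
    g = dataset$library, h = dataset$concentration, i = dataset$pathway,
    j = dataset$target, k = dataset$raw_count, stringsAsFactors = FALSE)
  names(out) <- schema_map[c("cell_line", "plate_id", "well", "role",
                             "compound_id", "compound_name", "library",
                             "concentration", "pathway", "target", "raw_count")]
  for (field in .derived_cols) {
    if (any(!is.na(dataset[[field]]))) {
      out[[schema_map[[field]]]] <- dataset[[field]]
    }
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Default 384-well plate layout
#'
#' The control complement carried on every screening plate: 14 DMSO
#' (0.2 percent vehicle) and 12 media-only negative-control wells, plus the
#' six positive-control agents in duplicate except Cisplatin (one well).
#' Negative controls occupy the outer columns interleaved by row; positive
#' controls (dosed at `positive_dose` micromolar) fill the remaining outer
#' wells.  All other wells are available for library compounds.
#'
#' @param n_dmso,n_media numbers of vehicle and media wells.
#' @param positive_dose dose of the positive-control wells, micromolar.
#' @return Data frame with class `plate_layout`: columns `row`, `column`,
#'   `role`, `control_name`, `dose`.
#' @export
default_plate_layout <- function(n_dmso = 14, n_media = 12, positive_dose = 10) {
  rows <- LETTERS[1:16]
  slots <- rbind(
    expand.grid(row = rows, column = 1L, stringsAsFactors = FALSE),
    expand.grid(row = rows, column = 24L, stringsAsFactors = FALSE),
    expand.grid(row = rows, column = 12L, stringsAsFactors = FALSE)
  )
  # interleave negative controls so neither class clusters on one edge
  pos_names <- c("Staurosporine", "Staurosporine", "Doxorubicin", "Doxorubicin",
                 "Mitomycin C", "Mitomycin C", "Paclitaxel", "Paclitaxel",
                 "Carboplatin", "Carboplatin", "Cisplatin")
  n_ctrl <- n_dmso + n_media + length(pos_names)
  if (n_ctrl > nrow(slots)) stop("control layout exceeds reserved wells")
  role <- rep(NA_character_, n_ctrl)
  idx_dmso <- seq(1, by = 2, length.out = n_dmso)
  idx_media <- seq(2, by = 2, length.out = n_media)
  role[idx_dmso] <- "dmso"
  role[idx_media] <- "media"
  role[is.na(role[seq_len(n_ctrl)])] <- "positive_control"
  lay <- data.frame(row = slots$row[seq_len(n_ctrl)],
                    column = as.integer(slots$column[seq_len(n_ctrl)]),
                    role = role,
                    control_name = NA_character_, dose = NA_real_,
                    stringsAsFactors = FALSE)
  lay$control_name[lay$role == "positive_control"] <- pos_names
  lay$dose[lay$role == "positive_control"] <- positive_dose
  class(lay) <- c("plate_layout", "data.frame")
  lay
}

#' Cell-line panel for the screen
#'
#' The default panel is the 13-line study set: 12 patient-derived low-grade
#' serous ovarian carcinoma (LGSOC) lines plus the immortalised normal
#' ovarian surface epithelium line IOSE-523, flagged as the toxicity
#' counter-screen control.  Seeding densities are the per-line optimised
#' cells/well values for the 384-well format.
#'
#' @param lines data frame with columns `name`, `is_control`,
#'   `mutation_status`, `seeding_density`; the default is the study panel.
#' @return The panel data frame, classed `cell_line_panel`.
#' @export
cell_line_panel <- function(lines = NULL) {
  if (is.null(lines)) {
    lines <- data.frame(
      name = c("iOvCa241", "VOA-14202", "VOA-7681", "VOA-1056", "VOA-6406",
               "VOA-10841", "VOA-3448", "VOA-3723", "VOA-4627", "VOA-4698",
               "AOCS-2", "SLC58", "IOSE-523"),
      is_control = c(rep(FALSE, 12), TRUE),
      mutation_status = c("KRAS G12D", "KRAS G12V", "KRAS G12V", "NRAS Q61R",
                          "NRAS Q61R", "NRAS Q61K", "Wildtype", "Wildtype",
                          "Wildtype", "Wildtype", "Wildtype", "Wildtype",
                          "Wildtype"),
      seeding_density = c(1800, 1500, 1700, 800, 1900, 1050, 1000, 1900,
                          600, 450, 750, 1050, 350),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(lines),
            all(c("name", "is_control", "seeding_density") %in% names(lines)))
  if (sum(lines$is_control) != 1L)
    stop("panel must flag exactly one control line")
  class(lines) <- c("cell_line_panel", "data.frame")
  lines
}

#' Validate a well-record dataset against layout and panel
#'
#' Report-only structural check: plate geometry (rows `A`--`P`, columns
#' 1--24), duplicate addresses, per-plate negative-control counts versus the
#' layout, and unknown cell lines.  The dataset is never modified.
#'
#' @param dataset a `well_data` data frame.
#' @param layout a `plate_layout` (default [default_plate_layout()]).
#' @param panel a `cell_line_panel` (default [cell_line_panel()]).
#' @return Data frame of violations (`plate_id`, `well`, `type`, `message`);
#'   zero rows when the dataset is well-formed.
#' @export
validate_dataset <- function(dataset, layout = default_plate_layout(),
                             panel = cell_line_panel()) {
  v <- list()
  add <- function(plate, well, type, message)
    data.frame(plate_id = plate, well = well, type = type, message = message,
               stringsAsFactors = FALSE)

  bad_geom <- !(dataset$row %in% LETTERS[1:16]) |
    is.na(dataset$column) | dataset$column < 1L | dataset$column > 24L
  if (any(bad_geom))
    v[[length(v) + 1L]] <- add(dataset$plate_id[bad_geom],
                               paste0(dataset$row[bad_geom], dataset$column[bad_geom]),
                               "geometry",
                               "well address outside 384-well geometry (A-P x 1-24)")

  key <- paste(dataset$plate_id, dataset$row, dataset$column)
  dup <- duplicated(key)
  if (any(dup))
    v[[length(v) + 1L]] <- add(dataset$plate_id[dup],
                               .well_string(dataset$row[dup], dataset$column[dup]),
                               "duplicate", "duplicate (plate, well) address")

  exp_dmso <- sum(layout$role == "dmso")
  exp_media <- sum(layout$role == "media")
  for (p in unique(dataset$plate_id)) {
    pd <- dataset[dataset$plate_id == p, ]
    n_dmso <- sum(pd$role == "dmso")
    n_media <- sum(pd$role == "media")
    if (n_dmso != exp_dmso)
      v[[length(v) + 1L]] <- add(p, NA_character_, "control_count",
        sprintf("control count mismatch: %d DMSO wells, layout expects %d",
                n_dmso, exp_dmso))
    if (n_media != exp_media)
      v[[length(v) + 1L]] <- add(p, NA_character_, "control_count",
        sprintf("control count mismatch: %d media wells, layout expects %d",
                n_media, exp_media))
  }

  unknown <- setdiff(unique(dataset$cell_line), panel$name)
  if (length(unknown))
    v[[length(v) + 1L]] <- add(NA_character_, NA_character_, "unknown_cell_line",
                               paste("cell line not in panel:", unknown))

  if (!length(v))
    return(data.frame(plate_id = character(), well = character(),
                      type = character(), message = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, v)
}
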