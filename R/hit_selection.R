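# Helpers over the long score table -----------------------------------------

.scores_of <- function(score_matrix) {
  if (inherits(score_matrix, "score_matrix")) score_matrix$scores
  else score_matrix
}

.lgsoc_lines <- function(panel) panel$name[!panel$is_control]
.control_line <- function(panel) panel$name[panel$is_control]

# Robust Z of one compound in one line at one dose (NA when unscored).
.z_at <- function(scores, compound, line, dose) {
  z <- scores$robust_z[scores$compound_id == compound &
                         scores$cell_line == line &
                         scores$concentration == dose]
  if (!length(z)) NA_real_ else z[1]
}

# Fraction of scored cancer lines with z <= threshold for each compound at
# a dose.  Denominator: lines with a non-missing score for that compound.
.hit_fraction <- function(scores, compounds, lines, dose, threshold) {
  sub <- scores[scores$cell_line %in% lines & scores$concentration == dose &
                  !is.na(scores$robust_z), ]
  n <- tapply(sub$robust_z, sub$compound_id, length)
  k <- tapply(sub$robust_z <= threshold, sub$compound_id, sum)
  frac <- rep(NA_real_, length(compounds))
  names(frac) <- compounds
  hit <- intersect(compounds, names(n))
  frac[hit] <- k[hit] / n[hit]
  frac
}

#' Categorise scored wells as cytotoxic, proliferative or neutral
#'
#' Applies the screen's robust Z cutoffs to every (compound, cell line,
#' dose) score: cytotoxic when `z` is at or below the cytotoxic threshold
#' (default -2, corresponding to roughly 50 percent cell death),
#' proliferative at or above the proliferative threshold (default +2),
#' neutral otherwise.  Boundary values are hits.
#'
#' @param score_matrix a [score_screen()] result or its long score table.
#' @param cytotoxic_threshold,proliferative_threshold robust Z cutoffs.
#' @return The long score table with a `category` column.
#' @export
call_hits <- function(score_matrix, cytotoxic_threshold = -2,
                      proliferative_threshold = 2) {
  s <- .scores_of(score_matrix)
  cat <- rep(NA_character_, nrow(s))
  ok <- !is.na(s$robust_z)
  cat[ok] <- "neutral"
  cat[ok & s$robust_z <= cytotoxic_threshold] <- "cytotoxic"
  cat[ok & s$robust_z >= proliferative_threshold] <- "proliferative"
  s$category <- cat
  s
}

#' High-confidence hit filter
#'
#' Selects compounds cytotoxic (robust Z at or below `cytotoxic_threshold`)
#' at the clinically relevant dose in at least `line_fraction` of the scored
#' cancer lines, while showing no cytotoxicity in the normal control line
#' (control robust Z strictly above `control_threshold`).  Compounds with no
#' control-line score cannot satisfy the counter-screen clause and are
#' excluded (reported in the `excluded_no_control` attribute).  Setting
#' `control_filter = FALSE` drops the counter-screen clause entirely.
#'
#' @param score_matrix a [score_screen()] result or long score table.
#' @param panel a [cell_line_panel()].
#' @param dose primary dose for the filter, micromolar.
#' @param cytotoxic_threshold robust Z hit cutoff (default -2).
#' @param line_fraction minimum fraction of scored cancer lines (default
#'   0.5, inclusive).
#' @param control_threshold control-line cutoff: the compound is kept when
#'   its control robust Z is strictly greater than this (default -2).
#' @param control_filter apply the counter-screen clause (default `TRUE`).
#' @return Sorted character vector of compound ids.
#' @export
high_confidence_filter <- function(score_matrix, panel, dose = 1,
                                   cytotoxic_threshold = -2,
                                   line_fraction = 0.5,
                                   control_threshold = -2,
                                   control_filter = TRUE) {
  s <- .scores_of(score_matrix)
  compounds <- sort(unique(s$compound_id))
  frac <- .hit_fraction(s, compounds, .lgsoc_lines(panel), dose,
                        cytotoxic_threshold)
  keep <- !is.na(frac) & frac >= line_fraction
  excluded <- character()
  if (control_filter) {
    ctrl <- vapply(compounds, .z_at, 0, scores = s,
                   line = .control_line(panel), dose = dose)
    no_ctrl <- keep & is.na(ctrl)
    excluded <- compounds[no_ctrl]
    keep <- keep & !is.na(ctrl) & ctrl > control_threshold
  }
  structure(compounds[keep], excluded_no_control = excluded)
}

#' Moderate-confidence hit filter
#'
#' The relaxed second tier: compounds not already in the high-confidence set
#' that show an effect (robust Z at or below the cutoff) at the low dose in
#' at least half of the scored cancer lines, but are themselves cytotoxic in
#' the control line at the higher dose (control robust Z at or below
#' `control_threshold`) and so failed the high-confidence counter-screen.
#' This recaptures compounds that a single normal line may have unfairly
#' vetoed.  Tiers are exclusive: the result never overlaps `high_set`.
#'
#' @inheritParams high_confidence_filter
#' @param high_set compound ids already selected as high confidence.
#' @param low_dose dose of the effect clause, micromolar (default 0.1).
#' @param control_dose dose of the control clause, micromolar (default 1).
#' @return Sorted character vector of compound ids.
#' @export
moderate_confidence_filter <- function(score_matrix, panel, high_set,
                                       low_dose = 0.1, control_dose = 1,
                                       cytotoxic_threshold = -2,
                                       line_fraction = 0.5,
                                       control_threshold = -2) {
  s <- .scores_of(score_matrix)
  compounds <- sort(setdiff(unique(s$compound_id), high_set))
  if (!length(compounds)) return(character())
  frac <- .hit_fraction(s, compounds, .lgsoc_lines(panel), low_dose,
                        cytotoxic_threshold)
  ctrl <- vapply(compounds, .z_at, 0, scores = s,
                 line = .control_line(panel), dose = control_dose)
  keep <- !is.na(frac) & frac >= line_fraction &
    !is.na(ctrl) & ctrl <= control_threshold
  compounds[keep]
}

#' Low-dose advancement filter for high-confidence hits
#'
#' Refines the high-confidence tier to compounds whose mean robust Z across
#' the cancer lines at the low dose (missing values excluded) is at or below
#' the threshold, i.e. compounds already cytotoxic at a physiologically
#' achievable concentration.
#'
#' @param high_set compound ids from [high_confidence_filter()].
#' @param score_matrix a [score_screen()] result or long score table.
#' @param panel a [cell_line_panel()].
#' @param dose low dose, micromolar (default 0.1).
#' @param mean_threshold mean robust Z cutoff (default -2, inclusive).
#' @return Sorted character vector, a subset of `high_set`.
#' @export
low_dose_advancement_filter <- function(high_set, score_matrix, panel,
                                        dose = 0.1, mean_threshold = -2) {
  if (!length(high_set)) return(character())
  s <- .scores_of(score_matrix)
  sub <- s[s$compound_id %in% high_set & s$concentration == dose &
             s$cell_line %in% .lgsoc_lines(panel) & !is.na(s$robust_z), ]
  m <- tapply(sub$robust_z, sub$compound_id, mean)
  sort(names(m)[m <= mean_threshold])
}

#' Combined secondary-validation candidate list
#'
#' Union of the advanced high-confidence and moderate-confidence tiers,
#' deduplicated and deterministically ordered (tier first, then compound id)
#' so hit lists are diffable between runs.
#'
#' @param advanced_high,moderate character vectors of compound ids.
#' @return Data frame with columns `compound_id`, `tier`.
#' @export
secondary_hit_list <- function(advanced_high, moderate) {
  moderate <- setdiff(moderate, advanced_high)
  data.frame(
    compound_id = c(sort(unique(advanced_high)), sort(unique(moderate))),
    tier = c(rep("high_advanced", length(unique(advanced_high))),
             rep("moderate", length(unique(moderate)))),
    stringsAsFactors = FALSE)
}

#' Tiered hit selection over a scored screen
#'
#' Runs the full selection cascade -- high-confidence filter at the primary
#' dose, low-dose advancement, moderate-confidence recapture -- and returns
#' the per-compound tier assignment with the supporting evidence.
#'
#' @inheritParams high_confidence_filter
#' @param low_dose the low dose used for advancement and the moderate tier.
#' @return An object of class `hit_selection`: a list with `table` (one row
#'   per compound: tier and evidence), `high`, `high_advanced`, `moderate`,
#'   `secondary` (the [secondary_hit_list()]), and the thresholds applied.
#' @export
select_hits <- function(score_matrix, panel, dose = 1, low_dose = 0.1,
                        cytotoxic_threshold = -2, line_fraction = 0.5,
                        control_threshold = -2, control_filter = TRUE) {
  s <- .scores_of(score_matrix)
  high <- high_confidence_filter(s, panel, dose, cytotoxic_threshold,
                                 line_fraction, control_threshold,
                                 control_filter)
  advanced <- low_dose_advancement_filter(high, s, panel, low_dose,
                                          cytotoxic_threshold)
  moderate <- moderate_confidence_filter(s, panel, high, low_dose, dose,
                                         cytotoxic_threshold, line_fraction,
                                         control_threshold)

  compounds <- sort(unique(s$compound_id))
  lg <- .lgsoc_lines(panel)
  frac1 <- .hit_fraction(s, compounds, lg, dose, cytotoxic_threshold)
  frac0 <- .hit_fraction(s, compounds, lg, low_dose, cytotoxic_threshold)
  ctrl1 <- vapply(compounds, .z_at, 0, scores = s,
                  line = .control_line(panel), dose = dose)
  sub <- s[s$cell_line %in% lg & s$concentration == low_dose &
             !is.na(s$robust_z), ]
  mean0 <- tapply(sub$robust_z, sub$compound_id, mean)[compounds]

  tier <- rep("none", length(compounds))
  tier[compounds %in% moderate] <- "moderate"
  tier[compounds %in% high] <- "high"
  tier[compounds %in% advanced] <- "high_advanced"
  tab <- data.frame(compound_id = compounds, tier = tier,
                    lgsoc_hit_fraction_1uM = unname(frac1),
                    lgsoc_hit_fraction_0p1uM = unname(frac0),
                    control_z_1uM = unname(ctrl1),
                    mean_z_0p1uM = unname(as.numeric(mean0)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(match(tab$tier, c("high_advanced", "high", "moderate", "none")),
                   tab$compound_id), ]
  rownames(tab) <- NULL

  structure(list(table = tab, high = high, high_advanced = advanced,
                 moderate = moderate,
                 secondary = secondary_hit_list(advanced, moderate),
                 thresholds = list(dose = dose, low_dose = low_dose,
                                   cytotoxic = cytotoxic_threshold,
                                   line_fraction = line_fraction,
                                   control = control_threshold,
                                   control_filter = control_filter)),
            class = "hit_selection")
}

#' @export
print.hit_selection <- function(x, ...) {
  cat("Tiered hit selection (", nrow(x$table), " compounds)\n", sep = "")
  cat("  high confidence:          ", length(x$high), "\n")
  cat("  ... advanced at low dose: ", length(x$high_advanced), "\n")
  cat("  moderate confidence:      ", length(x$moderate), "\n")
  cat("  secondary candidates:     ", nrow(x$secondary), "\n")
  if (!x$thresholds$control_filter)
    cat("  (counter-screen control filter disabled)\n")
  invisible(x)
}

#' @export
summary.hit_selection <- function(object, ...) {
  print(object)
  cat("\nTop of selection table:\n")
  print(utils::head(object$table, 10))
  invisible(object$table)
}

#' Aggregate hit targets or pathways
#'
#' Counts how often each annotated target (or pathway) occurs across a hit
#' set, splitting multi-valued annotations on `";"`.  Rows occurring fewer
#' than `min_occurrence` times are dropped.  Compounds without an annotation
#' are tallied under `"unannotated"`.  Passing two hit sets gives the
#' side-by-side comparison of selections with and without the counter-screen
#' filter.
#'
#' @param hit_set character vector of compound ids (or a named list of two
#'   such vectors for a comparison table).
#' @param annotations data frame with columns `compound_id` and the
#'   annotation `field`.
#' @param min_occurrence minimum count to report (default 2).
#' @param field which annotation to aggregate: `"target"` or `"pathway"`.
#' @return Data frame of `value` and one count column per hit set, sorted by
#'   decreasing count then value.
#' @export
aggregate_targets <- function(hit_set, annotations, min_occurrence = 2,
                              field = c("target", "pathway")) {
  field <- match.arg(field)
  sets <- if (is.list(hit_set)) hit_set else list(count = hit_set)
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))

  count_one <- function(ids) {
    ann <- annotations[[field]][match(ids, annotations$compound_id)]
    ann[is.na(ann) | ann == ""] <- "unannotated"
    vals <- unlist(strsplit(ann, ";", fixed = TRUE))
    vals <- trimws(vals)
    table(vals[vals != ""])
  }
  tabs <- lapply(sets, count_one)
  values <- sort(unique(as.character(unlist(lapply(tabs, names)))))
  out <- data.frame(value = values, stringsAsFactors = FALSE)
  if (!nrow(out)) {
    for (nm in names(tabs)) out[[nm]] <- integer()
    return(out)
  }
  for (nm in names(tabs)) {
    out[[nm]] <- as.integer(tabs[[nm]][values])
    out[[nm]][is.na(out[[nm]])] <- 0L
  }
  keep <- Reduce(`|`, lapply(names(tabs), function(nm) out[[nm]] >= min_occurrence))
  out <- out[keep, , drop = FALSE]
  out <- out[order(-out[[2]], out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Secondary-validation pass/fail assessment
#'
#' A compound reproduces its primary-screen activity when its normalised
#' viability at the confirmation dose falls strictly below `death_threshold`
#' (default 0.5, i.e. at least 50 percent cell death) in at least
#' `min_lines` of the `total_lines` validation cell lines.  Lines missing
#' from the data count against the compound.
#'
#' @param dataset a `well_data` data frame of the secondary screen with
#'   `normalized_count` set (replicate wells per line are averaged).
#' @param dose confirmation dose, micromolar (default 10).
#' @param death_threshold viability below which a line counts as killed.
#' @param min_lines minimum number of killed lines to pass (default 3).
#' @param total_lines number of validation lines (default 4).
#' @return Data frame: `compound_id`, `n_lines_tested`, `n_lines_killed`,
#'   `passed`.
#' @export
secondary_validation_assessment <- function(dataset, dose = 10,
                                            death_threshold = 0.5,
                                            min_lines = 3, total_lines = 4) {
  sub <- dataset[dataset$role == "compound" &
                   !is.na(dataset$concentration) &
                   dataset$concentration == dose &
                   !is.na(dataset$normalized_count), ]
  if (!nrow(sub))
    stop("no compound records at ", dose, " uM with normalised counts")
  key <- paste(sub$compound_id, sub$cell_line, sep = "\r")
  via <- tapply(sub$normalized_count, key, mean)
  parts <- strsplit(names(via), "\r", fixed = TRUE)
  per_line <- data.frame(compound_id = vapply(parts, `[`, "", 1L),
                         cell_line = vapply(parts, `[`, "", 2L),
                         viability = as.numeric(via),
                         stringsAsFactors = FALSE)
  killed <- tapply(per_line$viability < death_threshold,
                   per_line$compound_id, sum)
  tested <- tapply(per_line$viability, per_line$compound_id, length)
  ids <- sort(names(tested))
  if (any(tested[ids] < total_lines))
    message(sum(tested[ids] < total_lines),
            " compound(s) tested in fewer than ", total_lines,
            " lines; missing lines count as not killed")
  data.frame(compound_id = ids,
             n_lines_tested = as.integer(tested[ids]),
             n_lines_killed = as.integer(killed[ids]),
             passed = as.integer(killed[ids]) >= min_lines,
             row.names = NULL, stringsAsFactors = FALSE)
}
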