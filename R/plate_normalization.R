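#' Spatial-smoothing configuration
#'
#' Parameters of the loess plate-effect correction.  The surface is fitted
#' by 2-D locally weighted regression on (row index, column index); by
#' default on log counts, so the multiplicative edge-effect model becomes
#' additive, with the correction applied multiplicatively.
#'
#' @param span fraction of wells in each local neighbourhood, in (0, 1].
#' @param degree local polynomial degree, 0, 1 or 2.
#' @param toxic_exclusion_fraction wells whose raw count falls strictly below
#'   this fraction of the plate's negative-control reference are excluded
#'   from the fit (default 0.5, i.e. counts below 50 percent of the pooled
#'   DMSO/media median).
#' @param log_domain fit on log counts (default `TRUE`).
#' @param min_fit_wells minimum number of unflagged cell-seeded wells
#'   required to fit; below this, smoothing is skipped with a warning.
#' @param center `"median"` or `"mean"`: the plate-level centre of the
#'   fitted surface used to rescale corrected counts.
#' @param fit_wells `"compound"` (default) fits the surface on unflagged
#'   compound wells only, the homogeneous population whose spatial trend is
#'   the artefact of interest; `"all"` additionally includes negative and
#'   positive control wells.  Because controls sit in fixed columns at full
#'   (or fixed low) viability, including them biases the surface wherever
#'   the surrounding compounds are on average mildly active, so the
#'   compound-only fit is the default; control wells are always corrected
#'   by the surface evaluated at their own positions.
#' @return A list with class `smoothing_config`.
#' @export
smoothing_config <- function(span = 0.75, degree = 1,
                             toxic_exclusion_fraction = 0.5,
                             log_domain = TRUE, min_fit_wells = 30,
                             center = c("median", "mean"),
                             fit_wells = c("compound", "all")) {
  stopifnot(span > 0, span <= 1, degree %in% 0:2,
            toxic_exclusion_fraction > 0, toxic_exclusion_fraction < 1,
            min_fit_wells >= 3)
  structure(list(span = span, degree = as.integer(degree),
                 toxic_exclusion_fraction = toxic_exclusion_fraction,
                 log_domain = isTRUE(log_domain),
                 min_fit_wells = as.integer(min_fit_wells),
                 center = match.arg(center),
                 fit_wells = match.arg(fit_wells)),
            class = "smoothing_config")
}

.plate_check <- function(wells) {
  if (length(unique(wells$plate_id)) != 1L)
    stop("expected wells from a single plate")
}

#' Negative-control reference count for a plate
#'
#' The median raw count over the plate's pooled negative-control wells
#' (0.2 percent DMSO and media-only).  This is the reference against which
#' wells are judged toxic before spatial smoothing.
#'
#' @param wells `well_data` rows of one plate.
#' @return The reference count (numeric scalar).
#' @export
negative_control_reference <- function(wells) {
  .plate_check(wells)
  neg <- wells$raw_count[wells$role %in% c("dmso", "media")]
  neg <- neg[!is.na(neg)]
  if (!length(neg))
    stop("configuration error: plate ", wells$plate_id[1],
         " has no DMSO or media negative-control wells")
  stats::median(neg)
}

#' Flag highly toxic wells prior to smoothing
#'
#' Identifies compound (and positive-control) wells whose raw count is
#' strictly below `toxic_exclusion_fraction` of the plate's negative-control
#' reference.  These wells are excluded from the loess fit so that strong
#' cytotoxicity is not mistaken for a plate-location effect; negative-control
#' wells are never flagged.
#'
#' @param wells `well_data` rows of one plate.
#' @param config a [smoothing_config()].
#' @return Logical vector along `wells` rows: `TRUE` for flagged wells.
#' @export
flag_toxic_wells <- function(wells, config = smoothing_config()) {
  ref <- negative_control_reference(wells)
  flaggable <- wells$role %in% c("compound", "positive_control")
  flaggable & !is.na(wells$raw_count) &
    wells$raw_count < config$toxic_exclusion_fraction * ref
}

# Fit the loess spatial surface to the unflagged cell-seeded wells of one
# plate and return the multiplicative correction factor (centre / surface)
# evaluated at every well.  Returns NULL when too few wells support a fit.
.loess_surface_factor <- function(wells, seeded, flagged, config) {
  in_pop <- if (config$fit_wells == "compound") wells$role == "compound"
  else seeded
  fit_idx <- which(in_pop & !flagged & !is.na(wells$raw_count) &
                     wells$raw_count > 0)
  if (length(fit_idx) < config$min_fit_wells) return(NULL)
  df <- data.frame(r = match(wells$row, LETTERS), c = wells$column,
                   y = wells$raw_count)
  if (config$log_domain) df$y <- log(df$y)
  fit <- stats::loess(y ~ r + c, data = df[fit_idx, ],
                      span = config$span, degree = config$degree,
                      family = "gaussian", normalize = FALSE,
                      control = stats::loess.control(surface = "direct"))
  surf <- stats::predict(fit, newdata = df[, c("r", "c")])
  centre_fun <- if (config$center == "median") stats::median else mean
  centre <- centre_fun(surf[fit_idx])
  if (config$log_domain) exp(centre - surf) else centre / surf
}

#' Correct within-plate spatial effects by loess smoothing
#'
#' Fits a smooth surface over well coordinates to the unflagged fit
#' population of a plate (by default the compound wells; see
#' [smoothing_config()]) and divides it out: every cell-seeded well (including
#' wells excluded from the fit for toxicity) receives
#' `smoothed_count = raw_count * centre / surface(row, column)`, where the
#' centre is the plate-level median (or mean) of the fitted surface.  Flat
#' plates are left unchanged up to numerical precision, and flagged toxic
#' wells never influence their neighbours' correction.
#'
#' @param wells `well_data` rows of one plate.
#' @param config a [smoothing_config()].
#' @return The wells with `smoothed_count` populated (a new data frame;
#'   the input is not modified).
#' @export
loess_correct <- function(wells, config = smoothing_config()) {
  .plate_check(wells)
  out <- wells
  seeded <- wells$role != "empty"
  flagged <- flag_toxic_wells(wells, config)
  factor <- .loess_surface_factor(wells, seeded, flagged, config)
  if (is.null(factor)) {
    warning("plate ", wells$plate_id[1], ": fewer than ", config$min_fit_wells,
            " unflagged wells; smoothing skipped")
    out$smoothed_count <- ifelse(seeded, wells$raw_count, NA_real_)
    return(out)
  }
  out$smoothed_count <- ifelse(seeded, wells$raw_count * factor, NA_real_)
  out
}

#' Normalise a plate to its DMSO median
#'
#' Divides every smoothed count by the median smoothed count of the plate's
#' DMSO vehicle-control wells, converting counts to fold-change viabilities:
#' after this step the median normalised DMSO value on the plate is exactly
#' 1 and compound values read directly as fractions of baseline growth.
#'
#' @param wells `well_data` rows of one plate with `smoothed_count` set.
#' @return The wells with `normalized_count` populated.
#' @export
normalize_plate <- function(wells) {
  .plate_check(wells)
  if (all(is.na(wells$smoothed_count)))
    stop("smoothed_count missing: run loess_correct() first")
  dmso <- wells$smoothed_count[wells$role == "dmso"]
  dmso <- dmso[!is.na(dmso)]
  if (!length(dmso))
    stop("configuration error: plate ", wells$plate_id[1], " has no DMSO wells")
  med <- stats::median(dmso)
  if (med == 0)
    stop("degenerate plate ", wells$plate_id[1], ": DMSO median is zero")
  out <- wells
  out$normalized_count <- wells$smoothed_count / med
  out
}

#' Assign viability bins
#'
#' Discretises DMSO-normalised counts into the four screen viability bins:
#' high (> 1.15), normal (0.8--1.15), moderate (0.5 to below 0.8) and
#' low (< 0.5).  The boundaries 0.5 and 0.8 belong to the bin above and
#' 1.15 to normal, so every non-negative value maps to exactly one bin.
#'
#' @param normalized_count non-negative numeric vector of fold-changes.
#' @return Character vector of bins (`"high"`, `"normal"`, `"moderate"`,
#'   `"low"`); `NA` in, `NA` out.
#' @export
assign_viability_bin <- function(normalized_count) {
  v <- normalized_count
  if (any(v < 0, na.rm = TRUE)) stop("normalized_count must be non-negative")
  out <- rep(NA_character_, length(v))
  ok <- !is.na(v)
  out[ok & v > 1.15] <- "high"
  out[ok & v >= 0.8 & v <= 1.15] <- "normal"
  out[ok & v >= 0.5 & v < 0.8] <- "moderate"
  out[ok & v < 0.5] <- "low"
  out
}

#' Run the full per-plate normalisation over a screen
#'
#' Applies [loess_correct()], [normalize_plate()] and
#' [assign_viability_bin()] plate by plate.  Returns a new dataset; the
#' input is unmodified.
#'
#' @param dataset a `well_data` data frame covering one or more plates.
#' @param config a [smoothing_config()].
#' @return The dataset with `smoothed_count`, `normalized_count` and
#'   `viability_bin` populated.
#' @export
normalize_screen <- function(dataset, config = smoothing_config()) {
  pieces <- lapply(split(seq_len(nrow(dataset)), dataset$plate_id), function(idx) {
    plate <- normalize_plate(loess_correct(dataset[idx, , drop = FALSE], config))
    plate$viability_bin <- assign_viability_bin(plate$normalized_count)
    list(idx = idx, plate = plate)
  })
  out <- dataset
  for (p in pieces) out[p$idx, ] <- p$plate
  out
}
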