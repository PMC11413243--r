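#' Percent coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, length at least 2.
#' @return Percent CV (scalar).
#' @export
percent_cv <- function(values) {
  x <- values[!is.na(values)]
  if (length(x) < 2L) stop("percent_cv needs at least 2 values")
  m <- mean(x)
  if (m == 0) stop("percent_cv undefined: mean is zero")
  100 * stats::sd(x) / m
}

#' Z-prime factor
#'
#' The screening-assay quality statistic
#' `Z' = 1 - 3 * (sd(pos) + sd(neg)) / |mean(pos) - mean(neg)|`
#' (sample standard deviations, arithmetic means).  Values near 1 indicate
#' an excellent dynamic range between the positive control and the
#' negative-control baseline; values below 0 a failing control.  Returns
#' `NA` with a warning when the two arms have identical means.
#'
#' @param positive,negative numeric vectors (at least 2 values each) of the
#'   positive-control and negative-control measurements.
#' @return Z-prime (scalar, at most 1), or `NA`.
#' @export
z_prime <- function(positive, negative) {
  p <- positive[!is.na(positive)]
  n <- negative[!is.na(negative)]
  if (length(p) < 2L || length(n) < 2L)
    stop("z_prime needs at least 2 values in each arm")
  sep <- abs(mean(p) - mean(n))
  if (sep == 0) {
    warning("z_prime undefined: control arms have identical means")
    return(NA_real_)
  }
  1 - 3 * (stats::sd(p) + stats::sd(n)) / sep
}

# Mean of within-plate %CVs over a control's replicate wells; falls back to
# the CV of per-plate means when no plate carries >= 2 replicate wells
# (single-well controls such as Cisplatin).
.control_cv <- function(values, plates, method) {
  if (method == "pooled") return(percent_cv(values))
  per_plate_mean <- tapply(values, plates, mean)
  if (method == "plate_means") {
    if (length(per_plate_mean) < 2L) return(NA_real_)
    return(percent_cv(as.numeric(per_plate_mean)))
  }
  n_per_plate <- tapply(values, plates, length)
  if (any(n_per_plate >= 2L)) {
    cvs <- tapply(values, plates, function(x)
      if (length(x) >= 2L && mean(x) != 0) 100 * stats::sd(x) / mean(x) else NA_real_)
    return(mean(as.numeric(cvs), na.rm = TRUE))
  }
  if (length(per_plate_mean) < 2L) return(NA_real_)
  percent_cv(as.numeric(per_plate_mean))
}

#' Control performance summary for a screen
#'
#' For every (cell line, control) pair: the number of plates carrying the
#' control, the mean normalised count, the percent CV, and -- for positive
#' controls -- the per-plate Z-prime factor versus the same plate's DMSO
#' wells, summarised as its mean and the count of failing plates
#' (Z-prime below 0).  Negative controls (DMSO, media) are summarised
#' without Z-prime.  Rows are deterministically ordered by cell line then
#' control.
#'
#' @param dataset a `well_data` data frame with `normalized_count` set.
#' @param cv_method `"per_plate"` (default; within-plate percent CV over a
#'   control's replicate wells, averaged across plates), `"plate_means"`
#'   (percent CV across per-plate mean values) or `"pooled"` (across all
#'   wells of all plates).
#' @return An object of class `screen_qc`: a data frame with columns
#'   `cell_line`, `control`, `n_plates`, `mean_normalized`, `percent_cv`,
#'   `zprime_mean`, `zprime_failures`.
#' @export
control_summary <- function(dataset, cv_method = c("per_plate", "plate_means",
                                                   "pooled")) {
  cv_method <- match.arg(cv_method)
  d <- dataset[!is.na(dataset$normalized_count), ]
  if (!nrow(d)) stop("normalized_count missing: run normalize_screen() first")

  ctrl_label <- ifelse(d$role == "dmso", "DMSO",
                ifelse(d$role == "media", "Media",
                ifelse(d$role == "positive_control", d$compound_name,
                       NA_character_)))
  keep <- !is.na(ctrl_label)
  d <- d[keep, ]
  ctrl_label <- ctrl_label[keep]

  rows <- list()
  for (line in sort(unique(d$cell_line))) {
    dl <- d[d$cell_line == line, ]
    ll <- ctrl_label[d$cell_line == line]
    for (ctrl in sort(unique(ll))) {
      dc <- dl[ll == ctrl, ]
      zp_mean <- NA_real_
      zp_fail <- NA_integer_
      if (all(dc$role == "positive_control")) {
        zp <- vapply(unique(dc$plate_id), function(p) {
          pos <- dc$normalized_count[dc$plate_id == p]
          neg <- dl$normalized_count[dl$role == "dmso" & dl$plate_id == p]
          if (length(pos) < 2L || length(neg) < 2L) return(NA_real_)
          z_prime(pos, neg)
        }, 0)
        if (any(!is.na(zp))) {
          zp_mean <- mean(zp, na.rm = TRUE)
          zp_fail <- sum(zp < 0, na.rm = TRUE)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        cell_line = line, control = ctrl,
        n_plates = length(unique(dc$plate_id)),
        mean_normalized = mean(dc$normalized_count),
        percent_cv = .control_cv(dc$normalized_count, dc$plate_id, cv_method),
        zprime_mean = zp_mean, zprime_failures = zp_fail,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("screen_qc", "data.frame")
  out
}

#' @export
print.screen_qc <- function(x, digits = 3, ...) {
  cat("Screen control QC (", length(unique(x$cell_line)), " cell lines, ",
      length(unique(x$control)), " controls)\n", sep = "")
  y <- x
  class(y) <- "data.frame"
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print(y, ...)
  invisible(x)
}

#' Per-plate Z-prime table for positive controls
#'
#' The plate-resolved companion to [control_summary()]: one row per
#' (cell line, plate, positive control) with its Z-prime versus that
#' plate's DMSO wells.  Controls with a single well per plate are skipped
#' (the spread of one well is undefined).
#'
#' @param dataset a `well_data` data frame with `normalized_count` set.
#' @return Data frame: `cell_line`, `plate_id`, `control`, `zprime`.
#' @export
plate_zprime <- function(dataset) {
  d <- dataset[!is.na(dataset$normalized_count), ]
  pos <- d[d$role == "positive_control", ]
  rows <- list()
  for (key in unique(paste(pos$cell_line, pos$plate_id, pos$compound_name,
                           sep = "\r"))) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
    pc <- pos$normalized_count[pos$cell_line == parts[1] &
                                 pos$plate_id == parts[2] &
                                 pos$compound_name == parts[3]]
    if (length(pc) < 2L) next
    neg <- d$normalized_count[d$role == "dmso" & d$cell_line == parts[1] &
                                d$plate_id == parts[2]]
    if (length(neg) < 2L) next
    rows[[length(rows) + 1L]] <- data.frame(
      cell_line = parts[1], plate_id = parts[2], control = parts[3],
      zprime = z_prime(pc, neg), stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(cell_line = character(), plate_id = character(),
                      control = character(), zprime = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$cell_line, out$plate_id, out$control), ]
  rownames(out) <- NULL
  out
}
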