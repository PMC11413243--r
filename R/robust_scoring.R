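#' Drop non-specific doses from a screen
#'
#' Removes compound records at the given doses.  In the primary screen the
#' 10 micromolar concentration is dropped before scoring because it is
#' cytotoxic for the large majority of compounds and therefore carries no
#' compound-specific signal.  Control wells are always retained.
#'
#' @param dataset a `well_data` data frame.
#' @param drop_doses numeric vector of doses (micromolar) to remove.
#' @return The filtered dataset.
#' @export
filter_concentrations <- function(dataset, drop_doses = 10) {
  if (!length(drop_doses)) return(dataset)
  drop <- dataset$role == "compound" &
    !is.na(dataset$concentration) & dataset$concentration %in% drop_doses
  out <- dataset[!drop, , drop = FALSE]
  if (!any(out$role == "compound"))
    warning("all compound records removed by dose filter")
  rownames(out) <- NULL
  out
}

#' Robust Z-scores
#'
#' Centre by the median and scale by the median absolute deviation:
#' `z = (x - median(x)) / (consistency_constant * mad(x))` where
#' `mad(x) = median(|x - median(x)|)`.  The default consistency constant is
#' 1 (the raw MAD); set it to 1.4826 for the normal-consistent convention.
#'
#' @param values numeric vector, length at least 2.
#' @param consistency_constant multiplier applied to the MAD.
#' @param label context used in error messages (e.g. the cell line / dose
#'   slice being scored).
#' @return Numeric vector of scores, same length and order as `values`;
#'   `NA` values propagate.
#' @export
robust_z <- function(values, consistency_constant = 1, label = NULL) {
  x <- values[!is.na(values)]
  if (length(x) < 2L) stop("robust_z needs at least 2 non-missing values")
  med <- stats::median(x)
  mad0 <- stats::median(abs(x - med))
  if (mad0 == 0)
    stop("degenerate scale (MAD = 0)",
         if (!is.null(label)) paste0(" in slice ", label) else "")
  (values - med) / (consistency_constant * mad0)
}

#' Score a screen by per-line, per-dose robust Z
#'
#' Converts normalised counts into robust Z-scores separately for every
#' (cell line, concentration) slice, the scoring population being the
#' compound wells of that slice pooled across plates (control wells are
#' excluded).  Each cell line is scored independently, so one line's
#' distribution never influences another's scores.  Doses not in
#' `retained_doses` are dropped first via [filter_concentrations()].
#'
#' @param dataset a `well_data` data frame with `normalized_count` set.
#' @param retained_doses doses (micromolar) to score; default `c(0.1, 1)`.
#' @param consistency_constant passed to [robust_z()].
#' @param pool_doses if `TRUE`, score each cell line over both retained
#'   doses as one population instead of per dose.
#' @return A list with class `score_matrix`: `scores` (long data frame of
#'   `compound_id`, `cell_line`, `concentration`, `robust_z`) and `dataset`
#'   (the input records with `robust_z` annotated onto compound wells).
#' @export
score_screen <- function(dataset, retained_doses = c(0.1, 1),
                         consistency_constant = 1, pool_doses = FALSE) {
  all_doses <- unique(dataset$concentration[dataset$role == "compound"])
  d <- filter_concentrations(dataset, setdiff(all_doses, retained_doses))
  comp <- which(d$role == "compound" & !is.na(d$concentration))
  if (any(is.na(d$normalized_count[comp])))
    stop("normalized_count missing for compound records: run normalize_screen() first")

  slice_key <- if (pool_doses) d$cell_line[comp]
  else paste(d$cell_line[comp], d$concentration[comp], sep = " @ ")
  d$robust_z <- NA_real_
  for (s in split(comp, slice_key)) {
    d$robust_z[s] <- robust_z(d$normalized_count[s], consistency_constant,
                              label = paste0(d$cell_line[s[1]], " @ ",
                                             d$concentration[s[1]], " uM"))
  }

  scores <- data.frame(compound_id = d$compound_id[comp],
                       cell_line = d$cell_line[comp],
                       concentration = d$concentration[comp],
                       robust_z = d$robust_z[comp],
                       stringsAsFactors = FALSE)
  scores <- scores[order(scores$compound_id, scores$cell_line,
                         scores$concentration), ]
  rownames(scores) <- NULL
  structure(list(scores = scores, dataset = d), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  s <- x$scores
  cat("Robust Z score matrix:", length(unique(s$compound_id)), "compounds x",
      length(unique(s$cell_line)), "cell lines x",
      length(unique(s$concentration)), "dose(s)\n")
  cat("Doses (uM):", paste(sort(unique(s$concentration)), collapse = ", "), "\n")
  invisible(x)
}

#' Write scores in long format
#'
#' @param score_matrix a [score_screen()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(score_matrix, path) {
  utils::write.csv(score_matrix$scores, path, row.names = FALSE, na = "")
  invisible(path)
}
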