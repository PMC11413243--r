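#' Configuration of the synthetic-screen generator
#'
#' Defines the study conditions emulated by [simulate_screen()]: a 13-line
#' panel (12 cancer lines plus one normal control) screened on 384-well
#' plates carrying 14 DMSO, 12 media and duplicate positive-control wells,
#' with compounds at 0.1/1/10 micromolar, multiplicative spatial (edge)
#' effects, log-normal plate scale (batch) factors, Hill-curve compound
#' effects with per-line susceptibility, and negative-binomial counting
#' noise.
#'
#' @param n_compounds number of library compounds.
#' @param doses compound doses, micromolar.
#' @param panel a [cell_line_panel()].
#' @param layout a [default_plate_layout()].
#' @param n_plates plates per cell line; `NULL` (default) uses the minimum
#'   number that fits `n_compounds * length(doses)` wells.
#' @param growth_factor fold-expansion of seeded cells over the 72 h assay
#'   (scalar or named per-line vector).
#' @param edge_effect_amplitude maximum multiplicative depression of the
#'   spatial surface (default 0.15).
#' @param batch_sd standard deviation of the log plate-scale factor.
#' @param noise_dispersion negative-binomial overdispersion phi
#'   (variance = mu + phi * mu^2); 0 disables counting noise entirely.
#' @param effect_mix named proportions of compound classes
#'   `inactive`, `cytotoxic_specific`, `cytotoxic_pan`, `proliferative`
#'   (must sum to 1).
#' @param potency_range EC50 range, micromolar.
#' @param emax_range maximal kill-fraction range for cytotoxic classes.
#' @param hill_range Hill-coefficient range.
#' @param uplift_range viability uplift range for proliferative compounds.
#' @param mild_effect_sd scale of the mild nonspecific growth inhibition
#'   carried by library compounds of the `inactive` class (half-normal
#'   across compounds, saturable in dose with midpoint `mild_ec50`).  This
#'   emulates the broad low-grade anti-proliferative activity typical of
#'   drug libraries; it widens and left-shifts the scoring population so
#'   that a robust Z of -2 corresponds to roughly half-maximal cell death,
#'   and it is what makes the top dose nonspecifically toxic for much of
#'   the library.  Set to 0 for a perfectly inert background.
#' @param mild_effect_max cap on the mild inhibition fraction.
#' @param mild_ec50 dose midpoint (micromolar) of the mild inhibition.
#' @param susceptible_prob probability that each cancer line is susceptible
#'   to a given specific cytotoxic compound.
#' @param positive_control_viability named true viabilities of the positive
#'   controls (fractions of the DMSO baseline).
#' @param seed integer seed; identical (config, seed) gives bit-identical
#'   screens.
#' @return A list with class `simulation_config`.
#' @export
simulation_config <- function(n_compounds = 200, doses = c(0.1, 1, 10),
                              panel = cell_line_panel(),
                              layout = default_plate_layout(),
                              n_plates = NULL,
                              growth_factor = 3,
                              edge_effect_amplitude = 0.15,
                              batch_sd = 0.05,
                              noise_dispersion = 0.006,
                              effect_mix = c(inactive = 0.85,
                                             cytotoxic_specific = 0.06,
                                             cytotoxic_pan = 0.06,
                                             proliferative = 0.03),
                              potency_range = c(0.03, 0.3),
                              emax_range = c(0.75, 0.95),
                              hill_range = c(1, 2),
                              uplift_range = c(0.2, 0.5),
                              mild_effect_sd = 0.6,
                              mild_effect_max = 0.95,
                              mild_ec50 = 1,
                              susceptible_prob = 0.75,
                              positive_control_viability = c(
                                Staurosporine = 0.08, Doxorubicin = 0.20,
                                `Mitomycin C` = 0.25, Paclitaxel = 0.20,
                                Cisplatin = 0.35, Carboplatin = 0.75),
                              seed = 1) {
  stopifnot(n_compounds >= 1, all(doses > 0),
            abs(sum(effect_mix) - 1) < 1e-8,
            all(effect_mix >= 0),
            edge_effect_amplitude >= 0, edge_effect_amplitude < 1,
            batch_sd >= 0, noise_dispersion >= 0,
            mild_effect_sd >= 0, mild_effect_max > 0, mild_effect_max < 1,
            mild_ec50 > 0,
            susceptible_prob > 0, susceptible_prob <= 1)
  needed <- c("inactive", "cytotoxic_specific", "cytotoxic_pan", "proliferative")
  if (!setequal(names(effect_mix), needed))
    stop("effect_mix must name exactly: ", paste(needed, collapse = ", "))

  wells_per_plate <- 384L - nrow(layout)
  required <- ceiling(n_compounds * length(doses) / wells_per_plate)
  if (is.null(n_plates)) n_plates <- required
  if (n_plates < required)
    stop("configuration error: ", n_compounds, " compounds x ", length(doses),
         " doses need at least ", required, " plates per cell line (",
         wells_per_plate, " compound wells each); got ", n_plates)

  structure(list(n_compounds = as.integer(n_compounds), doses = doses,
                 panel = panel, layout = layout,
                 n_plates = as.integer(n_plates),
                 growth_factor = growth_factor,
                 edge_effect_amplitude = edge_effect_amplitude,
                 batch_sd = batch_sd, noise_dispersion = noise_dispersion,
                 effect_mix = effect_mix[needed],
                 potency_range = potency_range, emax_range = emax_range,
                 hill_range = hill_range, uplift_range = uplift_range,
                 mild_effect_sd = mild_effect_sd,
                 mild_effect_max = mild_effect_max, mild_ec50 = mild_ec50,
                 susceptible_prob = susceptible_prob,
                 positive_control_viability = positive_control_viability,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Hill-curve viability of one compound in one line at dose c (micromolar).
# Inactive-class compounds carry their mild nonspecific saturable
# inhibition in every line; cytotoxic compounds act only in susceptible
# lines.
.hill_viability <- function(effect_class, susceptible, ec50, emax, hill,
                            uplift, mild, mild_ec50, conc) {
  if (effect_class == "proliferative") return(1 + uplift)
  if (effect_class == "inactive")
    return(1 - mild * conc / (conc + mild_ec50))
  if (susceptible)
    return(1 - emax * conc^hill / (conc^hill + ec50^hill))
  1
}

# Smooth multiplicative spatial field over the plate: a radial edge
# depression plus a random low-order tilt, bounded so max|1 - S| equals the
# configured amplitude.
.spatial_field <- function(row_idx, col_idx, amplitude, tilt) {
  u <- (col_idx - 12.5) / 11.5
  v <- (row_idx - 8.5) / 7.5
  e <- 0.7 * (u^2 + v^2) / 2 +
    0.15 * (tilt[1] * u + 1) / 2 + 0.15 * (tilt[2] * v + 1) / 2
  1 - amplitude * e
}

.draw_counts <- function(mu, dispersion) {
  if (dispersion == 0) return(round(mu))
  stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
}

#' Simulate a complete screen with known ground truth
#'
#' Generates per-well raw counts for every cell line of the panel across as
#' many 384-well plates as the compound library needs, together with the
#' per-compound truth labels.  Expected counts follow
#' `seeding * growth * batch(plate) * S(row, col) * v(dose)`, where `S` is a
#' smooth spatial field and `v` the Hill-curve viability of the compound in
#' that line; observed counts are negative-binomial around the expectation.
#' Specific cytotoxic compounds spare the control line, pan-toxic compounds
#' kill it too -- the distinction the counter-screen filter is designed to
#' detect.  All randomness flows from `config$seed`; the caller's RNG state
#' is left untouched.
#'
#' @param config a [simulation_config()].
#' @return An object of class `screen_sim`: list with `wells` (a
#'   `well_data` frame, raw counts only), `truth` (one row per compound:
#'   `compound_id`, `effect_class`, `ec50`, `emax`, `hill`, `uplift`,
#'   `mild_inhibition`,
#'   `susceptible_lines` as a `";"`-joined string), `annotations` (compound
#'   annotation table) and `config`.
#' @export
simulate_screen <- function(config = simulation_config()) {
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  panel <- config$panel
  ids <- sprintf("QCL-%04d", seq_len(config$n_compounds))
  classes <- sample(names(config$effect_mix), config$n_compounds,
                    replace = TRUE, prob = config$effect_mix)
  ec50 <- stats::runif(config$n_compounds, config$potency_range[1],
                       config$potency_range[2])
  emax <- stats::runif(config$n_compounds, config$emax_range[1],
                       config$emax_range[2])
  hill <- stats::runif(config$n_compounds, config$hill_range[1],
                       config$hill_range[2])
  uplift <- stats::runif(config$n_compounds, config$uplift_range[1],
                         config$uplift_range[2])
  mild <- pmin(abs(stats::rnorm(config$n_compounds, 0, config$mild_effect_sd)),
               config$mild_effect_max)
  ec50[classes %in% c("inactive", "proliferative")] <- NA_real_
  emax[classes %in% c("inactive", "proliferative")] <- NA_real_
  hill[classes %in% c("inactive", "proliferative")] <- NA_real_
  uplift[classes != "proliferative"] <- NA_real_
  mild[classes != "inactive"] <- NA_real_

  lg <- panel$name[!panel$is_control]
  ctrl_line <- panel$name[panel$is_control]
  susceptible <- vapply(seq_len(config$n_compounds), function(i) {
    switch(classes[i],
      inactive = "",
      proliferative = paste(panel$name, collapse = ";"),
      cytotoxic_pan = paste(panel$name, collapse = ";"),
      cytotoxic_specific = {
        s <- lg[stats::runif(length(lg)) < config$susceptible_prob]
        paste(s, collapse = ";")
      })
  }, "")

  truth <- data.frame(compound_id = ids, effect_class = classes,
                      ec50 = ec50, emax = emax, hill = hill, uplift = uplift,
                      mild_inhibition = mild,
                      susceptible_lines = susceptible,
                      stringsAsFactors = FALSE)

  libraries <- sample(c("FDA", "kinase", "epigenetic"), config$n_compounds,
                      replace = TRUE, prob = c(0.6, 0.25, 0.15))
  target_pool <- sprintf("T%02d", 1:40)
  pathway_pool <- sprintf("PATH%02d", 1:15)
  targets <- vapply(seq_len(config$n_compounds), function(i)
    paste(sample(target_pool, sample(1:2, 1)), collapse = ";"), "")
  annotations <- data.frame(
    compound_id = ids, name = sprintf("CPD-%04d", seq_len(config$n_compounds)),
    library = libraries,
    clinical_phase = sample(c("Approved", "Phase I", "Phase II", "Phase III"),
                            config$n_compounds, replace = TRUE),
    target = targets,
    pathway = sample(pathway_pool, config$n_compounds, replace = TRUE),
    stringsAsFactors = FALSE)

  lay <- config$layout
  lay_key <- paste(lay$row, lay$column)
  all_wells <- expand.grid(row = LETTERS[1:16], column = 1:24,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  all_wells <- all_wells[order(all_wells$row, all_wells$column), ]
  compound_slots <- all_wells[!(paste(all_wells$row, all_wells$column) %in%
                                  lay_key), ]

  jobs <- expand.grid(compound = seq_len(config$n_compounds),
                      dose = config$doses, KEEP.OUT.ATTRS = FALSE)
  jobs <- jobs[order(jobs$compound, jobs$dose), ]

  plates <- list()
  for (li in seq_len(nrow(panel))) {
    line <- panel$name[li]
    seeding <- panel$seeding_density[li]
    growth <- if (length(config$growth_factor) > 1L)
      config$growth_factor[[line]] else config$growth_factor
    baseline <- seeding * growth
    sus_by_cpd <- strsplit(truth$susceptible_lines, ";", fixed = TRUE)

    for (p in seq_len(config$n_plates)) {
      plate_id <- sprintf("%s_P%02d", line, p)
      batch <- exp(stats::rnorm(1, 0, config$batch_sd))
      tilt <- stats::runif(2, -1, 1)

      lo <- (p - 1L) * nrow(compound_slots) + 1L
      hi <- min(p * nrow(compound_slots), nrow(jobs))
      pj <- if (lo <= nrow(jobs)) jobs[lo:hi, , drop = FALSE] else jobs[0, ]
      slots <- compound_slots[seq_len(nrow(pj)), , drop = FALSE]

      ci <- pj$compound
      via <- vapply(seq_len(nrow(pj)), function(k) {
        i <- ci[k]
        .hill_viability(classes[i], line %in% sus_by_cpd[[i]],
                        ec50[i], emax[i], hill[i], uplift[i], mild[i],
                        config$mild_ec50, pj$dose[k])
      }, 0)

      comp <- if (nrow(pj)) well_data(
        plate_id = plate_id, row = slots$row, column = slots$column,
        cell_line = line, role = "compound",
        compound_id = ids[ci], compound_name = annotations$name[ci],
        library = annotations$library[ci], concentration = pj$dose,
        pathway = annotations$pathway[ci], target = annotations$target[ci],
        raw_count = NA_real_) else NULL

      ctl_via <- rep(1, nrow(lay))
      is_pos <- lay$role == "positive_control"
      ctl_via[is_pos] <- config$positive_control_viability[lay$control_name[is_pos]]
      ctl <- well_data(
        plate_id = plate_id, row = lay$row, column = lay$column,
        cell_line = line, role = lay$role,
        compound_name = lay$control_name, concentration = lay$dose,
        raw_count = NA_real_)

      plate <- if (nrow(pj)) rbind(comp, ctl) else ctl
      via_all <- if (nrow(pj)) c(via, ctl_via) else ctl_via
      S <- .spatial_field(match(plate$row, LETTERS), plate$column,
                          config$edge_effect_amplitude, tilt)
      mu <- baseline * batch * S * via_all
      plate$raw_count <- .draw_counts(mu, config$noise_dispersion)
      plates[[length(plates) + 1L]] <- plate
    }
  }

  wells <- do.call(rbind, plates)
  wells <- wells[order(wells$cell_line, wells$plate_id, wells$row,
                       wells$column), ]
  rownames(wells) <- NULL
  class(wells) <- c("well_data", "data.frame")
  structure(list(wells = wells, truth = truth, annotations = annotations,
                 config = config),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Synthetic screen:", x$config$n_compounds, "compounds x",
      nrow(x$config$panel), "cell lines x", length(x$config$doses),
      "doses;", x$config$n_plates, "plate(s)/line,", nrow(x$wells),
      "wells\n")
  print(table(x$truth$effect_class))
  invisible(x)
}

#' Evaluate hit recovery against simulation truth
#'
#' Confusion-matrix rates for how well a predicted compound set recovers a
#' designated truth class.  Positives can be restricted to the strong end
#' of the class (minimum Emax, maximum EC50) to ask whether compounds that
#' genuinely kill at the screened doses are found.
#'
#' @param predicted compound ids called as hits (character vector, or a
#'   `hit_selection` whose high-confidence tier is used).
#' @param truth the `truth` table of a [simulate_screen()] result.
#' @param class_of_interest truth class treated as positive
#'   (default `"cytotoxic_specific"`).
#' @param emax_min,ec50_max optional restriction of the positive class.
#' @return List with `sensitivity`, `specificity`, `precision`, `n_positive`,
#'   `n_predicted`.
#' @export
truth_evaluation <- function(predicted, truth,
                             class_of_interest = "cytotoxic_specific",
                             emax_min = NULL, ec50_max = NULL) {
  if (inherits(predicted, "hit_selection")) predicted <- predicted$high
  predicted <- unique(as.character(predicted))
  if (length(predicted) && !any(predicted %in% truth$compound_id))
    stop("predicted compounds share no ids with the truth table")

  pos <- truth$effect_class == class_of_interest
  if (!is.null(emax_min)) pos <- pos & !is.na(truth$emax) & truth$emax >= emax_min
  if (!is.null(ec50_max)) pos <- pos & !is.na(truth$ec50) & truth$ec50 <= ec50_max
  pos_ids <- truth$compound_id[pos]
  neg_ids <- truth$compound_id[!pos]

  tp <- sum(pos_ids %in% predicted)
  fp <- sum(neg_ids %in% predicted)
  list(
    sensitivity = if (length(pos_ids)) tp / length(pos_ids) else NA_real_,
    specificity = if (length(neg_ids)) 1 - fp / length(neg_ids) else NA_real_,
    precision = if (length(predicted)) tp / length(predicted) else NA_real_,
    n_positive = length(pos_ids), n_predicted = length(predicted))
}
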