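#' The 2 x 2 x 2 analysis-method grid
#'
#' All eight combinations of kinetic model (two_param / three_param), VIF
#' source (individual / population) and ROI mode (whole_roi / pixel).
#'
#' @return Data frame with columns \code{model}, \code{vif_source},
#'   \code{roi_mode} and a compact \code{combo} label such as
#'   \code{"3p.indiv.pixel"}.
#' @export
method_grid <- function() {
  g <- expand.grid(model = c("two_param", "three_param"),
                   vif_source = c("population", "individual"),
                   roi_mode = c("whole_roi", "pixel"),
                   stringsAsFactors = FALSE)
  g$combo <- combo_label(g$model, g$vif_source, g$roi_mode)
  g
}

#' @rdname method_grid
#' @param model,vif_source,roi_mode Grid cell identifiers.
#' @export
combo_label <- function(model, vif_source, roi_mode) {
  paste(ifelse(model == "two_param", "2p", "3p"),
        ifelse(vif_source == "population", "pop", "indiv"),
        ifelse(roi_mode == "whole_roi", "whole", "pixel"),
        sep = ".")
}

#' Run the full analysis-method grid over a study
#'
#' For every available subject-visit: computes the delta-SI series, extracts
#' the individual VIF from the vessel mask; then builds the population VIF
#' from all individual VIFs across all subjects and visits; then fits every
#' cell of the 2 x 2 x 2 grid.  Missing visits are tolerated and logged.
#'
#' @param study A \code{dce_study} from \code{\link{generate_study}} (or an
#'   equivalently shaped list built from real data).
#' @param combos Subset of \code{\link{method_grid}} rows to run (default
#'   all 8).
#' @param bounds \code{\link{pk_bounds}} used by every fit.
#' @param threshold Enhancement-filter threshold for pixel mode.
#' @param verbose Emit progress messages.
#' @return Tidy data frame, one row per (subject, day, combo, parameter):
#'   columns \code{subject_id}, \code{visit_day}, \code{model},
#'   \code{vif_source}, \code{roi_mode}, \code{method_combo},
#'   \code{parameter}, \code{value}.  The fitted population-VIF parameters
#'   are attached as attribute \code{"population_vif"}.
#' @export
run_grid <- function(study, combos = method_grid(), bounds = pk_bounds(),
                     threshold = 0.5, verbose = FALSE) {
  stopifnot(inherits(study, "dce_study") || is.list(study))
  say <- function(...) if (verbose) message(sprintf(...))

  dsi <- list(); ivifs <- list(); keys <- list()
  for (s in seq_along(study$subjects)) {
    subj <- study$subjects[[s]]
    for (v in seq_along(subj$visits)) {
      ser <- subj$visits[[v]]
      if (is.null(ser)) {
        say("subject %d visit %d missing; skipped", s, v)
        next
      }
      ds <- delta_si(ser)
      key <- sprintf("s%d.v%d", s, v)
      dsi[[key]] <- ds
      ivifs[[key]] <- extract_individual_vif(ds, subj$vessel_mask)
      keys[[key]] <- list(s = s, v = v)
    }
  }
  if (length(ivifs) < 2)
    stop("need at least 2 available subject-visits")
  pop <- population_vif(unname(ivifs))
  say("population VIF: A1=%.3f m1=%.4f A2=%.3f m2=%.5f",
      pop$params["A1"], pop$params["m1"], pop$params["A2"],
      pop$params["m2"])

  rows <- list()
  for (key in names(dsi)) {
    ds <- dsi[[key]]
    info <- keys[[key]]
    subj <- study$subjects[[info$s]]
    for (i in seq_len(nrow(combos))) {
      cb <- combos[i, ]
      vif <- if (cb$vif_source == "individual") ivifs[[key]] else pop
      fit <- if (cb$roi_mode == "whole_roi") {
        fit_whole_roi(ds, subj$tumor_mask, vif, model = cb$model,
                      bounds = bounds)
      } else {
        fit_pixelwise(ds, subj$tumor_mask, vif, model = cb$model,
                      bounds = bounds, threshold = threshold)
      }
      agg <- fit$aggregate
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = ds$subject_id, visit_day = ds$visit_day,
        model = cb$model, vif_source = cb$vif_source,
        roi_mode = cb$roi_mode, method_combo = cb$combo,
        parameter = names(agg), value = unname(agg),
        row.names = NULL)
    }
    say("fitted %s", key)
  }
  out <- do.call(rbind, rows)
  attr(out, "population_vif") <- pop$params
  out
}

#' Summarise grid results: parameter values and repeatability by method
#'
#' Per method combination and parameter: the median and inter-quartile range
#' over subjects (each subject summarised by the mean of its day values),
#' the within-subject CV with confidence bounds computed from the per-day
#' values, and the log-scale inter/intra variance components.
#'
#' @param results Tidy results from \code{\link{run_grid}}.
#' @param conf_level Confidence level for wCV bounds.
#' @return Data frame with one row per (combo, parameter): \code{median},
#'   \code{iqr_lo}, \code{iqr_hi}, \code{wcv}, \code{wcv_lo}, \code{wcv_hi}
#'   (percent), \code{inter_vc}, \code{intra_vc}, \code{n_subjects}.
#' @export
summarize_grid <- function(results, conf_level = 0.95) {
  need <- c("subject_id", "visit_day", "method_combo", "parameter", "value")
  if (!all(need %in% names(results)))
    stop("`results` must be a run_grid output")
  cells <- unique(results[, c("model", "vif_source", "roi_mode",
                              "method_combo", "parameter")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    sub <- results[results$method_combo == cell$method_combo &
                     results$parameter == cell$parameter, ]
    subj_means <- tapply(sub$value, sub$subject_id, mean)
    qs <- quantile(subj_means, c(0.25, 0.5, 0.75), names = FALSE)
    n_visits <- tapply(sub$visit_day, sub$subject_id, length)
    if (all(n_visits < 2)) {
      warning(sprintf("%s %s: single visit only; wCV omitted",
                      cell$method_combo, cell$parameter))
      rep <- list(wcv = NA_real_, wcv_bounds = c(NA_real_, NA_real_),
                  inter_vc = NA_real_, intra_vc = NA_real_)
    } else {
      rep <- wcv(sub, conf_level = conf_level)
    }
    data.frame(cell, median = qs[2], iqr_lo = qs[1], iqr_hi = qs[3],
               wcv = rep$wcv, wcv_lo = rep$wcv_bounds[1],
               wcv_hi = rep$wcv_bounds[2],
               inter_vc = rep$inter_vc, intra_vc = rep$intra_vc,
               n_subjects = length(subj_means), row.names = NULL)
  })
  do.call(rbind, rows)
}
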