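#' Parameter bounds for the kinetic fit
#'
#' Positive-definite box constraints applied during fitting.  Endpoints
#' flagged open are excluded from the valid region: a fit pinned at (or
#' numerically indistinguishable from) an open endpoint is flagged invalid
#' and its parameters set to NaN, mirroring the practice of excluding
#' "not a number" pixels from downstream statistics.
#'
#' @param ktrans_range Ktrans range, 1/min; lower endpoint open.
#' @param ve_range ve range; lower endpoint open.
#' @param vp_range vp range; upper endpoint open.
#' @return An object of class \code{pk_bounds}.
#' @export
pk_bounds <- function(ktrans_range = c(1e-5, 10),
                      ve_range = c(1e-5, 1),
                      vp_range = c(0, 1)) {
  structure(list(
    lower = c(Ktrans = ktrans_range[1], ve = ve_range[1], vp = vp_range[1]),
    upper = c(Ktrans = ktrans_range[2], ve = ve_range[2], vp = vp_range[2]),
    open_lower = c(Ktrans = TRUE, ve = TRUE, vp = FALSE),
    open_upper = c(Ktrans = FALSE, ve = FALSE, vp = TRUE)
  ), class = "pk_bounds")
}

# TRUE when a parameter vector sits strictly inside the valid region
# (clear of open endpoints by a small tolerance).
within_bounds <- function(p, bounds) {
  nm <- names(p)
  lo <- bounds$lower[nm]; up <- bounds$upper[nm]
  tol <- 1e-8 * pmax(abs(up - lo), 1)
  ok_lo <- ifelse(bounds$open_lower[nm], p > lo + tol, p >= lo - tol)
  ok_up <- ifelse(bounds$open_upper[nm], p < up - tol, p <= up + tol)
  all(ok_lo & ok_up)
}

model_resid <- function(p, model, vif, times, ct) {
  pk <- if (model == "two_param") {
    list(Ktrans = p[1], ve = p[2], kep = p[1] / p[2])
  } else {
    list(Ktrans = p[1], ve = p[2], vp = p[3], kep = p[1] / p[2])
  }
  pred <- uptake_term(pk$Ktrans, pk$kep, vif, times)
  if (model == "three_param") pred <- pred + pk$vp * cp_at(vif, times)
  ct - pred
}

#' Fit a kinetic model to a single tissue curve
#'
#' Bounded Levenberg-Marquardt least squares of the two- or three-parameter
#' compartment model to one delta-SI tissue curve.  All frames are fitted,
#' including pre-injection baseline frames where the model predicts zero,
#' anchoring the baseline.  A fit that fails to converge, or whose parameters
#' land at or beyond an open bound endpoint, is returned with
#' \code{valid = FALSE} and all parameters NaN.
#'
#' @param ct Tissue delta-SI curve, one value per time.
#' @param times Seconds from injection (negative = pre-injection frames).
#' @param vif A \code{\link{vif_curve}}.
#' @param model \code{"two_param"} or \code{"three_param"}.
#' @param bounds A \code{\link{pk_bounds}}.
#' @param init Starting values \code{c(Ktrans, ve, vp)} (1/min, fractions);
#'   defaults near typical tumour values.
#' @param n_starts Number of starts: the default start plus Ktrans scaled
#'   down/up by 3x for additional starts (3 recommended for ROI-average
#'   curves, 1 for pixel curves where speed dominates).
#' @return A \code{\link{pk_params}} with \code{rss} filled in.
#' @export
fit_curve <- function(ct, times, vif, model = c("two_param", "three_param"),
                      bounds = pk_bounds(), init = c(0.1, 0.2, 0.02),
                      n_starts = 1) {
  model <- match.arg(model)
  stopifnot(inherits(vif, "vif_curve"))
  npar <- if (model == "two_param") 2L else 3L
  if (length(ct) != length(times))
    stop("curve and time grid lengths differ")
  if (length(ct) < npar + 1)
    stop("fewer time points than free parameters + 1")

  nm <- c("Ktrans", "ve", "vp")[seq_len(npar)]
  lower <- bounds$lower[nm]; upper <- bounds$upper[nm]
  start0 <- pmin(pmax(init[seq_len(npar)], lower), upper)
  scales <- c(1, 1 / 3, 3)[seq_len(max(1, min(n_starts, 3)))]
  starts <- lapply(scales, function(s) {
    st <- start0
    st[1] <- min(max(st[1] * s, lower[1]), upper[1])
    st
  })

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = unname(lower),
                         upper = unname(upper),
                         fn = model_resid, model = model, vif = vif,
                         times = times, ct = ct,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (fit$info %in% 1:4 && (is.null(best) || rss < best$rss))
      best <- list(par = setNames(fit$par, nm), rss = rss)
  }

  if (is.null(best) || !within_bounds(best$par, bounds)) {
    return(pk_params(NaN, NaN, vp = if (npar == 3) NaN else NULL,
                     model = model, valid = FALSE,
                     rss = if (is.null(best)) NA_real_ else best$rss))
  }
  pk_params(best$par[["Ktrans"]], best$par[["ve"]],
            vp = if (npar == 3) best$par[["vp"]] else NULL,
            model = model, valid = TRUE, rss = best$rss)
}

#' Pixel enhancement filter
#'
#' A pixel is kept for kinetic fitting only when its peak post-injection
#' signal change reaches at least \code{threshold} (default 50%) of its
#' baseline signal; pixels with non-significant enhancement are excluded
#' from further analysis.  The comparison is inclusive: a peak of exactly
#' 50% of baseline is kept.  Non-positive baselines cannot define a relative
#' increase and are excluded with a distinct reason code.
#'
#' @param pixel_curve Delta-SI curve for one pixel (all frames).
#' @param baseline_si The pixel's baseline SI (> 0 for a valid comparison).
#' @param post_idx Indices of post-injection frames within the curve.
#' @param threshold Fractional increase required (default 0.5).
#' @return List with \code{keep} (logical) and \code{reason} (one of
#'   \code{"ok"}, \code{"insufficient_enhancement"},
#'   \code{"nonpositive_baseline"}).
#' @export
enhancement_filter <- function(pixel_curve, baseline_si, post_idx,
                               threshold = 0.5) {
  if (!is.finite(baseline_si) || baseline_si <= 0)
    return(list(keep = FALSE, reason = "nonpositive_baseline"))
  peak <- max(pixel_curve[post_idx])
  if (peak >= threshold * baseline_si)
    list(keep = TRUE, reason = "ok")
  else
    list(keep = FALSE, reason = "insufficient_enhancement")
}

#' Select the analysed tumour slices
#'
#' Picks the \code{n} slices with the largest ROI cross-sectional area,
#' breaking ties toward the centre of the occupied slice range (the "central
#' slices" of the tumour).
#'
#' @param roi_mask 3D logical array.
#' @param n Number of slices to analyse (default 3).
#' @return Integer vector of slice indices, sorted.
#' @export
select_central_slices <- function(roi_mask, n = 3) {
  areas <- apply(roi_mask, 3, sum)
  occupied <- which(areas > 0)
  if (length(occupied) == 0) stop("ROI mask is empty")
  n <- min(n, length(occupied))
  centre <- mean(range(occupied))
  ord <- occupied[order(-areas[occupied], abs(occupied - centre))]
  sort(ord[seq_len(n)])
}

roi_slice_curves <- function(series, roi_mask, slice) {
  d <- dim(series$data)
  sl <- matrix(series$data[, , slice, ], nrow = d[1] * d[2], ncol = d[4])
  idx <- which(as.logical(roi_mask[, , slice]))
  list(curves = sl[idx, , drop = FALSE], idx = idx)
}

new_roi_fit_result <- function(mode, per_slice, aggregate, counts, model) {
  structure(list(mode = mode, per_slice = per_slice, aggregate = aggregate,
                 n_pixels_total = counts$total,
                 n_pixels_excluded_enhancement = counts$excluded,
                 n_pixels_nan = counts$nan,
                 model = model),
            class = "roi_fit_result")
}

#' @export
print.roi_fit_result <- function(x, ...) {
  cat(sprintf("<roi_fit_result> %s mode, %s, %d slice(s)\n",
              x$mode, x$model, length(x$per_slice)))
  cat("  aggregate:",
      paste(sprintf("%s=%.4g", names(x$aggregate), x$aggregate),
            collapse = ", "), "\n")
  if (x$mode == "pixel")
    cat(sprintf("  pixels: %d total, %d excluded (enhancement), %d NaN\n",
                x$n_pixels_total, x$n_pixels_excluded_enhancement,
                x$n_pixels_nan))
  invisible(x)
}

param_vec <- function(pk) {
  v <- c(Ktrans = pk$Ktrans, ve = pk$ve, kep = pk$kep)
  if (!is.null(pk$vp)) v <- c(v, vp = pk$vp)
  v
}

#' Whole-ROI kinetic fit
#'
#' For each analysed slice, averages the delta-SI curves over the ROI and
#' fits the kinetic model once to the mean curve (multi-start).  The
#' three-slice aggregate is the arithmetic mean of each parameter over the
#' per-slice fits; since kep is averaged per slice, the aggregate kep is the
#' mean of slice keps, not aggregate Ktrans / aggregate ve.
#'
#' @param series A delta-SI \code{\link{dynamic_series}}.
#' @param roi_mask 3D logical tumour mask.
#' @param vif A \code{\link{vif_curve}}.
#' @param model \code{"two_param"} or \code{"three_param"}.
#' @param slices Slice indices to analyse; default the three largest-area
#'   central slices.
#' @param ... Passed to \code{\link{fit_curve}} (bounds, init).
#' @return A \code{roi_fit_result} with \code{mode = "whole_roi"}.
#' @export
fit_whole_roi <- function(series, roi_mask, vif,
                          model = c("two_param", "three_param"),
                          slices = NULL, ...) {
  model <- match.arg(model)
  stopifnot(inherits(series, "dynamic_series"))
  if (series$units != "delta_si")
    stop("fit_whole_roi expects a delta-SI series (run delta_si first)")
  if (!identical(dim(roi_mask), dim(series$data)[1:3]))
    stop("ROI mask dimensions do not match the series")
  if (is.null(slices)) slices <- select_central_slices(roi_mask)
  times <- frame_times(series)

  per_slice <- list()
  for (sl in slices) {
    sc <- roi_slice_curves(series, roi_mask, sl)
    if (length(sc$idx) == 0) {
      warning(sprintf("slice %d has an empty ROI; skipped", sl))
      next
    }
    mean_curve <- colMeans(sc$curves)
    per_slice[[as.character(sl)]] <-
      fit_curve(mean_curve, times, vif, model = model, n_starts = 3, ...)
  }
  if (length(per_slice) == 0) stop("ROI is empty in every analysed slice")

  mat <- do.call(rbind, lapply(per_slice, param_vec))
  aggregate <- colMeans(mat)
  counts <- list(total = sum(vapply(slices, function(sl)
    sum(roi_mask[, , sl]), 0)), excluded = 0L, nan = 0L)
  new_roi_fit_result("whole_roi", per_slice, aggregate, counts, model)
}

#' Pixel-by-pixel kinetic fit
#'
#' Fits the kinetic model to every ROI pixel that passes the enhancement
#' filter; fits flagged NaN (non-convergent or at a positive-definite bound)
#' are excluded from summaries.  The per-slice summary is the median over
#' valid pixels of each parameter (kep medians are taken over per-pixel kep
#' values); the aggregate is the mean of the per-slice medians.  Parameter
#' maps are returned as 3D arrays (NA outside the ROI or where invalid).
#'
#' @inheritParams fit_whole_roi
#' @param threshold Enhancement-filter fractional increase (default 0.5).
#' @param summary_fun Per-slice summary over valid pixels (default
#'   \code{median}).
#' @return A \code{roi_fit_result} with \code{mode = "pixel"}; element
#'   \code{maps} holds one 3D array per parameter.
#' @export
fit_pixelwise <- function(series, roi_mask, vif,
                          model = c("two_param", "three_param"),
                          slices = NULL, threshold = 0.5,
                          summary_fun = median, ...) {
  model <- match.arg(model)
  stopifnot(inherits(series, "dynamic_series"))
  if (series$units != "delta_si")
    stop("fit_pixelwise expects a delta-SI series (run delta_si first)")
  if (is.null(series$baseline_si))
    stop("series lacks baseline_si (needed by the enhancement filter); ",
         "produce it with delta_si()")
  if (!identical(dim(roi_mask), dim(series$data)[1:3]))
    stop("ROI mask dimensions do not match the series")
  if (is.null(slices)) slices <- select_central_slices(roi_mask)
  times <- frame_times(series)
  d <- dim(series$data)
  post_idx <- seq(series$spec$injection_frame, d[4])

  pnames <- c("Ktrans", "ve", "kep", if (model == "three_param") "vp")
  maps <- lapply(pnames, function(p) array(NA_real_, dim = d[1:3]))
  names(maps) <- pnames

  per_slice <- list()
  n_total <- 0L; n_excl <- 0L; n_nan <- 0L
  for (sl in slices) {
    sc <- roi_slice_curves(series, roi_mask, sl)
    if (length(sc$idx) == 0) {
      warning(sprintf("slice %d has an empty ROI; skipped", sl))
      next
    }
    base_sl <- as.vector(series$baseline_si[, , sl])[sc$idx]
    n_total <- n_total + length(sc$idx)
    vals <- matrix(NA_real_, nrow = length(sc$idx), ncol = length(pnames),
                   dimnames = list(NULL, pnames))
    for (i in seq_along(sc$idx)) {
      filt <- enhancement_filter(sc$curves[i, ], base_sl[i], post_idx,
                                 threshold)
      if (!filt$keep) { n_excl <- n_excl + 1L; next }
      pk <- fit_curve(sc$curves[i, ], times, vif, model = model,
                      n_starts = 1, ...)
      if (!pk$valid) { n_nan <- n_nan + 1L; next }
      vals[i, ] <- param_vec(pk)[pnames]
    }
    valid_rows <- !is.na(vals[, 1])
    for (p in pnames) {
      m2 <- maps[[p]][, , sl]
      m2[sc$idx] <- vals[, p]
      maps[[p]][, , sl] <- m2
    }
    if (any(valid_rows)) {
      per_slice[[as.character(sl)]] <- list(
        summary = apply(vals[valid_rows, , drop = FALSE], 2, summary_fun),
        n_valid = sum(valid_rows))
    }
  }
  if (length(per_slice) == 0)
    stop(sprintf(paste0("no valid pixel in any analysed slice ",
                        "(%d total, %d excluded by enhancement, %d NaN)"),
                 n_total, n_excl, n_nan))

  mat <- do.call(rbind, lapply(per_slice, `[[`, "summary"))
  aggregate <- colMeans(mat)
  res <- new_roi_fit_result("pixel", per_slice, aggregate,
                            list(total = n_total, excluded = n_excl,
                                 nan = n_nan), model)
  res$maps <- maps
  res
}
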