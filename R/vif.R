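#' Extract an individual VIF from a vessel mask
#'
#' Builds a subject's vascular input function from the delta-SI curves of
#' voxels inside a vessel mask.  Candidate voxels are kept when (i) their
#' peak post-injection delta-SI is at or above a percentile threshold of the
#' in-mask peaks, (ii) that peak is strictly positive, and (iii) the peak
#' occurs within an early time-to-peak window after injection (a bolus
#' passes early; late-peaking voxels are partial-volume tissue).  The VIF is
#' the mean delta-SI curve of the selected voxels over the post-injection
#' frames, with time 0 at the injection frame.
#'
#' @param series A delta-SI \code{\link{dynamic_series}} (run
#'   \code{\link{delta_si}} first).
#' @param vessel_mask 3D logical array, same spatial dimensions as the series.
#' @param spec Baseline specification; defaults to the series' own.
#' @param peak_percentile In-mask peak percentile a voxel must reach
#'   (default 75).
#' @param ttp_window Number of post-injection frames within which the peak
#'   must occur (default 5).
#' @return A \code{\link{vif_curve}} with \code{source = "individual"} and
#'   \code{n_voxels} recording how many voxels were averaged.
#' @export
extract_individual_vif <- function(series, vessel_mask, spec = series$spec,
                                   peak_percentile = 75, ttp_window = 5) {
  stopifnot(inherits(series, "dynamic_series"))
  if (series$units != "delta_si")
    stop("extract_individual_vif expects a delta-SI series")
  d <- dim(series$data)
  if (!identical(dim(vessel_mask), d[1:3]))
    stop("vessel mask dimensions do not match the series")
  vox <- which(as.logical(vessel_mask))
  if (length(vox) == 0) stop("vessel mask is empty")

  flat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  curves <- flat[vox, , drop = FALSE]
  post <- seq(spec$injection_frame, d[4])
  peaks <- apply(curves[, post, drop = FALSE], 1, max)
  ttp <- apply(curves[, post, drop = FALSE], 1, which.max)

  thr <- quantile(peaks, peak_percentile / 100, names = FALSE, type = 7)
  keep <- peaks >= thr & peaks > 0 & ttp <= ttp_window
  if (!any(keep))
    stop("empty VIF: no vessel voxel passed peak/time-to-peak selection")

  mean_curve <- colMeans(curves[keep, post, drop = FALSE])
  times <- (post - spec$injection_frame) * series$frame_interval_s
  vif_curve(times, mean_curve, source = "individual",
            n_voxels = sum(keep))
}

# Given candidate rate pairs, solve the amplitudes by linear least squares
# (clipped at 0) and polish with bounded Levenberg-Marquardt.
biexp_fit_once <- function(times, values, m_start, lower, upper) {
  basis <- cbind(exp(-m_start[1] * times), exp(-m_start[2] * times))
  amps <- tryCatch(stats::coef(stats::lm.fit(basis, values)),
                   error = function(e) c(NA, NA))
  amps[!is.finite(amps) | amps < 0] <- max(values) / 2
  start <- pmin(pmax(c(amps[1], m_start[1], amps[2], m_start[2]), lower), upper)
  fit <- minpack.lm::nls.lm(
    par = start,
    lower = lower, upper = upper,
    fn = function(p, tt, vv)
      vv - p[1] * exp(-p[2] * tt) - p[3] * exp(-p[4] * tt),
    tt = times, vv = values,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  list(par = fit$par, rss = sum(fit$fvec^2), info = fit$info,
       message = fit$message)
}

#' Fit a biexponential decay to a sampled curve
#'
#' Bounded nonlinear least squares of
#' \code{A1 exp(-m1 t) + A2 exp(-m2 t)} to a (time, value) curve, with
#' multi-start initialisation: starting fast rates are log-spaced over the
#' plausible bolus-clearance range and the slow rate is a fixed fraction of
#' the fast one (sum-of-exponentials fitting has local minima; multiple
#' deterministic starts avoid the trap without randomness).  Amplitudes are
#' bounded below at 0 and rates must be positive, so a negative fitted
#' amplitude is impossible by construction.  The returned parameters are
#' ordered fast component first (\code{m1 > m2}).
#'
#' @param times Seconds from injection.
#' @param values Curve values (delta-SI).
#' @param rate_starts Starting fast rates, 1/s (default log-spaced
#'   \code{0.1, 0.0316, 0.01}).
#' @param rate_bounds Allowed rate range, 1/s.
#' @param amp_upper Upper amplitude bound; default 10x the curve maximum.
#' @return List with \code{params} (named \code{A1, m1, A2, m2}), \code{rss},
#'   and \code{fitted} values on the input grid.
#' @export
fit_biexp <- function(times, values,
                      rate_starts = 10^seq(-1, -2, length.out = 3),
                      rate_bounds = c(1e-6, 1),
                      amp_upper = 10 * max(values)) {
  if (length(times) != length(values) || length(times) < 5)
    stop("need at least 5 samples to fit a biexponential")
  if (max(values) <= 0) stop("curve has no positive values to fit")
  lower <- c(0, rate_bounds[1], 0, rate_bounds[1])
  upper <- c(amp_upper, rate_bounds[2], amp_upper, rate_bounds[2])
  fits <- lapply(rate_starts, function(m1)
    biexp_fit_once(times, values, c(m1, m1 / 30), lower, upper))
  ok <- vapply(fits, function(f) f$info %in% 1:4, logical(1))
  if (!any(ok))
    stop("biexponential fit failed to converge from every start: ",
         paste(unique(vapply(fits, `[[`, "", "message")), collapse = "; "))
  best <- fits[ok][[which.min(vapply(fits[ok], `[[`, 0, "rss"))]]
  p <- best$par
  if (p[2] < p[4]) p <- p[c(3, 4, 1, 2)]   # fast component first
  params <- setNames(p, c("A1", "m1", "A2", "m2"))
  list(params = params, rss = best$rss,
       fitted = biexp_eval(params, times))
}

#' Build a population VIF from individual VIFs
#'
#' Averages individual VIF curves pointwise across all supplied curves (all
#' subjects and visits, unweighted) on their common post-injection time grid,
#' then fits a biexponential decay to the mean curve with
#' \code{\link{fit_biexp}}.  The returned curve is the fitted biexponential
#' evaluated on the grid, tagged \code{source = "population"} and carrying
#' the fitted \code{(A1, m1, A2, m2)}.
#'
#' @param individual_vifs List of at least two \code{\link{vif_curve}}s on a
#'   common time grid.
#' @param ... Passed to \code{\link{fit_biexp}}.
#' @return A population \code{\link{vif_curve}}.
#' @export
population_vif <- function(individual_vifs, ...) {
  if (!is.list(individual_vifs) || length(individual_vifs) < 2)
    stop("need at least 2 individual VIF curves")
  if (!all(vapply(individual_vifs, inherits, logical(1), "vif_curve")))
    stop("all inputs must be vif_curve objects")
  times <- individual_vifs[[1]]$times
  same <- vapply(individual_vifs, function(v)
    length(v$times) == length(times) && max(abs(v$times - times)) < 1e-6,
    logical(1))
  if (!all(same)) stop("individual VIFs must share a common time grid")
  mean_curve <- rowMeans(vapply(individual_vifs, `[[`,
                                numeric(length(times)), "values"))
  fit <- fit_biexp(times, mean_curve, ...)
  vif <- vif_curve(times, fit$fitted, source = "population",
                   params = fit$params)
  vif$rss <- fit$rss
  vif
}

#' Export population VIF parameters as JSON
#'
#' Writes \code{\{A1, m1, A2, m2, units\}} for a population VIF.
#'
#' @param vif A population \code{\link{vif_curve}}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_vif_params_json <- function(vif, path) {
  stopifnot(inherits(vif, "vif_curve"))
  if (is.null(vif$params)) stop("VIF carries no biexponential parameters")
  obj <- c(as.list(vif$params),
           list(units = list(A = "delta_si", m = "1/s")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
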