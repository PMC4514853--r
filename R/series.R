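#' Baseline specification
#'
#' Defines which frames form the pre-contrast baseline and which frame is the
#' first post-contrast (injection) frame.  Frame indices are 1-based, as in
#' acquisition protocols ("frames 5-10"); internal code converts as needed.
#' Defaults follow a 50-frame protocol with 10 baseline scans: baseline
#' signal averaged over frames 5-10 (after steady state, before contrast),
#' injection at frame 11.
#'
#' @param baseline_frames Length-2 inclusive frame-index range (1-based).
#' @param injection_frame First post-contrast frame index (1-based).
#' @return An object of class \code{baseline_spec}.
#' @export
baseline_spec <- function(baseline_frames = c(5, 10), injection_frame = 11) {
  baseline_frames <- as.integer(baseline_frames)
  injection_frame <- as.integer(injection_frame)
  if (length(baseline_frames) != 2 || baseline_frames[1] < 1 ||
      baseline_frames[2] < baseline_frames[1])
    stop("baseline_frames must be an increasing 1-based inclusive range")
  if (baseline_frames[2] - baseline_frames[1] + 1 < 2)
    stop("the baseline range must contain at least 2 frames")
  if (injection_frame <= baseline_frames[2])
    stop("the baseline range must precede the injection frame")
  structure(list(baseline_frames = baseline_frames,
                 injection_frame = injection_frame),
            class = "baseline_spec")
}

#' Dynamic image series
#'
#' A 4D signal-intensity stack (x, y, slice, frame) with its frame timing and
#' baseline specification.  \code{data} may be raw SI or delta-SI; series
#' produced by \code{\link{delta_si}} carry the subtracted per-voxel baseline
#' in the \code{baseline_si} field and are flagged \code{units = "delta_si"}.
#'
#' @param data 4D numeric array (x, y, slice, frame).
#' @param frame_interval_s Frame interval in seconds (> 0).
#' @param spec A \code{\link{baseline_spec}}.
#' @param subject_id,visit_day Identifiers carried through to tidy outputs.
#' @param units \code{"si"} or \code{"delta_si"}.
#' @param baseline_si Optional 3D array of per-voxel baseline SI.
#' @return An object of class \code{dynamic_series}.
#' @export
dynamic_series <- function(data, frame_interval_s, spec = baseline_spec(),
                           subject_id = NA_character_, visit_day = NA_integer_,
                           units = c("si", "delta_si"), baseline_si = NULL) {
  units <- match.arg(units)
  if (!is.array(data) || length(dim(data)) != 4)
    stop("`data` must be a 4D array (x, y, slice, frame)")
  if (!is.numeric(frame_interval_s) || frame_interval_s <= 0)
    stop("`frame_interval_s` must be positive")
  if (dim(data)[4] < spec$baseline_frames[2])
    stop("series has fewer frames than the baseline range")
  structure(
    list(data = data, frame_interval_s = frame_interval_s, spec = spec,
         subject_id = subject_id, visit_day = visit_day, units = units,
         baseline_si = baseline_si),
    class = "dynamic_series"
  )
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<dynamic_series> %dx%dx%d voxels, %d frames @ %.1f s (%s units)\n",
    d[1], d[2], d[3], d[4], x$frame_interval_s, x$units))
  cat(sprintf("  subject %s, day %s; baseline frames %d-%d, injection frame %d\n",
              x$subject_id, x$visit_day, x$spec$baseline_frames[1],
              x$spec$baseline_frames[2], x$spec$injection_frame))
  invisible(x)
}

#' Frame times relative to injection
#'
#' Seconds from the injection frame for each acquired frame (frame i maps to
#' \code{(i - injection_frame) * frame_interval_s}; pre-injection frames are
#' negative).
#'
#' @param series A \code{dynamic_series}.
#' @return Numeric vector, one time per frame.
#' @export
frame_times <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  n <- dim(series$data)[4]
  (seq_len(n) - series$spec$injection_frame) * series$frame_interval_s
}

#' Signal change from baseline
#'
#' Converts a raw SI series to delta-SI: for each voxel the baseline is the
#' mean SI over the baseline frames, and \code{dSI(t) = SI(t) - SI(baseline)}
#' at every frame (baseline frames included, where the result is near zero).
#' The subtracted baseline volume is stored in the returned series so the
#' original SI can be reconstructed exactly.
#'
#' @param series A \code{dynamic_series} in SI units.
#' @param spec Baseline specification; defaults to the one carried by
#'   \code{series}.
#' @return A \code{dynamic_series} in delta-SI units with \code{baseline_si}
#'   set.
#' @export
delta_si <- function(series, spec = series$spec) {
  stopifnot(inherits(series, "dynamic_series"))
  if (series$units == "delta_si")
    stop("series is already in delta-SI units")
  d <- dim(series$data)
  if (d[4] < spec$baseline_frames[2])
    stop("series has fewer frames than the baseline range")
  idx <- seq(spec$baseline_frames[1], spec$baseline_frames[2])
  flat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4])
  baseline <- rowMeans(flat[, idx, drop = FALSE])
  out <- flat - baseline
  dynamic_series(array(out, dim = d), series$frame_interval_s, spec,
                 subject_id = series$subject_id, visit_day = series$visit_day,
                 units = "delta_si",
                 baseline_si = array(baseline, dim = d[1:3]))
}

#' Reconstruct raw SI from a delta-SI series
#'
#' Inverse of \code{\link{delta_si}}: adds the stored per-voxel baseline back.
#'
#' @param series A delta-SI \code{dynamic_series} with \code{baseline_si}.
#' @return A \code{dynamic_series} in SI units.
#' @export
restore_si <- function(series) {
  stopifnot(inherits(series, "dynamic_series"))
  if (series$units != "delta_si" || is.null(series$baseline_si))
    stop("series must be a delta-SI series carrying its baseline")
  d <- dim(series$data)
  flat <- matrix(series$data, nrow = prod(d[1:3]), ncol = d[4]) +
    as.vector(series$baseline_si)
  dynamic_series(array(flat, dim = d), series$frame_interval_s, series$spec,
                 subject_id = series$subject_id, visit_day = series$visit_day,
                 units = "si")
}
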