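#' Read a 4D dynamic series from NIfTI
#'
#' @param path NIfTI file holding a 4D (x, y, slice, frame) stack.
#' @param frame_interval_s Frame interval in seconds.
#' @param spec A \code{\link{baseline_spec}}.
#' @param subject_id,visit_day Identifiers.
#' @return A \code{\link{dynamic_series}} in SI units.
#' @export
read_dynamic_series <- function(path, frame_interval_s,
                                spec = baseline_spec(),
                                subject_id = NA_character_,
                                visit_day = NA_integer_) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 4) stop("expected a 4D NIfTI image")
  dynamic_series(arr, frame_interval_s, spec,
                 subject_id = subject_id, visit_day = visit_day)
}

#' Read a NIfTI byte mask
#'
#' @param path NIfTI file; nonzero voxels are in the mask.
#' @return 3D logical array.
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  if (length(dim(arr)) != 3) stop("expected a 3D NIfTI mask")
  arr != 0
}

#' Write pixel parameter maps as NIfTI volumes
#'
#' One volume per parameter, named \code{<prefix>_<parameter>.nii.gz}.
#'
#' @param fit A pixel-mode \code{roi_fit_result} (with \code{maps}).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_parameter_maps <- function(fit, dir, prefix = "map") {
  stopifnot(inherits(fit, "roi_fit_result"))
  if (is.null(fit$maps)) stop("fit carries no parameter maps")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(fit$maps), function(p) {
    path <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, p))
    RNifti::writeNifti(RNifti::asNifti(fit$maps[[p]]), path)
    path
  }, character(1))
  invisible(paths)
}

#' Read an acquisition configuration (YAML or JSON)
#'
#' Expected keys: \code{frame_interval_s}, \code{n_frames},
#' \code{baseline_frames} (length-2, 1-based inclusive),
#' \code{injection_frame}.
#'
#' @param path Config file path (extension decides the parser).
#' @return List with \code{frame_interval_s}, \code{n_frames} and a
#'   \code{\link{baseline_spec}} in \code{spec}.
#' @export
read_acquisition_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("frame_interval_s", "n_frames", "baseline_frames",
            "injection_frame")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0)
    stop("acquisition config lacks: ", paste(missing, collapse = ", "))
  list(frame_interval_s = as.numeric(cfg$frame_interval_s),
       n_frames = as.integer(cfg$n_frames),
       spec = baseline_spec(unlist(cfg$baseline_frames),
                            cfg$injection_frame))
}

#' Write a synthetic study to disk
#'
#' Per subject-visit 4D NIfTI series, per subject NIfTI masks, the
#' ground-truth table as CSV, and the design as YAML, laid out under
#' \code{dir/}.
#'
#' @param study A \code{dce_study}.
#' @param dir Output directory.
#' @return Invisibly, \code{dir}.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "dce_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  d <- study$design
  yaml::write_yaml(list(
    n_subjects = d$n_subjects, n_visits = d$n_visits,
    n_frames = d$n_frames, frame_interval_s = d$frame_interval_s,
    baseline_frames = as.integer(d$spec$baseline_frames),
    injection_frame = d$spec$injection_frame,
    shape = as.integer(d$shape),
    tumor_slices = as.integer(d$tumor_slices)
  ), file.path(dir, "design.yaml"))
  for (s in seq_along(study$subjects)) {
    subj <- study$subjects[[s]]
    sdir <- file.path(dir, sprintf("S%02d", s))
    dir.create(sdir, showWarnings = FALSE)
    RNifti::writeNifti(RNifti::asNifti(subj$tumor_mask * 1L),
                       file.path(sdir, "tumor_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(subj$vessel_mask * 1L),
                       file.path(sdir, "vessel_mask.nii.gz"))
    for (v in seq_along(subj$visits)) {
      if (is.null(subj$visits[[v]])) next
      RNifti::writeNifti(RNifti::asNifti(subj$visits[[v]]$data),
                         file.path(sdir, sprintf("day%d.nii.gz", v)))
    }
  }
  invisible(dir)
}

#' Write grid results as tidy CSV
#'
#' @param results \code{\link{run_grid}} output.
#' @param path Output CSV path.
#' @return Invisibly, \code{path}.
#' @export
write_results_csv <- function(results, path) {
  utils::write.csv(results, path, row.names = FALSE)
  invisible(path)
}
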