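#' Synthetic study design
#'
#' Acquisition and geometry settings for the in-silico test-retest study.
#' Defaults emulate a small-animal protocol: 12 subjects scanned on 3
#' consecutive days, 50 frames at 6.4 s (320 s total) with contrast injected
#' after 10 baseline frames, an 8-slice imaging volume with the tumour
#' occupying the central 3 slices, and a small vessel region carrying the
#' plasma curve.
#'
#' @param n_subjects,n_visits Study size (defaults 12 x 3).
#' @param n_frames Frames per series (default 50).
#' @param frame_interval_s Frame interval, seconds (default 6.4).
#' @param baseline_frames,injection_frame See \code{\link{baseline_spec}}.
#' @param shape Spatial dimensions (x, y, slices); default \code{c(20, 20, 8)}.
#' @param tumor_slices Slices containing tumour (default 4:6 of 8).
#' @param tumor_radii In-plane disc radius per tumour slice, voxels; the
#'   middle slice is largest so slice selection has a well-defined centre.
#' @param tumor_center In-plane centre (x, y).
#' @param vessel_box List with integer vectors \code{x}, \code{y}, \code{z}
#'   delimiting the vessel region.
#' @return An object of class \code{study_design}.
#' @export
study_design <- function(n_subjects = 12, n_visits = 3, n_frames = 50,
                         frame_interval_s = 6.4,
                         baseline_frames = c(5, 10), injection_frame = 11,
                         shape = c(20, 20, 8), tumor_slices = 4:6,
                         tumor_radii = c(4, 5, 4), tumor_center = c(10, 10),
                         vessel_box = list(x = 3:4, y = 3:4, z = 4:6)) {
  spec <- baseline_spec(baseline_frames, injection_frame)
  if (n_frames < injection_frame + 5)
    stop("need several post-injection frames")
  if (length(tumor_radii) != length(tumor_slices))
    stop("tumor_radii must give one radius per tumour slice")
  if (max(tumor_slices) > shape[3] || max(vessel_box$z) > shape[3])
    stop("tumour/vessel slices exceed the volume")
  structure(list(
    n_subjects = n_subjects, n_visits = n_visits, n_frames = n_frames,
    frame_interval_s = frame_interval_s, spec = spec, shape = shape,
    tumor_slices = tumor_slices, tumor_radii = tumor_radii,
    tumor_center = tumor_center, vessel_box = vessel_box,
    total_duration_s = n_frames * frame_interval_s
  ), class = "study_design")
}

#' Ground-truth configuration for the study generator
#'
#' Population medians and log-scale variation of the kinetic parameters,
#' plus signal/noise settings.  Medians default to typical tumour values
#' (Ktrans 0.11 /min, ve 0.21, vp 0.03); between-subject (inter) and
#' within-subject day-to-day (intra) log-SDs default to the scale of
#' variance components observed in small-animal test-retest experiments,
#' giving day-to-day wCVs of roughly 39% (Ktrans), 16% (ve) and 58% (vp).
#'
#' @param medians Named \code{c(Ktrans, ve, vp)} population medians
#'   (1/min, fractions).
#' @param inter_sd,intra_sd Named log-scale SDs for subject- and day-level
#'   lognormal variation.
#' @param voxel_log_sd Log-SD of the smoothed within-tumour heterogeneity
#'   field (0 = homogeneous tumours).
#' @param noise_sd Additive Gaussian SI noise SD (SI units).
#' @param baseline_si Named baseline SI levels \code{c(tumor, vessel,
#'   background)}.
#' @param vif_params Biexponential plasma curve \code{c(A1, m1, A2, m2)}
#'   driving the tissue kinetics (amplitudes in delta-SI, rates in 1/s).
#' @param bounds \code{\link{pk_bounds}} within which parameter draws are
#'   kept (out-of-bounds draws are redrawn).
#' @return An object of class \code{truth_config}.
#' @export
truth_config <- function(medians = c(Ktrans = 0.11, ve = 0.21, vp = 0.03),
                         inter_sd = c(Ktrans = 0.22, ve = 0.10, vp = 0.38),
                         intra_sd = c(Ktrans = 0.33, ve = 0.15, vp = 0.46),
                         voxel_log_sd = 0.2,
                         noise_sd = 0.004,
                         baseline_si = c(tumor = 0.06, vessel = 0.25,
                                         background = 0.04),
                         vif_params = c(A1 = 0.64, m1 = 0.0333,
                                        A2 = 0.42, m2 = 0.0010),
                         bounds = pk_bounds()) {
  vif_params <- check_biexp_params(vif_params)
  structure(list(medians = medians, inter_sd = inter_sd,
                 intra_sd = intra_sd, voxel_log_sd = voxel_log_sd,
                 noise_sd = noise_sd, baseline_si = baseline_si,
                 vif_params = vif_params, bounds = bounds),
            class = "truth_config")
}

disc_mask <- function(shape, center, radius) {
  xs <- matrix(seq_len(shape[1]), shape[1], shape[2])
  ys <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (xs - center[1])^2 + (ys - center[2])^2 <= radius^2
}

#' Build the tumour and vessel masks of a design
#'
#' @param design A \code{\link{study_design}}.
#' @return List with 3D logical arrays \code{tumor} and \code{vessel}.
#' @export
design_masks <- function(design) {
  tumor <- array(FALSE, dim = design$shape)
  for (i in seq_along(design$tumor_slices))
    tumor[, , design$tumor_slices[i]] <-
      disc_mask(design$shape, design$tumor_center, design$tumor_radii[i])
  vessel <- array(FALSE, dim = design$shape)
  vessel[design$vessel_box$x, design$vessel_box$y, design$vessel_box$z] <- TRUE
  if (any(tumor & vessel)) stop("tumour and vessel regions overlap")
  list(tumor = tumor, vessel = vessel)
}

# 3x3 in-plane mean smoothing of a 2D field (edge-replicated).
smooth2d <- function(f) {
  n1 <- nrow(f); n2 <- ncol(f)
  pad <- f[c(1, seq_len(n1), n1), c(1, seq_len(n2), n2)]
  out <- matrix(0, n1, n2)
  for (dx in 0:2) for (dy in 0:2)
    out <- out + pad[dx + seq_len(n1), dy + seq_len(n2)]
  out / 9
}

draw_visit_params <- function(log_subj, intra_sd, bounds, max_redraw = 100) {
  nm <- names(log_subj)
  for (i in seq_len(max_redraw)) {
    p <- exp(log_subj + rnorm(length(log_subj)) * intra_sd[nm])
    ok <- all(p > bounds$lower[nm] & p <= bounds$upper[nm]) &&
      p[["vp"]] < bounds$upper[["vp"]]
    if (ok) return(p)
  }
  warning("parameter draw repeatedly out of bounds; clamping")
  pmin(pmax(p, bounds$lower[nm] * 1.01), bounds$upper[nm] * 0.99)
}

#' Generate a synthetic 4D DCE study
#'
#' Simulates the full test-retest experiment: each subject draws log-normal
#' subject-level kinetic parameters around the population medians
#' (between-subject log-SD), each visit multiplies them by a lognormal day
#' effect (within-subject log-SD), optional smoothed lognormal within-tumour
#' heterogeneity modulates the voxel maps, tissue delta-SI follows the
#' three-parameter extended model driven by the biexponential plasma curve,
#' vessel voxels carry the plasma curve itself, and i.i.d. Gaussian noise is
#' added to the signal.  A baseline SI offset is written so that
#' \code{\link{delta_si}} round-trips.
#'
#' @param design A \code{\link{study_design}}.
#' @param truth A \code{\link{truth_config}}.
#' @param seed Optional RNG seed; the same seed reproduces the study
#'   bit-identically.
#' @param missing_visits Optional data frame with columns \code{subject},
#'   \code{visit}: visits to drop, emulating scan failures.
#' @return An object of class \code{dce_study}: the design, the truth table
#'   (one row per subject-visit with the ROI-level true parameters), and per
#'   subject the masks plus a \code{dynamic_series} (SI units) per visit
#'   (dropped visits are \code{NULL}).  With heterogeneity enabled each
#'   subject also carries per-visit true parameter maps.
#' @export
generate_study <- function(design = study_design(), truth = truth_config(),
                           seed = NULL, missing_visits = NULL) {
  if (!is.null(seed)) set.seed(seed)
  masks <- design_masks(design)
  nm <- c("Ktrans", "ve", "vp")
  times <- (seq_len(design$n_frames) - design$spec$injection_frame) *
    design$frame_interval_s
  cp <- biexp_eval(truth$vif_params, times)
  tum_idx <- which(masks$tumor)
  ves_idx <- which(masks$vessel)
  nvox <- prod(design$shape)

  truth_rows <- list()
  subjects <- vector("list", design$n_subjects)
  for (s in seq_len(design$n_subjects)) {
    log_subj <- log(truth$medians[nm]) + rnorm(3) * truth$inter_sd[nm]
    names(log_subj) <- nm
    visits <- vector("list", design$n_visits)
    truth_maps <- vector("list", design$n_visits)
    for (v in seq_len(design$n_visits)) {
      p <- draw_visit_params(log_subj, truth$intra_sd, truth$bounds)
      drop <- !is.null(missing_visits) &&
        any(missing_visits$subject == s & missing_visits$visit == v)
      truth_rows[[length(truth_rows) + 1]] <- data.frame(
        subject_id = sprintf("S%02d", s), visit_day = v,
        Ktrans = p[["Ktrans"]], ve = p[["ve"]], vp = p[["vp"]],
        kep = p[["Ktrans"]] / p[["ve"]], missing = drop)

      # voxel-level parameter maps (possibly heterogeneous)
      vox_par <- matrix(rep(p, each = length(tum_idx)),
                        nrow = length(tum_idx), ncol = 3,
                        dimnames = list(NULL, nm))
      if (truth$voxel_log_sd > 0) {
        for (j in nm) {
          field <- array(0, dim = design$shape)
          for (sl in design$tumor_slices) {
            f <- smooth2d(matrix(rnorm(design$shape[1] * design$shape[2]),
                                 design$shape[1], design$shape[2]))
            field[, , sl] <- f
          }
          fv <- field[tum_idx]
          fv <- (fv - mean(fv)) / sd(fv) * truth$voxel_log_sd
          vox_par[, j] <- pmin(pmax(vox_par[, j] * exp(fv),
                                    truth$bounds$lower[j] * 1.01),
                               truth$bounds$upper[j] * 0.99)
        }
        maps <- lapply(nm, function(j) {
          m <- array(NA_real_, dim = design$shape)
          m[tum_idx] <- vox_par[, j]
          m
        })
        names(maps) <- nm
        truth_maps[[v]] <- maps
      }
      if (drop) { visits[v] <- list(NULL); next }

      # tissue curves (closed-form extended model, biexponential plasma curve)
      kep_vox <- vox_par[, "Ktrans"] / vox_par[, "ve"]
      sig <- matrix(0, nrow = nvox, ncol = design$n_frames)
      for (i in seq_along(tum_idx)) {
        sig[tum_idx[i], ] <- vox_par[i, "vp"] * cp +
          convolve_biexp_closed_form(vox_par[i, "Ktrans"], kep_vox[i],
                                     truth$vif_params, times)
      }
      sig[ves_idx, ] <- rep(cp, each = length(ves_idx))

      base <- rep(truth$baseline_si[["background"]], nvox)
      base[tum_idx] <- truth$baseline_si[["tumor"]]
      base[ves_idx] <- truth$baseline_si[["vessel"]]
      si <- sig + base
      if (truth$noise_sd > 0)
        si <- si + rnorm(length(si)) * truth$noise_sd

      visits[[v]] <- dynamic_series(
        array(si, dim = c(design$shape, design$n_frames)),
        design$frame_interval_s, design$spec,
        subject_id = sprintf("S%02d", s), visit_day = v, units = "si")
    }
    subjects[[s]] <- list(tumor_mask = masks$tumor,
                          vessel_mask = masks$vessel,
                          visits = visits,
                          truth_maps = if (truth$voxel_log_sd > 0)
                            truth_maps else NULL)
  }
  structure(list(design = design, truth_config = truth,
                 truth = do.call(rbind, truth_rows),
                 subjects = subjects),
            class = "dce_study")
}

#' @export
print.dce_study <- function(x, ...) {
  cat(sprintf("<dce_study> %d subjects x %d visits, %d frames @ %.1f s\n",
              x$design$n_subjects, x$design$n_visits, x$design$n_frames,
              x$design$frame_interval_s))
  cat(sprintf("  volume %s, tumour slices %s, %d missing visit(s)\n",
              paste(x$design$shape, collapse = "x"),
              paste(range(x$design$tumor_slices), collapse = "-"),
              sum(x$truth$missing)))
  invisible(x)
}

#' Spheroid tumour volume from caliper diameters
#'
#' \code{(pi * X * Y^2) / 6000}: orthogonal diameters in mm give the volume
#' in cm^3.
#'
#' @param X,Y Orthogonal tumour diameters, mm (> 0).
#' @return Volume in cm^3.
#' @export
spheroid_volume <- function(X, Y) {
  if (any(!is.finite(c(X, Y))) || any(X <= 0) || any(Y <= 0))
    stop("diameters must be positive")
  pi * X * Y^2 / 6000
}
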