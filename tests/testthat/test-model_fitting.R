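test_that("fit_curve recovers noiseless parameters and shows the 2-vs-3-parameter bias", {
  vif <- pop_vif()
  truth <- pk_params(0.11, 0.21, vp = 0.03, model = "three_param")
  ct <- tofts_3p(truth, vif, acq_times)

  f3 <- fit_curve(ct, acq_times, vif, "three_param", n_starts = 3)
  expect_true(f3$valid)
  expect_lt(abs(f3$Ktrans - 0.11) / 0.11, 0.01)
  expect_lt(abs(f3$ve - 0.21) / 0.21, 0.01)
  expect_lt(abs(f3$vp - 0.03), 0.005)
  expect_identical(f3$kep, f3$Ktrans / f3$ve)

  # two-parameter fit absorbs the vascular term into a larger Ktrans
  f2 <- fit_curve(ct, acq_times, vif, "two_param", n_starts = 3)
  expect_true(f2$valid)
  expect_gt(f2$Ktrans, 0.11)

  # all-zero curve: optimiser pins at the positive-definite bound -> NaN
  f0 <- fit_curve(rep(0, 50), acq_times, vif, "two_param")
  expect_false(f0$valid)
  expect_true(is.nan(f0$Ktrans))

  expect_error(fit_curve(c(0, 1, 2), c(-6.4, 0, 6.4), vif, "three_param"),
               "fewer time points")
})

test_that("fit_curve works against a sampled (individual) VIF", {
  vs <- sampled_vif()
  truth <- pk_params(0.15, 0.25, vp = 0.02, model = "three_param")
  ct <- tofts_3p(truth, pop_vif(), acq_times)  # generated from the analytic curve
  f <- fit_curve(ct, acq_times, vs, "three_param", n_starts = 3)
  expect_true(f$valid)
  expect_lt(abs(f$Ktrans - 0.15) / 0.15, 0.01)
  expect_lt(abs(f$ve - 0.25) / 0.25, 0.01)
  expect_lt(abs(f$vp - 0.02), 0.005)
})

test_that("enhancement filter applies the 50% increase rule inclusively", {
  post <- 11:50
  mk <- function(peak) { x <- rep(0, 50); x[20] <- peak; x }
  # 49% increase: excluded
  expect_false(enhancement_filter(mk(49), 100, post)$keep)
  # exactly 50%: kept (inclusive boundary)
  expect_true(enhancement_filter(mk(50), 100, post)$keep)
  # non-positive baseline: excluded with its own reason code
  r0 <- enhancement_filter(mk(50), 0, post)
  expect_false(r0$keep)
  expect_equal(r0$reason, "nonpositive_baseline")
  expect_equal(enhancement_filter(mk(49), 100, post)$reason,
               "insufficient_enhancement")
})

test_that("whole-ROI fitting averages curves then parameters across slices", {
  truth <- pk_params(0.11, 0.21, vp = 0.03, model = "three_param")
  h <- homogeneous_series(truth)
  ds <- delta_si(h$series)
  fw <- fit_whole_roi(ds, h$mask, pop_vif(), model = "three_param")
  # homogeneous tumour: whole-ROI parameters equal the single-pixel truth
  expect_lt(abs(fw$aggregate[["Ktrans"]] - 0.11) / 0.11, 0.01)
  expect_lt(abs(fw$aggregate[["ve"]] - 0.21) / 0.21, 0.01)
  expect_lt(abs(fw$aggregate[["vp"]] - 0.03), 0.005)
  # three identical slices: aggregate equals each slice fit
  expect_equal(length(fw$per_slice), 3L)
  expect_equal(fw$aggregate[["Ktrans"]], fw$per_slice[[1]]$Ktrans)

  # one-voxel ROI is identical to fit_curve on that voxel
  mask1 <- array(FALSE, dim(h$mask)); mask1[4, 4, 2] <- TRUE
  f1 <- fit_whole_roi(ds, mask1, pop_vif(), model = "three_param",
                      slices = 2)
  fc <- fit_curve(ds$data[4, 4, 2, ], frame_times(ds), pop_vif(),
                  "three_param", n_starts = 3)
  expect_equal(f1$aggregate[["Ktrans"]], fc$Ktrans)
  expect_equal(f1$aggregate[["vp"]], fc$vp)

  expect_error(fit_whole_roi(ds, array(FALSE, dim(h$mask)), pop_vif()),
               "empty")
})

test_that("pixel-by-pixel fitting summarises valid pixels by the median", {
  # two pixel populations (Ktrans 0.05 / 0.15, equal counts + 1 extra low):
  # the slice median comes from the low population
  spec <- baseline_spec()
  n_frames <- 50
  shape <- c(4, 4, 1)
  low <- tofts_3p(pk_params(0.05, 0.2, vp = 0.02, model = "three_param"),
                  pop_vif(), acq_times)
  high <- tofts_3p(pk_params(0.15, 0.2, vp = 0.02, model = "three_param"),
                   pop_vif(), acq_times)
  flat <- matrix(0.02, nrow = prod(shape), ncol = n_frames)
  flat[1:6, ] <- rep(low, each = 6) + 0.02
  flat[7:11, ] <- rep(high, each = 5) + 0.02
  ser <- dynamic_series(array(flat, dim = c(shape, n_frames)), 6.4, spec,
                        units = "si")
  ds <- delta_si(ser)
  mask <- array(FALSE, shape); mask[1:11] <- TRUE
  fp <- fit_pixelwise(ds, mask, pop_vif(), model = "three_param")
  expect_equal(fp$n_pixels_total, 11L)
  expect_lt(abs(fp$aggregate[["Ktrans"]] - 0.05) / 0.05, 0.02)

  # homogeneous noiseless tumour: pixel median equals the whole-ROI fit
  truth <- pk_params(0.11, 0.21, vp = 0.03, model = "three_param")
  h <- homogeneous_series(truth)
  dsh <- delta_si(h$series)
  fw <- fit_whole_roi(dsh, h$mask, pop_vif(), model = "three_param")
  fpx <- fit_pixelwise(dsh, h$mask, pop_vif(), model = "three_param")
  for (p in c("Ktrans", "ve", "kep", "vp"))
    expect_equal(fpx$aggregate[[p]], fw$aggregate[[p]], tolerance = 1e-4)
  expect_equal(fpx$n_pixels_excluded_enhancement, 0L)
  expect_equal(fpx$n_pixels_nan, 0L)

  # exclusion accounting: non-enhancing pixels are counted, and an ROI with
  # no valid pixels errors with the counts
  mask_bg <- array(FALSE, shape); mask_bg[13:16] <- TRUE
  expect_error(fit_pixelwise(ds, mask_bg, pop_vif(), model = "three_param"),
               "excluded by enhancement")
})

test_that("central-slice selection prefers large ROI areas with centre tie-breaks", {
  m <- array(FALSE, c(6, 6, 8))
  m[1:3, 1:3, 3] <- TRUE   # 9 px
  m[1:4, 1:4, 4] <- TRUE   # 16 px
  m[1:3, 1:3, 5] <- TRUE   # 9 px
  m[1:2, 1:2, 6] <- TRUE   # 4 px
  expect_equal(select_central_slices(m), c(3, 4, 5))
  # tie between slices 3 and 5 broken toward the centre of the tumour extent
  expect_equal(select_central_slices(m, n = 2), c(4, 5))
  expect_error(select_central_slices(array(FALSE, c(2, 2, 2))), "empty")
})
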