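test_that("study design encodes the acquisition protocol", {
  d <- study_design()
  expect_equal(d$n_frames, 50)
  expect_equal(d$frame_interval_s, 6.4)
  expect_equal(d$total_duration_s, 320)
  expect_equal(d$spec$injection_frame, 11L)   # after 10 baseline scans
  expect_equal(d$spec$baseline_frames, c(5L, 10L))
  # injection frame maps to time zero
  st <- noiseless_study()
  expect_equal(frame_times(st$subjects[[1]]$visits[[1]])[11], 0)
  expect_error(study_design(injection_frame = 9))
  expect_error(baseline_spec(c(5, 10), 10))
})

test_that("spheroid volume follows the caliper formula", {
  expect_equal(spheroid_volume(10, 10), pi * 1000 / 6000, tolerance = 1e-12)
  expect_equal(round(spheroid_volume(10, 10), 4), 0.5236)
  # quadratic in Y, linear in X
  expect_equal(spheroid_volume(10, 20), 4 * spheroid_volume(10, 10))
  expect_equal(spheroid_volume(20, 10), 2 * spheroid_volume(10, 10))
  expect_error(spheroid_volume(0, 10), "positive")
  expect_error(spheroid_volume(10, -1), "positive")
})

test_that("zero-variance configuration produces identical visits and zero wCV", {
  st <- generate_study(
    study_design(n_subjects = 3, n_visits = 2, shape = c(12, 12, 8),
                 tumor_radii = c(2, 3, 2), tumor_center = c(7, 7)),
    truth_config(inter_sd = c(Ktrans = 0, ve = 0, vp = 0),
                 intra_sd = c(Ktrans = 0, ve = 0, vp = 0),
                 voxel_log_sd = 0, noise_sd = 0),
    seed = 1)
  expect_equal(st$subjects[[1]]$visits[[1]]$data,
               st$subjects[[1]]$visits[[2]]$data)
  expect_equal(st$subjects[[1]]$visits[[1]]$data,
               st$subjects[[3]]$visits[[2]]$data)
  expect_equal(st$truth$Ktrans, rep(0.11, 6))
  # downstream repeatability of the truth table is exactly zero
  d <- data.frame(subject_id = st$truth$subject_id, value = st$truth$Ktrans)
  expect_equal(wcv(d)$wcv, 0)
})

test_that("the same seed reproduces the study bit-identically", {
  de <- study_design(n_subjects = 2, n_visits = 2, shape = c(10, 10, 8),
                                    vessel_box = list(x = 1:2, y = 1:2,
                                                      z = 4:6),
                     tumor_radii = c(2, 3, 2), tumor_center = c(6, 6))
  s1 <- generate_study(de, truth_config(), seed = 99)
  s2 <- generate_study(de, truth_config(), seed = 99)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$subjects[[2]]$visits[[1]]$data,
                   s2$subjects[[2]]$visits[[1]]$data)
})

test_that("generated parameters respect bounds and the lognormal structure", {
  st <- generate_study(study_design(n_subjects = 8, n_visits = 3,
                                    shape = c(10, 10, 8),
                                    vessel_box = list(x = 1:2, y = 1:2,
                                                      z = 4:6),
                                    tumor_radii = c(2, 3, 2),
                                    tumor_center = c(6, 6)),
                       truth_config(), seed = 5)
  b <- pk_bounds()
  expect_true(all(st$truth$Ktrans > b$lower["Ktrans"] &
                    st$truth$Ktrans <= b$upper["Ktrans"]))
  expect_true(all(st$truth$ve > 0 & st$truth$ve <= 1))
  expect_true(all(st$truth$vp >= 0 & st$truth$vp < 1))
  expect_equal(st$truth$kep, st$truth$Ktrans / st$truth$ve)
  # heterogeneous maps exist and stay within bounds
  maps <- st$subjects[[1]]$truth_maps[[1]]
  expect_true(!is.null(maps))
  expect_true(all(maps$ve[!is.na(maps$ve)] <= 1))
})

test_that("missing visits are represented as NULL and logged in the truth table", {
  st <- generate_study(study_design(n_subjects = 2, n_visits = 3,
                                    shape = c(10, 10, 8),
                                    vessel_box = list(x = 1:2, y = 1:2,
                                                      z = 4:6),
                                    tumor_radii = c(2, 3, 2),
                                    tumor_center = c(6, 6)),
                       truth_config(voxel_log_sd = 0), seed = 2,
                       missing_visits = data.frame(subject = 2, visit = 3))
  expect_null(st$subjects[[2]]$visits[[3]])
  expect_false(is.null(st$subjects[[2]]$visits[[2]]))
  expect_equal(sum(st$truth$missing), 1)
})

test_that("whole-ROI fits recover the generator's parameters on noiseless data", {
  st <- noiseless_study()
  med_true <- median(st$truth$Ktrans)
  fits <- numeric(0)
  for (s in seq_along(st$subjects)) {
    subj <- st$subjects[[s]]
    for (v in seq_along(subj$visits)) {
      ds <- delta_si(subj$visits[[v]])
      ivif <- extract_individual_vif(ds, subj$vessel_mask)
      fw <- fit_whole_roi(ds, subj$tumor_mask, ivif, model = "three_param")
      truth_row <- st$truth[st$truth$subject_id == sprintf("S%02d", s) &
                              st$truth$visit_day == v, ]
      expect_lt(abs(fw$aggregate[["Ktrans"]] - truth_row$Ktrans) /
                  truth_row$Ktrans, 0.01)
      expect_lt(abs(fw$aggregate[["ve"]] - truth_row$ve) / truth_row$ve, 0.01)
      expect_lt(abs(fw$aggregate[["vp"]] - truth_row$vp), 0.005)
      fits <- c(fits, fw$aggregate[["Ktrans"]])
    }
  }
  # study-level median recovered within 5%
  expect_lt(abs(median(fits) - med_true) / med_true, 0.05)
})
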