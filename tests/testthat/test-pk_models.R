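test_that("two-parameter forward model matches the quadrature oracle and limits", {
  vif <- pop_vif()
  times <- c(0, 30, 60, 120, 249.6)

  # degenerate no-uptake limit
  pk0 <- pk_params(0, 0.21, model = "two_param")
  expect_equal(tofts_2p(pk0, vif, times), rep(0, length(times)))

  # oracle agreement at plausible tumour parameters
  pk <- pk_params(0.11, 0.21, model = "two_param")
  got <- tofts_2p(pk, vif, times)
  expect_equal(got, quad_uptake(0.11, pk$kep, times), tolerance = 1e-9)
  expect_true(got[1] == 0 && all(got >= 0) && all(is.finite(got)))

  # constant plasma level: Ct -> ve * c as t -> infinity
  const <- vif_curve(seq(0, 36000, by = 60), rep(0.5, 601))
  late <- tofts_2p(pk, const, 36000)
  expect_equal(late, 0.21 * 0.5, tolerance = 1e-3)
})

test_that("three-parameter model reduces to two-parameter at vp = 0 and adds the vascular term", {
  vif <- pop_vif()
  times <- acq_times
  pk2 <- pk_params(0.11, 0.21, model = "two_param")
  pk3_v0 <- pk_params(0.11, 0.21, vp = 0, model = "three_param")
  expect_identical(tofts_3p(pk3_v0, vif, times), tofts_2p(pk2, vif, times))

  # pure vascular term when Ktrans = 0
  pk_vasc <- pk_params(0, 0.21, vp = 0.04, model = "three_param")
  expect_equal(tofts_3p(pk_vasc, vif, times),
               0.04 * biexp_eval(pop_params, pmax(times, 0)) *
                 (times >= 0))

  # full model against the quadrature oracle at t = 120 s
  pk3 <- pk_params(0.11, 0.21, vp = 0.03, model = "three_param")
  got <- tofts_3p(pk3, vif, 120)
  expect_equal(got,
               0.03 * biexp_eval(pop_params, 120) +
                 quad_uptake(0.11, pk3$kep, 120),
               tolerance = 1e-9)
})

test_that("closed-form biexponential convolution is exact, including the confluent branch", {
  expect_equal(convolve_biexp_closed_form(0.11, 0.52, pop_params, 0), 0)
  expect_equal(convolve_biexp_closed_form(0, 0.52, pop_params, 60), 0)

  # dense-grid trapezoidal oracle at t = 60 s
  got <- convolve_biexp_closed_form(0.11, 0.52, pop_params, 60)
  expect_equal(got, trapz_conv(0.11, 0.52, 60), tolerance = 1e-7)

  # kep coinciding with the fast clearance rate: confluent limit
  kep_conf <- pop_params[["m1"]] * 60
  got_conf <- convolve_biexp_closed_form(0.11, kep_conf, pop_params, 60)
  expect_equal(got_conf, trapz_conv(0.11, kep_conf, 60), tolerance = 1e-7)
  # continuity across the switch
  eps <- 1e-10
  expect_equal(got_conf,
               convolve_biexp_closed_form(0.11, kep_conf + eps, pop_params, 60),
               tolerance = 1e-8)
})

test_that("numerical convolution handles degenerate inputs and matches the closed form", {
  zero <- vif_curve(study_grid, rep(0, length(study_grid)))
  expect_equal(convolve_numeric(0.5, zero, study_grid),
               rep(0, length(study_grid)))

  # biexponential on the acquisition grid: agreement with the closed form
  vs <- sampled_vif()
  kep <- 0.11 / 0.21
  num <- 0.11 * convolve_numeric(kep, vs, study_grid)
  clo <- convolve_biexp_closed_form(0.11, kep, pop_params, study_grid)
  expect_lt(max(abs(num - clo)) / max(clo), 1e-3)

  # impulse-like Cp: piecewise-linear treatment gives the convolution of a
  # triangular pulse with the kernel; compare to adaptive quadrature
  tt <- seq(0, 64, by = 6.4)
  imp <- rep(0, length(tt)); imp[3] <- 1
  vimp <- vif_curve(tt, imp)
  got <- convolve_numeric(1.2, vimp, tt, refine = 1)
  tri <- function(u) pmax(0, 1 - abs(u - tt[3]) / 6.4)
  want <- vapply(tt, function(ts) {
    if (ts == 0) return(0)
    stats::integrate(function(u) tri(u) * exp(-1.2 * (ts - u) / 60),
                     0, ts, rel.tol = 1e-12)$value / 60
  }, numeric(1))
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("numerical-convolution errors: extrapolation and invalid grids are refused", {
  vs <- sampled_vif(times = seq(6.4, 320, by = 6.4))  # support starts late
  expect_error(convolve_numeric(0.5, vs, c(3.2, 12.8)), "extrapolate")
  expect_error(convolve_numeric(0.5, sampled_vif(), 400), "extrapolate")
  pk <- pk_params(0.11, 0.21, model = "two_param")
  expect_error(tofts_2p(pk, pop_vif(), c(10, 5)), "increasing")
  expect_error(pk_params(-0.1, 0.2, model = "two_param"))
  expect_error(pk_params(0.1, 0, model = "two_param"))
  expect_error(pk_params(0.1, 0.2, vp = 1, model = "three_param"))
})

test_that("closed-form vs numerical agreement holds across random parameter draws", {
  set.seed(101)
  vs <- sampled_vif()
  for (i in 1:25) {
    Kt <- exp(log(0.11) + rnorm(1) * 0.4)
    ve <- min(exp(log(0.21) + rnorm(1) * 0.25), 1)
    kep <- Kt / ve
    clo <- convolve_biexp_closed_form(Kt, kep, pop_params, study_grid)
    num <- Kt * convolve_numeric(kep, vs, study_grid)
    expect_lt(max(abs(num - clo)) / max(clo), 1e-3)
  }
})

test_that("uptake scales monotonically in Ktrans at fixed washout rate", {
  # at fixed kep the uptake term is linear in Ktrans, so the curve is
  # pointwise non-decreasing in Ktrans
  kts <- seq(0.02, 0.5, length.out = 8)
  curves <- vapply(kts, function(kt)
    convolve_biexp_closed_form(kt, 0.52, pop_params, acq_times),
    numeric(length(acq_times)))
  for (j in seq_len(ncol(curves) - 1))
    expect_true(all(curves[, j + 1] >= curves[, j] - 1e-14))
  # kep identity is preserved by the constructor for any Ktrans
  for (kt in kts)
    expect_identical(pk_params(kt, 0.21, model = "two_param")$kep, kt / 0.21)
})

test_that("pk_params enforces its contract", {
  pk <- pk_params(0.11, 0.21, vp = 0.03, model = "three_param")
  expect_identical(pk$kep, 0.11 / 0.21)
  expect_true(pk$valid)
  bad <- pk_params(NaN, NaN, vp = NaN, model = "three_param", valid = FALSE)
  expect_false(bad$valid)
  expect_true(all(is.nan(c(bad$Ktrans, bad$ve, bad$vp, bad$kep))))
  expect_warning(pk_params(0.1, 0.9, vp = 0.2, model = "three_param"),
                 "implausible")
  expect_error(pk_params(0.1, 0.2, vp = 0.03, model = "two_param"))
  expect_error(pk_params(0.1, 0.2, model = "three_param"))
})
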