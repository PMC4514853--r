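# Shared fixtures and independent oracles.

# Published-style population plasma curve: amplitudes in delta-SI, rates 1/s.
pop_params <- c(A1 = 0.64, m1 = 0.0333, A2 = 0.42, m2 = 0.0010)

# Acquisition time grid: 50 frames at 6.4 s, injection at frame 11.
study_grid <- seq(0, 320, by = 6.4)
acq_times <- (1:50 - 11) * 6.4

pop_vif <- function(params = pop_params, times = study_grid) {
  vif_curve(times, biexp_eval(params, times), source = "population",
            params = params)
}

sampled_vif <- function(params = pop_params, times = study_grid) {
  vif_curve(times, biexp_eval(params, times), source = "individual")
}

# Adaptive-quadrature oracle for the uptake integral (works in minutes).
quad_uptake <- function(Ktrans, kep, t_s, params = pop_params) {
  vapply(t_s, function(ts) {
    if (ts <= 0) return(0)
    tm <- ts / 60
    f <- function(u) {
      (params[["A1"]] * exp(-params[["m1"]] * 60 * u) +
         params[["A2"]] * exp(-params[["m2"]] * 60 * u)) *
        exp(-kep * (tm - u))
    }
    Ktrans * stats::integrate(f, 0, tm, rel.tol = 1e-12)$value
  }, numeric(1))
}

# Dense-grid trapezoidal convolution oracle (independent of the package's
# segment-exact rule).
trapz_conv <- function(Ktrans, kep, t_s, params = pop_params, dt_s = 0.01) {
  vapply(t_s, function(ts) {
    if (ts <= 0) return(0)
    u <- seq(0, ts, by = dt_s) / 60
    g <- biexp_eval(params, u * 60) * exp(-kep * (ts / 60 - u))
    h <- diff(u)
    Ktrans * sum((g[-1] + g[-length(g)]) / 2 * h)
  }, numeric(1))
}

# Brute-force Bland-Altman wCV: direct formula evaluation.
wcv_brute <- function(data) {
  logs <- split(log(data$value), data$subject_id)
  ss <- sum(vapply(logs, function(x) sum((x - mean(x))^2), 0))
  df <- sum(vapply(logs, length, 0L) - 1)
  100 * (exp(sqrt(ss / df)) - 1)
}

# Brute-force one-way method-of-moments variance components.
vc_brute <- function(data) {
  logs <- split(log(data$value), data$subject_id)
  k <- vapply(logs, length, 0L)
  n <- sum(k); a <- length(logs)
  means <- vapply(logs, mean, 0)
  grand <- sum(unlist(logs)) / n
  msw <- sum(vapply(logs, function(x) sum((x - mean(x))^2), 0)) / (n - a)
  msb <- sum(k * (means - grand)^2) / (a - 1)
  k0 <- (n - sum(k^2) / n) / (a - 1)
  c(inter = max(0, (msb - msw) / k0), intra = msw)
}

# Small noiseless homogeneous study, cached across tests.
.fixture_env <- new.env(parent = emptyenv())
noiseless_study <- function(n_subjects = 2, n_visits = 2, seed = 42) {
  key <- sprintf("st_%d_%d_%d", n_subjects, n_visits, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_study(
      study_design(n_subjects = n_subjects, n_visits = n_visits),
      truth_config(voxel_log_sd = 0, noise_sd = 0), seed = seed)
  }
  .fixture_env[[key]]
}

# A raw-SI series whose tumour voxels all follow the same kinetic curve.
homogeneous_series <- function(pk, baseline = 0.05, shape = c(8, 8, 3),
                               vox = NULL, n_frames = 50,
                               spec = baseline_spec()) {
  times <- (seq_len(n_frames) - spec$injection_frame) * 6.4
  ct <- tofts_3p(pk, pop_vif(), times)
  arr <- array(baseline, dim = c(shape, n_frames))
  mask <- array(FALSE, dim = shape)
  if (is.null(vox)) {
    mask[3:6, 3:6, ] <- TRUE
  } else {
    mask[vox] <- TRUE
  }
  idx <- which(mask)
  flat <- matrix(arr, nrow = prod(shape), ncol = n_frames)
  flat[idx, ] <- rep(ct, each = length(idx)) + baseline
  list(series = dynamic_series(array(flat, dim = c(shape, n_frames)),
                               6.4, spec, units = "si"),
       mask = mask, times = times, ct = ct)
}
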