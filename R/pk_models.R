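#' Pharmacokinetic parameter set
#'
#' Holds the compartment-model parameters of a single tissue curve.
#' \code{kep} is always derived as \code{Ktrans / ve} (1/min), never stored
#' independently.  \code{ve + vp > 1} is physiologically implausible but is
#' only warned about, not rejected.  A parameter set is valid exactly when
#' none of its parameters is NaN.
#'
#' @param Ktrans Volume transfer constant, 1/min (>= 0; 0 is the degenerate
#'   no-uptake limit).
#' @param ve Extravascular extracellular volume fraction, in (0, 1].
#' @param vp Plasma volume fraction in [0, 1); \code{NULL} for the
#'   two-parameter model.
#' @param model \code{"two_param"} or \code{"three_param"}.
#' @param valid Logical validity flag; when \code{FALSE} all parameters are
#'   forced to NaN.
#' @param rss Residual sum of squares of the fit that produced the set
#'   (delta-SI^2 units), NA for hand-constructed sets.
#'
#' @return An object of class \code{pk_params}.
#' @export
pk_params <- function(Ktrans, ve, vp = NULL, model = c("two_param", "three_param"),
                      valid = TRUE, rss = NA_real_) {
  model <- match.arg(model)
  if (model == "two_param" && !is.null(vp) && !is.na(vp))
    stop("vp is not a parameter of the two-parameter model")
  if (model == "three_param" && is.null(vp))
    stop("the three-parameter model requires vp")
  if (isTRUE(valid)) {
    if (!is.finite(Ktrans) || Ktrans < 0)
      stop("Ktrans must be finite and >= 0 (1/min)")
    if (!is.finite(ve) || ve <= 0 || ve > 1)
      stop("ve must lie in (0, 1]")
    if (!is.null(vp)) {
      if (!is.finite(vp) || vp < 0 || vp >= 1)
        stop("vp must lie in [0, 1)")
      if (ve + vp > 1)
        warning("ve + vp > 1: physiologically implausible parameter set")
    }
  } else {
    Ktrans <- NaN
    ve <- NaN
    if (!is.null(vp)) vp <- NaN
  }
  kep <- Ktrans / ve
  valid <- !anyNA(c(Ktrans, ve, if (!is.null(vp)) vp, kep))
  structure(
    list(Ktrans = Ktrans, ve = ve, vp = if (is.null(vp)) NULL else vp,
         kep = kep, model = model, valid = valid, rss = rss),
    class = "pk_params"
  )
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("<pk_params> %s%s\n", x$model,
              if (x$valid) "" else " (invalid: NaN-flagged)"))
  cat(sprintf("  Ktrans = %.4g /min, ve = %.4g, kep = %.4g /min",
              x$Ktrans, x$ve, x$kep))
  if (!is.null(x$vp)) cat(sprintf(", vp = %.4g", x$vp))
  cat("\n")
  if (!is.na(x$rss)) cat(sprintf("  rss = %.4g\n", x$rss))
  invisible(x)
}

# Stable evaluation of (exp(-m t) - exp(-kep t)) / (kep - m) for t >= 0
# (minutes, 1/min).  Uses the expm1 form when (kep - m) t is small enough for
# the direct difference to cancel; the switch threshold is |d t| < 1e-8, below
# which the confluent (L'Hopital) branch t exp(-kep t) (1 + d t / 2) is exact
# to double precision.
exp_diff_ratio <- function(kep, m, t) {
  d <- kep - m
  x <- d * t
  out <- numeric(length(t))
  tiny <- abs(x) < 1e-8
  # confluent limit with first-order correction
  out[tiny] <- t[tiny] * exp(-kep * t[tiny]) * (1 + x[tiny] / 2)
  mid <- !tiny & abs(x) < 1
  # expm1 form: exp(-kep t) expm1(d t) / d
  out[mid] <- exp(-kep * t[mid]) * expm1(x[mid]) / d
  big <- !tiny & !mid
  out[big] <- (exp(-m * t[big]) - exp(-kep * t[big])) / d
  out
}

#' Closed-form convolution of the Tofts kernel with a biexponential VIF
#'
#' Analytic tissue uptake term for a plasma curve
#' \code{Cp(t) = A1 exp(-m1 t) + A2 exp(-m2 t)}:
#' \deqn{Ktrans \sum_i A_i (e^{-m_i t} - e^{-kep t}) / (kep - m_i).}
#' When \code{kep} coincides with a clearance rate the expression is evaluated
#' through its confluent limit \code{Ktrans A_i t e^{-kep t}}; the branch
#' switch happens at \code{|(kep - m_i) t| < 1e-8} (dimensionless), where the
#' limit form is exact to double precision.
#'
#' @param Ktrans Transfer constant, 1/min.
#' @param kep Reflux rate constant, 1/min.
#' @param biexp_params Named vector \code{c(A1, m1, A2, m2)}, rates in 1/s.
#' @param times Seconds from injection; negative times return 0.
#' @return Tissue uptake curve in delta-SI units.
#' @export
convolve_biexp_closed_form <- function(Ktrans, kep, biexp_params, times) {
  biexp_params <- check_biexp_params(biexp_params)
  if (!is.finite(Ktrans) || Ktrans < 0) stop("Ktrans must be >= 0")
  if (!is.finite(kep) || kep < 0) stop("kep must be >= 0")
  t_min <- pmax(times, 0) / 60
  m_min <- biexp_params[c("m1", "m2")] * 60   # 1/s -> 1/min
  A <- biexp_params[c("A1", "A2")]
  out <- Ktrans * (A[[1]] * exp_diff_ratio(kep, m_min[[1]], t_min) +
                   A[[2]] * exp_diff_ratio(kep, m_min[[2]], t_min))
  out[times < 0] <- 0
  out
}

# phi1(x) = (e^x - 1)/x, phi2(x) = (e^x (x - 1) + 1)/x^2, series-stabilised.
phi_funs <- function(x) {
  small <- abs(x) < 1e-4
  p1 <- numeric(length(x)); p2 <- numeric(length(x))
  xs <- x[small]
  p1[small] <- 1 + xs / 2 + xs^2 / 6 + xs^3 / 24
  p2[small] <- 0.5 + xs / 3 + xs^2 / 8 + xs^3 / 30
  xl <- x[!small]
  p1[!small] <- expm1(xl) / xl
  p2[!small] <- (expm1(xl) * (xl - 1) + xl) / xl^2
  list(p1 = p1, p2 = p2)
}

#' Numerical convolution of the Tofts kernel with a sampled VIF
#'
#' Evaluates \code{int_0^t Cp(u) exp(-kep (t - u)) du} (without the Ktrans
#' prefactor) treating the sampled VIF as piecewise linear between its
#' samples; each segment's integral against the exponential kernel is taken
#' in closed form, so the discretisation error is only in the interpolated
#' representation of Cp, which shrinks quadratically with the sampling step
#' (quartically with \code{refine > 1}, see below).  Requested times must lie
#' within the VIF's sampled support; times before the first sample raise an
#' extrapolation error, except that negative times (pre-injection frames) are
#' allowed and return 0 when the VIF starts at 0 s.
#'
#' With \code{refine > 1} the sampled curve is first interpolated onto a
#' \code{refine}-times finer grid with a cubic (FMM) spline before the
#' segment-exact convolution, reducing the representation error of a smooth
#' Cp from O(h^2) to O(h^4).  Use \code{refine = 1} for strict
#' piecewise-linear treatment (e.g. for impulse-like or already very finely
#' sampled curves, where a spline could overshoot or is unnecessary).
#'
#' @param kep Kernel rate constant, 1/min.
#' @param vif A \code{vif_curve} (times in s).
#' @param times Seconds from injection at which to evaluate.
#' @param refine Integer grid-refinement factor (default 8).
#' @return The convolution integral in delta-SI * min units (multiply by
#'   Ktrans in 1/min for a tissue curve).
#' @export
convolve_numeric <- function(kep, vif, times, refine = 8L) {
  stopifnot(inherits(vif, "vif_curve"))
  if (!is.finite(kep) || kep < 0) stop("kep must be >= 0")
  tol <- 1e-9
  pre <- times < vif$times[1]
  if (any(pre & times >= -tol & vif$times[1] > tol) || any(pre & times > tol))
    stop("requested time before the first VIF sample: refusing to extrapolate")
  if (any(times > max(vif$times) + tol))
    stop("requested time beyond the last VIF sample: refusing to extrapolate")

  u <- vif$times / 60                       # minutes
  cp <- vif$values
  refine <- max(1L, as.integer(refine))
  if (refine > 1L && length(u) > 2) {
    h0 <- diff(u)
    if (max(h0) - min(h0) < 1e-9 * max(h0)) {
      uf <- seq(u[1], u[length(u)], by = h0[1] / refine)
    } else {
      uf <- unique(c(unlist(lapply(seq_along(h0), function(j)
        seq(u[j], u[j + 1], length.out = refine + 1)[-(refine + 1)])),
        u[length(u)]))
    }
    cp <- stats::splinefun(u, cp, method = "fmm")(uf)
    u <- uf
  }
  n <- length(u)
  h <- diff(u)
  slope <- diff(cp) / h
  x <- kep * h
  ph <- phi_funs(x)
  # integral over segment j of Cp(u) e^{-kep (u_j+1 - u)} du
  seg <- exp(-x) * (cp[-n] * h * ph$p1 + slope * h^2 * ph$p2)

  node_vals <- numeric(n)
  if (n > 1) {
    if (kep * (max(u) - min(u)) < 400) {
      # vectorised: I(u_k) = e^{-kep u_k} sum_j seg_j e^{kep u_{j+1}}
      w <- exp(kep * (u[-1] - u[2]))        # rescaled to avoid overflow
      cs <- cumsum(seg * w)
      node_vals[-1] <- cs * exp(-kep * (u[-1] - u[2]))
    } else {
      for (j in seq_len(n - 1))
        node_vals[j + 1] <- node_vals[j] * exp(-x[j]) + seg[j]
    }
  }

  out <- numeric(length(times))
  tm <- times / 60
  inside <- tm >= u[1]
  idx <- findInterval(tm[inside], u, rightmost.closed = TRUE)
  exact <- abs(tm[inside] - u[idx]) <= tol / 60 + 1e-12
  val <- numeric(sum(inside))
  val[exact] <- node_vals[idx[exact]]
  if (any(!exact)) {
    k <- idx[!exact]
    tpart <- tm[inside][!exact]
    hp <- tpart - u[k]
    cp_t <- cp[k] + slope[k] * hp
    xp <- kep * hp
    php <- phi_funs(xp)
    segp <- exp(-xp) * (cp[k] * hp * php$p1 + slope[k] * hp^2 * php$p2)
    val[!exact] <- node_vals[k] * exp(-xp) + segp
  }
  out[inside] <- val
  out
}

cp_at <- function(vif, times) {
  out <- numeric(length(times))
  pos <- times >= 0
  if (!is.null(vif$params)) {
    out[pos] <- biexp_eval(vif$params, times[pos])
  } else {
    out[pos] <- approx(vif$times, vif$values, xout = times[pos], rule = 2)$y
  }
  out
}

uptake_term <- function(Ktrans, kep, vif, times) {
  if (Ktrans == 0) return(numeric(length(times)))
  if (!is.null(vif$params)) {
    convolve_biexp_closed_form(Ktrans, kep, vif$params, times)
  } else {
    Ktrans * convolve_numeric(kep, vif, times)
  }
}

check_model_times <- function(times) {
  if (length(times) == 0 || any(!is.finite(times)))
    stop("invalid time grid: times must be finite")
  if (any(diff(times) <= 0))
    stop("invalid time grid: times must be strictly increasing")
  times
}

#' Forward two-parameter (standard Tofts / Kety) model
#'
#' Tissue curve \code{Ct(t) = Ktrans int_0^t Cp(u) exp(-kep (t - u)) du} with
#' \code{kep = Ktrans / ve}.  For a VIF carrying biexponential parameters the
#' analytic convolution is used; otherwise the piecewise-linear numerical
#' convolution of the sampled curve.
#'
#' @param params A \code{pk_params} with \code{model = "two_param"}.
#' @param vif A \code{vif_curve}.
#' @param times Seconds from injection (strictly increasing); negative times
#'   (pre-injection) return 0.
#' @return Tissue curve Ct(t) in delta-SI units.
#' @export
tofts_2p <- function(params, vif, times) {
  stopifnot(inherits(params, "pk_params"), inherits(vif, "vif_curve"))
  if (params$model != "two_param")
    stop("tofts_2p requires a two-parameter pk_params")
  if (!params$valid) stop("cannot evaluate an invalid (NaN) parameter set")
  check_model_times(times)
  if (params$Ktrans < 0 || params$ve <= 0)
    stop("Ktrans must be >= 0 and ve > 0")
  uptake_term(params$Ktrans, params$kep, vif, times)
}

#' Forward three-parameter (extended Tofts / General Kinetic) model
#'
#' Adds the intravascular term \code{vp Cp(t)} to the two-parameter uptake
#' term.  With \code{vp = 0} the output equals \code{tofts_2p} exactly.
#'
#' @param params A \code{pk_params} with \code{model = "three_param"}.
#' @inheritParams tofts_2p
#' @return Tissue curve Ct(t) in delta-SI units.
#' @export
tofts_3p <- function(params, vif, times) {
  stopifnot(inherits(params, "pk_params"), inherits(vif, "vif_curve"))
  if (params$model != "three_param")
    stop("tofts_3p requires a three-parameter pk_params")
  if (!params$valid) stop("cannot evaluate an invalid (NaN) parameter set")
  check_model_times(times)
  if (params$Ktrans < 0 || params$ve <= 0)
    stop("Ktrans must be >= 0 and ve > 0")
  if (params$vp < 0 || params$vp >= 1)
    stop("vp must lie in [0, 1)")
  params$vp * cp_at(vif, times) +
    uptake_term(params$Ktrans, params$kep, vif, times)
}
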