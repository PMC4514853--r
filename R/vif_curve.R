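#' Vascular input function curve
#'
#' Container for a plasma concentration surrogate curve Cp(t) in delta-SI
#' units.  Times are seconds measured from the injection frame and must be
#' strictly increasing and non-negative.  A curve tagged
#' \code{source = "population"} must carry the biexponential parameters it was
#' fitted with, and its values must equal the biexponential evaluated at its
#' times.
#'
#' @param times Numeric vector, seconds from injection; non-negative, strictly
#'   increasing.
#' @param values Numeric vector of Cp(t) in delta-SI units; finite.
#' @param source One of \code{"individual"}, \code{"population"}.
#' @param params Optional named vector \code{c(A1, m1, A2, m2)}: amplitudes in
#'   delta-SI units and clearance rates in 1/s, fast component first
#'   (\code{m1 > m2}).  Required when \code{source = "population"}.
#' @param n_voxels Optional integer: number of vessel voxels averaged to form
#'   an individual curve.
#'
#' @return An object of class \code{vif_curve}.
#' @export
vif_curve <- function(times, values, source = c("individual", "population"),
                      params = NULL, n_voxels = NA_integer_) {
  source <- match.arg(source)
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have equal length")
  if (any(!is.finite(times)) || any(times < 0))
    stop("`times` must be finite and non-negative (seconds from injection)")
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing")
  if (any(!is.finite(values)))
    stop("`values` must be finite")
  if (!is.null(params)) {
    params <- check_biexp_params(params)
  }
  if (source == "population") {
    if (is.null(params))
      stop("a population VIF must carry its biexponential parameters")
    model_vals <- biexp_eval(params, times)
    if (max(abs(values - model_vals)) >
        1e-8 * max(abs(model_vals), 1e-12))
      stop("population VIF values do not match its biexponential parameters")
  }
  structure(
    list(times = times, values = values, source = source,
         params = params, n_voxels = as.integer(n_voxels)),
    class = "vif_curve"
  )
}

check_biexp_params <- function(params) {
  params <- unlist(params)
  if (length(params) != 4)
    stop("biexponential parameters must be c(A1, m1, A2, m2)")
  names(params) <- c("A1", "m1", "A2", "m2")
  if (any(!is.finite(params)) || any(params[c("A1", "A2")] < 0) ||
      any(params[c("m1", "m2")] <= 0))
    stop("biexponential amplitudes must be >= 0 and rates > 0")
  params
}

#' Evaluate a biexponential decay
#'
#' Computes \code{A1 exp(-m1 t) + A2 exp(-m2 t)} with rates in 1/s and
#' \code{t} in seconds from injection.  Negative times (pre-injection frames)
#' evaluate to zero, matching the convention that the plasma curve is zero
#' before bolus arrival.
#'
#' @param params Named vector \code{c(A1, m1, A2, m2)} (rates in 1/s).
#' @param times Seconds from injection (may be negative).
#' @return Numeric vector of Cp values in delta-SI units.
#' @export
biexp_eval <- function(params, times) {
  params <- check_biexp_params(params)
  out <- params[["A1"]] * exp(-params[["m1"]] * times) +
    params[["A2"]] * exp(-params[["m2"]] * times)
  out[times < 0] <- 0
  out
}

#' @export
print.vif_curve <- function(x, ...) {
  cat(sprintf("<vif_curve> %s, %d samples over [%g, %g] s\n",
              x$source, length(x$times), min(x$times), max(x$times)))
  if (!is.null(x$params)) {
    cat(sprintf("  Cp(t) = %.4g exp(-%.4g t) + %.4g exp(-%.4g t)  [t in s]\n",
                x$params["A1"], x$params["m1"],
                x$params["A2"], x$params["m2"]))
  }
  if (!is.na(x$n_voxels))
    cat(sprintf("  averaged from %d vessel voxels\n", x$n_voxels))
  invisible(x)
}

#' Write / read a VIF curve as two-column CSV
#'
#' Serialisation format: columns \code{time_s}, \code{delta_si}.
#'
#' @param vif A \code{vif_curve}.
#' @param path File path.
#' @param source Curve provenance tag used when reading back.
#' @return \code{read_vif_csv} returns a \code{vif_curve};
#'   \code{write_vif_csv} returns \code{path} invisibly.
#' @export
write_vif_csv <- function(vif, path) {
  stopifnot(inherits(vif, "vif_curve"))
  utils::write.csv(data.frame(time_s = vif$times, delta_si = vif$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vif_csv
#' @export
read_vif_csv <- function(path, source = "individual") {
  d <- utils::read.csv(path)
  vif_curve(d$time_s, d$delta_si, source = source)
}
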