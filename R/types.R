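#' Tri-exponential input-function parameters
#'
#' Parameterizes an arterial blood curve as a linear rise from zero at `t = 0`
#' to the peak at `t_peak`, followed by a sum of three decaying exponentials
#' `sum(A_i * exp(-lambda_i * (t - t_peak)))`. Amplitudes are stored sorted so
#' that rates satisfy `lambda1 > lambda2 > lambda3`.
#'
#' @param t_peak Peak time in minutes (>= 0).
#' @param amplitudes Numeric vector of three amplitudes in kBq/mL (>= 0, at
#'   least one positive).
#' @param rates Numeric vector of three decay rates in 1/min (> 0, distinct).
#' @return An object of class `triexp_params`.
#' @export
triexp_params <- function(t_peak, amplitudes, rates) {
  stopifnot(length(amplitudes) == 3L, length(rates) == 3L)
  if (t_peak < 0) abort("`t_peak` must be >= 0")
  if (any(amplitudes < 0) || all(amplitudes == 0)) {
    abort("amplitudes must be >= 0 with at least one > 0")
  }
  if (any(!is.finite(rates)) || any(rates <= 0)) {
    abort("rates must be finite and > 0")
  }
  if (anyDuplicated(rates)) abort("rates must be distinct")
  ord <- order(rates, decreasing = TRUE)
  structure(
    list(t_peak = t_peak, amplitudes = amplitudes[ord], rates = rates[ord]),
    class = "triexp_params"
  )
}

#' Evaluate a tri-exponential blood curve
#'
#' Zero at `t = 0`, linear rise to the peak, tri-exponential decay afterwards;
#' continuous at `t_peak`.
#'
#' @param params A [triexp_params()] object.
#' @param t Times in minutes (>= 0); vectorized.
#' @return Activity in kBq/mL.
#' @export
true_aif <- function(params, t) {
  stopifnot(inherits(params, "triexp_params"))
  if (any(t < 0)) abort("`t` must be >= 0")
  A <- params$amplitudes
  lam <- params$rates
  tp <- params$t_peak
  peak <- sum(A)
  out <- numeric(length(t))
  post <- t >= tp
  if (any(post)) {
    dt <- t[post] - tp
    out[post] <- A[1] * exp(-lam[1] * dt) + A[2] * exp(-lam[2] * dt) +
      A[3] * exp(-lam[3] * dt)
  }
  if (any(!post)) {
    out[!post] <- if (tp > 0) peak * t[!post] / tp else peak
  }
  out
}

#' Hill-type parent-fraction parameters
#'
#' Monotone non-increasing fraction of unmetabolized (parent) tracer in blood,
#' `f(t) = a + (1 - a) * c^b / (c^b + t^b)`, with `f(0) = 1` and asymptote `a`.
#'
#' @param a Plateau in `[0, 1]`.
#' @param b Shape exponent (> 0), unitless.
#' @param c Half-transition time in minutes (> 0).
#' @return An object of class `parent_fraction_params`.
#' @export
parent_fraction_params <- function(a, b, c) {
  if (a < 0 || a > 1) abort("`a` must be in [0, 1]")
  if (b <= 0 || c <= 0) abort("`b` and `c` must be > 0")
  structure(list(a = a, b = b, c = c), class = "parent_fraction_params")
}

#' Evaluate the parent-fraction curve
#'
#' @param params A [parent_fraction_params()] object.
#' @param t Times in minutes (>= 0); vectorized.
#' @return Fraction in `[0, 1]`.
#' @export
parent_fraction <- function(params, t) {
  stopifnot(inherits(params, "parent_fraction_params"))
  if (any(t < 0)) abort("`t` must be >= 0")
  cb <- params$c^params$b
  params$a + (1 - params$a) * cb / (cb + t^params$b)
}

#' Two-tissue-compartment rate constants
#'
#' @param K1 Plasma-to-tissue transfer, mL cm^-3 min^-1 (> 0).
#' @param k2,k3,k4 First-order rates in 1/min (> 0).
#' @param vB Fractional blood volume in `[0, 1)`; defaults to 0.05.
#' @return An object of class `twotc_params`.
#' @export
twotc_params <- function(K1, k2, k3, k4, vB = 0.05) {
  if (any(c(K1, k2, k3, k4) <= 0)) abort("rate constants must be > 0")
  if (vB < 0 || vB >= 1) abort("`vB` must be in [0, 1)")
  structure(list(K1 = K1, k2 = k2, k3 = k3, k4 = k4, vB = vB),
            class = "twotc_params")
}

#' Total volume of distribution implied by 2TC rate constants
#'
#' Closed form `VT = (K1/k2) * (1 + k3/k4)` for reversible two-tissue kinetics.
#'
#' @param params A [twotc_params()] object.
#' @return VT (unitless tissue:plasma concentration ratio, mL/cm^3).
#' @export
true_vt <- function(params) {
  stopifnot(inherits(params, "twotc_params"))
  (params$K1 / params$k2) * (1 + params$k3 / params$k4)
}

#' Input function on the uniform 1-s grid
#'
#' Container for a metabolite-corrected plasma curve (or a whole-blood curve)
#' sampled every second over 0-90 min.
#'
#' @param activity Numeric vector of length 5401 (kBq/mL, >= 0 after clipping).
#' @param provenance One of `"PSAIF"`, `"PBIF_scaled"`, `"whole_blood"`,
#'   `"true"`.
#' @return An object of class `input_function` with fields `time_s`,
#'   `activity`, `peak_time_s`, `provenance`.
#' @export
new_input_function <- function(activity, provenance = "PSAIF") {
  grid <- .grid_s()
  if (length(activity) != length(grid)) {
    abort(sprintf("`activity` must have length %d (1-s grid over 0-90 min)",
                  length(grid)))
  }
  if (any(!is.finite(activity))) abort("`activity` must be finite")
  activity <- pmax(activity, 0)
  structure(
    list(time_s = grid, activity = activity,
         peak_time_s = grid[which.max(activity)],
         provenance = provenance),
    class = "input_function"
  )
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf(
    "<input_function [%s]> 1-s grid 0-90 min, peak %.3g kBq/mL at %d s\n",
    x$provenance, max(x$activity), x$peak_time_s))
  invisible(x)
}

#' Interpolate an input function at arbitrary times
#'
#' @param x An `input_function`.
#' @param t_min Times in minutes within `[0, 90]`.
#' @return Activity in kBq/mL (linear interpolation on the 1-s grid).
#' @export
if_at <- function(x, t_min) {
  stopifnot(inherits(x, "input_function"))
  if (any(t_min < 0 | t_min > 90)) abort("`t_min` must lie in [0, 90]")
  approx(x$time_s / 60, x$activity, xout = t_min, rule = 2)$y
}

#' Area under a curve by the trapezoidal rule
#'
#' @param x An `input_function`, or a data frame with columns `time_min` and
#'   `value`.
#' @param t_lo,t_hi Integration bounds in minutes, within the curve domain.
#' @return AUC in kBq min/mL.
#' @export
auc <- function(x, t_lo = 0, t_hi = 90) {
  if (inherits(x, "input_function")) {
    tt <- x$time_s / 60
    vv <- x$activity
  } else {
    x <- as.data.frame(x)
    stopifnot(all(c("time_min", "value") %in% names(x)))
    tt <- x$time_min
    vv <- x$value
  }
  if (t_lo >= t_hi) abort("`t_lo` must be < `t_hi`")
  if (t_lo < min(tt) - 1e-9 || t_hi > max(tt) + 1e-9) {
    abort("integration bounds outside the curve domain")
  }
  inside <- tt > t_lo & tt < t_hi
  ts <- c(t_lo, tt[inside], t_hi)
  vs <- c(approx(tt, vv, xout = t_lo, rule = 2)$y, vv[inside],
          approx(tt, vv, xout = t_hi, rule = 2)$y)
  pracma::trapz(ts, vs)
}

#' Convert an injected dose from MBq to mCi
#'
#' @param mbq Dose in MBq.
#' @return Dose in mCi (1 mCi = 37 MBq).
#' @export
mbq_to_mci <- function(mbq) mbq / 37
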