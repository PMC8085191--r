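#' Dynamic-frame schedule
#'
#' Default 32-frame schedule over 90 min: 6x10 s, 4x30 s, 3x60 s, 2x120 s,
#' 5x240 s, 12x300 s. Frames are contiguous and non-overlapping.
#'
#' @param durations_s Frame durations in seconds.
#' @return A tibble with columns `frame`, `start_s`, `end_s`, `mid_min`.
#' @export
frame_schedule <- function(durations_s = c(rep(10, 6), rep(30, 4), rep(60, 3),
                                           rep(120, 2), rep(240, 5),
                                           rep(300, 12))) {
  if (any(durations_s <= 0)) abort("frame durations must be > 0")
  ends <- cumsum(durations_s)
  starts <- c(0, ends[-length(ends)])
  tibble::tibble(
    frame = seq_along(durations_s),
    start_s = starts,
    end_s = ends,
    mid_min = (starts + ends) / 2 / 60
  )
}

# convolution of a piecewise-linear curve (on a uniform grid, spacing dt_min)
# with exp(-theta * t); exact for the piecewise-linear interpolant
.conv_exp <- function(values, dt_min, theta) {
  n <- length(values)
  x <- theta * dt_min
  E <- exp(-x)
  if (x > 1e-5) {
    i1 <- (1 - E) / theta                      # int exp(-theta(dt-s)) ds
    i2 <- dt_min * (1 - E) / theta - (1 - (1 + x) * E) / theta^2
  } else {                                     # series guards for theta -> 0
    i1 <- dt_min * (1 - x / 2 + x^2 / 6)
    i2 <- dt_min^2 * (1 / 2 - x / 3 + x^2 / 8)
  }
  c0 <- values[-n]
  c1 <- values[-1]
  inc <- c0 * i1 + (c1 - c0) * i2 / dt_min
  c(0, stats::filter(inc, E, method = "recursive"))
}

#' Simulate a regional two-tissue-compartment TAC
#'
#' Solves `dC1/dt = K1 Cp - (k2 + k3) C1 + k4 C2`, `dC2/dt = k3 C1 - k4 C2`
#' from zero initial conditions using the analytic bi-exponential impulse
#' response convolved exactly with the piecewise-linear plasma curve. The
#' measured frame value is the frame average of
#' `(1 - vB) (C1 + C2) + vB C_blood`.
#'
#' @param aif Metabolite-corrected plasma input (`input_function`, 1-s grid).
#' @param params A [twotc_params()] object.
#' @param schedule A [frame_schedule()] tibble.
#' @param whole_blood Optional whole-blood `input_function` for the vB term;
#'   defaults to `aif`.
#' @param region Region label stored in the output.
#' @return A tibble (`region`, `frame`, `start_s`, `end_s`, `mid_min`,
#'   `activity_kBq_mL`).
#' @export
simulate_2tc <- function(aif, params, schedule = frame_schedule(),
                         whole_blood = aif, region = "region") {
  stopifnot(inherits(aif, "input_function"), inherits(params, "twotc_params"))
  if (max(schedule$end_s) > max(aif$time_s)) {
    abort("input function grid does not cover the frame schedule")
  }
  with(params, {
    s <- k2 + k3 + k4
    disc <- sqrt(s^2 - 4 * k2 * k4)
    th1 <- (s + disc) / 2                     # fast eigenrate
    th2 <- (s - disc) / 2                     # slow eigenrate
    # C1 + C2 = K1 * (phi1 exp(-th1 t) + phi2 exp(-th2 t)) (*) Cp
    phi1 <- (th1 - k3 - k4) / disc
    phi2 <- (k3 + k4 - th2) / disc
    dt_min <- 1 / 60
    tissue <- K1 * (phi1 * .conv_exp(aif$activity, dt_min, th1) +
                    phi2 * .conv_exp(aif$activity, dt_min, th2))
    meas <- (1 - vB) * tissue + vB * whole_blood$activity
    act <- vapply(seq_len(nrow(schedule)), function(i) {
      idx <- (schedule$start_s[i]:schedule$end_s[i]) + 1L
      pracma::trapz(aif$time_s[idx], meas[idx]) /
        (schedule$end_s[i] - schedule$start_s[i])
    }, numeric(1))
    tibble::tibble(region = region, frame = schedule$frame,
                   start_s = schedule$start_s, end_s = schedule$end_s,
                   mid_min = schedule$mid_min, activity_kBq_mL = act)
  })
}

#' Remove the vascular contribution from a measured TAC
#'
#' Inverts the blood-volume composition: `C_tissue = (C_pet - vB C_wb) /
#' (1 - vB)`, clipped at zero (negative intermediates trigger a warning).
#'
#' @param tac Tibble with `mid_min` (or `start_s`/`end_s`) and
#'   `activity_kBq_mL`.
#' @param whole_blood Whole-blood `input_function`.
#' @param vB Fractional blood volume in `[0, 1)`; default 0.05.
#' @return `tac` with `activity_kBq_mL` replaced by the tissue activity.
#' @export
blood_volume_correct <- function(tac, whole_blood, vB = 0.05) {
  if (vB < 0 || vB >= 1) abort("`vB` must be in [0, 1)")
  mid_min <- if ("mid_min" %in% names(tac)) tac$mid_min else
    (tac$start_s + tac$end_s) / 2 / 60
  # vB term uses the whole-blood value averaged over each frame, matching the
  # frame-averaged PET measurement
  wb <- if (all(c("start_s", "end_s") %in% names(tac))) {
    vapply(seq_len(nrow(tac)), function(i) {
      idx <- (tac$start_s[i]:tac$end_s[i]) + 1L
      pracma::trapz(whole_blood$time_s[idx], whole_blood$activity[idx]) /
        (tac$end_s[i] - tac$start_s[i])
    }, numeric(1))
  } else {
    if_at(whole_blood, mid_min)
  }
  tissue <- (tac$activity_kBq_mL - vB * wb) / (1 - vB)
  if (any(tissue < 0)) {
    warn(sprintf("%d corrected tissue values < 0 clipped to 0",
                 sum(tissue < 0)))
    tissue <- pmax(tissue, 0)
  }
  out <- tac
  out$activity_kBq_mL <- tissue
  out
}

#' Logan-plot coordinates
#'
#' For each usable frame mid-time `t_k`, computes
#' `y_k = int_0^{t_k} C dT / C(t_k)` and `x_k = int_0^{t_k} Cp dT / C(t_k)`.
#' The plasma integral is trapezoidal on the 1-s grid; the tissue integral is
#' trapezoidal over frame mid-times with a straight segment anchored at
#' `(0, 0)`. Frames with non-positive tissue activity are excluded.
#'
#' @param tissue Tibble with `mid_min` and `activity_kBq_mL` (vB-corrected).
#' @param cp Plasma input (`input_function`).
#' @return A tibble (`t_min`, `x`, `y`).
#' @export
logan_points <- function(tissue, cp) {
  stopifnot(inherits(cp, "input_function"))
  mid <- tissue$mid_min
  ct <- tissue$activity_kBq_mL
  int_cp_grid <- pracma::cumtrapz(cp$time_s / 60, cp$activity)[, 1]
  int_cp <- approx(cp$time_s / 60, int_cp_grid, xout = mid)$y
  int_ct <- pracma::cumtrapz(c(0, mid), c(0, ct))[-1, 1]
  keep <- ct > 0
  if (!any(keep)) abort("all frames excluded (non-positive tissue activity)")
  tibble::tibble(t_min = mid[keep], x = int_cp[keep] / ct[keep],
                 y = int_ct[keep] / ct[keep])
}

#' Linearity onset of the Logan plot (maximum-admissible-error criterion)
#'
#' Finds the smallest start index such that the line fitted to the points from
#' that index onward leaves every included point within `max_rel_error`
#' relative deviation. The deviation is measured against the fitted value by
#' default (`rel_to = "fitted"`); `rel_to = "observed"` is available. If no
#' start qualifies, the last three points are used and `fallback` is set.
#'
#' @param points Tibble from [logan_points()].
#' @param max_rel_error Threshold on the relative error (default 0.10).
#' @param rel_to Denominator of the relative error.
#' @return List with `index`, `t_star_min`, `n_points`, `fallback`.
#' @export
find_tstar <- function(points, max_rel_error = 0.10,
                       rel_to = c("fitted", "observed")) {
  rel_to <- match.arg(rel_to)
  n <- nrow(points)
  if (n < 3L) abort("need at least 3 Logan points")
  for (s in seq_len(n - 2L)) {
    xs <- points$x[s:n]
    ys <- points$y[s:n]
    slope <- stats::cov(xs, ys) / var(xs)
    yhat <- mean(ys) + slope * (xs - mean(xs))
    denom <- if (rel_to == "fitted") abs(yhat) else abs(ys)
    err <- max(abs(ys - yhat) / denom)
    if (err <= max_rel_error) {
      return(list(index = s, t_star_min = points$t_min[s],
                  n_points = n - s + 1L, fallback = FALSE))
    }
  }
  warn("no start index satisfies the error criterion; using the last 3 points")
  list(index = n - 2L, t_star_min = points$t_min[n - 2L], n_points = 3L,
       fallback = TRUE)
}

#' Fit the Logan regression from t* onward
#'
#' Ordinary least squares on the Logan coordinates at and after `t_star`;
#' the slope is the total volume of distribution VT.
#'
#' @param points Tibble from [logan_points()].
#' @param tstar Result of [find_tstar()], or a start index.
#' @return A one-row tibble (`VT`, `intercept`, `t_star_min`, `n_points`,
#'   `R2`, `AIC`, `pct_SE`, `fallback`). `AIC` uses the Gaussian-RSS form
#'   `n log(RSS/n) + 2k` with `k = 2`; `pct_SE` is the OLS standard error of
#'   the slope as a percentage of the slope.
#' @export
fit_logan <- function(points, tstar) {
  if (is.numeric(tstar)) tstar <- list(index = as.integer(tstar),
                                       t_star_min = points$t_min[tstar],
                                       fallback = FALSE)
  idx <- tstar$index:nrow(points)
  if (length(idx) < 3L) abort("need at least 3 points at/after t*")
  d <- points[idx, ]
  if (var(d$x) == 0) abort("degenerate Logan abscissa (zero variance)")
  fit <- lm(y ~ x, data = d)
  n <- nrow(d)
  rss <- sum(residuals(fit)^2)
  slope <- unname(coef(fit)[2])
  sm <- suppressWarnings(summary(fit))  # exact fits trip a summary.lm warning
  se <- sm$coefficients[2, 2]
  tibble::tibble(
    VT = slope,
    intercept = unname(coef(fit)[1]),
    t_star_min = tstar$t_star_min,
    n_points = n,
    R2 = sm$r.squared,
    AIC = n * log(rss / n) + 4,
    pct_SE = se / slope * 100,
    fallback = isTRUE(tstar$fallback)
  )
}

#' Logan VT from a measured TAC and an input function
#'
#' Convenience wrapper: blood-volume correction, Logan transform, automatic
#' t* search, OLS fit.
#'
#' @inheritParams blood_volume_correct
#' @param cp Plasma input (`input_function`).
#' @param max_rel_error t* criterion threshold (default 0.10).
#' @return A one-row tibble as in [fit_logan()].
#' @export
logan_vt <- function(tac, cp, whole_blood, vB = 0.05, max_rel_error = 0.10) {
  tissue <- blood_volume_correct(tac, whole_blood, vB)
  pts <- logan_points(tissue, cp)
  fit_logan(pts, find_tstar(pts, max_rel_error))
}
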