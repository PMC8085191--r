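#' Merge automated and manual blood samples
#'
#' @param auto,manual Data frames with columns `time_min` and `value`
#'   (activity, kBq/mL). `manual` may be empty.
#' @return A single time-sorted tibble; duplicate times across the inputs are
#'   an error.
#' @export
merge_blood_samples <- function(auto, manual) {
  auto <- tibble::as_tibble(auto)
  manual <- tibble::as_tibble(manual)
  if (nrow(auto) == 0 && nrow(manual) == 0) abort("no blood samples")
  merged <- dplyr::bind_rows(auto, manual)
  merged <- dplyr::arrange(merged, .data$time_min)
  if (anyDuplicated(merged$time_min)) {
    abort("duplicate sample times across automated and manual series")
  }
  merged
}

.triexp_predict <- function(t, t_peak, A1, A2, A3, l1, l2, l3) {
  peak <- A1 + A2 + A3
  out <- numeric(length(t))
  post <- t >= t_peak
  dt <- t[post] - t_peak
  out[post] <- A1 * exp(-l1 * dt) + A2 * exp(-l2 * dt) + A3 * exp(-l3 * dt)
  if (any(!post)) out[!post] <- if (t_peak > 0) peak * t[!post] / t_peak else peak
  out
}

# deterministic multi-start grid for the decay rates (1/min)
.triexp_rate_starts <- function() {
  expand.grid(l1 = c(8, 3, 1.5), l2 = c(0.8, 0.3), l3 = c(0.03, 0.01))
}

#' Fit a tri-exponential model to merged blood samples
#'
#' Nonlinear least squares (Levenberg-Marquardt) with a deterministic list of
#' log-spaced rate starts; for each rate start the amplitudes are initialized
#' by a linear fit of the post-peak samples on the exponential basis. The
#' lowest-RSS converged fit wins.
#'
#' @param samples Tibble with `time_min`, `value`; needs >= 7 samples spanning
#'   pre- and post-peak times.
#' @return List with `params` ([triexp_params()]), `report` (RSS, residuals,
#'   convergence of every start).
#' @export
fit_triexp <- function(samples) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) < 7L) abort("need at least 7 blood samples")
  if (max(samples$value) <= 0) abort("degenerate samples: no peak")
  t <- samples$time_min
  v <- samples$value
  tp0 <- t[which.max(v)]
  if (tp0 >= max(t)) {
    abort("samples must span pre- and post-peak times")
  }
  starts <- .triexp_rate_starts()
  attempts <- vector("list", nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    l0 <- unname(unlist(starts[i, ]))
    post <- t >= tp0
    basis <- cbind(exp(-l0[1] * (t[post] - tp0)),
                   exp(-l0[2] * (t[post] - tp0)),
                   exp(-l0[3] * (t[post] - tp0)))
    A0 <- tryCatch(qr.solve(basis, v[post]), error = function(e) NULL)
    if (is.null(A0)) A0 <- max(v) * c(0.7, 0.2, 0.1)
    A0 <- unname(pmax(A0, max(v) * 1e-3))
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ .triexp_predict(time_min, t_peak, A1, A2, A3, l1, l2, l3),
        data = samples,
        start = list(t_peak = tp0, A1 = A0[1], A2 = A0[2], A3 = A0[3],
                     l1 = l0[1], l2 = l0[2], l3 = l0[3]),
        lower = c(t_peak = min(t) / 2, A1 = 0, A2 = 0, A3 = 0,
                  l1 = 1e-4, l2 = 1e-4, l3 = 1e-4),
        upper = c(t_peak = 2 * tp0, A1 = Inf, A2 = Inf, A3 = Inf,
                  l1 = 50, l2 = 50, l3 = 50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      attempts[[i]] <- list(start = l0, rss = NA_real_, converged = FALSE)
      next
    }
    rss <- sum(residuals(fit)^2)
    attempts[[i]] <- list(start = l0, rss = rss, converged = TRUE)
    if (is.finite(rss) && (is.null(best) || rss < best$rss)) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("tri-exponential fit failed to converge from every start")
  }
  cf <- coef(best$fit)
  rates <- sort(unname(cf[c("l1", "l2", "l3")]), decreasing = TRUE)
  amps <- pmax(unname(cf[c("A1", "A2", "A3")])[
    order(unname(cf[c("l1", "l2", "l3")]), decreasing = TRUE)], 0)
  # enforce strictly decreasing rates for the params invariant (ties occur
  # when a component vanishes); perturbation is below fitting precision
  for (j in 2:3) {
    if (rates[j] >= rates[j - 1]) rates[j] <- rates[j - 1] * (1 - 1e-9)
  }
  if (all(amps == 0)) amps[1] <- 1e-12
  params <- triexp_params(t_peak = unname(cf["t_peak"]),
                          amplitudes = unname(amps), rates = unname(rates))
  list(params = params,
       report = list(rss = best$rss,
                     residuals = unname(residuals(best$fit)),
                     starts = attempts))
}

#' Fit the Hill-type parent-fraction model
#'
#' Fits `f(t) = a + (1 - a) c^b / (c^b + t^b)` to measured parent fractions;
#' `f(0) = 1` is enforced by the model form.
#'
#' @param fractions Tibble with `time_min`, `value`; fractions must lie in
#'   `[0, 1]`, >= 3 points.
#' @return List with `params` ([parent_fraction_params()]) and `report`.
#' @export
fit_parent_fraction <- function(fractions) {
  fractions <- tibble::as_tibble(fractions)
  if (nrow(fractions) < 3L) abort("need at least 3 parent-fraction points")
  if (any(fractions$value < 0 | fractions$value > 1)) {
    abort("parent fractions must lie in [0, 1]")
  }
  if (all(fractions$value == 1)) {
    # no metabolites measured anywhere: f is identically 1 (a = 1); the Hill
    # shape parameters are unidentifiable and kept at neutral values
    params <- parent_fraction_params(a = 1, b = 1,
                                     c = max(median(fractions$time_min), 1))
    return(list(params = params,
                report = list(rss = 0,
                              residuals = rep(0, nrow(fractions)),
                              starts = list())))
  }
  a0 <- max(min(fractions$value) * 0.8, 1e-3)
  c0 <- max(median(fractions$time_min), 1e-2)
  best <- NULL
  attempts <- list()
  for (b0 in c(0.5, 1, 2)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        value ~ a + (1 - a) * c^b / (c^b + time_min^b),
        data = fractions,
        start = list(a = a0, b = b0, c = c0),
        lower = c(a = 0, b = 1e-3, c = 1e-3),
        upper = c(a = 1, b = 20, c = 1e4),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    attempts[[length(attempts) + 1]] <- list(b_start = b0, rss = rss)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) abort("parent-fraction fit failed to converge")
  cf <- coef(best$fit)
  list(params = parent_fraction_params(a = unname(cf["a"]),
                                       b = unname(cf["b"]),
                                       c = unname(cf["c"])),
       report = list(rss = best$rss,
                     residuals = unname(residuals(best$fit)),
                     starts = attempts))
}

#' Metabolite-correct a total-blood curve
#'
#' Multiplies total-blood activity by the parent fraction. Accepts either a
#' sampled series (pointwise product) or a function of time (returns the
#' corrected function).
#'
#' @param total A tibble with `time_min`, `value`, or a function `t_min ->
#'   kBq/mL`.
#' @param f A [parent_fraction_params()] object.
#' @return Corrected series (tibble) or corrected function, matching `total`.
#' @export
metabolite_correct <- function(total, f) {
  stopifnot(inherits(f, "parent_fraction_params"))
  if (is.function(total)) {
    function(t) total(t) * parent_fraction(f, t)
  } else {
    total <- tibble::as_tibble(total)
    total$value <- total$value * parent_fraction(f, total$time_min)
    total
  }
}

#' Resample a curve to the 1-s grid and align its peak to 30 s
#'
#' Evaluates the curve on the uniform 1-s grid over 0-90 min and rigidly
#' time-shifts it so its maximum falls at t = 30 s. The left gap created by a
#' rightward shift is zero-padded; a leftward shift extends the right end by
#' evaluating the supplied curve beyond 90 min (analytic fits decay smoothly),
#' preserving the full 90-min span.
#'
#' @param curve A function `t_min -> kBq/mL` defined on `[0, 90]` (and a
#'   little beyond for leftward shifts), or a data frame with `time_min`,
#'   `value` (linearly interpolated, last value carried forward).
#' @param provenance Stored in the returned object.
#' @return An `input_function` with `peak_time_s = 30`.
#' @export
resample_and_align <- function(curve, provenance = "PSAIF") {
  if (!is.function(curve)) {
    d <- tibble::as_tibble(curve)
    curve_fn <- function(t) approx(d$time_min, d$value, xout = t, rule = 2)$y
  } else {
    curve_fn <- curve
  }
  grid_min <- .grid_min()
  vals <- curve_fn(grid_min)
  if (diff(range(vals)) == 0) abort("flat curve: no unique peak to align")
  peak_s <- .grid_s()[which.max(vals)]
  shift_s <- 30L - peak_s
  src <- grid_min - shift_s / 60
  out <- numeric(length(src))
  ok <- src >= 0
  out[ok] <- curve_fn(src[ok])
  new_input_function(out, provenance = provenance)
}

#' Process one session's blood table into a patient-specific input function
#'
#' Full chain: merge automated and manual samples, fit the tri-exponential
#' total-blood model, fit the parent-fraction model, metabolite-correct the
#' fitted curve, resample to the 1-s grid and align the peak to 30 s.
#'
#' @param blood Tibble with columns `time_min`, `activity_kBq_mL`,
#'   `sample_type` (`"auto"`/`"manual"`) and `parent_fraction` (NA where not
#'   measured), as written by [generate_cohort()].
#' @return List with `psaif` (aligned `input_function`), `whole_blood`
#'   (unaligned fitted total-blood `input_function`), `triexp`, `pf` (fit
#'   results), and `auc` (0-90 min AUC of the aligned PSAIF).
#' @export
process_psaif <- function(blood) {
  blood <- tibble::as_tibble(blood)
  auto <- blood[blood$sample_type == "auto",
                c("time_min", "activity_kBq_mL")]
  manual <- blood[blood$sample_type == "manual",
                  c("time_min", "activity_kBq_mL")]
  names(auto) <- names(manual) <- c("time_min", "value")
  merged <- merge_blood_samples(auto, manual)
  tri <- fit_triexp(merged)
  pf_data <- blood[!is.na(blood$parent_fraction),
                   c("time_min", "parent_fraction")]
  names(pf_data) <- c("time_min", "value")
  pf <- fit_parent_fraction(pf_data)
  corrected <- metabolite_correct(function(t) true_aif(tri$params, t),
                                  pf$params)
  psaif <- resample_and_align(corrected, provenance = "PSAIF")
  wb <- new_input_function(true_aif(tri$params, .grid_min()),
                           provenance = "whole_blood")
  list(psaif = psaif, whole_blood = wb, triexp = tri, pf = pf,
       auc = auc(psaif, 0, 90))
}
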