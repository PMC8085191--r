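.norm_schemes <- c("WEIGHT_DOSE", "AUC", "WEIGHT_AUC")

#' Normalize a patient-specific input function
#'
#' Divides the PSAIF by the subject-level factor of the chosen scheme:
#' `WEIGHT_DOSE` by weight x injected dose, `AUC` by the 0-90 min AUC of the
#' curve itself, `WEIGHT_AUC` by weight x AUC.
#'
#' @param psaif An `input_function` (1-s grid, peak at 30 s).
#' @param weight_kg,dose_MBq Subject weight and injected dose.
#' @param scheme One of `"WEIGHT_DOSE"`, `"AUC"`, `"WEIGHT_AUC"`.
#' @return A numeric vector of normalized values on the 1-s grid.
#' @export
normalize_psaif <- function(psaif, weight_kg, dose_MBq,
                            scheme = c("WEIGHT_DOSE", "AUC", "WEIGHT_AUC")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(psaif, "input_function"))
  factor <- switch(scheme,
    WEIGHT_DOSE = {
      if (weight_kg <= 0 || dose_MBq <= 0) abort("weight and dose must be > 0")
      weight_kg * dose_MBq
    },
    AUC = auc(psaif, 0, 90),
    WEIGHT_AUC = {
      if (weight_kg <= 0) abort("weight must be > 0")
      weight_kg * auc(psaif, 0, 90)
    })
  if (factor <= 0) abort("normalization factor must be > 0")
  psaif$activity / factor
}

#' Build a leave-one-out population-based input function
#'
#' Pointwise mean and sample SD over the normalized curves of every subject
#' except the excluded one.
#'
#' @param normalized Named list of numeric vectors on the shared 1-s grid
#'   (peaks aligned at 30 s), names are subject ids.
#' @param exclude Subject id to leave out.
#' @param scheme Normalization scheme label carried in the result.
#' @return A list of class `pbif_model` with `mean`, `sd`, `scheme`,
#'   `excluded_subject`, `n`.
#' @export
build_pbif <- function(normalized, exclude,
                       scheme = c("WEIGHT_DOSE", "AUC", "WEIGHT_AUC")) {
  scheme <- match.arg(scheme)
  if (!exclude %in% names(normalized)) {
    abort(sprintf("excluded subject '%s' not in cohort", exclude))
  }
  keep <- normalized[setdiff(names(normalized), exclude)]
  if (length(keep) < 2L) abort("need at least 2 contributing subjects")
  len <- lengths(keep)
  if (length(unique(len)) != 1L || len[1] != length(.grid_s())) {
    abort("contributing curves are not on the shared 1-s grid")
  }
  m <- do.call(cbind, keep)
  structure(list(
    mean = rowMeans(m),
    sd = apply(m, 1, sd),
    scheme = scheme,
    excluded_subject = exclude,
    n = length(keep)
  ), class = "pbif_model")
}

#' @export
print.pbif_model <- function(x, ...) {
  cat(sprintf("<pbif_model [%s]> n = %d contributors, excluding %s\n",
              x$scheme, x$n, x$excluded_subject))
  invisible(x)
}

#' Rescale a weight-dose PBIF into an individual input function
#'
#' @param pbif A `pbif_model` with scheme `WEIGHT_DOSE`.
#' @param weight_kg,dose_MBq The target subject's weight and injected dose.
#' @return An `input_function` with provenance `PBIF_scaled`.
#' @export
rescale_weight_dose <- function(pbif, weight_kg, dose_MBq) {
  stopifnot(inherits(pbif, "pbif_model"))
  if (pbif$scheme != "WEIGHT_DOSE") {
    abort("`rescale_weight_dose()` requires a WEIGHT_DOSE-normalized PBIF")
  }
  new_input_function(pbif$mean * weight_kg * dose_MBq,
                     provenance = "PBIF_scaled")
}

#' Scale a PBIF to an individual using late blood samples
#'
#' Computes the scale factor as the ratio of the mean late-sample activity to
#' the mean PBIF value at the same time points, then multiplies the PBIF mean
#' curve by it. For the `WEIGHT_AUC` scheme the subject's weight multiplies
#' back first and the tail factor supplies the AUC component.
#'
#' @param pbif A `pbif_model` with scheme `AUC` or `WEIGHT_AUC`.
#' @param late_samples Tibble with `time_min`, `value`: late blood activities
#'   (metabolite-corrected), all within `window`.
#' @param window Tail window in minutes, default 60-90 min.
#' @param weight_kg Subject weight; required for `WEIGHT_AUC`.
#' @return List with `input_function` (provenance `PBIF_scaled`) and `factor`.
#' @export
tail_scale <- function(pbif, late_samples, window = c(60, 90),
                       weight_kg = NULL) {
  stopifnot(inherits(pbif, "pbif_model"))
  if (!pbif$scheme %in% c("AUC", "WEIGHT_AUC")) {
    abort("`tail_scale()` applies to AUC or WEIGHT_AUC PBIFs")
  }
  late_samples <- tibble::as_tibble(late_samples)
  if (nrow(late_samples) == 0) abort("no late samples in the tail window")
  if (any(late_samples$time_min < window[1] - 1e-9 |
          late_samples$time_min > window[2] + 1e-9)) {
    abort("late samples must lie within the tail window")
  }
  base <- pbif$mean
  if (pbif$scheme == "WEIGHT_AUC") {
    if (is.null(weight_kg)) abort("`weight_kg` required for WEIGHT_AUC")
    base <- base * weight_kg
  }
  ref <- approx(.grid_min(), base, xout = late_samples$time_min)$y
  if (mean(ref) <= 0) abort("PBIF tail is zero over the window")
  factor <- mean(late_samples$value) / mean(ref)
  list(input_function = new_input_function(base * factor,
                                           provenance = "PBIF_scaled"),
       factor = factor)
}

#' Percent AUC error of a scaled PBIF relative to the PSAIF
#'
#' @param scaled,psaif `input_function`s on the same grid.
#' @return `|AUC(scaled) - AUC(psaif)| / AUC(psaif) * 100`.
#' @export
auc_percent_error <- function(scaled, psaif) {
  a_ref <- auc(psaif, 0, 90)
  if (a_ref == 0) abort("reference PSAIF has zero AUC")
  abs(auc(scaled, 0, 90) - a_ref) / a_ref * 100
}

#' Evaluate candidate tail-scaling time points
#'
#' Scales the PBIF by a single late blood sample taken at each candidate time
#' and reports the percent AUC error against the subject's PSAIF. The
#' candidates 37.5, 52.5 and 75 min are pseudo-time points: the sample value
#' is the arithmetic mean of the PSAIF samples bracketing them (30/45, 45/60,
#' 60/90 min), and the PBIF reference value at a pseudo-time is the mean of
#' the PBIF values at the same bracketing times.
#'
#' @param pbif A `pbif_model` (`AUC` or `WEIGHT_AUC`).
#' @param psaif The subject's `input_function`.
#' @param samples Tibble with `time_min`, `value` holding the subject's
#'   late samples at 30, 45, 60 and 90 min (PSAIF-derived,
#'   metabolite-corrected).
#' @param weight_kg Subject weight for `WEIGHT_AUC`.
#' @return Tibble with one row per candidate time (`time_min`,
#'   `pseudo`, `scale_factor`, `auc_pct_error`).
#' @export
evaluate_tail_timepoints <- function(pbif, psaif, samples, weight_kg = NULL) {
  stopifnot(inherits(pbif, "pbif_model"), inherits(psaif, "input_function"))
  samples <- tibble::as_tibble(samples)
  need <- c(30, 45, 60, 90)
  if (!all(need %in% samples$time_min)) {
    abort("samples at 30, 45, 60 and 90 min are required")
  }
  s_at <- function(t) samples$value[match(t, samples$time_min)]
  base <- pbif$mean
  if (pbif$scheme == "WEIGHT_AUC") {
    if (is.null(weight_kg)) abort("`weight_kg` required for WEIGHT_AUC")
    base <- base * weight_kg
  }
  p_at <- function(t) approx(.grid_min(), base, xout = t)$y
  brackets <- list(`37.5` = c(30, 45), `52.5` = c(45, 60), `75` = c(60, 90))
  candidates <- c(30, 37.5, 45, 52.5, 60, 75, 90)
  rows <- lapply(candidates, function(tc) {
    key <- as.character(tc)
    if (key %in% names(brackets)) {
      br <- brackets[[key]]
      sample_v <- mean(s_at(br))
      ref_v <- mean(p_at(br))
      pseudo <- TRUE
    } else {
      sample_v <- s_at(tc)
      ref_v <- p_at(tc)
      pseudo <- FALSE
    }
    factor <- sample_v / ref_v
    scaled <- new_input_function(base * factor, provenance = "PBIF_scaled")
    tibble::tibble(time_min = tc, pseudo = pseudo, scale_factor = factor,
                   auc_pct_error = auc_percent_error(scaled, psaif))
  })
  dplyr::bind_rows(rows)
}
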