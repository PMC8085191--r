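#' Symmetric percent relative difference (test-retest)
#'
#' `D = (retest - test) / ((retest + test) / 2) * 100`: the difference as a
#' percentage of the pair mean, antisymmetric in its arguments.
#'
#' @param test,retest Paired positive estimates; vectorized.
#' @return Signed percent difference.
#' @export
rel_diff_symmetric <- function(test, retest) {
  m <- (test + retest) / 2
  if (any(m <= 0)) abort("pair mean must be > 0")
  (retest - test) / m * 100
}

#' Reference-anchored percent relative difference (PBIF vs PSAIF)
#'
#' `D = (pbif - psaif) / psaif * 100`, referenced to the patient-specific
#' (gold standard) value. Unlike the symmetric form this is not antisymmetric:
#' swapping the arguments gives `-D / (1 + D/100)`.
#'
#' @param psaif Reference estimates (> 0); vectorized.
#' @param pbif Estimates under evaluation.
#' @return Signed percent difference.
#' @export
rel_diff_reference <- function(psaif, pbif) {
  if (any(psaif <= 0)) abort("reference values must be > 0")
  (pbif - psaif) / psaif * 100
}

#' Bland-Altman limits from a bias and SD
#'
#' @param bias Mean bias.
#' @param sd SD of the paired differences.
#' @param factor Coverage factor (1.96 for 95% limits; some tabulations use
#'   2.0).
#' @return Named vector `c(lower, upper)`.
#' @export
loa_limits <- function(bias, sd, factor = 1.96) {
  c(lower = bias - factor * sd, upper = bias + factor * sd)
}

#' Bland-Altman summary of paired percent differences
#'
#' @param diffs Vector of percent differences (length >= 2).
#' @param factor Limits-of-agreement coverage factor (default 1.96).
#' @return A one-row tibble (`n`, `mean_bias`, `sd`, `loa_low`, `loa_high`).
#'   SD is the sample (n-1) standard deviation.
#' @export
bland_altman <- function(diffs, factor = 1.96) {
  if (length(diffs) < 2L) abort("need at least 2 paired differences")
  bias <- mean(diffs)
  s <- sd(diffs)
  lim <- loa_limits(bias, s, factor)
  tibble::tibble(n = length(diffs), mean_bias = bias, sd = s,
                 loa_low = lim[["lower"]], loa_high = lim[["upper"]])
}

#' Coefficient of repeatability
#'
#' Default form `CR = 1.96 * sqrt(var(D) / (N - 1))`, the threshold below
#' which a repeat difference is expected with 95% probability, dividing the
#' variance of the differences by `N - 1` (a standard-error-like quantity).
#' `form = "conventional"` gives the textbook `1.96 * SD(D)`.
#'
#' @param diffs Vector of percent differences (length >= 2).
#' @param form `"se_like"` (default) or `"conventional"`.
#' @return CR (same units as `diffs`).
#' @export
coefficient_repeatability <- function(diffs, form = c("se_like",
                                                      "conventional")) {
  form <- match.arg(form)
  n <- length(diffs)
  if (n < 2L) abort("need at least 2 differences")
  switch(form,
         se_like = 1.96 * sqrt(var(diffs) / (n - 1)),
         conventional = 1.96 * sd(diffs))
}

#' Intraclass correlation coefficient for paired measurements
#'
#' Default is the two-way mixed, single-measure, consistency form ICC(3,1)
#' computed from the mean squares of a two-way (subject x measurement) layout;
#' `form = "agreement"` gives the absolute-agreement ICC(2,1).
#'
#' @param first,second Paired measurement vectors (length >= 3).
#' @param form `"consistency"` (default) or `"agreement"`.
#' @return ICC in `[-1, 1]`.
#' @export
icc <- function(first, second, form = c("consistency", "agreement")) {
  form <- match.arg(form)
  if (length(first) != length(second)) abort("series lengths differ")
  n <- length(first)
  if (n < 3L) abort("need at least 3 pairs")
  k <- 2
  y <- c(first, second)
  if (var(y) == 0) abort("zero total variance")
  subj <- factor(rep(seq_len(n), k))
  meas <- factor(rep(seq_len(k), each = n))
  grand <- mean(y)
  msr <- k * var(tapply(y, subj, mean))              # between subjects
  msc <- n * var(tapply(y, meas, mean))              # between measurements
  sst <- sum((y - grand)^2)
  sse <- sst - msr * (n - 1) - msc * (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  switch(form,
    consistency = (msr - mse) / (msr + (k - 1) * mse),
    agreement = (msr - mse) /
      (msr + (k - 1) * mse + k * (msc - mse) / n))
}

#' Compare normalization schemes with ANOVA, pairwise t-tests and normality
#'
#' One-way ANOVA across the per-scheme difference vectors, followed by all
#' pairwise paired t-tests with Bonferroni correction (`p` multiplied by the
#' number of comparisons, capped at 1) and a Shapiro-Wilk normality test per
#' scheme.
#'
#' @param diffs Named list of numeric vectors, one per scheme. For the paired
#'   t-tests all vectors must have equal length (same subject-region cases
#'   under each scheme).
#' @return List with `anova` (one-row tibble `F`, `p`), `pairwise` (tibble
#'   `scheme_a`, `scheme_b`, `p_raw`, `p_bonferroni`), `shapiro` (tibble
#'   `scheme`, `p`).
#' @export
compare_schemes <- function(diffs) {
  if (length(diffs) < 2L) abort("need at least 2 schemes")
  if (any(lengths(diffs) < 3L)) abort("each scheme needs at least 3 values")
  values <- unlist(diffs, use.names = FALSE)
  scheme <- factor(rep(names(diffs), lengths(diffs)))
  if (all(vapply(diffs, var, numeric(1)) == 0) &&
      var(vapply(diffs, mean, numeric(1))) == 0) {
    aov_row <- tibble::tibble(F = 0, p = 1)
  } else {
    fit <- aov(values ~ scheme)
    tab <- anova(fit)
    aov_row <- tibble::tibble(F = tab$`F value`[1], p = tab$`Pr(>F)`[1])
  }
  combos <- utils::combn(names(diffs), 2, simplify = FALSE)
  m <- length(combos)
  pairwise <- dplyr::bind_rows(lapply(combos, function(cb) {
    a <- diffs[[cb[1]]]
    b <- diffs[[cb[2]]]
    p <- if (length(a) == length(b) && sd(a - b) > 0) {
      t.test(a, b, paired = TRUE)$p.value
    } else if (length(a) == length(b)) {
      1
    } else {
      t.test(a, b)$p.value
    }
    tibble::tibble(scheme_a = cb[1], scheme_b = cb[2], p_raw = p,
                   p_bonferroni = min(1, m * p))
  }))
  shapiro <- dplyr::bind_rows(lapply(names(diffs), function(s) {
    p <- if (sd(diffs[[s]]) > 0) shapiro.test(diffs[[s]])$p.value else NA_real_
    tibble::tibble(scheme = s, p = p)
  }))
  list(anova = aov_row, pairwise = pairwise, shapiro = shapiro)
}

#' Normalize regional VT by a gray-matter composite
#'
#' Divides each regional VT by the (volume-weighted) mean VT of the
#' designated gray-matter regions within the same subject-session, removing
#' session-level multiplicative factors.
#'
#' @param vt_table Tibble with `subject_id`, `session`, `region`, `VT`.
#' @param gm_regions Character vector of gray-matter regions; defaults to all
#'   regions except white matter.
#' @param volumes Optional named numeric vector of region volumes used as
#'   weights; equal weights if omitted.
#' @return `vt_table` with an added `VT_gm_norm` column.
#' @export
gm_normalize <- function(vt_table,
                         gm_regions = setdiff(unique(vt_table$region),
                                              "white matter"),
                         volumes = NULL) {
  vt_table <- tibble::as_tibble(vt_table)
  missing_gm <- setdiff(gm_regions, unique(vt_table$region))
  if (length(missing_gm) > 0) {
    abort(paste("gray-matter regions absent from table:",
                paste(missing_gm, collapse = ", ")))
  }
  w <- if (is.null(volumes)) setNames(rep(1, length(gm_regions)), gm_regions)
       else volumes[gm_regions]
  composite <- vt_table |>
    dplyr::filter(.data$region %in% gm_regions) |>
    dplyr::group_by(.data$subject_id, .data$session) |>
    dplyr::summarise(
      gm_VT = sum(.data$VT * w[.data$region]) / sum(w[.data$region]),
      .groups = "drop")
  if (any(composite$gm_VT <= 0)) abort("gray-matter composite VT must be > 0")
  vt_table |>
    dplyr::left_join(composite, by = c("subject_id", "session")) |>
    dplyr::mutate(VT_gm_norm = .data$VT / .data$gm_VT) |>
    dplyr::select(-"gm_VT")
}
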