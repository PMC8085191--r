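# builds a tiny cohort of aligned PSAIF curves with controllable spread
toy_psaifs <- function(scales = c(1, 1.2, 0.9)) {
  base <- resample_and_align(function(t) true_aif(ref_triexp(), t) *
                               parent_fraction(ref_pf(), t))
  out <- lapply(scales, function(s) new_input_function(s * base$activity))
  names(out) <- sprintf("S%02d", seq_along(scales))
  out
}

test_that("normalization schemes divide by the documented factors", {
  ps <- toy_psaifs()[[1]]
  nd <- normalize_psaif(ps, weight_kg = 70, dose_MBq = 500,
                        scheme = "WEIGHT_DOSE")
  expect_equal(nd, ps$activity / (70 * 500))
  expect_equal(nd[ps$time_s == 30], max(ps$activity) / 35000)
  na <- normalize_psaif(ps, 70, 500, scheme = "AUC")
  expect_equal(pracma::trapz((0:5400) / 60, na), 1, tolerance = 1e-12)
  nwa <- normalize_psaif(ps, 70, 500, scheme = "WEIGHT_AUC")
  expect_equal(nwa, na / 70)
  # identical curves, different weights: normalized curves scale as 1/weight
  nwa2 <- normalize_psaif(ps, 140, 500, scheme = "WEIGHT_AUC")
  expect_equal(nwa2, nwa / 2)
  expect_error(normalize_psaif(ps, 0, 500, scheme = "WEIGHT_DOSE"), "> 0")
})

test_that("leave-one-out PBIF averages the remaining normalized curves", {
  curves <- toy_psaifs(c(1, 1, 1))
  vals <- lapply(curves, function(x) x$activity)
  m <- build_pbif(vals, exclude = "S01", scheme = "AUC")
  expect_equal(m$n, 2)
  expect_equal(m$mean, vals$S02)
  expect_equal(m$sd, rep(0, 5401))
  # {f, 3f}: mean 2f, sample SD sqrt(2) f
  f <- vals$S01
  m2 <- build_pbif(list(a = f, b = 3 * f, c = f), exclude = "c",
                   scheme = "AUC")
  expect_equal(m2$mean, 2 * f)
  expect_equal(m2$sd, sqrt(2) * f)
  expect_error(build_pbif(vals, exclude = "nope"), "not in cohort")
  expect_error(build_pbif(vals[1:2], exclude = "S01"), "at least 2")
  expect_error(build_pbif(list(a = f, b = f[-1], c = f), exclude = "a"),
               "shared 1-s grid")
})

test_that("an 18-subject cohort leaves 17 contributors per PBIF", {
  vals <- lapply(toy_psaifs(seq(0.8, 1.2, length.out = 18)),
                 function(x) x$activity)
  m <- build_pbif(vals, exclude = "S07", scheme = "WEIGHT_DOSE")
  expect_equal(m$n, 17)
})

test_that("the mean of all leave-one-out PBIFs equals the all-cohort mean", {
  vals <- lapply(toy_psaifs(c(0.7, 1, 1.4, 2)), function(x) x$activity)
  loo_means <- sapply(names(vals), function(id) {
    build_pbif(vals, exclude = id, scheme = "AUC")$mean
  })
  overall <- rowMeans(do.call(cbind, vals))
  expect_equal(rowMeans(loo_means), overall, tolerance = 1e-12)
})

test_that("weight-dose rescaling recovers the excluded subject under zero variability", {
  curves <- toy_psaifs(c(1, 1, 1))
  w <- 70; d <- 500
  vals <- lapply(curves, function(x) normalize_psaif(x, w, d, "WEIGHT_DOSE"))
  m <- build_pbif(vals, exclude = "S03", scheme = "WEIGHT_DOSE")
  indiv <- rescale_weight_dose(m, w, d)
  expect_equal(indiv$activity, curves$S03$activity, tolerance = 1e-9)
  expect_identical(indiv$provenance, "PBIF_scaled")
  # bilinearity in weight and dose
  indiv2 <- rescale_weight_dose(m, 2 * w, 2 * d)
  expect_equal(indiv2$activity, 4 * indiv$activity)
  m_auc <- build_pbif(lapply(curves, function(x)
    normalize_psaif(x, w, d, "AUC")), exclude = "S03", scheme = "AUC")
  expect_error(rescale_weight_dose(m_auc, w, d), "WEIGHT_DOSE")
})

test_that("weight-dose rescaling is invariant to compensating weight/dose rescaling", {
  curves <- toy_psaifs(c(0.8, 1, 1.3))
  w <- c(60, 75, 90); d <- c(450, 520, 600)
  build_indiv <- function(cc) {
    vals <- Map(function(x, wi, di) normalize_psaif(x, wi * cc, di / cc,
                                                    "WEIGHT_DOSE"),
                curves, w, d)
    names(vals) <- names(curves)
    m <- build_pbif(vals, exclude = "S02", scheme = "WEIGHT_DOSE")
    rescale_weight_dose(m, w[2] * cc, d[2] / cc)$activity
  }
  expect_equal(build_indiv(1), build_indiv(2.7), tolerance = 1e-12)
})

test_that("tail scaling ratios and errors follow their definitions", {
  curves <- toy_psaifs(c(1, 1, 1))
  vals <- lapply(curves, function(x) normalize_psaif(x, 70, 500, "AUC"))
  m <- build_pbif(vals, exclude = "S01", scheme = "AUC")
  tail_t <- c(60, 90)
  pb_at <- approx((0:5400) / 60, m$mean, xout = tail_t)$y
  # samples exactly twice the tail: factor 2
  twice <- tibble::tibble(time_min = tail_t, value = 2 * pb_at)
  ts <- tail_scale(m, twice)
  expect_equal(ts$factor, 2, tolerance = 1e-12)
  # samples equal to the tail: identity
  same <- tibble::tibble(time_min = tail_t, value = pb_at)
  expect_equal(tail_scale(m, same)$factor, 1, tolerance = 1e-12)
  expect_equal(tail_scale(m, same)$input_function$activity, m$mean,
               tolerance = 1e-12)
  expect_error(tail_scale(m, twice[0, ]), "no late samples")
  expect_error(tail_scale(m, tibble::tibble(time_min = 30, value = 1)),
               "within the tail window")
})

test_that("a shape-identical subject is recovered exactly by tail scaling", {
  # subject S03 is c times the population shape: scaled PBIF must reproduce
  # its PSAIF and give 0% AUC error
  curves <- toy_psaifs(c(1, 1, 2.5))
  vals <- lapply(curves, function(x) normalize_psaif(x, 70, 500, "AUC"))
  m <- build_pbif(vals, exclude = "S03", scheme = "AUC")
  tail_t <- c(60, 90)
  late <- tibble::tibble(time_min = tail_t,
                         value = if_at(curves$S03, tail_t))
  scaled <- tail_scale(m, late)$input_function
  expect_lt(auc_percent_error(scaled, curves$S03), 1e-6)
})

test_that("AUC percent error is the advertised ratio", {
  ps <- toy_psaifs()[[1]]
  expect_equal(auc_percent_error(ps, ps), 0)
  scaled <- new_input_function(1.01 * ps$activity)
  expect_equal(auc_percent_error(scaled, ps), 1, tolerance = 1e-9)
  # linear in the scale mismatch
  for (cc in c(0.8, 1.3)) {
    expect_equal(auc_percent_error(new_input_function(cc * ps$activity), ps),
                 abs(cc - 1) * 100, tolerance = 1e-9)
  }
})

test_that("tail-timepoint evaluation uses bracketing means and 7 candidates", {
  curves <- toy_psaifs(c(1, 1, 1.8))
  vals <- lapply(curves, function(x) normalize_psaif(x, 70, 500, "AUC"))
  m <- build_pbif(vals, exclude = "S03", scheme = "AUC")
  samp_t <- c(30, 45, 60, 90)
  samples <- tibble::tibble(time_min = samp_t,
                            value = if_at(curves$S03, samp_t))
  tbl <- evaluate_tail_timepoints(m, curves$S03, samples)
  expect_equal(nrow(tbl), 7)
  expect_equal(tbl$time_min, c(30, 37.5, 45, 52.5, 60, 75, 90))
  expect_equal(tbl$pseudo, c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  # shape-identical subject: every candidate scales exactly
  expect_true(all(tbl$auc_pct_error < 1e-6))
  # the 75-min pseudo-sample is the mean of the 60- and 90-min samples
  pb_at <- function(t) approx((0:5400) / 60, m$mean, xout = t)$y
  expect_equal(tbl$scale_factor[tbl$time_min == 75],
               mean(samples$value[samples$time_min %in% c(60, 90)]) /
                 mean(pb_at(c(60, 90))))
  expect_error(evaluate_tail_timepoints(m, curves$S03, samples[-1, ]),
               "required")
})
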