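# Region-level kinetic templates for a high-affinity-binder healthy adult.
# K1 reflects perfusion (lower in white matter); VT targets sit in the 3-5
# mL/cm^3 range typical of second-generation TSPO tracers; k3/k4 fixed so VT
# differences are carried by K1/k2.
.region_templates <- function() {
  tibble::tibble(
    region = c("white matter", "cerebellum", "thalamus", "caudate", "putamen",
               "pallidum", "brainstem", "hippocampus", "amygdala"),
    K1 = c(0.08, 0.16, 0.15, 0.13, 0.14, 0.12, 0.12, 0.13, 0.12),
    vt = c(3.7, 3.6, 4.5, 3.2, 3.8, 4.1, 4.9, 4.1, 4.0)
  )
}

#' Cohort configuration for the synthetic-study generator
#'
#' Defaults mirror the study design the package emulates: 18 subjects (12
#' Parkinson disease, 6 healthy volunteers), 5 healthy volunteers with a
#' same-day test-retest pair, a ~527 MBq injected dose, automated arterial
#' sampling every 15 s for 10 min plus manual samples at 20/30/45/60/90 min,
#' parent fractions at 5/10/20/30/45/60/90 min, and a 40% mixed-affinity
#' (MAB vs HAB) reduction in VT.
#'
#' @param n_subjects Cohort size.
#' @param fraction_pd Fraction of subjects in the PD group.
#' @param fraction_hab Fraction of high-affinity binders.
#' @param n_test_retest Number of healthy volunteers scanned twice.
#' @param weight_mean,weight_cv Body weight distribution (kg).
#' @param dose_mean,dose_cv Injected dose distribution (MBq), redrawn per
#'   session.
#' @param t_peak_mean,t_peak_sd Input-function peak time (min).
#' @param aif_amp_cv Lognormal CV of a common input-function amplitude factor
#'   (on top of dose/weight scaling).
#' @param aif_rate_cv Lognormal CV of each exponential decay rate.
#' @param pf_cv Lognormal CV of the parent-fraction half-time.
#' @param vt_cv Between-subject lognormal CV of the VT level (applied to K1,
#'   shared across regions).
#' @param session_cv Session-to-session (test-retest) lognormal CV of the VT
#'   level.
#' @param genotype_vt_ratio Multiplicative VT factor for MAB vs HAB (default
#'   0.60, a 40% reduction).
#' @param pd_vt_ratio Multiplicative VT factor for PD vs HV (default 1.15).
#' @param noise_scale Measurement noise scale; additive Gaussian with
#'   SD = `noise_scale * sqrt(C / duration_min)` on activities, and
#'   SD = `0.4 * noise_scale` on measured parent fractions.
#' @param seed Mandatory RNG seed (integer).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 18L,
                          fraction_pd = 12 / 18,
                          fraction_hab = 0.5,
                          n_test_retest = 5L,
                          weight_mean = 75, weight_cv = 0.15,
                          dose_mean = 526.4, dose_cv = 73.6 / 526.4,
                          t_peak_mean = 0.5, t_peak_sd = 0.05,
                          aif_amp_cv = 0.15,
                          aif_rate_cv = 0.10,
                          pf_cv = 0.10,
                          vt_cv = 0.5,
                          session_cv = 0.10,
                          genotype_vt_ratio = 0.60,
                          pd_vt_ratio = 1.15,
                          noise_scale = 0.05,
                          seed = NULL) {
  if (is.null(seed)) abort("`seed` is mandatory: no implicit entropy")
  if (n_subjects <= 0) abort("`n_subjects` must be positive")
  fr <- c(fraction_pd, fraction_hab)
  if (any(fr < 0 | fr > 1)) abort("fractions must lie in [0, 1]")
  cvs <- c(weight_cv, dose_cv, aif_amp_cv, aif_rate_cv, pf_cv, vt_cv,
           session_cv, noise_scale)
  if (any(cvs < 0)) abort("CVs and noise scale must be >= 0")
  structure(as.list(environment()), class = "cohort_config")
}

# lognormal multiplicative factor with unit median; cv = 0 -> exactly 1
.lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(rnorm(n, mean = 0, sd = sqrt(log(1 + cv^2))))
}

#' Simulate one session's blood-sample table
#'
#' Total-blood activity is `parent / f` at each sample time (the measured
#' blood contains both parent and metabolites), plus zero-mean Gaussian noise
#' with SD `noise_scale * sqrt(C / duration)`. The parent-fraction column is
#' populated only at the metabolite assay times.
#'
#' @param parent Function `t_min -> kBq/mL`: true metabolite-corrected
#'   (parent) plasma curve.
#' @param f A [parent_fraction_params()] object (or function `t_min ->
#'   fraction`).
#' @param times_min,durations_min Sample times and draw durations (min).
#' @param noise_scale Noise scale (0 for noise-free).
#' @param pf_times_min Times at which the parent fraction is assayed.
#' @return Tibble (`time_min`, `activity_kBq_mL`, `duration_min`,
#'   `sample_type`, `parent_fraction`).
#' @export
measured_blood <- function(parent, f, times_min, durations_min,
                           noise_scale = 0,
                           pf_times_min = c(5, 10, 20, 30, 45, 60, 90)) {
  f_fn <- if (is.function(f)) f else function(t) parent_fraction(f, t)
  fv <- f_fn(times_min)
  if (any(fv <= 0)) abort("parent fraction is 0 at a sample time")
  total <- parent(times_min) / fv
  if (noise_scale > 0) {
    total <- total + rnorm(length(total),
                           sd = noise_scale * sqrt(pmax(total, 0) /
                                                     durations_min))
    total <- pmax(total, 0)
  }
  pf <- rep(NA_real_, length(times_min))
  at_assay <- times_min %in% pf_times_min
  pf[at_assay] <- f_fn(times_min[at_assay])
  if (noise_scale > 0) {
    pf[at_assay] <- pmin(pmax(pf[at_assay] +
                                rnorm(sum(at_assay),
                                      sd = 0.4 * noise_scale), 1e-3), 1)
  }
  tibble::tibble(
    time_min = times_min,
    activity_kBq_mL = total,
    duration_min = durations_min,
    sample_type = ifelse(times_min <= 10, "auto", "manual"),
    parent_fraction = pf
  )
}

#' Generate a synthetic cohort with full ground truth
#'
#' Draws a subject manifest, per-session arterial blood tables (automated
#' 15-s sampling for 10 min plus manual samples at 20/30/45/60/90 min, parent
#' fractions at 5/10/20/30/45/60/90 min), 9 regional TACs on the 32-frame
#' schedule simulated from two-tissue-compartment kinetics, and ground-truth
#' tables (input-function and rate-constant parameters, true VT). The
#' tri-exponential parameters describe the total-blood curve; the true
#' metabolite-corrected input is that curve times the parent fraction, so the
#' processing chain is well-specified for noise-free data.
#'
#' @param config A [cohort_config()] object.
#' @return List of class `cohort` with tibbles `subjects`, `blood`, `tacs`,
#'   `truth`, `aif_truth`, plus `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, .generate_cohort_impl(config))
}

.generate_cohort_impl <- function(config) {
  n <- as.integer(config$n_subjects)
  n_pd <- round(config$fraction_pd * n)
  n_hab <- round(config$fraction_hab * n)
  ids <- sprintf("S%02d", seq_len(n))
  group <- c(rep("PD", n_pd), rep("HV", n - n_pd))
  # deterministic assignment: odd indices first, so both clinical groups get
  # a genotype mix and exactly n_hab subjects are HAB
  genotype <- rep("MAB", n)
  genotype[c(seq(1, n, by = 2), seq(2, n, by = 2))[seq_len(n_hab)]] <- "HAB"
  hv_idx <- which(group == "HV")
  retest_ids <- ids[hv_idx[seq_len(min(config$n_test_retest, length(hv_idx)))]]

  weight <- config$weight_mean * .lnorm_factor(n, config$weight_cv)
  vt_subject <- .lnorm_factor(n, config$vt_cv)

  subjects <- tibble::tibble(
    subject_id = ids, group = group, genotype = genotype,
    weight_kg = weight
  )
  sessions <- dplyr::bind_rows(
    tibble::tibble(subject_id = setdiff(ids, retest_ids), session = "single"),
    tidyr::expand_grid(subject_id = retest_ids,
                       session = c("test", "retest"))
  )
  sessions <- dplyr::arrange(sessions, match(.data$subject_id, ids),
                             match(.data$session,
                                   c("single", "test", "retest")))
  ns <- nrow(sessions)

  # per-session draws
  dose <- config$dose_mean * .lnorm_factor(ns, config$dose_cv)
  t_peak <- pmax(rnorm(ns, config$t_peak_mean, config$t_peak_sd), 0.2)
  amp_factor <- .lnorm_factor(ns, config$aif_amp_cv)
  rate_factor <- matrix(.lnorm_factor(3 * ns, config$aif_rate_cv), ncol = 3)
  pf_c <- 12 * .lnorm_factor(ns, config$pf_cv)
  session_factor <- .lnorm_factor(ns, config$session_cv)

  base_amp <- c(60, 8, 1.5)
  base_rate <- c(4, 0.4, 0.015)
  templates <- .region_templates()
  k3 <- 0.05
  k4 <- 0.05

  auto_t <- seq(0.25, 10, by = 0.25)
  manual_t <- c(20, 30, 45, 60, 90)
  times <- c(auto_t, manual_t)
  durations <- c(rep(0.25, length(auto_t)), rep(0.5, length(manual_t)))
  schedule <- frame_schedule()

  blood <- vector("list", ns)
  tacs <- vector("list", ns)
  truth <- vector("list", ns)
  aif_truth <- vector("list", ns)
  grid_min <- .grid_min()

  for (i in seq_len(ns)) {
    sid <- sessions$subject_id[i]
    j <- match(sid, ids)
    scale <- (dose[i] / config$dose_mean) / (weight[j] / config$weight_mean)
    amps <- base_amp * scale * amp_factor[i]
    rates <- sort(base_rate * rate_factor[i, ], decreasing = TRUE)
    tri <- triexp_params(t_peak = t_peak[i], amplitudes = amps, rates = rates)
    pf <- parent_fraction_params(a = 0.05, b = 1.5, c = pf_c[i])
    parent_fn <- function(t) true_aif(tri, t) * parent_fraction(pf, t)

    blood[[i]] <- dplyr::mutate(
      measured_blood(parent_fn, pf, times, durations, config$noise_scale),
      subject_id = sid, session = sessions$session[i], .before = 1)

    cp <- new_input_function(parent_fn(grid_min), provenance = "true")
    wb <- new_input_function(true_aif(tri, grid_min),
                             provenance = "whole_blood")
    g_fac <- if (genotype[j] == "MAB") config$genotype_vt_ratio else 1
    p_fac <- if (group[j] == "PD") config$pd_vt_ratio else 1
    k1_fac <- g_fac * p_fac * vt_subject[j] * session_factor[i]

    reg_list <- vector("list", nrow(templates))
    tru_list <- vector("list", nrow(templates))
    for (r in seq_len(nrow(templates))) {
      K1 <- templates$K1[r] * k1_fac
      k2 <- templates$K1[r] * (1 + k3 / k4) / templates$vt[r]
      pars <- twotc_params(K1, k2, k3, k4, vB = 0.05)
      tac <- simulate_2tc(cp, pars, schedule, whole_blood = wb,
                          region = templates$region[r])
      if (config$noise_scale > 0) {
        dur_min <- (tac$end_s - tac$start_s) / 60
        tac$activity_kBq_mL <- pmax(
          tac$activity_kBq_mL +
            rnorm(nrow(tac), sd = config$noise_scale *
                    sqrt(pmax(tac$activity_kBq_mL, 0) / dur_min)), 0)
      }
      reg_list[[r]] <- tac
      tru_list[[r]] <- tibble::tibble(
        region = templates$region[r], K1 = K1, k2 = k2, k3 = k3, k4 = k4,
        vB = 0.05, true_VT = true_vt(pars))
    }
    tacs[[i]] <- dplyr::mutate(dplyr::bind_rows(reg_list),
                               subject_id = sid,
                               session = sessions$session[i], .before = 1)
    truth[[i]] <- dplyr::mutate(dplyr::bind_rows(tru_list),
                                subject_id = sid,
                                session = sessions$session[i], .before = 1)
    aif_truth[[i]] <- tibble::tibble(
      subject_id = sid, session = sessions$session[i],
      t_peak = t_peak[i],
      A1 = amps[1], A2 = amps[2], A3 = amps[3],
      lambda1 = rates[1], lambda2 = rates[2], lambda3 = rates[3],
      pf_a = 0.05, pf_b = 1.5, pf_c = pf_c[i],
      dose_MBq = dose[i])
  }

  manifest <- dplyr::left_join(sessions, subjects, by = "subject_id")
  manifest$dose_MBq <- dose
  structure(list(
    subjects = manifest[, c("subject_id", "session", "group", "genotype",
                            "weight_kg", "dose_MBq")],
    blood = dplyr::bind_rows(blood),
    tacs = dplyr::bind_rows(tacs),
    truth = dplyr::bind_rows(truth),
    aif_truth = dplyr::bind_rows(aif_truth),
    config = config
  ), class = "cohort")
}

#' Write a cohort bundle to CSV files
#'
#' Writes `subjects.csv`, `blood.csv`, `tacs.csv`, `truth.csv` (UTF-8, header
#' row, times in the units named by each column).
#'
#' @param cohort A `cohort` from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$subjects, file.path(dir, "subjects.csv"),
            row.names = FALSE)
  blood <- cohort$blood[, c("subject_id", "session", "time_min",
                            "activity_kBq_mL", "sample_type",
                            "parent_fraction")]
  write.csv(blood, file.path(dir, "blood.csv"), row.names = FALSE)
  tacs <- cohort$tacs[, c("subject_id", "session", "region", "start_s",
                          "end_s", "activity_kBq_mL")]
  names(tacs)[4:5] <- c("frame_start_s", "frame_end_s")
  write.csv(tacs, file.path(dir, "tacs.csv"), row.names = FALSE)
  write.csv(cohort$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}
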