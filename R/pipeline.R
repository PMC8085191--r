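.session_key <- function(subject_id, session) paste(subject_id, session,
                                                    sep = "|")

#' Run the full study replica
#'
#' Simulates a cohort, processes every session's blood table into a PSAIF,
#' builds leave-one-out PBIFs under the requested normalization schemes,
#' estimates Logan VT for every region through the PSAIF route and each
#' PBIF route, and computes the agreement statistics: test-retest
#' Bland-Altman (symmetric percent differences, CR, ICC), PBIF-vs-PSAIF
#' Bland-Altman (PSAIF-referenced differences) per scheme, ANOVA with
#' Bonferroni pairwise tests across schemes, group/genotype contrasts, and
#' the candidate tail-scaling time-point table.
#'
#' @param config A [cohort_config()] (the seed lives here).
#' @param schemes Normalization schemes to evaluate.
#' @param tail_window Tail-scaling window in minutes.
#' @param max_rel_error Logan t* criterion threshold.
#' @param vB Fractional blood volume used in the VT estimation.
#' @param loa_factor Bland-Altman coverage factor.
#' @param out_dir Optional directory; when given, all result tables, the
#'   PSAIF curves and a JSON run manifest are written there.
#' @param quiet Suppress stage messages.
#' @return A list with `cohort`, `psaifs`, `logan_results`, `test_retest`,
#'   `pbif_agreement`, `scheme_comparison`, `tail_timepoints`,
#'   `group_contrasts`, `settings`.
#' @export
run_full <- function(config,
                     schemes = c("WEIGHT_DOSE", "AUC", "WEIGHT_AUC"),
                     tail_window = c(60, 90),
                     max_rel_error = 0.10,
                     vB = 0.05,
                     loa_factor = 1.96,
                     out_dir = NULL,
                     quiet = TRUE) {
  stopifnot(inherits(config, "cohort_config"))
  schemes <- match.arg(schemes, several.ok = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("stage 1/5: simulating cohort (n = %d)", config$n_subjects)
  cohort <- generate_cohort(config)
  sess <- cohort$subjects

  say("stage 2/5: fitting patient-specific input functions")
  psaifs <- list()
  for (i in seq_len(nrow(sess))) {
    key <- .session_key(sess$subject_id[i], sess$session[i])
    b <- cohort$blood[cohort$blood$subject_id == sess$subject_id[i] &
                        cohort$blood$session == sess$session[i], ]
    psaifs[[key]] <- tryCatch(process_psaif(b), error = function(e) {
      abort(sprintf("[input_function] PSAIF processing failed for %s: %s",
                    key, conditionMessage(e)))
    })
  }

  say("stage 3/5: Logan VT, PSAIF route")
  regions <- unique(cohort$tacs$region)
  n_clipped <- 0L
  logan_one <- function(sid, session, cp, wb, source, scheme) {
    rows <- lapply(regions, function(rg) {
      tac <- cohort$tacs[cohort$tacs$subject_id == sid &
                           cohort$tacs$session == session &
                           cohort$tacs$region == rg, ]
      # early noisy frames routinely clip to zero in the vB correction;
      # tally rather than warn once per region
      fit <- withCallingHandlers(
        logan_vt(tac, cp, wb, vB = vB, max_rel_error = max_rel_error),
        warning = function(w) {
          if (grepl("clipped", conditionMessage(w))) {
            hits <- suppressWarnings(
              as.integer(sub("^(\\d+) .*", "\\1", conditionMessage(w))))
            n_clipped <<- n_clipped + max(hits, 1L, na.rm = TRUE)
            invokeRestart("muffleWarning")
          }
        })
      dplyr::mutate(fit, subject_id = sid, session = session, region = rg,
                    if_source = source, scheme = scheme, .before = 1)
    })
    dplyr::bind_rows(rows)
  }
  logan_psaif <- dplyr::bind_rows(lapply(seq_len(nrow(sess)), function(i) {
    key <- .session_key(sess$subject_id[i], sess$session[i])
    logan_one(sess$subject_id[i], sess$session[i], psaifs[[key]]$psaif,
              psaifs[[key]]$whole_blood, "PSAIF", NA_character_)
  }))

  say("stage 4/5: leave-one-out PBIFs and PBIF-route Logan VT")
  # PBIF is built from one session per subject: 'single' or 'test'
  base_sess <- sess[sess$session %in% c("single", "test"), ]
  base_keys <- .session_key(base_sess$subject_id, base_sess$session)
  normalized <- lapply(schemes, function(sc) {
    out <- lapply(seq_len(nrow(base_sess)), function(i) {
      normalize_psaif(psaifs[[base_keys[i]]]$psaif,
                      weight_kg = base_sess$weight_kg[i],
                      dose_MBq = base_sess$dose_MBq[i],
                      scheme = sc)
    })
    names(out) <- base_sess$subject_id
    out
  })
  names(normalized) <- schemes

  logan_pbif <- list()
  tail_tables <- list()
  for (sc in schemes) {
    for (i in seq_len(nrow(sess))) {
      sid <- sess$subject_id[i]
      session <- sess$session[i]
      key <- .session_key(sid, session)
      model <- build_pbif(normalized[[sc]], exclude = sid, scheme = sc)
      if (sc == "WEIGHT_DOSE") {
        indiv <- rescale_weight_dose(model, sess$weight_kg[i],
                                     sess$dose_MBq[i])
      } else {
        late_t <- c(tail_window[1], tail_window[2])
        late <- tibble::tibble(time_min = late_t,
                               value = if_at(psaifs[[key]]$psaif, late_t))
        indiv <- tail_scale(model, late, window = tail_window,
                            weight_kg = sess$weight_kg[i])$input_function
      }
      logan_pbif[[paste(sc, key)]] <-
        logan_one(sid, session, indiv, psaifs[[key]]$whole_blood, "PBIF", sc)
    }
  }
  logan_results <- dplyr::bind_rows(logan_psaif, dplyr::bind_rows(logan_pbif))

  # candidate tail-scaling time points are always evaluated on AUC-normalized
  # PBIFs, independent of which schemes were requested for VT estimation
  auc_norm <- lapply(seq_len(nrow(base_sess)), function(i) {
    normalize_psaif(psaifs[[base_keys[i]]]$psaif,
                    weight_kg = base_sess$weight_kg[i],
                    dose_MBq = base_sess$dose_MBq[i], scheme = "AUC")
  })
  names(auc_norm) <- base_sess$subject_id
  for (i in seq_len(nrow(base_sess))) {
    sid <- base_sess$subject_id[i]
    key <- base_keys[i]
    model <- build_pbif(auc_norm, exclude = sid, scheme = "AUC")
    samp_t <- c(30, 45, 60, 90)
    samp <- tibble::tibble(time_min = samp_t,
                           value = if_at(psaifs[[key]]$psaif, samp_t))
    tail_tables[[sid]] <- dplyr::mutate(
      evaluate_tail_timepoints(model, psaifs[[key]]$psaif, samp),
      subject_id = sid, .before = 1)
  }
  tail_timepoints <- dplyr::bind_rows(tail_tables) |>
    dplyr::group_by(.data$time_min, .data$pseudo) |>
    dplyr::summarise(mean_auc_pct_error = mean(.data$auc_pct_error),
                     sd_auc_pct_error = sd(.data$auc_pct_error),
                     .groups = "drop")

  say("stage 5/5: agreement statistics")
  psaif_vt <- logan_results[logan_results$if_source == "PSAIF", ]
  tr <- psaif_vt[psaif_vt$session %in% c("test", "retest"), ] |>
    tidyr::pivot_wider(id_cols = c("subject_id", "region"),
                       names_from = "session", values_from = "VT")
  test_retest <- if (nrow(tr) > 0) {
    stats_by_region <- tr |>
      dplyr::group_by(.data$region) |>
      dplyr::summarise(
        d = list(rel_diff_symmetric(.data$test, .data$retest)),
        icc = if (dplyr::n() >= 3) icc(.data$test, .data$retest) else
          NA_real_,
        .groups = "drop")
    dplyr::bind_cols(
      stats_by_region["region"],
      dplyr::bind_rows(lapply(stats_by_region$d, bland_altman,
                              factor = loa_factor)),
      cr = vapply(stats_by_region$d, coefficient_repeatability, numeric(1)),
      icc = stats_by_region$icc)
  } else {
    tibble::tibble()
  }

  base_vt <- logan_results[logan_results$session %in% c("single", "test"), ]
  paired <- base_vt |>
    dplyr::filter(.data$if_source == "PBIF") |>
    dplyr::inner_join(
      base_vt |>
        dplyr::filter(.data$if_source == "PSAIF") |>
        dplyr::select("subject_id", "region", psaif_VT = "VT"),
      by = c("subject_id", "region")) |>
    dplyr::mutate(diff_pct = rel_diff_reference(.data$psaif_VT, .data$VT))
  pbif_by <- paired |>
    dplyr::group_by(.data$scheme, .data$region) |>
    dplyr::summarise(d = list(.data$diff_pct), .groups = "drop")
  pbif_agreement <- dplyr::bind_cols(
    pbif_by[, c("scheme", "region")],
    dplyr::bind_rows(lapply(pbif_by$d, bland_altman, factor = loa_factor)))

  scheme_comparison <- if (length(schemes) >= 2) {
    dplyr::bind_rows(lapply(regions, function(rg) {
      dd <- lapply(schemes, function(sc) {
        paired$diff_pct[paired$scheme == sc & paired$region == rg]
      })
      names(dd) <- schemes
      cmp <- compare_schemes(dd)
      tibble::tibble(region = rg, F = cmp$anova$F, p = cmp$anova$p,
                     pairwise = list(cmp$pairwise),
                     shapiro = list(cmp$shapiro))
    }))
  } else {
    tibble::tibble()
  }

  contrasts <- psaif_vt[psaif_vt$session %in% c("single", "test"), ] |>
    dplyr::left_join(cohort$subjects[!duplicated(cohort$subjects$subject_id),
                                     c("subject_id", "group", "genotype")],
                     by = "subject_id")
  group_contrasts <- contrasts |>
    dplyr::group_by(.data$region, .data$group, .data$genotype) |>
    dplyr::summarise(mean_VT = mean(.data$VT), n = dplyr::n(),
                     .groups = "drop")

  settings <- list(schemes = schemes, tail_window = tail_window,
                   max_rel_error = max_rel_error, vB = vB,
                   loa_factor = loa_factor,
                   n_frames_clipped = n_clipped,
                   config = unclass(config))
  result <- list(cohort = cohort, psaifs = psaifs,
                 logan_results = logan_results,
                 test_retest = test_retest,
                 pbif_agreement = pbif_agreement,
                 scheme_comparison = scheme_comparison,
                 tail_timepoints = tail_timepoints,
                 group_contrasts = group_contrasts,
                 settings = settings)
  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

#' Write run outputs to a directory
#'
#' @param result A list returned by [run_full()].
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(result$cohort, out_dir)
  psaif_tbl <- dplyr::bind_rows(lapply(names(result$psaifs), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    tibble::tibble(subject_id = parts[1], session = parts[2],
                   time_s = result$psaifs[[k]]$psaif$time_s,
                   activity_kBq_mL = result$psaifs[[k]]$psaif$activity)
  }))
  write.csv(psaif_tbl, file.path(out_dir, "psaif.csv"), row.names = FALSE)
  write.csv(result$logan_results, file.path(out_dir, "logan_results.csv"),
            row.names = FALSE)
  write.csv(result$test_retest,
            file.path(out_dir, "agreement_test_retest.csv"),
            row.names = FALSE)
  write.csv(result$pbif_agreement,
            file.path(out_dir, "agreement_pbif_vs_psaif.csv"),
            row.names = FALSE)
  if (nrow(result$scheme_comparison) > 0) {
    flat <- result$scheme_comparison |>
      dplyr::select("region", "F", "p") |>
      dplyr::left_join(
        result$scheme_comparison |>
          dplyr::select("region", "pairwise") |>
          tidyr::unnest("pairwise"),
        by = "region")
    write.csv(flat, file.path(out_dir, "scheme_comparison.csv"),
              row.names = FALSE)
  }
  write.csv(result$tail_timepoints, file.path(out_dir, "tail_timepoints.csv"),
            row.names = FALSE)
  write.csv(result$group_contrasts, file.path(out_dir, "group_contrasts.csv"),
            row.names = FALSE)
  jsonlite::write_json(result$settings, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Validate a cohort data bundle
#'
#' Schema and invariant checks for the CSV bundle written by [write_cohort()]
#' (or in-memory tables): required columns, positive weights and doses,
#' unique subject-session pairs, strictly increasing blood sample times,
#' fractions in range, contiguous non-overlapping TAC frames. Report-only:
#' never throws on bad data.
#'
#' @param x Either a directory containing `subjects.csv`, `blood.csv`,
#'   `tacs.csv`, or a list with tibbles `subjects`, `blood`, `tacs`.
#' @return A tibble (`table`, `check`, `detail`); zero rows when clean.
#' @export
validate_inputs <- function(x) {
  if (is.character(x)) {
    rd <- function(f) {
      p <- file.path(x, f)
      if (file.exists(p)) tibble::as_tibble(read.csv(p)) else NULL
    }
    x <- list(subjects = rd("subjects.csv"), blood = rd("blood.csv"),
              tacs = rd("tacs.csv"))
  }
  issues <- list()
  flag <- function(table, check, detail) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      table = table, check = check, detail = detail)
  }
  s <- x$subjects
  if (is.null(s)) {
    flag("subjects", "missing", "subjects table absent")
  } else {
    need <- c("subject_id", "session", "group", "genotype", "weight_kg",
              "dose_MBq")
    miss <- setdiff(need, names(s))
    if (length(miss)) flag("subjects", "columns",
                           paste("missing:", paste(miss, collapse = ", ")))
    if (all(c("weight_kg", "dose_MBq") %in% names(s))) {
      bad <- which(s$weight_kg <= 0 | s$dose_MBq <= 0)
      if (length(bad)) flag("subjects", "positivity",
                            paste("non-positive weight/dose rows:",
                                  paste(bad, collapse = ", ")))
    }
    if (all(c("subject_id", "session") %in% names(s))) {
      dup <- duplicated(s[, c("subject_id", "session")])
      if (any(dup)) flag("subjects", "uniqueness",
                         paste("duplicate subject-session rows:",
                               paste(which(dup), collapse = ", ")))
    }
  }
  b <- x$blood
  if (is.null(b)) {
    flag("blood", "missing", "blood table absent")
  } else {
    for (key in unique(.session_key(b$subject_id, b$session))) {
      parts <- strsplit(key, "|", fixed = TRUE)[[1]]
      bb <- b[b$subject_id == parts[1] & b$session == parts[2], ]
      if (any(diff(bb$time_min) <= 0)) {
        flag("blood", "monotone_time",
             paste0(key, ": non-increasing sample times at rows ",
                    paste(which(diff(bb$time_min) <= 0) + 1, collapse = ", ")))
      }
      if (any(bb$activity_kBq_mL < 0)) {
        flag("blood", "negativity", paste0(key, ": negative activity"))
      }
      pf <- bb$parent_fraction[!is.na(bb$parent_fraction)]
      if (any(pf < 0 | pf > 1)) {
        flag("blood", "fraction_range",
             paste0(key, ": parent fraction outside [0, 1]"))
      }
    }
  }
  tt <- x$tacs
  if (is.null(tt)) {
    flag("tacs", "missing", "tacs table absent")
  } else {
    start_col <- intersect(c("frame_start_s", "start_s"), names(tt))[1]
    end_col <- intersect(c("frame_end_s", "end_s"), names(tt))[1]
    if (is.na(start_col) || is.na(end_col)) {
      flag("tacs", "columns", "missing frame start/end columns")
    } else {
      grp <- paste(tt$subject_id, tt$session, tt$region, sep = "|")
      for (g in unique(grp)) {
        ft <- tt[grp == g, ]
        ft <- ft[order(ft[[start_col]]), ]
        gaps <- which(ft[[start_col]][-1] != ft[[end_col]][-nrow(ft)])
        if (length(gaps)) {
          flag("tacs", "contiguity",
               paste0(g, ": gap/overlap before frame ",
                      paste(gaps + 1, collapse = ", ")))
        }
        if (any(ft$activity_kBq_mL < 0)) {
          flag("tacs", "negativity", paste0(g, ": negative activity"))
        }
      }
    }
  }
  if (length(issues) == 0) {
    tibble::tibble(table = character(), check = character(),
                   detail = character())
  } else {
    dplyr::bind_rows(issues)
  }
}
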