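#' Eligibility gate: research authorization and adult age
#'
#' A patient enters the screen only with research authorization on file and
#' age >= 18 years at ICU admission (completed years at the index-stay
#' admission time).
#'
#' @param patient one-row data frame with `birth_date` and
#'   `research_authorization`.
#' @param index_stay one-row data frame with `admit_ts`, or `NULL` when the
#'   patient has no ICU stay (age is then unassessable and the patient is
#'   ineligible only if unauthorized; downstream gates will exclude them).
#' @return list with `eligible` (logical) and `reasons` (character vector,
#'   subset of `no_authorization`, `under_18`).
#' @export
check_eligibility <- function(patient, index_stay = NULL) {
  reasons <- character()
  if (!isTRUE(patient$research_authorization)) {
    reasons <- c(reasons, "no_authorization")
  }
  if (is.na(patient$birth_date)) {
    reasons <- c(reasons, "under_18")  # unverifiable age -> not demonstrably adult
  } else if (!is.null(index_stay) && nrow(index_stay)) {
    if (age_at(patient$birth_date, index_stay$admit_ts[1]) < 18) {
      reasons <- c(reasons, "under_18")
    }
  }
  list(eligible = !length(reasons), reasons = reasons)
}

#' Time zero: first PEEP >= threshold charted in an ICU area
#'
#' Scans ventilator records for the earliest PEEP at or above the threshold
#' that was charted in an ICU location during an ICU stay (procedural areas
#' excluded).  Also returns the ventilator mode at that record or, if blank,
#' the mode of the nearest-in-time ICU record with a non-empty mode.  The
#' stay containing time zero becomes the index stay.
#'
#' @param vents ventilator-settings data frame for one patient.
#' @param stays ICU-stays data frame for one patient.
#' @param cfg a [screen_config()].
#' @return list with `time_zero` (POSIXct or NULL), `mode` (character or NA),
#'   and `index_stay` (one-row data frame or NULL).
#' @export
find_time_zero <- function(vents, stays, cfg = screen_config()) {
  none <- list(time_zero = NULL, mode = NA_character_, index_stay = NULL)
  stays <- stays[stays$unit_class == "icu", , drop = FALSE]
  if (!nrow(vents) || !nrow(stays)) return(none)
  in_icu_stay <- vapply(vents$ts, function(t) {
    any(stays$admit_ts <= t & t <= stays$discharge_ts)
  }, logical(1))
  cand <- vents[vents$peep >= cfg$peep_threshold &
                  vents$location_class == "icu" & in_icu_stay, , drop = FALSE]
  if (!nrow(cand)) return(none)
  first <- cand[order(cand$ts), , drop = FALSE][1, , drop = FALSE]
  tz <- first$ts
  mode <- first$mode
  if (is.na(mode) || !nzchar(trimws(mode))) {
    pool <- vents[vents$location_class == "icu" &
                    nzchar(trimws(vents$mode)), , drop = FALSE]
    mode <- if (nrow(pool)) {
      pool$mode[order(abs(mins_diff(pool$ts, tz)), pool$ts)][1]
    } else NA_character_
  }
  idx <- which(stays$admit_ts <= tz & tz <= stays$discharge_ts)[1]
  list(time_zero = tz, mode = mode,
       index_stay = stays[idx, , drop = FALSE])
}

#' Construct PaO2/FiO2 measurements from blood gases and vital-sign FiO2
#'
#' Each PaO2 is paired with its same-result lab FiO2 when present; otherwise
#' with the nearest vital-sign FiO2 within the matching window (ties on
#' absolute time difference go to the earlier record, since pre-draw settings
#' better reflect the condition at the gas draw).  A PaO2 with neither source
#' yields no measurement.
#'
#' @param gases blood-gas data frame (`ts`, `pao2`, `fio2_lab`).
#' @param vitals vital-sign FiO2 data frame (`ts`, `fio2`).
#' @param cfg a [screen_config()]; `fio2_match_window` is in minutes.
#' @return data frame with columns `ts`, `pao2`, `fio2`, `fio2_source`
#'   ("lab"/"vitals"), `ratio`.
#' @export
build_pf_measurements <- function(gases, vitals, cfg = screen_config()) {
  empty <- data.frame(ts = as.POSIXct(character(), tz = "UTC"),
                      pao2 = numeric(), fio2 = numeric(),
                      fio2_source = character(), ratio = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(gases)) return(empty)
  rows <- lapply(seq_len(nrow(gases)), function(i) {
    pao2 <- gases$pao2[i]
    ts <- gases$ts[i]
    if (!is.na(gases$fio2_lab[i])) {
      fio2 <- gases$fio2_lab[i]
      src <- "lab"
    } else {
      if (!nrow(vitals)) return(NULL)
      dt <- abs(mins_diff(vitals$ts, ts))
      ok <- which(dt <= cfg$fio2_match_window)
      if (!length(ok)) return(NULL)
      pick <- ok[order(dt[ok], vitals$ts[ok])][1]
      fio2 <- vitals$fio2[pick]
      src <- "vitals"
    }
    data.frame(ts = ts, pao2 = pao2, fio2 = fio2, fio2_source = src,
               ratio = pao2 / fio2, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Qualifying P/F: worst ratio at or below threshold, at or after time zero
#'
#' The Berlin definition requires PEEP >= 5 during the P/F determination;
#' with intermittent charting, measurements at or after time zero are taken
#' as the qualifying pool.  Among qualifying measurements the minimum (worst)
#' ratio is returned; ties go to the earliest.
#'
#' @param pfs data frame from [build_pf_measurements()].
#' @param time_zero POSIXct anchor.
#' @param cfg a [screen_config()].
#' @return one-row data frame, or `NULL` when no measurement qualifies.
#' @export
qualifying_pf <- function(pfs, time_zero, cfg = screen_config()) {
  if (is.null(time_zero) || !nrow(pfs)) return(NULL)
  q <- pfs[pfs$ts >= time_zero & pfs$ratio <= cfg$pf_threshold, , drop = FALSE]
  if (!nrow(q)) return(NULL)
  q[order(q$ratio, q$ts), , drop = FALSE][1, , drop = FALSE]
}

#' Keyword adjudication of a chest X-ray report
#'
#' A report is positive when, after lowercasing and tokenizing on
#' non-alphanumeric characters, a token stemmed "bilateral" occurs within
#' `keyword_proximity` tokens before a finding token stemmed "infiltrate",
#' "opacity"/"opacification", or "edema", inside the same period-delimited
#' sentence.  This mirrors the published keyword combinations (bilateral
#' infiltrates / bilateral opacities / bilateral edema); there is no negation
#' or uncertainty handling.
#'
#' @param report_text free-text radiology report (character scalar).
#' @param keyword_proximity maximum token distance (default 3).
#' @return logical.
#' @examples
#' radiology_positive("Bilateral patchy airspace infiltrates.")
#' radiology_positive("Bilateral pleural effusions.")
#' @export
radiology_positive <- function(report_text, keyword_proximity = 3) {
  if (length(report_text) != 1L || is.na(report_text) ||
      !nzchar(trimws(report_text))) {
    return(FALSE)
  }
  sentences <- strsplit(tolower(report_text), ".", fixed = TRUE)[[1]]
  for (s in sentences) {
    toks <- strsplit(s, "[^a-z0-9]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) < 2) next
    bi <- which(startsWith(toks, "bilateral"))
    if (!length(bi)) next
    tgt <- which(grepl("^(infiltrat|opacit|opacif|o?edema)", toks))
    for (b in bi) {
      if (any(tgt > b & tgt <= b + keyword_proximity)) return(TRUE)
    }
  }
  FALSE
}

#' Positive chest X-ray within the imaging window around time zero
#'
#' @param reports radiology data frame for one patient.
#' @param time_zero POSIXct anchor.
#' @param cfg a [screen_config()]; `cxr_window` is in hours, applied
#'   symmetrically around time zero.
#' @return logical.
#' @export
positive_cxr_near <- function(reports, time_zero, cfg = screen_config()) {
  if (is.null(time_zero) || !nrow(reports)) return(FALSE)
  cxr <- reports[reports$modality == "chest_xray" &
                   abs(hours_diff(reports$ts, time_zero)) <= cfg$cxr_window, ,
                 drop = FALSE]
  if (!nrow(cxr)) return(FALSE)
  any(vapply(cxr$report_text, radiology_positive, logical(1),
             keyword_proximity = cfg$keyword_proximity))
}

#' Pulmonary-fibrosis exclusion from the comorbidity table
#'
#' Idiopathic pulmonary fibrosis, interstitial lung disease, and pulmonary
#' fibrosis exclude a patient (Charlson comorbidity index search).
#'
#' @param comorbidities comorbidity data frame for one patient.
#' @return logical; `TRUE` means excluded.
#' @export
fibrosis_excluded <- function(comorbidities) {
  nrow(comorbidities) > 0 &&
    any(comorbidities$category %in% .fibrosis_categories)
}

#' Total invasive mechanical-ventilation duration in hours
#'
#' Invasive records are grouped into episodes: consecutive records whose
#' inter-record gap is at most `vent_gap_merge` hours belong to one episode;
#' each episode lasts from its first to its last record and the episode
#' durations are summed.  A single isolated record contributes zero.  This is
#' a documented approximation of an institution-specific ventilation-duration
#' algorithm.
#'
#' @param vents ventilator-settings data frame for one patient.
#' @param cfg a [screen_config()].
#' @return duration in hours (numeric scalar).
#' @export
invasive_vent_duration <- function(vents, cfg = screen_config()) {
  inv <- vents[vents$invasive, , drop = FALSE]
  if (nrow(inv) < 2) return(0)
  ts <- sort(inv$ts)
  gaps <- hours_diff(ts[-1], ts[-length(ts)])
  episode <- cumsum(c(0, gaps > cfg$vent_gap_merge))
  starts <- tapply(as.numeric(ts), episode, min)
  ends <- tapply(as.numeric(ts), episode, max)
  sum(ends - starts) / 3600
}

#' Risk factors for ARDS within a window around ICU admission
#'
#' Returns the categories of risk-factor events (sepsis/septic shock,
#' pneumonia, aspiration, pancreatitis, trauma, drug overdose, shock,
#' multiple transfusion) recorded within `risk_factor_window` hours of the
#' index ICU admission, symmetric.
#'
#' @param events risk-factor data frame for one patient.
#' @param icu_admit POSIXct admission time of the index stay.
#' @param cfg a [screen_config()].
#' @return character vector of unique categories (possibly empty).
#' @export
find_risk_factors <- function(events, icu_admit, cfg = screen_config()) {
  if (!nrow(events) || is.null(icu_admit)) return(character())
  hit <- abs(hours_diff(events$ts, icu_admit)) <= cfg$risk_factor_window
  sort(unique(events$category[hit]))
}

#' Cardiogenic-edema exclusion
#'
#' A patient is excluded when any of the following holds: (a) cardiogenic
#' pulmonary edema, cardiogenic shock, or a positive acute decompensated
#' heart failure event during the index ICU stay; (b) any history of
#' coronary artery disease or chronic heart failure (regardless of
#' timestamp); (c) an ECG report within `ecg_window` hours of time zero whose
#' findings mention new ST changes or a left bundle branch block.
#'
#' @param cardiac cardiac-events data frame for one patient.
#' @param ecgs ECG-report data frame for one patient.
#' @param index_stay one-row data frame (the stay containing time zero).
#' @param time_zero POSIXct anchor.
#' @param cfg a [screen_config()].
#' @return list with `excluded` (logical) and `reasons` (character vector).
#' @export
cardiogenic_excluded <- function(cardiac, ecgs, index_stay, time_zero,
                                 cfg = screen_config()) {
  reasons <- character()
  acute <- c("cardiogenic_pulmonary_edema", "cardiogenic_shock", "adhf_positive")
  if (nrow(cardiac)) {
    if (!is.null(index_stay) && nrow(index_stay)) {
      in_stay <- cardiac$ts >= index_stay$admit_ts[1] &
        cardiac$ts <= index_stay$discharge_ts[1]
      hits <- unique(cardiac$category[cardiac$category %in% acute & in_stay])
      reasons <- c(reasons, hits)
    }
    hist_hits <- unique(cardiac$category[cardiac$category %in%
                                           c("cad_history", "chf_history")])
    reasons <- c(reasons, hist_hits)
  }
  if (nrow(ecgs) && !is.null(time_zero)) {
    near <- abs(hours_diff(ecgs$ts, time_zero)) <= cfg$ecg_window
    txt <- tolower(ecgs$findings_text[near])
    if (any(grepl("new st", txt) |
            grepl("left bundle branch block|\\blbbb\\b", txt))) {
      reasons <- c(reasons, "ecg_new_st_or_lbbb")
    }
  }
  list(excluded = length(reasons) > 0, reasons = unique(reasons))
}

#' Berlin severity stratum from a qualifying P/F ratio
#'
#' Mild: 200 <= P/F <= 300; moderate: 100 <= P/F < 200; severe: P/F < 100.
#' Only defined for qualifying ratios, i.e. 0 < ratio <= 300.
#'
#' @param ratio numeric vector of P/F ratios in (0, 300].
#' @return character vector: "mild", "moderate", or "severe".
#' @examples
#' grade_severity(c(250, 150, 99.9))
#' @export
grade_severity <- function(ratio) {
  if (!is.numeric(ratio) || any(is.na(ratio)) ||
      any(ratio <= 0 | ratio > 300)) {
    stop("grade_severity: ratio must be in (0, 300]", call. = FALSE)
  }
  ifelse(ratio < 100, "severe", ifelse(ratio < 200, "moderate", "mild"))
}

.gate_names <- c("eligibility", "time_zero", "qualifying_pf", "positive_cxr",
                 "fibrosis", "vent_duration", "risk_factor", "cardiogenic")

#' Screen one patient through the sequential ARDS gates
#'
#' Applies the gates in order (eligibility, time zero, qualifying P/F,
#' positive chest X-ray, fibrosis exclusion, invasive-ventilation duration,
#' risk factors, cardiogenic exclusion), short-circuiting at the first
#' failure; the trace records each gate actually evaluated.  A patient is
#' called ARDS only when every gate passes, in which case severity is graded
#' from the worst qualifying P/F ratio.
#'
#' @param store an `ehr_store`.
#' @param patient_id patient to screen (must exist in the store).
#' @param cfg a [screen_config()].
#' @return an object of class `screen_result`: `patient_id`, `ards`,
#'   `severity` ("none"/"mild"/"moderate"/"severe"), `time_zero`,
#'   `vent_mode`, `qualifying_pf` (one-row data frame or NULL),
#'   `exclusion_reasons`, and `trace` (data frame of evaluated gates).
#' @export
screen_patient <- function(store, patient_id, cfg = screen_config()) {
  stopifnot(inherits(store, "ehr_store"))
  i <- match(patient_id, store$patients$patient_id)
  if (is.na(i)) stop("unknown patient_id: ", patient_id, call. = FALSE)
  tabs <- lapply(store[setdiff(names(.ehr_schemas), "patients")],
                 function(t) t[t$patient_id == patient_id, , drop = FALSE])
  screen_one(store$patients[i, , drop = FALSE], tabs, cfg)
}

screen_one <- function(patient, tabs, cfg) {
  trace <- list()
  note <- function(gate, passed, detail = "") {
    trace[[length(trace) + 1L]] <<- data.frame(
      gate = gate, passed = passed, detail = detail, stringsAsFactors = FALSE)
  }
  result <- function(ards, severity = "none", time_zero = NULL, mode = NA,
                     qpf = NULL, reasons = character()) {
    structure(list(
      patient_id = patient$patient_id,
      ards = ards, severity = severity,
      time_zero = time_zero, vent_mode = mode,
      qualifying_pf = qpf,
      exclusion_reasons = reasons,
      trace = do.call(rbind, trace)
    ), class = "screen_result")
  }

  # gate 1: authorization + age (age at index-stay admission; with no time
  # zero yet, the first ICU stay stands in as the reference)
  stays <- tabs$icu_stays
  ref_stay <- if (nrow(stays)) stays[order(stays$admit_ts), ][1, , drop = FALSE] else NULL
  elig <- check_eligibility(patient, ref_stay)
  note("eligibility", elig$eligible, paste(elig$reasons, collapse = ";"))
  if (!elig$eligible) return(result(FALSE, reasons = elig$reasons))

  # gate 2: time zero = first PEEP >= threshold in an ICU area
  tz <- find_time_zero(tabs$vent_settings, stays, cfg)
  note("time_zero", !is.null(tz$time_zero),
       if (is.null(tz$time_zero)) "" else format_ts(tz$time_zero))
  if (is.null(tz$time_zero)) return(result(FALSE, reasons = "no_time_zero"))

  # gate 3: qualifying P/F at or after time zero
  pfs <- build_pf_measurements(tabs$blood_gas, tabs$vitals_fio2, cfg)
  qpf <- qualifying_pf(pfs, tz$time_zero, cfg)
  note("qualifying_pf", !is.null(qpf),
       if (is.null(qpf)) "" else sprintf("ratio=%.1f", qpf$ratio))
  if (is.null(qpf)) {
    return(result(FALSE, time_zero = tz$time_zero, mode = tz$mode,
                  reasons = "no_qualifying_pf"))
  }

  # gate 4: positive bilateral chest X-ray near time zero
  cxr <- positive_cxr_near(tabs$radiology, tz$time_zero, cfg)
  note("positive_cxr", cxr)
  if (!cxr) {
    return(result(FALSE, time_zero = tz$time_zero, mode = tz$mode, qpf = qpf,
                  reasons = "no_positive_cxr"))
  }

  # gate 5: IPF/ILD/pulmonary fibrosis exclusion
  fib <- fibrosis_excluded(tabs$comorbidities)
  note("fibrosis", !fib)
  if (fib) {
    return(result(FALSE, time_zero = tz$time_zero, mode = tz$mode, qpf = qpf,
                  reasons = "fibrosis"))
  }

  # gate 6: invasive ventilation duration
  dur <- invasive_vent_duration(tabs$vent_settings, cfg)
  long_enough <- dur >= cfg$min_vent_duration
  note("vent_duration", long_enough, sprintf("%.1f h", dur))
  if (!long_enough) {
    return(result(FALSE, time_zero = tz$time_zero, mode = tz$mode, qpf = qpf,
                  reasons = "vent_under_min"))
  }

  # gate 7: at least one ARDS risk factor near index ICU admission
  rf <- find_risk_factors(tabs$risk_factors, tz$index_stay$admit_ts[1], cfg)
  note("risk_factor", length(rf) > 0, paste(rf, collapse = ";"))
  if (!length(rf)) {
    return(result(FALSE, time_zero = tz$time_zero, mode = tz$mode, qpf = qpf,
                  reasons = "no_risk_factor"))
  }

  # gate 8: cardiogenic-edema exclusion
  card <- cardiogenic_excluded(tabs$cardiac_events, tabs$ecg, tz$index_stay,
                               tz$time_zero, cfg)
  note("cardiogenic", !card$excluded, paste(card$reasons, collapse = ";"))
  if (card$excluded) {
    return(result(FALSE, time_zero = tz$time_zero, mode = tz$mode, qpf = qpf,
                  reasons = "cardiogenic"))
  }

  # with a pf_threshold widened beyond 300 (non-Berlin, warned at config
  # time) ratios above the mild band are graded at its edge
  result(TRUE, severity = grade_severity(min(qpf$ratio, 300)),
         time_zero = tz$time_zero, mode = tz$mode, qpf = qpf)
}

#' @export
print.screen_result <- function(x, ...) {
  cat("Patient", x$patient_id, "-",
      if (x$ards) paste0("ARDS (", x$severity, ")") else
        paste0("negative (", paste(x$exclusion_reasons, collapse = "; "), ")"),
      "\n")
  if (!is.null(x$time_zero)) cat("  time zero:", format_ts(x$time_zero), "\n")
  if (!is.null(x$qualifying_pf)) {
    cat(sprintf("  qualifying P/F: %.1f (%s FiO2)\n",
                x$qualifying_pf$ratio, x$qualifying_pf$fio2_source))
  }
  invisible(x)
}

#' Screen every patient in a store
#'
#' Applies [screen_patient()] to all patients, in `patient_id` order, and
#' attaches a funnel table (patients surviving each sequential gate).
#'
#' @param store an `ehr_store`.
#' @param cfg a [screen_config()].
#' @param quiet suppress the funnel log.
#' @return an object of class `screen_results`: a list of `screen_result`
#'   objects with a `funnel` attribute (data frame `gate`, `n_passed`).
#' @export
screen_cohort <- function(store, cfg = screen_config(), quiet = TRUE) {
  stopifnot(inherits(store, "ehr_store"))
  ids <- sort(store$patients$patient_id)
  tab_names <- setdiff(names(.ehr_schemas), "patients")
  by_pid <- lapply(store[tab_names], function(t) {
    split(t, factor(t$patient_id, levels = ids))
  })
  empties <- lapply(store[tab_names], function(t) t[0, , drop = FALSE])
  patients <- store$patients[match(ids, store$patients$patient_id), ,
                             drop = FALSE]
  results <- lapply(seq_along(ids), function(k) {
    tabs <- lapply(tab_names, function(nm) {
      by_pid[[nm]][[ids[k]]] %||% empties[[nm]]
    })
    names(tabs) <- tab_names
    screen_one(patients[k, , drop = FALSE], tabs, cfg)
  })
  funnel <- data.frame(
    gate = c("screened", .gate_names),
    n_passed = c(length(results), vapply(.gate_names, function(g) {
      sum(vapply(results, function(r) {
        tr <- r$trace
        !is.null(tr) && any(tr$gate == g & tr$passed)
      }, logical(1)))
    }, integer(1))),
    stringsAsFactors = FALSE
  )
  if (!quiet) {
    message("screening funnel:")
    for (i in seq_len(nrow(funnel))) {
      message(sprintf("  %-15s %d", funnel$gate[i], funnel$n_passed[i]))
    }
  }
  structure(results, class = "screen_results", funnel = funnel)
}

#' @export
as.data.frame.screen_results <- function(x, ...) {
  rows <- lapply(unclass(x), screen_result_row)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

screen_result_row <- function(r) {
  qpf <- r$qualifying_pf
  flags <- stats::setNames(rep(NA, length(.gate_names)),
                           paste0("gate_", .gate_names))
  if (!is.null(r$trace)) {
    flags[paste0("gate_", r$trace$gate)] <- r$trace$passed
  }
  cbind(
    data.frame(
      patient_id = r$patient_id,
      ards = r$ards,
      severity = r$severity,
      time_zero = r$time_zero %||% as.POSIXct(NA, tz = "UTC"),
      vent_mode = r$vent_mode %||% NA_character_,
      pf_ratio = if (is.null(qpf)) NA_real_ else qpf$ratio,
      pf_ts = if (is.null(qpf)) as.POSIXct(NA, tz = "UTC") else qpf$ts,
      pf_pao2 = if (is.null(qpf)) NA_real_ else qpf$pao2,
      pf_fio2 = if (is.null(qpf)) NA_real_ else qpf$fio2,
      pf_source = if (is.null(qpf)) NA_character_ else qpf$fio2_source,
      exclusion_reasons = paste(r$exclusion_reasons, collapse = ";"),
      stringsAsFactors = FALSE
    ),
    as.data.frame(as.list(flags))
  )
}

#' Funnel table of a cohort screen
#'
#' @param results a `screen_results` object.
#' @return data frame with columns `gate` and `n_passed`; counts are
#'   monotone non-increasing down the gate sequence.
#' @export
screen_funnel <- function(results) {
  attr(results, "funnel")
}
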