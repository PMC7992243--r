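# Brute-force reference screen: evaluates every gate for every patient with
# no short-circuiting, and calls ARDS iff all gates pass.  Used to check the
# orchestration in screen_cohort() against the independently tested gates.
oracle_screen_patient <- function(store, pid, cfg = screen_config()) {
  p <- store$patients[store$patients$patient_id == pid, , drop = FALSE]
  tabs <- lapply(store[setdiff(names(ardscreen:::.ehr_schemas), "patients")],
                 function(t) t[t$patient_id == pid, , drop = FALSE])
  stays <- tabs$icu_stays
  ref <- if (nrow(stays)) {
    stays[order(stays$admit_ts), , drop = FALSE][1, , drop = FALSE]
  } else NULL

  g_elig <- check_eligibility(p, ref)$eligible
  tzres <- find_time_zero(tabs$vent_settings, stays, cfg)
  g_tz <- !is.null(tzres$time_zero)
  pfs <- build_pf_measurements(tabs$blood_gas, tabs$vitals_fio2, cfg)
  qpf <- if (g_tz) qualifying_pf(pfs, tzres$time_zero, cfg) else NULL
  g_pf <- !is.null(qpf)
  g_cxr <- g_tz && positive_cxr_near(tabs$radiology, tzres$time_zero, cfg)
  g_fib <- !fibrosis_excluded(tabs$comorbidities)
  g_vent <- invasive_vent_duration(tabs$vent_settings, cfg) >=
    cfg$min_vent_duration
  g_rf <- g_tz &&
    length(find_risk_factors(tabs$risk_factors, tzres$index_stay$admit_ts[1],
                             cfg)) > 0
  g_card <- !g_tz ||
    !cardiogenic_excluded(tabs$cardiac_events, tabs$ecg, tzres$index_stay,
                          tzres$time_zero, cfg)$excluded
  all(g_elig, g_tz, g_pf, g_cxr, g_fib, g_vent, g_rf, g_card)
}

oracle_screen_cohort <- function(store, cfg = screen_config()) {
  ids <- sort(store$patients$patient_id)
  stats::setNames(
    vapply(ids, function(pid) oracle_screen_patient(store, pid, cfg),
           logical(1)),
    ids)
}
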