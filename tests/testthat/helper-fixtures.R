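# Shared fixture builders: tiny EHR stores constructed in code.

uts <- function(x) as.POSIXct(x, tz = "UTC")

# Build a validated ehr_store from partial tables; absent tables are empty.
make_store <- function(...) {
  given <- list(...)
  tabs <- lapply(names(ardscreen:::.ehr_schemas), function(nm) {
    if (!is.null(given[[nm]])) given[[nm]] else ardscreen:::empty_table(nm)
  })
  names(tabs) <- names(ardscreen:::.ehr_schemas)
  val <- ardscreen:::validate_store_tables(tabs, quiet = TRUE)
  ardscreen:::new_ehr_store(val$tables, meta = list(rejected = val$rejected))
}

# A hand-built patient that passes every gate: PEEP 8 in the ICU from 06:00,
# P/F 120 two hours after time zero, bilateral-infiltrate CXR at +2 h,
# 48 h of invasive ventilation, pneumonia 12 h after admission, no cardiac
# events.  Mutate the returned tables to break individual gates.
clean_patient_tables <- function(pid = "PT01") {
  admit <- uts("2017-03-01 00:00:00")
  tz0 <- uts("2017-03-01 06:00:00")
  list(
    patients = data.frame(patient_id = pid,
                          birth_date = uts("1970-05-01"),
                          research_authorization = TRUE,
                          stringsAsFactors = FALSE),
    icu_stays = data.frame(patient_id = pid, admit_ts = admit,
                           discharge_ts = admit + 6 * 86400,
                           unit_class = "icu", stringsAsFactors = FALSE),
    vent_settings = data.frame(patient_id = pid,
                               ts = tz0 + 3600 * (0:48),
                               peep = 8, mode = "CMV volume control",
                               invasive = TRUE, location_class = "icu",
                               stringsAsFactors = FALSE),
    blood_gas = data.frame(patient_id = pid, ts = tz0 + 2 * 3600,
                           pao2 = 96, fio2_lab = 0.8,
                           stringsAsFactors = FALSE),
    radiology = data.frame(patient_id = pid, ts = tz0 + 2 * 3600,
                           modality = "chest_xray",
                           report_text = "Bilateral infiltrates are present.",
                           stringsAsFactors = FALSE),
    comorbidities = data.frame(patient_id = pid, category = "diabetes",
                               recorded_ts = admit - 86400,
                               stringsAsFactors = FALSE),
    risk_factors = data.frame(patient_id = pid, ts = admit + 12 * 3600,
                              category = "pneumonia", source = "diagnosis",
                              stringsAsFactors = FALSE),
    ecg = data.frame(patient_id = pid, ts = tz0 + 3600,
                     findings_text = "Sinus rhythm. No acute changes.",
                     stringsAsFactors = FALSE)
  )
}

clean_patient_store <- function(pid = "PT01") {
  do.call(make_store, clean_patient_tables(pid))
}

cohort_confusion <- function(cohort, cfg = screen_config()) {
  df <- as.data.frame(screen_cohort(cohort$store, cfg))
  confusion(stats::setNames(df$ards, df$patient_id),
            stats::setNames(cohort$gold$ards, cohort$gold$patient_id))
}
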