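patient_row <- function(auth = TRUE, birth = "1970-05-01") {
  data.frame(patient_id = "P1", birth_date = uts(birth),
             research_authorization = auth, stringsAsFactors = FALSE)
}
stay_row <- function(admit = "2017-03-01 00:00:00",
                     discharge = "2017-03-06 00:00:00") {
  data.frame(patient_id = "P1", admit_ts = uts(admit),
             discharge_ts = uts(discharge), unit_class = "icu",
             stringsAsFactors = FALSE)
}
vent_rows <- function(ts, peep = 8, invasive = TRUE, location = "icu",
                      mode = "CMV") {
  n <- length(ts)
  data.frame(patient_id = rep("P1", n), ts = ts,
             peep = rep_len(peep, n), mode = rep_len(mode, n),
             invasive = rep_len(invasive, n),
             location_class = rep_len(location, n),
             stringsAsFactors = FALSE)
}

test_that("eligibility requires authorization and adult age at admission", {
  stay <- stay_row()
  expect_true(check_eligibility(patient_row(), stay)$eligible)
  e <- check_eligibility(patient_row(auth = FALSE), stay)
  expect_false(e$eligible)
  expect_identical(e$reasons, "no_authorization")
  e <- check_eligibility(patient_row(birth = "2000-01-01"), stay)  # 17 at admit
  expect_false(e$eligible)
  expect_identical(e$reasons, "under_18")
  # 18th birthday on admission day counts as adult
  expect_true(check_eligibility(patient_row(birth = "1999-03-01"), stay)$eligible)
})

test_that("time zero is the first PEEP >= 5 charted in an ICU area during a stay", {
  stays <- stay_row()
  v <- vent_rows(uts(c("2017-03-01 10:00:00", "2017-03-01 11:00:00")),
                 peep = c(4, 5))
  tz <- find_time_zero(v, stays)
  expect_equal(tz$time_zero, uts("2017-03-01 11:00:00"))
  expect_identical(tz$mode, "CMV")

  # procedural-area records never define time zero
  vp <- vent_rows(uts("2017-03-01 10:00:00"), peep = 8,
                  location = "procedural_area")
  expect_null(find_time_zero(vp, stays)$time_zero)

  # records outside any ICU stay do not count
  vo <- vent_rows(uts("2017-03-10 10:00:00"), peep = 8)
  expect_null(find_time_zero(vo, stays)$time_zero)

  # nothing charted (home BiPAP) -> none
  expect_null(find_time_zero(vent_rows(uts(character())), stays)$time_zero)

  # blank mode at time zero borrows the nearest non-empty ICU mode
  vm <- vent_rows(uts(c("2017-03-01 10:00:00", "2017-03-01 12:00:00")),
                  peep = c(8, 8), mode = c("", "SIMV"))
  expect_identical(find_time_zero(vm, stays)$mode, "SIMV")
})

test_that("P/F pairs prefer lab FiO2 and fall back to nearest vitals within the window", {
  gas <- function(ts, pao2, fio2_lab = NA_real_) {
    data.frame(patient_id = rep("P1", length(ts)), ts = uts(ts), pao2 = pao2,
               fio2_lab = rep_len(fio2_lab, length(ts)),
               stringsAsFactors = FALSE)
  }
  vit <- function(ts, fio2) {
    data.frame(patient_id = rep("P1", length(ts)), ts = uts(ts), fio2 = fio2,
               stringsAsFactors = FALSE)
  }
  # lab FiO2 on the same result: direct division
  pf <- build_pf_measurements(gas("2017-03-01 12:00:00", 80, 0.8),
                              vit(character(0), numeric(0)))
  expect_equal(pf$ratio, 100)
  expect_identical(pf$fio2_source, "lab")

  # missing lab FiO2: nearest vitals within +/-15 min
  pf <- build_pf_measurements(
    gas("2017-03-01 12:00:00", 60),
    rbind(vit("2017-03-01 12:10:00", 0.50), vit("2017-03-01 12:20:00", 0.60)))
  expect_equal(pf$ratio, 120)
  expect_identical(pf$fio2_source, "vitals")

  # nearest vitals outside the window: no measurement
  pf <- build_pf_measurements(gas("2017-03-01 12:00:00", 60),
                              vit("2017-03-01 12:20:00", 0.5))
  expect_equal(nrow(pf), 0)

  # equal |dt| before and after: the earlier record wins
  pf <- build_pf_measurements(
    gas("2017-03-01 12:00:00", 60),
    rbind(vit("2017-03-01 11:50:00", 0.40), vit("2017-03-01 12:10:00", 0.60)))
  expect_equal(pf$fio2, 0.40)
})

test_that("qualifying P/F is the worst ratio <= 300 at or after time zero", {
  tz0 <- uts("2017-03-01 06:00:00")
  pfs <- data.frame(ts = tz0 + 3600 * (1:3), pao2 = 1,
                    fio2 = 1, fio2_source = "lab",
                    ratio = c(250, 180, 320), stringsAsFactors = FALSE)
  expect_equal(qualifying_pf(pfs, tz0)$ratio, 180)
  pfs$ratio <- c(310, 320, 330)
  expect_null(qualifying_pf(pfs, tz0))
  expect_null(qualifying_pf(pfs[0, ], tz0))
  # measurements before time zero never qualify
  pfs$ratio <- c(100, 150, 200)
  expect_null(qualifying_pf(pfs, tz0 + 5 * 3600))
})

test_that("radiology keyword adjudication follows stem + proximity within a sentence", {
  expect_true(radiology_positive("Bilateral opacities consistent with pulmonary edema."))
  expect_false(radiology_positive("Right lower lobe infiltrate. Left lung clear."))
  expect_false(radiology_positive("Bilateral pleural effusions."))
  expect_true(radiology_positive("Bilateral patchy airspace infiltrates."))
  # 4 tokens of separation exceeds the default proximity of 3
  expect_false(radiology_positive("Bilateral somewhat patchy dependent infiltrates."))
  # sentence boundary blocks the pairing
  expect_false(radiology_positive("Findings are bilateral. Infiltrates unlikely."))
  # finding before the bilateral token does not count
  expect_false(radiology_positive("Infiltrates, not clearly bilateral."))
  expect_false(radiology_positive(""))
  expect_true(radiology_positive("bilateral EDEMA noted"))  # case-insensitive
})

test_that("the chest X-ray window is +/-12 h around time zero", {
  tz0 <- uts("2017-03-01 06:00:00")
  rep_at <- function(h, text) {
    data.frame(patient_id = "P1", ts = tz0 + h * 3600, modality = "chest_xray",
               report_text = text, stringsAsFactors = FALSE)
  }
  pos <- "Bilateral infiltrates."
  neg <- "Left lung clear."
  expect_true(positive_cxr_near(rep_at(6, pos), tz0))
  expect_false(positive_cxr_near(rep_at(20, pos), tz0))
  expect_false(positive_cxr_near(rbind(rep_at(6, neg), rep_at(20, pos)), tz0))
  expect_true(positive_cxr_near(rep_at(-6, pos), tz0))  # symmetric window
})

test_that("fibrosis exclusion triggers on IPF/ILD/pulmonary fibrosis only", {
  com <- function(cat) data.frame(patient_id = rep("P1", length(cat)),
                                  category = cat,
                                  recorded_ts = rep(uts("2016-01-01"),
                                                    length(cat)),
                                  stringsAsFactors = FALSE)
  expect_true(fibrosis_excluded(com("ipf")))
  expect_true(fibrosis_excluded(com(c("diabetes", "pulmonary_fibrosis"))))
  expect_false(fibrosis_excluded(com(c("diabetes", "chf"))))
  expect_false(fibrosis_excluded(com(character(0))))
})

test_that("invasive ventilation duration merges episodes across gaps <= 1 h", {
  # contiguous 11 h -> below the 12 h minimum
  v <- vent_rows(uts("2017-03-01 08:00:00") + seq(0, 11, by = 0.5) * 3600)
  expect_equal(invasive_vent_duration(v), 11)
  # exactly 12.0 h passes the boundary
  v12 <- vent_rows(uts("2017-03-01 08:00:00") + seq(0, 12, 0.5) * 3600)
  expect_gte(invasive_vent_duration(v12), screen_config()$min_vent_duration)
  # 08:00-16:00 and 16:30-22:30 merge across the 0.5 h gap into 14.5 h
  ts <- c(uts("2017-03-01 08:00:00") + seq(0, 8, 0.5) * 3600,
          uts("2017-03-01 16:30:00") + seq(0, 6, 0.5) * 3600)
  expect_equal(invasive_vent_duration(vent_rows(ts)), 14.5)
  # a 2 h gap splits the episodes: only the spans count
  ts2 <- c(uts("2017-03-01 08:00:00") + c(0, 1, 2) * 3600,
           uts("2017-03-01 12:00:00") + c(0, 1) * 3600)
  expect_equal(invasive_vent_duration(vent_rows(ts2)), 3)
  # single or no invasive record -> 0
  expect_equal(invasive_vent_duration(vent_rows(uts("2017-03-01 08:00:00"))), 0)
  expect_equal(invasive_vent_duration(
    vent_rows(uts("2017-03-01 08:00:00") + 0:20 * 3600, invasive = FALSE)), 0)
})

test_that("risk factors count only within +/-72 h of ICU admission", {
  admit <- uts("2017-03-01 00:00:00")
  ev <- function(h, cat = "sepsis_septic_shock") {
    n <- length(h)
    data.frame(patient_id = rep("P1", n), ts = admit + h * 3600,
               category = rep_len(cat, n), source = rep("diagnosis", n),
               stringsAsFactors = FALSE)
  }
  expect_identical(find_risk_factors(ev(24), admit), "sepsis_septic_shock")
  expect_identical(find_risk_factors(ev(80), admit), character(0))
  expect_identical(find_risk_factors(ev(numeric(0)), admit), character(0))
  expect_identical(find_risk_factors(ev(-48, "trauma"), admit), "trauma")
  expect_identical(find_risk_factors(rbind(ev(10), ev(20, "pneumonia")), admit),
                   c("pneumonia", "sepsis_septic_shock"))
})

test_that("cardiogenic exclusion covers acute events in the stay, any history, and near-time-zero ECG", {
  stay <- stay_row()
  tz0 <- uts("2017-03-01 06:00:00")
  card <- function(cat, ts) {
    data.frame(patient_id = rep("P1", length(cat)), ts = uts(ts),
               category = cat, stringsAsFactors = FALSE)
  }
  ecg <- function(text, ts) {
    ts <- if (inherits(ts, "POSIXct")) ts else uts(ts)
    data.frame(patient_id = rep("P1", length(text)), ts = ts,
               findings_text = text, stringsAsFactors = FALSE)
  }
  no_card <- card(character(0), character(0))
  no_ecg <- ecg(character(0), character(0))

  expect_true(cardiogenic_excluded(card("adhf_positive", "2017-03-02 00:00:00"),
                                   no_ecg, stay, tz0)$excluded)
  # acute event outside the index stay does not exclude
  expect_false(cardiogenic_excluded(card("adhf_positive", "2017-04-01 00:00:00"),
                                    no_ecg, stay, tz0)$excluded)
  # CAD/CHF history excludes regardless of timestamp
  expect_true(cardiogenic_excluded(card("cad_history", "2010-01-01 00:00:00"),
                                   no_ecg, stay, tz0)$excluded)
  # ECG with new LBBB at +20 h excludes; the same text at +30 h does not
  expect_true(cardiogenic_excluded(no_card,
                                   ecg("new LBBB noted", tz0 + 20 * 3600),
                                   stay, tz0)$excluded)
  expect_false(cardiogenic_excluded(no_card,
                                    ecg("LBBB noted", tz0 + 30 * 3600),
                                    stay, tz0)$excluded)
  expect_true(cardiogenic_excluded(no_card,
                                   ecg("New ST-segment elevation", tz0),
                                   stay, tz0)$excluded)
  expect_false(cardiogenic_excluded(no_card,
                                    ecg("Sinus rhythm. No acute changes.", tz0),
                                    stay, tz0)$excluded)
})

test_that("severity grading partitions (0, 300] with the stated boundaries", {
  expect_identical(grade_severity(250), "mild")
  expect_identical(grade_severity(150), "moderate")
  expect_identical(grade_severity(99.9), "severe")
  expect_identical(grade_severity(200), "mild")
  expect_identical(grade_severity(100), "moderate")
  expect_identical(grade_severity(300), "mild")
  expect_error(grade_severity(301), "ratio")
  expect_error(grade_severity(0), "ratio")
  # total, disjoint, exhaustive on a fine grid
  grid <- seq(0.5, 300, by = 0.5)
  sev <- grade_severity(grid)
  expect_true(all(sev %in% c("mild", "moderate", "severe")))
  expect_identical(sev, ifelse(grid < 100, "severe",
                               ifelse(grid < 200, "moderate", "mild")))
})

test_that("the full-gate fixture patient is ARDS moderate; single-row mutations flip it", {
  store <- clean_patient_store()
  res <- screen_patient(store, "PT01")
  expect_true(res$ards)
  expect_identical(res$severity, "moderate")
  expect_equal(res$qualifying_pf$ratio, 120)
  expect_equal(res$time_zero, uts("2017-03-01 06:00:00"))
  expect_identical(res$exclusion_reasons, character(0))
  expect_true(all(res$trace$passed))

  # + IPF comorbidity -> excluded for fibrosis
  tabs <- clean_patient_tables()
  tabs$comorbidities <- rbind(tabs$comorbidities,
                              data.frame(patient_id = "PT01", category = "ipf",
                                         recorded_ts = uts("2016-01-01")))
  res <- screen_patient(do.call(make_store, tabs), "PT01")
  expect_false(res$ards)
  expect_identical(res$exclusion_reasons, "fibrosis")

  # no ventilator records (home BiPAP) -> no time zero
  tabs <- clean_patient_tables()
  tabs$vent_settings <- NULL
  res <- screen_patient(do.call(make_store, tabs), "PT01")
  expect_false(res$ards)
  expect_identical(res$exclusion_reasons, "no_time_zero")
  expect_identical(res$severity, "none")
})

test_that("trace is sound: the recorded failing gate reproduces the failure in isolation", {
  mutations <- list(
    no_qualifying_pf = function(t) { t$blood_gas <- NULL; t },
    no_positive_cxr = function(t) {
      t$radiology$report_text <- "Left lung clear."; t },
    vent_under_min = function(t) {
      t$vent_settings <- t$vent_settings[1:9, ]; t },
    no_risk_factor = function(t) { t$risk_factors <- NULL; t },
    cardiogenic = function(t) {
      t$cardiac_events <- data.frame(patient_id = "PT01",
                                     ts = uts("2017-03-02 00:00:00"),
                                     category = "cardiogenic_shock"); t }
  )
  for (reason in names(mutations)) {
    tabs <- mutations[[reason]](clean_patient_tables())
    res <- screen_patient(do.call(make_store, tabs), "PT01")
    expect_false(res$ards, info = reason)
    expect_identical(res$exclusion_reasons, reason)
    tr <- res$trace
    expect_false(tr$passed[nrow(tr)], info = reason)
    expect_true(all(tr$passed[-nrow(tr)]), info = reason)
  }
})

test_that("cohort screening is deterministic and its funnel is monotone", {
  coh <- generate_cohort(cohort_spec(40, 0.4, seed = 21,
                                     edge_case_rates = list(short_vent = 0.1)))
  r1 <- screen_cohort(coh$store)
  r2 <- screen_cohort(coh$store)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  funnel <- screen_funnel(r1)
  expect_true(all(diff(funnel$n_passed) <= 0))
  expect_equal(funnel$n_passed[1], 40)
  # byte-identical results files
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_screen_results(r1, f1); write_screen_results(r2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("widening any window or threshold never loses an ARDS call", {
  coh <- generate_cohort(cohort_spec(
    60, 0.4, seed = 31,
    edge_case_rates = list(late_sepsis = 0.05, missing_pf_and_cxr = 0.05,
                           unilateral_cxr = 0.1)))
  base_cfg <- screen_config()
  n_pos <- function(cfg) sum(as.data.frame(screen_cohort(coh$store, cfg))$ards)
  base <- n_pos(base_cfg)
  wider <- list(
    suppressWarnings(screen_config(pf_threshold = 400)),
    screen_config(fio2_match_window = 60),
    screen_config(cxr_window = 48),
    screen_config(risk_factor_window = 120)
  )
  for (cfg in wider) expect_gte(n_pos(cfg), base)
  # adding an exclusion-triggering row can only hurt, never help
  store2 <- coh$store
  store2$comorbidities <- rbind(
    store2$comorbidities,
    data.frame(patient_id = store2$patients$patient_id[1], category = "ipf",
               recorded_ts = uts("2016-01-01")))
  expect_lte(n_pos_after <- sum(as.data.frame(
    screen_cohort(store2, base_cfg))$ards), base)
})

test_that("screen_cohort matches the non-short-circuit brute-force reference", {
  for (s in 1:10) {
    coh <- generate_cohort(cohort_spec(
      20, 0.4, seed = 1000 + s,
      edge_case_rates = list(late_sepsis = 0.05, cardiogenic_mimic = 0.05,
                             home_bipap_no_peep = 0.05, short_vent = 0.05)))
    df <- as.data.frame(screen_cohort(coh$store))
    oracle <- oracle_screen_cohort(coh$store)
    expect_identical(stats::setNames(df$ards, df$patient_id), oracle,
                     info = paste("seed", s))
  }
})
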