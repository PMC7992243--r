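# CSV schemas: one file per table, exact header names. Empty string = missing.
.ehr_schemas <- list(
  patients       = c("patient_id", "birth_date", "research_authorization"),
  icu_stays      = c("patient_id", "admit_ts", "discharge_ts", "unit_class"),
  vent_settings  = c("patient_id", "ts", "peep", "mode", "invasive", "location_class"),
  blood_gas      = c("patient_id", "ts", "pao2", "fio2_lab"),
  vitals_fio2    = c("patient_id", "ts", "fio2"),
  radiology      = c("patient_id", "ts", "modality", "report_text"),
  comorbidities  = c("patient_id", "category", "recorded_ts"),
  risk_factors   = c("patient_id", "ts", "category", "source"),
  cardiac_events = c("patient_id", "ts", "category"),
  ecg            = c("patient_id", "ts", "findings_text")
)

.fibrosis_categories <- c("ipf", "ild", "pulmonary_fibrosis")

# Charlson comorbidity categories plus the fibrosis entries used for exclusion
.comorbidity_categories <- c(
  "mi", "chf", "pvd", "cvd", "dementia", "copd", "rheumatologic",
  "peptic_ulcer", "mild_liver_disease", "diabetes", "diabetes_complications",
  "hemiplegia", "renal_disease", "malignancy", "severe_liver_disease",
  "metastatic_cancer", "aids", .fibrosis_categories
)

.risk_factor_categories <- c(
  "sepsis_septic_shock", "pneumonia", "aspiration", "pancreatitis",
  "trauma", "drug_overdose", "shock", "multiple_transfusion"
)

.cardiac_categories <- c(
  "cardiogenic_pulmonary_edema", "cardiogenic_shock", "adhf_positive",
  "cad_history", "chf_history"
)

.location_classes <- c("icu", "procedural_area")

#' Normalize inspired-oxygen fractions
#'
#' FiO2 appears in real extracts both as a fraction (0.21-1.0) and as a
#' percentage (21-100).  Fractions are kept, percentages are divided by 100,
#' and values in the ambiguous gap (1, 21) or outside (0.21, 100) are
#' flagged invalid rather than guessed at, because a silent misread corrupts
#' every downstream P/F ratio.
#'
#' @param x numeric vector of raw FiO2 values (NA allowed = missing).
#' @return list with `value` (normalized fraction, NA where missing or
#'   invalid) and `valid` (logical; missing counts as valid).
#' @export
normalize_fio2 <- function(x) {
  x <- as.numeric(x)
  value <- rep(NA_real_, length(x))
  valid <- rep(TRUE, length(x))
  frac <- !is.na(x) & x >= 0.21 & x <= 1.0
  pct  <- !is.na(x) & x >= 21 & x <= 100
  bad  <- !is.na(x) & !frac & !pct
  value[frac] <- x[frac]
  value[pct] <- x[pct] / 100
  valid[bad] <- FALSE
  list(value = value, valid = valid)
}

new_ehr_store <- function(tables, meta = list()) {
  structure(c(tables, list(meta = meta)), class = "ehr_store")
}

#' @export
print.ehr_store <- function(x, ...) {
  cat("EHR store:", nrow(x$patients), "patients\n")
  for (nm in names(.ehr_schemas)) {
    cat(sprintf("  %-15s %6d rows\n", nm, nrow(x[[nm]])))
  }
  rej <- x$meta$rejected
  if (!is.null(rej) && sum(unlist(rej)) > 0) {
    cat("  rejected rows:", sum(unlist(rej)), "\n")
  }
  invisible(x)
}

# Row-level validation shared by the CSV loader and the synthetic generator.
# Rows violating invariants are dropped (not fatal) with per-table counts,
# mirroring how dirty real-world extracts are handled.
validate_store_tables <- function(tabs, quiet = FALSE) {
  rejected <- list()
  drop_rows <- function(tab, name, keep, why) {
    n_bad <- sum(!keep)
    if (n_bad > 0) {
      rejected[[name]] <<- (rejected[[name]] %||% 0L) + n_bad
      if (!quiet) message(name, ": dropped ", n_bad, " row(s) - ", why)
      tab <- tab[keep, , drop = FALSE]
      rownames(tab) <- NULL
    }
    tab
  }

  p <- tabs$patients
  p <- drop_rows(p, "patients",
                 nzchar(p$patient_id) & !is.na(p$birth_date) &
                   !is.na(p$research_authorization),
                 "missing id, birth date, or authorization flag")
  p <- drop_rows(p, "patients", !duplicated(p$patient_id), "duplicate patient_id")
  tabs$patients <- p
  ids <- p$patient_id

  s <- tabs$icu_stays
  s <- drop_rows(s, "icu_stays",
                 !is.na(s$admit_ts) & !is.na(s$discharge_ts) &
                   s$admit_ts < s$discharge_ts &
                   s$unit_class %in% .location_classes,
                 "unparseable or inverted interval, or unknown unit class")
  if (nrow(s) > 1) {
    s <- s[order(s$patient_id, s$admit_ts), , drop = FALSE]
    keep <- rep(TRUE, nrow(s))
    last_end <- list()
    for (i in seq_len(nrow(s))) {
      pid <- s$patient_id[i]
      prev <- last_end[[pid]]
      if (!is.null(prev) && s$admit_ts[i] < prev) {
        keep[i] <- FALSE
      } else {
        last_end[[pid]] <- s$discharge_ts[i]
      }
    }
    s <- drop_rows(s, "icu_stays", keep, "overlapping stay for same patient")
  }
  tabs$icu_stays <- s

  v <- tabs$vent_settings
  v <- drop_rows(v, "vent_settings",
                 !is.na(v$ts) & !is.na(v$peep) & is.finite(v$peep) &
                   v$peep >= 0 & !is.na(v$invasive) &
                   v$location_class %in% .location_classes,
                 "missing timestamp, negative PEEP, or unknown location class")
  tabs$vent_settings <- v

  g <- tabs$blood_gas
  fl <- normalize_fio2(g$fio2_lab)
  g$fio2_lab <- fl$value
  g <- drop_rows(g, "blood_gas",
                 !is.na(g$ts) & !is.na(g$pao2) & is.finite(g$pao2) &
                   g$pao2 > 0 & fl$valid,
                 "missing timestamp, non-positive PaO2, or ambiguous FiO2")
  tabs$blood_gas <- g

  vf <- tabs$vitals_fio2
  fv <- normalize_fio2(vf$fio2)
  vf$fio2 <- fv$value
  vf <- drop_rows(vf, "vitals_fio2",
                  !is.na(vf$ts) & fv$valid & !is.na(fv$value),
                  "missing timestamp or FiO2 outside 0.21-1.0 after normalization")
  tabs$vitals_fio2 <- vf

  r <- tabs$radiology
  r <- drop_rows(r, "radiology",
                 !is.na(r$ts) & r$modality %in% c("chest_xray", "other") &
                   (r$modality != "chest_xray" | nzchar(trimws(r$report_text))),
                 "missing timestamp, unknown modality, or empty chest X-ray report")
  tabs$radiology <- r

  cm <- tabs$comorbidities
  cm <- drop_rows(cm, "comorbidities",
                  !is.na(cm$recorded_ts) & cm$category %in% .comorbidity_categories,
                  "missing timestamp or category outside the Charlson/fibrosis set")
  tabs$comorbidities <- cm

  rf <- tabs$risk_factors
  rf <- drop_rows(rf, "risk_factors",
                  !is.na(rf$ts) & rf$category %in% .risk_factor_categories &
                    rf$source %in% c("diagnosis", "note"),
                  "missing timestamp or unknown category/source")
  tabs$risk_factors <- rf

  ce <- tabs$cardiac_events
  ce <- drop_rows(ce, "cardiac_events",
                  !is.na(ce$ts) & ce$category %in% .cardiac_categories,
                  "missing timestamp or unknown category")
  tabs$cardiac_events <- ce

  e <- tabs$ecg
  e <- drop_rows(e, "ecg",
                 !is.na(e$ts) & nzchar(trimws(e$findings_text)),
                 "missing timestamp or empty findings text")
  tabs$ecg <- e

  # referential integrity + birth date precedes all of a patient's timestamps
  birth <- stats::setNames(tabs$patients$birth_date, tabs$patients$patient_id)
  for (nm in setdiff(names(.ehr_schemas), "patients")) {
    tab <- tabs[[nm]]
    ok <- tab$patient_id %in% ids
    tab <- drop_rows(tab, nm, ok, "orphan patient_id")
    ts_col <- intersect(c("ts", "admit_ts", "recorded_ts"), names(tab))[1]
    if (!is.na(ts_col) && nrow(tab)) {
      ok <- tab[[ts_col]] >= birth[tab$patient_id]
      tab <- drop_rows(tab, nm, ok, "timestamp precedes patient birth date")
    }
    tabs[[nm]] <- tab
  }

  list(tables = tabs, rejected = rejected)
}

#' Load a validated EHR store from a directory of CSV extracts
#'
#' Expects the ten schema-named files (`patients.csv`, `icu_stays.csv`,
#' `vent_settings.csv`, `blood_gas.csv`, `vitals_fio2.csv`, `radiology.csv`,
#' `comorbidities.csv`, `risk_factors.csv`, `cardiac_events.csv`, `ecg.csv`).
#' Unknown columns are tolerated; a missing required column or file is fatal.
#' Timestamps are parsed as UTC; FiO2 percentages are converted to
#' fractions; rows that violate table invariants are dropped with a logged
#' count per table rather than aborting the load.
#'
#' @param data_dir directory containing the CSV files.
#' @param config a [screen_config()]; stored in the metadata block.
#' @param quiet suppress row-rejection messages.
#' @return an object of class `ehr_store`: the ten tables as data frames plus
#'   a `meta` list (config snapshot, source dir, rejection counts, study
#'   window).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' cohort <- generate_cohort(cohort_spec(n_patients = 5, seed = 1))
#' write_ehr_store(cohort$store, dir)
#' store <- load_ehr_store(dir)
#' nrow(store$patients)
#' @export
load_ehr_store <- function(data_dir, config = screen_config(), quiet = FALSE) {
  if (!dir.exists(data_dir)) {
    stop("data directory not found: ", data_dir, call. = FALSE)
  }
  raw <- list()
  for (nm in names(.ehr_schemas)) {
    path <- file.path(data_dir, paste0(nm, ".csv"))
    if (!file.exists(path)) {
      stop("required file missing: ", paste0(nm, ".csv"), call. = FALSE)
    }
    tab <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, na.strings = NULL)
    missing_cols <- setdiff(.ehr_schemas[[nm]], names(tab))
    if (length(missing_cols)) {
      stop("file ", paste0(nm, ".csv"), " is missing required column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    raw[[nm]] <- tab[, .ehr_schemas[[nm]], drop = FALSE]
  }

  tabs <- list(
    patients = data.frame(
      patient_id = trimws(raw$patients$patient_id),
      birth_date = parse_ts(raw$patients$birth_date),
      research_authorization = parse_bool(raw$patients$research_authorization),
      stringsAsFactors = FALSE
    ),
    icu_stays = data.frame(
      patient_id = trimws(raw$icu_stays$patient_id),
      admit_ts = parse_ts(raw$icu_stays$admit_ts),
      discharge_ts = parse_ts(raw$icu_stays$discharge_ts),
      unit_class = trimws(raw$icu_stays$unit_class),
      stringsAsFactors = FALSE
    ),
    vent_settings = data.frame(
      patient_id = trimws(raw$vent_settings$patient_id),
      ts = parse_ts(raw$vent_settings$ts),
      peep = suppressWarnings(as.numeric(raw$vent_settings$peep)),
      mode = trimws(raw$vent_settings$mode),
      invasive = parse_bool(raw$vent_settings$invasive),
      location_class = trimws(raw$vent_settings$location_class),
      stringsAsFactors = FALSE
    ),
    blood_gas = data.frame(
      patient_id = trimws(raw$blood_gas$patient_id),
      ts = parse_ts(raw$blood_gas$ts),
      pao2 = suppressWarnings(as.numeric(raw$blood_gas$pao2)),
      fio2_lab = suppressWarnings(as.numeric(
        replace(raw$blood_gas$fio2_lab, !nzchar(trimws(raw$blood_gas$fio2_lab)), NA)
      )),
      stringsAsFactors = FALSE
    ),
    vitals_fio2 = data.frame(
      patient_id = trimws(raw$vitals_fio2$patient_id),
      ts = parse_ts(raw$vitals_fio2$ts),
      fio2 = suppressWarnings(as.numeric(raw$vitals_fio2$fio2)),
      stringsAsFactors = FALSE
    ),
    radiology = data.frame(
      patient_id = trimws(raw$radiology$patient_id),
      ts = parse_ts(raw$radiology$ts),
      modality = trimws(raw$radiology$modality),
      report_text = raw$radiology$report_text,
      stringsAsFactors = FALSE
    ),
    comorbidities = data.frame(
      patient_id = trimws(raw$comorbidities$patient_id),
      category = trimws(raw$comorbidities$category),
      recorded_ts = parse_ts(raw$comorbidities$recorded_ts),
      stringsAsFactors = FALSE
    ),
    risk_factors = data.frame(
      patient_id = trimws(raw$risk_factors$patient_id),
      ts = parse_ts(raw$risk_factors$ts),
      category = trimws(raw$risk_factors$category),
      source = trimws(raw$risk_factors$source),
      stringsAsFactors = FALSE
    ),
    cardiac_events = data.frame(
      patient_id = trimws(raw$cardiac_events$patient_id),
      ts = parse_ts(raw$cardiac_events$ts),
      category = trimws(raw$cardiac_events$category),
      stringsAsFactors = FALSE
    ),
    ecg = data.frame(
      patient_id = trimws(raw$ecg$patient_id),
      ts = parse_ts(raw$ecg$ts),
      findings_text = raw$ecg$findings_text,
      stringsAsFactors = FALSE
    )
  )

  val <- validate_store_tables(tabs, quiet = quiet)
  all_ts <- do.call(c, lapply(val$tables[setdiff(names(.ehr_schemas), "patients")],
                              function(t) {
                                col <- intersect(c("ts", "admit_ts", "recorded_ts"),
                                                 names(t))[1]
                                t[[col]]
                              }))
  meta <- list(
    config = config,
    source_dir = normalizePath(data_dir),
    rejected = val$rejected,
    study_window = if (length(all_ts) && any(!is.na(all_ts)))
      range(all_ts, na.rm = TRUE) else NULL
  )
  new_ehr_store(val$tables, meta)
}

#' Write an EHR store back to schema-named CSV files
#'
#' Inverse of [load_ehr_store()]: timestamps are serialized to second
#' precision in UTC so a write/load round trip preserves contents.
#'
#' @param store an `ehr_store`.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_ehr_store <- function(store, out_dir) {
  stopifnot(inherits(store, "ehr_store"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(.ehr_schemas)) {
    tab <- store[[nm]]
    out <- tab
    for (col in names(out)) {
      if (inherits(out[[col]], "POSIXct")) out[[col]] <- format_ts(out[[col]])
      if (is.logical(out[[col]])) out[[col]] <- ifelse(out[[col]], "true", "false")
      if (is.numeric(out[[col]])) {
        out[[col]] <- ifelse(is.na(out[[col]]), "",
                             format(out[[col]], trim = TRUE, scientific = FALSE))
      }
    }
    utils::write.csv(out, file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = TRUE, na = "")
  }
  invisible(out_dir)
}

#' Write per-patient screening results to CSV
#'
#' One row per patient: verdict, severity, time zero, qualifying P/F,
#' semicolon-joined exclusion reasons, and one pass/fail flag per evaluated
#' gate (empty where the gate was never reached).
#'
#' @param results a `screen_results` object from [screen_cohort()] or a list
#'   of single-patient results.
#' @param out path to write.
#' @return `out`, invisibly.
#' @export
write_screen_results <- function(results, out) {
  df <- as.data.frame(results)
  if (!nrow(df)) stop("no screening results to write", call. = FALSE)
  out_df <- df
  out_df$time_zero <- format_ts(df$time_zero)
  out_df$pf_ts <- format_ts(df$pf_ts)
  for (col in names(out_df)) {
    if (is.logical(out_df[[col]])) {
      out_df[[col]] <- ifelse(is.na(out_df[[col]]), "",
                              ifelse(out_df[[col]], "true", "false"))
    }
  }
  ok <- tryCatch({
    utils::write.csv(out_df, out, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write results to ", out, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(out)
}

#' Read a screening-results CSV written by [write_screen_results()]
#'
#' @param path CSV path.
#' @return data frame with typed columns (`ards` logical, timestamps POSIXct).
#' @export
read_screen_results <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  df$ards <- parse_bool(df$ards)
  df$time_zero <- parse_ts(df$time_zero)
  if ("pf_ts" %in% names(df)) df$pf_ts <- parse_ts(df$pf_ts)
  for (col in c("pf_ratio", "pf_pao2", "pf_fio2")) {
    if (col %in% names(df)) {
      df[[col]] <- suppressWarnings(as.numeric(replace(df[[col]],
                                                       !nzchar(df[[col]]), NA)))
    }
  }
  for (col in grep("^gate_", names(df), value = TRUE)) {
    df[[col]] <- parse_bool(df[[col]])
  }
  df
}
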