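.positive_edge_keys <- c("missing_pf_and_cxr", "late_sepsis", "home_bipap_no_peep")
.negative_edge_keys <- c("cardiogenic_mimic", "cardiogenic_mimic_defeat",
                         "fibrosis_mimic", "short_vent", "unilateral_cxr")

#' Specification of a synthetic ICU cohort
#'
#' Drives [generate_cohort()].  Gold-positive patients are generated to
#' satisfy every screening gate; gold-negative patients violate exactly one
#' gate.  Edge-case rates inject the documented failure archetypes:
#' `missing_pf_and_cxr`, `late_sepsis` (risk factor recorded >72 h after ICU
#' admission), and `home_bipap_no_peep` are gold-positive patients whose data
#' make the screen miss them; `cardiogenic_mimic` is a gold-negative with
#' structured cardiac events (caught by the exclusion),
#' `cardiogenic_mimic_defeat` a gold-negative whose cardiogenic edema is
#' documented only in free-text notes and therefore yields a false positive;
#' `fibrosis_mimic`, `short_vent`, and `unilateral_cxr` are gold-negative
#' single-gate violators.
#'
#' @param n_patients cohort size.
#' @param ards_prevalence probability a patient is gold-positive.
#' @param seed integer seed; the generator is deterministic given the seed
#'   and uses one stream per patient (keyed by seed and patient index), so
#'   growing the cohort never perturbs earlier patients.
#' @param edge_case_rates named list of per-patient archetype probabilities
#'   (fractions of the whole cohort).  Positive-side rates must sum to at
#'   most `ards_prevalence`, negative-side rates to at most
#'   `1 - ards_prevalence`.
#' @param jitter_minutes uniform charting jitter applied to event offsets,
#'   on a 1-minute grid.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients, ards_prevalence = 0.3, seed = 1,
                        edge_case_rates = list(), jitter_minutes = 30) {
  stopifnot(n_patients >= 1, n_patients == round(n_patients))
  if (ards_prevalence < 0 || ards_prevalence > 1) {
    stop("ards_prevalence must be in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(names(edge_case_rates),
                 c(.positive_edge_keys, .negative_edge_keys))
  if (length(bad)) {
    stop("unknown edge-case archetype(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  rates <- vapply(edge_case_rates, as.numeric, numeric(1))
  if (length(rates) && (any(rates < 0) || any(rates > 1) || sum(rates) > 1)) {
    stop("edge-case rates must be in [0, 1] and sum to at most 1",
         call. = FALSE)
  }
  pos_sum <- sum(rates[names(rates) %in% .positive_edge_keys])
  neg_sum <- sum(rates[names(rates) %in% .negative_edge_keys])
  if (pos_sum > ards_prevalence + 1e-12) {
    stop("gold-positive edge-case rates exceed the ARDS prevalence",
         call. = FALSE)
  }
  if (neg_sum > 1 - ards_prevalence + 1e-12) {
    stop("gold-negative edge-case rates exceed 1 - prevalence", call. = FALSE)
  }
  structure(list(n_patients = as.integer(n_patients),
                 ards_prevalence = ards_prevalence,
                 seed = as.integer(seed),
                 edge_case_rates = as.list(rates),
                 jitter_minutes = jitter_minutes),
            class = "cohort_spec")
}

.patient_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + as.numeric(i) * 7919) %% 2147483629)
}

.study_start <- function() as.POSIXct("2017-03-01 00:00:00", tz = "UTC")

#' Chest X-ray narrative for a synthetic patient
#'
#' Draws a short radiology report from the current RNG stream.  Positive
#' reports embed one qualifying bilateral phrase (bilateral infiltrates /
#' opacities / edema, possibly with interposed qualifiers) among distractor
#' sentences; negative reports contain unilateral or non-qualifying findings,
#' including the decoy "bilateral pleural effusions".
#'
#' @param positive should the report satisfy [radiology_positive()]?
#' @return character scalar.
#' @export
generate_report_text <- function(positive) {
  openers <- c("Portable chest radiograph.",
               "Endotracheal tube in standard position.",
               "Comparison with prior exam.")
  closers <- c("Heart size within normal limits.",
               "No pneumothorax.",
               "Osseous structures unremarkable.")
  pos <- c("Bilateral infiltrates are present.",
           "There are bilateral patchy airspace infiltrates.",
           "Diffuse bilateral opacities are noted.",
           "Bilateral opacities consistent with pulmonary edema.",
           "Findings compatible with bilateral edema.")
  neg <- c("Right lower lobe infiltrate. Left lung clear.",
           "Bilateral pleural effusions. No focal consolidation.",
           "Lungs are clear. No acute cardiopulmonary process.",
           "Left basilar atelectasis. Right lung unremarkable.",
           "Mild unilateral opacity in the right base.")
  core <- if (positive) sample(pos, 1) else sample(neg, 1)
  paste(sample(openers, 1), core, sample(closers, 1))
}

# One patient's rows for every table, generated from a dedicated RNG stream.
# Returns list(tables = <list of data frames>, gold = <logical>,
#              archetype = <final archetype name>).
make_patient <- function(pid, archetype, pseed, jitter_minutes = 30) {
  set.seed(pseed)
  m <- function(mins) mins * 60  # minutes -> seconds
  jit <- function() if (jitter_minutes > 0)
    sample(-jitter_minutes:jitter_minutes, 1) else 0

  admit <- .study_start() + m(sample(0:(20 * 1440), 1))
  age_years <- sample(20:89, 1)
  birth <- admit - age_years * 365.25 * 86400
  discharge <- admit + m(5 * 1440)
  tz <- admit + m(360)  # base time zero: 6 h after admission

  if (archetype == "non_ards") {
    archetype <- paste0("non_ards_",
                        sample(c("healthy", "high_pf", "unilateral_cxr",
                                 "no_risk_factor", "cardiogenic_history",
                                 "fibrosis", "short_vent"), 1))
  }
  stratum <- sample(c("mild", "moderate", "severe"), 1)
  if (archetype == "ards") archetype <- paste0("ards_", stratum)

  ratio <- switch(stratum,
                  mild = runif(1, 201, 299),
                  moderate = runif(1, 101, 198),
                  severe = runif(1, 40, 98))
  gold <- archetype %in% c(paste0("ards_", c("mild", "moderate", "severe")),
                           .positive_edge_keys)

  # --- defaults: a clean gold-positive patient, then archetype mutations ---
  vent_hours <- 0:16
  peep <- 8
  invasive <- TRUE
  has_vent <- TRUE
  has_gas <- TRUE
  has_cxr <- TRUE
  cxr_positive <- TRUE
  high_pf <- FALSE
  fibrosis <- FALSE
  cardiac_rows <- NULL
  rf_category <- sample(.risk_factor_categories, 1)
  rf_offset_min <- sample(60:2880, 1)  # 1-48 h after admission
  has_rf <- TRUE

  if (archetype == "missing_pf_and_cxr") {
    has_gas <- FALSE
    has_cxr <- FALSE
  } else if (archetype == "late_sepsis") {
    rf_category <- "sepsis_septic_shock"
    rf_offset_min <- sample((80 * 60):(120 * 60), 1)  # 80-120 h after admission
  } else if (archetype == "home_bipap_no_peep") {
    has_vent <- FALSE  # home BiPAP: PEEP never electronically recorded
  } else if (archetype == "cardiogenic_mimic") {
    cardiac_rows <- data.frame(patient_id = pid, ts = tz + m(240),
                               category = "adhf_positive",
                               stringsAsFactors = FALSE)
  } else if (archetype == "cardiogenic_mimic_defeat") {
    cardiac_rows <- NULL  # cardiogenic edema documented in notes only
  } else if (archetype == "fibrosis_mimic" ||
             archetype == "non_ards_fibrosis") {
    fibrosis <- TRUE
  } else if (archetype == "short_vent" || archetype == "non_ards_short_vent") {
    vent_hours <- 0:8
  } else if (archetype == "unilateral_cxr" ||
             archetype == "non_ards_unilateral_cxr") {
    cxr_positive <- FALSE
  } else if (archetype == "non_ards_healthy") {
    peep <- sample(3:4, 1)
    high_pf <- TRUE
    cxr_positive <- FALSE
  } else if (archetype == "non_ards_high_pf") {
    high_pf <- TRUE
  } else if (archetype == "non_ards_no_risk_factor") {
    has_rf <- FALSE
  } else if (archetype == "non_ards_cardiogenic_history") {
    cardiac_rows <- data.frame(patient_id = pid,
                               ts = admit - m(sample(1440:14400, 1)),
                               category = sample(c("cad_history",
                                                   "chf_history"), 1),
                               stringsAsFactors = FALSE)
  }
  if (high_pf) ratio <- runif(1, 320, 450)

  tabs <- list()
  tabs$patients <- data.frame(
    patient_id = pid, birth_date = birth, research_authorization = TRUE,
    stringsAsFactors = FALSE)
  tabs$icu_stays <- data.frame(
    patient_id = pid, admit_ts = admit, discharge_ts = discharge,
    unit_class = "icu", stringsAsFactors = FALSE)

  if (has_vent) {
    vts <- tz + m(60 * vent_hours)
    tabs$vent_settings <- data.frame(
      patient_id = pid, ts = c(tz - m(120), vts),
      peep = c(min(peep, 4), rep(peep, length(vts))),
      mode = "CMV volume control",
      invasive = invasive, location_class = "icu", stringsAsFactors = FALSE)
  }

  if (has_gas) {
    gas1_ts <- tz + m(120 + jit())
    fio2_1 <- round(runif(1, 0.4, 1.0), 2)
    gas2_ts <- tz + m(360 + jit())
    ratio2 <- ratio * 1.25
    vit_ts <- gas2_ts - m(7)
    fio2_2 <- 0.5
    tabs$blood_gas <- data.frame(
      patient_id = pid, ts = c(gas1_ts, gas2_ts),
      pao2 = round(c(ratio * fio2_1, ratio2 * fio2_2), 1),
      fio2_lab = c(fio2_1, NA_real_), stringsAsFactors = FALSE)
    tabs$vitals_fio2 <- data.frame(
      patient_id = pid, ts = vit_ts, fio2 = fio2_2, stringsAsFactors = FALSE)
  }

  if (has_cxr) {
    tabs$radiology <- data.frame(
      patient_id = pid, ts = tz + m(180 + jit()), modality = "chest_xray",
      report_text = generate_report_text(cxr_positive),
      stringsAsFactors = FALSE)
  }

  comorb <- if (fibrosis) sample(.fibrosis_categories, 1) else
    sample(c("diabetes", "copd", "renal_disease", "peptic_ulcer"), 1)
  tabs$comorbidities <- data.frame(
    patient_id = pid, category = comorb, recorded_ts = admit - m(1440),
    stringsAsFactors = FALSE)

  if (has_rf) {
    tabs$risk_factors <- data.frame(
      patient_id = pid, ts = admit + m(rf_offset_min),
      category = rf_category, source = sample(c("diagnosis", "note"), 1),
      stringsAsFactors = FALSE)
  }

  tabs$cardiac_events <- cardiac_rows
  tabs$ecg <- data.frame(
    patient_id = pid, ts = tz + m(60),
    findings_text = "Sinus rhythm, rate 92. No acute changes.",
    stringsAsFactors = FALSE)

  list(tables = tabs, gold = gold, archetype = archetype)
}

#' Generate a labeled synthetic ICU cohort
#'
#' Produces a validated `ehr_store` plus gold-standard labels.  Each
#' patient's gold label is drawn Bernoulli(`ards_prevalence`) from the
#' patient's own RNG stream; conditional on the label, the patient is an
#' edge-case archetype with probability `rate / prevalence` (positive side)
#' or `rate / (1 - prevalence)` (negative side), so expected archetype counts
#' equal `rate * n_patients`.  With all edge-case rates zero the screen
#' recovers the gold labels exactly by construction.
#'
#' @param spec a [cohort_spec()].
#' @return list with `store` (an `ehr_store`), `gold` (data frame
#'   `patient_id`, `ards`, `archetype`), and `spec`.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 20, seed = 42))
#' table(cohort$gold$ards)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  prev <- spec$ards_prevalence
  rates <- spec$edge_case_rates
  pos_keys <- intersect(names(rates), .positive_edge_keys)
  neg_keys <- intersect(names(rates), .negative_edge_keys)

  ids <- sprintf("SP%05d", seq_len(n))
  draws <- lapply(seq_len(n), function(i) {
    set.seed(.patient_seed(spec$seed, i))
    u <- runif(1)
    gold <- u < prev
    if (gold) {
      arch <- "ards"
      if (length(pos_keys) && prev > 0) {
        p <- unlist(rates[pos_keys]) / prev
        v <- runif(1)
        cum <- cumsum(p)
        hit <- which(v < cum)
        if (length(hit)) arch <- pos_keys[hit[1]]
      }
    } else {
      arch <- "non_ards"
      if (length(neg_keys) && prev < 1) {
        p <- unlist(rates[neg_keys]) / (1 - prev)
        v <- runif(1)
        cum <- cumsum(p)
        hit <- which(v < cum)
        if (length(hit)) arch <- neg_keys[hit[1]]
      }
    }
    make_patient(ids[i], arch, .patient_seed(spec$seed, i) + 1L,
                 spec$jitter_minutes)
  })
  assemble_cohort(draws, spec)
}

#' Generate a study-style cohort with exact composition
#'
#' Emulates purposeful sampling: a cohort of `n` patients with an exact
#' number of gold positives, a chosen set of miss archetypes among the
#' positives (patients the screen will miss), and a chosen number of
#' gold-negative patients constructed to defeat the cardiogenic exclusion
#' (screen false positives).  Deterministic given the seed.
#'
#' @param n cohort size (default 50).
#' @param n_positive exact number of gold-positive patients.
#' @param miss_archetypes character vector (possibly empty) of archetypes
#'   from `missing_pf_and_cxr`, `late_sepsis`, `home_bipap_no_peep`; its
#'   length is the number of screen false negatives.
#' @param n_cardiogenic_fp number of `cardiogenic_mimic_defeat` patients
#'   (screen false positives).
#' @param seed integer seed.
#' @param jitter_minutes charting jitter, as in [cohort_spec()].
#' @return list with `store`, `gold`, and `spec` (NULL).
#' @examples
#' coh <- staged_cohort(n = 50, n_positive = 18,
#'                      miss_archetypes = "missing_pf_and_cxr",
#'                      n_cardiogenic_fp = 1, seed = 7)
#' sum(coh$gold$ards)
#' @export
staged_cohort <- function(n = 50, n_positive, miss_archetypes = character(),
                          n_cardiogenic_fp = 0, seed = 1,
                          jitter_minutes = 30) {
  stopifnot(n_positive <= n, length(miss_archetypes) <= n_positive,
            n_cardiogenic_fp <= n - n_positive)
  bad <- setdiff(miss_archetypes, .positive_edge_keys)
  if (length(bad)) {
    stop("unknown miss archetype(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ids <- sprintf("SP%05d", seq_len(n))
  n_miss <- length(miss_archetypes)
  n_neg <- n - n_positive
  archetypes <- c(miss_archetypes,
                  rep("ards", n_positive - n_miss),
                  rep("cardiogenic_mimic_defeat", n_cardiogenic_fp),
                  rep("non_ards", n_neg - n_cardiogenic_fp))
  draws <- lapply(seq_len(n), function(i) {
    make_patient(ids[i], archetypes[i], .patient_seed(seed, i) + 1L,
                 jitter_minutes)
  })
  assemble_cohort(draws, NULL)
}

assemble_cohort <- function(draws, spec) {
  tabs <- lapply(names(.ehr_schemas), function(nm) {
    parts <- lapply(draws, function(d) d$tables[[nm]])
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (!length(parts)) return(empty_table(nm))
    as.data.frame(data.table::rbindlist(parts))
  })
  names(tabs) <- names(.ehr_schemas)
  val <- validate_store_tables(tabs, quiet = TRUE)
  gold <- data.frame(
    patient_id = vapply(draws, function(d) d$tables$patients$patient_id,
                        character(1)),
    ards = vapply(draws, function(d) d$gold, logical(1)),
    archetype = vapply(draws, function(d) d$archetype, character(1)),
    stringsAsFactors = FALSE
  )
  store <- new_ehr_store(val$tables,
                         meta = list(config = screen_config(),
                                     rejected = val$rejected,
                                     synthetic_spec = spec))
  list(store = store, gold = gold, spec = spec)
}

empty_table <- function(nm) {
  proto <- list(
    patients = data.frame(patient_id = character(),
                          birth_date = as.POSIXct(character(), tz = "UTC"),
                          research_authorization = logical()),
    icu_stays = data.frame(patient_id = character(),
                           admit_ts = as.POSIXct(character(), tz = "UTC"),
                           discharge_ts = as.POSIXct(character(), tz = "UTC"),
                           unit_class = character()),
    vent_settings = data.frame(patient_id = character(),
                               ts = as.POSIXct(character(), tz = "UTC"),
                               peep = numeric(), mode = character(),
                               invasive = logical(),
                               location_class = character()),
    blood_gas = data.frame(patient_id = character(),
                           ts = as.POSIXct(character(), tz = "UTC"),
                           pao2 = numeric(), fio2_lab = numeric()),
    vitals_fio2 = data.frame(patient_id = character(),
                             ts = as.POSIXct(character(), tz = "UTC"),
                             fio2 = numeric()),
    radiology = data.frame(patient_id = character(),
                           ts = as.POSIXct(character(), tz = "UTC"),
                           modality = character(), report_text = character()),
    comorbidities = data.frame(patient_id = character(),
                               category = character(),
                               recorded_ts = as.POSIXct(character(),
                                                        tz = "UTC")),
    risk_factors = data.frame(patient_id = character(),
                              ts = as.POSIXct(character(), tz = "UTC"),
                              category = character(), source = character()),
    cardiac_events = data.frame(patient_id = character(),
                                ts = as.POSIXct(character(), tz = "UTC"),
                                category = character()),
    ecg = data.frame(patient_id = character(),
                     ts = as.POSIXct(character(), tz = "UTC"),
                     findings_text = character())
  )
  proto[[nm]]
}

#' Write gold-standard labels to CSV
#' @param gold data frame with `patient_id`, `ards`, `archetype`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  out <- gold
  out$ards <- ifelse(out$ards, "true", "false")
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read gold-standard labels written by [write_gold()]
#' @param path CSV path.
#' @return data frame with logical `ards`.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) stop("gold file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", na.strings = NULL)
  if (!all(c("patient_id", "ards") %in% names(df))) {
    stop("gold file must have patient_id and ards columns", call. = FALSE)
  }
  df$ards <- parse_bool(df$ards)
  df
}
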