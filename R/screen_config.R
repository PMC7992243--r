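#' Screening configuration
#'
#' Bundles every tunable threshold and window of the ARDS screen.  Defaults
#' encode the published algorithm: PEEP >= 5 cm H2O defines time zero,
#' PaO2/FiO2 <= 300 qualifies, vital-sign FiO2 is matched to a PaO2 within
#' +/- 15 minutes, the chest X-ray must fall within 12 hours of time zero,
#' ECG findings are queried within +/- 24 hours of time zero, ARDS risk
#' factors within +/- 72 hours of ICU admission, and patients with less than
#' 12 hours of invasive mechanical ventilation are excluded.
#'
#' @param peep_threshold minimum PEEP (cm H2O) defining time zero.
#' @param pf_threshold maximum qualifying PaO2/FiO2 ratio.  Raising it above
#'   300 leaves the Berlin definition and triggers a warning.
#' @param fio2_match_window minutes; half-width of the window used to match a
#'   vital-sign FiO2 to a PaO2 when the lab FiO2 is missing.
#' @param cxr_window hours; half-width of the chest X-ray window around time
#'   zero.
#' @param ecg_window hours; half-width of the ECG query window around time
#'   zero.
#' @param risk_factor_window hours; half-width of the risk-factor window
#'   around ICU admission.
#' @param min_vent_duration hours; minimum total invasive-ventilation
#'   duration (patients below it are excluded).
#' @param vent_gap_merge hours; charting gaps up to this length join two
#'   invasive ventilation records into one episode.
#' @param keyword_proximity tokens; maximum distance between "bilateral" and
#'   a qualifying finding token in a radiology sentence.
#' @return an object of class `screen_config` (a named list).
#' @examples
#' cfg <- screen_config()
#' cfg$pf_threshold
#' @export
screen_config <- function(peep_threshold = 5,
                          pf_threshold = 300,
                          fio2_match_window = 15,
                          cxr_window = 12,
                          ecg_window = 24,
                          risk_factor_window = 72,
                          min_vent_duration = 12,
                          vent_gap_merge = 1,
                          keyword_proximity = 3) {
  cfg <- list(
    peep_threshold = peep_threshold,
    pf_threshold = pf_threshold,
    fio2_match_window = fio2_match_window,
    cxr_window = cxr_window,
    ecg_window = ecg_window,
    risk_factor_window = risk_factor_window,
    min_vent_duration = min_vent_duration,
    vent_gap_merge = vent_gap_merge,
    keyword_proximity = keyword_proximity
  )
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("screen_config: '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (pf_threshold != 300) {
    warning("pf_threshold != 300 departs from the Berlin definition",
            call. = FALSE)
  }
  structure(cfg, class = "screen_config")
}

#' @export
print.screen_config <- function(x, ...) {
  cat("ARDS screen configuration:\n")
  units <- c(peep_threshold = "cm H2O", pf_threshold = "",
             fio2_match_window = "min", cxr_window = "h", ecg_window = "h",
             risk_factor_window = "h", min_vent_duration = "h",
             vent_gap_merge = "h", keyword_proximity = "tokens")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %-20s %g %s\n", nm, x[[nm]], units[[nm]]))
  }
  invisible(x)
}

as_screen_config <- function(x) {
  if (inherits(x, "screen_config")) return(x)
  if (is.null(x)) return(screen_config())
  do.call(screen_config, as.list(x)[names(x) %in% names(formals(screen_config))])
}
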