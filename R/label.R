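#' Band raw clinical readings into low-level context labels
#'
#' Raw blood glucose, blood pressure and water intake readings are mapped to
#' clinical low-level context labels by the banding tables in the
#' configuration. The printed glucose bands intentionally leave gaps
#' (exactly 70, 108--120, 180--215 and 280--314 mg/dL); readings falling in a
#' gap receive the sentinel `UnspecifiedBG` and are excluded from clinical
#' context fusion rather than forced into a neighbouring band. Blood
#' pressure is banded per component (systolic, diastolic) and the pair is
#' labeled with the more severe of the two component labels (severity order
#' LowBP < NormalBP < PreHypertension < HypertensionStageI <
#' HypertensionStageII); a pair whose two components both fall in printed
#' gaps gets `UnspecifiedBP`. Water intake is a strict three-way split
#' around the daily threshold (default 2000 mL, optional tolerance band of
#' width 0 by default).
#'
#' @param value Blood glucose in mg/dL (non-negative), or accumulated water
#'   intake in mL/day.
#' @param systolic,diastolic Blood pressure components in mmHg (positive).
#' @param config A `cf_config` object.
#' @return A character vector of labels.
#' @export
#' @examples
#' label_blood_glucose(c(315, 90, 50, 200))
#' label_blood_pressure(165, 102)
#' label_water_intake(c(1200, 2000, 2500))
label_blood_glucose <- function(value, config = load_config()) {
  if (any(value < 0, na.rm = TRUE)) abort("blood glucose must be non-negative")
  apply_bands(value, config$labeling$blood_glucose, sentinel = "UnspecifiedBG")
}

#' @rdname label_blood_glucose
#' @export
label_blood_pressure <- function(systolic, diastolic, config = load_config()) {
  if (any(c(systolic, diastolic) <= 0, na.rm = TRUE)) {
    abort("blood pressure components must be positive")
  }
  bands <- config$labeling$blood_pressure
  sys_lab <- apply_bands(systolic, bands$systolic, sentinel = NA_character_)
  dia_lab <- apply_bands(diastolic, bands$diastolic, sentinel = NA_character_)
  severity <- unlist(config$labeling$bp_severity_order)
  pick <- function(a, b) {
    if (is.na(a) && is.na(b)) {
      return("UnspecifiedBP")
    }
    ranks <- match(c(a, b), severity)
    c(a, b)[which.max(replace_na_num(ranks, -Inf))]
  }
  map2_chr_base(sys_lab, dia_lab, pick)
}

#' @rdname label_blood_glucose
#' @export
label_water_intake <- function(value, config = load_config()) {
  if (any(value < 0, na.rm = TRUE)) abort("water intake must be non-negative")
  thr <- config$labeling$water$threshold_ml
  tol <- config$labeling$water$tolerance_ml %||% 0
  dplyr::case_when(
    value > thr + tol ~ "OverHydration",
    value < thr - tol ~ "Dehydration",
    TRUE ~ "NormalIntake"
  )
}

replace_na_num <- function(x, by) {
  x[is.na(x)] <- by
  x
}

map2_chr_base <- function(x, y, f) {
  vapply(seq_along(x), function(i) f(x[[i]], y[[i]]), character(1))
}

# first band (in config order) containing the value; bounds are strict
# unless *_closed
apply_bands <- function(value, bands, sentinel) {
  out <- rep(sentinel, length(value))
  undecided <- !is.na(value)
  for (b in bands) {
    lo_ok <- if (is.null(b$lower)) {
      rep(TRUE, length(value))
    } else if (isTRUE(b$lower_closed)) value >= b$lower else value > b$lower
    hi_ok <- if (is.null(b$upper)) {
      rep(TRUE, length(value))
    } else if (isTRUE(b$upper_closed)) value <= b$upper else value < b$upper
    hit <- undecided & lo_ok & hi_ok
    out[hit] <- b$label
    undecided <- undecided & !hit
  }
  out
}

#' Label every raw clinical reading in an LLC log
#'
#' Non-clinical records pass through untouched; BloodGlucose, BloodPressure
#' and WaterIntake records with a raw reading get their `label` column
#' filled from the banding tables. Already-labeled clinical records keep
#' their label.
#'
#' @param records An LLC log tibble (see [llc_log()]).
#' @param config A `cf_config` object.
#' @return The LLC log with clinical labels filled in.
#' @export
label_readings <- function(records, config = load_config()) {
  records <- as_llc_log(records)
  bg <- which(records$category == "BloodGlucose" & is.na(records$label) &
    !is.na(records$value))
  if (length(bg) > 0) {
    records$label[bg] <- label_blood_glucose(records$value[bg], config)
  }
  bp <- which(records$category == "BloodPressure" & is.na(records$label) &
    !is.na(records$systolic) & !is.na(records$diastolic))
  if (length(bp) > 0) {
    records$label[bp] <- label_blood_pressure(
      records$systolic[bp], records$diastolic[bp], config
    )
  }
  wa <- which(records$category == "WaterIntake" & is.na(records$label) &
    !is.na(records$value))
  if (length(wa) > 0) {
    records$label[wa] <- label_water_intake(records$value[wa], config)
  }
  records
}
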