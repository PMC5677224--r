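#' Construct a low-level context (LLC) log
#'
#' The LLC log is the package's canonical event table: one row per timestamped
#' observation of a user. Categorical observations (Activity, Location,
#' Emotion, Food) carry a `label`; clinical observations (BloodGlucose,
#' BloodPressure, WaterIntake) carry a raw reading (`value` in mg/dL or mL,
#' or `systolic`/`diastolic` in mmHg) and may carry a label once banded.
#' Intervals are half-open `[start, end)` epoch seconds; instantaneous
#' readings have `end == start`.
#'
#' @param user_id Character, user identifiers.
#' @param category One of Activity, Location, Emotion, Food, BloodGlucose,
#'   BloodPressure, WaterIntake.
#' @param label Vocabulary term, or `NA` for unlabeled raw readings.
#' @param start,end Epoch seconds (half-open interval).
#' @param value Numeric reading (mg/dL for blood glucose, mL/day accumulated
#'   for water intake), or `NA`.
#' @param systolic,diastolic Blood pressure components in mmHg, or `NA`.
#' @return A tibble with the canonical LLC columns.
#' @export
#' @examples
#' llc_log(
#'   user_id = "u1", category = "Activity", label = "Eating",
#'   start = 0, end = 600
#' )
llc_log <- function(user_id = character(), category = character(),
                    label = NA_character_, start = numeric(), end = numeric(),
                    value = NA_real_, systolic = NA_real_,
                    diastolic = NA_real_) {
  tibble(
    user_id = as.character(user_id),
    category = as.character(category),
    label = as.character(label),
    value = as.numeric(value),
    systolic = as.numeric(systolic),
    diastolic = as.numeric(diastolic),
    start = as.numeric(start),
    end = as.numeric(end)
  )
}

llc_columns <- c(
  "user_id", "category", "label", "value", "systolic", "diastolic",
  "start", "end"
)

as_llc_log <- function(df) {
  for (col in llc_columns) {
    if (!col %in% names(df)) {
      df[[col]] <- if (col %in% c("user_id", "category", "label")) {
        NA_character_
      } else {
        NA_real_
      }
    }
  }
  as_tibble(df)[llc_columns]
}

#' Validate LLC records against the vocabulary
#'
#' Checks every record invariant and returns the violations instead of
#' raising: unknown category, label outside the category's vocabulary,
#' `end < start`, and clinical records carrying neither a raw value nor a
#' label.
#'
#' @param records An LLC log tibble (see [llc_log()]).
#' @param config A `cf_config` object.
#' @return A tibble of violations (`row`, `field`, `message`); zero rows when
#'   every record is clean.
#' @export
validate_llc <- function(records, config = load_config()) {
  records <- as_llc_log(records)
  cv <- category_vocab(config$vocabulary)
  out <- list()
  bad_cat <- which(!records$category %in% names(cv))
  if (length(bad_cat) > 0) {
    out <- c(out, list(tibble(
      row = bad_cat, field = "category",
      message = paste0("unknown category: ", records$category[bad_cat])
    )))
  }
  ok_cat <- setdiff(seq_len(nrow(records)), bad_cat)
  has_label <- ok_cat[!is.na(records$label[ok_cat])]
  bad_label <- has_label[map_lgl(has_label, function(i) {
    !records$label[i] %in% cv[[records$category[i]]]
  })]
  if (length(bad_label) > 0) {
    out <- c(out, list(tibble(
      row = bad_label, field = "label",
      message = paste0(
        "unknown ", tolower(records$category[bad_label]), " label: ",
        records$label[bad_label]
      )
    )))
  }
  neg <- which(!is.na(records$end) & !is.na(records$start) &
    records$end < records$start)
  if (length(neg) > 0) {
    out <- c(out, list(tibble(
      row = neg, field = "interval", message = "negative duration"
    )))
  }
  clinical <- c("BloodGlucose", "BloodPressure", "WaterIntake")
  bare <- which(records$category %in% clinical &
    is.na(records$label) & is.na(records$value) &
    is.na(records$systolic) & is.na(records$diastolic))
  if (length(bare) > 0) {
    out <- c(out, list(tibble(
      row = bare, field = "value",
      message = "clinical record carries neither raw value nor label"
    )))
  }
  if (length(out) == 0) {
    return(tibble(row = integer(), field = character(), message = character()))
  }
  arrange(list_rbind(out), row)
}

#' Read or write an LLC log
#'
#' Delimited text (CSV with header) and JSON-lines with the canonical column
#' names are supported interchangeably.
#'
#' @param path File path; `.jsonl`/`.ndjson` extensions select JSON-lines,
#'   anything else is read or written as CSV.
#' @param records An LLC log tibble.
#' @return `read_llc()` returns the LLC log tibble; `write_llc()` returns the
#'   path invisibly.
#' @export
read_llc <- function(path) {
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    df <- jsonlite::stream_in(file(path), verbose = FALSE)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
  }
  as_llc_log(df)
}

#' @rdname read_llc
#' @export
write_llc <- function(records, path) {
  records <- as_llc_log(records)
  if (grepl("\\.(jsonl|ndjson)$", path)) {
    con <- file(path, open = "w")
    on.exit(close(con))
    jsonlite::stream_out(records, con, verbose = FALSE)
  } else {
    write.csv(records, path, row.names = FALSE, na = "")
  }
  invisible(path)
}
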