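#' Verify candidate high-level context instances
#'
#' Syntactic checks (asserted labels belong to the property's vocabulary,
#' domain-mandatory properties are present) and semantic checks (no
#' assertion violates a property range) on unclassified instances. Failures
#' are reported, not raised.
#'
#' @param instances An instance tibble from [build_instances()].
#' @param config A `cf_config` object.
#' @return A tibble of inconsistencies (`instance_id`, `check`, `message`);
#'   zero rows when every instance is consistent.
#' @export
verify_hlc <- function(instances, config = load_config()) {
  pv <- property_vocab(config$vocabulary)
  cols <- c(
    hasActivity = "activity", hasLocation = "location",
    hasEmotion = "emotion", hasFood = "food",
    hasBloodGlucose = "blood_glucose", hasBloodPressure = "blood_pressure"
  )
  out <- list()
  for (prop in names(cols)) {
    vals <- instances[[cols[[prop]]]]
    bad <- which(!is.na(vals) & !vals %in% pv[[prop]])
    if (length(bad) > 0) {
      out <- c(out, list(tibble(
        instance_id = instances$instance_id[bad], check = "range",
        message = paste0(prop, " value outside its vocabulary: ", vals[bad])
      )))
    }
  }
  miss <- function(rows, prop) {
    tibble(
      instance_id = instances$instance_id[rows], check = "mandatory",
      message = paste0("mandatory property absent: ", prop)
    )
  }
  n_bad <- which(instances$domain == "N" & is.na(instances$food))
  if (length(n_bad) > 0) out <- c(out, list(miss(n_bad, "hasFood")))
  c_bad <- which(instances$domain == "C" & is.na(instances$blood_glucose) &
    is.na(instances$blood_pressure))
  if (length(c_bad) > 0) {
    out <- c(out, list(miss(c_bad, "hasBloodGlucose/hasBloodPressure")))
  }
  neg <- which(instances$end < instances$start)
  if (length(neg) > 0) {
    out <- c(out, list(tibble(
      instance_id = instances$instance_id[neg], check = "interval",
      message = "negative duration"
    )))
  }
  if (length(out) == 0) {
    return(tibble(
      instance_id = character(), check = character(), message = character()
    ))
  }
  list_rbind(out)
}

def_property_cols <- c(
  hasActivity = "activity", hasLocation = "location", hasEmotion = "emotion",
  hasFood = "food", hasBloodGlucose = "blood_glucose",
  hasBloodPressure = "blood_pressure"
)

# does each row satisfy one class definition?  Closure semantics: the
# asserted value is the complete value set of the property, so a universal
# restriction holds iff the asserted value (when present) is allowed, and an
# existential restriction holds iff the property is asserted with a witness.
definition_matches <- function(instances, def) {
  ok <- rep(instances$domain == def$domain, length.out = nrow(instances))
  for (prop in names(def$existential)) {
    v <- instances[[def_property_cols[[prop]]]]
    ok <- ok & !is.na(v) & v %in% def$existential[[prop]]
  }
  for (prop in names(def$universal)) {
    v <- instances[[def_property_cols[[prop]]]]
    ok <- ok & (is.na(v) | v %in% def$universal[[prop]])
  }
  ok
}

# why did the nearest definition of the domain reject this row?
unidentified_reason <- function(row, defs) {
  best <- NULL
  best_fail <- NULL
  for (def in defs) {
    if (def$domain != row$domain) next
    fail <- character()
    for (prop in names(def$existential)) {
      v <- row[[def_property_cols[[prop]]]]
      if (is.na(v)) {
        fail <- c(fail, paste0("missing:", prop))
      } else if (!v %in% def$existential[[prop]]) {
        fail <- c(fail, paste0("value:", prop))
      }
    }
    for (prop in names(def$universal)) {
      v <- row[[def_property_cols[[prop]]]]
      if (!is.na(v) && !v %in% def$universal[[prop]]) {
        fail <- c(fail, paste0("value:", prop))
      }
    }
    fail <- unique(fail)
    if (is.null(best) || length(fail) < length(best_fail)) {
      best <- def
      best_fail <- fail
    }
  }
  if (is.null(best) || length(best_fail) == 0) {
    return("no_matching_class")
  }
  missing <- grep("^missing:", best_fail, value = TRUE)
  if (length(missing) > 0) missing[[1]] else best_fail[[1]]
}

clinical_state <- function(bg, bp, clinical) {
  states <- unlist(clinical$severity_order)
  rank <- function(label, map) {
    s <- unlist(map)[label]
    ifelse(is.na(label) | is.na(s), NA_integer_, match(s, states))
  }
  r <- pmax(
    rank(bg, clinical$blood_glucose),
    rank(bp, clinical$blood_pressure),
    na.rm = TRUE
  )
  ifelse(is.finite(r), states[r], NA_character_)
}

#' Classify unclassified high-level context instances
#'
#' Physical-activity and nutrition instances are classified against the
#' configured class definitions: an instance is a member of a class iff every
#' mandatory existential restriction is witnessed by an asserted value and
#' every asserted value of a constrained property lies in the class's
#' universal allowed set. Closure is applied automatically at classification
#' time (each asserted value is treated as the complete value set of its
#' property), which reproduces per-instance world closure without a general
#' description-logic reasoner. Clinical instances are classified by the
#' severity mapping: each blood glucose / blood pressure label maps to a
#' health state and the more severe state wins.
#'
#' An instance matching no class gets the sentinel `Unidentified` together
#' with a `reason` code naming the missing mandatory property (or the
#' offending value) of the nearest class definition. Two sibling classes
#' matching the same instance signal an inconsistent definition set and
#' raise an error.
#'
#' @param instances An instance tibble from [build_instances()].
#' @param config A `cf_config` object.
#' @return The instances with `inferred_class` and `reason` columns added.
#' @export
#' @examples
#' cfg <- load_config()
#' inst <- tibble::tibble(
#'   instance_id = "ex", user_id = "Bob", domain = "N", group_id = "ex",
#'   activity = "Eating", location = "Restaurant", emotion = "Happiness",
#'   food = "FriedFood", blood_glucose = NA, blood_pressure = NA,
#'   start = 0, end = 1800, source_ids = list(1:4)
#' )
#' classify_hlc(inst, cfg)$inferred_class
classify_hlc <- function(instances, config = load_config()) {
  n <- nrow(instances)
  inferred <- rep(NA_character_, n)
  if (n == 0) {
    instances$inferred_class <- character()
    instances$reason <- character()
    return(instances)
  }
  defs <- config$classes
  match_count <- rep(0L, n)
  for (def in defs) {
    hit <- definition_matches(instances, def)
    clash <- hit & match_count > 0
    if (any(clash)) {
      abort(paste0(
        "inconsistent class definitions: instance ",
        instances$instance_id[which(clash)[1]], " matches both ",
        inferred[which(clash)[1]], " and ", def$name
      ))
    }
    inferred[hit] <- def$name
    match_count <- match_count + hit
  }
  cc <- which(instances$domain == "C")
  if (length(cc) > 0) {
    inferred[cc] <- clinical_state(
      instances$blood_glucose[cc], instances$blood_pressure[cc],
      config$clinical
    )
  }
  reason <- rep(NA_character_, n)
  unid <- which(is.na(inferred))
  for (i in unid) {
    reason[i] <- if (instances$domain[i] == "C") {
      "missing:hasBloodGlucose"
    } else {
      unidentified_reason(instances[i, ], defs)
    }
  }
  inferred[unid] <- "Unidentified"
  instances$inferred_class <- inferred
  instances$reason <- reason
  instances
}

#' Classify a stream and mark change-point notifications
#'
#' Every instance gets an inferred class; within each user and domain
#' (ordered by start time) an instance is marked for notification only when
#' its class differs from the user's previous class in that domain, so
#' downstream consumers are notified on change rather than on every
#' recognition.
#'
#' @param instances An instance tibble, time-ordered per user.
#' @param config A `cf_config` object.
#' @return The classified instances with a logical `notified` column.
#' @export
classify_stream <- function(instances, config = load_config()) {
  classified <- classify_hlc(instances, config)
  if (nrow(classified) == 0) {
    classified$notified <- logical()
    return(classified)
  }
  classified |>
    group_by(user_id, domain) |>
    arrange(start, instance_id, .by_group = TRUE) |>
    mutate(notified = inferred_class != lag(inferred_class, default = "")) |>
    ungroup() |>
    arrange(user_id, start, domain)
}
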