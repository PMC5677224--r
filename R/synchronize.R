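#' Group temporally concurrent LLC records
#'
#' Two records of one user are concurrent when their half-open intervals
#' overlap or their start times differ by at most the synchronization window
#' (default 15 s); instantaneous clinical readings are length-zero intervals,
#' so a reading strictly inside an activity interval, or within the window of
#' another start, joins that group. Grouping is the transitive closure of
#' the pairwise criterion, computed with a single sorted sweep per user.
#'
#' @param records An LLC log tibble; within each user, rows must be sorted by
#'   `start` (an error otherwise).
#' @param window Window length in seconds; defaults to the configured
#'   `engine$window_seconds`.
#' @param config A `cf_config` object.
#' @return The records with two added columns: `.id` (input row) and
#'   `group_id` (user-qualified concurrency group).
#' @export
#' @examples
#' log <- llc_log(
#'   user_id = "u1",
#'   category = c("Activity", "Location", "Emotion"),
#'   label = c("Eating", "Restaurant", "Happiness"),
#'   start = c(0, 5, 10), end = c(60, 60, 55)
#' )
#' synchronize(log)
synchronize <- function(records, window = NULL, config = load_config()) {
  window <- window %||% config$engine$window_seconds
  if (window <= 0) abort("window length must be positive")
  records <- as_llc_log(records)
  records$.id <- seq_len(nrow(records))
  if (nrow(records) == 0) {
    records$group_id <- character()
    return(records)
  }
  unsorted <- records |>
    group_by(user_id) |>
    summarise(bad = is.unsorted(start), .groups = "drop")
  if (any(unsorted$bad)) {
    abort(paste0(
      "records not sorted by start time for user(s): ",
      paste(unsorted$user_id[unsorted$bad], collapse = ", ")
    ))
  }
  records |>
    group_by(user_id) |>
    mutate(group_id = paste0(user_id, "/g", sweep_groups(start, end, window))) |>
    ungroup()
}

# sorted sweep: record j joins the open component iff it overlaps some member
# (start < max end seen) or starts within `window` of some member's start
# (start <= max start + window); equivalent to connected components of the
# pairwise relation because starts are non-decreasing
sweep_groups <- function(start, end, window) {
  n <- length(start)
  gid <- integer(n)
  g <- 0L
  reach_end <- -Inf
  reach_start <- -Inf
  for (i in seq_len(n)) {
    if (!(start[i] < reach_end || start[i] <= reach_start + window)) {
      g <- g + 1L
      reach_end <- -Inf
      reach_start <- -Inf
    }
    gid[i] <- g
    reach_end <- max(reach_end, end[i])
    reach_start <- max(reach_start, start[i])
  }
  gid
}

# within a group, keep one record per category: longest interval, ties broken
# by earliest start then input order
dedup_group <- function(group) {
  group |>
    mutate(.dur = end - start) |>
    arrange(category, desc(.dur), start, label, .id) |>
    distinct(category, .keep_all = TRUE) |>
    select(-".dur")
}

empty_instances <- function() {
  tibble(
    instance_id = character(), user_id = character(), domain = character(),
    group_id = character(),
    activity = character(), location = character(), emotion = character(),
    food = character(), blood_glucose = character(),
    blood_pressure = character(),
    start = numeric(), end = numeric(), source_ids = list()
  )
}

one_instance <- function(group, domain, members) {
  tibble(
    instance_id = paste0(group$group_id[1], "/", domain),
    user_id = group$user_id[1],
    domain = domain,
    group_id = group$group_id[1],
    activity = assertion_of(members, "Activity"),
    location = assertion_of(members, "Location"),
    emotion = assertion_of(members, "Emotion"),
    food = assertion_of(members, "Food"),
    blood_glucose = assertion_of(members, "BloodGlucose"),
    blood_pressure = assertion_of(members, "BloodPressure"),
    start = min(members$start),
    end = max(members$end),
    source_ids = list(members$.id)
  )
}

assertion_of <- function(members, category) {
  lab <- members$label[members$category == category]
  if (length(lab) == 0) NA_character_ else lab[[1]]
}

#' Instantiate candidate high-level contexts from a concurrency group
#'
#' One group of concurrent LLC records can seed up to three unclassified
#' high-level context instances, one per domain:
#' * physical activity (`instantiate_pa`): requires an Activity record;
#'   attaches `hasActivity` and, when present, `hasLocation`/`hasEmotion`;
#' * nutrition (`instantiate_n`): requires a Food record *and* an Activity
#'   record labeled Eating; attaches `hasFood` plus the physical-activity
#'   assertions;
#' * clinical (`instantiate_c`): requires at least one labeled BloodGlucose
#'   or BloodPressure record (gap sentinels excluded); water intake never
#'   triggers a clinical instance.
#'
#' When a group holds several records of one category, the longest-interval
#' record wins (ties: earliest start). Each instance's interval spans the
#' records that contribute its assertions.
#'
#' @param group A tibble of records from one synchronization group (as
#'   produced by [synchronize()]).
#' @return A one-row instance tibble, or `NULL` when the group does not
#'   qualify for the domain.
#' @export
instantiate_pa <- function(group) {
  members <- dedup_group(group) |>
    filter(category %in% c("Activity", "Location", "Emotion"))
  if (!"Activity" %in% members$category) {
    return(NULL)
  }
  one_instance(group, "PA", members)
}

#' @rdname instantiate_pa
#' @export
instantiate_n <- function(group) {
  members <- dedup_group(group) |>
    filter(category %in% c("Activity", "Location", "Emotion", "Food"))
  eating <- any(members$category == "Activity" & members$label == "Eating",
    na.rm = TRUE
  )
  if (!eating || !"Food" %in% members$category) {
    return(NULL)
  }
  one_instance(group, "N", members)
}

#' @rdname instantiate_pa
#' @export
instantiate_c <- function(group) {
  members <- dedup_group(group) |>
    filter(
      category %in% c("BloodGlucose", "BloodPressure"),
      !is.na(label),
      !label %in% c("UnspecifiedBG", "UnspecifiedBP")
    )
  if (nrow(members) == 0) {
    return(NULL)
  }
  one_instance(group, "C", members)
}

#' Build all candidate high-level context instances
#'
#' Runs the three domain instantiators over every synchronization group.
#'
#' @param records An LLC log tibble. When it lacks a `group_id` column it is
#'   passed through [synchronize()] first.
#' @param window,config Passed to [synchronize()].
#' @return An instance tibble (one row per candidate HLC) with the asserted
#'   labels, the interval, and `source_ids` referencing the contributing
#'   records.
#' @export
build_instances <- function(records, window = NULL, config = load_config()) {
  if (!"group_id" %in% names(records)) {
    records <- synchronize(records, window = window, config = config)
  }
  if (nrow(records) == 0) {
    return(empty_instances())
  }
  groups <- split(records, records$group_id)
  out <- map(groups, function(g) {
    list_rbind(keep(
      list(instantiate_pa(g), instantiate_n(g), instantiate_c(g)),
      ~ !is.null(.x)
    ))
  })
  out <- list_rbind(keep(out, ~ nrow(.x) > 0))
  if (nrow(out) == 0) {
    return(empty_instances())
  }
  arrange(out, user_id, start, domain)
}

#' Report LLC records consumed by no instance
#'
#' Every input record is either referenced by at least one instance or shows
#' up here, so nothing is silently dropped.
#'
#' @param records Synchronized records (with `.id`).
#' @param instances The instance tibble from [build_instances()].
#' @return The subset of `records` referenced by no instance.
#' @export
unconsumed_report <- function(records, instances) {
  used <- unique(unlist(instances$source_ids))
  filter(records, !.id %in% used)
}
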