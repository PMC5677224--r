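#' Temporal duration builtin
#'
#' @param start,end Epoch seconds, `end >= start`.
#' @param unit `"Hours"` or `"Days"`.
#' @return Numeric duration: hours are `(end - start) / 3600` exactly, days
#'   are `(end - start) / 86400`.
#' @export
#' @examples
#' temporal_duration(0, 7200, "Hours")
#' temporal_duration(0, 604800, "Days")
temporal_duration <- function(start, end, unit = c("Hours", "Days")) {
  unit <- match.arg(unit)
  if (any(end < start)) abort("end must be >= start")
  (end - start) / switch(unit,
    Hours = 3600,
    Days = 86400
  )
}

rule_prop_cols <- c(
  hasActivity = "activity", hasLocation = "location", hasEmotion = "emotion",
  hasFood = "food"
)

local_day <- function(t, tz_offset) floor((t + tz_offset) / 86400)

#' Evaluate one behavioral rule
#'
#' Executes a conjunctive temporal rule over the classified high-level
#' context history and the low-level context log, within a rolling window
#' ending at the evaluation time (default seven days, the configured
#' `horizontal_window_days`). The rule's pattern atoms bind context rows per
#' user, property atoms filter on assertions, per-row duration atoms filter
#' individual contexts, and aggregation atoms (weekly duration sum, distinct
#' calendar-day count, per-day group size) aggregate before the final
#' comparisons — mirroring the collection-then-aggregation phases of the
#' source query language. A rule with no matching context rows yields no
#' result (conjunctive-join semantics), so e.g. a user who never exercised is
#' not selected as sedentary.
#'
#' Day-level quantities (`?d`, `?no_of_days`, per-day grouping) count
#' distinct user-local calendar days touched by the matched contexts, which
#' is what makes "performed daily" (`equal(?no_of_days, 7)`) satisfiable on
#' real streams.
#'
#' @param rule One rule from the configuration (`config$rules[[i]]`).
#' @param facts A list with elements `hlc` (classified instance tibble from
#'   [classify_hlc()]) and `llc` (LLC log tibble).
#' @param at Evaluation time, epoch seconds; the window is
#'   `[at - 7 days, at)` on context start times.
#' @param config A `cf_config` object.
#' @param tz_offset Seconds to add before calendar-day grouping (per-user
#'   timezone handling; default UTC).
#' @return A tibble of behavioral contexts: `user_id`, `rule_id`, `behavior`,
#'   the evaluation window, the qualifying `day` (for per-day rules), and
#'   the bound values `hours`, `days`, `frequency`.
#' @export
evaluate_rule <- function(rule, facts, at, config = load_config(),
                          tz_offset = 0) {
  wdays <- config$engine$horizontal_window_days %||% 7
  w0 <- at - wdays * 86400

  pattern <- rule$atoms[[1]]
  rows <- if (identical(pattern$atom, "hlc")) {
    facts$hlc |> filter(inferred_class == pattern$class)
  } else if (identical(pattern$atom, "llc")) {
    facts$llc |>
      filter(category == pattern$category, label == pattern$label) |>
      mutate(instance_id = paste0("llc", row_number()))
  } else {
    abort("first rule atom must bind contexts (hlc or llc)")
  }
  rows <- rows |> filter(start >= w0, start < at)

  scope <- list() # var name -> "row" | "user" | "day"
  row_var <- list() # var name -> column name in rows
  user_sum_var <- NULL # var summed over matched rows (weekly total)
  count_days_var <- NULL
  per_day_var <- NULL
  comparisons <- list()

  for (a in rule$atoms[-1]) {
    switch(a$atom,
      property = {
        col <- rule_prop_cols[[a$property]]
        if (is.null(col)) abort(paste0("unknown builtin property ", a$property))
        rows <- rows |> filter(!is.na(.data[[col]]), .data[[col]] == a$equals)
      },
      duration = {
        dur <- temporal_duration(rows$start, rows$end, a$unit %||% "Hours")
        colname <- paste0(".v_", a$var)
        rows[[colname]] <- dur
        if (identical(a$aggregate %||% "none", "sum")) {
          scope[[a$var]] <- "user"
          user_sum_var <- a$var
        } else {
          scope[[a$var]] <- "row"
        }
        row_var[[a$var]] <- colname
      },
      countDays = {
        scope[[a$var]] <- "user"
        count_days_var <- a$var
      },
      perDayCount = {
        scope[[a$var]] <- "day"
        per_day_var <- a$var
      },
      lessThan = ,
      greaterThan = ,
      equal = {
        sc <- scope[[a$var]]
        if (is.null(sc)) abort(paste0("comparison on unbound variable ", a$var))
        if (sc == "row") {
          v <- rows[[row_var[[a$var]]]]
          keep <- switch(a$atom,
            lessThan = v < a$value,
            greaterThan = v > a$value,
            equal = v == a$value
          )
          rows <- rows[keep, , drop = FALSE]
        } else {
          comparisons <- c(comparisons, list(a))
        }
      },
      abort(paste0("unknown builtin ", a$atom))
    )
  }

  empty <- tibble(
    user_id = character(), rule_id = integer(), behavior = character(),
    window_start = numeric(), window_end = numeric(), day = numeric(),
    hours = numeric(), days = numeric(), frequency = numeric()
  )
  if (nrow(rows) == 0) {
    return(empty)
  }
  rows$.day <- local_day(rows$start, tz_offset)
  dur_col <- if (length(row_var) > 0) row_var[[length(row_var)]] else NULL

  test <- function(v, cmp) {
    switch(cmp$atom,
      lessThan = v < cmp$value,
      greaterThan = v > cmp$value,
      equal = v == cmp$value
    )
  }

  if (!is.null(per_day_var)) {
    out <- rows |>
      group_by(user_id, day = .day) |>
      summarise(
        frequency = n(),
        hours = if (is.null(dur_col)) NA_real_ else sum(.data[[dur_col]]),
        .groups = "drop"
      )
    for (cmp in comparisons) {
      v <- switch(scope[[cmp$var]],
        day = out$frequency,
        abort(paste0("unsupported mixed scope for ", cmp$var))
      )
      out <- out[test(v, cmp), , drop = FALSE]
    }
    out <- out |> mutate(days = NA_real_)
  } else {
    out <- rows |>
      group_by(user_id) |>
      summarise(
        hours = if (is.null(dur_col)) NA_real_ else sum(.data[[dur_col]]),
        days = as.numeric(n_distinct(.day)),
        .groups = "drop"
      )
    for (cmp in comparisons) {
      v <- if (!is.null(user_sum_var) && cmp$var == user_sum_var) {
        out$hours
      } else if (!is.null(count_days_var) && cmp$var == count_days_var) {
        out$days
      } else {
        abort(paste0("comparison on unknown user-scope variable ", cmp$var))
      }
      out <- out[test(v, cmp), , drop = FALSE]
    }
    out <- out |> mutate(day = NA_real_, frequency = NA_real_)
  }

  out |>
    mutate(
      rule_id = as.integer(rule$id), behavior = rule$name,
      window_start = w0, window_end = at
    ) |>
    select(
      user_id, rule_id, behavior, window_start, window_end, day,
      hours, days, frequency
    ) |>
    arrange(user_id, day)
}

#' Evaluate every configured behavioral rule
#'
#' @param facts A list with `hlc` (classified instances) and `llc` (LLC log).
#' @param at Evaluation time, epoch seconds.
#' @param config A `cf_config` object.
#' @param tz_offset Seconds added before calendar-day grouping.
#' @return A tibble of behavioral contexts ordered by rule id then user; a
#'   user may satisfy several rules and appears once per qualifying rule (and
#'   per qualifying day for per-day rules).
#' @export
run_all_rules <- function(facts, at, config = load_config(), tz_offset = 0) {
  out <- map(config$rules, evaluate_rule,
    facts = facts, at = at, config = config, tz_offset = tz_offset
  )
  list_rbind(out) |> arrange(rule_id, user_id, day)
}
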