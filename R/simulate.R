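#' User profile archetypes for the synthetic stream generator
#'
#' A profile fixes a user's daily schedule (ordered episodes of activity,
#' location and emotion), meal plan, clinical sampling times and value
#' distributions, and a per-category missingness rate. Six archetypes cover
#' the behavioral spectrum the rule engine distinguishes: `sedentary` (one
#' 1-hour gym walk per week), `lightly_active` (a daily 20-minute gym walk),
#' `moderately_active` (a daily 30-minute run), `very_active` (a daily
#' 2-hour run), `extremely_active` (two daily 90-minute gym sessions) and
#' `irregular_eater` (no exercise, five meals a day). Clinical values are
#' drawn from per-archetype normal distributions truncated to the interior
#' of a fixed clinical band, so an undegraded stream contains no unlabeled
#' gap readings.
#'
#' @param archetype One of the six archetype names.
#' @param user_id User identifier.
#' @param tz_offset Seconds added to epoch time before calendar-day grouping.
#' @return A `cf_profile` list.
#' @export
#' @examples
#' user_profile("sedentary", "u1")$archetype
user_profile <- function(archetype = c(
                           "sedentary", "lightly_active", "moderately_active",
                           "very_active", "extremely_active", "irregular_eater"
                         ),
                         user_id = "u1", tz_offset = 0) {
  archetype <- match.arg(archetype)
  # (mean, sd, clamp lo, clamp hi); clamp bounds sit strictly inside a
  # printed clinical band so the intended label is known by construction
  clin <- switch(archetype,
    sedentary = list(
      bg_am = c(240, 20, 216, 279), bg_pm = c(240, 20, 216, 279),
      bg_label = "HighBG",
      sys = c(150, 6, 141, 158), dia = c(94, 3, 91, 98),
      bp_label = "HypertensionStageI", water = c(1500, 200, 500, 1900)
    ),
    lightly_active = list(
      bg_am = c(150, 12, 121, 179), bg_pm = c(150, 12, 121, 179),
      bg_label = "BorderlineBG",
      sys = c(130, 4, 121, 138), dia = c(84, 2, 81, 88),
      bp_label = "PreHypertension", water = c(2200, 150, 2050, 2800)
    ),
    moderately_active = list(
      bg_am = c(90, 8, 71, 107), bg_pm = c(90, 8, 71, 107),
      bg_label = "NormalBG",
      sys = c(110, 6, 95, 120), dia = c(72, 4, 65, 80),
      bp_label = "NormalBP", water = c(2400, 150, 2050, 2900)
    ),
    very_active = list(
      bg_am = c(90, 8, 71, 107), bg_pm = c(90, 8, 71, 107),
      bg_label = "NormalBG",
      sys = c(108, 6, 95, 120), dia = c(70, 4, 65, 80),
      bp_label = "NormalBP", water = c(2600, 150, 2100, 3200)
    ),
    extremely_active = list(
      bg_am = c(62, 4, 52, 69), bg_pm = c(62, 4, 52, 69),
      bg_label = "LowBG",
      sys = c(105, 5, 95, 120), dia = c(68, 4, 65, 80),
      bp_label = "NormalBP", water = c(2800, 200, 2100, 3500)
    ),
    irregular_eater = list(
      bg_am = c(330, 15, 315, 380), bg_pm = c(330, 15, 315, 380),
      bg_label = "DangerouslyHighBG",
      sys = c(170, 8, 160, 190), dia = c(105, 4, 100, 115),
      bp_label = "HypertensionStageII", water = c(1400, 200, 500, 1900)
    )
  )
  structure(
    list(
      user_id = user_id, archetype = archetype, tz_offset = tz_offset,
      clinical = clin
    ),
    class = "cf_profile"
  )
}

# deterministic meal plans (food items cycle with the day index)
meal_foods <- list(
  breakfast = c(
    "Bread", "Milk", "BoiledEgg", "Oatmeal", "Yogurt", "Banana", "FriedEgg"
  ),
  lunch = c(
    "Rice", "FriedFood", "Chicken", "Pasta", "HamBurger", "Salmon", "Noodles"
  ),
  dinner = c("Beef", "Tofu", "Pizza", "Mackerel", "Chicken", "Rice", "Ham")
)

# one archetype's day plan: episodes (activity, location, emotion, offsets),
# meals (slot, offsets, location) and exercise sessions; offsets are seconds
# from local midnight, chosen so distinct groups are separated by more than
# the 15-s synchronization window
day_plan <- function(profile, day) {
  a <- profile$archetype
  ep <- function(activity, location, emotion, start, end, class) {
    tibble(
      activity = activity, location = location, emotion = emotion,
      start = start, end = end, class = class
    )
  }
  base <- list(
    ep("Sleeping", "Home", "Neutral", 0, 25200, "Sleeping"),
    ep("Act_InVehicle", "Outdoors", "Neutral", 35100, 36000, "Commuting"),
    ep("Working", "Office", "Boredom", 36300, 43200, "OfficeWork"),
    ep("Working", "Office", "Neutral", 46800, 61200, "OfficeWork"),
    ep("Cooking", "Home", "Neutral", 68700, 69900, "HouseWork"),
    ep("Gaming", "Home", "Happiness", 72600, 79200, "Amusement"),
    ep("LyingDown", "Home", "Boredom", 79500, 86100, "Inactivity")
  )
  exercise <- switch(a,
    sedentary = if (day == 3) {
      list(ep("Act_Walking", "Loc_Gym", "Neutral", 27600, 31200, "Exercising"))
    },
    lightly_active =
      list(ep("Act_Walking", "Loc_Gym", "Happiness", 27600, 28800, "Exercising")),
    moderately_active =
      list(ep("Act_Running", "Loc_Gym", "Happiness", 27600, 29400, "Exercising")),
    very_active =
      list(ep("Act_Running", "Outdoors", "Happiness", 27600, 34800, "Exercising")),
    extremely_active = list(
      ep("Act_Running", "Loc_Gym", "Happiness", 27600, 33000, "Exercising"),
      ep("Act_Stretching", "Loc_Gym", "Neutral", 63000, 68400, "Exercising")
    ),
    irregular_eater = NULL
  )
  f <- function(slot) meal_foods[[slot]][(day - 1) %% 7 + 1]
  meals <- list(
    list(food = f("breakfast"), location = "Home", start = 25800, end = 27000),
    list(food = f("lunch"), location = "Restaurant", start = 43800, end = 45600),
    list(food = f("dinner"), location = "Home", start = 70200, end = 72000)
  )
  if (a == "irregular_eater") {
    meals <- c(meals, list(
      list(food = "Apple", location = "Home", start = 28200, end = 28800),
      list(food = "Peanut", location = "Home", start = 63000, end = 63600)
    ))
  }
  list(
    episodes = c(base, exercise),
    meals = meals,
    clinical_times = c(am = 25320, pm = 72300),
    water_time = 75600
  )
}

rclamp <- function(n, spec) pmin(pmax(rnorm(n, spec[1], spec[2]), spec[3]), spec[4])

nutrient_class <- function(food, config) {
  for (def in config$classes) {
    if (def$domain == "N" && food %in% def$existential$hasFood) {
      return(def$name)
    }
  }
  NA_character_
}

#' Generate one user's synthetic LLC stream with ground truth
#'
#' Builds the user's multi-day event stream from the profile's schedule and
#' returns it together with construction-time ground truth: one high-level
#' context truth row per scheduled episode, meal and clinical sampling, and
#' behavioral truth computed by a direct tally over the schedule (independent
#' of the rule engine under test). Clinical records carry raw values only;
#' the pipeline's labeler bands them.
#'
#' @param profile A `cf_profile` from [user_profile()].
#' @param days Number of simulated days (>= 1).
#' @param seed Integer seed; fixed `(profile, days, seed)` is fully
#'   deterministic.
#' @param config A `cf_config` object.
#' @param t0 Epoch second of the first local midnight.
#' @return A list: `llc` (the raw LLC log, sorted per user by start),
#'   `truth_hlc` (`user_id`, `domain`, `truth_class`, `start`, `end`) and
#'   `truth_behavior` (same schema as [run_all_rules()] output).
#' @export
generate_user_stream <- function(profile, days, seed = 1,
                                 config = load_config(), t0 = 999993600) {
  if (!inherits(profile, "cf_profile")) abort("profile must be a cf_profile")
  if (days < 1) abort("days must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)

  u <- profile$user_id
  clin <- profile$clinical
  llc <- list()
  truth <- list()
  sessions <- list() # exercise tally input
  eating <- list() # meal tally input

  for (day in seq_len(days)) {
    off <- t0 + (day - 1) * 86400
    plan <- day_plan(profile, day)
    for (e in plan$episodes) {
      s <- off + e$start
      t <- off + e$end
      llc <- c(llc, list(llc_log(
        user_id = u, category = c("Activity", "Location", "Emotion"),
        label = c(e$activity, e$location, e$emotion), start = s, end = t
      )))
      truth <- c(truth, list(tibble(
        user_id = u, domain = "PA", truth_class = e$class, start = s, end = t
      )))
      if (e$class == "Exercising") {
        sessions <- c(sessions, list(tibble(
          day = local_day(s, profile$tz_offset),
          hours = (t - s) / 3600,
          activity = e$activity, location = e$location, start = s
        )))
      }
    }
    for (m in plan$meals) {
      s <- off + m$start
      t <- off + m$end
      llc <- c(llc, list(llc_log(
        user_id = u,
        category = c("Activity", "Location", "Emotion", "Food"),
        label = c("Eating", m$location, "Happiness", m$food),
        start = s, end = t
      )))
      truth <- c(truth, list(tibble(
        user_id = u, domain = c("PA", "N"),
        truth_class = c("Inactivity", nutrient_class(m$food, config)),
        start = s, end = t
      )))
      eating <- c(eating, list(tibble(
        day = local_day(s, profile$tz_offset), start = s
      )))
    }
    for (slot in c("am", "pm")) {
      ct <- off + plan$clinical_times[[slot]]
      bg <- rclamp(1, clin[[paste0("bg_", slot)]])
      sy <- rclamp(1, clin$sys)
      di <- rclamp(1, clin$dia)
      llc <- c(llc, list(
        llc_log(
          user_id = u, category = "BloodGlucose", value = bg,
          start = ct, end = ct
        ),
        llc_log(
          user_id = u, category = "BloodPressure", systolic = sy,
          diastolic = di, start = ct + 10, end = ct + 10
        )
      ))
      truth <- c(truth, list(tibble(
        user_id = u, domain = "C",
        truth_class = clinical_state(
          clin$bg_label, clin$bp_label, config$clinical
        ),
        start = ct, end = ct + 10
      )))
    }
    wt <- off + plan$water_time
    llc <- c(llc, list(llc_log(
      user_id = u, category = "WaterIntake", value = rclamp(1, clin$water),
      start = wt, end = wt
    )))
  }

  llc <- list_rbind(llc) |> arrange(start, category)
  truth_hlc <- list_rbind(truth) |> arrange(start, domain)
  at <- t0 + days * 86400
  truth_behavior <- tally_behavior(
    sessions = if (length(sessions)) list_rbind(sessions) else NULL,
    eating = if (length(eating)) list_rbind(eating) else NULL,
    user_id = u, at = at, config = config
  )
  list(llc = llc, truth_hlc = truth_hlc, truth_behavior = truth_behavior, at = at)
}

# direct schedule tally of the six behaviors; deliberately straight-line
# code, independent of the rule engine
tally_behavior <- function(sessions, eating, user_id, at,
                           config = load_config()) {
  w0 <- at - (config$engine$horizontal_window_days %||% 7) * 86400
  out <- list()
  row <- function(rule_id, behavior, day = NA_real_, hours = NA_real_,
                  days = NA_real_, frequency = NA_real_) {
    tibble(
      user_id = user_id, rule_id = as.integer(rule_id), behavior = behavior,
      window_start = w0, window_end = at, day = day, hours = hours,
      days = days, frequency = frequency
    )
  }
  ss <- if (is.null(sessions)) NULL else filter(sessions, start >= w0, start < at)
  ee <- if (is.null(eating)) NULL else filter(eating, start >= w0, start < at)

  if (!is.null(ss) && nrow(ss) > 0) {
    gym <- ss[ss$location == "Loc_Gym", ]
    if (nrow(gym) > 0 && sum(gym$hours) < 2 && length(unique(gym$day)) < 7) {
      out <- c(out, list(row(1, "Sedentary Behavior",
        hours = sum(gym$hours), days = length(unique(gym$day))
      )))
    }
    walk <- ss[ss$activity == "Act_Walking", ]
    if (nrow(walk) > 0 && sum(walk$hours) > 1 && sum(walk$hours) < 3 &&
      length(unique(walk$day)) == 7) {
      out <- c(out, list(row(2, "Lightly Active",
        hours = sum(walk$hours), days = 7
      )))
    }
    run <- ss[ss$activity == "Act_Running", ]
    if (nrow(run) > 0 && sum(run$hours) > 3 && sum(run$hours) < 5 &&
      length(unique(run$day)) == 7) {
      out <- c(out, list(row(3, "Moderately Active",
        hours = sum(run$hours), days = 7
      )))
    }
    q <- ss[ss$hours > 1 & ss$hours < 3, ]
    if (nrow(q) > 0 && length(unique(q$day)) == 7) {
      out <- c(out, list(row(4, "Very Active", hours = sum(q$hours), days = 7)))
    }
    if (nrow(q) > 0) {
      per_day <- table(q$day)
      for (d in names(per_day)[per_day == 2]) {
        out <- c(out, list(row(5, "Extremely Active",
          day = as.numeric(d),
          hours = sum(q$hours[q$day == as.numeric(d)]), frequency = 2
        )))
      }
    }
  }
  if (!is.null(ee) && nrow(ee) > 0) {
    per_day <- table(ee$day)
    for (d in names(per_day)[per_day > 2]) {
      out <- c(out, list(row(6, "Meal Frequency",
        day = as.numeric(d),
        frequency = as.numeric(per_day[[d]])
      )))
    }
  }
  if (length(out) == 0) {
    return(tibble(
      user_id = character(), rule_id = integer(), behavior = character(),
      window_start = numeric(), window_end = numeric(), day = numeric(),
      hours = numeric(), days = numeric(), frequency = numeric()
    ))
  }
  list_rbind(out) |> arrange(rule_id, user_id, day)
}

#' Randomly drop records from a stream
#'
#' Each record is dropped independently with probability `rate`,
#' deterministically for a fixed seed — the degradation used to study how
#' missing low-level contexts produce unidentified high-level contexts.
#'
#' @param records An LLC log tibble.
#' @param rate Drop probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return The degraded LLC log.
#' @export
inject_missingness <- function(records, rate, seed = 1) {
  if (rate < 0 || rate > 1) abort("rate must be in [0, 1]")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  keep <- runif(nrow(records)) >= rate
  records[keep, , drop = FALSE]
}

#' Generate a multi-user synthetic cohort
#'
#' Users cycle through the six archetypes; each user's stream is generated
#' with a distinct sub-seed derived from the master seed.
#'
#' @param n_users Number of users (>= 1).
#' @param days Days per user.
#' @param seed Master seed.
#' @param missingness Drop probability applied to the combined stream
#'   (0 = clean).
#' @param config A `cf_config` object.
#' @return A list: `llc` (combined log, possibly degraded), `clean_llc`,
#'   `truth_hlc`, `truth_behavior`, `profiles`, and the evaluation time `at`.
#' @export
#' @examples
#' cohort <- generate_cohort(3, 2, seed = 7)
#' dplyr::count(cohort$llc, category)
generate_cohort <- function(n_users, days, seed = 1, missingness = 0,
                            config = load_config()) {
  if (n_users < 1) abort("n_users must be >= 1")
  archetypes <- c(
    "sedentary", "lightly_active", "moderately_active",
    "very_active", "extremely_active", "irregular_eater"
  )
  profiles <- map(seq_len(n_users), function(i) {
    user_profile(archetypes[(i - 1) %% length(archetypes) + 1],
      user_id = sprintf("u%02d", i)
    )
  })
  streams <- imap(profiles, function(p, i) {
    sub_seed <- (abs(seed) * 10007 + i * 7919) %% 2147483647
    generate_user_stream(p, days, seed = sub_seed, config = config)
  })
  clean <- list_rbind(map(streams, "llc"))
  degraded <- if (missingness > 0) {
    inject_missingness(clean, missingness, seed = (abs(seed) + 13) %% 2147483647)
  } else {
    clean
  }
  list(
    llc = degraded,
    clean_llc = clean,
    truth_hlc = list_rbind(map(streams, "truth_hlc")),
    truth_behavior = list_rbind(map(streams, "truth_behavior")),
    profiles = profiles,
    at = streams[[1]]$at
  )
}
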