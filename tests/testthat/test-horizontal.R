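cfg <- load_config()
rule <- function(id) cfg$rules[[id]]
AT <- 999993600 + 7 * 86400

hlc_row <- function(user, class, activity, location, start, hours) {
  tibble::tibble(
    instance_id = paste0(user, "_", start), user_id = user, domain = "PA",
    inferred_class = class, activity = activity, location = location,
    start = start, end = start + hours * 3600
  )
}
no_llc <- tibble::tibble(
  user_id = character(), category = character(), label = character(),
  start = numeric(), end = numeric()
)

test_that("duration builtin is exact in hours and days", {
  expect_equal(temporal_duration(0, 7200, "Hours"), 2.0)
  expect_equal(temporal_duration(0, 0, "Days"), 0.0)
  expect_equal(temporal_duration(0, 604800, "Days"), 7.0)
  expect_error(temporal_duration(10, 0, "Hours"), ">=")
})

test_that("a single short gym session selects the user as sedentary", {
  facts <- list(
    hlc = hlc_row("u1", "Exercising", "Act_Running", "Loc_Gym", AT - 3 * 86400, 1.5),
    llc = no_llc
  )
  out <- evaluate_rule(rule(1), facts, AT, cfg)
  expect_equal(out$user_id, "u1")
  expect_equal(out$hours, 1.5)
  expect_equal(out$days, 1)

  # three hours of weekly exercising fails lessThan(h, 2)
  facts3 <- list(
    hlc = hlc_row("u1", "Exercising", "Act_Running", "Loc_Gym", AT - 3 * 86400, 3),
    llc = no_llc
  )
  expect_equal(nrow(evaluate_rule(rule(1), facts3, AT, cfg)), 0)

  # no exercising contexts at all -> no binding -> no result
  expect_equal(nrow(evaluate_rule(rule(1), list(hlc = hlc_row(
    "u1", "OfficeWork", "Working", "Office", AT - 86400, 8
  ), llc = no_llc), AT, cfg)), 0)
})

test_that("daily walking and running select lightly/moderately active over a full week", {
  walk <- do.call(rbind, lapply(0:6, function(d) {
    hlc_row("u2", "Exercising", "Act_Walking", "Loc_Gym", AT - (d + 1) * 86400 + 27600, 1 / 3)
  }))
  out <- evaluate_rule(rule(2), list(hlc = walk, llc = no_llc), AT, cfg)
  expect_equal(out$user_id, "u2")
  expect_equal(out$hours, 7 / 3)
  expect_equal(out$days, 7)
  # six days only -> equal(d, 7) fails
  expect_equal(
    nrow(evaluate_rule(rule(2), list(hlc = walk[-1, ], llc = no_llc), AT, cfg)), 0
  )

  run <- do.call(rbind, lapply(0:6, function(d) {
    hlc_row("u3", "Exercising", "Act_Running", "Outdoors", AT - (d + 1) * 86400 + 27600, 0.5)
  }))
  out3 <- evaluate_rule(rule(3), list(hlc = run, llc = no_llc), AT, cfg)
  expect_equal(out3$hours, 3.5)
})

test_that("two-hour daily sessions select very active with no_of_days = 7", {
  daily <- do.call(rbind, lapply(0:6, function(d) {
    hlc_row("u4", "Exercising", "Act_Running", "Outdoors", AT - (d + 1) * 86400 + 27600, 2)
  }))
  out <- evaluate_rule(rule(4), list(hlc = daily, llc = no_llc), AT, cfg)
  expect_equal(out$user_id, "u4")
  expect_equal(out$days, 7)
  expect_equal(out$hours, 14)
})

test_that("twice-daily sessions report each qualifying day as extremely active", {
  twice <- do.call(rbind, lapply(0:6, function(d) {
    rbind(
      hlc_row("u5", "Exercising", "Act_Running", "Loc_Gym", AT - (d + 1) * 86400 + 27600, 1.5),
      hlc_row("u5", "Exercising", "Act_Stretching", "Loc_Gym", AT - (d + 1) * 86400 + 63000, 1.5)
    )
  }))
  out <- evaluate_rule(rule(5), list(hlc = twice, llc = no_llc), AT, cfg)
  expect_equal(nrow(out), 7)
  expect_equal(unique(out$frequency), 2)
  expect_equal(unique(out$hours), 3)
})

test_that("four daily meals select the user with frequency 4", {
  meals <- tibble::tibble(
    user_id = "u6", category = "Activity", label = "Eating",
    start = AT - 86400 + c(25800, 43800, 63000, 70200),
    end = AT - 86400 + c(27000, 45600, 63600, 72000)
  )
  out <- evaluate_rule(rule(6), list(hlc = hlc_row(
    "u6", "OfficeWork", "Working", "Office", AT - 86400, 1
  )[0, ], llc = meals), AT, cfg)
  expect_equal(out$frequency, 4)

  # two meals a day does not qualify
  out2 <- evaluate_rule(rule(6), list(hlc = NULL, llc = meals[1:2, ]), AT, cfg)
  expect_equal(nrow(out2), 0)
})

test_that("run_all_rules is deterministic, handles empty facts, and reports multi-rule users", {
  empty <- list(hlc = hlc_row("x", "Exercising", "Act_Running", "Loc_Gym", 0, 1)[0, ], llc = no_llc)
  expect_equal(nrow(run_all_rules(empty, AT, cfg)), 0)

  twice <- do.call(rbind, lapply(0:6, function(d) {
    rbind(
      hlc_row("u5", "Exercising", "Act_Running", "Loc_Gym", AT - (d + 1) * 86400 + 27600, 1.5),
      hlc_row("u5", "Exercising", "Act_Stretching", "Loc_Gym", AT - (d + 1) * 86400 + 63000, 1.5)
    )
  }))
  out <- run_all_rules(list(hlc = twice, llc = no_llc), AT, cfg)
  # qualifies for Very Active (rule 4) and Extremely Active (rule 5, per day)
  expect_setequal(unique(out$rule_id), c(4L, 5L))
  expect_equal(sum(out$rule_id == 5), 7)
})

test_that("rule evaluation matches the nested-loop join oracle on random fact bases", {
  for (seed in 1:30) {
    fb <- random_factbase(seed, AT)
    expect_rule_match(
      evaluate_rule(rule(1), fb, AT, cfg), oracle_rule1(fb$hlc, AT),
      c("user_id", "hours", "days")
    )
    expect_rule_match(
      evaluate_rule(rule(2), fb, AT, cfg),
      oracle_rule23(fb$hlc, AT, "Act_Walking", 1, 3),
      c("user_id", "hours", "days")
    )
    expect_rule_match(
      evaluate_rule(rule(4), fb, AT, cfg), oracle_rule4(fb$hlc, AT),
      c("user_id", "hours", "days")
    )
    expect_rule_match(
      evaluate_rule(rule(5), fb, AT, cfg), oracle_rule5(fb$hlc, AT),
      c("user_id", "day", "hours", "frequency")
    )
    expect_rule_match(
      evaluate_rule(rule(6), fb, AT, cfg), oracle_rule6(fb$llc, AT),
      c("user_id", "day", "frequency")
    )
  }
})

test_that("shuffling facts never changes rule results", {
  fb <- random_factbase(99, AT)
  base <- run_all_rules(fb, AT, cfg)
  set.seed(1)
  shuffled <- list(
    hlc = fb$hlc[sample(nrow(fb$hlc)), ],
    llc = fb$llc[sample(nrow(fb$llc)), ]
  )
  expect_equal(run_all_rules(shuffled, AT, cfg), base)
})

test_that("adding exercise can only remove an already-selected user from the sedentary rule", {
  # for a user already selected, extra exercise grows the weekly total and
  # the day count, so the selection can only be lost, never re-gained
  set.seed(42)
  checked <- 0
  for (i in 1:40) {
    fb <- random_factbase(i + 400, AT)
    before <- evaluate_rule(rule(1), fb, AT, cfg)$user_id
    if (length(before) == 0) next
    extra <- hlc_row(
      sample(before, 1), "Exercising", "Act_Running",
      "Loc_Gym", AT - sample(1:6, 1) * 86400, runif(1, 0.2, 3)
    )
    fb$hlc <- rbind(fb$hlc, extra)
    after <- evaluate_rule(rule(1), fb, AT, cfg)$user_id
    expect_true(all(after %in% before))
    checked <- checked + 1
  }
  expect_gt(checked, 5)
})
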