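cfg <- load_config()

sync_ids <- function(records, window = 15) {
  synchronize(records, window = window, config = cfg)$group_id
}

test_that("overlapping and window-close records group; distant ones do not", {
  overlapping <- llc_log(
    user_id = "u1", category = c("Activity", "Location", "Emotion"),
    label = c("Eating", "Restaurant", "Happiness"),
    start = c(0, 5, 10), end = c(60, 60, 55)
  )
  expect_length(unique(sync_ids(overlapping)), 1)

  distant <- llc_log(
    user_id = "u1", category = c("Activity", "Location"),
    label = c("Sleeping", "Home"), start = c(0, 100), end = c(10, 120)
  )
  expect_length(unique(sync_ids(distant)), 2)

  # transitive closure: 0 -> 10 -> 20 chain under a 15-s window
  chain <- llc_log(
    user_id = "u1", category = c("Activity", "Location", "Emotion"),
    label = c("Working", "Office", "Neutral"),
    start = c(0, 10, 20), end = c(1, 11, 21)
  )
  expect_length(unique(sync_ids(chain)), 1)
})

test_that("grouping equals the all-pairs transitive-closure oracle", {
  set.seed(301)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    start <- sort(runif(n, 0, 3600))
    dur <- ifelse(runif(n) < 0.3, 0, runif(n, 0, 400))
    recs <- llc_log(
      user_id = "u1", category = "Activity", label = "Working",
      start = start, end = start + dur
    )
    got <- synchronize(recs, window = 15, config = cfg)$group_id
    want <- oracle_sync_components(start, start + dur, 15)
    # same partition: groups induce identical co-membership
    expect_equal(
      outer(got, got, "=="), outer(want, want, "=="),
      label = paste("replicate", rep)
    )
  }
})

test_that("unsorted input is rejected and equal-timestamp permutations are stable", {
  unsorted <- llc_log(
    user_id = "u1", category = c("Activity", "Location"),
    label = c("Working", "Office"), start = c(100, 0), end = c(200, 50)
  )
  expect_error(synchronize(unsorted, config = cfg), "not sorted")

  tied <- llc_log(
    user_id = "u1", category = c("Activity", "Location", "Emotion"),
    label = c("Working", "Office", "Neutral"),
    start = 0, end = c(600, 300, 600)
  )
  a <- build_instances(tied, config = cfg) |> dplyr::select(-source_ids)
  b <- build_instances(tied[c(3, 1, 2), ], config = cfg) |>
    dplyr::select(-source_ids)
  expect_equal(a, b)
})

test_that("physical-activity instantiation needs an Activity record", {
  with_act <- llc_log(
    user_id = "u1", category = c("Activity", "Location"),
    label = c("Sleeping", "Home"), start = 0, end = 28800
  ) |> synchronize(config = cfg)
  inst <- instantiate_pa(with_act)
  expect_equal(inst$activity, "Sleeping")
  expect_equal(inst$location, "Home")
  expect_true(is.na(inst$emotion))

  loc_only <- llc_log("u1", "Location", "Home", start = 0, end = 600) |>
    synchronize(config = cfg)
  expect_null(instantiate_pa(loc_only))

  meal <- llc_log(
    user_id = "u1", category = c("Activity", "Location", "Emotion"),
    label = c("Eating", "Restaurant", "Happiness"), start = 0, end = 1800
  ) |> synchronize(config = cfg)
  expect_equal(instantiate_pa(meal)$domain, "PA")
})

test_that("nutrition instantiation needs Food plus an Eating activity", {
  full <- llc_log(
    user_id = "u1",
    category = c("Activity", "Food", "Location", "Emotion"),
    label = c("Eating", "FriedFood", "Restaurant", "Happiness"),
    start = 0, end = 1800
  ) |> synchronize(config = cfg)
  inst <- instantiate_n(full)
  expect_equal(inst$domain, "N")
  expect_equal(inst$food, "FriedFood")
  expect_equal(
    sum(!is.na(c(inst$activity, inst$location, inst$emotion, inst$food))), 4
  )

  no_eating <- llc_log(
    user_id = "u1", category = c("Activity", "Food"),
    label = c("Working", "Rice"), start = 0, end = 600
  ) |> synchronize(config = cfg)
  expect_null(instantiate_n(no_eating))

  no_food <- llc_log("u1", "Activity", "Eating", start = 0, end = 600) |>
    synchronize(config = cfg)
  expect_null(instantiate_n(no_food))
})

test_that("clinical instantiation excludes gap sentinels and water intake", {
  both <- llc_log(
    user_id = "u1", category = c("BloodGlucose", "BloodPressure"),
    label = c("DangerouslyHighBG", "HypertensionStageII"),
    start = c(0, 10), end = c(0, 10)
  ) |> synchronize(config = cfg)
  inst <- instantiate_c(both)
  expect_equal(inst$blood_glucose, "DangerouslyHighBG")
  expect_equal(inst$blood_pressure, "HypertensionStageII")

  sentinel <- llc_log("u1", "BloodGlucose", "UnspecifiedBG", start = 0, end = 0) |>
    synchronize(config = cfg)
  expect_null(instantiate_c(sentinel))

  water <- llc_log("u1", "WaterIntake", "Dehydration", start = 0, end = 0) |>
    synchronize(config = cfg)
  expect_null(instantiate_c(water))
})

test_that("no record is silently dropped and instances obey the window criterion", {
  cohort <- generate_cohort(2, 2, seed = 5, config = cfg)
  labeled <- label_readings(cohort$llc, cfg)
  synced <- synchronize(labeled, config = cfg)
  inst <- build_instances(synced, config = cfg)
  used <- unique(unlist(inst$source_ids))
  unconsumed <- unconsumed_report(synced, inst)
  expect_setequal(c(used, unconsumed$.id), synced$.id)
  # every instance's sources pairwise satisfy the criterion (all-pairs check)
  for (i in sample(nrow(inst), min(nrow(inst), 40))) {
    src <- synced[synced$.id %in% inst$source_ids[[i]], ]
    comp <- oracle_sync_components(src$start, src$end, 15)
    expect_length(unique(comp), 1)
  }
})
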