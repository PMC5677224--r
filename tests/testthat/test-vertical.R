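cfg <- load_config()

test_that("verification reports missing mandatory properties and range violations", {
  ok <- make_instance("N",
    activity = "Eating", location = "Restaurant",
    emotion = "Happiness", food = "FriedFood"
  )
  expect_equal(nrow(verify_hlc(ok, cfg)), 0)

  no_food <- make_instance("N", activity = "Eating", location = "Home")
  v <- verify_hlc(no_food, cfg)
  expect_true(any(grepl("mandatory property absent: hasFood", v$message)))

  wrong_range <- make_instance("N",
    activity = "Eating", location = "Home",
    food = "Restaurant" # a Location term asserted as hasFood
  )
  v2 <- verify_hlc(wrong_range, cfg)
  expect_true(any(v2$check == "range" & grepl("hasFood", v2$message)))
})

test_that("worked examples classify to the expected classes", {
  fats <- make_instance("N",
    activity = "Eating", emotion = "Happiness",
    food = "FriedFood", location = "Restaurant"
  )
  expect_equal(classify_hlc(fats, cfg)$inferred_class, "Fats")

  carbs <- make_instance("N",
    activity = "Eating", emotion = "Neutral",
    food = "Rice", location = "Home"
  )
  expect_equal(classify_hlc(carbs, cfg)$inferred_class, "Carbohydrates")

  gym_meal <- make_instance("N",
    activity = "Eating", food = "FriedFood",
    location = "Loc_Gym"
  )
  expect_equal(classify_hlc(gym_meal, cfg)$inferred_class, "Unidentified")

  clinical <- make_instance("C", bg = "DangerouslyHighBG")
  expect_equal(classify_hlc(clinical, cfg)$inferred_class, "VeryHighRiskHealthState")

  # severity-max when both clinical properties are present
  mixed <- make_instance("C", bg = "NormalBG", bp = "HypertensionStageI")
  expect_equal(classify_hlc(mixed, cfg)$inferred_class, "HighRiskHealthState")
})

test_that("removing any mandatory assertion yields Unidentified with a reason", {
  full <- make_instance("N",
    activity = "Eating", emotion = "Happiness",
    food = "FriedFood", location = "Restaurant"
  )
  expect_equal(classify_hlc(full, cfg)$inferred_class, "Fats")
  for (col in c("activity", "location", "food")) {
    broken <- full
    broken[[col]] <- NA_character_
    out <- classify_hlc(broken, cfg)
    expect_equal(out$inferred_class, "Unidentified", label = col)
    expect_match(out$reason, "^missing:", label = col)
  }
  # the reason names the missing property
  no_loc <- full
  no_loc$location <- NA_character_
  expect_equal(classify_hlc(no_loc, cfg)$reason, "missing:hasLocation")
})

test_that("classification agrees with the axiom-by-axiom oracle and stays disjoint", {
  inst <- random_instances(3000, seed = 77, cfg = cfg)
  got <- classify_hlc(inst, cfg)$inferred_class
  want <- vapply(
    seq_len(nrow(inst)),
    function(i) oracle_classify_one(inst[i, ], cfg$classes),
    character(1)
  )
  expect_equal(got, want)
})

test_that("classification is order-independent across the definition list", {
  inst <- random_instances(400, seed = 5, cfg = cfg)
  shuffled <- cfg
  shuffled$classes <- cfg$classes[sample(length(cfg$classes))]
  expect_equal(
    classify_hlc(inst, cfg)$inferred_class,
    classify_hlc(inst, shuffled)$inferred_class
  )
})

test_that("ambiguous sibling definitions raise a configuration error", {
  broken <- cfg
  # make two PA classes both claim the Sleeping activity without disjointness
  broken$classes[[1]]$existential$hasActivity <- "Sleeping"
  broken$classes[[1]]$existential$hasLocation <- "Home"
  broken$classes[[1]]$universal <- list()
  inst <- make_instance("PA", activity = "Sleeping", location = "Home")
  expect_error(classify_hlc(inst, broken), "matches both")
})

test_that("stream classification notifies only on class changes", {
  mk <- function(classes) {
    n <- length(classes)
    tibble::tibble(
      instance_id = sprintf("i%04d", seq_len(n)), user_id = "u1",
      domain = "PA", group_id = sprintf("g%04d", seq_len(n)),
      activity = c(
        Sleeping = "Sleeping", OfficeWork = "Working",
        Exercising = "Act_Running"
      )[classes],
      location = c(
        Sleeping = "Home", OfficeWork = "Office",
        Exercising = "Loc_Gym"
      )[classes],
      emotion = NA_character_, food = NA_character_,
      blood_glucose = NA_character_, blood_pressure = NA_character_,
      start = seq_len(n) * 1000, end = seq_len(n) * 1000 + 500,
      source_ids = as.list(seq_len(n))
    )
  }
  out <- classify_stream(mk(c("Sleeping", "Sleeping", "OfficeWork")), cfg)
  expect_equal(sum(out$notified), 2)

  same <- classify_stream(mk(rep("Sleeping", 25)), cfg)
  expect_equal(sum(same$notified), 1)

  set.seed(123)
  seq3 <- sample(c("Sleeping", "OfficeWork", "Exercising"), 1000, replace = TRUE)
  stream <- classify_stream(mk(seq3), cfg)
  expect_equal(stream$inferred_class, unname(c(
    Sleeping = "Sleeping", OfficeWork = "OfficeWork", Exercising = "Exercising"
  )[seq3]))
  # brute-force change-point scan
  expect_equal(sum(stream$notified), 1 + sum(seq3[-1] != seq3[-1000]))
  expect_lte(sum(stream$notified), nrow(stream))
})
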