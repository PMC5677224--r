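# Independent oracles used across the suite.  Each one recomputes the
# quantity under test by the most literal route available (printed
# inequalities, all-pairs closure, axiom-by-axiom loops, nested-loop joins)
# and deliberately shares no code with the package internals.

# --- clinical banding: the printed inequalities, tested one by one ---------

oracle_bg <- function(v) {
  if (v >= 315) return("DangerouslyHighBG")
  if (v > 215 && v < 280) return("HighBG")
  if (v > 120 && v < 180) return("BorderlineBG")
  if (v > 70 && v < 108) return("NormalBG")
  if (v > 50 && v < 70) return("LowBG")
  if (v <= 50) return("DangerouslyLowBG")
  "UnspecifiedBG"
}

oracle_bp_component <- function(v, which) {
  if (which == "sys") {
    if (v >= 160) return("HypertensionStageII")
    if (v > 140 && v < 159) return("HypertensionStageI")
    if (v > 120 && v < 139) return("PreHypertension")
    if (v < 90) return("LowBP")
    if (v <= 120) return("NormalBP")
  } else {
    if (v >= 100) return("HypertensionStageII")
    if (v > 90 && v < 99) return("HypertensionStageI")
    if (v > 80 && v < 89) return("PreHypertension")
    if (v < 60) return("LowBP")
    if (v <= 80) return("NormalBP")
  }
  NA_character_
}

bp_severity <- c(
  LowBP = 1, NormalBP = 2, PreHypertension = 3,
  HypertensionStageI = 4, HypertensionStageII = 5
)

oracle_bp <- function(s, d) {
  a <- oracle_bp_component(s, "sys")
  b <- oracle_bp_component(d, "dia")
  if (is.na(a) && is.na(b)) return("UnspecifiedBP")
  if (is.na(a)) return(b)
  if (is.na(b)) return(a)
  if (bp_severity[[a]] >= bp_severity[[b]]) a else b
}

# --- synchronizer: all-pairs concurrency + transitive closure --------------

oracle_sync_components <- function(start, end, window) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      concurrent <- (start[i] < end[j] && start[j] < end[i]) ||
        abs(start[i] - start[j]) <= window
      if (concurrent) {
        ri <- find(i)
        rj <- find(j)
        parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# --- classifier: literal axiom-by-axiom evaluation -------------------------

inst_col <- c(
  hasActivity = "activity", hasLocation = "location",
  hasEmotion = "emotion", hasFood = "food",
  hasBloodGlucose = "blood_glucose", hasBloodPressure = "blood_pressure"
)

# clinical severity lookup, written out from the package's documented
# default mapping
oracle_c_state <- function(bg, bp) {
  state_rank <- c(
    NormalHealthState = 1, ModerateHealthState = 2,
    HighRiskHealthState = 3, VeryHighRiskHealthState = 4
  )
  bg_map <- c(
    NormalBG = "NormalHealthState", LowBG = "ModerateHealthState",
    BorderlineBG = "ModerateHealthState", HighBG = "HighRiskHealthState",
    DangerouslyLowBG = "VeryHighRiskHealthState",
    DangerouslyHighBG = "VeryHighRiskHealthState"
  )
  bp_map <- c(
    NormalBP = "NormalHealthState", LowBP = "ModerateHealthState",
    PreHypertension = "ModerateHealthState",
    HypertensionStageI = "HighRiskHealthState",
    HypertensionStageII = "VeryHighRiskHealthState"
  )
  states <- c(
    if (!is.na(bg)) bg_map[[bg]] else NULL,
    if (!is.na(bp)) bp_map[[bp]] else NULL
  )
  if (length(states) == 0) return("Unidentified")
  states[[which.max(state_rank[states])]]
}

oracle_classify_one <- function(row, defs) {
  if (row$domain == "C") {
    return(oracle_c_state(row$blood_glucose, row$blood_pressure))
  }
  matches <- character()
  for (def in defs) {
    if (def$domain != row$domain) next
    ok <- TRUE
    for (prop in names(def$existential)) {
      v <- row[[inst_col[[prop]]]]
      if (is.na(v) || !(v %in% def$existential[[prop]])) ok <- FALSE
    }
    for (prop in names(def$universal)) {
      v <- row[[inst_col[[prop]]]]
      if (!is.na(v) && !(v %in% def$universal[[prop]])) ok <- FALSE
    }
    if (ok) matches <- c(matches, def$name)
  }
  if (length(matches) > 1) stop("disjointness violated: ", paste(matches, collapse = "/"))
  if (length(matches) == 0) "Unidentified" else matches
}

random_instances <- function(n, seed, cfg) {
  set.seed(seed)
  voc <- cfg$vocabulary
  maybe <- function(pool, p_na = 0.25) {
    out <- sample(unlist(pool), n, replace = TRUE)
    out[runif(n) < p_na] <- NA_character_
    out
  }
  starts <- sort(runif(n, 0, 7 * 86400))
  tibble::tibble(
    instance_id = sprintf("r%05d", seq_len(n)),
    user_id = sample(c("a", "b", "c"), n, replace = TRUE),
    domain = sample(c("PA", "N", "C"), n, replace = TRUE,
      prob = c(0.45, 0.35, 0.2)
    ),
    group_id = sprintf("g%05d", seq_len(n)),
    activity = maybe(voc$activities),
    location = maybe(voc$locations),
    emotion = maybe(voc$emotions),
    food = maybe(names(voc$foods)),
    blood_glucose = maybe(voc$bg_labels, p_na = 0.4),
    blood_pressure = maybe(voc$bp_labels, p_na = 0.4),
    start = starts,
    end = starts + runif(n, 0, 7200),
    source_ids = as.list(seq_len(n))
  )
}

# --- rule engine: nested-loop joins per rule -------------------------------

oracle_day <- function(t) floor(t / 86400)

oracle_weekly_rule <- function(hlc, at, filter_fn, h_lo, h_hi, d_test) {
  w0 <- at - 7 * 86400
  out <- list()
  for (u in sort(unique(hlc$user_id))) {
    rows <- hlc[hlc$user_id == u & hlc$inferred_class == "Exercising" &
      hlc$start >= w0 & hlc$start < at, , drop = FALSE]
    rows <- rows[filter_fn(rows), , drop = FALSE]
    if (nrow(rows) == 0) next
    h <- sum((rows$end - rows$start) / 3600)
    d <- length(unique(oracle_day(rows$start)))
    if (is.na(h_lo) || h > h_lo) {
      if (is.na(h_hi) || h < h_hi) {
        if (d_test(d)) {
          out[[u]] <- tibble::tibble(user_id = u, hours = h, days = d)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(user_id = character(), hours = numeric(), days = numeric()))
  }
  do.call(rbind, out)
}

oracle_rule1 <- function(hlc, at) {
  w0 <- at - 7 * 86400
  out <- list()
  for (u in sort(unique(hlc$user_id))) {
    rows <- hlc[hlc$user_id == u & hlc$inferred_class == "Exercising" &
      !is.na(hlc$location) & hlc$location == "Loc_Gym" &
      hlc$start >= w0 & hlc$start < at, , drop = FALSE]
    if (nrow(rows) == 0) next
    h <- sum((rows$end - rows$start) / 3600)
    d <- length(unique(oracle_day(rows$start)))
    if (h < 2 && d < 7) out[[u]] <- tibble::tibble(user_id = u, hours = h, days = d)
  }
  if (length(out) == 0) {
    return(tibble::tibble(user_id = character(), hours = numeric(), days = numeric()))
  }
  do.call(rbind, out)
}

oracle_rule23 <- function(hlc, at, act, lo, hi) {
  oracle_weekly_rule(
    hlc, at,
    function(rows) !is.na(rows$activity) & rows$activity == act,
    lo, hi, function(d) d == 7
  )
}

oracle_rule4 <- function(hlc, at) {
  w0 <- at - 7 * 86400
  out <- list()
  for (u in sort(unique(hlc$user_id))) {
    rows <- hlc[hlc$user_id == u & hlc$inferred_class == "Exercising" &
      hlc$start >= w0 & hlc$start < at, , drop = FALSE]
    h <- (rows$end - rows$start) / 3600
    rows <- rows[h > 1 & h < 3, , drop = FALSE]
    if (nrow(rows) == 0) next
    d <- length(unique(oracle_day(rows$start)))
    if (d == 7) {
      out[[u]] <- tibble::tibble(
        user_id = u, hours = sum((rows$end - rows$start) / 3600), days = d
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(user_id = character(), hours = numeric(), days = numeric()))
  }
  do.call(rbind, out)
}

oracle_rule5 <- function(hlc, at) {
  w0 <- at - 7 * 86400
  out <- list()
  for (u in sort(unique(hlc$user_id))) {
    rows <- hlc[hlc$user_id == u & hlc$inferred_class == "Exercising" &
      hlc$start >= w0 & hlc$start < at, , drop = FALSE]
    h <- (rows$end - rows$start) / 3600
    rows <- rows[h > 1 & h < 3, , drop = FALSE]
    if (nrow(rows) == 0) next
    for (d in sort(unique(oracle_day(rows$start)))) {
      day_rows <- rows[oracle_day(rows$start) == d, , drop = FALSE]
      if (nrow(day_rows) == 2) {
        out[[paste(u, d)]] <- tibble::tibble(
          user_id = u, day = d,
          hours = sum((day_rows$end - day_rows$start) / 3600), frequency = 2
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      user_id = character(), day = numeric(), hours = numeric(),
      frequency = numeric()
    ))
  }
  do.call(rbind, out)
}

oracle_rule6 <- function(llc, at) {
  w0 <- at - 7 * 86400
  out <- list()
  eats <- llc[llc$category == "Activity" & !is.na(llc$label) &
    llc$label == "Eating" & llc$start >= w0 & llc$start < at, , drop = FALSE]
  for (u in sort(unique(eats$user_id))) {
    rows <- eats[eats$user_id == u, , drop = FALSE]
    for (d in sort(unique(oracle_day(rows$start)))) {
      k <- sum(oracle_day(rows$start) == d)
      if (k > 2) {
        out[[paste(u, d)]] <- tibble::tibble(
          user_id = u, day = d, frequency = as.numeric(k)
        )
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      user_id = character(), day = numeric(), frequency = numeric()
    ))
  }
  do.call(rbind, out)
}

# random fact base for rule-engine equivalence runs (<= 200 facts)
random_factbase <- function(seed, at) {
  set.seed(seed)
  users <- paste0("u", seq_len(sample(2:4, 1)))
  hlc <- list()
  llc <- list()
  for (u in users) {
    n <- sample(5:40, 1)
    starts <- sort(runif(n, at - 8.5 * 86400, at + 0.5 * 86400))
    dur <- runif(n, 0.1, 4) * 3600
    hlc[[u]] <- tibble::tibble(
      instance_id = paste0(u, "_", seq_len(n)),
      user_id = u,
      domain = "PA",
      inferred_class = sample(c("Exercising", "OfficeWork", "Sleeping"),
        n,
        replace = TRUE, prob = c(0.6, 0.2, 0.2)
      ),
      activity = sample(c("Act_Walking", "Act_Running", "Act_Stretching"),
        n,
        replace = TRUE
      ),
      location = sample(c("Loc_Gym", "Outdoors", "Home"), n, replace = TRUE),
      start = starts,
      end = starts + dur
    )
    m <- sample(0:15, 1)
    if (m > 0) {
      es <- sort(runif(m, at - 8.5 * 86400, at + 0.5 * 86400))
      llc[[u]] <- tibble::tibble(
        user_id = u, category = "Activity", label = "Eating",
        value = NA_real_, systolic = NA_real_, diastolic = NA_real_,
        start = es, end = es + 1200
      )
    }
  }
  list(
    hlc = do.call(rbind, hlc),
    llc = if (length(llc)) do.call(rbind, llc) else
      tibble::tibble(
        user_id = character(), category = character(), label = character(),
        value = numeric(), systolic = numeric(), diastolic = numeric(),
        start = numeric(), end = numeric()
      )
  )
}

# compare engine output with an oracle tibble on shared columns
expect_rule_match <- function(engine_out, oracle_out, cols) {
  a <- as.data.frame(engine_out[order(engine_out$user_id, engine_out$day), cols, drop = FALSE])
  b <- as.data.frame(oracle_out[do.call(order, as.list(oracle_out[intersect(c("user_id", "day"), names(oracle_out))])), , drop = FALSE])
  rownames(a) <- NULL
  rownames(b) <- NULL
  expect_equal(nrow(a), nrow(b))
  for (col in cols) {
    if (col %in% names(b)) expect_equal(a[[col]], b[[col]], tolerance = 1e-10)
  }
}

# tiny worked-example instance builder
make_instance <- function(domain, activity = NA, location = NA, emotion = NA,
                          food = NA, bg = NA, bp = NA, user = "Bob",
                          start = 0, end = 1800) {
  tibble::tibble(
    instance_id = paste0("ex_", domain), user_id = user, domain = domain,
    group_id = "g", activity = as.character(activity),
    location = as.character(location), emotion = as.character(emotion),
    food = as.character(food), blood_glucose = as.character(bg),
    blood_pressure = as.character(bp), start = start, end = end,
    source_ids = list(integer())
  )
}
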