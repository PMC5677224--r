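#' Path to the packaged default model configuration
#'
#' The packaged configuration plays the T-Box role: it carries the controlled
#' vocabularies (activities, locations, emotions, the 57-item food list and
#' its 10 groups, the clinical label sets), the high-level context class
#' definitions with their existential/universal restrictions, the clinical
#' severity mapping, the labeling bands, and the six behavioral rules.
#'
#' @return File path of the packaged YAML configuration.
#' @export
#' @examples
#' cfg <- load_config()
#' cfg
default_config_path <- function() {
  system.file("extdata", "default_config.yaml",
    package = "contextfuse", mustWork = TRUE
  )
}

#' Load and validate a model configuration
#'
#' Reads the declarative configuration (vocabulary, class definitions,
#' clinical mapping, labeling bands, behavioral rules, engine parameters) and
#' validates every structural invariant: the food map is a total function
#' onto disjoint groups, every term referenced by a class definition or rule
#' exists in the vocabulary, existential witness sets are subsets of the
#' universal allowed sets, sibling classes within a domain are structurally
#' disjoint, and every clinical label maps to a health state.
#'
#' @param path Path to a YAML configuration file, or a pre-parsed list with
#'   the same structure. Defaults to the packaged configuration.
#' @return A `cf_config` object (a validated list).
#' @export
load_config <- function(path = default_config_path()) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  problems <- validate_config(cfg)
  if (length(problems) > 0) {
    abort(c("invalid configuration", setNames(problems, rep("x", length(problems)))),
      class = "cf_config_error"
    )
  }
  cfg$vocabulary$foods <- unlist(cfg$vocabulary$foods)
  for (i in seq_along(cfg$classes)) {
    cfg$classes[[i]]$existential <- lapply(cfg$classes[[i]]$existential, unlist)
    cfg$classes[[i]]$universal <- lapply(cfg$classes[[i]]$universal, unlist)
  }
  structure(cfg, class = "cf_config")
}

cf_properties <- c(
  "hasActivity", "hasLocation", "hasEmotion", "hasFood",
  "hasBloodGlucose", "hasBloodPressure"
)

cf_categories <- c(
  "Activity", "Location", "Emotion", "Food",
  "BloodGlucose", "BloodPressure", "WaterIntake"
)

# vocabulary set governing each property / category
property_vocab <- function(vocab) {
  list(
    hasActivity = unlist(vocab$activities),
    hasLocation = unlist(vocab$locations),
    hasEmotion = unlist(vocab$emotions),
    hasFood = names(unlist(vocab$foods)),
    hasBloodGlucose = unlist(vocab$bg_labels),
    hasBloodPressure = unlist(vocab$bp_labels)
  )
}

category_vocab <- function(vocab) {
  list(
    Activity = unlist(vocab$activities),
    Location = unlist(vocab$locations),
    Emotion = unlist(vocab$emotions),
    Food = names(unlist(vocab$foods)),
    BloodGlucose = unlist(vocab$bg_labels),
    BloodPressure = unlist(vocab$bp_labels),
    WaterIntake = unlist(vocab$water_labels)
  )
}

#' Validate a configuration list
#'
#' @param cfg A configuration list (as read from YAML).
#' @return Character vector of violation messages, empty when the
#'   configuration is clean. Each message names the offending key.
#' @export
validate_config <- function(cfg) {
  p <- character()
  need <- c(
    "vocabulary", "hlc_classes", "labeling", "classes", "clinical",
    "engine", "rules"
  )
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    return(paste0("missing top-level key: ", missing))
  }

  voc <- cfg$vocabulary
  foods <- unlist(voc$foods)
  if (anyDuplicated(names(foods))) {
    dups <- unique(names(foods)[duplicated(names(foods))])
    p <- c(p, paste0(
      "vocabulary$foods: item assigned to two groups: ",
      paste(dups, collapse = ", ")
    ))
  }
  groups <- unlist(voc$food_groups)
  bad_group <- setdiff(unique(foods), groups)
  if (length(bad_group) > 0) {
    p <- c(p, paste0(
      "vocabulary$foods: unknown group(s): ",
      paste(bad_group, collapse = ", ")
    ))
  }
  unused <- setdiff(groups, foods)
  if (length(unused) > 0) {
    p <- c(p, paste0(
      "vocabulary$food_groups: empty group(s): ",
      paste(unused, collapse = ", ")
    ))
  }

  hlc <- cfg$hlc_classes
  doms <- list(PA = unlist(hlc$PA), N = unlist(hlc$N), C = unlist(hlc$C))
  for (pair in list(c("PA", "N"), c("PA", "C"), c("N", "C"))) {
    ov <- intersect(doms[[pair[1]]], doms[[pair[2]]])
    if (length(ov) > 0) {
      p <- c(p, paste0(
        "hlc_classes: domains ", pair[1], "/", pair[2],
        " share class(es): ", paste(ov, collapse = ", ")
      ))
    }
  }

  pv <- property_vocab(voc)
  for (def in cfg$classes) {
    where <- paste0("classes$", def$name %||% "<unnamed>")
    if (is.null(def$name) || is.null(def$domain)) {
      p <- c(p, paste0(where, ": needs name and domain"))
      next
    }
    if (!def$domain %in% c("PA", "N")) {
      p <- c(p, paste0(where, ": domain must be PA or N (C uses clinical mapping)"))
      next
    }
    if (!def$name %in% doms[[def$domain]]) {
      p <- c(p, paste0(where, ": not listed in hlc_classes$", def$domain))
    }
    for (kind in c("existential", "universal")) {
      for (prop in names(def[[kind]])) {
        if (!prop %in% cf_properties) {
          p <- c(p, paste0(where, "$", kind, ": unknown property ", prop))
          next
        }
        bad <- setdiff(unlist(def[[kind]][[prop]]), pv[[prop]])
        if (length(bad) > 0) {
          p <- c(p, paste0(
            where, "$", kind, "$", prop, ": term(s) not in vocabulary: ",
            paste(bad, collapse = ", ")
          ))
        }
      }
    }
    for (prop in names(def$existential)) {
      uni <- unlist(def$universal[[prop]])
      if (!is.null(def$universal[[prop]]) &&
        length(setdiff(unlist(def$existential[[prop]]), uni)) > 0) {
        p <- c(p, paste0(
          where, "$existential$", prop,
          ": witness set not a subset of the universal set"
        ))
      }
    }
  }

  # structural disjointness: sibling definitions must differ on at least one
  # existential property with disjoint witness sets, otherwise a single
  # instance could be a member of two classes at once
  defs <- cfg$classes
  for (dom in c("PA", "N")) {
    dd <- keep(defs, ~ identical(.x$domain, dom))
    if (length(dd) < 2) next
    for (i in seq_len(length(dd) - 1)) {
      for (j in seq(i + 1, length(dd))) {
        shared <- intersect(names(dd[[i]]$existential), names(dd[[j]]$existential))
        disjoint <- any(map_lgl(shared, function(prop) {
          length(intersect(
            unlist(dd[[i]]$existential[[prop]]),
            unlist(dd[[j]]$existential[[prop]])
          )) == 0
        }))
        if (!disjoint) {
          p <- c(p, paste0(
            "classes: ", dd[[i]]$name, " and ", dd[[j]]$name,
            " are not structurally disjoint"
          ))
        }
      }
    }
  }

  cl <- cfg$clinical
  states <- unlist(cl$severity_order)
  if (!setequal(states, doms$C)) {
    p <- c(p, "clinical$severity_order: must enumerate exactly the C classes")
  }
  for (nm in c("blood_glucose", "blood_pressure")) {
    lbls <- if (nm == "blood_glucose") unlist(voc$bg_labels) else unlist(voc$bp_labels)
    m <- unlist(cl[[nm]])
    miss <- setdiff(lbls, names(m))
    if (length(miss) > 0) {
      p <- c(p, paste0(
        "clinical$", nm, ": unmapped label(s): ", paste(miss, collapse = ", ")
      ))
    }
    bad <- setdiff(unname(m), states)
    if (length(bad) > 0) {
      p <- c(p, paste0(
        "clinical$", nm, ": unknown state(s): ", paste(bad, collapse = ", ")
      ))
    }
  }

  for (nm in c("blood_glucose")) {
    for (b in cfg$labeling[[nm]]) {
      if (!is.null(b$lower) && !is.null(b$upper) && b$lower >= b$upper) {
        p <- c(p, paste0("labeling$", nm, "$", b$label, ": lower >= upper"))
      }
    }
  }

  for (r in cfg$rules) {
    where <- paste0("rules$", r$id %||% "<no id>")
    bound <- character()
    for (a in r$atoms) {
      kind <- a$atom
      if (kind %in% c("hlc", "llc", "duration", "countDays", "perDayCount")) {
        bound <- c(bound, a$var)
      }
      if (kind %in% c("duration", "countDays", "perDayCount", "property") &&
        !is.null(a$of %||% a$var) && kind != "property") {
        if (!(a$of %in% bound)) {
          p <- c(p, paste0(where, ": atom uses unbound input ", a$of))
        }
      }
      if (kind == "hlc" && !a$class %in% unlist(doms)) {
        p <- c(p, paste0(where, ": unknown HLC class ", a$class))
      }
      if (kind == "property" && !a$property %in% cf_properties) {
        p <- c(p, paste0(where, ": unknown property ", a$property))
      }
    }
    unbound <- setdiff(unlist(r$select), bound)
    if (length(unbound) > 0) {
      p <- c(p, paste0(
        where, ": consequent variable(s) not bound: ",
        paste(unbound, collapse = ", ")
      ))
    }
  }

  p
}

#' Serialize a configuration in canonical form
#'
#' The canonical form sorts the food map alphabetically and writes YAML with
#' fixed options, so `write_config(load_config(path))` is idempotent:
#' re-loading and re-serializing the output reproduces it byte for byte.
#'
#' @param config A `cf_config` object.
#' @param path Optional output path; when `NULL` the YAML text is returned.
#' @return The YAML text, invisibly when written to `path`.
#' @export
write_config <- function(config, path = NULL) {
  cfg <- unclass(config)
  foods <- unlist(cfg$vocabulary$foods)
  cfg$vocabulary$foods <- as.list(foods[order(names(foods))])
  for (i in seq_along(cfg$classes)) {
    cfg$classes[[i]]$existential <- lapply(cfg$classes[[i]]$existential, function(x) as.list(sort(unlist(x))))
    cfg$classes[[i]]$universal <- lapply(cfg$classes[[i]]$universal, function(x) as.list(sort(unlist(x))))
  }
  txt <- yaml::as.yaml(cfg, indent = 2, line.sep = "\n")
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Structural counts of a configuration
#'
#' @param config A `cf_config` object.
#' @return A one-row tibble with the model's structural counts: food items,
#'   food groups, clinical label set sizes, and high-level context class
#'   counts per domain.
#' @export
config_counts <- function(config) {
  v <- config$vocabulary
  tibble(
    food_items = length(unlist(v$foods)),
    food_groups = length(unique(unname(unlist(v$foods)))),
    bg_labels = length(unlist(v$bg_labels)),
    bp_labels = length(unlist(v$bp_labels)),
    water_labels = length(unlist(v$water_labels)),
    pa_classes = length(unlist(config$hlc_classes$PA)),
    n_classes = length(unlist(config$hlc_classes$N)),
    c_classes = length(unlist(config$hlc_classes$C)),
    rules = length(config$rules)
  )
}

#' @export
print.cf_config <- function(x, ...) {
  cts <- config_counts(x)
  cat("<cf_config>\n")
  cat(sprintf(
    "  vocabulary: %d activities, %d locations, %d emotions, %d food items in %d groups\n",
    length(unlist(x$vocabulary$activities)), length(unlist(x$vocabulary$locations)),
    length(unlist(x$vocabulary$emotions)), cts$food_items, cts$food_groups
  ))
  cat(sprintf(
    "  clinical labels: %d blood glucose, %d blood pressure, %d water intake\n",
    cts$bg_labels, cts$bp_labels, cts$water_labels
  ))
  cat(sprintf(
    "  HLC classes: %d physical activity, %d nutrition, %d clinical\n",
    cts$pa_classes, cts$n_classes, cts$c_classes
  ))
  cat(sprintf(
    "  %d behavioral rules; sync window %ds\n",
    cts$rules, x$engine$window_seconds
  ))
  invisible(x)
}
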