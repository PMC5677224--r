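cf_iri <- "http://contextfuse.org/mmco#"
xsd_decimal <- "http://www.w3.org/2001/XMLSchema#decimal"

category_predicate <- c(
  Activity = "hasActivity", Location = "hasLocation", Emotion = "hasEmotion",
  Food = "hasFood", BloodGlucose = "hasBloodGlucose",
  BloodPressure = "hasBloodPressure",
  # package extension: the context model lists WaterIntake among the
  # low-level categories without a printed object property
  WaterIntake = "hasWaterIntake"
)

fmt_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

#' Export contexts as an RDF graph
#'
#' Serializes LLC records (and, optionally, classified HLC instances) using
#' the context model's property vocabulary (`hasActivity`, `hasLocation`,
#' `hasEmotion`, `hasFood`, `hasBloodGlucose`, `hasBloodPressure`,
#' `hasUser`, `hasStartTime`, `hasEndTime`, `isContextOf`) under a single
#' package-owned IRI prefix. Triples are emitted in a canonical sorted
#' order, so export → import → export is byte-identical.
#'
#' @param records An LLC log tibble (labels must be filled in).
#' @param instances Optional classified instance tibble.
#' @param dialect `"ntriples"` or `"turtle"`.
#' @return A single character string holding the serialized graph.
#' @export
#' @examples
#' log <- llc_log(
#'   user_id = "u1", category = "Activity", label = "Eating",
#'   start = 0, end = 600
#' )
#' cat(export_rdf(log, dialect = "turtle"))
export_rdf <- function(records, instances = NULL,
                       dialect = c("ntriples", "turtle")) {
  dialect <- match.arg(dialect)
  records <- as_llc_log(records)
  triples <- list()
  add <- function(s, p, o, literal = FALSE) {
    tibble(s = s, p = p, o = o, literal = literal)
  }
  if (nrow(records) > 0) {
    id <- sprintf("llc_%06d", seq_len(nrow(records)))
    triples <- c(triples, list(
      add(id, "hasUser", paste0("user_", records$user_id)),
      add(id, category_predicate[records$category], records$label),
      add(id, "hasStartTime", fmt_num(records$start), literal = TRUE),
      add(id, "hasEndTime", fmt_num(records$end), literal = TRUE)
    ))
  }
  if (!is.null(instances) && nrow(instances) > 0) {
    hid <- paste0("hlc_", gsub("[^A-Za-z0-9_]", "_", instances$instance_id))
    triples <- c(triples, list(
      add(hid, "hasUser", paste0("user_", instances$user_id)),
      add(paste0("user_", instances$user_id), "isContextOf", hid),
      add(hid, "hasStartTime", fmt_num(instances$start), literal = TRUE),
      add(hid, "hasEndTime", fmt_num(instances$end), literal = TRUE)
    ))
    for (prop in names(def_property_cols)) {
      v <- instances[[def_property_cols[[prop]]]]
      ok <- !is.na(v)
      if (any(ok)) {
        triples <- c(triples, list(add(hid[ok], prop, v[ok])))
      }
    }
    cls <- !is.na(instances$inferred_class)
    if (any(cls)) {
      triples <- c(triples, list(
        add(hid[cls], "rdf_type", instances$inferred_class[cls])
      ))
    }
  }
  tt <- list_rbind(triples) |>
    filter(!is.na(o)) |>
    distinct() |>
    arrange(s, p, o)
  serialize_triples(tt, dialect)
}

serialize_triples <- function(tt, dialect) {
  term <- function(x) paste0("<", cf_iri, x, ">")
  lit <- function(x) paste0("\"", x, "\"^^<", xsd_decimal, ">")
  obj <- ifelse(tt$literal, lit(tt$o), term(tt$o))
  if (dialect == "ntriples") {
    lines <- paste0(term(tt$s), " ", term(tt$p), " ", obj, " .")
    return(paste0(paste(sort(lines), collapse = "\n"), "\n"))
  }
  # turtle: one block per subject, predicates sorted
  obj_c <- ifelse(tt$literal, lit(tt$o), paste0("cf:", tt$o))
  header <- paste0("@prefix cf: <", cf_iri, "> .\n")
  blocks <- tt |>
    mutate(po = paste0("cf:", p, " ", obj_c)) |>
    group_by(s) |>
    summarise(
      block = paste0(
        "cf:", s[1], " ",
        paste(sort(po), collapse = " ;\n    "), " ."
      ),
      .groups = "drop"
    ) |>
    arrange(s)
  paste0(header, "\n", paste(blocks$block, collapse = "\n"), "\n")
}

#' Parse a graph serialized by [export_rdf()]
#'
#' @param text The serialized graph (either dialect).
#' @return A triple tibble (`s`, `p`, `o`, `literal`).
#' @export
parse_rdf <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@prefix")]
  strip <- function(x) sub(paste0("^<?(cf:|", cf_iri, ")"), "", sub(">$", "", x))
  out <- list()
  subject <- NULL
  for (ln in lines) {
    terminated <- grepl("[.;]$", ln)
    ln2 <- sub("\\s*[.;]$", "", ln)
    parts <- regmatches(ln2, regexec(
      "^(\\S+)?\\s*(\\S+)\\s+(\"[^\"]*\"\\^\\^\\S+|\\S+)\\s*$", ln2
    ))[[1]]
    if (length(parts) == 0) next
    if (nzchar(parts[2] %||% "")) {
      maybe_subj <- parts[2]
    }
    # a line starting a new subject has three terms; continuation lines two
    toks <- strsplit(ln2, "\\s+")[[1]]
    if (length(toks) >= 3) {
      subject <- strip(toks[1])
      p <- strip(toks[2])
      o <- paste(toks[3:length(toks)], collapse = " ")
    } else {
      p <- strip(toks[1])
      o <- toks[2]
    }
    literal <- startsWith(o, "\"")
    o <- if (literal) sub("^\"([^\"]*)\".*$", "\\1", o) else strip(o)
    out <- c(out, list(tibble(s = subject, p = p, o = o, literal = literal)))
    if (!terminated) next
  }
  if (length(out) == 0) {
    return(tibble(
      s = character(), p = character(), o = character(), literal = logical()
    ))
  }
  list_rbind(out) |> distinct()
}

rdf_to_llc <- function(triples) {
  llc <- triples |> filter(startsWith(s, "llc_"))
  if (nrow(llc) == 0) {
    return(as_llc_log(tibble()))
  }
  wide <- llc |>
    mutate(p = ifelse(p %in% category_predicate, "label", p)) |>
    select(s, p, o) |>
    pivot_wider(names_from = p, values_from = o)
  cat_of <- llc |>
    filter(p %in% category_predicate) |>
    mutate(category = names(category_predicate)[match(p, category_predicate)]) |>
    select(s, category)
  wide |>
    left_join(cat_of, by = "s") |>
    transmute(
      user_id = sub("^user_", "", hasUser),
      category = category,
      label = label,
      start = as.numeric(hasStartTime),
      end = as.numeric(hasEndTime),
      .rdf_id = s
    ) |>
    arrange(user_id, start, .rdf_id) |>
    select(-".rdf_id") |>
    as_llc_log()
}

utils::globalVariables(c("s", "p", "o", "po", "hasUser", "hasStartTime", "hasEndTime", ".rdf_id"))

#' Retrieve concurrent low-level contexts from an exported graph
#'
#' Graph-backed equivalent of [synchronize()]: reconstructs the LLC records
#' of one user from a graph produced by [export_rdf()], restricts them to a
#' time window, and groups the concurrent ones with the same sliding-window
#' criterion.
#'
#' @param graph Serialized graph text, or a parsed triple tibble.
#' @param user User identifier.
#' @param from,to Optional window bounds (epoch seconds) on record starts.
#' @param window,config Passed to [synchronize()].
#' @return The user's records with `group_id`, as from [synchronize()].
#' @export
query_concurrent <- function(graph, user, from = -Inf, to = Inf,
                             window = NULL, config = load_config()) {
  triples <- if (is.character(graph)) parse_rdf(graph) else graph
  recs <- rdf_to_llc(triples) |>
    filter(user_id == user, start >= from, start < to) |>
    arrange(start, category)
  synchronize(recs, window = window, config = config)
}
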