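#' Canonical high-level context class order
#'
#' The fifteen recognized classes in the fixed legend order used by the
#' confusion matrix (Amusement through VeryHighRiskHealthState).
#'
#' @param config A `cf_config` object.
#' @return Character vector of the 15 class names.
#' @export
hlc_class_order <- function(config = load_config()) {
  c(
    "Amusement", "Commuting", "Exercising", "Gardening", "Carbohydrates",
    "Fats", "HouseWork", "Inactivity", "OfficeWork", "Protein", "Sleeping",
    "HighRiskHealthState", "ModerateHealthState", "NormalHealthState",
    "VeryHighRiskHealthState"
  )
}

#' Confusion matrix over the recognized classes
#'
#' Rows are truth classes, columns are predicted classes plus an extra
#' `Unidentified` column for candidates matching no class definition.
#'
#' @param predicted,truth Aligned character vectors of class labels (equal
#'   length; an error otherwise).
#' @param classes Class order; defaults to [hlc_class_order()].
#' @return An integer matrix, `length(classes)` rows by
#'   `length(classes) + 1` columns.
#' @export
confusion <- function(predicted, truth, classes = hlc_class_order()) {
  if (length(predicted) != length(truth)) {
    abort("predicted and truth must have equal length")
  }
  pred_levels <- c(classes, "Unidentified")
  m <- table(
    factor(truth, levels = classes),
    factor(predicted, levels = pred_levels)
  )
  matrix(as.integer(m),
    nrow = length(classes),
    dimnames = list(truth = classes, predicted = pred_levels)
  )
}

#' Precision, recall and F-measure from a confusion matrix
#'
#' Standard per-class definitions: precision `TP / (TP + FP)` (NA, not 0,
#' when the class is never predicted), recall `TP / (TP + FN)`, F the
#' harmonic mean. Predictions in the `Unidentified` column count as false
#' negatives of the truth class but as false positives of no class. Macro
#' scores average over classes with defined values. Two secondary metrics
#' reproduce the source framework's own printed definitions literally:
#' `paper_precision` (correctly inferred contexts divided by the number of
#' classes defined in the model) and `paper_recall` (correctly inferred
#' contexts divided by the instances in the dataset).
#'
#' @param matrix A confusion matrix from [confusion()].
#' @return A list: `per_class` tibble, `macro_precision`, `macro_recall`,
#'   `macro_f`, `accuracy`, `paper_precision`, `paper_recall`.
#' @export
precision_recall_f <- function(matrix) {
  classes <- rownames(matrix)
  tp <- diag(matrix[, classes, drop = FALSE])
  fp <- colSums(matrix)[classes] - tp
  fn <- rowSums(matrix) - tp
  precision <- ifelse(tp + fp == 0, NA_real_, tp / (tp + fp))
  recall <- ifelse(tp + fn == 0, NA_real_, tp / (tp + fn))
  f <- ifelse(
    is.na(precision) | is.na(recall) | precision + recall == 0,
    NA_real_, 2 * precision * recall / (precision + recall)
  )
  total <- sum(matrix)
  list(
    per_class = tibble(
      class = classes, tp = as.integer(tp), fp = as.integer(fp),
      fn = as.integer(fn), precision = unname(precision),
      recall = unname(recall), f_measure = unname(f)
    ),
    macro_precision = mean(precision, na.rm = TRUE),
    macro_recall = mean(recall, na.rm = TRUE),
    macro_f = mean(f, na.rm = TRUE),
    accuracy = if (total == 0) NA_real_ else sum(tp) / total,
    paper_precision = sum(tp) / length(classes),
    paper_recall = if (total == 0) NA_real_ else sum(tp) / total
  )
}

#' Account for unidentified contexts by missing-property reason
#'
#' @param classified A classified instance tibble from [classify_hlc()].
#' @return Counts of `Unidentified` instances partitioned by domain and
#'   reason code (which mandatory low-level context was missing, or which
#'   asserted value fell outside every class's allowed set).
#' @export
unidentified_report <- function(classified) {
  classified |>
    filter(inferred_class == "Unidentified") |>
    count(domain, reason, name = "n") |>
    arrange(domain, reason)
}

# greedy interval alignment of truth rows to predicted instances within
# (user, domain); each prediction is consumed at most once, the largest
# overlap wins
align_instances <- function(instances, truth_hlc) {
  truth_hlc <- truth_hlc |> mutate(.tid = row_number())
  instances <- instances |> mutate(.pid = row_number())
  pairs <- truth_hlc |>
    inner_join(
      instances |>
        select(
          .pid, user_id, domain, inferred_class,
          pred_start = start, pred_end = end
        ),
      by = c("user_id", "domain"), relationship = "many-to-many"
    ) |>
    mutate(overlap = pmin(end, pred_end) - pmax(start, pred_start)) |>
    filter(overlap >= 0) |>
    arrange(desc(overlap), start)
  taken_t <- logical(nrow(truth_hlc))
  taken_p <- logical(nrow(instances))
  keep <- logical(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    ti <- pairs$.tid[i]
    pi <- pairs$.pid[i]
    if (!taken_t[ti] && !taken_p[pi]) {
      taken_t[ti] <- TRUE
      taken_p[pi] <- TRUE
      keep[i] <- TRUE
    }
  }
  matched <- pairs[keep, ] |>
    select(user_id, domain, truth_class, predicted = inferred_class, start, end)
  list(
    matched = arrange(matched, user_id, start, domain),
    unmatched_truth = truth_hlc[!taken_t, ] |> select(-".tid"),
    unmatched_predicted = instances[!taken_p, ] |> select(-".pid")
  )
}

#' Score pipeline output against ground truth
#'
#' Aligns predicted high-level context instances with truth rows (per user
#' and domain, by interval overlap), builds the 15-class confusion matrix
#' with its `Unidentified` column, computes per-class and macro
#' precision/recall/F, the accuracy / misclassified / unidentified fractions
#' (which sum to 1 over the aligned pairs), the unidentified-reason
#' histogram, and the recognized vs communicated (change-point) counts.
#'
#' @param classified A classified instance tibble, ideally from
#'   [classify_stream()] so notification marks are available.
#' @param truth_hlc Ground-truth rows
#'   (`user_id`, `domain`, `truth_class`, `start`, `end`).
#' @param config A `cf_config` object.
#' @return A `cf_evaluation` object; see [tidy.cf_evaluation()] and
#'   [glance.cf_evaluation()].
#' @export
#' @examples
#' cohort <- generate_cohort(2, 2, seed = 1)
#' run <- run_pipeline(cohort$llc, truth_hlc = cohort$truth_hlc)
#' glance(run$evaluation)
evaluate_pipeline <- function(classified, truth_hlc, config = load_config()) {
  aligned <- align_instances(classified, truth_hlc)
  m <- confusion(
    aligned$matched$predicted, aligned$matched$truth_class,
    classes = hlc_class_order(config)
  )
  scores <- precision_recall_f(m)
  n <- nrow(aligned$matched)
  unid <- sum(aligned$matched$predicted == "Unidentified")
  correct <- sum(aligned$matched$predicted == aligned$matched$truth_class)
  recognized <- sum(classified$inferred_class != "Unidentified")
  communicated <- if ("notified" %in% names(classified)) {
    sum(classified$notified)
  } else {
    NA_integer_
  }
  structure(
    list(
      matrix = m,
      per_class = scores$per_class,
      macro_precision = scores$macro_precision,
      macro_recall = scores$macro_recall,
      macro_f = scores$macro_f,
      paper_precision = scores$paper_precision,
      paper_recall = scores$paper_recall,
      accuracy = if (n == 0) NA_real_ else correct / n,
      misclassified_fraction =
        if (n == 0) NA_real_ else (n - correct - unid) / n,
      unidentified_fraction = if (n == 0) NA_real_ else unid / n,
      aligned = aligned,
      unidentified = unidentified_report(classified),
      n_matched = n,
      n_truth = nrow(truth_hlc),
      n_predicted = nrow(classified),
      recognized = recognized,
      communicated = communicated
    ),
    class = "cf_evaluation"
  )
}

#' @export
print.cf_evaluation <- function(x, ...) {
  cat("<cf_evaluation>\n")
  cat(sprintf(
    "  %d truth contexts, %d predicted, %d aligned\n",
    x$n_truth, x$n_predicted, x$n_matched
  ))
  cat(sprintf(
    "  accuracy %.2f%%, misclassified %.2f%%, unidentified %.2f%%\n",
    100 * x$accuracy, 100 * x$misclassified_fraction,
    100 * x$unidentified_fraction
  ))
  cat(sprintf(
    "  macro precision %.3f, recall %.3f, F %.3f\n",
    x$macro_precision, x$macro_recall, x$macro_f
  ))
  if (!is.na(x$communicated)) {
    cat(sprintf(
      "  recognized %d, communicated on change %d\n",
      x$recognized, x$communicated
    ))
  }
  invisible(x)
}

#' Tidy an evaluation into per-class scores
#'
#' @param x A `cf_evaluation` object.
#' @param ... Unused.
#' @return A tibble with one row per class: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_measure`.
#' @export
tidy.cf_evaluation <- function(x, ...) {
  x$per_class
}

#' One-row evaluation summary
#'
#' @param x A `cf_evaluation` object.
#' @param ... Unused.
#' @return A one-row tibble with the overall accuracy, misclassified and
#'   unidentified fractions, macro scores, and recognized/communicated
#'   counts.
#' @export
glance.cf_evaluation <- function(x, ...) {
  tibble(
    n_truth = x$n_truth, n_predicted = x$n_predicted,
    n_matched = x$n_matched,
    accuracy = x$accuracy,
    misclassified_fraction = x$misclassified_fraction,
    unidentified_fraction = x$unidentified_fraction,
    macro_precision = x$macro_precision, macro_recall = x$macro_recall,
    macro_f = x$macro_f,
    recognized = x$recognized, communicated = x$communicated
  )
}

#' Confusion-matrix heat map
#'
#' @param object A `cf_evaluation` object.
#' @param ... Unused.
#' @return A ggplot: truth classes by predicted classes (plus the
#'   `Unidentified` column), tile fill giving counts.
#' @export
autoplot.cf_evaluation <- function(object, ...) {
  df <- as_tibble(as.data.frame.table(object$matrix, responseName = "Count"))
  names(df)[1:2] <- c("Truth", "Prediction")
  df$Truth <- factor(df$Truth, levels = rev(rownames(object$matrix)))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = Prediction, y = Truth, fill = Count)
  ) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(
      ggplot2::aes(label = ifelse(Count > 0, Count, "")),
      size = 3
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(
      x = "Predicted class", y = "True class",
      title = "High-level context confusion matrix"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
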