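#' Confusion counts with RT as the positive class
#'
#' The resistant-treated (RT) group is the positive class and the
#' sensitive-treated (ST) group the negative class throughout: a false
#' positive is an ST plant misjudged as resistant, the costliest error in
#' resistance screening.
#'
#' @param truth,estimate Equal-length label vectors over `{positive,
#'   negative}` labels.
#' @param positive Positive class label (default `"RT"`).
#' @param negative Negative class label; inferred as the other label seen.
#' @return One-row tibble with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(truth, estimate, positive = "RT", negative = NULL) {
  if (length(truth) != length(estimate)) stop("label vectors differ in length")
  labs <- unique(c(truth, estimate))
  if (is.null(negative)) {
    # the study's convention: RT positive, ST negative (and vice versa);
    # anything else must be drawn from the observed two-class set
    negative <- if (positive %in% c("RT", "ST")) {
      setdiff(c("RT", "ST"), positive)
    } else {
      setdiff(labs, positive)
    }
  }
  if (length(negative) != 1L || !all(labs %in% c(positive, negative))) {
    stop("labels must be drawn from exactly two classes")
  }
  tibble::tibble(
    TP = sum(truth == positive & estimate == positive),
    FP = sum(truth == negative & estimate == positive),
    TN = sum(truth == negative & estimate == negative),
    FN = sum(truth == positive & estimate == negative)
  )
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/total, precision = TP/(TP+FP), recall = TP/(TP+FN),
#' F1 = harmonic mean of precision and recall, FPR = FP/(FP+TN). A zero
#' denominator yields `NaN` (explicitly undefined, matching the "NaN"
#' rendering used in reports), never a silent 0.
#'
#' @param counts One-row data frame with `TP`, `FP`, `TN`, `FN` (total > 0).
#' @return One-row tibble: `accuracy`, `precision`, `recall`, `f1`, `fpr`.
#' @export
metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  total <- tp + fp + tn + fn
  if (any(total <= 0)) stop("no evaluated samples")
  div <- function(num, den) ifelse(den == 0, NaN, num / den)
  precision <- div(tp, tp + fp)
  recall <- div(tp, tp + fn)
  f1 <- ifelse(is.nan(precision) | is.nan(recall) | precision + recall == 0,
               NaN, 2 * precision * recall / (precision + recall))
  tibble::tibble(
    accuracy = div(tp + tn, total),
    precision = precision,
    recall = recall,
    f1 = f1,
    fpr = div(fp, fp + tn)
  )
}

#' F1 as the harmonic mean of precision and recall
#'
#' @param precision,recall Numeric vectors in `[0, 1]`.
#' @return `2 * precision * recall / (precision + recall)`; `NaN` when the
#'   denominator is 0.
#' @export
harmonic_f1 <- function(precision, recall) {
  ifelse(precision + recall == 0, NaN,
         2 * precision * recall / (precision + recall))
}

#' Evaluate predictions into a metric row
#'
#' @param truth,estimate Label vectors.
#' @param positive Positive class (default `"RT"`).
#' @return One-row tibble of the five metrics plus `n`.
#' @export
evaluate_predictions <- function(truth, estimate, positive = "RT") {
  counts <- confusion(truth, estimate, positive)
  dplyr::bind_cols(metrics(counts), tibble::tibble(n = length(truth)))
}

#' Aggregate metric tables
#'
#' Means of the metric columns within groups, skipping undefined (`NaN`)
#' values explicitly; `n_undefined` counts the skipped values across the
#' metric columns of each group.
#'
#' @param results Data frame with metric columns.
#' @param ... Grouping columns (tidy-select, passed to [dplyr::group_by()]).
#' @param metric_names Metric columns to average.
#' @return Tibble of group keys, metric means, `n_rows`, `n_undefined`.
#' @export
summarize_metrics <- function(results, ...,
                              metric_names = intersect(
                                c("accuracy", "precision", "recall",
                                  "f1", "fpr"),
                                names(results))) {
  results |>
    dplyr::group_by(...) |>
    dplyr::summarize(
      n_rows = dplyr::n(),
      n_undefined = sum(!is.finite(as.matrix(
        dplyr::pick(dplyr::all_of(metric_names))))),
      dplyr::across(dplyr::all_of(metric_names),
                    ~ mean(.x[is.finite(.x)])),
      .groups = "drop"
    )
}
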