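#' Kennard-Stone sample selection
#'
#' Deterministic greedy selection: the first two picks are the pair at
#' maximal Euclidean distance; every later pick maximizes its minimum
#' distance to the already-selected set. All ties break to the lowest row
#' index, so the result is a pure function of row order.
#'
#' @param X Numeric matrix (rows = samples); all values finite.
#' @param k Number of samples to select, `2 <= k <= nrow(X)`.
#' @return Integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= nrow(X)")
  if (!all(is.finite(X))) stop("features must be finite")
  D <- as.matrix(stats::dist(X))
  # maximal pair; scan row-major over i < j so ties hit the lowest indices
  best <- c(1L, 2L); best_d <- -Inf
  for (i in seq_len(n - 1)) {
    j_rel <- which.max(D[i, (i + 1):n])
    d <- D[i, i + j_rel]
    if (d > best_d) { best_d <- d; best <- c(i, i + j_rel) }
  }
  sel <- best
  if (k > 2) {
    min_d <- pmin(D[, sel[1]], D[, sel[2]])
    for (step in 3:k) {
      min_d[sel] <- -Inf
      cand <- which.max(min_d)  # which.max returns the first (lowest) index
      sel <- c(sel, cand)
      min_d <- pmin(min_d, D[, cand])
    }
  }
  as.integer(sel)
}

#' Kennard-Stone 4:1 train/test split
#'
#' Selects `round(ratio * n)` training rows (round-half-up) by
#' [kennard_stone()] on the index feature columns; the remainder is the test
#' set. Distances are computed on raw index values (set `scale = TRUE` for
#' standardized distances).
#'
#' @param index_table Output of [spectral_index_table()]; flagged rows are
#'   excluded before splitting.
#' @param ratio Training fraction (default 0.8, i.e. 4:1).
#' @param feature_names Feature columns; defaults to registry indices
#'   present.
#' @param scale Standardize features before computing distances?
#' @return The (unflagged) table with an added `role` column
#'   (`"train"`/`"test"`).
#' @export
ks_split <- function(index_table, ratio = 0.8,
                     feature_names = intersect(spectral_index_registry()$name,
                                               names(index_table)),
                     scale = FALSE) {
  tbl <- index_table
  if (".flagged" %in% names(tbl)) tbl <- dplyr::filter(tbl, !.data$.flagged)
  n <- nrow(tbl)
  if (n < 5L) stop("need at least 5 rows for a 4:1 split")
  k <- round_half_up(ratio * n)
  if (k < 2 || k >= n) stop("ratio leaves an empty train or test set")
  X <- as.matrix(as.data.frame(tbl)[, feature_names, drop = FALSE])
  if (scale) X <- base::scale(X)
  train_idx <- kennard_stone(X, k)
  dplyr::mutate(tbl, role = ifelse(dplyr::row_number() %in% train_idx,
                                   "train", "test"))
}

#' Enumerate cross-experiment transfer tasks
#'
#' All ordered pairs of distinct experiments crossed with all sampling days:
#' the source domain is the full source experiment, the target domain is one
#' sampling day of the target experiment. Three experiments and four days
#' give 24 tasks.
#'
#' @param experiments Experiment labels (>= 2).
#' @param dats Sampling days.
#' @return Tibble with `source`, `target`, `dat`, sorted and unique.
#' @export
build_transfer_tasks <- function(experiments, dats = c(2, 4, 6, 8)) {
  if (length(unique(experiments)) < 2L) stop("need at least two experiments")
  tidyr::expand_grid(source = unique(experiments),
                     target = unique(experiments),
                     dat = dats) |>
    dplyr::filter(.data$source != .data$target) |>
    dplyr::arrange(.data$source, .data$target, .data$dat)
}
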