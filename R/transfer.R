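#' Source-domain updating
#'
#' Moves a seeded simple random sample of the target domain into the source
#' domain; the model is then evaluated on the remaining ("new") target
#' domain. The update level is expressed relative to the target-domain size
#' (the study's convention) and the plan also reports the equivalent
#' fraction of the source domain.
#'
#' @param source,target Data frames (rows = samples).
#' @param level Fraction of the target domain to move, in (0, 1);
#'   `round(level * nrow(target))` must be >= 1 and < `nrow(target)`.
#' @param seed Integer seed for the draw.
#' @param stratify Optional column name for class-stratified sampling
#'   (proportional within class); default simple random.
#' @return List with `source` (augmented), `target` (reduced), and `plan`
#'   (one-row tibble: `level`, `k_moved`, `seed`, `source_ratio`).
#' @export
update_source <- function(source, target, level, seed = 1, stratify = NULL) {
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  nt <- nrow(target)
  k <- round_half_up(level * nt)
  if (k < 1) stop("level moves no target samples")
  if (k >= nt) stop("level leaves an empty reduced target domain")
  idx <- withr::with_seed(seed, {
    if (is.null(stratify)) {
      sample(nt, k)
    } else {
      cls <- as.character(target[[stratify]])
      picks <- unlist(lapply(unique(cls), function(cl) {
        rows <- which(cls == cl)
        sample(rows, round_half_up(level * length(rows)))
      }))
      head(picks, k)
    }
  })
  list(
    source = dplyr::bind_rows(source, target[idx, , drop = FALSE]),
    target = target[-idx, , drop = FALSE],
    plan = tibble::tibble(level = level, k_moved = length(idx), seed = seed,
                          source_ratio = length(idx) / nrow(source))
  )
}

.variants <- c("SVM", "TCA_SVM", "Update_SVM", "Update_TCA_SVM")

#' Run one model variant on one transfer task
#'
#' The four variants compose the pipeline differently. `SVM`: train on the
#' full source (standardized), predict the target. `TCA_SVM`: fit primal
#' TCA on (source, target) features, train on the embedded source
#' (unstandardized), predict the embedded target. `Update_SVM`: move
#' `level` of the target into the source, train on the augmented source
#' (unstandardized), predict the reduced target. `Update_TCA_SVM`: update
#' first, then TCA on (augmented source, reduced target), then the SVM on
#' embeddings, predicting the reduced target. Standardization is on only
#' for the plain no-transfer SVM, mirroring the study's toggle.
#'
#' @param data Index table for all experiments (RT/ST rows are selected
#'   internally; flagged rows dropped).
#' @param source,target Experiment labels; `dat` the target sampling day.
#' @param dat Target-domain sampling day.
#' @param variant One of `"SVM"`, `"TCA_SVM"`, `"Update_SVM"`,
#'   `"Update_TCA_SVM"`.
#' @param m,mu TCA dimensionality and regularizer.
#' @param level Update level (required for Update variants; must be NULL
#'   for the others).
#' @param C SVM box constraint.
#' @param seed Seed for the update draw.
#' @param feature_names Feature columns.
#' @return One-row tibble: task fields, `variant`, `level`, `seed`,
#'   `source_ratio`, the five metrics and `n` (target rows evaluated).
#' @export
run_transfer_task <- function(data, source, target, dat,
                              variant = .variants,
                              m = 5, mu = 1, level = NULL, C = 1, seed = 1,
                              feature_names = intersect(
                                spectral_index_registry()$name, names(data))) {
  variant <- match.arg(variant)
  if (source == target) stop("source and target experiments must differ")
  is_update <- variant %in% c("Update_SVM", "Update_TCA_SVM")
  if (is_update && (is.null(level) || level <= 0)) {
    stop(sprintf("%s requires a positive update level", variant))
  }
  if (".flagged" %in% names(data)) data <- dplyr::filter(data, !.data$.flagged)
  data <- dplyr::filter(data, .data$group %in% c("RT", "ST"))
  src <- dplyr::filter(data, .data$experiment == source)
  tgt <- dplyr::filter(data, .data$experiment == target, .data$dat == !!dat)
  if (nrow(src) == 0L || nrow(tgt) == 0L) {
    stop("task domains are empty in the supplied data")
  }

  source_ratio <- NA_real_
  if (is_update) {
    upd <- update_source(src, tgt, level, seed)
    src <- upd$source
    tgt <- upd$target
    source_ratio <- upd$plan$source_ratio
  }

  if (variant %in% c("TCA_SVM", "Update_TCA_SVM")) {
    Xs <- as.matrix(as.data.frame(src)[, feature_names, drop = FALSE])
    Xt <- as.matrix(as.data.frame(tgt)[, feature_names, drop = FALSE])
    tca <- fit_tca_primal(Xs, Xt, m = m, mu = mu)
    emb_s <- as.data.frame(predict(tca, Xs))
    emb_s$group <- src$group
    emb_t <- as.data.frame(predict(tca, Xt))
    model <- train_svm(emb_s, feature_names = colnames(tca$W),
                       standardize = FALSE, C = C)
    pred <- predict(model, as.matrix(emb_t))
  } else {
    model <- train_svm(src, feature_names = feature_names,
                       standardize = !is_update, C = C)
    pred <- predict(model, tgt)
  }

  dplyr::bind_cols(
    tibble::tibble(source = source, target = target, dat = dat,
                   variant = variant,
                   level = if (is_update) level else NA_real_,
                   seed = seed, source_ratio = source_ratio),
    evaluate_predictions(tgt$group, pred)
  )
}

#' Run all transfer tasks for a set of variants and seeds
#'
#' One row per (task x variant x seed). Deterministic variants (`SVM`,
#' `TCA_SVM`) are computed once per task and replicated across seeds so the
#' long table is balanced; Update variants are re-drawn per seed.
#'
#' @param data Index table for all experiments.
#' @param tasks Tibble from [build_transfer_tasks()]; defaults to all tasks
#'   over the experiments present.
#' @param variants Variants to run.
#' @param m,mu,level,C Model parameters.
#' @param seeds Integer seeds for the update draws.
#' @return Long results tibble.
#' @export
run_transfer_tasks <- function(data, tasks = NULL, variants = .variants,
                               m = 5, mu = 1, level = 0.5, C = 1,
                               seeds = 1:10) {
  if (is.null(tasks)) {
    tasks <- build_transfer_tasks(unique(data$experiment),
                                  sort(unique(data$dat)))
  }
  out <- list()
  for (t in seq_len(nrow(tasks))) {
    for (v in variants) {
      if (v %in% c("SVM", "TCA_SVM")) {
        row <- run_transfer_task(data, tasks$source[t], tasks$target[t],
                                 tasks$dat[t], v, m = m, mu = mu, C = C,
                                 seed = seeds[1])
        rows <- purrr::map(seeds, function(s) dplyr::mutate(row, seed = s))
        out[[length(out) + 1L]] <- purrr::list_rbind(rows)
      } else {
        rows <- purrr::map(seeds, function(s) {
          run_transfer_task(data, tasks$source[t], tasks$target[t],
                            tasks$dat[t], v, m = m, mu = mu,
                            level = level, C = C, seed = s)
        })
        out[[length(out) + 1L]] <- purrr::list_rbind(rows)
      }
    }
  }
  purrr::list_rbind(out)
}
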