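#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA: the between/within mean-square
#' ratio on (k - 1, N - k) degrees of freedom. Degenerate inputs are handled
#' explicitly: identical values in every group give F = 0, p = 1; positive
#' between-group but zero within-group variance gives F = Inf, p = 0 with a
#' flag.
#'
#' @param values Numeric response vector.
#' @param groups Group labels, same length as `values`; every group needs at
#'   least two observations.
#' @return A tibble with columns `F`, `p`, `df1`, `df2`, `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least two groups")
  if (any(table(groups) < 2L)) stop("every group needs at least two values")
  k <- nlevels(groups)
  n <- length(values)
  ssb <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - mean(values))^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ssw == 0 && ssb == 0) {
    return(tibble::tibble(F = 0, p = 1, df1 = k - 1L, df2 = n - k,
                          degenerate = TRUE))
  }
  if (ssw == 0) {
    return(tibble::tibble(F = Inf, p = 0, df1 = k - 1L, df2 = n - k,
                          degenerate = TRUE))
  }
  fit <- stats::anova(stats::lm(values ~ groups))
  tibble::tibble(F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
                 df1 = fit$Df[1], df2 = fit$Df[2], degenerate = FALSE)
}

#' Holm-Bonferroni step-down adjustment
#'
#' @param p P-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Pairwise Welch t-tests over the four groups
#'
#' Raw two-sided Welch p-values for each unordered pair, in the fixed order
#' RT-RW, RT-ST, RT-SW, RW-ST, RW-SW, ST-SW (or the analogous order for a
#' different group set). Pairs of identical constant groups get p = 1;
#' constant groups with different means get p = 0.
#'
#' @param values Numeric response vector.
#' @param groups Group labels; each group needs >= 2 values.
#' @param group_order Group ordering defining the pair sequence.
#' @return Tibble with `group1`, `group2`, `p_raw`.
#' @export
pairwise_welch <- function(values, groups,
                           group_order = intersect(.groups_all,
                                                   unique(groups))) {
  groups <- as.character(groups)
  if (any(table(groups) < 2L)) stop("every group needs at least two values")
  pairs <- t(combn(group_order, 2))
  p <- apply(pairs, 1, function(pr) {
    x <- values[groups == pr[1]]
    y <- values[groups == pr[2]]
    if (sd(x) == 0 && sd(y) == 0) {
      return(if (mean(x) == mean(y)) 1 else 0)
    }
    tryCatch(stats::t.test(x, y)$p.value, error = function(e) NA_real_)
  })
  tibble::tibble(group1 = pairs[, 1], group2 = pairs[, 2], p_raw = p)
}

#' Compact letter display from pairwise decisions
#'
#' Insert-and-absorb algorithm: starting from one letter shared by all
#' groups, each significant pair splits every letter column containing both
#' members; columns that become subsets of another are absorbed. Groups
#' share a letter if and only if their pair is non-significant; the letter
#' set is minimal and letters are assigned in group order.
#'
#' @param decisions Tibble with `group1`, `group2` and logical `significant`.
#' @param groups Group labels in display order.
#' @return Named character vector: group -> letter string.
#' @export
compact_letters <- function(decisions, groups = .groups_all) {
  cols <- list(groups)  # each column: set of groups sharing one letter
  for (i in seq_len(nrow(decisions))) {
    if (!decisions$significant[i]) next
    g1 <- decisions$group1[i]; g2 <- decisions$group2[i]
    new_cols <- list()
    for (col in cols) {
      if (g1 %in% col && g2 %in% col) {
        new_cols <- c(new_cols, list(setdiff(col, g1)), list(setdiff(col, g2)))
      } else {
        new_cols <- c(new_cols, list(col))
      }
    }
    # absorb columns fully contained in another
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      for (b in seq_along(new_cols)) {
        if (a != b && keep[a] &&
            all(new_cols[[a]] %in% new_cols[[b]]) &&
            (length(new_cols[[a]]) < length(new_cols[[b]]) ||
             (length(new_cols[[a]]) == length(new_cols[[b]]) && a > b))) {
          keep[a] <- FALSE
        }
      }
    }
    cols <- new_cols[keep]
  }
  cols <- cols[lengths(cols) > 0]
  # order columns by their first member's position in `groups`
  first_pos <- vapply(cols, function(col) min(match(col, groups)), numeric(1))
  cols <- cols[order(first_pos)]
  out <- setNames(rep("", length(groups)), groups)
  for (j in seq_along(cols)) {
    letter <- letters[j]
    for (g in cols[[j]]) out[g] <- paste0(out[g], letter)
  }
  out
}

#' Descriptive screening of the index table
#'
#' For every (index x sampling day x experiment) stratum: a one-way ANOVA
#' across the four groups, pairwise Welch t-tests with Holm-Bonferroni
#' adjustment applied within the stratum's six pairs, and a compact letter
#' display at level `alpha`. Strata with a missing or degenerate group are
#' reported with status `"missing"`, never dropped silently.
#'
#' @param index_table Output of [spectral_index_table()].
#' @param alpha Significance level for letters (default 0.05).
#' @param index_names Index columns to screen; defaults to the registry set
#'   present in the table.
#' @return Long tibble: one row per (index, experiment, dat, pair) with
#'   columns `F`, `p_anova`, `p_raw`, `p_adj`, `significant`, a `letters`
#'   summary string (e.g. `"RT=a; RW=a; ST=b; SW=a"`), and `status`.
#' @export
screen_indices <- function(index_table, alpha = 0.05,
                           index_names = intersect(spectral_index_registry()$name,
                                                   names(index_table))) {
  stopifnot(length(index_names) > 0)
  groups_present <- intersect(.groups_all, unique(index_table$group))
  strata <- dplyr::distinct(index_table, .data$experiment, .data$dat)
  out <- list()
  for (s in seq_len(nrow(strata))) {
    sub <- dplyr::filter(index_table,
                         .data$experiment == strata$experiment[s],
                         .data$dat == strata$dat[s])
    for (idx in index_names) {
      v <- sub[[idx]]
      ok <- is.finite(v)
      g <- sub$group[ok]
      v <- v[ok]
      counts <- table(factor(g, levels = groups_present))
      if (any(counts < 2L)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          index = idx, experiment = strata$experiment[s], dat = strata$dat[s],
          F = NA_real_, p_anova = NA_real_,
          group1 = NA_character_, group2 = NA_character_,
          p_raw = NA_real_, p_adj = NA_real_, significant = NA,
          letters = NA_character_, status = "missing")
        next
      }
      aov_row <- one_way_anova(v, g)
      pw <- pairwise_welch(v, g, group_order = groups_present)
      pw$p_adj <- holm_adjust(pw$p_raw)
      pw$significant <- pw$p_adj < alpha
      lets <- compact_letters(pw, groups_present)
      let_str <- paste(sprintf("%s=%s", names(lets), lets), collapse = "; ")
      out[[length(out) + 1L]] <- dplyr::mutate(
        pw,
        index = idx, experiment = strata$experiment[s], dat = strata$dat[s],
        F = aov_row$F, p_anova = aov_row$p, letters = let_str, status = "ok",
        .before = 1)
    }
  }
  purrr::list_rbind(out) |>
    dplyr::relocate("index", "experiment", "dat", "F", "p_anova",
                    "group1", "group2", "p_raw", "p_adj", "significant",
                    "letters", "status")
}
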