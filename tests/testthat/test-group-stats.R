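test_that("one-way ANOVA matches the sums-of-squares oracle", {
  # hand case: groups {1,2} and {3,4}: SSB = 4, SSW = 1, F = 8 on (1, 2)
  res <- one_way_anova(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(res$F, 8)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 2)
  expect_equal(res$p, stats::pf(8, 1, 2, lower.tail = FALSE))

  withr::with_seed(5, {
    for (rep in 1:20) {
      g <- rep(c("RT", "RW", "ST", "SW"), each = sample(3:8, 1))
      v <- rnorm(length(g))
      got <- one_way_anova(v, g)
      want <- hand_anova(v, g)
      expect_equal(got$F, want$F, tolerance = 1e-10)
      expect_equal(got$p, want$p, tolerance = 1e-10)
    }
  })
})

test_that("degenerate ANOVA inputs are flagged, not crashed", {
  same <- one_way_anova(rep(2, 8), rep(c("a", "b"), each = 4))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  sep <- one_way_anova(c(1, 1, 5, 5), c("a", "a", "b", "b"))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)
  expect_true(sep$degenerate)
  expect_error(one_way_anova(1:3, c("a", "a", "b")), "at least two values")
})

test_that("ANOVA type-I error is near the nominal level", {
  withr::with_seed(1234, {
    rejections <- vapply(seq_len(1000), function(i) {
      v <- rnorm(40)
      g <- rep(c("RT", "RW", "ST", "SW"), each = 10)
      one_way_anova(v, g)$p < 0.05
    }, logical(1))
  })
  expect_gt(mean(rejections), 0.03)
  expect_lt(mean(rejections), 0.07)
})

test_that("Holm adjustment matches hand step-down and its containments", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(rep(1, 5)), rep(1, 5))
  expect_error(holm_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  withr::with_seed(8, {
    for (rep in 1:25) {
      p <- runif(sample(2:8, 1))^2
      adj <- holm_adjust(p)
      expect_equal(adj, hand_holm(p))
      expect_true(all(adj >= p))
      alpha <- 0.05
      holm_rej <- adj < alpha
      bonf_rej <- pmin(p * length(p), 1) < alpha
      raw_rej <- p < alpha
      expect_true(all(!holm_rej | raw_rej))   # holm subset of unadjusted
      expect_true(all(!bonf_rej | holm_rej))  # bonferroni subset of holm
    }
  })
})

test_that("pairwise Welch tests use the fixed pair order", {
  withr::with_seed(3, {
    v <- c(rnorm(10), rnorm(10), rnorm(10, 10), rnorm(10))
    g <- rep(c("RT", "RW", "ST", "SW"), each = 10)
  })
  pw <- pairwise_welch(v, g)
  expect_equal(nrow(pw), 6)
  expect_equal(paste(pw$group1, pw$group2),
               c("RT RW", "RT ST", "RT SW", "RW ST", "RW SW", "ST SW"))
  st_pairs <- pw$group1 == "ST" | pw$group2 == "ST"
  expect_true(max(pw$p_raw[st_pairs]) < min(pw$p_raw[!st_pairs]))

  ident <- pairwise_welch(rep(c(1, 1, 2, 2), each = 3),
                          rep(c("RT", "RW", "ST", "SW"), each = 3),
                          group_order = c("RT", "RW", "ST", "SW"))
  expect_equal(ident$p_raw[1], 1)  # RT-RW identical constants
  expect_equal(ident$p_raw[6], 1)  # ST-SW identical constants
  expect_equal(ident$p_raw[2], 0)  # RT-ST distinct constants
})

letters_fixture <- function(sig) {
  tibble::tibble(group1 = spectransfer:::.pair_order[, 1],
                 group2 = spectransfer:::.pair_order[, 2],
                 significant = sig)
}

test_that("compact letters reproduce the canonical patterns", {
  all_ns <- compact_letters(letters_fixture(rep(FALSE, 6)))
  expect_true(all(all_ns == "a"))

  # only ST differs from each of RT/RW/SW
  st_only <- letters_fixture(c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE))
  lets <- compact_letters(st_only)
  expect_equal(unname(lets[c("RT", "RW", "SW")]), rep("a", 3))
  expect_equal(unname(lets["ST"]), "b")

  all_sig <- compact_letters(letters_fixture(rep(TRUE, 6)))
  expect_equal(length(unique(all_sig)), 4)
  expect_true(all(nchar(all_sig) == 1))
})

# brute-force minimal clique cover: candidate letters are subsets containing
# no significant pair; every group and every non-significant pair must be
# covered; minimize the number of letters
brute_force_letters <- function(decisions, groups = c("RT", "RW", "ST", "SW")) {
  is_sig <- matrix(FALSE, 4, 4, dimnames = list(groups, groups))
  for (i in seq_len(nrow(decisions))) {
    if (decisions$significant[i]) {
      is_sig[decisions$group1[i], decisions$group2[i]] <- TRUE
      is_sig[decisions$group2[i], decisions$group1[i]] <- TRUE
    }
  }
  subsets <- unlist(lapply(1:4, function(k) combn(groups, k, simplify = FALSE)),
                    recursive = FALSE)
  ok <- Filter(function(s) {
    length(s) < 2 || all(!is_sig[t(combn(s, 2))])
  }, subsets)
  need_pairs <- which(!is_sig & upper.tri(is_sig), arr.ind = TRUE)
  for (n_letters in 1:4) {
    combos <- combn(seq_along(ok), n_letters, simplify = FALSE)
    for (cmb in combos) {
      cover <- ok[cmb]
      groups_covered <- all(groups %in% unlist(cover))
      pairs_covered <- all(apply(need_pairs, 1, function(pr) {
        a <- groups[pr[1]]; b <- groups[pr[2]]
        any(vapply(cover, function(s) a %in% s && b %in% s, logical(1)))
      }))
      if (groups_covered && (nrow(need_pairs) == 0 || pairs_covered)) {
        return(n_letters)
      }
    }
  }
  4L
}

test_that("compact letters are valid and minimal for all 64 decision sets", {
  for (code in 0:63) {
    sig <- as.logical(bitwAnd(code, 2^(0:5)))
    dec <- letters_fixture(sig)
    lets <- compact_letters(dec)
    # validity: share a letter iff pair non-significant
    for (i in 1:6) {
      g1 <- dec$group1[i]; g2 <- dec$group2[i]
      shares <- any(strsplit(lets[g1], "")[[1]] %in%
                      strsplit(lets[g2], "")[[1]])
      expect_equal(shares, !dec$significant[i],
                   info = sprintf("code %d pair %s-%s", code, g1, g2))
    }
    # minimality vs brute force
    n_used <- length(unique(unlist(strsplit(lets, ""))))
    expect_equal(n_used, brute_force_letters(dec),
                 info = sprintf("code %d", code))
  }
})

test_that("screening covers every index x day stratum with Holm letters", {
  cfg <- small_config(seed = 6)
  idx <- spectral_index_table(simulate_experiment(cfg, "Exp1"))
  scr <- screen_indices(idx)
  expect_equal(nrow(dplyr::distinct(scr, index, dat)), 16 * 4)
  expect_equal(nrow(scr), 16 * 4 * 6)  # six pairs per stratum
  expect_true(all(scr$status == "ok"))
  expect_true(all(scr$p_adj >= scr$p_raw, na.rm = TRUE))

  # a missing stratum is reported, not dropped
  idx_missing <- dplyr::filter(idx, !(group == "SW" & dat == 8))
  scr2 <- screen_indices(idx_missing)
  miss <- dplyr::filter(scr2, dat == 8)
  expect_true(all(miss$status == "missing"))
})
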