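# Shared fixtures and independent oracles for the suite.

# small generator configuration for fast tests
small_config <- function(seed = 42, noise = TRUE, ...) {
  domains <- default_domains()
  if (!noise) domains <- lapply(domains, function(d) {
    domain_shift(d$gain, d$offset, d$wavelength_shift, 0)
  })
  generator_config(n_plants_per_group = 6, leaves_per_plant = 2,
                   domains = domains, seed = seed, ...)
}

# configuration with identity domains and no random effects: pure base curves
deterministic_config <- function(seed = 1) {
  generator_config(n_plants_per_group = 2, leaves_per_plant = 1,
                   domains = list(Exp1 = domain_shift(),
                                  Exp2 = domain_shift()),
                   plant_effect_sd = 0, leaf_effect_sd = 0, seed = seed)
}

# one-row wide spectra tibble from a reflectance function of wavelength
spectrum_row <- function(f, wl = seq(450, 902, by = 2)) {
  vals <- as.list(setNames(vapply(wl, f, numeric(1)), paste0("wl_", wl)))
  tibble::as_tibble(vals)
}

flat_spectrum <- function(value = 0.5) spectrum_row(function(w) value)

# step spectrum: 0.1 below 700 nm, 0.5 at >= 700 nm
step_spectrum <- function() {
  spectrum_row(function(w) if (w < 700) 0.1 else 0.5)
}

# independent Holm step-down: sort, multiply by (m - i + 1), cumulative max,
# cap at 1, restore order
hand_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(cummax(p[o] * (m - seq_len(m) + 1)), 1)
  adj[order(o)]
}

# brute-force Kennard-Stone written independently from the implementation:
# naive loops over the greedy definition with lowest-index tie-breaks
brute_force_ks <- function(X, k) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- NULL; best_d <- -1
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (d(i, j) > best_d) { best_d <- d(i, j); best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < k) {
    cand_best <- NULL; cand_d <- -1
    for (i in setdiff(1:n, sel)) {
      mind <- min(vapply(sel, function(s) d(i, s), numeric(1)))
      if (mind > cand_d) { cand_d <- mind; cand_best <- i }
    }
    sel <- c(sel, cand_best)
  }
  sel
}

# direct sums-of-squares one-way ANOVA oracle
hand_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups,
                    function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(F = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# random confusion counts with all-positive total
random_counts <- function() {
  tibble::tibble(TP = sample(0:20, 1), FP = sample(0:20, 1),
                 TN = sample(0:20, 1), FN = sample(0:20, 1))
}
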