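#' Between-experiment domain shift
#'
#' A compact instrument/environment model for why spectra of the same leaf
#' differ between independent experiments: a multiplicative gain, an additive
#' reflectance offset, a wavelength registration error, and per-band Gaussian
#' noise. The noiseless part is affine in reflectance and a shift in
#' wavelength, so its effect on a known curve is exactly computable.
#'
#' @param gain Multiplicative reflectance factor, > 0.
#' @param offset Additive reflectance offset.
#' @param wavelength_shift Registration error in nm: a band labelled
#'   \eqn{\lambda} actually measures \eqn{\lambda + \Delta}. Must be smaller
#'   in magnitude than half the spectral range in use.
#' @param noise_sd Per-band Gaussian noise standard deviation (reflectance
#'   units), >= 0.
#' @return An object of class `domain_shift`.
#' @export
domain_shift <- function(gain = 1, offset = 0, wavelength_shift = 0,
                         noise_sd = 0) {
  stopifnot(gain > 0, noise_sd >= 0)
  structure(list(gain = gain, offset = offset,
                 wavelength_shift = wavelength_shift, noise_sd = noise_sd),
            class = "domain_shift")
}

#' Senescence model for the sensitive-treated (ST) group
#'
#' Glyphosate-sensitive treated plants senesce progressively: the chlorophyll
#' absorption dip at 670 nm becomes shallower, the red edge shifts toward the
#' blue, and the NIR plateau declines. Divergence from the other three groups
#' starts after `onset_dat` and grows linearly with `DAT - onset_dat`, so at
#' 2 DAT the four groups are indistinguishable while 6-8 DAT are separable.
#'
#' @param dip_recovery Reduction in chlorophyll dip depth per day after onset
#'   (reflectance units/day).
#' @param red_edge_shift Blue shift of the red-edge inflection per day after
#'   onset (nm/day).
#' @param plateau_decline Drop in NIR plateau reflectance per day after onset
#'   (reflectance units/day).
#' @param onset_dat Day after treatment at which ST divergence begins.
#' @return An object of class `senescence_model`.
#' @export
senescence_model <- function(dip_recovery = 0.01, red_edge_shift = 5,
                             plateau_decline = 0.03, onset_dat = 4) {
  stopifnot(dip_recovery >= 0, plateau_decline >= 0, onset_dat >= 0)
  structure(list(dip_recovery = dip_recovery, red_edge_shift = red_edge_shift,
                 plateau_decline = plateau_decline, onset_dat = onset_dat),
            class = "senescence_model")
}

#' Healthy-leaf base curve parameters
#'
#' The noiseless leaf curve is a logistic red-edge step from a low visible
#' level to a NIR plateau, minus Gaussian pigment absorption dips centred at
#' 670 nm (chlorophyll) and 500 nm (carotenoid).
#'
#' @param visible Reflectance level in the visible range.
#' @param nir_plateau Reflectance level of the NIR plateau.
#' @param red_edge_centre,red_edge_width Centre (nm) and width (nm) of the
#'   logistic red-edge transition.
#' @param chl_dip_depth,chl_dip_centre,chl_dip_sd Chlorophyll absorption dip:
#'   depth (reflectance), centre (nm), Gaussian sd (nm).
#' @param car_dip_depth,car_dip_centre,car_dip_sd Carotenoid absorption dip.
#' @return An object of class `base_curve`.
#' @export
base_curve <- function(visible = 0.08, nir_plateau = 0.55,
                       red_edge_centre = 715, red_edge_width = 10,
                       chl_dip_depth = 0.05, chl_dip_centre = 670,
                       chl_dip_sd = 25,
                       car_dip_depth = 0.03, car_dip_centre = 500,
                       car_dip_sd = 20) {
  structure(list(visible = visible, nir_plateau = nir_plateau,
                 red_edge_centre = red_edge_centre,
                 red_edge_width = red_edge_width,
                 chl_dip_depth = chl_dip_depth,
                 chl_dip_centre = chl_dip_centre, chl_dip_sd = chl_dip_sd,
                 car_dip_depth = car_dip_depth,
                 car_dip_centre = car_dip_centre, car_dip_sd = car_dip_sd),
            class = "base_curve")
}

#' Default domain shifts for three synthetic experiments
#'
#' Gains, offsets, registration errors and noise levels sized so that a
#' classifier trained naively on one experiment degrades on another, while a
#' projection- or updating-based transfer strategy can recover.
#'
#' @return A named list of three [domain_shift()] objects (`Exp1`-`Exp3`).
#' @export
default_domains <- function() {
  list(
    Exp1 = domain_shift(gain = 1.00, offset = 0.000, wavelength_shift = 0,
                        noise_sd = 0.006),
    Exp2 = domain_shift(gain = 0.92, offset = 0.020, wavelength_shift = 2,
                        noise_sd = 0.010),
    Exp3 = domain_shift(gain = 1.08, offset = -0.015, wavelength_shift = -2,
                        noise_sd = 0.008)
  )
}

#' Configuration for the synthetic spectra generator
#'
#' Bundles the wavelength grid, the experimental design (groups, plants,
#' leaves, sampling days), the leaf curve and senescence model, the
#' per-experiment domain shifts, and a seed. Identical configurations with
#' the same seed produce bit-identical output.
#'
#' @param wavelengths Strictly increasing wavelength grid in nm.
#' @param n_plants_per_group Plants per group per experiment (>= 1).
#' @param leaves_per_plant Leaves imaged per plant (>= 1).
#' @param dats Sampling days after treatment.
#' @param groups Subset of `c("RT", "RW", "ST", "SW")`.
#' @param base A [base_curve()].
#' @param senescence A [senescence_model()].
#' @param domains Named list of [domain_shift()], one per experiment.
#' @param plant_effect_sd,leaf_effect_sd Relative (fractional) Gaussian random
#'   effects on chlorophyll dip depth and NIR plateau at the plant and leaf
#'   level.
#' @param seed Integer seed.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(wavelengths = seq(450, 902, by = 2),
                             n_plants_per_group = 40,
                             leaves_per_plant = 3,
                             dats = c(2, 4, 6, 8),
                             groups = c("RT", "RW", "ST", "SW"),
                             base = base_curve(),
                             senescence = senescence_model(),
                             domains = default_domains(),
                             plant_effect_sd = 0.10,
                             leaf_effect_sd = 0.10,
                             seed = 1) {
  stopifnot(all(diff(wavelengths) > 0),
            n_plants_per_group >= 1, leaves_per_plant >= 1,
            length(dats) >= 1, length(groups) >= 1)
  if (!all(groups %in% .groups_all)) {
    stop("groups must be drawn from RT, RW, ST, SW")
  }
  rng <- diff(range(wavelengths))
  for (d in domains) {
    if (abs(d$wavelength_shift) >= rng / 2) {
      stop("a domain wavelength_shift exceeds half the spectral range")
    }
  }
  structure(list(wavelengths = wavelengths,
                 n_plants_per_group = as.integer(n_plants_per_group),
                 leaves_per_plant = as.integer(leaves_per_plant),
                 dats = dats, groups = groups, base = base,
                 senescence = senescence, domains = domains,
                 plant_effect_sd = plant_effect_sd,
                 leaf_effect_sd = leaf_effect_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# closed-form noiseless leaf curve at wavelengths `wl` for one leaf.
# `dip_effect`/`plateau_effect` are relative perturbations (plant + leaf
# random effects); senescence applies only to ST after its onset day.
leaf_curve <- function(wl, group, dat, base, senescence,
                       dip_effect = 0, plateau_effect = 0) {
  ramp <- if (group == "ST" && dat > senescence$onset_dat) {
    dat - senescence$onset_dat
  } else {
    0
  }
  dip <- pmax(base$chl_dip_depth * (1 + dip_effect) -
                senescence$dip_recovery * ramp, 0)
  plateau <- base$nir_plateau * (1 + plateau_effect) -
    senescence$plateau_decline * ramp
  centre <- base$red_edge_centre - senescence$red_edge_shift * ramp
  r <- base$visible +
    (plateau - base$visible) * plogis((wl - centre) / base$red_edge_width) -
    dip * exp(-(wl - base$chl_dip_centre)^2 / (2 * base$chl_dip_sd^2)) -
    base$car_dip_depth * exp(-(wl - base$car_dip_centre)^2 /
                               (2 * base$car_dip_sd^2))
  pmin(pmax(r, 0.001), 0.999)
}

#' Simulate one leaf spectrum
#'
#' Evaluates the closed-form leaf curve for a group and sampling day, applies
#' a domain shift (registration error, gain, offset, optional noise), and
#' clips to (0.001, 0.999). With an identity domain, zero effects and zero
#' noise this is the deterministic base curve.
#'
#' @param group One of the configured group labels.
#' @param dat One of the configured sampling days.
#' @param domain A [domain_shift()]; default identity.
#' @param config A [generator_config()].
#' @param dip_effect,plateau_effect Relative random-effect perturbations of
#'   the chlorophyll dip depth and NIR plateau for this leaf.
#' @param noise Logical; draw per-band Gaussian noise from the current RNG
#'   stream (`domain$noise_sd`). Leave `FALSE` for the noiseless curve.
#' @return A tibble with columns `wavelength` (nm) and `reflectance`.
#' @export
simulate_spectrum <- function(group, dat, domain = domain_shift(),
                              config = generator_config(),
                              dip_effect = 0, plateau_effect = 0,
                              noise = FALSE) {
  if (!group %in% config$groups) {
    stop(sprintf("unknown group label '%s'", group))
  }
  if (!dat %in% config$dats) {
    stop(sprintf("day %s is not in the configured sampling days", dat))
  }
  wl <- config$wavelengths
  r <- leaf_curve(wl + domain$wavelength_shift, group, dat, config$base,
                  config$senescence, dip_effect, plateau_effect)
  r <- domain$gain * r + domain$offset
  if (noise && domain$noise_sd > 0) {
    r <- r + rnorm(length(wl), 0, domain$noise_sd)
  }
  tibble::tibble(wavelength = wl,
                 reflectance = pmin(pmax(r, 0.001), 0.999))
}

#' Simulate a full experiment of leaf spectra
#'
#' Generates one spectrum per (group x plant x leaf x sampling day) under the
#' experiment's domain shift. Plant- and leaf-level random effects perturb
#' the chlorophyll dip depth and NIR plateau and are held fixed across days,
#' mimicking repeated imaging of the same plants. Output is deterministic in
#' `config$seed` and the experiment's position among the configured domains.
#'
#' @param config A [generator_config()].
#' @param experiment_id Name of a domain in `config$domains`.
#' @return A wide tibble with one row per leaf spectrum: columns
#'   `experiment`, `plant_id`, `leaf_id`, `cultivar` (R/S), `treatment`
#'   (T/W), `group`, `dat`, then `wl_<nm>` reflectance columns.
#' @export
simulate_experiment <- function(config = generator_config(),
                                experiment_id = "Exp1") {
  if (!experiment_id %in% names(config$domains)) {
    stop(sprintf("unknown experiment_id '%s'", experiment_id))
  }
  exp_index <- match(experiment_id, names(config$domains))
  domain <- config$domains[[experiment_id]]
  wl <- config$wavelengths
  shifted <- wl + domain$wavelength_shift

  design <- tidyr::expand_grid(
    group = config$groups,
    plant = seq_len(config$n_plants_per_group),
    leaf = seq_len(config$leaves_per_plant),
    dat = config$dats
  )

  withr::with_seed(config$seed + 7919L * exp_index, {
    n_plants <- length(config$groups) * config$n_plants_per_group
    plant_fx <- matrix(rnorm(n_plants * 2, 0, config$plant_effect_sd),
                       ncol = 2)
    n_leaves <- n_plants * config$leaves_per_plant
    leaf_fx <- matrix(rnorm(n_leaves * 2, 0, config$leaf_effect_sd),
                      ncol = 2)

    plant_key <- paste(design$group, design$plant)
    leaf_key <- paste(design$group, design$plant, design$leaf)
    pi <- match(plant_key, unique(plant_key))
    li <- match(leaf_key, unique(leaf_key))
    dip_eff <- plant_fx[pi, 1] + leaf_fx[li, 1]
    plat_eff <- plant_fx[pi, 2] + leaf_fx[li, 2]

    refl <- matrix(0, nrow = nrow(design), ncol = length(wl))
    for (i in seq_len(nrow(design))) {
      refl[i, ] <- leaf_curve(shifted, design$group[i], design$dat[i],
                              config$base, config$senescence,
                              dip_eff[i], plat_eff[i])
    }
    refl <- domain$gain * refl + domain$offset
    if (domain$noise_sd > 0) {
      refl <- refl + matrix(rnorm(length(refl), 0, domain$noise_sd),
                            nrow = nrow(refl))
    }
    refl <- pmin(pmax(refl, 0.001), 0.999)
  })

  colnames(refl) <- paste0("wl_", wl)
  dplyr::bind_cols(
    tibble::tibble(
      experiment = experiment_id,
      plant_id = sprintf("%s_%s_P%02d", experiment_id, design$group,
                         design$plant),
      leaf_id = design$leaf,
      cultivar = substr(design$group, 1, 1),
      treatment = substr(design$group, 2, 2),
      group = design$group,
      dat = design$dat
    ),
    tibble::as_tibble(refl)
  )
}

#' Simulate all configured experiments
#'
#' @param config A [generator_config()].
#' @return Row-bound tibble of [simulate_experiment()] over every domain.
#' @export
simulate_study <- function(config = generator_config()) {
  purrr::map(names(config$domains),
             function(id) simulate_experiment(config, id)) |>
    purrr::list_rbind()
}
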