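#' The sixteen-index spectral feature registry
#'
#' Declarative registry of the vegetation indices used as the feature space
#' for all screening and classification: each entry is a name and an
#' arithmetic formula over `R<nm>` band reflectances. Formulas are the
#' canonical literature forms. The blue bands of EVI and SIPI are mapped to
#' 450 nm, the floor of the analysed 450-902 nm window.
#'
#' The registry is data: pass a modified tibble to swap indices in or out
#' without code changes.
#'
#' @return A tibble with columns `name` and `formula`; required wavelengths
#'   are parsed from the formula.
#' @export
spectral_index_registry <- function() {
  tibble::tribble(
    ~name,          ~formula,
    "NDVI",         "(R800 - R670) / (R800 + R670)",
    "GNDVI",        "(R800 - R550) / (R800 + R550)",
    "RDVI",         "(R800 - R670) / sqrt(R800 + R670)",
    "EVI",          "2.5 * (R800 - R670) / (R800 + 6 * R670 - 7.5 * R450 + 1)",
    "NRI",          "(R570 - R670) / (R570 + R670)",
    "TVI",          "0.5 * (120 * (R750 - R550) - 200 * (R670 - R550))",
    "PRI",          "(R531 - R570) / (R531 + R570)",
    "ARI",          "1 / R550 - 1 / R700",
    "PSRI",         "(R680 - R500) / R750",
    "SIPI",         "(R800 - R450) / (R800 - R680)",
    "TCARI",        "3 * ((R700 - R670) - 0.2 * (R700 - R550) * (R700 / R670))",
    "OSAVI",        "1.16 * (R800 - R670) / (R800 + R670 + 0.16)",
    "TCARI_OSAVI",  "(3 * ((R700 - R670) - 0.2 * (R700 - R550) * (R700 / R670))) / (1.16 * (R800 - R670) / (R800 + R670 + 0.16))",
    "MCARI",        "((R700 - R670) - 0.2 * (R700 - R550)) * (R700 / R670)",
    "ZM",           "R750 / R710",
    "CRI550",       "1 / R510 - 1 / R550"
  )
}

# wavelengths referenced by a registry formula, e.g. c(800, 670)
formula_wavelengths <- function(formula) {
  as.numeric(unique(regmatches(formula,
                               gregexpr("(?<=R)[0-9]+", formula,
                                        perl = TRUE))[[1]]))
}

#' Reflectance at the nearest grid band
#'
#' Maps a requested wavelength to the nearest band of the table's grid
#' (ties to the lower wavelength); an error if the nearest band is more than
#' `tolerance` nm away.
#'
#' @param data Wide spectra tibble.
#' @param wavelength Requested wavelength in nm.
#' @param tolerance Maximum nm distance to the nearest band.
#' @return Numeric vector of reflectance, one value per row.
#' @export
band_at <- function(data, wavelength, tolerance = 5) {
  m <- spectra_matrix(data)
  i <- nearest_band(attr(m, "wavelengths"), wavelength, tolerance)
  unname(m[, i])
}

#' Compute one spectral index
#'
#' Band lookups that fail (no grid band within 5 nm) are errors; legitimate
#' degenerate arithmetic (a zero denominator) yields `NaN`, the explicit
#' "undefined" marker, never an error and never a silent 0.
#'
#' @param data Wide spectra tibble.
#' @param formula Arithmetic expression over `R<nm>` terms.
#' @return Numeric vector, one value per row; `NaN`/`Inf` mark undefined.
#' @export
compute_index <- function(data, formula) {
  wls <- formula_wavelengths(formula)
  env <- new.env(parent = baseenv())
  for (w in wls) assign(paste0("R", w), band_at(data, w), envir = env)
  v <- eval(parse(text = formula)[[1]], envir = env)
  v[!is.finite(v)] <- NaN
  v
}

#' Build the samples-by-indices feature table
#'
#' One row per input spectrum, one column per registry index (in registry
#' order), with all label columns carried through. Rows where any index is
#' undefined are flagged via `.flagged` and are excluded from modelling by
#' default downstream.
#'
#' @param data Wide spectra tibble (non-empty).
#' @param registry Index registry tibble; default [spectral_index_registry()].
#' @return Tibble: label columns, then one numeric column per index, then
#'   `.flagged`.
#' @export
spectral_index_table <- function(data, registry = spectral_index_registry()) {
  if (nrow(data) == 0L) stop("empty spectra table")
  if (anyDuplicated(registry$name)) stop("registry names must be unique")
  vals <- purrr::map(registry$formula, function(f) compute_index(data, f))
  names(vals) <- registry$name
  idx <- tibble::as_tibble(vals)
  labels <- dplyr::select(data, -dplyr::all_of(wl_cols(data)))
  dplyr::bind_cols(labels, idx) |>
    dplyr::mutate(.flagged = apply(is.na(idx), 1, any))
}
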