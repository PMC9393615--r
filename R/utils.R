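#' @importFrom rlang .data
#' @importFrom stats plogis rnorm runif median sd setNames predict
#' @importFrom utils read.csv head combn
NULL

# canonical group labels and the fixed pairwise-comparison order used everywhere
.groups_all <- c("RT", "RW", "ST", "SW")
.pair_order <- matrix(
  c("RT", "RW",
    "RT", "ST",
    "RT", "SW",
    "RW", "ST",
    "RW", "SW",
    "ST", "SW"),
  ncol = 2, byrow = TRUE
)

#' Wavelength helpers for wide spectra tables
#'
#' Spectra tables store one leaf per row with reflectance in columns named
#' `wl_<nm>`. These helpers locate those columns and convert between the
#' wide table and a plain numeric matrix.
#'
#' @param data A data frame with `wl_<nm>` reflectance columns.
#' @return `wl_cols()` returns the column names; `wl_grid()` the numeric
#'   wavelengths (nm); `spectra_matrix()` a rows-by-bands numeric matrix with
#'   a `wavelengths` attribute.
#' @export
wl_cols <- function(data) {
  grep("^wl_[0-9]+(\\.[0-9]+)?$", names(data), value = TRUE)
}

#' @rdname wl_cols
#' @export
wl_grid <- function(data) {
  as.numeric(sub("^wl_", "", wl_cols(data)))
}

#' @rdname wl_cols
#' @export
spectra_matrix <- function(data) {
  cols <- wl_cols(data)
  if (length(cols) == 0L) stop("no `wl_<nm>` reflectance columns found")
  m <- as.matrix(as.data.frame(data)[, cols, drop = FALSE])
  dimnames(m) <- list(NULL, cols)
  attr(m, "wavelengths") <- as.numeric(sub("^wl_", "", cols))
  m
}

# round-half-up (R's round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

# nearest band index for a requested wavelength; error beyond `tolerance` nm.
# Ties between two equally near bands resolve to the lower wavelength.
nearest_band <- function(wavelengths, wavelength, tolerance = 5) {
  d <- abs(wavelengths - wavelength)
  i <- which(d == min(d))[1]  # grid sorted ascending, so first hit = lower wl
  if (d[i] > tolerance) {
    stop(sprintf("no band within %g nm of %g nm (nearest: %g nm)",
                 tolerance, wavelength, wavelengths[i]))
  }
  i
}

# label a spectra table's grouping: cultivar + treatment -> RT/RW/ST/SW
add_group_column <- function(data) {
  if (!all(c("cultivar", "treatment") %in% names(data))) {
    stop("expected `cultivar` and `treatment` columns")
  }
  dplyr::mutate(data, group = paste0(.data$cultivar, .data$treatment),
                .after = "treatment")
}
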