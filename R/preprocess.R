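#' Black/white reference calibration
#'
#' Converts raw counts to reflectance with the standard two-point
#' correction `(raw - dark) / (white - dark)`. No clipping is applied:
#' out-of-range reflectance is an outlier signal handled downstream, not
#' silently repaired.
#'
#' @param raw,dark,white [spectral_cube()]s sharing shape and wavelengths;
#'   `white - dark` must be strictly positive everywhere.
#' @return A reflectance [spectral_cube()].
#' @export
calibrate <- function(raw, dark, white) {
  stopifnot(inherits(raw, "spectral_cube"), inherits(dark, "spectral_cube"),
            inherits(white, "spectral_cube"))
  if (!identical(dim(raw$values), dim(dark$values)) ||
      !identical(dim(raw$values), dim(white$values)) ||
      !isTRUE(all.equal(raw$wavelengths, dark$wavelengths)) ||
      !isTRUE(all.equal(raw$wavelengths, white$wavelengths))) {
    stop("raw, dark and white cubes must share shape and wavelengths")
  }
  denom <- white$values - dark$values
  if (any(denom <= 0)) {
    stop("white - dark must be positive for every pixel and band")
  }
  spectral_cube((raw$values - dark$values) / denom, raw$wavelengths,
                kind = "reflectance")
}

#' Threshold segmentation of the plant region
#'
#' Separates plant from background by thresholding reflectance at a single
#' band (nearest grid band to the requested wavelength, within 5 nm).
#'
#' @param cube A reflectance [spectral_cube()].
#' @param wavelength Segmentation wavelength in nm.
#' @param threshold Reflectance threshold; pixels strictly above are plant.
#' @return A logical rows x cols mask.
#' @export
segment_plant <- function(cube, wavelength = 792, threshold = 0.1) {
  stopifnot(inherits(cube, "spectral_cube"))
  if (cube$kind != "reflectance") {
    stop("segment_plant expects a reflectance cube; calibrate first")
  }
  band <- nearest_band(cube$wavelengths, wavelength)
  cube$values[, , band] > threshold
}

#' Remove manually annotated stem rectangles from a mask
#'
#' Rectangles use 0-based pixel coordinates, half-open on both axes:
#' `[x, x + width) x [y, y + height)` with `x` the column and `y` the row.
#' A rectangle extending outside the image is an error, not a silent clip.
#'
#' @param mask Logical matrix.
#' @param rectangles Data frame with columns `x`, `y`, `width`, `height`.
#' @return The mask with all rectangle pixels set `FALSE`.
#' @export
remove_stems <- function(mask, rectangles) {
  stopifnot(is.matrix(mask), is.logical(mask))
  if (is.null(rectangles) || nrow(rectangles) == 0L) return(mask)
  for (i in seq_len(nrow(rectangles))) {
    r <- rectangles[i, ]
    if (r$x < 0 || r$y < 0 || r$width < 1 || r$height < 1 ||
        r$x + r$width > ncol(mask) || r$y + r$height > nrow(mask)) {
      stop(sprintf("stem rectangle %d is outside the image bounds", i))
    }
    mask[(r$y + 1):(r$y + r$height), (r$x + 1):(r$x + r$width)] <- FALSE
  }
  mask
}

#' Label connected leaf components
#'
#' 8-connected components of a binary mask, filtered to a minimum pixel
#' area and labelled 1..k in raster order (row-major) of each component's
#' first pixel. Labelling is done by iterative label propagation to the
#' eight neighbours, which is exact and fast for tray-sized masks.
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component size in pixels.
#' @return An integer matrix; 0 is background, components are 1..k.
#' @export
extract_leaves <- function(mask, min_area = 50) {
  stopifnot(is.matrix(mask), is.logical(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  # raster-order (row-major) provisional labels so that the final relabelling
  # tie-break is already encoded in the label values
  raster_id <- (row(mask) - 1L) * nc + col(mask)  # row-major position

  shift <- function(m, dr, dc) {
    out <- matrix(Inf, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  labf <- matrix(Inf, nr, nc)
  labf[mask] <- raster_id[mask]
  repeat {
    nb <- labf
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                   c(0, 1), c(1, -1), c(1, 0), c(1, 1))) {
      nb <- pmin(nb, shift(labf, d[1], d[2]))
    }
    nb[!mask] <- Inf
    if (all(nb[mask] == labf[mask])) break
    labf <- nb
  }
  comp <- matrix(0L, nr, nc)
  if (any(mask)) {
    roots <- labf[mask]
    sizes <- table(roots)
    keep <- as.numeric(names(sizes)[sizes >= min_area])
    keep <- keep[order(keep)]  # raster order of first pixel
    comp[mask] <- match(roots, keep, nomatch = 0L)
  }
  comp
}

#' Mean spectrum of one component
#'
#' @param cube A reflectance [spectral_cube()].
#' @param component Logical matrix (or integer matrix with `label` given)
#'   selecting the component's pixels; must be non-empty.
#' @param label Component label to select when `component` is integer.
#' @param labels Optional named list/one-row data frame of sample labels
#'   (experiment, cultivar, treatment, dat, plant_id, leaf_id) carried into
#'   the output.
#' @return One-row wide tibble: labels, `n_pixels`, then `wl_<nm>` columns.
#' @export
mean_spectrum <- function(cube, component, label = NULL, labels = NULL) {
  stopifnot(inherits(cube, "spectral_cube"))
  sel <- if (is.logical(component)) component else component == label
  n <- sum(sel)
  if (n == 0L) stop("component is empty")
  vals <- apply(cube$values, 3, function(plane) mean(plane[sel]))
  out <- tibble::as_tibble(as.list(setNames(vals,
                                            paste0("wl_", cube$wavelengths))))
  out <- dplyr::bind_cols(tibble::tibble(n_pixels = n), out)
  if (!is.null(labels)) {
    out <- dplyr::bind_cols(tibble::as_tibble(as.list(labels)), out)
  }
  out
}

#' Trim a spectra table to an analysis wavelength window
#'
#' Keeps reflectance columns with `low <= wavelength <= high` (inclusive).
#' Idempotent; errors if no band falls in the window.
#'
#' @param data Wide spectra tibble with `wl_<nm>` columns.
#' @param low,high Window bounds in nm.
#' @return The tibble with out-of-window reflectance columns dropped.
#' @export
trim_bands <- function(data, low = 450, high = 902) {
  stopifnot(low <= high)  # equal bounds keep a single band (inclusive window)
  cols <- wl_cols(data)
  wl <- as.numeric(sub("^wl_", "", cols))
  drop <- cols[wl < low | wl > high]
  if (length(drop) == length(cols)) {
    stop("no bands remain in the requested window")
  }
  dplyr::select(data, -dplyr::all_of(drop))
}

#' Screen leaf spectra for measurement outliers
#'
#' Applies, in order: (1) any band below `min_reflectance` or above
#' `max_reflectance`; (2) mean near-infrared (780-900 nm) reflectance below
#' `nir_floor` (a leaf should have a bright NIR plateau; a background or
#' mis-segmented spectrum does not); (3) Euclidean distance to the spectrum's
#' stratum mean (experiment x group x dat, as available) exceeding
#' `distance_mult` times the stratum's median such distance. The distance
#' rule is evaluated once against the full input, not iterated.
#'
#' @param data Wide spectra tibble.
#' @param min_reflectance,max_reflectance Physical band limits.
#' @param nir_floor Minimum mean reflectance over 780-900 nm.
#' @param distance_mult Multiplier of the stratum median distance.
#' @return The input with logical `.outlier` and character `.reason`
#'   (`NA` for retained rows) columns appended.
#' @export
reject_outliers <- function(data, min_reflectance = 0, max_reflectance = 1.2,
                            nir_floor = 0.15, distance_mult = 4) {
  m <- spectra_matrix(data)
  wl <- attr(m, "wavelengths")
  reason <- rep(NA_character_, nrow(m))

  bad_band <- apply(m, 1, function(r) any(r < min_reflectance | r > max_reflectance))
  reason[bad_band] <- "band outside physical range"

  nir <- wl >= 780 & wl <= 900
  if (any(nir)) {
    low_nir <- rowMeans(m[, nir, drop = FALSE]) < nir_floor
    reason[is.na(reason) & low_nir] <- "mean NIR reflectance below floor"
  }

  strata_cols <- intersect(c("experiment", "group", "dat"), names(data))
  key <- if (length(strata_cols)) {
    do.call(paste, c(as.data.frame(data)[strata_cols], sep = "|"))
  } else {
    rep("all", nrow(m))
  }
  for (k in unique(key)) {
    idx <- which(key == k)
    if (length(idx) < 3L) next
    centre <- colMeans(m[idx, , drop = FALSE])
    d <- sqrt(rowSums((m[idx, , drop = FALSE] -
                         matrix(centre, length(idx), ncol(m), byrow = TRUE))^2))
    med <- median(d)
    if (med > 0) {
      far <- d > distance_mult * med
      hit <- idx[far]
      reason[hit[is.na(reason[hit])]] <- "far from stratum mean spectrum"
    }
  }

  dplyr::mutate(data, .outlier = !is.na(reason), .reason = reason)
}

#' Extract per-leaf mean spectra from a rendered or measured scene
#'
#' The full preprocessing chain: calibrate with the dark/white references,
#' segment the plant at 792 nm / 0.1 reflectance, remove annotated stem
#' rectangles, label 8-connected leaves, and average each leaf's pixels.
#'
#' @param raw,dark,white [spectral_cube()]s.
#' @param stems Data frame of stem rectangles (`x, y, width, height`).
#' @param min_area Minimum leaf area in pixels.
#' @param wavelength,threshold Segmentation parameters.
#' @return Wide tibble, one row per detected leaf (`leaf` label in raster
#'   order), with `n_pixels` and `wl_<nm>` columns.
#' @export
extract_leaf_spectra <- function(raw, dark, white, stems = NULL,
                                 min_area = 50, wavelength = 792,
                                 threshold = 0.1) {
  refl <- calibrate(raw, dark, white)
  mask <- segment_plant(refl, wavelength, threshold)
  if (!is.null(stems)) mask <- remove_stems(mask, stems)
  comp <- extract_leaves(mask, min_area)
  k <- max(comp)
  if (k == 0L) return(tibble::tibble())
  purrr::map(seq_len(k), function(i) {
    mean_spectrum(refl, comp, label = i, labels = list(leaf = i))
  }) |>
    purrr::list_rbind()
}
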