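#' Render a synthetic hyperspectral tray scene
#'
#' Places each supplied leaf spectrum as a non-overlapping ellipse on a dark
#' background, attaches a stem rectangle beneath each leaf, and converts
#' reflectance to raw counts through dark/white reference frames:
#' `raw = dark + reflectance * (white - dark)`, plus optional pixel noise.
#' Background reflectance is flat and below the 0.1 segmentation threshold
#' at 792 nm by construction; leaves and stems are above it.
#'
#' Leaves are laid out on a grid with margins, so placements never overlap;
#' an error is raised if more spectra are supplied than grid cells exist.
#'
#' @param spectra Wide tibble of leaf spectra (`wl_<nm>` columns), one row
#'   per leaf to draw.
#' @param n_rows,n_cols Image size in pixels.
#' @param leaf_rx,leaf_ry Ellipse semi-axes in pixels.
#' @param stem_height,stem_width Stem rectangle size in pixels.
#' @param background_reflectance Flat background reflectance (< 0.1).
#' @param dark_counts,white_counts Reference frame count levels.
#' @param pixel_noise_sd Per-pixel reflectance noise added to leaf/stem
#'   pixels before the affine counts transform.
#' @return A list of class `hsi_scene`: `raw`, `dark`, `white`
#'   ([spectral_cube()]s), `stems` (tibble of 0-based half-open rectangles
#'   `x, y, width, height`), and `leaves` (tibble of leaf centres with the
#'   input row index).
#' @export
render_cube <- function(spectra, n_rows = 60, n_cols = 90,
                        leaf_rx = 9, leaf_ry = 6,
                        stem_height = 4, stem_width = 3,
                        background_reflectance = 0.05,
                        dark_counts = 100, white_counts = 4000,
                        pixel_noise_sd = 0) {
  refl <- spectra_matrix(spectra)
  wl <- attr(refl, "wavelengths")
  n_leaf <- nrow(refl)

  cell_w <- 2 * leaf_rx + 4
  cell_h <- 2 * leaf_ry + stem_height + 6
  per_row <- n_cols %/% cell_w
  n_fit <- per_row * (n_rows %/% cell_h)
  if (n_leaf > n_fit) {
    stop(sprintf("cannot place %d leaves without overlap (capacity %d)",
                 n_leaf, n_fit))
  }

  n_bands <- length(wl)
  rmat <- matrix(background_reflectance, n_rows, n_cols)
  refl_cube <- array(background_reflectance, c(n_rows, n_cols, n_bands))
  owner <- matrix(0L, n_rows, n_cols)   # which leaf's spectrum a pixel carries

  stems <- vector("list", n_leaf)
  leaves <- vector("list", n_leaf)
  for (i in seq_len(n_leaf)) {
    gx <- (i - 1) %% per_row
    gy <- (i - 1) %/% per_row
    cx <- gx * cell_w + cell_w / 2          # 0-based pixel coordinates
    cy <- gy * cell_h + leaf_ry + 2
    px <- rep(seq_len(n_cols) - 1, each = n_rows)
    py <- rep(seq_len(n_rows) - 1, times = n_cols)
    inside <- ((px - cx) / leaf_rx)^2 + ((py - cy) / leaf_ry)^2 <= 1
    owner[cbind(py[inside] + 1, px[inside] + 1)] <- i
    sx <- round(cx - stem_width / 2)
    sy <- round(cy + leaf_ry + 1)
    stems[[i]] <- tibble::tibble(x = sx, y = sy,
                                 width = stem_width, height = stem_height)
    owner[(sy + 1):(sy + stem_height), (sx + 1):(sx + stem_width)] <- i
    leaves[[i]] <- tibble::tibble(leaf_row = i, cx = cx, cy = cy)
  }

  assigned <- which(owner > 0L)
  for (b in seq_len(n_bands)) {
    plane <- matrix(background_reflectance, n_rows, n_cols)
    plane[assigned] <- refl[owner[assigned], b]
    refl_cube[, , b] <- plane
  }
  if (pixel_noise_sd > 0) {
    noise <- array(rnorm(length(refl_cube), 0, pixel_noise_sd),
                   dim = dim(refl_cube))
    mask3 <- array(rep(owner > 0L, n_bands), dim = dim(refl_cube))
    refl_cube <- refl_cube + noise * mask3
  }

  dark <- array(dark_counts, dim = dim(refl_cube))
  white <- array(white_counts, dim = dim(refl_cube))
  raw <- dark + refl_cube * (white - dark)

  structure(list(
    raw = spectral_cube(raw, wl, "raw"),
    dark = spectral_cube(dark, wl, "raw"),
    white = spectral_cube(white, wl, "raw"),
    stems = purrr::list_rbind(stems),
    leaves = purrr::list_rbind(leaves)
  ), class = "hsi_scene")
}
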