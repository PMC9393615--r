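#' Hyperspectral cube container
#'
#' A minimal in-memory cube: a rows x cols x bands numeric array plus the
#' per-band wavelengths and whether the values are raw counts or reflectance.
#'
#' @param values 3-D numeric array (rows x cols x bands).
#' @param wavelengths Strictly increasing nm values, one per band.
#' @param kind `"raw"` (counts) or `"reflectance"`.
#' @return An object of class `spectral_cube`.
#' @export
spectral_cube <- function(values, wavelengths, kind = c("raw", "reflectance")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(values)) == 3L,
            dim(values)[3] == length(wavelengths),
            all(diff(wavelengths) > 0))
  structure(list(values = values, wavelengths = wavelengths, kind = kind),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<spectral_cube> %d x %d pixels, %d bands (%g-%g nm), %s\n",
              d[1], d[2], d[3], min(x$wavelengths), max(x$wavelengths),
              x$kind))
  invisible(x)
}

#' Write and read ENVI cubes (BIL interleave)
#'
#' Minimal ENVI support: a plain-text `.hdr` with `samples`, `lines`,
#' `bands`, `data type` (4 = float32), `interleave = bil`, `byte order = 0`
#' and a `wavelength` list, alongside a binary data file. Band-interleaved-
#' by-line layout: for each image line, all bands of that line in sequence.
#'
#' @param cube A [spectral_cube()].
#' @param path File stem; `<path>.hdr` and `<path>.bil` are written/read.
#' @return `write_envi()` returns `path` invisibly; `read_envi()` returns a
#'   [spectral_cube()] (kind taken from a `spectransfer kind` header note,
#'   defaulting to `"raw"`).
#' @export
write_envi <- function(cube, path) {
  stopifnot(inherits(cube, "spectral_cube"))
  d <- dim(cube$values)
  hdr <- c(
    "ENVI",
    "description = {synthetic cube written by spectransfer}",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 4",
    "interleave = bil",
    "byte order = 0",
    sprintf("kind = %s", cube$kind),
    sprintf("wavelength = {%s}",
            paste(format(cube$wavelengths, trim = TRUE), collapse = ", "))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".bil"), "wb")
  on.exit(close(con))
  # BIL: line-major, band within line, sample within band
  for (line in seq_len(d[1])) {
    block <- t(cube$values[line, , ])     # bands x samples
    writeBin(as.numeric(t(block)), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' @rdname write_envi
#' @export
read_envi <- function(path) {
  hdr_lines <- readLines(paste0(path, ".hdr"))
  hdr <- paste(hdr_lines, collapse = "\n")
  get_field <- function(name) {
    m <- regmatches(hdr, regexpr(sprintf("%s\\s*=\\s*[^\n{]+", name), hdr))
    if (length(m) == 0) stop(sprintf("header field '%s' missing", name))
    trimws(sub(".*=", "", m))
  }
  samples <- as.integer(get_field("samples"))
  lines <- as.integer(get_field("lines"))
  bands <- as.integer(get_field("bands"))
  dtype <- as.integer(get_field("data type"))
  interleave <- tolower(get_field("interleave"))
  if (dtype != 4L) stop("only data type 4 (float32) is supported")
  if (interleave != "bil") stop("only BIL interleave is supported")
  kind <- tryCatch(get_field("kind"), error = function(e) "raw")
  wl_txt <- regmatches(hdr, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", hdr))
  if (length(wl_txt) == 0) stop("wavelength list missing from header")
  wl <- as.numeric(strsplit(gsub(".*\\{|\\}", "", wl_txt), ",")[[1]])

  con <- file(paste0(path, ".bil"), "rb")
  on.exit(close(con))
  raw <- readBin(con, what = "numeric", n = samples * lines * bands,
                 size = 4, endian = "little")
  values <- array(0, dim = c(lines, samples, bands))
  per_line <- samples * bands
  for (line in seq_len(lines)) {
    block <- matrix(raw[((line - 1) * per_line + 1):(line * per_line)],
                    nrow = bands, byrow = TRUE)  # bands x samples
    values[line, , ] <- t(block)
  }
  spectral_cube(values, wl,
                kind = if (kind %in% c("raw", "reflectance")) kind else "raw")
}
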