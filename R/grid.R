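#' Wavelength grids
#'
#' A wavelength grid records which sensor produced a spectrum and the
#' wavelength (nm) of every channel. The Vis-NIR handheld device emits two
#' derived spectra per scan (one per light source); these are concatenated, so
#' a Vis-NIR grid carries 1200 channels in two 600-channel blocks, each block
#' strictly increasing over 400-1000 nm. The NIR device yields a single
#' 252-channel block over 900-1700 nm.
#'
#' @param sensor `"visnir"` or `"nir"`.
#' @param wavelengths_nm Numeric vector of channel wavelengths in nm.
#' @param block Integer vector assigning each channel to a source block
#'   (all `1` for NIR; `1`/`2` for the two Vis-NIR blocks).
#' @return A `wavelength_grid` object (list with `sensor`, `wavelengths_nm`,
#'   `block`, `n_channels`).
#' @examples
#' g <- nir_grid()
#' g$n_channels
#' @export
wavelength_grid <- function(sensor, wavelengths_nm, block = rep(1L, length(wavelengths_nm))) {
  sensor <- match.arg(sensor, c("visnir", "nir"))
  wavelengths_nm <- as.numeric(wavelengths_nm)
  block <- as.integer(block)
  if (length(block) != length(wavelengths_nm)) {
    abort("`block` must have one entry per wavelength.")
  }
  for (b in unique(block)) {
    w <- wavelengths_nm[block == b]
    if (any(diff(w) <= 0)) {
      abort(sprintf("wavelengths must be strictly increasing within block %d", b))
    }
  }
  structure(
    list(
      sensor = sensor,
      wavelengths_nm = wavelengths_nm,
      block = block,
      n_channels = length(wavelengths_nm)
    ),
    class = "wavelength_grid"
  )
}

#' @rdname wavelength_grid
#' @export
visnir_grid <- function() {
  w <- seq(400, 1000, length.out = 600)
  wavelength_grid("visnir", c(w, w), rep(1:2, each = 600))
}

#' @rdname wavelength_grid
#' @export
nir_grid <- function() {
  wavelength_grid("nir", seq(900, 1700, length.out = 252))
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf(
    "<wavelength_grid> sensor=%s, %d channels, %d block(s), %.0f-%.0f nm\n",
    x$sensor, x$n_channels, length(unique(x$block)),
    min(x$wavelengths_nm), max(x$wavelengths_nm)
  ))
  invisible(x)
}

# channel column names: sensor-prefixed nm values, block-disambiguated for
# visnir (the two source blocks share the nm axis)
channel_names <- function(grid) {
  if (grid$sensor == "visnir") {
    sprintf("vis%d_%.4f", grid$block, grid$wavelengths_nm)
  } else {
    sprintf("nir_%.4f", grid$wavelengths_nm)
  }
}

# reconstruct a grid from channel column names (used when no sidecar exists)
grid_from_names <- function(nms) {
  m <- stringr::str_match(nms, "^(vis([12])|nir)_([0-9.]+)$")
  if (anyNA(m[, 1])) {
    abort("cannot parse wavelength column names; expected e.g. 'vis1_400.0000' or 'nir_900.0000'")
  }
  sensor <- if (all(m[, 2] == "nir")) "nir" else "visnir"
  block <- ifelse(is.na(m[, 3]), 1L, as.integer(m[, 3]))
  wavelength_grid(sensor, as.numeric(m[, 4]), block)
}

grids_equal <- function(a, b, tol = 1e-8) {
  identical(a$sensor, b$sensor) &&
    a$n_channels == b$n_channels &&
    identical(a$block, b$block) &&
    max(abs(a$wavelengths_nm - b$wavelengths_nm)) <= tol
}
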