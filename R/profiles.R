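#' Species absorption profiles
#'
#' Default band models for the four species. In the visible range the haem
#' pigments (myoglobin/haemoglobin) absorb around 418, 546 and 578 nm, with
#' pigment load ordered beef > lamb > pork > chicken; the 970 nm water band
#' and a fat-related C-H band near 930 nm are shared. In the NIR range all
#' species share the 1450 nm O-H first overtone (water) and the 1200 nm C-H
#' second overtone (fat), with smaller compositional differences between
#' species than in the visible — which is why the Vis-NIR sensor separates
#' species more readily than the NIR sensor in this simulator.
#'
#' Bands are Gaussian in wavelength; heights are in arbitrary reflectance-
#' derived units (the absolute scale of handheld instruments is arbitrary).
#'
#' @param species One of `"lamb"`, `"beef"`, `"chicken"`, `"pork"`.
#' @param sensor `"visnir"` or `"nir"`.
#' @return A `species_profile` list with `species`, `sensor`,
#'   `band_centers_nm`, `band_heights`, `band_widths_nm`, `block` (source
#'   block of each band) and `baseline_coeffs` (polynomial in scaled
#'   wavelength).
#' @examples
#' species_profile("beef", "visnir")$band_heights
#' @export
species_profile <- function(species, sensor) {
  species <- match.arg(species, SPECIES_LEVELS)
  sensor <- match.arg(sensor, c("visnir", "nir"))
  h <- function(lamb, beef, chicken, pork) {
    c(lamb = lamb, beef = beef, chicken = chicken, pork = pork)[[species]]
  }
  if (sensor == "visnir") {
    # block 1: LED-derived spectrum, visible emphasis (haem pigments)
    # block 2: bulb-derived spectrum, red/NIR emphasis (fat, water)
    bands <- tibble(
      center = c(418, 546, 578, 760, 970, 418, 546, 578, 930, 970),
      width  = c(12, 15, 12, 30, 40, 14, 16, 13, 35, 40),
      block  = c(rep(1L, 5), rep(2L, 5)),
      height = c(
        h(0.45, 0.55, 0.18, 0.30),
        h(0.28, 0.35, 0.10, 0.18),
        h(0.24, 0.30, 0.09, 0.16),
        h(0.06, 0.06, 0.06, 0.07),
        h(0.20, 0.20, 0.22, 0.20),
        h(0.36, 0.44, 0.14, 0.24),
        h(0.22, 0.28, 0.08, 0.14),
        h(0.19, 0.24, 0.07, 0.13),
        h(0.12, 0.10, 0.08, 0.16),
        h(0.25, 0.25, 0.27, 0.25)
      )
    )
    baseline <- c(0.25, 0.05)
  } else {
    bands <- tibble(
      center = c(1200, 1450, 1510, 1650),
      width  = c(60, 80, 70, 60),
      block  = rep(1L, 4),
      height = c(
        h(0.260, 0.240, 0.210, 0.320),
        h(0.600, 0.620, 0.660, 0.560),
        h(0.220, 0.235, 0.200, 0.190),
        h(0.115, 0.105, 0.095, 0.135)
      )
    )
    baseline <- c(0.30, 0.10)
  }
  structure(
    list(
      species = species, sensor = sensor,
      band_centers_nm = bands$center,
      band_heights = bands$height,
      band_widths_nm = bands$width,
      block = bands$block,
      baseline_coeffs = baseline
    ),
    class = "species_profile"
  )
}

# Gaussian band design matrix for one grid: n_channels x n_bands.
# bands outside a channel's block contribute nothing there.
band_design <- function(profile, grid) {
  G <- matrix(0, grid$n_channels, length(profile$band_centers_nm))
  for (j in seq_along(profile$band_centers_nm)) {
    sel <- grid$block == profile$block[j]
    w <- grid$wavelengths_nm[sel]
    G[sel, j] <- exp(-(w - profile$band_centers_nm[j])^2 /
                       (2 * profile$band_widths_nm[j]^2))
  }
  G
}

# baseline polynomial evaluated per channel on wavelength scaled to [-1, 1]
# within each block
baseline_curve <- function(profile, grid) {
  out <- numeric(grid$n_channels)
  for (b in unique(grid$block)) {
    sel <- grid$block == b
    w <- grid$wavelengths_nm[sel]
    lam <- 2 * (w - min(w)) / (max(w) - min(w)) - 1
    out[sel] <- Reduce(`+`, lapply(seq_along(profile$baseline_coeffs), function(k) {
      profile$baseline_coeffs[k] * lam^(k - 1)
    }))
  }
  out
}

#' Evaluate a species profile on a grid
#'
#' @param profile A [species_profile()].
#' @param grid A matching [wavelength_grid()].
#' @return Numeric vector of length `grid$n_channels` (noise-free spectrum).
#' @export
profile_spectrum <- function(profile, grid) {
  stopifnot(profile$sensor == grid$sensor)
  drop(baseline_curve(profile, grid) + band_design(profile, grid) %*% profile$band_heights)
}
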