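#' Read and write spectra tables
#'
#' Spectra are serialised as plain CSV: metadata columns `sample_id`,
#' `species`, `form`, `replicate` followed by one column per wavelength
#' channel, named by nm value with a sensor/block prefix (`vis1_546.0000`,
#' `nir_1450.0000`). An optional JSON sidecar (`<path>.grid.json`) carries the
#' grid; without it the grid is reconstructed from the column names.
#' Round-tripping a dataset through write/read preserves metadata exactly and
#' intensities to serialisation precision.
#'
#' @param path CSV file path.
#' @return `read_spectra()` returns a [spectra_tbl()]; `write_spectra()`
#'   returns `path` invisibly.
#' @examples
#' ds <- simulate_spectra(sim_config(n_samples_per_species = 1, sensor = "nir",
#'                                   replicates_per_sample = 2, seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_spectra(ds, f)
#' ds2 <- read_spectra(f)
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  attr(tab, "spec") <- NULL
  attr(tab, "problems") <- NULL
  required <- c("sample_id", "species", "form", "replicate")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    abort(sprintf("spectra file lacks metadata column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  chan_cols <- setdiff(names(tab), required)
  if (!length(chan_cols)) abort("spectra file has no wavelength columns")
  sidecar <- paste0(path, ".grid.json")
  grid <- if (file.exists(sidecar)) {
    g <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    wavelength_grid(g$sensor, g$wavelengths_nm, g$block)
  } else {
    grid_from_names(chan_cols)
  }
  X <- as.matrix(tab[chan_cols])
  if (nrow(X) > 0 && !is.numeric(X)) {
    bad <- which(!vapply(tab[chan_cols], is.numeric, logical(1)))
    abort(sprintf("non-numeric intensities in column(s): %s",
                  paste(chan_cols[bad], collapse = ", ")))
  }
  spectra_tbl(X, tab[required], grid)
}

#' @rdname read_spectra
#' @param ds A [spectra_tbl()].
#' @param sidecar Write the `<path>.grid.json` grid sidecar (default `TRUE`).
#' @export
write_spectra <- function(ds, path, sidecar = TRUE) {
  stopifnot(inherits(ds, "spectra_tbl"))
  readr::write_csv(as_tibble(ds), path, progress = FALSE)
  if (sidecar) {
    g <- spectra_grid(ds)
    jsonlite::write_json(
      list(sensor = g$sensor, wavelengths_nm = g$wavelengths_nm, block = g$block),
      paste0(path, ".grid.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
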