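#' Spectra tables
#'
#' The universal currency of the package: a tibble with one row per scan,
#' metadata columns `sample_id`, `species`, `form`, `replicate`, followed by
#' one numeric column per wavelength channel. The wavelength grid travels with
#' the table as an attribute, so no stage ever has to assume a sensor.
#'
#' All scans of one `sample_id` must share `species` and `form` (replicates of
#' a physical sample), and intensities must be finite with no missing values.
#'
#' @param X Numeric matrix, scans in rows, channels in columns.
#' @param meta Data frame with columns `sample_id`, `species`
#'   (lamb/beef/chicken/pork), `form` (intact/ground), `replicate`.
#' @param grid A [wavelength_grid()] whose channel count matches `ncol(X)`.
#' @return A `spectra_tbl` (tibble subclass).
#' @examples
#' g <- nir_grid()
#' X <- matrix(rnorm(2 * g$n_channels), 2)
#' meta <- data.frame(sample_id = "S1", species = "pork",
#'                    form = "ground", replicate = 1:2)
#' ds <- spectra_tbl(X, meta, g)
#' @export
spectra_tbl <- function(X, meta, grid) {
  X <- as.matrix(X)
  if (!inherits(grid, "wavelength_grid")) abort("`grid` must be a wavelength_grid")
  if (ncol(X) != grid$n_channels) {
    abort(sprintf("X has %d channels but grid expects %d", ncol(X), grid$n_channels))
  }
  meta <- as_tibble(meta)
  required <- c("sample_id", "species", "form", "replicate")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    abort(sprintf("metadata is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(meta) != nrow(X)) abort("one metadata row per scan is required")
  meta <- meta[required]
  meta$sample_id <- as.character(meta$sample_id)
  meta$species <- as.character(meta$species)
  meta$form <- as.character(meta$form)
  meta$replicate <- as.integer(meta$replicate)
  validate_meta(meta)
  if (nrow(X) > 0 && (anyNA(X) || any(!is.finite(X)))) {
    abort("spectra must be finite with no missing values")
  }
  colnames(X) <- channel_names(grid)
  out <- bind_cols(meta, as_tibble(X, .name_repair = "minimal"))
  attr(out, "grid") <- grid
  class(out) <- c("spectra_tbl", class(out))
  out
}

validate_meta <- function(meta) {
  bad_sp <- setdiff(unique(meta$species), SPECIES_LEVELS)
  if (length(bad_sp)) {
    abort(sprintf("unknown species label(s): %s (expected %s)",
                  paste(bad_sp, collapse = ", "), paste(SPECIES_LEVELS, collapse = "/")))
  }
  bad_fm <- setdiff(unique(meta$form), FORM_LEVELS)
  if (length(bad_fm)) {
    abort(sprintf("unknown form label(s): %s (expected intact/ground)",
                  paste(bad_fm, collapse = ", ")))
  }
  if (nrow(meta) && (anyNA(meta$replicate) || any(meta$replicate < 1))) {
    abort("`replicate` must be a positive integer")
  }
  per_sample <- dplyr::distinct(meta, .data$sample_id, .data$species, .data$form)
  dup <- per_sample$sample_id[duplicated(per_sample$sample_id)]
  if (length(dup)) {
    abort(sprintf("sample(s) with inconsistent species/form across scans: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  invisible(meta)
}

META_COLS <- c("sample_id", "species", "form", "replicate")

#' Accessors for spectra tables
#'
#' `spectra_matrix()` returns the scan-by-channel intensity matrix,
#' `spectra_meta()` the metadata tibble, and `spectra_grid()` the attached
#' [wavelength_grid()].
#'
#' @param ds A [spectra_tbl()].
#' @return A matrix, tibble, or `wavelength_grid` respectively.
#' @export
spectra_matrix <- function(ds) {
  stopifnot(inherits(ds, "spectra_tbl"))
  m <- as.matrix(ds[, setdiff(names(ds), META_COLS), drop = FALSE])
  rownames(m) <- NULL
  m
}

#' @rdname spectra_matrix
#' @export
spectra_meta <- function(ds) {
  as_tibble(ds)[META_COLS]
}

#' @rdname spectra_matrix
#' @export
spectra_grid <- function(ds) {
  attr(ds, "grid")
}

#' @export
print.spectra_tbl <- function(x, ...) {
  g <- spectra_grid(x)
  cat(sprintf("# spectra_tbl: %d scans x %d channels (%s)\n",
              nrow(x), g$n_channels, g$sensor))
  NextMethod()
}

# subsetting rows of a spectra_tbl keeps the grid attribute
keep_grid <- function(new, old) {
  attr(new, "grid") <- spectra_grid(old)
  if (!inherits(new, "spectra_tbl")) class(new) <- c("spectra_tbl", class(new))
  new
}

#' Subset scans of a spectra table
#'
#' @param ds A [spectra_tbl()].
#' @param rows Integer row (scan) indices to keep, in order.
#' @return A `spectra_tbl` with those scans.
#' @export
spectra_rows <- function(ds, rows) {
  keep_grid(dplyr::slice(as_tibble(ds), rows), ds)
}

#' Concatenate the two Vis-NIR source blocks into one dataset
#'
#' The Vis-NIR instrument produces two derived spectra per scan (one per light
#' source); analysis uses their concatenation, giving 1200 variables per scan.
#'
#' @param block_a,block_b Numeric matrices with equal row counts and 600
#'   channels each.
#' @param grid_a,grid_b [wavelength_grid()]s of the two blocks (single-block,
#'   600 channels each).
#' @param meta Metadata data frame, one row per scan (see [spectra_tbl()]).
#' @return A `spectra_tbl` with 1200 channels.
#' @export
concatenate_dual_scans <- function(block_a, block_b, grid_a, grid_b, meta) {
  block_a <- as.matrix(block_a); block_b <- as.matrix(block_b)
  if (nrow(block_a) != nrow(block_b)) {
    abort(sprintf("row counts differ: %d vs %d", nrow(block_a), nrow(block_b)))
  }
  if (ncol(block_a) != 600 || ncol(block_b) != 600) {
    abort(sprintf("each block must have 600 channels (got %d and %d)",
                  ncol(block_a), ncol(block_b)))
  }
  if (grid_a$n_channels != 600 || grid_b$n_channels != 600) {
    abort("block grids must each carry 600 channels")
  }
  grid <- wavelength_grid(
    "visnir",
    c(grid_a$wavelengths_nm, grid_b$wavelengths_nm),
    rep(1:2, each = 600)
  )
  spectra_tbl(cbind(block_a, block_b), meta, grid)
}

#' Group scans by physical sample
#'
#' Returns one row per sample in first-appearance order, with the scan (row)
#' indices of its replicates as a list-column. The groups always partition the
#' scan indices: splitting and cross-validation operate on these groups so
#' replicates of one sample never straddle a train/test boundary.
#'
#' @param ds A [spectra_tbl()].
#' @return A tibble with columns `sample_id`, `species`, `form`, `rows`
#'   (list of integer vectors), `n_scans`.
#' @export
sample_groups <- function(ds) {
  meta <- spectra_meta(ds)
  if (nrow(meta) == 0) {
    return(tibble(sample_id = character(), species = character(),
                  form = character(), rows = list(), n_scans = integer()))
  }
  meta$`.row` <- seq_len(nrow(meta))
  out <- meta %>%
    group_by(.data$sample_id) %>%
    summarise(
      species = first(.data$species),
      form = first(.data$form),
      rows = list(.data$.row),
      n_scans = length(.data$.row),
      .groups = "drop"
    )
  # restore first-appearance order
  out[match(unique(meta$sample_id), out$sample_id), ]
}
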