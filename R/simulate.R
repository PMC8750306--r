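#' Simulation configuration
#'
#' Parameters of the synthetic acquisition campaign. Defaults mirror the
#' acquisition design the package targets: 6 replicate scans per sample
#' (five edge points plus the centre), multiplicative/additive scatter per
#' scan, channel noise, a per-sample latent deviation (biological variation
#' between animals), and extra replicate-level heterogeneity for intact meat
#' (intact cuts present a less homogeneous surface than ground meat).
#'
#' @param n_samples_per_species Either a single count or a named vector with
#'   entries for lamb/beef/chicken/pork.
#' @param replicates_per_sample Scans per sample (default 6).
#' @param sensor `"visnir"` (1200 channels, two 600-channel blocks) or
#'   `"nir"` (252 channels).
#' @param form `"intact"` or `"ground"`.
#' @param scatter_mult_sd SD of the per-scan multiplicative scatter factor
#'   (scan intensity is scaled by `1 + N(0, scatter_mult_sd)`).
#' @param scatter_add_sd SD of the per-scan additive baseline offset.
#' @param noise_sd SD of independent channel noise.
#' @param sample_sd SD of the relative per-sample deviation applied to band
#'   heights (drawn once per sample).
#' @param intact_extra_replicate_sd Extra relative band-height jitter per
#'   replicate, applied only when `form = "intact"`.
#' @param species_effect Scale on between-species profile differences:
#'   1 keeps the default profiles, 0 collapses all species onto the mean
#'   profile (a null simulation with no species signal).
#' @param seed Integer seed; identical seeds give bit-identical datasets
#'   (R's default Mersenne-Twister generator).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples_per_species = 40,
                       replicates_per_sample = 6,
                       sensor = c("visnir", "nir"),
                       form = c("intact", "ground"),
                       scatter_mult_sd = 0.05,
                       scatter_add_sd = 0.02,
                       noise_sd = 0.005,
                       sample_sd = 0.08,
                       intact_extra_replicate_sd = 0.03,
                       species_effect = 1,
                       seed = 1L) {
  sensor <- match.arg(sensor)
  form <- match.arg(form)
  if (length(n_samples_per_species) == 1) {
    n_samples_per_species <- setNames(rep(as.integer(n_samples_per_species), 4), SPECIES_LEVELS)
  }
  if (!all(SPECIES_LEVELS %in% names(n_samples_per_species))) {
    abort("`n_samples_per_species` must be a single count or named for all four species")
  }
  n_samples_per_species <- vapply(SPECIES_LEVELS, function(s)
    as.integer(n_samples_per_species[[s]]), integer(1))
  if (any(n_samples_per_species < 1) || replicates_per_sample < 1) {
    abort("sample and replicate counts must be positive")
  }
  sds <- c(scatter_mult_sd, scatter_add_sd, noise_sd, sample_sd, intact_extra_replicate_sd)
  if (any(sds < 0)) abort("all sd parameters must be >= 0")
  structure(
    list(
      n_samples_per_species = n_samples_per_species,
      replicates_per_sample = as.integer(replicates_per_sample),
      sensor = sensor, form = form,
      scatter_mult_sd = scatter_mult_sd, scatter_add_sd = scatter_add_sd,
      noise_sd = noise_sd, sample_sd = sample_sd,
      intact_extra_replicate_sd = intact_extra_replicate_sd,
      species_effect = species_effect, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a four-species spectra dataset
#'
#' Draws, for each sample, a latent relative deviation of its band heights
#' (once per sample), then per replicate adds intact-surface jitter (if
#' `form = "intact"`), evaluates the Gaussian band model on the sensor grid,
#' and applies multiplicative scatter, additive offset and channel noise.
#' Vis-NIR rows are built as two 600-channel source blocks and passed through
#' [concatenate_dual_scans()], matching the real acquisition geometry.
#'
#' @param cfg A [sim_config()].
#' @return A [spectra_tbl()] with
#'   `sum(n_samples_per_species) * replicates_per_sample` scans.
#' @examples
#' ds <- simulate_spectra(sim_config(n_samples_per_species = 2, sensor = "nir",
#'                                   seed = 7))
#' dim(spectra_matrix(ds))
#' @export
simulate_spectra <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  grid <- if (cfg$sensor == "visnir") visnir_grid() else nir_grid()
  profiles <- lapply(SPECIES_LEVELS, species_profile, sensor = cfg$sensor)
  names(profiles) <- SPECIES_LEVELS
  # all profiles share band geometry; species differ in heights only
  G <- band_design(profiles[[1]], grid)
  base <- baseline_curve(profiles[[1]], grid)
  H <- vapply(profiles, function(p) p$band_heights, numeric(ncol(G)))
  Hbar <- rowMeans(H)
  H <- Hbar + cfg$species_effect * (H - Hbar)   # species_effect = 0 -> null

  n_rep <- cfg$replicates_per_sample
  n_rows <- sum(cfg$n_samples_per_species) * n_rep
  withr::with_seed(cfg$seed, {
    X <- matrix(0, n_rows, grid$n_channels)
    meta <- vector("list", sum(cfg$n_samples_per_species))
    row <- 0L; samp <- 0L
    for (sp in SPECIES_LEVELS) {
      for (i in seq_len(cfg$n_samples_per_species[[sp]])) {
        samp <- samp + 1L
        sid <- sprintf("%s_%03d", sp, i)
        h_sample <- H[, sp] * (1 + rnorm(nrow(H), 0, cfg$sample_sd))
        for (r in seq_len(n_rep)) {
          # jitter drawn unconditionally so intact/ground runs with one seed
          # share every other random draw (paired comparisons)
          jit <- rnorm(nrow(H))
          rep_sd <- if (cfg$form == "intact") cfg$intact_extra_replicate_sd else 0
          h_rep <- h_sample * (1 + rep_sd * jit)
          spec <- base + drop(G %*% h_rep)
          mult <- 1 + rnorm(1, 0, cfg$scatter_mult_sd)
          add <- rnorm(1, 0, cfg$scatter_add_sd)
          row <- row + 1L
          X[row, ] <- mult * spec + add + rnorm(grid$n_channels, 0, cfg$noise_sd)
        }
        meta[[samp]] <- tibble(sample_id = sid, species = sp,
                               form = cfg$form, replicate = seq_len(n_rep))
      }
    }
    meta <- bind_rows(meta)
    if (cfg$sensor == "visnir") {
      ga <- wavelength_grid("visnir", grid$wavelengths_nm[1:600], rep(1L, 600))
      gb <- wavelength_grid("visnir", grid$wavelengths_nm[601:1200], rep(1L, 600))
      concatenate_dual_scans(X[, 1:600, drop = FALSE], X[, 601:1200, drop = FALSE],
                             ga, gb, meta)
    } else {
      spectra_tbl(X, meta, grid)
    }
  })
}

#' Campaign-sized benchmark datasets
#'
#' Generates the two synthetic datasets used throughout the package's
#' examples and checks, sized like a realistic dual-sensor survey:
#' a Vis-NIR dataset of 157 samples (lamb 37, beef 40, chicken 40, pork 40)
#' with 6 replicates each, i.e. 942 scans x 1200 channels, and a NIR dataset
#' of 161 samples (lamb 41, beef 48, chicken 40, pork 32), i.e. 966 scans x
#' 252 channels.
#'
#' @param seed Integer master seed (the two datasets use `seed` and
#'   `seed + 1`).
#' @param form `"intact"` or `"ground"`.
#' @return A list with elements `visnir` and `nir`, each a [spectra_tbl()].
#' @export
benchmark_datasets <- function(seed = 1L, form = "intact") {
  list(
    visnir = simulate_spectra(sim_config(
      n_samples_per_species = c(lamb = 37, beef = 40, chicken = 40, pork = 40),
      sensor = "visnir", form = form, seed = seed
    )),
    nir = simulate_spectra(sim_config(
      n_samples_per_species = c(lamb = 41, beef = 48, chicken = 40, pork = 32),
      sensor = "nir", form = form, seed = seed + 1L
    ))
  )
}
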