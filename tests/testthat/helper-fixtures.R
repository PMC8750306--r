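# small datasets shared across test files; built in code, never stored
tiny_nir <- function(n = 3, seed = 42, ...) {
  simulate_spectra(sim_config(n_samples_per_species = n, sensor = "nir",
                              seed = seed, ...))
}

tiny_visnir <- function(n = 3, seed = 42, ...) {
  simulate_spectra(sim_config(n_samples_per_species = n, sensor = "visnir",
                              seed = seed, ...))
}

# brute-force pairwise AUROC oracle (ties count one half)
auroc_brute <- function(target, other) {
  s <- 0
  for (t in target) for (o in other) {
    s <- s + if (t < o) 1 else if (t == o) 0.5 else 0
  }
  s / (length(target) * length(other))
}

# pooled within-sample replicate variance of a dataset
pooled_within_variance <- function(ds) {
  X <- spectra_matrix(ds)
  grp <- sample_groups(ds)
  v <- vapply(grp$rows, function(r) {
    mean(apply(X[r, , drop = FALSE], 2, var))
  }, numeric(1))
  mean(v)
}
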