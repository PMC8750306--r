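test_that("screening produces one record per combination with four AUROCs", {
  ds <- tiny_visnir(n = 5, seed = 19)
  grid <- screening_grid(pp = c("snv", ""), quarter = "full",
                         algorithm = "mahalanobis")
  rec <- screen_occ(ds, grid, n_repeats = 4, seed = 5)
  expect_equal(nrow(rec), 2)
  expect_true(all(c("auroc_lamb", "auroc_beef", "auroc_chicken", "auroc_all")
                  %in% names(rec)))
  expect_true(all(rec$auroc_all >= 0 & rec$auroc_all <= 1, na.rm = TRUE))
  # deterministic under the master seed
  rec2 <- screen_occ(ds, grid, n_repeats = 4, seed = 5)
  expect_equal(rec$auroc_all, rec2$auroc_all)
})

test_that("failed pre-processing marks the combo failed without aborting", {
  ds <- tiny_nir(n = 5, seed = 23)
  # savgol window far wider than a quarter of 252 channels still works, so
  # force failure via a window wider than the spectrum
  grid <- screening_grid(pp = c("snv", "savgol(w=301,p=2,d=1)"),
                         algorithm = "simca")
  rec <- screen_occ(ds, grid, n_repeats = 2, seed = 1)
  expect_false(rec$failed[rec$pp == "snv"])
  expect_true(rec$failed[rec$pp != "snv"])
  expect_true(is.na(rec$auroc_all[rec$failed]))
})

test_that("triplet selection is greedy on per-class coverage with manual override", {
  rec <- tibble::tibble(
    combo_id = c("dominant", "lamb_spec", "beef_spec", "chicken_spec"),
    pp = "snv", quarter = "full", algorithm = "simca",
    auroc_lamb = c(0.95, 0.99, 0.60, 0.60),
    auroc_beef = c(0.95, 0.60, 0.99, 0.60),
    auroc_chicken = c(0.95, 0.60, 0.60, 0.99),
    auroc_all = c(0.95, 0.7, 0.7, 0.7),
    n_repeats = 80, failed = FALSE
  )
  class(rec) <- c("screening_records", class(rec))
  picked <- select_triplet(rec)
  expect_equal(picked[1], "dominant")   # maximises the min over classes

  # three orthogonal specialists are all selected when no combo dominates
  rec2 <- rec[-1, ]
  expect_setequal(select_triplet(rec2),
                  c("lamb_spec", "beef_spec", "chicken_spec"))

  expect_equal(select_triplet(rec, manual = c("beef_spec", "lamb_spec", "chicken_spec")),
               c("beef_spec", "lamb_spec", "chicken_spec"))
  expect_error(select_triplet(rec, manual = c("a", "b")), "exactly 3")
  expect_error(select_triplet(rec[1:2, ]), "at least 3")
})

test_that("the fitted ensemble passes every training pork sample under scenario 1", {
  ds <- tiny_visnir(n = 6, seed = 29)
  split <- split_samples(ds, "duplex", 0.7)
  grid <- screening_grid(pp = c("snv", "savgol(w=11,p=2,d=1)"),
                         algorithm = c("simca", "mahalanobis"))
  rec <- screen_occ(ds, grid, n_repeats = 4, seed = 11)
  ens <- fit_ensemble(ds, split, select_triplet(rec), grid)
  dec_train <- classify_samples(ens, ds, scenario = 1, rows = split$train_rows)
  rates <- correct_classification_rate(dec_train)
  expect_equal(rates$rate[rates$species == "pork"], 100)

  # scenario 2 limits never exceed scenario 1 limits
  for (m in ens$members) {
    expect_lte(m$model$class_limits[["2"]], m$model$class_limits[["1"]])
  }
})

test_that("null simulations yield chance-level AUROC through the full screen", {
  ds <- simulate_spectra(sim_config(n_samples_per_species = 6, sensor = "nir",
                                    seed = 37, species_effect = 0))
  grid <- screening_grid(pp = "snv", algorithm = "mahalanobis")
  n_rep <- 30
  rec <- screen_occ(ds, grid, n_repeats = n_rep, seed = 13)
  # the AUROC of each repeat is itself a mean over many pairs; across
  # repeats its spread is far below the binomial bound used here
  se <- 0.5 / sqrt(n_rep)
  expect_lt(abs(rec$auroc_all - 0.5), 3 * se)
})
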