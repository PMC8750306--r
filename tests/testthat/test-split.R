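test_that("duplex seeds the farthest pairs and honours the fraction", {
  reps <- matrix(c(0, 12, 1, 11), ncol = 1)
  out <- duplex_assign(reps, 0.5)
  expect_equal(out$train, c(1, 2))   # positions 0 and 12
  expect_equal(out$test, c(3, 4))    # positions 1 and 11
  expect_equal(sort(c(out$train, out$test)), 1:4)

  # identical representatives: tie-break by index, sizes still honoured
  same <- matrix(1, 10, 3)
  out2 <- duplex_assign(same, 0.7)
  expect_length(out2$test, 3)
  expect_length(out2$train, 7)
  expect_equal(sort(c(out2$train, out2$test)), 1:10)
})

test_that("kennard-stone picks the farthest pair first and is order-insensitive", {
  reps <- matrix(c(0, 10, 5, 1), ncol = 1)
  expect_equal(kennard_stone_assign(reps, n_train = 2)$train, c(1, 2))
  expect_warning(kennard_stone_assign(reps, n_train = 4), "empty")

  set.seed(5)
  R <- matrix(rnorm(12 * 3), 12)
  base <- kennard_stone_assign(R, 0.5)
  perm <- sample(12)
  permuted <- kennard_stone_assign(R[perm, , drop = FALSE], 0.5)
  expect_equal(sort(perm[permuted$train]), base$train)
})

test_that("group-aware splits never separate replicates and stratify by species", {
  ds <- tiny_visnir(n = 5, seed = 13)
  meta <- spectra_meta(ds)
  for (method in c("duplex", "kennard_stone", "random")) {
    sp <- split_samples(ds, method, train_fraction = 0.7, seed = 99)
    expect_length(intersect(sp$train_groups, sp$test_groups), 0)
    expect_setequal(c(sp$train_groups, sp$test_groups), unique(meta$sample_id))
    expect_setequal(c(sp$train_rows, sp$test_rows), seq_len(nrow(ds)))
    # each sample's scans all on one side
    for (sid in sp$train_groups) {
      expect_true(all(which(meta$sample_id == sid) %in% sp$train_rows))
    }
    # all species in the test set
    expect_setequal(unique(meta$species[sp$test_rows]),
                    c("lamb", "beef", "chicken", "pork"))
  }
  # random splits are seed-reproducible
  a <- split_samples(ds, "random", seed = 7)
  b <- split_samples(ds, "random", seed = 7)
  expect_identical(a$train_groups, b$train_groups)
})

test_that("venetian blinds implements modular fold assignment at unit level", {
  vb <- venetian_blinds(25, n_splits = 10, thickness = 1)
  expect_equal(vb$folds[[1]]$validation, c(1, 11, 21))
  expect_equal(vb$folds[[10]]$validation, c(10, 20))
  all_val <- sort(unlist(lapply(vb$folds, `[[`, "validation")))
  expect_equal(all_val, 1:25)

  vb2 <- venetian_blinds(8, n_splits = 4, thickness = 2)
  expect_equal(vb2$folds[[1]]$validation, c(1, 2))
  expect_equal(vb2$folds[[2]]$validation, c(3, 4))
})

test_that("cv fold generators partition units and respect seeds", {
  loo <- cv_folds("loo", n_units = 5)
  expect_length(loo$folds, 5)
  expect_equal(sort(unlist(lapply(loo$folds, `[[`, "validation"))), 1:5)

  rs1 <- cv_folds("random_subsets", 12, params = list(s = 3, r = 2), seed = 4)
  rs2 <- cv_folds("random_subsets", 12, params = list(s = 3, r = 2), seed = 4)
  expect_identical(rs1$folds, rs2$folds)
  expect_length(rs1$folds, 6)
  # each repetition partitions the units
  expect_equal(sort(unlist(lapply(rs1$folds[1:3], `[[`, "validation"))), 1:12)

  kf <- cv_folds("kfold", 10, params = list(k = 5), seed = 2)
  expect_equal(sort(unlist(lapply(kf$folds, `[[`, "validation"))), 1:10)
  expect_error(cv_folds("kfold", 10, params = list(k = 5)), "seed")
})

test_that("repeated random CV of the target class keeps replicates together", {
  ds <- tiny_nir(n = 6, seed = 17)
  groups <- sample_groups(ds)
  pork <- groups[groups$species == "pork", ]
  splits <- repeated_random_cv(pork, n_repeats = 80, train_fraction = 0.7, seed = 3)
  expect_length(splits, 80)
  meta <- spectra_meta(ds)
  for (s in splits[c(1, 40, 80)]) {
    expect_length(intersect(s$train_groups, s$test_groups), 0)
    for (sid in s$train_groups) {
      expect_true(all(which(meta$sample_id == sid) %in% s$train_rows))
    }
  }
  again <- repeated_random_cv(pork, n_repeats = 80, train_fraction = 0.7, seed = 3)
  expect_identical(lapply(splits, `[[`, "train_groups"),
                   lapply(again, `[[`, "train_groups"))
})
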