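test_that("PCA models expose orthonormal loadings and exact reconstruction", {
  set.seed(51)
  line <- outer(rnorm(30), c(1, 2, -1))   # rank-1 data in 3-D
  pc1 <- fit_pca(line, 1)
  expect_equal(pc1$explained[1], 1, tolerance = 1e-9)

  X <- matrix(rnorm(20 * 6), 20)
  pc <- fit_pca(X, 6)
  Xc <- sweep(X, 2, pc$center, "-")
  expect_equal(pc$scores %*% t(pc$loadings), Xc, tolerance = 1e-9)
  G <- crossprod(pc$scores)
  expect_lt(max(abs(G[lower.tri(G)])), 1e-8)
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_error(fit_pca(line, 3), "rank")
})

test_that("T2/Q outlier flags calibrate to their nominal level", {
  set.seed(52)
  # data with genuine 3-component structure so the estimated eigenvalues are
  # close to their population values
  L <- qr.Q(qr(matrix(rnorm(8 * 3), 8)))
  draw <- function(n) {
    cbind(rnorm(n, 0, 5), rnorm(n, 0, 3), rnorm(n, 0, 2)) %*% t(L) +
      matrix(rnorm(n * 8, 0, 0.2), n)
  }
  X <- draw(300)
  pc <- fit_pca(X, 3)
  fresh <- draw(2000)
  fl <- outlier_flags(pc, fresh, alpha = 0.05, rule = "either")
  se <- sqrt(0.05 * 0.95 / 2000)
  expect_lt(abs(mean(fl$t2_out) - 0.05), 3 * se + 0.01)

  centre_row <- matrix(pc$center, 1)
  fl0 <- outlier_flags(pc, centre_row)
  expect_equal(fl0$t2, 0, tolerance = 1e-18)
  expect_false(fl0$flag)

  far <- matrix(pc$center, 1) + 5 * t(qr.Q(qr(cbind(pc$loadings, rnorm(8))))[, 4])
  expect_true(outlier_flags(pc, far, rule = "either")$q_out)
})

test_that("full-rank PLS-DA reproduces indicator least squares", {
  set.seed(53)
  for (i in 1:3) {
    X <- matrix(rnorm(20 * 8), 20)
    y <- sample(c("lamb", "beef", "pork"), 20, replace = TRUE)
    fit <- meatspec:::plsda_core(X, y, 8)
    Yhat <- meatspec:::plsda_predict_core(fit, X, 8)$response
    ls <- cbind(1, X) %*% qr.solve(cbind(1, X), meatspec:::class_indicator(y))
    expect_equal(unname(Yhat), unname(ls), tolerance = 1e-8)
  }
})

test_that("PLS-DA agrees with an independent implementation on a small instance", {
  skip_if_not_installed("mixOmics")
  set.seed(54)
  X <- matrix(rnorm(30 * 10), 30)
  y <- rep(c("a", "b", "c"), each = 10)
  ours <- meatspec:::plsda_core(X, y, 2)
  ref <- mixOmics::plsda(X, factor(y), ncomp = 2, scale = FALSE)
  # latent scores agree up to sign and scale per component
  for (a in 1:2) {
    expect_gt(abs(cor(ours$Tscores[, a], ref$variates$X[, a])), 0.999)
  }
})

test_that("PLS-DA separates separable classes and selects few LVs", {
  set.seed(55)
  x <- c(rnorm(20, -2, 0.5), rnorm(20, 2, 0.5))
  X <- cbind(x, matrix(rnorm(40 * 4, 0, 0.1), 40))
  y <- rep(c("a", "b"), each = 20)
  m <- fit_plsda(X, y, max_lv = 4)
  expect_equal(m$n_lv, 1)
  expect_equal(m$cv_error[1], 0)
  expect_equal(as.character(predict(m, X)), y)
})

test_that("permuted labels destroy PLS-DA generalisation", {
  set.seed(56)
  ds <- tiny_nir(n = 5, seed = 57)
  X <- snv(spectra_matrix(ds))
  meta <- spectra_meta(ds)
  perm_labels <- sample(meta$species)
  m <- fit_plsda(X, perm_labels, max_lv = 5, groups = meta$sample_id)
  # 4 balanced classes: chance error 0.75; binomial tolerance over 120 scans
  expect_gt(min(m$cv_error), 0.75 - 3 * sqrt(0.75 * 0.25 / nrow(X)) - 0.05)
})

test_that("VIP scores satisfy their algebraic identity and flag informative variables", {
  set.seed(58)
  X <- matrix(rnorm(60 * 12), 60)
  y <- rep(c("a", "b"), each = 30)
  X[, 4] <- X[, 4] + ifelse(y == "a", 2, -2)   # single informative variable
  m <- fit_plsda(X, y, max_lv = 3)
  v <- vip_scores(m)
  expect_equal(sum(v^2), ncol(X), tolerance = 1e-6)
  expect_gt(v[4], 1)
  expect_equal(which.max(v), 4)
})

test_that("SVM tuning finds a separating spec and respects determinism", {
  set.seed(59)
  x <- c(rnorm(24, -3), rnorm(24, 3))
  X <- cbind(x, rnorm(48, 0, 0.2))
  y <- rep(c("a", "b"), each = 24)
  tuned <- tune_svm(X, y, kernels = c("quadratic", "rbf"), cost = c(1, 10),
                    gamma = c(0.1, 1))
  expect_equal(max(tuned$results$cv_accuracy), 1)
  tuned2 <- tune_svm(X, y, kernels = c("quadratic", "rbf"), cost = c(1, 10),
                     gamma = c(0.1, 1))
  expect_identical(tuned$best, tuned2$best)

  # label permutation gives chance-level CV accuracy
  yp <- withr::with_seed(60, sample(y))
  null_tuned <- tune_svm(X, yp, kernels = "rbf", cost = 1, gamma = 0.1)
  expect_lt(abs(null_tuned$best$cv_accuracy - 0.5), 3 * sqrt(0.25 / 48) + 0.15)
  expect_error(tune_svm(X, rep("a", 48)), "2 classes")
})

test_that("confusion metrics implement the four standard formulas", {
  cm <- confusion_counts(
    truth = c(rep("pork", 10), rep("beef", 20)),
    pred = c(rep("pork", 8), rep("beef", 2), rep("beef", 15), rep("pork", 5))
  )
  pork <- cm[cm$class == "pork", ]
  expect_equal(pork$tp, 8); expect_equal(pork$fn, 2)
  expect_equal(pork$tn, 15); expect_equal(pork$fp, 5)
  met <- classification_metrics(cm)
  mp <- met[met$class == "pork", ]
  expect_equal(mp$sensitivity, 0.800)
  expect_equal(mp$specificity, 0.750)
  expect_equal(mp$accuracy, 23 / 30)
  expect_equal(mp$error, 7 / 30)
  expect_equal(met$error + met$accuracy, rep(1, nrow(met)))
  # degenerate denominator warns and yields NA
  cm0 <- confusion_counts(truth = c("a", "a"), pred = c("a", "a"), classes = c("a", "b"))
  expect_warning(m0 <- classification_metrics(cm0), "sensitivity")
  expect_true(is.na(m0$sensitivity[m0$class == "b"]))
})

test_that("evaluation blocks are leak-free and internally consistent", {
  ds <- tiny_visnir(n = 5, seed = 61)
  split <- split_samples(ds, "duplex", 0.7)
  ev <- evaluate_on_split(ds, split, "plsda", pp = "snv", max_lv = 6)
  # test block never uses training rows
  expect_length(intersect(split$train_rows, split$test_rows), 0)
  # metrics recomputable from the emitted confusion counts
  met <- ev$test$metrics
  expect_equal(met$sensitivity, met$tp / (met$tp + met$fn))
  expect_equal(met$accuracy + met$error, rep(1, nrow(met)))
  # separable synthetic data: strong test accuracy
  expect_gt(ev$test$accuracy, 0.85)
})

test_that("leave-class-out allocations conserve the held-out spectra", {
  ds <- tiny_visnir(n = 4, seed = 63)
  lco <- leave_class_out(ds, "plsda", pp = "snv", max_lv = 4,
                         held_out = c("pork", "chicken"))
  for (cl in c("pork", "chicken")) {
    sub <- lco[lco$held_out == cl, ]
    n_held <- sum(spectra_meta(ds)$species == cl)
    expect_equal(sum(sub$n), n_held)
    expect_equal(sum(sub$pct), 100, tolerance = 1e-9)
    expect_false(cl %in% as.character(sub$destination))
  }
  lco2 <- leave_class_out(ds, "plsda", pp = "snv", max_lv = 4,
                          held_out = c("pork", "chicken"))
  expect_equal(lco$n, lco2$n)
})

test_that("parameter recovery: accuracy approaches 100% at low noise and 25% at null", {
  clean <- simulate_spectra(sim_config(
    n_samples_per_species = 6, sensor = "visnir", seed = 65,
    noise_sd = 1e-4, sample_sd = 0.02, scatter_mult_sd = 0.01,
    scatter_add_sd = 0.005
  ))
  sp <- split_samples(clean, "duplex", 0.7)
  ev <- evaluate_on_split(clean, sp, "plsda", pp = "snv", max_lv = 8)
  expect_gt(ev$test$accuracy, 0.95)

  null_ds <- simulate_spectra(sim_config(
    n_samples_per_species = 6, sensor = "visnir", seed = 66, species_effect = 0
  ))
  spn <- split_samples(null_ds, "duplex", 0.7)
  evn <- evaluate_on_split(null_ds, spn, "plsda", pp = "snv", max_lv = 4)
  n_test <- length(spn$test_rows)
  expect_lt(abs(evn$test$accuracy - 0.25), 3 * sqrt(0.25 * 0.75 / n_test) + 0.1)
})
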