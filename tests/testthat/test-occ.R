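test_that("class distances have the pinned per-algorithm geometry", {
  set.seed(41)
  # Mahalanobis: standard-normal 2-D scores, identity covariance
  n <- 4000
  X <- cbind(rnorm(n), rnorm(n), 0.01 * rnorm(n))
  m <- fit_occ(X, "mahalanobis", n_components = 2)
  # a query at component-space offset (3, 4) sds from the mean: distance 5
  q <- matrix(colMeans(X), 1) +
    3 * sqrt(m$state$lambda[1]) * t(m$state$loadings[, 1]) +
    4 * sqrt(m$state$lambda[2]) * t(m$state$loadings[, 2])
  expect_equal(class_distance(m, q), 5, tolerance = 0.05)

  # kNN distance: 1-D training scores {0, 1, 2}, query at 5 -> distance 3
  Xk <- matrix(c(0, 1, 2), ncol = 1) %*% t(c(1, 0)) + matrix(0, 3, 2)
  mk <- fit_occ(Xk + cbind(0, c(-1e-6, 0, 1e-6)), "knn_dist", n_components = 1, k = 1)
  dq <- class_distance(mk, matrix(c(5, 0), 1))
  expect_equal(dq, 3, tolerance = 1e-3)

  # PCA residual: query in the span of the retained PCs has Q = 0
  set.seed(42)
  Xr <- matrix(rnorm(30 * 5), 30)
  mr <- fit_occ(Xr, "pca_residual", n_components = 3)
  in_span <- matrix(colMeans(Xr), 1) + 2 * t(mr$state$loadings[, 1])
  expect_lt(class_distance(mr, in_span), 1e-18)
  # doubling the orthogonal residual quadruples Q
  v_orth <- qr.Q(qr(cbind(mr$state$loadings, rnorm(5))))[, 4]
  q1 <- matrix(colMeans(Xr) + v_orth, 1)
  q2 <- matrix(colMeans(Xr) + 2 * v_orth, 1)
  expect_equal(class_distance(mr, q2) / class_distance(mr, q1), 4, tolerance = 1e-6)
})

test_that("SIMCA distances are self-normalised on training data", {
  set.seed(43)
  X <- matrix(rnorm(40 * 12), 40)
  m <- fit_occ(X, "simca", n_components = 3)
  parts <- meatspec:::simca_parts(m$state, X)
  expect_equal(mean(parts$q) / m$state$q_bar, 1, tolerance = 1e-12)
  expect_equal(mean(parts$t2) / m$state$t2_bar, 1, tolerance = 1e-12)
  expect_true(all(class_distance(m, X) >= 0))
})

test_that("a training row has zero 1-NN distance and OCSVM distances are oriented", {
  set.seed(44)
  X <- matrix(rnorm(25 * 8), 25)
  mk <- fit_occ(X, "knn_dist", n_components = 2, k = 1)
  expect_lt(class_distance(mk, X[3, , drop = FALSE]), 1e-10)

  mo <- fit_occ(X, "ocsvm")
  d_train <- class_distance(mo, X)
  d_far <- class_distance(mo, X + 50)
  expect_true(all(d_train >= 0))
  expect_gt(min(d_far), max(d_train) - 1e-9)
})

test_that("AUROC matches the brute-force pairwise count, ties included", {
  expect_equal(auroc(c(1, 2), c(3, 4)), 1)
  expect_equal(auroc(c(2, 2), c(2, 2)), 0.5)
  expect_equal(auroc(c(1, 3), c(2, 4)), 0.75)
  set.seed(45)
  for (i in 1:5) {
    n_t <- sample(5:200, 1); n_o <- sample(5:200, 1)
    t <- sample(1:40, n_t, replace = TRUE)   # integer-valued => many ties
    o <- sample(1:40, n_o, replace = TRUE)
    expect_equal(auroc(t, o), auroc_brute(t, o), tolerance = 1e-12)
  }
  expect_error(auroc(numeric(0), 1), "nonempty")
})

test_that("AUROC is invariant under strictly monotone transforms", {
  set.seed(46)
  t <- rexp(50); o <- rexp(60) + 0.5
  a <- auroc(t, o)
  expect_equal(auroc(log(t), log(o)), a)
  expect_equal(auroc(t^3, o^3), a)
})

test_that("scenario class limits behave as specified", {
  m0 <- structure(list(algorithm = "simca", class_limits = list()),
                  class = "occ_model")
  d <- c(0.1, 0.5, 0.9)
  m1 <- set_class_limit(m0, d, scenario = 1)
  expect_gte(m1$class_limits[["1"]], 0.9)
  expect_true(all(d <= m1$class_limits[["1"]]))

  set.seed(47)
  d100 <- runif(100)
  m2 <- set_class_limit(m0, d100, scenario = 2)
  expect_equal(sum(d100 > m2$class_limits[["2"]]), 5, tolerance = 1)
  expect_lte(m2$class_limits[["2"]], set_class_limit(m0, d100, 1)$class_limits[["1"]])
  expect_error(set_class_limit(m0, numeric(0), 1), "no training distances")
})

test_that("median replicate aggregation drives the vote as specified", {
  # replicate distances {1,1,1,9,9,9} -> median 5, out for limit 2
  expect_equal(median(c(1, 1, 1, 9, 9, 9)), 5)

  # vote rule on hand-built decisions
  dec <- tibble::tibble(
    sample_id = c("a", "b"), species = c("pork", "pork"),
    form = "intact",
    in_class_1 = c(FALSE, TRUE), in_class_2 = c(FALSE, TRUE),
    in_class_3 = c(TRUE, FALSE),
    n_out = c(2L, 1L),
    flag = ifelse(c(2L, 1L) >= 2, "not_pork_meat", "pork_in_class")
  )
  expect_equal(dec$flag, c("not_pork_meat", "pork_in_class"))
  rates <- correct_classification_rate(structure(dec, class = c("ensemble_decisions", class(dec))))
  expect_equal(rates$rate[rates$species == "pork"], 50)
})
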