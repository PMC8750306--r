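test_that("SNV standardises every row and rejects constants", {
  expect_equal(drop(snv(matrix(c(1, 2, 3), 1))), c(-1, 0, 1))
  X <- matrix(rnorm(10 * 40), 10)
  out <- snv(X)
  expect_lt(max(abs(rowMeans(out))), 1e-12)
  expect_lt(max(abs(apply(out, 1, sd) - 1)), 1e-12)
  expect_error(snv(matrix(5, 1, 3)), "zero-variance")
})

test_that("polynomial detrend removes exactly its basis", {
  idx <- seq_len(50)
  quad <- matrix(2 + 0.3 * idx - 0.01 * idx^2, 1)
  expect_lt(max(abs(detrend_poly(quad, 2))), 1e-9)

  pulse <- numeric(50); pulse[25] <- 1
  row <- quad + matrix(pulse, 1)
  resid <- detrend_poly(row, 2)
  # residual is orthogonal to the polynomial basis (normal equations)
  B <- cbind(1, idx, idx^2)
  expect_lt(max(abs(crossprod(B, drop(resid)))) / max(abs(B)), 1e-8)

  r <- matrix(rnorm(50), 1)
  expect_equal(detrend_poly(r, 0), r - mean(r))
  expect_error(detrend_poly(r, 50), "smaller")
})

test_that("MSC recovers affinely distorted spectra", {
  ref <- 1 + sin(seq(0, 3, length.out = 80))
  distorted <- matrix(1 + 2 * ref, 1)
  expect_equal(drop(msc(distorted, reference = ref)), ref, tolerance = 1e-9)
  expect_equal(drop(msc(matrix(ref, 1), reference = ref)), ref, tolerance = 1e-9)
  expect_equal(drop(msc(matrix(3 * ref, 1), reference = ref, mode = "median_ratio")),
               ref, tolerance = 1e-9)
  expect_error(msc(matrix(3 * c(0, ref[-1]), 1), reference = c(0, ref[-1]),
                   mode = "median_ratio"), "zero")
  # weighted mode with uniform weights reduces to the mean fit
  X <- matrix(rnorm(3 * 80, mean = 2), 3)
  expect_equal(msc(X, reference = ref, mode = "weighted"),
               msc(X, reference = ref, mode = "mean"), tolerance = 1e-10)
})

test_that("EMSC removes polynomial interference exactly", {
  p <- 100
  ref <- 2 + cos(seq(0, 4, length.out = p))
  lam <- 2 * (seq_len(p) - 1) / (p - 1) - 1
  expect_equal(drop(emsc(matrix(ref + 0.01 * lam, 1), reference = ref, poly_degree = 1)),
               ref, tolerance = 1e-9)
  expect_equal(drop(emsc(matrix(5 + 2 * ref + lam^2, 1), reference = ref, poly_degree = 2)),
               ref, tolerance = 1e-9)
  # degree 0 coincides with plain MSC
  X <- matrix(rnorm(4 * p, 3), 4)
  expect_equal(emsc(X, reference = ref, poly_degree = 0),
               msc(X, reference = ref), tolerance = 1e-10)
})

test_that("Savitzky-Golay reproduces polynomials and differentiates ramps", {
  idx <- seq_len(80)
  quad <- matrix(1 + idx + 0.05 * idx^2, 1)
  expect_equal(savgol(quad, 11, 2, 0), quad, tolerance = 1e-9)
  ramp <- matrix(4 * idx, 1)
  d1 <- savgol(ramp, 11, 2, 1)
  expect_equal(drop(d1)[6:75], rep(4, 70), tolerance = 1e-9)
  d2 <- savgol(ramp, 11, 2, 2)
  expect_lt(max(abs(drop(d2)[6:75])), 1e-9)
  expect_error(savgol(ramp, 10, 2, 1), "odd")
  expect_error(savgol(ramp, 11, 1, 2), "odd|>=")
})

test_that("gap-segment derivatives have the pinned stencil convention", {
  idx <- seq_len(60)
  quad <- matrix(idx^2, 1)
  g2 <- gap_segment(quad, gap = 5, segment = 5, order = 2)
  expect_equal(as.numeric(g2), rep(2, ncol(g2)), tolerance = 1e-9)

  expect_lt(max(abs(gap_segment(matrix(7, 1, 60), 5, 5, 1))), 1e-12)

  ramp <- matrix(3 * idx, 1)
  g1 <- gap_segment(ramp, gap = 5, segment = 5, order = 1)
  expect_equal(as.numeric(g1), rep(3, ncol(g1)), tolerance = 1e-9)

  # trimmed channels are reported
  expect_true(all(attr(g2, "channels") >= 1 & attr(g2, "channels") <= 60))
  expect_error(gap_segment(matrix(1:5, 1), 5, 5, 2), "wider")
})

test_that("wavelet features have dyadic counts and additive-shift invariance", {
  X <- matrix(rnorm(3 * 252), 3)
  expect_equal(ncol(dwt_features(X, "daub_short", 5:7)), 7)
  expect_equal(ncol(dwt_features(X, "la8", 3:5)), 28)
  expect_lt(max(abs(dwt_features(matrix(2, 1, 252), "la8", 3:5))), 1e-10)
  expect_equal(dwt_features(X, "daub_short"), dwt_features(X + 5, "daub_short"),
               tolerance = 1e-8)
  expect_error(dwt_features(X, "daub_short", levels = 8), "levels")
})

test_that("quarter splitting is floor-balanced and lossless", {
  X <- matrix(seq_len(1200), 1)
  q1 <- split_quarters(X, 1)
  expect_equal(attr(q1, "channels"), 1:300)
  X2 <- matrix(seq_len(252), 1)
  sizes <- vapply(1:4, function(q) ncol(split_quarters(X2, q)), numeric(1))
  expect_equal(sizes, rep(63, 4))
  glued <- do.call(cbind, lapply(1:4, function(q) unclass(split_quarters(X2, q))[, , drop = FALSE]))
  expect_equal(unname(glued), unname(X2))
})

test_that("OSC scores are orthogonal to the class structure and reapplication is exact", {
  set.seed(31)
  X <- matrix(rnorm(20 * 60), 20)
  y <- rep(c("a", "b"), each = 10)
  m <- osc_fit(X, y, n_components = 2)
  Y <- cbind(as.numeric(y == "a"), as.numeric(y == "b"))
  expect_lt(max(abs(cor(m$Tscores, Y))), 1e-8)
  # explained variance non-increasing over components
  norms <- colSums(m$Tscores^2) * colSums(m$P^2)
  expect_true(all(diff(norms) <= 1e-8 * norms[1]))
  # applying to the training data reproduces the deflated training matrix
  deflated <- X
  for (k in 1:2) deflated <- deflated - tcrossprod(m$Tscores[, k], m$P[, k])
  expect_equal(osc_apply(m, X), deflated, tolerance = 1e-8)
})

test_that("chains fit state on training rows only (leak freedom)", {
  set.seed(7)
  Xtr <- matrix(rnorm(12 * 40, mean = 3), 12)
  Xte <- matrix(rnorm(6 * 40, mean = 3), 6)
  fit1 <- apply_chain("msc(mode=mean)|center(mode=mean)", Xtr, Xte)
  # mutating the test rows must not change fitted state or train output
  fit2 <- apply_chain("msc(mode=mean)|center(mode=mean)", Xtr, Xte * 100 + 7)
  expect_identical(fit1$states, fit2$states)
  expect_identical(fit1$train, fit2$train)
  # permuting test rows permutes output rows identically (row-local apply)
  perm <- c(3, 1, 2, 6, 5, 4)
  fit3 <- apply_chain("msc(mode=mean)|center(mode=mean)", Xtr, Xte[perm, ])
  expect_equal(fit3$test, fit1$test[perm, ], tolerance = 1e-12)
})

test_that("chain application is deterministic and snv chains standardise both partitions", {
  set.seed(8)
  Xtr <- matrix(rnorm(10 * 50), 10); Xte <- matrix(rnorm(4 * 50), 4)
  a <- apply_chain("center(mode=mean)|savgol(w=11,p=2,d=1)", Xtr, Xte)
  b <- apply_chain("center(mode=mean)|savgol(w=11,p=2,d=1)", Xtr, Xte)
  expect_identical(a$train, b$train)
  expect_identical(a$test, b$test)

  s <- apply_chain("snv", Xtr, Xte)
  expect_lt(max(abs(apply(s$train, 1, sd) - 1)), 1e-12)
  expect_lt(max(abs(apply(s$test, 1, sd) - 1)), 1e-12)

  expect_error(apply_chain("osc(ncomp=1)", Xtr, Xte), "labels")
})

test_that("chain strings round-trip through the canonical grammar", {
  s <- "msc(mode=mean)|savgol(w=11,p=2,d=1)"
  expect_equal(format(pp_spec(s)), s)
  expect_equal(format(pp_spec("snv")), "snv")
  expect_equal(format(pp_spec("")), "raw")
  expect_error(pp_spec("warp(x=1)"), "unknown operator")
  expect_error(pp_spec("snv(bad=1)"), "unknown parameter")
  # channel masks propagate through trimming steps
  fit <- apply_chain("quarter(q=2)|gapseg(gap=5,seg=5,order=2)",
                     matrix(rnorm(5 * 252), 5))
  expect_true(all(fit$channels > 63 & fit$channels <= 126))
})
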