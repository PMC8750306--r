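#' Standard normal variate (SNV)
#'
#' Standardises each spectrum (row) to mean 0 and unit sample standard
#' deviation, removing multiplicative scatter and additive offsets.
#'
#' @param X Numeric matrix, spectra in rows.
#' @return Matrix of the same shape.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) abort("SNV needs at least 2 channels per spectrum")
  m <- rowMeans(X)
  s <- sqrt(rowSums((X - m)^2) / (ncol(X) - 1))
  zero <- which(s < .Machine$double.eps * 100)
  if (length(zero)) {
    abort(sprintf("SNV undefined for zero-variance row(s): %s",
                  paste(zero, collapse = ", ")))
  }
  (X - m) / s
}

# orthonormal polynomial basis in channel index, degree 0..deg
poly_basis <- function(n, deg) {
  idx <- seq_len(n) / n
  B <- vapply(0:deg, function(k) idx^k, numeric(n))
  qr.Q(qr(B))
}

#' Polynomial detrending
#'
#' Subtracts from each spectrum its least-squares polynomial (in channel
#' index) of the given degree; degree 0 removes the row mean.
#'
#' @param X Numeric matrix, spectra in rows.
#' @param degree Polynomial degree (default 2).
#' @return Matrix of the same shape.
#' @export
detrend_poly <- function(X, degree = 2) {
  X <- as.matrix(X)
  if (degree < 0) abort("`degree` must be >= 0")
  if (degree >= ncol(X)) abort("`degree` must be smaller than the channel count")
  Q <- poly_basis(ncol(X), degree)
  X - (X %*% Q) %*% t(Q)
}

# core MSC against a fixed reference (stateful half; exported wrapper below)
msc_apply <- function(X, reference, mode = "mean", weights = NULL) {
  X <- as.matrix(X)
  if (length(reference) != ncol(X)) abort("reference length must match channel count")
  if (mode == "median_ratio") {
    if (any(reference == 0)) abort("median-ratio MSC requires a reference without zeros")
    ratio <- sweep(X, 2, reference, "/")
    med <- apply(ratio, 1, median)
    if (any(abs(med) < .Machine$double.eps * 100)) abort("median ratio of 0 in some row")
    return(X / med)
  }
  w <- if (mode == "weighted" && !is.null(weights)) {
    if (length(weights) != ncol(X) || any(weights < 0)) {
      abort("`weights` must be a non-negative vector, one weight per channel")
    }
    weights
  } else rep(1, ncol(X))
  sw <- sum(w)
  rbar <- sum(w * reference) / sw
  rc <- reference - rbar
  denom <- sum(w * rc^2)
  b <- drop(X %*% (w * rc)) / denom   # sum(w * rc) = 0, so centering x is implicit
  xbar <- rowSums(sweep(X, 2, w, "*")) / sw
  a <- xbar - b * rbar
  if (any(abs(b) < 1e-12)) {
    abort(sprintf("MSC slope ~ 0 for row(s): %s",
                  paste(which(abs(b) < 1e-12), collapse = ", ")))
  }
  (X - a) / b
}

#' Multiplicative scatter/signal correction (MSC)
#'
#' Regresses each spectrum against a reference spectrum and removes the
#' fitted offset and slope. Modes: `"mean"` (ordinary least-squares fit
#' against the reference, the classic MSC), `"weighted"` (same fit with
#' per-channel weights), `"median_ratio"` (divide by the median of the
#' channel-wise ratio to the reference). The reference defaults to the column
#' mean of `X`; inside a fitted chain it is learned from training rows only.
#'
#' @param X Numeric matrix, spectra in rows.
#' @param reference Optional reference spectrum (defaults to `colMeans(X)`).
#' @param mode `"mean"`, `"weighted"` or `"median_ratio"`.
#' @param weights Channel weights for `mode = "weighted"` (default uniform).
#' @return Matrix of the same shape.
#' @export
msc <- function(X, reference = NULL, mode = c("mean", "weighted", "median_ratio"),
                weights = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(reference)) reference <- colMeans(X)
  msc_apply(X, reference, mode, weights)
}

# EMSC against a fixed reference: x = a + b*ref + sum_k c_k lambda^k
emsc_apply <- function(X, reference, poly_degree = 2) {
  X <- as.matrix(X)
  p <- ncol(X)
  lam <- 2 * (seq_len(p) - 1) / (p - 1) - 1   # scaled wavelength axis
  D <- cbind(1, reference)
  if (poly_degree >= 1) {
    D <- cbind(D, vapply(seq_len(poly_degree), function(k) lam^k, numeric(p)))
  }
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) abort("EMSC design is rank-deficient for this reference")
  C <- qr.coef(qrD, t(X))              # (2 + deg) x n
  b <- C[2, ]
  if (any(abs(b) < 1e-12)) abort("EMSC slope ~ 0 for some row")
  interference <- t(D[, -2, drop = FALSE] %*% C[-2, , drop = FALSE])
  (X - interference) / b
}

#' Extended multiplicative signal correction (EMSC)
#'
#' MSC extended with polynomial wavelength terms: each spectrum is modelled
#' as `a + b * reference + sum_k c_k * lambda^k` (lambda affinely scaled to
#' \[-1, 1\] for conditioning) and the additive/polynomial interference is
#' removed before dividing by the multiplicative factor `b`. With
#' `poly_degree = 0` EMSC reduces to plain MSC.
#'
#' @inheritParams msc
#' @param poly_degree Degree of the wavelength polynomial (default 2).
#' @return Matrix of the same shape.
#' @export
emsc <- function(X, reference = NULL, poly_degree = 2) {
  X <- as.matrix(X)
  if (poly_degree < 0) abort("`poly_degree` must be >= 0")
  if (is.null(reference)) reference <- colMeans(X)
  emsc_apply(X, reference, poly_degree)
}

#' Savitzky-Golay smoothing and derivatives
#'
#' Applies a Savitzky-Golay filter (local polynomial least squares) to each
#' spectrum; `deriv = 1` or `2` yields smoothed derivatives with respect to
#' channel index. Edge channels are handled by the polynomial fits within the
#' first/last window (no trimming).
#'
#' @param X Numeric matrix, spectra in rows.
#' @param window Odd filter length (default 11).
#' @param polyorder Local polynomial order (default 2); must satisfy
#'   `window > polyorder >= deriv`.
#' @param deriv Derivative order 0, 1 or 2.
#' @return Matrix of the same shape.
#' @export
savgol <- function(X, window = 11, polyorder = 2, deriv = 0) {
  X <- as.matrix(X)
  if (window %% 2 != 1 || window <= polyorder || polyorder < deriv || deriv < 0 || deriv > 2) {
    abort("need odd `window` > `polyorder` >= `deriv` (deriv in 0..2)")
  }
  if (ncol(X) < window) abort("spectrum shorter than the filter window")
  t(apply(X, 1, function(x) signal::sgolayfilt(x, p = polyorder, n = window, m = deriv, ts = 1)))
}

#' Gap-segment (Norris) derivatives
#'
#' Finite-difference derivatives computed on segment-averaged points: with
#' `s(i)` the mean over the segment-length window centred at channel `i`,
#' the first derivative is `(s(i+h) - s(i-h)) / (2h)` with
#' `h = ceiling(gap/2) + floor(segment/2)`, and the second derivative is
#' `(s(i+g) - 2 s(i) + s(i-g)) / g^2` with `g = gap + segment - 1`, both in
#' channel units. Channels whose stencil leaves the spectrum are trimmed; the
#' retained channel indices are attached as attribute `"channels"`.
#'
#' @param X Numeric matrix, spectra in rows.
#' @param gap Gap size in channels (default 5).
#' @param segment Odd segment length in channels (default 5).
#' @param order Derivative order, 1 or 2.
#' @return Matrix with fewer columns; `attr(, "channels")` gives the original
#'   channel index of each retained column.
#' @export
gap_segment <- function(X, gap = 5, segment = 5, order = 2) {
  X <- as.matrix(X)
  if (gap < 1 || segment < 1) abort("`gap` and `segment` must be >= 1")
  if (segment %% 2 != 1) abort("`segment` must be odd (centred windows)")
  if (!order %in% 1:2) abort("`order` must be 1 or 2")
  n <- ncol(X)
  half <- (segment - 1) / 2
  off <- if (order == 1) ceiling(gap / 2) + floor(segment / 2) else gap + segment - 1
  lo <- half + off + 1
  hi <- n - half - off
  if (lo > hi) abort("gap-segment stencil wider than the spectrum")
  # segment means: s[i] defined for i in (half+1)..(n-half)
  kern <- rep(1 / segment, segment)
  S <- t(apply(X, 1, function(x) stats::filter(x, kern, sides = 2)))
  idx <- lo:hi
  D <- if (order == 1) {
    (S[, idx + off, drop = FALSE] - S[, idx - off, drop = FALSE]) / (2 * off)
  } else {
    (S[, idx + off, drop = FALSE] - 2 * S[, idx, drop = FALSE] +
       S[, idx - off, drop = FALSE]) / off^2
  }
  structure(D, channels = idx)
}

# column centering with training statistics
center_fit <- function(X, mode = "mean") {
  if (mode == "mean") colMeans(X) else apply(X, 2, median)
}

#' Column centering
#'
#' Subtracts per-channel training statistics (mean or median). Standalone use
#' centers `X` on itself; in a fitted chain the statistics come from training
#' rows only and are reused on test rows.
#'
#' @param X Numeric matrix.
#' @param mode `"mean"` or `"median"`.
#' @param stats Optional precomputed per-channel statistics.
#' @return Matrix of the same shape.
#' @export
center_cols <- function(X, mode = c("mean", "median"), stats = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (is.null(stats)) stats <- center_fit(X, mode)
  sweep(X, 2, stats, "-")
}

#' Orthogonal signal correction (OSC)
#'
#' Removes from `X` components that explain X-variance but are orthogonal to
#' the response `Y` (class indicators): each component's score vector is
#' orthogonalised against `Y`, its loading regressed on the (deflated) data,
#' and `X` deflated. `osc_apply()` projects new rows onto the stored weights
#' and deflates identically, so correction of test data uses training
#' information only.
#'
#' @param X Numeric matrix (training spectra).
#' @param Y Numeric indicator matrix (one column per class) or a factor.
#' @param n_components Number of OSC components to remove (default 1).
#' @param max_iter,tol Convergence controls of the inner power iteration.
#' @return `osc_fit()` returns an `osc_model` with weights `W`, loadings `P`
#'   and the removed training scores `Tscores`; `osc_apply()` returns the
#'   corrected matrix.
#' @export
osc_fit <- function(X, Y, n_components = 1, max_iter = 100, tol = 1e-10) {
  X <- as.matrix(X)
  if (is.factor(Y) || is.character(Y)) Y <- class_indicator(Y)
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) abort("X and Y must have the same number of rows")
  if (n_components < 1) abort("`n_components` must be >= 1")
  if (n_components >= qr(X)$rank) abort("`n_components` must be below rank(X)")
  # projection removing the Y subspace from a score vector
  QY <- qr.Q(qr(Y))
  orth <- function(t) t - QY %*% crossprod(QY, t)
  W <- P <- NULL
  Tsc <- NULL
  Xd <- X
  for (k in seq_len(n_components)) {
    t <- prcomp(Xd, center = FALSE, rank. = 1)$x[, 1]
    for (it in seq_len(max_iter)) {
      t_old <- t
      t <- drop(orth(t))
      p <- drop(crossprod(Xd, t)) / sum(t^2)
      t <- drop(Xd %*% p) / sum(p^2)
      if (sum((t - t_old)^2) / max(sum(t^2), 1e-300) < tol) break
    }
    t <- drop(orth(t))
    # exact weights: minimum-norm solution of Xd w = t (t lies in the row
    # space of Xd when channels outnumber scans, the usual spectral case)
    w <- drop(ginv(Xd) %*% t)
    t <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t)) / sum(t^2)
    Xd <- Xd - tcrossprod(t, p)
    W <- cbind(W, w); P <- cbind(P, p); Tsc <- cbind(Tsc, t)
  }
  structure(list(W = W, P = P, Tscores = Tsc, Y_basis = QY),
            class = "osc_model")
}

#' @rdname osc_fit
#' @param model An `osc_model`.
#' @export
osc_apply <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$W)) abort("channel count differs from the fitted OSC model")
  for (k in seq_len(ncol(model$W))) {
    t <- drop(X %*% model$W[, k])
    X <- X - tcrossprod(t, model$P[, k])
  }
  X
}

# wavelet filter banks (decomposition low-pass; high-pass by QMF)
WT_FILTERS <- list(
  # 2-tap Daubechies (Haar)
  daub_short = c(0.7071067811865476, 0.7071067811865476),
  # 8-tap least-asymmetric Daubechies (symlet)
  la8 = c(-0.07576571478927333, -0.02963552764599851, 0.49761866763201545,
          0.8037387518059161, 0.29785779560527736, -0.09921954357684722,
          -0.012603967262037833, 0.0322231006040427)
)

# one periodic analysis step: returns list(approx, detail)
dwt_step <- function(a, h) {
  N <- length(a)
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)   # QMF high-pass
  half <- N / 2
  idx <- outer(2 * (seq_len(half) - 1), seq_len(L) - 1, "+") %% N + 1
  A <- matrix(a[idx], half, L)
  list(approx = drop(A %*% h), detail = drop(A %*% g))
}

#' Discrete wavelet transform features
#'
#' Interpolates each spectrum linearly onto `interp_points` equally spaced
#' points, runs a full dyadic DWT with periodic extension, and returns the
#' concatenated detail coefficients of the requested levels. Defaults follow
#' the two screened settings: the 2-tap Daubechies (Haar) wavelet with levels
#' 5-7 (4 + 2 + 1 = 7 features) and the 8-tap least-asymmetric wavelet with
#' levels 3-5 (16 + 8 + 4 = 28 features). Detail coefficients are invariant
#' to additive constants, so baseline offsets drop out by construction.
#'
#' @param X Numeric matrix, spectra in rows.
#' @param family `"daub_short"` (Haar) or `"la8"` (8-tap symlet).
#' @param levels Integer vector of decomposition levels to keep (defaults:
#'   5:7 for `daub_short`, 3:5 for `la8`).
#' @param interp_points Dyadic interpolation length (default 128).
#' @return Feature matrix, one row per spectrum.
#' @export
dwt_features <- function(X, family = c("daub_short", "la8"), levels = NULL,
                         interp_points = 128) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (log2(interp_points) %% 1 != 0) abort("`interp_points` must be a power of 2")
  max_level <- log2(interp_points)
  if (is.null(levels)) levels <- if (family == "daub_short") 5:7 else 3:5
  if (any(levels < 1 | levels > max_level)) {
    abort(sprintf("levels must lie in 1..%d for %d points", max_level, interp_points))
  }
  h <- WT_FILTERS[[family]]
  feats <- t(apply(X, 1, function(x) {
    a <- approx(seq_along(x), x, n = interp_points)$y
    details <- vector("list", max_level)
    for (L in seq_len(max_level)) {
      st <- dwt_step(a, h)
      details[[L]] <- st$detail
      a <- st$approx
    }
    unlist(details[sort(levels)], use.names = FALSE)
  }))
  structure(feats, channels = NULL)
}

#' Select a contiguous quarter of the spectrum
#'
#' Splits the channel axis into 4 contiguous quarters (floor-balanced when
#' the channel count is not divisible by 4) and returns the selected quarter,
#' or all channels for `"full"`.
#'
#' @param X Numeric matrix, spectra in rows.
#' @param quarter `"full"`, or 1-4.
#' @return Matrix; `attr(, "channels")` gives the retained channel indices.
#' @export
split_quarters <- function(X, quarter = "full") {
  X <- as.matrix(X)
  if (identical(quarter, "full")) return(structure(X, channels = seq_len(ncol(X))))
  quarter <- as.integer(quarter)
  if (!quarter %in% 1:4) abort("`quarter` must be 'full' or 1..4")
  n <- ncol(X)
  sizes <- rep(n %/% 4, 4) + c(rep(1, n %% 4), rep(0, 4 - n %% 4))
  ends <- cumsum(sizes)
  idx <- (ends[quarter] - sizes[quarter] + 1):ends[quarter]
  structure(X[, idx, drop = FALSE], channels = idx)
}

# one-hot indicator matrix for a class vector
class_indicator <- function(y) {
  y <- as.character(y)
  classes <- sort(unique(y))
  Y <- vapply(classes, function(cl) as.numeric(y == cl), numeric(length(y)))
  colnames(Y) <- classes
  Y
}
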