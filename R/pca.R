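#' Principal component analysis of spectra
#'
#' Mean-centred SVD with scores, orthonormal loadings and per-component
#' explained variance fractions; the full singular spectrum is retained so
#' that residual (Q) limits can be computed.
#'
#' @param X Numeric matrix (pre-processed spectra) or a [spectra_tbl()].
#' @param n_components Components to retain.
#' @return A `pca_model`.
#' @export
fit_pca <- function(X, n_components = 2) {
  if (inherits(X, "spectra_tbl")) X <- spectra_matrix(X)
  X <- as.matrix(X)
  pc <- prcomp(X, center = TRUE)
  r <- sum(pc$sdev > pc$sdev[1] * 1e-10)
  if (n_components > r) {
    abort(sprintf("`n_components` (%d) exceeds the rank (%d)", n_components, r))
  }
  structure(
    list(
      center = pc$center,
      loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
      scores = pc$x[, seq_len(n_components), drop = FALSE],
      sdev_all = pc$sdev,
      explained = pc$sdev[seq_len(n_components)]^2 / sum(pc$sdev^2),
      n_components = n_components,
      n_train = nrow(X)
    ),
    class = "pca_model"
  )
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> %d components (%s%% variance)\n", x$n_components,
              paste(sprintf("%.1f", 100 * x$explained), collapse = " + ")))
  invisible(x)
}

#' @export
tidy.pca_model <- function(x, ...) {
  tibble(component = seq_len(x$n_components),
         std_dev = x$sdev_all[seq_len(x$n_components)],
         explained_fraction = x$explained,
         cumulative_fraction = cumsum(x$explained))
}

#' @export
glance.pca_model <- function(x, ...) {
  tibble(n_components = x$n_components, n_train = x$n_train,
         total_explained = sum(x$explained))
}

#' Project new spectra onto a PCA model
#'
#' @param object A `pca_model`.
#' @param newdata Matrix or [spectra_tbl()].
#' @param ... Unused.
#' @return Score matrix.
#' @export
predict.pca_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_tbl")) newdata <- spectra_matrix(newdata)
  sweep(as.matrix(newdata), 2, object$center, "-") %*% object$loadings
}

# T2/Q statistics for either decomposition type
latent_stats <- function(model, X) {
  if (inherits(model, "pca_model")) {
    Xc <- sweep(as.matrix(X), 2, model$center, "-")
    Tsc <- Xc %*% model$loadings
    lambda <- model$sdev_all[seq_len(model$n_components)]^2
    resid <- Xc - tcrossprod(Tsc, model$loadings)
    lambda_rest <- model$sdev_all[-seq_len(model$n_components)]^2
    n <- model$n_train
  } else if (inherits(model, "plsda_model")) {
    Xc <- sweep(as.matrix(X), 2, model$x_center, "-")
    Tsc <- Xc %*% model$R[, seq_len(model$n_lv), drop = FALSE]
    lambda <- apply(model$Tscores[, seq_len(model$n_lv), drop = FALSE], 2, var)
    Xhat <- tcrossprod(Tsc, model$P[, seq_len(model$n_lv), drop = FALSE])
    resid <- Xc - Xhat
    # residual spectrum approximated from the training residuals
    lambda_rest <- model$resid_eig
    n <- nrow(model$Tscores)
  } else {
    abort("`model` must be a pca_model or plsda_model")
  }
  list(
    t2 = rowSums(sweep(Tsc^2, 2, lambda, "/")),
    q = rowSums(resid^2),
    lambda_rest = lambda_rest,
    k = length(lambda),
    n = n
  )
}

#' Q-residual / Hotelling T-squared outlier flags
#'
#' The T-squared limit uses the F-distribution scaling
#' `k (n-1) / (n-k) * F(1-alpha; k, n-k)`; the Q limit uses the
#' Jackson-Mudholkar approximation from the residual eigenvalue spectrum.
#' By default a row is flagged only when BOTH statistics exceed their limits
#' (conservative removal); `rule = "either"` flags on one exceedance.
#'
#' @param model A `pca_model` or `plsda_model`.
#' @param X Rows to assess (matrix or [spectra_tbl()]), in the model's
#'   feature space.
#' @param alpha Significance level (default 0.05).
#' @param rule `"both"` or `"either"`.
#' @return An `outlier_flags` tibble: `t2`, `q`, their limits, per-statistic
#'   exceedances and the combined `flag`.
#' @export
outlier_flags <- function(model, X, alpha = 0.05, rule = c("both", "either")) {
  rule <- match.arg(rule)
  if (inherits(X, "spectra_tbl")) X <- spectra_matrix(X)
  st <- latent_stats(model, X)
  if (st$k < 1) abort("the decomposition must retain at least one component")
  t2_lim <- st$k * (st$n - 1) / (st$n - st$k) * qf(1 - alpha, st$k, st$n - st$k)
  q_lim <- jackson_mudholkar_limit(st$lambda_rest, alpha)
  t2_out <- st$t2 > t2_lim
  q_out <- if (is.finite(q_lim)) st$q > q_lim else rep(FALSE, length(st$q))
  out <- tibble(
    row = seq_along(st$t2), t2 = st$t2, q = st$q,
    t2_limit = t2_lim, q_limit = q_lim,
    t2_out = t2_out, q_out = q_out,
    flag = if (rule == "both") t2_out & q_out else t2_out | q_out
  )
  class(out) <- c("outlier_flags", class(out))
  out
}

jackson_mudholkar_limit <- function(lambda_rest, alpha) {
  lambda_rest <- lambda_rest[lambda_rest > max(lambda_rest, 0) * 1e-12]
  if (!length(lambda_rest)) return(Inf)
  th1 <- sum(lambda_rest); th2 <- sum(lambda_rest^2); th3 <- sum(lambda_rest^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 == 0) return(Inf)
  ca <- qnorm(1 - alpha)
  th1 * (ca * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2)^(1 / h0)
}
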