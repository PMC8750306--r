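# NIPALS PLS2 on centred data. Returns weights W, X-loadings P, Y-loadings Q,
# scores T and the projection matrix R = W (P'W)^-1 with which
# T = Xc R for new data.
nipals_pls2 <- function(Xc, Yc, ncomp, max_iter = 500, tol = 1e-12) {
  n <- nrow(Xc); p <- ncol(Xc); m <- ncol(Yc)
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); Tsc <- matrix(0, n, ncomp)
  Xd <- Xc; Yd <- Yc
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(apply(Yd, 2, var))]
    if (sum(u^2) < 1e-300) abort("response deflated to zero; too many components")
    t <- rep(0, n)
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xd, u)); w <- w / sqrt(sum(w^2))
      t_new <- drop(Xd %*% w)
      q <- drop(crossprod(Yd, t_new)) / sum(t_new^2)
      u <- drop(Yd %*% q) / sum(q^2)
      if (sum((t_new - t)^2) / max(sum(t_new^2), 1e-300) < tol) { t <- t_new; break }
      t <- t_new
    }
    pvec <- drop(crossprod(Xd, t)) / sum(t^2)
    Xd <- Xd - tcrossprod(t, pvec)
    Yd <- Yd - tcrossprod(t, q)
    W[, a] <- w; P[, a] <- pvec; Q[, a] <- q; Tsc[, a] <- t
  }
  R <- W %*% solve(crossprod(P, W))
  list(W = W, P = P, Q = Q, Tscores = Tsc, R = R)
}

#' Partial least squares discriminant analysis (PLS-DA)
#'
#' Fits a PLS2 decomposition (NIPALS) of the training spectra against the
#' one-hot class indicator matrix and selects the number of latent variables
#' (LVs) by group-aware venetian-blinds cross-validation: the LV count with
#' the lowest CV misclassification error wins, ties going to fewer LVs.
#' Class assignment is the argmax of the predicted indicator values (ties go
#' to the alphabetically first class).
#'
#' @param X Training spectra matrix (already pre-processed) or a
#'   [spectra_tbl()] (then `labels`/`groups` default to its metadata).
#' @param labels Class labels, one per row.
#' @param max_lv Largest LV count tried (default 10, capped by rank).
#' @param folds A `cv_folds` over the sample groups, or `NULL` for
#'   venetian blinds (10 splits, thickness 1).
#' @param groups Sample id per row (replicates share a group and always
#'   share a fold); defaults to one group per row for plain matrices.
#' @return A `plsda_model` with weights, loadings, regression coefficients
#'   `B`, the CV error curve and the chosen `n_lv`.
#' @export
fit_plsda <- function(X, labels = NULL, max_lv = 10, folds = NULL, groups = NULL) {
  if (inherits(X, "spectra_tbl")) {
    meta <- spectra_meta(X)
    if (is.null(labels)) labels <- meta$species
    if (is.null(groups)) groups <- meta$sample_id
    X <- spectra_matrix(X)
  }
  X <- as.matrix(X)
  labels <- as.character(labels)
  if (length(labels) != nrow(X)) abort("one label per row is required")
  if (length(unique(labels)) < 2) abort("PLS-DA needs at least 2 classes")
  if (is.null(groups)) groups <- as.character(seq_len(nrow(X)))
  groups <- as.character(groups)
  if (max_lv >= nrow(X)) abort("`max_lv` must be below the number of training rows")
  max_lv <- min(max_lv, qr(scale(X, scale = FALSE))$rank)

  Y <- class_indicator(labels)
  unit_ids <- unique(groups)
  if (is.null(folds)) {
    folds <- venetian_blinds(length(unit_ids),
                             n_splits = min(10, length(unit_ids)), thickness = 1)
  }
  # CV misclassification per LV count, replicates never split across folds
  err <- matrix(NA_real_, length(folds$folds), max_lv)
  for (f in seq_along(folds$folds)) {
    tr_units <- unit_ids[folds$folds[[f]]$train]
    va_units <- unit_ids[folds$folds[[f]]$validation]
    tr <- which(groups %in% tr_units); va <- which(groups %in% va_units)
    if (!length(va) || length(unique(labels[tr])) < 2) next
    fit <- plsda_core(X[tr, , drop = FALSE], labels[tr], max_lv)
    for (a in seq_len(max_lv)) {
      pred <- plsda_predict_core(fit, X[va, , drop = FALSE], a)$class
      err[f, a] <- mean(pred != labels[va])
    }
  }
  cv_error <- colMeans(err, na.rm = TRUE)
  n_lv <- which.min(cv_error)   # ties: first minimum = fewer LVs
  final <- plsda_core(X, labels, max_lv)
  structure(
    c(final, list(n_lv = n_lv, max_lv = max_lv, cv_error = cv_error,
                  cv_scheme = folds$scheme)),
    class = "plsda_model"
  )
}

# core fit without CV (all components up to ncomp)
plsda_core <- function(X, labels, ncomp) {
  Y <- class_indicator(labels)
  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  Xc <- sweep(X, 2, x_center, "-")
  Yc <- sweep(Y, 2, y_center, "-")
  dec <- nipals_pls2(Xc, Yc, ncomp)
  Xhat <- tcrossprod(dec$Tscores, dec$P)
  resid <- Xc - Xhat
  resid_eig <- svd(resid, nu = 0, nv = 0)$d^2 / max(nrow(X) - 1, 1)
  c(dec, list(classes = colnames(Y), x_center = x_center, y_center = y_center,
              resid_eig = resid_eig,
              B = dec$R %*% t(dec$Q)))
}

plsda_predict_core <- function(fit, X, a) {
  Xc <- sweep(as.matrix(X), 2, fit$x_center, "-")
  Ba <- fit$R[, seq_len(a), drop = FALSE] %*% t(fit$Q[, seq_len(a), drop = FALSE])
  Yhat <- sweep(Xc %*% Ba, 2, fit$y_center, "+")
  colnames(Yhat) <- fit$classes
  cls <- fit$classes[apply(Yhat, 1, which.max)]
  list(response = Yhat, class = cls)
}

#' Predict species with a fitted PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param newdata Matrix in the model's feature space or a [spectra_tbl()].
#' @param type `"class"` (default), `"response"` (predicted indicator
#'   values) or `"share"` (softmax shares of the indicator predictions,
#'   used for the leave-class-out cutoff).
#' @param n_lv LV count (defaults to the CV-selected one).
#' @param ... Unused.
#' @return Character vector or numeric matrix.
#' @export
predict.plsda_model <- function(object, newdata, type = c("class", "response", "share"),
                                n_lv = NULL, ...) {
  type <- match.arg(type)
  if (inherits(newdata, "spectra_tbl")) newdata <- spectra_matrix(newdata)
  a <- n_lv %||% object$n_lv
  pr <- plsda_predict_core(object, newdata, a)
  switch(type,
    class = pr$class,
    response = pr$response,
    share = {
      e <- exp(pr$response - apply(pr$response, 1, max))
      e / rowSums(e)
    }
  )
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt(p * sum_a SSY_a (w_ja / ||w_a||)^2 / sum_a SSY_a)` over the
#' model's selected LVs, where `SSY_a` is the Y-variance explained by
#' component a. The squares of the scores average to 1, and the usual
#' "greater than one" rule marks informative variables.
#'
#' @param model A `plsda_model`.
#' @param n_lv LV count (defaults to the selected one).
#' @return Numeric vector of VIP scores, one per variable.
#' @export
vip_scores <- function(model, n_lv = NULL) {
  stopifnot(inherits(model, "plsda_model"))
  a_max <- n_lv %||% model$n_lv
  W <- model$W[, seq_len(a_max), drop = FALSE]
  ssy <- vapply(seq_len(a_max), function(a) {
    sum(model$Tscores[, a]^2) * sum(model$Q[, a]^2)
  }, numeric(1))
  Wn2 <- sweep(W^2, 2, colSums(W^2), "/")
  p <- nrow(W)
  sqrt(p * drop(Wn2 %*% ssy) / sum(ssy))
}

#' @export
print.plsda_model <- function(x, ...) {
  cat(sprintf("<plsda_model> %d classes, %d LVs selected of %d (CV error %.3f)\n",
              length(x$classes), x$n_lv, x$max_lv, x$cv_error[x$n_lv]))
  invisible(x)
}

#' @export
tidy.plsda_model <- function(x, ...) {
  tibble(
    variable = seq_len(nrow(x$W)),
    vip = vip_scores(x),
    selected = vip_scores(x) > 1
  )
}

#' @export
glance.plsda_model <- function(x, ...) {
  tibble(n_lv = x$n_lv, max_lv = x$max_lv,
         cv_error = x$cv_error[x$n_lv],
         n_classes = length(x$classes),
         cv_scheme = x$cv_scheme)
}
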