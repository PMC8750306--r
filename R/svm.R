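#' Grid-tuned kernel SVM for speciation
#'
#' Grid search over kernel (RBF, quadratic, cubic), cost and RBF width,
#' selected by group-aware cross-validation accuracy (replicates of one
#' sample never validate a model trained on their siblings). Ties prefer the
#' simpler kernel (quadratic, then cubic, then RBF) and the smaller cost.
#' Features are standardised with training statistics before fitting.
#'
#' @param X Training spectra matrix or a [spectra_tbl()].
#' @param labels Class labels (defaults to dataset species).
#' @param groups Sample id per row (defaults to dataset sample ids).
#' @param kernels Subset of `"quadratic"`, `"cubic"`, `"rbf"`.
#' @param cost Cost grid (default `c(0.1, 1, 10, 100)`).
#' @param gamma RBF width grid (default `10^(-3:1)`); polynomial kernels use
#'   `1/n_features`.
#' @param folds A `cv_folds` over sample groups, or `NULL` for venetian
#'   blinds (10, 1).
#' @return An `svm_tuning` list: `best` (one-row tibble), `results` (full
#'   grid with CV accuracy), and `model` (the best SVM refitted on all
#'   training rows, with probability estimates enabled).
#' @export
tune_svm <- function(X, labels = NULL, groups = NULL,
                     kernels = c("quadratic", "cubic", "rbf"),
                     cost = c(0.1, 1, 10, 100),
                     gamma = 10^(-3:1),
                     folds = NULL) {
  if (inherits(X, "spectra_tbl")) {
    meta <- spectra_meta(X)
    if (is.null(labels)) labels <- meta$species
    if (is.null(groups)) groups <- meta$sample_id
    X <- spectra_matrix(X)
  }
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) < 2) abort("SVM tuning needs at least 2 classes")
  if (is.null(groups)) groups <- as.character(seq_len(nrow(X)))
  groups <- as.character(groups)
  kernels <- match.arg(kernels, c("quadratic", "cubic", "rbf"), several.ok = TRUE)

  ctr <- colMeans(X); scl <- apply(X, 2, sd); scl[scl < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, ctr, "-"), 2, scl, "/")

  unit_ids <- unique(groups)
  if (is.null(folds)) {
    folds <- venetian_blinds(length(unit_ids),
                             n_splits = min(10, length(unit_ids)), thickness = 1)
  }
  specs <- bind_rows(
    if (any(kernels != "rbf")) tidyr::expand_grid(
      kernel = setdiff(kernels, "rbf"), cost = cost, gamma = 1 / ncol(Xs)),
    if ("rbf" %in% kernels) tidyr::expand_grid(
      kernel = "rbf", cost = cost, gamma = gamma)
  )
  fit_one <- function(kernel, cost, gamma, Xtr, ytr, prob = FALSE) {
    if (kernel == "rbf") {
      e1071::svm(Xtr, ytr, kernel = "radial", cost = cost, gamma = gamma,
                 scale = FALSE, probability = prob)
    } else {
      e1071::svm(Xtr, ytr, kernel = "polynomial",
                 degree = if (kernel == "quadratic") 2 else 3,
                 gamma = gamma, coef0 = 1, cost = cost,
                 scale = FALSE, probability = prob)
    }
  }
  acc <- pmap(specs, function(kernel, cost, gamma) {
    hits <- 0; total <- 0
    for (f in folds$folds) {
      tr <- which(groups %in% unit_ids[f$train])
      va <- which(groups %in% unit_ids[f$validation])
      if (!length(va) || nlevels(droplevels(labels[tr])) < 2) next
      m <- fit_one(kernel, cost, gamma, Xs[tr, , drop = FALSE], droplevels(labels[tr]))
      pred <- predict(m, Xs[va, , drop = FALSE])
      hits <- hits + sum(as.character(pred) == as.character(labels[va]))
      total <- total + length(va)
    }
    tibble(kernel = kernel, cost = cost, gamma = gamma,
           cv_accuracy = hits / total)
  }) %>% list_rbind()
  kernel_rank <- match(acc$kernel, c("quadratic", "cubic", "rbf"))
  best <- acc[order(-acc$cv_accuracy, kernel_rank, acc$cost, acc$gamma), ][1, ]
  model <- fit_one(best$kernel, best$cost, best$gamma, Xs, labels, prob = TRUE)
  structure(
    list(best = best, results = acc, model = model,
         center = ctr, scale = scl, classes = levels(labels)),
    class = "svm_tuning"
  )
}

#' @export
print.svm_tuning <- function(x, ...) {
  cat(sprintf("<svm_tuning> best: %s kernel, cost %g, gamma %g (CV accuracy %.3f)\n",
              x$best$kernel, x$best$cost, x$best$gamma, x$best$cv_accuracy))
  invisible(x)
}

#' @export
glance.svm_tuning <- function(x, ...) x$best

#' Predict with a tuned SVM
#'
#' @param object An `svm_tuning` from [tune_svm()].
#' @param newdata Matrix in the model's feature space or [spectra_tbl()].
#' @param type `"class"` or `"share"` (class probabilities via the fitted
#'   pairwise-coupling estimates).
#' @param ... Unused.
#' @return Character vector or probability matrix.
#' @export
predict.svm_tuning <- function(object, newdata, type = c("class", "share"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "spectra_tbl")) newdata <- spectra_matrix(newdata)
  Xs <- sweep(sweep(as.matrix(newdata), 2, object$center, "-"), 2, object$scale, "/")
  if (type == "class") {
    as.character(predict(object$model, Xs))
  } else {
    pr <- attr(predict(object$model, Xs, probability = TRUE), "probabilities")
    pr[, sort(colnames(pr)), drop = FALSE]
  }
}
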