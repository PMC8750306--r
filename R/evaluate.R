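#' Train/CV/test evaluation of a discriminant pipeline
#'
#' Fits a leak-free pipeline (optional pre-processing chain fitted on the
#' training partition only, then PLS-DA or tuned SVM) on the training rows of
#' a group-aware split, and reports per-class confusion counts and metrics
#' for three blocks: resubstitution on the training rows, cross-validated
#' predictions of held-out folds within the training partition, and the
#' untouched test rows.
#'
#' @param ds A [spectra_tbl()].
#' @param split A `split_result` from [split_samples()].
#' @param method `"plsda"` or `"svm"`.
#' @param pp Optional chain string / [pp_spec()] fitted on training rows.
#' @param max_lv PLS-DA LV ceiling.
#' @param ... Further arguments to [fit_plsda()] or [tune_svm()].
#' @return A `split_evaluation` list with elements `train`, `cv`, `test`
#'   (each `confusion` + `metrics`), the fitted `model` and `pp_fit`.
#' @export
evaluate_on_split <- function(ds, split, method = c("plsda", "svm"), pp = NULL,
                              max_lv = 10, ...) {
  method <- match.arg(method)
  X <- spectra_matrix(ds)
  meta <- spectra_meta(ds)
  tr <- split$train_rows; te <- split$test_rows
  fit <- apply_chain(pp_spec(pp %||% character()),
                     X[tr, , drop = FALSE], X[te, , drop = FALSE],
                     Y_train = meta$species[tr])
  y_tr <- meta$species[tr]; g_tr <- meta$sample_id[tr]
  unit_ids <- unique(g_tr)
  folds <- venetian_blinds(length(unit_ids),
                           n_splits = min(10, length(unit_ids)), thickness = 1)

  model <- if (method == "plsda") {
    fit_plsda(fit$train, y_tr, max_lv = max_lv, folds = folds, groups = g_tr, ...)
  } else {
    tune_svm(fit$train, y_tr, groups = g_tr, folds = folds, ...)
  }
  predict_fun <- function(Xm) as.character(predict(model, Xm, type = "class"))

  # cross-validated predictions: refit per fold inside the training partition
  cv_truth <- character(0); cv_pred <- character(0)
  for (f in folds$folds) {
    tr_u <- unit_ids[f$train]; va_u <- unit_ids[f$validation]
    i_tr <- which(g_tr %in% tr_u); i_va <- which(g_tr %in% va_u)
    if (!length(i_va) || length(unique(y_tr[i_tr])) < 2) next
    sub <- if (method == "plsda") {
      m <- plsda_core(fit$train[i_tr, , drop = FALSE], y_tr[i_tr], model$n_lv)
      plsda_predict_core(m, fit$train[i_va, , drop = FALSE], model$n_lv)$class
    } else {
      tuned <- tune_svm(fit$train[i_tr, , drop = FALSE], y_tr[i_tr],
                        groups = g_tr[i_tr],
                        kernels = model$best$kernel, cost = model$best$cost,
                        gamma = model$best$gamma,
                        folds = venetian_blinds(length(unique(g_tr[i_tr])),
                                                n_splits = min(5, length(unique(g_tr[i_tr])))))
      predict(tuned, fit$train[i_va, , drop = FALSE])
    }
    cv_truth <- c(cv_truth, y_tr[i_va]); cv_pred <- c(cv_pred, sub)
  }
  block <- function(truth, pred) {
    cm <- confusion_counts(truth, pred, classes = sort(unique(meta$species)))
    list(confusion = cm, metrics = classification_metrics(cm),
         accuracy = mean(truth == pred))
  }
  structure(
    list(
      train = block(y_tr, predict_fun(fit$train)),
      cv = block(cv_truth, cv_pred),
      test = block(meta$species[te], predict_fun(fit$test)),
      model = model, pp_fit = fit, method = method, split = split
    ),
    class = "split_evaluation"
  )
}

#' @export
print.split_evaluation <- function(x, ...) {
  cat(sprintf("<split_evaluation> %s: accuracy train %.3f / cv %.3f / test %.3f\n",
              x$method, x$train$accuracy, x$cv$accuracy, x$test$accuracy))
  invisible(x)
}

#' @export
tidy.split_evaluation <- function(x, ...) {
  bind_rows(
    mutate(x$train$metrics, block = "train"),
    mutate(x$cv$metrics, block = "cv"),
    mutate(x$test$metrics, block = "test")
  ) %>% select("block", dplyr::everything())
}

#' @export
glance.split_evaluation <- function(x, ...) {
  tibble(method = x$method,
         train_accuracy = x$train$accuracy,
         cv_accuracy = x$cv$accuracy,
         test_accuracy = x$test$accuracy)
}

#' Leave-class-out validation
#'
#' Excludes one species entirely, fits a 3-class model on the remaining
#' data, and presents the held-out class as a test set: each held-out
#' spectrum is allocated to the predicted class only when that class's
#' probability share exceeds `cutoff`, otherwise it is counted as
#' `"unassigned"`. Reports the allocation counts/percentages per destination
#' and the 3-class CV accuracy, for each held-out class in turn.
#'
#' @param ds A [spectra_tbl()].
#' @param method `"plsda"` or `"svm"`.
#' @param cutoff Probability-share cutoff (default 0.5).
#' @param pp Optional pre-processing chain fitted on the retained classes.
#' @param max_lv PLS-DA LV ceiling.
#' @param held_out Classes to hold out (default: each in turn).
#' @return An `lco_result` tibble: `held_out`, `destination`, `n`, `pct`,
#'   `cv_accuracy`.
#' @export
leave_class_out <- function(ds, method = c("plsda", "svm"), cutoff = 0.5,
                            pp = NULL, max_lv = 10,
                            held_out = sort(unique(spectra_meta(ds)$species))) {
  method <- match.arg(method)
  X <- spectra_matrix(ds)
  meta <- spectra_meta(ds)
  out <- map(held_out, function(cl) {
    keep <- which(meta$species != cl)
    drop_rows <- which(meta$species == cl)
    fit <- apply_chain(pp_spec(pp %||% character()),
                       X[keep, , drop = FALSE], X[drop_rows, , drop = FALSE],
                       Y_train = meta$species[keep])
    g_keep <- meta$sample_id[keep]
    folds <- venetian_blinds(length(unique(g_keep)),
                             n_splits = min(10, length(unique(g_keep))))
    model <- if (method == "plsda") {
      fit_plsda(fit$train, meta$species[keep], max_lv = max_lv,
                folds = folds, groups = g_keep)
    } else {
      tune_svm(fit$train, meta$species[keep], groups = g_keep, folds = folds)
    }
    cv_acc <- if (method == "plsda") 1 - model$cv_error[model$n_lv] else
      model$best$cv_accuracy
    shares <- predict(model, fit$test, type = "share")
    best_cl <- colnames(shares)[apply(shares, 1, which.max)]
    best_sh <- apply(shares, 1, max)
    dest <- ifelse(best_sh > cutoff, best_cl, "unassigned")
    tibble(held_out = cl,
           destination = factor(dest, levels = c(setdiff(sort(unique(meta$species)), cl),
                                                 "unassigned"))) %>%
      count(.data$held_out, .data$destination, .drop = FALSE) %>%
      mutate(pct = 100 * .data$n / sum(.data$n), cv_accuracy = cv_acc)
  }) %>% list_rbind()
  class(out) <- c("lco_result", class(out))
  out
}
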