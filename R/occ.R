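#' Fit a one-class classifier on target-class spectra
#'
#' Models the target class (pork) only; [class_distance()] then measures how
#' far any spectrum lies from that class, with smaller = more target-like.
#' Algorithms:
#' \describe{
#'   \item{simca}{PCA class model; distance is the geometric mean of the
#'     training-mean-normalised Q residual and Hotelling T-squared,
#'     `sqrt((Q/Qbar) * (T2/T2bar))`.}
#'   \item{knn_dist}{Mean Euclidean distance to the k nearest training
#'     points in PCA score space (defaults: 2 PCs, k = 1).}
#'   \item{pca_residual}{The Q statistic (squared orthogonal residual).}
#'   \item{mahalanobis}{Mahalanobis distance to the training mean in PCA
#'     score space.}
#'   \item{ocsvm}{One-class SVM with RBF kernel (nu = 0.05, gamma =
#'     `1/(n_channels * var(X))`); distances are the reversed decision
#'     values `max(0, m - f(x))` with `m` the maximum training decision
#'     value, so the "smaller = in-class" orientation matches the rest.}
#' }
#'
#' @param X Numeric matrix of target-class training spectra, already
#'   pre-processed by the model's chain.
#' @param algorithm One of `"simca"`, `"knn_dist"`, `"pca_residual"`,
#'   `"mahalanobis"`, `"ocsvm"`.
#' @param n_components PCA components (defaults: SIMCA 3, kNN 2,
#'   PCA-residual 3, Mahalanobis 3).
#' @param k Neighbour count for `knn_dist` (default 1).
#' @param nu,gamma One-class SVM parameters (defaults 0.05 and
#'   `1/(n_channels * var(X))`).
#' @return An `occ_model`.
#' @export
fit_occ <- function(X, algorithm = c("simca", "knn_dist", "pca_residual",
                                     "mahalanobis", "ocsvm"),
                    n_components = NULL, k = 1, nu = 0.05, gamma = NULL) {
  algorithm <- match.arg(algorithm)
  X <- as.matrix(X)
  if (is.null(n_components)) {
    n_components <- switch(algorithm, knn_dist = 2L, 3L)
  }
  state <- list()
  if (algorithm != "ocsvm") {
    if (nrow(X) < n_components + 1) {
      abort("need more target training rows than components")
    }
    if (n_components > qr(X - matrix(colMeans(X), nrow(X), ncol(X), byrow = TRUE))$rank) {
      abort("`n_components` exceeds the rank of the centred training data")
    }
    pc <- prcomp(X, center = TRUE, rank. = n_components)
    lambda <- pc$sdev[seq_len(n_components)]^2
    if (any(lambda < 1e-12)) abort("degenerate PCA component (zero variance)")
    state <- list(center = pc$center, loadings = pc$rotation,
                  lambda = lambda, scores = pc$x)
    if (algorithm == "simca") {
      d <- simca_parts(state, X)
      state$q_bar <- mean(d$q)
      state$t2_bar <- mean(d$t2)
      if (state$q_bar < 1e-300 || state$t2_bar < 1e-300) {
        abort("degenerate SIMCA normalisation (zero mean Q or T2 on training data)")
      }
    }
  } else {
    if (is.null(gamma)) gamma <- 1 / (ncol(X) * var(as.vector(X)))
    fit <- e1071::svm(X, y = NULL, type = "one-classification",
                      kernel = "radial", gamma = gamma, nu = nu, scale = FALSE)
    f_train <- drop(attr(predict(fit, X, decision.values = TRUE), "decision.values"))
    state <- list(svm = fit, m = max(f_train))
  }
  structure(
    list(algorithm = algorithm, n_components = n_components, k = k,
         nu = nu, gamma = if (algorithm == "ocsvm") gamma else NULL,
         state = state, n_train = nrow(X), n_channels = ncol(X),
         class_limits = list()),
    class = "occ_model"
  )
}

# SIMCA building blocks: scores, T2 (variance-scaled) and Q residual
simca_parts <- function(state, X) {
  Xc <- sweep(as.matrix(X), 2, state$center, "-")
  Tsc <- Xc %*% state$loadings
  resid <- Xc - Tsc %*% t(state$loadings)
  list(
    t2 = rowSums(sweep(Tsc^2, 2, state$lambda, "/")),
    q = rowSums(resid^2),
    scores = Tsc
  )
}

#' Class distance of spectra to a fitted one-class model
#'
#' @param model An `occ_model` from [fit_occ()].
#' @param X Matrix pre-processed identically to the training data.
#' @return Non-negative numeric vector, one distance per row (smaller =
#'   more target-like).
#' @export
class_distance <- function(model, X) {
  stopifnot(inherits(model, "occ_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$n_channels) {
    abort(sprintf("query has %d channels, model expects %d", ncol(X), model$n_channels))
  }
  st <- model$state
  switch(model$algorithm,
    simca = {
      d <- simca_parts(st, X)
      sqrt((d$q / st$q_bar) * (d$t2 / st$t2_bar))
    },
    pca_residual = simca_parts(st, X)$q,
    mahalanobis = {
      Tsc <- simca_parts(st, X)$scores
      sqrt(rowSums(sweep(Tsc^2, 2, st$lambda, "/")))
    },
    knn_dist = {
      Tsc <- simca_parts(st, X)$scores
      k <- min(model$k, nrow(st$scores))
      apply(Tsc, 1, function(t) {
        d <- sqrt(colSums((t(st$scores) - t)^2))
        mean(sort(d)[seq_len(k)])
      })
    },
    ocsvm = {
      f <- drop(attr(predict(st$svm, X, decision.values = TRUE), "decision.values"))
      pmax(0, st$m - f)
    }
  )
}

#' Area under the ROC curve for class distances
#'
#' Mann-Whitney formulation: the fraction of (target, other) pairs in which
#' the target distance is smaller than the other distance, ties counted one
#' half. Invariant under any strictly monotone transform of the distances.
#'
#' @param target_distances Distances of target-class (pork) spectra.
#' @param other_distances Distances of non-target spectra.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(target_distances, other_distances) {
  n_t <- length(target_distances); n_o <- length(other_distances)
  if (n_t == 0 || n_o == 0) abort("both distance vectors must be nonempty")
  r <- rank(c(target_distances, other_distances), ties.method = "average")
  u <- sum(r[(n_t + 1):(n_t + n_o)]) - n_o * (n_o + 1) / 2
  u / (n_t * n_o)
}

#' Per-sample median class distances
#'
#' The final classification uses the median class distance of a sample's
#' replicate scans (robust to the odd aberrant scan).
#'
#' @param model An `occ_model`.
#' @param X Pre-processed spectra matrix.
#' @param groups A [sample_groups()] tibble whose `rows` index into `X`.
#' @return Tibble `sample_id`, `species`, `form`, `distance`.
#' @export
median_sample_distance <- function(model, X, groups) {
  d <- class_distance(model, X)
  tibble(
    sample_id = groups$sample_id,
    species = groups$species,
    form = groups$form,
    distance = map_dbl(groups$rows, ~ median(d[.x]))
  )
}

#' Set a class limit for a scenario
#'
#' Scenario 1 sets the limit just above the maximum training-sample median
#' distance, so 100% of target training samples fall in-class (no pork ever
#' missed — the halal-screening requirement). Scenario 2 sets the limit at a
#' quantile (default 0.95) of the training distances, trading a small loss of
#' target sensitivity for a stricter limit that rejects non-target samples
#' more reliably.
#'
#' @param model An `occ_model`.
#' @param target_train_distances Per-sample median distances of the
#'   target-class training samples.
#' @param scenario 1 or 2.
#' @param q Quantile used by scenario 2 (default 0.95).
#' @return The model with the limit stored in `class_limits` (and the limit
#'   as attribute `"limit"`).
#' @export
set_class_limit <- function(model, target_train_distances, scenario, q = 0.95) {
  stopifnot(inherits(model, "occ_model"))
  if (!length(target_train_distances)) abort("no training distances supplied")
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:2) abort("`scenario` must be 1 or 2")
  limit <- if (scenario == 1) {
    max(target_train_distances) * (1 + 1e-9)
  } else {
    unname(quantile(target_train_distances, q))
  }
  model$class_limits[[as.character(scenario)]] <- limit
  attr(model, "limit") <- limit
  model
}

#' @export
print.occ_model <- function(x, ...) {
  cat(sprintf("<occ_model> %s (%s), fitted on %d target scans\n",
              x$algorithm,
              if (x$algorithm == "ocsvm") sprintf("nu=%.3g", x$nu)
              else sprintf("%d PCs", x$n_components),
              x$n_train))
  if (length(x$class_limits)) {
    cat("  class limits:",
        paste(sprintf("scenario %s = %.4g", names(x$class_limits),
                      unlist(x$class_limits)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
glance.occ_model <- function(x, ...) {
  tibble(
    algorithm = x$algorithm,
    n_components = x$n_components,
    k = x$k, nu = x$nu,
    n_train = x$n_train,
    n_channels = x$n_channels,
    limit_scenario1 = x$class_limits[["1"]] %||% NA_real_,
    limit_scenario2 = x$class_limits[["2"]] %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
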