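#' Venetian blinds fold assignment
#'
#' Unit `i` (0-based) goes to fold `floor(i / thickness) mod n_splits`.
#' Applied at the sample-group level ("1 sample per split"), so replicates of
#' one sample always share a fold.
#'
#' @param n_units Number of units (samples) to assign.
#' @param n_splits Number of folds (default 10).
#' @param thickness Consecutive units per blind (default 1).
#' @return A `cv_folds` object: list with `scheme`, `params` and `folds`,
#'   each fold a list of `train` and `validation` unit indices (1-based).
#' @export
venetian_blinds <- function(n_units, n_splits = 10, thickness = 1) {
  if (n_units < n_splits) abort("need at least as many units as splits")
  assign <- (((seq_len(n_units) - 1) %/% thickness) %% n_splits) + 1
  folds <- lapply(seq_len(n_splits), function(f) {
    list(train = which(assign != f), validation = which(assign == f))
  })
  structure(list(scheme = "venetian_blinds",
                 params = list(n_splits = n_splits, thickness = thickness),
                 folds = folds),
            class = "cv_folds")
}

#' Cross-validation fold generators
#'
#' Builds folds over units (sample groups). Schemes: `"venetian_blinds"`,
#' `"kfold"` (contiguous after a seeded shuffle), `"loo"` (leave-one-out),
#' `"random_subsets"` (repeated random s-fold partitions). Within one
#' repetition the validation folds partition the units.
#'
#' @param scheme One of the schemes above.
#' @param n_units Number of units.
#' @param params Scheme parameters: `n_splits`, `thickness` (venetian),
#'   `k` (kfold), `s` and `r` (random_subsets: folds per repeat, repeats).
#' @param seed Seed for the stochastic schemes.
#' @return A `cv_folds` object.
#' @export
cv_folds <- function(scheme = c("venetian_blinds", "kfold", "loo", "random_subsets"),
                     n_units, params = list(), seed = NULL) {
  scheme <- match.arg(scheme)
  folds <- switch(scheme,
    venetian_blinds = {
      p <- modifyList(list(n_splits = 10, thickness = 1), params)
      return(venetian_blinds(n_units, p$n_splits, p$thickness))
    },
    loo = lapply(seq_len(n_units), function(i) {
      list(train = setdiff(seq_len(n_units), i), validation = i)
    }),
    kfold = {
      p <- modifyList(list(k = 5), params)
      if (is.null(seed)) abort("`seed` is required for kfold")
      perm <- withr::with_seed(seed, sample(n_units))
      assign <- cut(seq_along(perm), breaks = p$k, labels = FALSE)
      lapply(seq_len(p$k), function(f) {
        v <- sort(perm[assign == f])
        list(train = setdiff(seq_len(n_units), v), validation = v)
      })
    },
    random_subsets = {
      p <- modifyList(list(s = 5, r = 3), params)
      if (is.null(seed)) abort("`seed` is required for random_subsets")
      withr::with_seed(seed, {
        unlist(lapply(seq_len(p$r), function(rep_i) {
          perm <- sample(n_units)
          assign <- cut(seq_along(perm), breaks = p$s, labels = FALSE)
          lapply(seq_len(p$s), function(f) {
            v <- sort(perm[assign == f])
            list(train = setdiff(seq_len(n_units), v), validation = v)
          })
        }), recursive = FALSE)
      })
    }
  )
  structure(list(scheme = scheme, params = params, folds = folds),
            class = "cv_folds")
}

#' @export
print.cv_folds <- function(x, ...) {
  cat(sprintf("<cv_folds> %s, %d folds\n", x$scheme, length(x$folds)))
  invisible(x)
}

# translate unit-level folds to scan-row folds via a sample_groups table
fold_rows <- function(folds, groups) {
  lapply(folds$folds, function(f) {
    list(train = sort(unlist(groups$rows[f$train])),
         validation = sort(unlist(groups$rows[f$validation])))
  })
}

#' Repeated random splits of the target class
#'
#' The screening protocol: 80 independent seeded group-level 70/30 splits of
#' the target-class samples, replicates always kept together.
#'
#' @param groups A [sample_groups()] tibble (target-class samples only).
#' @param n_repeats Number of repetitions (default 80).
#' @param train_fraction Group-level training fraction (default 0.7).
#' @param seed Master seed; each repetition draws its own derived seed.
#' @return List of `split_result`s of length `n_repeats`.
#' @export
repeated_random_cv <- function(groups, n_repeats = 80, train_fraction = 0.7,
                               seed = 1L) {
  n <- nrow(groups)
  if (n < 2) abort("need at least 2 target-class samples")
  n_tr <- max(1, min(n - 1, round(train_fraction * n)))
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, n_repeats))
  lapply(rep_seeds, function(s) {
    tr <- withr::with_seed(s, sort(sample(n, n_tr)))
    new_split_result(groups$sample_id[tr], groups$sample_id[-tr], groups)
  })
}
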