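#' Per-sample representative spectra
#'
#' Distance-based splitting operates on samples, not scans: each sample is
#' represented by the mean of its replicate spectra, by default after SNV so
#' that scatter differences do not dominate the distances.
#'
#' @param ds A [spectra_tbl()].
#' @param standardise Apply SNV before averaging (default `TRUE`).
#' @return Matrix with one row per sample (rownames = sample ids), in
#'   first-appearance order.
#' @export
sample_representatives <- function(ds, standardise = TRUE) {
  X <- spectra_matrix(ds)
  if (standardise) X <- snv(X)
  grp <- sample_groups(ds)
  reps <- t(vapply(grp$rows, function(r) colMeans(X[r, , drop = FALSE]),
                   numeric(ncol(X))))
  rownames(reps) <- grp$sample_id
  reps
}

new_split_result <- function(train_groups, test_groups, groups) {
  rows_of <- function(ids) sort(unlist(groups$rows[match(ids, groups$sample_id)]))
  structure(
    list(train_groups = train_groups, test_groups = test_groups,
         train_rows = rows_of(train_groups), test_rows = rows_of(test_groups)),
    class = "split_result"
  )
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d train / %d test samples (%d / %d scans)\n",
              length(x$train_groups), length(x$test_groups),
              length(x$train_rows), length(x$test_rows)))
  invisible(x)
}

# max-min farthest-point assignment shared by duplex and Kennard-Stone;
# ties always break towards the lowest row index
farthest_pair <- function(D, avail) {
  sub <- D[avail, avail, drop = FALSE]
  diag(sub) <- -Inf
  k <- which.max(sub)   # first maximum in column-major order = lowest indices
  i <- (k - 1) %% length(avail) + 1
  j <- (k - 1) %/% length(avail) + 1
  sort(c(avail[i], avail[j]))
}

next_farthest <- function(D, selected, avail) {
  d_min <- apply(D[avail, selected, drop = FALSE], 1, min)
  avail[which.max(d_min)]
}

#' Duplex assignment of group representatives
#'
#' Classic duplex partitioning: the two mutually farthest groups (Euclidean
#' distance between representatives) seed the training set, the next farthest
#' pair seeds the test set, and remaining groups are assigned alternately —
#' each time the group farthest (max-min) from the growing set — to train and
#' test in turn, until the test set reaches its quota; the rest go to train.
#' Ties break towards the lowest input index, so the assignment is fully
#' deterministic.
#'
#' @param representatives Matrix, one row per group (rownames used as ids).
#' @param train_fraction Fraction of groups for training, in (0, 1).
#' @return List with `train` and `test` integer index vectors.
#' @export
duplex_assign <- function(representatives, train_fraction = 0.7) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must lie strictly between 0 and 1")
  }
  n <- nrow(representatives)
  if (n < 4) abort("duplex needs at least 4 groups")
  n_test <- max(1, round((1 - train_fraction) * n))
  D <- as.matrix(stats::dist(representatives))
  avail <- seq_len(n)
  train <- farthest_pair(D, avail); avail <- setdiff(avail, train)
  test <- farthest_pair(D, avail); avail <- setdiff(avail, test)
  turn <- "train"
  while (length(avail)) {
    if (turn == "train" || length(test) >= n_test) {
      pick <- next_farthest(D, train, avail)
      train <- c(train, pick)
      turn <- "test"
    } else {
      pick <- next_farthest(D, test, avail)
      test <- c(test, pick)
      turn <- "train"
    }
    avail <- setdiff(avail, pick)
    if (length(test) >= n_test && turn == "test") turn <- "train"
  }
  list(train = sort(train), test = sort(test))
}

#' Kennard-Stone assignment of group representatives
#'
#' Max-min (farthest point) selection: the mutually farthest pair seeds the
#' training set, then the group farthest from the selected set is added until
#' the training quota is met; the remainder is the test set.
#'
#' @inheritParams duplex_assign
#' @param n_train Number of groups to select (default
#'   `round(train_fraction * n)`).
#' @return List with `train` and `test` integer index vectors.
#' @export
kennard_stone_assign <- function(representatives, train_fraction = 0.7,
                                 n_train = NULL) {
  n <- nrow(representatives)
  if (is.null(n_train)) {
    if (train_fraction <= 0 || train_fraction > 1) {
      abort("`train_fraction` must lie in (0, 1]")
    }
    n_train <- round(train_fraction * n)
  }
  if (n < 2) abort("Kennard-Stone needs at least 2 groups")
  n_train <- max(2, min(n, n_train))
  D <- as.matrix(stats::dist(representatives))
  train <- farthest_pair(D, seq_len(n))
  avail <- setdiff(seq_len(n), train)
  while (length(train) < n_train && length(avail)) {
    pick <- next_farthest(D, train, avail)
    train <- c(train, pick)
    avail <- setdiff(avail, pick)
  }
  if (!length(avail)) warn("Kennard-Stone selected every group; test set is empty")
  list(train = sort(train), test = sort(avail))
}

#' Group-aware train/test split of a spectra dataset
#'
#' Partitions samples (never individual scans: all replicates of one sample
#' land on the same side) into training and test sets. Distance-based methods
#' (`"duplex"`, `"kennard_stone"`) operate on per-sample representative
#' spectra ([sample_representatives()]); `"random"` samples uniformly with a
#' seed. The split runs within each species stratum so that every species is
#' represented on both sides.
#'
#' @param ds A [spectra_tbl()].
#' @param method `"duplex"`, `"kennard_stone"` or `"random"`.
#' @param train_fraction Group-level training fraction (default 0.7).
#' @param stratify Split within each species separately (default `TRUE`).
#' @param standardise SNV before computing representative distances.
#' @param seed Seed for `method = "random"`.
#' @return A `split_result`: `train_groups`, `test_groups` (sample ids) and
#'   `train_rows`, `test_rows` (scan indices).
#' @export
split_samples <- function(ds, method = c("duplex", "kennard_stone", "random"),
                          train_fraction = 0.7, stratify = TRUE,
                          standardise = TRUE, seed = NULL) {
  method <- match.arg(method)
  groups <- sample_groups(ds)
  reps <- sample_representatives(ds, standardise = standardise)
  strata <- if (stratify) split(seq_len(nrow(groups)), groups$species) else
    list(all = seq_len(nrow(groups)))
  pick_one <- function(idx) {
    R <- reps[idx, , drop = FALSE]
    sel <- switch(method,
      duplex = duplex_assign(R, train_fraction),
      kennard_stone = kennard_stone_assign(R, train_fraction),
      random = {
        if (is.null(seed)) abort("`seed` is required for random splits")
        n_tr <- max(1, round(train_fraction * length(idx)))
        tr <- sort(sample(seq_along(idx), n_tr))
        list(train = tr, test = setdiff(seq_along(idx), tr))
      }
    )
    list(train = idx[sel$train], test = idx[sel$test])
  }
  sels <- if (method == "random") {
    withr::with_seed(seed, lapply(strata, pick_one))
  } else {
    lapply(strata, pick_one)
  }
  train_idx <- sort(unlist(lapply(sels, `[[`, "train")))
  test_idx <- sort(unlist(lapply(sels, `[[`, "test")))
  new_split_result(groups$sample_id[train_idx], groups$sample_id[test_idx], groups)
}

#' Serialise a split to a tibble
#'
#' @param split A `split_result`.
#' @return Tibble with columns `sample_id`, `partition`.
#' @export
split_table <- function(split) {
  tibble(
    sample_id = c(split$train_groups, split$test_groups),
    partition = rep(c("train", "test"),
                    c(length(split$train_groups), length(split$test_groups)))
  )
}
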