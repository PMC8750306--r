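#' Build a screening grid
#'
#' Expands pre-processing chains x spectrum subsets x one-class algorithms
#' into the combination table consumed by [screen_occ()].
#'
#' @param pp Character vector of chain strings (see [pp_spec()]); `""` or
#'   `"raw"` means no pre-processing.
#' @param quarter Character/integer vector from `"full"`, `1`-`4`.
#' @param algorithm Character vector of [fit_occ()] algorithms.
#' @return Tibble with columns `pp`, `quarter`, `algorithm`, `combo_id`.
#' @export
screening_grid <- function(pp = c("snv", "snv|detrend(deg=2)",
                                  "savgol(w=11,p=2,d=1)", "savgol(w=11,p=2,d=2)",
                                  "dwt(family=daub_short,lo=5,hi=7)",
                                  "dwt(family=la8,lo=3,hi=5)"),
                           quarter = "full",
                           algorithm = c("simca", "knn_dist", "pca_residual",
                                         "mahalanobis", "ocsvm")) {
  g <- tidyr::expand_grid(pp = pp, quarter = as.character(quarter),
                          algorithm = algorithm)
  g$pp <- ifelse(g$pp %in% c("", "raw"), "", g$pp)
  g$combo_id <- sprintf("%s @ %s [%s]", g$algorithm,
                        ifelse(g$pp == "", "raw", g$pp),
                        ifelse(g$quarter == "full", "full", paste0("q", g$quarter)))
  g
}

# full chain string for one combo (subset applied first)
combo_chain <- function(pp, quarter) {
  qstep <- if (!identical(quarter, "full")) sprintf("quarter(q=%s)", quarter) else NULL
  paste(c(qstep, if (nzchar(pp)) pp), collapse = "|")
}

#' AUROC screening of pre-processing x one-class algorithm combinations
#'
#' For each combination and each of `n_repeats` repeated random 70/30 splits
#' of the target-class (pork) samples: fit the chain and the one-class model
#' on the training pork scans, compute class distances for the held-out pork
#' scans and for all non-target scans, and record the AUROC of pork against
#' lamb, beef, chicken, and all non-target scans pooled. Reported AUROCs are
#' means over the repeats. Combinations whose pre-processing fails are marked
#' failed rather than aborting the screen.
#'
#' @param ds A [spectra_tbl()] containing all four species.
#' @param grid A [screening_grid()] tibble.
#' @param n_repeats Repetitions (default 80).
#' @param train_fraction Target-class training fraction per repeat (0.7).
#' @param seed Master seed for the repeated splits.
#' @param target Target species (default `"pork"`).
#' @return A `screening_records` tibble: one row per combination with mean
#'   AUROC columns `auroc_lamb`, `auroc_beef`, `auroc_chicken`, `auroc_all`.
#' @export
screen_occ <- function(ds, grid = screening_grid(), n_repeats = 80,
                       train_fraction = 0.7, seed = 1L, target = "pork") {
  meta <- spectra_meta(ds)
  if (!all(SPECIES_LEVELS %in% meta$species)) {
    abort("screening requires all four species in the dataset")
  }
  X <- spectra_matrix(ds)
  groups <- sample_groups(ds)
  target_groups <- groups[groups$species == target, ]
  splits <- repeated_random_cv(target_groups, n_repeats, train_fraction, seed)
  other_species <- setdiff(SPECIES_LEVELS, target)
  other_rows <- lapply(other_species, function(sp) which(meta$species == sp))
  names(other_rows) <- other_species

  records <- pmap(grid, function(pp, quarter, algorithm, combo_id) {
    chain <- combo_chain(pp, quarter)
    per_rep <- matrix(NA_real_, n_repeats, 4)
    ok <- TRUE
    for (r in seq_len(n_repeats)) {
      res <- tryCatch({
        tr_rows <- splits[[r]]$train_rows
        ho_rows <- splits[[r]]$test_rows
        fit <- apply_chain(chain, X[tr_rows, , drop = FALSE])
        model <- fit_occ(fit$train, algorithm)
        d_ho <- class_distance(model, pp_apply(fit, X[ho_rows, , drop = FALSE]))
        d_other <- lapply(other_rows, function(rows) {
          class_distance(model, pp_apply(fit, X[rows, , drop = FALSE]))
        })
        c(vapply(other_species, function(sp) auroc(d_ho, d_other[[sp]]), numeric(1)),
          auroc(d_ho, unlist(d_other, use.names = FALSE)))
      }, error = function(e) NULL)
      if (is.null(res)) { ok <- FALSE; break }
      per_rep[r, ] <- res
    }
    tibble(
      combo_id = combo_id, pp = pp, quarter = quarter, algorithm = algorithm,
      auroc_lamb = if (ok) mean(per_rep[, 1]) else NA_real_,
      auroc_beef = if (ok) mean(per_rep[, 2]) else NA_real_,
      auroc_chicken = if (ok) mean(per_rep[, 3]) else NA_real_,
      auroc_all = if (ok) mean(per_rep[, 4]) else NA_real_,
      n_repeats = n_repeats, failed = !ok
    )
  }) %>% list_rbind()
  class(records) <- c("screening_records", class(records))
  records
}

#' Select the screening triplet
#'
#' Automatic stand-in for the expert's manual choice of three models jointly
#' covering the highest per-class AUROCs: greedily pick the combination
#' maximising the minimum AUROC over lamb/beef/chicken, then twice more pick
#' the combination that most raises the ensemble's weakest per-class
#' best-of-selected AUROC. Ties break by `auroc_all`, then by combination id.
#' Supply `manual` to bypass the rule with three explicit combination ids.
#'
#' @param records A `screening_records` tibble from [screen_occ()].
#' @param manual Optional character vector of exactly 3 `combo_id`s.
#' @return Character vector of 3 combination ids.
#' @export
select_triplet <- function(records, manual = NULL) {
  if (!is.null(manual)) {
    if (length(manual) != 3) abort("`manual` must name exactly 3 combinations")
    missing_ids <- setdiff(manual, records$combo_id)
    if (length(missing_ids)) {
      abort(sprintf("unknown combo id(s): %s", paste(missing_ids, collapse = ", ")))
    }
    return(manual)
  }
  rec <- records[!records$failed, , drop = FALSE]
  if (nrow(rec) < 3) abort("need at least 3 non-failed screening records")
  cls <- c("auroc_lamb", "auroc_beef", "auroc_chicken")
  A <- as.matrix(rec[cls])
  selected <- integer(0)
  for (step in 1:3) {
    cand <- setdiff(seq_len(nrow(rec)), selected)
    obj <- vapply(cand, function(i) {
      rows <- c(selected, i)
      min(apply(A[rows, , drop = FALSE], 2, max))
    }, numeric(1))
    ord <- order(-obj, -rec$auroc_all[cand], rec$combo_id[cand])
    selected <- c(selected, cand[ord[1]])
  }
  rec$combo_id[selected]
}

#' Fit the screening ensemble on a training split
#'
#' Fits each selected combination's chain and one-class model on the
#' target-class training scans, computes the per-sample median training
#' distances and calibrates both scenario class limits.
#'
#' @param ds A [spectra_tbl()].
#' @param split A `split_result` from [split_samples()].
#' @param triplet Character vector of combination ids (from
#'   [select_triplet()]); the matching rows of `grid` define chains and
#'   algorithms.
#' @param grid The [screening_grid()] the ids come from.
#' @param target Target species (default `"pork"`).
#' @param q Scenario-2 quantile (default 0.95).
#' @return An `occ_ensemble` object.
#' @export
fit_ensemble <- function(ds, split, triplet, grid, target = "pork", q = 0.95) {
  if (length(triplet) != 3) abort("the ensemble uses exactly 3 models")
  X <- spectra_matrix(ds)
  groups <- sample_groups(ds)
  train_target <- groups[groups$species == target &
                           groups$sample_id %in% split$train_groups, ]
  if (!nrow(train_target)) abort("no target-class samples in the training split")
  tr_rows <- sort(unlist(train_target$rows))
  members <- lapply(triplet, function(id) {
    row <- grid[match(id, grid$combo_id), ]
    if (is.na(row$algorithm)) abort(sprintf("combo id '%s' not present in grid", id))
    chain <- combo_chain(row$pp, row$quarter)
    fit <- apply_chain(chain, X[tr_rows, , drop = FALSE])
    model <- fit_occ(fit$train, row$algorithm)
    # per-sample median distances of the training target samples
    local_groups <- train_target
    local_groups$rows <- lapply(local_groups$rows, function(r) match(r, tr_rows))
    med <- median_sample_distance(model, fit$train, local_groups)
    model <- set_class_limit(model, med$distance, 1)
    model <- set_class_limit(model, med$distance, 2, q = q)
    list(combo_id = id, chain = fit, model = model, train_distances = med)
  })
  structure(list(members = members, target = target, q = q, split = split),
            class = "occ_ensemble")
}

#' @export
print.occ_ensemble <- function(x, ...) {
  cat(sprintf("<occ_ensemble> 3 one-class models, target = %s\n", x$target))
  for (m in x$members) cat("  -", m$combo_id, "\n")
  invisible(x)
}

#' Classify samples with the 2-of-3 ensemble vote
#'
#' For each sample the median class distance of its replicate scans is
#' compared to each member model's class limit for the chosen scenario; a
#' sample is flagged `"not_pork_meat"` when two or more of the three models
#' place it out-of-class, and `"pork_in_class"` otherwise.
#'
#' @param ensemble An `occ_ensemble` from [fit_ensemble()].
#' @param ds A [spectra_tbl()] of samples to classify.
#' @param scenario 1 (limit passes every target training sample) or 2
#'   (quantile limit).
#' @param rows Optional scan indices restricting classification (e.g. a test
#'   partition); samples are formed within the restriction.
#' @return An `ensemble_decisions` tibble: `sample_id`, `species`, `form`,
#'   one in-class column per model, `n_out`, `flag`.
#' @export
classify_samples <- function(ensemble, ds, scenario = 1, rows = NULL) {
  stopifnot(inherits(ensemble, "occ_ensemble"))
  scenario <- as.character(as.integer(scenario))
  if (!is.null(rows)) ds <- spectra_rows(ds, rows)
  X <- spectra_matrix(ds)
  groups <- sample_groups(ds)
  if (!nrow(groups)) abort("no samples to classify")
  votes <- vapply(ensemble$members, function(m) {
    limit <- m$model$class_limits[[scenario]]
    if (is.null(limit)) abort(sprintf("no class limit stored for scenario %s", scenario))
    med <- median_sample_distance(m$model, pp_apply(m$chain, X), groups)
    med$distance <= limit
  }, logical(nrow(groups)))
  votes <- matrix(votes, nrow = nrow(groups))
  n_out <- rowSums(!votes)
  out <- tibble(
    sample_id = groups$sample_id,
    species = groups$species,
    form = groups$form,
    in_class_1 = votes[, 1], in_class_2 = votes[, 2], in_class_3 = votes[, 3],
    n_out = as.integer(n_out),
    flag = ifelse(n_out >= 2, "not_pork_meat", "pork_in_class")
  )
  class(out) <- c("ensemble_decisions", class(out))
  out
}

#' Correct classification rate per species
#'
#' A target-class (pork) sample is correct when flagged `pork_in_class`; a
#' non-target sample is correct when flagged `not_pork_meat`.
#'
#' @param decisions An `ensemble_decisions` tibble.
#' @param target Target species (default `"pork"`).
#' @return Tibble `species`, `n`, `n_correct`, `rate` (percent).
#' @export
correct_classification_rate <- function(decisions, target = "pork") {
  decisions %>%
    as_tibble() %>%
    mutate(correct = ifelse(.data$species == target,
                            .data$flag == "pork_in_class",
                            .data$flag == "not_pork_meat")) %>%
    group_by(.data$species) %>%
    summarise(n = n(), n_correct = sum(.data$correct),
              rate = 100 * mean(.data$correct), .groups = "drop") %>%
    arrange(match(.data$species, SPECIES_LEVELS))
}
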