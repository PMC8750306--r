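#' Run a configured end-to-end analysis
#'
#' Executes the full pipeline from a declarative configuration: obtain data
#' (CSV file or simulation), split samples group-aware, then either run the
#' one-class screening + ensemble classification (method `occ`) or fit and
#' evaluate a discriminant model (method `plsda`/`svm`). All numeric outputs
#' are written as CSV into `outdir` together with a reproducibility manifest
#' (config, seeds, package version); re-running the same config reproduces
#' every table.
#'
#' Config structure (list or YAML file):
#' \preformatted{
#' data:   file: spectra.csv           # OR simulate: {n_samples_per_species,
#'                                     #   sensor, form, seed, ...}
#' split:  {method: duplex, train_fraction: 0.7}
#' method: occ                         # or plsda / svm
#' occ:    {pp: [snv, "savgol(w=11,p=2,d=1)"], algorithms: [simca, ocsvm],
#'          n_repeats: 80, scenario: [1, 2], q: 0.95}
#' disc:   {pp: snv, max_lv: 10}
#' seed:   1
#' }
#'
#' @param config List or path to a YAML file.
#' @param outdir Output directory (created if missing); `NULL` writes
#'   nothing and just returns the bundle.
#' @return A `pipeline_result` list of the stage outputs, invisibly when
#'   `outdir` is used.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$seed)) abort("config must carry an explicit `seed`")
  seed <- as.integer(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  ds <- stage("data", {
    if (!is.null(cfg$data$file)) {
      read_spectra(cfg$data$file)
    } else if (!is.null(cfg$data$simulate)) {
      sim_args <- cfg$data$simulate
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      simulate_spectra(do.call(sim_config, sim_args))
    } else abort("config needs data$file or data$simulate")
  })
  split_cfg <- modifyList(list(method = "duplex", train_fraction = 0.7), cfg$split %||% list())
  split <- stage("split", split_samples(
    ds, method = split_cfg$method, train_fraction = split_cfg$train_fraction,
    seed = seed + 1L
  ))
  method <- cfg$method %||% "occ"
  results <- list(dataset = ds, split = split, config = cfg, method = method)

  if (method == "occ") {
    occ_cfg <- modifyList(
      list(pp = c("snv", "savgol(w=11,p=2,d=1)"),
           algorithms = c("simca", "knn_dist", "mahalanobis"),
           quarter = "full", n_repeats = 80, scenario = c(1, 2), q = 0.95),
      cfg$occ %||% list()
    )
    grid <- screening_grid(pp = occ_cfg$pp, quarter = occ_cfg$quarter,
                           algorithm = occ_cfg$algorithms)
    records <- stage("screen", screen_occ(
      spectra_rows(ds, split$train_rows), grid,
      n_repeats = occ_cfg$n_repeats, seed = seed + 2L
    ))
    triplet <- stage("triplet", select_triplet(records))
    ensemble <- stage("ensemble", fit_ensemble(ds, split, triplet, grid, q = occ_cfg$q))
    decisions <- list(); rates <- list()
    for (sc in occ_cfg$scenario) {
      dec <- stage("classify", classify_samples(ensemble, ds, scenario = sc,
                                                rows = split$test_rows))
      decisions[[as.character(sc)]] <- dec
      rates[[as.character(sc)]] <- mutate(correct_classification_rate(dec),
                                          scenario = sc)
    }
    results <- c(results, list(records = records, triplet = triplet,
                               ensemble = ensemble, decisions = decisions,
                               rates = list_rbind(rates)))
  } else {
    disc_cfg <- modifyList(list(pp = "snv", max_lv = 10), cfg$disc %||% list())
    ev <- stage("evaluate", evaluate_on_split(ds, split, method = method,
                                              pp = disc_cfg$pp,
                                              max_lv = disc_cfg$max_lv))
    results <- c(results, list(evaluation = ev))
  }
  class(results) <- "pipeline_result"
  if (!is.null(outdir)) {
    write_pipeline(results, outdir, seed)
    return(invisible(results))
  }
  results
}

write_pipeline <- function(results, outdir, seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_csv(x, file.path(outdir, name), progress = FALSE)
  w(split_table(results$split), "split.csv")
  if (results$method == "occ") {
    w(as_tibble(results$records), "screening_records.csv")
    for (sc in names(results$decisions)) {
      w(as_tibble(results$decisions[[sc]]), sprintf("decisions_scenario%s.csv", sc))
    }
    w(results$rates, "classification_rates.csv")
  } else {
    w(tidy(results$evaluation), "metrics.csv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("meatspec")),
    seed = seed,
    method = results$method,
    config = results$config,
    n_scans = nrow(results$dataset),
    written = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

#' Human-readable result tables
#'
#' Formats pipeline outputs the way screening and validation results are
#' usually tabulated: per-combination AUROC tables, per-species correct
#' classification rates by scenario, train/CV/test metric blocks, and
#' leave-class-out allocation tables. Percentages are shown to one decimal.
#'
#' @param x A pipeline or stage result (`pipeline_result`,
#'   `screening_records`, `ensemble_decisions` rates tibble,
#'   `split_evaluation`, or `lco_result`).
#' @param ... Unused.
#' @return A tibble (or named list of tibbles for `pipeline_result`).
#' @export
report <- function(x, ...) UseMethod("report")

#' @export
report.default <- function(x, ...) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x))) {
    return(tibble(note = "no results"))
  }
  as_tibble(x)
}

#' @export
report.screening_records <- function(x, ...) {
  as_tibble(x) %>%
    mutate(across(dplyr::starts_with("auroc_"), ~ round(.x, 3))) %>%
    arrange(dplyr::desc(.data$auroc_all)) %>%
    rename(`pork vs lamb` = "auroc_lamb", `pork vs beef` = "auroc_beef",
           `pork vs chicken` = "auroc_chicken", `pork vs all` = "auroc_all")
}

#' @export
report.split_evaluation <- function(x, ...) {
  tidy(x) %>%
    mutate(across(c("sensitivity", "specificity", "accuracy", "error"),
                  ~ round(100 * .x, 1)))
}

#' @export
report.lco_result <- function(x, ...) {
  as_tibble(x) %>% mutate(pct = round(.data$pct, 1),
                          cv_accuracy = round(100 * .data$cv_accuracy, 1))
}

#' @export
report.pipeline_result <- function(x, ...) {
  if (x$method == "occ") {
    list(
      screening = report(x$records),
      rates = x$rates %>%
        mutate(rate = round(.data$rate, 1)) %>%
        tidyr::pivot_wider(id_cols = "species", names_from = "scenario",
                           values_from = "rate", names_prefix = "scenario_")
    )
  } else {
    list(metrics = report(x$evaluation))
  }
}
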