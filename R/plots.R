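#' Plot spectra coloured by species
#'
#' @param object A [spectra_tbl()].
#' @param n_max Plot at most this many scans (thinned deterministically).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spectra_tbl <- function(object, n_max = 60, ...) {
  grid <- spectra_grid(object)
  idx <- unique(round(seq(1, nrow(object), length.out = min(n_max, nrow(object)))))
  long <- spectra_rows(object, idx)
  df <- as_tibble(long) %>%
    mutate(scan = dplyr::row_number()) %>%
    pivot_longer(cols = -c("sample_id", "species", "form", "replicate", "scan"),
                 names_to = "channel", values_to = "intensity")
  df$wavelength <- grid$wavelengths_nm[match(df$channel, channel_names(grid))]
  df$block <- factor(grid$block[match(df$channel, channel_names(grid))])
  ggplot(df, aes(x = .data$wavelength, y = .data$intensity,
                 group = interaction(.data$scan, .data$block),
                 colour = .data$species)) +
    geom_line(alpha = 0.5, linewidth = 0.3) +
    labs(x = "wavelength (nm)", y = "intensity (a.u.)",
         title = sprintf("%s spectra", grid$sensor)) +
    theme_minimal()
}

#' Score plot of a PCA model
#'
#' @param object A `pca_model` from [fit_pca()].
#' @param labels Optional point labels (e.g. species) for colouring.
#' @param components Two components to display (default 1:2).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_model <- function(object, labels = NULL, components = 1:2, ...) {
  sc <- object$scores[, components, drop = FALSE]
  df <- tibble(x = sc[, 1], y = sc[, 2],
               label = if (is.null(labels)) "scores" else as.character(labels))
  ggplot(df, aes(x = .data$x, y = .data$y, colour = .data$label)) +
    geom_point(alpha = 0.8) +
    labs(
      x = sprintf("PC%d (%.1f%%)", components[1], 100 * object$explained[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2], 100 * object$explained[components[2]])
    ) +
    theme_minimal()
}

#' CV error curve of a PLS-DA model
#'
#' @param object A `plsda_model`.
#' @param ... Unused.
#' @return A ggplot of CV misclassification error against LV count, with the
#'   selected LV marked.
#' @export
autoplot.plsda_model <- function(object, ...) {
  df <- tibble(lv = seq_along(object$cv_error), cv_error = object$cv_error)
  ggplot(df, aes(x = .data$lv, y = .data$cv_error)) +
    geom_line() + geom_point() +
    geom_vline(xintercept = object$n_lv, linetype = "dashed") +
    labs(x = "latent variables", y = "CV misclassification error") +
    theme_minimal()
}

#' Heatmap of screening AUROCs
#'
#' @param records A `screening_records` tibble from [screen_occ()].
#' @return A ggplot tile map of the per-contrast AUROCs per combination.
#' @export
plot_screening <- function(records) {
  df <- as_tibble(records) %>%
    filter(!.data$failed) %>%
    pivot_longer(cols = dplyr::starts_with("auroc_"),
                 names_to = "contrast", values_to = "auroc") %>%
    mutate(contrast = sub("auroc_", "pork vs ", .data$contrast))
  ggplot(df, aes(x = .data$contrast, y = .data$combo_id, fill = .data$auroc)) +
    geom_tile() +
    geom_text(aes(label = sprintf("%.2f", .data$auroc)), size = 3) +
    scale_fill_gradient(limits = c(0.5, 1), low = "white", high = "steelblue",
                        oob = scales_squish) +
    labs(x = NULL, y = NULL, fill = "AUROC") +
    theme_minimal()
}

# minimal local squish (avoids a scales dependency for one helper)
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}
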