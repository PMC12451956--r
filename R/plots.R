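#' Heatmap of a percent-identity matrix
#'
#' @param identity_tbl Long-form output of [identity_matrix()].
#' @return A ggplot object (tiles labelled with rounded identities).
#' @export
plot_identity_matrix <- function(identity_tbl) {
  ggplot2::ggplot(identity_tbl,
                  ggplot2::aes(x = .data$label_b, y = .data$label_a,
                               fill = .data$identity)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$identity)), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "% identity") +
    ggplot2::labs(x = NULL, y = NULL, title = "Pairwise sequence identity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' TM-score / RMSD comparison chart
#'
#' Scores per compared pair with the fold-similarity (TM = 0.5) and
#' structural-difference (RMSD = 0.3 nm) reference lines.
#'
#' @param comparison Tibble from [compare_structures()] (rows with status
#'   `"ok"` are plotted).
#' @return A ggplot object.
#' @export
plot_structure_comparison <- function(comparison) {
  df <- filter(comparison, .data$status == "ok") |>
    mutate(pair = paste(.data$label_a, "vs", .data$label_b)) |>
    tidyr::pivot_longer(c("tm_ab", "rmsd_kabsch_nm"),
                        names_to = "metric", values_to = "value") |>
    mutate(metric = dplyr::recode(.data$metric, tm_ab = "TM-score",
                                  rmsd_kabsch_nm = "RMSD (nm)"))
  ref <- tibble(metric = c("TM-score", "RMSD (nm)"), yintercept = c(0.5, 0.3))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pair, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = ref,
                        ggplot2::aes(yintercept = .data$yintercept),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Structural comparison") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Replicate-summary bar chart (mean with SD error bars)
#'
#' @param quant A `kynu_quant` tibble from [quantify_samples()].
#' @return A ggplot object, faceted by analyte.
#' @export
plot_quant_summary <- function(quant) {
  ggplot2::ggplot(quant, ggplot2::aes(x = .data$sample, y = .data$mean_uM)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_uM - .data$sd_uM, 0),
                   ymax = .data$mean_uM + .data$sd_uM), width = 0.2) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "concentration (uM)",
                  title = "Total metabolite concentrations (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Calibration-curve plot
#'
#' @param x A `kynu_calibration`.
#' @param ... Unused.
#' @return A ggplot object of standards with the fitted line.
#' @export
autoplot.kynu_calibration <- function(x, ...) {
  df <- as_tibble(x$fit$model)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$conc, y = .data$area)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "concentration (uM)", y = "peak area",
                  title = sprintf("%s calibration (r² = %.4f)",
                                  x$analyte, x$r_squared)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
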