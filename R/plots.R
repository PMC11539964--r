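#' Bland-Altman plot
#'
#' Per-pair differences against per-pair means with the mean difference and
#' the 1.96-SD limits of agreement.
#'
#' @param ba A [bland_altman()] result.
#' @return A ggplot object.
#' @export
plot_bland_altman <- function(ba) {
  df <- data.frame(mean = ba$means, difference = ba$differences)
  ggplot2::ggplot(df, ggplot2::aes(x = mean, y = difference)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = ba$mean_difference, linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = c(ba$loa_low, ba$loa_high),
                        linetype = "dashed", linewidth = 0.4) +
    ggplot2::labs(x = "Mean of SUV Error Ratios (original, synthetic)",
                  y = "Difference (original - synthetic)",
                  title = "Bland-Altman agreement of SUV Error Ratios") +
    ggplot2::theme_minimal()
}

#' Lesion Error Ratio against lesion diameter
#'
#' Scatter of per-pair Lesion Error Ratios with the least-squares trend line;
#' a flat trend at unity indicates the synthetic lesions reproduce the
#' originals' AC-error behaviour across sizes.
#'
#' @param records The per-pair records from [run_validation1()] /
#'   [run_matched_study()].
#' @return A ggplot object.
#' @export
plot_lesion_error_trend <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = diameter_mm, y = lesion_error_ratio)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        linewidth = 0.4) +
    ggplot2::labs(x = "Lesion diameter (mm)", y = "Lesion Error Ratio") +
    ggplot2::theme_minimal()
}

#' Box plot of extreme SUV differences per target site
#'
#' Distribution across the phantom cohort of each VOI's signed
#' largest-magnitude voxel difference percentage.
#'
#' @param table Per-insertion table from [run_validation2()] /
#'   [run_targeted_study()].
#' @return A ggplot object.
#' @export
plot_site_boxplot <- function(table) {
  table$site <- factor(table$site, levels = unique(table$site))
  ggplot2::ggplot(table, ggplot2::aes(x = site, y = diff_max_pct)) +
    ggplot2::geom_boxplot() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "Maximum SUV difference (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Per-VOI SUV histograms under the two attenuation corrections
#'
#' @param voi_suv The `voi_suv` element of [run_validation2()]'s result.
#' @return A ggplot object (faceted by insertion).
#' @export
plot_voi_histograms <- function(voi_suv) {
  df <- do.call(rbind, lapply(names(voi_suv), function(k) {
    v <- voi_suv[[k]]
    rbind(data.frame(insertion = k, method = "CTAC", suv = v$ctac),
          data.frame(insertion = k, method = "MRAC", suv = v$mrac))
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = suv, fill = method)) +
    ggplot2::geom_histogram(alpha = 0.6, position = "identity", bins = 20) +
    ggplot2::facet_wrap(~insertion, scales = "free") +
    ggplot2::labs(x = "SUV", y = "Voxels") +
    ggplot2::theme_minimal()
}

save_plot <- function(p, path, width = 6, height = 4.5) {
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}
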