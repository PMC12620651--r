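#' Plot a simulation trajectory
#'
#' Trend lines of the GEBV/GPCP arm differences across cycles: the
#' usefulness-criterion gap (`delta_uc`) and the heterozygosity gap
#' (`delta_h`), faceted, with one line per seed when several seeds are
#' present.
#'
#' @param object A `sim_trajectory` tibble from [run_experiment()] or
#'   [run_experiment_multi()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sim_trajectory <- function(object, ...) {
  df <- object |>
    dplyr::distinct(.data$cycle, .data$delta_uc, .data$delta_h,
                    dplyr::across(dplyr::any_of("seed"))) |>
    tidyr::pivot_longer(c("delta_uc", "delta_h"), names_to = "metric",
                        values_to = "value")
  has_seed <- "seed" %in% names(df)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$value))
  p <- if (has_seed) {
    p + ggplot2::geom_line(ggplot2::aes(group = .data$seed), alpha = 0.4) +
      ggplot2::stat_summary(fun = mean, geom = "line", linewidth = 1)
  } else {
    p + ggplot2::geom_line()
  }
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(
      ~metric, scales = "free_y",
      labeller = ggplot2::as_labeller(c(delta_uc = "ΔUC (GPCP - GEBV)",
                                        delta_h = "ΔH (GPCP - GEBV)"))
    ) +
    ggplot2::labs(x = "cycle", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a ranked cross table
#'
#' Merit of the top crosses in rank order; a quick look at how sharply
#' predicted cross performance drops off.
#'
#' @param object A `cross_table` from [predict_crosses()].
#' @param top Number of crosses to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cross_table <- function(object, top = 50, ...) {
  df <- utils::head(tibble::as_tibble(object), top)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$merit)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = "cross rank", y = "predicted cross merit") +
    ggplot2::theme_minimal()
}
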