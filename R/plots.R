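#' Plot a cumulative recombination map
#'
#' Cumulative frequency of crossover positions along the SC (signed % of SC
#' length, 0 = centromere), as produced by [cumulative_distribution()].
#'
#' @param object A `synrec_recmap`.
#' @param ... Further `synrec_recmap` objects to overlay (e.g. the 2-CO and
#'   3-CO classes).
#' @return A ggplot object.
#' @export
autoplot.synrec_recmap <- function(object, ...) {
  maps <- c(list(object), list(...))
  dat <- purrr::map_dfr(maps, function(m) {
    as_tibble(m) |> mutate(co_class = paste0(attr(m, "co_class"), " CO"))
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin + 10,
                                    y = .data$cumulative,
                                    colour = .data$co_class)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "SC position (% of length; 0 = centromere)",
                  y = "cumulative CO frequency", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot window landscapes by region class
#'
#' Distribution of a per-window statistic (tandem-repeat bp or gene count)
#' across region labels.
#'
#' @param windows Labelled window tibble.
#' @param value Column to plot.
#' @return A ggplot object.
#' @export
plot_window_landscape <- function(windows, value = "tr_bp") {
  dat <- windows |> filter(!is.na(.data$label))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$label,
                                    y = .data[[value]])) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = value) +
    ggplot2::theme_minimal()
}

#' Plot crossover densities inside vs outside a region
#'
#' Boxplot of per-cell densities for any number of density estimates.
#'
#' @param ... Named `synrec_density` objects.
#' @return A ggplot object.
#' @export
plot_density_comparison <- function(...) {
  gr <- list(...)
  nm <- names(gr) %||% purrr::map_chr(gr, "label")
  dat <- purrr::map2_dfr(gr, nm, function(g, n) {
    g$per_cell |> mutate(group = n)
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$density)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::labs(x = NULL, y = "MLH1 foci / um") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
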