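# ggplot2 displays for result objects

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_hline
#'   labs scale_y_continuous facet_grid theme_minimal
#' @export
ggplot2::autoplot

#' Plot a CNV size distribution
#'
#' @param object a `cnv_size_distribution` from [size_distribution()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cnv_size_distribution
#' @export
autoplot.cnv_size_distribution <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$bin, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    labs(x = "CNV length", y = "Fraction of CNVs") +
    theme_minimal()
}

#' Plot locus carrier frequencies and hotspot calls
#'
#' One point per tested locus at its genomic start, iPSC carrier frequency
#' on the y axis, hotspots highlighted; the dashed line marks the hotspot
#' frequency threshold.
#'
#' @param object a `cnv_hotspots` from [call_hotspots()].
#' @param freq_threshold dashed reference line (default 0.05).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cnv_hotspots
#' @export
autoplot.cnv_hotspots <- function(object, freq_threshold = 0.05, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(
    x = .data$start / 1e6, y = .data$freq_ipsc, colour = .data$is_hotspot
  )) +
    geom_point(alpha = 0.8) +
    geom_hline(yintercept = freq_threshold, linetype = "dashed") +
    facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    labs(
      x = "Position (Mb)", y = "iPSC carrier frequency",
      colour = "Hotspot"
    ) +
    theme_minimal()
}

#' Plot per-pair CNV burden
#'
#' @param object a `cnv_burden` from [burden_test()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cnv_burden
#' @export
autoplot.cnv_burden <- function(object, ...) {
  df <- object$pairs %>%
    tidyr::pivot_longer(
      c("n_parental", "n_ipsc"), names_to = "member", values_to = "n_cnv"
    ) %>%
    mutate(member = if_else(.data$member == "n_ipsc", "iPSC", "parental"))
  ggplot(df, aes(x = .data$member, y = .data$n_cnv, group = .data$sample_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    geom_point(alpha = 0.5) +
    labs(x = NULL, y = "CNV count per sample") +
    theme_minimal()
}
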