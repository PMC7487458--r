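# broom-style tidiers for fitted/test objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @method tidy g_test
#' @export
tidy.g_test <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' @method tidy cnv_burden
#' @export
tidy.cnv_burden <- function(x, ...) {
  tibble(
    estimate = x$estimate, statistic = x$statistic, df = x$df,
    p.value = x$p.value, n_pairs = x$n_pairs, degenerate = x$degenerate
  )
}

#' @method glance cnv_burden
#' @export
glance.cnv_burden <- function(x, ...) tidy.cnv_burden(x)

#' @method tidy cnv_hotspots
#' @export
tidy.cnv_hotspots <- function(x, ...) {
  as_tibble(x) %>%
    select(
      "locus_id", "chrom", "start", "end", "stratum", "n_ipsc", "n_gain",
      "n_loss", "n_control", "freq_ipsc", "freq_control", "G", "p",
      "is_hotspot"
    )
}

#' @method glance cnv_hotspots
#' @export
glance.cnv_hotspots <- function(x, ...) {
  tibble(
    n_loci = nrow(x), n_hotspots = sum(x$is_hotspot),
    m = attr(x, "m"), alpha = attr(x, "alpha"),
    alpha_adjusted = if (nrow(x)) x$alpha_adjusted[1] else NA_real_
  )
}

#' @method tidy cnv_polymorphic
#' @export
tidy.cnv_polymorphic <- function(x, ...) {
  as_tibble(x) %>%
    select(
      "region_id", "chrom", "start", "end", "stratum", "n_carriers",
      "n_total", "freq_total", "n_control", "p_vs_controls",
      "n_mutually_exclusive", "is_polymorphic"
    )
}

#' @method glance cnv_pipeline
#' @export
glance.cnv_pipeline <- function(x, ...) {
  s <- x$summary
  tibble(
    n_segments = s$n_segments,
    n_ipsc_specific = s$n_ipsc_specific_segments,
    n_loci_tested = s$n_loci_tested,
    n_hotspots = s$n_hotspots,
    n_polymorphic = s$n_polymorphic,
    burden_t = s$burden$t, burden_p = s$burden$p,
    alpha_adjusted = s$alpha_adjusted
  )
}
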