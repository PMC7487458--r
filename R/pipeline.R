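#' Pipeline thresholds
#'
#' All thresholds default to the analysis' standard values and are logged
#' verbatim in the run summary.
#'
#' @param min_probes minimum probes per CNV run (10).
#' @param min_length segment length filter in bp (100000, strict `>`).
#' @param inherited_frac paired-overlap fraction above which an iPSC segment
#'   is inherited (0.5).
#' @param merge_reciprocal reciprocal-overlap locus merge cutoff (0.10).
#' @param control_cov maximum control-coverage fraction of a locus (0.10).
#' @param hotspot_freq minimum iPSC carrier frequency of a hotspot (0.05).
#' @param control_freq maximum control carrier frequency of a hotspot
#'   (0.002).
#' @param alpha family-wise error rate for the Bonferroni-adjusted G-test
#'   (0.05).
#' @param polymorphic_freq study-cohort frequency threshold for polymorphic
#'   regions (0.05).
#' @param polymorphic_min_subjects mutually-exclusive donor threshold (10,
#'   strict `>`).
#' @return named list of class `"cnv_params"`.
#' @export
cnv_params <- function(min_probes = 10L, min_length = 100000,
                       inherited_frac = 0.5, merge_reciprocal = 0.10,
                       control_cov = 0.10, hotspot_freq = 0.05,
                       control_freq = 0.002, alpha = 0.05,
                       polymorphic_freq = 0.05,
                       polymorphic_min_subjects = 10L) {
  p <- list(
    min_probes = as.integer(min_probes), min_length = min_length,
    inherited_frac = inherited_frac, merge_reciprocal = merge_reciprocal,
    control_cov = control_cov, hotspot_freq = hotspot_freq,
    control_freq = control_freq, alpha = alpha,
    polymorphic_freq = polymorphic_freq,
    polymorphic_min_subjects = as.integer(polymorphic_min_subjects)
  )
  fr <- c(
    "inherited_frac", "merge_reciprocal", "control_cov", "hotspot_freq",
    "control_freq", "alpha", "polymorphic_freq"
  )
  bad <- fr[vapply(p[fr], function(v) v < 0 || v > 1, logical(1))]
  if (length(bad)) {
    abort(paste0("fraction parameter(s) outside [0, 1]: ", paste(bad, collapse = ", ")))
  }
  class(p) <- "cnv_params"
  p
}

#' Run the full reprogramming-CNV analysis
#'
#' Executes the whole workflow on one cohort: probe masking, per-sample
#' run segmentation, length filtering, paired subtraction of inherited
#' CNVs, reciprocal-overlap locus merging, control-coverage screening,
#' hotspot classification (G-test, Bonferroni), polymorphic-region
#' detection, paired burden test, size distribution, and optional gene
#' annotation. The result is a pure function of its inputs.
#'
#' @param calls sparse calls tibble (`sample_id`, `probe_id`, `state`), or a
#'   `cnv_cohort` from [generate_cohort()] (in which case `probe_map` and
#'   `manifest` are taken from it).
#' @param probe_map probe map tibble.
#' @param manifest sample manifest tibble.
#' @param exclusions optional exclusion intervals ([read_exclusion_bed()]).
#' @param genes optional gene intervals ([read_gene_bed()]).
#' @param params thresholds from [cnv_params()].
#' @return list of class `"cnv_pipeline"`: `segments` (all samples, post
#'   length filter), `ipsc_specific`, `loci` (control-screened), `hotspots`,
#'   `polymorphic`, `burden`, `size_dist`, `summary` (thresholds, counts,
#'   statistics), `params`.
#' @export
run_cnv_pipeline <- function(calls, probe_map = NULL, manifest = NULL,
                             exclusions = NULL, genes = NULL,
                             params = cnv_params()) {
  if (inherits(calls, "cnv_cohort")) {
    probe_map <- calls$probe_map
    manifest <- calls$manifest
    calls <- calls$calls
  }
  manifest <- validate_manifest(manifest)
  pm <- mask_probes(probe_map, exclusions)

  segments_all <- segment_calls(calls, pm, manifest, min_probes = params$min_probes)
  segments <- filter_by_length(segments_all, min_length_bp = params$min_length)

  roles <- setNames(manifest$role, manifest$sample_id)
  seg_role <- roles[segments$sample_id]
  control_segments <- segments[seg_role == "control", , drop = FALSE]
  parental_segments <- segments[seg_role == "parental", , drop = FALSE]
  study_segments <- segments[seg_role != "control", , drop = FALSE]

  ipsc_specific <- subtract_inherited(study_segments, manifest,
                                      max_frac = params$inherited_frac)
  loci_all <- merge_loci(ipsc_specific, manifest, threshold = params$merge_reciprocal)
  loci <- filter_vs_controls(loci_all, control_segments, max_cov = params$control_cov)
  hotspots <- call_hotspots(
    loci, manifest,
    control_segments = control_segments,
    parental_segments = parental_segments,
    alpha = params$alpha,
    freq_ipsc_min = params$hotspot_freq,
    freq_control_max = params$control_freq,
    merge_threshold = params$merge_reciprocal
  )
  if (!is.null(genes)) hotspots <- annotate_genes(hotspots, genes)

  polymorphic <- find_polymorphic(
    study_segments, manifest,
    control_segments = control_segments,
    merge_threshold = params$merge_reciprocal,
    freq_min = params$polymorphic_freq,
    alpha = params$alpha,
    min_subjects = params$polymorphic_min_subjects
  )
  burden <- burden_test(study_segments, manifest)
  size_dist <- size_distribution(ipsc_specific)

  summary <- list(
    thresholds = unclass(params),
    n_samples = nrow(manifest),
    n_probes = nrow(pm),
    n_segments = nrow(segments),
    n_ipsc_specific_segments = nrow(ipsc_specific),
    n_loci_premerge = nrow(loci_all),
    n_loci_tested = nrow(loci),
    bonferroni_m = attr(hotspots, "m"),
    alpha_adjusted = if (attr(hotspots, "m") > 0) params$alpha / attr(hotspots, "m") else NA,
    n_hotspots = sum(hotspots$is_hotspot),
    n_polymorphic = sum(polymorphic$is_polymorphic),
    burden = list(
      t = burden$statistic, df = burden$df, p = burden$p.value,
      mean_difference = burden$estimate, n_pairs = burden$n_pairs,
      degenerate = burden$degenerate
    ),
    size_distribution = setNames(
      as.list(size_dist$fraction), as.character(size_dist$bin)
    )
  )

  out <- list(
    segments = segments, ipsc_specific = ipsc_specific, loci = loci,
    hotspots = hotspots, polymorphic = polymorphic, burden = burden,
    size_dist = size_dist, summary = summary, params = params
  )
  class(out) <- "cnv_pipeline"
  out
}

#' @export
print.cnv_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Reprogramming-CNV pipeline run\n")
  cat(sprintf(
    "  %d segments (> %g bp) in %d samples; %d iPSC-specific; %d loci tested\n",
    s$n_segments, s$thresholds$min_length, s$n_samples, s$n_ipsc_specific_segments,
    s$n_loci_tested
  ))
  cat(sprintf(
    "  %d hotspots (alpha_adjusted = %.3g, m = %d); %d polymorphic regions\n",
    s$n_hotspots, s$alpha_adjusted, s$bonferroni_m, s$n_polymorphic
  ))
  cat(sprintf(
    "  burden: t = %.3f, df = %d, p = %.3f\n",
    s$burden$t, s$burden$df, s$burden$p
  ))
  invisible(x)
}

#' Write all pipeline artifacts to a directory
#'
#' Emits `segments.tsv`, `ipsc_specific.tsv`, `loci.tsv`, `hotspots.tsv`
#' (report-style columns, with p-values below 1e-4 printed as `<0.0001` in
#' the `p_printed` column), `polymorphic.tsv` and `summary.json`.
#'
#' @param result a `cnv_pipeline` result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_results <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segments(result$segments, file.path(dir, "segments.tsv"))
  write_segments(result$ipsc_specific, file.path(dir, "ipsc_specific.tsv"))
  write_loci(result$loci, file.path(dir, "loci.tsv"))
  hs <- as_tibble(result$hotspots) %>%
    mutate(p_printed = if_else(.data$p < 1e-4, "<0.0001", sprintf("%.4f", .data$p)))
  write_loci(hs, file.path(dir, "hotspots.tsv"))
  write_loci(as_tibble(result$polymorphic), file.path(dir, "polymorphic.tsv"))
  write_run_summary(result$summary, file.path(dir, "summary.json"))
  invisible(dir)
}
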