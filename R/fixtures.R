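# Worked-example fixtures: the published ten-hotspot contingency table
# (counts as printed, used as regression input for the statistics) and a
# small hand-checkable probe-track example.

#' Published hotspot contingency rows
#'
#' The ten reported iPSC-specific CNV hotspot rows with their printed
#' duplication/deletion carrier counts in 82 iPSC lines and 1093 controls
#' (X-chromosome rows compare the 42 female lines with the 568 female
#' controls). These counts are inputs for statistics regression tests, not
#' recomputed results.
#'
#' @return tibble with `chrom`, `start`, `end`, `band`, `dup_ipsc`,
#'   `del_ipsc`, `dup_ctrl`, `del_ctrl`, `n_ipsc`, `n_ctrl`, `stratum`.
#' @export
table1_hotspot_counts <- function() {
  tibble(
    chrom = c("chr4", "chr4", "chr5", "chr6", "chr7", "chr10", "chr13", "chr20", "chrX", "chrX"),
    start = c(62690392L, 92930866L, 147202104L, 94291842L, 121549706L,
              54932474L, 55695571L, 29620219L, 112880475L, 114766295L),
    end = c(62945462L, 94220988L, 147449067L, 94849832L, 122245008L,
            55398702L, 56471149L, 31558271L, 113795367L, 114897324L),
    band = c("q13.1", "q22.1-q22.2", "q32", "q16.1", "q31.32",
             "q21.1", "q21.1", "q11.21", "q23", "q23"),
    dup_ipsc = c(5L, 38L, 8L, 2L, 12L, 6L, 5L, 5L, 27L, 8L),
    del_ipsc = c(0L, 2L, 0L, 2L, 0L, 0L, 0L, 0L, 0L, 0L),
    dup_ctrl = c(1L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),
    del_ctrl = c(0L, 1L, 0L, 0L, 0L, 0L, 2L, 0L, 0L, 0L),
    n_ipsc = c(rep(82L, 8), 42L, 42L),
    n_ctrl = c(rep(1093L, 8), 568L, 568L),
    stratum = c(rep("all", 8), "female_only", "female_only")
  )
}

#' Small worked probe-track example
#'
#' A single-chromosome probe map (40 probes at 20-kb spacing) and a dense
#' call matrix for one female parental/iPSC pair whose segmentation can be
#' checked by hand: the iPSC track carries a 12-probe gain (probes 5-16, a
#' qualifying 220-kb segment), a 9-probe loss (probes 20-28, one probe short
#' of the run threshold, never called) and an isolated noise probe (35);
#' the parental track is at baseline everywhere.
#'
#' @return list with `probe_map`, `matrix` (dense calls), `manifest`, and
#'   `expected_segments` (the hand-enumerated qualifying segments).
#' @export
worked_example <- function() {
  pm <- tibble(
    probe_id = sprintf("wp%02d", 1:40),
    chrom = "chr1",
    pos = as.integer((0:39) * 20000 + 1)
  )
  state_ipsc <- rep(2L, 40)
  state_ipsc[5:16] <- 3L   # 12-probe gain: pos 80001..300001, 220001 bp
  state_ipsc[20:28] <- 1L  # 9-probe loss: below run threshold
  state_ipsc[35] <- 3L     # isolated noise probe
  mat <- tibble(
    probe_id = pm$probe_id,
    EX01_P = rep(2L, 40),
    EX01_S1 = state_ipsc
  )
  manifest <- tibble(
    sample_id = c("EX01_P", "EX01_S1"),
    donor_id = "EX01",
    role = c("parental", "ipsc"),
    sex = "female"
  )
  expected <- tibble(
    sample_id = "EX01_S1", chrom = "chr1",
    start = pm$pos[5], end = pm$pos[16],
    direction = "gain", n_probes = 12L,
    length = as.numeric(pm$pos[16]) - pm$pos[5] + 1
  )
  list(probe_map = pm, matrix = mat, manifest = manifest, expected_segments = expected)
}

#' Write the fixture suite to a directory
#'
#' Emits (a) `table1_counts.tsv`, the ten published hotspot contingency
#' rows, and (b) the worked probe-track example (`example_probe_map.tsv`,
#' `example_calls.tsv`, `example_manifest.tsv`,
#' `example_expected_segments.tsv`).
#'
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_fixture_suite <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(table1_hotspot_counts(), file.path(outdir, "table1_counts.tsv"))
  ex <- worked_example()
  write_probe_map(ex$probe_map, file.path(outdir, "example_probe_map.tsv"))
  write_call_matrix(ex$matrix, file.path(outdir, "example_calls.tsv"))
  write_manifest(ex$manifest, file.path(outdir, "example_manifest.tsv"))
  write_segments(ex$expected_segments, file.path(outdir, "example_expected_segments.tsv"))
  invisible(outdir)
}
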