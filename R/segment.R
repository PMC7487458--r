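#' Call CNV segments from per-probe copy-number states
#'
#' Scans each sample's probe-level copy-number states for maximal runs of at
#' least `min_probes` consecutive probes (in probe-map order) that deviate
#' from the sex-appropriate baseline in the same direction. All probes of a
#' run must lie strictly on one side of baseline (all above = gain, all below
#' = loss); a baseline probe or a probe deviating in the opposite direction
#' terminates the run, and runs never span chromosome boundaries. Segment
#' coordinates are the positions of the first and last probe of the run,
#' 1-based inclusive.
#'
#' Copy-number states are supplied sparsely: `calls` lists only probes whose
#' state deviates from (or is asserted at) baseline; probes absent from
#' `calls` are taken to be at baseline. Use [calls_from_matrix()] to convert
#' a dense probe-by-sample matrix.
#'
#' @param calls a data frame with columns `sample_id`, `probe_id`, `state`
#'   (integer copy number, >= 0).
#' @param probe_map probe map (after masking, see [mask_probes()]).
#' @param manifest sample manifest with columns `sample_id`, `sex`
#'   (see [read_manifest()]); sex drives the baseline on X/Y.
#' @param min_probes minimum run length in probes (default 10).
#' @return a tibble of segments: `sample_id`, `chrom`, `start`, `end`,
#'   `direction` (`"gain"`/`"loss"`), `n_probes`, `length` (bp,
#'   `end - start + 1`).
#' @export
segment_calls <- function(calls, probe_map, manifest, min_probes = 10L) {
  if (min_probes < 1L) abort("min_probes must be >= 1")
  pm <- validate_probe_map(probe_map) %>%
    group_by(.data$chrom) %>%
    mutate(idx = row_number()) %>%
    ungroup()
  calls <- as_tibble(calls)
  if (nrow(calls) == 0L) return(empty_segments())
  if (any(is.na(calls$state)) || any(calls$state < 0L)) {
    abort("copy-number states must be non-negative integers (no missing values)")
  }
  unknown_sample <- setdiff(unique(calls$sample_id), manifest$sample_id)
  if (length(unknown_sample)) {
    abort(paste0(
      "calls contain sample(s) absent from the manifest: ",
      paste(head(unknown_sample, 5), collapse = ", ")
    ))
  }

  x <- calls %>%
    inner_join(pm, by = "probe_id") %>%
    left_join(select(manifest, "sample_id", "sex"), by = "sample_id")
  dropped <- nrow(calls) - nrow(x)
  if (dropped > 0L) {
    # probes masked out (or never mapped) cannot contribute to a run
    inform(paste0(dropped, " call(s) on probes absent from the probe map were ignored"))
  }
  if (nrow(x) == 0L) return(empty_segments())

  sexed <- chrom_class(x$chrom) %in% c("X", "Y")
  if (any(sexed & (is.na(x$sex) | !x$sex %in% c("male", "female")))) {
    bad <- unique(x$sample_id[sexed & (is.na(x$sex) | !x$sex %in% c("male", "female"))])
    abort(paste0(
      "sex is required for samples with X/Y probes: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  # female Y probes are excluded from analysis
  x <- x[!(chrom_class(x$chrom) == "Y" & x$sex == "female"), , drop = FALSE]
  if (nrow(x) == 0L) return(empty_segments())

  x <- x %>%
    mutate(
      baseline = baseline_state(.data$chrom, .data$sex),
      dirn = sign(.data$state - .data$baseline)
    ) %>%
    filter(.data$dirn != 0L) %>%
    arrange(.data$sample_id, .data$chrom, .data$idx)
  if (nrow(x) == 0L) return(empty_segments())

  new_run <- with(x, {
    sample_id != lag(sample_id, default = "") |
      chrom != lag(chrom, default = "") |
      idx != lag(idx, default = -1L) + 1L |
      dirn != lag(dirn, default = 0L)
  })
  x$run_id <- cumsum(new_run)

  x %>%
    group_by(.data$run_id) %>%
    summarise(
      sample_id = .data$sample_id[1],
      chrom = .data$chrom[1],
      start = min(.data$pos),
      end = max(.data$pos),
      direction = if (.data$dirn[1] > 0L) "gain" else "loss",
      n_probes = n(),
      .groups = "drop"
    ) %>%
    filter(.data$n_probes >= min_probes) %>%
    mutate(length = as.numeric(.data$end) - .data$start + 1) %>%
    select("sample_id", "chrom", "start", "end", "direction", "n_probes", "length") %>%
    arrange(.data$sample_id, .data$chrom, .data$start)
}

#' Retain CNV segments larger than a minimum length
#'
#' Keeps exactly the segments whose length is strictly greater than
#' `min_length_bp` (a segment of exactly `min_length_bp` is removed). Input
#' order is preserved.
#'
#' @param segments a segments tibble (see [segment_calls()]).
#' @param min_length_bp minimum length in bp (default 100000, i.e. keep
#'   segments larger than 100 kb).
#' @return the filtered segments tibble.
#' @export
filter_by_length <- function(segments, min_length_bp = 100000) {
  check_segments(segments)
  if (!"length" %in% names(segments)) {
    segments <- mutate(segments, length = as.numeric(.data$end) - .data$start + 1)
  }
  filter(segments, .data$length > min_length_bp)
}
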