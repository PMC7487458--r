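#' Validate a probe map
#'
#' A probe map is the coordinate lattice for segmentation: one row per array
#' probe with columns `probe_id`, `chrom`, `pos` (1-based). Positions must be
#' strictly increasing within each chromosome and probe ids unique
#' genome-wide.
#'
#' @param probe_map a data frame with columns `probe_id`, `chrom`, `pos`.
#' @return the probe map as a tibble, sorted by chromosome and position.
#' @export
validate_probe_map <- function(probe_map) {
  need <- c("probe_id", "chrom", "pos")
  miss <- setdiff(need, names(probe_map))
  if (length(miss)) {
    abort(paste0("probe map is missing column(s): ", paste(miss, collapse = ", ")))
  }
  pm <- as_tibble(probe_map) %>%
    mutate(pos = as.integer(.data$pos)) %>%
    arrange(.data$chrom, .data$pos)
  if (anyDuplicated(pm$probe_id)) {
    dup <- pm$probe_id[duplicated(pm$probe_id)][1]
    abort(paste0("probe ids must be unique genome-wide (duplicate: ", dup, ")"))
  }
  ok <- pm %>%
    group_by(.data$chrom) %>%
    summarise(mono = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(ok$mono)) {
    abort(paste0(
      "probe positions must be strictly increasing within chromosome(s): ",
      paste(ok$chrom[!ok$mono], collapse = ", ")
    ))
  }
  pm
}

#' Remove probes falling in excluded regions
#'
#' Drops every probe whose position lies inside any exclusion interval
#' (centromeres, antibody variable regions, T-cell receptor loci,
#' pseudoautosomal regions, the X-transposed region, ...). Masking is applied
#' before segmentation so excluded regions can neither seed nor bridge probe
#' runs. Probe order is preserved.
#'
#' @param probe_map a probe map (see [validate_probe_map()]).
#' @param exclusions a data frame of intervals with columns `chrom`, `start`,
#'   `end` (1-based inclusive, as returned by [read_exclusion_bed()]) and
#'   optionally `category`. `NULL` or zero rows returns the map unchanged.
#' @return the masked probe map (tibble).
#' @export
#' @examples
#' pm <- tibble::tibble(
#'   probe_id = paste0("p", 1:5), chrom = "chr1",
#'   pos = c(100L, 200L, 300L, 400L, 500L)
#' )
#' excl <- tibble::tibble(chrom = "chr1", start = 150L, end = 350L)
#' mask_probes(pm, excl)
mask_probes <- function(probe_map, exclusions = NULL) {
  pm <- validate_probe_map(probe_map)
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(pm)
  }
  if (nrow(exclusions) && any(exclusions$end < exclusions$start)) {
    abort("exclusion intervals must satisfy start <= end")
  }
  orphan <- setdiff(unique(exclusions$chrom), unique(pm$chrom))
  if (length(orphan)) {
    inform(paste0(
      "ignoring exclusion intervals on chromosome(s) absent from the probe map: ",
      paste(orphan, collapse = ", ")
    ))
  }
  probes_gr <- GenomicRanges::GRanges(
    seqnames = pm$chrom,
    ranges = IRanges::IRanges(start = pm$pos, width = 1L)
  )
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(probes_gr, intervals_to_gr(exclusions))
  ) > 0L
  pm[!hit, , drop = FALSE]
}
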