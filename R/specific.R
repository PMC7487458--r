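#' Reciprocal overlap of two interval sets
#'
#' For paired intervals (1-based inclusive) returns
#' `min(overlap_bp / length(a), overlap_bp / length(b))`, the reciprocal
#' overlap used for cross-sample locus merging. Intervals on different
#' chromosomes, or disjoint intervals, return 0; adjacency shares no bp under
#' inclusive coordinates and also returns 0.
#'
#' @param a,b data frames with columns `chrom`, `start`, `end`; rows are
#'   paired (shorter input recycled).
#' @return numeric vector of reciprocal-overlap fractions in \[0, 1\].
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 1, end = 1000)
#' b <- tibble::tibble(chrom = "chr1", start = 901, end = 2000)
#' reciprocal_overlap(a, b) # 100 bp shared -> min(0.1, 100/1100)
reciprocal_overlap <- function(a, b) {
  n <- max(nrow(a), nrow(b))
  idx_a <- rep_len(seq_len(nrow(a)), n)
  idx_b <- rep_len(seq_len(nrow(b)), n)
  ov <- pmax(
    0,
    pmin(a$end[idx_a], b$end[idx_b]) - pmax(a$start[idx_a], b$start[idx_b]) + 1
  )
  ov[a$chrom[idx_a] != b$chrom[idx_b]] <- 0
  len_a <- a$end[idx_a] - a$start[idx_a] + 1
  len_b <- b$end[idx_b] - b$start[idx_b] + 1
  ifelse(ov > 0, pmin(ov / len_a, ov / len_b), 0)
}

#' Remove inherited CNVs by paired parental comparison
#'
#' An iPSC segment is considered inherited, and removed, if it overlaps more
#' than `max_frac` of its own length with any single CNV segment (of either
#' direction) called in the parental sample of the same donor. All other iPSC
#' segments are returned unchanged; parental and control segments in the
#' input are dropped from the output.
#'
#' @param segments segments tibble covering iPSC and parental samples (as
#'   from [segment_calls()] + [filter_by_length()]).
#' @param manifest sample manifest with `sample_id`, `donor_id`, `role`;
#'   every iPSC sample must have a parental sample with the same donor id.
#' @param max_frac overlap fraction (of the iPSC segment's length) above
#'   which the segment is excluded (default 0.5, strict: fraction must
#'   exceed `max_frac`).
#' @return tibble of iPSC-specific segments.
#' @export
subtract_inherited <- function(segments, manifest, max_frac = 0.5) {
  check_segments(segments)
  validate_manifest(manifest)
  segs <- segments %>%
    left_join(select(manifest, "sample_id", "donor_id", "role"), by = "sample_id")
  if (any(is.na(segs$role))) {
    bad <- unique(segs$sample_id[is.na(segs$role)])
    abort(paste0(
      "segments contain sample(s) absent from the manifest: ",
      paste(head(bad, 5), collapse = ", ")
    ))
  }
  ipsc <- filter(segs, .data$role == "ipsc") %>% mutate(.seg = row_number())
  parental <- filter(segs, .data$role == "parental")
  if (nrow(ipsc) == 0L) return(empty_segments())
  orphan <- setdiff(unique(ipsc$donor_id), unique(manifest$donor_id[manifest$role == "parental"]))
  if (length(orphan)) {
    abort(paste0(
      "iPSC sample(s) without a parental sample for donor(s): ",
      paste(head(orphan, 5), collapse = ", ")
    ))
  }
  if (nrow(parental) == 0L) {
    return(select(ipsc, -".seg", -"donor_id", -"role"))
  }
  hits <- ipsc %>%
    inner_join(
      select(parental, "donor_id", "chrom", p_start = "start", p_end = "end"),
      by = c("donor_id", "chrom"), relationship = "many-to-many"
    ) %>%
    mutate(
      ov = pmax(0, pmin(.data$end, .data$p_end) - pmax(.data$start, .data$p_start) + 1),
      frac = .data$ov / (.data$end - .data$start + 1)
    ) %>%
    filter(.data$frac > max_frac)
  ipsc %>%
    filter(!.data$.seg %in% hits$.seg) %>%
    select(-".seg", -"donor_id", -"role")
}

#' Merge CNV segments across samples into loci
#'
#' Clusters segments by single linkage under the relation
#' `reciprocal_overlap >= threshold`: two segments join the same locus if
#' they are connected through a chain of pairwise reciprocal overlaps. Locus
#' coordinates are the span (min start, max end) of the member segments.
#' Autosomal loci are built from all samples (`stratum = "all"`); segments on
#' X or Y are clustered within sex (`"female_only"` / `"male_only"`),
#' matching sex-stratified frequency analysis. Carrier counts are per
#' distinct sample: a sample with several member segments of one direction
#' counts once for that direction.
#'
#' @param segments segments tibble (any pool: iPSC-specific, parental+iPSC,
#'   controls, ...).
#' @param manifest sample manifest (`sample_id`, `role`, `sex`).
#' @param threshold reciprocal-overlap fraction linking two segments into one
#'   locus (default 0.10; membership uses `>=`).
#' @return a tibble of loci: `locus_id`, `chrom`, `start`, `end`, `stratum`,
#'   per-role carrier counts (`n_ipsc`, `n_ipsc_gain`, `n_ipsc_loss`,
#'   `n_parental`, `n_control`, `n_control_gain`, `n_control_loss`),
#'   `member_count`, and a `members` list-column with the member segments.
#' @export
merge_loci <- function(segments, manifest, threshold = 0.10) {
  check_segments(segments)
  if (nrow(segments) == 0L) {
    return(tibble(
      locus_id = character(), chrom = character(), start = integer(),
      end = integer(), stratum = character(),
      n_ipsc = integer(), n_ipsc_gain = integer(), n_ipsc_loss = integer(),
      n_parental = integer(), n_control = integer(),
      n_control_gain = integer(), n_control_loss = integer(),
      member_count = integer(), members = list()
    ))
  }
  segs <- segments %>%
    left_join(select(manifest, "sample_id", "role", "sex"), by = "sample_id") %>%
    mutate(
      stratum = if_else(
        chrom_class(.data$chrom) %in% c("X", "Y"),
        paste0(.data$sex, "_only"), "all"
      )
    )
  if (any(is.na(segs$role))) {
    abort("segments contain samples absent from the manifest")
  }
  sexed <- chrom_class(segs$chrom) %in% c("X", "Y")
  if (any(sexed & (is.na(segs$sex) | !segs$sex %in% c("male", "female")))) {
    abort("sex is required in the manifest for samples with X/Y segments")
  }

  # cluster within (chromosome, stratum); encoding both in seqnames keeps
  # strata apart in a single overlap query
  gr <- GenomicRanges::GRanges(
    seqnames = paste0(segs$chrom, "|", segs$stratum),
    ranges = IRanges::IRanges(start = segs$start, end = segs$end)
  )
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (length(q)) {
    ov <- pmax(
      0,
      pmin(segs$end[q], segs$end[s]) - pmax(segs$start[q], segs$start[s]) + 1
    )
    ro <- pmin(
      ov / (segs$end[q] - segs$start[q] + 1),
      ov / (segs$end[s] - segs$start[s] + 1)
    )
    keep <- ro >= threshold
    q <- q[keep]; s <- s[keep]
  }
  g <- igraph::graph_from_edgelist(
    cbind(q, s), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, nrow(segs) - igraph::vcount(g)))
  segs$.locus <- igraph::components(g)$membership[seq_len(nrow(segs))]

  loci <- segs %>%
    group_by(.data$.locus) %>%
    summarise(
      members = list(as_tibble(dplyr::pick(
        "sample_id", "chrom", "start", "end", "direction", "role"
      ))),
      chrom = .data$chrom[1],
      start = min(.data$start),
      end = max(.data$end),
      stratum = .data$stratum[1],
      n_ipsc = n_distinct(.data$sample_id[.data$role == "ipsc"]),
      n_ipsc_gain = n_distinct(.data$sample_id[.data$role == "ipsc" & .data$direction == "gain"]),
      n_ipsc_loss = n_distinct(.data$sample_id[.data$role == "ipsc" & .data$direction == "loss"]),
      n_parental = n_distinct(.data$sample_id[.data$role == "parental"]),
      n_control = n_distinct(.data$sample_id[.data$role == "control"]),
      n_control_gain = n_distinct(.data$sample_id[.data$role == "control" & .data$direction == "gain"]),
      n_control_loss = n_distinct(.data$sample_id[.data$role == "control" & .data$direction == "loss"]),
      member_count = n(),
      .groups = "drop"
    ) %>%
    arrange(.data$chrom, .data$start, .data$end) %>%
    mutate(locus_id = sprintf("L%04d", row_number())) %>%
    select(-".locus") %>%
    dplyr::relocate("locus_id")
  loci
}

#' Screen loci against control-cohort CNV coverage
#'
#' Retains a locus only if the fraction of its bases covered by the union of
#' all control-cohort CNV segments intersecting it is strictly below
#' `max_cov`. This positional screen (frequency-agnostic) removes loci lying
#' in copy-number polymorphic territory before hotspot testing; it is
#' distinct from the later carrier-frequency threshold on controls.
#'
#' @param loci loci tibble from [merge_loci()].
#' @param control_segments segments tibble for the control cohort (same
#'   segmentation and length filter as the study samples).
#' @param max_cov maximum tolerated covered fraction (default 0.10, strict).
#' @return the retained loci, with a `control_coverage` column added.
#' @export
filter_vs_controls <- function(loci, control_segments, max_cov = 0.10) {
  if (nrow(loci) == 0L) {
    return(mutate(loci, control_coverage = numeric(0)))
  }
  if (is.null(control_segments) || nrow(control_segments) == 0L) {
    return(mutate(loci, control_coverage = 0))
  }
  check_segments(control_segments, "control_segments")
  loci_gr <- intervals_to_gr(loci)
  ctrl_red <- GenomicRanges::reduce(intervals_to_gr(control_segments))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(loci_gr, ctrl_red))
  covered <- rep(0, nrow(loci))
  if (length(hits)) {
    w <- GenomicRanges::width(IRanges::pintersect(
      loci_gr[S4Vectors::queryHits(hits)], ctrl_red[S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(w, S4Vectors::queryHits(hits), sum)
    covered[as.integer(names(agg))] <- as.numeric(agg)
  }
  loci$control_coverage <- covered / (loci$end - loci$start + 1)
  filter(loci, .data$control_coverage < max_cov)
}

#' Count carrier samples of a region within an independent segment pool
#'
#' A sample is a carrier of a region if it has at least one segment with
#' reciprocal overlap `>= threshold` with the region (the same linkage rule
#' used by [merge_loci()]). For sex-stratified regions (`stratum`
#' `"female_only"`/`"male_only"`), only samples of that sex are counted.
#'
#' @param regions tibble with `chrom`, `start`, `end` and optionally
#'   `stratum`.
#' @param segments segment pool to count carriers in (e.g. control or
#'   parental segments).
#' @param manifest sample manifest (needed for sex when regions are
#'   stratified).
#' @param threshold reciprocal-overlap membership cutoff (default 0.10).
#' @return tibble with one row per region: `n_any`, `n_gain`, `n_loss`.
#' @export
count_region_carriers <- function(regions, segments, manifest = NULL, threshold = 0.10) {
  out <- tibble(
    n_any = integer(nrow(regions)),
    n_gain = integer(nrow(regions)),
    n_loss = integer(nrow(regions))
  )
  if (nrow(regions) == 0L || is.null(segments) || nrow(segments) == 0L) {
    return(out)
  }
  check_segments(segments)
  segs <- segments
  if (!is.null(manifest)) {
    segs <- left_join(segs, select(manifest, "sample_id", "sex"), by = "sample_id")
  } else {
    segs$sex <- NA_character_
  }
  reg_gr <- intervals_to_gr(regions)
  seg_gr <- intervals_to_gr(segs)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(reg_gr, seg_gr))
  if (!length(hits)) return(out)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmax(
    0,
    pmin(regions$end[q], segs$end[s]) - pmax(regions$start[q], segs$start[s]) + 1
  )
  ro <- pmin(
    ov / (regions$end[q] - regions$start[q] + 1),
    ov / (segs$end[s] - segs$start[s] + 1)
  )
  keep <- ro >= threshold
  q <- q[keep]; s <- s[keep]
  if (!length(q)) return(out)
  strat <- if ("stratum" %in% names(regions)) regions$stratum[q] else rep("all", length(q))
  sex_need <- sub("_only$", "", strat)
  keep2 <- strat == "all" | (!is.na(segs$sex[s]) & segs$sex[s] == sex_need)
  q <- q[keep2]; s <- s[keep2]
  if (!length(q)) return(out)
  carriers <- tibble(
    region = q, sample_id = segs$sample_id[s], direction = segs$direction[s]
  )
  any_n <- carriers %>% distinct(.data$region, .data$sample_id) %>% count(.data$region)
  gain_n <- carriers %>% filter(.data$direction == "gain") %>%
    distinct(.data$region, .data$sample_id) %>% count(.data$region)
  loss_n <- carriers %>% filter(.data$direction == "loss") %>%
    distinct(.data$region, .data$sample_id) %>% count(.data$region)
  out$n_any[any_n$region] <- any_n$n
  out$n_gain[gain_n$region] <- gain_n$n
  out$n_loss[loss_n$region] <- loss_n$n
  out
}
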