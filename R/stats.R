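#' Likelihood-ratio (G) chi-square test on a contingency table
#'
#' Computes `G = 2 * sum(O * ln(O / E))` with expected counts from the row
#' and column margins (convention `0 * ln 0 = 0`, no continuity correction)
#' and an upper-tail chi-square p-value at `df = (nrow - 1) * (ncol - 1)`.
#' A table with an all-zero row or column margin returns `G = 0, p = 1`.
#'
#' @param x a matrix of non-negative integer counts (2x2 for the pooled
#'   carrier test; any RxC table is accepted).
#' @return an object of class `"g_test"`: a list with `statistic`, `df`,
#'   `p.value`, `observed`, `expected`.
#' @export
#' @examples
#' # 5/82 iPSC carriers vs 1/1093 control carriers
#' g_test(matrix(c(5, 77, 1, 1092), nrow = 2, byrow = TRUE))
g_test <- function(x) {
  x <- as.matrix(x)
  if (any(is.na(x)) || any(x < 0)) abort("counts must be non-negative (no NA)")
  rs <- rowSums(x)
  cs <- colSums(x)
  df <- (nrow(x) - 1L) * (ncol(x) - 1L)
  if (any(rs == 0) || any(cs == 0)) {
    out <- list(
      statistic = 0, df = df, p.value = 1,
      observed = x, expected = x * NA_real_
    )
    class(out) <- "g_test"
    return(out)
  }
  e <- outer(rs, cs) / sum(x)
  terms <- ifelse(x > 0, x * log(x / e), 0)
  g <- 2 * sum(terms)
  out <- list(
    statistic = g, df = df,
    p.value = pchisq(g, df = df, lower.tail = FALSE),
    observed = x, expected = e
  )
  class(out) <- "g_test"
  out
}

#' @export
print.g_test <- function(x, ...) {
  cat("Likelihood-ratio (G) chi-square test\n")
  cat(sprintf("G = %.4g, df = %d, p = %.4g\n", x$statistic, x$df, x$p.value))
  invisible(x)
}

# internal: cohort size for a role within a stratum
stratum_size <- function(manifest, role, stratum) {
  m <- manifest[manifest$role == role, , drop = FALSE]
  vapply(stratum, function(s) {
    if (s == "all") nrow(m) else sum(m$sex == sub("_only$", "", s), na.rm = TRUE)
  }, integer(1), USE.NAMES = FALSE)
}

#' Carrier frequencies of loci in the iPSC and control cohorts
#'
#' Carriers are distinct samples with at least one member segment of any
#' direction. Denominators are the stratum cohort sizes: all iPSC lines /
#' all controls for autosomal loci, the same-sex subsets for loci on X or Y.
#'
#' @param loci loci tibble with carrier-count columns (`n_ipsc`,
#'   `n_control`; if absent they are taken as gain + loss counts) and a
#'   `stratum` column.
#' @param manifest sample manifest.
#' @return `loci` with `n_ipsc_total`, `n_control_total`, `freq_ipsc`,
#'   `freq_control` columns added.
#' @export
carrier_frequency <- function(loci, manifest) {
  validate_manifest(manifest)
  if (!"stratum" %in% names(loci)) loci$stratum <- "all"
  if (!"n_ipsc" %in% names(loci)) {
    loci$n_ipsc <- loci$n_ipsc_gain + loci$n_ipsc_loss
  }
  if (!"n_control" %in% names(loci)) {
    if (all(c("n_control_gain", "n_control_loss") %in% names(loci))) {
      loci$n_control <- loci$n_control_gain + loci$n_control_loss
    } else {
      loci$n_control <- 0L
    }
  }
  loci$n_ipsc_total <- stratum_size(manifest, "ipsc", loci$stratum)
  loci$n_control_total <- stratum_size(manifest, "control", loci$stratum)
  if (nrow(loci) && any(loci$n_ipsc_total == 0L)) {
    abort("empty iPSC stratum for at least one locus (no samples of the required sex)")
  }
  if (nrow(loci) && any(loci$n_control_total == 0L) && any(loci$n_control > 0L)) {
    abort("empty control stratum for at least one locus")
  }
  loci$freq_ipsc <- loci$n_ipsc / loci$n_ipsc_total
  loci$freq_control <- ifelse(
    loci$n_control_total > 0L, loci$n_control / loci$n_control_total, 0
  )
  loci
}

#' Classify reprogramming-associated CNV hotspots
#'
#' For each iPSC-specific, control-screened locus, computes carrier
#' frequencies in the iPSC and control cohorts (sex-stratified on X/Y), the
#' likelihood-ratio chi-square test on the pooled 2x2 carrier table, and a
#' Bonferroni-adjusted significance threshold `alpha / m` where `m` is the
#' number of loci tested in this run. A locus is a hotspot iff its iPSC
#' frequency exceeds `freq_ipsc_min`, its control frequency is below
#' `freq_control_max`, its p-value is at most the adjusted threshold, and no
#' paired parental sample carries a qualifying segment at the locus.
#'
#' @param loci loci tibble (iPSC-specific, after [filter_vs_controls()]).
#' @param manifest sample manifest.
#' @param control_segments control-cohort segments; when supplied, control
#'   carrier counts are (re)computed by reciprocal-overlap membership
#'   ([count_region_carriers()]).
#' @param parental_segments parental segments for the belt-and-braces check
#'   that hotspots are absent from the germline; when `NULL`, the loci's
#'   `n_parental` column (0 for an iPSC-specific pool) is used.
#' @param alpha family-wise error rate before Bonferroni division
#'   (default 0.05).
#' @param freq_ipsc_min minimum iPSC carrier frequency (default 0.05,
#'   strict `>`).
#' @param freq_control_max maximum control carrier frequency (default 0.002,
#'   strict `<`).
#' @param merge_threshold reciprocal-overlap membership cutoff used when
#'   counting control/parental carriers (default 0.10).
#' @param test `"pooled"` (2x2 on carriers of any direction, default) or
#'   `"by_direction"` (2x3: gain / loss / none).
#' @return a tibble of class `"cnv_hotspots"`, one row per locus, sorted by
#'   chromosome then start, with `freq_ipsc`, `freq_control`, `G`, `p`,
#'   `alpha_adjusted`, `is_hotspot`, `n_gain`, `n_loss` columns; attributes
#'   `m` (loci tested) and `alpha`.
#' @export
call_hotspots <- function(loci, manifest, control_segments = NULL,
                          parental_segments = NULL, alpha = 0.05,
                          freq_ipsc_min = 0.05, freq_control_max = 0.002,
                          merge_threshold = 0.10,
                          test = c("pooled", "by_direction")) {
  test <- match.arg(test)
  validate_manifest(manifest)
  m <- nrow(loci)
  if (m == 0L) {
    out <- tibble(
      locus_id = character(), chrom = character(), start = integer(),
      end = integer(), stratum = character(), n_ipsc = integer(),
      n_gain = integer(), n_loss = integer(), n_control = integer(),
      n_ipsc_total = integer(), n_control_total = integer(),
      freq_ipsc = numeric(), freq_control = numeric(), G = numeric(),
      p = numeric(), alpha_adjusted = numeric(), n_parental_carriers = integer(),
      is_hotspot = logical()
    )
    class(out) <- c("cnv_hotspots", class(out))
    attr(out, "m") <- 0L
    attr(out, "alpha") <- alpha
    return(out)
  }
  if (!is.null(control_segments)) {
    cc <- count_region_carriers(loci, control_segments, manifest, merge_threshold)
    loci$n_control <- cc$n_any
    loci$n_control_gain <- cc$n_gain
    loci$n_control_loss <- cc$n_loss
  }
  if (!is.null(parental_segments)) {
    pc <- count_region_carriers(loci, parental_segments, manifest, merge_threshold)
    loci$n_parental_carriers <- pc$n_any
  } else {
    loci$n_parental_carriers <- if ("n_parental" %in% names(loci)) loci$n_parental else 0L
  }
  loci <- carrier_frequency(loci, manifest)
  alpha_adjusted <- alpha / m

  tests <- lapply(seq_len(m), function(i) {
    if (test == "pooled") {
      tab <- matrix(
        c(
          loci$n_ipsc[i], loci$n_ipsc_total[i] - loci$n_ipsc[i],
          loci$n_control[i], loci$n_control_total[i] - loci$n_control[i]
        ),
        nrow = 2, byrow = TRUE
      )
    } else {
      tab <- matrix(
        c(
          loci$n_ipsc_gain[i], loci$n_ipsc_loss[i],
          loci$n_ipsc_total[i] - loci$n_ipsc[i],
          loci$n_control_gain[i], loci$n_control_loss[i],
          loci$n_control_total[i] - loci$n_control[i]
        ),
        nrow = 2, byrow = TRUE
      )
    }
    g_test(tab)
  })
  loci$G <- vapply(tests, function(t) t$statistic, numeric(1))
  loci$p <- vapply(tests, function(t) t$p.value, numeric(1))
  loci$alpha_adjusted <- alpha_adjusted
  loci$is_hotspot <- loci$freq_ipsc > freq_ipsc_min &
    loci$freq_control < freq_control_max &
    loci$p <= alpha_adjusted &
    loci$n_parental_carriers == 0L
  out <- loci %>%
    rename(n_gain = "n_ipsc_gain", n_loss = "n_ipsc_loss") %>%
    arrange(.data$chrom, .data$start)
  class(out) <- c("cnv_hotspots", class(out))
  attr(out, "m") <- m
  attr(out, "alpha") <- alpha
  out
}

#' Identify polymorphic CNV regions with frequent rearrangement
#'
#' Builds regions from the pooled parental + iPSC CNV segments
#' (pre-subtraction) by reciprocal-overlap merging, then flags regions that
#' are (1) frequent in the study cohort (`freq_total > freq_min` over all
#' parental + iPSC samples), (2) similarly common in the population
#' (`p > alpha` on the likelihood-ratio chi-square test against the control
#' cohort), and (3) mutually exclusive within pairs in more than
#' `min_subjects` donors. A donor counts as mutually exclusive when the
#' region is present in its parental sample XOR in at least one of its iPSC
#' lines.
#'
#' @param segments segments tibble covering parental and iPSC samples
#'   (post length-filter, before inherited subtraction); other roles are
#'   ignored.
#' @param manifest sample manifest with donor pairings.
#' @param control_segments control-cohort segments.
#' @param merge_threshold reciprocal-overlap merge/membership cutoff
#'   (default 0.10).
#' @param freq_min study-cohort frequency threshold (default 0.05, strict).
#' @param alpha the region is "common in the population" when the test
#'   p-value is strictly above `alpha` (default 0.05).
#' @param min_subjects required number of mutually exclusive donors
#'   (default 10, strict `>`).
#' @return a tibble of class `"cnv_polymorphic"`, one row per candidate
#'   region with `freq_total`, `p_vs_controls`, `n_mutually_exclusive`,
#'   `is_polymorphic`.
#' @export
find_polymorphic <- function(segments, manifest, control_segments = NULL,
                             merge_threshold = 0.10, freq_min = 0.05,
                             alpha = 0.05, min_subjects = 10L) {
  validate_manifest(manifest)
  ipsc_donors <- unique(manifest$donor_id[manifest$role == "ipsc"])
  if (length(ipsc_donors) == 0L ||
      !all(ipsc_donors %in% manifest$donor_id[manifest$role == "parental"])) {
    abort("manifest must pair every iPSC line with a parental sample of the same donor")
  }
  pool_ids <- manifest$sample_id[manifest$role %in% c("parental", "ipsc")]
  pool <- filter(segments, .data$sample_id %in% pool_ids)
  regions <- merge_loci(pool, manifest, merge_threshold)
  if (nrow(regions) == 0L) {
    out <- tibble(
      region_id = character(), chrom = character(), start = integer(),
      end = integer(), stratum = character(), n_carriers = integer(),
      n_total = integer(), freq_total = numeric(), n_control = integer(),
      n_control_total = integer(), p_vs_controls = numeric(),
      n_mutually_exclusive = integer(), is_polymorphic = logical()
    )
    class(out) <- c("cnv_polymorphic", class(out))
    return(out)
  }
  regions$n_carriers <- regions$n_ipsc + regions$n_parental
  regions$n_total <- stratum_size(manifest, "ipsc", regions$stratum) +
    stratum_size(manifest, "parental", regions$stratum)
  regions$freq_total <- regions$n_carriers / regions$n_total

  cc <- count_region_carriers(regions, control_segments, manifest, merge_threshold)
  regions$n_control <- cc$n_any
  regions$n_control_total <- stratum_size(manifest, "control", regions$stratum)

  tests <- lapply(seq_len(nrow(regions)), function(i) {
    g_test(matrix(
      c(
        regions$n_carriers[i], regions$n_total[i] - regions$n_carriers[i],
        regions$n_control[i], regions$n_control_total[i] - regions$n_control[i]
      ),
      nrow = 2, byrow = TRUE
    ))
  })
  regions$G <- vapply(tests, function(t) t$statistic, numeric(1))
  regions$p_vs_controls <- vapply(tests, function(t) t$p.value, numeric(1))

  pairing <- select(manifest, "sample_id", "donor_id", "role")
  regions$n_mutually_exclusive <- vapply(seq_len(nrow(regions)), function(i) {
    mem <- regions$members[[i]] %>%
      distinct(.data$sample_id) %>%
      left_join(pairing, by = "sample_id")
    by_donor <- pairing %>%
      filter(.data$donor_id %in% ipsc_donors, .data$role %in% c("parental", "ipsc")) %>%
      mutate(carrier = .data$sample_id %in% mem$sample_id) %>%
      group_by(.data$donor_id) %>%
      summarise(
        par = any(.data$carrier[.data$role == "parental"]),
        ips = any(.data$carrier[.data$role == "ipsc"]),
        .groups = "drop"
      )
    sum(xor(by_donor$par, by_donor$ips))
  }, integer(1))

  regions$is_polymorphic <- regions$freq_total > freq_min &
    regions$p_vs_controls > alpha &
    regions$n_mutually_exclusive > min_subjects
  out <- regions %>%
    rename(region_id = "locus_id") %>%
    arrange(.data$chrom, .data$start)
  class(out) <- c("cnv_polymorphic", class(out))
  out
}

#' Paired CNV-burden test
#'
#' Tests whether reprogramming changes the per-sample CNV count with a
#' paired t-test: each iPSC line's post-length-filter segment count is paired
#' with its donor's parental count (the parental count is reused across a
#' donor's clones). Samples with no segments count zero. Degenerate cases
#' follow fixed conventions: all differences zero returns `t = 0, p = 1`;
#' zero variance with nonzero mean returns `p = 0` with `degenerate = TRUE`.
#'
#' @param segments segments tibble (post length-filter) for parental and
#'   iPSC samples.
#' @param manifest sample manifest with donor pairings.
#' @return an object of class `"cnv_burden"`: list with `statistic` (t),
#'   `df`, `p.value`, `estimate` (mean iPSC - parental difference),
#'   `n_pairs`, `pairs` (per-line counts), `degenerate`.
#' @export
burden_test <- function(segments, manifest) {
  validate_manifest(manifest)
  check_segments(segments)
  counts <- segments %>%
    count(.data$sample_id, name = "n_cnv")
  lines <- manifest %>%
    filter(.data$role == "ipsc") %>%
    select("sample_id", "donor_id") %>%
    left_join(counts, by = "sample_id") %>%
    mutate(n_ipsc = dplyr::coalesce(.data$n_cnv, 0L)) %>%
    select(-"n_cnv")
  parents <- manifest %>%
    filter(.data$role == "parental") %>%
    select(parental_id = "sample_id", "donor_id") %>%
    left_join(counts, by = c(parental_id = "sample_id")) %>%
    mutate(n_parental = dplyr::coalesce(.data$n_cnv, 0L)) %>%
    select(-"n_cnv")
  pairs <- inner_join(lines, parents, by = "donor_id") %>%
    mutate(diff = .data$n_ipsc - .data$n_parental)
  n <- nrow(pairs)
  if (n < 2L) abort("burden test requires at least 2 iPSC/parental pairs")
  d <- pairs$diff
  degenerate <- FALSE
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(d)) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    tt <- t.test(pairs$n_ipsc, pairs$n_parental, paired = TRUE)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  out <- list(
    statistic = t_stat, df = n - 1L, p.value = p, estimate = mean(d),
    n_pairs = n, pairs = pairs, degenerate = degenerate
  )
  class(out) <- "cnv_burden"
  out
}

#' @export
print.cnv_burden <- function(x, ...) {
  cat("Paired CNV-burden t-test\n")
  cat(sprintf(
    "mean(iPSC - parental) = %.3f over %d pairs; t = %.3f, df = %d, p = %.4g%s\n",
    x$estimate, x$n_pairs, x$statistic, x$df, x$p.value,
    if (x$degenerate) " (degenerate: zero variance)" else ""
  ))
  invisible(x)
}

#' CNV segment size distribution
#'
#' Bins segment lengths into the standard reporting bins: below 500 kb,
#' 500 kb to 1 Mb, 1 Mb to 5 Mb, and at least 5 Mb (left-closed at 500 kb,
#' 1 Mb and 5 Mb). Fractions sum to 1 over non-empty input; empty input
#' returns all-zero fractions with attribute `empty = TRUE`.
#'
#' @param segments segments tibble (post length-filter).
#' @return a tibble of class `"cnv_size_distribution"` with `bin`, `n`,
#'   `fraction`.
#' @export
size_distribution <- function(segments) {
  labs <- c("<500kb", "500kb-1Mb", "1Mb-5Mb", ">=5Mb")
  if (nrow(segments) == 0L) {
    out <- tibble(bin = factor(labs, levels = labs), n = 0L, fraction = 0)
    class(out) <- c("cnv_size_distribution", class(out))
    attr(out, "empty") <- TRUE
    return(out)
  }
  check_segments(segments)
  len <- as.numeric(segments$end) - segments$start + 1
  bin <- cut(len, breaks = c(0, 5e5, 1e6, 5e6, Inf), labels = labs, right = FALSE)
  out <- tibble(bin = factor(labs, levels = labs)) %>%
    left_join(count(tibble(bin = bin), .data$bin), by = "bin") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L), fraction = .data$n / length(len))
  class(out) <- c("cnv_size_distribution", class(out))
  attr(out, "empty") <- FALSE
  out
}

#' Annotate loci with overlapping genes
#'
#' Lists, per locus, every gene whose interval overlaps the locus by at
#' least 1 bp; symbols are deduplicated and ordered by gene start.
#'
#' @param loci loci tibble.
#' @param genes gene intervals with columns `chrom`, `start`, `end`,
#'   `symbol` (1-based inclusive, as from [read_gene_bed()]); `NULL` or
#'   empty yields empty annotations.
#' @return `loci` with `genes` (list-column of symbol vectors) and
#'   `genes_str` (comma-separated) columns added.
#' @export
annotate_genes <- function(loci, genes = NULL) {
  if (nrow(loci) == 0L || is.null(genes) || nrow(genes) == 0L) {
    loci$genes <- replicate(nrow(loci), character(0), simplify = FALSE)
    loci$genes_str <- character(nrow(loci))
    return(loci)
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(intervals_to_gr(loci), intervals_to_gr(genes))
  )
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  per <- split(s, q)
  loci$genes <- lapply(seq_len(nrow(loci)), function(i) {
    idx <- per[[as.character(i)]]
    if (is.null(idx)) return(character(0))
    idx <- idx[order(genes$start[idx])]
    unique(genes$symbol[idx])
  })
  loci$genes_str <- vapply(loci$genes, paste, character(1), collapse = ",")
  loci
}
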