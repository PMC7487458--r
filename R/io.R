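# File formats. All on-disk tables are TSV; interval tables are written
# 1-based inclusive (stated in a comment header), BED files are 0-based
# half-open on disk and converted on read/write by rtracklayer.

version_header <- function() {
  paste0(
    "# ipscnv ", as.character(utils::packageVersion("ipscnv")),
    "; coordinates: 1-based inclusive"
  )
}

read_tsv_checked <- function(path, col_types, required) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- suppressWarnings(readr::read_tsv(
    path, comment = "#", col_types = col_types,
    show_col_types = FALSE, progress = FALSE
  ))
  prob <- readr::problems(x)
  if (nrow(prob)) {
    abort(paste0(
      "parse error in ", path, ", row ", prob$row[1], ", column ", prob$col[1],
      ": expected ", prob$expected[1], ", got '", prob$actual[1], "'"
    ))
  }
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    abort(paste0(path, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  x
}

#' Validate a sample manifest
#'
#' A manifest has one row per sample: `sample_id`, `donor_id`, `role`
#' (`parental`, `ipsc` or `control`) and `sex` (`male`/`female`). Every iPSC
#' line must share a donor with a parental sample (multiple clones per donor
#' are allowed) and control samples must not share donors with study
#' samples.
#'
#' @param manifest a data frame.
#' @return the manifest as a tibble (invisibly usable in pipes).
#' @export
validate_manifest <- function(manifest) {
  need <- c("sample_id", "donor_id", "role", "sex")
  miss <- setdiff(need, names(manifest))
  if (length(miss)) {
    abort(paste0("manifest is missing column(s): ", paste(miss, collapse = ", ")))
  }
  m <- as_tibble(manifest)
  if (anyDuplicated(m$sample_id)) {
    abort(paste0(
      "duplicate sample id in manifest: ",
      m$sample_id[duplicated(m$sample_id)][1]
    ))
  }
  bad_role <- setdiff(unique(m$role), c("parental", "ipsc", "control"))
  if (length(bad_role)) {
    abort(paste0("unknown role(s) in manifest: ", paste(bad_role, collapse = ", ")))
  }
  bad_sex <- !is.na(m$sex) & !m$sex %in% c("male", "female")
  if (any(bad_sex)) {
    abort(paste0("unknown sex value(s): ", paste(unique(m$sex[bad_sex]), collapse = ", ")))
  }
  ipsc_donors <- unique(m$donor_id[m$role == "ipsc"])
  unpaired <- setdiff(ipsc_donors, m$donor_id[m$role == "parental"])
  if (length(unpaired)) {
    abort(paste0(
      "iPSC line(s) without a parental sample for donor(s): ",
      paste(head(unpaired, 5), collapse = ", ")
    ))
  }
  study_donors <- unique(m$donor_id[m$role != "control"])
  shared <- intersect(study_donors, m$donor_id[m$role == "control"])
  if (length(shared)) {
    abort(paste0(
      "control sample(s) share donor id(s) with study samples: ",
      paste(head(shared, 5), collapse = ", ")
    ))
  }
  m
}

#' Read / write a probe map
#'
#' TSV with header `probe_id  chrom  pos` (1-based positions).
#'
#' @param path file path.
#' @return a validated probe-map tibble.
#' @export
read_probe_map <- function(path) {
  x <- read_tsv_checked(
    path, readr::cols(probe_id = "c", chrom = "c", pos = "i"),
    c("probe_id", "chrom", "pos")
  )
  validate_probe_map(x)
}

#' @rdname read_probe_map
#' @param probe_map probe-map tibble to write.
#' @export
write_probe_map <- function(probe_map, path) {
  writeLines(version_header(), path)
  readr::write_tsv(validate_probe_map(probe_map), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write a sample manifest
#'
#' TSV with header `sample_id  donor_id  role  sex`.
#'
#' @param path file path.
#' @return a validated manifest tibble.
#' @export
read_manifest <- function(path) {
  x <- read_tsv_checked(
    path, readr::cols(sample_id = "c", donor_id = "c", role = "c", sex = "c"),
    c("sample_id", "donor_id", "role", "sex")
  )
  validate_manifest(x)
}

#' @rdname read_manifest
#' @param manifest manifest tibble to write.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_tsv(validate_manifest(manifest), path)
  invisible(path)
}

#' Read / write a dense probe-call matrix
#'
#' TSV with `probe_id` as the first column and one integer copy-number-state
#' column per sample. Missing states are not allowed: every probe of the map
#' must carry a state for every sample.
#'
#' @param path file path.
#' @return a wide tibble (`probe_id` + one column per sample).
#' @export
read_call_matrix <- function(path) {
  x <- read_tsv_checked(path, readr::cols(probe_id = "c", .default = "i"), "probe_id")
  if (ncol(x) < 2L) abort(paste0(path, " has no sample columns"))
  if (anyNA(x)) {
    abort(paste0(path, " contains missing states; impute to baseline or drop the probe upstream"))
  }
  x
}

#' @rdname read_call_matrix
#' @param mat wide call matrix to write.
#' @export
write_call_matrix <- function(mat, path) {
  readr::write_tsv(mat, path)
  invisible(path)
}

#' Convert between dense call matrices and sparse calls
#'
#' The in-memory working representation of probe states is sparse: a tibble
#' `sample_id, probe_id, state` listing only probes deviating from the
#' sex-appropriate baseline (all other probes are at baseline).
#' `calls_from_matrix()` extracts those deviations from a dense matrix;
#' `calls_to_matrix()` rebuilds the dense matrix, filling baseline states.
#' Female Y states are emitted as the female X/Y convention dictates:
#' `calls_to_matrix()` writes 0 for female Y probes (excluded from analysis).
#'
#' @param mat wide call matrix (see [read_call_matrix()]).
#' @param probe_map probe map covering the matrix rows.
#' @param manifest sample manifest covering the matrix columns.
#' @return `calls_from_matrix()`: sparse calls tibble;
#'   `calls_to_matrix()`: wide tibble.
#' @export
calls_from_matrix <- function(mat, probe_map, manifest) {
  pm <- validate_probe_map(probe_map)
  m <- validate_manifest(manifest)
  samples <- setdiff(names(mat), "probe_id")
  unknown <- setdiff(samples, m$sample_id)
  if (length(unknown)) {
    abort(paste0("matrix column(s) not in manifest: ", paste(head(unknown, 5), collapse = ", ")))
  }
  missing_probes <- setdiff(pm$probe_id, mat$probe_id)
  if (length(missing_probes)) {
    abort(paste0(
      "matrix lacks state(s) for probe(s): ",
      paste(head(missing_probes, 5), collapse = ", ")
    ))
  }
  mat <- mat[match(pm$probe_id, mat$probe_id), , drop = FALSE]
  sex <- setNames(m$sex, m$sample_id)
  purrr::map_dfr(samples, function(sid) {
    base <- baseline_state(pm$chrom, sex[[sid]])
    st <- mat[[sid]]
    keep <- !is.na(base) & st != base
    tibble(sample_id = sid, probe_id = pm$probe_id[keep], state = as.integer(st[keep]))
  })
}

#' @rdname calls_from_matrix
#' @param calls sparse calls tibble.
#' @param samples sample ids to emit as columns (default: all manifest
#'   samples present in `calls`).
#' @export
calls_to_matrix <- function(calls, probe_map, manifest, samples = NULL) {
  pm <- validate_probe_map(probe_map)
  m <- validate_manifest(manifest)
  samples <- samples %||% intersect(m$sample_id, unique(calls$sample_id))
  sex <- setNames(m$sex, m$sample_id)
  out <- tibble(probe_id = pm$probe_id)
  for (sid in samples) {
    base <- baseline_state(pm$chrom, sex[[sid]])
    base[is.na(base)] <- 0L # female Y probes: excluded, written as 0
    st <- base
    rows <- calls[calls$sample_id == sid, , drop = FALSE]
    hit <- match(rows$probe_id, pm$probe_id)
    st[hit[!is.na(hit)]] <- as.integer(rows$state[!is.na(hit)])
    out[[sid]] <- st
  }
  out
}

# internal: import a BED file as a 1-based inclusive tibble
read_bed_tibble <- function(path, name_col) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  gr <- tryCatch(
    rtracklayer::import(path, format = "BED"),
    error = function(e) abort(paste0("parse error in ", path, ": ", conditionMessage(e)))
  )
  nm <- if ("name" %in% names(S4Vectors::mcols(gr))) {
    as.character(S4Vectors::mcols(gr)$name)
  } else {
    rep(NA_character_, length(gr))
  }
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  out[[name_col]] <- nm
  out
}

#' Read / write exclusion regions (BED)
#'
#' On disk BED is 0-based half-open; in memory intervals are 1-based
#' inclusive. The exclusion category (centromere, Ig_variable, TCR, PAR,
#' XTR, ...) travels in the BED name field.
#'
#' @param path file path.
#' @return tibble `chrom`, `start`, `end`, `category` (1-based inclusive).
#' @export
read_exclusion_bed <- function(path) {
  read_bed_tibble(path, "category")
}

#' @rdname read_exclusion_bed
#' @param exclusions exclusion tibble to write.
#' @export
write_exclusion_bed <- function(exclusions, path) {
  gr <- intervals_to_gr(exclusions)
  S4Vectors::mcols(gr)$name <- exclusions$category %||% NA_character_
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read gene intervals (BED)
#'
#' Gene symbols travel in the BED name field; coordinates are converted to
#' 1-based inclusive on read.
#'
#' @param path file path.
#' @return tibble `chrom`, `start`, `end`, `symbol`.
#' @export
read_gene_bed <- function(path) {
  read_bed_tibble(path, "symbol")
}

#' Read / write CNV segments
#'
#' BED-like TSV `sample_id chrom start end direction n_probes length`,
#' 1-based inclusive coordinates (stated in the comment header).
#'
#' @param path file path.
#' @return segments tibble.
#' @export
read_segments <- function(path) {
  x <- read_tsv_checked(
    path,
    readr::cols(
      sample_id = "c", chrom = "c", start = "i", end = "i",
      direction = "c", n_probes = "i", length = "d"
    ),
    c("sample_id", "chrom", "start", "end", "direction")
  )
  bad <- !x$direction %in% c("gain", "loss")
  if (any(bad)) {
    abort(paste0(
      "parse error in ", path, ", row ", which(bad)[1],
      ": direction must be 'gain' or 'loss'"
    ))
  }
  check_segments(x, path)
}

#' @rdname read_segments
#' @param segments segments tibble to write.
#' @export
write_segments <- function(segments, path) {
  writeLines(version_header(), path)
  readr::write_tsv(check_segments(segments), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read / write loci tables
#'
#' TSV mirroring the hotspot-report columns
#' (`chrom start end stratum n_ipsc_gain n_ipsc_loss n_ctrl_gain n_ctrl_loss
#' member_count`); the `members` list-column is not serialized.
#'
#' @param path file path.
#' @return loci tibble (without members).
#' @export
read_loci <- function(path) {
  read_tsv_checked(
    path,
    readr::cols(
      locus_id = "c", chrom = "c", start = "i", end = "i", stratum = "c",
      .default = "d"
    ),
    c("chrom", "start", "end", "stratum")
  )
}

#' @rdname read_loci
#' @param loci loci tibble to write.
#' @export
write_loci <- function(loci, path) {
  flat <- loci[, !vapply(loci, is.list, logical(1)), drop = FALSE]
  writeLines(version_header(), path)
  readr::write_tsv(flat, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a machine-readable run summary
#'
#' @param summary named list (thresholds, counts, statistics).
#' @param path output JSON path.
#' @export
write_run_summary <- function(summary, path) {
  jsonlite::write_json(summary, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
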