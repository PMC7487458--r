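# Independent oracles: deliberately naive implementations (explicit loops,
# per-base scans, union-find over a full pairwise matrix, numerical
# integration) used to check the package's vectorised/overlap-join paths.

# O(n*m) per-probe point-in-interval scan
oracle_mask <- function(probe_map, exclusions) {
  keep <- vapply(seq_len(nrow(probe_map)), function(i) {
    p <- probe_map[i, ]
    !any(vapply(seq_len(nrow(exclusions)), function(j) {
      e <- exclusions[j, ]
      e$chrom == p$chrom && p$pos >= e$start && p$pos <= e$end
    }, logical(1)))
  }, logical(1))
  probe_map[keep, , drop = FALSE]
}

# exhaustive maximal-run scan over a dense state vector for ONE sample.
# states: tibble chrom, pos, state (every probe present), baseline: integer
# vector aligned with rows.
oracle_runs <- function(states, baseline, min_probes) {
  out <- list()
  for (ch in unique(states$chrom)) {
    s <- states[states$chrom == ch, ]
    b <- baseline[states$chrom == ch]
    d <- sign(s$state - b)
    i <- 1
    while (i <= nrow(s)) {
      if (d[i] == 0) { i <- i + 1; next }
      j <- i
      while (j < nrow(s) && d[j + 1] == d[i]) j <- j + 1
      if (j - i + 1 >= min_probes) {
        out[[length(out) + 1]] <- tibble::tibble(
          chrom = ch, start = s$pos[i], end = s$pos[j],
          direction = if (d[i] > 0) "gain" else "loss",
          n_probes = j - i + 1
        )
      }
      i <- j + 1
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(chrom = character(), start = integer(), end = integer(),
                   direction = character(), n_probes = integer())
}

# brute-force shared-bp count for small intervals
oracle_reciprocal_overlap <- function(a, b) {
  if (a$chrom != b$chrom) return(0)
  shared <- length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
  if (shared == 0) return(0)
  min(shared / (a$end - a$start + 1), shared / (b$end - b$start + 1))
}

# union-find single-linkage clustering over the exhaustive pairwise
# reciprocal-overlap matrix
oracle_cluster <- function(segments, threshold) {
  n <- nrow(segments)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      ro <- oracle_reciprocal_overlap(segments[i, ], segments[j, ])
      if (ro >= threshold) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# per-base occupancy array for control coverage of a locus
oracle_coverage <- function(locus, control_segments) {
  pos <- locus$start:locus$end
  covered <- rep(FALSE, length(pos))
  for (j in seq_len(nrow(control_segments))) {
    cs <- control_segments[j, ]
    if (cs$chrom != locus$chrom) next
    covered <- covered | (pos >= cs$start & pos <= cs$end)
  }
  sum(covered) / length(pos)
}

# 2*sum(O*ln(O/E)) with margin-derived E; chi-square upper tail by numerical
# integration of the density (independent of pchisq)
oracle_g_test <- function(tab, df = 1) {
  rs <- rowSums(tab); cs <- colSums(tab); tot <- sum(tab)
  g <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- rs[i] * cs[j] / tot
      if (tab[i, j] > 0) g <- g + tab[i, j] * log(tab[i, j] / e)
    }
  }
  g <- 2 * g
  dens <- function(x) x^(df / 2 - 1) * exp(-x / 2) / (2^(df / 2) * gamma(df / 2))
  p <- if (g <= 0) 1 else stats::integrate(dens, g, Inf, rel.tol = 1e-10)$value
  list(G = g, p = p)
}

# textbook paired t evaluation
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t_stat <- mean(d) / (stats::sd(d) / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), df = n - 1)
  list(t = t_stat, df = n - 1, p = p)
}

# random-track generator: dense states on a small lattice with planted runs
# and isolated noise, plus the tibbles the package consumes
random_track <- function(n_probes = 2000, spacing = 1000, n_runs = 8,
                         run_len = c(3, 40), noise = 15, chroms = c("chr1", "chr2")) {
  per <- ceiling(n_probes / length(chroms))
  pm <- dplyr::bind_rows(lapply(chroms, function(ch) {
    tibble::tibble(chrom = ch, pos = as.integer((seq_len(per) - 1) * spacing + 1))
  }))
  pm$probe_id <- sprintf("r%05d", seq_len(nrow(pm)))
  pm <- pm[, c("probe_id", "chrom", "pos")]
  state <- rep(2L, nrow(pm))
  for (k in seq_len(n_runs)) {
    len <- sample(run_len[1]:run_len[2], 1)
    i <- sample(nrow(pm) - len, 1)
    state[i:(i + len - 1)] <- sample(c(0L, 1L, 3L, 4L), 1)
  }
  for (k in seq_len(noise)) {
    state[sample(nrow(pm), 1)] <- sample(c(1L, 3L), 1)
  }
  list(probe_map = pm, state = state)
}

small_manifest <- function(...) {
  tibble::tibble(...)
}
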