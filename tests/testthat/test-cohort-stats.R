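study_manifest <- function(n_ipsc = 82, n_ctrl = 1093, n_female_ipsc = 42,
                           n_female_ctrl = 568) {
  d <- sprintf("D%03d", seq_len(n_ipsc))
  sexes_i <- c(rep("female", n_female_ipsc), rep("male", n_ipsc - n_female_ipsc))
  sexes_c <- c(rep("female", n_female_ctrl), rep("male", n_ctrl - n_female_ctrl))
  dplyr::bind_rows(
    tibble::tibble(sample_id = paste0(d, "_P"), donor_id = d, role = "parental", sex = sexes_i),
    tibble::tibble(sample_id = paste0(d, "_S1"), donor_id = d, role = "ipsc", sex = sexes_i),
    tibble::tibble(
      sample_id = sprintf("C%04d", seq_len(n_ctrl)),
      donor_id = sprintf("CD%04d", seq_len(n_ctrl)),
      role = "control", sex = sexes_c
    )
  )
}

test_that("G test: independence gives G = 0, p = 1; zero margins return (0, 1); negatives error", {
  eq <- g_test(matrix(c(10, 90, 10, 90), nrow = 2, byrow = TRUE))
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p.value, 1)
  zm <- g_test(matrix(c(0, 82, 0, 1093), nrow = 2, byrow = TRUE))
  expect_equal(zm$statistic, 0)
  expect_equal(zm$p.value, 1)
  expect_error(g_test(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("G test reproduces the independently integrated likelihood-ratio statistic", {
  got <- g_test(matrix(c(5, 77, 1, 1092), nrow = 2, byrow = TRUE))
  want <- oracle_g_test(matrix(c(5, 77, 1, 1092), nrow = 2, byrow = TRUE))
  expect_equal(got$statistic, want$G, tolerance = 1e-10)
  expect_equal(got$p.value, want$p, tolerance = 1e-6)
  # the worked magnitude: G about 21.7, p about 3e-6
  expect_equal(got$statistic, 21.7, tolerance = 0.01)
  expect_lt(got$p.value, 1e-5)
  set.seed(61)
  for (rep in 1:25) {
    tab <- matrix(sample.int(200, 4), nrow = 2)
    got <- g_test(tab)
    want <- oracle_g_test(tab)
    expect_equal(got$statistic, want$G, tolerance = 1e-10)
    expect_equal(got$p.value, want$p, tolerance = 1e-8)
  }
})

test_that("G agrees with Pearson chi-square within 15% when expected counts are large", {
  set.seed(71)
  for (rep in 1:20) {
    tab <- matrix(sample(30:300, 4), nrow = 2)
    if (any(outer(rowSums(tab), colSums(tab)) / sum(tab) < 5)) next
    g <- g_test(tab)$statistic
    x2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$statistic)
    if (g > 0.5) expect_lt(abs(g - x2) / g, 0.15)
  }
})

test_that("carrier frequencies use stratum denominators and match a direct recount", {
  man <- study_manifest()
  t1 <- table1_hotspot_counts()
  loci <- tibble::tibble(
    chrom = t1$chrom, start = t1$start, end = t1$end, stratum = t1$stratum,
    n_ipsc = t1$dup_ipsc + t1$del_ipsc,
    n_control = t1$dup_ctrl + t1$del_ctrl
  )
  out <- carrier_frequency(loci, man)
  expect_equal(out$n_ipsc_total, t1$n_ipsc)
  expect_equal(out$n_control_total, t1$n_ctrl)
  # the recurrent chr4 region: (38 + 2) / 82 = 48.8% of lines carry an event
  expect_equal(round(100 * out$freq_ipsc[2], 1), 48.8)
  # zero carriers give zero frequency
  z <- carrier_frequency(
    tibble::tibble(chrom = "chr1", start = 1, end = 2, stratum = "all",
                   n_ipsc = 0L, n_control = 0L), man
  )
  expect_equal(z$freq_ipsc, 0)
  expect_equal(z$freq_control, 0)
})

test_that("carrier counting by membership matches a per-sample brute force on random cohorts", {
  set.seed(81)
  man <- study_manifest(n_ipsc = 10, n_ctrl = 20, n_female_ipsc = 5, n_female_ctrl = 10)
  ids <- man$sample_id[man$role == "control"]
  region <- tibble::tibble(chrom = "chr1", start = 5e5, end = 9e5, stratum = "all")
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    s <- sample.int(1.5e6, n)
    segs <- tibble::tibble(
      sample_id = sample(ids, n, replace = TRUE), chrom = "chr1",
      start = as.integer(s), end = as.integer(s + sample.int(6e5, n)),
      direction = sample(c("gain", "loss"), n, replace = TRUE),
      n_probes = 10L
    ) |> dplyr::mutate(length = end - start + 1)
    got <- count_region_carriers(region, segs, man)$n_any
    is_c <- vapply(seq_len(n), function(i) {
      oracle_reciprocal_overlap(region, segs[i, ]) >= 0.10
    }, logical(1))
    expect_equal(got, length(unique(segs$sample_id[is_c])))
  }
})

test_that("hotspot classification enforces every gate with strict thresholds", {
  man <- study_manifest()
  base <- tibble::tibble(
    locus_id = "L1", chrom = "chr1", start = 1e6, end = 2e6, stratum = "all",
    n_ipsc_gain = 5L, n_ipsc_loss = 0L, n_ipsc = 5L,
    n_parental = 0L, n_control = 0L,
    n_control_gain = 0L, n_control_loss = 0L,
    member_count = 5L
  )
  hs <- call_hotspots(base, man)
  expect_true(hs$is_hotspot)
  # 3/82 = 3.7% misses the 5% frequency gate regardless of p
  low <- dplyr::mutate(base, n_ipsc = 3L, n_ipsc_gain = 3L)
  expect_false(call_hotspots(low, man)$is_hotspot)
  # exactly 5% is not enough: the threshold is strict
  at5 <- dplyr::mutate(base, n_ipsc = 4L, n_ipsc_gain = 4L) # 4/82 = 4.9%
  expect_false(call_hotspots(at5, man)$is_hotspot)
  # control frequency must stay under 0.2%: 3/1093 = 0.27% fails, 2/1093 = 0.18% passes
  hot2 <- dplyr::mutate(base, n_ipsc = 30L, n_ipsc_gain = 30L)
  expect_true(call_hotspots(dplyr::mutate(hot2, n_control = 2L, n_control_gain = 2L), man)$is_hotspot)
  expect_false(call_hotspots(dplyr::mutate(hot2, n_control = 3L, n_control_gain = 3L), man)$is_hotspot)
  # a parental carrier at the locus revokes hotspot status
  expect_false(call_hotspots(dplyr::mutate(base, n_parental = 1L), man)$is_hotspot)
})

test_that("adding control carriers can only revoke hotspot status (monotone)", {
  man <- study_manifest()
  base <- tibble::tibble(
    locus_id = "L1", chrom = "chr1", start = 1e6, end = 2e6, stratum = "all",
    n_ipsc_gain = 10L, n_ipsc_loss = 0L, n_ipsc = 10L, n_parental = 0L,
    n_control = 0L, n_control_gain = 0L, n_control_loss = 0L, member_count = 10L
  )
  status <- vapply(0:6, function(k) {
    call_hotspots(dplyr::mutate(base, n_control = k, n_control_gain = k), man)$is_hotspot
  }, logical(1))
  expect_true(all(diff(as.integer(status)) <= 0))
})

test_that("Bonferroni adjustment satisfies alpha_adjusted * m == alpha", {
  man <- study_manifest()
  m <- 17
  loci <- tibble::tibble(
    locus_id = sprintf("L%02d", 1:m), chrom = "chr1",
    start = as.numeric(1:m) * 1e6, end = as.numeric(1:m) * 1e6 + 2e5,
    stratum = "all", n_ipsc_gain = 1L, n_ipsc_loss = 0L, n_ipsc = 1L,
    n_parental = 0L, n_control = 0L, n_control_gain = 0L,
    n_control_loss = 0L, member_count = 1L
  )
  hs <- call_hotspots(loci, man, alpha = 0.05)
  expect_equal(unique(hs$alpha_adjusted) * attr(hs, "m"), 0.05)
  expect_equal(attr(hs, "m"), m)
})

test_that("X-stratified hotspot rows test female lines against female controls", {
  man <- study_manifest()
  xlocus <- tibble::tibble(
    locus_id = "LX", chrom = "chrX", start = 1e6, end = 2e6,
    stratum = "female_only", n_ipsc_gain = 8L, n_ipsc_loss = 0L, n_ipsc = 8L,
    n_parental = 0L, n_control = 0L, n_control_gain = 0L,
    n_control_loss = 0L, member_count = 8L
  )
  hs <- call_hotspots(xlocus, man)
  expect_equal(hs$n_ipsc_total, 42L)
  expect_equal(hs$n_control_total, 568L)
  expect_true(hs$is_hotspot)
})

test_that("polymorphic regions need frequency, population commonness and more than 10 XOR donors", {
  man <- study_manifest(n_ipsc = 100, n_ctrl = 1093)
  region <- list(chrom = "chr1", start = 1e6, end = 1.4e6)
  mk_pool <- function(n_par_only, n_ipsc_only, n_both) {
    par_only <- sprintf("D%03d_P", seq_len(n_par_only))
    ipsc_only <- sprintf("D%03d_S1", n_par_only + seq_len(n_ipsc_only))
    both_d <- n_par_only + n_ipsc_only + seq_len(n_both)
    both <- c(sprintf("D%03d_P", both_d), sprintf("D%03d_S1", both_d))
    ids <- c(par_only, ipsc_only, both)
    tibble::tibble(
      sample_id = ids, chrom = region$chrom,
      start = as.integer(region$start), end = as.integer(region$end),
      direction = "gain", n_probes = 20L,
      length = region$end - region$start + 1
    )
  }
  ctrl_ids <- man$sample_id[man$role == "control"]
  mk_ctrl <- function(k) {
    tibble::tibble(
      sample_id = ctrl_ids[seq_len(k)], chrom = region$chrom,
      start = as.integer(region$start), end = as.integer(region$end),
      direction = "loss", n_probes = 20L,
      length = region$end - region$start + 1
    )
  }
  # 11 XOR donors (6 parental-only + 5 iPSC-only), 5 shared; freq 16/200 = 8%;
  # control frequency matched to give p > 0.05
  pool <- mk_pool(6, 5, 5)
  ctrl <- mk_ctrl(87) # 87/1093 = 7.96%
  res <- find_polymorphic(pool, man, ctrl)
  expect_equal(nrow(res), 1)
  expect_equal(res$n_mutually_exclusive, 11L)
  expect_gt(res$p_vs_controls, 0.05)
  expect_true(res$is_polymorphic)
  # exactly 10 XOR donors is not enough (strictly more than 10)
  pool10 <- mk_pool(5, 5, 6)
  res10 <- find_polymorphic(pool10, man, ctrl)
  expect_equal(res10$n_mutually_exclusive, 10L)
  expect_false(res10$is_polymorphic)
  # present in both members of every pair: zero XOR donors
  pool_both <- mk_pool(0, 0, 12)
  res_b <- find_polymorphic(pool_both, man, mk_ctrl(131))
  expect_equal(res_b$n_mutually_exclusive, 0L)
  expect_false(res_b$is_polymorphic)
  # a rare-in-controls region fails the commonness gate
  res_rare <- find_polymorphic(pool, man, mk_ctrl(2))
  expect_lt(res_rare$p_vs_controls, 0.05)
  expect_false(res_rare$is_polymorphic)
})

test_that("polymorphic detection requires a paired manifest", {
  man <- tibble::tibble(
    sample_id = c("A", "C1"), donor_id = c("DA", "CD1"),
    role = c("parental", "control"), sex = "female"
  )
  segs <- tibble::tibble(
    sample_id = "A", chrom = "chr1", start = 1L, end = 10L,
    direction = "gain", n_probes = 10L, length = 10
  )
  expect_error(find_polymorphic(segs, man, NULL), "pair")
})

test_that("burden test follows paired-t conventions and the textbook formula", {
  man <- study_manifest(n_ipsc = 4, n_ctrl = 2, n_female_ipsc = 2, n_female_ctrl = 1)
  mk_segs <- function(ipsc_counts, par_counts) {
    rows <- list()
    for (i in seq_along(ipsc_counts)) {
      d <- sprintf("D%03d", i)
      if (ipsc_counts[i] > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = paste0(d, "_S1"), chrom = "chr1",
          start = as.integer(seq_len(ipsc_counts[i]) * 1e6),
          end = as.integer(seq_len(ipsc_counts[i]) * 1e6 + 2e5),
          direction = "gain", n_probes = 10L, length = 2e5 + 1
        )
      }
      if (par_counts[i] > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          sample_id = paste0(d, "_P"), chrom = "chr2",
          start = as.integer(seq_len(par_counts[i]) * 1e6),
          end = as.integer(seq_len(par_counts[i]) * 1e6 + 2e5),
          direction = "loss", n_probes = 10L, length = 2e5 + 1
        )
      }
    }
    dplyr::bind_rows(rows)
  }
  # differences (1, 0, -1, 0): symmetric, t = 0, p = 1
  b0 <- burden_test(mk_segs(c(3, 2, 1, 2), c(2, 2, 2, 2)), man)
  expect_equal(b0$statistic, 0)
  expect_equal(b0$p.value, 1)
  expect_equal(b0$df, 3L)
  # constant nonzero differences: degenerate, p reported as 0 with a flag
  b2 <- burden_test(mk_segs(c(4, 4, 4, 4), c(2, 2, 2, 2)), man)
  expect_true(b2$degenerate)
  expect_equal(b2$p.value, 0)
  # all-equal pairs: t = 0, p = 1, not flagged
  b1 <- burden_test(mk_segs(c(2, 2, 2, 2), c(2, 2, 2, 2)), man)
  expect_equal(b1$statistic, 0)
  expect_equal(b1$p.value, 1)
  expect_false(b1$degenerate)
  # random paired counts match the textbook formula
  set.seed(91)
  for (rep in 1:10) {
    ipsc <- sample(0:6, 4, replace = TRUE)
    par <- sample(0:6, 4, replace = TRUE)
    if (stats::sd(ipsc - par) == 0) next
    b <- burden_test(mk_segs(ipsc, par), man)
    want <- oracle_paired_t(ipsc, par)
    expect_equal(b$statistic, want$t, tolerance = 1e-10)
    expect_equal(b$p.value, want$p, tolerance = 1e-10)
  }
  # fewer than 2 pairs errors
  man1 <- study_manifest(n_ipsc = 1, n_ctrl = 2, n_female_ipsc = 1, n_female_ctrl = 1)
  expect_error(burden_test(mk_segs(2, 1), man1), "at least 2")
})

test_that("size distribution uses left-closed bins at 500 kb, 1 Mb and 5 Mb", {
  mk <- function(lens) {
    tibble::tibble(
      sample_id = "s", chrom = "chr1", start = 1L,
      end = as.integer(lens), direction = "gain", n_probes = 10L,
      length = lens
    )
  }
  all200 <- size_distribution(mk(rep(2e5, 7)))
  expect_equal(all200$fraction, c(1, 0, 0, 0))
  quarters <- size_distribution(mk(c(2e5, 6e5, 2e6, 7e6)))
  expect_equal(quarters$fraction, rep(0.25, 4))
  # boundary values land in the right-hand bin (left-closed)
  edges <- size_distribution(mk(c(5e5, 1e6, 5e6)))
  expect_equal(edges$n, c(0L, 1L, 1L, 1L))
  set.seed(101)
  lens <- sample(c(1e5 + 1, 3e5, 5e5, 9e5, 1e6, 4e6, 5e6, 9e6), 50, replace = TRUE)
  got <- size_distribution(mk(lens))
  want <- c(
    mean(lens < 5e5), mean(lens >= 5e5 & lens < 1e6),
    mean(lens >= 1e6 & lens < 5e6), mean(lens >= 5e6)
  )
  expect_equal(got$fraction, want)
  expect_equal(sum(got$fraction), 1)
  empty <- size_distribution(mk(numeric(0)))
  expect_equal(empty$fraction, rep(0, 4))
  expect_true(attr(empty, "empty"))
})

test_that("gene annotation lists overlapping symbols deduplicated in start order", {
  loci <- tibble::tibble(chrom = "chr1", start = 1e6, end = 2e6)
  expect_equal(annotate_genes(loci, NULL)$genes_str, "")
  genes <- tibble::tibble(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(1e6, 1.5e6, 2.5e6, 1e6),
    end = c(2e6, 1.6e6, 3e6, 2e6),
    symbol = c("EXACT", "INSIDE", "BEYOND", "OTHERCHR")
  )
  ann <- annotate_genes(loci, genes)
  expect_equal(ann$genes[[1]], c("EXACT", "INSIDE"))
  # brute-force interval join on random gene sets
  set.seed(111)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    s <- sample.int(5e6, n)
    g <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = s, end = s + sample.int(5e5, n),
      symbol = sprintf("G%03d", seq_len(n))
    )
    lo <- tibble::tibble(chrom = "chr1", start = 2e6, end = 3e6)
    got <- annotate_genes(lo, g)$genes[[1]]
    hit <- g$chrom == "chr1" & g$start <= 3e6 & g$end >= 2e6
    want <- g$symbol[hit][order(g$start[hit])]
    expect_equal(got, unique(want))
  }
})
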