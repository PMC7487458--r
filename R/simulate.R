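# Synthetic paired-cohort generator. Emulates the study design the pipeline
# expects: paired parental/iPSC samples sharing inherited CNVs, de novo
# iPSC CNVs including recurrent hotspot loci, polymorphic regions whose
# presence flips between pair members, a large control cohort, and isolated
# probe-level noise. Every planted event is recorded in a truth table whose
# spans are snapped to probe positions, so truth equals what a correct
# pipeline can recover.

#' Default miniature genome
#'
#' Four 60-Mb autosomes plus a 60-Mb X at 2-kb probe spacing (~150k probes),
#' an SNP-array-like density at desk scale.
#'
#' @return tibble `chrom`, `length`, `spacing` (bp).
#' @export
default_genome <- function() {
  tibble(
    chrom = c("chr1", "chr2", "chr3", "chr4", "chrX"),
    length = 6e7, spacing = 2000
  )
}

default_hotspots <- function() {
  tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr3", "chr4", "chr4", "chrX", "chrX"),
    start = c(5e6, 2e7, 8e6, 3e7, 1.2e7, 4e7, 7e6, 3.3e7, 1e7, 3.5e7) + 1,
    end = c(5.4e6, 2.03e7, 8.5e6, 3.025e7, 1.26e7, 4.035e7, 7.3e6, 3.35e7, 1.04e7, 3.53e7),
    carrier_prob = c(0.06, 0.10, 0.14, 0.18, 0.22, 0.26, 0.31, 0.36, 0.41, 0.45),
    gain_frac = c(1, 1, 1, 1, 0.9, 1, 0.5, 1, 1, 1)
  )
}

default_polymorphic <- function() {
  tibble(
    chrom = c("chr1", "chr1", "chr2", "chr2", "chr3", "chr4", "chr4"),
    start = c(3.2e7, 4.5e7, 1.5e7, 5e7, 2.5e7, 1.8e7, 5e7) + 1,
    end = c(3.23e7, 4.54e7, 1.535e7, 5.03e7, 2.55e7, 1.825e7, 5.04e7),
    presence_prob = 0.15
  )
}

default_control_loci <- function() {
  loci <- tibble(
    chrom = c(
      rep("chr1", 5), rep("chr2", 5), rep("chr3", 5), rep("chr4", 5), "chrX", "chrX"
    ),
    start = c(
      2e6, 9e6, 2.6e7, 3.8e7, 5.2e7,
      3e6, 1.2e7, 2.2e7, 4e7, 5.5e7,
      5e6, 1.8e7, 3.1e7, 4.7e7, 5.5e7,
      3e6, 1.3e7, 2.5e7, 4.2e7, 5.6e7,
      2e7, 5e7
    ) + 1,
    end = c(
      2.3e6, 9.25e6, 2.64e7, 3.82e7, 5.235e7,
      3.3e6, 1.22e7, 2.24e7, 4.03e7, 5.525e7,
      5.35e6, 1.83e7, 3.12e7, 4.74e7, 5.53e7,
      3.25e6, 1.34e7, 2.53e7, 4.22e7, 5.635e7,
      2.03e7, 5.025e7
    )
  )
  loci$freq <- rep(c(0.005, 0.01, 0.02, 0.03, 0.05), length.out = nrow(loci))
  loci$direction <- rep(c("gain", "loss"), length.out = nrow(loci))
  loci
}

#' Simulation configuration for a synthetic paired cohort
#'
#' Defaults describe the study design the pipeline targets: 82 donors (42
#' female) with one iPSC clone each, 1093 controls (568 female), a mean of 2
#' inherited and 2 background de novo CNVs per line, ten recurrent hotspot
#' loci at carrier fractions 0.06-0.45 (two on X, planted in female lines),
#' seven polymorphic regions at per-member presence 0.15 drawn independently
#' for parental and iPSC members (and at the same frequency in controls),
#' 22 control CNV loci at population frequencies 0.005-0.05, and ~25
#' isolated noise probes per track.
#'
#' With `carrier_mode = "fixed"` (default) each planted locus receives a
#' random carrier subset of exactly `round(prob * n_eligible)` samples, so
#' planted frequencies are exact and truth recovery measures pipeline
#' correctness; `"bernoulli"` draws carrier status per sample instead.
#'
#' @param seed integer seed; the cohort is a deterministic function of the
#'   full configuration.
#' @param genome tibble `chrom`, `length`, `spacing` (see
#'   [default_genome()]).
#' @param n_donors,n_female_donors,clones_per_donor study-cohort layout.
#' @param n_controls,n_female_controls control-cohort layout.
#' @param inherited_rate mean inherited CNVs per donor (Poisson).
#' @param inherited_length log-uniform length bounds (bp).
#' @param de_novo_rate mean background de novo CNVs per iPSC line (Poisson).
#' @param n_de_novo optional fixed total number of background de novo CNVs
#'   (overrides `de_novo_rate`; events are assigned to uniformly drawn
#'   lines).
#' @param de_novo_length log-uniform length bounds (bp).
#' @param hotspots planted hotspot loci: `chrom`, `start`, `end`,
#'   `carrier_prob`, `gain_frac`.
#' @param polymorphic planted polymorphic regions: `chrom`, `start`, `end`,
#'   `presence_prob`.
#' @param control_loci control CNV loci: `chrom`, `start`, `end`, `freq`,
#'   `direction`.
#' @param noise_per_track mean number of isolated noise runs per sample
#'   track (Poisson).
#' @param noise_run_max maximal noise run length in probes (must stay below
#'   10, the segmentation threshold).
#' @param carrier_mode `"fixed"` or `"bernoulli"` (see Details).
#' @param jitter_probes planted member boundaries are independently shifted
#'   by up to this many probes on each side, emulating breakpoint
#'   uncertainty (0 disables).
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       genome = default_genome(),
                       n_donors = 82L, n_female_donors = 42L,
                       clones_per_donor = 1L,
                       n_controls = 1093L, n_female_controls = 568L,
                       inherited_rate = 2, inherited_length = c(1.2e5, 2e6),
                       de_novo_rate = 2, n_de_novo = NULL,
                       de_novo_length = c(1.2e5, 1e6),
                       hotspots = default_hotspots(),
                       polymorphic = default_polymorphic(),
                       control_loci = default_control_loci(),
                       noise_per_track = 25, noise_run_max = 1L,
                       carrier_mode = c("fixed", "bernoulli"),
                       jitter_probes = 2L) {
  cfg <- list(
    seed = as.integer(seed), genome = as_tibble(genome),
    n_donors = as.integer(n_donors),
    n_female_donors = as.integer(n_female_donors),
    clones_per_donor = as.integer(clones_per_donor),
    n_controls = as.integer(n_controls),
    n_female_controls = as.integer(n_female_controls),
    inherited_rate = inherited_rate, inherited_length = inherited_length,
    de_novo_rate = de_novo_rate,
    n_de_novo = if (is.null(n_de_novo)) NULL else as.integer(n_de_novo),
    de_novo_length = de_novo_length,
    hotspots = as_tibble(hotspots), polymorphic = as_tibble(polymorphic),
    control_loci = as_tibble(control_loci),
    noise_per_track = noise_per_track,
    noise_run_max = as.integer(noise_run_max),
    carrier_mode = match.arg(carrier_mode),
    jitter_probes = as.integer(jitter_probes)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` object.
#' @export
validate_sim_config <- function(cfg) {
  g <- cfg$genome
  if (!all(c("chrom", "length", "spacing") %in% names(g))) {
    abort("genome must have columns chrom, length, spacing")
  }
  if (cfg$n_female_donors > cfg$n_donors || cfg$n_female_controls > cfg$n_controls) {
    abort("female counts cannot exceed cohort sizes")
  }
  if (cfg$noise_run_max >= 10L || cfg$noise_run_max < 1L) {
    abort("noise_run_max must be in 1..9 (noise must stay below the 10-probe run threshold)")
  }
  if (cfg$jitter_probes < 0L) abort("jitter_probes must be >= 0")
  spacing <- setNames(g$spacing, g$chrom)

  planted <- bind_rows(
    select(cfg$hotspots, "chrom", "start", "end"),
    select(cfg$polymorphic, "chrom", "start", "end"),
    select(cfg$control_loci, "chrom", "start", "end")
  )
  if (nrow(planted)) {
    if (!all(planted$chrom %in% g$chrom)) {
      abort("planted loci reference chromosomes absent from the genome")
    }
    s <- spacing[planted$chrom]
    n_probes <- floor((planted$end - 1) / s) - ceiling((planted$start - 1) / s) + 1
    len <- planted$end - planted$start + 1
    ok <- (n_probes - 2L * cfg$jitter_probes) >= 10 &
      (len - 2 * cfg$jitter_probes * s) > 1e5
    if (!all(ok)) {
      abort(paste0(
        "planted locus spans must contain >= 10 probes and exceed 100 kb ",
        "(after boundary jitter) at the configured spacing; offending span(s): ",
        paste(head(paste0(planted$chrom, ":", planted$start, "-", planted$end)[!ok], 3),
              collapse = ", ")
      ))
    }
    # planted loci of all categories must be mutually disjoint (with a
    # jitter-wide guard band) so the truth table stays unambiguous
    guard <- (2L * cfg$jitter_probes + 2L) * s
    expanded <- mutate(planted, start = .data$start - guard, end = .data$end + guard)
    gr <- intervals_to_gr(expanded)
    if (any(GenomicRanges::countOverlaps(gr) > 1L)) {
      abort("planted loci must not overlap (including a jitter guard band)")
    }
  }
  cfg
}

# internal: probe lattice for a simulated genome
build_probe_map <- function(genome) {
  per <- purrr::pmap_dfr(genome, function(chrom, length, spacing) {
    n <- ((length - 1) %/% spacing) + 1
    tibble(chrom = chrom, pos = as.integer((seq_len(n) - 1) * spacing + 1))
  })
  tibble(
    probe_id = sprintf("p%07d", seq_len(nrow(per))),
    chrom = per$chrom, pos = per$pos
  )
}

#' Generate a synthetic paired cohort with planted truth
#'
#' Produces a probe map, sparse per-probe copy-number calls for every
#' parental, iPSC and control sample, a sample manifest, and a truth table
#' of all planted events. Deterministic given the configuration (same
#' config, same seed: identical output). Inherited CNVs appear in both pair
#' members; hotspot events only in iPSC tracks (female lines only for X
#' loci); polymorphic-region presence is drawn independently for parental
#' and iPSC members and at matched frequency in controls; isolated noise
#' runs are shorter than the 10-probe calling threshold and never touch a
#' planted span.
#'
#' @param cfg a [sim_config()] object.
#' @return a list of class `"cnv_cohort"`: `probe_map`, `calls` (sparse
#'   tibble `sample_id, probe_id, state`), `manifest`, `truth` (planted
#'   events: `category`, `locus_id`, `sample_id`, `chrom`, `start`, `end`,
#'   `direction`, `n_probes`), `noise` (noise runs), `config`.
#' @export
generate_cohort <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(cfg$seed)
  g <- cfg$genome
  pm <- build_probe_map(g)
  nper <- setNames(
    vapply(g$chrom, function(ch) sum(pm$chrom == ch), integer(1)), g$chrom
  )
  off <- setNames(cumsum(c(0L, unname(nper)[-length(nper)])), g$chrom)
  spac <- setNames(g$spacing, g$chrom)
  glen <- setNames(g$length, g$chrom)
  jit <- cfg$jitter_probes

  ## ---- manifest -------------------------------------------------------
  donor_id <- sprintf("D%03d", seq_len(cfg$n_donors))
  donor_sex <- sample(c(
    rep("female", cfg$n_female_donors),
    rep("male", cfg$n_donors - cfg$n_female_donors)
  ))
  parental <- tibble(
    sample_id = paste0(donor_id, "_P"), donor_id = donor_id,
    role = "parental", sex = donor_sex
  )
  lines <- tidyr::crossing(
    tibble(donor_id = donor_id, sex = donor_sex),
    clone = seq_len(cfg$clones_per_donor)
  ) %>%
    mutate(
      sample_id = sprintf("%s_S%d", .data$donor_id, .data$clone),
      role = "ipsc"
    ) %>%
    select("sample_id", "donor_id", "role", "sex")
  controls <- tibble(
    sample_id = sprintf("C%04d", seq_len(cfg$n_controls)),
    donor_id = sprintf("CD%04d", seq_len(cfg$n_controls)),
    role = "control",
    sex = sample(c(
      rep("female", cfg$n_female_controls),
      rep("male", cfg$n_controls - cfg$n_female_controls)
    ))
  )
  manifest <- bind_rows(parental, lines, controls)
  sex_of <- setNames(manifest$sex, manifest$sample_id)
  donor_of_line <- setNames(lines$donor_id, lines$sample_id)

  snap1 <- function(chrom, start, end) {
    s <- spac[[chrom]]
    i1 <- max(1L, as.integer(ceiling((start - 1) / s)) + 1L)
    i2 <- min(nper[[chrom]], as.integer(floor((end - 1) / s)) + 1L)
    c(i1, i2)
  }
  jitter_draw <- function(n) {
    if (jit == 0L) rep(0L, n) else sample.int(2L * jit + 1L, n, replace = TRUE) - jit - 1L
  }

  events <- list()
  add_events <- function(category, locus_id, sample_ids, chrom, i1, i2, direction) {
    n <- length(sample_ids)
    if (n == 0L) return(invisible(NULL))
    d1 <- jitter_draw(n); d2 <- jitter_draw(n)
    j1 <- pmax(1L, i1 + d1)
    j2 <- pmin(nper[[chrom]], i2 + d2)
    events[[length(events) + 1L]] <<- tibble(
      category = category, locus_id = locus_id, sample_id = sample_ids,
      chrom = chrom, i1 = j1, i2 = j2, direction = direction
    )
    invisible(NULL)
  }
  draw_carriers <- function(eligible, prob) {
    if (length(eligible) == 0L || prob <= 0) return(character(0))
    if (cfg$carrier_mode == "fixed") {
      k <- round(prob * length(eligible))
      if (k == 0L) return(character(0))
      sample(eligible, k)
    } else {
      eligible[rbinom(length(eligible), 1L, prob) == 1L]
    }
  }
  eligible_by_sex <- function(pool_ids, chrom) {
    cls <- chrom_class(chrom)
    if (cls == "X") {
      pool_ids[sex_of[pool_ids] == "female"]
    } else if (cls == "Y") {
      pool_ids[sex_of[pool_ids] == "male"]
    } else {
      pool_ids
    }
  }

  ## ---- planted loci ---------------------------------------------------
  hs <- cfg$hotspots
  for (i in seq_len(nrow(hs))) {
    ii <- snap1(hs$chrom[i], hs$start[i], hs$end[i])
    carriers <- draw_carriers(eligible_by_sex(lines$sample_id, hs$chrom[i]), hs$carrier_prob[i])
    dirn <- ifelse(runif(length(carriers)) < hs$gain_frac[i], "gain", "loss")
    add_events("hotspot_member", sprintf("H%02d", i), carriers, hs$chrom[i], ii[1], ii[2], dirn)
  }
  po <- cfg$polymorphic
  for (i in seq_len(nrow(po))) {
    ii <- snap1(po$chrom[i], po$start[i], po$end[i])
    id <- sprintf("P%02d", i)
    par_c <- draw_carriers(eligible_by_sex(parental$sample_id, po$chrom[i]), po$presence_prob[i])
    ips_c <- draw_carriers(eligible_by_sex(lines$sample_id, po$chrom[i]), po$presence_prob[i])
    ctl_c <- draw_carriers(eligible_by_sex(controls$sample_id, po$chrom[i]), po$presence_prob[i])
    add_events("polymorphic_member", id, par_c, po$chrom[i], ii[1], ii[2],
               sample(c("gain", "loss"), length(par_c), replace = TRUE))
    add_events("polymorphic_member", id, ips_c, po$chrom[i], ii[1], ii[2],
               sample(c("gain", "loss"), length(ips_c), replace = TRUE))
    add_events("control", id, ctl_c, po$chrom[i], ii[1], ii[2],
               sample(c("gain", "loss"), length(ctl_c), replace = TRUE))
  }
  cl <- cfg$control_loci
  for (i in seq_len(nrow(cl))) {
    ii <- snap1(cl$chrom[i], cl$start[i], cl$end[i])
    carriers <- draw_carriers(eligible_by_sex(controls$sample_id, cl$chrom[i]), cl$freq[i])
    add_events("control", sprintf("C%02d", i), carriers, cl$chrom[i], ii[1], ii[2], cl$direction[i])
  }

  ## ---- random events (inherited, background de novo) ------------------
  planted_spans <- bind_rows(
    select(hs, "chrom", "start", "end"),
    select(po, "chrom", "start", "end"),
    select(cl, "chrom", "start", "end")
  )
  guard <- (jit + 1L)
  forbid_global <- planted_spans %>%
    mutate(
      start = .data$start - guard * spac[.data$chrom],
      end = .data$end + guard * spac[.data$chrom]
    )
  occupied <- forbid_global # grows as random events are placed

  place_random <- function(len_bounds, extra_forbid, sex = NULL) {
    for (try in seq_len(200L)) {
      ci <- sample.int(nrow(g), 1L, prob = g$length)
      chrom <- g$chrom[ci]
      if (!is.null(sex) && chrom_class(chrom) == "Y" && sex == "female") next
      len <- exp(runif(1, log(len_bounds[1]), log(len_bounds[2])))
      if (len >= glen[[chrom]] - 2 * spac[[chrom]]) next
      start <- floor(runif(1, 1, glen[[chrom]] - len))
      end <- start + len - 1
      busy <- bind_rows(occupied, extra_forbid)
      clash <- any(
        busy$chrom == chrom & busy$start <= end + guard * spac[[chrom]] &
          busy$end >= start - guard * spac[[chrom]]
      )
      if (clash) next
      ii <- snap1(chrom, start, end)
      if (ii[2] - ii[1] + 1L < 10L) next
      return(list(chrom = chrom, i1 = ii[1], i2 = ii[2]))
    }
    abort("failed to place a random event after 200 attempts; genome too crowded")
  }

  # inherited: appear in the parental sample and every clone of the donor
  n_inh <- rpois(cfg$n_donors, cfg$inherited_rate)
  for (d in seq_len(cfg$n_donors)) {
    if (n_inh[d] == 0L) next
    donor_tracks <- c(
      parental$sample_id[d],
      lines$sample_id[lines$donor_id == donor_id[d]]
    )
    donor_spans <- empty_span_tbl()
    for (k in seq_len(n_inh[d])) {
      ev <- place_random(cfg$inherited_length, donor_spans, sex = donor_sex[d])
      s_pos <- (ev$i1 - 1L) * spac[[ev$chrom]] + 1
      e_pos <- (ev$i2 - 1L) * spac[[ev$chrom]] + 1
      donor_spans <- bind_rows(donor_spans, tibble(chrom = ev$chrom, start = s_pos, end = e_pos))
      dirn <- sample(c("gain", "loss"), 1L)
      # identical span in every member of the pair (no jitter within a donor:
      # inherited calls arise from the same germline breakpoints)
      events[[length(events) + 1L]] <- tibble(
        category = "inherited", locus_id = NA_character_,
        sample_id = donor_tracks, chrom = ev$chrom,
        i1 = ev$i1, i2 = ev$i2, direction = dirn
      )
    }
    occupied <- bind_rows(occupied, donor_spans)
  }

  # background de novo: iPSC lines only, low frequency
  if (!is.null(cfg$n_de_novo)) {
    bg_lines <- sample(lines$sample_id, cfg$n_de_novo, replace = TRUE)
  } else {
    n_bg <- rpois(nrow(lines), cfg$de_novo_rate)
    bg_lines <- rep(lines$sample_id, n_bg)
  }
  line_spans <- list()
  for (sid in bg_lines) {
    extra <- line_spans[[sid]] %||% empty_span_tbl()
    ev <- place_random(cfg$de_novo_length, extra, sex = sex_of[[sid]])
    s_pos <- (ev$i1 - 1L) * spac[[ev$chrom]] + 1
    e_pos <- (ev$i2 - 1L) * spac[[ev$chrom]] + 1
    line_spans[[sid]] <- bind_rows(extra, tibble(chrom = ev$chrom, start = s_pos, end = e_pos))
    occupied <- bind_rows(occupied, tibble(chrom = ev$chrom, start = s_pos, end = e_pos))
    dirn <- sample(c("gain", "loss"), 1L)
    events[[length(events) + 1L]] <- tibble(
      category = "de_novo", locus_id = NA_character_, sample_id = sid,
      chrom = ev$chrom, i1 = ev$i1, i2 = ev$i2, direction = dirn
    )
  }

  ev <- bind_rows(events)
  # drop any X/Y events that ended up in male tracks for sex-restricted
  # planting (eligibility already enforces this; belt and braces)
  if (nrow(ev)) {
    ev$start <- mapply(function(ch, i) (i - 1L) * spac[[ch]] + 1, ev$chrom, ev$i1)
    ev$end <- mapply(function(ch, i) (i - 1L) * spac[[ch]] + 1, ev$chrom, ev$i2)
    ev$n_probes <- ev$i2 - ev$i1 + 1L
  } else {
    ev <- tibble(
      category = character(), locus_id = character(), sample_id = character(),
      chrom = character(), i1 = integer(), i2 = integer(),
      direction = character(), start = numeric(), end = numeric(),
      n_probes = integer()
    )
  }

  ## ---- noise ----------------------------------------------------------
  all_samples <- manifest$sample_id
  n_noise <- rpois(length(all_samples), cfg$noise_per_track)
  noise_rows <- vector("list", length(all_samples))
  for (t in seq_along(all_samples)) {
    if (n_noise[t] == 0L) next
    sid <- all_samples[t]
    track_ev <- ev[ev$sample_id == sid, , drop = FALSE]
    # forbid: inside or adjacent to an event span, or female-Y territory
    acc_i1 <- integer(0); acc_i2 <- integer(0); acc_ch <- character(0)
    want <- n_noise[t]
    cand_g <- sample.int(nrow(pm), max(10L, want * 4L), replace = TRUE)
    cand_len <- sample.int(cfg$noise_run_max, length(cand_g), replace = TRUE)
    for (j in seq_along(cand_g)) {
      if (length(acc_i1) >= want) break
      ch <- pm$chrom[cand_g[j]]
      if (chrom_class(ch) == "Y" && sex_of[[sid]] == "female") next
      i1 <- cand_g[j] - off[[ch]]
      i2 <- i1 + cand_len[j] - 1L
      if (i2 > nper[[ch]]) next
      clash_ev <- any(track_ev$chrom == ch & track_ev$i1 <= i2 + 1L & track_ev$i2 >= i1 - 1L)
      if (clash_ev) next
      clash_acc <- any(acc_ch == ch & acc_i1 <= i2 + 1L & acc_i2 >= i1 - 1L)
      if (clash_acc) next
      acc_ch <- c(acc_ch, ch); acc_i1 <- c(acc_i1, i1); acc_i2 <- c(acc_i2, i2)
    }
    if (length(acc_i1)) {
      noise_rows[[t]] <- tibble(
        sample_id = sid, chrom = acc_ch, i1 = acc_i1, i2 = acc_i2,
        direction = sample(c("gain", "loss"), length(acc_i1), replace = TRUE)
      )
    }
  }
  noise <- bind_rows(noise_rows)
  if (nrow(noise)) {
    noise$start <- mapply(function(ch, i) (i - 1L) * spac[[ch]] + 1, noise$chrom, noise$i1)
    noise$end <- mapply(function(ch, i) (i - 1L) * spac[[ch]] + 1, noise$chrom, noise$i2)
    noise$n_probes <- noise$i2 - noise$i1 + 1L
  } else {
    noise <- tibble(
      sample_id = character(), chrom = character(), i1 = integer(),
      i2 = integer(), direction = character(), start = numeric(),
      end = numeric(), n_probes = integer()
    )
  }

  ## ---- emit sparse calls ---------------------------------------------
  emit <- bind_rows(
    select(ev, "sample_id", "chrom", "i1", "i2", "direction"),
    select(noise, "sample_id", "chrom", "i1", "i2", "direction")
  )
  if (nrow(emit)) {
    np <- emit$i2 - emit$i1 + 1L
    gidx <- sequence(np, from = emit$i1 + off[emit$chrom])
    sid <- rep(emit$sample_id, np)
    dirn <- rep(ifelse(emit$direction == "gain", 1L, -1L), np)
    base <- baseline_state(pm$chrom[gidx], sex_of[sid])
    # gains occasionally reach two extra copies: same-direction runs may mix
    # states (direction, not exact state, defines run homogeneity)
    mag <- sample.int(2L, length(gidx), replace = TRUE, prob = c(0.85, 0.15))
    mag <- ifelse(dirn < 0L, pmin(mag, base), mag)
    calls <- tibble(
      sample_id = sid,
      probe_id = pm$probe_id[gidx],
      state = as.integer(base + dirn * mag)
    )
  } else {
    calls <- tibble(sample_id = character(), probe_id = character(), state = integer())
  }

  truth <- ev %>%
    select("category", "locus_id", "sample_id", "chrom", "start", "end",
           "direction", "n_probes") %>%
    arrange(.data$category, .data$chrom, .data$start, .data$sample_id)

  out <- list(
    probe_map = pm, calls = calls, manifest = manifest, truth = truth,
    noise = select(noise, "sample_id", "chrom", "start", "end", "direction", "n_probes"),
    config = cfg
  )
  class(out) <- "cnv_cohort"
  out
}

empty_span_tbl <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric())
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic CNV cohort: %d probes, %d samples (%d parental, %d iPSC, %d control), %d planted events\n",
    nrow(x$probe_map), nrow(x$manifest),
    sum(x$manifest$role == "parental"), sum(x$manifest$role == "ipsc"),
    sum(x$manifest$role == "control"), nrow(x$truth)
  ))
  invisible(x)
}

#' Write a cohort's files to a directory
#'
#' Emits `probe_map.tsv`, `manifest.tsv`, sparse `calls.tsv`
#' (`sample_id probe_id state`; probes absent from the file are at the
#' sex-appropriate baseline) and `truth.tsv`.
#'
#' @param cohort a `cnv_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_probe_map(cohort$probe_map, file.path(dir, "probe_map.tsv"))
  write_manifest(cohort$manifest, file.path(dir, "manifest.tsv"))
  readr::write_tsv(cohort$calls, file.path(dir, "calls.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
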