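---
title: "Calling reprogramming-associated CNV hotspots from probe-level array states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling reprogramming-associated CNV hotspots from probe-level array states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipscnv)
library(dplyr)
```

## The problem and the model

Reprogramming somatic cells to induced pluripotent stem cells (iPSCs) can
introduce de novo copy-number variants (CNVs), and certain genomic regions
acquire them recurrently across independent lines. Distinguishing such
*reprogramming-associated hotspots* from ordinary copy-number polymorphism
requires three comparisons at once: each iPSC line against its own parental
cells (to remove inherited variation), lines against each other (to find
recurrence), and the study cohort against a large population control panel
(to remove common polymorphism). `ipscnv` implements that screen from the
point where array processing ends: per-probe integer copy-number states.

The underlying model is deliberately non-parametric. A CNV is evidenced by
a *probe run*: consecutive probes, in genomic order, whose states all lie
strictly on one side of the sex-appropriate baseline. No intensity model,
no HMM — the upstream genotyping software has already reduced the data to
integer states, and the run rule turns isolated state-calling errors into
no-ops (a single discordant probe can never produce a ≥10-probe run). The
statistical model enters only at the cohort level, where carrier counts in
a 2×2 table are compared with the likelihood-ratio chi-square (G) test,

$$G = 2\sum_{ij} O_{ij}\,\ln(O_{ij}/E_{ij}), \qquad
p = P(\chi^2_{1} \ge G),$$

with expected counts from the table margins and the convention
$0\ln 0 = 0$. Under independence and moderate counts $G$ is asymptotically
$\chi^2_1$; the suite checks agreement with Pearson's statistic when all
expected counts exceed 5.

## Pipeline stages and their assumptions

1. **Probe masking.** Exclusion BEDs (centromeres, antibody variable
   regions, T-cell receptor loci, pseudoautosomal regions, the
   X-transposed region) are applied to the probe map *before*
   segmentation, so excluded territory can neither seed nor bridge a run.
   Masking first is the stricter reading; the alternative (clipping
   segments afterwards) could let two sub-threshold runs join across an
   excluded gap.
2. **Segmentation** (`segment_calls()`): maximal runs of
   `min_probes = 10` same-direction probes. Direction, not exact state,
   defines homogeneity: states 3 and 4 may share one gain run, since both
   deviate upward. Both a baseline probe and an opposite-direction probe
   terminate a run — the strictest deterministic reading; no gap tolerance.
   Baselines are 2 on autosomes, 2/1 (female/male) on X, 1 on male Y;
   female Y probes are excluded outright. Segment coordinates are the
   first/last probe positions, 1-based inclusive, and all files use that
   convention (BED input is converted from 0-based half-open on read).
3. **Length filter**: strictly greater than `min_length = 100000` bp — a
   segment of exactly 100 kb is dropped.
4. **Inherited subtraction** (`subtract_inherited()`): an iPSC segment is
   removed when a *single* parental segment (either direction) covers more
   than `inherited_frac = 0.5` of the iPSC segment's length. The
   comparison is one-way and per-segment, not against the union of
   parental calls: a union rule could delete a large iPSC segment that is
   only patchily covered by several small parental variants, which is
   evidence of a different event, not inheritance. Direction-agnostic,
   because a locus that is copy-number unstable in the donor should not be
   credited to reprogramming regardless of sign.
5. **Locus merging** (`merge_loci()`): single-linkage clustering under
   reciprocal overlap ≥ `merge_reciprocal = 0.10`. Single linkage is the
   natural closure of a pairwise "same locus" relation and is
   order-independent, hence deterministic. Locus coordinates are the span
   (min start, max end) of members. On X and Y, loci are built within sex
   strata, because frequencies there are only comparable within sex. One
   sample contributes at most one carrier per locus and direction, however
   many member segments it has.
6. **Control screen** (`filter_vs_controls()`): a locus is kept when the
   union of control-cohort segments covers strictly less than
   `control_cov = 0.10` of its bases. This positional screen is
   frequency-agnostic and distinct from the later carrier-frequency
   condition: it asks "is this territory copy-number polymorphic at all?",
   not "how many controls carry this exact event?".
7. **Hotspot classification** (`call_hotspots()`): iPSC carrier frequency
   > `hotspot_freq = 0.05`, control carrier frequency <
   `control_freq = 0.002`, G-test `p ≤ alpha / m` with `alpha = 0.05` and
   `m` = the number of loci actually tested in the run, and zero carriers
   among paired parental samples. `m` is recomputed each run rather than
   hard-coded, and logged (`summary$bonferroni_m`); a fixed historical
   threshold would silently miscalibrate on any other locus count. The
   2×2 test pools gains and losses into one carrier state — recurrence of
   *any* rearrangement at the locus is the signal; a per-direction 2×3
   variant is available (`test = "by_direction"`). Control and parental
   carriers of a locus are counted by the same ≥10% reciprocal-overlap
   membership rule used for merging.
8. **Polymorphic regions** (`find_polymorphic()`): built from the *pooled,
   pre-subtraction* parental + iPSC segments; a region qualifies when its
   study frequency exceeds `polymorphic_freq = 0.05` (denominator: all
   parental + all iPSC samples), the G-test against controls gives
   `p > 0.05` (common in the population), and the region is present in the
   parental sample XOR in ≥1 iPSC line of the same donor for strictly more
   than `polymorphic_min_subjects = 10` donors. The per-sample (not
   per-donor) frequency denominator keeps the carrier unit identical to
   the hotspot analysis.
9. **Burden** (`burden_test()`): paired t on per-line post-filter CNV
   counts, each line paired with its donor's parental count (the parental
   count is reused across clones of one donor, keeping the line as the
   experimental unit). Degenerate inputs have fixed conventions: all
   differences zero → `t = 0, p = 1`; zero variance with nonzero mean →
   `p = 0` with a `degenerate` flag rather than an error, so pipelines
   never crash on pathological fixtures.

All thresholds live in `cnv_params()` with the defaults above and are
echoed verbatim into the JSON run summary, making every run
self-describing. The pipeline is a pure function of (inputs, parameters):
repeated runs are byte-identical.

## The synthetic cohort generator

No array data accompany the method, so `generate_cohort()` provides
cohorts with known ground truth. The default configuration mirrors the
study design the pipeline targets:

* a miniature genome of four 60-Mb autosomes plus a 60-Mb X at 2-kb probe
  spacing (~150,000 probes) — array-like probe density at a size where a
  full cohort simulates in seconds;
* 82 donors (42 female) with one iPSC clone each, and 1093 controls
  (568 female, 525 male);
* inherited CNVs (mean 2 per donor, log-uniform 120 kb–2 Mb) present
  identically in both pair members;
* background de novo CNVs in iPSC lines only (mean 2 per line by default,
  or a fixed planted total via `n_de_novo`, consistent with a cohort of
  roughly 170–200 qualifying iPSC-specific loci);
* ten hotspot loci (two on X, planted in female lines) at carrier
  fractions 0.06–0.45, gain-dominated;
* seven polymorphic regions at per-member presence 0.15, drawn
  *independently* for parental and iPSC members and planted at the same
  frequency in controls — so they are frequent, population-common, and
  rearranging, exactly the profile the polymorphic screen looks for;
* 22 control CNV loci at population frequencies 0.005–0.05;
* isolated probe noise (mean 25 runs per track, run length < 10) that by
  construction can never produce a qualifying segment.

Planted spans snap to probe positions and member boundaries are jittered
by up to 2 probes per side, so recovered segments match truth up to
breakpoint uncertainty while remaining above every threshold. Events of
different categories never overlap (rejection sampling with a jitter-wide
guard band), keeping the truth table unambiguous.

**Carrier drawing.** With `carrier_mode = "fixed"` (default) each planted
locus receives a random carrier subset of exactly `round(p · n_eligible)`
samples; `"bernoulli"` draws per-sample indicators instead. The fixed mode
is the right default for a *planted-truth* generator: it makes the planted
frequency exact, so truth recovery measures pipeline correctness rather
than binomial sampling luck. With Bernoulli draws, a locus planted at
carrier probability 0.06 in 82 lines would fall below the 5% frequency
gate in almost half of cohorts — a property of the binomial, not of the
pipeline — and equally the "common in controls" comparison for polymorphic
regions would fail its `p > 0.05` gate in ~5% of region draws even at
perfectly matched frequencies. Fixed-count planting removes exactly that
nuisance randomness while leaving *which* samples carry each event, event
directions, boundary jitter, background placement and noise fully random.

What the generator does **not** emulate: raw intensities and B-allele
frequencies, state-calling error structure correlated along the genome,
mosaicism, probe-density inhomogeneity, and linkage between nearby CNVs.
Passing recovery tests therefore demonstrates the correctness of the
calling logic under clean state calls, not robustness to upstream
genotyping artefacts.

## Numerical and degenerate-input choices

* Strict inequalities follow the rule definitions: length `> 100 kb`,
  frequency `> 5%`, control rarity `< 0.2%`, control coverage `< 10%`,
  mutually exclusive donors `> 10`; membership and merging use `≥ 10%`
  reciprocal overlap. The suite exercises both sides of every boundary.
* A 2×2 table with an all-zero row or column margin returns `G = 0, p = 1`
  (no evidence either way), never an error.
* Adjacent intervals share no bases under 1-based inclusive coordinates:
  reciprocal overlap of `[1,100]` and `[101,200]` is 0.
* Empty inputs propagate as empty tibbles with correct columns; an empty
  post-filter CNV set yields a successful zero-locus run summary.
* p-values are kept at full precision internally; the report writer prints
  values below 1e-4 as `<0.0001`.

## Problem sizes used by the test suite

The suite validates the segmentation against a brute-force run enumerator
on 100 random tracks of up to 10,000 probes; locus merging against a
union-find oracle over the exhaustive pairwise overlap matrix; the control
screen against a per-base occupancy scan; and the G test against an
independent evaluation with the tail probability obtained by numerical
integration of the chi-square density. Full-scale recovery uses 20
simulated cohorts at the default study geometry (82 paired lines, 1093
controls, ~150k probes, 200 planted background CNVs), requiring exact
recovery of all planted hotspot and polymorphic regions with no false
positives in at least 19/20 and 18/20 cohorts respectively. These sizes
were chosen so the whole suite runs comfortably on a laptop while the
cohort-scale checks still operate at the full sample geometry of the
design.

## Known limitations

* The method inherits the resolution limits of probe-run calling: events
  smaller than 10 probe spacings or 100 kb are invisible by definition,
  balanced rearrangements are invisible in principle, and low-level
  mosaicism is below the integer-state representation.
* The G-test is asymptotic; at very small carrier counts its p-values are
  approximate (the hotspot gates make this mostly moot, since a locus must
  have ≥5% iPSC carriers to qualify).
* Bonferroni over the tested loci is conservative when loci are correlated
  (e.g. overlapping strata).
* The polymorphic-region XOR criterion treats a donor's clones
  collectively ("any clone carries"); with many clones per donor this is a
  permissive reading.
* Cytoband annotation is not computed; the report echoes band labels only
  when supplied externally. Gene annotation is a plain interval join, not
  a functional-enrichment analysis.
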