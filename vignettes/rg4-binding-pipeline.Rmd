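---
title: "Methods: RG4 prediction, CLIP enrichment and RP-MS differential binding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: RG4 prediction, CLIP enrichment and RP-MS differential binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rg4tools)
```

# Scope and model

RNA G-quadruplexes (RG4s) are four-stranded structures formed by stacked
G-quartets in G-rich RNA. Work on the proteins that recognize these
elements typically combines three computational stages, all implemented
here:

1. **RG4 motif prediction** — a QGRS-style scanner locating windows with
   four equal-length G-runs (tetrad number *g* ≥ 2) separated by three
   loops, scored and thresholded, on annotated transcripts
   (5′UTR/CDS/3′UTR).
2. **CLIP-site enrichment** — testing whether protein binding sites from
   CLIP-seq overlap predicted RG4s more often than random sites of
   matched length, with Fisher's exact test, densities per Mb and
   bound-fraction summaries.
3. **RP-MS differential binding** — label-free quantification of
   proteins affinity-purified with a folded quadruplex bait (WT) versus
   its 7-deaza-guanine unfolded version (7dG): filtering, log2,
   missing-not-at-random (MNAR) imputation, a paired sign-flip
   permutation FDR test, and classification into RG4-BPs (ratio
   WT/7dG ≥ 1.5 at q ≤ 0.05) and G-rich-BPs (ratio ≤ 1/1.5).

Closed-form assay quantifications (ddCt expression, RIP enrichment,
polysome translational efficiency, reporter ratios, clonogenic survival)
round out the toolbox, and synthetic-data generators provide every input
with known ground truth so each stage is testable offline.

# RG4 scanner

`enumerate_qgrs()` emits, for every distinct window of at most
`max_qgrs_length` (default 30) nt, the maximal-*g* decomposition into
four G-runs with loops in `[loop_min, loop_max]` (defaults 0–36).
`select_hits()` drops candidates below the score threshold (default 19)
and resolves overlaps greedily by score, with ties broken by smaller
start and shorter span — the behaviour users of non-overlapping QGRS
reports expect.

**Scoring.** The G-score rewards more tetrads, shorter loops and even
loops. Because the published scoring constants of the original tool are
not fully pinned down, the package uses an explicit surrogate with the
same behavioural contract:

$$\mathrm{score} = 20\,(g-2) + \tfrac12\,(L_{max} - 4g - \textstyle\sum_i l_i) - (\max_i l_i - \min_i l_i)$$

which is strictly increasing in \(g\), non-increasing in total loop
length, maximal for even loops, and places the canonical
`GGGAAGGGAAGGGAAGGG` motif (g = 3, loops 2/2/2) at score 26, above the
threshold of 19. The scorer identity is recorded in every catalog
(`scorer` field) so results remain attributable if the scoring is ever
swapped.

**Conventions.** Coordinates are 0-based half-open (BED-compatible);
U/T are equivalent and case is ignored; `N` never counts as G; only the
sense strand is scanned (RG4s are a property of the transcript itself);
hits straddling a region boundary are assigned by their start position —
a deterministic rule where no convention is established.

# Synthetic transcriptome

`simulate_transcriptome()` plants exact quadruplex motifs into i.i.d.
background sequence. Defaults emulate a compact mRNA transcriptome:
5′UTR ≈ 200 nt, CDS ≈ 1.2 kb (forced to a multiple of 3), 3′UTR ≈
800 nt, 45% GC, and roughly one motif per kb of UTR versus 0.3/kb of
CDS, reflecting the untranslated-region skew of quadruplex motifs in
real transcriptomes.

The generator makes the planted truth table *provably exact* rather than
merely likely: every background G-run at least as long as the planted
run length is broken during generation, planted motifs keep at least one
scanning window (30 nt) of separation, sit fully inside their region,
and receive non-G flanks so their G-runs stay maximal. Consequently the
only candidates with the planted tetrad number are the planted motifs
themselves, and shorter-tetrad background candidates (g = 2 scores at
most 11) cannot pass the threshold. The planting-recovery tests
therefore expect 100% sensitivity, not an approximation. The price is a
slight depletion of long G-runs in the background relative to a truly
i.i.d. sequence — acceptable for a ground-truth benchmark, but worth
remembering when extrapolating to real transcriptomes, which also
contain imperfect, bulged or two-tetrad motifs this generator does not
model. When a Poisson draw asks for more motifs than a region can host
at the required spacing the count is capped at capacity; a region that
cannot host even one motif while its rate is positive is rejected with a
diagnostic.

# Synthetic CLIP sites and enrichment statistics

`simulate_clip_sites()` draws site lengths from a normal distribution
(default 40 ± 10 nt, the scale of called CLIP peaks) and places each
site by weighted sampling over valid start positions: starts whose
interval would overlap a planted motif carry weight
`g4_enrichment_factor`, all others weight 1. A factor of 1 is exactly
uniform placement; 0 forbids overlap entirely. Because sites are
intervals, the uniform-case overlap probability is the *eligible-start
fraction* (a site of length \(L\) overlaps a motif \([s,e)\) from any
start in \([s-L+1, e)\)), not the nucleotide coverage of the motifs —
the tests check the former, which is the exact quantity.

`clip_enrichment()` reproduces the enrichment recipe: observed sites are
annotated to regions by start position and extended by ±25 nt;
background sites are drawn uniformly at the rounded mean *raw* site
length (10,000 by default), region-stratified so that, e.g., the 3′UTR
contrast only competes against 3′UTR sequence space — isolating RG4
enrichment from regional base-composition differences. An unstratified
`"all"` contrast is included. Both observed and background sites are
extended by the same flank before overlap: extending only the observed
sites would make them systematically longer than the background and
bias the null, a mismatch the calibration tests would catch
immediately.

Fisher's exact two-sided p is computed in-package as the exhaustive
hypergeometric tail sum (probabilities at most that of the observed
table, with the conventional \(1+10^{-7}\) tie tolerance); the test
suite verifies it against `stats::fisher.test()` and an independent
binomial-coefficient enumeration to \(10^{-10}\). The odds ratio is the
sample OR \(ad/bc\) with the Haldane–Anscombe 0.5 correction (flagged)
when a cell is zero. Densities per Mb divide the number of overlapped
RG4s by the *merged* length of the site set so overlapping sites are not
double-counted. Overlaps are same-strand only and require at least
`min_overlap` (default 1) shared nt.

**Calibration problem sizes.** The null-calibration property (uniform
p-values at enrichment factor 1) is checked on the unstratified contrast
with 400 sites against 4,000 background sites over a 40-transcript
genome, 200 independent draws; per-region tables at this scale are too
discrete for a meaningful Kolmogorov–Smirnov comparison, while the
combined contrast has wide hypergeometric support. Power is checked at
factor 8 with 500 sites, where the test should — and does — reject at
p < 0.01 in at least 95% of runs.

# Synthetic LFQ and the differential-binding test

`simulate_lfq()` builds a paired pull-down design: four biological
replicate pairs by default, per-protein log2 baselines N(27, 2) on the
MaxQuant LFQ scale, a per-protein per-pair batch shift N(0, 0.25) shared
by the WT and 7dG members of a pair (making the paired analysis
genuinely better than an unpaired one), residual noise N(0, 0.3) — a
replicate CV around 20%, typical of label-free protein quantification —
and a signed condition effect (+1.5 log2, on 10% of proteins by
default). Dropout acts on the raw intensity scale with logistic
probability `plogis(slope * (midpoint - x))` (defaults midpoint 24,
slope 1), so low-abundance measurements vanish preferentially — the MNAR
structure the imputation stage exists to handle. At slope 0 the rule
degenerates to constant 0.5 dropout (MCAR). Contaminant and
reverse-decoy rows are appended and flagged.

The analysis follows the standard Perseus-style chain:

* **Filtering** removes flagged rows and keeps proteins with ≥ 3 valid
  values in *at least one* condition — the one-sided rule, because a
  protein fully absent under one bait is exactly the interesting case
  and imputation is designed to support it; a strict both-conditions
  mode is a switch.
* **Imputation** draws each missing value from
  N(m − 1.8·s, (0.3·s)²) per sample column, m and s from that column's
  observed values — the classic downshifted-Gaussian "lowest range of
  intensities" imputation.
* **Testing** uses paired differences and sign-flip permutations,
  exhaustive (2ⁿ patterns) up to 12 pairs. Two patterns — the identity
  and its global negation — reproduce the observed statistics exactly;
  keeping them would floor the estimated FDR at 2/2ⁿ (0.125 at n = 4)
  and make q ≤ 0.05 unreachable, so they are excluded from the null.
  The per-protein permutation p-value over *all* patterns is reported
  alongside (its minimum, 2/16 at n = 4, is a property the tests pin).
  FDR(θ) is the mean null exceedance count per pattern divided by the
  observed count; q-values are the running minimum over weaker
  thresholds, monotone in rank, capped at 1.
* **The s0 offset.** With three degrees of freedom the plain paired t
  has heavy null tails driven by proteins whose difference variance is
  small by chance, and no realistic effect size separates from that
  tail at FDR 0.05. This is precisely the failure mode the SAM fudge
  factor addresses, so the default is `s0 = "auto"`: the median
  per-protein standard error of the paired differences, a scale-free
  choice computed from the data rather than a tuned constant. `s0 = 0`
  (the plain t) and any fixed value remain available. With s0 = 0,
  zero-variance nonzero differences receive infinite |t|, are ranked
  top and flagged.
* **Classification**: background-listed proteins first, then RG4-BP
  (q ≤ 0.05, ratio ≥ 1.5), G-rich-BP (q ≤ 0.05, ratio ≤ 1/1.5),
  otherwise unclassified. The WT/7dG ratio uses post-imputation means
  (the imputation exists precisely to make ratios with one-sided
  missingness well defined); the observed-only ratio is kept as a
  diagnostic column.

Under the generator's defaults the pipeline recovers planted
WT-preferring binders with sensitivity well above 0.7 at empirical
false-discovery proportion below 0.1, and flags essentially nothing on
all-null data (both properties are part of the test suite, at 10 and 20
seeds respectively, 1,000 proteins each).

# Assay quantifications

All assay formulas are closed-form and scale-invariant:

* ddCt expression: ΔΔCT = (Ct_target − Ct_ref)_treated −
  (Ct_target − Ct_ref)_control, fold = 2^(−ΔΔCT). The Livak sign
  convention is the default because a lower Ct means more template; the
  literal positive-sign form, which inverts fold directions, is
  available via `literal_sign = TRUE` for comparison with reports that
  print it.
* RIP enrichment: E = eff^(Ct_IgG − Ct_IP) per gene (input cancels),
  normalized to a reference gene; amplification efficiency is
  configurable (default 2, i.e. 100%).
* Translational efficiency: TE = HP/(NP + LP + HP) from pooled
  polysome fractions, plus condition/control ratios.
* Reporter ratio: Rluc/Fluc, optionally normalized to a control pair.
* Clonogenic survival: PE(%) = colonies/plated × 100; survival
  fraction = PE_treated/PE_control.

`simulate_assays()` constructs fixtures by inverting these formulas, so
round-trip recovery is exact to 1e-9 — the property the tests assert.

# Numerical and reproducibility notes

* Every generator and every stochastic stage takes an explicit seed and
  runs on a private RNG stream, restoring the session's `.Random.seed`;
  identical config + seed gives bit-identical output, including
  byte-identical FASTA files.
* Ties in hit selection are resolved deterministically (score, then
  start, then span); candidate deduplication prefers larger tetrad
  number, then score, then lexicographic loops.
* Degenerate inputs fail loudly: empty site sets, columns with fewer
  than two observed values, site lengths exceeding every sequence,
  regions too short for a planted motif, unpaired replicate labels and
  malformed BED lines (reported with line numbers) are all errors, not
  warnings.

# Known limitations

* The scanner models only perfect four-run motifs: no bulges, no
  G4Hunter-style sliding scores, no thermodynamics, no DNA G4s.
* CLIP sites are simulated at called-peak level; read-level artefacts
  (crosslink bias, PCR duplicates) are upstream of this pipeline.
* The LFQ generator plants a single shared effect size per run and does
  not model peptide-level roll-up or match-between-runs.
* Transcript coordinates only; genome-space analyses would need a
  liftover layer on top.
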