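# rg4tools

Tools for studying the protein machinery that recognizes RNA
G-quadruplex (RG4) forming G-rich sequences and its consequences for
mRNA translation. The package is aimed at computational biologists who
work with CLIP-seq binding sites, RNA pull-down proteomics (RP-MS) and
the standard wet-lab quantifications that accompany them, and who want
every stage of that analysis reproducible and testable on synthetic data
with known ground truth.

## What it implements

**RG4 motif prediction.** A QGRS-style scanner finds windows of at most
30 nt containing four equal-length G-runs (tetrad number *g* ≥ 2) with
loops of 0–36 nt, scores them with a G-score

    score = 20 (g − 2) + ½ (30 − 4g − Σ lᵢ) − (max lᵢ − min lᵢ)

(rewarding more tetrads, shorter and more even loops; the canonical
`GGGAAGGGAAGGGAAGGG` motif scores 26), keeps hits with score ≥ 19, and
resolves overlaps greedily by score. Hits are assigned to the
5′UTR/CDS/3′UTR by start position.

**CLIP-site enrichment.** Binding sites (BED6, 0-based half-open) are
extended ±25 nt and intersected with the RG4 catalog; enrichment against
10,000 random background sites of matched length is tested per region
with Fisher's exact test (two-sided hypergeometric tail), alongside RG4
densities per Mb, the fraction of predicted RG4s bound, and target-set
intersections.

**RP-MS differential binding.** From a MaxQuant-style LFQ protein-group
table comparing a folded quadruplex bait (WT) with its 7-deaza-guanine
unfolded version (7dG): contaminant/reverse filtering, log2, ≥ 3-valid
filtering, downshifted-Gaussian imputation of missing values
(N(m − 1.8 s, (0.3 s)²) per sample), a paired sign-flip permutation FDR
test (exhaustive at 4 pairs), and classification into **RG4-BPs**
(WT/7dG ≥ 1.5 at q ≤ 0.05) and **G-rich-BPs** (≤ 1/1.5).

**Assay quantifications.** 2^−ΔΔCT expression, RIP enrichment
normalized to IgG/input/reference, polysome translational efficiency
TE = HP/(NP+LP+HP), Rluc/Fluc reporter ratios, and plating efficiency /
clonogenic survival.

**Synthetic data.** Generators for transcriptomes with exactly planted
quadruplex motifs, CLIP sites with tunable G4 placement enrichment,
paired LFQ matrices with planted fold differences and intensity-
dependent (MNAR) dropout, and assay fixtures built by inverting the
quantification formulas. All generators are seeded and bit-reproducible.

## Worked example

```r
library(rg4tools)

sim  <- simulate_transcriptome(sim_transcriptome_config(n_transcripts = 50, seed = 101))
cat1 <- predict_catalog(sim$sequences, sim$regions)
print(cat1)
#> RG4 catalog: 56 accepted hits (scorer: surrogate_gscore_v1, threshold >= 19)
#>  region n_hits region_nt
#>    utr5     10      9522
#>     cds     14     60990
#>    utr3     32     38889

sites <- simulate_clip_sites(sim, sim_clip_config(n_sites = 400,
                                                  g4_enrichment_factor = 6,
                                                  seed = 102))
enr <- clip_enrichment(sites, cat1, sim$regions,
                       enrich_config(n_background = 5000, seed = 103))
enr$enrichment[, c("region", "a", "b", "c", "d", "odds_ratio", "p_value")]
#>   region  a   b   c    d odds_ratio  p_value
#> 1    all 67 333 259 4741       3.68 1.77e-15
#> 2   utr5 12  27 600 4400       3.26 1.61e-03
#> 3    cds 18 181 131 4869       3.70 1.21e-05
#> 4   utr3 37 125 430 4570       3.15 6.70e-08
```

67 of 400 simulated CLIP sites (extended ±25 nt) overlap a predicted
RG4 versus 259 of 5,000 matched random sites — an odds ratio of 3.7 and
p ≈ 2·10⁻¹⁵, correctly detecting the 6× placement enrichment the
generator planted; the per-region rows show the same signal inside each
transcript region.

```r
lfq <- simulate_lfq(sim_lfq_config(seed = 104))   # 1000 proteins, 4 pairs,
run <- run_differential(lfq$table, ms_config(seed = 105))  # 10% planted binders
run$summary$class_counts
#>       RG4-BP    G-rich-BP unclassified   background     excluded
#>           88            3          832            0           99
head(run$results[order(run$results$q_value),
                 c("protein_id", "log2_ratio", "t_stat", "q_value", "class")])
#>     protein_id log2_ratio   t_stat q_value  class
#> 76      P00076   1.689291 3.811912       0 RG4-BP
#> 85      P00085   1.477844 4.111478       0 RG4-BP
#> ...
```

88 proteins are called RG4-BPs (the generator planted 100 WT-preferring
binders at +1.5 log2); 99 low-abundance or flagged rows were excluded by
the validity filter.

```r
ddct_expression(20, 18, 22, 18)        # 4: two-cycle relative Ct shift
polysome_te(50, 20, 30)                # 0.3: heavy-polysome share
clonogenic_survival(200, 500)$pe       # 40: plating efficiency (%)
```

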