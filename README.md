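# promarch

Promoter architecture analysis: distinguishing developmental
(focused-initiation) from housekeeping (dispersed-initiation) core
promoters from 5'-end sequencing data.

## The problem

RNA polymerase II core promoters are not interchangeable. Developmental
promoters carry position-specific sequence elements — TATA-box, initiator
(INR), downstream promoter element (DPE) — and fire from a focused 1–3 bp
region. Housekeeping promoters carry a different motif vocabulary (TCT,
DRE, Ohler1/6) and initiate over a dispersed 50–100 bp region in the
nucleosome-depleted region upstream of a well positioned +1 nucleosome.
Telling these regimes apart, and measuring how each responds when a
general transcription factor is depleted, requires a chain of fairly
particular computational steps. `promarch` packages that chain for R
users working with CAGE/STAP-seq 5'-end tags, MNase fragments and
spike-in-normalized PRO-seq counts:

* **TSS correction** (`correct_tss`, `collapse_by_tss`): reassign
  annotated TSSs to CAGE-supported positions with a ±250 bp then ±500 bp
  primary/fallback search; keep the longest transcript per unique TSS.
* **Motif classification** (`score_promoters`, `apply_thresholds`,
  `assign_class`, `kmeans_overview`, `select_prototypes`): positional PWM
  scoring with percent-of-optimum normalization,
  `percent = 100 (S* − S_min)/(S_max − S_min)`, strict thresholds
  (TATA > 90%, INR > 95%, DPE > 98%, TCT > 95%, Ohler1 > 95%,
  Ohler6 > 97%, Ohler7 > 95%, DRE > 98%), and an exclusive class label
  per promoter.
* **Initiation shape** (`initiation_metrics` and friends): dominant TSS,
  dominant fraction (count at dominant / total), activated-TSS count
  (positions above 20% of the dominant count) and initiation width.
* **Chromatin alignment** (`call_plus1`, `cage_mnase_crosscorrelation`,
  `anchored_metaprofile`): +1 nucleosome centers from 100–200 bp MNase
  fragment centers in a +1..+200 bp window, and the CAGE × MNase
  cross-correlation over lags −50..+200 whose ~125 bp peak is the
  signature of nucleosome-anchored housekeeping initiation.
* **Depletion response** (`spike_size_factors`, `call_downregulated`,
  `fisher_motif_enrichment`, `chip_zscore`): spike-in size factors
  (per-sample spike reads, geometric mean 1), an exact conditional
  binomial test on replicate-summed counts, down-calls at fold > 1.5 and
  FDR < 0.05, Fisher motif enrichment and ChIP signal z-scores.
* **Synthetic data** (`sim_config`, `simulate_*`, `run_simulate`,
  `run_analyze`): a deterministic seeded generator of the full data stack
  with ground truth, used by the test suite for parameter recovery.

## Worked example

Simulate 20 promoters per class and run the classification and chromatin
analyses:

```r
library(promarch)

cfg   <- sim_config(n_per_class = 20, seed = 42)
land  <- simulate_promoter_landscape(cfg)
cage  <- simulate_cage(land$truth, cfg)

scores <- score_promoters(land$genome, land$truth)
labels <- assign_class(apply_thresholds(scores$percent))
table(truth = land$truth$class, called = labels)
#>           called
#> truth      DPE DRE INR Ohler1/6 TATA TCT
#>   DPE       19   0   0        0    0   1
#>   DRE        0  20   0        0    0   0
#>   INR        0   0  20        0    0   0
#>   Ohler1/6   0   0   0       20    0   0
#>   TATA       0   0   0        0   20   0
#>   TCT        0   0   0        0    0  20

m <- initiation_metrics(cage, land$truth)
round(tapply(m$dominant_fraction, land$truth$mode, median), 3)
#> dispersed   focused
#>     0.155     0.799

frags <- simulate_mnase(land$truth, cfg)
hk    <- land$truth[land$truth$mode == "dispersed", ]
calls <- call_plus1(frags, hk)
median(calls$offset)
#> [1] 124
```

119 of 120 promoters are assigned their true class; focused promoters
put ~80% of initiation on the dominant TSS versus ~15% for dispersed
ones; and the called +1 nucleosome sits a median 124 bp downstream of the
dominant TSS (the generator programs +125). The same flow runs end to end
on disk via `run_simulate()` / `run_analyze()` (or the thin CLI in
`inst/scripts/promarch-pipeline.R`), writing FASTA/BED12/bedGraph/TSV
inputs and one TSV per result table.

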