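---
title: "Methods: promoter architecture analysis with promarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter architecture analysis with promarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promarch)
```

# Scope and model

Metazoan core promoters fall into broad regulatory regimes. Developmental
promoters carry position-specific elements (TATA-box, INR, DPE) and
initiate transcription from a focused 1–3 bp region; housekeeping
promoters carry elements such as TCT, DRE and the Ohler1/6 motifs,
initiate over a dispersed 50–100 bp region inside the nucleosome-depleted
region, and sit ~125 bp upstream of a well positioned +1 nucleosome.
`promarch` implements the computational workflow that distinguishes these
regimes from sequencing data:

1. **TSS correction** — annotated TSSs are reassigned to CAGE-supported
   positions (5'-end tag argmax) before any sequence analysis.
2. **Positional PWM classification** — core promoter sequence is scored
   with PWMs inside TSS-relative windows, normalized to percent of the
   optimal score, thresholded to binary motif flags, and reduced to one
   exclusive class per promoter.
3. **Initiation-shape statistics** — dominant TSS, dominant fraction,
   activated-TSS count and initiation width on per-base 5'-end profiles.
4. **Chromatin alignment** — +1 nucleosome calling from MNase fragment
   centers and CAGE × MNase cross-correlation around dominant TSSs.
5. **Depletion response** — spike-in size factors, exact conditional
   down-regulation calls, Fisher motif enrichment, and ChIP z-scores.

A seeded generator (`sim_config()`, `simulate_*()`) produces genomes,
promoters and all data layers with ground truth, so every estimator can be
validated by parameter recovery.

# TSS correction

Following the standard CAGE-correction protocol, each transcript is
searched at ±250 bp in a primary CAGE signal, then in ordered fallback
signals, then again at ±500 bp, and otherwise left uncorrected; the
corrected TSS is the maximum-count position of the first window with any
tag, and the longest transcript per unique corrected TSS is kept. Three
choices the protocol leaves open are fixed here: a *hit* is any position
with count ≥ 1 (a `min_count` option raises the bar); fallback tracks are
searched sequentially in user order rather than pooled, which keeps the
provenance of each correction attributable to one dataset; ties break to
the position closest to the annotation, then upstream-most.

# PWM scoring and classification

Raw scores are sums of log2 odds (motif probability over background, N
contributing 0). Because published thresholds are expressed as "% of the
optimal score", the raw score is min–max normalized:

$$\mathrm{percent} = 100\,\frac{S^{*}-S_{\min}}{S_{\max}-S_{\min}}$$

where \(S^{*}\) is the best raw score over the allowed motif-start
offsets and \(S_{\max}, S_{\min}\) sum the per-position maxima and minima
of the log-odds matrix. This is the standard construction and is testable
against brute-force enumeration of all \(4^L\) sequences. Scanning is
sense-strand only; DRE is quasi-palindromic, so a reverse-strand scan
would add little and is deliberately omitted from the default.

Motif flags use strict thresholds (TATA > 90, INR > 95, DPE > 98,
TCT > 95, Ohler1 > 95, Ohler6 > 97, Ohler7 > 95, DRE > 98 percent).
Flags may overlap; the exclusive label applies the precedence
TCT > TATA > DPE > INR > DRE > Ohler1/6, chosen so that the more
position-specific element names the class (e.g. a TATA+INR promoter is a
TATA-box promoter). Both representations are emitted because grouped
analyses can legitimately use either. The search windows and the PWMs
themselves are configurable package defaults: the PWMs are built from
consensus-like strings (0.85 on the consensus base), since no matrix set
is bundled with the workflow, and any laboratory PWM collection can be
supplied as whitespace-delimited text via `read_pwms()`.

An unsupervised overview (`kmeans_overview()`, Lloyd's algorithm, k = 9,
best of restarts) reproduces the threshold-free view of motif
co-occurrence. Prototype selection (`select_prototypes()`) applies the
stricter published co-occurrence rules on top of a ≥ 5 tpm CAGE activity
filter; activity is measured as tags within ±50 bp of the corrected TSS
per million mapped tags (the window is a package choice). One rule
requires a perfect DRE match ("DRE = 100%"); under strict
greater-than semantics this is encoded as `> 99.999`, i.e. only
floating-point-perfect matches pass.

# Initiation shape

All shape statistics operate on sense-oriented per-base count profiles.
The dominant TSS is the count argmax (ties upstream); the dominant
fraction divides its count by the profile total. Activated TSSs are
positions whose count exceeds 20% of the dominant count; because the 20%
rule is quoted both as "more than 20%" and as "at least 20%" in the
literature, both readings are first-class modes (`strict`, `inclusive`)
rather than silently unified. Initiation width spans the first to last position
with count at or above a floor (default 1); the floor exists because the
width statistic is otherwise dominated by single stray tags at deep
coverage, and the source description does not state whether one was used.

Metaprofiles average sum-normalized profiles over promoters anchored
either on a motif occurrence (requiring exactly one occurrence within
±120 bp of the dominant TSS; `motif_anchors()`) or on the called +1
nucleosome center.

# Chromatin alignment

+1 nucleosome centers are called as the coverage argmax of centers of
100–200 bp (inclusive) MNase fragments within +1..+200 bp downstream of
the dominant TSS; ties break toward the TSS. Both a 150 bp and a
+1..+200 bp downstream search are in circulation for this call; the wider
window is the default and the window is a parameter.

Cross-correlation is computed per promoter as the Pearson correlation
between the CAGE vector over −50..+200 and the fragment-center vector
shifted by each lag, the shifted vector being read from the untruncated
signal so no edge is zero-padded. Pearson correlation on raw vectors
equals the stated z-scored construction and makes the curve invariant to
global scaling of either signal. Promoters with a constant CAGE vector or
fewer than 10 in-window fragment centers are excluded; lags where the
shifted center vector is constant contribute NA and are dropped from that
lag's mean. The curve reports mean, sd and n per lag.

# Depletion response

Spike-in size factors are proportional to per-sample spike read tallies,
rescaled to geometric mean 1; dividing counts by them yields
per-cell-comparable values, which is what makes a *global* loss of
transcription measurable at all — library-size normalization erases it by
construction.

Down-regulation is called from replicate-summed counts with an exact
conditional test: given the gene total \(n = c + t\), the depleted total
is Binomial\((n, \pi_0)\) under the null, with \(\pi_0\) the depleted
share of the size-factor sums; the two-sided p-value sums all outcome
probabilities no larger than the observed one. Fold changes use
normalized condition sums with a 0.5 pseudocount; genes below 10
normalized counts are reported not-testable; q-values are
Benjamini–Hochberg; a gene is *down* when fold change ≥ 1.5 down and
q < 0.05. The test is a deliberately simple, fully specified contract —
it does not estimate per-gene dispersion. It is exactly calibrated for
Poisson-level counts and becomes anti-conservative by roughly a factor
\(1+\phi\mu\) under negative-binomial overdispersion \(\phi\); the
generator therefore defaults to \(\phi = 0\) and exposes \(\phi\) as a
dial for robustness exploration. Analyses of overdispersed biological
replicates should swap in a dispersion-aware test behind the same
normalization entry point.

Motif enrichment uses Fisher's exact test computed directly from the
hypergeometric distribution with strict tie semantics (the textbook
"sum of tables no more probable than observed" definition); the odds
ratio is \(ad/bc\) with a Haldane 0.5 correction only when a cell is
zero. ChIP z-scores normalize promoter coverage in a 1-kb TSS window by
nascent transcription per unit gene length, average per class, and
standardize each factor across the six class means (a per-promoter
variant would answer a different question; the class-mean reading matches
how such heatmaps are displayed).

# The synthetic-data generator

The generator emulates the study conditions, not real genome complexity:

* six promoter classes, 100 per class by default, on one contig with
  alternating strands and 3000 bp spacing; each 121-bp core carries its
  class consensus motif(s) at fixed TSS-relative offsets (TATA −31,
  INR 0, DPE +28, TCT 0, DRE −60, Ohler1 −45) over an i.i.d. uniform
  background;
* CAGE: Poisson(200) tags per promoter. Focused promoters put 80% of
  tags on the dominant TSS with geometric decay within ±3 bp. Dispersed
  promoters spread tags over a 100-bp window ending 30 bp upstream of the
  +1 nucleosome center with random Gamma(1) per-position weights, except
  that the position at the design TSS carries a fixed 15% share: real
  dispersed promoters retain a clear minor dominant TSS, and without one
  the ~125 bp dominant-TSS-to-nucleosome relationship would be
  statistically unidentifiable from the cross-correlation (the anchor
  would smear uniformly over the initiation window);
* MNase: 200 fragments per promoter, centers Normal around the true +1
  center (sd 10 bp housekeeping, 40 bp developmental — the
  strong-vs-loose positioning contrast), lengths round(Normal(147, 10))
  redrawn outside [80, 220] so the [100, 200] filter has work to do;
* PRO-seq: 2000 genes, LogNormal(log 200, 1) baselines, two conditions ×
  two replicates at depth 2 × 10^6, spike fraction κ = 0.01, reads split
  spike-vs-reference by Binomial(depth, κ/(κ + O_s)) where O_s is the
  sample's true relative output — a 4-fold global loss therefore raises
  the spike fraction ~4-fold, which is the signature spike normalization
  recovers and library-size normalization destroys.

Determinism: every promoter and sample draws from its own
counter-derived substream, so outputs are bit-identical for identical
(config, seed) and stable under subsetting. Draw order is documented per
function.

What the generator does **not** emulate: realistic base composition (GC
bias, repeats), motif degeneracy beyond the PWM softness, overlapping or
bidirectional promoters, MNase digestion bias, and (by default)
biological count overdispersion. Passing recovery tests therefore shows
the estimators are correct under their stated assumptions, not that those
assumptions hold in any particular real dataset.

# Numerical choices and degenerate inputs

* Intervals are 0-based half-open throughout; conversion happens only at
  format boundaries (FASTA/BED/bedGraph via Biostrings/rtracklayer).
* Ties: dominant TSS and TSS-correction ties break upstream (correction
  first breaks to the annotated position); +1 calls break toward the TSS.
* All-zero profiles, empty down-sets, empty metaprofile anchor sets and
  zero spike tallies are errors, not silent NAs; skipped promoters
  (contig edges, N-touching dinucleotides, multi-occurrence motifs,
  zero-nascent genes) are counted and reported as attributes.
* Problem sizes in the shipped tests and the acceptance script are
  100 promoters per class, 200 fragments and 200 CAGE tags per promoter,
  and 2000 genes — the package's chosen desk-scale study conditions; all
  statistics scale to larger inputs without modification.

# Known limitations

* The exact conditional test's calibration requires Poisson-level noise
  (see above); it is a contract-compatible substitute for
  dispersion-aware NB machinery, not a replacement.
* Sense-strand-only PWM scanning slightly understates quasi-palindromic
  motif matches on the reverse strand.
* tpm activity uses a fixed ±50 bp window; promoters with extremely
  dispersed initiation leak some signal outside it.
* The k-means overview is a visualization aid; cluster identities are
  seed-stable but arbitrary in label.
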