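---
title: "Predicting 35S enhancer target-gene activation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting 35S enhancer target-gene activation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Activation tagging inserts a T-DNA carrying tandem CaMV 35S enhancers into
a plant genome; genes flanking the insertion site may or may not be
transcriptionally activated, and distance alone does not decide it.
`timgo` predicts, for one insertion event next to one gene, whether the
gene is activated (`Ac`) or not (`NAc`), using three inputs: the gene's
promoter sequence (PROMOTER, the 1,500 bp upstream of the translation
start site, TLS), the sequence between gene and enhancer (MIDDLE, 300 bp
centred between TLS and enhancer), and the enhancer-TLS distance.

The TLS rather than the transcription start site anchors the promoter
window because activation-tagging panels are annotated by start codon;
1,500 bp covers a typical 1 kb upstream region plus a ~500 bp 5' UTR.

## Two-layer architecture

**First layer.** Sixteen RBF-kernel SVMs, one per (feature encoding,
region) pair: CGI, DNP, TNP, DACC, TACC and PseKNC each on PROMOTER and
MIDDLE; Kmer+Motif and RevKmer+Motif on PROMOTER; Kmer and RevKmer on
MIDDLE. Count-based encodings (k-mer, RevKmer classes, motif occurrence)
are first reduced to fragments whose occurrence differs between classes
by a per-fragment Welch t-test at p < 0.05 (no multiple-testing
correction: selection, not inference — the null-retention rate is itself
tested), then further reduced by Fisher-score ranking with a
cross-validation-chosen cutoff (the LIBSVM `fselect` convention): the
t-test prunes to nominally informative fragments, the F-score step
removes the surviving noise dimensions that would otherwise dilute the
RBF kernel. Features are min-max scaled to [-1, 1]. PROMOTER features are
then weighted by the activation probability of a logistic regression of
label on distance; this both injects the distance signal and separates
records that share one promoter but were observed under different
insertion events.

**Second layer.** Each first-layer model contributes its predicted label
and its positive/negative confidence (Platt-type probabilities from the
SVM), giving 48 meta-features. Meta-features for second-layer training
come from internal stacking folds, so the second layer never sees a
first-layer prediction made by a model trained on that same record. The
meta-features are ranked by greedy mRMR (MID variant: relevance minus
mean redundancy, mutual information on 3 equal-frequency bins), the
smallest prefix maximizing cross-validated SVM accuracy is kept, and a
LADTree — an alternating decision tree grown by LogitBoost — is fitted on
the selected columns. LADTree exists otherwise only in WEKA; the
implementation here follows the LogitBoost formulation: per boosting
step, working response $z_i = (y_i - p_i) / (p_i(1-p_i))$ (clipped to
$\pm 4$) and weights $w_i = p_i(1-p_i)$ drive a weighted least-squares
search over (precondition node, feature, threshold) stumps; each branch
adds half the weighted-mean response as its prediction value; a record's
margin is the sum of the prediction nodes on every path it satisfies.

## The nine encodings

* **Kmer / RevKmer** — occurrence counts of all words of length
  $k_{\min}..k_{\max}$; RevKmer merges each word with its reverse
  complement (class representative: lexicographic minimum), making the
  encoding strand-agnostic. Windows containing `N` are skipped, not
  imputed. Default ranges: 3–6 (PROMOTER), 3–5 (MIDDLE); the vocabulary
  grows as $\sum_k 4^k$ (5,440 for 3–6; 349,504 for 3–9), so larger
  maxima trade memory and time for longer-site sensitivity.
* **Motif** — IUPAC consensus strings are converted to position
  probability matrices (degenerate positions uniform, 0.01 pseudocount,
  renormalised) and scanned on both strands as log2-odds against a
  0-order background estimated from the scanned promoter set. Hits are
  thresholded on the exact score p-value computed by dynamic programming
  over a 1/1000-granularity discretised score distribution; palindromic
  self-matches are reported once. Per motif, four features: hit count,
  mean score, coding-strand fraction, mean distance to the TLS. Note a
  structural property of exact p-values: a perfect match of an
  $m$-mer has p-value about $4^{-m}$, so at the conventional $10^{-4}$
  threshold motifs shorter than ~7 bp cannot produce hits; short-motif
  signal is instead carried by the k-mer encodings, and users scanning
  short consensi in isolation should raise the threshold.
* **CGI** — newcpgreport-style CpG-island detection (window 100 bp, min
  length 200 bp, min GC 50%, min observed/expected CpG 0.6, with
  OE = #CG · len / (#C · #G)), summarised as island count, total length,
  mean distance to TLS, mean GC%, mean OE. The "CpG ratio" field is
  reported as GC% (the newcpgreport report field); the raw CpG count is
  kept in the island table.
* **DNP / TNP** — per-oligonucleotide composition weighted by
  physicochemical property values: 15 dinucleotide properties × 16
  dinucleotides = 240 dimensions; 12 trinucleotide properties × 64
  trinucleotides = 768.
* **DACC / TACC** — auto- and cross-covariance of the standardized
  property signals along the sequence at lags 1..4:
  $15 \cdot 4 + 15 \cdot 14 \cdot 4 = 900$ and
  $12 \cdot 4 + 12 \cdot 11 \cdot 4 = 576$ dimensions.
* **PseKNC** — $4^k$ normalised k-tuple frequencies plus $\lambda = 4$
  correlation factors $\theta_j$ (mean squared difference of the
  dinucleotide property vectors at offset $j$), weight $w = 0.2$, shared
  denominator $1 + w\sum\theta$; all components sum to 1 and the vector
  length is $4^k + \lambda$ (the index ranges of the defining equation
  force this length). $k$ is chosen per region by internal CV from 2–6;
  longer sequences tend to select larger $k$.

### Property tables

The original 15 dinucleotide properties derive from a PCA of the DiProDB
compilation and the 12 trinucleotide properties from the Pse-in-One
distribution; neither is redistributable here. The package therefore
ships **synthetic** standardized property tables of the same shape
(`inst/extdata/*_properties_synthetic.tsv`, 16×15 and 64×12, mean 0 / sd
1 per property). Every dimension count, covariance identity and PseKNC
contract depends only on table shape and standardization, and all are
tested against independent oracles; users analysing real panels should
substitute a real property compilation via `read_property_table()`.
Likewise the bundled motif library is a compact set of ~40 well-known
plant cis-element consensi (G-box, ABRE, W-box, GT-1, MYB/MYC cores,
...) standing in for the full ~2,087-entry PLACE + RegSite collection,
which users can supply in the same two-column TSV format.

## Synthetic panels

`simulate_dataset()` emulates an activation-tagging panel so the whole
pipeline is testable without any external data: enhancer-TLS distances
are log-uniform on [200 bp, 40 kb]; the activation label is Bernoulli
with probability $\mathrm{logistic}(\beta_0 + \beta_1 d)$ (defaults
$\beta_0 = 1.25$, $\beta_1 = -1.5\times10^{-4}$ per bp, giving a roughly
balanced panel whose activation fraction halves by ~10 kb — the
qualitative distance decay seen in real panels); conditional on the
label, motifs are planted into the promoter (defaults: G-box `CACGTG` at
0.9/0.1 in Ac/NAc, a weaker ABRE-like `ACGTGGC` at 0.5/0.2), at uniform
positions and random orientation — so strand-agnostic detectors are
favoured exactly as theory predicts. Backgrounds are i.i.d. bases at 44%
GC (rice-like); genes sit on non-overlapping cassettes with an `ATG`
planted at the TLS, half on each strand.

What this does **not** emulate: higher-order sequence composition,
positional motif preference, CpG-island structure (a 44% GC i.i.d.
background rarely contains one — see degenerate inputs below), chromatin
context, or correlated insertion events. Passing tests on synthetic
panels therefore demonstrate that the machinery recovers signals of the
planted kinds — distance decay and differential motif content — not that
the published accuracies transfer to any particular real panel.

## Numerical and degenerate-input choices

* Welch (unequal-variance) t-tests throughout; fragments with zero
  variance in both groups are dropped. If a filter retains nothing, the
  10 smallest-p fragments are kept with a warning so the model stays
  fittable.
* An all-constant feature matrix (typically CGI on MIDDLE windows, where
  a 300 bp window at 44% GC almost never contains a 200 bp island) would
  otherwise abort training; instead that model becomes a class-prior
  stub (constant prediction, prior confidences) and a warning is
  emitted. The 16-model roster and the 48-column meta-feature contract
  are preserved; mRMR ranks such constant columns last and the second
  layer ignores them.
* SVM tuning uses a deliberately small grid (cost {1, 32} at the 1/d
  gamma heuristic, 3-fold internal CV) — a compromise between the
  exhaustive LIBSVM-guide grid and the cost of nested CV; the grid is a
  `timgo_config()` argument.
* Stacking uses 3 internal folds; outer evaluation 5 folds, stratified,
  fold confusion matrices pooled (micro-averaged). Fold assignment deals
  shuffled records round-robin within class, so class counts per fold
  differ by at most 1.
* mRMR ties break toward the lower column index; incremental selection
  returns the *smallest* prefix attaining the maximum CV accuracy.
* Logistic weighting is applied after per-feature scaling (weights in
  (0,1) preserve the [-1,1] range); weighting preserves direction and
  only rescales norms.
* MIDDLE windows shorter than 300 bp (enhancer closer than the window)
  are clipped to the bases strictly between TLS and enhancer; promoter
  windows are clipped at contig edges with a warning.
* The PseKNC k range is configurable (2–6 by default; panels differing
  in sequence length may justify 2–7): internal CV picks k per region.
* Distance bins for stratified reporting are half-open `(lo, hi]` kb
  intervals with edges 0, 2, 5, 10, 15, 20, 25, Inf.

## Problem sizes used by the test-suite and acceptance runs

Unit tests run on toy contigs and an 80-record shared panel. The
end-to-end checks (planted-signal CV above 70%, permuted-label CV at
chance, stacking benefit, leakage guard) run on a 300-record panel — the
size of a real balanced training set for this problem — with the default
configuration; full-scale 3–9-mer vocabularies are exercised in the
enumeration checks but not in the end-to-end fits, whose default k
ranges are 3–6/3–5 as discussed above.

## Known limitations

* The bundled property tables are synthetic stand-ins; DNP/TNP/DACC/
  TACC/PseKNC values on real data are only as meaningful as the property
  table supplied.
* Exact-p motif scanning cannot fire on short consensi at the default
  threshold (see above).
* LADTree here is binary-class only, with univariate threshold splits.
* The mRMR variant is MID; MIQ is not implemented.
* Confidence calibration inherits LIBSVM's Platt scaling, which is
  unreliable for very small training folds.
* On 300-record synthetic panels the stack's margin over the
  distance-only logistic baseline is modest (roughly −1 to +9 accuracy
  points across panel draws): most of the planted label signal *is*
  distance, the sequence signal arrives through stump splits on SVM
  confidences, and five-fold estimates at n = 300 carry ~2.5-point
  binomial noise. Single-panel comparisons against the baseline should
  therefore not be over-read.
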