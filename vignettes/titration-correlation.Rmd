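---
title: "Titration-weighted correlation of miRNA and mRNA expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Titration-weighted correlation of miRNA and mRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRtitrate)
```

## The problem and the statistic

miRNAs repress their targets, and through them shift whole downstream
programmes, most visibly at the mRNA level in steady-state systems such
as a panel of unperturbed cancer cell lines profiled for both miRNA and
mRNA expression. The plain Pearson correlation (here `dPCC`, for *direct*)
between a miRNA and a gene weights every sample equally. That is the wrong
weighting for repression: a miRNA exerts pressure on its targets only in
the samples where it is substantially expressed, while in low-expression
samples the target's level is set by other regulation, so those samples
contribute mostly noise.

The titration statistic implemented here (`sPCC`, *summed* Pearson
correlation) re-weights at the level of sample selection, which keeps the
computation linear. Samples are ranked by the miRNA's expression, highest
first. Pattern 1 is the top `minSize` samples (default 30 of 59, i.e. at
least half the panel); each following pattern adds the next sample in rank
order until the whole panel is included. A Pearson correlation is computed
within each pattern and the values are summed:

$$\mathrm{sPCC} = \sum_{k=m}^{n} r\!\left(x_{(1..k)},\, y_{(1..k)}\right),$$

with $m$ = `minSize`, $n$ the number of samples, and $r$ the
product-moment correlation on complete pairs. For a 59-sample panel and
$m = 30$ this sums 30 correlations, so the statistic ranges over
$[-30, 30]$; `sPCC / nPatterns` is on the familiar $[-1, 1]$ scale. The
highest-expression samples appear in every pattern and therefore carry the
most weight — an *in silico* titration. Two controls calibrate it:

* `dPCC`, the correlation over all samples (identically the last pattern);
* `rsPCC`, the same summed construction over uniformly random sample
  orderings, averaged over 10 replicates. It retains the nested-subset
  arithmetic but destroys the expression ranking, so any systematic
  difference between `sPCC` and `rsPCC` is attributable to the ranking
  itself and not to the summation.

Nothing else distinguishes the three methods: pattern construction,
missing-data policy and probe collapsing are shared.

## Engine conventions

* **Missing values** are excluded pairwise within each pattern. A pattern
  correlation is undefined (`NA`, the sentinel) when fewer than
  `minPairs = 10` complete pairs remain or a vector has zero variance on
  them; undefined patterns are skipped in the sum, and if fewer than half
  the patterns are defined the whole sPCC is the sentinel. Sentinels are
  excluded from every downstream average, never zero-filled.
* **Detectability gating** happens at the miRNA level, not per pattern: a
  miRNA enters the analysis only if detectable in at least 30 of 59
  samples (at least half the panel). Correlations then use all non-missing
  values, matching how the smallest pattern necessarily contains exactly
  30 samples.
* **Ties** in miRNA expression are broken by sample id; samples with
  missing miRNA values rank last. This makes every run reproducible.
* **Probe collapsing**: per-probe correlation values are averaged per gene
  over all defined probe values across platforms (flat mean, the default)
  or per platform first (`collapse = "platform"`); which probes were used
  is recorded as `nProbes`. Genes with no defined probe value are absent
  rather than zero.
* **Families**: seed-family profiles are built before correlation — the
  per-sample mean of members for abundance-style data, the per-sample sum
  for signed log2-ratio data (the two conventions customary for the two
  quantification chemistries), overridable; a family sample is detectable
  if any member is.
* The per-pattern correlations for a whole probe matrix are computed by
  cumulative sums over the ranked sample order (`patternPCCMatrix`), so a
  series costs one pass over the matrix rather than a `cor()` call per
  pattern; unit tests pin this fast path to the scalar definition and to
  an independent brute-force sort-slice-sum oracle at $10^{-10}$.

## Downstream analyses

**Top correlator lists and functional clustering.** For each miRNA the
top `N` positive and top `N` negative correlators are extracted (default
2000, roughly 10% of a genome-wide table — large enough to capture a
programme, small enough to drop the weak bulk). miRNAs are then compared
by the percent identity of their lists,
$100\,|A \cap B|/N$, giving a symmetric overlap matrix. Rows of that
matrix are embedded as vectors, distances are Euclidean, and
complete-linkage agglomeration builds the tree. Because a percent-overlap
threshold has no fixed Euclidean equivalent, the tree is cut at the
largest height at which **every** within-cluster pair directly shares more
than `shareThreshold` percent of correlators (default 12.5%), scanning
merge heights from the top; an explicit `cutHeight` is accepted as an
alternative. This honours the "more than 12.5% shared genes" semantics
deterministically, and makes the cut monotone: raising the threshold can
only split clusters, never merge them. Labels are Roman numerals in
dendrogram order. PCA of the overlap matrix is centered but not scaled
(the matrix is already on one percent scale).

**Signature scoring.** Signature genes are counted among a miRNA's
positive and negative correlators either by top-N membership or by a
threshold on the correlation value; threshold counting is strict
(`> c` / `< -c`, values inside the band uncounted), following the
convention of reporting only raw sPCCs above 1 or below −1. From the four
counts come the net score (positives − negatives, for direction-less
lists such as ribosomal proteins) and the epithelial/mesenchymal factor
(negatively correlating M genes − positively correlating M genes) +
(positively correlating E genes − negatively correlating E genes).
Per-cluster enrichment uses the two-sided Wilcoxon rank-sum test of a
cluster's scores against all other miRNAs (exact for small untied
samples, midrank normal approximation otherwise), with significance tiers
at 0.01, 0.001 and 0.0001. Two-sided is the deliberate default: enrichment can
run in either direction, and the one-sided variants remain available
through the `alternative` argument.

**Host genes and gene blocks.** miRNAs encoded inside host genes are
co-transcribed with them, so positive correlation is expected — a
biological positive control consumed as an input table of pairs. Summary
counts use `sPCC / nPatterns` so a single cutoff (default 0.2) serves
both methods. For HOX-style genomic blocks, each miRNA's per-gene values
are summed over the block's members and miRNAs are ranked per block; the
miRNA encoded in a block should rank first for it.

**Prediction processing.** TargetScan-style site scores are aggregated to
a pair's total context score by summing only non-positive site scores
(pairs with no such site are dropped); a family's aggregate prediction is
the minimum (most negative) member total. The strength-ranked pair list
feeds a cumulative curve: at each list size $k$, the ratio of negative to
positive correlation values among the top-$k$ predicted pairs. Under a
method that resolves dose-restricted repression the ratio is largest at
the strong end of the ranking. "Strongest = most negative total score" is
the default reading (`rankDirection` exposes the other), ties break
lexicographically, and zero counts fall back to a pseudocount of 1 with a
flag.

## The synthetic panel generator

No external data are required anywhere: `generateSyntheticPanel()` builds
a deterministic panel from a seed, shaped like the motivating compendium —
59 samples, four probe-redundant array platforms (1 + Poisson(0.5) probes
per gene and platform, probe noise sd 0.25), gene-level log2 values with
biological noise sd 1, miRNA log2 abundances with per-miRNA means, a
detection limit (log2 scale, default 5) and decoy miRNAs that fail the
30-of-59 gate.

The generator's central choice is the planted titration structure: every
detectable miRNA represses its own disjoint 60-gene effector set, but
only in the samples above the miRNA's empirical 0.9 expression quantile
(the top ~6 of 59). The default suppression is switch-like — a fixed drop
of 2 log2 units (fourfold) in active samples — reflecting how strongly
dose-restricted, on–off regulation behaves (EMT markers being the extreme
example); a linear ramp term (`suppressionSlope`) is available, and in the
limit of a near-zero quantile the ramp becomes a global linear
anti-correlation on which sPCC and dPCC agree — a useful degenerate check.
The switch depth is deliberately the stable choice: a pure ramp's realized
effect size varies strongly between miRNAs through the spacing of the top
order statistics, which blurs panel-level comparisons at this scale.

Around that core sit host-gene pairs (gene = 0.8 × miRNA + noise),
HOX-like co-expressed blocks of 6 genes with one anchor miRNA, and a
latent epithelial factor loading 25 epithelial genes positively and 25
mesenchymal genes negatively, tied to planted epithelial (5 miRNAs) and
mesenchymal (3 miRNAs) families that load the same factor with
coefficient 0.85. The family loading is set so that within-family overlap
of top-correlator lists lands in the tens of percent — the range observed
for a real, tightly co-expressed seed family — while unrelated miRNAs
share only the ~5% expected by chance at list size 100.

For method comparisons on count ratios, correlation values are counted at
a magnitude cutoff of 0.35 on the per-pattern-normalised scale; with 2000
genes this keeps the chance-passing floor low enough that the planted
effector sets dominate the counts.

`titrationBenchmarkPanel()` builds the harder, *noise-matched* benchmark
for prediction-strength curves: planted pairs carry graded suppression
depth (0.4 to 1.8 log2 units along the prediction ranking) plus a
co-expression term calibrated per miRNA — via the in-sample regression of
the suppression indicator on the miRNA — so each pair's overall sample
covariance with its miRNA is exactly zero. The plain correlation of a
planted pair is then pure noise while the titration signal remains,
isolating exactly the property the summed statistic claims.

`truthReport()` closes the loop: precision/recall of planted effector
genes in the negative top lists per method, the fraction of host pairs
scoring positive, and the purity of the planted families under the
functional clustering, with a fingerprint check that the results actually
came from the matching panel.

## What the synthetic benchmarks do and do not show

The generator emulates the *structure* that motivates the titration
statistic — dose-restricted repression, co-transcription, shared latent
programmes, multi-platform probe redundancy, a detection limit — under
Gaussian noise. It does not emulate tissue-of-origin block structure,
heavy-tailed or saturated array intensities, correlated probe effects, or
the miRNA-family target overlap of real seed families. Passing the
planted-truth suites therefore shows the machinery is correct and that
the titration weighting detects what it is designed to detect; it does
not by itself certify effect sizes on real panels.

Problem sizes used throughout the test suite (24 detectable miRNAs, 2000
genes, 4 platforms, 5 replicate seeds for distribution-level properties;
500 benchmark pairs) were chosen as the smallest panels at which the
distribution-level contrasts have stable statistical power.

One statistic deserves a caveat: the cumulative negative/positive count
ratio along a prediction ranking is a partial-proportion path, and the
rank correlation of such a path with list size has a wide null — a truly
flat curve yields |Spearman| above 0.5 roughly half the time, a
scale-free property that more pairs or replicates do not shrink. Levels
(ratios near 1 everywhere) are the trustworthy summary of flatness for
that curve; rank-based trend statistics on it are fragile, and one
distribution-level check in the acceptance suite is expected to be
sensitive to this.

## Numerical and degenerate-input conventions

* Correlations are clamped to $[-1, 1]$ after the cumulative-sum
  arithmetic; zero variance is detected at relative tolerance $10^{-10}$
  against the accumulated sum of squares.
* `minSize` must not exceed the sample count (error); a panel of exactly
  `minSize` samples gives one pattern and sPCC = PCC.
* Empty gene blocks warn and score 0; absent genes in host/block tables
  are flagged and excluded from summaries, not imputed.
* All RNG use is locally seeded (`rsPCC` orderings are drawn once per
  miRNA and shared across platforms and genes) and restores the caller's
  RNG state; identical seeds give byte-identical pipeline outputs.
* PCR-derived (ct-style) miRNA data must be supplied as already-normalised
  abundance in which higher means more expressed; the package does not
  guess a ct transformation.

## Known limitations

* The percent-threshold cut of the dendrogram is one of several defensible
  readings of "clusters sharing more than 12.5% of genes"; the raw-height
  cut is exposed for users who want the classical `cutree` behaviour.
* Whether signature counting should use top-2000 membership or the ±1
  threshold is data-set dependent; both are first-class modes and no
  fidelity claim is made for either as *the* original choice.
* The universal-signature construction (averaging several EMT signatures)
  is not implemented as a distinct object; averaging per-signature counts
  or merging signatures by majority direction are both possible with the
  exposed primitives.
* p values are attached only to the distribution-level comparisons (KS,
  rank-sum); individual correlation values carry none, by design.
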