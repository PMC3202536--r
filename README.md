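# miRtitrate

Titration-weighted correlation of miRNA and mRNA expression across
steady-state cell-line panels.

## The problem

miRNAs repress their targets and, through them, entire downstream
programmes — but only in the samples where the miRNA is substantially
expressed. A plain Pearson correlation between a miRNA and a gene across
a panel (here called the *direct* PCC, `dPCC`) weights every sample
equally, so the low-expression samples, where the target's level is set
by other regulation, contribute mostly noise and dilute genuine
repression signals.

`miRtitrate` implements the *summed* Pearson correlation (`sPCC`), an
in-silico titration. Samples are ranked by the miRNA's expression,
highest first; nested "patterns" are formed from the top `m` samples up
to the full panel (for 59 samples and the default `m = 30`, 30 patterns
of sizes 30..59), a Pearson correlation is computed within each pattern,
and the values are summed:

    sPCC = sum over k = m..n of  r( x[top k], y[top k] )

The highest-expression samples sit in every pattern and carry the most
weight. `sPCC / nPatterns` lies in [-1, 1]; the last pattern is exactly
the plain correlation. A randomised control (`rsPCC`: the same sum over
random sample orderings, 10 replicates averaged) calibrates how much of a
score is due to the ranking rather than the summation.

On top of the engine the package provides the surrounding workflow:
multi-platform probe-to-gene collapsing, seed-family profile aggregation
(mean for abundance data, sum for log2 ratios), top-correlator extraction
(default 2000 genes per sign), functional clustering of miRNAs by percent
overlap of their correlator lists (complete linkage, cut so that every
within-cluster pair shares more than 12.5% of correlators), PCA of the
overlap matrix, gene-signature scoring (net scores and the
epithelial/mesenchymal factor with Wilcoxon cluster enrichment),
host-gene and gene-block (HOX-style) validation scores, TargetScan-style
context-score processing with prediction-strength ratio curves, flat-TSV
export with forward/reverse queries, and a fully deterministic synthetic
panel generator with planted dose-restricted suppression so that every
stage is testable without external downloads.

## Worked example

Generate a synthetic 59-sample panel (24 detectable miRNAs, 2000 genes on
4 probe-redundant platforms, every miRNA repressing a planted 60-gene
effector set only in its top-expression samples), gate detectability, and
correlate one miRNA genome-wide:

```r
library(miRtitrate)

panel    <- generateSyntheticPanel(syntheticConfig(seed = 42))
profiles <- detectabilityFilter(panel$mirna, limit = 5, minSamples = 30)
length(profiles)
#> [1] 24

tables <- computeCorrelations(profiles["syn-miR-23"], panel$mrna,
                              panel$probeMap, methods = c("spcc", "dpcc"))
tables[[1]]
#> CorrelationTable for syn-miR-23: 2000 genes, 30 patterns (min size 30)
#>   columns: gene, sPCC, dPCC, nProbes

tab <- as.data.frame(tables[[1]])
head(tab[order(tab$sPCC), c("gene", "sPCC", "dPCC")], 5)
#>          gene      sPCC       dPCC
#> 1334 SYNG1334 -18.09278 -0.4724121
#> 1341 SYNG1341 -18.00047 -0.3646576
#> 1355 SYNG1355 -17.08251 -0.4430830
#> 1349 SYNG1349 -16.57115 -0.4066388
#> 1358 SYNG1358 -16.40221 -0.3198876
```

The five strongest negative sPCCs (about −17 to −18 of a possible −30,
i.e. −0.55 to −0.6 per pattern) are all members of this miRNA's planted
effector set (`panel$truth$suppressed[["syn-miR-23"]]`, genes
SYNG1321–SYNG1380). Ranking all 2000 genes by each method and asking what
fraction of the top 60 negative correlators are planted:

```r
planted <- panel$truth$suppressed[["syn-miR-23"]]
mean(head(tab$gene[order(tab$sPCC)], 60) %in% planted)
#> [1] 0.8166667
mean(head(tab$gene[order(tab$dPCC)], 60) %in% planted)
#> [1] 0.7333333
```

The titration weighting recovers more of the dose-restricted repression
than the equal-weight correlation; `truthReport()` computes these
recovery metrics panel-wide, and `runFullAnalysis()` chains gating,
correlation, clustering, signature scoring and TSV export into one
reproducible run (see the vignette in `vignettes/` for the model, the
generator's planted structure and all conventions).

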