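---
title: "Methods: discordant-twin differential expression and cross-phenotype meta-analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discordant-twin differential expression and cross-phenotype meta-analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twindiff)
```

## The design and its statistical model

A discordant monozygotic (MZ) twin pair consists of genetically identical
twins of whom exactly one is affected by the phenotype under study. For a
probe measured on both twins of pair $i$, the within-pair difference
$d_i = x_{\mathrm{aff},i} - x_{\mathrm{unaff},i}$ cancels every additive
component shared by the pair — genetic background, shared environment,
pair-level batch — leaving the phenotype-associated effect plus independent
measurement noise. `twindiff` analyses these differences on the
platform-native intensity scale throughout; no log-transform is applied by
the package (the differences it reports are in the same units as the input
matrix, and an analyst who prefers log-scale analysis should transform
before loading). All sign conventions are affected minus unaffected:
positive means higher expression in the affected twin.

The per-probe model is the classical paired $t$: with $n$ complete pairs,
$\bar d$ and sample SD $s_d$,

$$ t = \frac{\bar d}{s_d/\sqrt n}, \qquad t \sim t_{n-1} \text{ under } H_0, $$

two-sided. Pairs missing either measurement for a probe are excluded for
that probe only (pairwise deletion maximizes usable pairs). Probes with
fewer than `min_pairs = 3` complete pairs or with $s_d = 0$ are flagged
(`insufficient_pairs`, `zero_variance`) and carry no $t$ or $p$; both kinds
are barred from gene summarization — a zero-variance probe would get
infinite inverse-variance weight.

## Probe-to-gene summarization

Microarray platforms interrogate most genes with several probes of
different binding affinity, so probe-level estimates of one gene share a
true effect but differ in scale and precision. Each gene's `ok` probes are
pooled by inverse-variance fixed-effect meta-analysis
($w_j = 1/\mathrm{se}_j^2$), yielding a gene-level mean difference, SE, and
a two-sided normal $p$-value from $z = \hat\mu/\mathrm{se}(\hat\mu)$.
Decisions a user should know about:

* **Single-probe genes** keep the probe's estimate and SE but receive the
  same normal-reference $p$ as pooled genes, so all gene-level $p$-values
  within a study come from one reference distribution; the difference from
  the probe's $t$-based $p$ shrinks as pairs grow.
* **Multi-gene probes** (annotation cells like `"A /// B"`) contribute to
  every mapped gene and the affected rows are flagged `multi_mapped`.
  This preserves sensitivity at the cost of correlated gene statistics.
* **No cross-probe correlation adjustment**: probes of one gene are pooled
  as if independent although they measure the same samples. This is the
  standard naive inverse-variance summarization; its pooled SE is
  anti-conservative in proportion to the residual inter-probe correlation.
* **Ranking**: `abs_rank` orders genes by descending $|\hat\mu|$ (ties
  broken alphabetically), 1 = largest absolute difference.

## Two-gate significance

Within each study, gene $p$-values get Benjamini–Hochberg adjustment over
exactly that study's summarized genes, and the effect-size threshold
$\tau_{95}$ is the 95th percentile of that study's $|\hat\mu|$ distribution
(type-7 linear interpolation, the dominant default in scientific software;
the percentile and the FDR level are configurable). A gene is significant
when $q < 0.05$ **and** $|\hat\mu| > \tau_{95}$, both strict. The second
gate caps selections near 5% of tested genes and suppresses the
small-$n$ pathology where tiny but stable differences reach low FDR.

## Cross-phenotype integration

For every study pair, the package reports the overlap percentage
$100\,|S_A \cap S_B| / |M_A \cap M_B|$ (significant-in-both over
measured-in-both; the diagonal is the study's own significant fraction)
and the Spearman correlation of gene-level mean differences over
co-measured genes (average ranks for ties; two-sided $p$ from
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$, reported unadjusted).

Each gene measured anywhere is then meta-analyzed across the $k$ studies
measuring it with the DerSimonian–Laird moment estimator:
$Q = \sum w_j(m_j - \hat\mu_{FE})^2$,
$\hat\tau^2 = \max\!\big(0, (Q - (k{-}1)) / (\sum w - \sum w^2/\sum w)\big)$,
random-effects weights $1/(\mathrm{se}_j^2 + \hat\tau^2)$, a Wald $z$ test
for the pooled effect (no Knapp–Hartung adjustment, matching common
practice), $I^2 = \max(0, (Q - (k{-}1))/Q) \cdot 100$, and QEp from the
$\chi^2_{k-1}$ upper tail. Genes measured in a single study are retained
in the table with the conventions $Q = 0$, $\tau^2 = 0$, $I^2 = 0$,
$\mathrm{QEp} = 1$ — this keeps BH well defined over the full table — but
are barred from overall selection. *Overall significant* means: BH-adjusted
meta $p < 0.05$, $|$pooled estimate$|$ above the 95th percentile of pooled
estimates over all meta-analyzed genes, and $k > 1$. The reference
distribution for that threshold is the per-gene meta-estimate distribution
(not the union of per-study distributions); this was a genuinely open
design point and is surfaced as the `percentile` argument plus the choice
of table passed to `effect_threshold()`. Genes with BH-adjusted
QEp < 0.05 form the heterogeneous set.

Note an expected estimator property: under true homogeneity
($\tau = 0$) the DL estimate $\hat\tau^2$, and hence $I^2$, truncates at
zero with probability $P(\chi^2_{k-1} \le k{-}1) \approx 0.5{-}0.6$, so a
large spike of $I^2 = 0$ genes in real compendia is not evidence of a bug;
the acceptance script reports this fraction.

## Sex stratification

Sex is a pair-level attribute (MZ twins share it); a within-pair conflict
is rejected at load. `stratified_analysis()` keeps the labelled studies
with at least `min_pairs` same-sex pairs, restricts each to those pairs,
and re-runs the identical pipeline — including recomputing the
effect-size thresholds within the stratum, so a sex-specific run is never
judged against pooled-run thresholds. `cross_sex_overlap()` intersects the
two overall-significant sets.

## The synthetic cohort generator

`simulate_cohort()` draws, for study $s$, gene $g$ on its panel, probe $k$,
pair $i$, twin $t$:

$$ y = \beta_g + o_k + \pi_i + \mathbf{1}[t\ \mathrm{affected}]\,\delta_{gs} + \varepsilon,
\quad \varepsilon \sim N(0, \sigma^2), $$

with per-gene baseline $\beta_g \sim N(100, 25^2)$, probe offset
$o_k \sim N(0, 0.5^2)$, pair effect $\pi_i \sim N(0, 1)$, and
$\delta_{gs} \sim N(\mu_g, \tau^2)$ for affected genes, $0$ otherwise.
Pair effects and probe offsets cancel in within-pair differences, so the
difference for any probe of gene $g$ is $N(\delta_{gs}, 2\sigma^2)$ — the
exact sampling model the paired $t$ assumes, which makes SE-based oracles
exact. Defaults emulate the reference seven-study compendium
(`twin_cohort_design()`): its pair counts 10–44 (92 pairs across the five
GEO-sourced studies), a 25,000-gene universe at 80% per-study platform
coverage (≈20,000 genes per study, matching the reference range
18.6k–22.8k), 1–4 probes per gene, sex labels in the three studies that
carry them (CFS, MDD, OB), 5% affected genes with $\mu_g \sim N(0,1)$,
$\tau = 0.25$, $\sigma = 1$ — effect and noise scales a practitioner would
call realistic for normalized single-channel arrays, fixed once as the
package's reference condition. Every draw comes from one generator seeded
by `seed`; identical configurations reproduce cohorts (and emitted files)
byte for byte.

What the generator deliberately does **not** emulate: intensity-dependent
(MA-plot) noise, probe-specific scale differences (offsets are additive
only), cross-study batch structure beyond probe offsets, and annotation
errors. Passing calibration tests therefore shows the estimators are
correct under their own assumptions, not that real compendia satisfy those
assumptions.

## Numerical and I/O choices

* TSV only (tab-delimited, UTF-8, "." decimal); `NA` or empty on read,
  `NA` on write. Result tables render floats to 6 significant digits and
  sort rows by gene then study, so outputs are byte-stable.
* Incomplete pairs are dropped with a warning; two affected members in a
  pair, duplicate probe IDs, or a sex conflict are errors naming the file.
* `bh_fdr()`, `effect_threshold()` and the Spearman test are thin,
  contract-checked surfaces over `stats::p.adjust`, `stats::quantile(type
  = 7)` and `stats::cor.test(method = "spearman", exact = FALSE)`.
* Degenerate inputs: empty estimate lists, non-positive SEs and mixed-study
  tables error early; $k=1$ meta rows follow the conventions above;
  `Q` is clamped at 0 against floating-point cancellation.

## Problem sizes used in validation

The shipped tests validate estimator exactness on small randomized inputs
(against `stats::t.test`, `metafor::rma.uni(method = "DL")` and
independently coded closed forms), calibration on simulated cohorts of
2,000–5,000 genes with 10–30 pairs and 20–500 replicates, and determinism
plus throughput on the full reference-scale seven-study configuration
(~20,000 genes/study, ~50,000 probes/study), which completes in well under
a minute per run on one CPU. These sizes were chosen to make Monte-Carlo
bands tight enough to detect real miscalibration while keeping the whole
suite fast.

## Known limitations

Inverse-variance pooling over correlated probes understates gene-level
SEs; no moderated (limma-style) variance shrinkage is offered, so very
small studies lean on the effect-size gate for error control; the overall
effect-size threshold's reference distribution is a convention (see
above); and batch correction is out of scope — inputs are assumed
within-study normalized.
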