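---
title: "Calling allele-specific expression in clonal F1-hybrid cohorts"
author: "asecall"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling allele-specific expression in clonal F1-hybrid cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asecall)
```

## The model

For gene $g$ in clonal line $s$, the allele-informative evidence is the
pooled count $k$ of strain-A reads out of $n$ reads over the gene's
cSNPs (per-SNP depths outside $[3, 2000]$ are discarded before pooling:
too shallow carries no information, too deep is usually a mapping
artifact).  Under the null of balanced expression,
$k \sim \mathrm{Binomial}(n, 0.5)$.  The two-sided exact p-value is the
doubled tail of the more extreme count,

$$p = \min\!\bigl(1,\ 2\,\Pr(X \ge \max(k, n-k))\bigr),$$

which is symmetric in $k \leftrightarrow n-k$.  The doubled-tail
convention (rather than the minimum-likelihood convention of
`binom.test`) is chosen for transparency; at the effect-size threshold
used for calls the two rarely disagree.

With $q = \max(p_A, 1-p_A)$ the majority-allele proportion, each
evaluable gene-line is classified by effect size *and* significance:

| category      | rule                               |
|---------------|------------------------------------|
| monoallelic   | $q \ge 0.85$ and $p \le 0.05$      |
| trend         | $0.70 \le q < 0.85$ and $p \le 0.05$ |
| biallelic     | $q < 0.70$                         |
| excluded      | $q \ge 0.70$ and $p > 0.05$        |

All comparisons are inclusive as written, so boundary values fall in the
more extreme category.  A gene-line is evaluable when RPKM $\ge 3$
(expressed above background) and pooled depth $\ge 10$ (minimally
powered: at $n = 10$ only $k \in \{0, 1, 9, 10\}$ can reach
significance).  Raw p-values are deliberately not multiplicity-adjusted:
the call requires a large effect *and* significance, and error control
is reported separately as a per-line analytic FDR,

$$\widehat{\mathrm{FDR}}_s
  = \frac{\sum_{g\ \text{evaluable}} \Pr(\text{call} \mid n_g, p = 0.5)}
         {\#\{\text{monoallelic calls in } s\}},$$

an exact expectation under the null rather than a permutation estimate —
fast, deterministic, and sufficient because the null is fully specified.
When there are no calls the FDR is flagged `NA` rather than divided by
zero.

## Cross-line patterns

Per gene, lines are summarized into `n_evaluable` and `n_monoallelic`
(trend/excluded lines count as evaluable but contribute no direction
evidence by default; `use_trend_direction = TRUE` opts in).  Genes
evaluable in fewer than `min_evaluable = 2` lines are dropped.  The
pattern taxonomy is a pure function of the per-line directions plus the
cross metadata:

* **imprinted_maternal / imprinted_paternal** — every monoallelic line
  expresses the allele of the same parental origin *and* both reciprocal
  cross directions are represented among those lines;
* **both_alleles_observed** — both strains appear among monoallelic
  lines without origin consistency (haplotype-independent, i.e. random
  allelic exclusion);
* **strainX_only / strainX_or_biallelic** — one strain wherever
  monoallelic, with or without additional biallelic lines;
* **biallelic_all** — no monoallelic line.

With a 3+1 reciprocal design a single reciprocal line is decisive for
imprinting.  This is a real limitation, not an implementation artifact:
a random-monoallelic gene whose reciprocal line happens to express the
opposite strain from all other monoallelic lines is indistinguishable
from an imprinted gene without external data (we measured this mimicry
at ≈0.13–0.17 per random gene at high penetrance).  Confirming
imprinting candidates against independent tissue data is out of scope
here; the classifier flags candidates only.

For the X chromosome, the consensus active X per line is the majority
direction over monoallelic X genes, excluding the Xist-like gene, which
is transcribed from the *inactive* X and must show the reverse
direction in every line.  Escape candidates are X genes evaluable but
non-conforming (biallelic, or significant in the anti-consensus
direction) in at least two lines.

## The expression cost of monoallelic expression

For genes monoallelic in some lines and biallelic in others, the paired
analysis takes per-gene means of log2(RPKM) in each state and
summarizes $\Delta_g = \overline{\log_2 \mathrm{bi}} -
\overline{\log_2 \mathrm{mono}}$ with a one-sample t-test; the headline
quantity is the ratio $100 \cdot 2^{-\bar\Delta}$ percent.  Means are
unweighted (pooled depth does not enter), trend/excluded lines are
omitted, and a per-line two-group Welch comparison with decile tables is
available as a cruder cross-check.  `dosage_model_expectation()` returns
0.5, the ratio if the number of active alleles were the only factor —
observed ratios near 0.64 indicate partial compensation.

## What the synthetic generator emulates

`generate_cohort()` draws a full cohort from a forward model:

* per-gene base expression: log2(RPKM) $\sim N(4.5, 2^2)$, per-line
  lognormal noise sd 0.4 (log2 scale) — a broad, realistic dynamic
  range in which ~7% of gene-lines fall below the RPKM threshold;
* pooled SNP depth: negative binomial with mean 50 and size 2 per
  gene-line, split equally over 1–5 cSNPs (each SNP takes an equal NB
  share, so the pooled depth is exactly NB(2, mean 50)); depth is drawn
  independently of expression, a simplification discussed below;
* allelic classes planted per gene with a per-line penetrance (allelic
  exclusion is stochastic): strain-biased genes always silence the same
  strain, random-monoallelic genes choose the expressed allele per line
  by fair coin, imprinted genes follow parental origin, X-linked genes
  follow the clone's active X; the silenced allele still contributes a
  1% contamination of reads (fully clean silencing is rare in practice);
* monoallelic states multiply the transcript level by
  `dosage_ratio = 0.6417`, so the expression-cost analysis has a known
  truth;
* escape and Xist-like genes have their base expression floored at the
  cohort median, since their real counterparts are constitutively well
  expressed;
* everything derives from one seed; equal configs give byte-identical
  cohorts.

Evaluability is *emergent*: depths and RPKM are drawn and the caller's
thresholds do the selecting, so the caller is honestly exercised near
its boundaries.

### The packaged profiles and their calibration

`cohort_profile("nsc-autosome")` encodes a four-line cohort (three lines
of one cross direction, one reciprocal) with 7,750 autosomal genes:
91 strain-A-biased at penetrance 0.66, 40 strain-B-biased at 0.88,
34 random at 0.90, two weak tiers of 550 strain-biased genes at
penetrance 0.10 (the reservoir of genes monoallelic in exactly one
line), and 3 imprinted genes at penetrance 1.  The class plan was
solved analytically from the per-class recovery rates and then refined
on simulation replicates so that the *expected* downstream composition
matches the cohort this design emulates: ≈7,200 genes evaluable in ≥2
lines, ≈476 monoallelic in ≥1 line, ≈170 in ≥2 lines, ≈8 classified
imprinted and ≈18 haplotype-independent, with per-line FDR in the
low-percent range.  Because classified-imprinted includes
random-mimics (above), the planted imprinted count is smaller than the
expected classified count.

Two numbers deserve honesty: the imprinted and both-alleles classes are
small (≈8 and ≈18 genes), and under fair-coin allele choice and
stochastic penetrance a single cohort draw has a standard deviation
near 3 genes for each.  Calibration is therefore assessed on means over
replicate cohorts (the test suite uses ten; Monte-Carlo SE ≈1), while
any single cohort can land a few genes off.  That variance is a
property of the study design being emulated, not a tunable.

`cohort_profile("nsc-x")` plants 292 X-linked genes with one active X
per clone (three clones share one direction, one is opposite), a
four-gene escape set and one Xist-like gene; ≈260–268 genes come out
evaluable in ≥1 line of which all but the escape set are monoallelic,
the consensus active X matches the planted configuration, and the
Xist-like gene is reversed in every line where it is evaluable.

### What passing synthetic tests does not show

The generator has no read-level errors, no alignment or mapping bias
(reference bias toward strain A is a known real-world hazard), no
overdispersion of allele counts beyond binomial (no beta-binomial
clonal heterogeneity), no correlation between depth and expression
level, and no linkage structure along chromosomes.  Recovery on these
cohorts validates the *logic and calibration* of the caller, not its
robustness to those artifacts.

## Numerical and design choices

* Doubled-tail two-sided p-value, capped at 1; ties at thresholds go to
  the more extreme category.
* Reads at different SNPs of a gene are pooled as independent
  observations; paired-end double counting is ignored.
* Clustering of the allelic-proportion matrix: Euclidean distance,
  average linkage; non-evaluable cells are imputed at the neutral value
  0.5 *for distance only* (never for calling); rows pre-sorted by label
  so equal inputs cluster identically; all-missing rows dropped with a
  warning.
* TSV coordinates are 1-based inclusive; strain A is always the
  reference-named strain in outputs.  The VCF importer reads per-sample
  `AD` depths of pre-phased strain alleles and requires a `GENE` INFO
  key.
* Problem sizes in the test suite (cohorts of a few hundred genes for
  unit properties, ten full-profile replicates for calibration, 5,000
  genes for null calibration) were chosen as the smallest that leave
  the binomial standard errors well inside the tolerances being
  asserted.

## Known limitations

Single-reciprocal imprinting evidence (above); no beta-binomial option;
no isoform-level quantification; no multiple-testing adjustment of
per-gene p-values (by design, FDR is reported cohort-wise); heatmap
rendering is convenience output without stability guarantees beyond the
cluster orders.
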