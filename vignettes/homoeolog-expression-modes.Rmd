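---
title: "Methods: homoeolog expression modes in synthetic allopolyploids"
author: "HomoeoExpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog expression modes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HomoeoExpress)
```

# The design this package analyzes

A synthetic allotetraploid (genome AADD) is compared with its two diploid
parents at the level of subgenomes and of 1:1 collinear homoeologous gene
pairs. The parental reference is not a physical sample but an equal-mass
in-silico mixture of the two parents' reads ("Mix") mapped against the
concatenated A+D reference: per gene, the expected Mix signal is half the
corresponding pure-parent rate, because each parent contributes half the
sequencing mass at fixed depth. Two tetraploid lines are analyzed: a
euploid (EUP) and a line carrying homozygous homoeologous segment
exchanges (X190), in which terminal segments of chromosomes 2D and 3D are
replaced by their 2A/3A counterparts, duplicating the A copies (copy
number ×2) and deleting the D copies (×0) inside those intervals. Each
genotype is observed under four conditions (mock-2d, PEG6000-2d, mock-5d,
NaCl-5d).

# Statistical model

## Normalization

Median-of-ratios size factors: with counts $k_{gj}$,
$s_j = \mathrm{median}_g\, k_{gj} / (\prod_{j'} k_{gj'})^{1/n}$ over genes
with a nonzero geometric mean. Factors are reported exactly as this
formula returns them; the normalization contract lives in their ratios
(scaling one library by $c$ scales its factor relative to all others by
$c$, while the geometric-mean reference absorbs $c^{1/n}$). Pipelines
compute one factor set over the samples their contrasts use (Mix and the
tetraploid lines); pure-parent samples express only one subgenome, so no
gene has a nonzero geometric mean across a matrix that includes them.

## Dispersion

Counts are negative binomial, $\mathrm{Var} = \mu + \alpha\mu^2$. Per
unit, $\alpha$ is a method-of-moments estimate on normalized counts pooled
within groups,
$\hat\alpha = (\hat v - \bar\xi\,\hat\mu)/\hat\mu^2$ with
$\bar\xi = \mathrm{mean}(1/s_j)$, floored at $10^{-8}$. With few
replicates this estimate is very noisy, so it is shrunk toward a
parametric trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted across units by a
gamma-family GLM (with outlier trimming and a flat-median fallback). The
combination is arithmetic, weighted by residual degrees of freedom against
a prior weight (default 10): at 3 vs 3 replicates the trend dominates,
which is what keeps the Wald test calibrated; at 50 replicates the
per-unit estimate dominates. Shrinkage is configurable
(`computeDispersions(shrink = FALSE)`).

## Wald test

For a two-group contrast the effect is the log ratio of group mean
normalized counts; a pseudocount of 0.5 enters only when a group mean is
exactly zero, so finite fold changes can be reported. The standard error
comes from the NB Fisher information of the two group log-means,
$I_g = \sum_j s_j\mu_g/(1+\alpha s_j\mu_g)$, giving
$z = \log(m_2/m_1)\,/\sqrt{1/I_1 + 1/I_2}$ against a normal reference.
No fold-change shrinkage is applied: reported log2 fold changes are raw
ratios. BH adjustment runs across all tested units of one contrast;
DEGs are padj < 0.05, strictly. No independent filtering or outlier
replacement is performed — the mean-count window is the only screen.

## Filters, in pipeline order

1. **HE / scaffold exclusion** — a gene is removed iff its interval
   overlaps an HE interval by ≥ 1 bp or its chromosome is unplaced. The
   exclusion applies to every genotype's analyses, including the euploid,
   so the DEG universes of EUP and X190 stay identical and comparable;
   otherwise the copy-number-amplified HE genes would inflate one line's
   DEG count by construction.
2. **Mean-count window** — a gene survives iff its arithmetic mean raw
   count over *all* samples lies in [10, 5000]. Both boundaries are
   inclusive: the rule removes means *below* 10 or *above* 5000, so the
   boundary values themselves survive.
3. **Pair length disparity** — a pair survives iff
   $|l_A - l_D|/\max(l_A, l_D) \le 0.10$. The denominator is a genuine
   open choice (the rule could use the shorter length or the mean); the
   longer transcript is used here because it is the conservative reading —
   it removes every pair the other denominators would remove, and more.
   Because surviving pairs differ by at most 10 %, copy-vs-copy contrasts
   are run on raw counts without transcript-length normalization.
4. **Expressed in at least one subgenome** — "expressed" is
   operationalized as the same mean-count ≥ 10 criterion used gene-wise.
   This is a documented package choice, not a claim about any particular
   study's unstated definition; both the threshold and the disparity
   denominator are arguments.

## Modes and attribution

For each analyzed pair, the A-vs-D contrast treats the two copies' counts
across the same samples as the two groups of the Wald test, each sample's
size factor serving both of its copy columns. The parental call is
computed *within Mix samples* — each Mix library contributes both copies —
which makes the parental and progeny contrasts structurally symmetric
(same replicate number, same normalization); whether a study computes the
parental call from Mix or from separate pure-parent libraries is an open
design point, and Mix is this package's documented choice. Crossing the
parental call with the progeny call yields modes 1–9 (conserved 1–3,
convergent 4–5, divergent 6–7, reversed 8–9); BH adjustment is per
contrast across analyzed pairs only, not across all genes, because the
pair universe is the analysis set. Percentages in summaries are rounded
half-up to two decimals, so printed tables match conventional reporting.

Attribution then labels each pair with its per-copy progeny-vs-Mix
direction (up / down / unchanged at padj < 0.05) and cross-tabulates the
labels per mode: convergent and divergent modes are expected to be driven
mostly by a change in a single copy.

## Enrichment

One-tailed hypergeometric over-representation, $P(X \ge k)$ for $k$ DEGs
among $n$ drawn from a universe of $N$ expressed genes of which $K$ carry
the term. The universe is the post-filter expressed set of the relevant
subgenome, terms with fewer than five expressed genes are excluded before
testing, and BH runs across the surviving terms. Annotations are taken as
flat gene-to-term pairs; no GO-graph propagation is attempted (whether to
propagate is an open question in such analyses, and the flat map keeps
the test exactly interpretable against its input).

# The simulator

`simConfig()` defaults define the study conditions:

| parameter | default | rationale |
|---|---|---|
| pairs / singletons / scaffolds | 2500 / 600+600 / 60+60 | desk-scale catalog with all gene classes present |
| replicates | 3 | typical bulk RNA-seq design (the underlying study design does not fix n; it is configurable) |
| dispersion α | 0.05 | mid-range for plant bulk RNA-seq |
| fold change | 4 | well-separated planted effects |
| baseline rate | log-uniform 50–1500 | inside the [10, 5000] mean window after halving in Mix |
| library factors | log-uniform 0.7–1.4 | exercises size-factor estimation |
| mode proportions | 8/8/60/9/7/3/4.5/0.3/0.2 % | the shape reported for nascent allopolyploids: conserved majority, convergent > divergent, reversed rare |
| length-disparity fraction | 0.2 | a fifth of pairs violate the 10 % rule, deterministically assigned so tallies are exact |
| HE intervals | Chr2A 0.8–51.8 Mb ×2, Chr2D 0.4–58.0 Mb ×0, Chr3A 684.6 Mb–end ×2, Chr3D 557.4 Mb–end ×0 | homozygous terminal segment replacement geometry |
| chromosome lengths | A 750 Mb, D 650 Mb | wheat-scale chromosomes accommodating the HE coordinates |

Genes are laid out at increasing positions, pair members at matching ranks
on matching chromosomes (collinearity). Modes are planted per pair and
condition; parental rates split a log-uniform baseline geometrically by
$\sqrt{f}$, and progeny states are realized by per-copy multipliers —
one-copy changes for convergent/divergent modes (which copy is Bernoulli,
default 0.5), two opposite changes for reversed modes. Mix is simulated as
its own sample group rather than computed from parent samples, preserving
the count noise of a sequenced mixture. Singleton genes carry planted
DEGs (defaults 5 % A, 10 % D — a mild D bias — with an optional
chromosome burst, default Chr5D under mock-2d). One master seed feeds
deterministic per-stage sub-streams, so identical configs give
byte-identical output files.

What the generator does *not* emulate: read-level artifacts (mapping
bias, multi-mapping between subgenomes), isoforms, biological covariance
between conditions, partial or heterozygous HEs, and dispersion that
varies per gene beyond the planted trend. Passing recovery tests
therefore show the statistics are implemented correctly and calibrated
under the stated model — not that real allopolyploid data meet that
model.

# Numerical choices and degenerate inputs

* Dispersion floor $10^{-8}$; constant counts return the floor.
* Dispersion 0 in the simulator means Poisson counts.
* Ratio ties: a pair is A=D whenever padj ≥ 0.05, including padj exactly
  0.05 (strict DEG inequality).
* Percentages round half away from zero (base R's `round` would give
  banker's rounding).
* Empty DEG sets, empty mode tables and zero-count summaries return
  well-formed all-zero objects rather than errors.
* Readers reject malformed input (negative, non-integer or missing
  counts, duplicate ids, start ≥ end) naming the offending row; nothing
  is coerced silently.
* Intervals are 0-based half-open on disk (BED convention) and 1-based
  closed in memory (GRanges convention); the conversion happens once in
  the readers/writers.

# Test and validation scale

The shipped suite validates each operation against independent oracles:
exhaustive enumeration for the 3×3 mode table and for hypergeometric
tails (all instances with N ≤ 25), a literal step-up implementation for
BH on 1000 random vectors, DESeq2's reference implementation for size
factors, and Monte-Carlo calibration of the Wald test (5000-gene null at
3 vs 3, type-I error within [0.03, 0.07]; 500 planted 4-fold genes,
power ≥ 90 %). Mode recovery is scored on a 2000-pair study over all four
conditions (≥ 90 % of pairs assigned their planted mode; observed ≈ 98 %)
together with an exact subgenome-swap symmetry check (relabeling A↔D maps
modes 1↔2, 4↔5, 6↔7, 8↔9 and fixes 3). These sizes were chosen so the
whole suite runs in a few minutes on one CPU while keeping every
Monte-Carlo bound comfortably away from its threshold.

# Known limitations

* The DE engine is a two-group Wald test; multi-factor designs,
  likelihood-ratio tests and fold-change shrinkage are out of scope.
* Cis/trans regulatory decomposition is not computed; convergent vs
  divergent proportions are reported as evidence, interpretation is left
  to the analyst.
* HE breakpoints are inputs, never inferred from the data.
* With 3 replicates, calibration leans on dispersion-trend shrinkage; on
  real data with gene-specific dispersion far from any trend, the test
  can be anticonservative for those genes.
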