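---
title: "Mining context-specific coexpression across many expression datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining context-specific coexpression across many expression datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexnet)
```

## The problem and the model

Public expression repositories hold hundreds of independently designed
experiments for well-studied organisms. Pooling all their samples into one
large matrix and correlating genes across it is the obvious move and the
wrong one: a regulatory relationship that is active only in roots, or only
under nitrogen starvation, contributes a strong correlation in the handful
of experiments that probe that context and noise everywhere else, so the
pooled estimate is diluted toward zero. `coexnet` instead treats the
*dataset* as the unit of evidence. For a focal gene $x$ (in the motivating
application, nitrate transporters of the NRT2/NPF/CLCa/SLAH families) and
any other gene $i$, the per-dataset Pearson correlation $r_k$ is computed
within each dataset $k$ over all of its samples, and the meta-analytic
coexpression weight is the plain average

$$R_{x,i} = \frac{1}{n}\sum_{k=1}^{n} r_k,$$

where $n$ counts the datasets in which the pair is measurable (both genes
present, both with nonzero variance); the table records this count as the
pair's *support*. Averaging defined weights only — rather than dividing by
the full corpus size — avoids penalizing genes absent from some platforms
or contexts; with a single-platform corpus the two conventions coincide.
The tissue-stratified variant $R'_{x,i}$ is the same average restricted to
the datasets whose samples all come from one tissue; a dataset's tissue is
defined by unanimity of its sample labels and is `"mixed"` otherwise.

Gene-to-pathway coexpression averages the gene-level weights over a gene
set $p$ with $m$ in-universe members,

$$R'_{x,p} = \frac{1}{m}\sum_{k \in p} R'_{x,k},$$

computed on a further-restricted dataset subset: only tissue-matched
datasets in which $x$ itself is differentially expressed contribute, on
the rationale that datasets where the focal transporter does not respond
carry no information about its regulatory context. Significance is
assessed by replacing the pathway with $B$ random gene sets of the same
size drawn from the gene universe minus $x$, scored identically; the
score is declared significant when *no* null replicate exceeds it, which
with the default $B = 100$ corresponds to an empirical $p$ below 0.01.
The numeric empirical $p$ is reported with the $(b+1)/(B+1)$ convention
so it is never zero, but the downstream network uses the binary flag, not
the number. Ties between a null score and the observed score do not count
as exceeding. Comparisons are on signed scores: the networks of interest
are built from positive coexpression, and the ranking policy (signed by
default, $|R|$ optionally) is a network-assembly choice, not a scoring
one.

## Differential expression and the DE-frequency profile

Each dataset is scanned gene by gene with a one-way fixed-effects ANOVA
across its replicate groups (an omnibus test, which reduces to the pooled
two-sample $t^2$ when there are two groups), followed by
Benjamini–Hochberg adjustment *within* the dataset's gene family. The
default DE call is $q < 0.001$; the threshold and whether it applies to
$q$ or raw $p$ are configuration parameters, since corpus studies have
used both conventions. Genes with zero variance in a dataset are
untestable there and are excluded from that dataset's BH family; datasets
with fewer than two replicate groups of two or more samples are
untestable outright. The DE-frequency table then reports, per gene and
tissue, the fraction of that tissue's testable datasets flagging the
gene — the statistic used to contrast, say, root-specific and
leaf-specific transporter activity. A dataset not measuring a gene is
excluded from that gene's denominator.

## Why a fixed correlation cutoff is not used

The smallest correlation significantly different from zero depends
strongly on sample size: under the bivariate-normal null,
$r^* = t^*/\sqrt{t^{*2} + n - 2}$ with $t^*$ the two-sided $\alpha$
critical value of Student's $t$ on $n-2$ degrees of freedom —
`critical_pcc(10, 0.05)` is 0.63 while `critical_pcc(100, 0.05)` is 0.20.
A single cutoff applied across a heterogeneous corpus would therefore be
alternately too lax and too strict. The pipeline sidesteps the issue the
way hub-focused studies do: it ranks partners and keeps the top $k$
(default 20) per focal gene, and lets edge width carry the averaged
weight. Boundary ties are broken by ascending gene ID so networks are
reproducible byte for byte.

## Network assembly rules

The gene network is the union of top-$k$ partner lists over the focal
genes; when one focal gene occurs in another's top-$k$ the pair yields a
single undirected edge. The edge count is therefore bounded by
$|F| \cdot k + \binom{|F|}{2}$. The pathway network keeps, per focal
gene, only significant pathway scores, ranks them across tissues jointly,
takes the top 10 (the per-transporter reading of the caption rule), and
then drops edges supported by fewer than 5 datasets of the tissue. Both
networks export to GraphML (full typed attributes, exact re-import), SIF
and TSV. Finally, the gene-network members minus the focal genes are
tested for gene-set over-representation with the hypergeometric upper
tail against the measured-gene universe — the standard array-background
choice, made explicit here because enrichment p-values are meaningless
without naming the background.

## The synthetic test bed

Real corpus inputs (normalized series with curated replicate groups and
tissue labels) are expensive; every statistical property of the pipeline
is instead exercised on synthetic collections with known planted
structure. Each dataset is a genes × samples Gaussian matrix on a
log-expression-like scale: gene-specific baselines uniform on [4, 12]
(the typical RMA range), residual noise with `noise_sd = 1` expression
unit, 12 samples in 2 replicate groups per dataset by default — the
corpus inclusion minimum. Planted partners are generated from the focal
gene's *standardized final* latent (after any planted group shift), so
the population correlation equals the requested $\rho$ exactly even when
the focal gene is also a planted DE gene; planted DE genes receive a mean
shift $\delta$ (expression units) on even-numbered replicate groups in
tissue-matched datasets. One global seed expands into per-dataset
substreams via a fixed counter scheme (`seed + 92821 k mod 2^31 - 1`), so
enlarging a collection never perturbs the datasets already generated.

What the generator deliberately does not emulate: probe-level artifacts,
batch effects, missing values, heavy-tailed or count-like noise, and
correlated background structure. Tests passing on this bed demonstrate
that the estimators and decision rules do what they claim under the
model's assumptions — Gaussian noise, independent datasets — not that
the pipeline is robust to everything a real microarray corpus contains.

Because $\rho$ is enforced at the population level, recovery checks use
tolerance bands: across $n$ datasets of $s$ samples the averaged weight
has standard error about $(1-\rho^2)/\sqrt{(s-3)\,n}$ (Fisher-z delta
method), and the test suite asserts recovery within two such standard
errors at $\rho \in \{0.5, 0.8\}$ on 30 datasets of 20 samples. Detection
power for planted DE is likewise checked where exact noncentral-$t$
theory supports it: at $\delta/\sigma = 4$ the $p < 10^{-6}$ criterion
reaches 99% power only with replicate groups of about 14, so that is the
setting the power test uses.

## Numerical and design choices

* Degenerate ANOVA inputs follow fixed conventions rather than erroring:
  zero within-group variance with unequal means gives $p = 0$ (flagged);
  zero variance everywhere gives $p = 1$ (flagged, untestable).
* Correlations pool all samples of a dataset regardless of replicate
  group — one $r_k$ per dataset — and pairs are computed
  pairwise-complete with no imputation.
* The permutation null reuses the observed score's dataset restriction,
  so observed and null scores are exchangeable; the focal gene is
  excluded from the sampling pool to keep its self-correlation of 1 out
  of the null.
* Every stochastic stage takes an explicit seed; batch scoring derives a
  per-combination substream (`seed + 48271 i`) so a single combination's
  null is reproducible in isolation.
* Duplicate gene rows are rejected, not collapsed: probeset-to-locus
  collapsing belongs to corpus preprocessing, where the user can document
  the rule used; the pipeline core assumes one row per gene.
* Simulation sizes in the tests (up to 30 datasets × 20 samples × 1000
  genes, 1000-dataset DE nulls, 2000 permutation triples) were chosen as
  the smallest designs whose sampling error is well below the assertion
  bands.

## Known limitations

Stratified averages weight every dataset equally regardless of its
sample count, as the plain-average definition dictates; a
precision-weighted variant would behave differently for very
heterogeneous corpora. The empirical-p resolution is bounded by $B$
(at $B = 100$, nothing below 1/101), which is why the significance flag
rather than the numeric $p$ drives edge inclusion. Enrichment treats
gene sets as flat lists with no ontology structure. And the DE
restriction for pathway scoring makes those scores conditional on the
focal gene responding somewhere in the tissue — transporters that are
constitutively expressed yield no pathway edges by construction.
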