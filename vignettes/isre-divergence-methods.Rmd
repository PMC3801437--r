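---
title: "Methods: ISG classification and ISRE motif divergence"
author: "isremotif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ISG classification and ISRE motif divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isremotif)
```

## The scientific question

Type-I interferon (IFN-β) induces hundreds of interferon-stimulated genes
(ISGs) through the ISGF3 complex (tyrosine-phosphorylated STAT1 and STAT2
with IRF9) binding interferon-stimulated response elements (ISREs) in ISG
promoters. A distinct complex built from *unphosphorylated* STATs, U-ISGF3,
sustains a subset of those genes at late times. This package implements the
two computational halves of that analysis:

1. **Classification** — from duplicate bead-array expression data, identify
   genes induced by IFN-β, intersect them with genes induced by upregulating
   a non-phosphorylatable STAT1 mutant (Y701F, a proxy for U-ISGF3
   activity), exclude the IFN-γ-responsive overlap, and so partition ISGs
   into a *U-ISGF3-induced* set and a *classical-ISGF3-only* set.
2. **Motif comparison** — scan both sets' promoters for ISREs with a
   position weight matrix (PWM), collect each gene's best site extended by
   its 5′/3′ flanks, and ask whether the two site populations differ, using
   a symmetrized position-averaged Kullback–Leibler (KL) divergence with a
   label-permutation significance test.

The biological claim being probed is that U-ISGF3-responsive promoters carry
canonical ISRE cores with *additional conserved flanking sequence*, so the
statistic must be sensitive to flank differences while ignoring
sampling noise in the shared core.

## Expression classification

Arrays are quantile-normalized: each column's rank-*r* value is replaced by
the mean of all columns' rank-*r* values, so all samples share one empirical
distribution. Replicates (duplicates in the emulated design) are reduced by
their linear-scale mean. A gene is called induced when all three gates hold:

* differential p-value ≤ 0.05 (inclusive),
* treated average signal > 25 (strict),
* fold change > 2 (strict), with fold = mean(treated)/mean(control) on the
  linear scale.

The differential test is a two-sample pooled-variance t-test on
log2(value + 1). This choice is deliberate: it is reproducible from the
numbers alone with only two replicates per condition, needs no vendor
software, and its pooled variance is the natural small-*n* default. Welch
and limma's moderated-t are available (`test =` argument) for sensitivity
analysis; no multiple-testing correction is applied by default because the
filter criteria are raw per-gene p-values (a BH option would be a one-line
wrapper around `p.adjust` and deliberately is not the default). Set algebra
then defines the groups: `u_isgf3 = ifnb ∩ yf`,
`isgf3_only = ifnb − u_isgf3 − ifng`.

Two unstated details were resolved as follows: the signal filter is applied
*after* normalization (the filter refers to the analyzed, i.e. normalized,
signals), and when several probes map to one gene the maximum-mean probe
would be taken (the synthetic data are probe-unique, so this path is
exercised only by user data).

## Promoter windows and PWM scanning

Promoter windows span 2500 bp upstream to 500 bp downstream of the
transcription start site. The downstream span is read as *including* the TSS
base, giving 3001 bp; the convention is configurable, and windows clipped at
chromosome ends are flagged. Minus-strand windows are reverse-complemented
so all sequences read 5′→3′ relative to their gene. Internally coordinates
are 0-based half-open; BED output keeps that convention.

A placement of a width-*L* PWM is scored in bits as
\[ s = \sum_{i=1}^{L} \log_2 \frac{p_i(b_i)}{q(b_i)} \]
against a background \(q\) that defaults to the base composition of the
analyzed window set (uniform and user-supplied backgrounds are options).
Count matrices become probabilities with an additive pseudocount,
\((c+\epsilon)/(n+4\epsilon)\), default \(\epsilon = 0.01\) for scanning.
Both strands are scanned; placements overlapping `N` are skipped. The
bundled ISRE matrix (`isre_matrix()`) is a *synthetic stand-in* with the
canonical tandem-GAAAC architecture, shipped because the commercial
reference matrices cannot be redistributed; any JASPAR/TRANSFAC/MEME file
can be substituted.

Set-level over-representation uses a CLOVER-style statistic: per sequence,
the arithmetic mean over all placements (both strands) of the likelihood
ratio \(\prod_i p_i(b_i)/q(b_i)\); the set score is the mean over sequences
of the natural log of that per-sequence mean. Significance comes from
composition-preserving shuffles of each window
(`p = (1 + #{null ≥ obs}) / (n_null + 1)`). The original enrichment tool is
cited without formulas in the literature this package follows, so this exact
score is fixed here as the package's reproducible definition; it shares the
original's ingredients (averaged likelihood ratios, sequence-shuffle null)
without claiming numerical identity.

For motif comparison, `collect_group_sites()` keeps each gene's best-scoring
site (ties: smaller offset, then plus strand), extends it by `flank_width`
(default 5 bp) on each side, and reverse-complements minus-strand sites so
all are in motif orientation. The default score threshold is 60% of the
PWM's maximum attainable score, a conventional relative-score cut; genes
with no site above it are omitted and reported. Sites are anchored on the
PWM match — no realignment is performed, so an alignment-free per-position
comparison downstream is valid.

## Divergence statistic and its null

Group PFMs are estimated from the aligned flank-extended sites with a
Laplace-half pseudocount (0.5), which guarantees strictly positive
probabilities and finite divergences. The statistic is, per position,
the Jeffreys-type arithmetic mean of the two directed KL divergences,

\[ D_i = \tfrac{1}{2}\Big[\sum_b p_i(b)\log_2\frac{p_i(b)}{q_i(b)}
   + \sum_b q_i(b)\log_2\frac{q_i(b)}{p_i(b)}\Big], \]

averaged over positions: \( \bar D = \frac{1}{L}\sum_i D_i \) (bits; a
natural-log variant is a trivial rescale). \(\bar D \ge 0\) with equality
iff the PFMs coincide, and it is symmetric in its arguments — both are
property-tested.

Significance is by label permutation: pooled sites are relabelled uniformly
at random preserving group sizes, PFMs rebuilt, \(\bar D\) recomputed, and
`p = (1 + #{perm ≥ obs}) / (n_perm + 1)` (default 999 permutations). The
permutation null was chosen over analytic approximations because the
per-position divergences of a plug-in PFM estimator are biased upward at
small *n* in a way that depends on the pseudocount; exchangeability is the
only assumption the permutation test needs, and the add-one p-value
estimator keeps it exact and bounded in \([1/(n_{perm}+1), 1]\).

Exploratory structure in the site populations is exposed by k-means on
one-hot-encoded sites (4L-dimensional vectors, Lloyd's algorithm, best of 20
restarts, silhouette-selected *k*, purity against group labels). Logo
tables report per-position information content
\(IC_i = 2 + \sum_b p\log_2 p - e(n)\) with the standard small-sample
correction \(e(n) = 3/(2\ln(2)\,n)\) on by default, and letter heights
\(p_i(b)\,IC_i\).

## The synthetic-data generator

The generator exists so that every stage has a planted ground truth.

**Expression.** Four conditions (control, IFN-β, Y701F-STAT1, IFN-γ) in
duplicate. Per-gene baselines are log-normal (log2 mean 7, sd 1.5 —
mid-dynamic-range bead-array intensities); induced gene–condition pairs
multiply the baseline by a fold drawn log2-uniformly from [4, 16]; every
sample gets multiplicative log-normal noise (additive Gaussian on log2,
sd 0.2 by default — a typical between-duplicate spread for well-expressed
probes; the emulated study does not publish its noise characteristics, so
these defaults are calibration placeholders, not estimates). Membership
mirrors the studied partition: `ifnb_only`, `u_isgf3` (induced by IFN-β and
Y701F), `ifng_overlap` (induced by IFN-β and IFN-γ).

**Promoters.** I.i.d. background with composition A/C/G/T =
0.3/0.2/0.2/0.3 (human promoter-like), default length 3000 bp. Each
sequence carries one embedded ISRE core sampled column-wise from the core
PWM (one site per promoter by default, matching the one-conserved-element
analysis; a multi-site mode exists). Group A cores get background flanks;
group B cores get flanks matching a fixed group consensus with probability
`flank_conservation` per base (width 5 bp per side by default). The whole
flank+core+flank block is reverse-complemented with probability 0.5.
Setting conservation to 0 makes the groups exchangeable — the null
configuration used for calibration.

What the generator does **not** emulate: bead-level technical structure
(probe effects, bead variance), first-order sequence dependence (a
transition-model background is configurable but i.i.d. is the default), CpG
islands, repeats, or multiple motif classes per promoter. Passing tests
therefore demonstrate correctness of the statistics under a clean generative
model, not robustness to every artefact of real arrays or real promoters.

## Numerical choices and degenerate inputs

* Quantile normalization breaks ties by original row order, so output
  columns are exact permutations of one common vector (checked to 1e-9).
  Note that when a large fraction of a small panel is strongly induced,
  rank-mean averaging compresses true fold changes — an inherent property
  of the method, negligible at genome scale (≈4% induced in the study-scale
  runs here) but visible on toy panels.
* Zero control means make fold change undefined: the gene is flagged,
  excluded, and a warning raised.
* Scanning allows zero PWM probabilities (score −∞, never selected);
  KL requires strict positivity and fails with a pointer to the
  pseudocount.
* K-means on one-hot vectors can contain duplicate points; a deterministic
  jitter of ~1e-6 keeps Lloyd's random starts distinct and moves reported
  sums of squares by < 1e-9.
* All stochastic stages take explicit integer seeds and are
  byte-reproducible under them.

## Problem sizes used in the shipped checks

The calibration and power experiments are sized to be decisive yet quick:
power uses 100 seeded datasets of 30 promoters (3 kb) per group at flank
conservation 0.9 with 999 permutations each; type-I calibration uses 1000
exchangeable-null datasets with 199 permutations each (rejection must fall
inside the binomial 95% CI of 0.05); scan/set-score oracle equivalence uses
100 random windows up to 100 bp against brute-force enumeration at 1e-9.
The study-scale classification check uses a 4000-gene panel with 150
planted induced genes (the 48/29/73 structure), run through the complete
file-based workflow including normalization.

## Known limitations

* The differential test on n = 2 duplicates has low power by construction;
  the defaults reproduce the studied filter logic rather than optimize
  detection.
* The CLOVER-style score and the permutation null are this package's fixed,
  documented definitions of loosely specified upstream methods; numbers are
  reproducible against *this* definition.
* Site collection keeps one site per gene; promoters with several distinct
  ISREs contribute only their best match to the PFMs.
* The symmetrized KL compares aligned, equal-length site sets; motifs that
  differ by indels or alignment offset are out of scope.
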