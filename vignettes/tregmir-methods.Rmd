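---
title: "Methods: miRNA/mRNA integration for TGF-beta/atRA-induced Tregs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA/mRNA integration for TGF-beta/atRA-induced Tregs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tregmir)
```

## The scientific problem

Naive CD4+ T cells activated in the presence of IL-2 plus TGF-beta and
all-trans retinoic acid (atRA) differentiate into induced regulatory T
cells (iTregs) far more efficiently than with IL-2 alone. One proposed
mechanism is post-transcriptional: the TGF-beta/atRA condition switches on
a set of microRNAs that destabilize transcripts required for the competing
pro-inflammatory Th17 program (notably IL-6/JAK/STAT components). The
analytical question this package addresses is how to go from one-colour
microarray signal matrices for three conditions — freshly isolated naive T
cells (`naive`), activation with IL-2 alone (`med`), and activation plus
TGF-beta/atRA (`tgf_atra`) — to

1. the set of miRs *exclusively detected* under TGF-beta/atRA,
2. the concordantly downregulated transcripts predicted to be their
   targets, with targeting-multiplicity and context++ score statistics, and
3. the pathways enriched in those targets.

The experimental design is three donors (umbilical cord blood units), each
contributing one array per condition: a paired 3 x 3 design, nine profiles
per platform.

## Pipeline and models

### Normalization

Signals are quantile normalized on the linear scale, forcing every
sample's empirical distribution to the common reference (the row mean of
the column-sorted matrix). Ties within a sample receive the mean of the
reference values at the ranks they jointly occupy — the standard
convention, and the one that makes the map idempotent on tie-free data.
Values are then transformed with `log2(x + offset)` (offset 1 by default,
guarding near-zero signals) and replicate probes of one feature are
collapsed by their arithmetic mean. The order — normalize, log, average —
follows the usual one-colour array convention; it is configurable because
nothing in the data dictates it.

miR differential expression is computed at the feature (miR) level after
replicate-probe averaging; mRNA differential expression is computed at the
probe level, with probes mapped to unique gene symbols only when the
down/up-regulated gene universes are built. This mirrors how such analyses
report "transcript probes" first and unique genes second.

### Moderated t-tests

For each feature, a one-way group-means model gives per-condition means
and a pooled residual variance \(s_g^2\) on \(d_g = N - G\) degrees of
freedom. Variances are shrunk toward a common prior \(s_0^2\) with prior
degrees of freedom \(d_0\), estimated by moment matching of
\(\log s_g^2\) against a scaled F distribution: with
\(e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)\), the excess of
\(\mathrm{var}(e_g)\) over \(\psi'(d_g/2)\) identifies \(\psi'(d_0/2)\)
(solved by Newton iteration on the trigamma function), and \(s_0^2\) is
recovered from \(\bar e\). When the observed spread does not exceed the
sampling variability, \(d_0 = \infty\) and \(s_0^2\) is the
bias-corrected geometric mean \(\exp(\bar e)\). The moderated statistic is

\[
\tilde t_g = \frac{\bar y_{gA} - \bar y_{gB}}
  {\tilde s_g \sqrt{1/n_A + 1/n_B}},
\qquad
\tilde s_g^2 = \frac{d_0 s_0^2 + d_g s_g^2}{d_0 + d_g},
\]

with \(d_0 + d_g\) degrees of freedom and two-sided p-values. With
\(d_0 = 0\) this is exactly the classical pooled two-sample t (a tested
identity); with \(d_0 = \infty\) every feature uses \(s_0^2\).
Benjamini–Hochberg adjustment is applied per contrast, and "DE in any
condition" is the union of the per-contrast significant sets — the
standard per-contrast convention. The three contrasts are
`tgf_vs_naive`, `med_vs_naive` and `tgf_vs_med`.

Although the design is donor-paired, the default fit is an unpaired
group-means model: the pairing term is deliberately omitted, which is
conservative (donor variance inflates the residual rather than the false
positive rate). The unit tests cross-check the whole moderated-t path
against limma's `lmFit`/`eBayes` on heteroscedastic data.

### Exclusivity filtering and set logic

Detection calls (the Agilent `gIsGeneDetected` analogue) are collapsed
from probe to miR level by an any/all policy (default: detected if any
probe is). The exclusivity rule is read strictly: a miR must be detected
in *all* `tgf_atra` samples and undetected in *all* `naive` and all
`med` samples (`all_all`). A laxer `all_any` policy (complete absence in
at least one of the two comparison groups) is available but non-default;
the strict reading is what "exclusively detected" means, and the strict
set is provably contained in the laxer one. Three-set Venn partitions of
the per-contrast up/down sets, and a cross-check that ties the
"commonly induced, not induced by activation alone" miRs back to the
detection-call exclusive set, complete this stage.

### Target mapping and enrichment

A TargetScan-style site table (gene symbol, transcript, miR, per-site
context++ score; the release-7 flat-file header or a generic 4-column
dialect) is indexed after miR-name normalization (species prefix
stripped, stem case-folded, arm suffix preserved). A gene is "in the
database" if any of its transcripts appears; per-gene context++ scores
are summed over all sites of all query miRs across the gene's
transcripts, and a per-transcript view is retained in the records. Query
miRs absent from the database are reported separately and excluded from
per-miR averages. The headline statistics are the fraction of the
down-regulated universe targeted by at least one query miR, the fractions
targeted by >= 2 and >= 15 miRs (relative to targeted genes), targets per
miR (mean/min/max), and the contrast of all of these against the
up-regulated universe.

Pathway enrichment is a local Functional-Annotation-Chart stand-in: for
each gene set, the hypergeometric upper tail \(P(X \ge k)\) (one-sided
Fisher) and the conservative EASE variant computed with overlap
\(\max(k-1, 0)\); EASE is the default because it is what the DAVID chart
reports. The default background is the set of unique genes measured on
the mRNA platform (the uploaded-universe convention); the
database-gene background is selectable. BH adjustment is applied across
terms.

### Assay closed forms

Two wet-lab quantities are provided as formulas: relative qPCR expression
\(2^{-\Delta\Delta Ct}\) with \(\Delta\Delta Ct\) anchored at the
*median* control \(\Delta Ct\) (so an odd-sized control group has median
RQ exactly 1), and percent suppression
\(100\,(1 - \text{cocultured}/\text{alone})\) from proliferation
fractions, which may legitimately be negative.

## The synthetic-data generator

`simulate_treg_arrays()` generates the full input bundle (miR and mRNA
signal matrices, probe-level detection calls, sample sheet, target
database, pathway GMT, ground truth) with the statistical structure the
analysis assumes:

* **Signal model.** log2 signal = baseline + condition effect + donor
  effect + probe-affinity offset + N(0, `noise_sd`); the stored matrix is
  `2^log2` (positive, log-normal). Detection calls threshold the noisy
  log2 signal at `detection_threshold` per probe and sample.
* **Design.** Three donors shared across the three conditions (paired),
  `replicate_probe_copies` probes per miR, surplus mRNA probes
  re-measuring random genes.
* **miR structure.** A mixture of expressed and unexpressed baselines;
  30 *exclusive* miRs planted `detection_margin` (2.5 log2 units) below
  threshold in naive/med and the same margin above it in `tgf_atra`
  (a 6-sigma gap at the default noise, so the strict filter recovers them
  essentially always); 20 activation-induced miRs (up in both activated
  conditions); 20 + 20 additional TGF/atRA-only induced/repressed miRs.
  This yields roughly 90-120 DE miRs of 851 and makes the miR profiles
  cluster the way the emulated study describes: the `tgf_atra` samples
  group on their own while naive and med profiles are more alike.
* **mRNA structure.** Pools of genes repressed (-1.5 log2) or induced
  (+1.5) in `tgf_atra` only, plus activation-driven pools moving in both
  activated conditions. Each exclusive miR draws
  `n_planted_targets_per_mir` targets from the repressed pool (overlaps
  between miRs create the >= 2-miR multiplicity) plus random decoy
  targets; non-exclusive decoy miRs target random genes so the down-vs-up
  coverage contrast is non-degenerate. Two exclusive miRs are withheld
  from the database to exercise the absent-from-db reporting.
* **Scores and pathways.** Per-site context++ scores are uniform on
  [-0.6, -0.05]; one planted pathway is drawn from the repressed pool
  (so enrichment has a known right answer) alongside random pathways.
* **Determinism.** All randomness flows through the single config seed
  with fixed RNG kinds; the same config and seed reproduce the dataset
  byte for byte, and the caller's RNG state is restored.

None of the effect magnitudes are reported by array studies of this kind
at the level needed here, so the defaults are chosen once as realistic
for strong treatment effects on a one-colour platform (fold changes of
about 3x against residual noise of 0.4 log2 units, donor effects slightly
smaller than treatment effects) and are not revisited.

**What the generator does not emulate:** probe-level spatial artifacts,
dye chemistry, background-correction internals, intensity-dependent
variance trends, and correlated (pathway-structured) expression noise.
Passing the planted-recovery tests therefore shows the pipeline is
correct under the assumed signal model, not that real arrays meet those
assumptions.

## Numerical choices and degenerate inputs

* Quantile-normalization ties take the mean reference value of the
  occupied ranks; idempotence is exact only for tie-free columns.
* A constant sample column under the Spearman metric has undefined
  correlation; its distance is defined as 1, with a warning.
* `estimate_hyperparameters()` requires at least 10 features with
  positive variance, drops zero variances from the moment fit, and errors
  when all variances are zero.
* Zero posterior standard errors yield t = 0 when the effect is 0 and
  +/- Inf (p = 0) otherwise.
* The trigamma inverse is a Newton iteration with closed-form guards for
  very large and very small arguments.
* BH adjustment delegates to `stats::p.adjust(method = "BH")`.
* Unmapped probes in universe building are dropped and counted;
  duplicate `(miR, site)` rows in the target database are deduplicated
  and counted; rows with unparsable scores are dropped and counted.

## Problem sizes used in the tests

The shipped test-suite and acceptance script run entirely on synthetic
data: the default 851-miR x 2000-probe x 9-sample dataset for the
planted-recovery and pipeline checks, 2000-feature simulations for the
moderated-t oracle, hyperparameter-recovery (10 seeds) and FDR-control
(50 seeds) properties, and small enumerable fixtures for the exact
combinatorial oracles (Venn regions, brute-force target double loops,
hypergeometric tails at N <= 200). These sizes keep a full run in the
tens of seconds on one CPU while leaving every statistical property
testable; all of them scale up through the config if desired.

## Known limitations

* The pipeline quantifies *predicted* targeting (context++ sites), not
  measured repression; the planted ground truth conflates the two by
  construction, which real data will not.
* BH per contrast (rather than globally across contrasts) and the
  unpaired fit are conventions, selectable but not exhaustively explored.
* The enrichment stand-in scores user-supplied GMT sets; it does not
  reproduce any annotation database or term clustering.
* Full-scale reproduction of the motivating study's counts requires the
  original deposited arrays (GEO series GSE93858) and a TargetScan
  release-7 flat file; the package reads both formats, but those runs are
  download-gated and outside the shipped tests.
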