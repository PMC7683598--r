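---
title: "coregscan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coregscan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

coregscan asks whether whole functional classes of transcriptional
regulators — transcription factors (TF), coactivators (COA), corepressors
(COR) and mixed-function coregulators (MIXED) — are altered in tumor
cohorts more than chance predicts, and then follows the significant
classes down to individual genes: recurrent-alteration filtering,
cross-cohort intersection, quartile-stratified survival screening, and a
cis-regulation cascade that intersects a regulator's binding peaks with
chromatin states and differential expression. This vignette records the
statistical model behind each stage, the parameters that matter, and the
design decisions taken where the methodology was genuinely open.

# The gene-class catalog

Classes are built from ontology-style annotation records plus canonical
TF lists. Each record resolves to positive or negative evidence of
transcriptional control by case-insensitive substring matching of its term
label against configurable phrase lists (`default_phrase_config()`);
records that match no phrase and carry no explicit polarity are an error
rather than silently dropped, because a silently ignored record would bias
class composition.

Classes must be disjoint. The precedence is **TF > MIXED > COA/COR**: a
gene on any canonical TF list is a TF regardless of coregulator evidence;
among the rest, genes with both positive and negative evidence are MIXED,
and only exclusive evidence yields COA or COR. TF-first reflects that the
canonical lists are curated independently of the ontology evidence and
are the higher-confidence assignment; the provenance column records every
contributing source so the choice is auditable. Gene identity is the
upper-cased symbol; synonym resolution is deliberately *not* performed —
callers must harmonize symbols upstream, because silent synonym matching
is a common source of irreproducible gene lists.

# Alteration scores

**Tumor–normal Z-scores.** For cohorts with ≥ 2 normal samples,
\(Z_{gs} = (x_{gs} - \bar x_{g,\mathrm{normal}})/s_{g,\mathrm{normal}}\)
with the \(n-1\) SD. Genes detectable in fewer than 80% of samples are
dropped first ("at least 80%" is a non-strict bound, so 79% detection is
excluded); *detectable* means non-missing and above a configurable floor
(default 0), since detectability is otherwise undefined for continuous
matrices. The 80% applies to all samples by default (configurable),
because restricting to tumors only would let a gene absent from every
normal pass the filter and then produce undefined Z-scores. Zero-variance
genes are dropped with a warning rather than yielding infinities.

**Median-centered Z-scores** serve cohorts without normals:
\((x - \mathrm{median}_g)/s_g\) per gene row.

**Mutation burden.** The per-gene score is
\(\sqrt{m_g / L_g}\), where \(m_g\) is the cohort-summed mutation count
and \(L_g\) the *genomic union* of all exon intervals (alternative exons
counted once — summing them would double-count shared bases). The square
root damps the dependence of the score's spread on cohort size. The
pre-sqrt rate and a per-tumor variant are exposed because the verbal
definition of this normalization admits more than one reading; the choice
is recorded in the output rather than hidden.

**Copy number** uses GISTIC codes as provided: deep calls are ±2, "any"
calls |code| ≥ 1. Codes outside {−2..2} are an error.

All genomic coordinates throughout the package are 0-based half-open.

# The family resampling test

For class \(C\) (\(k\) genes) with scores over a universe \(U\) of
\(n\) detected genes, the observed statistic is compared with \(B\)
random size-\(k\) subsets of \(U\), sampled without replacement within
each draw. The empirical p-value uses the add-one estimator
\(p = (1 + r)/(B + 1)\) with \(r\) the number of draws at least as
extreme. Consequences worth knowing:

* the p-value can never be 0; its floor is exactly \(1/(B+1)\)
  (\(10^{-5}\) at \(B = 10^5\));
* when the class *is* the universe, every draw reproduces the observed
  statistic and \(p = 1\) exactly;
* ties count against significance (conservative).

Because permuting a vector changes floating-point summation order, two
algebraically identical statistics can differ in the last bits; extremes
are therefore counted with a \(\sqrt{\varepsilon_{\mathrm{mach}}}\)-scale
tolerance, in the conservative direction. Without it the
class-equals-universe identity fails on real hardware.

Three statistics are implemented because the methodology is described
both as a proportion-beyond-threshold (fraction of class genes altered by
more than \(t = 2\) Z-scores) and as a mean-rank comparison; the mean
score is the natural third. The panel default is the proportion statistic
with \(t = 2\). Note that the per-gene score entering the panel is the
*mean Z across tumors*, whose spread shrinks with cohort size; a
\(|Z| > 2\) proportion on that scale is a stringent recurrence criterion,
and for diffuse shifts (many genes, modest effect) the `mean` or
`mean_rank` statistics are the powerful choice — the package's own
recovery experiments use `mean` for exactly that reason. Resampling is
over the cohort-detected universe, not the full catalog, so the test asks
"is this class unusual *among genes this cohort can see*".

FDR is Benjamini–Hochberg across the whole panel within each data type;
classes that are empty after detection-restriction appear as flagged
skipped rows so a silent drop can never masquerade as a negative result.
Hypergeometric over-representation against external gene sets (fitness
genes, loss-of-function-protected genes) uses the upper tail of
`phyper`.

# Filtering, clustering, intersection

The recurrent-alteration filter keeps genes with \(|Z| > t\) (strict) in
at least a fraction \(f\) of tumors (non-strict). Both published
threshold variants ship as presets (`text-2.0`, `figure-2.5`, both with
\(f = 0.35\)); direction defaults to `either` because filtered heatmaps
show both tails. The filter is monotone in both parameters, which the
tests verify.

Tumor clustering is hierarchical (Euclidean, complete linkage — the
defaults of the common clustered-heatmap tools), cut at \(k = 2\);
cluster–clinical association is a Pearson chi-squared without continuity
correction, with continuous clinical variables dichotomized at the median
first. Cross-cohort gene lists are intersected exactly: a membership
matrix over the union plus exclusive combination sizes, whose sum equals
the union size by construction.

# Survival screening

Per gene, tumors are split at the expression quartiles (linear
interpolation quantiles): lower group ≤ Q1, upper group ≥ Q3, middle half
excluded. Boundary ties are *included* by default (group sizes may exceed
n/4); a strict rule is available. The split is monotone-invariant, so
whether raw expression or Z-scores are supplied is immaterial unless
missingness differs. Groups are compared with the standard two-group
log-rank test (hypergeometric variance, no extra tie correction), the
survival curve itself is the product-limit estimator via the `survival`
package, and BH correction runs across the genes actually screened within
one cohort; genes with an undefined split (constant expression) are
reported `NA` and excluded from both sides of the correction.

# The cis-regulation cascade

Peaks are linked to genes whose anchor lies within \(W = 100\) kb
(defensible given reported median enhancer–target distances well above
promoter scale); the anchor is the TSS by default with a gene-body option.
Distance is strand-ignorant, from the nearest peak edge, with 0 for
overlap; with half-open intervals a peak whose nearest edge is exactly
\(W\) away is linked and \(W + 1\) is not. Peaks are retained if they
overlap a chromatin-state segment by ≥ 1 bp (half-open: touching
intervals share no base). Both operations run on GenomicRanges overlap
machinery and are property-tested against brute-force all-pairs loops.

Cohort-side differential expression between upper- and lower-quartile
tumors of the index regulator uses a two-sample rank-sum test with
logFC = difference of group means — a deliberate, documented substitution
for a count-model DE fit, appropriate here because only the significance
flag and direction enter the cascade. Knockdown DE is an input (or comes
from the synthetic generator). DEG significance defaults to FDR < 0.05
and |logFC| > 1.5, configurable because published DEG counts for the same
experiment differ between threshold statements.

The final network is the exact three-set intersection — linked AND
knockdown-significant AND cohort-significant — annotated with directions
and optionally truncated to the top \(k\) genes by absolute cohort logFC
(the criterion for "most altered" is otherwise unstated; |logFC| ranking
is the package's documented choice). Correlation profiles (Spearman by
default, robust to cohort outliers) are compared set-vs-background with a
two-sample KS test, reporting D, p and the shift direction
("more_positive" for the coactivator-like pattern).

# The synthetic generator

`simulate_cohort()` emulates a localized-cancer cohort: per-gene Gaussian
baselines shared by tumors and normals (the pipeline consumes Z-scores,
so only location/scale matter and log-normal realism is irrelevant);
GISTIC background drawn iid per cell (real CNA segment geometry is *not*
modeled); Poisson mutations at ~2 coding mutations/Mb/tumor driven by
simulated exon structures; exponential proportional-hazards survival with
linear predictor \(\sum_g \beta_g Z_{gs}\) and independent exponential
censoring calibrated to the requested censoring fraction. Defaults (150
tumors, 30 matched normals, class fractions ≈ 13/6.6/4.2/4.1% of 10,000
genes) mirror the detected-class proportions of a typical localized
cohort. Planted effects shift selected (gene, tumor) cells by `z_shift`
gene-SDs (expression), force ±2 codes (CNA), or multiply mutation rates
by \(e^{z\_shift}\); the truth record stores the resolved genes and
tumors so every effect is recoverable by direct inspection.

`simulate_cistrome()` lays genes on one synthetic chromosome with spacing
\(2W + 50\) kb, which *guarantees* that inter-gene-midpoint decoy peaks
are > W from every TSS; truth peaks sit inside a truth gene's window and
always overlap a state segment, stateless decoys sit inside non-truth
windows with no state. This makes the noiseless cascade-recovery test
exact rather than probabilistic. `simulate_knockdown_de()` plants the
1993-down/1607-up skew with mean logFC −1.11/+0.83 (SD 0.35) on a
uniform-p background; its recorded significance rule (FDR < 0.05,
|logFC| > 0.5) keeps a zero-DEG configuration structurally empty while
flagging ~95% of planted effects.

What passing tests on these fixtures show: the statistics are calibrated
and the machinery is exact under the generator's assumptions
(independent genes, Gaussian noise, iid CNA cells, proportional hazards).
What they do not show: robustness to gene–gene correlation, batch
structure, segment-level CNA, non-proportional hazards, or annotation
errors — all present in real cohorts.

# Numerical choices and problem sizes

* Empirical p: add-one estimator, conservative tie handling with
  \(\sqrt{\varepsilon}\) tolerance (above).
* Every stochastic function takes an explicit seed; identical
  (seed, config) runs are byte-identical on disk, which the tests verify
  by checksum.
* Validation problem sizes were chosen to give stable pass/fail behavior
  at interactive runtimes: 500 null classes at \(B = 2000\) over a
  10,000-gene universe for calibration; 20 seeds for each recovery
  experiment (class 300, 30% × 40% affected, shift −1.0; hazard
  coefficient 1.0 at n = 200); \(B = 50{,}000\) against exhaustive
  enumeration on a 10-gene universe; 100 random interval fixtures; the
  pipeline demo at 2,000 genes and \(B = 5000\).

# Known limitations

* The catalog module consumes annotation tables; it does not query
  ontology services, so reproducing any specific published class census
  depends on supplying that annotation snapshot.
* The rank-sum quartile DE is not a count-model DE; effect-size estimates
  (logFC as mean difference) are on the input scale, not a modeled fold
  change.
* The mean-rank statistic and the proportion statistic can disagree for
  classes with heavy-tailed score distributions; both are reported rather
  than adjudicated.
* Survival screening is univariable log-rank only — no Cox adjustment,
  matching the screening design it implements.
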