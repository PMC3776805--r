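---
title: "Methods: reference-gene stability assessment with stabref"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-gene stability assessment with stabref}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabref)
```

# The problem

A qPCR experiment measures a target gene's quantification cycle (Cq) in
each sample, but Cq confounds true expression with how much cDNA was loaded
into the well. The standard remedy is to divide by the signal of reference
("housekeeping") genes assumed stable across the panel. When that assumption
fails — a "reference" regulated along the very axis under study — the
normalized profile of the target inherits the reference's regulation, which
can relocate an apparent expression peak to the wrong developmental stage.
`stabref` implements the two standard statistics for vetting candidate
references (geNorm M and the qBase coefficient of variation), the
efficiency-corrected quantification chain they operate on, a read-count
digital screen for nominating candidates, and generators of synthetic data
with known truth against which every stage is verified.

# Quantification model

## From Cq to relative quantities

Technical replicates are averaged on the Cq scale (arithmetic mean, SD with
the n−1 denominator, SE = SD/√n). Averaging before the exponential
transformation was a genuinely open choice: averaging RQs instead weights
replicates unevenly after exponentiation, and replicate Cq noise is well
approximated as additive Gaussian on the cycle scale, so the cycle-scale
mean is the natural estimator. A singleton replicate is allowed but its SE
is set to 0 with a warning, since no within-well spread is estimable.

With per-gene amplification efficiency $E_g$ (amplification factor
$1+E_g$), the relative quantity of gene $g$ in sample $s$ is

$$\mathrm{RQ}_{gs} = (1+E_g)^{\,Cq_{g,\mathrm{cal}} - Cq_{gs}},$$

where the calibrator is the sample with the lowest mean Cq for that gene
(ties broken by sample-label order so reruns are deterministic). RQ is
therefore in (0, 1] with RQ = 1 exactly at the calibrator. The standard
error follows the delta method on the exponent,
$\mathrm{SE(RQ)} = \mathrm{RQ}\cdot\ln(1+E)\cdot \mathrm{SE}(Cq)$.

## Normalization factors and NRQ

For a reference set of $f$ genes the per-sample normalization factor is the
geometric mean $\mathrm{NF}_s = (\prod_g \mathrm{RQ}_{gs})^{1/f}$, with
relative errors combined in quadrature and scaled by $1/f$. A target's
normalized relative quantity is $\mathrm{NRQ}_s =
\mathrm{RQ}_{ts}/\mathrm{NF}_s$, optionally rescaled so a chosen group
(e.g. the first developmental stage) has mean 1; relative SEs of RQ and NF
add in quadrature. Two consequences worth noting, both verified as
invariance tests: adding a constant to one gene's Cq everywhere (an assay
offset) changes nothing downstream, and shifting every gene in one sample
(a loading change) cancels exactly in NRQ.

The single-reference Pfaffl ratio between two groups uses group-mean Cq:
$(1+E_t)^{\Delta Cq_t} / (1+E_r)^{\Delta Cq_r}$. Group means rather than
per-sample ratios are the default because two-group stage comparisons are
the typical use; per-sample NRQ profiles cover the rest.

# Stability statistics

## geNorm M

$V_{jk}$ is the SD across samples of $\log_2(\mathrm{RQ}_{js}/
\mathrm{RQ}_{ks})$ and $M_j = \mathrm{mean}_{k\neq j} V_{jk}$. Log base 2
is the geNorm convention; any fixed base scales all M equally, so the
ranking is base-invariant. Stepwise elimination removes the largest-M gene
and recomputes until two genes remain — pairwise ratios cannot separate the
final two, so they share rank 1. Each gene's reported M is its value at
elimination. Exact ties (proportional genes) are broken by gene-label
order, the later label leaving first, and every tie-break is logged in the
report. The implementation is tested for exact agreement (1e−12) with a
brute-force double-loop oracle on hundreds of random panels.

A gene is individually acceptable when $M < 0.5$ (strict — the boundary
value is rejected, a convention the report records); the algorithm's own
ceiling of 1.5 is only flagged, never enforced.

## qBase CV

Each candidate is normalized by the factor of the *full* candidate set,
including itself, and its CV = SD/mean across samples is reported along
with the arithmetic mean CV of the set (acceptable when < 25%). Including
the gene in its own factor matches reporting a single panel-level mean CV;
the limiting cases (one reference ⇒ CV = 0; mutually proportional
references ⇒ mean CV = 0) are tested. Tissue panels with distinct
transcriptomes (floral buds vs fruits vs leaves) should be fitted
separately — pooling was the other open option, and pooled fits answer a
different question (stability across tissues) than the per-panel fits the
statistics were designed for. Both genotypes of a panel are pooled into one
fit, since references are meant to serve the panel as a whole.

# Amplification curves

Cq calling subtracts a baseline (mean fluorescence over cycles 3–10, an
early window preceding the exponential phase; instruments estimate theirs
similarly but do not document a rule) and finds the first crossing of a
30 RFU threshold, linearly interpolated between flanking cycles — the
smallest-assumption crossing estimator. The threshold is applied to
baseline-subtracted fluorescence; applying it to raw signal would make Cq
depend on lamp background. Curves that never cross are flagged and excluded
with a reason rather than given a sentinel value.

Efficiency is fitted per reaction from the window of linearity: sliding
windows of 5, then 4, then 3 consecutive cycles (more points preferred —
more stable slope) across the exponential phase, OLS of log10(F) on cycle,
accepting the largest window size with $R^2 \ge 0.998$ and tie-breaking by
highest $R^2$; $E = 10^{\mathrm{slope}} - 1$, so $(1+E) = 10^{\mathrm{slope}}$
holds exactly in every fit. The exponential phase is bounded below by 3×
the baseline-noise SD (readings indistinguishable from background carry no
slope information) and above by 80% of the maximum baseline-subtracted
signal (plateau onset bends the log-linear relation downward). Per-gene
efficiencies are arithmetic means ± SEM over accepted reactions; means
outside [0.85, 1.10] — the span of acceptable assays in practice — draw a
warning but are not rejected, and genes with no accepted reaction are
reported as missing rather than defaulted to E = 1.

At realistic noise the per-reaction estimate is dispersed: with noise of 2%
of the plateau the usable band spans only ~3.7 doublings, most accepted
windows have 3–4 points, and single-reaction estimates scatter with SD
≈ 0.17 around an unbiased center. Averaging over ~50 reactions brings the
mean within ≈ ±0.03 of truth; per-gene efficiencies should always be pooled
over many plates/reactions, never taken from one curve.

# Digital screen

Unigenes are filtered by presence — either ≥ 7 present calls (count ≥ 1)
across the 8 libraries or ≥ 7 reads in all 8; both conventions appear in
practice and neither is privileged here. Virtual fold expression between
libraries is $m/(n\,[M/N])$ with whole-library totals $M, N$ (not column
sums of retained unigenes). The per-unigene CV is computed on proportions
(count/total): identical to the CV of folds wherever folds are defined,
but independent of the reference-library choice and still defined when a
non-reference library has zero counts. A zero in the *reference* library
leaves the fold profile undefined: the unigene is flagged and excluded
rather than imputed. The omission analysis reports
$\Delta CV = CV(\mathrm{remaining}) - CV(\mathrm{all})$, so regulation
confined to the omitted series shows as $\Delta CV < 0$; zero changes are
counted separately from decreases and increases.

# QC gates

The 3′:5′ assay amplifies one amplicon near each end of an oligo-dT-primed
transcript; degradation inflates the 3′:5′ abundance ratio
$A^{\,Cq_{5'} - Cq_{3'}}$. The comparative-Cq amplification factor defaults
to the classical $A = 2$, with an override for measured efficiencies.
Failure requires ratio > 4.43 strictly (the boundary passes), and a missing
Cq fails closed. Purity bounds are inclusive where stated as ranges
(A260/280 in [1.9, 2.1] for buds and leaves, [1.75, 2.1] for fruits — the
leaf panel reuses the bud bounds) and strict where stated as an inequality
(A260/230 > 2.0). The 4.43 cutoff is treated as a configurable constant of
`run_config()`, not re-derived.

# Synthetic-data generators

`simulate_cq()` draws, per sample, a log2 loading factor
(N(0, `loading_sd`)) shared by all genes — the cDNA-input variation that
normalization exists to remove — plus per-gene biological noise
(N(0, `bio_sd`), log2) and a group-level regulation profile, and converts
log2 expression $x$ to cycles via $Cq = base_{cq} - x/\log_2(1+E)$, so one
doubling is exactly one cycle at E = 1. Replicate noise is additive
Gaussian on the Cq scale (`tech_sd`), the standard technical-noise model.
Regulation is geometric across ordered groups
($\mathrm{fold}^{k/(G-1)}$ for group $k$), the simplest monotone profile;
an explicit per-group profile (e.g. `c(1, 2, 8, 4)`, peaking at the third
stage) covers non-monotone targets and the construction of compensating
"bad references" for the peak-shift demonstration.

Default panel sizes used throughout the tests — 10 genes (6 stable at
`bio_sd` 0.05, 4 regulated at fold 4), 16 samples in 4 ordered groups, 2
replicates, `loading_sd` 0.3, `tech_sd` 0.1 cycles — are modest but
representative for a reference-gene validation study of this design
(a 13-gene × 32-sample study is of the same order), and keep full 200-seed
recovery sweeps fast.

`simulate_curves()` builds baseline + capped exponential + Gaussian read
noise (defaults: baseline 50 RFU, plateau 1000 RFU, start 0.01 RFU,
40 cycles — a dynamic range and threshold placement typical of SYBR
instruments). `simulate_counts()` draws Poisson counts around
library_size × proportion × multiplier, with "stable" defined as all
multipliers equal to 1; default 8 libraries of 1e5 reads (454-scale depth,
split 4 bud + 4 fruit).

What the generators deliberately do *not* emulate: amplification
inhibitors and pipetting outliers (no heavy-tailed Cq noise),
between-plate/run effects, primer-dimer and non-specific amplification,
overdispersed (beyond-Poisson) read counts, and any sequence-level
features. Passing recovery tests therefore demonstrates correctness of the
statistics and the pipeline's plumbing under the stated noise model — not
robustness to assay artifacts, which real studies control upstream (melt
curves, no-template controls, inter-run calibrators).

# Numerical and degenerate-input choices

- Sample SD uses the n−1 denominator everywhere.
- Exact M ties use a 1e−15 comparison window and the label-order rule.
- Incomplete gene × sample grids: samples missing any gene are dropped with
  a message before stability analysis (the pairwise statistics require
  complete matrices); genes without an efficiency are an error, not E = 1.
- Non-numeric Cq entries ("ND") read from CSV become NA with a warning —
  never zero; duplicate (sample, gene, replicate) rows are an error naming
  the lines.
- Two-gene panels yield a degenerate report with both genes at rank 1.
- Written tables use 6 significant digits for diffable regression output.

# Known limitations

- No NormFinder/BestKeeper rankings and no geNorm $V_{n/n+1}$ pairwise
  variation statistic for choosing the number of references; set choice is
  assessed by `compare_reference_sets()` instead.
- No inter-run calibration or absolute quantification; no standard-curve
  (dilution-series) efficiency estimation.
- The digital screen is purely descriptive (no count-model testing), by
  design.
- Error propagation is first-order (delta method); for very low-expression
  wells with large SE(Cq) the log-normal asymmetry of RQ is not captured.
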