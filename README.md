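# stabref

Selection and validation of reference (housekeeping) genes for qPCR
normalization, with a digital expression-stability screen over sequencing
read-count libraries.

Quantitative PCR expression estimates are only as good as the genes they are
normalized to. `stabref` is for researchers choosing reference genes for a
new tissue panel or experimental system — e.g. developmental series of fruit
or cold-acclimating floral buds — who need to (i) screen candidates *in
silico* from read-count libraries, (ii) rank candidates measured by qPCR by
their expression stability, and (iii) demonstrate what an unstable reference
does to a target gene's apparent expression profile.

## What it computes

**geNorm stability ranking.** For candidate genes with relative quantities
`RQ_gs` (gene *g*, sample *s*), the pairwise variation of genes *j*, *k* is

    V_jk = SD_s [ log2( RQ_js / RQ_ks ) ]

and the stability of gene *j* is `M_j = mean_{k != j} V_jk`. Lower M = more
stable. The least stable gene is removed and M recomputed until two genes
remain; those two share the best rank. Genes with `M < 0.5` (and candidate
sets with mean CV < 25%) are considered acceptable for a homogeneous panel;
geNorm's own default ceiling is `M = 1.5`.

**Efficiency-corrected quantification (qBase model).** Replicate Cq values
are averaged, transformed with each gene's amplification efficiency E via
`RQ = (1+E)^(Cq_cal - Cq)` (calibrator = lowest-Cq sample), combined into a
per-sample normalization factor `NF_s = geometric mean of reference RQs`,
and propagated to normalized relative quantities `NRQ = RQ/NF` with
delta-method standard errors. Single-reference Pfaffl ratios
`(1+E_t)^dCq_t / (1+E_r)^dCq_r` are available for two-group comparisons.

**Amplification curves.** Cq is called where baseline-subtracted
fluorescence crosses a fixed threshold (default 30 RFU, linearly
interpolated), and per-reaction efficiency is fitted window-of-linearity
style: sliding 5-, 4-, then 3-point OLS fits of log10(F) against cycle,
accepting the largest window with `R^2 >= 0.998`, with `(1+E) = 10^slope`.

**Digital screen.** From a unigene x library read-count panel: present-call
filtering (>= 7 present calls, or >= 7 reads in every library), virtual fold
expression `m/(n[M/N])`, per-unigene CV = SD/mean of library proportions,
and a library-omission analysis reporting how CVs change when, say, the
fruit series is dropped.

**QC gates.** 3':5' amplification-ratio RNA-integrity gate (fail when
`> 4.43`) and panel-specific A260/A280 / A260/A230 purity gates.

All of it is exercised end-to-end on seeded synthetic generators
(`simulate_cq()`, `simulate_curves()`, `simulate_counts()`) whose ground
truth — true loadings, stabilities, efficiencies, fold profiles — is
returned next to the data.

## Worked example

Simulate a fruit-development panel of five stable candidates plus a
GAPDH-like gene carrying a 3-fold developmental trend, then rank:

```r
library(stabref)
genes <- c(lapply(c("RH8", "UBC9", "CACS", "PPR", "TIP41"), function(g)
             gene_sim_spec(g, base_cq = 24, bio_sd = 0.1)),
           list(gene_sim_spec("GAPDH", base_cq = 22, bio_sd = 0.1,
                              trend_fold = 3)))
spec <- cq_sim_spec(genes,
                    groups = rep(c("green", "white", "pink", "blue"), each = 4),
                    n_replicates = 2, loading_sd = 0.4, tech_sd = 0.15,
                    seed = 11)
sim <- simulate_cq(spec)
eff <- efficiency_set(c(RH8 = 0.95, UBC9 = 1.02, CACS = 0.91, PPR = 0.99,
                        TIP41 = 0.88, GAPDH = 1.05))
fit <- gene_stability(sim$data, eff)
print(fit)
```

```
Reference-gene stability report
  6 genes x 16 samples; best pair: CACS & PPR (M = 0.1137)
  mean M = 0.2365, mean CV = 0.1558, set accepted (M < 0.5, CV < 0.25)
  gene      M rank      cv accepted
  CACS 0.1137    1 0.08742     TRUE
   PPR 0.1137    1 0.09549     TRUE
 TIP41 0.1517    3 0.10779     TRUE
   RH8 0.1652    4 0.11423     TRUE
  UBC9 0.1826    5 0.13141     TRUE
 GAPDH 0.6919    6 0.39843    FALSE
```

The five genes simulated as stable are ranked with low M and CV and
accepted; the trending gene lands last (M = 0.69, CV = 40%) and is
rejected. `M = 0.1137` for the final pair means their log2 expression ratio
has a standard deviation of about 0.11 cycles-equivalent across the 16
samples — they move together. Normalized target profiles then come from a
normalization factor over the accepted set:

```r
nf2 <- normalization_factor(fit$rq, fit$best_pair)
head(normalized_rq(fit$rq, "GAPDH", nf2, rescale_group = "green"), 4)
#>   sample group       nrq         se
#> 1    S01 green 0.8698185 0.10757635
#> 2    S02 green 1.1465500 0.05024134
#> 3    S03 green 1.0378748 0.04138690
#> 4    S04 green 0.9457567 0.08455858
```

`plot(fit)` draws the familiar stability bar chart, and
`compare_reference_sets()` quantifies how far two candidate normalization
factors diverge — including whether a target's apparent peak stage moves
when an unstable single reference is used.

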