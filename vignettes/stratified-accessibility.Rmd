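---
title: "Stratified differential accessibility for sex-dimorphic chromatin"
author: "dimorphatac"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified differential accessibility for sex-dimorphic chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dimorphatac)
```

# Scope and model

`dimorphatac` analyses ATAC-seq fragment counts across a genome in which
the X chromosome's effective copy number differs between compared groups:
female *Drosophila* carry two X chromosomes while males carry one that is
partially compensated by the DCC at its binding sites. The package's core
is a negative-binomial differential-accessibility engine that is run
*independently within chromosome strata* (X versus autosomes), with
Benjamini–Hochberg adjustment within each stratum and concatenation of the
per-stratum lists. A pooled mode (single normalization, single adjustment)
is retained deliberately: contrasting the two modes on simulated data is
the package's demonstration of why the stratification matters.

Counts for region $i$ in sample $j$ are modelled as
$K_{ij} \sim \mathrm{NB}(s_j q_{ij},\ \alpha_i)$ with variance
$\mu + \alpha\mu^2$. The statistical choices, in order of appearance:

* **Size factors** are median-of-ratios: the reference is the per-region
  geometric mean across samples (regions containing any zero are excluded
  from the reference set), each sample's factor is the median ratio to the
  reference, and factors are rescaled to geometric mean 1 within their
  stratum. A stratum without a single all-positive region is an error
  (the advice is to increase depth), not a silent fallback.
* **Dispersion** is estimated by method of moments on normalized counts,
  with variances pooled within condition groups, then shrunk to the trend
  $\alpha(m) = a_0 + a_1/m$ fitted by least squares over regions with mean
  above 1. Final values are the trend, floored at $10^{-4}$. With fewer
  than 10 usable regions the median raw value is used. A full
  empirical-Bayes treatment is intentionally out of scope: with two
  replicates per condition the trend is the only stable quantity, and the
  moment estimator keeps every step closed-form and testable (the trend's
  recovery of planted $(a_0, a_1)$ is itself a test).
* **The test** is a Wald z on moderated group means rather than a full GLM
  fit: $\log_2\mathrm{FC} = \log_2\frac{m_B + c}{m_A + c}$ with $c = 1/2$
  count, and a standard error that propagates
  $\mathrm{Var}(K) = \mu + \alpha\mu^2$ of each sample through the group
  means. For balanced 2-vs-2 designs this is the same quantity a one-
  parameter GLM would test, without an IRLS loop; the moderation constant
  keeps fold changes finite at zero counts and its influence vanishes for
  means above ~50 (an invariance the tests assert). Orientation is always
  *target over reference* and is recorded in the result's `orientation`
  attribute, because a fixed convention is the only reliable cure for sign
  bugs when two comparisons are later intersected.
* **FDR scope.** BH is applied within (comparison × stratum) and the lists
  concatenated — the stratified procedure's defining step. A `fdr_scope =
  "global"` flag exists for comparison but is not the default.

# Condition-specific elements

Two oriented comparisons that share a consensus region set (for the fly
design: male fru+ vs male fru−, and male fru+ vs female fru+) are
intersected: regions significant in both with a shared fold-change sign
are `opened_in_target` / `closed_in_target`; shared significance with
opposite signs is reported as `discordant` with a warning rather than
dropped, because zero discordance is a *finding* about real data, not an
assumption. The intersection requires literally identical region sets; the
alternative — interval-overlap matching of two independently derived lists
— introduces an arbitrary overlap threshold and is not implemented.

# Peak calling

The caller is a deliberately simple local-background scan: midpoint
coverage is tested in 200-bp windows every 50 bp against a Poisson
expectation $\lambda = w \cdot \max(\text{genome rate},
\text{rates over 5 and 10 kb centred on the window})$, p-values are
upper-tail Poisson, BH is applied over all windows genome-wide, and
windows below the q threshold (default $10^{-3}$) that touch are merged,
keeping the minimum p/q and the leftmost coverage maximum as summit.
Midpoint counting is used for calling (and for every other counting step
in the package — one rule everywhere); span counting exists for display.
The Poisson tail is validated against direct pmf summation to a relative
error below $10^{-9}$.

# Motif strength with exact p-values

Scanning uses the PWM's log-odds against a 0-order background (default:
the scan set's empirical base composition), with probabilities
pseudocounted as $p' = (p + \kappa\,\mathrm{bg})/(1 + \kappa)$. Scores are
discretized to $\varepsilon = 0.01$ bits and the *exact* distribution of a
single width-$w$ alignment score under the background is computed by
column-wise convolution on that integer grid; scanning reports, per
region, the maximum score over both strands and its tail probability. The
grid makes the scanner and the null distribution share one score space, so
for any width ≤ 6 the reported tails equal brute-force enumeration over
all $4^w$ sequences exactly — an equivalence the acceptance checks assert,
not merely approximate.

P-values are per-alignment, uncorrected for region length, and the best
hit per region is the minimum — the convention of best-hit motif-strength
comparisons. Because longer regions get more chances at a good chance
match, class comparisons report the class length distributions alongside,
and a length-corrected option ($1 - (1-p)^{2(L-w+1)}$) is available but
off by default since the simulated classes share one length distribution.
Class contrasts use the two-sample KS test on $-\log_{10} p$ and a Fisher
exact test on the 2×2 table at the well-matched threshold ($p < 10^{-3}$).

# Relative distance and annotation

The relative distance of a query midpoint $a$ between consecutive
reference midpoints $b_1 < b_2$ is $\min(a-b_1, b_2-a)/(b_2-b_1) \in
[0, 0.5]$; uniform placement gives a flat law with mean 0.25, clustering
at reference sites shifts mass toward 0. Queries outside the reference
span are skipped and counted. The fraction of queries overlapping a
reference interval by ≥ 1 bp is reported alongside, since "more than half
of recovered male-biased X regions sit on tether sites" is the kind of
statement the statistic exists to support.

Annotation classifies region midpoints with precedence promoter > exon >
intron > intergenic. The promoter window is ± 50 bp around a TSS —
unusually narrow, taken at face value from the upstream analysis this
package mirrors, and exposed as a parameter precisely because it is
debatable. Nearest genes are measured midpoint-to-TSS (not to the gene
boundary), ties broken lexicographically. Term enrichment is an
upper-tail hypergeometric test against a *user-supplied* background (the
selected set must be a subset of it), BH-adjusted across terms; no
ontology database is bundled.

# The synthetic-data generator

The generator is first-class, tested code; its defaults are the study
conditions the analysis assumes:

* 4 conditions (male/female × fru+/fru−) × 2 replicates; genome chrX 2 Mb
  + two 3-Mb autosomes with 300 non-overlapping 400-bp peaks each.
* Expected counts factorize as $\mu_{ij} = s_j f_i \mu_0 x_{ij} d_{ij}
  g_{ij}$: $x = 2$ for female samples at X peaks, $d = $ `dcc_boost` for
  male samples at DCC peaks, $g = 2^{\pm\Delta}$ for male fru+ samples at
  planted opened/closed peaks. Library factors $s_j$ are log-uniform in
  (0.7, 1.4) to force nontrivial normalization.
* `baseline_mu = 50`, `alpha = 0.05`, $\Delta = 2$, 40 opened + 30 closed
  autosomal peaks — the planted-recovery conditions. Planted effects are
  autosomal by default so X effects stay attributable to dosage.
* The per-peak cell fraction $f_i \in (0.3, 1)$ models elements used by
  subpopulations of the profiled cells; no measured value for this
  fraction exists, so it is a documented free parameter, applied equally
  to all conditions so that differential effects ride on top of it.
* Fragments realize the count matrix exactly (midpoints uniform within the
  peak; count-in-peak equals the matrix cell, assertable exactly), on top
  of Poisson background at $10^{-3}$ fragments/bp, with lengths from a
  0.6/0.4 mixture of N(75, 25) and N(200, 40) truncated at 20 bp —
  sub-nucleosomal and mono-nucleosomal components. Realized library depth
  is therefore an emergent quantity ($\approx$ 50–60 k fragments/sample at
  defaults), not an independent dial.
* Sequences are i.i.d. at GC 0.43 with the motif consensus planted at
  class-dependent rates (default 0.8 in closed, 0.1 elsewhere), uniform
  position and strand; tether sites are the DCC peak midpoints, giving
  the relative-distance analysis a known truth.

`bias_demo_config()` freezes the dosage-demonstration variant: no planted
FruM effects, DCC boost 2 at 10% of X peaks, cell fraction 1 (dosage
compensation is chromosome-wide and cell-autonomous, so element-level
usage heterogeneity is irrelevant to it), and deep, tightly replicated
libraries (`baseline_mu = 500`, `alpha = 0.02`). The demonstration
concerns normalization behaviour, not detection power at marginal
coverage: with shallow counts the pooled mode's miscalls and the
stratified mode's DCC recovery would both be diluted by noise and the
contrast between modes — the thing being demonstrated — would be
obscured. The planted-recovery analysis, by contrast, is run at the
shallow settings above, with cell fraction 1 so that the stated
`baseline_mu` *is* the peak mean.

What the generator does **not** emulate: Tn5 insertion sequence bias,
duplicate reads, GC-dependent amplification, chromatin domains or any
spatial autocorrelation of accessibility, and annotation complexity
(overlapping transcripts, alternative TSSs). Passing tests therefore show
that the algorithms do what they claim under the stated statistical model
— not that the model captures every property of real libraries.

# Determinism and numerical choices

Every stage derives a child seed from the global seed by a stable hash of
the stage name, so stages are reproducible in isolation and identical
configurations give byte-identical outputs (the manifest records the
config hash, thresholds and per-stage row counts; its wall-time field is
the one intentionally non-reproducible value). Ties are always broken
deterministically (leftmost summit, smallest position then + strand,
lexicographic gene ids). Degenerate inputs fail loudly: unknown
chromosomes, overlapping bedGraph lines, mixed-strand genes, empty
intervals and sub-motif-length sequences are errors or flagged results,
never silent drops.

Problem sizes used by the test-suite and acceptance computations — 900
peaks for recovery runs, 2 000 regions × 100 seeds for calibration,
200 + 200 regions for the motif-class contrast, $10^4$ queries for the
relative-distance law — were chosen as the smallest sizes at which the
binomial/KS tolerances in use are comfortably away from their thresholds;
they are package choices, stated here so that readers scaling the
simulations up or down know what the reference points were.

# Known limitations

* The Wald test assumes the trend dispersion; with two replicates per
  group, region-specific dispersion outliers are invisible to it.
* The stratified correction assumes stratum labels are correct and total;
  a genome specification error surfaces as a hard error, by design.
* Per-alignment motif p-values ignore region-length differences between
  classes (reported, not corrected, by default).
* The expression arm shares the count engine and therefore its
  assumptions; transcript-level quantification and isoform analysis are
  out of scope.
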