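---
title: "Methods: paired tumor-normal contrasts by age of onset"
author: "onsetOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired tumor-normal contrasts by age of onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(onsetOmics)
```

# The design

Every analysis in this package assumes a paired tumor–normal design:
each person contributes one carcinoma sample and one adjacent healthy
colon sample, and persons belong to one of two age-of-onset groups
(EOCRC, diagnosed at or below 40 years; LOCRC, above 40). Pairing is the
design's strength — the person-to-person variance, which in bulk tissue
dwarfs most tumor effects, cancels out of every within-person contrast —
and the `PairedDesign` class exists to make that contract checkable:
unique samples, at most one tumor and one normal per person, a constant
onset group per person. Samples that lose their partner (an assay
failure, say) stay in the object but are excluded by every paired model,
with the exclusion counted.

# The paired model and its estimation

For one feature (expression probe or CpG locus) with response $Y$ (log2
intensity or beta value),

$$Y_{ij} = \mu + T_i + P_j + \varepsilon_{ij},$$

with tissue $T$ fixed, person $P$ random, and
$\varepsilon \sim N(0, \delta^2)$ i.i.d. Estimation is by the method of
moments: the observed mean squares are equated to their expectations,

$$\mathrm{E[MS_{person}]} = \sigma^2_\varepsilon + 2\sigma^2_{person},
\qquad \mathrm{E[MS_{error}]} = \sigma^2_\varepsilon,$$

and the linear system is solved (`momVarianceComponents()`). Because the
package fits the paired model only on complete pairs, the design is
always balanced and the solution is closed-form:
$\hat\sigma^2_{person} = (\mathrm{MS_{person}} - \mathrm{MS_{error}})/2$.
A method-of-moments solution can be negative; negative components are
clamped to zero and flagged rather than reported, since a negative
variance has no interpretation. The tissue F-test uses the residual mean
square after person as its denominator, which on this design makes it
*exactly* the squared paired t-test — the suite asserts equality to
1e-10, which is the package's primary correctness oracle.

Two degenerate cases are handled explicitly. Fewer than two complete
pairs makes the feature inestimable: it is skipped with the reason code
`too_few_pairs`, never silently dropped. A zero residual (all paired
differences identical) would make the F statistic infinite; the fit
keeps the effect estimate, reports the p-value at the representable
boundary, and flags `degenerate_zero_residual` (with a zero effect the
p is 1).

## Fold changes

Tumor−normal differences $e$ on the log2 scale are reported as signed
ratios: $2^e$ when $e \ge 0$ and $-2^{-e}$ otherwise, the "−1/x"
convention in which a 12 % decrease prints as −1.12 and values live in
$(-\infty,-1] \cup [1,\infty)$. Confidence intervals are computed on the
log2 scale as $e \pm t_{0.975,\nu}\,\mathrm{se}$ and each endpoint is
mapped through the same transform, which preserves ordering. With no
residual degrees of freedom the CI is reported missing and the point
estimate kept.

# The interaction model

To ask whether the magnitude of the tumor effect differs by onset group
the package fits

$$Y = \mu + T + G + (T \times G) + \varepsilon$$

over all samples of both groups, where $G$ is the onset group. Note what
is *not* in this model: the person term. That is a deliberate fidelity
choice — the analysis plan this package reproduces defines the
interaction model without it — and it has a
statistical consequence worth understanding. In the balanced paired
design the interaction contrast
$(\bar Y_{T,E} - \bar Y_{N,E}) - (\bar Y_{T,L} - \bar Y_{N,L})$ cancels
person effects exactly, but the pooled within-cell mean square that
estimates its error does *not*: person variance inflates it. The test is
therefore **conservative** (never anti-conservative) whenever person
variance is present; it is exact when person variance is zero, which is
how the type-I-error calibration in the test suite defines the global
null ("all effects zero" including the person effect). The alternative —
adding the person term back — would sharpen the interaction test, and a
user can approximate it by quantile-normalizing first (per-sample
location shifts are removed by normalization) or by running
`fitInteraction` on person-centred values. The package documents rather
than second-guesses the model it reproduces.

The same machinery reports per-group tissue effects. For the two-column
(late/early) tables the per-group fold changes and p-values come from
the *paired* model refit within each group, so each group's own estimate
keeps the pairing advantage; only the interaction p comes from the
fixed-effects model above.

# Gene-set analysis

The gene-set mixed model is

$$Y = \mu + T + P + G + S(T{\times}P) + \varepsilon,$$

with gene $G$ fixed and the sample effect $S$ random, nested in
tissue × person (one level per physical sample). The analysis runs at
the gene level — probes of one gene are first averaged per sample on the
log2 scale, since the chip targets many genes with several probes but
the model is declared gene-level — and the result is expressed at the
set level by averaging the member genes' results.

The package exploits an algebraic identity instead of a general mixed
solver: on a balanced design, testing the tissue effect against the
sample stratum $S(T{\times}P)$ is *identical* to collapsing each sample
to its mean over member genes and running the paired model on the
collapsed values. `fitGeneSet()` therefore (i) averages probes to genes,
(ii) collapses genes to a per-sample set mean for the tissue test, CI
and per-group fold changes, and (iii) computes the full
$T/P/G/S(T{\times}P)/\varepsilon$ sums-of-squares decomposition for the
variance components, solved by method of moments with

$$\mathrm{E[MS_P]} = \sigma^2_\varepsilon + g\sigma^2_S + 2g\sigma^2_P,\quad
\mathrm{E[MS_S]} = \sigma^2_\varepsilon + g\sigma^2_S,\quad
\mathrm{E[MS_\varepsilon]} = \sigma^2_\varepsilon$$

for $g$ member genes. Two invariants pin the construction down: a
single-gene set reproduces that gene's paired fit exactly, and a set of
identical genes keeps the common fold change.

Genes listed in a set but absent from the chip are dropped and counted
(`n_genes_missing`), not errors — curated sets routinely exceed chip
content. A set with no member on the chip is an error naming the missing
symbols.

## Enrichment score

Whether significant genes over-represent a category is tested by an
uncorrected 2×2 Pearson chi-square comparing "significant genes in the
category / all significant genes" against the category's share of the
whole chip; the enrichment score is $-\log_{10} p$. Base 10 was chosen
because study-style reporting writes p-values as $10^{-x}$; the
"negative log" convention leaves the base open. Degenerate inputs (no
significant genes; a category spanning the chip) score 0 with a flag
instead of erroring, so screens over many categories never abort.

# Differential methylation

The methylation score of a locus is $\beta = M/(M+U)$ from methylated
and unmethylated intensities, in $[0,1]$; a locus with $M+U=0$ is
missing, not zero. Loci in the "deep sea" (more than 4 kb from any CpG
island) are excluded before testing. Within each onset group every
remaining locus gets the paired model; delta beta is the mean of
within-person (tumor − normal) differences, so unpaired samples never
contribute. Benjamini–Hochberg FDR is applied *within each group
separately* — the published per-group DML totals are defined that way —
and a locus is a DML in a group at $q \le 0.05$.

The five-class partition crosses group membership with the interaction
test at $\alpha = 0.05$ (left unadjusted deliberately; the
interaction-significant count is orders of magnitude below the
FDR-surviving counts, and adjusting it would change the partition's
meaning):

| class | DML in | interaction p |
|---|---|---|
| I | both | ≥ α |
| II | both | < α |
| III | EOCRC only | ≥ α |
| IV ("EOCRC specific") | EOCRC only | < α |
| V ("LOCRC specific") | LOCRC only | < α |
| `locrc_only_ns` | LOCRC only | ≥ α |

The last class is unnamed in the usual presentation of this partition;
it is retained so that every locus receives exactly one class and the
bookkeeping closes: $|I|+|II|$ equals the common-DML count and
$|III|+|IV|$ the EOCRC-only count, which the suite asserts on every
simulated dataset. `summarizePartition()` adds per-class delta-beta
extrema and the $|\Delta\beta| \ge 0.1$ / $\ge 0.2$ magnitude bins used
to judge marker robustness.

# Clinical statistics

Contingency analyses use the uncorrected Pearson chi-square with its
asymptotic p-value — no Yates correction and no Fisher fallback, because
published clinical tables of this style (including every p-value this
package's regression suite reproduces) are computed that way. The
smallest expected cell count is reported so the caller can judge
validity; a zero margin is an error. Stratified tests (e.g. LVI by onset
within each stage) run one test per stratum and mark untestable strata
rather than aborting. `tTestFromSummary()` implements pooled and Welch
two-sample t-tests from summary statistics for verifying published
means-and-SD rows; note that one published CEA comparison is not
recoverable from its printed summaries (likely because of unrecorded
missing values), so no test asserts it.

# The synthetic world

The generator's defaults state the emulated study rather than a
convenient test case:

* 67 EOCRC and 98 LOCRC persons, one tumor and one normal sample each;
  an option drops a fraction of normals to emulate assay failures.
* Expression: $Y = \mu + \text{tissue} (+ \text{interaction}) +
  \text{person} + \varepsilon$ with $\mu = 8$ log2 units (a mid-range
  microarray intensity), $\sigma_{person} = 1.0$,
  $\sigma_\varepsilon = 0.5$ — magnitudes the study does not report,
  chosen once for realistic test power and kept. Designated gene sets
  carry a $\log_2 1.09$ tumor effect with an extra $\log_2(1.14/1.09)$
  in LOCRC only, mirroring the strongest published set-level contrast
  (1.14-fold vs 1.09-fold).
* Methylation: baseline beta uniform on $[0.2, 0.75]$; designated DML
  add class-specific deltas (shared 0.20; shared-but-different 0.25 vs
  0.12; EOCRC-specific 0.08 — deliberately below the 0.1 robustness
  bin, as the emulated class IV "rarely exceeds 10 %"; LOCRC-specific
  0.20). Person effects and noise act on the logit scale and are mapped
  back through the inverse logit, clipped to $[0.001, 0.999]$, so beta
  stays bounded without truncation pile-up at 0/1. Region classes
  follow the 450K manifest proportions (about 36 % deep sea), and
  deep-sea loci are never designated DML.
* Clinical covariates are drawn per person from group-specific category
  distributions matching the study's clinical table; an exact-counts
  mode reproduces any requested cross-tabulation to the person.
* One random stream per run, seeded explicitly; sub-streams derive from
  stable named keys (expression / methylation / clinical), so adding a
  generator never perturbs another and identical seeds give identical
  bytes on disk.

What the generator does **not** emulate — and what a green test
therefore does not establish: probe-level intensity chemistry and
background, batch and chip effects, copy-number contamination of beta
values, correlation between neighbouring CpGs, heavy-tailed expression
noise, and any dependence between clinical covariates and the molecular
effects. Tests on this synthetic world validate the *statistical
machinery* (estimator identities, calibration, bookkeeping), not
biological claims.

# Numerical choices

* Quantile normalization maps each sample to the across-sample mean of
  sorted vectors; ties receive the mean of the reference values at the
  tied ranks, and missing cells are excluded from ranking (quantile
  interpolation bridges unequal counts) and restored as missing — no
  imputation anywhere. The operation is idempotent on tie-free data; a
  tie feeds its averaged value back into the reference, so exact
  idempotency under ties is unattainable for any implementation of this
  scheme (the deviation is ~1e-3 and second applications are stable).
  The implementation is cross-checked against `limma`'s on complete
  data.
* BH FDR is the classic step-up computed via a reverse cumulative
  minimum, order-preserving, never below the raw p, verified against a
  brute-force oracle and `p.adjust`.
* Full-precision TSV serialisation uses 17 significant digits, making
  write/read round trips bit-exact for doubles.
* Seeds derived from the run seed stay below $2^{31}$.

# Limitations

The engine is method-of-moments ANOVA, not REML: no shrinkage across
features (no limma-style moderation), no continuous covariates, no
unbalanced mixed denominators (the paired model is balanced by
construction after pair filtering, so the Satterthwaite machinery that
unbalanced data would need is intentionally absent). The interaction
test without a person term is conservative under person variance, as
discussed. FDR control is asserted under independence; correlated loci
retain BH's usual robustness caveats. None of the clinical analyses
model follow-up time — the emulated study design has none.
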