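---
title: "Credibility re-analysis of association meta-analyses: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Credibility re-analysis of association meta-analyses: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacred)
```

## The problem

A field synopsis gathers every meta-analysis relating genetic variants to
one disease and asks which statistically significant pooled results are
credible. The inputs are sparse: for each variant-comparison pair, a
pooled odds ratio, its 95% confidence interval, a p-value, sample sizes,
and occasionally a minor allele frequency. `metacred` rebuilds the full
inferential chain from these printed numbers alone.

Everything downstream rests on one normal approximation: the pooled log
odds ratio is treated as Gaussian, with standard error recovered from the
interval as $SE = (\ln U - \ln L)/(2\,z_{(1+\gamma)/2})$ for a
level-$\gamma$ interval. This assumes the published interval was itself
computed on the log scale from a normal approximation — true of
essentially all inverse-variance meta-analyses — and inherits whatever
rounding the journal applied to OR, L and U. That rounding is the dominant
error source in everything this package recomputes (see *Reconciliation*
below).

## FPRP and BFDP

`fprp()` implements the false-positive report probability: the posterior
probability of the null given a significant finding, a prior probability
$\pi$ of true association, the observed two-sided p-value, and power
$1-\beta$ against a detection odds ratio $OR_1$,

$$\mathrm{FPRP} = \frac{p(1-\pi)}{p(1-\pi) + (1-\beta)\pi}.$$

Two conventions for the power's critical value coexist in the literature:
a fixed two-sided level (usually $\alpha = 0.05$) or the observed $|z|$
(the convention of Wacholder's spreadsheet, where the test's level is set
at the observed p-value). Both are implemented behind
`cred_config(fprp_alpha_mode = )`; the default is `"observed_p"`. On the
bundled observational table this default also tracks the printed cells
best (median absolute deviation 0.006 versus 0.012 for the fixed-level
convention).

`bfdp()` implements Wakefield's Bayesian false discovery probability via
the approximate Bayes factor under a normal prior on the log odds ratio.
The prior's spread is set by $\kappa$, the 97.5th percentile of the prior
odds-ratio distribution under the alternative (default 1.5, a
conventionally "moderate" genetic effect). BFDP uses a single $\kappa$
regardless of the FPRP detection-OR grid, because published synopsis
tables print one BFDP column per prior, not one per detection OR.

Noteworthiness thresholds default to FPRP $<$ 0.2 and BFDP $<$ 0.8, the
values used throughout this literature. Prior ladders default per study
type — 0.05/0.001 for candidate-gene (observational) records, 0.001/10⁻⁶
for GWAS records — and can be overridden globally.

### Numerical strategy

GWAS records in the bundled tables reach $|z| \approx 19$, where the
two-sided p-value ($10^{-77}$) underflows double precision. All tail
probabilities are therefore carried in log space (`pnorm(log.p = TRUE)`,
log-sum-exp for the power's two tails, and a logistic transform of
$\log BF + \log\mathrm{PO}$ for BFDP). The contract, enforced by
property-based tests, is:

* for $|z| \le 8$, the log-space values agree with naive direct-formula
  evaluation to $10^{-10}$ relative error;
* for $|z|$ up to at least 50, `log_p` and `bfdp(log = TRUE)` remain
  finite and correctly ordered;
* FPRP returns an explicit `NA` ("undefined") only when the p-value and
  the power jointly underflow to exact zero; an undefined value is never
  counted noteworthy. This mirrors the "not computable" dash cells in the
  published tables — their spreadsheet failed in the inverse-normal at
  extreme z — without reproducing the failure itself: the log-space
  routines compute valid values where the spreadsheet could not, and
  those cells are reported as `printed_missing` during reconciliation
  rather than scored.

Protective effects (OR $<$ 1) are profiled through $|z|$ with the same
positive detection odds ratio, which is algebraically identical to
inverting the odds ratio and mirroring the interval; profile invariance
under OR $\leftrightarrow$ 1/OR is tested.

`qnorm()` supplies every quantile (nothing is hard-coded at 1.96), so
non-95% intervals are handled by passing `ci_level`.

## Significance filtering and deduplication

`filter_significant()` keeps records with $p$ strictly below the
type-specific threshold (0.05 observational, $5\times10^{-8}$ GWAS) *and*
an interval excluding 1. "Strictly below" follows the source convention;
records at exactly the threshold drop. Missing p-values are reconstructed
from the interval first. One consequence of taking printed bounds at face
value: two bundled rows whose lower bound prints as exactly 1.00 are
excluded by the interval rule even though the source counted them
significant at more decimal places; neither affects any variant-level
count.

`deduplicate()` resolves multiple meta-analyses of one association —
key (variant, comparison, study type, subtype, ethnicity) — by most
recent year, then largest total sample, then first-seen with a warning.
Subtype and ethnicity are in the key so stratified rows coexist with
overall rows; the source is silent here, but subgroup tables cannot be
reproduced otherwise.

## Printed versus recomputed counting

`run_reanalysis()` counts noteworthy rows and variants twice where
possible: from its own recomputed grid, and from the printed statistic
columns of a fixture (`counts_printed`). The printed mode exists because
the published spreadsheet ran on unrounded data; recomputation from
2-decimal ORs cannot match its cells exactly, and headline counts sit on
threshold comparisons of those cells. Variant-level counts treat a
variant as noteworthy when *any* of its genetic-model rows is — the rule
that reconciles the published "4 of 8 variants" statement with its
19-row table.

`compare_to_printed()` quantifies the printed/recomputed gap cell by
cell. On the observational table the median absolute deviation is about
0.006 (maximum 0.08), consistent with input rounding; the deviations are
diagnostics, not scores.

## Attributable risk

`single_par()` uses Levin's allele-frequency form
$f(OR-1)/(f(OR-1)+1)$, identified by exact (10-decimal) reproduction of
the published per-SNP PAR column, including the magnitude convention for
protective alleles. `joint_par()` reports both $\prod_i(1-PAR_i)$ and
$1-\prod_i(1-PAR_i)$: the published joint value (44.2%) is numerically
the former, while the conventional joint attributable risk under
independence is the latter (55.8%). Whether the source mislabelled the
product cannot be determined from its text, so both are first-class
outputs and neither is silently "corrected".

## The synthetic generator

`simulate_catalog()` emulates the upstream process the synopsis consumed:
per variant, a control minor-allele frequency drawn uniformly from
`maf_range`, study-level allele counts Binomial$(2n, f)$ with the case
frequency given by the odds transform of a true OR, and fixed-effect
inverse-variance pooling (Woolf variances, 0.5 continuity correction on
zero cells) down to one OR/CI/p record. Defaults — 100 variants, 10%
non-null at OR 1.2, five studies of 1000 cases and 1000 controls, MAF in
(0.05, 0.5) — describe a modest candidate-gene literature; tests that
need other regimes say so explicitly (e.g. 20 studies of 2000/2000 for
parameter recovery, 500 null GWAS-labelled variants for the
false-noteworthiness rate, 1000 single-study replicates for the null-z
Kolmogorov–Smirnov check).

What it deliberately does not emulate: between-study heterogeneity
(random effects), linkage disequilibrium between variants, genotype-level
(dominant/recessive) models, covariates, or publication bias.
Heterogeneity enters the real pipeline only through user-supplied Venice
replication grades, so a fixed-effect generator exercises every code path
the package has; but a green simulator test says nothing about how FPRP
behaves under the heterogeneity or selection effects present in real
literatures. Determinism is guaranteed by `withr::with_seed` around
integer binomial draws, and the caller's RNG state is left untouched.

## Venice grading

Grades arrive either as pre-formed strings (`"A + C + C"`) or as raw
inputs: minor-group count for amount (A $>$ 1000, C $<$ 100 by default)
and $I^2$ for replication (A $<$ 25, C $>$ 50). This synopsis' source did
not restate its numeric cut-offs, so the defaults follow the Venice
criteria literature and are configurable arguments. Bias has no
computable rule here and is always user-supplied. In combination, any C
forces low credibility even when other grades are missing (C dominates
NA); any missing grade without a C yields NA — the mapping that
reproduces the published credibility column for all 19 observational
rows, including its two NA rows. Whether "amount" should grade
minor-allele counts or total sample size is not stated in the source;
`grade_amount()` takes whichever count the caller passes.

## Problem sizes and runtime

The test suite runs the full fixtures (19 + 47 + 36 records, each profile
a prior × detection-OR grid), 200–300-case property fuzzes for the math
core, and simulator runs of 500–1000 variants; the whole suite completes
in well under a minute on a single core, and the acceptance script in
seconds. These sizes were chosen as the smallest that make the
statistical assertions sharp (e.g. the KS test at n = 1000, pooled-OR
recovery within ±0.1 at 20 × 2000/2000).

## Known limitations

* Recomputed FPRP/BFDP inherit the rounding of printed ORs and intervals;
  exact reproduction of spreadsheet cells is only possible in printed
  mode.
* The exact conventions behind the published cells (fixed-α versus
  observed-p power, printed versus reconstructed p) cannot be uniquely
  identified from rounded inputs; both are implemented, agreement is
  ~±0.05, and the default is the best-tracking faithful choice.
* PAR assumes independent variants and uses published allelic ORs as
  relative-risk surrogates, as the source did; no confidence intervals
  are attached because the source provides none.
* No random-effects pooling, exact Bayes factors, or multiple-testing
  procedures beyond the fixed noteworthiness thresholds.
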