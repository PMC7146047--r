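---
title: "Genetic association meta-analysis from genotype counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic association meta-analysis from genotype counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpmeta)
library(dplyr)
```

snpmeta pools case-control genetic association studies that report nothing
more than genotype counts. That is the common situation in candidate-gene
meta-analysis: each primary study prints a 3 x 2 table (CC / CT / TT by
case / control status) and the synthesis has to rebuild every effect size
from those integers. The package implements the whole chain — contrast
construction, Hardy-Weinberg screening, fixed- and random-effects pooling
with heterogeneity-driven model choice, publication-bias tests and
leave-one-out sensitivity — and ships a complete worked data set on two
complement factor I (*CFI*) polymorphisms (rs10033900 and rs2285714) and
age-related macular degeneration (AMD), against which the whole pipeline is
continuously tested.

Throughout, T is the wild-type and C the mutant allele, mutant-bearing
genotypes are the exposure, and an odds ratio (OR) below 1 therefore reads
as a protective C allele.

## The five genetic models

A biallelic SNP admits five classical 2 x 2 contrasts, built by
`build_contrasts()`:

| model | exposed | unexposed | note |
|---|---|---|---|
| `allele` | C alleles | T alleles | each subject contributes 2 alleles |
| `heterozygote` | CT | TT | CC carriers dropped |
| `dominant` | CC + CT | TT | |
| `homozygote` | CC | TT | CT carriers dropped |
| `recessive` | CC | CT + TT | |

The heterozygote and homozygote models are *conditional* contrasts: the
excluded genotype is removed from the table rather than folded into a
margin. This is the convention the pairwise column labels ("CT vs. TT",
"CC vs. TT") imply, and the only one under which the bundled data reproduce
their published pooled estimates.

The allele model treats the two alleles of one subject as independent,
which is exact under Hardy-Weinberg equilibrium and a mild approximation
otherwise; that is one reason control groups are screened for HWE at all.

## Per-study effects

For a table with cells $a, b, c, d$ (exposed cases, unexposed cases,
exposed controls, unexposed controls), `study_effects()` computes

$$\log \widehat{OR} = \log\frac{ad}{bc}, \qquad
  \widehat{se} = \sqrt{\tfrac1a + \tfrac1b + \tfrac1c + \tfrac1d},$$

with a Haldane-Anscombe correction — 0.5 added to **all four** cells —
applied only to studies containing a zero cell. The bundled tables contain
no zero cells, so the correction never touches the shipped reproduction; it
exists for degenerate simulated or user data. A study with an entirely
empty margin (no cases, or no exposed subjects in either group) carries no
information about the OR and raises an error instead of a fabricated
estimate.

## Heterogeneity and the pooling rule

`cochran_q()` computes Cochran's
$Q = \sum_i w_i (\hat\theta_i - \hat\theta_{IV})^2$ with fixed
inverse-variance weights $w_i = 1/\widehat{se}_i^2$, referred to
$\chi^2_{k-1}$, along with $I^2 = \max(0, (Q - df)/Q)$ and the
DerSimonian-Laird moment estimator

$$\hat\tau^2 = \max\!\left(0,\;
  \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right).$$

`select_and_pool()` applies the conventional decision rule: when the Q-test
p-value exceeds `q_threshold` (default **0.10**, the field's customary lax
threshold, chosen because Q is underpowered at typical $k$) the studies are
pooled with the **Mantel-Haenszel fixed-effect** estimator on the raw count
tables,

$$\widehat{OR}_{MH} = \frac{\sum_i a_i d_i / n_i}{\sum_i b_i c_i / n_i},$$

with the Robins-Breslow-Greenland variance for its logarithm; otherwise
with **DerSimonian-Laird random effects**, i.e. inverse-variance pooling of
the per-study log ORs with weights $1/(\widehat{se}_i^2 + \hat\tau^2)$.
Using MH (not inverse-variance) on the fixed branch matters: MH is defined
directly on the counts, is stable with sparse cells, and is what the
standard Stata/RevMan toolchain computes, so reproduction of published
fixed-effect rows depends on it. The rule is applied *independently per
stratum and per model*, each cell using its own Q — that is the only
reading under which the published subgroup confidence intervals of the
bundled data set are all reproduced.

The pooled Z test is two-sided against the standard normal,
$Z = \log\widehat{OR} / \widehat{se}(\log\widehat{OR})$, and 95% CIs are
Wald intervals on the log scale throughout.

```{r}
studies <- cfi_studies("rs10033900_total")
glance(select_and_pool(build_contrasts(studies, "allele")))
```

## Hardy-Weinberg screening

`hwe_test()` is the Pearson chi-square test with 1 degree of freedom
(three genotype classes minus one estimated allele frequency), no
continuity correction and no exact-test branch: this plain form is what
reproduces the HWE column published with the bundled data to three
decimals, and is the field's default for control-group quality checks.
Monomorphic groups are an error — the test is undefined there.

Screening is reported, not enforced: the rs2285714 control group of Wu 2013
violates HWE at p < 0.001, yet it stays in the default pool because the
published synthesis retained it (and dropping a third of a 3-study
meta-analysis silently would be worse than reporting the flag). Users who
want the stricter behaviour call `filter_hwe()` explicitly.

## Publication-bias tests

`egger_test()` is the classical Egger regression: OLS of the standard
normal deviate $\hat\theta_i/\widehat{se}_i$ on precision
$1/\widehat{se}_i$, the intercept tested with $k - 2$ degrees of freedom.
`begg_test()` is the Begg-Mazumdar rank correlation: deviations from the
fixed-effect mean are standardized by the conditional variance
$v_i^* = \widehat{se}_i^2 - (\sum_j 1/\widehat{se}_j^2)^{-1}$, and the
Kendall score $S$ between standardized effects and variances gives
$z = (|S| - c)\big/\sqrt{k(k-1)(2k+5)/18}$.

Two numerical choices deserve a note.

* **Begg continuity correction.** The correction $c = 1$ is exposed as a
  flag and **off by default**: the uncorrected statistic is the plain
  Begg-Mazumdar form, matches `metafor::ranktest()`, and reproduces the
  published rs2285714 value (z = 0.52) exactly. Published tables in this
  literature mix the two conventions — with only 3 studies the corrected
  statistic collapses to 0 — so the choice is made once, globally, and
  asserted in the tests rather than adapted per data set.
* **A reproducibility caveat on the bundled data.** Our Egger and Begg
  implementations reproduce the published bias-test rows for the
  rs10033900 recessive contrast and for all rs2285714 contrasts to every
  printed decimal, and agree with `metafor::regtest(model = "lm")` and
  `metafor::ranktest()` to machine precision on all sets. The published
  allele, heterozygote, dominant and homozygote rows for rs10033900,
  however, cannot be derived from the published genotype counts (the
  allele row is not even internally consistent: its printed coefficient
  divided by its printed SE does not give its printed t). The acceptance
  suite records those published values as printed and documents the
  discrepancy instead of absorbing it.

## Sensitivity analysis

`leave_one_out()` re-runs the full selection-and-pooling pipeline $k$
times, omitting one study each time. A study is flagged **influential**
when the re-pooled OR falls outside the all-study 95% CI — the criterion of
the standard influence plot, where each omitted-study estimate is drawn
against the overall confidence limits. Whether omission flips the
nominal significance of the pooled Z test is reported separately as
`sign_flip` but deliberately kept out of the flag: with an overall p-value
just under $\alpha$, omitting *any* appreciable study flips significance,
so a flag defined that way would mark borderline meta-analyses as globally
fragile rather than identify individual aberrant studies. (On the bundled
12-study allele set, two omissions flip a p of 0.029 to just above 0.05
while every re-pooled estimate stays well inside the overall CI — no study
is influential.)

## The pipeline surface

`run_analysis()` ties the stages together for a stratified analysis (total,
ethnicity, source of control, AMD type, genotyping method) and returns
plain tibbles; `render_report()` serializes them deterministically to
markdown, CSV or JSON with the presentation rounding used in published
tables (OR/CI to 2 decimals, p to 3, so p < 0.0005 prints as "0.000").
Disease-subtype strata come from a *separate* study table
(`cfi_studies("rs10033900_by_type")`) because subtypes are case subsets of
the same cohorts sharing control groups: they can be compared within the
subtype block but must not be appended to the total-AMD pool. Strata with
one study are reported unpooled rather than dropped. `reproduce_cfi()` runs
the complete bundled analysis in one call.

```{r}
rep <- reproduce_cfi()
filter(rep$rs10033900$results, stratum_factor == "total", model == "allele")
```

## The synthetic-study generator

`simulate_meta()` generates study sets with exactly the structure the
estimators assume, so that every stage is testable without external data.
Control genotypes are multinomial draws from HWE proportions at a control
mutant-allele frequency `maf`; a per-study log OR is drawn from
$N(\log OR_{true}, \tau^2)$; the case allele frequency is implied by
multiplying the control allele *odds* by that study's OR; and case
genotypes are drawn under HWE at the induced frequency. This multiplicative
allelic model is the simplest generative mechanism consistent with the
allele-contrast analysis, and it fixes the true value of every
genotype-level contrast for oracle checks. HWE violations are injected by
an inbreeding-style distortion (F = 0.5) of the control genotype
probabilities.

Defaults are the observed conditions of the bundled rs10033900 set — 12
studies, control C-allele frequency 0.43 (the pooled control frequency),
true OR 0.87 and $\tau^2$ = 0.032 (its headline allele-model random-effects
estimates), case sizes uniform on 100-1100 and control sizes on 55-1260
(its observed ranges) — so a default simulation is "another data set like
the bundled one".

What the generator does **not** emulate: linkage disequilibrium between
SNPs, covariate or population-stratification structure, genotyping error,
and selective publication (its studies are a complete sample, so bias tests
on simulated sets should be null). Passing simulation-based tests therefore
says the estimators are correct under the stated sampling model, not that
real literatures are free of those complications.

Simulation-based checks in the test suite use sizes chosen to make the
Monte-Carlo error small relative to the asserted tolerances while keeping
the suite quick: 1000 replicates of k = 12 for the Q-test type-I rate
(Monte-Carlo sd ~0.95% against a +/-3% band) and 200 replicates of k = 50
for recovery and CI coverage of a true OR of 0.8.

## Known limitations

* DL $\hat\tau^2$ is noisy and downward-biased at small $k$; with $k = 2$
  or 3 the random-effects branch is close to fixed-effect pooling. No
  Hartung-Knapp small-sample adjustment is offered.
* Wald CIs on the log OR undercover slightly in very sparse tables; no
  exact or profile intervals.
* No Peto OR, risk ratios or differences; no meta-regression; no
  trim-and-fill or other selection-model corrections — the bias tests are
  diagnostics only.
* Egger's test is known to be anticonservative for binary outcomes with
  large effects; with $k \le 10$ both bias tests have little power.
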