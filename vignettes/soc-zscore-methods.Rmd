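---
title: "SOC-level Z-score safety profiles: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SOC-level Z-score safety profiles: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(socsafety)
```

## The statistic

For each drug *j* the pipeline produces a 27-vector of counts
$N_i^j$: the number of drug-event combinations (one suspect-drug ×
mapped-reaction pair per retained report) falling into system organ
class (SOC) *i*. The safety-concern metric standardizes each count
against the drug's own distribution across the 27 classes:

$$Z_i^j = \frac{N_i^j - \mu_j}{\sigma_j}, \qquad
\mu_j = \frac{1}{27}\sum_{i=1}^{27} N_i^j, \qquad
\sigma_j = \sqrt{\tfrac{1}{27}\sum_{i=1}^{27}(N_i^j-\mu_j)^2}.$$

This is a *within-drug* disproportionality measure: it asks which organ
classes dominate a drug's adverse-event profile, not whether the drug
generates more reports than others. It therefore cancels overall
reporting volume (prescription rates, time on market) by construction,
which is also its main interpretive limitation: a drug whose events are
genuinely uniform across organ systems shows no signal anywhere, no
matter how toxic.

Three algebraic consequences of the population standardization are used
as test invariants throughout the package:

* $\sum_i Z_i = 0$ and $\sum_i Z_i^2 = 27$ whenever $\sigma_j > 0$;
* hence $|Z_i| \le \sqrt{26} \approx 5.099$, attained exactly by a
  one-hot profile; and
* at most $\lfloor 27/2^2 \rfloor = 6$ classes can exceed $Z = 2$.

$Z$ is invariant under positive affine transformations
$N \mapsto aN + b$ of the whole profile, so the one-hot profile
$(100, 0 \times 26)$ and the shifted profile $(3, 1 \times 26)$ have
identical Z-vectors — a convenient closed-form check.

### The standard-deviation divisor

The mean is defined with divisor 27, and no Bessel correction is stated
for $\sigma_j$; we take the population divisor (27) as the default.
It is also what makes the $\sum Z^2 = 27$ invariant exact. Because the
sample-SD reading (divisor 26) is defensible, `computeZscores()` takes
`divisor = "sample"`, which shrinks every Z by the constant
$\sqrt{26/27} \approx 0.981$ — band assignments can differ only for
values within 2% of a boundary.

### Bands and degenerate profiles

Z-scores are banded $(2,\infty)$ / $(1,2]$ / $(0,1]$ / $(-1,0]$ /
$(-\infty,-1]$: *significantly frequent*, *frequent*, *slightly
frequent*, *likely infrequent*, *infrequent*. The significance rule is
strictly $Z > 2$, which forces $Z = 2$ out of the top band; we apply
the same "boundary belongs to the band below" convention at every cut,
since the band prose does not assign the endpoints. When all 27 counts
are equal ($\sigma_j = 0$, e.g. a drug with a single mapped event) the
Z-vector is undefined; we return `NA` with band `undefined` rather than
0 or ±∞, and such drugs are listed but never called significant.
A profile with zero total is an error, not an `NA`: it cannot occur
for drugs that enter aggregation with at least one record.

## Cleaning model

A spontaneous-reporting archive mixes resubmissions and fragments. The
cleaning stage makes the following choices:

* **Completeness** means case id, at least one non-empty drug name and
  at least one non-empty reaction could be located; anything less is
  dropped and counted.
* **The duplicate key** is the case id together with the
  *order-insensitive sets* of normalized drug names and reaction terms
  of the whole report. Per-report semantics is the only reading under
  which "keep the latest version of the report" is well defined. The
  highest case version survives; a tie keeps the later report in input
  order with a warning (receipt dates are outside the dialect).
* **Suspect roles**: only primary-suspect (PS) and secondary-suspect
  (SS) mentions generate drug-event records; concomitant and
  interacting drugs are ignored to limit false positives. A drug
  mentioned as both PS and SS in one report counts once per reaction,
  because the unit is the drug-event combination.
* **Within-report repeats** of the same normalized reaction term
  collapse to one before counting (transcription repeats would
  otherwise double-count); the collapse is tallied.
* Sex strata: records are female/male only under the configured codes;
  everything else (unknown, unreported, or other values) stays in the
  overall stream but is excluded from the sex tables, so
  overall = female + male + unspecified always holds.

Drug matching in free text (trial interventions and FAERS verbatim
names) is whole-token phrase matching on normalized text: a synonym
matches only as a contiguous run of whole alphanumeric tokens. This is
deliberately conservative — substring matching is unusable on real drug
lists, where "chloroquine" is a substring of "hydroxychloroquine". A
synonym claimed by two drugs aborts the lexicon load rather than being
resolved by precedence, because a silent wrong assignment would corrupt
every downstream count.

## What the simulator emulates — and what it does not

`simulateCorpus()` encodes exactly the data model the statistic
assumes: each drug's reactions are i.i.d. categorical draws over the 27
SOCs; a planted (drug, SOC) pair multiplies that SOC's weight by
$\lambda \ge 1$ before renormalization, so with a uniform baseline the
hot-SOC probability is $\lambda/(26+\lambda)$. Duplicates are exact
re-emissions of a clean report with version 2, replicating the
duplicate key precisely, so the cleaner's effect is predictable from
the manifest. Incomplete reports are *extra* reports missing the case
id, the drug rows or the reaction rows, so they never perturb the
ground-truth counts (reports missing their id are written with unique
version numbers so that they remain distinct join keys). One seeded
RNG stream drives all draws in a fixed order — lexicon ATC codes,
trials, reports in drug order, then corruption — and the frozen
micro-fixture regression-tests that order.

Defaults are chosen as plausible conventions, not estimates, since no
distributional statement about report volume exists to copy: 20 drugs ×
200 reports, uniform SOC baseline, 1 + Poisson(1) reactions per report,
sexes F/M/UNK at 0.55/0.40/0.05, roles PS/SS/C at 0.75/0.20/0.05, 5%
duplicate and 5% incomplete rates, half of reactions reported as LLTs.

What it does **not** model, by design: reporting-rate confounders
(stimulated reporting, time on market), indication bias, severity,
doses, drug–drug interactions, and correlated reactions within a
report. Passing tests therefore demonstrate that the implementation
computes its statistic correctly under the statistic's own model — not
that the metric is robust to the biases of real spontaneous data.

## Numerical and design notes

* The ground-truth manifest counts *unique mapped suspect reactions*
  per report, i.e. exactly what a correct pipeline should recover; the
  oracle-equivalence tests then compare against an independent
  brute-force recount written as plain nested loops with its own
  normalization and matching code.
* Problem sizes in the tests — corpora of 40–200 reports per drug, a
  5,000-report oracle corpus, 10 planted-signal seeds, 1,000 random
  profiles for the moment invariants — were chosen so the full suite
  exercises every path at comfortably testable scale while invariants
  are asserted at 1e-9.
* Null calibration: with $\lambda = 1$ and ~200–400 reactions per drug,
  about 3% of (drug, SOC) cells exceed $Z = 2$ by chance. The metric
  applies no multiple-testing correction, so significant calls on real
  data should be read as ranking, not inference.
* Trial status exclusion is exact on *withdrawn*, *suspended*,
  *terminated* after case-folding, and composite statuses such as
  "Terminated (halted)" are excluded by prefix; any unknown status
  passes through. Only the interventions field is searched for drugs
  (titles are not).
* Ambiguous intervention strings matching several drugs credit every
  match; a drug's trial count is per-trial deduplicated. Drugs with
  codes in several ATC first-letter classes contribute their full
  totals to each class, and duplicate letters within one drug collapse.
* A report missing from the demographic file still analyzes (sex
  becomes unspecified); joins never fail on missing keys, they produce
  incomplete or sexless reports that the cleaning rules handle.

## Session info

```{r}
sessionInfo()
```
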