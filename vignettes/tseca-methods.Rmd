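---
title: "Methods: direct-vs-indirect inconsistency and TSECA score aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: direct-vs-indirect inconsistency and TSECA score aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tseca)
```

## The problem

When two treatments B and C have rarely or never been compared head to
head, their relative effect can be estimated *indirectly* through trials
that each compared one of them to a common comparator A. The adjusted
indirect comparison preserves within-trial randomisation, but its validity
rests on assumptions that are not guaranteed by randomisation itself:

* **similarity** — the relative effect estimated in the AvB trials is
  generalizable to the populations and settings of the AvC trials (and
  vice versa); it fails when *effect modifiers* (variables that change the
  relative, not just absolute, effect) are distributed unevenly between
  the two trial sets;
* **consistency** — direct BvC evidence and the indirect estimate via A
  target the same quantity; required whenever the two are mixed.

`tseca` implements the quantitative side of studying these assumptions on
collections of three-set evidence networks: the inconsistency statistic,
the aggregation rules for structured similarity/consistency assessment
scores, the agreement and association analyses connecting the two, and a
simulator that generates networks with *known* true inconsistency so the
whole chain can be calibrated.

## Effect estimation and pooling

Each trial is a 2x2 table. The log odds ratio and its variance use the
standard cell formulas; a table containing any zero cell gets 0.5 added to
all four cells first, and tables with zero events (or all events) in both
arms are excluded from pooling rather than patched — they carry no
information about the odds ratio. This is the usual convention in
Cochrane-style meta-analysis of sparse binary data; it is a convention,
not a theorem, and sensitivity to it matters mainly when events are rare.

Pooling within a comparison set is inverse-variance, either fixed-effect
or random-effects with the DerSimonian–Laird moment estimator (the
package default). The choice is exposed as `pooling = c("dl", "fixed")`
throughout because neither dominates: DL is the conservative default for
heterogeneous review collections, while under exact homogeneity the
fixed-effect model is the correctly specified one. The test suite
cross-checks both closed forms against `metafor`.

All 95% intervals use the quantile 1.96 exactly (not 1.959964). The
difference is invisible at reporting precision and the round value keeps
worked examples stable and hand-checkable.

## The inconsistency statistic

With pooled A-anchored estimates, the Bucher indirect estimate is
`log OR(BvC) = log OR(BvA) − log OR(CvA)` with variances adding. The
discrepancy between direct and indirect evidence is measured on the log
odds ratio scale:

\[ w = \log OR_{dir} - \log OR_{ind}, \qquad
   se_w = \sqrt{se_{dir}^2 + se_{ind}^2}, \qquad z = w / se_w . \]

`exp(w)` is the ratio of odds ratios (ROR), 1 under perfect consistency;
`|w|` is the absolute discrepancy used in the association analyses. The
two-sided normal test at `alpha = 0.05` matches the convention of
classifying reviews as showing "statistically significant inconsistency";
no multiplicity adjustment is applied across reviews, since the per-review
classification is itself the quantity of interest. Orientation is carried
as explicit metadata (`"BvA"`, `"CvA"`, `"BvC"`) and functions error
rather than guess when it is missing or mismatched — sign errors are the
dominant practical hazard in indirect comparisons.

`se_from_ci()` back-calculates a standard error from a printed 95%
interval, so published summary estimates can be analysed without
trial-level data. When trial data are available both routes (raw tables
vs printed summaries) are provided, and the test suite verifies they
agree when fed consistent inputs.

## TSECA score aggregation

The instruments score trial similarity (TSA), quality similarity (QSA) and
evidence consistency (ECA) on a 1 (very low) to 5 (very high) scale, by
two independent assessors. The package implements the arithmetic, not the
judgement:

* overall TSA/ECA = unweighted mean of the item scores (participants,
  interventions, outcomes, plus free-form extras). No weighting is used
  because components and overall scores live on the same printed scale
  with none reported.
* trial quality is averaged per set weighted by patient numbers; the QSA
  score maps the between-set difference as `5 − |Δ|`, clipped to the
  scale. The mapping is one deliberate design decision among several
  monotone options; it is isolated behind `qsa_score()` precisely so an
  assessor-judged alternative can be swapped in.
* two assessors are combined by simple averaging; half- and quarter-point
  scores are therefore first-class.
* `min_item_score()` returns the minimum item score across instruments —
  the conservative summary motivated by the fact that a single divergent
  variable can violate the assumptions even when averages look fine.
* ECA exceeding TSA is flagged as a warning, not an error: the ordering
  holds "in principle" but two independent assessors can legitimately
  produce violations.

## Agreement and association

Interassessor agreement uses the Bland–Altman method: mean and SD of
paired differences, limits of agreement `mean ± 1.96·sd`, and a
normal-approximation CI for the mean difference (`t`-based by flag; at
n = 94 they differ in the third decimal).

The association between scores and observed inconsistency is analysed two
ways, because no single statistic is canonical here: (i) reviews are split
at empirical quartile cut points of each score (type-7 linear-interpolation
quantiles, membership by `<=` on the upper bound) and the proportions with
significant inconsistency are compared by Pearson chi-square without
continuity correction, `df = groups − 1` — this convention exactly
reproduces published subgroup p-values from their printed counts (see
`scripts/acceptance.R`); (ii) Pearson and Spearman correlations of score
against `|w|`, with a zero-variance input reported as *undefined* rather
than silently zero.

## The synthetic-data generator

`sim_config()` + `simulate_network()` generate three-set networks on the
logit scale: per trial, a reference-arm event probability is drawn from a
Beta law, the trial log OR is `mu_set + N(0, tau²)`, and arm events are
binomial. Direct BvC trials use `mu = (mu_ab − mu_ac) + omega`, so `omega`
**is** the true inconsistency and the estimator `w` targets it directly.
Giving AvB and AvC different Beta baselines reproduces the classic
effect-modification mechanism of imbalanced baseline risks between trial
sets.

Default conditions (chosen once, as the study conditions the package is
meant to emulate):

| parameter | default | rationale |
|---|---|---|
| `n_reviews` | 94 | size of the review collection being emulated |
| `k_ab`, `k_ac`, `k_bc` | 3 | small networks typical of indirect-comparison reviews |
| `n_per_arm` | 50–300 | common trial sizes for binary outcomes |
| baseline Beta | (2, 2) | broad, mean 0.5, avoids degenerate all-zero arms |
| `tau` | 0.1 | mild between-trial heterogeneity |
| `omega` | 0 | consistency holds unless asked otherwise |
| `score_center`, `score_slope` | 3.7, 0.45 | overall scores centred near 3.7–3.85 with range ≈ 2.6–4.8, the spread seen when trained assessors rate heterogeneous collections |
| `assessor_bias` | 0.29 | magnitude of a systematic interassessor shift on outcome-measure similarity scoring |
| `score_noise` | 0.44 | paired-difference SD ≈ 0.62, i.e. a mean-difference CI of about ±0.13 at 94 reviews |
| `granularity` | 0.25 | quarter-point scoring grid (averages like 4.79 are representable) |

A single seed drives per-review substreams, so review *r* is reproduced
bit-identically regardless of how many reviews are drawn. The latent
similarity `delta` behind the scores is, by default, *independent* of the
true inconsistency (`delta_link = 0`): there is no established
quantitative law linking perceived similarity to actual inconsistency, so
the generator exposes the link strength as a free parameter instead of
asserting one. Consequently, passing association tests under the default
shows correct null behaviour of the analysis chain — it says nothing about
whether real scores predict real inconsistency.

What the generator does **not** emulate: multi-arm trials, non-binary
outcomes, selection and reporting biases, correlated quality and effect
sizes, and the qualitative text of assessments. Calibration results on
synthetic data transfer to real collections only to the extent that these
simplifications are tolerable.

## Numerical and calibration choices

* Problem sizes: the calibration suites use 2000 replicates for the
  type-I error (binomial SE ≈ 0.005 at the nominal 0.05) and 200
  replicates per grid point for parameter recovery and power, at 5 trials
  per set and 200 patients per arm — large enough that Monte-Carlo error
  is a small fraction of the effects being measured.
* The type-I calibration is run with **fixed-effect** pooling because its
  null (`tau = 0`) makes the fixed model correctly specified; the DL
  default is slightly conservative there (it spends degrees of freedom
  estimating a variance that is truly zero), which the suite checks as a
  one-sided bound rather than calling it miscalibration.
* Degenerate inputs: all-equal score vectors collapse to a single
  quantile group with a warning; zero-variance association inputs are
  reported as undefined; inestimable trials are excluded with their count
  logged per review; incomplete networks are excluded from the joint
  analysis with a warning but remain representable for single-comparison
  use.
* `write_results()` writes full double precision; round trips are exact
  to ~1e-12 relative error.

## Limitations

The package analyses two-arm binary-outcome trials on the OR scale only;
reviews whose outcome statistic cannot be expressed as an OR are rejected
at input rather than converted. Networks larger than three treatment
nodes, node-splitting, Bayesian mixed treatment comparison and
meta-regression adjustment for effect modifiers are out of scope. The QSA
mapping and the overall-score aggregation are declared conventions for
quantities whose published definitions are incomplete; both sit behind
single functions so alternatives can be substituted without touching the
rest of the pipeline.
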