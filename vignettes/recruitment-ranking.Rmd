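---
title: "Ranking EHR registrants for clinical-study recruitment: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking EHR registrants for clinical-study recruitment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recruitcbr)
```

## The problem

Clinical studies that recruit through an opt-in research register can search
the registrants' linked electronic health records (EHRs) for likely
participants. The conventional strategy translates the study's
inclusion/exclusion criteria into database queries over coded EHR fields.
`recruitcbr` implements the alternative this package is about: case-based
reasoning (CBR). Already-recruited participants define what a suitable
participant's coded record looks like, and every other registrant is ranked
by similarity to that target. The package also implements the full
evaluation harness for comparing the two strategies, and a synthetic cohort
generator so that every stage is testable without access to protected
patient data.

## Data model

Clinical facts are held in long entity–attribute–value (EAV) form: one row
per coded event, with four entities — diagnoses (ICD-10), procedures
(OPCS-4), prescriptions (BNF codes) and laboratory tests (read codes).
Codes are opaque strings; no dictionary validation or hierarchy rollup is
attempted. Lab result values and prescription quantities are carried
through I/O but do not enter the similarity computation: nothing in the
method definition uses them, and occurrence counts alone already encode
intensity of care. Dates are likewise optional and unused by the core
pipeline — the extraction window of a real dataset is a curation fact, not
a model input.

Before analysis, persons with no meaningful clinical data are excluded. The
strict filter (`all_four`, the default) retains a person only with at least
one event in every entity, mirroring how both the participant cohorts and
the registrant pool are defined; a looser `any` mode is exposed because the
exclusion rule can also be read disjunctively. Lab events whose test
description is missing (empty code) never count toward coverage.

## The CBR model

For one study (a *project*) with known participants:

1. **Featured codes.** Per entity, a code's *support* is the fraction of
   training participants carrying it at least once (repeat occurrences
   count once here — sharing a code is a per-person notion). Selection
   requires a minimum of 10 codes with support ≥ 0.8: if at least 10 codes
   pass, all passers are kept (`threshold_met`); if some but fewer than 10
   pass, the list is topped up to 10 by descending support
   (`topped_up`) — so a *minimum* of 10 is honoured while *all* passers
   are kept when more than 10 pass and *all observed codes* are kept when
   none does; a flag (`top_up = FALSE`)
   restricts to the passers alone for sensitivity analysis; if no code
   passes, every observed code is retained (`all_retained`). Ties in
   support are broken lexicographically so selection is deterministic
   across platforms.

2. **Target profile.** The weight of featured code $c$ is the central
   tendency of its occurrence count across training participants,
   non-carriers contributing zeros. The default tendency is the mean;
   the median is exposed because "central tendency" is a family, not a
   statistic. Occurrence means event multiplicity by default — a person
   prescribed the same drug twelve times is more like a chronic user than
   a one-off — with a binary presence/absence option as the conservative
   alternative.

3. **Entity similarities.** Each person's occurrence-count vector over the
   featured codes is compared to the profile weights by cosine similarity
   $\cos(u, w) = u \cdot w / (\lVert u\rVert\,\lVert w\rVert)$, once per
   entity, giving four scores in $[0, 1]$ (entries are nonnegative). A
   person carrying none of an entity's featured codes has a zero vector;
   its cosine is defined as 0, i.e. maximally dissimilar, so such persons
   sink in the ranking rather than being undefined.

4. **Combined score.** A linear regression (ordinary least squares, taken
   literally rather than substituting logistic regression) of the 0/1
   recruitment label on the four entity similarities yields four entity
   weights plus an intercept. Four weights cannot be identified from
   positives alone, so the training design is the training-fold
   participants (label 1) plus a seeded random sample of registrants
   outside the fold's test set (label 0; 500 by default, a config knob).
   Weights are unconstrained in sign. Rank-deficient designs (a constant
   similarity column is common in degenerate cohorts) are solved by the
   minimum-norm least-squares solution.

5. **Scaling.** The fitted score is min-max scaled to $[0, 1]$ within each
   test set. The map is strictly monotone, so it cannot change any rank,
   ROC or ranking metric; it exists to make scores and cut-offs comparable
   across folds. If all raw scores coincide, every scaled score is 0.5.

## Cross-validation and test-set assembly

Each project is analysed by two-fold cross-validation: participants are
split at random into halves differing in size by at most one; each half
trains the profile and regression while the other half is hidden in a
large test set consisting of the held-out participants, a seeded random
draw of registrants (30,000 by default, scaled down in the package's own
experiments), and all database-identified but non-recruited candidates.
Duplicates keep their database flag. The random draw is made independently
per fold with a derived sub-seed; sharing one draw across both folds would
be an equally defensible design, and both folds draw from the same pool
either way. Regression negatives are drawn from registrants *outside* the fold's
test set, so no person ever appears on both sides of a fold (asserted at
run time).

## Evaluation

* **ROC AUC** in the Mann–Whitney formulation (ties credited 1/2),
  identical to the trapezoidal area under the ROC curve, with the standard
  quality bands (≥ 0.9 excellent, 0.8–0.9 good, 0.7–0.8 fair, 0.6–0.7
  poor, 0.5–0.6 fail, below 0.5 worse than random guessing).
* **Bootstrap CI**: percentile interval from 2000 replicates, stratified
  by class so every replicate retains both classes (non-stratified
  resampling is a flag). When a class has fewer than 2 members no stable
  interval exists and an `NA` marker is returned rather than an error —
  this is exactly what two-participant cohorts produce.
* **Cut-off sweep**: thresholds 0 to 1 in steps of 0.01 (a percent axis);
  the performance metric is the scaled sum of sensitivity and specificity,
  implemented as their arithmetic mean so it lies in $[0, 1]$ — any
  positive affine scaling leaves the argmax unchanged. The smallest
  maximizing threshold is reported for reproducibility.
* **Ranking metrics**: precision at 5 and 10, average precision (MAP) and
  reciprocal rank (MRR) of the list ordered by decreasing scaled score.
  Ties in the score are broken by a seeded random shuffle before a stable
  sort — deterministic yet unbiased with respect to person identity.
  Each metric is reported alongside its *Upper* reference (the ideal list
  with all relevant persons on top: P@k = min(n, k)/k, MAP = MRR = 1) and
  its *Lower* reference (a seeded uniformly random list; one realization
  by default, with an option to average several).
* **Top-50 overlap**: the proportion of the top 50 ranked persons that the
  database-query strategy also identified — the consistency measure
  between CBR and database search.

Suites of projects aggregate to grand means over all ranking lists (two
per project) and a pooled cut-off sweep.

## The synthetic cohort generator

Real register data live in a safe haven and cannot leave it, so the
generator produces populations with the statistical structure the method
assumes:

* **Heavy-tailed background usage.** Each entity has a vocabulary
  (default 500 codes) sampled under a Zipf law with exponent 1.2 — clinical
  code usage is strongly head-heavy, a few common codes accounting for
  most events.
* **Guaranteed coverage.** Event counts per person per entity are
  1 + Poisson(mean − 1), so every generated person passes the strict
  inclusion filter by construction; the filter itself is exercised with
  hand-built fixtures instead of rejection sampling.
* **Signature structure.** Each entity has a set of signature codes
  (default 12, on the order of the handful of codes a study's eligibility
  criteria revolve around) carried by participants with probability 0.9
  (penetrance) and by non-participants with probability 0.02, with
  occurrence multiplicity 1 + Poisson(1) for carriers.
* **Database flags** are drawn independently of the codes (sensitivity
  0.7 among participants, 0.005 slack among non-participants) so the
  top-50 overlap has nontrivial behaviour rather than restating the
  ranking.

A *null* variant sets penetrance equal to carriage, decoupling labels from
codes entirely; a correct pipeline scores it at chance.

What the generator does **not** emulate: realistic code strings, calendar
structure, comorbidity correlations between codes or entities, or
scattered multi-phenotype cohorts. Passing tests on synthetic data
therefore demonstrate that the pipeline recovers planted structure and
stays honest under the null — not that real cohorts are this separable.
Indeed, at penetrance 0.9 over four entities the synthetic signal is so
strong that even single-training-case profiles rank the held-out
participant perfectly, which real degenerate cohorts demonstrably do not.

## Problem sizes and numerical choices

The package's own experiments (tests and the acceptance script) run the
full pipeline at a scaled-down geometry chosen to keep a complete
multi-seed study in minutes on one core: 20-participant cohorts,
2,000-registrant test draws from a pool of 2,500 (the extra 500 form the
reservoir for regression negatives, which must come from outside the test
set), 400 negatives, and 200 bootstrap replicates where the CI is not
itself under study (2000 where it is). Determinism is end to end: every
random stage (fold split, registrant draw, negative sample, bootstrap,
tie-break, lower reference) uses a sub-seed derived from one master seed,
and reruns produce byte-identical CSV reports.

Other numerical conventions: zero-vector cosine is 0; degenerate constant
score sets scale to 0.5; the cut-off grid tie-break takes the smallest
maximizer; support ties order lexicographically; AUC uses midranks, exact
under ties.

## Known limitations

* OLS on a 0/1 label is a linear probability model; predicted scores are
  not probabilities (min-max scaling makes no such claim either). A
  logistic link is the obvious variant and would change fitted weights but
  not the general framework.
* The composition of regression negatives (how many, from where) is a
  design choice; results at extreme class imbalance can be sensitive to it.
* Ranking metrics on 30,000-person lists with a handful of relevant items
  are nearly degenerate (P5 and P10 are almost always 0); the Upper/Lower
  references exist precisely to calibrate that.
* The generator's independence assumptions (codes independent given
  carriage; database flags independent of scores) make synthetic data an
  easier target than real EHRs.
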