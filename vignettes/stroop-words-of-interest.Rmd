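---
title: "Words of interest from modified Stroop latencies: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Words of interest from modified Stroop latencies: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement idea

In a modified (emotional) Stroop task the participant names the ink colour
of a word while ignoring its meaning. Words that are personally salient —
emotionally charged, or tied to an unresolved daily-life issue — capture
attention and slow the colour-naming response. `stroopwoi` turns that
interference effect into an individual-level screening statistic: a **word
of interest** is a word whose colour-naming latency, standardised within
the participant, exceeds a chosen z cut-off. The ranked list of such words
is a candidate agenda of the issues currently loading on the person; the
per-category percentages of flagged words feed group-level models of how
interference differs between adults with ADHD and neurotypical controls.

The task has seven analysed rounds: one on ADHD-typical personality traits
(related / unrelated / distraction words), one on emotion words (positive /
neutral / negative, each rated −3…+3 by the participant), and five
daily-life domains (work and study; relationships and family; social
connections; hobbies and free time; self-image and confidence). Every word
is shown twice, once in red and once in blue. With 10 words per domain, the
five domains form the 50-word issue inventory from which the headline
"issues per participant" count is taken.

## Preprocessing

Latency preprocessing runs in a fixed, audited order:

1. **Fast-trial filter.** Raw trials faster than 100 ms are anticipations
   or accidental key presses and are dropped. The rule is *strictly*
   smaller-than: a 100 ms trial is kept.
2. **Colour averaging.** The word's latency is the mean of its red and blue
   presentations, `(lat_red + lat_blue) / 2`. If one colour was removed by
   the fast filter the surviving trial is used alone (`n_colors_used = 1`)
   rather than discarding the word — coverage of the 50-word inventory is
   worth more than the variance reduction of the second trial, and the
   fallback is visible in the output.
3. **Slow-word filter.** Word means larger than 2,000 ms reflect lapses or
   interruptions and are removed, again strictly greater-than. The order —
   fast rule on raw trials, slow rule on averaged means — follows the
   description of the averaging step preceding extreme-value removal, and
   both thresholds are arguments, not constants.
4. **Within-participant z-scoring.** Mean latency differs far more between
   participants than the interference effect itself, so word means are
   standardised within participant: `z = (x − m) / s` with the sample SD
   (n − 1). The default scope standardises each task round separately
   (`per_section`), because rounds differ in difficulty, priming and
   fatigue; `all_sections` pools a participant's words and is offered for
   sensitivity analysis. Standardisation could in principle also run the
   other way — each word across participants — but only the
   within-participant direction neutralises the dominant nuisance,
   between-participant variation in mean latency, so that is the
   implemented default.

Each stage reports counts in/out, so the outlier removals in any dataset
are fully traceable. Response accuracy is deliberately *not* filtered:
emotional interference in ADHD shows in response time rather than accuracy,
and the protocol defines no error-trial exclusion.

## The words-of-interest statistic

Given a participant's z table and a cut-off `t`, the flagged set is
`{word : z > t}` — strictly above, so a word exactly at the cut-off is not
flagged. Flags are sorted z-descending with ties broken by word text so
reports are reproducible bit for bit. The conventional cut-off grid is
0.5, 1.0, 1.5 and 2.0; 1.5 is the working default because it yields a
handful of issues per participant, and the cut-off is explicitly a
therapist-settable dial, not a fitted parameter.

The **percentage of words of interest** for a (section, category) cell
divides the flagged count by the *designed* word-list size of that cell,
not by the number of words that survived preprocessing. A word removed as
a slow outlier therefore still counts in the denominator. This keeps
percentages comparable across participants with different outlier counts;
it also means percentages are conservative for participants with many
removals.

The headline `n_issues` counts flagged words across the five daily-life
domains only (out of the 50-word inventory); personality and emotion flags
are computed and reported but kept separate, since they serve validation
rather than issue discovery. A defensible alternative would count only
the "related" subset of each domain; we count all 50 inventory words and
expose the full section/category breakdown, so either convention can be
read off a profile.

## Group-level models

**Two-way ANOVA.** Diagnosis (ADHD vs control) × word category (related /
unrelated / distraction) on the personality-round percentages, run at each
of the four cut-offs. Sums of squares are type II via `car::Anova`: every
participant contributes all three categories, so non-balance arises only
between diagnosis groups, where type II is the conventional choice. Effect
sizes are partial eta squared, `SS_term / (SS_term + SS_error)`. On exactly
balanced data the implementation agrees with a from-scratch sums-of-squares
decomposition to 1e-10 (tested).

**Moderated regression.** OLS of emotion-word mean latency on the
participant's *own* valence rating (−3…+3), diagnosis (control = 0,
ADHD = 1), and their product. A negative interaction coefficient means
negative words slow ADHD participants relative to controls. Only the rated
emotion words (positive/neutral/negative) enter; unrated distraction
fillers do not. The model has three predictors; per-term partial eta
squared is computed from type-II sums of squares obtained by model
comparison, which stays defined even on noise-free data.

**Logistic diagnostic model.** Diagnosis is predicted from the
personality-related percentage and the five daily-life domain percentages
(model 1), optionally plus the screener total (model 2). Percentages enter
as proportions (0–1), so a reported odds ratio is per full-scale change of
a predictor; on the raw 0–100 scale the per-unit odds ratios of such
bounded predictors become astronomically large or small and hard to read.
We report the likelihood-ratio chi-square against the intercept-only
model, McFadden pseudo-R², Wald z per predictor, and sensitivity /
specificity / percent correct at a predicted-probability threshold of 0.5
(an argument, not a constant). Perfect separation — common in
small cohorts with seven predictors — is detected (including the
near-zero-deviance case that IRLS reports as converged) and flagged, with
metrics still computed from the achieved predictions.

Participants who self-suspect undiagnosed ADHD are a first-class
`excluded_suspected` state: individual reports are still produced for
them, but every group model drops them.

## The synthetic cohort generator

No participant data are distributed with the task, so the generator is the
package's test bed. It emulates, per participant and word, two trials
(red, blue) with latency

```
latency = baseline_p + effects(word) + exGaussian(mu, sigma, tau)
```

* **Ex-Gaussian noise** (Gaussian convolved with an exponential tail;
  mean `mu + tau`) is the standard model for right-skewed reaction times.
  Defaults `mu = 500`, `sigma = 60`, `tau = 100` ms are conventional
  colour-naming magnitudes from the reaction-time literature; no
  empirical group RT summaries exist here to calibrate against.
* **Baseline heterogeneity**: participant intercepts are Gaussian with SD
  80 ms — large between-participant variation is precisely why the
  pipeline standardises within participant.
* **Valence model** on rated emotion words:
  `b_valence·v + b_diagnosis·d + b_interaction·v·d` with defaults
  (2.68, 20.89, −8.36) ms, the reference coefficient values, where `v` is
  the participant's own (noisy, rounded, clipped) rating and `d` the
  diagnosis indicator.
* **Related-word shift**: ADHD participants respond 30 ms slower to
  related words (personality and daily-life). The 30 ms default is our
  choice of a plausible interference magnitude, comparable to the
  reference diagnosis main effect (≈21 ms).
* **Planted issues**: each ADHD participant gets `k = 3` daily-life words
  (spread over distinct domains, as real issues plausibly are) shifted by
  3.0 within-participant word-mean SDs, where that SD is
  `sqrt((sigma² + tau²)/2)` for a two-trial mean (≈ 82 ms, so a ≈ 247 ms
  shift). These are the ground truth for recovery tests.
* **Contamination**: 0.2% of trials are replaced by a latency drawn
  uniformly on 4,000–6,000 ms and 0.05% on 5–95 ms. The ranges are chosen
  so an injected trial *deterministically* trips its outlier rule (a
  4,000 ms trial averaged with any plausible partner still exceeds the
  2,000 ms word-mean cut), which lets audit tests match removal counts to
  injected counts exactly when `sigma` and `tau` are small.
* **Ratings**: `clip(round((norm − 4) + N(0, 0.7)), −3, +3)` — the 1–7
  selection-norm valence rescaled to the −3…+3 survey scale, perturbed by
  individual taste (SD 0.7 scale points, under one survey step), then
  discretised as the instrument does. The regression consumes the
  discrete ratings as reals.
* **Reproducibility**: one global seed derives a per-participant substream
  (`(seed·10007 + i) mod (2³¹−1)`), so enlarging a cohort never reshuffles
  existing participants, and equal seeds give byte-identical output.

Ground truth (planted words, expected latencies, injected contamination,
generating coefficients) is emitted beside the data and never consumed by
the pipeline under test.

### What the generator does and does not emulate

It reproduces the statistical structure the analyses assume: baseline
heterogeneity, right-skewed trial noise, a linear valence×diagnosis
effect, category-level interference shifts, planted focal issues, and rare
extreme latencies. It does *not* simulate sequential effects (practice,
fatigue, priming carry-over between the domain rounds), colour-naming
errors, word-level lexical variation (length, frequency), correlations
between a participant's issues and their valence ratings, or screener item
responses (screener totals are drawn from two overlapping normals, 45 vs
25, SD 10, truncated at zero). Passing recovery tests on synthetic cohorts
therefore demonstrates that the pipeline is a consistent estimator of the
structure it assumes — not that real Stroop data satisfy those
assumptions.

## Numerical and calibration notes

Problem sizes for the standard simulation checks were fixed once: 500
participants for the null calibration of the flagged count, 200 replicates
of 120 participants × 24 emotion words for interaction-coefficient
recovery, 200 participants for planted-issue recall, and 200 randomised
fixtures per oracle-equivalence family. At these sizes the Monte-Carlo
standard error of each reported quantity is an order of magnitude below
the tolerance used to judge it.

Two calibration facts are worth stating plainly, both computed by
`analysis/05_simulation_checks.R` and the acceptance suite:

* **Interaction recovery is unbiased**: cohorts generated from the
  reference coefficients return a mean estimated valence×diagnosis
  coefficient of ≈ −8.36 ms/unit over 200 replicates, matching the
  generating value.
* **The null flagged count is skew-inflated**: with no planted effects the
  pipeline flags ≈ 3.9–4.0 of 50 daily-life words per participant at
  z > 1.5. Under Gaussian latencies the expectation would be ≈ 3.3
  (50 · P(z > 1.5), slightly less for the within-section sample size of
  10); the ex-Gaussian default (`tau/sigma ≈ 1.7`) fattens the upper tail
  of within-participant z-scores and raises the null rate by roughly 0.6
  words. The reference per-participant mean of 3.38 sits between the
  Gaussian and ex-Gaussian null values. We keep the conventional
  ex-Gaussian defaults rather than tuning the noise shape toward either
  number; analysts comparing against a Gaussian-null expectation should
  use `tau_ms = 0` explicitly.

Degenerate inputs are rejected rather than patched: zero within-group
latency variance, standardisation groups smaller than 3 words (the bound
is an argument), a single diagnosis group, or an empty word-list category
all raise classed errors naming the offending unit. Ties in z are broken
by word text; boundary values at both outlier rules are kept (strict
inequalities); the two-word standardisation example {400, 600} gives
z = ±1/√2 under the n − 1 convention, which the tests pin down so the
convention cannot drift silently.

## Known limitations

* The synthetic word list is structural placeholder text, not the study's
  Dutch stimuli; nothing in the pipeline depends on the word strings
  beyond identity.
* Percentages are analysed with ordinary ANOVA/regression; a
  repeated-measures or mixed-effects treatment of the within-participant
  category factor is out of scope, as is any correction across the four
  cut-offs.
* The logistic models are fitted and evaluated in-sample; reported
  sensitivity/specificity are optimistic relative to held-out
  performance.
* Longitudinal tracking of issues across sessions is a documented
  extension, not implemented.
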