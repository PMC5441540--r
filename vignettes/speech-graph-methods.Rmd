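---
title: "Quantifying thought disorder from speech graph connectedness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thought disorder from speech graph connectedness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speechdisorg)
```

## The measurement model

A short verbal report — in the intended protocol, a 30-second memory
report — is reduced to its ordered word tokens and represented as a
directed multigraph: each distinct word is a node, and every consecutive
token pair contributes one directed edge. Three connectedness attributes
summarize the trajectory:

* **E**, the number of edges. For a contiguous report this is exactly the
  token count minus one, so E is a direct verbosity measure.
* **LCC**, the node count of the largest component whose members are
  linked by some path when edge direction is ignored.
* **LSC**, the node count of the largest component whose members are all
  *mutually* reachable along directed paths. Mutual reachability requires
  recurrent loops — returning to words already said — so LSC captures the
  recursive, goal-directed structure of organized discourse, and collapses
  in speech that rarely revisits its own words.

Because E scales with verbosity, two controls are provided: dividing each
attribute by the word rate (the token count of the time-limited report),
or, for protocols without a time limit, averaging attributes over sliding
30-word windows (`windowed_attributes()`, step 1 by default).

```{r attrs}
connectedness(tokenize("the dog chased the cat and the cat chased the dog"))
```

## The shuffle null and the random-like call

Connectedness values are not comparable across reports with different
vocabularies, so each report is referred to its own null: 1000 surrogate
reports obtained by uniformly permuting the token sequence and rebuilding
the graph. Every surrogate preserves the node set and the edge count, so
the null holds verbosity and vocabulary fixed and destroys only temporal
structure. The report's z-scores are

LSCz = (LSC − LSCmr) / LSCsdr,  LCCz = (LCC − LCCmr) / LCCsdr,

with means and population standard deviations taken over the surrogates.
A report is **random-like** when the designated attribute (LSCz by
default) lies in the closed band [−2, 2]: its loop structure is
indistinguishable from chance rearrangements of its own words.

Two degeneracies are resolved by explicit rules rather than left to
floating-point accident:

* A report whose words are all distinct has a loop-free path graph, and so
  does every shuffle: sd = 0 and the original equals the null value. Such
  reports get z = 0 and are classified random-like — loop-free speech
  *is* indistinguishable from its shuffles.
* sd = 0 with a differing original (impossible for permutation surrogates,
  but reachable through the API) yields a signed infinite sentinel, a
  warning, and a non-random-like call.

A structural fact of this graph construction is worth stating: a graph
built from one contiguous token sequence is always weakly connected, so
LCC equals the distinct-word count for the original *and* for every
surrogate. LCCz is therefore identically zero here. The package computes
and reports it for interface completeness, but all discriminative
information in the surrogate comparison lives in LSCz. (Reports assembled
from disjoint fragments would break this degeneracy; the package models
whole contiguous reports.)

### Why "far from random" means LSCz below −2

There is a hard asymmetry in the achievable z range that shapes the whole
design. If a word occurs at positions *i* < *j* of the sequence, the path
segment between them is a directed cycle, so *every* word spoken between
two occurrences of the same word joins one strong component. Under random
permutation, repeated words land far apart and their spans merge, which
drives the null LSC toward its ceiling (the distinct-word count). Numerical
exploration across multiset shapes shows the largest attainable positive
LSCz is about +2. Strongly structured speech therefore shows up on the
*negative* side: recurrence concentrated in tight local loops (a-b-a-b
...) yields an LSC far *below* the shuffle null, and |LSCz| — the distance
from the null — is the usable effect size. The monotonicity property the
package tests is accordingly: the median |LSCz| grows strictly with the
generator's recurrence parameter, while structureless sequences sit at 0.

## The Disorganization Index

Connectedness attributes are combined into a single severity-anchored
score in two ways.

**Fixed equations.** `reference_index_models()` ships four published
affine combinations (for combined negative-image + dream attributes,
negative-image only, dream only, and a chronic-sample dream protocol with
30-word-window attributes). They are immutable constants; evaluating one
is `predict(model, attributes)`, and a subject missing an attribute (an
unrecallable dream) raises an error naming it so callers can fall back to
the negative-image-only equation — the pipeline does this automatically.

**Re-derivation.** `fit_disorg_index()` reproduces the construction
procedure on new data: candidate attributes (pre-filtered to those showing
Bonferroni-corrected group differences), Belsley-style collinearity
pruning, then ordinary least squares of the symptom score (patients only,
complete cases per model). The pruning operationalizes the
condition-index rule: scale the design (intercept included, never
droppable) to unit column length, take the SVD, compute each component's
condition index (largest singular value over that component's) and the
variance-decomposition proportion of each variable on each component;
while any condition index exceeds 10, drop the variable with the largest
proportion on an offending component. Ties go first to the larger
proportion summed over offending components, then to input order, keeping
the earlier-listed variable — so a duplicated column always loses its
later copy. The threshold 10 is the conventional one and the default.

Fit quality is reported as R², the overall F-test p, n, and the post-hoc
**observed power**: with effect size f² = R²/(1−R²) and noncentrality
λ = f²·n, power is the mass of the noncentral F(k, n−k−1, λ) beyond the
α = 0.05 critical value. The alternative convention λ = f²·(n−k−1)
differs negligibly at these sample sizes; the λ = f²·n form is fixed and
documented. The prevalence-based planning formula N = Z²P(1−P)/d² is
included (`sample_size_estimate()`), rounded up with a floor of 1.

## Statistics battery

Group comparisons use rank tests (Kruskal–Wallis with tie correction,
two-sided Wilcoxon rank-sum, exact at small n without ties), 2×2
chi-square for prevalence tables (no continuity correction by default,
flag available), Spearman correlations, and a partial Spearman for
confounder adjustment defined as the Pearson correlation of
rank-transformed variables residualized on rank-transformed covariates —
one of several non-equivalent definitions in circulation, hence stated
explicitly. Multiplicity is handled by comparing raw p-values to α/m
(`bonferroni_alpha()`), not by inflating p-values. Distributional checks
are per-group Kolmogorov–Smirnov against a normal with estimated
parameters (labeled approximate) and a Levene test, mean-centered by
default with a median-centering option.

One calibration caveat the test suite makes explicit: the chi-square
approximation to the Kruskal–Wallis tail overstates extreme tails at very
small n (at three groups of three, the fully separated configuration has
exact permutation p = 6/1680 ≈ 0.004 against an approximate 0.027). The
package reports the conventional approximation; exact enumeration at such
sizes lives in the test oracles.

## Classification

Diagnosis (schizophrenia-like vs. everyone else) and severity (a median
split of the patient symptom scores, `high` strictly above the patient
median) are classified with Gaussian class-conditional Naive Bayes,
stratified k-fold cross-validation (10 folds by default, seeded), class
priors re-estimated per training fold, and per-class variances floored at
1e-9 of the overall variance so a degenerate fold cannot produce infinite
densities. Out-of-fold posteriors are pooled into a single vector; the
confusion-matrix panel (sensitivity, specificity as true-negative rate,
precision, recall, F-measure, accuracy in percent) uses a 0.5 posterior
threshold on that pool.

AUC needs more care. Computing one Mann–Whitney rank AUC on the pooled
posteriors (a single ROC) carries a systematic *pessimistic bias under
the null*: each fold's posteriors have their own calibration, and mixing
them scrambles the cross-fold ranking in an anti-informative way (a
held-out point that deviates upward drags its own training class mean
downward). Simulation at n = 100–200 with an uninformative feature puts
the pooled null mean near 0.48 — eight Monte-Carlo standard errors below
0.5 — and the same bias reproduces with an independent Naive Bayes
implementation, while the average of per-fold AUCs sits at 0.500. The
reported `auc` is therefore the mean of per-fold AUCs (folds whose test
set lacks a class are excluded; if no fold is valid the pooled value is
used), and the single-ROC value is kept alongside as `auc_pooled` for
comparability with panel-style reports that pool.

## The synthetic cohort generator

No clinical transcripts ship with the package; instead, a generator
produces token sequences whose loop structure is controlled by one
interpretable parameter. At each step, with probability ρ the process
revisits an already-used word, otherwise it emits a fresh word from an
unbounded vocabulary. Revisits are recency-weighted (weight 0.8^s for a
word last used s steps ago), producing the tight local loops that move
LSC away from the shuffle null; uniform revisits are also available and
are deliberately near-exchangeable, i.e. they stay at the null at any ρ —
a useful negative control. Report lengths are uniform on 40–120 tokens,
emulating 30-second reports.

Default per-group recurrence: schizophrenia-like ρ = 0.025, bipolar-like
0.05, control-like 0.12. These were calibrated once, at design time,
against the target random-like prevalence gradient of roughly 64% / 30% /
5% with the default 1000-surrogate null, and then frozen. Group sizes
default to 11/10/21.

Symptom scores are generated from *measured* attributes, not group
labels: score = 30 − 0.25·LSC + 1.0·LSCz + 0·LCC + N(0, 2.5²), clipped to
the feasible PANSS-negative range [7, 49]; control-like subjects are not
clinical and get no score. Two deliberate choices here:

* The LCC coefficient defaults to zero. In this generator LCC is nearly
  the distinct-word count, which for fixed-ish report lengths is almost a
  constant column — its Belsley condition index against the intercept
  straddles the pruning threshold, so a nonzero LCC effect would be
  unidentifiable by the method's own rule. A zero coefficient keeps the
  generating model inside the class the fitter can recover.
* The intercept and slopes keep raw scores inside [7, 49] for essentially
  every subject, so the clipping is inert and the generating model really
  is linear — parameter-recovery tests depend on this.

What the generator does *not* emulate: natural-language semantics, Zipfian
vocabularies, per-group verbosity differences (lengths are
group-independent, so unlike clinical data, low-recurrence groups have
*more* distinct words), or item-level symptom structure. Passing tests
demonstrate that the pipeline measures what it defines and recovers what
it generates — not that any clinical effect size is reproduced.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest sizes
chosen as sensible defaults for a laptop-scale check: oracle equivalence
on 1000 random sequences with vocabularies up to 12 words; surrogate
conservation on a 100-token report with the full 1000 surrogates; null
calibration of the random-like call on 500 structureless reports (the
±2 sd band covers 93–97%, the slack reflecting the discreteness of LSC);
parameter recovery over 200 replicate cohorts of 21 patients with a
100-surrogate null (the generating symptom score is computed from the
*measured* attributes, so a smaller surrogate count changes the
attributes, not the recoverability); classification null calibration over
500 cross-validation runs at n = 100. Population (divisor-n) standard
deviations are used for surrogate nulls; with 1000 surrogates the choice
is numerically immaterial but is fixed. All stochastic stages take
explicit seeds and restore the caller's RNG state.

## Limitations

* LCCz carries no information for contiguous reports (see above); users
  feeding fragmented text should re-examine that degeneracy.
* The partial Spearman is one specific definition; results can differ
  slightly from other partial-rank-correlation conventions.
* Observed power is post-hoc by construction and shares the usual
  circularity caveats of observed power; it is reported because the
  construction procedure reports it, not as a design tool.
* The generator's negative-LSCz regime is a property of contiguous-path
  graphs under permutation nulls, not a clinical claim about the sign of
  any group's z-scores in real data.
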