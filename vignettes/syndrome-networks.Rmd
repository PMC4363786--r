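---
title: "Symptom networks and syndrome patterns: models and methods"
author: "zhengnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Symptom networks and syndrome patterns: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zhengnet)
```

# The problem

In Traditional Chinese Medicine, a *syndrome* (ZHENG) is a diagnostic
category assigned to a patient from clinical signs; *syndrome
differentiation* is the act of deciding which syndromes a patient has.
zhengnet works on inquiry cohorts of the kind used to study depression
syndromes: each patient carries 36 ordinal symptom grades (0 = none,
1 = low, 2 = median, 3 = high; two menses items are female-only) and a
0/1 label for each of seven syndromes — blood deficiency (BD), blood
stasis (BS), fire hot (FH), phlegmatic hygrosis (PH), Qi deficiency
(QD), Qi stagnation (QS) and Yin deficiency (YD).

The package asks four questions of such a cohort:

1. How well can each syndrome be predicted from the symptoms
   (per-syndrome binary classifiers, benchmarked under repeated
   cross-validation)?
2. Which symptoms characterise each syndrome (Fisher's score ranking)?
3. How do symptoms interact *within* a syndrome (weighted
   mutual-information networks on positive sets), and which of those
   interactions are specific to the syndrome rather than to depression
   at large (a label-shuffling permutation test)?
4. How do the syndromes relate to each other (Tanimoto co-occurrence
   networks)?

# Models and procedures

## Fisher's score

For a feature $F_r$ and a two-class label, the score is

$$S(F_r) = \frac{\sum_i P_i\,(\mu_{ir}-\mu_r)^2}{\sum_i P_i\,\sigma_{ir}^2},$$

the ratio of between-class to within-class variance. Conventions the
formula leaves open, and our choices: $\sigma^2_{ir}$ is the
*population* (divide-by-$n_i$) class variance, and $P_i$ the empirical
class proportion — the common Fisher-score conventions. A constant
feature scores 0 (numerator and denominator both vanish); perfectly
separated classes with zero within-class spread score `Inf`. Ties in a
ranking are broken by catalog index so rankings are deterministic. The
top $k=12$ symptoms form a syndrome's "key symptom" representation.

## Weighted mutual information

Dependence between two symptoms $X, Y$ on a data set is scored by

$$\mathrm{wMI}(X;Y) = \sum_{x}\sum_{y} w(x,y)\,P(x,y)\,
\log\frac{P(x,y)}{P(x)P(y)},$$

with $w(x,y) = 1 - 0.2\,|x-y|$ (1.0 on concordant grades down to 0.4
for the 0/3 pair), so discordant grade combinations contribute less.
Probabilities are raw empirical frequencies with no pseudocounts: the
estimator is specified without smoothing and positive sets are
moderate-sized, so smoothing would bias small joints more than it
stabilises them. Cells with $P(x,y)=0$ contribute nothing
($0\log 0 := 0$), which also means absent grade values drop out of the
sums automatically.

The logarithm base is **2 (bits) by default** and configurable to the
natural log. The wMI definition does not fix a base, yet the edge
threshold $\theta = 0.1$ is only meaningful relative to one; we adopt
$\theta$ on the bit scale and surface the base in every report
(`manifest.json` records it). Note that with the distance weights the
sum is not a true mutual information and can be negative; only the
unit-weight special case is guaranteed non-negative. Thresholding is
`>=` ("equal to or larger than $\theta$").

A syndrome's network is built on its **positive set** (all patients
labelled 1); the global depression network uses the whole cohort as its
positive set and all 36 symptoms as nodes, while per-syndrome networks
use the top-12 key symptoms.

## Dynamic interactions: the permutation test

To ask whether an edge is specific to a syndrome rather than inherited
from depression-wide symptom similarity, the syndrome's label column is
shuffled $N$ times (default 10000). Each shuffle forms a new positive
set of the same size, on which the wMI of every edge of the *original*
network is recomputed — the node set and edge list are fixed; nothing
is re-selected per shuffle. For edge $(u,v)$,

$$P_g = \frac{n_g}{N}, \qquad P_l = 1 - P_g,$$

where $n_g$ counts shuffles with permuted wMI **equal to or greater**
than the original (ties count toward $n_g$). $P_g < 0.1$ calls the edge
an *increased* interaction, $P_l < 0.1$ a *decreased* one; any cutoff
below 0.5 makes the classes mutually exclusive. P-values are the raw
$n/N$ estimator — $P_g = 0$ is possible at finite $N$ — and no
multiple-testing correction is applied by default, matching the 0.1
screening cutoff; a Benjamini–Hochberg option exists in
`classifyDynamic()`.

## Syndrome co-occurrence

Two syndromes with $a$ and $b$ positives sharing $c$ patients have
Tanimoto similarity $c/(a+b-c)$; pairs at $\ge 0.5$ form the syndrome
network. Each pair also gets a one-sided Fisher's exact test p-value on
its 2×2 table; one-sided (enrichment) because the question asked of the
network is whether syndromes co-occur more than independence predicts.

## Classifiers

Naive Bayes and TAN are implemented in the package from their defining
equations; the SVM (linear-kernel C-classifier via libsvm/e1071) and
the decision tree (information-gain rpart with cost-complexity
pruning, standing in the C4.5 role) are delegated to established
implementations, with no claim of bit-compatibility with WEKA output.

* **Naive Bayes**: MAP over $P(C)\prod_i P(F_i\mid C)$ with Laplace
  pseudocount 1 on the 4-grade conditional tables (unsmoothed tables
  can zero out a posterior on unseen grade/class combinations) and the
  empirical class prior.
* **TAN**: Chow–Liu augmentation — the feature tree is the maximum
  spanning tree of pairwise *class-conditional* mutual information
  (deterministic Prim construction, ties to the lowest feature index,
  rooted at the first feature), so each feature's parents are the class
  plus at most one feature. This is the canonical construction for the
  cited "tree-augmented naive Bayes" family; the exact WEKA search
  ("local TAN") is not documented and not replicated.
* MAP ties break toward the negative class, the majority in most
  syndromes.

Evaluation is stratified 5-fold cross-validation repeated 10 times
(stratification is the common tool default; the source protocol does
not say). Fold assignments are drawn up front from the seed, so two
methods evaluated with the same seed share folds and their per-repeat
accuracies are paired; `compareMethods()` runs the two-sided paired
t-test on those 10 pairs, returning $p=1$ on identical vectors and
$p=0$ on a constant non-zero shift (degenerate-variance cases).

# The synthetic cohort generator

The original 364-patient cohort is not deposited, so the package ships
a generator, `defaultDepressionSpec()` + `generateCohort()`, that
emulates its stated structure and plants recoverable ground truth:

* **n = 364 patients**, ~70% female (clinical depression cohorts skew
  female); male patients have the two menses symptoms zeroed.
* **Labels first**: independent Bernoulli prevalences — QS 0.62,
  QD 0.55, FH 0.48 above PH 0.33, BD 0.28, YD 0.25, BS 0.12 (the
  published distribution is only qualitative: QS/QD/FH enriched, BS
  rare; these values are a plausible reading of it, not published
  numbers) — tilted toward co-occurrence by pairwise odds multipliers
  (QS–QD 4, FH–QS 4, and mild 2× tilts among BD/PH/QD) through a Gibbs
  sweep over the 7-label vector. Because a positive tilt would inflate
  the marginals, the base odds are recalibrated by a short damped
  fixed-point loop so the realised prevalences match the spec.
* **Grades second**: background symptoms i.i.d. from a baseline grade
  distribution (0.45/0.30/0.17/0.08 — mostly none-to-low, as expected
  of inquiry items in a general cohort); each active syndrome shifts
  its key symptoms upward by `grade + shift` clipped at 3 (shift 2 for
  its top-6 key symptoms, 1 for ranks 7–12; the larger shift wins when
  key sets overlap); one clinically coupled pair per syndrome (e.g.
  the two dizziness items in PH, the two epigastric-obstruction items
  in QS) has the second member copied from the first with probability
  0.8 among that syndrome's positives.
* A single integer seed drives everything; the planted truth is kept
  in `metadata(cohort)$truth`.

**What it does and does not emulate.** The generator reproduces the
*statistical shape* the analysis relies on — ordinal grades, label
prevalences and co-occurrence, class-conditional mean shifts, and
syndrome-specific pairwise coupling. It does not reproduce the real
cohort's marginal tables (unpublished), inter-symptom similarity that
is independent of syndromes (e.g. near-duplicate questionnaire items),
rater subjectivity, or any longitudinal structure. Tests that pass on
generated cohorts therefore validate the *machinery* (estimators,
selection rules, calibration of the permutation test) and its power
against planted effects; they say nothing about the clinical findings
themselves, which require the original data.

# Numerical choices and degenerate inputs

* wMI and the permutation test share one code path from grade-pair
  counts, so a permuted statistic that should tie the original is
  bitwise equal and the "ties count toward $n_g$" rule needs no
  tolerance.
* `positiveSet()` refuses empty positive sets; network construction
  refuses empty cohorts; `fisherScore()` refuses single-class labels;
  `repeatedCV()` refuses classes smaller than the fold count, naming
  the offending class.
* The average clustering coefficient counts degree-<2 nodes as 0 (one
  of the two common conventions; which one produced the published
  table cannot be determined), with `excludeLowDegree = TRUE` as the
  alternative. Average path length, diameter and radius are reported
  only for connected networks.
* Cross-validation, shuffles and the generator consume a seed set once
  per call; reruns with one seed are byte-identical.

# Problem sizes used in the validation suite

The test suite exercises the statistical claims at sizes chosen to
keep the whole suite fast while leaving the Monte-Carlo bounds sharp:
permutation exactness on 6-patient toys against exhaustive enumeration
($N = 20000$ vs all 20 label arrangements); null calibration of the
dynamic-edge rate over 25 cohorts of n = 364 at $N = 1000$ (expected
rate 0.2 at cutoff 0.1 per tail); Fisher-ranking recovery of 12
planted key symptoms over 50 seeds; increased-interaction recovery of
a 0.9-coupled pair over 50 replicates at $N = 2000$; TAN-vs-NB over 25
seeds of 5-fold CV repeated 5 times. Null-rate convergence of naive
Bayes to the majority rate is asserted at n = 2000, where
finite-sample table noise no longer depresses accuracy below the
majority rate (at n = 364 a correct NB sits a few points below it;
the implementation is instead checked there by exact prediction
agreement with an independent implementation, `e1071::naiveBayes`).

# Known limitations

* With distance weights, wMI is a heuristic dependence score, not an
  information measure; magnitudes are only comparable within one
  weight matrix and log base.
* The permutation p-values are raw and unsmoothed; at small $N$ the
  granularity is $1/N$, and no correction is made for testing many
  edges.
* The delegate classifiers (SVM, decision tree) follow their R
  implementations' defaults and are not tuned; the benchmark is a
  sanity comparison, not a leaderboard.
* The generator's prevalences and effect sizes are fixed, documented
  choices; they are plausible rather than estimated from data.

# A worked run

```{r pipeline, eval = FALSE}
library(zhengnet)
cfg <- pipelineConfig(seed = 1, outputDir = "zhengnet-results")
res <- runPipeline(cfg)
res$topology
```

The pipeline writes the cohort (when simulated), classifier
evaluations with paired t-tests, Fisher rankings and top-12 tables,
the 8 networks as edge lists and GraphML, the topology summary,
classified dynamic interactions, the syndrome network, and a JSON
manifest recording every setting — including the ones the method
leaves open (log base, smoothing, clustering convention) — so a report
is self-describing.
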