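---
title: "Contraction of memory and interval bias in 2AFC frequency discrimination"
author: "intervalbias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Contraction of memory and interval bias in 2AFC frequency discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intervalbias)
```

## The problem

In a two-alternative forced-choice (2AFC) frequency-discrimination trial a
listener hears two brief tones and reports which was higher. Standard
protocols place a constant *reference* tone (1000 Hz here) in one of the two
intervals and a staircase-controlled *comparison* tone in the other. Although
signal-detection reasoning treats the two intervals as exchangeable,
performance depends systematically on where the reference falls — the
*interval bias* — and, puzzlingly, the direction of that bias differs between
protocols:

* **Reference-Lower** (comparison always above the reference): accuracy is
  higher when the reference is in the *second* interval.
* **Reference** (comparison above or below, at random): accuracy is higher
  when the reference is in the *first* interval.

This package implements a single mechanism that produces both: the remembered
frequency of the *first* tone is contracted toward a *memory trace* of the
first tones heard earlier in the block. Whether that contraction helps or
hurts depends on the protocol's stimulus statistics, which is exactly what
differs between the two designs.

## The observer models

All models give the probability of responding "first tone higher" as a probit
function of a decision variable built from log-frequencies $x_1(t), x_2(t)$:

* **Linear history model** (`p_first_higher_full`):
  $P = \Phi\!\big(a_0 x_1(t) + \sum_{k=1}^{K} a_k x_1(t-k) + b\,x_2(t) + c\,m(t)\big)$,
  where $m(t)$ is the running mean of the first tones of trials $1..t-1$.
  Noise is implicit in the overall weight scale.
* **Memory-trace model** (`p_first_higher_memory_trace`): the same linear
  form with a *fixed* weight vector, divided by a free noise parameter
  $\sigma$: $P = \Phi(\hat D(t)/\sigma)$. One free parameter per block.
* **Naive model** (`p_first_higher_naive`): $P = \Phi((x_1 - x_2)/\sigma)$ —
  no history.
* **Response-bias model** (`p_first_higher_response_bias`):
  $P = \Phi((x_1 - x_2)/\sigma + \beta)$ — a horizontal shift of the
  psychometric function instead of a history effect. We place $\beta$
  outside the $1/\sigma$ scaling, so it is a fixed criterion shift in
  probit units.

### Default contraction weights

The fixed weights of the memory-trace model are a package default, not an
empirical estimate (the estimates they stand in for were published only in
graphical form elsewhere). They are constructed from four interpretable
quantities:

```{r}
default_trace_weights()
```

* translation invariance: $a_0 + \sum a_k + c = -b = 1$, so adding a
  constant to all log-frequencies (a global transposition) leaves behavior
  unchanged;
* total contraction $\gamma = \sum a_k + c = 0.35$: the fraction of the
  first tone's weight ceded to history;
* half of $\gamma$ on the long-run trace $m(t)$, half on the $K = 3$ most
  recent first tones with geometric decay 0.6 — recent trials matter
  disproportionately, a robust feature of serial-dependence data.

These defaults were chosen once to embody a moderately contracting observer;
they are overridable everywhere (`trace_weights()`).

### Early trials

Before trial $k+1$ the lag-$k$ term has no stimulus to attach to, and before
trial 2 the running mean does not exist. All unavailable history terms
*self-anchor on the current first tone*: their weight falls on $x_1(t)$
itself. Trial 1 is then exactly history-free
($P = \Phi(x_1 - x_2)$-shaped), and early trials are unbiased. The obvious
alternative — letting missing terms contribute zero — is not benign: with
translation-invariant weights it leaves a residual weight of
$-(\text{missing})\cdot x_1$ in the decision variable, about $-1.2$ in
log-frequency units at trial 1, which forces a near-deterministic "second
higher" response for any realistic $\sigma$. The running mean $m(t)$
excludes the current trial's tone: the prior is formed before the current
observation arrives.

## The experiment simulator

`simulate_block()` closes the loop that generated the study's data: a
3-down-1-up staircase controls the percent frequency difference (start 20%,
steps 4.5/2/1/0.5/0.1% advancing after every 4th reversal), `make_trial()`
draws the per-trial configuration (reference interval, comparison direction),
the observer responds stochastically given its history, and correctness feeds
back into the staircase. Blocks have 80 trials; memory resets between blocks.

Numerical guards on the staircase: the tracked difference is floored at 0.1%
(the smallest step) so it can never reach zero, and capped at 99% so a
comparison placed *below* the reference keeps a positive frequency even under
a near-chance responder. A reversal is a change in movement direction; the
first movement sets the direction without counting one; step changes take
effect on the movement after the 4th, 8th, 12th and 16th reversal,
cumulatively.

The default observer noise is $\sigma = 0.04$ (log-frequency units) for
reference-lower simulations and $\sigma = 0.03$ for reference-protocol
simulations. These values are anchored on the published mean thresholds of
the two experiments (about 4% and 3.3% frequency difference at the
staircase's 79.4% convergence point); at $\sigma = 0.04$ the simulated
memory-trace observer reproduces a ~4% mean JND in reference-lower blocks.

Per-block seeds are derived deterministically from a single master seed and
recorded in the manifest, so every dataset is reproducible bit-for-bit.

```{r}
tab <- simulate_experiment(protocol_spec("reference"),
                           observer("memory_trace", sigma = 0.03),
                           n_participants = 20, blocks_per_participant = 1,
                           master_seed = 1)
percent_correct_by_reference(tab)
```

### What the generator does and does not emulate

It emulates the trial structure, stimulus statistics, staircase dynamics and
a history-sensitive stochastic observer. It does **not** emulate lapses,
attention drift, learning across blocks, or audibility effects. One visible
consequence: during the first ~15 trials the staircase marches down from the
easy 20% start and a lapse-free model observer is essentially at ceiling in
both trial groups, so all-trials splits are mildly diluted relative to human
data, where accuracy is imperfect even in that phase. Passing property tests
on this generator therefore demonstrate internal consistency of the
mechanism, not that human data contain no other ingredients.

## Estimation choices

* **Per-block maximum likelihood** (`fit_block`): $\sigma$ (and $\beta$) are
  fitted per 80-trial block, $\sigma$ on the log scale to enforce
  positivity, from 100 starting points drawn Normal(0, 10) in the fitted
  parameter space. The local search is derivative-free: Brent line search in
  a ±30 window around each start for the one-parameter models, Nelder-Mead
  for the two-parameter model. Likelihood contributions are clipped at
  $10^{-12}$ to keep logs finite.
* **Model comparison** (`compare_models_across_blocks`): BIC
  ($k\ln n - 2\ln L$) when parameter counts differ, raw likelihood when they
  match; ties count one half. The BIC difference is also correlated
  (Pearson and Spearman) with each block's interval-bias magnitude;
  zero-variance inputs are flagged rather than propagated as NaN.
* **JND**: the conventional staircase summary — mean percent difference over
  the last 20 trials (`jnd_from_block`). In no-reference blocks the
  uniformly drawn base tone provides the percent denominator.
* **Subset JNDs and the ratio $r$** (`jnd_ratio`): a staircase yields one
  aggregate threshold, so thresholds for the interleaved Ref1/Ref2 subsets
  are estimated from probit-GLM psychometric fits of correctness on percent
  difference, with a free intercept (the point of subjective equality is
  displaced in reference-lower data, so the curve must not be forced through
  chance at zero difference). The subset JND is the difference at which the
  fitted curve crosses 79.4%, *censored to the range of differences the
  staircase actually sampled*: contraction can flatten a subset's accuracy
  against difficulty (it helps hard trials and hurts easy ones), in which
  case the crossing is unidentified and only its side of the sampled range
  is known. The censoring keeps $r$ finite and sign-correct; its price is
  that extreme ratios saturate, so $r$ is reported as a median and read
  directionally.
* **Bias classification** (`classify_bias_trials`): trial $t$ benefits from
  contraction iff $(m(t) - x_1)(x_1 - x_2) > 0$, with $m(t)$ the running
  mean of prior first tones; trial 1 is neutral. This is the model's own
  geometry. Note that in reference-containing protocols this label is
  strongly tied to the trial type (in reference-lower, every Ref1 trial is
  Bias−), so the clean dissociation between contraction benefit and
  response repetition is only measurable in no-reference data — which is
  why the repetition control lives there.
* **Population statistics**: trials pool within participant; means, SEMs,
  paired t-tests and Cohen's $d$ (mean difference / SD of differences) are
  computed across participants; no multiple-comparison correction is
  applied. Participants missing a trial group are excluded from the paired
  test and counted.

## Known limitations

* The fixed contraction weights are a structured default, not fitted values;
  analyses that depend on their exact magnitudes (model-comparison win
  rates, the size — not the sign — of the biases, the size of $r$) should be
  read qualitatively.
* The memory-trace model ignores the second tone's history, which is a
  deliberate simplification the data of this paradigm support.
* The MAT 5.0 reader covers numeric arrays in plain or zlib-compressed
  elements — sufficient for deposited `s1`/`s2`/`c` trial matrices, not a
  general MAT parser.
* Problem sizes in the test suite (tens of participants, 20-block recovery
  studies) are chosen to make the checks sharp yet quick; the analysis
  scripts under `analysis/` run the full study sizes (49×2, 152×1, 150×1
  blocks).
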