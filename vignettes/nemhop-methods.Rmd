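---
title: "Inferring signalling hierarchies from perturbation screens with nemhop"
author: "nemhop authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring signalling hierarchies from perturbation screens with nemhop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemhop)
```

## The model

A gene-perturbation screen knocks out (or mutates) each of $S$ genes — the
*signals* — and measures the transcriptional response of $E$ downstream
*effect* genes.  A Nested Effects Model (NEM) explains such data with two
layers:

* a binary **signals graph** $\Gamma \in \{0,1\}^{S\times S}$ with unit
  diagonal, where $\gamma_{ks}=1$ means that perturbing $k$ also perturbs
  $s$;
* a sparse **effects attachment** $\Theta$: each effect gene is attached to
  exactly one signal, or to a reserved *null node*.

The model predicts that effect $e$, attached to signal $s$, responds to the
perturbation of $k$ exactly when there is a two-step path
$k \to s \to e$, i.e. when $\gamma_{ks}=1$.  Effects on the null node are
predicted always inactive, which acts as a built-in feature selection.  The
data enter as a log-odds matrix $R \in \mathbb{R}^{E\times S}$:
$R_{ek}$ weighs the evidence that effect $e$ changed upon perturbation of
$k$ against the evidence that it did not (such matrices are produced
upstream by a moderated-$t$/FDR pipeline, e.g. with limma; that step is out
of scope here).  NEMs work best when the perturbation effects are genuinely
nested, i.e. when the underlying structure is hierarchical.

With a row-stochastic attachment prior $\nu \in \mathbb{R}^{E\times(S+1)}$
(last column = null node) and edge-wise independent priors
$p_{ks} \in (0,1)$ on the off-diagonal entries of $\Gamma$, the attachment
integrates out in closed form, giving the marginal log posterior

$$\log P(\Gamma \mid R) \;=\; \sum_{e=1}^{E}\log\Big(
  \sum_{s=1}^{S}\nu_{es}\,e^{\sum_k \gamma_{ks}R_{ek}}
  + \nu_{e,\mathrm{null}}\Big)
  \;+\; \sum_{k\neq s}\log P(\gamma_{ks}) \;+\; \mathrm{const}.$$

Only score *differences* between graphs are meaningful; the additive
constant is never needed.  All of this is implemented in
`log_posterior()`, with the responsibilities
$\omega_{es} \propto \nu_{es}\,e^{\sum_k \gamma_{ks}R_{ek}}$ available from
`attachment_posterior()`.  Every sum of exponentials is evaluated in log
space (log-sum-exp), so strongly negative or positive log-odds cannot
overflow.

Effects whose log-odds row has no strictly positive entry can never raise
the score by being attached anywhere; `filter_effects()` removes them
before estimation (a row with maximum exactly 0 is removed too — attaching
it gains exactly nothing).  On real screens this roughly halves the effect
set.

## EM with a closed-form M-step

`run_em()` maximizes the marginal posterior over $\Gamma$ by EM.  The
E-step computes $\omega$ under the current graph; the expected complete log
posterior is *linear* in the entries of $\Gamma$, so the M-step decomposes
edge-wise and is available in closed form (`em_update()`): the off-diagonal
edge $(k,s)$ is switched on exactly when

$$\textstyle\sum_e \omega_{es} R_{ek} + \log\frac{p_{ks}}{1-p_{ks}} > 0.$$

Ties (a statistic of exactly zero) leave the edge absent — the sparser
graph, deterministically.  Iteration stops when the graph (binary, so
compared exactly) stops changing; this typically takes a handful of
updates, and one full run costs a few matrix products per iteration even
for thousands of effects.  The score sequence is monotonically
non-decreasing; the test suite verifies the closed form against an
exhaustive maximization over all $2^{S(S-1)}$ graphs on small instances.
The discrete update could in principle cycle rather than fix; `run_em()`
detects revisits and returns the best-scoring graph of the cycle with a
flag (we have not observed cycles in practice, but the possibility is
handled rather than assumed away).

## Mode-hopping MCMC

The marginal posterior over graphs is rugged: EM from different starts ends
in different local maxima.  `run_chain()` therefore runs a Metropolis–
Hastings chain whose *underlying* state is a raw graph; each proposal flips
`n_flips` (default 1) off-diagonal entries chosen uniformly — a symmetric
proposal — and is then mapped to its nearest local maximum by EM.  The
acceptance test plugs the *mapped* graphs' scores into the Hastings ratio:

$$P(\text{accept}) = \min\!\big(1, \exp(\hat s^\ast - \hat s)\big),$$

where $\hat s^\ast$ and $\hat s$ are the scores of the EM images of the
proposal and of the current state.  The recorded series of mapped graphs is
then approximately a sample from the posterior *restricted to the set of
local maxima*.

The word *approximately* can be made precise.  The construction is standard
Metropolis–Hastings on the raw graph space with target density
$h(\Gamma) \propto \exp\big(\hat s(\Gamma)\big)$, where $\hat s(\Gamma)$ is
the score of $\Gamma$'s EM image; consequently a local maximum $L$ is
visited with stationary probability proportional to
$e^{s(L)}\,\lvert\mathrm{basin}(L)\rvert$ — the posterior weight of $L$
*times the size of its EM basin of attraction*.  The test suite verifies
this exact law on a small instance by enumerating all graphs, their EM
images and basins (chain frequencies match it to within total-variation
distance 0.05 at desk scale).  The restriction-to-local-maxima reading —
frequencies $\propto e^{s(L)}$ alone — holds exactly only when basins are
balanced or one mode dominates the posterior; on small noisy instances with
several competing maxima the basin factor distorts frequencies noticeably.
In the intended regime (thousands of effects, a strongly dominant mode) the
distinction is immaterial because the top mode carries essentially all
mass.  An alternative construction that proposes flips from the current
*mapped* graph was evaluated and discarded: its inter-maximum kernel is
asymmetric and empirically matches the restricted posterior worse than the
raw-state chain.

Because EM is deterministic, the chain memoizes the EM image of every raw
graph it has visited; after burn-in most steps are cache hits, which is
what makes tens of thousands of steps cheap.  Chains are seeded and
bit-reproducible.

## Empirical Bayes attachment prior

The attachment prior matters: a uniform $\nu$ wastes mass on implausible
attachments, while the (unknown) true deterministic prior would make the
true graph the top scorer.  `run_mc_eminem()` takes the middle road:

1. initialize $\nu$ in a data-driven fashion (`init_prior()`): the
   attachment posterior under the identity graph, i.e. the row-normalized
   $(e^{R_{e1}},\dots,e^{R_{eS}},1)$;
2. sample graphs by mode-hopping MCMC under the current $\nu$;
3. replace $\nu$ by the average attachment posterior over the sampled
   graphs (`update_prior()`);
4. repeat 2–3 until the prior changes by less than `tol` (max-abs,
   default $10^{-3}$) or `max_rounds` (default 5) is reached.

The final graph is the highest-scoring sampled local maximum of the last
round; the final attachment is the per-effect argmax of the attachment
posterior under that graph and prior, with ties broken toward the
lexicographically smallest label for reproducibility.  Each round is warm
started from the final state of the previous chain.  The default edge prior
is 0.5 per edge (no structure preference); setting it below 0.5 penalizes
every edge equally and is the natural sparsity weight — the only parameter
worth tuning in practice.

## What the simulator emulates

`sample_nem()` + `generate_logodds()` reproduce the benchmark protocol used
to validate the method:

* the true signals graph is drawn uniformly among *acyclic* off-diagonal
  edge sets of a requested size (rejection sampling), then given a unit
  diagonal — perturbation hierarchies are the regime NEMs are designed for;
* each effect attaches uniformly to a signal, except a `null_fraction`
  (default 20%) assigned to the null node;
* the data are the log-odds of an optimal binary test with type-I error
  $\alpha$ and type-II error $\beta$: predicted-effect cells carry
  $\log\frac{1-\beta}{\alpha}$ with probability $1-\beta$ and
  $\log\frac{\beta}{1-\alpha}$ otherwise; predicted-silent cells carry the
  positive value with probability $\alpha$.

This two-valued noise model is deliberately simple: real screens have
continuous, correlated effect sizes, batch structure and miscalibrated
error levels, none of which the generator emulates.  Passing benchmarks
here demonstrates correct inference *under the model's own assumptions*,
not robustness to model misspecification.

Defaults for the benchmark grids (`benchmark_scenarios()`): 11 signals (or
5–14 in the size grid), 1000 effects, as many true edges as signals,
$\alpha = 0.05$, $\beta \in \{0.01, 0.05, 0.1, 0.2\}$, 10 replicates.
These are desk-scale choices: chains of 500 steps with 3 Empirical Bayes
rounds (`benchmark_config()`) rather than the tens of thousands of steps
one would use — and the package supports — on a full-size screen; effect
counts are in the thousands either way.  `evaluate_edges()` scores
off-diagonal edge recovery (sensitivity/specificity), `prior_l1()` the
normalized $L_1$ distance between an attachment prior and the true
unit-vector prior (division by 2 maps it to $[0,1]$), and
`posterior_quantile()` the rank of the true graph among uniformly random
graphs under the marginal posterior (strict comparison, so a duplicate of
the truth does not count as beaten — negligible once $S$ is moderately
large).

## Baselines

Three internal ablations calibrate the full sampler:

* `fit_em_only()` — one EM run from the identity graph with the data-driven
  prior; no sampling, no prior re-estimation;
* `fit_random_sampling()` — the best of $N$ *EM-mapped* uniform random
  graphs, budget-matched at one EM call per MCMC step.  (Scoring raw
  unmapped random graphs, available as `map = FALSE`, is far weaker: a
  uniform random graph carries about half of all possible edges, so even
  the best of hundreds of such draws retains dozens of false edges);
* `fit_exhaustive()` — the global MAP by enumeration, feasible to $S=4$;
  used as an oracle.

## Numerical and design choices

* Log-space arithmetic everywhere a sum of exponentials occurs; tie-breaks
  are deterministic (edge ties → absent; attachment ties → smallest label).
* $\Gamma$ is *not* forced transitively closed: the two-step-path semantics
  is applied to $\Gamma$ as given, and the generator uses the same
  semantics, so estimator and truth live in the same space.
* Bidirectional edges in a fitted graph mean the two signals are
  indistinguishable from their intervention effects;
  `merge_indistinguishable()` groups mutual-edge pairs transitively,
  concatenates labels, ORs adjacencies and averages log-odds columns
  (the mean preserves the log-odds scale; the aggregation rule is a
  convention, as merged nodes' members are interchangeable anyway).
* `group_effects()` derives each attached effect's direction of regulation
  only over perturbations with a *predicted* effect, consistent with the
  nested semantics; net-sign ties are excluded from both direction groups
  and reported (no principled tie direction exists).
* The null node is an extra attachment column, never a graph node; the
  edge prior excludes the (fixed) diagonal.
* Degenerate inputs: data with no positively responding effect yield an
  empty model with a warning; a zero-edge scenario yields the identity
  graph; all-zero data make every graph score equal, and the conventions
  above keep the output deterministic.

## Known limitations

* The mode-hopping stationary distribution is exactly
  $e^{s(L)}\lvert\mathrm{basin}(L)\rvert$, not $e^{s(L)}$: with several
  competing local maxima of comparable score, sampled frequencies
  over-represent maxima with large basins (see above).  Point estimation
  (the best sampled graph) is unaffected; frequency-based uncertainty
  summaries inherit the bias.
* Under strong-signal conditions (thousands of effects, well-separated
  log-odds) the marginal posterior concentrates so sharply that the true
  graph outscores every uniformly random graph by thousands of nats under
  *any* reasonable attachment prior; the posterior-quantile diagnostic then
  saturates at 1 and cannot resolve prior quality — the $L_1$ distance to
  the true prior (or the score *gap* to the best random graph) remains
  informative there.
* The sampler assumes effects attach independently given the graph; real
  co-regulated genes violate independence, which tends to overstate
  confidence in the attachment posterior.
* Uniformity of the random-DAG generator is over edge *sets*, and rejection
  sampling becomes slow as the edge count approaches the acyclic maximum
  $S(S-1)/2$; benchmark densities (edges ≈ signals) are far from that
  regime.
* No automatic tuning of the sparsity weight, and no marginalization over
  the attachment prior's uncertainty.
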