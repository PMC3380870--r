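# nemhop — Nested Effects Model inference by EM and mode-hopping MCMC

`nemhop` reconstructs the signalling hierarchy among perturbed genes from
the high-dimensional downstream readouts of a perturbation screen (e.g.
genome-wide expression after each of a panel of knockouts).  It implements
MC EMiNEM-style structure learning for **Nested Effects Models (NEMs)**:
a closed-form Expectation–Maximization algorithm for the marginal structure
posterior, a mode-hopping Metropolis–Hastings sampler over the EM local
maxima, and an Empirical Bayes loop that re-estimates the effect-attachment
prior from the sampled graphs.  A simulation engine, baseline learners and
benchmark metrics are included.

## The model in one paragraph

A NEM has a binary **signals graph** Γ (S × S, unit diagonal) among the
perturbed genes and a sparse **attachment** Θ linking each observed effect
gene to one signal or to a *null node*.  Effect *e* attached to signal *s*
is predicted to respond to the perturbation of *k* exactly when
Γ\[k,s\] = 1 (a two-step path k → s → e); null-attached effects never
respond.  The data are a log-odds matrix R (effects × perturbations).
With a row-stochastic attachment prior ν and edge-wise priors p on Γ, the
attachment integrates out:

    log P(Γ | R) = Σ_e log( Σ_s ν[e,s] · exp(Σ_k Γ[k,s] R[e,k]) + ν[e,null] )
                 + Σ_{k≠s} log P(γ_ks)  + const.

EM maximizes this with an edge-wise closed-form M-step
(edge (k,s) on iff Σ_e ω\[e,s\] R\[e,k\] + logit p\[k,s\] > 0); the
mode-hopping chain proposes random edge flips, maps each proposal to a
local maximum by EM, and applies the Hastings test to the *mapped* scores,
so the samples live on the set of local maxima.  See the methods vignette
(`vignettes/nemhop-methods.Rmd`) for the full account.

## Worked example

Simulate a 5-signal screen with 300 effect genes under the two-valued
α/β noise model (α = 0.05, β = 0.1, 20 % of effects on the null node),
then fit it:

```r
library(nemhop)
set.seed(7)
scenario <- sim_scenario(n_signals = 5, n_effects = 300, n_edges = 5,
                         alpha = 0.05, beta = 0.1, null_fraction = 0.2)
truth <- sample_nem(scenario)
r     <- generate_logodds(truth)

fit <- run_mc_eminem(r, config = mc_eminem_config(n_steps = 2000,
                                                  burn_in = 1000,
                                                  thin = 10,
                                                  max_rounds = 3),
                     seed = 1)
fit
#> MC EMiNEM fit: 5 signals, 5 edges, score 1252.632
#>   241 of 300 effects retained; 64 attached to the null node
#>   3 Empirical Bayes round(s); round limit reached

evaluate_edges(fit$final_graph, truth$graph)
#> sensitivity specificity
#>           1           1

fit$final_graph
#>     S01 S02 S03 S04 S05
#> S01   1   0   0   0   0
#> S02   0   1   0   0   0
#> S03   1   1   1   0   0
#> S04   0   0   1   1   0
#> S05   1   1   0   0   1
```

Reading the output: 59 of the 300 effects had no positive log-odds entry
and were filtered before estimation (they can never improve the score);
of the 241 retained, 64 ended on the null node.  The fitted graph's edges
(e.g. S01 → S03: perturbing S01 also perturbs S03) recovered the true
5-edge hierarchy exactly — sensitivity and specificity 1 — at this noise
level.  The final attachment posterior is essentially deterministic per
effect:

```r
head(attachment_posterior(fit$final_graph, r[fit$kept, ], fit$final_prior), 3)
#>                S01          S02          S03          S04          S05        .null
#> e0001 1.030932e-19 1.030932e-19 7.179743e-07 9.999988e-01 6.839414e-12 5.292208e-07
#> e0002 1.000000e+00 6.839423e-12 1.114103e-14 6.206395e-22 9.074443e-11 4.802390e-17
#> e0003 8.396937e-16 8.396937e-16 9.999905e-01 9.525896e-06 6.515163e-17 5.041309e-12
```

Downstream helpers: `merge_indistinguishable()` collapses mutually linked
(indistinguishable) signals, `group_effects()` groups attached effects by
signal × direction of regulation for enrichment analysis, and
`consensus_graph()` summarizes fits across seeds.  A thin command line
(`inst/cli/nemhop.R`) exposes `fit`, `simulate` and `benchmark`
subcommands.

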