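# thermodiv

From published phylogenies to a climate–macroevolution claim, in one
tested R package. `thermodiv` re-implements, at desk scale, the inference
chain used to argue that speciation rates track global palaeo-temperature:

1. **Supertree assembly** — source trees are encoded by matrix
   representation with parsimony (MRP: taxa subtended by a node score 1,
   other taxa in that tree 0, absent taxa `?`, rooted by an all-zero
   hypothetical outgroup), searched heuristically for most-parsimonious
   trees (with an exhaustive oracle at small sizes), and summarized by
   consensus and rooted maximum agreement subtrees.
2. **Fossil time-scaling** — the 'equal' method with a 0.1 Myr minimum
   branch duration: fossil first occurrences are hard node minima, and
   free intervals along uncalibrated chains are divided equally. Date
   robustness is probed by moving 10/15/20% of calibrations to adjacent
   nodes.
3. **Diversification shifts** — a compound-Poisson birth–death shift model
   with per-tip sampling fractions, sampled by reversible-jump MCMC
   (optionally Metropolis-coupled). The reconstructed-process likelihood
   propagates, along each branch,

   E' = μ − (λ+μ)E + λE²,  D' = −(λ+μ)D + 2λED,

   with tip conditions E = 1−f, D = f, a factor λ at each node and
   survival conditioning at the root. Shifts are ranked by Bayes factor
   (posterior vs. Poisson-prior odds of ≥1 shift per branch), branches
   with fewer than five tips excluded.
4. **Temperature correlation** — speciation rate-through-time curves on a
   0.1 Myr grid, one per posterior sample, correlated against a smoothed,
   linearly interpolated oxygen-isotope series (negated so higher =
   warmer) by Pearson's r and by the detrended cross-correlation
   coefficient ρ_DCCA(s), with a Student t-test on the coefficient mean.
   A negative mean reads "speciation faster when cooler".

A synthetic-data module generates every input with known ground truth —
birth–death trees with planted shift regimes, AR(1) temperature-like
series, temperature-coupled histories (λ(t) = exp(a + b·temp(t))),
overlapping source-tree decompositions and fossil-like minimum-age
calibrations — so the whole chain is testable end to end without any
external data. The methods vignette
(`vignettes/thermodiv-methods.Rmd`) documents every model, default and
deliberately fixed convention.

## Worked example

Simulate a 60 Myr radiation whose speciation rate jumps five-fold at
15 Ma inside one clade, then recover the shift and correlate the
posterior's rate curves with a temperature-like series:

```r
library(thermodiv)

sim <- simulateBDTree(lambda = 0.06, mu = 0, T = 60,
                      shifts = data.frame(age = 15, lambda = 0.3, mu = 0),
                      seed = 7)
shiftEvents(sim$config)
#>   child age lambda mu
#> 1   224  15    0.3  0

post <- rjmcmcRun(sim$tree, generations = 30000, store = 3000, seed = 99)
post
#> BDPosterior: 2700 samples on a 156-tip tree; shifts per sample 1-7 (median 2)

head(shiftSummary(post)$shifts, 3)
#>     child nTips branchAge        prob   priorProb  bayesFactor significant
#> 178   224    72 13.549057 1.000000000 0.011168159 4.780289e+05        TRUE
#> 179   223    73 29.803787 0.018518519 0.008919508 2.096487e+00       FALSE
#> 28    302     7  9.881188 0.008148148 0.006997703 1.165754e+00   FALSE
```

The true shift branch (child node 224) is recovered with marginal
probability 1 and a Bayes factor of ~5 × 10⁵; its nearest competitor, the
parent branch, sits at BF ≈ 2. Correlating every posterior rate curve with
an (uncoupled) AR(1) temperature proxy:

```r
curves <- rttCurves(post)
proxy <- resampleToGrid(
  tukeySmooth(simulateProxy(0.9, 0.15, span = c(0, 60), seed = 3), 5),
  span = c(0, max(attr(curves, "age"))))
correlatePosterior(curves, proxy, method = "dcca")
#> CorrelationDistribution [dcca(s=148)]: n=2700, mean=-0.0518, se=0.0004427, t=-117, p=0
#>   note: posterior draws are autocorrelated; the t-test treats the
#>   coefficients as independent and overstates precision
```

Here the proxy was generated independently of the tree, and the mean
coefficient is accordingly small (−0.05); the temperature-coupled
generator `simulateCoupledHistory()` produces histories where the
coefficient distribution is strongly signed (see the acceptance
experiments). The full chain — source trees → MRP → search → consensus
and MAST → 'equal' scaling → perturbation scenarios → shift inference →
both correlation tracks — runs from a single YAML configuration via
`runPipeline()` or `Rscript scripts/pipeline.R config.yaml`, writing a
JSON report with per-scenario coefficient distributions.

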