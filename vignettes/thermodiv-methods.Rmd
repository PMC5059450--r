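---
title: "Methods: from source trees to temperature-correlated speciation rates"
author: "thermodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from source trees to temperature-correlated speciation rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thermodiv` re-implements, at desk scale and with full tests, an inference
chain that runs from a pile of published phylogenies to a quantitative claim
about climate and macroevolution: assemble the source trees into one
supertree, date it with fossil minima, infer where and when speciation rates
shifted, and correlate the resulting rate-through-time curves against a
palaeo-temperature proxy. This vignette is the package's own account of each
stage: the model, its assumptions, the tunable parameters, and the places
where a genuinely open design choice had to be fixed.

Throughout, ages are in Ma before present (present = 0, increasing into the
past), durations in Myr, and rates in events per lineage per Myr. All grids
use 0.1 Myr steps so that rate curves and proxy series bin identically.

## 1. Supertree assembly by matrix representation with parsimony

Source trees rarely share all taxa, so they are combined through MRP:
every informative internal node of every source tree becomes one binary
character (1 = tip subtended by the node, 0 = tip present in that source
tree but not subtended, `?` = tip absent from that tree), and the matrix is
rooted by an all-zero hypothetical outgroup (`mrpEncode()`). A source set is
usable only when the overlap graph with edges between trees sharing at
least two taxa is connected (`checkOverlap()`); one shared taxon cannot
orient the trees against each other.

Parsimony lengths are computed by Sankoff dynamic programming
(`fitchScore()`), which handles polytomies and missing data exactly; for a
rooted candidate tree over the real taxa, the all-zero outgroup is adjoined
above the root, which reduces to taking `min(c0, c1 + 1)` at the root. The
search comes in two forms: `exhaustiveSearch()` enumerates every rooted
binary topology (practical to nine taxa; the enumeration is cached per
taxon count) and is the internal oracle, and `heuristicSearch()` runs
random-addition starting trees refined by rooted-NNI hill climbing. NNI
rather than TBR is a deliberate simplification: it keeps the search honest
at package scale, and the exhaustive oracle quantifies what it costs (in
the shipped experiments the heuristic attains the exhaustive optimum in
at least 95 of 100 random matrices).

Conflict among equally parsimonious trees is summarized two ways: strict
or majority consensus (`consensusTree()`), and pruning to a maximum
agreement subtree (`mastPair()`), a dynamic program over node pairs of two
rooted binary trees. Two fixed conventions matter here. First, agreement
is *rooted*: `((A,B),(C,D))` versus `((A,C),(B,D))` agree on at most two
tips, although the unrooted answer would be three. Second, ties among
equal-size agreement sets are broken toward the lexicographically smallest
taxon set, which makes the operation deterministic and symmetric in its
arguments. Multi-tree pruning is iterated pairwise MAST in input order — a
documented heuristic, not an exact multi-tree MAST.

## 2. Fossil time-scaling: the 'equal' method

Fossil first occurrences are hard minimum ages. `resolveCalibrations()`
attaches each calibration to the crown (MRCA) or stem (its parent) of the
named clade, keeping the older age when two calibrations land on one node.
`equalScale()` then dates the tree:

* every node gets a lower bound: descendants' bounds plus the minimum
  branch duration (`min_bl`, default 0.1 Myr), raised to the calibration
  age where one exists;
* calibrated nodes sit exactly at their bound — so a parent and child both
  calibrated at 50 Ma become 50.1 and 50;
* each maximal chain of uncalibrated nodes between an assigned ancestor
  and its oldest calibrated (or tip) descendant divides the free interval
  equally among the chain's branches, with individual bounds still
  respected; the chain follows the child with the largest lower bound,
  and side branches are dated recursively below their assigned chain node;
* an uncalibrated root sits at its lower bound.

This fixes one concrete rule out of the family of 'equal'-style
time-scaling procedures; the package's contract is the invariant set
(floors respected, minima respected, identity under full consistent
calibration), which the tests exercise on a thousand random tree and
calibration draws.

Robustness to calibration placement is probed by `perturbCalibrations()`:
a fraction of entries (the study design used 0.10, 0.15 and 0.20) moves to
an adjacent node — parent or a uniformly chosen internal child, by coin
flip; always a child at the root; always the parent where no internal
child exists — with the fossil age unchanged. Whether the original
procedure moved dates to parents and children with equal probability is
not recorded anywhere; the coin flip is this package's documented choice,
as is perturbing calibration entries (which exist before scaling) rather
than dated-tree nodes.

## 3. Birth–death rate shifts by reversible-jump MCMC

The diversification model is a compound-Poisson shift process on a fixed
dated tree: a root regime $(\lambda_0, \mu_0)$ and $k$ shift events, each
sitting strictly inside a branch and starting a new constant-rate regime
inherited tipward until overridden. Regimes are constant in time — the
principal simplification relative to frameworks with exponentially
time-varying rates within regimes. The correlation stage consumes only
rate-through-time curves, and constant regimes keep a closed-form
likelihood that an independent ODE integration can verify to $10^{-6}$.

The likelihood is the reconstructed-process density with per-tip sampling
fractions: along each branch the extinction probability and lineage
density satisfy

$$E' = \mu - (\lambda+\mu)E + \lambda E^2, \qquad
  D' = -(\lambda+\mu)D + 2\lambda E D,$$

with tip conditions $E = 1 - f$, $D = f$, a factor $\lambda$ at every
internal node, and survival conditioning $(1-E_{\mathrm{root}})^{-2}$.
Writing $x = 1 - E$ turns the $E$ equation into a logistic ODE, giving the
closed-form segment propagation implemented in compiled code. At an
internal node the two daughter branches can propagate different $E$ values
once sampling fractions or regimes differ below — a known indeterminacy of
shift models on reconstructed trees; this package takes the mean of the two
values, a symmetric convention applied identically in the analytic code
and the numerical oracle.

The sampler (`rjmcmcRun()`) mixes five moves: log-scale multiplier updates
of one regime's $\lambda$ or $\mu$, shift birth (branch chosen
proportional to duration, age uniform on the branch, regime drawn from the
prior, acceptance $\gamma/(k+1)$ times the likelihood ratio), shift death
($k/\gamma$), and a position move. Priors: $k \sim \mathrm{Poisson}(\gamma)$
with $\gamma = 1$ by default; $\lambda$ and $\mu$ exponential with means
anchored on the tree's Yule point estimate $\hat\lambda = (n-1)/L$ ($L$ =
total branch length) and $\hat\lambda/10$ respectively. Anchoring the
regime prior on the Yule estimate keeps prior-drawn shift regimes on the
scale the data support; the light extinction prior reflects that the Yule
estimate's extinction component is zero and that extinction is weakly
identified on extant-only trees — a heavier turnover prior visibly shifts
the marginal $\lambda$ interval upward. Optional Metropolis coupling heats
the likelihood by $1/(1 + 0.1\,(j-1))$ with periodic adjacent swaps;
samples always come from the cold chain. Default run sizes (20,000
generations, 1,000 stored, 10% burn-in, one chain) are package-scale
choices; the study-scale layout (4 chains, $2\times10^7$ generations,
10,000 stored, 9,000 retained) is available through the same arguments.

`shiftSummary()` reports per-branch marginal shift probabilities with a
Bayes-factor criterion — posterior odds of at least one shift on the
branch against the prior odds $1 - e^{-\gamma \ell/L}$ — excluding
branches subtending fewer than five tips, the reporting filter of the
original analysis. `rttCurve()` averages $\lambda$ arithmetically over the
branches of a focal clade crossing each 0.1 Myr grid age (branch crossing
is child-inclusive, parent-exclusive, so counts are unambiguous at node
ages); whether the original curves were arithmetic branch means or a
rate-matrix average is not recorded, and the arithmetic mean is the
documented choice here. The grid runs from the clade origin (rounded down
to the grid, and one step further when the origin falls exactly on a grid
point, where no branch crosses) to the present.

## 4. Temperature proxy and the two-track correlation

The oxygen-isotope series loads from a two-column CSV (`age Ma, value`),
is smoothed by a centred running mean (`tukeySmooth()`, default window 5
points, clipped at the ends; "Tukey smoothing" classically means running
*medians*, so that variant sits behind `median = TRUE`, but the
implemented default follows the literal "running mean" wording), and is
linearly interpolated onto the 0.1 Myr grid (`resampleToGrid()`), never
extrapolated. Values are negated by default so the proxy *increases with
warmth*: benthic oxygen-isotope ratios rise as climate cools, and the
sign convention of the results — a coefficient of $-1$ means speciation
increases with cooler temperature — requires the warmth-increasing axis.
`negate = FALSE` gives the raw orientation.

`correlatePosterior()` computes one coefficient per posterior rate curve
over the overlapping grid span: Pearson's product-moment coefficient, or
the detrended cross-correlation coefficient $\rho_{\mathrm{DCCA}}(s)$ —
cumulative mean-centred profiles, least-squares linear detrending in every
overlapping window of $s+1$ points, detrended covariance normalized by the
two detrended-fluctuation roots. The box size defaults to
$\lfloor N/4 \rfloor$ (no value is recorded in the source analysis).
Curves with no defined coefficient — constant curves, and curves whose
cumulative profile is exactly linear (for example a curve differing from
constant only at its first grid point) — are dropped and counted in the
result's `note`. A one-sample two-sided Student t-test assesses whether
the coefficient mean differs from zero. The posterior draws are not
independent, so this p-value overstates precision; the result object says
so rather than silently correcting, mirroring how the original analysis
reported it.

## 5. What the synthetic generators emulate

`synthgen`-side functions create every input with known ground truth:

* `simulateBDTree()` — forward Gillespie birth–death from one origin
  lineage, optional planned shifts applied to a random extant lineage at
  given ages, extinct lineages pruned, tips binomially subsampled; returns
  the realized tree *and* the true shift configuration mapped onto it.
  Stopping is by age or by tip count (exclusively).
* `simulateProxy()` — stationary AR(1) noise around an optional linear
  trend: the minimal model with the autocorrelation DCCA exists to handle.
  Fractional noise is deliberately out of scope.
* `simulateCoupledHistory()` — inhomogeneous pure birth with
  $\lambda(t) = \exp(a + b\,\mathrm{temp}(t))$, $\mathrm{temp} = -$value;
  $b<0$ makes speciation faster when cooler. Extinction stays at zero so
  event-time reasoning stays exact. Specifications whose expected tip
  count exceeds $10^5$ are refused.
* `decomposeToSourceTrees()` and `sampleFossilCalibrations()` — induced
  subtrees rejection-sampled to a connected overlap graph, and minimum-age
  calibrations $\mathrm{age} \times (1-|\varepsilon|)$ that are valid
  minima by construction.

What these do *not* emulate: real source-tree estimation error (induced
subtrees are always topologically correct), taxonomy reconciliation,
fossil age measurement error beyond systematic underestimation, and any
structured climate signal beyond AR(1)-plus-trend. Passing tests therefore
demonstrate that the chain of algorithms is correct and that the
inference logic recovers planted signals when its assumptions hold — not
that those assumptions hold for any particular empirical system.

## 6. The shipped verification experiments

`scripts/acceptance.R` reruns the package's verification experiments from
scratch at fixed problem sizes chosen as package-scale defaults: 100
random matrices of 5–7 taxa for the parsimony oracle; a 32-taxon model
tree decomposed into 10 source trees of 28 tips for the supertree round
trip (smaller source trees leave the MRP matrix genuinely underdetermined,
with several tied optima — a property of the data, not the search); 50
random trees for the likelihood oracle; 20 hundred-tip Yule trees for
interval coverage; one ~200-tip tree with a five-fold shift on a clade of
at least 20 tips for detection; and four coupled histories per coupling
sign for sign recovery, pooled.

Two experiment-design notes deserve emphasis. First, on shift-free data
the posterior shift count essentially reproduces its Poisson(1) prior,
which puts *equal* mass on zero and one shift; the meaningful no-false-
detection statement is that the posterior-to-prior odds of at least one
shift stay near 1 (far below the significance threshold of 5), and that is
what the experiment asserts. Second, the coupled histories use a
trendless, highly persistent AR(1) temperature ($\phi = 0.99$). With a
monotone (trending) proxy, the deep-time portion of every rate curve —
where only a handful of branches exist and prior-drawn regimes contribute
right-skewed noise — correlates spuriously with *any* monotone series;
with a wandering trendless proxy that artifact decorrelates across
replicate histories while the built-in coupling persists, and the
recovered coefficient means carry the correct sign in both directions
under both Pearson and DCCA.

## 7. Known limitations

* Clade-persistent regimes express tree-wide *temporal* trends only
  indirectly; the package shares this limitation with the framework it
  re-implements, and the vignette's sign-recovery design exists precisely
  to work within it.
* The t-test on posterior coefficient distributions inherits the
  dependence of posterior draws; treat its p-value as descriptive.
* Iterated pairwise MAST can prune more taxa than an exact multi-tree
  maximum agreement subtree would.
* The heuristic search has no TBR or ratchet stage; for matrices beyond a
  few dozen taxa, expect to raise `replicates`.
* The 'equal' scaling rule is one fixed member of its family; other
  implementations may place uncalibrated nodes differently while
  satisfying the same invariants.
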