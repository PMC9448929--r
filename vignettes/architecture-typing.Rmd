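---
title: "Architecture typing, oscillator dynamics and lesion vulnerability of structural connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Architecture typing, oscillator dynamics and lesion vulnerability of structural connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectotype)
```

## The analysis in one paragraph

`connectotype` takes a population of structural-connectivity (SC) matrices —
weighted, symmetric, nonnegative graphs whose nodes are grey-matter parcels
and whose edges summarize white-matter tract strength — and asks three
questions. First, do subjects fall into distinct *architecture types*, i.e.
clusters of mutually similar wiring diagrams? Second, do those types produce
distinct simulated neural dynamics when each SC is used as the coupling
matrix of a Kuramoto phase-oscillator model? Third, do the types respond
differently to simulated injury, modelled as cumulative removal of the most
connected (hub) nodes? Because the reference population of young-adult
diffusion connectomes is access-restricted, the package ships a synthetic
population generator with two planted archetypes whose statistical structure
is calibrated to the reference population's similarity profile; every stage
of the pipeline is exercised and tested against that generator.

## Stage 1: similarity and modularity over subjects

Each subject's 100-node SC is averaged down to a 7-system representation:
entry (S, T) of the coarse matrix is the mean weight of all fine edges
joining systems S and T. The 21 between-system values form the subject's
edge vector, and similarity between two subjects is the Pearson correlation
of their vectors. Clustering maximizes the modularity

$$ Q(\gamma) \;=\; \frac{1}{2m}\sum_{j,h}\bigl[A_{jh} - \gamma P_{jh}\bigr]\,
\delta(\sigma_j,\sigma_h), \qquad P_{jh} = \frac{s_j s_h}{2m}, $$

where $A$ is the (nonnegative-clipped) similarity matrix, $s$ its row sums,
$2m$ its total weight, and $\gamma$ the resolution. We keep the unit
self-similarity diagonal in $A$: the optimization sees the similarity matrix
exactly as built. This matters at small sample sizes — dropping the diagonal
adds one null-model penalty term per subject to every partition, which for a
few dozen subjects is the same order as the entire within-cluster
correlation excess and would make the two-module split unreachable; for
hundreds of subjects the choice is immaterial. The optimizer is a greedy
multi-level (Louvain-style) local-moving scheme with restarts over random
node orders (deterministic given the seed; ties broken toward fewer modules,
then the lexicographically smallest assignment). If no partition beats the
configuration null — including the case where only self-similarity does,
leaving every subject alone — the sample is declared unorganizable and a
single module is returned.

The resolution is not free: following the minimum-resolution rule, the
pipeline scans an ascending $\gamma$ grid (default 0.5–1.5 in steps of 0.01)
and keeps the first value whose optimal partition has exactly two modules,
each holding at least 5% of subjects. Robustness is assessed two ways:
k-fold cross-validation (withheld subjects are assigned to the module with
the highest mean similarity, and scored against the whole-sample partition),
and subset classification, where the similarity matrix is rebuilt from only
the fine edges within one system (or between one pair of systems) and the
resulting partition is scored against the whole-network reference after
maximal-overlap label matching.

## Stage 2: Kuramoto dynamics

Each SC is normalized so the mean of all $n(n-1)$ off-diagonal couplings is
1 (structural zeros included), and drives the phase model

$$ \dot\theta_j = \omega_j + K \sum_h C_{jh}\,\sin(\theta_h - \theta_j), $$

with natural frequencies drawn from a normal distribution at 60 Hz (sd 1 Hz,
converted to rad/s — the sine coupling requires angular units) and initial
phases uniform on $[0, 2\pi)$. There is no $1/N$ factor in the coupling sum;
the mean-1 normalization of $C$ carries the scale. Integration is classical
4th-order Runge-Kutta with step $10^{-4}$ s (a 60 Hz cycle is ~16.7 ms, so
this is ~167 steps per cycle; halving the step changes measured synchrony by
under $10^{-3}$, which the test suite checks). The order parameter
$r(t)e^{i\phi(t)} = \tfrac1N\sum_j e^{i\theta_j(t)}$ is recorded every 1 ms;
*synchrony* is its time-mean and *metastability* its (population) standard
deviation, both over the window after a burn-in of the first fifth of the
simulation. Sweeping the global coupling $K$ (default grid 0–2) yields two
critical couplings per network: the first $K$ whose synchrony is within 10%
of the network's own maximum over the grid, and the $K$ of maximum
metastability. Frequencies and initial phases are drawn once per replicate
and held fixed across the whole grid, so the critical-coupling curves are
smooth in $K$.

## Stage 3: targeted lesioning

Nodes are ranked by strength (weighted degree) within each subject — binary
degree is uninformative on near-fully-dense SC matrices — ranks are averaged
across the population, and the shared ranking defines which nodes are
severed at each cumulative level (defaults 5%, 10%, 25%, 50%, 75%; the top
$\lceil \ell n \rceil$ nodes). Lesioned nodes keep their rows and columns at
zero rather than being deleted, so the oscillator count and the order
parameter's denominator stay fixed. The coupling matrix is normalized once,
before lesioning: renormalizing afterwards would silently restore the total
drive the lesion removed (a flag exists for the renormalizing variant).
Graph metrics are recomputed per level with the connection-length transform
$d = 1/w$: global efficiency uses the harmonic convention (unreachable pairs
contribute zero), the characteristic path length averages reachable ordered
pairs and reports the unreachable count, betweenness uses ordered-pair
normalization $1/((n-1)(n-2))$, and the clustering coefficient follows the
binary formula $2t_j/(k_j(k_j-1))$ on the thresholded graph by default, with
a geometric-mean weighted variant as an option.

## The synthetic population generator

The generator is the package's stand-in for the restricted reference data
and defines the study conditions for all tests. Its construction is
hierarchical:

* A fixed 7x7 coarse base template (within-system weights exceed
  between-system weights; between weights are heterogeneous).
* Archetype 2 multiplies within-system weights by $(1 + \texttt{contrast})$
  and between-system weights by $(1 - \texttt{contrast}\cdot g_{st})$, then
  rescales between weights by one constant so both templates have equal mean.
  The fixed pattern $g_{st}$ has mean ~1 and spread set by `shape`. The two
  knobs are deliberately separate because they control different
  observables: the mean shift (concentration) is invisible to Pearson
  similarity on between-system vectors but governs the dynamics and lesion
  response, while the `shape` deviations alter the relative between-system
  pattern and set the across-type similarity.
* Each coarse template is expanded to the fine parcellation through a fixed
  lognormal edge texture (log-sd `texture_sd`, internally seeded — it is
  part of the archetype definition, not subject noise). Between-system
  texture is shared by both archetypes; within-system texture correlates at
  `texture_cor` across archetypes, planting the within-system signal that
  subset classification detects.
* Subjects apply two layers of lognormal noise — one factor per system pair
  (`sigma_coarse`) and one per fine edge (`sigma`) — and are rescaled to a
  common mean edge weight (default $10^{-4}$). The hierarchy is necessary:
  purely edge-level noise averages out over the ~200 fine edges behind each
  coarse edge and cannot produce realistic subject-level variability at the
  system scale.

Defaults (`contrast = 0.45`, `shape = 0.25`, `sigma_coarse = 0.075`,
`sigma = 0.25`, `texture_sd = 0.45`, `texture_cor = 0.5`) were calibrated
once, by grid search, to the reference population's similarity profile —
mean within-type correlation ~0.942 and across-type ~0.906 at the 7-system
level (the calibration utility `population_calibration()` reproduces the
measurement) — with the concentration set so the within-concentrated
archetype shows the qualitative dynamics signature of the reference
analysis: higher synchrony critical coupling, higher metastability critical
coupling, lower synchrony area-under-curve.

What the generator does *not* emulate: spatial embedding and
distance-dependent wiring, realistic degree/strength marginals (synthetic
nets are near-fully dense, which is why the binary clustering coefficient is
degenerate on them), sex differences (both sexes share the two archetypes,
matching the reference finding that architectures do not differ by sex), and
edge-weight autocorrelation beyond the system-pair blocks. Tests passing on
this generator therefore validate the pipeline's statistical machinery, not
claims about any particular empirical population.

One spec-level expectation is knowingly not met by the calibrated generator:
concentrating weight into the (few) within-system edges *lowers* the mean
weighted clustering coefficient of archetype 2 on these dense matrices,
because the (far more numerous) between-system triangles are diluted; the
test suite asserts the concentration ratio itself instead.

## Numerical and design choices

* **Edge order**: vectors use fixed row-major upper-triangle order;
  between-system subsets canonicalize the system pair alphabetically.
* **Symmetry tolerance**: inputs may deviate from symmetry by up to 1e-9
  (relative) and are symmetrized; larger asymmetry is an error, since
  tractography outputs are symmetric up to write precision.
* **Diagonals** are stored as zero everywhere; the coarse matrix returns
  within-system means as a separate attribute (constants add nothing to
  Pearson correlation, and the reference vectorization uses between-system
  entries only).
* **Negative similarities** are clipped to zero before modularity (a no-op
  in practice: empirical similarities sit near +0.9); a signed variant is
  out of scope.
* **Q normalization** by $2m$ follows the standard convention; it rescales
  Q without changing the optimum.
* **Critical-coupling ties** resolve to the first grid point; the
  "maximum synchrony" in the 90% rule is each network's own maximum over
  its grid.
* **Degenerate nodes** (degree < 2) receive clustering coefficient and
  betweenness 0 rather than NaN; all-zero matrices are rejected by the
  scaling and normalization steps with explicit degenerate-input errors.
* **Seeds**: one master seed; per-subject, per-replicate and per-restart
  streams are derived from (master, index) pairs, so populations extend
  without reshuffling and every stage is reproducible in isolation.
* **Per-sex resolution**: the minimum-gamma search runs per similarity
  matrix (hence per sex), and the chosen gamma is recorded with the
  partition.

## Problem sizes

Tests and the bundled acceptance analysis run at desk scale, chosen to keep
the full suite in the tens of minutes on one CPU: clustering stages use 40
subjects per sex at the full 100-node parcellation; dynamics stages use a
reduced 21-node parcellation (7 systems x 3 nodes), simulations of 10-12 s
at $dt = 10^{-4}$ s, 21-point coupling grids, and 1-2 replicates; the
synchrony-collapse check runs two full-size (100-node) subjects at T = 5 s.
Group-comparison checks on dynamics use a paired design (identical frequency
and phase draws across subjects) to isolate architectural effects from draw
noise. Full-scale runs (100 s, 100 nodes, denser grids) are available
through the same functions and `run_pipeline()`'s configuration.

## Known limitations

* The modularity landscape of near-uniform similarity matrices is shallow;
  with very few subjects (tens), the two-module split sits close to the
  configuration null and the minimum-gamma rule can be sensitive to the
  grid step. The cross-validation stage is the guard against over-reading
  such splits.
* Kuramoto critical couplings are quantized to the sweep grid; differences
  smaller than the grid step are invisible.
* The lesion model severs whole nodes by population-mean rank; it does not
  model spatially structured or biomechanically derived damage.
* Because the generator's edge weights span well under an order of
  magnitude, the nodes surviving a severe (75%) lesion retain near-average
  mutual couplings and their remnant still synchronizes; the order
  parameter therefore collapses to roughly the surviving fraction of
  oscillators (~0.25 of its intact value) rather than all the way to the
  incoherent floor that strongly heavy-tailed empirical connectomes show.
* Weighted-graph metrics assume the connection-length transform $d = 1/w$;
  other monotone transforms would change numbers but not orderings within
  this pipeline.
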