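# connectotype

Architecture typing, oscillator dynamics and lesion vulnerability for
populations of brain structural connectomes.

## What it does

White-matter wiring differs between people. Given a population of
structural-connectivity (SC) matrices — symmetric, nonnegative weighted
graphs over grey-matter parcels — `connectotype`:

1. **Groups subjects into architecture types.** Each 100-node SC is averaged
   to a 7-system representation; subjects are compared by Pearson
   correlation of their 21 between-system edge weights, and the resulting
   subject-similarity matrix is clustered by maximizing modularity

   *Q*(γ) = (1/2m) Σ<sub>jh</sub> [A<sub>jh</sub> − γ·s<sub>j</sub>s<sub>h</sub>/(2m)] δ(σ<sub>j</sub>, σ<sub>h</sub>),

   at the smallest resolution γ producing two nontrivial modules. The split
   is validated by k-fold cross-validation and by re-clustering on edge
   subsets (single systems or system pairs).
2. **Simulates neural dynamics per subject** with a Kuramoto phase model,
   dθ<sub>j</sub>/dt = ω<sub>j</sub> + K Σ<sub>h</sub> C<sub>jh</sub> sin(θ<sub>h</sub> − θ<sub>j</sub>),
   on the mean-normalized SC, sweeping the global coupling K to locate each
   network's critical coupling for synchrony (first K within 10% of maximum
   synchrony) and for metastability (K of peak order-parameter variability).
3. **Lesions hubs cumulatively** — nodes ranked by population-mean strength,
   top 5/10/25/50/75% severed — and re-measures weighted graph metrics
   (global efficiency, mean shortest path length, betweenness, clustering)
   and dynamics, comparing architecture types by one-way ANOVA with
   Tukey-Kramer correction.

The restricted reference population is replaced by a **synthetic generator**
(`population_spec()` / `generate_population()`) with two planted archetypes
per sex, calibrated so that within-type / across-type similarity at the
system level is ≈ 0.94 / 0.91.

## Worked example

```r
library(connectotype)

spec <- population_spec(n_per_group = 20, sexes = "male", seed = 1)
pop  <- generate_population(spec)          # 40 subjects, 2 planted archetypes
res  <- cluster_population(pop$subjects, seed = 1)
res$partition
#> <module_partition> 40 subjects -> 2 module(s), gamma = 0.98, Q = 0.0232
#> module
#>  1  2
#> 20 20
table(found = res$partition$assignment, planted = pop$labels$archetype)
#>      planted
#> found  1  2
#>     1 20  0
#>     2  0 20

cv <- crossval_accuracy(res$similarity, res$partition, k = 5, seed = 1)
cv$accuracy
#> [1] 0.975
```

The minimum-resolution search finds γ* = 0.98, the two modules recover the
planted archetypes exactly, and 97.5% of withheld subjects return to their
module under 5-fold cross-validation. Dynamics and lesioning continue from
the same objects:

```r
sw <- coupling_sweep(pop$subjects[[1]], K_grid = seq(0, 2, 0.1),
                     T = 10, n_reps = 2, seed = 1)
sw$Kcrit_syn            # first K within 10% of max synchrony
plan <- rank_nodes(pop$subjects)
lesioned <- lesion_experiment(pop$subjects[1:4], plan)
```

`run_pipeline(pipeline_config(outdir = "run1"))` executes every stage
(generate → cluster → metrics → simulate → lesion → report) and writes CSV/
JSON artifacts plus a run manifest; `inst/cli/connectotype.R` wraps it for
the shell.

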