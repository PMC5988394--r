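# phasentropy

Temporal complexity of dynamic phase-synchrony brain networks.

## What this is for

Resting-state fMRI connectivity is not static: the pattern of which brain
regions are synchronized reorganizes on the scale of tens of seconds,
shifting between *segregated* (tightly clustered modules) and *integrated*
(diverse between-module links) configurations. `phasentropy` implements an
end-to-end analysis of how temporally complex those network fluctuations
are, for researchers working with parcellated node-by-time BOLD (or any
band-limited multichannel) signals:

1. **Instantaneous phase synchrony.** Each node signal `y_m[t]` is mapped
   to its analytic associate `z_m[t] = y_m[t] + i H{y_m}[t]`; the pairwise
   phase difference is stored as `d_mn[t] = |sin(phi_m[t] - phi_n[t])|`,
   and per-frame binary graphs keep edges with `d < sin(theta)`
   (default `theta = pi/16`).
2. **Time-resolved topology.** Per frame and node: clustering coefficient
   `CC_i = 2 t_i / (k_i (k_i - 1))` (segregation) and participation
   coefficient `PC_i = 1 - sum_m (k_i(m)/k_i)^2` (integration, over a
   Louvain partition at resolution `gamma = 2`).
3. **Temporal complexity.** Sample entropy
   `SampEn(m, r, N) = -ln(U^{m+1} / U^m)` of each node's CC and PC series
   (`m = 2`, `tau = 1`, `r = 0.2 SD`; Chebyshev distance, self-matches
   excluded) — near 0 for regular series, ~2.2 for white noise.
4. **Group statistics.** Pooled CC–PC correlation, t-test on node-averaged
   SampEn (PC vs CC), metric-vs-SampEn correlations across nodes,
   PCA-based network groupings with one-way ANOVA + Bonferroni post-hoc,
   multivariate phase-randomized surrogate contrasts, and density sweeps
   over thresholds `pi/4 ... pi/24`.

A first-class synthetic-data module (`gen_coupled_phase_network()` and
friends) generates band-limited coupled-oscillator networks with planted
modular structure, segregation/integration state switching, connector
nodes, and reference signals (sine banks, uniform noise, fractional
Brownian motion) for entropy benchmarking. All tests run against this
generator; no real recordings are required or included.

## Worked example

```r
library(phasentropy)

cfg <- synthetic_config(seed = 1)        # 128 nodes, T = 200, TR = 3 s
group <- gen_group(cfg, n_subjects = 5)  # shared structure, subject noise
runs <- lapply(seq_along(group), function(i)
  run_subject(group[[i]], pipeline_config(seed = 100 + i)))

metrics <- lapply(runs, `[[`, "metrics")
emaps   <- lapply(runs, `[[`, "entropy")

pooled_cc_pc_correlation(metrics)
metric_vs_entropy_correlation(metrics, emaps)
compare_entropy_distributions(emaps)$t
```

Output from this exact script:

```
> pooled_cc_pc_correlation(metrics)
[1] -0.4153529
attr(,"n")
[1] 128000
> metric_vs_entropy_correlation(metrics, emaps)
        cc         pc
-0.4963581  0.7138987
> compare_entropy_distributions(emaps)$t
[1] -15.59155
```

Reading: clustering and participation are anticorrelated over the
128,000 pooled (subject, node, frame) samples — segregation and
integration trade off (r = −0.42). Highly clustered nodes have *more
regular* clustering series (r = −0.50), while high-participation nodes
have *more irregular* participation series (r = +0.71). The negative t
(clustering SampEn exceeding participation SampEn) is a documented
finite-parcellation effect: at 128 nodes the participation series are
sparse and their plain sample entropy is deflated — see the
"finite-size caveat" section of the methods vignette.

## Command line

```sh
Rscript inst/scripts/phasentropy-cli.R simulate --preset coupled \
    --nodes 64 --timepoints 200 --dt 3 --seed 1 --out y.tsv
Rscript inst/scripts/phasentropy-cli.R connectivity --in y.tsv --dt 3 \
    --band 0.03,0.07 --theta 0.196 --out graphs/
Rscript inst/scripts/phasentropy-cli.R entropy --in metrics.tsv \
    --metric cc --out entropy.tsv
```

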