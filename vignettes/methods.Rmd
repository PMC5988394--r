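---
title: "Temporal complexity of dynamic phase-synchrony networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal complexity of dynamic phase-synchrony networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phasentropy)
```

## The pipeline

`phasentropy` quantifies how the *topology* of a functional brain network
fluctuates over time, and how temporally complex those fluctuations are.
Starting from a node-by-time matrix $Y$ of band-limited signals (one row
per brain region, sampled every TR seconds), the per-subject pipeline is:

1. **Temporal preprocessing.** Optional censoring of high-motion frames
   (framewise displacement $\ge$ 0.5 mm) with cubic-spline refill, then a
   zero-phase band-pass (default 0.03–0.07 Hz).
2. **Instantaneous phase.** Each row's discrete analytic associate
   $z_m[t] = y_m[t] + i\,\tilde y_m[t]$ (Hilbert transform via the FFT);
   the argument $\varphi_m[t]$ is the instantaneous phase. Meaningful
   phases require narrow-band, mean-centered rows (the Bedrosian
   condition); the package warns when the band-occupancy check fails.
3. **Phase-synchrony graphs.** The pairwise phase difference is stored as
   $d_{mn}[t] = |\sin(\varphi_m[t]-\varphi_n[t])| \in [0,1]$ (0 =
   phase-locked). At each frame, an edge joins pairs with
   $d < \sin\theta$, default $\theta = \pi/16$.
4. **Time-resolved graph metrics.** Per frame: the binary clustering
   coefficient $CC_i = 2t_i / (k_i(k_i-1))$ (segregation) and the
   participation coefficient $PC_i = 1 - \sum_m (k_i(m)/k_i)^2$
   (integration), the latter over a Louvain partition at resolution
   $\gamma$ (default 2).
5. **Sample entropy.** For each node, the temporal complexity of the
   $CC_i[t]$ and $PC_i[t]$ series is summarized by
   $\mathrm{SampEn}(m, r, N) = -\ln(U^{m+1}/U^m)$ with $m = 2$,
   $\tau = 1$, $r = 0.2\,\mathrm{SD}$.
6. **Group statistics.** Pooled CC–PC correlation, a two-sample $t$ test
   on node-averaged SampEn (PC vs CC), node-wise correlations between a
   metric's time average and its SampEn, PCA-defined network groupings
   with a one-way ANOVA and Bonferroni post-hoc, a multivariate
   phase-randomized surrogate contrast, and a density threshold sweep.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| band | 0.03–0.07 Hz | slow-oscillation band that satisfies the narrow-band phase condition and avoids respiratory/cardiac artifacts |
| $\theta$ | $\pi/16$ | retains only strongly synchronous pairs; comparison is `d < sin(theta)` (see below) |
| $\gamma$ | 2 | finer modules; reduces frames in which a node's links are all intramodular (PC $= 0$) |
| SampEn $m, \tau, r$ | 2, 1, 0.2·SD | short records (T = 200) support $m = 2$; $r$ proportional to SD makes SampEn amplitude-invariant |
| FD threshold | 0.5 mm | conventional motion-censoring cutoff |

### Numerical and convention choices

* **Threshold semantics.** The stored quantity is $|\sin\Delta\varphi|$,
  so thresholding "phase difference less than $\theta$" is implemented as
  $d < \sin\theta$. Near 0 this equals $|\Delta\varphi| < \theta$, but it
  *also* admits antiphase pairs ($|\Delta\varphi| \approx \pi$): the sine
  conflates in-phase and antiphase alignment. Both are edges by design;
  `compare = "angle"` gives the (nearly identical) direct comparison
  $d < \theta$.
* **Filter realization.** The band-pass is an FFT-domain real response
  with raised-cosine transition edges rather than a forward-backward IIR:
  no IIR design library is available in the deployment environment, and a
  real spectral response is *exactly* zero-phase, which is the property a
  phase pipeline actually needs. DC is always removed.
* **Degenerate metric values.** $CC_i = 0$ when $k_i < 2$ (the 0/0 case)
  and $PC_i = 0$ when $k_i = 0$, the standard toolbox conventions; both
  keep the metric defined at every node and frame.
* **Modularity convention.** $Q = \sum_c [e_c/m - \gamma (d_c/2m)^2]$;
  the resolution multiplies the null term. The Louvain sweep order is
  seed-controlled, and the returned $Q$ is re-evaluated independently
  from the labels so a backend change cannot silently change conventions.
* **SampEn counting.** Both $U^m$ and $U^{m+1}$ run over the same
  $N - m\tau$ templates (self-matches excluded, Chebyshev distance,
  $\le r$), making the conditional probability a ratio of counts over a
  common pair set. SD uses the population (1/N) convention. Undefined
  results (zero matches) propagate as flagged missing values, never as
  infinities, so group statistics must drop them explicitly.
* **Censoring at the record edges.** Censored frames before the first (or
  after the last) retained frame take the nearest retained value; cubic
  extrapolation is unstable.
* **Streaming.** Per-frame graphs are built from the phase matrix one
  frame at a time; the $N \times N \times T$ tensor is only materialized
  by `phase_difference_tensor()` when explicitly requested, so large
  parcellations are not precluded.
* **PCA network definition.** Networks are the first $K$ eigenvectors of
  the raw (uncentered) group-average synchrony matrix $1-\bar d$;
  winner-take-all on absolute loadings, so the assignment is invariant to
  sign flips. Nodes whose top two absolute loadings differ by less than
  10% are flagged ambiguous; an unseparated spectrum (e.g. an identity
  matrix) is an error rather than an arbitrary assignment.
* **The $t$ test** on SampEn(PC) vs SampEn(CC) is an unpaired two-sample
  Student test by default, matching the named procedure; a paired variant
  is available since the two values come from the same subjects.

## The synthetic world

No real recordings ship with the package, so all tests run on a
synthetic generator whose job is to *state* a world with the features the
analysis assumes, not to imitate any particular dataset.

`gen_coupled_phase_network()` integrates first-order phase dynamics
(Euler substeps sized so that step × coupling ≤ 0.1) with a hierarchical
coupling structure:

* **Modules** (default 6) each split into two loosely bound
  **micromodules**; within-micromodule coupling (0.3 rad/s) is far above
  the Kuramoto critical coupling for the node frequency spread
  (SD 0.0015 Hz), so module cores are deeply phase-locked and their
  clustering is high and *smooth* in time.
* **A module frequency ladder** (centers ±0.004 Hz around the band
  center) makes locked modules drift through mutual alignment a few times
  per scan, rather than holding frozen phase relations.
* **Ring coupling** between frequency-adjacent modules switches between
  a weak "segregated" value (0.015 rad/s) and a stronger "integrated"
  value (20% of the within coupling) on an eight-block schedule (75 s
  dwell). Ring — not global mean-field — coupling was a deliberate
  choice: near-critical *global* coupling produces whole-network locking
  epochs, and a fully synchronized network is a single community, i.e.
  zero participation everywhere. Integration spreads through chains of
  partially overlapping phase arcs instead.
* **Connectors** (25% of nodes) are weakly anchored to their module,
  feel a weak global pull, and carry mild phase diffusion: they wander
  between phase clusters, providing the persistent, irregular
  between-module participation seen at connector nodes in real data.
* **Node traits** (module membership, connector status, coupling jitter)
  are drawn from the config seed and shared across a simulated group,
  like anatomy; per-subject seeds drive frequencies, initial phases and
  noise.

Calibration protocol: the free parameters were set from time-scale
arguments (locking vs drift rates relative to the threshold window) and
adjusted until the *descriptive* regime matched the kind of data the
pipeline targets — ~6 detected modules, smooth metric time series, edge
densities in the tens of percent at $\theta = \pi/16$, clustering SampEn
well below the white-noise ceiling — and then frozen. They were not tuned
against the acceptance sign criteria.

What the generator does **not** emulate: hemodynamic convolution,
spatially correlated measurement noise, non-sinusoidal waveforms,
scanner drift, or subject motion. A green end-to-end test therefore
establishes that the pipeline recovers planted segregation/integration
structure of this idealized kind — not that it would do so on any real
recording.

### Finite-size caveat on the participation coefficient

At desk scale (128 nodes, edge density ~0.1–0.3) a node's total degree
is a few dozen, and frames in which all of a node's links fall inside one
Louvain module are common: 25–60% of participation-coefficient samples
are exactly zero in most regimes of the generator, whereas at thousands
of nodes PC zeros essentially never occur. Sparse, blocky zero runs
deflate plain SampEn (the same effect the sparsity simulations
demonstrate), so at coarse scales the nonzero-only SampEn variant
(`nonzero_pc = TRUE`, used automatically by `density_sweep()`) is worth
inspecting alongside the plain default. The package keeps plain SampEn
as the default for `run_subject()` to match the main-analysis convention
at large parcellations, and reports the zero fraction so users can
judge.

A concrete consequence, measured on the bundled generator at 128 nodes:
the segregation/integration anticorrelation and both
metric-versus-entropy correlation signs recover robustly across seeded
group simulations, but the *ordering* "participation SampEn exceeds
clustering SampEn" does not — plain PC SampEn is deflated by the zero
runs, while the nonzero-only variant repairs the ordering at the cost of
inverting the node-wise PC-versus-SampEn correlation (which, at this
scale, is itself carried by the sparsity gradient). That ordering should
be regarded as a large-parcellation phenomenon (degrees of order
10^2–10^3), not something a 128-node analysis can exhibit.

## Known limitations

* Binarized graphs only; weighted analyses are out of scope.
* The antiphase conflation of the $|\sin|$ storage is inherited by
  design and documented rather than "fixed".
* Louvain is a stochastic heuristic; partitions (and PC) are
  reproducible only given the recorded seeds. Run-to-run $Q$ variability
  is itself measured (coefficient of variation < 0.01 on benchmark
  graphs).
* SampEn is undefined when no template pairs match; short or heavily
  censored records exacerbate this, and undefined nodes are dropped
  (flagged) from group statistics.
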