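---
title: "Dynamic modular brain networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic modular brain networks: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynmodnet)
```

## The analysis in one paragraph

`dynmodnet` quantifies how the modular organization of cortical activity
reorganizes over the course of a short task trial, and how that
reorganization differs between experimental conditions. Band-limited ROI
time series (typically alpha-band, 8–13 Hz, source-localized EEG) are cut
into short sliding windows; within each window, phase-lagged coupling
between every pair of nodes is measured with the weighted phase lag index
(WPLI); the per-window connectivity matrices become the layers of a
weighted multilayer graph whose community structure is found by repeated
generalized Louvain maximization of multilayer modularity; and the
resulting partition ensembles are summarized as flexibility, integration,
recruitment and node-to-system density at the level of large-scale
functional systems (SMN, DMN, VN, ATN, TPN). Per-trial metric values from
two conditions are then compared with paired t statistics, Cohen's
$d_z$ effect sizes, Benjamini–Hochberg FDR control, Anderson–Darling
normality checks, and analytic post-hoc power.

## Models and estimators

### WPLI

For band-limited signals $x_i$, $x_j$ in a window, the per-sample
cross-spectrum of their analytic signals is $S_{ij}(t) = z_i(t)
\overline{z_j(t)}$, and

$$\mathrm{WPLI}_{ij} \;=\;
\frac{\left|\;\overline{\mathrm{Im}\,S_{ij}}\;\right|}
     {\overline{\left|\mathrm{Im}\,S_{ij}\right|}},$$

the bar denoting the within-window sample mean. Only the lagged
(imaginary) part of the cross-spectrum contributes, so zero-lag coupling
— notably volume conduction — is invisible by construction. When the
denominator vanishes (identical or exactly zero-lag signals) the index is
defined as 0: zero evidence of lagged interaction. A debiased squared
variant (`debias = TRUE`) is available; the plain estimator is the
default. The analytic signal is computed once per node over the full
analysis segment and then windowed, so per-window Hilbert edge transients
never arise.

### Multilayer modularity and generalized Louvain

The $L$ window-wise WPLI matrices $A^{(l)}$ form the intralayer weights
of a multilayer graph with ordinal interlayer coupling: node $i$ in layer
$l$ is coupled to itself in layers $l \pm 1$ with uniform weight
$\omega$. The quality of a node-by-layer partition $g$ is

$$Q = \frac{1}{2\mu} \sum_{ijlr}
 \left[ \left( A^{(l)}_{ij} - \gamma \frac{k^{(l)}_i k^{(l)}_j}{2m_l} \right)
 \delta_{lr} + \delta_{ij}\,\omega\,[\,|l-r|=1\,] \right]
 \delta(g_{il},\, g_{jr}),$$

with per-layer Newman–Girvan null at resolution $\gamma$ and $2\mu$ the
total edge weight including the interlayer couplings. The generalized
Louvain heuristic alternates randomized single-vertex moves with
community aggregation until no move improves $Q$; since the scan order is
random the algorithm is non-deterministic, so community detection is
repeated (500 times per trial at study scale; 50 repetitions already give
stable ensemble means at the problem sizes used here) and all metrics are
averaged over the repetitions. The move phase is implemented in C++ on
the dense modularity matrix; every repetition is seeded from one base
seed via a documented splitting scheme, making whole analyses exactly
reproducible.

### Module-allegiance metrics

From each repetition's labels: **flexibility** of a node is $F = S/T$,
the number of consecutive-window label changes over the number of windows
(maximum $(T-1)/T$; the alternative $T-1$ denominator is not used — the
$T$ convention keeps 12-window trials on the familiar $0\ldots 11/12$
scale). The **allegiance matrix** $P_{ij}$ is the fraction of
(repetition, layer) observations in which $i$ and $j$ share a module;
pooling over repetitions *and* layers uses all available observations (a
per-layer variant is available). **Recruitment** of a system is the mean
allegiance among its own nodes; **pairwise integration** between two
systems is the mean allegiance across them, and **overall integration**
averages the six pairwise values among SMN, DMN, VN and ATN. These are
raw co-occurrence probabilities — no permutation-null normalization is
applied by default, keeping the values interpretable as probabilities.
**Node-to-system density** is the mean WPLI weight from one node to a
target system across layers, independent of any partition.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| window length / overlap | 300 ms / 50 % | 12 layers for a 2 s trial at 500 Hz |
| band | 8–13 Hz | alpha; carrier band of the generator |
| $\gamma$ | 1 | intralayer resolution |
| $\omega$ | 0.25 | interlayer coupling (see below) |
| repetitions $R$ | 500 study scale, 50 desk scale | Louvain restarts per trial |
| FDR $\alpha$ | 0.05 | per-contrast family over systems or system pairs |

**Choice of $\omega$.** WPLI matrices have entries in $[0,1]$ and
modularity increments of order $0.1$–$0.3$; an interlayer coupling of 1
per adjacent-layer link then dominates every intralayer gain, labels
freeze across layers, and measured flexibility collapses to a small
noise floor with almost no sensitivity to genuine module switching. We
calibrated $\omega$ against the synthetic generator's ground truth
(planted versus detected per-trial flexibility): $\omega = 0.25$ roughly
maximizes the tracking correlation (≈ 0.67 at desk scale) while keeping
spurious switching moderate, and is the package default. Both $\gamma$
and $\omega$ are exposed everywhere, recorded in run outputs, and worth a
sensitivity check in any real analysis, since flexibility values are not
comparable across different $(\gamma, \omega)$.

## The synthetic generator

Real task EEG for this design is not redistributable, so the package
ships a generator that emulates the study conditions and — more
importantly — plants a known truth that the whole pipeline must recover.

Each trial draws a **module schedule**: window 1 is a balanced random
partition of the nodes into `n_modules`; at each later window every node
resamples its module uniformly with its system's switch probability
(resampling may return the current module, so with $K$ modules the
per-window change probability is $p\,(K-1)/K$). Planted flexibility is
$F = S/T$ applied to this schedule — an exact, closed-form target.

Signals follow a common-carrier model: each module owns one band-limited
Gaussian carrier (≈ 1 Hz linewidth) that persists for the whole trial,
and every node receives its current module's carrier at a fixed nonzero
per-node phase lag (magnitudes uniform on $[\pi/8,\, 3\pi/8]$,
alternating sign by node index; zero lag is rejected because WPLI is
blind to it — that blindness is a feature being exercised, not a bug),
plus independent Gaussian noise. Three design points deserve emphasis:

* **Modules persist; nodes migrate.** When a node switches modules it
  cross-fades (raised cosine, ≤ 20 ms) from its old to its new carrier;
  nothing else changes. Non-switching pairs therefore stay coherent
  through other nodes' switches, which is what makes planted flexibility
  recoverable at all.
* **Distinct carrier frequencies.** Module carriers get evenly spaced
  centre frequencies inside the band (± 0.15 Hz jitter, shuffled), the
  way distinct alpha generators have distinct peak frequencies. Two
  independent *equal-frequency* narrowband carriers hold an almost
  constant phase difference across a 300 ms window, which plain WPLI
  cannot tell apart from genuine coupling; distinct centre frequencies
  make cross-module phase differences rotate within every window,
  exactly the structure WPLI discriminates against.
* **Window-aligned segments.** Schedule changes take effect at the
  midpoints of window overlaps, so layer $w$'s WPLI is dominated by
  schedule column $w$.

Generator defaults (`n_modules = 2`, `switch_prob = 0.4`,
`noise_sd = 0.3`, coupling 1) were chosen once, by calibrating planted
effect recoverability at desk scale — the generator's stated purpose —
and give planted per-node flexibility ≈ 0.18, within the range
task-EEG dynamic-network studies report.

**What the generator does not emulate:** volume conduction and source
leakage (zero-lag mixing), 1/f background spectra, amplitude dynamics
and event-related desynchronization, inter-participant variability, and
artifacts. Passing the planted-recovery tests therefore shows the
pipeline is *correct and sensitive under its own model*, not that any
particular effect in real EEG would be detected with the same power.

## Signal conditioning

The optional front end reproduces a standard EEG cleanup: an order-5
Butterworth band-pass (0.3–50 Hz), a biquad notch at 60 Hz with
$Q = 30$, epoching (−1 to +2 s around events, with a selector for the
2 s analysis segment), and alpha-band selection. All filters are applied
forward–backward (zero phase), the EEGLAB-style convention, because WPLI
phase estimates must not inherit filter phase; the magnitude order is
doubled as a consequence. High-order IIR band-passes are numerically
fragile in direct form, so the Butterworth is realized as cascaded
second-order sections built from the closed-form analog prototype, with
nearest-zero pairing, and applied with steady-state initial conditions
plus odd-reflection padding — without these, a 0.3 Hz high-pass edge at
500 Hz (pole radius 0.9988) rings for seconds and can swamp short
records. A $Q=30$ notch has a 2 Hz rejection bandwidth per pass and
noticeable (≈ 10 %) attenuation within a few Hz of 60 Hz; with the
analysis band at 8–13 Hz this is immaterial, but users notching near
their band of interest should raise `q`. Independent-component artifact
rejection is deliberately out of scope; `as_roi_ts()` accepts externally
cleaned, source-localized epochs.

## Numerical conventions

* Sliding windows are 0-based half-open sample intervals; trailing
  samples that do not fill a window are dropped (`floor((n - w)/step) +
  1` windows).
* WPLI is defined as 0 when its denominator vanishes; amplitude scaling
  of either input leaves it unchanged to machine precision.
* Louvain move gains use a $10^{-12}$ improvement tolerance; labels are
  canonicalized to $1..K$ in order of first appearance, and all
  downstream metrics are invariant to label permutation.
* Degenerate inputs error early and loudly: flexibility needs $T \ge 2$,
  recruitment needs $\ge 2$ nodes in the system, paired tests need
  $n \ge 3$ and non-constant differences, percent change needs a nonzero
  baseline.
* Percent change between conditions with unequal trial counts is
  computed between per-condition means; per-trial pairing (by index) is
  used when counts match.

## Statistics

Condition contrasts use the classical two-tailed paired t on per-trial
values, $d_z = \bar d / s_d$ with the $n-1$ denominator, and
Benjamini–Hochberg FDR at $\alpha = 0.05$ applied per contrast across
the units tested (all systems, or all system pairs — one family per
contrast). Anderson–Darling (estimated-parameter case) checks normality
of the metric distributions. Post-hoc power uses the exact noncentral-t
two-tailed power at the observed $d_z$; an optional pre-aggregation step
averages repeated trials sharing a grouping value before pairing.
Pearson correlation with Fisher-z intervals relates per-trial effect
magnitudes to an ordinal experience code. Significance stars follow
\*\*\* $p<0.005$, \*\* $p<0.01$, \* $p<0.05$ on FDR-adjusted values.

## Desk-scale problem sizes

The shipped tests and the acceptance script run the full pipeline at a
reduced but structurally identical scale: 12 nodes (2 per system), 12
windows, 50 trials per condition, $R = 50$ repetitions, and exhaustive
modularity checks on graphs of up to 6 nodes × 2 layers, where global
optima can be enumerated. These sizes were chosen so every claim is
verified against an independent oracle (closed forms, brute-force
enumeration, Monte-Carlo simulation) in minutes on one CPU; study-scale
parameters (80 nodes, $R = 500$) are the documented defaults of the same
functions.

## Known limitations

* The bundled 80-node table is a constructed stand-in (AAL cortical
  names with a literature-typical system assignment), clearly labelled
  synthetic and fully replaceable; any real analysis should supply its
  own ROI-to-system table.
* Flexibility, integration and recruitment all depend on $(\gamma,
  \omega)$; absolute values should not be compared across parameter
  settings or window geometries.
* With 300 ms windows in a 5 Hz-wide band, each window contains very few
  independent phase observations, so single-layer WPLI estimates are
  intrinsically noisy; inference leans on the repetition ensemble and on
  trial counts, and adjacent layers share half their samples, which
  smooths genuine module switches over neighbouring windows.
* No consensus clustering, multiresolution sweeps, or directed
  connectivity; one connectivity metric (WPLI) in this version.
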