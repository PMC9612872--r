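---
title: "Quantifying cell migration with trackmsd: models, estimators, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell migration with trackmsd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trackmsd)
```

## The problem

In a gap-closure (scratch) assay, two cell monolayers separated by a defined
cell-free gap are imaged by time-lapse microscopy (typically every 15 min for
15 h, i.e. 61 frames) and individual cells are tracked, yielding per-cell
tables of (frame, x, y) positions. The question is how cells move: how fast,
how far, and above all *how directed* their motion is. trackmsd turns such
track tables into per-cell motility metrics, mean squared displacement (MSD)
curves, and an estimate of the anomalous-diffusion exponent that separates
random from persistent migration.

## Model and estimators

### Time-averaged and ensemble MSD

For one trajectory observed at frames $f_1 < f_2 < \dots$, the time-averaged
MSD at lag $\tau = k\,\Delta t$ is the mean of
$(x_j - x_i)^2 + (y_j - y_i)^2$ over **all** observed (overlapping) pairs
with $f_j - f_i = k$. Gaps in a track (cells lost for some frames) are kept
as gaps: pairs that were not observed contribute nothing, and nothing is
interpolated. The ensemble MSD of a line is the unweighted mean of the
per-cell curves, lag by lag, over the cells whose curve contains that lag —
the "average over $n$ cells" convention, which keeps long tracks from
dominating pooled pair counts.

### The exponent $\alpha$

Migration regimes are summarised by the power law
$\mathrm{MSD}(\tau) \sim \tau^{\alpha}$: $\alpha = 1$ is Brownian
(diffusive) motion, $\alpha < 1$ sub-diffusive, $\alpha > 1$ super-diffusive,
and $\alpha = 2$ ballistic (straight-line) motion. `fit_alpha()` estimates
$\alpha$ as the slope of an ordinary least-squares regression of
$\log \mathrm{MSD}$ on $\log \tau$ (natural logs; the slope is
base-invariant), with a 95% confidence interval
$\hat\alpha \pm t_{0.975,\,n-2}\,\mathrm{SE}$, exactly what `lm()` reports.
Lags with MSD $= 0$ have no defensible log value and are dropped with a
warning, never clamped.

`classify_regime()` reads the CI: Brownian if it contains 1, sub-diffusive
if it lies below 1, ballistic-like if it contains 2, super-diffusive
otherwise. `compare_groups()` implements the published decision rule for
comparing lines: a patient line differs from the controls (nominal
$P < 0.05$) when the mean of the control $\alpha$ estimates falls outside
that line's 95% CI; intervals are closed, so exact boundary equality counts
as overlap (conservative).

### Why there are two confidence intervals

The regression CI above is faithful to how such analyses are usually
published, and the pipeline reports it. It is, however, **not** a calibrated
95% interval for an ensemble exponent: all lags of an ensemble curve average
the same cells, so the per-lag values are strongly correlated and the whole
curve tilts coherently from sample to sample. In simulation (100-cell
Brownian ensembles, 61 frames), the nominal 95% regression CI covers the
true $\alpha = 1$ in only ~10–17% of replicate runs — an order of magnitude
too narrow — at every choice of fitted lag range.

`ensemble_alpha()` therefore offers a CI built by bootstrap resampling of
whole cells, the actual independent replication units. Its point estimate is
identical to the regression fit; its percentile interval is several times
wider and covers at ~90–95% in the same simulations. All regime-recovery
tests in the package (Brownian recovery, fractional-Brownian-motion
parameter recovery, the persistent-random-walk super-diffusive bound) use
the bootstrap interval; reproduction of published per-line intervals and the
group decision rule use the regression interval, as published.

### Motility metrics and the speed test

`cell_metrics()` reports mean speed (average of per-interval speeds, each
step divided by its *actual* elapsed time so frame gaps do not inflate
speed), net displacement (first to last position), path length, and
straightness (net/path, in [0, 1]). Line summaries are mean ± s.d. with the
sample (n−1) denominator; a single cell gets s.d. 0 by convention.

`compare_speeds()` provides the two-tailed paired t-test
($t = \bar d / (s_d/\sqrt n)$, $df = n - 1$) and Welch's unpaired test.
Cells from two different lines have no natural pairing, so the pipeline
defaults to Welch; if a paired test is requested it pairs cells by speed
rank, requires equal group sizes, and warns loudly. A zero-variance paired
difference is an error, not a silent $t = \infty$.

## The simulator: what it emulates, and what it does not

`simulate_tracks()` generates 61-frame, 15-min-interval trajectories (both
defaults changeable) under seven models:

| model | key parameters (units) | theoretical MSD |
|---|---|---|
| brownian | D (µm²/min) | $4D\tau$ |
| ballistic | v (µm/min) | $v^2\tau^2$ |
| prw | mean speed (µm/min), persistence P (min) | Fürth: ballistic for $\tau \ll P$, diffusive for $\tau \gg P$ |
| fbm | Hurst H, scale σ (µm/min^H) | $2\sigma^2\tau^{2H}$ |
| circular | radius r (µm), angular speed (rad/min) | bounded by $(2r)^2$ |
| back_and_forth | amplitude (µm), period (min) | bounded, oscillatory |
| mixture | component weights + configs | mixture of the above |

Numerical choices worth recording:

* **PRW** uses the exact joint Ornstein–Uhlenbeck transition for velocity
  *and* integrated position (Gillespie's update), not an Euler scheme, so
  the ballistic-to-diffusive crossover has no step-size bias. The stationary
  per-axis velocity s.d. is `speed / sqrt(pi/2)`, making the configured
  value the *mean scalar speed* (2-D Rayleigh).
* **fBm** is exact: per axis, a Cholesky factor of the covariance
  $\mathrm{cov}(t,s) = \tfrac{\sigma^2}{2}(t^{2H} + s^{2H} - |t-s|^{2H})$
  transforms i.i.d. normals. At the desk scale of 61 frames this is cheap
  and makes $\alpha = 2H$ recovery a true parameter-recovery test. A
  non-positive-definite covariance (degenerate/duplicated times) is a
  classed error advising a time-grid jitter.
* **Isotropy**: one independent process per axis; MSD adds over axes.
* **Determinism**: a config's seed makes output bitwise-reproducible, and
  simulation restores the caller's RNG state.

`make_study_like_panel()` builds a five-line fixture shaped like a typical
control-vs-patient comparison: three control lines as persistent random
walks with long persistence (ensemble $\alpha \approx 1.5{-}1.7$) and two
patient lines as mixtures of Brownian wanderers (weight 0.45), circular
movers (0.20), back-and-forth movers (0.20) and a minority of directed
cells (0.15), landing at $\alpha \approx 1.1{-}1.3$. The weights are
fixture choices — no published mixture proportions exist to estimate them
from — and the persistence times (140/160/200 min) were chosen once so the
control ensemble exponents land in the stated band.

What the simulator does **not** emulate: cell–cell interactions, contact
inhibition, proliferation or death during the assay, gap-closure front
dynamics, and tracking noise or mislinking. A green recovery test therefore
establishes that the estimators recover known exponents from clean
trajectories of the stated geometry — not that any particular biological
dataset was reproduced.

## Differential-expression triage

The transcriptome module is a deliberately small filter, not a DE model:
`filter_de()` keeps genes with $|\log_2 \mathrm{FC}| > 1$ and FDR-adjusted
$p < 0.05$ (both strict, matching ">" and "<" as conventionally printed);
`restrict_gene_set()` intersects with a curated migration panel;
`common_transcripts()` intersects survivor sets across lines. The
">1-fold difference" phrasing common in methods sections is ambiguous; the
package reads it as $|\log_2 \mathrm{FC}| > 1$ (i.e. >2-fold linear) —
a literal "any difference" reading would pass everything — and exposes the
threshold as a parameter. Gene identifiers are opaque case-sensitive
strings; alias resolution would need an external database and is out of
scope. `simulate_de_tables()` plants survivor counts $(m, n)$ with overlap
$k$ exactly, giving the triage a controllable end-to-end fixture.

## Pipeline and I/O conventions

`read_manual_tracking()` accepts ImageJ Manual-Tracking-style exports
(columns matched case-insensitively, locale-tolerant header normalisation,
pixels × pixel size → µm) and the package's own calibrated CSV with
`#key=value` metadata. Coordinates keep the image convention (y downward):
every statistic in the package is invariant to axis orientation. Time zero
is each trajectory's first observed frame. Duplicate (track, slice) rows
are an integrity error, never averaged away.

`run_pipeline()` chains load/simulate → length filter → metrics → ensemble
MSD → $\alpha$ fit → regime → group decision → speed test, tags any failure
with its stage and line id, and `write_run_report()` emits JSON plus
per-line CSV curves. Run configs for the CLI are JSON (no TOML parser in
the supported stack). Reports are deterministic given the config seed,
modulo the timestamp in the provenance block.

## Known limitations

* The regression CI under-covers for ensemble fits (see above); that is a
  property of the published method, reproduced deliberately, with the
  bootstrap interval as the calibrated alternative.
* $\alpha$ is fitted per line on the ensemble curve (one $\alpha$ per
  line); a per-cell $\alpha$ distribution can be computed by mapping
  `fit_alpha` over cells but is not the headline output.
* The default fit uses all available lags. Large-lag MSD values rest on few
  pairs and are noisy; `max_lag_fraction` exposes truncation, and the
  choice is recorded in every report.
* Rank-pairing unrelated cells for a paired t-test is statistically
  questionable; it exists for fidelity, warns when used, and Welch is the
  default.
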