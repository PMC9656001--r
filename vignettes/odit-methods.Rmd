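---
title: "Sequential kNN anomaly detection and localization: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequential kNN anomaly detection and localization: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(odit)
```

## The problem

A system is observed through a stream of $d$-dimensional measurements
$x_1, x_2, \dots$ At an unknown time $\tau$ the generating distribution
switches from a nominal $f_0$ to some anomalous $f_1 \neq f_0$, and the
anomaly persists. The goal of sequential (quickest) detection is to raise an
alarm at a stopping time $T$ as soon as possible after $\tau$ while keeping
alarms before $\tau$ rare: minimize the average detection delay
$E[(T-\tau)^+]$ subject to a false alarm constraint. When $f_0$ and $f_1$
are both known, the CUSUM recursion on the log-likelihood ratio,
$S_t = \max(0, S_{t-1} + \log f_1(x_t)/f_0(x_t))$, is the minimax-optimal
solution. In practice — multichannel physiological recordings, IoT traffic,
video features — neither distribution is known and $d$ is large, which is
the regime this package targets: only a training set of $N$ nominal
observations is assumed.

## The detector

**Training.** The nominal matrix is randomly split into a ranked set
$X_{N_1}$ (fraction `n1_frac`) and a reference set $X_{N_2}$. Each ranked
point $x_m$ gets a total kNN distance

$$L_m = \sum_{n=k-s+1}^{k} g_n(x_m)^\gamma,$$

where $g_n$ is the Euclidean distance to its $n$-th nearest neighbor in
$X_{N_2}$. The $K = \lfloor N_1 (1-\alpha)\rfloor$ points with smallest
$L_m$ estimate the minimum-volume set containing nominal mass $1-\alpha$;
the borderline value $L_{(K)}$ is the only quantity the test phase needs.
Inverse kNN distance behaves as a surrogate likelihood, which is what makes
the construction distribution-free.

**Testing.** Each arriving $x_t$ yields $L_t$ against the same reference
set and the anomaly evidence

$$D_t = d\,(\log L_t - \log L_{(K)}),$$

negative inside the estimated minimum-volume set and positive outside. The
detection statistic follows the CUSUM-like recursion
$\Delta_t = \max(\Delta_{t-1} + D_t,\, 0)$, $\Delta_0 = 0$, with an alarm at
$T = \min\{t : \Delta_t \ge h\}$. For $k=s=\gamma=1$ and a growing reference
set, $D_t$ converges in probability to the log-likelihood ratio against a
uniform alternative pinned at the density level of the borderline point, so
the procedure approaches CUSUM optimality under an uninformative anomaly
model; for $\gamma \neq 1$ the evidence is that log ratio scaled by
$\gamma$. The $d$ factor is applied literally for all $s$ and $\gamma$ even
though the convergence argument covers $s=\gamma=1$; it only rescales $h$,
and keeping it uniform preserves comparability across parameterizations.

**Localization.** After an alarm the onset is estimated as
$\hat\tau = \max\{t < T : \Delta_t = 0\}$ (0 if the statistic never touched
zero — the pre-stream sentinel). For each dimension $i$, contributions
$\delta^i_t = \sum_{n=k-s+1}^{k}(x_{t,i} - y_{n,i})^2$ over the summed
neighbors are collected for $t = \hat\tau+1, \dots, \hat\tau+S$ (possibly
past $T$ itself) and compared to the nominal training means $\mu_i$ by a
one-sided t-test at level $\beta$:
flag $i$ when $(\bar\delta_i - \mu_i)/(\eta_i/\sqrt S) \ge \theta$, with
$\theta$ the $(1-\beta)$ Student-t quantile on $S-1$ degrees of freedom.
Contributions always use the squared form: the additive decomposition
$\sum_i \delta^i_t = L_t$ holds exactly only for $\gamma = 2$, and the
per-dimension t-test needs additivity, so the squared form is used even
when detection runs with another $\gamma$. The $\mu_i$ are computed at fit
time from the ranked points against their own reference-set neighbors —
the only neighbor set consistent with the test-phase contributions.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 1 | neighbor depth; larger is more robust to nominal outliers, slower to react |
| `s` | 1 | how many of the top-k neighbors are summed (1 = k-th only) |
| `gamma` | 1 | distance exponent; emphasizes large distances when > 1 |
| `alpha` | 0.05 | minimum-volume-set level; secondary to `h` |
| `h` | — | detection threshold, the one knob that trades delay against false alarms; calibrate with `odit_calibrate()` |
| `n1_frac` | 0.3 | ranked-set fraction; the reference set should stay the larger part since it drives the accuracy of the distance-based likelihood surrogate |
| `standardize` | off | per-dimension z-scoring by training statistics. Off by default because Euclidean geometry is scale-sensitive and rescaling is itself a modeling choice; enable for heterogeneous units |
| `S` (localization) | 10 | post-onset window; small values react fastest, `S = 2` is the smallest valid |
| `beta` (localization) | 0.05 | per-dimension one-sided test level; no multiplicity correction, matching a per-dimension decision semantics |

## Numerical choices

* `log(0)` guard: $L_t$ is floored at $10^{-12}$ before the logarithm, so a
  test point duplicating a reference row yields large negative, not
  infinite, evidence.
* kNN ties break by reference row index; all randomized steps (partition,
  tree build, generators) are driven by explicit seeds, so runs are
  bit-reproducible.
* Degenerate training with $L_{(K)} = 0$ (at least $K$ duplicated points)
  is a fit-time error — the evidence would be undefined for every test
  point.
* Zero-variance contribution columns in localization flag a dimension iff
  its mean exceeds $\mu_i$ (reported as $\pm\infty$ t-statistics).
* The online state keeps its contribution history in a ring buffer (default
  cap $10^4$ rows, truncated from the oldest end) so unbounded nominal
  stretches cannot exhaust memory; the buffer is cleared whenever
  $\Delta_t = 0$ because localization never looks behind the last zero.
* Threshold calibration sweeps a 60-point logarithmic grid on
  $[10^{-2}, 10^3]$ and returns the smallest threshold whose empirical
  false-alarm frequency over nominal streams meets the target; an
  unattainable target returns the top of the grid with a warning.

## Approximate nearest neighbors

The exact backend scans the full reference set per query ($O(N_2 d)$). The
approximate backend builds a priority-search k-means tree: recursive
k-means with branching factor $C$ (farthest-point initialization, at most
`Imax` Lloyd iterations per node, empty clusters keep their centers,
unsplittable nodes become leaves), leaves holding at most `leaf_size`
points. A query descends best-first by centroid distance, pooling leaf
candidates until at least $B$ points have been examined, for
$O(B d \log N_2 / \log C)$ per query. Because the search scores a subset,
approximate distances can only over-estimate exact ones — approximate
evidence dominates exact evidence — and $B \ge N_2$ reproduces the exact
backend bitwise. When this backend is selected it is used in training too,
so borderline and test distances carry the same bias. Defaults $C = 100$,
$B = 1000$, `Imax` 10, `leaf_size` 32.

## What the simulations emulate — and what they do not

`gen_mean_change()` reproduces the change-in-mean study: i.i.d. standard
Gaussian nominal data (identity covariance — the shift is specified in
nominal standard deviations, which fixes only the scale, so independent
unit-variance dimensions are the natural completion), a $+3$-sd shift in a
random 10% of $d = 50$ dimensions at $\tau = 200$. `gen_corr_change()`
reproduces the change-in-correlation study: diagonal $\Sigma_0$ with
variances drawn log-uniformly on $[0.5, 2]$ (positive with moderate spread;
the study leaves them "randomly chosen"), and $\Sigma_1$ replacing a random
$10\times10$ block with a Wishart-derived correlation block rescaled so the
marginal variances are preserved exactly. The Wishart degrees of freedom
default to the block size — the smallest value giving an almost-surely
positive-definite sample, hence strong injected correlations.
`gen_surrogate_stream()` is a deliberately simple AR(1) multichannel
stand-in for biosignal onsets (variance and cross-channel coupling grow
after onset); it is labelled synthetic and is not a model of real EEG.

The correlation-change design is intrinsically hard for any density-based
detector: with variances preserved, the expected nominal log-likelihood of
post-change points is exactly unchanged
($\mathrm{tr}(\Sigma_0^{-1}\Sigma_1) = d$), so the evidence distribution
changes only in its tails and detection delays are far longer than for mean
shifts — the test suite therefore checks that post-change segments alarm at
a multiple of the calibrated nominal rate rather than demanding certain
detection in a short window.

These generators share none of the hard features of real recordings:
temporal dependence under the null (the mean-change design is i.i.d.),
nonstationary baselines, heterogeneous units, artifacts. Passing the
simulation suite therefore demonstrates correctness of the method under
its stated assumptions, not field performance.

Evaluation semantics: a trial's false alarm is a first alarm before $\tau$;
after a false alarm monitoring resumes (statistic reset) so the detection
rate counts alarms at $t \ge \tau$ within the horizon; the average
detection delay is the mean of $T - \tau$ over detected trials. The
per-trial definition is used because the run-length expectation in the
formal constraint is not measurable from finite trials.

## Study-replica choices

The replica of the mean-shift study (also run by `scripts/acceptance.R`)
uses $N = 5\times10^4$ training rows with $N_1 = 0.38N$, $k=s=\gamma=1$,
$\alpha = 0.05$, 50 trial streams of horizon 400 with $\tau = 200$, and
1000 nominal-only streams for threshold calibration (resolving empirical
false-alarm rates down to $10^{-3}$). These sizes were chosen as the
smallest giving stable estimates of the two reported quantities. For the
localization ROC the study does not state the post-onset window; we use
$S = 3$, the smallest window whose t statistic has a well-defined mean
(one degree of freedom — $S = 2$ — gives a Cauchy-like statistic), keeping
localization latency minimal. The pooled ROC sweeps the flagging threshold
over all observed t-statistics, augmented with the trivial endpoints.

The convergence property is checked in one dimension with test points
uniform on $[-6, 6]$: with $k = 1$ the evidence carries an irreducible
additive noise of variance $\pi^2/6$ (the log of an Exp(1) variable), so
the correlation with the log-likelihood ratio is only visible once the LLR
variance across test points dominates that floor; the chosen support is
the narrowest symmetric one that achieves it with margin. The same noise
floor is why the kNN density estimator is tested at $k = 100$ (its
consistency regime) rather than at $k = 1$, where the estimate is
unbiased only in a median sense and has unbounded mean absolute error.

## Worked example

```{r example, eval = FALSE}
set.seed(7)
train <- matrix(rnorm(20000 * 8), ncol = 8)        # nominal history
model <- odit_fit(train, odit_params(seed = 1))

nominal <- lapply(1:100, function(i) matrix(rnorm(200 * 8), ncol = 8))
cal <- odit_calibrate(model, nominal, target_far = 0.02)

stream <- rbind(matrix(rnorm(150 * 8), ncol = 8),
                sweep(matrix(rnorm(150 * 8), ncol = 8), 2,
                      c(3, 3, 0, 0, 0, 0, 0, 0), "+"))
det <- odit_detect(model, stream, h = cal$h)
det                                   # alarm shortly after t = 150
odit_localize(det, model, S = 10)     # flags dimensions 1 and 2
```

## Known limitations

* Euclidean geometry: without standardization, dimensions on large scales
  dominate the distances.
* The evidence scale grows with $d$, so thresholds are not comparable
  across dimensionalities; always calibrate on nominal data.
* The minimum-volume-set estimate, like all kNN constructions, degrades in
  very high dimensions relative to sample size; the reference set should be
  large (it, not the ranked set, controls the quality of the likelihood
  surrogate).
* Localization tests each dimension marginally; correlated anomalies
  spread contribution mass across the involved dimensions and single-sided
  testing ignores anomalously small contributions by design.
* The approximate backend trades delay for speed: over-estimated distances
  inflate evidence slightly, and the calibrated threshold absorbs the bias
  only when calibration uses the same backend.
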