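---
title: "Lead-lag analysis with oriented areas: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lead-lag analysis with oriented areas: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyclicity)
```

## The model

The package treats an n-channel recording as one trajectory
$X(t) = (x_1(t), \dots, x_n(t))$ and quantifies pairwise temporal precedence
with the oriented area

$$a_{kl} = \tfrac12 \int \big(x_k \,\dot x_l - x_l\, \dot x_k\big)\,dt,$$

the signed area enclosed by the parametric plot of the pair. Three properties
make it the right primitive for aperiodic signals such as infraslow BOLD
activity. It is invariant under monotone reparametrizations of the time axis,
so it needs no assumption of stationarity, a base frequency, or consistent
rhythm. It vanishes identically on proportional signals and on signals with
disjoint supports, so synchronous (e.g. bilaterally mirrored) channels and
unrelated channels both read as "no lead-lag". And it is signed:
$a_{kl} > 0$ is the heuristic signature of $x_k$ leading $x_l$.

On sampled data the curve is interpolated linearly, and the package evaluates
the integral with the left-endpoint shoelace sum
$\tfrac12\sum_i (x_i \Delta y_i - y_i \Delta x_i)$, which is *exact* for the
piecewise-linear curve — no quadrature rule is left open. If the continuous
signals are perturbed by terms with $C^1$ norms $C_k$, $C_l$ vanishing at
sample points spaced $\Delta$ apart, the area moves by at most
$2 C_k C_l \Delta$ (`discretization_error_bound()`), which is what justifies
the discretization and what the time-warp tests check against.

The skew-symmetric lead matrix $A = (a_{kl})$ has purely imaginary
eigenvalues $\pm i\lambda_s$. Under the chain-of-offsets model (COOM) —
every channel an amplitude-scaled, phase-shifted copy of one seed waveform,
$x_k(t) = a_k\,\varphi(\omega t - \alpha_k)$, the sensor-side description of
a traveling wave — the lead matrix is a sum of rank-2 terms, one per
harmonic of $\varphi$, with entries proportional to
$a_k a_l \sum_m m |c_m|^2 \sin(m(\alpha_l - \alpha_k))$. When one harmonic
dominates, $A$ is nearly rank 2, the ratio $|\lambda_1|/|\lambda_3|$ is
large, and the components of the leading eigenvector (the constellation) are
the images of $a_k e^{i\alpha_k}$ under one linear map of the plane — so
their cyclic order *is* the sweep order of the wave. The pipeline in
`cyclicity()` exploits exactly this: eigendecompose, orient, fit the
constellation ellipse, rank, read phases.

Time-resolved structure comes from the trajectory
$a_{kl}(t) = \tfrac12\int_0^t$: its persistent direction changes (sublevel
persistence, longest bars) are lead-lag reversals, and the summed length of
the 10 longest bars is the pair's burstiness.

## Parameters that matter

* `dt` (s) — sampling interval. Metadata only: no oriented-area computation
  uses it (that is the point of reparametrization invariance); it converts
  frames to seconds in reports. Default 0.72 s, the HCP repetition time.
* `pair_index` — which conjugate eigenvalue pair to analyze; 1 (default) is
  the dominant ripple. Conjugate pairs are counted once, so `pair_index = 2`
  is the third eigenvalue in the all-eigenvalues convention.
* `keep_top` (channels) — how many top-ranked channels enter the phase
  ordering; default 20 (24 is the common alternative). This is a knee-point
  style cutoff: channels not reached by the ripple cluster near the origin
  and their phases are noise.
* `p` (features) — reversal features kept per trajectory; default 10, with 5
  as the stricter choice. Larger `p` admits shorter-lived (noisier) direction
  changes.
* `n_bars` — bars summed by burstiness; default 10. The statistic is
  deliberately insensitive to this (8 vs 20 gives rank correlation > 0.99 on
  the simulated task population; checked by `run_experiment("bars-robustness")`).
* `signed_mode` — `"both"` (default) analyzes $f$ and $-f$ together so that
  both up-to-down and down-to-up role switches count; `"f"` restricts to
  minima of the trajectory itself.

## The normalization

Channels are centered and divided by the *square root* of their quadratic
variation $\sum_i (x_{i+1} - x_i)^2$, so every channel leaves with unit
quadratic variation — an energy normalization under which burstiness is
comparable across pairs and recordings. Dividing by the quadratic variation
itself is a defensible alternative reading and is available
(`normalize(rec, divisor = "qv")`); the two differ per channel only by a
positive scale and give identical orderings, ranks and reversal times up to
that scale. No detrending beyond centering is performed. A constant channel
has no energy to normalize and is rejected by name rather than repaired.

## What the simulator emulates — and what it does not

`coom_spec()`/`coom_series()` generate the chain-of-offsets model directly:
a seed waveform (Fourier coefficients, or a Gaussian bump for solitary
pulses), offsets $\alpha_k$, amplitudes, i.i.d. Gaussian frame noise with
SNR defined as (signal RMS / noise sd)². The study conditions used
throughout the tests and replication experiments are an infraslow wave
($\omega = 2\pi/100$ rad/s ≈ 0.01 Hz) observed for 864 s at 0.72 s per
frame — 1200 frames, the dimensions of an HCP resting run — with offsets
spread over $[0, 0.9\pi]$ so the constellation occupies a half-plane and the
zero-phase axis is well defined.

`wave_series()` reduces traveling-wave fields
$U(\xi, t) = a(\xi)\,u(\omega t - h(\xi))$ to the same model with
$\alpha_k = h(\xi_k)$ (offsets are stored in phase units of the waveform
argument; the reduction is tested as an exact equality). `ripple_train()`
emits solitary lagged pulses with rest between events; the lead matrix is
insensitive to the length of the calm intervals, which the tests verify with
grid-aligned event times so that resampling effects do not intrude.

`block_pair()` emulates task runs as a two-channel pair: channel 1 a train
of solitary Gaussian activity pulses (width 1.5 s, one per 5 s on average),
channel 2 the same train lagged by ±2 frames with the sign alternating
across design blocks. Pulse times are jittered uniformly by ±1 s per
recording: spontaneous events are not phase-locked to the task schedule
across subjects, and without jitter any common divisor of the pulse spacing
and the block length would imprint the same beat on every simulated pair —
an alignment artifact, not a property of the design. The social design
alternates the lead-lag sign at the 38-s segment interval over a full
1200-frame session. The motor run's published structure — 10 movement blocks
of 12 s, each preceded by a 3-s cue, plus three 15-s fixations — fixes 13
blocks but not their order; it is emulated as 13 contiguous 15-s blocks
(cue + movement = 15 s) of alternating sign, which reproduces the claim
actually tested: reversals concentrate at block onsets and offsets, and the
counted epochs equal the block count up to edge effects.

The simulator deliberately omits hemodynamic response convolution, 1/f and
physiological noise spectra, spatial correlation, and amplitude
nonstationarity. Passing tests therefore demonstrate that the *pipeline*
recovers planted lead-lag structure under realistic dimensions and noise
levels — not that real BOLD data satisfies the chain-of-offsets model. The
heterogeneous "population" used for the burstiness experiments varies lag
(1–4 frames), SNR (5–20) and pulse rate across pairs, because real ROI pairs
differ in coupling; with identical pairs the between-pair variance would be
pure seed noise and rank-based statistics would be meaningless.

## Numerical and algorithmic choices

* **Eigendecomposition** goes through the Hermitian matrix $iA$ and the
  symmetric eigensolver, so eigenvalues are exactly real in the rotated
  frame and magnitudes never acquire spurious real parts. Inputs are checked
  skew-symmetric to a relative $10^{-9}$.
* **Orientation of the constellation.** Eigenvectors come in conjugate
  (mirror-image) pairs. The tie is broken with the most confident
  leader-follower pair: for $(k^*, l^*) = \arg\max |a_{kl}|$, the signed
  angle from point $k^*$ to point $l^*$ must match the sign of $a_{k^*l^*}$.
  Reference pairs with an ill-defined angle (a component at the origin, or
  angle exactly 0 or $\pi$) are skipped for the next largest entry. The
  operation is deterministic and seed-free.
* **Ellipse fit.** The quadratic form is fitted by linear least squares on
  $q(z_i) = 1$ with design $(x_i^2, 2x_iy_i, y_i^2)$ — closed form, no
  iteration. The fitted form is origin-centered (the eigenvector scale is
  arbitrary, so the natural family of level sets is centered); if the
  minimizer is not positive definite (points collinear with the origin) its
  eigenvalues are clipped at $10^{-6}$ of the largest and the result is
  flagged, never silently used.
* **Phase ordering** rotates the kept points so their centroid lands on the
  positive real axis and orders by ascending argument in $(-\pi, \pi]$ —
  counterclockwise from the negative real axis, so the cut falls in the gap
  opposite the cluster. A centroid at the origin makes the rotation
  ill-defined and is an error, not a guess.
* **Persistence** uses union-find with path halving and the elder rule;
  value ties are resolved by the smaller time index being older, endpoints
  count as extrema when their single neighbor is larger/smaller. The
  implementation is checked feature-for-feature (values *and* indices)
  against an independent brute-force threshold-sweep oracle on a thousand
  random and tied sequences.
* **Reversal features** come from one merged list: finite features of the
  trajectory and of its negation, the `p` longest overall. This single-list
  convention is forced by the burstiness definition (the 10 longest bars of
  the trajectory, direction changes of either polarity included) and makes
  reversal events exactly the births and deaths of the kept features.
* **Epoch statistics.** Event stamps pooled across pairs are clustered by
  splitting sorted stamps at gaps exceeding 5 frames. For the pooled
  (multi-pair) spacing statistic, clusters supported by a single pair are
  discarded: pooling exists precisely to read the carpet's collective peaks,
  and an isolated one-pair stamp is indistinguishable from noise. (Any
  support threshold from 2 to 4 pairs gives the same epochs on the social
  simulation.) Per-recording epoch counts use all events of that recording's
  kept features.
* **Ties everywhere** (ranks, feature spans, reference pairs) break by
  channel label or earlier time index; all analysis operations are
  deterministic functions of their inputs.
* **The COOM closed form's constant.** Direct integration fixes the sign
  convention of the analytic lead matrix as $\sin(\alpha_l - \alpha_k)$ —
  positive entry when channel $k$'s offset is smaller, i.e. $k$ leads —
  with per-period constant $4\pi$ under the coefficient convention
  $\varphi(s) = \sum_m 2\,\mathrm{Re}(c_m e^{ims})$. Because both the sign
  and the constant depend on that normalization convention,
  `analytic_lead_matrix()` by default calibrates the single positive scalar
  against quadrature of one dense period and refuses a negative calibration;
  the uncalibrated closed form is available and agrees to $10^{-4}$.

## Problem sizes

The replication experiments run at desk scale: 50 recordings for the
reversal-spacing and epoch-count experiments, 100 seeded draws for order
recovery, 200 pairs per arm for the burstiness contrast and bar-count
robustness, all at 1200 frames (social/rest) or 271 frames (motor) and
n = 10 channels for the wave experiments. These sizes hold the full suite to
a few minutes while keeping the binomial/rank statistics well resolved.

## Known limitations

* The lead heuristic ($a_{kl} > 0$ means $k$ leads) is exact for shifted
  copies with small offsets; for offsets beyond half a period the sign wraps,
  as $\sin(\alpha_l - \alpha_k)$ does. Cyclic order is the invariant object,
  not a global linear order.
* The phase ordering needs a constellation concentrated away from the
  origin-symmetric configuration; offsets spread over a full circle make the
  centroid rotation degenerate (reported as an error).
* Ripples of comparable strength (close $|\lambda_1|, |\lambda_3|$) mix;
  only the dominance ratio warns about this. Analysis of lower pairs is
  supported but markedly less stable, as the ordering histograms show.
* Persistence-based reversal detection reports *when* direction changes
  persist, not *why*; it cannot distinguish task-locked reversals from any
  other exogenous switching with the same timing.
* The simulator's noise is white and Gaussian; heavy-tailed or temporally
  correlated noise will lower the effective SNR of every stage and is not
  modeled.
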