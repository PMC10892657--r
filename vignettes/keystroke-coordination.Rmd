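---
title: "Modelling coordinated middle/ring-finger keystrokes"
author: "ringcast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling coordinated middle/ring-finger keystrokes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ringcast)
```

## The scientific problem

When a pianist strikes keys with the middle and ring fingers together, the
two fingers do not move independently: shared tendons and neural drive make
the ring finger's motion strongly "enslaved" to its neighbour. ringcast
models this coordination as a regression problem. The middle finger's
metacarpophalangeal (MCP) joint state — rotation angle $\theta_1$, angular
velocity $\omega_1$ and angular acceleration $a_1$ — predicts the ring
finger's MCP rotation angle $\beta_1$ at the same instant. Two scopes are
supported:

* **individual**: a 3-input network fitted to one performer's recordings;
* **multi-individual**: a 6-input network that adds the subject covariates
  ring-finger length, middle-finger length, and years of piano training, so a
  single model transfers across performers.

Angles come from 3D joint-centre trajectories. With $P_0$ and $P_1$ the MCP
and PIP joint centres and $\hat z$ the vertical axis of the hand-fixed frame,

$$\theta_1 = \arccos\left(\hat z \cdot \frac{P_1 - P_0}{\lVert P_1 - P_0
\rVert}\right),$$

and $\omega_1 = d\theta_1/dt$, $a_1 = d\omega_1/dt$. The same construction on
the ring finger gives $\beta_1$.

## The model and its training

The predictor is a single-hidden-layer feedforward network with 13
hyperbolic-tangent ("tansig") hidden units and a linear ("purelin") output:

$$\hat\beta_1 = W_2 \tanh(W_1 x + b_1) + b_2 .$$

Inputs and the target are min–max scaled to $[-1, 1]$ with ranges captured on
the training split only; errors are always reported in denormalized degrees.
Training is full-batch Levenberg–Marquardt (LM) on the analytic Jacobian of
the residuals: each epoch solves $(J^\top J + \mu I)\,\delta = J^\top r$,
accepts the step (and divides the damping $\mu$ by 10) when the MSE drops,
and otherwise multiplies $\mu$ by 10 and retries. Training stops at the epoch
budget, when the MSE gradient falls below `grad_tol`, or when $\mu$ exceeds
`mu_max` (the natural LM convergence signal). The accepted-step loss history
is non-increasing by construction.

Toolbox descriptions of this network family often quote a learning rate and
a batch size alongside "Levenberg–Marquardt". Standard LM has neither — it is
a damped Gauss–Newton method and inherently full-batch — so ringcast
implements canonical LM as the default trainer and additionally exposes a
mini-batch gradient-descent trainer (`train_config(trainer = "sgd")`,
learning rate 0.01, batch size 32) for fidelity experiments against such
configurations. Whether the emulated workflow normalized its inputs is
likewise unknowable; normalization is the package default because the tanh
layer saturates otherwise, and it can be audited through the stored ranges.

### Metaheuristic weight initialization

Backpropagation networks are sensitive to their random initial weights. The
`"ga-bp"` and `"ssa-bp"` variants replace the uniform $[-0.5, 0.5]$ random
initialization with a search over the flattened 66- (individual) or
105-dimensional (multi) weight vector inside $[-3, 3]$ per coordinate, a
range that covers the useful tanh input region for normalized features:

* **GA**: real-coded genetic algorithm — population 50, 100 generations,
  arithmetic crossover with probability 0.6, per-gene Gaussian mutation
  (probability 0.2, SD = 0.1 × range), tournament-2 selection, 1-elitism.
* **SSA**: sparrow search algorithm — population 50, 100 iterations,
  explorer ratio 0.7, vigilante ratio 0.2. Constants the configuration
  tables leave unstated use canonical values: safety threshold 0.8, alarm
  value drawn uniformly per iteration, per-update uniform $\alpha$, and
  dispersal of the worse-ranked half of the followers.

The fitness of a candidate vector is the raw forward-pass MSE on the
training features — no gradient steps happen inside the fitness call. This is
the standard GA-BP/SSA-BP arrangement and the only reading compatible with a
50 × 100 evaluation budget; the searched optimum then seeds one LM run.

## The synthetic cohort generator

The human recordings the model family was designed for are not publicly
available, so `simulate_cohort()` generates datasets with the statistical
structure the analysis assumes. Defaults reproduce the measurement protocol:
12 subjects, 30 sets of 25 metronome-paced keystrokes each (9000 cycles; the
single-subject protocol uses 100 sets = 2500 cycles), one cycle every
0.75 s. Per cycle the middle MCP angle follows a smooth flexion pulse

$$\theta_1(t) = \theta_{\mathrm{rest}} + A \sin^2(\pi t / T),$$

with rest angle 10°, amplitude 40° — a shape chosen to mimic measured
keystroke curves (single smooth peak per press, $C^2$ at cycle boundaries);
the true waveform of any given pianist is unknown and both values are
configurable. The ring finger's ground-truth angle is produced by an
injected coupling law

$$\beta_1(t) = c + g(\mathrm{subject})\,\theta_1(t - \ell), \qquad
g = g_0 + g_L (L_{\mathrm{ring}} - L_{\mathrm{mid}}) + g_T\,Y,$$

with defaults $g_0 = 0.8$, $g_L = 0.01/\mathrm{mm}$,
$g_T = 0.005/\mathrm{yr}$, lag $\ell = 20$ ms, offset $c = 2°$. The linear
form is deliberate: it lies inside the 13-unit network's function class, so
parameter recovery is a meaningful end-to-end check (a tanh-saturating
variant is available for robustness experiments). The gain stays well inside
$(0, 2)$ for the sampled population — finger lengths are truncated normals
with means 84.4/79.1 mm and SDs 4.3/4.5 mm, training years uniform on
[5, 15] ("several years" of training, with no distribution to copy).

Joint centres are then placed by planar forward kinematics in the vertical
finger plane, with phalanx lengths in the fixed anthropometric proportions
0.46/0.31/0.23 of total finger length; PIP/DIP angles follow the MCP
excursion with ratios 0.5/0.3 (they shape the curl but do not enter the
model). Sensor noise has two configurable components applied in this order:
Gaussian angle-domain noise (SD 2° by default) on every generating angle
before forward kinematics, then Gaussian position noise (SD 0.5 mm) on every
coordinate. The sampling rate defaults to 100 Hz (hand-tracking cameras of
this class run 50–120 Hz).

What the generator does *not* emulate: tempo drift and missed beats (cycles
are exactly metronome-locked), out-of-plane MCP abduction, soft-tissue
artefacts, marker occlusion and dropout, serially correlated sensor noise,
and any nonlinearity or hysteresis of the true inter-finger coupling beyond
the optional tanh variant. Passing tests therefore demonstrate that the
pipeline recovers a known coupling under realistic amplitudes and noise —
not that the fitted networks describe human physiology.

## Numerical choices

* **Derivatives**: second-order central differences, one-sided second-order
  stencils at the series ends, uniform sampling enforced at 1e-9 relative
  tolerance. For a 40°-amplitude, 0.75 s-period sinusoid at 100 Hz the
  interior error stays below 0.5 °/s; the end stencils carry the larger
  one-sided truncation constant ($A c^3 h^2 / 3 \approx 0.8$ °/s).
* **Smoothing**: optional centred moving average before differentiation
  (window 1 = off; 5 recommended and used by the experiment pipeline —
  cutting angle noise by about $\sqrt 5$ matters mostly for the
  twice-differentiated acceleration channel).
* **Angle safety**: the arccos argument is clamped to $[-1, 1]$; segments
  shorter than 1e-6 mm raise a degenerate-segment error listing frames.
* **LM solves**: Cholesky on $J^\top J + \mu I$ with an SVD pseudo-inverse
  fallback for ill-conditioned systems.
* **MAPE guard**: frames with $|\beta_1| < 1°$ are excluded from MAPE and
  the exclusion count is reported in every `eval_report`; with the default
  offset and gain the true angle never approaches 0°, so the guard is
  normally idle.
* **Cycle segmentation** is metronome-based (fixed windows of
  `round(T · fs)` frames anchored at $t = 0$), not signal-based — synthetic
  recordings are phase-locked by construction.
* **Problem sizes**: features are built for every frame, but the trainer and
  the metaheuristic fitness see at most 25 000 training rows, taken as a
  deterministic stride subsample (`max_train_frames`). At 100 Hz the
  study-protocol training splits contain 150 000–619 000 frames of a
  heavily oversampled 1.3 Hz movement, so the subsample loses essentially
  no information; held-out evaluation always uses every test frame.
* **Seed discipline**: every stage seed is `derive_seed(master, stage)`, so
  experiments are bit-reproducible and adding a model variant never changes
  another variant's draw.

## What the end-to-end experiments show

With the default cohort conditions, the individual-scope BP model and the
multi-scope SSA-BP model both reach held-out RMSEs around 1.2–1.4°, well
inside the sub-5° regime reported for this model family — the network
recovers the injected coupling down to the sensor-noise floor, which
window-5 smoothing places just above 1°.

One qualitative claim deserves an honest caveat. On real recordings the
metaheuristic variants outperform plain BP because LM from a random start
occasionally converges to a poor local minimum. The synthetic default
coupling is linear and fully representable, so LM usually equalizes all
three variants at the noise floor; plain BP still shows exactly the expected
instability (roughly one seed in three lands near 4.7° instead of 1.25° on
the default multi cohort), while SSA-BP never does. The *mean* held-out RMSE
therefore reproduces the published ordering (BP ≈ 2.4° vs SSA-BP ≈ 1.3° over
three seeds), but a *median* over a few seeds discards BP's failures and can
rank plain BP marginally (≈ 0.02°) ahead. This is a property of the
deliberately easy synthetic target, not of the optimizers; the sphere
benchmarks and the training-MSE comparisons in the test suite show both
metaheuristics doing their job.

## Known limitations

* The coupling law is an invention: real inter-finger coordination is
  nonlinear, velocity-dependent and person-specific in ways three covariates
  cannot capture.
* Predicted angular velocity, where needed, is obtained by differentiating
  the predicted $\beta_1$ series; the model itself outputs the angle only.
* The trajectory CSV dialect is this package's own interchange format, not a
  hand-tracker vendor format.
* No regularization or early-stopping validation split is implemented
  (matching the emulated workflow); multi-scope generalization relies on the
  training cohort spanning the covariate range, and degrades sharply when
  fewer than ~4 subjects are available for training.
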