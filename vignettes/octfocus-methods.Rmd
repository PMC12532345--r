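---
title: "Stabilizing OCT retinal acquisition: the model behind octfocus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilizing OCT retinal acquisition: the model behind octfocus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(octfocus)
```

## The problem

During in vivo OCT imaging of the retina, two axial disturbances degrade
image stability: rigid axial motion of the head, which shifts the retinal
cross-section inside the imaging window, and accommodative fluctuation of
the eye's lens, which moves the focal plane relative to the retinal layers.
Motion displaces the image; defocus redistributes intensity between the
inner and the outer retinal bands, because the confocal collection
efficiency falls off away from the focal plane. At high numerical aperture
both effects are strong enough to defeat naive frame-to-frame registration:
a frame focused on the inner retina and a frame focused on the outer retina
have genuinely different axial intensity profiles, and correlation-style
alignment can lock the wrong pair of bands together.

`octfocus` implements a two-stage, non-iterative correction loop that runs
on B-scan intensity alone: integer-pixel axial registration on masked edge
maps, followed by a single-step deep deterministic policy gradient (DDPG)
agent that maps a pair of averaged A-scan profiles to a defocus correction
in diopters. Everything — training data, rewards, and evaluation — comes
from a physics simulator of the defocused A-scan, so the whole loop is
trainable and testable with no hardware.

## The forward model

A rendered A-scan is

I(z; zf) = R(z − s) · T(z − s − zf) · A(z − s) · H(z) + N(z),

where

* `R(z)` is the axial reflectivity of the retina phantom: two Gaussian
  bands (a shallower "inner retina" and a deeper, brighter "outer retina")
  over a low background, or a single-band "foveal" variant;
* `s` is the rigid axial shift of the retina (µm);
* `T(u) = 1 / ((u / 2 n zR_eff)² + 1)` is the confocal point spread
  function of a Gaussian beam with diffuse reflection, with
  `zR_eff = M² · zR` inflating the Rayleigh length by a beam quality factor
  to emulate residual ocular aberration. `T` is 1 at focus and reaches half
  maximum at `|u| = 2 n zR_eff`;
* `A(u) = μ_B · exp(−2 μ_OCT u)` is single-scattering attenuation,
  evaluated in tissue coordinates so it travels with the retina;
* `H(z) = sinc²(π z / 2 z_RD) · exp(−π² ω² / (8 ln 2) · (z / z_RD)²)` is
  the spectral-domain sensitivity roll-off with maximum ranging depth
  `z_RD = λ₀² / 4Δλ` and `ω = δλ/Δλ`;
* `N(z)` is additive zero-mean Gaussian noise with a nonnegativity clamp —
  the simplest stationary choice consistent with an additive noise floor.
  Speckle statistics are deliberately not modeled; the package targets the
  *relative axial intensity distribution*, not full-wave realism, and omits
  all depth-independent intensity factors.

A coordinate convention deserves emphasis: the reflectivity, the attenuation
*and the focal plane* all travel with the retina under rigid motion (`s`
appears in `T`'s argument above), while only the spectrometer roll-off
`H(z)` is anchored to the image. This is the physical situation — head
motion displaces the whole eye, retina and ocular optics together, so the
OCT path length (hence the image position) changes but the focus-to-retina
relationship does not. The alternative convention, a focal plane fixed in
image coordinates, is subtly wrong and catastrophically so for training:
under it the correction that best restores the reference's intensity
distribution is not the applied defocus but the applied defocus minus the
motion expressed in diopters (up to ±0.54 D for ±200 µm of motion), so the
reward and the evaluation label disagree and no agent can reach
millidiopter accuracy even in principle. `FocusState` therefore expresses
`focal_depth_zf` in retina-anchored coordinates
(`reference_zf + defocus · diopter_to_depth`), and the renderer adds the
axial shift when evaluating the CPSF.

Default parameters describe an 810 nm system at NA ≈ 0.1 in the eye:
`zR = 26 µm`, `M² = 1.5`, `n = 1.38`, spectrometer `Δλ = 0.049 nm`,
`δλ = 0.06 nm` (so `z_RD ≈ 3.3 mm`), `μ_OCT = 0.001 /µm`, and 384 depth
pixels at 3 µm/pixel. The 3 µm pitch is a deliberate choice: integer-pixel
registration then has a quantization-limited residual standard deviation of
`3/√12 ≈ 0.87 µm`. Lens diopters convert to focal-depth shift at
370 µm/D, the reduced-eye value (f²/n with f = 22.2 mm, n = 1.336); only
the linearity of this conversion matters to the agent.

The key *signal* in this model is that the ratio of inner-band to
outer-band peak intensity is monotone in focal depth — sweeping the focus
from the inner to the outer band moves collection efficiency from one band
to the other. The simulator test-suite asserts this monotonicity; it is
what the agent learns to invert.

## Motion and accommodation trajectories

Session disturbances follow Ornstein–Uhlenbeck processes: mean-reverting,
continuous random fluctuations. We use the exact AR(1) discretization

x_{t+1} = μ + e^{−θΔt}(x_t − μ) + σ √(1 − e^{−2θΔt}) ε_t,  x_0 ~ N(μ, σ²),

initialized from the stationary law, so the configured σ *is* the
stationary standard deviation regardless of `θΔt` (a Euler–Maruyama step
would only approximate it). Defaults: θ = 5 /s and Δt = 40 ms — a ~0.2 s
correlation time, plausible for head micro-motion and accommodative
micro-fluctuation; session amplitudes of σ = 53.2 µm (motion) and 0.27 D
(defocus) are the conditions under which the closed loop is evaluated.

## Stage 1: focus-robust axial registration

Both frames are reduced to average A-scans, then to *edge detection maps*
(EDM): Gaussian smoothing (σ = 3 px), first derivative, absolute value,
normalization to max 1. Band edges stay put as focus changes even though
band intensities do not, so EDMs are far more focus-robust than raw
profiles. They still inherit the two-band ambiguity — each band contributes
an edge cluster — so a peak detector (prominence ≥ 0.3 of the maximum,
clusters separated by ≥ 40 px) finds the band clusters, and when at least
two high-intensity clusters are present the map is zeroed from the window
start through the valley between the two strongest clusters, leaving only
outer-retina edges. With fewer than two clusters (foveal profiles) no mask
is applied. After masking the map is renormalized to max 1.

Two robustness details matter in practice. First, the detection thresholds
must admit a band whose edges have been dimmed by the worst-case defocus of
the training range: at ±0.85 D from mid-retina the dimmer band's strongest
edge falls to roughly 0.15 of the profile maximum, so the defaults
(prominence ≥ 0.1 of max, high-intensity threshold 0.12) sit just below
that physical floor while remaining far above the noise of a 64-column
averaged A-scan. Second, masking is applied only when *both* profiles of a
pair expose two high-intensity clusters: masking one side and not the other
would compare an outer-only map against a two-band map and reintroduce
exactly the ambiguity the mask exists to remove. With stricter thresholds
and independent per-profile masking, cross-focus pairs misregister grossly
(tens of pixels) on a substantial fraction of frames; with these two rules
the search is sub-pixel-consistent across the full training distribution.

Registration is then an exhaustive search over integer displacements
p ∈ [−Np, +Np] maximizing the negative root-mean-square difference between
the two masked EDMs, comparing only the overlap and normalizing by its
length (this avoids padding artifacts biasing large shifts). Ties resolve
to the smallest |p| — a minimal-motion prior. `Np` defaults to 200 µm at
the pixel pitch (67 px at 3 µm), covering the simulated motion range. The
sign convention is fixed: positive `shift_pixels` means the target sits
deeper than the reference, and the correction to apply is its negation.
Sub-pixel registration is explicitly out of scope; the residual is
quantization-limited by design.

## Stage 2: single-step DDPG focus correction

**Observation.** Each B-scan is divided laterally into M = 4 sub-regions;
each sub-region is averaged into an A-scan and Gaussian-smoothed along
depth (σ = 2 px, reflect boundaries) — enough channels to capture lateral
structure variation, few enough for a lightweight 1-D CNN. The observation
stacks the reference and the motion-corrected target channels as
`[ref_1..ref_M, tgt_1..tgt_M]`. Each `(ref_m, tgt_m)` pair is normalized
*jointly* — subtract the mean and divide by the (population) standard
deviation of the concatenation. Joint normalization is load-bearing:
per-array standardization would erase the relative-brightness contrast
between reference and target, which *is* the defocus signal.

**Reward.** After a candidate correction is applied in simulation, the
reward is the negative minimum Euclidean distance between the jointly
normalized average A-scans over a sliding window of integer shifts
b ∈ [−Nb, +Nb] (Nb = 15 px). The window forgives residual axial motion up
to Nb pixels, so the reward grades focus similarity rather than
registration accuracy.

**Networks.** The actor is a 1-D CNN: two blocks of conv(kernel 3) →
ReLU → max-pool(2) growing 2M → 16 → 32 channels, flattened into fully
connected layers of 128, 64, 32 ReLU units and one tanh output in (−1, 1);
with `action_scale = 1 D`, the output covers ±1 D, containing both the
±0.6 D training range and the ±0.5 D evaluation sweeps. The critic owns an
*independent* copy of the actor's conv/FC trunk that compresses the
observation to a single value; that value is concatenated with the action
and fed through a deep feed-forward stack of 500, 1000, 1000, 1000, 1000,
500, 200 ReLU units to a linear reward estimate. Sharing the trunk with
the live actor would entangle the two losses, so the critic's copy is
trained by the critic loss only.

Two initialization choices are load-bearing, and both were found the hard
way (a collapsed, observation-independent embedding):

* the critic trunk's single-value output is *linear* with ordinary init —
  the actor-style near-zero tanh output would start deep in saturation
  (ReLU activations give the pre-activation a large fixed offset) and be
  pinned at ±1, where the tanh gradient is exactly zero, within a handful
  of coherent critic updates;
* dense layers use Glorot (fan-average) initialization. Fan-in-only
  scaling hands the critic head's first layer (2 inputs, 500 outputs)
  unit-variance weights, which amplify the backward pass ~250× into the
  embedding and action inputs and reduce both the trunk gradient and the
  actor's ∂Q/∂a to noise.

**Training loop.** Episodes are single-step: reference and target frames
are drawn (defocus ~ U(−0.6, 0.6) D, motion ~ U(−200, 200) µm, a shared
initial placement within ±100 µm, reference focus uniform over a 0.5 D
range about the mid-retina focus), motion is corrected first, the actor
acts, and the immediate reward is computed from a re-rendered frame.
Because the return *is* the immediate reward, the critic target needs no
bootstrapping and no discount; target networks are maintained with Polyak
averaging (τ = 0.005) purely as a stabilizer, and the critic regresses the
reward directly. Several exploration tricks exploit the single-step
structure:

* per episode, `n_noise_profiles = 6` Gaussian perturbations of the actor's
  action are each applied and rewarded, yielding six transitions from one
  observation — cheap local curvature information for the critic (episodes
  are far cheaper than gradient updates here, so the environment is
  sampled generously);
* the first 60 episodes use uniform random actions over (−1, 1), so the
  critic sees the whole action range before the actor starts climbing it,
  followed by 300 critic-only regression updates on that warmup buffer
  before the first actor update — the actor then ascends an informative
  landscape from the start;
* exploration noise anneals linearly from σ = 0.3 to 0.02 action units
  over the first 80 % of training.

The networks are implemented in the package itself (batched base-R matrix
algebra over BLAS, with small C kernels for im2col, pooling and the
fused in-place Adam/Polyak updates); no external NN framework is used.
Gradient correctness is pinned by finite-difference tests. Adam learning
rates are 3e-4 (actor) and 1e-3 (critic), decayed linearly to 20% over the
run to steady the end-of-training policy, with minibatch 32, one update
per environment step, and TD3-style delayed actor updates (every second
critic update) — desk-scale choices for a single-CPU training run chosen
so the full training criterion can run inside a test suite. Divergence
(non-finite loss or action) aborts with diagnostics.

## Fast fine-tuning via A-scan focus interpolation

Adapting the agent to a new retinal structure does not require full
retraining. A sparse *focus sweep* — one registered, channel-reduced frame
per focus value, e.g. 0.1 D knots over (−0.8, 0.8) D — is interpolated
per depth pixel along the focus axis (linear by default; cubic splines
optionally; linear is monotone-safe and exact at knots) into a dense
focus → A-scan map. The DDPG loop then runs against map lookups instead of
fresh renders: an episode samples a reference focus and a defocus, looks up
both channel sets, rolls the target by a small random residual shift (±2 px)
to preserve the reward's motion tolerance, and rewards corrections by map
lookup. Non-uniform knot spacing is supported (denser sampling where the
focal plane transits between bands is the natural refinement). At 0.1 D
knot spacing, interpolated channels match directly rendered ones to well
under 5 % relative RMS, which is the fidelity the package's tests enforce.

## Closed-loop sessions and read-outs

`run_session()` renders 100 frames (4 s at 40 ms) under OU motion and
defocus, corrects each frame independently — registration first, then the
agent — and records applied/corrected/residual motion and defocus plus the
reward per frame. The first frame is the reference by default (any frame
or an external file can be designated instead — the reference is the
user's "prompt" for where the retina should sit and be focused).
`session_metrics()` reports sample standard deviations (n−1): applied
motion sd ≈ 53 µm should collapse to ≈ 0.87 µm (the 3 µm quantization
floor), applied defocus sd ≈ 0.27 D to the millidiopter level for a
converged agent. `kymograph()` collapses a stack to a depth × time image:
motion-only correction leaves visible intensity redistribution over time,
full correction leaves a near-uniform band pattern. The ordering matters —
correcting focus on unregistered frames (available as
`order = "focus_first"` for ablation) degrades the defocus prediction,
which is why motion correction runs first.

## Numerical choices and degenerate inputs

* Sub-pixel motion is rendered by linear interpolation of the reflectivity;
  registration is integer-pixel, so residuals are quantization-limited.
* Shifted-out samples are filled with the (attenuated) background level,
  avoiding spurious edges at the window borders.
* A constant A-scan has a zero EDM and is flagged degenerate; frames where
  both edge maps are degenerate raise an un-registrable error, which
  sessions log and skip rather than abort.
* Joint normalization rejects constant pairs (zero joint sd).
* Argmax ties in the registration metric resolve to the smallest |shift|.
* All stochastic entry points take explicit seeds; identical seeds give
  bit-identical renders, trajectories, and training runs.

## What the simulator does and does not show

The phantom reproduces the *structure* that the method exploits — two
bright bands whose relative intensity shifts with focal depth, band-edge
geometry stable under focus change, realistic attenuation and roll-off
envelopes — and the disturbance statistics of a fixated human subject. It
does not reproduce speckle, vascular shadows, pathology, lateral structure
within a B-scan beyond smooth gain variation, or full-wave diffraction.
Passing the package's tests therefore demonstrates that the pipeline
recovers motion and focus *under the stated physics*, not that it will do
so on any particular clinical scanner; the focus-map fine-tuning stage
exists precisely because real retinas differ from any phantom. Training
problem sizes in the tests (1200 episodes, 100-frame sessions, 50-episode
transfer evaluations) are desk-scale choices documented above.

## Known limitations

* Integer-pixel registration: ±0.5 px systematic floor, and strong
  asymmetric defocus between the frames can shift apparent band edges by
  1 px occasionally (the CPSF tilts band profiles slightly).
* The critic's single-value observation bottleneck makes representation
  learning the slowest part of training; budgets below ~1000 episodes
  leave the policy near its no-skill baseline (0.3 D).
* Desk-scale convergence: at the default budget (3000 episodes, roughly
  ten minutes on one CPU) the agent reaches a held-out mean absolute focus
  error of about 0.06–0.09 D — an order of magnitude above the no-skill
  baseline's 0.3 D, but not millidiopter-class. The error is 0.03–0.05 D
  through most of the ±0.45 D range and degrades sharply at the extreme
  negative end of the training range, where both bands sit far from focus
  and the band-ratio signal physically flattens. A supervised-regression
  ceiling experiment with the same actor architecture and comparable
  compute plateaus near 0.026 D, so millidiopter accuracy under these
  conditions requires substantially more training compute and/or a
  reflectivity profile richer than the minimal two-band phantom.
* The diopter↔depth conversion is treated as linear and subject-independent.
* No lateral tracking, no blink handling, no hardware lens driver — the
  package emits diopter commands, it does not execute them.
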