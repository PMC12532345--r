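# octfocus

Axial motion and defocus stabilization for OCT retinal B-scan acquisition,
with no hardware in the loop.

Real-time OCT imaging of the human retina is destabilized by two axial
disturbances: rigid head motion, which shifts the retinal cross-section
inside the imaging window, and accommodative micro-fluctuation, which moves
the focal plane between the retinal layers and redistributes intensity
between the inner and outer retinal bands. `octfocus` implements a
two-stage correction loop driven by B-scan intensity alone, plus the
physics simulator needed to train and validate it entirely in silico:

1. **Axial registration** — frames are reduced to average A-scans, then to
   edge detection maps (EDM: Gaussian smoothing, first derivative, absolute
   value, max-1 normalization). Peak clusters locate the retinal bands and
   the inner-retina edges are masked out; the axial shift is the integer
   displacement `p ∈ [−Np, Np]` maximizing the negative Euclidean distance
   `R_m = −√(1/N · Σ (E_r(z) − E_t(z−p))²)` between the masked maps.
   Masking removes the dual-peak ambiguity that makes raw-intensity
   correlation lock the wrong bands together when the two frames are
   focused on different layers.
2. **Defocus correction** — a single-step deep deterministic policy
   gradient (DDPG) agent maps the pair of (registered) multi-channel
   averaged A-scans to a focus correction in diopters. The actor is a
   lightweight 1-D CNN (two conv/max-pool blocks, 16→32 channels, FC
   128-64-32, tanh output); the critic compresses the observation to one
   value through its own copy of that architecture and regresses the
   immediate reward `R_f = −min_b ED(A_rⁿ(z), A_tⁿ(z−b))`, a
   sliding-window negative Euclidean distance between jointly normalized
   average A-scans that forgives residual axial motion up to `N_b` pixels.
3. **Simulator** — defocused A-scans follow
   `I(z; z_f) = R(z) T(z−z_f) A(z) H(z) + N(z)`: a two-band retina
   reflectivity phantom weighted by the confocal point spread function
   `T(u) = 1/((u/2nz_R,eff)² + 1)`, exponential tissue attenuation, and
   spectral-domain sensitivity roll-off; session disturbances follow
   Ornstein–Uhlenbeck processes. A focus-sweep interpolation module builds
   a dense focus→A-scan map from ~20 sparse frames for fast fine-tuning on
   a new retinal structure.

The neural networks, backprop and Adam are implemented inside the package
(base-R matrix algebra over BLAS with small C kernels); there is no
external deep-learning dependency.

## Worked example

```r
library(octfocus)

params  <- oct_params()        # 810 nm, NA ~0.1, 3 um axial pixels
phantom <- make_phantom()      # two-band retina reflectivity profile

## train the focus-correction agent in the simulator (~10 min on 1 CPU)
agent <- train_focus_agent(phantom, params,
                           agent_config(rng_seed = 1L), verbose = TRUE)

## held-out accuracy on fresh episodes from the training distribution
ev <- evaluate_agent(agent, n_episodes = 100, rng_seed = 18)
ev$mean_abs_error
#> [1] 0.04894705

## closed-loop correction session: 100 frames, 4 s, OU disturbances
ses <- run_session(agent,
                   ou_motion  = ou_params(stationary_sigma = 53.2),
                   ou_defocus = ou_params(stationary_sigma = 0.27),
                   n_frames = 100, rng_seed = 42)
print(ses)
#> Simulated correction session (100 frames, motion_first)
#>   axial motion: applied sd 56.2 um -> residual sd 1.16 um
#>   defocus:      applied sd 0.230 D -> residual sd 0.0143 D
```

The applied motion (sd ≈ 53 µm) collapses essentially to the
integer-pixel quantization floor (3/√12 ≈ 0.87 µm at 3 µm pixels, plus a
small defocus-dependent apparent-edge shift): a ~50× suppression. The
applied accommodative fluctuation (sd ≈ 0.27 D) is reduced ~16× to the
hundredth-of-a-diopter level, the agent's single-step prediction accuracy
at this desk-scale training budget (see the methods vignette for the
convergence analysis). `kymograph(ses$corrected_stack)` renders the
depth-vs-time view of the stabilized stack; `session_metrics(ses)` returns
the summary statistics programmatically, and `write_trace()` exports the
per-frame trace as CSV.

To adapt a trained agent to a new retinal structure from a sparse focus
sweep (the fast path that replaces full retraining):

```r
sweep <- acquire_sweep(sweep_source_simulator(new_phantom, params),
                       focus_values = seq(-0.8, 0.8, by = 0.1), params)
fmap  <- build_focus_map(sweep)            # dense focus -> A-scan map
tuned <- finetune_agent(agent, fmap, steps = 300)
```

A thin command-line interface wrapping these functions (subcommands
`simulate`, `register`, `train`, `evaluate`, `session`) is installed at
`inst/cli/octfocus.R`; configuration files are YAML
(`inst/extdata/default_config.yaml` documents every field).

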