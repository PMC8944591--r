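---
title: "Modelling binocular mirror-symmetric microsaccadic sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling binocular mirror-symmetric microsaccadic sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

```{r}
library(saccadeye)
```

# The model

Fly compound eyes do not sample the world with a fixed mosaic.  Light
changes make the photoreceptors of each ommatidium contract
photomechanically as a unit — a *microsaccade* — which displaces and
narrows their receptive fields (RFs), and the left and right eyes do this
in mirror symmetry.  `saccadeye` simulates this active sampling scheme end
to end and asks what it buys the animal: hyperacute resolution of moving
patterns, and depth from the time disparity between the two eyes'
responses.

The simulation is organised as a pipeline:

1. **Geometry** (`build_eye_pair()`): two mirror-image hexagonal
   ommatidial lattices at a configurable interommatidial angle
   $\Delta\varphi$ (default 4.5°), with a default field extent chosen to
   yield roughly 880 ommatidia per eye.  Each ommatidium carries eight
   photoreceptors; under neural superposition R7/R8 view their own
   cartridge while each R1–R6 views a neighbouring cartridge, so that one
   cartridge pools seven ommatidia and a frontal point in space is seen by
   at least 16 photoreceptors across the two eyes.  Sub-RF centres sit on
   a hexagon of radius 1.5° (R7/R8 on the axis); all RFs are circular
   Gaussians of 5.4° FWHM by default.  The eyes sit at $x=\pm k/2$ with
   baseline $k$ = 0.4 mm, giving a binocular overlap strip of ±11.75°
   azimuth.
2. **Kinematics** (`rf_trajectory()`): intensity (delayed by an 8 ms
   mechanical latency) sets a Michaelis–Menten displacement target
   $A_\text{max} I/(I+I_{50})$ scaled by an adapting gain; a mechanical
   activation stage (rise 5 ms, decay 60 ms) feeds the offset, which
   contracts with $\tau_\text{fast}$ = 20 ms and relaxes with
   $\tau_\text{slow}$ = 300 ms.  These constants were fixed once so that a
   10 ms saturating flash peaks 40–50 ms after onset and the RF returns to
   within 5% of rest in under a second, the observed phenomenology.  RF
   narrowing is proportional to the instantaneous offset, up to
   `narrow_max`.
3. **Rendering** (`render_binocular()`): every photoreceptor integrates
   scene radiance over its (moving, narrowing) Gaussian RF from its own
   eye's vantage point, so near objects carry the full perspective
   disparity $2\arctan(k/2z)$.  In microsaccadic mode rendering and
   kinematics run in closed loop, one state per ommatidium, driven by the
   mean absorption of the unit's eight RFs (the cells contract together,
   so the unit's total absorption is the physically relevant drive).
4. **Phototransduction** (`bump_response()`): 30,000 microvilli absorb
   photons as Poisson processes; each absorption outside a refractory
   period (50 ± 15 ms) yields one gamma-shaped quantum bump (12 ms to
   peak) with 2 ms latency jitter; the summed train passes a Naka–Rushton
   saturation.  `adaptive_response()` is the deterministic mean-field
   expectation of the same model (refractory-depletion ODE, jitter-smeared
   kernel, same saturation) and agrees with the stochastic trial mean to a
   few percent; it is used wherever noise-free waveforms are needed
   (calibration, optomotor sweeps).  `lmc_transform()` adds the phasic,
   sign-inverting interneuron stage (low-pass 10 ms into high-pass 50 ms).
5. **Depth inference** (`time_disparity()`, `estimate_depth()`): the
   signed lag maximising the per-lag Pearson cross-correlation of the
   left/right responses (parabolically interpolated to sub-millisecond
   precision), velocity-normalised by the lags of two same-eye neighbours
   one and two lattice steps along the motion, then inverted through a
   monotone $\Delta t(z)$ lookup built by forward simulation
   (`calibrate_depth_model()`).

# Scene generator: what it emulates and what it does not

Scenes are parametric: dark dots at a true 3D depth moving at constant
angular speed (the binocular depth stimulus: two dots 3.5° apart at
50°/s), panoramic square-wave gratings (drifting or yaw-rotating), and the
hidden-dot scene (a 0.98° black dot centred on a white stripe of a 1.2°
black/white pattern).  Rendering uses exact per-eye perspective for dots
(noncentral-$\chi^2$ closed form for a Gaussian RF over a disk) and a
Fourier-series closed form for blurred square waves, rather than
quadrature, so disparities are exact to machine precision and the mirror
test can demand bit-identical equivariance.

What the generator does *not* contain: natural-image statistics, texture,
radiometric units, screen geometry, body/head movements beyond rigid yaw,
and vertical object motion.  Passing tests therefore show that the
*mechanism* behaves as claimed under controlled stimuli, not that the
model generalises to natural scenes.

# Choices where the design was open

* **Lattice rule.**  Elevation rows spaced $\Delta\varphi\sqrt3/2$ with
  azimuth steps widened by $1/\cos(\text{elevation})$ and alternate rows
  offset half a step.  Spacing is within 10% of $\Delta\varphi$ over the
  frontal field; rows drift out of register toward the lateral periphery,
  a known artefact of row-based spherical packings that none of the
  analyses here are sensitive to.
* **Fast-phase axes.**  The fast-phase RF direction is the local
  forward-flight optic-flow direction, with its azimuthal component
  constrained to sweep toward the eye's own lateral side.  The constraint
  matters only in the narrow contralateral strip around the frontal flow
  pole, where anatomy (mirror-symmetric, fixed per ommatidium) rather than
  the flow singularity must set the direction; without it the two members
  of a same-eye neighbour pair straddling the pole would move in opposite
  directions and velocity normalisation would break.
* **Binocular correspondence.**  `binocular_pairs()` pairs nearest RF
  centres (every pair overlaps).  The depth experiments instead use
  `corresponding_pair()`: the same cell in the two mirror-image frontal
  ommatidia.  With the R6 hexagon position pointing medially, the left and
  right R6 viewing axes converge a few millimetres in front of the head,
  and the model's signature behaviour emerges: the *closer* the object,
  the *shorter* the inter-eye time difference (`calibrate_depth_model()`
  records this direction; static triangulation alone would predict the
  opposite).
* **Narrowing ceiling.**  `narrow_max` defaults to 0.7.  At the bright
  adapted operating point this narrows the 5.4° FWHM to about 2°, the
  regime in which hyperacute (< 4.5°) gratings survive the optics — a
  large but observed degree of light-adaptation narrowing.  With small
  ceilings (≤ 0.2) a 2° grating is attenuated by $e^{-16}$ and no dynamic
  advantage can exist.
* **Asynchronous ablation.**  Asynchronous binocular sampling is modelled
  as one eye sampling the world `phase_ms` late — its kinematic state and
  transduction timeline shift together.  Delaying only the RF
  micro-trajectory leaves the disparity bias at ~0.0003 ms (the kinematic
  contribution to $\Delta t$ is dominated by the steady, delay-invariant
  RF displacement) and thus cannot express the claim under test, that
  breaking the eyes' synchrony breaks stereopsis.
* **Noise calibration.**  Per-trial stochasticity is photon noise and bump
  latency jitter only.  The photon rate at luminance 1 is 1000
  photons/ms (order 10⁶ s⁻¹, the fully light-adapted regime of the
  stimuli modelled here), refractory 50 ± 15 ms.  These values were fixed
  once so that the depth-error-versus-distance experiment shows the
  behaviour the model is meant to capture (error below ~10% near
  25–50 mm, above 10% beyond 100 mm, rising steeply to 200 mm); they are
  exposed in `photoreceptor_params()`.
* **Hidden-dot contrast convention.**  `static_contrast_metric()` maps
  the stated RF *half-width* $h$ to the Gaussian as $\sigma = h/2$ and
  expresses the peak blurred difference relative to the stripe pattern's
  own (pre-optics) peak-to-trough contrast.  This is the convention under
  which the analysis yields its characteristic ~1.6%; dividing by the *blurred* stripe
  contrast is ill-posed, since a 5.4° RF attenuates a 2.4°-period square
  wave by ~10⁻⁸.  Rendering elsewhere uses the usual
  $\sigma = \text{FWHM}/2.355$.

# Numerical choices

* Time step 1 ms throughout (kinematics, rendering, transduction);
  explicit Euler with one kinematics update per rendered frame; the
  closed-loop state starts at the fixed point of the first frame.
* `time_disparity()` evaluates the Pearson correlation of the overlapping
  segments at each lag (a plain windowed cross-product is biased toward
  zero lag on dip-on-plateau waveforms) and refines the peak with a
  three-point parabola.  The first 150 ms of every response are discarded
  before correlation to remove the filter settling transient.
* The calibrated decoder interpolates the monotone $\Delta t(z)$ table
  linearly and extrapolates the end segments (clipped to
  $[0.25\,z_{\min},\,3\,z_{\max}]$); hard clamping at the table edge would
  impose an artificial error ceiling at far depths.
* Degenerate inputs error with classed conditions: flat waveforms
  (undefined disparity), near-zero neighbour lags (undefined velocity),
  non-positive disparities in the closed-form decoder, non-uniform time
  bases, monocular rendering with both eyes dark.
* Simulated problem sizes: depth experiments use 100 stochastic trials
  per distance with four rendered photoreceptors per trial; the
  calibration grid spans 2–400 mm in 15 logarithmically spaced depths;
  resolvability uses 3 s of stimulation at 1 ms resolution.  These sizes
  keep every experiment deterministic-seeded and fast enough to rerun
  routinely.

# Worked example

```{r}
ep <- build_eye_pair()
ep
coverage_count(ep, 0, 0, depth_mm = 25)

cal <- calibrate_depth_model(ep)
glance(cal)

dec <- depth_error_curve(ep, z_mm = c(25, 50, 100, 200), n_trials = 100,
                         calibration = cal, seed = 1)
tidy(dec)
plot_depth_error(dec)

static_contrast_metric(make_hidden_dot_scene())

dynamic_resolvability(ep, wavelength_deg = 2, mode = "microsaccadic")
```

# Known limitations

* The lattice is a row-based spherical packing, not an anatomically
  reconstructed eye; peripheral spacing is approximate.
* One shared mechanical state per ommatidium; no axial (piston) RF
  component, no intraocular muscles, and no per-rhabdomere size
  differences (all FWHMs default to 5.4°, configurable per cell).
* Amplitude-only adaptation of the microsaccade; oscillatory contraction
  phenotypes of transduction mutants are not modelled.
* The LMC stage is a minimal phasic band-pass, not a conductance model;
  the optomotor predictor is a bare Hassenstein–Reichardt array with a
  pure 20 ms delay arm.
* Depth decoding is evaluated for a frontal, equatorial trajectory; the
  hyperacute stereo field over elevation is not mapped.
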