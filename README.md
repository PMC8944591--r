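# saccadeye

Active visual sampling in the fly compound eye, simulated end to end.

Insect photoreceptors are not passive pixels: light changes make the
R1–R8 cells of each ommatidium contract photomechanically as a unit
(a *microsaccade*), displacing and narrowing their receptive fields, and
the two eyes do this in mirror symmetry. `saccadeye` builds the binocular
sampling geometry (hexagonal lattices at the 4.5° interommatidial angle,
neural-superposition pooling, ~880 ommatidia per eye, 0.4 mm baseline),
drives it with two-phase microsaccade kinematics, renders synthetic
scenes through the moving receptive fields with true per-eye perspective,
converts light to voltage with a stochastic quantum-bump photoreceptor
model (plus a deterministic mean-field surrogate and a phasic
interneuron stage), and evaluates what the scheme buys the animal:

* **Hyperacute depth from time disparity.** For corresponding left/right
  photoreceptors a fixed baseline $k$ apart, a moving object's depth $z$
  is encoded in the lag $\Delta t$ between the two eyes' response
  waveforms. The decoder cross-correlates the waveforms (sub-millisecond
  parabolic interpolation), velocity-normalises with same-eye neighbour
  lags ($\hat\omega = \Delta\varphi/\Delta t_\text{nbr}$), and inverts a
  simulation-calibrated monotone $\Delta t(z)$ map; the closed-form
  baseline $z = k\,/\,(2\tan(\omega\,\Delta t/2))$ is also provided.
* **Static-versus-dynamic acuity.** The "old theory" contrast of a fine
  dot hidden among stripes under a static Gaussian receptive field;
  grating resolvability through the full dynamic pipeline (modulation
  SNR at the stimulus frequency); and a Hassenstein–Reichardt correlator
  prediction of the optomotor response, including its sign reversal for
  hyperacute gratings.
* **Ablations.** Monocular, asynchronous (one eye sampling late) and
  asymmetric (one eye static) sampling versus the mirror-symmetric
  binocular control, on paired seeds.

Everything is seeded and reproducible; results come back as tibbles with
`tidy()` / `glance()` methods and `plot_*()` / `autoplot()` displays.

## Worked example

```r
library(saccadeye)

ep <- build_eye_pair()
ep
#> <eye_pair>
#>   876 ommatidia per eye (4.5 deg spacing), 14016 photoreceptors total
#>   baseline 0.40 mm; binocular overlap 23.5 deg azimuth

coverage_count(ep, 0, 0, depth_mm = 25)
#> [1] 18
```

A frontal point 25 mm away falls inside 18 photoreceptor receptive
fields across the two eyes (the superposition pooling is why a single
point is seen by at least 16 cells).

```r
static_contrast_metric(make_hidden_dot_scene())
#> # A tibble: 1 x 3
#>   peak_diff control_contrast relative_pct
#>       <dbl>            <dbl>        <dbl>
#> 1    0.0159                1         1.59
```

A 0.98° black dot hidden among 1.2° stripes changes a static 5.4°
half-width receptive field's image by only ~1.6% of the stripe contrast
— invisible to a static eye, which is the classical argument against
hyperacute 2D vision.

```r
cal <- calibrate_depth_model(ep)
glance(cal)
#> # A tibble: 1 x 4
#>   omega_ref_dps n_depths monotone direction
#>           <dbl>    <int> <lgl>    <chr>
#> 1            50       15 TRUE     shorter_when_closer

dec <- depth_error_curve(ep, z_mm = c(25, 50, 100, 200), n_trials = 100,
                         calibration = cal, seed = 1)
tidy(dec)
#> # A tibble: 4 x 5
#>   z_true_mm mean_rel_error sd_rel_error failure_rate     n
#>       <dbl>          <dbl>        <dbl>        <dbl> <int>
#> 1        25         0.0393       0.0368            0   100
#> 2        50         0.0801       0.0691            0   100
#> 3       100         0.202        0.205             0   100
#> 4       200         0.481        0.618             0   100
```

The calibrated decoder is monotone over 2–400 mm and — because the
converging R6 pair starts with a large axis separation that perspective
disparity eats into — a *closer* object yields a *shorter* inter-eye
time difference. Under the default photon-noise and bump-jitter
configuration the mean relative depth error stays below ~10% out to
about 50 mm and exceeds 10% from 100 mm on, rising steeply at 200 mm:
the model fly cannot range distant objects.

```r
dynamic_resolvability(ep, wavelength_deg = 2, mode = "microsaccadic", seed = 21)$modulation_snr
#> [1] 18.8
dynamic_resolvability(ep, wavelength_deg = 2, mode = "static", seed = 21)$modulation_snr
#> [1] 0
```

A 2° grating (finer than the 4.5° ommatidial spacing) is resolvable only
when the receptive fields move and narrow microsaccadically.

Figure-level recipes are packaged behind one runner:

```r
run_experiment("hidden_dot_contrast", out_dir = "results")
run_experiment("stereo_ablation")   # monocular / asynchronous / asymmetric
run_experiment("optomotor")         # coarse vs hyperacute, both yaw signs
```

See `vignette("saccadeye-methods")` for the model, its assumptions, the
parameter defaults and the design decisions.

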