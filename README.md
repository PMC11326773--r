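# oscomp — oscillation component analysis for multichannel M/EEG

Multichannel neurophysiological recordings (EEG, MEG, sEEG, LFP) mix a
small number of underlying cortical oscillations into tens or hundreds of
sensors. Frequency-domain summaries and ICA-style blind source separation
struggle here: the first cannot tell spatially distinct generators of the
same rhythm apart, and the second has no notion of temporal dynamics and
fails outright on (near-)Gaussian oscillatory signals. `oscomp` is for
electrophysiologists and methods researchers who want the decomposition
itself to come from a generative model of oscillations, so that the number
of components, their parameters, and their sensor maps are all estimated —
not chosen by eye.

## The model

Each latent oscillation is a damped stochastic rotation in two dimensions
(an analytic-signal pair):

```
x_t = a R(f) x_{t-1} + v_t,        v_t ~ N2(0, sigma^2 I),
R(f) = [[cos w, -sin w], [sin w, cos w]],   w = 2 pi f / fs,
```

with center frequency `f` (Hz), damping factor `a` in (0, 1) and
process-noise variance `sigma^2`. `M` such oscillators stack into a
block-diagonal 2M-dimensional state space, and the `L` sensors observe

```
y_t = C x_t + e_t,                 e_t ~ N_L(0, R),
```

where each row block `c_{l,m}` of the mixing matrix `C` is a 2-vector
encoding the amplitude and phase of oscillation `m` at channel `l`.
Priors: `vec(C) ~ N(0, alpha^{-1} I)` and `R ~ Inverse-Wishart(Psi, nu)`.

Inference is variational Bayes under the factorization
`q(C) q({x_t}) q(R)` — a Kalman smoother for the states (with the
`E[C' R^{-1} C]` second-moment correction), conjugate Gaussian and
inverse-Wishart updates for `C` and `R` — wrapped in a generalized EM
outer loop that re-estimates `(f, a, sigma^2)` per oscillator and `alpha`
in closed form. The negative variational free energy (ELBO) monitors
convergence and, evaluated over a grid of candidate `M`, gives the
model-structure posterior `q(M) ∝ exp(F_M)` used to select the number of
oscillations.

## Worked example

The package ships a seeded synthetic study with the structure the method
targets: three AR(2) sources — a 1.6 Hz slow/delta rhythm shared by two
channel groups with a 10 ms lag, plus independent 10 Hz and 12 Hz alpha
rhythms — mixed into 8 channels with spatially colored noise.

```r
library(oscomp)

study <- sim_fixture_eeg("reduced", seed = 1)
model <- oca_fit(study$rec, study$truth$noise_cov,
                 candidate_Ms = c(2, 3, 4, 5, 6, 8, 10), seed = 1)
tidy(model$grid)
#> # A tibble: 7 × 4
#>       M free_energy          q selected
#>   <int>       <dbl>      <dbl> <lgl>
#> 1     2     -28245. 0          FALSE
#> 2     3     -26267. 1.000e+  0 TRUE
#> 3     4     -26290. 9.28 e- 11 FALSE
#> 4     5     -26328. 3.34 e- 27 FALSE
#> 5     6     -26372. 1.64 e- 46 FALSE
#> 6     8     -26439. 9.65 e- 76 FALSE
#> 7    10     -26498. 3.64 e-101 FALSE
```

The free energy peaks sharply at `M = 3`: the empirical-Bayes posterior
identifies the three generating oscillations from the data alone. The
fitted components:

```r
tidy(model)
#> # A tibble: 3 × 6
#>   component frequency damping sigma2 band       max_map_magnitude
#>       <int>     <dbl>   <dbl>  <dbl> <chr>                  <dbl>
#> 1         1      1.31   0.991 0.0391 slow/delta             0.900
#> 2         2      9.79   0.972 0.0576 alpha                  1.06
#> 3         3     11.8    0.971 0.0524 alpha                  1.25
```

Center frequencies land close to the generating 1.6 / 10 / 12 Hz (the
slow estimate sits a little low because a broadband AR(2) rhythm is not
exactly a single damped rotation). Because each channel's mixing entry is
a 2-vector, inter-channel *phase* is part of the map: the 10 ms lag
between the two slow-source channel groups is read straight off the
fitted mixing phases,

```r
mixing_phase_lag(model, which.min(model$bank$f),
                 channels_ref = 1:2, channels_lag = 3:4)
#> [1] 12.02   # ms; truth is 10 ms, i.e. one sample at fs = 100 Hz
```

Downstream helpers include `get_sources()` (paired real/imaginary
component time courses), `oca_apply()` (sensor-space reconstruction from
any component subset), `get_noise_covariance()` (residual noise
covariance; here within 23% relative Frobenius error of the true
simulation covariance), `instantaneous_amplitude_phase()`,
`band_coherency()` (the alpha band above splits 0.598 : 0.402 between the
two alpha components), `principal_angles()` for comparing mixing-map
subspaces, and `pac_profile()` for phase–amplitude coupling. A thin
command-line front end lives in `inst/scripts/oca-cli.R`
(`simulate` / `fit` / `transform` / `reconstruct` / `report`).

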