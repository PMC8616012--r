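# polarcyte

Single-particle optical cytometry for aquatic suspensions, combining
**polarized light scattering** with a simultaneous **chlorophyll
fluorescence** channel. The scientific problem: microalgae, cyanobacteria
and microplastics co-occur in natural waters and are poorly separated by
intensity-only optics — polarization encodes particle microstructure while
fluorescence encodes pigment content, and only their combination classifies
both biological and non-biological particles reliably. The package is aimed
at instrument builders and analysts working with division-of-amplitude
polarimeters on sparse particle suspensions.

## The model

A particle transiting the focused beam scatters light whose polarization
state is the Stokes vector S = [I, Q, U, V]ᵀ, reduced to scale-invariant
features

    q = Q/I,  u = U/I,  v = V/I,  DOP = √(q² + u² + v²).

A four-channel polarization-state analyzer records voltages
I_PSA = [I_L, I_0, I_90, I_135]ᵀ related to the incident state by the
instrument matrix A; calibration fits A by least squares over known probe
states and measurement inverts it, S_s = A⁻¹ I_PSA. A fifth detector
records the fluorescence integral F_m over the same transit window, and the
normalized fluorescence F = F_m / I cancels the particle's unknown position
in the focal volume. Per particle the method yields six features
[I, q, u, v, DOP, F], classified by Fisher LDA projection and a
radial-kernel SVM.

The package implements every stage — ideal-element Mueller matrices, the
analyzer forward model, calibration and inversion, rolling-median baseline
and pulse detection, the fluorescence yield / solid-angle / detector
physics chain with occupancy and photodamage checks, and a seeded
instrument simulator that stands in for the hardware with known ground
truth. See `vignettes/polarcyte-methods.Rmd` for the full account.

## Worked example

Simulate a mixed suspension of a non-fluorescent "microplastic" class and a
fluorescent "algae" class, detect transits, and extract per-particle
features:

```r
library(polarcyte)
d <- experiment_design(
  classes = list(
    particle_class("microplastic", diattenuation = 0.30, retardance = 70,
                   depol = 0.70),
    particle_class("algae", diattenuation = 0.15, retardance = 40,
                   depol = 0.85, f_ratio_mean = 0.5, f_ratio_sd = 0.1)),
  arrival_rate = 30, duration = 0.5, seed = 7, noise_sd = 0.002)

particles <- sample_particles(d)
traces <- render_traces(particles, d)
traces
#> Multichannel trace set: 100000 samples x 5 channels @ 2e+05 Hz (0.5 s)

pulses <- detect_pulses(traces, k_threshold = 5, min_width = 8)
nrow(pulses)          # 23 events: every planted transit recovered
feats <- features_from_pulses(pulses, d$instrument)
head(round(feats[, c("q", "u", "v", "dop", "F", "snr")], 3))
#>       q     u     v   dop     F     snr
#> 1 0.145 0.893 0.150 0.917 0.554 122.976
#> 2 0.120 0.730 0.138 0.753 0.001 159.585
#> 3 0.099 0.789 0.072 0.799 0.593 114.096
#> 4 0.056 0.755 0.231 0.792 0.000 124.312
#> 5 0.104 0.802 0.039 0.809 0.451 240.993
#> 6 0.070 0.715 0.257 0.763 0.002 141.497
```

The two classes are indistinguishable in DOP alone here but split cleanly
on F: the algae-class mean F recovered from the traces is 0.514 (planted
0.5) while the microplastic class sits at 0.000 — the fluorescence ratio is
what tells biology from plastic. For classification benchmarks use the
presets:

```r
b <- make_benchmark_suite("algae4", seed = 11, n_per_class = 300)
svm_train_eval(b, b$label, feature_set = "pol5+F", seed = 3)
```

A thin command-line front end covers the same operations
(`inst/cli/polarcyte simulate|extract|physics`).

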