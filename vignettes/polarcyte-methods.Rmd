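---
title: "Measuring and classifying single particles by polarized scattering and fluorescence"
author: "polarcyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and classifying single particles by polarized scattering and fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarcyte)
```

## The measurement problem

Suspended particles in natural waters — microalgae, cyanobacteria,
microplastics, mineral grains — are hard to tell apart with intensity-only
optics. Two signals carry complementary information about a single particle
transiting a focused laser beam:

* the **polarization state of the scattered light**, which encodes
  microstructure (surface roughness, internal organization, birefringence)
  largely independently of size, and
* the **fluorescence** excited by blue light near the chlorophyll-a
  absorption peak, which reports intracellular pigment and therefore
  biological origin.

`polarcyte` implements the full analysis chain for an instrument that
measures both at once: a division-of-amplitude polarization-state analyzer
(PSA) with four parallel detectors, a co-registered fluorescence detector,
pulse-level feature extraction, and a classification stage. Because the
corresponding hardware produces no publicly deposited raw data, the package
also contains a seeded instrument simulator that generates multichannel
voltage traces with known ground truth; every claim the test suite makes is
made against that simulator.

## Stokes–Mueller model

A beam's polarization state is the Stokes vector
$S = [I, Q, U, V]^\top$: total intensity and the residual intensities of
horizontal linear, 45° linear and right-handed circular polarization. The
normalized components and degree of polarization are

$$q = Q/I,\quad u = U/I,\quad v = V/I,\qquad
\mathrm{DOP} = \sqrt{q^2 + u^2 + v^2}.$$

These are scale invariant, which is what makes them usable per particle:
the unknown transit depth multiplies all channels equally and cancels.

Optical elements act as $4\times4$ Mueller matrices. The package provides
the ideal linear polarizer (`mueller_polarizer`, idempotent, $M_{11}=1/2$)
and linear retarder (`mueller_waveplate`, lossless, preserves $I$ and DOP).

**Handedness convention.** The instrument's circular channel is built from
a quarter-wave plate at 135° followed by a vertical polarizer, described as
selecting the *left-handed* circular component. That description fixes the
convention only up to a global sign, which the source description leaves
open; `polarcyte` fixes it as: $V > 0$ is right-handed circular, and the
retarder at zero fast-axis angle has the $U\!-\!V$ block
$[\cos\delta, \sin\delta; -\sin\delta, \cos\delta]$. Under this pair of
choices the channel chain projects onto $(I - V)/2$, i.e. it indeed selects
left-handed light, so the convention is self-consistent with the channel
naming. All circular-channel arithmetic in the package derives from this
single documented choice.

```{r convention}
chain <- list(mueller_waveplate(90, 135), mueller_polarizer(90))
as.numeric(apply_element(chain, c(1, 0, 0, -1)))[1]  # LCP: passes
as.numeric(apply_element(chain, c(1, 0, 0,  1)))[1]  # RCP: blocked
```

## The analyzer forward model and its instrument matrix

The PSA splits the collected beam with one 50:50 and two 30:70
non-polarizing splitters into four channels analyzed at left-circular, 0°,
90° and 45°. The instrument matrix $A$ maps a Stokes vector to the four
detector voltages $I_{PSA} = [I_L, I_0, I_{90}, I_{135}]^\top$; row $k$ is
the detector gain times the channel throughput times the first row of the
channel's Mueller product.

Two details are not derivable from the optical description and are exposed
as configuration rather than guessed:

* **Splitter assignment.** Which splitter output feeds which channel is
  unstated. The default routes the 50:50 cube first and a 30:70 cube per
  arm, giving throughputs $(0.15, 0.35, 0.15, 0.35)$ — the most equal
  arrangement this splitter set allows. Since the matrix is calibrated
  before use, the assignment affects only conditioning, never correctness.
* **The fluorescence pick-off.** Whether the 50:50 splitter feeding the
  fluorescence arm is absorbed into calibration or modeled explicitly is
  exposed as `psa_prefactor` (default 1, i.e. absorbed).

```{r matrix}
A <- theoretical_instrument_matrix()
A
```

## Calibration and inversion

Calibration solves $\min_A \sum_i \|A s_i - v_i\|^2$ over probe states with
known Stokes vectors — the default probe set is the six canonical states
(H, V, ±45°, RCP, LCP), the standard well-conditioned choice. With exactly
four independent probes the least-squares solution is the exact solve; a
rank-deficient probe set fails with the unobserved Stokes direction named.
Measurement inverts the relation, $S_s = A^{-1} I_{PSA}$.

A Stokes vector inverted from noisy voltages can land outside the physical
cone ($\mathrm{DOP} > 1$). Such vectors are **flagged, never clipped**:
clipping would bias every downstream class statistic toward the cone
boundary, whereas the flag lets the analyst decide.

`calibration_error_report` quantifies end-to-end reconstruction error on
held-out states as percentages. Whether such an error should be quoted
worst-case or RMS, and against which denominator, is a genuinely open
convention, so the report gives worst-case and RMS against both full scale
(the $[-1,1]$ range, i.e. 2) and half range (1). Noiselessly, a calibrated
ideal analyzer reconstructs to machine precision.

## From traces to per-particle features

A transit appears as a simultaneous pulse on all five channels. The
pipeline is:

1. **Baseline**: running median over 501 samples (default), with noise SD
   from the MAD of the residual — both robust to sparse pulses at the ≲1%
   duty cycles implied by single-particle occupancy.
2. **Detection** on the *sum* of the four scattering channels (a
   polarization-independent trigger): at least `min_width` consecutive
   samples above baseline $+ k\,\sigma_{noise}$; events closer than
   `min_separation` merge. SNR is defined as
   $(\text{peak} - \text{baseline})/\sigma_{noise}$ of the summed trace —
   the instrument literature uses SNR without defining it, so the package
   documents one definition and makes it configurable.
3. **Integration**: per-channel baseline-subtracted sums times the sample
   interval (volt·seconds), half-open index windows. The fluorescence
   integral $F_m$ uses the *same window* as the scattering pulse; that
   coincidence is the method's central premise.
4. **Features**: $S = A^{-1} I_{PSA}$, then $q,u,v,\mathrm{DOP}$, and
   $F = F_m / I$, which cancels the transit-position factor. Records with
   $I$ at or below a floor (default $5\sigma_{noise}\cdot
   \text{min\_width}\cdot dt$) are dropped and counted rather than raised,
   because division by a near-zero $I$ is meaningless, not exceptional.

The default sampling rate (200 kHz) puts ≥20 samples across a 0.1 ms
transit, the shortest dwell the optical geometry implies.

## Fluorescence physics chain

The volumetric fluorescence emission of a chlorophyll-containing cell is
modeled as the five-factor product
$F' = \mathrm{PAR}\cdot[\mathrm{chla}]\cdot \bar a^* \cdot Q_a^*
\cdot \phi_F$ in µmol photons/(m³·s). Unit handling is deliberately split:
`fluorescence_yield` does only the product; `photon_rate_to_nW` converts
photon rate to radiant power at a stated emission wavelength (default
685 nm, the chl-a emission peak); `collection_fraction` applies the
solid-angle ratio $\Omega/4\pi$ (0.014 sr → 0.111%); `detector_voltage`
applies the radiant sensitivity (default 5 V/nW) and a separate DAQ gain.
The DAQ gain exists because sensitivity alone does not close the loop from
emitted power to recorded volts on real acquisition chains; its default is
1 and no value is guessed. The published end-to-end figure for this chain
(9.75 nW total emission) depends on literature parameters not reproduced
here, so it is not used as a regression value anywhere in the package.

Two operational checks accompany the chain. `occupancy` gives the expected
particle count in the scattering volume and the Poisson probability of a
coincidence — at $10^5$ particles/mL and 0.01 µL the expectation is exactly
1, the single-particle ceiling. `exposure_check` compares the energy
deposited during one transit against a photoinhibition threshold
(816.43 µJ default); the geometric interception factor (cell cross-section
over focal-spot area, capped at 1) matters because a micron-scale cell in a
10 µm spot intercepts only ~1% of the beam power.

## The instrument simulator

The simulator is the package's stand-in for hardware, and its defaults are
the study conditions the tests assume.

* **Mueller families are parametric, not Mie-computed.** Each particle
  class is a jittered product of a linear diattenuator, a linear retarder
  and an isotropic depolarizer — three factors that are individually
  physical, so every generated matrix maps physical Stokes vectors to
  physical ones. No per-class Mueller matrices of real samples are
  published for this geometry, and a Mie/T-matrix layer is out of scope, so
  the class parameters are constructed and clearly labeled synthetic.
* **Arrivals** are a Poisson process; **transits** are Gaussian profiles
  (SD = transit time/4) with lognormal amplitude — the natural model for a
  focal-volume crossing of a Gaussian beam. Overlapping transits render
  additively and are counted, mirroring the ≤1-occupancy assumption.
* **Noise** is additive Gaussian per channel (no noise model is published;
  it is configurable).
* A **seed is mandatory**; every generated dataset is byte-reproducible.

Three presets mirror the structure (not the numbers) of the motivating
experiments: `ps10-family` (three non-fluorescent microsphere classes plus
a fluorescent twin of the smooth polystyrene class), `algae4` (four
microalgae-like classes, two polarization-overlapping but
fluorescence-distinct, class-mean F ordered P.G. > M.A. > D.S. > P.T. with
the widest spread for P.G.), and `submicron` (low-amplitude classes
including two cyanobacteria analogues). Preset class parameters are the
package's own constructed values.

**What passing tests do and do not show.** The simulator emulates sparse
transits, class-structured polarization and fluorescence, and detector
noise. It does not emulate Mie resonances, detector impulse response,
stirring hydrodynamics, multi-particle coincidences beyond linear
superposition, or drift. Tests passing on these synthetics demonstrate the
*pipeline* is correct and the *classification logic* behaves as designed;
they do not certify accuracy numbers on real instrument data, which is why
the published confusion-matrix percentages are treated as directional
targets only.

## Classification

`lda_project` implements the Fisher criterion directly — eigenvectors of
$S_W^{-1} S_B$ with unit-norm columns and a sign fixed by the
largest-magnitude loading (the deterministic tie-break) — with an optional
ridge on $S_W$ for near-singular scatter; the test suite cross-checks the
projection direction against an independent reference implementation.
`svm_train_eval` wraps a radial-kernel SVM: stratified 70/30 split, z-score
standardization fitted on the training split only (I and F live on very
different scales than q, u, v), and a small grid over cost and kernel width
scored by 5-fold CV — kernel and grid are package choices, as none are
published. Reports carry per-class accuracy and row-normalized confusion
matrices and are exactly reproducible under a fixed seed.

```{r classify}
b <- make_benchmark_suite("algae4", seed = 11, n_per_class = 150)
r_pol <- svm_train_eval(b, b$label, feature_set = "pol5", seed = 3,
                        cost_grid = c(1, 10), gamma_grid = c(0.1, 1))
r_all <- svm_train_eval(b, b$label, feature_set = "pol5+F", seed = 3,
                        cost_grid = c(1, 10), gamma_grid = c(0.1, 1))
round(100 * rbind(pol5 = r_pol$per_class_accuracy,
                  `pol5+F` = r_all$per_class_accuracy), 1)
```

The polarization-overlapping pair (P.G., M.A.) is rescued by the
fluorescence feature while the polarization-distinct pair is already well
classified — the qualitative signature the combined measurement exists to
produce.

## Problem sizes and numerical choices

The bundled checks run at deliberately modest scale, chosen as the smallest
sizes at which the statistical claims are stable: benchmark presets use
150–300 particles per class; detection recall/precision aggregates 100
seeded runs of 15 000-sample traces with seven planted pulses each;
Monte-Carlo unbiasedness checks use $10^3$–$10^4$ repeats with 4-standard-
error bands. Degenerate inputs are handled explicitly: singular instrument
matrices refuse inversion with the condition number, rank-deficient probe
sets name the unobserved subspace, sub-floor intensities are counted
rejections, and an even baseline window is rounded up to odd.

## Known limitations

Polarization optics are ideal (no partial polarizers, no wavelength
dependence); splitters are polarization-neutral; no real-time streaming; no
coincidence deconvolution; no emission-spectrum modeling. The fluorescence
chain's absolute voltage scale is only as good as the supplied DAQ gain.
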