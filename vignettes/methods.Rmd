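---
title: "Decoding acoustoelectric brain-imaging signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding acoustoelectric brain-imaging signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abidecode)
```

## The decoding problem

Acoustoelectric brain imaging measures local current sources by tagging
them with focused ultrasound.  Acoustic pressure perturbs conductivity
(Δσ/σ₀ = −KΔP, with K of order 10⁻⁹ Pa⁻¹ in physiological saline), so a
recording electrode sees, on top of the ordinary low-frequency potential,
a high-frequency *acoustoelectric* (AE) component generated only where
the beam is focused.  The ultrasound is pulsed at a repetition frequency
(PRF) of 1 kHz, far below the MHz carrier but well within a
20 kHz acquisition band, so the PRF band of the recording acts as the
carrier: the local source waveform rides on it as an amplitude
modulation.  Decoding is the recovery of that waveform, one focal spot at
a time; scanning the focus and mapping the decoded amplitude produces an
image of the source distribution.

Two decoders are implemented:

* **DAE** — band-pass the recording around the PRF (±30 Hz), build the
  analytic signal x̃ = x + j·x̂ with the Hilbert transform and use its
  modulus A(t), the envelope, as the decoded timing signal.
* **aDAF** — expand the same envelope in harmonics of the record
  fundamental f₀ = fs/n by least squares.  With the time index t = 0…n−1
  and m = ⌊n/2⌋ harmonics, orthogonality gives closed-form coefficients
  a₀ = mean(A), aᵢ = (2/n)Σ A(t)cos(i2πt/n), bᵢ = (2/n)Σ A(t)sin(i2πt/n),
  amplitude cᵢ = √(aᵢ²+bᵢ²).  The decoded timing signal keeps a₀ plus the
  single harmonic with the largest cᵢ inside a candidate band (default
  1–50 Hz).  Everything outside that one harmonic — i.e. nearly all of
  the envelope's noise — is discarded, which is the entire mechanism of
  aDAF's advantage over DAE.

Both decoders operate on whole records with no windowing or zero padding,
so harmonic frequencies are exact multiples of f₀.  No off-grid frequency
refinement is attempted: the benchmark records are constructed so that
source frequencies coincide with fit harmonics, and on such records the
grid is exact.  For non-integer-period sources the fit leaks across
neighbouring harmonics like any rectangular-window DFT; this is a
documented limitation, not an error.

## The phantom simulator

`simulate_recording()` emulates a saline-chamber bench: stimulation
electrodes drive sinusoidal current sources (7–13 Hz, tens to hundreds of
mV), a scanned focused transducer pulses at 1 kHz, and a recording
electrode samples at 20 kHz.  The generated voltage is

V(t) = g·p(t)·A₀·[1 + μ·M(t)/M_max] + g_LF·S(t) + ε(t)

with p(t) a unit-peak raised-cosine pulse train (0.2 ms pulses at the
PRF), A₀ = K·ΔP the carrier scale (defaults 10⁻⁹ Pa⁻¹ × 10⁶ Pa),
S(t) = Σ αₛ sin(2πfₛt+φₛ) the raw source sum,
M(t) = Σ wₛ·αₛ sin(2πfₛt+φₛ) its focally weighted version with Gaussian
weights wₛ = exp(−d²/2σ²) (σ = 0.6 mm), and ε white Gaussian noise.

Design notes, in decreasing order of consequence:

* **Pedestal amplitude modulation.**  The benchmark's decoded traces
  preserve the sign and phase of the source at its own frequency, which
  the magnitude envelope of a sign-flipping modulation cannot do.  The
  simulator therefore modulates a pedestal: carrier amplitude
  A₀(1 + μ·M/M_max) with modulation index μ ≤ 1 (default 0.8), making the
  envelope affine — hence sign- and phase-preserving — in M(t).  This is
  a modeling choice of the package, not a property that envelope
  demodulation grants for free.
* **Modulation normalizer.**  M_max = Σ αₛ is the largest value M(t)
  could attain at any focus (all weights 1).  A per-focus normalizer
  would make the modulation depth identical at every spot and erase all
  spatial contrast, so the global normalizer is the only self-consistent
  reading; it also makes decoded amplitude ratios track source amplitude
  ratios exactly, which the two-source amplitude benchmarks (ratios 2 and
  3) require.  A side effect is that the per-source depth scales with
  1/Σαₛ: multi-source layouts divide the available depth among sources.
* **The MHz carrier is not represented.**  At fs = 20 kHz it is
  unobservable; the pulse train at the PRF is the carrier, which is
  exactly what the recorded band can contain.  The lead-field/beam
  geometry is collapsed to the isotropic Gaussian wₛ; directional
  sensitivity is out of scope.
* **Determinism.**  All randomness is the additive noise, drawn under a
  config seed that is saved and restored around the draw (the global RNG
  stream is untouched).  Scan spot i uses seed `seed + i − 1`, so scans
  are reproducible and spots independent.

What the simulator does *not* emulate: acoustic propagation, tissue
heterogeneity, transducer beamforming, electrode impedance, drift,
line interference, or any non-Gaussian noise.  Tests passing on these
phantoms therefore demonstrate correctness of the decoding and imaging
chain under its stated signal model — not robustness to every artifact
of a wet-lab recording.

## Preprocessing

Recordings are decimated to 5 kHz (8th-order Butterworth anti-alias at
80 % of the target Nyquist, then integer-factor decimation) and band-pass
filtered with a 3rd-order Butterworth over PRF ± 30 Hz, zero-phase by
default.  Zero-phase application doubles the effective magnitude order;
a single-pass option exists (`zero_phase = FALSE`) since the original
description does not say which was used.

Both filters are applied *circularly*: the digital transfer function is
evaluated on the record's own DFT grid and multiplied in the frequency
domain (|H|² for zero-phase).  For integer-period records this is the
exact steady-state response with no start-up transient.  The alternative
— time-domain filtering with padded edges — is untenable here because the
low-frequency leakage exceeds the in-band AE signal by roughly five
orders of magnitude: any kink introduced by the padding rings into the
record at the passband frequency and buries the signal near the edges
(measured as a ceiling of r ≈ 0.81 on otherwise noiseless records).  The
trade-off is wrap-around leakage for non-periodic content; at the default
record lengths this is far below the scenarios' noise floor.

## Imaging and metrics

Per-spot decoded amplitudes (cₖ for aDAF; √2 × RMS of the mean-removed
envelope for DAE, exact for a single sinusoidal modulation) are assembled
on the scan grid, interpolated onto a 0.01 mm lattice (separable natural
cubic splines; bilinear option with the exact 4-neighbour-mean midpoint
property), and scored:

* **dB maps** use the amplitude convention 20·log₁₀(v/peak), floored at a
  5 dB display range.  SNR uses the power convention
  10·log₁₀(P_signal/P_noise) with P_signal the mean squared ROI-peak
  amplitude (one peak per source ROI, default radius 1.5 mm — the bench
  description marks sources with circles but gives no radii) and P_noise
  the mean squared background amplitude.
* **−3 dB source width** is the length of the contiguous interval around
  a line-profile peak above peak·10^(−3/20), with linearly interpolated
  crossings.  For a Gaussian profile of width σ the closed form is
  2σ√(2·ln 10^(3/20)) ≈ 1.663 σ, which the tests use as an oracle.

Scenario widths are measured on the y-axis profiles through each source
(single-peaked by construction); the x profile through a multi-source row
would need per-source segmentation for the same job.

## Parameters and calibration

| parameter | default | why |
|---|---|---|
| fs_record | 20 kHz | acquisition rate of the emulated bench |
| duration | 2 s | integer cycles for 7/8/10/13 Hz; f₀ = 0.5 Hz |
| prf / pulse_width | 1 kHz / 0.2 ms | bench pulser settings |
| focal_sigma | 0.6 mm | mm-scale focus; −3 dB map width ≈ 1 mm |
| modulation_index | 0.8 | deep but unclipped pedestal AM |
| lf_leak_gain | 1 | leakage comparable to the source drive; fully rejected by the band-pass |
| noise_sd (1-source) | 1.5·10⁻³ | calibrated so DAE's source correlation falls in 0.6–0.85, the regime the decoder comparison is defined in |
| noise_sd (multi-source, imaging) | 1.5·10⁻⁴ | global pedestal normalization divides per-source depth by the source count; this level restores the same operating point and gives maps with measurable widths and DAE SNR near 15 dB |
| candidate band | 1–50 Hz | excludes drift/DC and residual PRF-beat components |
| roi_radius / interp step / dynamic range | 1.5 mm / 0.01 mm / 5 dB | imaging conventions of the benchmark |

Noise calibration was done once on the 1-source scenarios by scanning
noise_sd over a decade and fixing the value whose DAE correlation median
sat mid-range; it was not revisited afterwards.

## Numerical choices

* The harmonic fit is computed via the FFT (aᵢ = (2/n)Re Xᵢ,
  bᵢ = −(2/n)Im Xᵢ) and verified in the tests against a direct-summation
  oracle to 10⁻¹⁰.  For even n the Nyquist harmonic i = n/2 is
  cosine-only with weight 1/n (not 2/n), which makes the expansion
  complete and the Parseval identity exact:
  mean(A²) = a₀² + Σ cᵢ²/2 (+ c_{n/2}² unhalved for even n).
* The decoded aDAF trace includes a₀.  Correlation metrics are
  mean-removed so this is inconsequential for them; amplitude reporting
  uses cₖ only.
* Dominant-harmonic ties break toward the lower index; the DC term is
  never eligible.
* Cubic map interpolation can overshoot below zero between nodes;
  negative values are clipped to zero so maps remain valid amplitudes.
* `analytic_signal()` returns `complex(real = x, imaginary = Im(·))`, so
  the real part is the input bit-for-bit.

## Problem sizes

Unit tests use 0.125–1 s records; the decoder benchmarks use the full
2 s records (n = 10⁴ after decimation); scan benchmarks run the complete
10×5 and 24×5 grids with interpolation to 0.01 mm, repeated over 10 seeds
for the ordering battery.  The full suite runs in a few minutes on one
core.

## Known limitations

* The pedestal-AM forward model is the package's answer to how envelope
  decoding can preserve source sign and phase; real AE recordings may
  behave differently for bipolar sources.
* Absolute voltage scale is arbitrary (pulser and amplifier gains are
  free parameters); only relative quantities — correlations, ratios,
  SNRs, widths — are meaningful.
* Absolute SNR values depend on the unreported ROI definitions of the
  original bench; only orderings and relative improvements are treated
  as reproducible.
* Single-harmonic output assumes a monochromatic source at the focus;
  `top_m > 1` keeps more harmonics but no sliding-window or
  time-varying tracking is provided.
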