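# abidecode

Decoders, phantom simulation and imaging metrics for **acoustoelectric
brain imaging (ABI)** signals.

ABI maps current sources by scanning a focused ultrasound beam over the
region of interest: acoustic pressure modulates local conductivity
(Δσ/σ₀ = −KΔP), so the recorded voltage contains a high-frequency
"acoustoelectric" (AE) component that carries the local low-frequency
current signal as an amplitude modulation of the ultrasound pulse train.
With a pulse repetition frequency (PRF) of 1 kHz, the PRF band of the
recording is the effective carrier, and decoding means recovering the
source waveform from that carrier's envelope.

The package implements and compares two decoders:

* **DAE** (decoding algorithm with envelope), the baseline: band-pass the
  recording around the PRF, form the analytic signal
  x̃(t) = x(t) + j·x̂(t) via the Hilbert transform, and take the envelope
  A(t) = |x̃(t)| as the decoded timing signal.
* **aDAF** (adaptive decoding algorithm based on Fourier fitting): expand
  that envelope in harmonics of the record fundamental ω₀ = 2π/n,

  A(t) ≈ a₀ + Σᵢ aᵢ cos(i·2πt/n) + bᵢ sin(i·2πt/n),  cᵢ² = aᵢ² + bᵢ²,

  with the least-squares coefficients aᵢ = (2/n)ΣA(t)cos(i·2πt/n),
  bᵢ = (2/n)ΣA(t)sin(i·2πt/n), and keep the single largest-amplitude
  harmonic in a low-frequency candidate band (default 1–50 Hz) as the
  decoded timing signal.  Rejecting every other harmonic strips the
  broadband envelope noise, which is what improves correlation, amplitude
  accuracy, image SNR and −3 dB source width over DAE.

Since the phantom bench (saline chamber, scanned focused transducer,
stimulation electrodes) is hardware, the package ships a seeded simulator
of those experiments: a 1 kHz raised-cosine pulse train,
pedestal-amplitude-modulated by the focally weighted sum of sinusoidal
current sources (7–13 Hz), plus low-frequency leakage of the source
drives and white noise, recorded at 20 kHz.  Every benchmark layout
(1-source at 8/10/13 Hz, 2-source frequency/amplitude pairs, 3-source
triangle, and the 10×5 and 24×5 imaging scans) is available by name, with
known ground truth for every test.

## Worked example

Simulate the 8 Hz single-source phantom at its calibrated noise level and
compare the two decoders:

```r
library(abidecode)

sc <- run_scenario("1source-8", seed = 1)
sc$report
#> # A tibble: 2 × 8
#>   scenario  focus_x focus_y method source_frequency decoded_frequency correlation amplitude
#> 1 1source-8       0       0 DAE                   8                NA       0.732 0.000228
#> 2 1source-8       0       0 aDAF                  8                 8       0.997 0.000146
```

At a noise level where the plain envelope tracks the 8 Hz source with
r ≈ 0.73, the adaptive single-harmonic decoder reaches r ≈ 0.997 and
identifies the source frequency exactly (harmonic 16 of a 2 s record =
8 Hz).  The pieces compose with the pipe:

```r
cfg <- sc$config
decoded <- simulate_recording(cfg, focus = c(0, 0)) |>
  preprocess(fs_out = 5000, halfwidth = 30, order = 3) |>   # 5 kHz, PRF ± 30 Hz
  adaf_decode(band = c(1, 50))

glance(decoded)
#> # A tibble: 1 × 6
#>   method    fs selected_harmonic frequency amplitude  phase
#> 1 aDAF    5000                16         8  0.000146 0.0754

tidy(attr(decoded, "fit"))   # full harmonic table
autoplot(decoded)            # decoded timing signal
```

Imaging scans reconstruct amplitude maps, interpolate them to a 0.01 mm
lattice and score them:

```r
sc <- run_scenario("image-2source", seed = 1)
sc$report
#> # A tibble: 2 × 4
#>   scenario      method snr_db width_mm
#> 1 image-2source DAE      16.1     1.04
#> 2 image-2source aDAF     27.1     1.00
autoplot(to_db(sc$maps$aDAF$interpolated))   # 5 dB dynamic-range map
```

`snr_db` is 10·log₁₀ of ROI-peak power over background power; `width_mm`
is the −3 dB width of the line profile through each source.

A thin command-line front end ships in `inst/scripts/abidecode`
(subcommands `simulate`, `preprocess`, `decode`, `scenario`).

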