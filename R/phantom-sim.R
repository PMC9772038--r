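#' Describe low-frequency current sources in the phantom
#'
#' A source is a point current injector at a position in the scan plane,
#' driven sinusoidally.  Vector arguments are recycled tibble-style so a
#' multi-source layout is one call.
#'
#' @param x,y Source position in mm.
#' @param frequency Drive frequency in Hz (> 0).
#' @param amplitude Drive amplitude in mV (>= 0).
#' @param phase Initial phase in radians.
#' @return A tibble with one row per source and columns
#'   `x`, `y`, `frequency`, `amplitude`, `phase`.
#' @examples
#' source_spec(x = c(-8, -2), y = 0, frequency = 10, amplitude = 100)
#' @export
source_spec <- function(x, y, frequency, amplitude = 100, phase = 0) {
  out <- tibble::tibble(x = as.numeric(x), y = as.numeric(y),
                        frequency = as.numeric(frequency),
                        amplitude = as.numeric(amplitude),
                        phase = as.numeric(phase))
  if (nrow(out) == 0L) stop_config("at least one source is required")
  if (any(!is.finite(unlist(out)))) stop_config("source fields must be finite")
  if (any(out$frequency <= 0)) stop_config("source `frequency` must be > 0")
  if (any(out$amplitude < 0)) stop_config("source `amplitude` must be >= 0")
  out
}

#' Describe the focused-ultrasound transducer
#'
#' The MHz carrier itself is unobservable at the recording rate; what the
#' recording contains is the pulse train at the pulse repetition frequency
#' (PRF), which acts as the effective carrier.  The beam/lead-field product
#' is collapsed to an isotropic Gaussian focal sensitivity of width
#' `focal_sigma`.
#'
#' @param prf Pulse repetition frequency in Hz.
#' @param pulse_width Pulse duration in seconds; must be < 1/prf.
#' @param carrier_phase Constant carrier phase in radians (kept for
#'   completeness; the pulse train is real-valued so it only shifts pulse
#'   timing and defaults to 0).
#' @param focal_sigma Gaussian focal-sensitivity width in mm.
#' @param gain Dimensionless acquisition gain.
#' @return A `transducer_spec` list.
#' @export
transducer_spec <- function(prf = 1000, pulse_width = 2e-4, carrier_phase = 0,
                            focal_sigma = 0.6, gain = 1) {
  check_number(prf, "prf", lower = 0, strict_lower = TRUE)
  check_number(pulse_width, "pulse_width", lower = 0, strict_lower = TRUE)
  if (pulse_width >= 1 / prf) {
    stop_config("`pulse_width` (%g s) must be shorter than one PRF period (%g s)",
                pulse_width, 1 / prf)
  }
  check_number(carrier_phase, "carrier_phase")
  check_number(focal_sigma, "focal_sigma", lower = 0, strict_lower = TRUE)
  check_number(gain, "gain")
  structure(list(prf = prf, pulse_width = pulse_width,
                 carrier_phase = carrier_phase,
                 focal_sigma = focal_sigma, gain = gain),
            class = "transducer_spec")
}

#' Configure a synthetic acoustoelectric phantom
#'
#' Bundles the sources, transducer and acquisition settings that define one
#' simulated experiment.  The acoustoelectric interaction constant and peak
#' focal pressure only enter through their product, the carrier amplitude
#' `A0 = ae_constant * pressure_peak`.
#'
#' @param sources Tibble from [source_spec()].
#' @param transducer A [transducer_spec()].
#' @param fs_record Recording sampling rate in Hz; must exceed `2 * prf`.
#' @param duration Record length in seconds.  Scenarios are chosen so that
#'   every source frequency completes an integer number of cycles, putting
#'   source lines exactly on harmonics of the record fundamental.
#' @param ae_constant Acoustoelectric interaction constant in 1/Pa
#'   (order 1e-9 in physiological saline).
#' @param pressure_peak Peak focal pressure in Pa.
#' @param modulation_index Depth of the pedestal amplitude modulation,
#'   in (0, 1].  Keeping it <= 1 keeps the envelope affine (and therefore
#'   sign- and phase-preserving) in the summed source signal.
#' @param lf_leak_gain Gain of the low-frequency leakage of the source
#'   drive into the recording (removed later by the PRF band-pass).
#' @param noise_sd Standard deviation of additive white Gaussian noise, in
#'   recording units.
#' @param seed Integer seed; fixes the noise realization.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(sources,
                           transducer = transducer_spec(),
                           fs_record = 20000,
                           duration = 2,
                           ae_constant = 1e-9,
                           pressure_peak = 1e6,
                           modulation_index = 0.8,
                           lf_leak_gain = 1,
                           noise_sd = 0,
                           seed = 1L) {
  if (!is.data.frame(sources) || nrow(sources) == 0L) {
    stop_config("`sources` must be a non-empty source_spec tibble")
  }
  sources <- source_spec(sources$x, sources$y, sources$frequency,
                         sources$amplitude, sources$phase)
  if (!inherits(transducer, "transducer_spec")) {
    stop_config("`transducer` must be a transducer_spec")
  }
  check_number(fs_record, "fs_record", lower = 2 * transducer$prf,
               strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  check_number(ae_constant, "ae_constant", lower = 0, strict_lower = TRUE)
  check_number(pressure_peak, "pressure_peak", lower = 0, strict_lower = TRUE)
  check_number(modulation_index, "modulation_index", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(lf_leak_gain, "lf_leak_gain", lower = 0)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(seed, "seed")
  cycles <- duration * sources$frequency
  if (any(abs(cycles - round(cycles)) > 1e-9)) {
    warn(paste("some source frequencies do not complete an integer number of",
               "cycles in `duration`; their lines will not coincide with fit",
               "harmonics (spectral leakage)"))
  }
  structure(list(sources = sources, transducer = transducer,
                 fs_record = fs_record, duration = duration,
                 ae_constant = ae_constant, pressure_peak = pressure_peak,
                 modulation_index = modulation_index,
                 lf_leak_gain = lf_leak_gain, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Define a rectangular scan grid
#'
#' @param x_min,x_max,x_step,y_min,y_max,y_step Grid extent and step in mm.
#' @return A `scan_grid` list with precomputed `x` and `y` coordinate vectors.
#' @examples
#' scan_grid(-9, 0, 1, -2, 2, 1)  # the 10 x 5 two-source scan region
#' @export
scan_grid <- function(x_min, x_max, x_step = 1, y_min, y_max, y_step = 1) {
  check_number(x_step, "x_step", lower = 0, strict_lower = TRUE)
  check_number(y_step, "y_step", lower = 0, strict_lower = TRUE)
  if (x_max < x_min || y_max < y_min) {
    stop_config("grid max must be >= min on each axis")
  }
  x <- seq(x_min, x_max, by = x_step)
  y <- seq(y_min, y_max, by = y_step)
  structure(list(x_min = x_min, x_max = x_max, x_step = x_step,
                 y_min = y_min, y_max = y_max, y_step = y_step,
                 x = x, y = y, n_spots = length(x) * length(y)),
            class = "scan_grid")
}

#' Raised-cosine pulse train at the pulse repetition frequency
#'
#' One smooth unit-peak pulse per PRF period, the first starting at t = 0.
#' Pulses are raised-cosine (Hann) shaped with support `pulse_width`,
#' sampled on a half-sample-offset grid and normalized to a peak of
#' exactly 1.
#'
#' @param transducer A [transducer_spec()].
#' @param fs Sampling rate in Hz (> 2 * prf).
#' @param duration Duration in seconds.
#' @return Numeric vector of length `round(duration * fs)` with values in
#'   \[0, 1\].
#' @export
make_pulse_train <- function(transducer, fs, duration) {
  if (!inherits(transducer, "transducer_spec")) {
    stop_config("`transducer` must be a transducer_spec")
  }
  check_number(fs, "fs", lower = 2 * transducer$prf, strict_lower = TRUE)
  check_number(duration, "duration", lower = 0, strict_lower = TRUE)
  n <- round(duration * fs)
  k <- max(1L, round(transducer$pulse_width * fs))
  shape <- sin(pi * (seq_len(k) - 0.5) / k)^2
  shape <- shape / max(shape)
  p <- numeric(n)
  n_pulses <- ceiling(duration * transducer$prf)
  # constant carrier_phase shifts pulse timing by phase/(2*pi) of a period
  t_shift <- transducer$carrier_phase / (2 * pi) / transducer$prf
  for (j in seq_len(n_pulses) - 1L) {
    start <- round((j / transducer$prf + t_shift) * fs)
    idx <- start + seq_len(k)          # 1-based: first sample at t = start/fs
    keep <- idx >= 1L & idx <= n
    p[idx[keep]] <- shape[keep]
  }
  p
}

#' Gaussian focal sensitivity weight
#'
#' Scalar stand-in for the lead-field/beam product: the contribution of a
#' source to the signal at a focal spot falls off as a Gaussian in the
#' focus-to-source distance.
#'
#' @param focus Numeric length-2 `(x, y)` focal-spot position in mm.
#' @param source Numeric length-2 source position, or a matrix/data frame
#'   of positions (columns x, y).
#' @param focal_sigma Gaussian width in mm (> 0).
#' @return Weight(s) in \[0, 1\]: `exp(-d^2 / (2 * focal_sigma^2))`.
#' @export
focal_weight <- function(focus, source, focal_sigma) {
  check_number(focal_sigma, "focal_sigma", lower = 0, strict_lower = TRUE)
  if (is.data.frame(source)) source <- cbind(source$x, source$y)
  if (is.null(dim(source))) source <- matrix(source, ncol = 2)
  d2 <- (source[, 1] - focus[[1]])^2 + (source[, 2] - focus[[2]])^2
  exp(-d2 / (2 * focal_sigma^2))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Simulate one acoustoelectric recording at a focal spot
#'
#' The recorded voltage is the sum of (i) the acoustoelectric component: the
#' PRF pulse train whose amplitude is pedestal-modulated by the
#' focal-weighted sum of the source drives, (ii) low-frequency leakage of
#' the raw source sum, and (iii) white Gaussian noise:
#' \deqn{V(t) = g\,p(t)\,A_0\,[1 + \mu M(t)/M_{max}] + g_{LF} S(t) + \epsilon(t)}
#' with \eqn{M(t)} the focal-weighted source sum, \eqn{M_{max}} its maximum
#' possible amplitude, \eqn{A_0} the carrier amplitude and \eqn{\mu} the
#' modulation index.
#'
#' @param config A [phantom_config()].
#' @param focus Numeric length-2 `(x, y)` focal position in mm.
#' @param seed Optional seed override (used by [simulate_scan()] to give
#'   each spot an independent, reproducible noise stream).
#' @return An `ae_recording`: a tibble with columns `time` (s) and
#'   `voltage`, carrying `fs`, `prf`, `focus` and `seed` attributes.
#' @examples
#' cfg <- phantom_config(source_spec(0, 0, frequency = 8), duration = 0.5)
#' rec <- simulate_recording(cfg, focus = c(0, 0))
#' @export
simulate_recording <- function(config, focus, seed = NULL) {
  if (!inherits(config, "phantom_config")) {
    stop_config("`config` must be a phantom_config")
  }
  if (length(focus) != 2L || !all(is.finite(as.numeric(unlist(focus))))) {
    stop_config("`focus` must be a finite (x, y) pair in mm")
  }
  focus <- as.numeric(unlist(focus))
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  tr <- config$transducer
  src <- config$sources
  n <- round(config$duration * config$fs_record)
  t <- (seq_len(n) - 1L) / config$fs_record

  w <- focal_weight(focus, src, tr$focal_sigma)
  drives <- lapply(seq_len(nrow(src)), function(i) {
    src$amplitude[i] * sin(2 * pi * src$frequency[i] * t + src$phase[i])
  })
  s_lf <- Reduce(`+`, drives)
  m <- Reduce(`+`, Map(`*`, w, drives))
  # global normalizer: the largest amplitude M(t) could attain at any focus
  # (all weights at 1), so modulation depth carries the spatial contrast
  m_max <- sum(src$amplitude)
  modulation <- if (m_max > 0) config$modulation_index * m / m_max else 0

  a0 <- config$ae_constant * config$pressure_peak
  p <- make_pulse_train(tr, config$fs_record, config$duration)
  v <- tr$gain * p * a0 * (1 + modulation) + config$lf_leak_gain * s_lf
  if (config$noise_sd > 0) {
    v <- v + with_seed(seed, rnorm(n, 0, config$noise_sd))
  }
  new_ae_tibble(tibble::tibble(time = t, voltage = v), "ae_recording",
                fs = config$fs_record, prf = tr$prf, focus = focus,
                seed = seed)
}

#' Simulate a full scan over a grid of focal spots
#'
#' Spots are visited row-major: all x positions of the first y row, then the
#' next row.  Spot `i` (1-based) uses seed `config$seed + i - 1`, so scans
#' are reproducible and spots statistically independent.
#'
#' @param config A [phantom_config()].
#' @param grid A [scan_grid()].
#' @return An `ae_scan` tibble with one row per spot: `spot`, `focus_x`,
#'   `focus_y`, `seed` and a `recording` list-column of `ae_recording`s.
#' @export
simulate_scan <- function(config, grid) {
  if (!inherits(grid, "scan_grid")) stop_config("`grid` must be a scan_grid")
  spots <- tidyr::expand_grid(focus_y = grid$y, focus_x = grid$x)[, c(2, 1)]
  spots <- dplyr::mutate(spots, spot = dplyr::row_number(),
                         seed = config$seed + dplyr::row_number() - 1L)
  recs <- purrr::pmap(spots, function(focus_x, focus_y, spot, seed) {
    simulate_recording(config, c(focus_x, focus_y), seed = seed)
  })
  out <- dplyr::bind_cols(spots[, c("spot", "focus_x", "focus_y", "seed")],
                          tibble::tibble(recording = recs))
  new_ae_tibble(out, "ae_scan", grid = grid, config = config)
}
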