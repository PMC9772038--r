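# Shared fixtures: small, fast phantom configurations.

# short single-source phantom; 0.5 s keeps unit tests quick while all
# default frequencies still complete integer cycles
quick_config <- function(frequency = 8, noise_sd = 0, lf_leak_gain = 1,
                         duration = 0.5, seed = 1L, ...) {
  phantom_config(source_spec(0, 0, frequency = frequency),
                 duration = duration, noise_sd = noise_sd,
                 lf_leak_gain = lf_leak_gain, seed = seed, ...)
}

# bare recording wrapper for synthetic test signals
as_recording <- function(x, fs, prf = 1000) {
  abidecode:::new_ae_tibble(
    tibble::tibble(time = (seq_along(x) - 1) / fs, voltage = x),
    "ae_recording", fs = fs, prf = prf)
}

# integer-period time grid
tgrid <- function(duration, fs) (seq_len(round(duration * fs)) - 1) / fs

# direct-summation discrete Fourier oracle for the harmonic fit
# (independent of the FFT path used by fourier_fit)
dft_oracle <- function(x) {
  n <- length(x)
  m <- n %/% 2
  t <- seq_len(n) - 1
  a <- b <- numeric(m)
  for (i in seq_len(m)) {
    a[i] <- 2 / n * sum(x * cos(i * 2 * pi * t / n))
    b[i] <- 2 / n * sum(x * sin(i * 2 * pi * t / n))
  }
  if (n %% 2 == 0) {
    a[m] <- sum(x * cos(pi * t)) / n
    b[m] <- 0
  }
  list(a0 = mean(x), a = a, b = b)
}
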