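#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns `x + i * H(x)`: negative frequencies are zeroed, positive
#' frequencies doubled (DC and, for even lengths, the Nyquist bin kept
#' as-is).  The real part equals the input exactly; the modulus is the
#' instantaneous amplitude (envelope).
#'
#' @param x Numeric vector, length >= 2.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop_input("`x` must be a numeric vector of length >= 2")
  }
  if (!all(is.finite(x))) stop_input("`x` contains non-finite samples")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- fft(h * fft(x), inverse = TRUE) / n
  complex(real = x, imaginary = Im(z))
}

#' Envelope decoder (DAE)
#'
#' The baseline decoder: the decoded timing signal is the magnitude of the
#' analytic signal of the band-passed recording, i.e. the instantaneous
#' amplitude A(t).  The reported scalar amplitude is the oscillation
#' amplitude of the envelope, `sqrt(2)` times the RMS of the mean-removed
#' envelope (exact for a single sinusoidal modulation).
#'
#' @param x An `ae_recording`, data frame with a voltage column, or numeric
#'   vector (then supply `fs`).
#' @param fs Sampling rate in Hz (taken from `x` when possible).
#' @return An `ae_decoded` tibble with columns `time` and `signal`, and
#'   attributes `method = "DAE"`, `fs`, `amplitude`, plus `envelope`
#'   (identical to `signal` for this decoder).
#' @examples
#' t <- seq(0, 1, by = 1 / 5000)[-5001]
#' x <- (1 + 0.5 * sin(2 * pi * 8 * t)) * cos(2 * pi * 1000 * t)
#' d <- dae_decode(x, fs = 5000)
#' attr(d, "amplitude")  # ~0.5
#' @export
dae_decode <- function(x, fs = NULL) {
  tr <- resolve_trace(x, fs)
  a <- Mod(analytic_signal(tr$samples))
  amp <- sqrt(2) * sqrt(mean((a - mean(a))^2))
  out <- tibble::tibble(time = (seq_along(a) - 1L) / tr$fs, signal = a)
  new_ae_tibble(out, "ae_decoded",
                fs = tr$fs, method = "DAE", envelope = a,
                selected_harmonic = NA_integer_, frequency = NA_real_,
                amplitude = amp, phase = NA_real_,
                focus = attr(x, "focus"))
}

#' Least-squares Fourier fit of an envelope
#'
#' Expands a trace into harmonics of the record fundamental `fs / n`:
#' \deqn{A(t) \approx a_0 + \sum_{i=1}^{m} a_i \cos(2\pi i t/n) + b_i \sin(2\pi i t/n)}
#' with `m = floor(n / 2)` and the time index running 0..n-1.  By the
#' orthogonality of the trigonometric basis the least-squares coefficients
#' are `a_i = (2/n) sum A_t cos(...)`, `b_i = (2/n) sum A_t sin(...)`,
#' `a_0 = mean(A)`; the harmonic amplitude is `c_i = sqrt(a_i^2 + b_i^2)`.
#' For even `n` the Nyquist harmonic `i = n/2` is cosine-only with a `1/n`
#' normalization, which makes the expansion exactly complete.
#'
#' Computed via the FFT; identical (to rounding) to the direct sums.
#'
#' @param a An envelope or decoded trace (tibble), or numeric vector
#'   (then supply `fs`).
#' @param fs Sampling rate in Hz.
#' @return A `harmonic_fit` object: list with `a0`, vectors `a`, `b`, `c`
#'   over harmonics 1..m, `n`, `fs`, `fundamental` (= fs/n, Hz) and the
#'   residual sum of squares `rss` of the full reconstruction (zero up to
#'   rounding, since the basis is complete).
#' @export
fourier_fit <- function(a, fs = NULL) {
  tr <- resolve_trace(a, fs)
  x <- tr$samples
  n <- length(x)
  if (n < 4L) stop_input("need at least 4 samples to fit harmonics")
  m <- n %/% 2L
  ft <- fft(x)
  idx <- seq_len(m) + 1L            # bins 1..m
  ai <- 2 / n * Re(ft[idx])
  bi <- -2 / n * Im(ft[idx])
  if (n %% 2L == 0L) {              # Nyquist term: cosine-only, weight 1/n
    ai[m] <- Re(ft[m + 1L]) / n
    bi[m] <- 0
  }
  a0 <- mean(x)
  # full-basis reconstruction via the inverse FFT of the coefficient
  # spectrum (equivalent to summing all m harmonics, O(n log n))
  spec <- complex(real = rep(0, n))
  spec[1] <- n * a0
  hi <- if (n %% 2L == 0L) m - 1L else m
  if (hi >= 1L) {
    spec[1L + seq_len(hi)] <- n / 2 * complex(real = ai[seq_len(hi)],
                                              imaginary = -bi[seq_len(hi)])
    spec[n + 1L - seq_len(hi)] <- Conj(spec[1L + seq_len(hi)])
  }
  if (n %% 2L == 0L) spec[m + 1L] <- n * ai[m]
  recon <- Re(fft(spec, inverse = TRUE) / n)
  fit <- structure(list(a0 = a0, a = ai, b = bi, c = sqrt(ai^2 + bi^2),
                        n = n, fs = tr$fs, fundamental = tr$fs / n,
                        rss = sum((x - recon)^2)),
                   class = "harmonic_fit")
  fit
}

# sum of selected harmonics on the t = 0..n-1 grid
reconstruct_harmonics <- function(a0, a, b, n, which) {
  t <- seq_len(n) - 1L
  out <- rep(a0, n)
  for (k in which) {
    w <- 2 * pi * k * t / n
    out <- out + a[k] * cos(w) + b[k] * sin(w)
  }
  out
}

#' Select the dominant harmonic in a frequency band
#'
#' Returns the index of the largest-amplitude harmonic whose frequency
#' falls inside `band` (default 1-50 Hz, which excludes drift and residual
#' PRF-beat components).  The DC term is never eligible; ties break toward
#' the lower index.
#'
#' @param decomp A `harmonic_fit`.
#' @param band Length-2 numeric `(low, high)` in Hz.
#' @return Integer harmonic index `k`; its frequency is
#'   `k * decomp$fundamental`.
#' @export
select_dominant <- function(decomp, band = c(1, 50)) {
  if (!inherits(decomp, "harmonic_fit")) {
    stop_input("`decomp` must be a harmonic_fit")
  }
  if (length(band) != 2L || !all(is.finite(band)) || band[2] <= band[1]) {
    stop_input("`band` must be an increasing (low, high) pair in Hz")
  }
  freq <- seq_along(decomp$c) * decomp$fundamental
  ok <- which(freq >= band[1] & freq <= band[2])
  if (length(ok) == 0L) {
    stop_input("no harmonic falls inside the band [%g, %g] Hz (fundamental %g Hz)",
               band[1], band[2], decomp$fundamental)
  }
  ok[which.max(decomp$c[ok])]       # which.max takes the first maximum: ties
}                                   # break toward the lowest index

#' Adaptive Fourier-fit decoder (aDAF)
#'
#' Envelope demodulation followed by a least-squares harmonic expansion of
#' the envelope; the decoded timing signal keeps the DC term plus the
#' single dominant harmonic inside `band`:
#' `a0 + a_k cos(2 pi k t / n) + b_k sin(2 pi k t / n)`.
#'
#' @inheritParams dae_decode
#' @param band Candidate frequency band in Hz passed to
#'   [select_dominant()].
#' @param top_m Number of largest harmonics to keep (default 1, the
#'   adaptive single-harmonic decoder; larger values are exploratory).
#' @return An `ae_decoded` tibble with attributes `method = "aDAF"`,
#'   `selected_harmonic` (k), `frequency` (k * fs / n, Hz), `amplitude`
#'   (c_k), `phase` (atan2(a_k, b_k), so the harmonic is
#'   `c_k sin(2 pi f t + phase)`), the `harmonic_fit`, and the envelope.
#' @examples
#' t <- seq(0, 2, by = 1 / 5000)[-10001]
#' x <- (1 + 0.5 * sin(2 * pi * 8 * t)) * cos(2 * pi * 1000 * t)
#' d <- adaf_decode(x, fs = 5000)
#' attr(d, "frequency")  # 8 Hz
#' @export
adaf_decode <- function(x, fs = NULL, band = c(1, 50), top_m = 1L) {
  check_number(top_m, "top_m", lower = 1)
  env <- dae_decode(x, fs)
  fit <- fourier_fit(attr(env, "envelope"), fs = attr(env, "fs"))
  k <- select_dominant(fit, band)
  keep <- k
  if (top_m > 1L) {
    freq <- seq_along(fit$c) * fit$fundamental
    ok <- which(freq >= band[1] & freq <= band[2])
    keep <- ok[order(fit$c[ok], decreasing = TRUE)][seq_len(min(top_m, length(ok)))]
  }
  y <- reconstruct_harmonics(fit$a0, fit$a, fit$b, fit$n, keep)
  out <- tibble::tibble(time = (seq_len(fit$n) - 1L) / fit$fs, signal = y)
  new_ae_tibble(out, "ae_decoded",
                fs = fit$fs, method = "aDAF", envelope = attr(env, "envelope"),
                selected_harmonic = as.integer(k),
                frequency = k * fit$fundamental,
                amplitude = fit$c[k],
                phase = atan2(fit$a[k], fit$b[k]),
                fit = fit, focus = attr(x, "focus"))
}

#' Decode a recording with either method
#'
#' Convenience dispatcher used by the scenario runner.
#'
#' @inheritParams adaf_decode
#' @param method `"dae"` or `"adaf"`.
#' @return An `ae_decoded` tibble.
#' @export
decode <- function(x, method = c("adaf", "dae"), fs = NULL, band = c(1, 50)) {
  method <- match.arg(tolower(method), c("adaf", "dae"))
  if (method == "dae") dae_decode(x, fs) else adaf_decode(x, fs, band)
}
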