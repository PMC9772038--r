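#' Pearson correlation between two traces
#'
#' @param a,b Equal-length numeric vectors (length >= 3), neither constant.
#' @return The product-moment correlation coefficient.
#' @export
pearson_corr <- function(a, b) {
  if (length(a) != length(b)) stop_input("traces must have equal length")
  if (length(a) < 3L) stop_input("need at least 3 samples")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop_input("non-finite samples")
  if (sd(a) == 0 || sd(b) == 0) {
    stop_input("correlation undefined for a constant trace")
  }
  stats::cor(a, b)
}

#' Correlation of a decoded trace with the known source sinusoid
#'
#' Builds the source waveform `sin(2 pi f t + phase)` on the decoded
#' trace's own time base and correlates after mean removal of both.
#'
#' @param decoded An `ae_decoded` tibble.
#' @param frequency Source frequency in Hz.
#' @param phase Source phase in radians (default 0).
#' @return Pearson correlation coefficient.
#' @export
source_correlation <- function(decoded, frequency, phase = 0) {
  check_number(frequency, "frequency", lower = 0, strict_lower = TRUE)
  src <- sin(2 * pi * frequency * decoded$time + phase)
  pearson_corr(decoded$signal - mean(decoded$signal), src - mean(src))
}

#' Decoded amplitude ratio between two traces
#'
#' Uses each decoder's amplitude convention: the dominant-harmonic
#' amplitude `c_k` for aDAF, and `sqrt(2)` times the RMS of the
#' mean-removed envelope for DAE (both stored in the `amplitude`
#' attribute at decode time).
#'
#' @param d1,d2 `ae_decoded` tibbles.
#' @return `amplitude(d1) / amplitude(d2)`.
#' @export
amplitude_ratio <- function(d1, d2) {
  a1 <- attr(d1, "amplitude")
  a2 <- attr(d2, "amplitude")
  if (is.null(a1) || is.null(a2)) stop_input("inputs must be decoded traces")
  if (!is.finite(a2) || a2 <= 0) stop_input("denominator amplitude must be > 0")
  a1 / a2
}

#' Relative improvement, in percent
#'
#' `100 * |new - old| / old`: the magnitude of the change of a quality
#' metric relative to its baseline value.  Aggregate improvements over
#' several cases are the unweighted mean of the per-case percentages.
#'
#' @param new,old Metric values; `old` must be > 0.  Vectorized.
#' @return Percent improvement(s).
#' @examples
#' relative_improvement(1.82, 1.60)                      # 13.75
#' mean(relative_improvement(0.99, c(0.79, 0.62, 0.83))) # 34.76
#' @export
relative_improvement <- function(new, old) {
  if (any(!is.finite(new)) || any(!is.finite(old))) {
    stop_input("values must be finite")
  }
  if (any(old <= 0)) stop_input("baseline `old` must be > 0")
  100 * abs(new - old) / old
}

#' One-sided magnitude spectrum
#'
#' FFT magnitude spectrum from 0 to fs/2, normalized so that an
#' integer-period unit-amplitude sinusoid reads 1.0 at its frequency.
#'
#' @param trace An `ae_decoded`/`ae_recording` tibble or numeric vector.
#' @param fs Sampling rate in Hz (taken from the object when possible).
#' @return A tibble with columns `frequency` (Hz) and `magnitude`.
#' @export
spectrum_tbl <- function(trace, fs = NULL) {
  tr <- resolve_trace(trace, fs)
  x <- tr$samples
  n <- length(x)
  if (n < 4L) stop_input("need at least 4 samples")
  ft <- fft(x)
  m <- n %/% 2L
  mag <- Mod(ft[seq_len(m + 1L)]) / n
  mag[2:(m + 1L)] <- 2 * mag[2:(m + 1L)]
  if (n %% 2L == 0L) mag[m + 1L] <- mag[m + 1L] / 2   # Nyquist bin unpaired
  tibble::tibble(frequency = (0:m) * tr$fs / n, magnitude = mag)
}

#' Compare both decoders on one preprocessed recording
#'
#' @param rec A raw `ae_recording`.
#' @param frequency True source frequency in Hz (for the correlation).
#' @param phase True source phase in radians.
#' @param band Candidate band for aDAF.
#' @param fs_out,halfwidth,order Preprocessing settings.
#' @return A two-row tibble (one per method) with `method`, `frequency`,
#'   `correlation`, `amplitude`.
#' @export
compare_decoders <- function(rec, frequency, phase = 0, band = c(1, 50),
                             fs_out = 5000, halfwidth = 30, order = 3) {
  pre <- preprocess(rec, fs_out = fs_out, halfwidth = halfwidth, order = order)
  purrr::map_dfr(c("dae", "adaf"), function(mth) {
    d <- decode(pre, method = mth, band = band)
    tibble::tibble(method = attr(d, "method"),
                   frequency = frequency,
                   correlation = source_correlation(d, frequency, phase),
                   amplitude = attr(d, "amplitude"))
  })
}
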