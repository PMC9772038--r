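#' Tidy a harmonic fit
#'
#' One row per harmonic: index, frequency, cosine/sine coefficients,
#' amplitude and phase (the harmonic is
#' `amplitude * sin(2 pi frequency t + phase)`).
#'
#' @param x A `harmonic_fit` from [fourier_fit()].
#' @param ... Unused.
#' @return A tibble with columns `harmonic`, `frequency`, `a`, `b`,
#'   `amplitude`, `phase`.
#' @export
tidy.harmonic_fit <- function(x, ...) {
  tibble::tibble(harmonic = seq_along(x$c),
                 frequency = seq_along(x$c) * x$fundamental,
                 a = x$a, b = x$b, amplitude = x$c,
                 phase = atan2(x$a, x$b))
}

#' Glance at a harmonic fit
#'
#' @inheritParams tidy.harmonic_fit
#' @return A one-row tibble: `a0`, `n`, `fs`, `fundamental`, `rss`,
#'   `dominant` (index of the largest harmonic in the default 1-50 Hz
#'   band) and `dominant_freq`.
#' @export
glance.harmonic_fit <- function(x, ...) {
  k <- tryCatch(select_dominant(x), error = function(e) NA_integer_)
  tibble::tibble(a0 = x$a0, n = x$n, fs = x$fs, fundamental = x$fundamental,
                 rss = x$rss, dominant = k,
                 dominant_freq = if (is.na(k)) NA_real_ else k * x$fundamental)
}

#' Tidy a decoded trace
#'
#' @param x An `ae_decoded` from [dae_decode()] or [adaf_decode()].
#' @param ... Unused.
#' @return The `time`/`signal` tibble with a `method` column prepended.
#' @export
tidy.ae_decoded <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), time = x$time, signal = x$signal)
}

#' Glance at a decoded trace
#'
#' @inheritParams tidy.ae_decoded
#' @return One-row tibble: `method`, `fs`, `selected_harmonic`,
#'   `frequency`, `amplitude`, `phase`.
#' @export
glance.ae_decoded <- function(x, ...) {
  tibble::tibble(method = attr(x, "method"), fs = attr(x, "fs"),
                 selected_harmonic = attr(x, "selected_harmonic"),
                 frequency = attr(x, "frequency"),
                 amplitude = attr(x, "amplitude"),
                 phase = attr(x, "phase"))
}
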