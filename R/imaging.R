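#' Assemble per-spot decoded amplitudes into an image
#'
#' @param grid The [scan_grid()] the amplitudes were measured on.
#' @param amplitudes Numeric vector, one non-negative value per focal spot,
#'   in [simulate_scan()] order (x fastest within each y row).
#' @return An `ae_image`: tibble with columns `x`, `y` (mm) and
#'   `amplitude`, carrying the grid coordinates and steps as attributes.
#' @export
build_image <- function(grid, amplitudes) {
  if (!inherits(grid, "scan_grid")) stop_config("`grid` must be a scan_grid")
  if (length(amplitudes) != grid$n_spots) {
    stop_input("expected %d amplitudes (one per focal spot), got %d",
               grid$n_spots, length(amplitudes))
  }
  if (!all(is.finite(amplitudes))) stop_input("amplitudes must be finite")
  if (any(amplitudes < 0)) stop_input("amplitudes must be non-negative")
  df <- tidyr::expand_grid(y = grid$y, x = grid$x)[, c("x", "y")]
  df$amplitude <- as.numeric(amplitudes)
  new_ae_tibble(df, "ae_image",
                x_coords = grid$x, y_coords = grid$y,
                x_step = grid$x_step, y_step = grid$y_step)
}

image_matrix <- function(img) {
  xs <- attr(img, "x_coords")
  ys <- attr(img, "y_coords")
  matrix(img$amplitude, nrow = length(ys), ncol = length(xs), byrow = TRUE,
         dimnames = NULL)
}

matrix_to_image <- function(m, xs, ys, x_step, y_step) {
  df <- tidyr::expand_grid(y = ys, x = xs)[, c("x", "y")]
  df$amplitude <- as.numeric(t(m))
  new_ae_tibble(df, "ae_image", x_coords = xs, y_coords = ys,
                x_step = x_step, y_step = y_step)
}

#' Interpolate an image onto a fine lattice
#'
#' Separable interpolation (along x, then along y) onto a regular lattice
#' of spacing `step` spanning the original extent.  The default `"cubic"`
#' mode uses natural cubic splines; `"linear"` is bilinear.  Original grid
#' nodes are reproduced exactly.
#'
#' @param img An `ae_image`.
#' @param step Output lattice spacing in mm (default 0.01).
#' @param method `"cubic"` (default) or `"linear"`.
#' @return An `ae_image` on the fine lattice.  Cubic interpolation can
#'   overshoot slightly below zero between nodes; negative values are
#'   clipped to 0 so the result remains a valid amplitude map.
#' @export
interpolate_image <- function(img, step = 0.01, method = c("cubic", "linear")) {
  method <- match.arg(method)
  check_number(step, "step", lower = 0, strict_lower = TRUE)
  xs <- attr(img, "x_coords")
  ys <- attr(img, "y_coords")
  if (length(xs) < 2L || length(ys) < 2L) {
    stop_input("need at least 2 grid points per axis to interpolate")
  }
  m <- image_matrix(img)
  fine_axis <- function(lo, hi) {
    seq(lo, by = step, length.out = floor(round((hi - lo) / step, 6)) + 1L)
  }
  xf <- fine_axis(xs[1], xs[length(xs)])
  yf <- fine_axis(ys[1], ys[length(ys)])
  interp1 <- function(x, y, xout) {
    if (method == "cubic") spline(x, y, xout = xout, method = "natural")$y
    else approx(x, y, xout = xout)$y
  }
  m1 <- t(apply(m, 1L, function(row) interp1(xs, row, xf)))
  m2 <- apply(m1, 2L, function(col) interp1(ys, col, yf))
  m2 <- matrix(m2, nrow = length(yf), ncol = length(xf))
  m2[m2 < 0] <- 0
  matrix_to_image(m2, xf, yf, step, step)
}

#' Convert an amplitude image to decibels
#'
#' Amplitude convention: `20 * log10(value / peak)`, floored at
#' `-dynamic_range`; the peak pixel maps to 0 dB.
#'
#' @param img An `ae_image`.
#' @param dynamic_range Display floor in dB (default 5, i.e. values below
#'   -5 dB are clipped to -5 dB).
#' @return An `ae_image_db` tibble with columns `x`, `y`, `db`.
#' @export
to_db <- function(img, dynamic_range = 5) {
  check_number(dynamic_range, "dynamic_range", lower = 0, strict_lower = TRUE)
  peak <- max(img$amplitude)
  if (peak <= 0) stop_input("image peak must be positive to convert to dB")
  db <- 20 * log10(pmax(img$amplitude, 0) / peak)
  db <- pmax(db, -dynamic_range)
  out <- tibble::tibble(x = img$x, y = img$y, db = db)
  new_ae_tibble(out, "ae_image_db",
                x_coords = attr(img, "x_coords"),
                y_coords = attr(img, "y_coords"),
                dynamic_range = dynamic_range, peak = peak)
}

#' Image signal-to-noise ratio
#'
#' Power-convention SNR in dB: `10 * log10(P_signal / P_noise)`, where
#' `P_signal` is the mean squared amplitude of the per-source ROI peak
#' pixels (one peak per circular ROI) and `P_noise` the mean squared
#' amplitude over all pixels outside every ROI.
#'
#' @param img An `ae_image` (typically interpolated).
#' @param source_positions Data frame or list of `(x, y)` source positions
#'   in mm.
#' @param roi_radius ROI radius around each source in mm (default 1.5).
#' @return SNR in dB (`Inf` with a warning if the background is exactly
#'   zero).
#' @export
compute_snr <- function(img, source_positions, roi_radius = 1.5) {
  check_number(roi_radius, "roi_radius", lower = 0, strict_lower = TRUE)
  pos <- if (is.data.frame(source_positions)) {
    cbind(source_positions$x, source_positions$y)
  } else if (is.list(source_positions)) {
    do.call(rbind, lapply(source_positions, as.numeric))
  } else {
    matrix(as.numeric(source_positions), ncol = 2, byrow = TRUE)
  }
  in_any_roi <- rep(FALSE, nrow(img))
  peaks <- numeric(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    d2 <- (img$x - pos[i, 1])^2 + (img$y - pos[i, 2])^2
    roi <- d2 <= roi_radius^2
    if (!any(roi)) stop_input("ROI %d contains no pixels", i)
    peaks[i] <- max(img$amplitude[roi])
    in_any_roi <- in_any_roi | roi
  }
  if (all(in_any_roi)) stop_input("background region is empty: shrink `roi_radius`")
  p_signal <- mean(peaks^2)
  p_noise <- mean(img$amplitude[!in_any_roi]^2)
  if (p_noise == 0) {
    warn("background power is exactly zero; SNR is +Inf")
    return(Inf)
  }
  10 * log10(p_signal / p_noise)
}

#' Extract a line profile from an image
#'
#' Nearest-row (or column) extraction at a fixed coordinate; run on the
#' interpolated image for sub-grid localization.
#'
#' @param img An `ae_image`.
#' @param axis `"x"` for a profile along x at fixed y, `"y"` for the
#'   converse.
#' @param fixed The fixed coordinate in mm; must lie within the extent.
#' @return An `ae_profile` tibble with columns `position` (mm, strictly
#'   increasing) and `value`.
#' @export
line_profile <- function(img, axis = c("x", "y"), fixed = 0) {
  axis <- match.arg(axis)
  xs <- attr(img, "x_coords")
  ys <- attr(img, "y_coords")
  along <- if (axis == "x") xs else ys
  across <- if (axis == "x") ys else xs
  if (fixed < min(across) || fixed > max(across)) {
    stop_input("`fixed` = %g mm is outside the image extent [%g, %g]",
               fixed, min(across), max(across))
  }
  at <- across[which.min(abs(across - fixed))]
  rows <- if (axis == "x") img$y == at else img$x == at
  sub <- img[rows, ]
  pos <- if (axis == "x") sub$x else sub$y
  o <- order(pos)
  new_ae_tibble(tibble::tibble(position = pos[o], value = sub$amplitude[o]),
                "ae_profile", axis = axis, fixed = at)
}

#' Source width at -3 dB
#'
#' Width of the contiguous interval around the profile peak where the
#' amplitude stays at or above `peak * 10^(-3/20)`; the crossing positions
#' are located by linear interpolation between samples.  This is the
#' resolution metric used for reconstructed source maps.
#'
#' @param profile An `ae_profile` (or data frame with `position`, `value`).
#' @return Width in mm.
#' @export
source_width_3db <- function(profile) {
  pos <- profile$position
  val <- profile$value
  if (length(pos) < 3L) stop_input("profile too short to measure a width")
  if (any(diff(pos) <= 0)) stop_input("profile positions must be strictly increasing")
  k <- which.max(val)
  if (k == 1L || k == length(val)) {
    stop_input("profile peak lies on the boundary; width not measurable")
  }
  thr <- val[k] * 10^(-3 / 20)
  cross_at <- function(i, j) {  # linear interpolation of the thr crossing
    pos[i] + (thr - val[i]) * (pos[j] - pos[i]) / (val[j] - val[i])
  }
  left <- k
  while (left > 1L && val[left - 1L] >= thr) left <- left - 1L
  lo <- if (left == 1L) pos[1L] else cross_at(left - 1L, left)
  right <- k
  nv <- length(val)
  while (right < nv && val[right + 1L] >= thr) right <- right + 1L
  hi <- if (right == nv) pos[nv] else cross_at(right + 1L, right)
  hi - lo
}

#' Decode every spot of a scan
#'
#' Runs the preprocessing chain and one decoder over each recording of a
#' scan and returns per-spot results; pipe into [build_image()] via
#' `scan_image()` or use directly.
#'
#' @param scan An `ae_scan` from [simulate_scan()].
#' @param method `"adaf"`, `"dae"`, or both; each recording is
#'   preprocessed once and decoded with every requested method.
#' @param fs_out,halfwidth,order Preprocessing settings (see
#'   [preprocess()]).
#' @param band Candidate band for [select_dominant()].
#' @return A tibble with `spot`, `focus_x`, `focus_y`, `method`,
#'   `amplitude`, `frequency`, one row per spot and method.
#' @export
decode_scan <- function(scan, method = c("adaf", "dae"), fs_out = 5000,
                        halfwidth = 30, order = 3, band = c(1, 50)) {
  method <- match.arg(method, several.ok = TRUE)
  res <- purrr::map2(scan$recording, scan$spot, function(rec, spot) {
    pre <- preprocess(rec, fs_out = fs_out, halfwidth = halfwidth,
                      order = order)
    purrr::map_dfr(method, function(mth) {
      d <- decode(pre, method = mth, band = band)
      tibble::tibble(spot = spot, method = attr(d, "method"),
                     amplitude = attr(d, "amplitude"),
                     frequency = attr(d, "frequency"))
    })
  })
  dplyr::left_join(dplyr::bind_rows(res),
                   scan[, c("spot", "focus_x", "focus_y")], by = "spot") |>
    dplyr::select("spot", "focus_x", "focus_y", "method", "amplitude",
                  "frequency")
}

#' Reconstruct an image from a scan with one decoder
#'
#' @inheritParams decode_scan
#' @param interp_step If not `NULL`, interpolate the map at this spacing
#'   (mm) before returning.
#' @return An `ae_image`.
#' @export
scan_image <- function(scan, method = c("adaf", "dae"), interp_step = NULL,
                       ...) {
  method <- match.arg(method)
  dec <- decode_scan(scan, method = method, ...)
  img <- build_image(attr(scan, "grid"), dec$amplitude[order(dec$spot)])
  if (!is.null(interp_step)) img <- interpolate_image(img, step = interp_step)
  img
}
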