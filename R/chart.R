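# Campbell-Robson chart and Gabor grating rendering with noisy-bit dithering,
# plus the chart's log axis mappings.

#' Campbell-Robson chart specification
#'
#' Geometry and axis ranges for a rendered Campbell-Robson chart: the carrier
#' frequency sweeps logarithmically from `sf_lo` (left) to `sf_hi` (right) and
#' the Michelson contrast sweeps logarithmically from `c_hi` (bottom) to
#' `c_lo` (top), so stripes fade out towards the top of the image. The default
#' is the 1920 x 1080 px, 14.4 x 8.12 degree configuration;
#' `chart_spec_ubc()` gives the 1920 x 1200 px, 9-degree-tall variant.
#'
#' @param sf_lo,sf_hi Frequency axis endpoints, cycles per degree.
#' @param c_lo,c_hi Michelson contrast endpoints in `(0, 1]`, `c_lo < c_hi`.
#' @param width_deg,height_deg Extent in degrees of visual angle.
#' @param width_px,height_px Pixel dimensions.
#' @param mean_level Background gray level on the continuous 8-bit scale.
#' @return An object of class `chart_spec`.
#' @export
chart_spec <- function(sf_lo = 0.16, sf_hi = 40, c_lo = 0.001, c_hi = 0.5,
                       width_deg = 14.4, height_deg = 8.12,
                       width_px = 1920, height_px = 1080,
                       mean_level = 127.5) {
  if (!(sf_lo > 0 && sf_hi > sf_lo)) {
    stop("chart_spec: need 0 < sf_lo < sf_hi", call. = FALSE)
  }
  if (!(c_lo > 0 && c_hi > c_lo && c_hi <= 1)) {
    stop("chart_spec: need 0 < c_lo < c_hi <= 1", call. = FALSE)
  }
  if (width_deg <= 0 || height_deg <= 0 || width_px < 2 || height_px < 2) {
    stop("chart_spec: extents must be positive", call. = FALSE)
  }
  if (sf_hi >= width_px / (2 * width_deg)) {
    stop(sprintf(
      "chart_spec: sf_hi = %g cpd violates Nyquist (limit %.2f cpd at %d px over %g deg)",
      sf_hi, width_px / (2 * width_deg), width_px, width_deg), call. = FALSE)
  }
  structure(list(sf_lo = sf_lo, sf_hi = sf_hi, c_lo = c_lo, c_hi = c_hi,
                 width_deg = width_deg, height_deg = height_deg,
                 width_px = width_px, height_px = height_px,
                 mean_level = mean_level),
            class = "chart_spec")
}

#' @rdname chart_spec
#' @export
chart_spec_ubc <- function() {
  chart_spec(height_deg = 9, height_px = 1200)
}

#' Chart frequency axis mapping
#'
#' `sf_at` maps a horizontal fraction `u` (0 = left) to the spatial frequency
#' labelled at that column, `sf = sf_lo * (sf_hi / sf_lo)^u`; `sf_frac` is its
#' inverse.
#'
#' @param chart A [chart_spec].
#' @param u Horizontal fraction(s) in `[0, 1]`.
#' @param sf Spatial frequency (cycles per degree) within the chart range.
#' @return `sf_at`: cycles per degree; `sf_frac`: fraction(s).
#' @export
sf_at <- function(chart, u) {
  if (any(!is.finite(u)) || any(u < 0) || any(u > 1)) {
    stop("sf_at: u must lie in [0, 1]", call. = FALSE)
  }
  chart$sf_lo * (chart$sf_hi / chart$sf_lo)^u
}

#' @rdname sf_at
#' @export
sf_frac <- function(chart, sf) {
  log(sf / chart$sf_lo) / log(chart$sf_hi / chart$sf_lo)
}

#' Chart contrast axis mapping
#'
#' `contrast_at` maps a vertical fraction `v` measured from the *bottom*
#' (0 = bottom row, maximum contrast) to the Michelson contrast at that row,
#' `contrast = c_hi * (c_lo / c_hi)^v`; `contrast_frac` is its inverse.
#'
#' @param chart A [chart_spec].
#' @param v Vertical fraction(s) from the bottom, in `[0, 1]`.
#' @param contrast Michelson contrast within the chart range.
#' @return `contrast_at`: Michelson contrast; `contrast_frac`: fraction(s).
#' @export
contrast_at <- function(chart, v) {
  if (any(!is.finite(v)) || any(v < 0) || any(v > 1)) {
    stop("contrast_at: v must lie in [0, 1]", call. = FALSE)
  }
  chart$c_hi * (chart$c_lo / chart$c_hi)^v
}

#' @rdname contrast_at
#' @export
contrast_frac <- function(chart, contrast) {
  log(contrast / chart$c_hi) / log(chart$c_lo / chart$c_hi)
}

#' Noisy-bit dithering
#'
#' Stochastic rounding of continuous luminance levels to integer display
#' levels: level `L` becomes `floor(L) + 1` with probability `frac(L)` and
#' `floor(L)` otherwise, so the expected displayed value equals the ideal
#' value. Spatial pooling of the independent per-pixel draws extends the
#' effective luminance resolution beyond 8 bits. Out-of-range input is
#' clipped to `[0, 255]` with a warning.
#'
#' @param level Numeric vector, matrix or array of ideal levels in
#'   `[0, 255]`.
#' @param seed Optional integer; when given, the draws come from a local
#'   seeded stream (the caller's RNG state is untouched).
#' @return Integer levels with the same dimensions as `level`.
#' @export
#' @examples
#' table(noisy_bit(rep(100.25, 1e4), seed = 1))
noisy_bit <- function(level, seed = NULL) {
  draw <- function() {
    if (any(level < 0) || any(level > 255)) {
      warning("noisy_bit: levels outside [0, 255] clipped")
      level <- pmin(pmax(level, 0), 255)
    }
    fl <- floor(level)
    out <- fl + (stats::runif(length(level)) < (level - fl))
    storage.mode(out) <- "integer"
    dim(out) <- dim(level)
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Render a Campbell-Robson chart
#'
#' Builds the chart image row by row. The ideal continuous luminance at
#' column fraction `u` and row with bottom-fraction `v` is
#' `mean_level * (1 + contrast_at(v) * sin(2 * pi * Phi(u)))`, where `Phi` is
#' the cumulative phase of the log-swept carrier,
#' `Phi(x) = sf_lo * W * (r^(x/W) - 1) / log(r)` with `r = sf_hi / sf_lo` and
#' `W` the chart width in degrees. Using the phase integral (rather than
#' `sin(2 pi sf(x) x)`) makes the *local* frequency at every column equal the
#' labelled axis value. With `dither = TRUE` the continuous image is
#' quantised with [noisy_bit].
#'
#' @param chart A [chart_spec].
#' @param dither Apply noisy-bit quantisation? Default `TRUE`.
#' @param seed Seed for the dither stream (required reproducibility hook;
#'   ignored when `dither = FALSE`).
#' @return A `height_px` x `width_px` matrix; row 1 is the top of the chart.
#'   Integer levels when dithered, continuous otherwise.
#' @export
render_chart <- function(chart, dither = TRUE, seed = 1) {
  stopifnot(inherits(chart, "chart_spec"))
  u <- (seq_len(chart$width_px) - 0.5) / chart$width_px
  x <- u * chart$width_deg
  r <- chart$sf_hi / chart$sf_lo
  phase <- chart$sf_lo * chart$width_deg * (r^(x / chart$width_deg) - 1) / log(r)
  carrier <- sin(2 * pi * phase)
  v <- (chart$height_px - seq_len(chart$height_px) + 0.5) / chart$height_px
  contrast <- contrast_at(chart, v)
  img <- chart$mean_level * (1 + outer(contrast, carrier))
  if (dither) noisy_bit(img, seed = seed) else img
}

#' Gabor grating specification
#'
#' A sinusoidal grating revealed through a Gaussian window, as used for the
#' gold-standard threshold measurements.
#'
#' @param sf Spatial frequency, cycles per degree; positive.
#' @param contrast Michelson contrast at the envelope centre, in `(0, 1]`
#'   (0 is accepted and yields a uniform field).
#' @param orientation `"vertical"` (stripes vary along x) or `"horizontal"`.
#' @param window_fwhm_deg Full width at half maximum of the Gaussian window,
#'   degrees of visual angle (default 2).
#' @param size_deg Image extent in degrees (square).
#' @param size_px Image extent in pixels (square).
#' @param mean_level Background gray level.
#' @return An object of class `grating_spec`.
#' @export
grating_spec <- function(sf, contrast,
                         orientation = c("vertical", "horizontal"),
                         window_fwhm_deg = 2, size_deg = 6, size_px = 512,
                         mean_level = 127.5) {
  orientation <- match.arg(orientation)
  if (!(sf > 0)) stop("grating_spec: sf must be positive", call. = FALSE)
  if (contrast < 0 || contrast > 1) {
    stop("grating_spec: contrast must lie in [0, 1]", call. = FALSE)
  }
  if (sf >= size_px / (2 * size_deg)) {
    stop(sprintf(
      "grating_spec: sf = %g cpd violates Nyquist (limit %.2f cpd)",
      sf, size_px / (2 * size_deg)), call. = FALSE)
  }
  structure(list(sf = sf, contrast = contrast, orientation = orientation,
                 window_fwhm_deg = window_fwhm_deg, size_deg = size_deg,
                 size_px = size_px, mean_level = mean_level),
            class = "grating_spec")
}

#' Render a Gabor grating
#'
#' Cosine-phase sinusoid along the axis orthogonal to the grating
#' orientation, multiplied by a Gaussian envelope whose FWHM is
#' `window_fwhm_deg`, on a uniform background: the Michelson contrast at the
#' envelope centre equals `contrast`. Horizontal and vertical renders of the
#' same spec are exact transposes.
#'
#' @param g A [grating_spec].
#' @param dither Apply noisy-bit quantisation? Default `TRUE`.
#' @param seed Seed for the dither stream.
#' @return A `size_px` x `size_px` matrix (integer when dithered).
#' @export
render_grating <- function(g, dither = TRUE, seed = 1) {
  stopifnot(inherits(g, "grating_spec"))
  n <- g$size_px
  coord <- ((seq_len(n) - (n + 1) / 2)) * g$size_deg / n  # degrees, centred
  sigma <- g$window_fwhm_deg / (2 * sqrt(2 * log(2)))
  envelope <- exp(-outer(coord^2, coord^2, "+") / (2 * sigma^2))
  wave <- cos(2 * pi * g$sf * coord)
  carrier <- if (g$orientation == "vertical") {
    matrix(wave, n, n, byrow = TRUE)   # varies along x (columns)
  } else {
    matrix(wave, n, n, byrow = FALSE)  # varies along y (rows)
  }
  img <- g$mean_level * (1 + g$contrast * envelope * carrier)
  if (dither) noisy_bit(img, seed = seed) else img
}
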