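## Spectral quantification of pulsatility: per-frame mean velocity, short-time
## Fourier transform, fundamental/harmonic amplitudes, heart rate and
## displacement amplitude.
##
## Timing: differential frames carry true mid-interval timestamps. Because only
## MB-1 of every MB consecutive tau_B intervals are measured (the last B-scan
## of a position pairs with nothing), the series has one missing tau_B slot per
## position boundary. Spectral analysis, phase gating and displacement
## integration therefore regrid the series onto the uniform tau_B grid with
## linear in-fill of those gaps, which keeps the frequency axis exact. Plain
## numeric series are taken as already uniform.

#' Per-frame mean chorioscleral velocity
#'
#' Averages the angle-corrected velocity over the valid A-scans of each
#' differential frame inside a rectangular region of interest. Frames with
#' fewer than 10% valid A-scans are in-filled by linear interpolation along
#' the frame axis and flagged.
#'
#' @param field A `velocity_field` (ideally after [clean_series()]).
#' @param roi Optional list with `x = c(lo, hi)` (A-scan range) and
#'   `frames = c(lo, hi)`; defaults to the full extent.
#' @param min_valid Minimum fraction of valid A-scans per frame.
#' @return A tibble with `frame`, `time` (s), `v` (m/s), `valid_frac` and
#'   `interpolated`.
#' @export
frame_mean_velocity <- function(field, roi = NULL, min_valid = 0.1) {
  if (!inherits(field, "velocity_field"))
    stop_usage("field must be a velocity_field")
  X <- nrow(field$v_rcs); Fn <- ncol(field$v_rcs)
  xr <- roi$x %||% c(1, X)
  fr <- roi$frames %||% c(1, Fn)
  if (xr[1] < 1 || xr[2] > X || fr[1] < 1 || fr[2] > Fn || xr[1] > xr[2] ||
      fr[1] > fr[2])
    stop_usage("empty or out-of-range roi")
  xi <- xr[1]:xr[2]; fi <- fr[1]:fr[2]
  vv <- field$v_rcs[xi, fi, drop = FALSE]
  ok <- field$valid[xi, fi, drop = FALSE] | field$interpolated[xi, fi, drop = FALSE]
  vv[!ok] <- NA
  v <- colMeans(vv, na.rm = TRUE)
  vf <- colMeans(ok)
  v[vf == 0] <- NA
  low <- vf < min_valid | is.na(v)
  interpolated <- low
  if (any(low) && any(!low)) {
    okf <- which(!low)
    v[low] <- approx(okf, v[okf], xout = seq_along(v), rule = 2)$y[low]
  }
  tibble(frame = fi, time = field$frame_stats$time[fi], v = v,
         valid_frac = vf, interpolated = interpolated)
}

# Regrid a timestamped series onto the uniform dt grid (linear in-fill).
regrid_series <- function(v, time = NULL, dt = NULL) {
  if (is.null(time)) {
    if (is.null(dt)) dt <- 1
    return(list(v = v, dt = dt, t0 = 0,
                measured = rep(TRUE, length(v))))
  }
  if (is.null(dt)) dt <- min(diff(time))
  grid <- seq(time[1], time[length(time)] + dt / 4, by = dt)
  vg <- approx(time, v, xout = grid, rule = 2)$y
  measured <- vapply(grid, function(g) any(abs(time - g) < dt / 4), logical(1))
  list(v = vg, dt = dt, t0 = grid[1], measured = measured)
}

as_series <- function(series) {
  if (is.data.frame(series)) {
    if (!all(c("time", "v") %in% names(series)))
      stop_usage("a series data frame needs 'time' and 'v' columns")
    list(v = series$v, time = series$time)
  } else {
    list(v = as.numeric(series), time = NULL)
  }
}

#' Short-time Fourier spectra of a velocity series
#'
#' Sliding-window amplitude spectra of the detrended, Hann-tapered series.
#' The step is `window * (1 - overlap)` frames, giving
#' `floor((N - window)/step) + 1` windows (a 1200-frame series at the default
#' 256/75% settings yields 15 windows). Amplitudes are taper-gain compensated
#' so a pure sinusoid of amplitude V produces a peak of height V.
#'
#' @param series Numeric vector (uniform sampling assumed) or a tibble with
#'   `time` and `v` columns as produced by [frame_mean_velocity()] (regridded
#'   onto the uniform `dt` grid first).
#' @param window Window length in frames (default 256).
#' @param overlap Fractional window overlap in \[0, 1) (default 0.75).
#' @param taper `"hann"` (default) or `"rect"`.
#' @param dt Frame period in seconds; defaults to the series' own spacing, or
#'   1 (frequencies in cycles/frame) for plain numeric input.
#' @param detrend Remove a per-window linear trend before the FFT (default
#'   TRUE; suppresses residual drift leaking into the lowest bins).
#' @return A `pulse_spectrum`: `freq` (Hz), `bands` (amplitude, one column per
#'   window), `mean_spectrum`, `window_count` and the parameters.
#' @export
stft_spectra <- function(series, window = 256, overlap = 0.75,
                         taper = c("hann", "rect"), dt = NULL,
                         detrend = TRUE) {
  taper <- match.arg(taper)
  s <- as_series(series)
  rg <- regrid_series(s$v, s$time, dt)
  v <- rg$v; dt <- rg$dt
  N <- length(v)
  if (N < window)
    stop_usage("series (", N, " frames) shorter than the STFT window (",
               window, "): use a smaller window")
  if (overlap < 0 || overlap >= 1) stop_usage("overlap must be in [0, 1)")
  step <- max(1L, as.integer(round(window * (1 - overlap))))
  count <- floor((N - window) / step) + 1
  w <- if (taper == "hann")
    0.5 - 0.5 * cos(2 * pi * seq(0, window - 1) / (window - 1))
  else rep(1, window)
  nf <- floor(window / 2)
  freq <- (1:nf) / (window * dt)
  bands <- matrix(NA_real_, nf, count)
  idx0 <- seq_len(window)
  for (k in seq_len(count)) {
    seg <- v[(k - 1) * step + idx0]
    if (detrend) {
      fitc <- lsfit(idx0, seg)$coefficients
      seg <- seg - (fitc[1] + fitc[2] * idx0)
    } else {
      seg <- seg - mean(seg)
    }
    sp <- fft(seg * w)
    bands[, k] <- 2 * Mod(sp[2:(nf + 1)]) / sum(w)
  }
  structure(list(freq = freq, bands = bands,
                 mean_spectrum = rowMeans(bands),
                 window = window, overlap = overlap, taper = taper, dt = dt,
                 window_count = count, normalization = "raw",
                 f0 = NA_real_, A_fund = NA_real_, A_harm1 = NA_real_,
                 A_harm2 = NA_real_, no_pulsation = NA),
            class = "pulse_spectrum")
}

#' @export
print.pulse_spectrum <- function(x, ...) {
  cat(sprintf("<pulse_spectrum> %d windows of %d frames (%.0f%% overlap), %d bins up to %.2f Hz\n",
              x$window_count, x$window, 100 * x$overlap, length(x$freq),
              max(x$freq)))
  if (!is.na(x$f0))
    cat(sprintf("  f0 = %.3f Hz (%.0f bpm), A_fund = %.3g, A_harm1 = %.3g\n",
                x$f0, heart_rate_bpm(x$f0), x$A_fund, x$A_harm1))
  invisible(x)
}

#' Fundamental and harmonic amplitudes of the mean spectrum
#'
#' The fundamental frequency f0 is the location of the highest mean-spectrum
#' amplitude inside the heart-rate search band; harmonic amplitudes are the
#' maxima within +/-1 bin of the integer multiples of f0. If no peak rises at
#' least 3x above the spectrum median, a "no pulsation detected" flag is set
#' (with a warning) and the amplitudes are still returned.
#'
#' @param spectrum A `pulse_spectrum`.
#' @param hr_band Heart-rate search band in Hz (default 2-10 Hz).
#' @return The spectrum with `f0`, `A_fund`, `A_harm1`, `A_harm2` and
#'   `no_pulsation` populated.
#' @export
extract_fundamental <- function(spectrum, hr_band = c(2, 10)) {
  if (!inherits(spectrum, "pulse_spectrum"))
    stop_usage("spectrum must be a pulse_spectrum")
  freq <- spectrum$freq; m <- spectrum$mean_spectrum
  if (hr_band[2] >= max(freq))
    stop_usage("hr_band exceeds the spectral range (Nyquist ",
               sprintf("%.2f", max(freq)), " Hz)")
  in_band <- which(freq >= hr_band[1] & freq <= hr_band[2])
  if (length(in_band) == 0) stop_usage("hr_band contains no frequency bin")
  k0 <- in_band[which.max(m[in_band])]
  f0 <- freq[k0]
  harm_amp <- function(mult) {
    kh <- which.min(abs(freq - mult * f0))
    lo <- max(1, kh - 1); hi <- min(length(freq), kh + 1)
    if (abs(freq[kh] - mult * f0) > 1.5 * (freq[2] - freq[1])) return(NA_real_)
    max(m[lo:hi])
  }
  spectrum$f0 <- f0
  spectrum$A_fund <- m[k0]
  spectrum$A_harm1 <- harm_amp(2)
  spectrum$A_harm2 <- harm_amp(3)
  spectrum$no_pulsation <- m[k0] < 3 * median(m)
  if (isTRUE(spectrum$no_pulsation))
    warning("no pulsation detected: fundamental peak is not 3x above the ",
            "spectrum median", call. = FALSE)
  spectrum
}

#' Heart rate in beats per minute
#'
#' @param f0 Fundamental frequency in Hz.
#' @return `60 * f0` in bpm.
#' @examples
#' heart_rate_bpm(3.8)  # 228 bpm
#' @export
heart_rate_bpm <- function(f0) {
  if (any(f0 <= 0)) stop_usage("f0 must be positive")
  60 * f0
}

#' Peak-to-peak displacement amplitude from a velocity series
#'
#' Integrates the mean-removed velocity over time (cumulative sum times the
#' frame period) and reports the mean peak-to-peak excursion of the resulting
#' displacement over `n_cycles` consecutive cardiac cycles. For a sinusoidal
#' velocity of amplitude V at frequency f this equals `V / (pi * f)`.
#'
#' @param series Numeric vector or a `time`/`v` tibble (regridded first).
#' @param f0 Fundamental frequency in Hz.
#' @param n_cycles Number of consecutive cycles to average (default 5).
#' @param dt Frame period in seconds (required for plain numeric input unless
#'   frequencies are in cycles/frame).
#' @return Mean peak-to-peak displacement in meters.
#' @export
displacement_amplitude <- function(series, f0, n_cycles = 5, dt = NULL) {
  if (missing(f0) || is.null(f0) || is.na(f0) || f0 <= 0)
    stop_usage("displacement_amplitude needs the fundamental frequency f0")
  s <- as_series(series)
  rg <- regrid_series(s$v, s$time, dt)
  v <- rg$v; dt <- rg$dt
  cyc <- 1 / (f0 * dt)
  if (length(v) < n_cycles * cyc)
    stop_usage("series too short: needs at least ", n_cycles,
               " cardiac cycles (", ceiling(n_cycles * cyc), " frames)")
  d <- cumsum(v - mean(v)) * dt
  pp <- vapply(seq_len(n_cycles), function(c) {
    lo <- floor((c - 1) * cyc) + 1
    hi <- min(length(d), ceiling(c * cyc))
    max(d[lo:hi]) - min(d[lo:hi])
  }, numeric(1))
  mean(pp)
}

#' Normalize spectral amplitudes to the per-subject maximum
#'
#' Divides each subject's amplitudes by that subject's maximum response, so
#' the maximum maps to 1. Scale-invariant statistics (such as the coefficient
#' of variation of repeated measurements) are unchanged.
#'
#' @param amplitudes Numeric vector of spectral amplitudes.
#' @param subject Optional grouping vector (same length); if omitted all
#'   values belong to one subject.
#' @return Normalized amplitudes.
#' @export
normalize_per_subject <- function(amplitudes, subject = NULL) {
  if (length(amplitudes) < 1) stop_usage("need at least one measurement")
  if (is.null(subject)) subject <- rep(1L, length(amplitudes))
  out <- numeric(length(amplitudes))
  for (s in unique(subject)) {
    idx <- subject == s
    mx <- max(amplitudes[idx])
    if (mx <= 0) stop_usage("all-zero amplitudes for subject '", s,
                            "': cannot normalize")
    out[idx] <- amplitudes[idx] / mx
  }
  out
}
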