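## Retrospective cardiac gating of the velocity data: instantaneous cardiac
## phase from the band-passed analytic signal, 20-bin phase binning with
## 3-adjacent-bin averaging, and velocity thresholding for region analysis.

# analytic signal via the one-sided spectrum (Hilbert transform)
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

#' Assign a cardiac phase to every frame
#'
#' Band-passes the per-frame mean velocity around the fundamental frequency
#' (+/- 30%), takes the instantaneous phase of the analytic signal and maps it
#' to \[0, 1) with phase 0 at the positive-going zero crossing of the
#' velocity. The instantaneous phase tolerates heart-rate drift over the
#' acquisition, unlike rigid folding at a fixed f0. Timestamped series are
#' regridded onto the uniform frame grid first and the phases sampled back at
#' the measured frames.
#'
#' @param series Numeric vector or `time`/`v` tibble from
#'   [frame_mean_velocity()].
#' @param f0 Fundamental frequency in Hz from [extract_fundamental()].
#' @param dt Frame period in seconds (for plain numeric input).
#' @param band Relative band half-width (default 0.3).
#' @return A `cardiac_gating` tibble with `frame`, `phase` in \[0, 1) and the
#'   attributes `f0` and `n_frames`.
#' @export
assign_cardiac_phase <- function(series, f0, dt = NULL, band = 0.3) {
  if (missing(f0) || is.null(f0) || is.na(f0) || f0 <= 0)
    stop_usage("cardiac gating needs a detected fundamental frequency f0 ",
               "(no pulsation detected?)")
  s <- as_series(series)
  rg <- regrid_series(s$v, s$time, dt)
  v <- rg$v; dt <- rg$dt
  fs <- 1 / dt
  lo <- (1 - band) * f0 / (fs / 2)
  hi <- min(0.99, (1 + band) * f0 / (fs / 2))
  if (lo <= 0 || lo >= hi)
    stop_usage("f0 incompatible with the frame rate: cannot band-pass")
  bf <- signal::butter(2, c(lo, hi), type = "pass")
  vf <- signal::filtfilt(bf, v - mean(v))
  a <- analytic_signal(vf)
  # arg(analytic) of sin(2*pi*f*t) is 2*pi*f*t - pi/2; shift so that phase 0
  # sits at the positive-going zero crossing and a velocity maximum maps to
  # 0.25
  phase <- ((Arg(a) + pi / 2) / (2 * pi)) %% 1
  idx <- if (is.null(s$time)) seq_along(s$v) else which(rg$measured)
  idx <- idx[seq_len(min(length(idx), length(s$v)))]
  out <- tibble(frame = seq_along(s$v), phase = phase[idx])
  attr(out, "f0") <- f0
  attr(out, "dt") <- dt
  class(out) <- c("cardiac_gating", class(out))
  out
}

#' Gate velocity maps over the cardiac cycle and average
#'
#' Divides the heart cycle into `n_bins` sections of equal duration and, for
#' each section, averages the per-A-scan velocity over all frames whose
#' section lies within the `n_adjacent`-wide window centered on it (3 adjacent
#' sections by default, cyclic). Positions with no frame in a bin's window are
#' flagged empty (rendered missing, never interpolated).
#'
#' @param field A `velocity_field`.
#' @param gating A `cardiac_gating` from [assign_cardiac_phase()] covering the
#'   field's frames.
#' @param n_bins Number of equal phase sections (default 20).
#' @param n_adjacent Width of the averaging window in sections; must be odd
#'   (a center bin is required).
#' @return A `gated_maps` object: `maps` (X by NB by n_bins array of mean
#'   velocities, NA where empty), `counts` (frames per bin, window width 1)
#'   and `bin` (per-frame bin assignment).
#' @export
gate_and_average <- function(field, gating, n_bins = 20, n_adjacent = 3) {
  if (!inherits(field, "velocity_field"))
    stop_usage("field must be a velocity_field")
  if (n_adjacent %% 2 == 0)
    stop_usage("n_adjacent must be odd: the averaging window needs a center bin")
  n_frames <- ncol(field$v_rcs)
  if (nrow(gating) < n_frames)
    stop_usage("gating does not cover all ", n_frames, " frames")
  phase <- gating$phase[seq_len(n_frames)]
  bin <- pmin(floor(phase * n_bins), n_bins - 1)   # 0-based bins
  X <- nrow(field$v_rcs)
  NB <- max(field$frame_stats$b)
  half <- (n_adjacent - 1) / 2
  maps <- array(NA_real_, dim = c(X, NB, n_bins))
  vv <- field$v_rcs
  vv[!(field$valid | field$interpolated)] <- NA
  fb <- field$frame_stats$b
  for (bn in 0:(n_bins - 1)) {
    inwin <- ((bin - bn + half) %% n_bins) <= (n_adjacent - 1)
    if (!any(inwin)) next
    for (p in unique(fb[inwin])) {
      sel <- inwin & fb == p
      m <- rowMeans(vv[, sel, drop = FALSE], na.rm = TRUE)
      m[is.nan(m)] <- NA
      maps[, p, bn + 1] <- m
    }
  }
  structure(list(maps = maps, counts = tabulate(bin + 1, nbins = n_bins),
                 bin = bin, n_bins = n_bins, n_adjacent = n_adjacent,
                 units = "m/s"),
            class = "gated_maps")
}

#' @export
print.gated_maps <- function(x, ...) {
  cat(sprintf("<gated_maps> %d bins (window %d), %d x %d maps, %.1f%% covered\n",
              x$n_bins, x$n_adjacent, dim(x$maps)[1], dim(x$maps)[2],
              100 * mean(!is.na(x$maps))))
  invisible(x)
}

#' Threshold an en-face velocity map into motion regions
#'
#' Marks pixels whose velocity magnitude exceeds the cutoff (12 um/s by
#' default, the display threshold used for localized-deformation maps).
#' Invalid/missing pixels are never marked.
#'
#' @param map An [enface_map()] or numeric matrix (m/s).
#' @param cutoff Velocity cutoff in m/s (default `12e-6`).
#' @return Logical matrix, `TRUE` where `|v| > cutoff`.
#' @export
threshold_regions <- function(map, cutoff = 12e-6) {
  v <- if (inherits(map, "enface_map")) map$values else map
  valid <- if (inherits(map, "enface_map")) map$valid else !is.na(v)
  out <- valid & !is.na(v) & abs(v) > cutoff
  out
}
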