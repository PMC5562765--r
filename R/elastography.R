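## Core method: inter-B-scan phase differencing, phasor bulk-motion
## correction, chorioscleral relative phase, velocity conversion, incidence
## angle correction and motion-outlier handling.
##
## Conventions (stated once, tested):
##  * the differential signal is dS = S_i * Conj(S_{i+1}), so a phase that
##    GROWS between repetitions yields a NEGATIVE measured phase difference;
##  * positive velocity means motion toward the beam source (decreasing z);
##  * depth averaging of phases uses amplitude-weighted phasor (complex-sum)
##    averaging throughout — immune to +/-pi wrapping;
##  * no phase unwrapping across frames: velocities beyond the unambiguous
##    range lambda_c/(4*n*tau_B) alias, mirroring the instrument limit.

#' Phase difference between consecutive repeated B-scans
#'
#' Computes `dS(x, z) = S_{b,i} * Conj(S_{b,i+1})` and its argument
#' `dphi in (-pi, pi]`, together with a reflectivity mask: phase information
#' is only used for pixels whose pair-mean amplitude exceeds the threshold.
#'
#' @param volume An `oct_volume`.
#' @param b Slow-axis position (1..NB).
#' @param i Repetition index of the first frame of the pair (1..MB-1).
#' @param threshold Absolute reflectivity threshold; defaults to the
#'   volume-level noise-quantile threshold (see [threshold_mask()]).
#' @return A `phase_diff_frame`: `dS`, `dphi`, `mask` (X by Z), `amp`
#'   (pair-mean amplitude), and the frame identity `b`, `i`.
#' @export
phase_difference <- function(volume, b, i, threshold = NULL) {
  if (!inherits(volume, "oct_volume")) stop_usage("volume must be an oct_volume")
  meta <- volume$meta
  if (b < 1 || b > meta$NB) stop_usage("position b out of range 1..", meta$NB)
  if (i < 1 || i > meta$MB - 1)
    stop_usage("repetition i out of range 1..", meta$MB - 1,
               " (differential frames pair i with i+1)")
  s1 <- volume$samples[b, i, , ]
  s2 <- volume$samples[b, i + 1, , ]
  dS <- s1 * Conj(s2)
  amp <- (Mod(s1) + Mod(s2)) / 2
  thr <- threshold %||% volume_threshold(volume)
  structure(list(dS = dS, dphi = Arg(dS), mask = amp > thr, amp = amp,
                 threshold = thr, b = b, i = i, meta = meta),
            class = "phase_diff_frame")
}

#' Bulk-motion phase per A-scan
#'
#' The bulk phase shift of a differential frame is estimated per A-scan as the
#' argument of the complex vector sum of the masked differential signal over
#' the retinal slab `[z_I, z_R]` (the retina serves as the motion reference).
#' The complex sum makes the estimate wrap-robust: two equal-amplitude pixels
#' at +2.9 and -2.9 rad average to pi, not to the arithmetic mean 0.
#' A-scans with no masked retinal pixel are flagged and in-filled by
#' interpolation along x.
#'
#' @param frame A `phase_diff_frame`.
#' @param layers A `layer_model` valid at the frame's position.
#' @return A `bulk_phase`: `dphi_bulk` (radians per A-scan), `valid`, and the
#'   retinal phasor sum `phasor`.
#' @export
bulk_phase <- function(frame, layers) {
  if (!inherits(frame, "phase_diff_frame"))
    stop_usage("frame must be a phase_diff_frame")
  if (!inherits(layers, "layer_model")) stop_usage("layers must be a layer_model")
  X <- nrow(frame$dS); Z <- ncol(frame$dS)
  zi <- layers$z_I[, frame$b]; zr <- layers$z_R[, frame$b]
  zg <- matrix(rep(seq_len(Z), each = X), X, Z)
  slab <- zg >= matrix(zi, X, Z) & zg <= matrix(zr, X, Z)
  w <- frame$dS * (frame$mask & slab)
  phasor <- rowSums(w)
  valid <- Mod(phasor) > 0
  if (!any(valid))
    stop_usage("frame invalid: no masked retinal pixels for bulk estimation")
  dphi <- Arg(phasor)
  if (any(!valid)) {
    ok <- which(valid)
    dphi <- approx(ok, dphi[ok], xout = seq_len(X), rule = 2)$y
  }
  structure(list(dphi_bulk = wrap_pi(dphi), valid = valid, phasor = phasor,
                 b = frame$b, i = frame$i),
            class = "bulk_phase")
}

#' Bulk-corrected chorioscleral relative phase per A-scan
#'
#' The chorioscleral phase is the amplitude-weighted phasor average of the
#' masked differential signal below the RPE; subtracting the bulk phase in the
#' phasor domain gives the relative retina-to-chorioscleral phase
#' `dphi_RCS(x) = arg( sum_{z > z_R} dS(x,z) * exp(-j*dphi_bulk(x)) )`.
#'
#' @param frame A `phase_diff_frame`.
#' @param bulk The [bulk_phase()] of the same frame.
#' @param layers A `layer_model`.
#' @param cs_depth Chorioscleral slab depth in pixels below the RPE; `NULL`
#'   (default) uses every masked pixel below the RPE.
#' @param cs_offset Guard band in pixels between the segmented RPE and the
#'   top of the chorioscleral slab (default 2): the RPE is bright and static,
#'   so a one-pixel segmentation quantization error would otherwise leak its
#'   reflectivity into the moving-slab phasor and bias the velocity low.
#' @return List with `dphi_rcs` (radians per A-scan, NA where no masked
#'   chorioscleral pixel exists) and `valid`.
#' @export
relative_cs_phase <- function(frame, bulk, layers, cs_depth = NULL,
                              cs_offset = 2) {
  if (!inherits(frame, "phase_diff_frame"))
    stop_usage("frame must be a phase_diff_frame")
  if (!inherits(bulk, "bulk_phase")) stop_usage("bulk must be a bulk_phase")
  if (!inherits(layers, "layer_model"))
    stop_usage("layers missing: segment before computing the CS phase")
  X <- nrow(frame$dS); Z <- ncol(frame$dS)
  zr <- layers$z_R[, frame$b]
  zg <- matrix(rep(seq_len(Z), each = X), X, Z)
  hi <- if (is.null(cs_depth)) Z else pmin(Z, zr + cs_offset + cs_depth)
  slab <- zg > matrix(zr + cs_offset, X, Z) & zg <= matrix(hi, X, Z)
  phasor <- rowSums(frame$dS * (frame$mask & slab))
  corrected <- phasor * exp(-1i * bulk$dphi_bulk)
  valid <- Mod(phasor) > 0
  dphi <- ifelse(valid, Arg(corrected), NA_real_)
  list(dphi_rcs = dphi, valid = valid)
}

#' Convert a phase difference to axial velocity
#'
#' `v = dphi * lambda_c / (4 * pi * n * tau_B)`. With the 840 nm / 1.35 /
#' 7.65 ms acquisition this maps the unambiguous phase range (-pi, pi] onto
#' axial velocities of up to 20.33 um/s in magnitude.
#'
#' @param dphi Phase difference(s) in radians, |dphi| <= pi.
#' @param meta An [acquisition_meta()].
#' @return Axial velocity in m/s (positive toward the beam source).
#' @examples
#' phase_to_velocity(pi, acquisition_meta()) * 1e6  # 20.33 um/s
#' @export
phase_to_velocity <- function(dphi, meta) {
  dphi * meta$lambda_c / (4 * pi * meta$n_refr * meta$tau_B)
}

#' Incidence-angle correction of axial velocity
#'
#' `v_RCS = v / cos(alpha)` reconstructs motion perpendicular to the fundus
#' from its axial component. Above the cap the correction would amplify noise
#' unboundedly, so the value is flagged invalid (`NA`) instead.
#'
#' @param v Axial velocity (m/s), vectorized.
#' @param alpha Incidence angle(s), radians.
#' @param cap Maximum usable angle (default 60 deg).
#' @return Corrected velocity, `NA` where `alpha >= cap`.
#' @export
angle_correct <- function(v, alpha, cap = pi / 3) {
  out <- v / cos(alpha)
  out[alpha >= cap] <- NA_real_
  out
}

#' Compute the chorioscleral velocity field of a volume
#'
#' Runs the whole per-frame chain — phase differencing, reflectivity masking,
#' phasor bulk correction, chorioscleral phasor averaging, velocity conversion
#' and incidence-angle correction — over all `NB * (MB - 1)` differential
#' frames.
#'
#' @param volume An `oct_volume`.
#' @param layers A `layer_model` with fitted normals
#'   (see [fit_surface_normals()]).
#' @param cs_depth,cs_offset Passed to [relative_cs_phase()].
#' @param threshold Absolute reflectivity threshold (default: volume noise
#'   quantile).
#' @return A `velocity_field`: matrices `v` and `v_rcs` (X by n_frames, m/s),
#'   `valid`, `interpolated`, and a tibble `frame_stats` with per-frame
#'   identity `(b, i)`, mid-interval `time`, the circular variance of the
#'   bulk-corrected retinal phase (`circ_var`, the decorrelation proxy used by
#'   [clean_series()]) and the fraction of valid A-scans.
#' @export
compute_velocity_field <- function(volume, layers, cs_depth = NULL,
                                   cs_offset = 2, threshold = NULL) {
  if (is.null(layers$alpha))
    stop_usage("layers need fitted normals: call fit_surface_normals() first")
  meta <- volume$meta
  NB <- meta$NB; MB <- meta$MB; X <- meta$n_ascans
  thr <- threshold %||% volume_threshold(volume)
  n_frames <- NB * (MB - 1)
  v <- matrix(NA_real_, X, n_frames)
  v_rcs <- matrix(NA_real_, X, n_frames)
  valid <- matrix(FALSE, X, n_frames)
  circ_var <- numeric(n_frames)
  valid_frac <- numeric(n_frames)
  bs <- integer(n_frames); is <- integer(n_frames); tm <- numeric(n_frames)

  Z <- meta$n_depth
  zg <- matrix(rep(seq_len(Z), each = X), X, Z)
  for (b in seq_len(NB)) {
    zi <- layers$z_I[, b]; zr <- layers$z_R[, b]
    ret_slab <- zg >= matrix(zi, X, Z) & zg <= matrix(zr, X, Z)
    hi <- if (is.null(cs_depth)) Z else pmin(Z, zr + cs_offset + cs_depth)
    cs_slab <- zg > matrix(zr + cs_offset, X, Z) & zg <= matrix(hi, X, Z)
    alpha_b <- layers$alpha[, b]
    for (i in seq_len(MB - 1)) {
      f <- (b - 1) * (MB - 1) + i
      bs[f] <- b; is[f] <- i
      k <- (b - 1) * MB + i  # global B-scan index of the first of the pair
      tm[f] <- ((k - 1) + 0.5) * meta$tau_B
      s1 <- volume$samples[b, i, , ]
      s2 <- volume$samples[b, i + 1, , ]
      dS <- s1 * Conj(s2)
      mask <- (Mod(s1) + Mod(s2)) / 2 > thr
      ret_phasor <- rowSums(dS * (mask & ret_slab))
      bval <- Mod(ret_phasor) > 0
      if (!any(bval)) { circ_var[f] <- 1; next }
      dphi_bulk <- Arg(ret_phasor)
      if (any(!bval)) {
        okb <- which(bval)
        dphi_bulk <- approx(okb, dphi_bulk[okb], xout = seq_len(X),
                            rule = 2)$y
      }
      cs_phasor <- rowSums(dS * (mask & cs_slab))
      cs_ok <- Mod(cs_phasor) > 0
      dphi_rcs <- ifelse(cs_ok, Arg(cs_phasor * exp(-1i * dphi_bulk)),
                         NA_real_)
      vi <- phase_to_velocity(dphi_rcs, meta)
      va <- angle_correct(vi, alpha_b, cap = layers$alpha_cap)
      ok <- cs_ok & !is.na(va) & layers$valid[, b]
      v[, f] <- vi
      v_rcs[, f] <- ifelse(ok, va, NA_real_)
      valid[, f] <- ok
      valid_frac[f] <- mean(ok)
      # decorrelation proxy: weighted circular variance of the bulk-corrected
      # retinal differential phase over the frame
      w <- dS * (mask & ret_slab) * exp(-1i * dphi_bulk)
      denom <- sum(Mod(w))
      circ_var[f] <- if (denom > 0) 1 - Mod(sum(w)) / denom else 1
    }
  }
  structure(list(
    v = v, v_rcs = v_rcs, valid = valid,
    interpolated = matrix(FALSE, X, n_frames),
    frame_stats = tibble(frame = seq_len(n_frames), b = bs, i = is, time = tm,
                         circ_var = circ_var, valid_frac = valid_frac,
                         excluded = FALSE),
    meta = meta, alpha = layers$alpha, threshold = thr
  ), class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat(sprintf("<velocity_field> %d A-scans x %d frames, %.1f%% valid, %d excluded frames\n",
              nrow(x$v_rcs), ncol(x$v_rcs), 100 * mean(x$valid),
              sum(x$frame_stats$excluded)))
  invisible(x)
}

#' Exclude motion-corrupted frames and substitute by interpolation
#'
#' Severe axial or transversal motion decorrelates the phase differences of a
#' whole frame. Frames whose retinal circular variance (decorrelation proxy)
#' exceeds `limit` are excluded and their per-A-scan velocities replaced by
#' linear interpolation between the nearest valid frames (nearest-valid copy
#' at the series boundaries).
#'
#' @param field A `velocity_field`.
#' @param limit Circular-variance exclusion limit in \[0, 1\] (default 0.5).
#' @return The cleaned `velocity_field` with `interpolated` flags set.
#' @export
clean_series <- function(field, limit = 0.5) {
  if (!inherits(field, "velocity_field"))
    stop_usage("field must be a velocity_field")
  bad <- field$frame_stats$circ_var > limit
  if (!any(bad)) return(field)
  if (mean(bad) > 0.5)
    stop_usage("acquisition unusable: more than 50% of frames exceed the ",
               "motion-decorrelation limit")
  n <- ncol(field$v_rcs)
  good <- which(!bad)
  for (x in seq_len(nrow(field$v_rcs))) {
    row <- field$v_rcs[x, ]
    ok <- intersect(good, which(!is.na(row)))
    if (length(ok) >= 2) {
      filled <- approx(ok, row[ok], xout = seq_len(n), rule = 2)$y
      row[bad] <- filled[bad]
    } else if (length(ok) == 1) {
      row[bad] <- row[ok]
    }
    field$v_rcs[x, ] <- row
    vrow <- field$v[x, ]
    okv <- intersect(good, which(!is.na(vrow)))
    if (length(okv) >= 2)
      vrow[bad] <- approx(okv, vrow[okv], xout = seq_len(n), rule = 2)$y[bad]
    else if (length(okv) == 1) vrow[bad] <- vrow[okv]
    field$v[x, ] <- vrow
  }
  field$valid[, bad] <- !is.na(field$v_rcs[, bad])
  field$interpolated[, bad] <- !is.na(field$v_rcs[, bad])
  field$frame_stats$excluded <- bad
  field
}
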