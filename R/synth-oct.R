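## Synthetic complex-OCT phantom generator with exact ground truth.
##
## Signal model: fully developed speckle, i.e. one independent complex
## circular-Gaussian draw per voxel, scaled by a tissue-class reflectivity
## (vitreous/background 0, neural retina, a bright RPE line, a chorioscleral
## slab). The chorioscleral pulsation and the global bulk drift are applied as
## pure phase ramps (the measured displacements, <= ~300 nm, are far below one
## axial pixel, so sub-pixel phase encoding is the physically dominant effect
## and keeps the ground truth exact): a B-scan acquired at time t carries the
## voxel phase offset 4*pi*n*d(t)/lambda_c, where d is the bulk displacement
## for all voxels plus, below the RPE only, the chorioscleral displacement.
## Flow voxels are decorrelated between repetitions by an AR(1) mixture with a
## fresh speckle draw, giving an analytically known inter-repetition complex
## correlation. Everything is deterministic given the seed.

#' Cardiac displacement waveform
#'
#' Sum-of-harmonics displacement d(t) = sum_k a_k * sin(2*pi*k*f0*t + p_k),
#' periodic with period 1/f0. This is the inverse of the Fourier decomposition
#' used to quantify pulse waveforms (fundamental plus harmonics).
#'
#' @param t Times in seconds (vectorized).
#' @param spec List with `f0` (fundamental frequency, Hz), `amplitudes`
#'   (meters, one per harmonic k = 1..K) and optional `phases` (radians,
#'   default 0).
#' @return Displacement in meters, same length as `t`.
#' @examples
#' cardiac_waveform(1 / 16, list(f0 = 4, amplitudes = 100e-9)) # 100 nm
#' @export
cardiac_waveform <- function(t, spec) {
  if (is.null(spec$f0) || !is.finite(spec$f0) || spec$f0 <= 0)
    stop_usage("waveform spec needs a positive fundamental frequency f0")
  a <- spec$amplitudes
  if (is.null(a) || length(a) == 0)
    stop_usage("waveform spec needs a non-empty harmonic amplitude list")
  p <- spec$phases %||% rep(0, length(a))
  if (length(p) != length(a))
    stop_usage("phases must match amplitudes in length")
  d <- numeric(length(t))
  for (k in seq_along(a))
    d <- d + a[k] * sin(2 * pi * k * spec$f0 * t + p[k])
  d
}

# peak-to-peak excursion of a waveform spec over one period
waveform_pp <- function(spec, n_grid = 4096) {
  tt <- seq(0, 1 / spec$f0, length.out = n_grid)
  d <- cardiac_waveform(tt, spec)
  max(d) - min(d)
}

# rescale harmonic amplitudes so the peak-to-peak displacement equals pp
waveform_with_pp <- function(spec, pp) {
  cur <- waveform_pp(spec)
  spec$amplitudes <- spec$amplitudes * (pp / cur)
  spec
}

#' Phantom configuration
#'
#' Describes the layered geometry, reflectivity, cardiac pulsation, bulk
#' motion, flow voxels and noise of a synthetic OCT volume.
#'
#' @param meta [acquisition_meta()] for the phantom (a reduced 128 x 5 x 128
#'   x 96 geometry by default, to keep simulated volumes light).
#' @param ilm_coef Named numeric vector of 2-D polynomial coefficients (in
#'   depth pixels) for the ILM surface over normalized coordinates
#'   u, v in \[-1, 1\]: `c0 + cx*u + cy*v + cxx*u^2 + cxy*u*v + cyy*v^2`.
#' @param retina_px Retinal thickness in pixels (ILM to RPE).
#' @param rpe_px Thickness of the bright RPE line in pixels.
#' @param cs_px Chorioscleral slab thickness in pixels (below the RPE).
#' @param reflectivity Per-component amplitude scale for the speckle,
#'   named `retina`, `rpe`, `cs`.
#' @param noise_floor Per-component standard deviation of the additive complex
#'   detection noise (same units as reflectivity).
#' @param cs_pulse Cardiac waveform spec for the chorioscleral displacement
#'   (see [cardiac_waveform()]); `f0` must lie inside `meta$hr_band`.
#' @param bulk Global axial drift spec: `list(type = "sinusoid", amplitude,
#'   freq, jitter_sd)` or `list(type = "linear", rate, jitter_sd)` (rate in
#'   m/s). `jitter_sd` is a white per-B-scan phase jitter in radians.
#' @param vessels List of flow tubes, each
#'   `list(plexus = "scp"|"dcp"|"cs", x0, radius_px, level)` with `x0` in
#'   A-scan pixels and `level` the inter-repetition decorrelation in \[0, 1\]
#'   (complex correlation between consecutive repetitions is `1 - level`).
#'   Tubes run along the whole slow axis at a class-typical depth.
#' @param pulse_patch Optional `list(x = c(lo, hi), y = c(lo, hi))` of
#'   fractional en-face coordinates restricting the chorioscleral pulsation to
#'   a rectangular patch (outside the patch the CS slab is static).
#' @param pulse_along_normal If `TRUE` (default) the pulsatile displacement is
#'   directed along the local surface normal, so its axial (measured)
#'   component is `d(t) * cos(alpha)`; if `FALSE` the displacement is applied
#'   axially everywhere.
#' @param seed Mandatory integer RNG seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(meta = acquisition_meta(NB = 128L, MB = 5L,
                                                   n_ascans = 128L,
                                                   n_depth = 96L),
                           ilm_coef = c(c0 = 20),
                           retina_px = 40,
                           rpe_px = 1,
                           cs_px = 30,
                           reflectivity = c(retina = 1, rpe = 3, cs = 0.8),
                           noise_floor = 0.05,
                           cs_pulse = list(f0 = 3.8,
                                           amplitudes = c(135e-9, 25e-9),
                                           phases = c(0, pi / 3)),
                           bulk = list(type = "sinusoid", amplitude = 150e-9,
                                       freq = 0.5, jitter_sd = 0.02),
                           vessels = list(),
                           pulse_patch = NULL,
                           pulse_along_normal = TRUE,
                           seed) {
  if (missing(seed) || is.null(seed))
    stop_usage("phantom_config requires an explicit seed")
  validate_meta(meta)
  cfg <- list(meta = meta, ilm_coef = ilm_coef, retina_px = retina_px,
              rpe_px = rpe_px, cs_px = cs_px, reflectivity = reflectivity,
              noise_floor = noise_floor, cs_pulse = cs_pulse, bulk = bulk,
              vessels = vessels, pulse_patch = pulse_patch,
              pulse_along_normal = isTRUE(pulse_along_normal),
              seed = as.integer(seed))
  if (any(cs_pulse$amplitudes > 0)) {
    if (cs_pulse$f0 < meta$hr_band[1] || cs_pulse$f0 > meta$hr_band[2])
      stop_usage("cs_pulse$f0 must lie inside meta$hr_band")
    # warn (not error) if any per-frame interface phase step could wrap:
    # wrapping is a legitimate test case, but usually unintended.
    vmax <- 2 * pi * cs_pulse$f0 *
      sum(seq_along(cs_pulse$amplitudes) * cs_pulse$amplitudes)
    dphi_max <- 4 * pi * meta$n_refr * vmax * meta$tau_B / meta$lambda_c
    if (dphi_max > pi)
      warning("per-frame interface phase step can exceed pi: ",
              "velocities will wrap", call. = FALSE)
  }
  class(cfg) <- "phantom_config"
  cfg
}

# evaluate the ILM polynomial on the (x, position) grid, in pixels
eval_ilm <- function(coef, X, NB) {
  u <- if (X > 1) 2 * (seq_len(X) - 1) / (X - 1) - 1 else 0
  v <- if (NB > 1) 2 * (seq_len(NB) - 1) / (NB - 1) - 1 else 0
  g <- function(nm) if (nm %in% names(coef)) coef[[nm]] else 0
  outer(u, v, function(U, V)
    g("c0") + g("cx") * U + g("cy") * V +
      g("cxx") * U^2 + g("cxy") * U * V + g("cyy") * V^2)
}

# true incidence angle from a depth surface in physical units
surface_alpha <- function(z_px, meta) {
  zs <- z_px * meta$axial_pixel
  dx <- meta$fov_transverse / meta$n_ascans
  dy <- meta$fov_transverse / meta$NB
  gx <- zs * 0
  gy <- zs * 0
  nx <- nrow(zs); ny <- ncol(zs)
  if (nx > 2) gx[2:(nx - 1), ] <- (zs[3:nx, ] - zs[1:(nx - 2), ]) / (2 * dx)
  if (nx > 1) {
    gx[1, ] <- (zs[2, ] - zs[1, ]) / dx
    gx[nx, ] <- (zs[nx, ] - zs[nx - 1, ]) / dx
  }
  if (ny > 2) gy[, 2:(ny - 1)] <- (zs[, 3:ny] - zs[, 1:(ny - 2)]) / (2 * dy)
  if (ny > 1) {
    gy[, 1] <- (zs[, 2] - zs[, 1]) / dy
    gy[, ny] <- (zs[, ny] - zs[, ny - 1]) / dy
  }
  atan(sqrt(gx^2 + gy^2))
}

#' Generate a complex OCT phantom with ground truth
#'
#' @param config A [phantom_config()].
#' @return A list with elements `volume` (an `oct_volume`) and `truth`
#'   (class `ground_truth`: chorioscleral and bulk displacement sampled at the
#'   B-scan timestamps `t = frame_index * tau_B`, true surfaces `z_I`/`z_R`
#'   in pixels, true incidence angle `alpha`, the flow-voxel mask, and the
#'   pulsation patch mask).
#' @examples
#' cfg <- phantom_config(meta = acquisition_meta(NB = 8, MB = 5,
#'                                               n_ascans = 32, n_depth = 64),
#'                       seed = 1)
#' ph <- generate_phantom(cfg)
#' dim(ph$volume$samples)
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config"))
    stop_usage("config must be a phantom_config")
  meta <- config$meta
  NB <- meta$NB; MB <- meta$MB; X <- meta$n_ascans; Z <- meta$n_depth
  set.seed(config$seed)

  z_I <- eval_ilm(config$ilm_coef, X, NB)
  z_R <- z_I + config$retina_px
  z_Ir <- round(z_I); z_Rr <- round(z_R)
  cs_hi <- z_Rr + config$rpe_px - 1 + config$cs_px
  if (any(z_Ir < 2) || any(cs_hi > Z))
    stop_usage("phantom geometry does not fit the depth range: ",
               "adjust ilm_coef / thicknesses / n_depth")

  alpha <- surface_alpha(z_R, meta)

  # B-scan timestamps: frame_index = (b-1)*MB + (i-1), uniform at tau_B
  n_scan <- NB * MB
  t_scan <- (seq_len(n_scan) - 1) * meta$tau_B

  d_cs <- cardiac_waveform(t_scan, config$cs_pulse)
  bulk <- config$bulk %||% list(type = "sinusoid", amplitude = 0, freq = 0.5,
                                jitter_sd = 0)
  d_bulk <- switch(bulk$type %||% "sinusoid",
    sinusoid = (bulk$amplitude %||% 0) * sin(2 * pi * (bulk$freq %||% 0.5) * t_scan),
    linear = (bulk$rate %||% 0) * t_scan,
    stop_usage("unknown bulk motion type '", bulk$type, "'"))
  k_phase <- 4 * pi * meta$n_refr / meta$lambda_c
  jit <- rnorm(n_scan, 0, bulk$jitter_sd %||% 0)
  d_bulk_eff <- d_bulk + jit / k_phase   # jitter folded into the bulk truth
  phi_bulk_scan <- k_phase * d_bulk_eff
  phi_cs_scan <- k_phase * d_cs

  # en-face patch restricting the pulsation (1 inside, 0 outside)
  patch <- matrix(1, X, NB)
  if (!is.null(config$pulse_patch)) {
    px <- pmax(1, pmin(X, round(config$pulse_patch$x * (X - 1) + 1)))
    py <- pmax(1, pmin(NB, round(config$pulse_patch$y * (NB - 1) + 1)))
    patch[] <- 0
    patch[px[1]:px[2], py[1]:py[2]] <- 1
  }
  cs_gain <- if (config$pulse_along_normal) cos(alpha) * patch else patch

  refl <- config$reflectivity
  vessel_depth_frac <- c(scp = 0.3, dcp = 0.8)   # fraction of retinal depth
  flow_mask <- array(FALSE, dim = c(X, Z, NB))
  S <- array(complex(real = 0, imaginary = 0), dim = c(NB, MB, X, Z))
  zg <- matrix(rep(seq_len(Z), each = X), X, Z)

  for (b in seq_len(NB)) {
    zi <- z_Ir[, b]; zr <- z_Rr[, b]
    zim <- matrix(zi, X, Z); zrm <- matrix(zr, X, Z)
    amp <- matrix(0, X, Z)
    amp[zg >= zim & zg < zrm] <- refl[["retina"]]
    amp[zg >= zrm & zg < zrm + config$rpe_px] <- refl[["rpe"]]
    amp[zg >= zrm + config$rpe_px &
          zg < zrm + config$rpe_px + config$cs_px] <- refl[["cs"]]

    # static speckle for this position (shared by all repetitions)
    G <- amp * matrix(complex(real = rnorm(X * Z), imaginary = rnorm(X * Z)),
                      X, Z)

    # flow voxels: AR(1) decorrelation across repetitions
    fm <- matrix(FALSE, X, Z)
    rho <- matrix(1, X, Z)
    for (vs in config$vessels) {
      zc <- switch(vs$plexus,
        scp = zi + vessel_depth_frac[["scp"]] * config$retina_px,
        dcp = zi + vessel_depth_frac[["dcp"]] * config$retina_px,
        cs = zr + config$rpe_px + 0.4 * config$cs_px,
        stop_usage("unknown vessel plexus '", vs$plexus, "'"))
      zcm <- matrix(zc, X, Z)
      xm <- matrix(seq_len(X), X, Z)
      inside <- (xm - vs$x0)^2 + (zg - zcm)^2 <= vs$radius_px^2
      fm <- fm | inside
      rho[inside] <- 1 - vs$level
    }
    flow_mask[, , b] <- fm
    nf <- sum(fm)
    Fcur <- if (nf > 0)
      amp[fm] * complex(real = rnorm(nf), imaginary = rnorm(nf)) else complex(0)

    cs_phase_gain <- cs_gain[, b]   # per A-scan
    below_rpe <- zg > zrm           # CS motion applies strictly below the RPE

    for (i in seq_len(MB)) {
      k <- (b - 1) * MB + i
      Gi <- G
      if (nf > 0) {
        if (i > 1) {
          fresh <- amp[fm] * complex(real = rnorm(nf), imaginary = rnorm(nf))
          Fcur <- rho[fm] * Fcur + sqrt(1 - rho[fm]^2) * fresh
        }
        Gi[fm] <- Fcur
      }
      phase <- phi_bulk_scan[k] +
        (phi_cs_scan[k] * cs_phase_gain) * below_rpe
      frame <- Gi * exp(1i * phase)
      if (config$noise_floor > 0)
        frame <- frame + config$noise_floor *
          matrix(complex(real = rnorm(X * Z), imaginary = rnorm(X * Z)), X, Z)
      S[b, i, , ] <- frame
    }
  }

  truth <- structure(list(
    t_scan = t_scan, d_cs = d_cs, d_bulk = d_bulk_eff,
    z_I = z_Ir, z_R = z_Rr, alpha = alpha,
    flow_mask = flow_mask, patch = patch, config = config
  ), class = "ground_truth")

  list(volume = complex_volume(S, meta), truth = truth)
}

#' Ground-truth chorioscleral velocity at the differential-frame times
#'
#' The measured quantity is the relative axial velocity of the chorioscleral
#' complex with respect to the retina, with positive velocity meaning motion
#' toward the beam source (decreasing depth). For a phantom displacement
#' d_cs(t) (positive = deeper), the expected velocity at the differential
#' frame between repetitions i and i+1 is `-(d_cs(t+tau_B) - d_cs(t))/tau_B`.
#'
#' @param truth A `ground_truth` object.
#' @return A tibble with `frame`, `time` (mid-interval, seconds) and `v` (m/s).
#' @export
gt_velocity_series <- function(truth) {
  meta <- truth$config$meta
  MB <- meta$MB; NB <- meta$NB
  b <- rep(seq_len(NB), each = MB - 1)
  i <- rep(seq_len(MB - 1), times = NB)
  k <- (b - 1) * MB + i
  tibble(
    frame = seq_along(k),
    time = (truth$t_scan[k] + truth$t_scan[k + 1]) / 2,
    v = -(truth$d_cs[k + 1] - truth$d_cs[k]) / meta$tau_B
  )
}

#' Named catalog of phantom presets
#'
#' Ready-made [phantom_config()]s covering the regimes exercised by the
#' method: `flat_quiet` (static layered phantom), `pulsing_65mmhg_like`
#' (strong pulsation, 300 nm peak-to-peak chorioscleral displacement — the
#' largest displacement scale observed in vivo), `tilted` (inclined and curved
#' retina, non-constant incidence angle), `bulk_heavy` (dominant axial bulk
#' drift) and `with_vessels` (flow tubes in all three vascular plexuses).
#'
#' @param seed Integer seed stored in every preset.
#' @return Named list of `phantom_config` objects.
#' @export
phantom_presets <- function(seed = 1L) {
  base_pulse <- list(f0 = 3.8, amplitudes = c(135e-9, 25e-9),
                     phases = c(0, pi / 3))
  tilt_meta <- acquisition_meta(NB = 128L, MB = 5L, n_ascans = 128L,
                                n_depth = 96L, fov_transverse = 0.75e-3,
                                axial_pixel = 4e-6)
  list(
    flat_quiet = phantom_config(
      cs_pulse = list(f0 = 3.8, amplitudes = 0),
      bulk = list(type = "sinusoid", amplitude = 0, freq = 0.5, jitter_sd = 0),
      seed = seed),
    pulsing_65mmhg_like = phantom_config(
      cs_pulse = waveform_with_pp(base_pulse, 300e-9),
      seed = seed),
    tilted = phantom_config(
      meta = tilt_meta,
      # ~10 deg incline along x plus a mild curvature in y; the shallow edge
      # stays below the noise-sampling rows at the top of the scan
      ilm_coef = c(c0 = 28,
                   cx = tan(10 * pi / 180) * (tilt_meta$fov_transverse / 2) /
                     tilt_meta$axial_pixel,
                   cyy = 4),
      retina_px = 20, cs_px = 12,
      cs_pulse = waveform_with_pp(base_pulse, 300e-9),
      seed = seed),
    bulk_heavy = phantom_config(
      cs_pulse = waveform_with_pp(base_pulse, 150e-9),
      bulk = list(type = "sinusoid", amplitude = 1.5e-6, freq = 0.5,
                  jitter_sd = 0.05),
      seed = seed),
    with_vessels = phantom_config(
      cs_pulse = waveform_with_pp(base_pulse, 300e-9),
      vessels = list(
        list(plexus = "scp", x0 = 38, radius_px = 6, level = 1),
        list(plexus = "dcp", x0 = 80, radius_px = 2, level = 1),
        list(plexus = "cs", x0 = 56, radius_px = 4, level = 1),
        list(plexus = "cs", x0 = 100, radius_px = 4, level = 1)),
      seed = seed)
  )
}
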