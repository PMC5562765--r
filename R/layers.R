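## ILM/RPE surface segmentation and incidence-angle geometry.
##
## The RPE is detected as the brightest line of the median-filtered
## reflectivity of each A-scan (it is the most reflective band in the posterior
## eye), the ILM as the shallowest supra-threshold pixel; both surfaces are
## median-smoothed transversally. This deliberately simple detector sits
## behind a small interface (a layer_model carrying z_I, z_R and validity), so
## a graph-based segmenter can be dropped in for real data where the
## brightest-line assumption may not hold.

#' Reflectivity threshold for an amplitude map
#'
#' Phase information is only used for pixels exceeding a reflectivity
#' threshold. The default `"noise_quantile"` method sets the threshold to
#' `factor` times the `q`-th quantile of the non-tissue background amplitude;
#' the background is taken from `background` if supplied, otherwise from the
#' shallowest `bg_rows` depth pixels (vitreous above the ILM).
#'
#' @param amplitude Numeric matrix (x by z) or array of reflectivity
#'   amplitudes.
#' @param method `"noise_quantile"` or `"absolute"`.
#' @param param For `"absolute"`: the threshold value. For `"noise_quantile"`:
#'   optional list with `q` (default 0.99), `factor` (default 2),
#'   `background` (numeric vector of background amplitudes) or `bg_rows`
#'   (default 8).
#' @return Logical mask of the same shape (`TRUE` = supra-threshold), with the
#'   threshold attached as attribute `"threshold"`.
#' @export
threshold_mask <- function(amplitude, method = c("noise_quantile", "absolute"),
                           param = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(amplitude))) stop_usage("amplitude must be finite")
  thr <- if (method == "absolute") {
    if (!is.numeric(param) || length(param) != 1)
      stop_usage("absolute thresholding needs a single numeric param")
    param
  } else {
    p <- if (is.list(param)) param else list()
    bg <- p$background
    if (is.null(bg)) {
      n_bg <- p$bg_rows %||% 8
      if (is.matrix(amplitude)) {
        bg <- as.vector(amplitude[, seq_len(min(n_bg, ncol(amplitude)))])
      } else {
        nz <- dim(amplitude)[length(dim(amplitude))]
        idx <- slice.index(amplitude, length(dim(amplitude))) <= min(n_bg, nz)
        bg <- amplitude[idx]
      }
    }
    (p$factor %||% 2) * quantile(bg, p$q %||% 0.99, names = FALSE)
  }
  mask <- amplitude > thr
  if (!any(mask)) stop_usage("no valid pixels above the reflectivity threshold")
  attr(mask, "threshold") <- thr
  mask
}

# volume-level reflectivity threshold from the shallow background rows
volume_threshold <- function(volume, q = 0.99, factor = 2, bg_rows = 8) {
  Z <- volume$meta$n_depth
  bg <- Mod(volume$samples[, , , seq_len(min(bg_rows, Z)), drop = FALSE])
  factor * quantile(bg, q, names = FALSE)
}

# repetition-averaged amplitude for the whole volume, X x Z x NB
volume_amplitude <- function(volume) {
  A <- Mod(volume$samples)   # NB x MB x X x Z
  MB <- dim(A)[2]
  am <- A[, 1, , ]
  for (i in 2:MB) am <- am + A[, i, , ]
  aperm(am / MB, c(2, 3, 1))
}

# running median of 3 along the first margin (preserves thin bright lines in
# depth while suppressing transverse speckle outliers)
median3_rows <- function(m) {
  n <- nrow(m)
  if (n < 3) return(m)
  up <- m[c(1, 1:(n - 1)), , drop = FALSE]
  dn <- m[c(2:n, n), , drop = FALSE]
  m + up + dn - pmax(m, up, dn) - pmin(m, up, dn)
}

#' Segment the ILM and RPE surfaces
#'
#' Per A-scan: the RPE depth `z_R` is the maximum of the repetition-averaged,
#' transversally median-filtered amplitude (the RPE is the brightest band),
#' the ILM depth `z_I` the shallowest supra-threshold pixel. The median filter
#' runs along x only, so a thin bright RPE line survives it. A-scans without
#' supra-threshold pixels (or with inverted surfaces) are marked invalid and
#' in-filled by transverse interpolation; both surfaces are median-smoothed
#' along x and the slow axis.
#'
#' @param volume An `oct_volume`.
#' @param params List of detector parameters: `smooth_x`/`smooth_y` (odd
#'   running-median window along the fast/slow axis, defaults 9 and 5),
#'   `threshold` (list passed to [threshold_mask()], default noise-quantile).
#' @return A `layer_model` with `z_I`, `z_R` (X by NB matrices, pixels),
#'   `valid`, and the metadata; surface normals are added by
#'   [fit_surface_normals()].
#' @export
segment_layers <- function(volume, params = list()) {
  if (!inherits(volume, "oct_volume")) stop_usage("volume must be an oct_volume")
  meta <- volume$meta
  X <- meta$n_ascans; NB <- meta$NB
  p <- modifyList(list(smooth_x = 9, smooth_y = 5,
                       threshold = list(q = 0.99, factor = 2, bg_rows = 8)),
                  params)
  thr <- volume_threshold(volume, q = p$threshold$q %||% 0.99,
                          factor = p$threshold$factor %||% 2,
                          bg_rows = p$threshold$bg_rows %||% 8)
  if (!is.finite(thr) || thr <= 0 || max(Mod(volume$samples)) <= thr)
    stop_usage("no tissue found: no supra-threshold reflectivity in volume")

  z_I <- matrix(NA_real_, X, NB)
  z_R <- matrix(NA_real_, X, NB)
  amp_all <- volume_amplitude(volume)
  for (b in seq_len(NB)) {
    filt <- median3_rows(amp_all[, , b])
    above <- filt > thr
    hit <- which(rowSums(above) > 0)
    if (length(hit) == 0) next
    z_R[hit, b] <- max.col(filt[hit, , drop = FALSE], ties.method = "first")
    z_I[hit, b] <- apply(above[hit, , drop = FALSE], 1, which.max)
  }
  valid <- !is.na(z_I) & !is.na(z_R) & (z_I < z_R)
  z_I[!valid] <- NA; z_R[!valid] <- NA
  if (!any(valid)) stop_usage("no tissue found: every A-scan is sub-threshold")

  fill_and_smooth <- function(zm) {
    for (b in seq_len(NB)) {  # transverse in-fill of invalid A-scans
      row <- zm[, b]
      if (anyNA(row)) {
        ok <- which(!is.na(row))
        if (length(ok) >= 2) {
          row <- approx(ok, row[ok], xout = seq_len(X), rule = 2)$y
        } else if (length(ok) == 1) row[] <- row[ok]
        zm[, b] <- row
      }
    }
    if (anyNA(zm)) {  # whole positions invalid: in-fill along the slow axis
      for (x in seq_len(X)) {
        row <- zm[x, ]
        ok <- which(!is.na(row))
        if (length(ok) >= 2)
          zm[x, ] <- approx(ok, row[ok], xout = seq_len(NB), rule = 2)$y
        else if (length(ok) == 1) zm[x, ] <- row[ok]
      }
    }
    kx <- min(p$smooth_x, X - (1 - X %% 2)); ky <- min(p$smooth_y, NB - (1 - NB %% 2))
    if (kx >= 3) zm <- apply(zm, 2, runmed, k = kx, endrule = "median")
    if (ky >= 3) zm <- t(apply(zm, 1, runmed, k = ky, endrule = "median"))
    zm
  }
  z_I <- fill_and_smooth(z_I)
  z_R <- fill_and_smooth(z_R)
  bad <- z_I >= z_R
  if (any(bad)) {
    z_I[bad] <- pmax(1, z_R[bad] - 1)
    valid[bad] <- FALSE
  }

  structure(list(z_I = z_I, z_R = z_R, valid = valid, meta = meta,
                 params = p, fit = NULL, g = NULL, alpha = NULL,
                 alpha_cap = pi / 3),
            class = "layer_model")
}

#' @export
print.layer_model <- function(x, ...) {
  cat(sprintf("<layer_model> %d x %d A-scans, %.1f%% valid, normals %s\n",
              nrow(x$z_I), ncol(x$z_I), 100 * mean(x$valid),
              if (is.null(x$alpha)) "not fitted" else "fitted"))
  invisible(x)
}

#' Construct a layer model directly from surfaces
#'
#' Mostly useful for testing and for plugging in an external segmenter.
#' @param z_I,z_R ILM and RPE depth matrices (X by NB, pixels).
#' @param meta An [acquisition_meta()].
#' @param valid Optional validity matrix.
#' @return A `layer_model`.
#' @export
layer_model <- function(z_I, z_R, meta, valid = NULL) {
  if (!all(dim(z_I) == dim(z_R)))
    stop_usage("z_I and z_R must have matching dimensions")
  if (any(z_I >= z_R, na.rm = TRUE))
    stop_usage("inverted surfaces: z_I must lie above (be smaller than) z_R")
  if (is.null(valid)) valid <- !is.na(z_I) & !is.na(z_R)
  structure(list(z_I = z_I, z_R = z_R, valid = valid, meta = meta,
                 params = list(), fit = NULL, g = NULL, alpha = NULL,
                 alpha_cap = pi / 3),
            class = "layer_model")
}

#' Fit a smooth surface and compute normals and incidence angles
#'
#' Least-squares 2-D polynomial fit (default degree 2) to the RPE surface in
#' physical coordinates; the unit surface normal is
#' `g = [-dz/dx, -dz/dy, 1] / |.|` and the incidence angle
#' `alpha = arccos(g_z)` measures the tilt of the fundus against the beam
#' direction `[0, 0, 1]`. A-scans steeper than `alpha_cap` (default 60 deg,
#' where the `1/cos(alpha)` correction would amplify noise excessively) are
#' flagged invalid for velocity correction.
#'
#' @param model A `layer_model`.
#' @param degree Total polynomial degree of the fit.
#' @param alpha_cap Cap on the incidence angle, radians.
#' @return The `layer_model` with `fit`, `g` (X by NB by 3) and `alpha`
#'   populated.
#' @export
fit_surface_normals <- function(model, degree = 2, alpha_cap = pi / 3) {
  if (!inherits(model, "layer_model")) stop_usage("model must be a layer_model")
  meta <- model$meta
  X <- nrow(model$z_R); NB <- ncol(model$z_R)
  dx <- meta$fov_transverse / meta$n_ascans
  dy <- meta$fov_transverse / meta$NB
  xs <- (seq_len(X) - (X + 1) / 2) * dx
  ys <- (seq_len(NB) - (NB + 1) / 2) * dy
  xg <- rep(xs, times = NB); yg <- rep(ys, each = X)
  zg <- as.vector(model$z_R) * meta$axial_pixel
  ok <- as.vector(model$valid) & !is.na(zg)
  terms <- expand.grid(p = 0:degree, q = 0:degree)
  terms <- terms[terms$p + terms$q <= degree, , drop = FALSE]
  design <- function(x, y)
    vapply(seq_len(nrow(terms)),
           function(k) x^terms$p[k] * y^terms$q[k], numeric(length(x)))
  A <- design(xg[ok], yg[ok])
  qr_A <- qr(A)
  if (qr_A$rank < ncol(A))
    stop_usage("degenerate surface fit: rank-deficient design ",
               "(reduce the polynomial degree)")
  cf <- qr.coef(qr_A, zg[ok])

  # analytic derivatives of the fitted polynomial
  ddx <- ddy <- numeric(length(xg))
  for (k in seq_len(nrow(terms))) {
    pk <- terms$p[k]; qk <- terms$q[k]
    if (pk > 0) ddx <- ddx + cf[k] * pk * xg^(pk - 1) * yg^qk
    if (qk > 0) ddy <- ddy + cf[k] * qk * xg^pk * yg^(qk - 1)
  }
  zfit <- as.vector(design(xg, yg) %*% cf)
  gn <- sqrt(ddx^2 + ddy^2 + 1)
  g <- array(c(-ddx / gn, -ddy / gn, 1 / gn), dim = c(X, NB, 3))
  alpha <- matrix(acos(pmin(1, 1 / gn)), X, NB)

  model$fit <- list(degree = degree, terms = terms, coef = cf,
                    z_fit = matrix(zfit / meta$axial_pixel, X, NB))
  model$g <- g
  model$alpha <- alpha
  model$alpha_cap <- alpha_cap
  model$valid <- model$valid & (alpha < alpha_cap)
  model
}
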