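## OCT angiography: amplitude-decorrelation motion contrast from repeated
## B-scans, plexus slab definition, en-face maximum-intensity projection,
## Frangi vesselness enhancement, large-vessel/optic-nerve-head exclusion and
## flux quantification.

#' Amplitude-decorrelation flow signal
#'
#' Pairwise amplitude decorrelation averaged over the MB-1 consecutive
#' repetition pairs:
#' `D = 1 - (1/(MB-1)) * sum_i 2*A_i*A_{i+1} / (A_i^2 + A_{i+1}^2)`,
#' computed per voxel from the amplitudes (so it is insensitive to bulk phase).
#' `D` is 0 for identical repetitions, grows toward ~0.27 (median) for fully
#' decorrelated speckle, is symmetric in the pair and invariant to global
#' amplitude scaling. Voxels whose repetition-mean amplitude is below the
#' noise floor are set to 0.
#'
#' @param volume An `oct_volume` with `MB >= 2`.
#' @param position Slow-axis position (1..NB) for a single X-by-Z map, or
#'   `NULL` (default) for the full X-by-Z-by-NB array.
#' @param noise_threshold Amplitude below which voxels are zeroed; defaults to
#'   the volume-level noise-quantile threshold.
#' @return Numeric matrix (X by Z) or array (X by Z by NB) of flow signal in
#'   \[0, 1\].
#' @export
decorrelation <- function(volume, position = NULL, noise_threshold = NULL) {
  if (!inherits(volume, "oct_volume")) stop_usage("volume must be an oct_volume")
  meta <- volume$meta
  if (meta$MB < 2) stop_usage("decorrelation needs MB >= 2 repeated B-scans")
  thr <- noise_threshold %||% volume_threshold(volume)
  X <- meta$n_ascans; Z <- meta$n_depth
  one <- function(b) {
    s <- volume$samples[b, , , , drop = FALSE]
    dim(s) <- dim(volume$samples)[2:4]
    A <- Mod(s)
    acc <- matrix(0, X, Z)
    amean <- matrix(0, X, Z)
    for (i in seq_len(meta$MB - 1)) {
      a1 <- matrix(A[i, , ], X, Z); a2 <- matrix(A[i + 1, , ], X, Z)
      den <- a1^2 + a2^2
      r <- ifelse(den > 0, 2 * a1 * a2 / den, 1)
      acc <- acc + r
    }
    for (i in seq_len(meta$MB)) amean <- amean + matrix(A[i, , ], X, Z)
    D <- 1 - acc / (meta$MB - 1)
    D[amean / meta$MB < thr] <- 0
    pmin(pmax(D, 0), 1)
  }
  if (!is.null(position)) {
    if (position < 1 || position > meta$NB)
      stop_usage("position out of range 1..", meta$NB)
    return(one(position))
  }
  out <- array(0, dim = c(meta$n_ascans, meta$n_depth, meta$NB))
  for (b in seq_len(meta$NB)) out[, , b] <- one(b)
  out
}

#' Define the three plexus slabs relative to the segmented surfaces
#'
#' Superficial retinal capillary plexus (SCP): the upper `scp_frac` of the
#' retinal slab `[z_I, z_R)`; deeper retinal capillary plexus (DCP): the rest
#' of the retinal slab; chorioscleral plexus (CS): `[z_R, z_R + cs_depth]`.
#' SCP and DCP tile the retina with no gap or overlap and the ranges follow
#' the surfaces per A-scan (constant offsets in surface-relative coordinates).
#'
#' @param layers A `layer_model`.
#' @param scp_frac Fraction of the retinal depth assigned to the SCP
#'   (default 0.6).
#' @param cs_depth Chorioscleral slab depth in pixels (default 40, clipped to
#'   the volume depth).
#' @return A `slab_set`: list of per-A-scan inclusive-exclusive depth bounds
#'   `lo`/`hi` (X by NB matrices) for `SCP`, `DCP`, `CS` (CS upper bound
#'   inclusive, encoded as `hi`).
#' @export
define_slabs <- function(layers, scp_frac = 0.6, cs_depth = 40) {
  if (!inherits(layers, "layer_model")) stop_usage("layers must be a layer_model")
  if (any(layers$z_I >= layers$z_R, na.rm = TRUE))
    stop_usage("inverted surfaces: z_I must lie above z_R")
  zi <- layers$z_I; zr <- layers$z_R
  split <- zi + scp_frac * (zr - zi)
  Z <- layers$meta$n_depth
  structure(list(
    SCP = list(lo = zi, hi = split),          # [lo, hi)
    DCP = list(lo = split, hi = zr),          # [lo, hi)
    CS = list(lo = zr, hi = pmin(zr + cs_depth, Z + 1)),  # [lo, hi)
    scp_frac = scp_frac, cs_depth = cs_depth
  ), class = "slab_set")
}

#' En-face maximum-intensity projection of a flow volume over a slab
#'
#' @param flow X-by-Z-by-NB flow array from [decorrelation()].
#' @param slabs A `slab_set` from [define_slabs()].
#' @param slab One of `"SCP"`, `"DCP"`, `"CS"`.
#' @return An [enface_map()] (X by NB, dimensionless).
#' @export
enface_mip <- function(flow, slabs, slab = c("SCP", "DCP", "CS")) {
  slab <- match.arg(slab)
  if (!inherits(slabs, "slab_set")) stop_usage("slabs must be a slab_set")
  s <- slabs[[slab]]
  X <- dim(flow)[1]; Z <- dim(flow)[2]; NB <- dim(flow)[3]
  vals <- matrix(NA_real_, X, NB)
  zg <- seq_len(Z)
  for (b in seq_len(NB)) {
    for (x in seq_len(X)) {
      lo <- s$lo[x, b]; hi <- s$hi[x, b]
      idx <- zg[zg >= lo & zg < hi]
      if (length(idx) == 0) next
      vals[x, b] <- max(flow[x, idx, b])
    }
  }
  if (all(is.na(vals))) stop_usage("empty slab: no depth pixels in range")
  enface_map(vals, units = "dimensionless")
}

## ---- Frangi vesselness ------------------------------------------------------

# scale-normalized Hessian of a matrix after Gaussian smoothing at sigma
hessian_at_scale <- function(m, sigma) {
  sm <- EBImage::gblur(m, sigma = sigma)
  nx <- nrow(sm); ny <- ncol(sm)
  shift <- function(a, dx, dy) {
    xs <- pmin(pmax(seq_len(nx) + dx, 1), nx)
    ys <- pmin(pmax(seq_len(ny) + dy, 1), ny)
    a[xs, ys, drop = FALSE]
  }
  dxx <- shift(sm, 1, 0) + shift(sm, -1, 0) - 2 * sm
  dyy <- shift(sm, 0, 1) + shift(sm, 0, -1) - 2 * sm
  dxy <- (shift(sm, 1, 1) + shift(sm, -1, -1) -
            shift(sm, 1, -1) - shift(sm, -1, 1)) / 4
  list(dxx = dxx * sigma^2, dyy = dyy * sigma^2, dxy = dxy * sigma^2)
}

#' Frangi vesselness enhancement of an en-face map
#'
#' Multi-scale Hessian eigenvalue ridge filter for bright curvilinear
#' structures: at each scale the Hessian eigenvalues |lambda1| <= |lambda2|
#' yield a blobness ratio `Rb = |l1|/|l2|` and structureness
#' `S = sqrt(l1^2 + l2^2)`; the response
#' `exp(-Rb^2/(2 beta^2)) * (1 - exp(-S^2/(2 c^2)))` is kept where
#' `lambda2 < 0` (bright ridges) and maximized over scales. The output is
#' normalized to \[0, 1\] (a constant map returns all zeros).
#'
#' @param map An [enface_map()] or numeric matrix.
#' @param scales Gaussian scales in pixels (default `c(2, 4, 8)`).
#' @param beta Blobness sensitivity (default 0.5).
#' @param c Structureness sensitivity; default half the maximum Frobenius
#'   Hessian norm per scale.
#' @return An [enface_map()] with vesselness in \[0, 1\].
#' @export
vesselness <- function(map, scales = c(2, 4, 8), beta = 0.5, c = NULL) {
  m <- if (inherits(map, "enface_map")) map$values else map
  valid <- if (inherits(map, "enface_map")) map$valid else !is.na(m)
  if (any(scales <= 0)) stop_usage("scales must be positive")
  m[!valid] <- 0
  if (any(!is.finite(m))) stop_usage("map must be finite")
  best <- matrix(0, nrow(m), ncol(m))
  for (s in scales) {
    h <- hessian_at_scale(m, s)
    tmp <- (h$dxx - h$dyy) / 2
    disc <- sqrt(tmp^2 + h$dxy^2)
    mu <- (h$dxx + h$dyy) / 2
    e1 <- mu + disc; e2 <- mu - disc
    # order |l1| <= |l2|
    swap <- abs(e1) > abs(e2)
    l1 <- ifelse(swap, e2, e1)
    l2 <- ifelse(swap, e1, e2)
    S2 <- l1^2 + l2^2
    cc <- if (is.null(c)) {
      mx <- sqrt(max(S2))
      if (mx > 0) mx / 2 else 1
    } else c
    rb2 <- ifelse(l2 != 0, (l1 / l2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    v[l2 >= 0] <- 0   # bright ridges only
    best <- pmax(best, v)
  }
  mx <- max(best)
  if (mx > 0) best <- best / mx
  best[!valid] <- NA
  enface_map(best, units = "dimensionless",
             valid = valid)
}

#' Large-vessel exclusion mask
#'
#' Segments the larger superficial vessels (whose shadows would contaminate
#' the flux of the deeper plexuses) by thresholding the vesselness response at
#' large scales only, then dilating by a safety margin. The returned mask
#' marks EXCLUDED pixels.
#'
#' @param scp_enface SCP en-face map (an [enface_map()] or matrix).
#' @param scales Large-vessel scales in pixels (default `c(6, 8)`).
#' @param threshold Vesselness threshold in \[0, 1\] (default 0.25).
#' @param margin Dilation margin in pixels (default 2).
#' @return Logical matrix, `TRUE` = excluded.
#' @export
large_vessel_mask <- function(scp_enface, scales = c(6, 8), threshold = 0.25,
                              margin = 2) {
  m <- if (inherits(scp_enface, "enface_map")) scp_enface$values else scp_enface
  m[is.na(m)] <- 0
  if (max(m) - min(m) <= 0)
    return(matrix(FALSE, nrow(m), ncol(m)))
  v <- vesselness(m, scales = scales)$values
  mask <- !is.na(v) & v > threshold
  if (margin > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2 * margin + 1, "disc")
    mask <- EBImage::dilate(mask, brush) > 0
  }
  mask
}

#' Optic-nerve-head exclusion disk
#'
#' Circular exclusion mask centered at the optic nerve head. At the native
#' transverse sampling (1.5 mm / 512 A-scans) the default 150-pixel diameter
#' corresponds to roughly 440 um on the retina.
#'
#' @param dim Map dimensions `c(n_x, n_y)`.
#' @param center ONH center in pixels `c(x, y)` (defaults to the map center).
#' @param diameter_px Disk diameter in pixels (default 150).
#' @param meta Optional [acquisition_meta()]; if given, the physical diameter
#'   in meters is attached as attribute `"diameter_m"`.
#' @return Logical matrix, `TRUE` = excluded, with attribute `"diameter_m"`
#'   when `meta` is supplied.
#' @export
onh_disk_mask <- function(dim, center = NULL, diameter_px = 150, meta = NULL) {
  center <- center %||% (dim + 1) / 2
  if (center[1] < 1 || center[1] > dim[1] || center[2] < 1 ||
      center[2] > dim[2])
    stop_usage("ONH center must lie inside the map")
  xg <- matrix(seq_len(dim[1]), dim[1], dim[2])
  yg <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2])
  mask <- (xg - center[1])^2 + (yg - center[2])^2 <= (diameter_px / 2)^2
  if (!is.null(meta))
    attr(mask, "diameter_m") <- diameter_px * meta$fov_transverse / meta$n_ascans
  mask
}

#' Flux of an en-face angiogram
#'
#' The flux is the mean flow-signal intensity over the detected blood-flow
#' region. The region is defined by the vesselness map (retinal plexuses) or
#' the raw flow signal (chorioscleral plexus) exceeding a threshold, minus any
#' exclusion masks (large vessels, optic nerve head); the averaged intensity
#' is the raw flow value (a switch selects the vesselness-enhanced values
#' instead).
#'
#' @param enface Flow en-face map (an [enface_map()]).
#' @param vessel_map Optional vesselness [enface_map()] defining the region;
#'   if `NULL` the region comes from the flow signal itself.
#' @param exclude Optional logical exclusion matrix (TRUE = excluded).
#' @param flow_threshold Region threshold; default is the map's background
#'   `median + 3 * MAD` (computed on the region-defining values).
#' @param intensity `"raw"` (default) averages the raw flow signal;
#'   `"vesselness"` averages the enhanced values.
#' @return A one-row tibble with `flux`, `n_pixels`, `threshold` and `empty`
#'   (TRUE when no pixel qualified; flux is 0 then, with a warning).
#' @export
flux <- function(enface, vessel_map = NULL, exclude = NULL,
                 flow_threshold = NULL, intensity = c("raw", "vesselness")) {
  intensity <- match.arg(intensity)
  if (!inherits(enface, "enface_map")) stop_usage("enface must be an enface_map")
  region_vals <- if (is.null(vessel_map)) enface$values else vessel_map$values
  ok <- enface$valid & !is.na(region_vals)
  if (!is.null(vessel_map)) ok <- ok & vessel_map$valid
  if (!is.null(exclude)) ok <- ok & !exclude
  thr <- flow_threshold %||% {
    vals <- region_vals[ok]
    median(vals) + 3 * mad(vals)
  }
  region <- ok & region_vals > thr
  src <- if (intensity == "raw") enface$values else region_vals
  n <- sum(region)
  if (n == 0) {
    warning("empty blood-flow region: flux set to 0", call. = FALSE)
    return(tibble(flux = 0, n_pixels = 0L, threshold = thr, empty = TRUE))
  }
  tibble(flux = mean(src[region]), n_pixels = as.integer(n), threshold = thr,
         empty = FALSE)
}

#' Per-plexus flux table of a volume
#'
#' Convenience orchestration: decorrelation, slab projections, vesselness
#' enhancement of the retinal plexuses, large-vessel and optic-nerve-head
#' exclusion, and the flux of each plexus. Larger-vessel exclusion applies to
#' the DCP and CS plexuses only (shadowing artefacts), following the method.
#'
#' @param volume An `oct_volume`.
#' @param layers A segmented `layer_model`.
#' @param scp_frac,cs_depth Passed to [define_slabs()].
#' @param scales Frangi scales for the retinal plexuses.
#' @param onh Optional list `list(center, diameter_px)` for the exclusion
#'   disk; `NULL` disables it.
#' @param flow_threshold Optional fixed region threshold.
#' @return A tibble with one row per plexus (`slab`, `flux`, `n_pixels`,
#'   `threshold`, `empty`), plus the maps as attributes (`enface`,
#'   `vesselness`, `large_vessel_mask`).
#' @export
angio_flux <- function(volume, layers, scp_frac = 0.6, cs_depth = 40,
                       scales = c(2, 4, 8), onh = NULL,
                       flow_threshold = NULL) {
  flow <- decorrelation(volume)
  slabs <- define_slabs(layers, scp_frac = scp_frac, cs_depth = cs_depth)
  maps <- lapply(c(SCP = "SCP", DCP = "DCP", CS = "CS"),
                 function(s) enface_mip(flow, slabs, s))
  ves <- lapply(maps[c("SCP", "DCP")], vesselness, scales = scales)
  lv <- large_vessel_mask(maps$SCP)
  onh_mask <- if (!is.null(onh)) {
    onh_disk_mask(dim(maps$SCP$values), center = onh$center,
                  diameter_px = onh$diameter_px, meta = volume$meta)
  } else matrix(FALSE, nrow(maps$SCP$values), ncol(maps$SCP$values))
  rows <- list(
    SCP = flux(maps$SCP, vessel_map = ves$SCP, exclude = onh_mask,
               flow_threshold = flow_threshold),
    DCP = flux(maps$DCP, vessel_map = ves$DCP, exclude = lv | onh_mask,
               flow_threshold = flow_threshold),
    CS = flux(maps$CS, vessel_map = NULL, exclude = lv | onh_mask,
              flow_threshold = flow_threshold)
  )
  out <- do.call(rbind, lapply(names(rows), function(s)
    cbind(tibble(slab = s), rows[[s]])))
  attr(out, "enface") <- maps
  attr(out, "vesselness") <- ves
  attr(out, "large_vessel_mask") <- lv
  attr(out, "onh_mask") <- onh_mask
  out
}
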