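## Domain types and container I/O for complex OCT volumes and derived maps.
##
## Coordinate convention: z increases with depth (the ILM lies above the RPE,
## so z_I < z_R); x is the fast scan axis; the slow axis enumerates B-scan
## positions. Samples are stored as a 4-D complex array indexed
## (position b, repetition i, A-scan x, depth z), 1-based in R.
## All physical quantities are SI internally; micrometers/nanometers appear
## only at presentation boundaries.

#' Acquisition metadata for a complex OCT volume
#'
#' Bundles the physical and sampling parameters of a repeated-B-scan OCT
#' acquisition. Defaults correspond to a small-animal retinal scanner:
#' superluminescent diode centered at 840 nm (100 nm bandwidth), 7.65 ms
#' inter-B-scan time (130 Hz frame rate), tissue refractive index 1.35,
#' 400 slow-axis positions with 5 B-scan repetitions each, 512 A-scans per
#' B-scan over a 1.5 mm transverse field of view.
#'
#' @param lambda_c Center wavelength in meters.
#' @param delta_lambda Source bandwidth in meters (informational).
#' @param tau_B Inter-B-scan time in seconds; the temporal baseline of all
#'   phase differences.
#' @param n_refr Tissue refractive index (dimensionless).
#' @param NB Number of slow-axis positions.
#' @param MB Number of repeated B-scans per position (must be >= 2).
#' @param n_ascans A-scans per B-scan (fast axis).
#' @param n_depth Depth pixels per A-scan.
#' @param fov_transverse Transverse extent of the scan field in meters
#'   (applies to both fast and slow axes).
#' @param axial_pixel Depth sampling in meters per pixel. Not a property the
#'   instrument prints; it must be supplied with the data (about 2 um is
#'   typical for a 3.8 um axial resolution system).
#' @param hr_band Plausible heart-rate search band in Hz, length-2 numeric.
#'
#' @return An object of class `oct_meta` (a validated list).
#' @examples
#' m <- acquisition_meta(NB = 8, MB = 5, n_ascans = 32, n_depth = 64)
#' m$tau_B
#' @export
acquisition_meta <- function(lambda_c = 840e-9,
                             delta_lambda = 100e-9,
                             tau_B = 7.65e-3,
                             n_refr = 1.35,
                             NB = 400L,
                             MB = 5L,
                             n_ascans = 512L,
                             n_depth = 1024L,
                             fov_transverse = 1.5e-3,
                             axial_pixel = 2e-6,
                             hr_band = c(2, 10)) {
  meta <- list(
    lambda_c = lambda_c, delta_lambda = delta_lambda, tau_B = tau_B,
    n_refr = n_refr, NB = as.integer(NB), MB = as.integer(MB),
    n_ascans = as.integer(n_ascans), n_depth = as.integer(n_depth),
    fov_transverse = fov_transverse, axial_pixel = axial_pixel,
    hr_band = as.numeric(hr_band)
  )
  validate_meta(meta)
  class(meta) <- "oct_meta"
  meta
}

validate_meta <- function(meta) {
  num <- c("lambda_c", "delta_lambda", "tau_B", "n_refr", "fov_transverse",
           "axial_pixel")
  for (f in num) {
    v <- meta[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop_usage("metadata field '", f, "' must be a single positive number")
  }
  for (f in c("NB", "MB", "n_ascans", "n_depth")) {
    v <- meta[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 1)
      stop_usage("metadata field '", f, "' must be a positive count")
  }
  if (meta$MB < 2)
    stop_usage("MB must be >= 2: phase differencing needs repeated B-scans")
  hb <- meta$hr_band
  if (length(hb) != 2 || any(!is.finite(hb)) || hb[1] <= 0 || hb[1] >= hb[2])
    stop_usage("hr_band must be an increasing positive pair of frequencies")
  invisible(meta)
}

#' @export
print.oct_meta <- function(x, ...) {
  cat(sprintf(
    "<oct_meta> %d positions x %d reps x %d A-scans x %d depth px\n",
    x$NB, x$MB, x$n_ascans, x$n_depth))
  cat(sprintf("  lambda_c %.0f nm, tau_B %.3f ms, n %.2f, FoV %.2f mm, dz %.2f um\n",
              x$lambda_c * 1e9, x$tau_B * 1e3, x$n_refr,
              x$fov_transverse * 1e3, x$axial_pixel * 1e6))
  invisible(x)
}

#' Construct a complex OCT volume
#'
#' Couples the raw complex samples S(b, i, x, z) = A * exp(j*phi) with their
#' acquisition metadata and validates that the declared geometry matches the
#' stored array shape.
#'
#' @param samples 4-D complex array with dimensions
#'   `c(meta$NB, meta$MB, meta$n_ascans, meta$n_depth)`.
#' @param meta An [acquisition_meta()] object.
#' @return An object of class `oct_volume`.
#' @export
complex_volume <- function(samples, meta) {
  if (!inherits(meta, "oct_meta")) stop_usage("meta must be an oct_meta object")
  if (!is.complex(samples))
    stop_usage("samples must be a complex array (amplitude-and-phase data)")
  want <- c(meta$NB, meta$MB, meta$n_ascans, meta$n_depth)
  if (length(dim(samples)) != 4L || !all(dim(samples) == want))
    stop_usage("sample array shape (", paste(dim(samples), collapse = "x"),
               ") disagrees with declared NB x MB x X x Z (",
               paste(want, collapse = "x"), ")")
  if (anyNA(samples) || any(!is.finite(Re(samples))) || any(!is.finite(Im(samples))))
    stop_usage("samples must be finite")
  structure(list(samples = samples, meta = meta), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  cat("<oct_volume>\n")
  print(x$meta)
  invisible(x)
}

## HDF5 container dialect ------------------------------------------------------
## One file; double datasets /samples_re and /samples_im with dims
## NB x MB x X x Z (real and imaginary parts are stored separately because a
## complex HDF5 datatype is not portable across bindings); every metadata field
## is a root attribute in SI units.

h5_meta_fields <- c("lambda_c", "delta_lambda", "tau_B", "n_refr", "NB", "MB",
                    "n_ascans", "n_depth", "fov_transverse", "axial_pixel",
                    "hr_band")

#' Write a complex OCT volume to an HDF5 container
#'
#' @param volume An `oct_volume`.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @seealso [read_volume()]
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, "oct_volume")) stop_usage("volume must be an oct_volume")
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  dims <- dim(volume$samples)
  # speckle data are incompressible; store contiguous for speed
  for (nm in c("samples_re", "samples_im"))
    rhdf5::h5createDataset(path, nm, dims = dims, storage.mode = "double",
                           level = 0, chunk = NULL)
  rhdf5::h5write(Re(volume$samples), path, "samples_re")
  rhdf5::h5write(Im(volume$samples), path, "samples_im")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  for (f in h5_meta_fields)
    rhdf5::h5writeAttribute(volume$meta[[f]], fid, f)
  invisible(path)
}

#' Read a complex OCT volume from an HDF5 container
#'
#' Fails loudly: a missing dataset or metadata attribute raises an error
#' naming the field; storage that is not a real/imaginary dataset pair raises
#' a type error.
#'
#' @param path HDF5 file following the dialect written by [write_volume()].
#' @return An `oct_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_usage("input file not found: ", path)
  ls <- rhdf5::h5ls(path)
  have <- ls$name[ls$group == "/"]
  if (!all(c("samples_re", "samples_im") %in% have))
    stop_usage("not a complex OCT container: expected datasets ",
               "'samples_re' and 'samples_im' (complex storage) in ", path)
  attrs <- rhdf5::h5readAttributes(path, "/")
  missing <- setdiff(h5_meta_fields, names(attrs))
  if (length(missing) > 0)
    stop_usage("container format error: missing metadata attribute(s) ",
               paste(sprintf("'%s'", missing), collapse = ", "))
  meta <- acquisition_meta(
    lambda_c = as.numeric(attrs$lambda_c),
    delta_lambda = as.numeric(attrs$delta_lambda),
    tau_B = as.numeric(attrs$tau_B),
    n_refr = as.numeric(attrs$n_refr),
    NB = as.integer(attrs$NB), MB = as.integer(attrs$MB),
    n_ascans = as.integer(attrs$n_ascans),
    n_depth = as.integer(attrs$n_depth),
    fov_transverse = as.numeric(attrs$fov_transverse),
    axial_pixel = as.numeric(attrs$axial_pixel),
    hr_band = as.numeric(attrs$hr_band)
  )
  re <- rhdf5::h5read(path, "samples_re")
  im <- rhdf5::h5read(path, "samples_im")
  if (!is.numeric(re) || !is.numeric(im))
    stop_usage("container type error: sample datasets are not numeric")
  complex_volume(complex(real = re, imaginary = im) |>
                   array(dim = dim(re)), meta)
}

## En-face maps ---------------------------------------------------------------

#' Construct an en-face map
#'
#' A scalar grid over (A-scan x, slow-axis position or frame) with a units tag
#' and a validity mask. Masked entries are excluded from every statistic the
#' package computes.
#'
#' @param values Numeric matrix (x along rows).
#' @param units Units tag, e.g. `"m/s"`, `"a.u."`, `"dimensionless"`.
#' @param valid Logical matrix of the same shape; defaults to `!is.na(values)`.
#' @return An object of class `enface_map`.
#' @export
enface_map <- function(values, units = "a.u.", valid = NULL) {
  if (!is.matrix(values)) stop_usage("values must be a matrix")
  if (is.null(valid)) valid <- !is.na(values)
  if (!is.logical(valid) || !all(dim(valid) == dim(values)))
    stop_usage("valid mask must be a logical matrix matching values")
  if (any(valid & !is.finite(values)))
    stop_usage("map must be finite where valid")
  structure(list(values = values, units = units, valid = valid),
            class = "enface_map")
}

#' @export
print.enface_map <- function(x, ...) {
  cat(sprintf("<enface_map> %d x %d [%s], %.1f%% valid\n",
              nrow(x$values), ncol(x$values), x$units,
              100 * mean(x$valid)))
  invisible(x)
}

#' Write an en-face map to TIFF or CSV
#'
#' TIFF export stores two 32-bit pages: the values mapped affinely onto
#' \[0, 1\] and the validity mask; the affine scale/offset, units and shape go
#' into a JSON sidecar (`<path>.json`) so that [read_enface()] reconstitutes
#' values and missing entries exactly. CSV export writes one `x,y,value` row
#' per valid pixel (masked entries are omitted).
#'
#' @param map An [enface_map()].
#' @param path Output path.
#' @param format `"tiff"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_enface <- function(map, path, format = c("tiff", "csv")) {
  if (!inherits(map, "enface_map")) stop_usage("map must be an enface_map")
  if (length(format) == 1 && !format %in% c("tiff", "csv"))
    stop_usage("unknown format '", format, "': use 'tiff' or 'csv'")
  format <- match.arg(format)
  v <- map$values
  v[!map$valid] <- NA
  if (format == "csv") {
    idx <- which(map$valid, arr.ind = TRUE)
    df <- data.frame(x = idx[, 1], y = idx[, 2], value = v[idx])
    df <- df[order(df$x, df$y), , drop = FALSE]
    write.csv(df, path, row.names = FALSE)
  } else {
    vv <- v[map$valid]
    offset <- if (length(vv)) min(vv) else 0
    scale <- if (length(vv) && max(vv) > offset) max(vv) - offset else 1
    norm <- (v - offset) / scale
    norm[!map$valid] <- 0
    tiff::writeTIFF(list(norm, map$valid * 1), path, bits.per.sample = 32L)
  }
  sidecar <- list(units = map$units, format = format,
                  shape = dim(map$values), n_valid = sum(map$valid))
  if (format == "tiff")
    sidecar <- c(sidecar, list(offset = if (exists("offset")) offset else 0,
                               scale = if (exists("scale")) scale else 1))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an en-face map written by [write_enface()]
#'
#' @param path Path previously passed to [write_enface()].
#' @param format `"tiff"` or `"csv"`.
#' @param shape For CSV input, the full map dimensions (rows omitted from the
#'   CSV come back as invalid); defaults to the sidecar shape.
#' @return An [enface_map()].
#' @export
read_enface <- function(path, format = c("tiff", "csv"), shape = NULL) {
  format <- match.arg(format)
  side_path <- paste0(path, ".json")
  sidecar <- if (file.exists(side_path)) jsonlite::read_json(side_path) else NULL
  units <- sidecar$units %||% "a.u."
  if (format == "csv") {
    df <- read.csv(path)
    shape <- shape %||% unlist(sidecar$shape)
    if (is.null(shape)) stop_usage("CSV maps need a shape (no sidecar found)")
    v <- matrix(NA_real_, shape[1], shape[2])
    v[cbind(df$x, df$y)] <- df$value
    enface_map(v, units = units)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    norm <- pages[[1]]
    valid <- pages[[2]] > 0.5
    offset <- sidecar$offset %||% 0
    scale <- sidecar$scale %||% 1
    v <- norm * scale + offset
    v[!valid] <- NA
    enface_map(v, units = units, valid = valid)
  }
}

#' @rdname autoplot-octpulse
#' @method autoplot enface_map
#' @export
autoplot.enface_map <- function(object, ...) {
  idx <- which(object$valid | !object$valid, arr.ind = TRUE)
  df <- data.frame(x = idx[, 1], y = idx[, 2],
                   value = ifelse(object$valid[idx], object$values[idx], NA))
  ggplot(df, aes(x = .data$y, y = .data$x, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey80", name = object$units) +
    labs(x = "slow axis / frame", y = "A-scan (x)") +
    theme_minimal()
}
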