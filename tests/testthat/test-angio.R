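# Angiography: decorrelation oracle values and invariances, slab geometry,
# projections, vesselness behaviour, exclusion masks and flux semantics.

test_that("decorrelation matches hand evaluation and its invariances", {
  meta <- small_meta(NB = 1L, X = 1L, Z = 1L, MB = 2L)
  vol <- complex_volume(array(complex(real = c(1, 3), imaginary = 0),
                              dim = c(1, 2, 1, 1)), meta)
  # single pair (1, 3): D = 1 - 6/10 = 0.4
  expect_equal(decorrelation(vol, 1, noise_threshold = 0)[1, 1], 0.4)
  # symmetry in the pair
  vol2 <- complex_volume(array(complex(real = c(3, 1), imaginary = 0),
                               dim = c(1, 2, 1, 1)), meta)
  expect_equal(decorrelation(vol2, 1, noise_threshold = 0)[1, 1], 0.4)
  # invariance to global amplitude scaling
  vol3 <- complex_volume(vol$samples * 7, meta)
  expect_equal(decorrelation(vol3, 1, noise_threshold = 0)[1, 1], 0.4)
  # identical repetitions: D = 0
  vol4 <- complex_volume(array(complex(real = c(2, 2), imaginary = 0),
                               dim = c(1, 2, 1, 1)), meta)
  expect_equal(decorrelation(vol4, 1, noise_threshold = 0)[1, 1], 0)
})

test_that("flow voxels decorrelate clearly above static tissue", {
  # Oracle (2e6-sample Monte Carlo on exact Rayleigh draws): the median
  # pair-averaged amplitude decorrelation of fully decorrelated speckle over
  # MB = 5 repetitions is 0.1919 (mean 1 - pi/4 = 0.2146).
  ph <- vessel_phantom()
  D <- decorrelation(ph$volume)
  flow <- ph$truth$flow_mask
  zi <- ph$truth$z_I[1, 1]; zr <- ph$truth$z_R[1, 1]
  tissue <- array(FALSE, dim(flow))
  tissue[, zi:(zr + 20), ] <- TRUE
  static <- tissue & !flow
  expect_equal(median(D[flow]), 0.1919, tolerance = 0.1)
  expect_lt(median(D[static]), 0.02)
  expect_gte(median(D[flow]) - median(D[static]), 0.17)
})

test_that("slab arithmetic follows the configured fractions and tiles the retina", {
  meta <- small_meta(NB = 4L, X = 4L, Z = 120L)
  layers <- layer_model(matrix(20, 4, 4), matrix(60, 4, 4), meta)
  slabs <- define_slabs(layers, scp_frac = 0.6, cs_depth = 40)
  expect_equal(slabs$SCP$lo[1, 1], 20)
  expect_equal(slabs$SCP$hi[1, 1], 44)   # 20 + 0.6 * 40
  expect_equal(slabs$DCP$lo[1, 1], 44)
  expect_equal(slabs$DCP$hi[1, 1], 60)
  expect_equal(slabs$CS$lo[1, 1], 60)
  expect_equal(slabs$CS$hi[1, 1], 100)
  # no gap, no overlap: SCP hi == DCP lo, DCP hi == CS lo
  expect_identical(slabs$SCP$hi, slabs$DCP$lo)
  expect_identical(slabs$DCP$hi, slabs$CS$lo)
  # boundaries follow the surfaces at constant surface-relative offsets
  zi <- matrix(15 + 3 * (1:4), 4, 4, byrow = TRUE)
  tilted <- layer_model(zi, zi + 40, meta)
  st <- define_slabs(tilted)
  expect_true(all(st$SCP$hi - st$SCP$lo == 24))
  expect_true(all(st$CS$lo - zi == 40))
})

test_that("en-face MIP projects the slab maximum", {
  meta <- small_meta(NB = 3L, X = 4L, Z = 50L)
  layers <- layer_model(matrix(10, 4, 3), matrix(30, 4, 3), meta)
  slabs <- define_slabs(layers, cs_depth = 10)
  flow <- array(0, dim = c(4, 50, 3))
  flow[2, 15, 1] <- 1                      # single hot voxel in the SCP slab
  m <- enface_mip(flow, slabs, "SCP")
  expect_equal(m$values[2, 1], 1)
  expect_equal(sum(m$values), 1)
  # single-voxel-deep slab equals that plane
  layers2 <- layer_model(matrix(10, 4, 3), matrix(30, 4, 3), meta)
  s2 <- define_slabs(layers2, cs_depth = 1)
  flow2 <- array(runif(4 * 50 * 3), dim = c(4, 50, 3))
  m2 <- enface_mip(flow2, s2, "CS")
  expect_equal(m2$values, flow2[, 30, ])
})

test_that("vesselness is zero on constant maps, peaks on ridges, suppresses blobs", {
  expect_true(all(vesselness(matrix(1, 64, 64))$values == 0))
  expect_error(vesselness(matrix(1, 64, 64), scales = -1), "positive")
  # Gaussian ridge of width sigma = 3 along y
  xg <- matrix(seq_len(64), 64, 64)
  ridge <- exp(-(xg - 32)^2 / (2 * 3^2))
  v <- vesselness(ridge)
  # the response peaks on the ridge crest and decays away from it
  expect_equal(which.max(v$values[, 32]), 32)
  expect_gt(v$values[32, 32], 0.9)
  expect_gt(v$values[32, 32], 4 * v$values[20, 32])
  # isotropic blob of equal contrast responds less than the ridge
  yg <- t(xg)
  blob <- exp(-((xg - 32)^2 + (yg - 32)^2) / (2 * 3^2))
  vb <- vesselness(blob, c = 0.5)
  vr <- vesselness(ridge, c = 0.5)
  expect_gt(vr$values[32, 32], vb$values[32, 32])
})

test_that("large-vessel mask excludes the wide tube but spares the narrow one", {
  ph <- vessel_phantom()
  D <- decorrelation(ph$volume)
  layers <- layer_model(ph$truth$z_I, ph$truth$z_R, ph$volume$meta)
  slabs <- define_slabs(layers, cs_depth = 25)
  scp <- enface_mip(D, slabs, "SCP")
  lv <- large_vessel_mask(scp)
  wide_cols <- abs(seq_len(64) - 19) <= 5
  narrow <- enface_mip(D, slabs, "DCP")
  narrow_cols <- abs(seq_len(64) - 44) <= 1
  expect_gte(mean(lv[wide_cols, ]), 0.5)
  expect_gte(mean(!lv[narrow_cols, ]), 0.8)
  # dilation grows the mask monotonically
  lv0 <- large_vessel_mask(scp, margin = 0)
  lv2 <- large_vessel_mask(scp, margin = 2)
  expect_true(all(lv2[lv0]))
  expect_gte(sum(lv2), sum(lv0))
  # a static noise-free phantom yields an empty mask
  quiet <- phantom_config(meta = small_meta(NB = 16L, X = 64L),
                          cs_pulse = list(f0 = 4, amplitudes = 0),
                          bulk = list(type = "sinusoid", amplitude = 0,
                                      freq = 0.5, jitter_sd = 0),
                          noise_floor = 0, seed = 3)
  phq <- generate_phantom(quiet)
  Dq <- decorrelation(phq$volume, noise_threshold = 0.3)
  layq <- layer_model(phq$truth$z_I, phq$truth$z_R, phq$volume$meta)
  scpq <- enface_mip(Dq, define_slabs(layq, cs_depth = 25), "SCP")
  expect_false(any(large_vessel_mask(scpq)))
})

test_that("the ONH exclusion disk has the stated physical diameter and area", {
  meta <- acquisition_meta()   # 1.5 mm over 512 A-scans
  mask <- onh_disk_mask(c(512, 400), diameter_px = 150, meta = meta)
  expect_equal(round(attr(mask, "diameter_m") * 1e6, -1), 440)
  expect_equal(sum(mask), pi * 75^2, tolerance = 0.02)
  expect_false(any(onh_disk_mask(c(64, 64), diameter_px = 0)))
  expect_error(onh_disk_mask(c(64, 64), center = c(100, 1)), "inside")
})

test_that("flux is the mean over the detected region with mean semantics", {
  vals <- matrix(0.01, 40, 40)
  vals[10:20, 10:20] <- 0.5
  m <- enface_map(vals, units = "dimensionless")
  fx <- flux(m, flow_threshold = 0.2)
  expect_equal(fx$flux, 0.5)
  expect_equal(fx$n_pixels, 121L)
  # halving the region at fixed intensity leaves flux unchanged
  vals2 <- matrix(0.01, 40, 40); vals2[10:20, 10:15] <- 0.5
  fx2 <- flux(enface_map(vals2), flow_threshold = 0.2)
  expect_equal(fx2$flux, 0.5)
  # halving the intensity halves the flux
  fx3 <- flux(enface_map(vals / 2), flow_threshold = 0.1)
  expect_equal(fx3$flux, 0.25)
  # permutation invariance
  set.seed(11)
  perm <- matrix(sample(vals), 40, 40)
  fx4 <- flux(enface_map(perm), flow_threshold = 0.2)
  expect_equal(fx4$flux, fx$flux)
  expect_lte(fx$flux, max(vals))
  # empty region: flux 0 with a warning
  expect_warning(fx5 <- flux(enface_map(matrix(0.1, 5, 5)),
                             flow_threshold = 0.9), "empty")
  expect_equal(fx5$flux, 0)
  expect_true(fx5$empty)
})

test_that("flux decreases monotonically with the configured flow level in every slab", {
  fluxes <- lapply(c(0.9, 0.4, 0.1), function(level) {
    ph <- generate_phantom(vessel_config(level = level, seed = 77))
    layers <- layer_model(ph$truth$z_I, ph$truth$z_R, ph$volume$meta)
    suppressWarnings(angio_flux(ph$volume, layers, cs_depth = 25, onh = NULL))
  })
  for (slab in c("SCP", "DCP", "CS")) {
    vals <- vapply(fluxes, function(f) f$flux[f$slab == slab], numeric(1))
    expect_true(all(diff(vals) < 0),
                label = paste("monotone flux in", slab))
  }
})
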