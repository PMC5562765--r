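# Phantom generator: waveform, determinism, speckle statistics, phase
# encoding and flow decorrelation against the configured ground truth.

test_that("cardiac waveform matches direct term-by-term evaluation", {
  # single harmonic at quarter period: sin(pi/2) = 1
  expect_equal(cardiac_waveform(1 / 16, list(f0 = 4, amplitudes = 100e-9)),
               100e-9)
  # two harmonics evaluated by explicit summation
  spec <- list(f0 = 3.5, amplitudes = c(120e-9, 30e-9), phases = c(0.2, 1.1))
  t <- 0.1
  expected <- 120e-9 * sin(2 * pi * 3.5 * t + 0.2) +
    30e-9 * sin(2 * pi * 2 * 3.5 * t + 1.1)
  expect_equal(cardiac_waveform(t, spec), expected)
  expect_error(cardiac_waveform(0, list(f0 = 4, amplitudes = numeric(0))),
               "harmonic")
})

test_that("cardiac waveform is periodic with period 1/f0", {
  set.seed(3)
  for (rep in 1:5) {
    spec <- list(f0 = runif(1, 2, 8),
                 amplitudes = runif(3, 1e-9, 2e-7),
                 phases = runif(3, -pi, pi))
    t <- runif(10, 0, 2)
    expect_equal(cardiac_waveform(t + 1 / spec$f0, spec),
                 cardiac_waveform(t, spec), tolerance = 1e-10)
  }
})

test_that("static noise-free phantom has bit-identical repetitions", {
  cfg <- phantom_config(meta = small_meta(NB = 4L, X = 32L, Z = 80L),
                        retina_px = 30, cs_px = 20, ilm_coef = c(c0 = 16),
                        cs_pulse = list(f0 = 4, amplitudes = 0),
                        bulk = list(type = "sinusoid", amplitude = 0,
                                    freq = 0.5, jitter_sd = 0),
                        noise_floor = 0, seed = 9)
  ph <- generate_phantom(cfg)
  for (i in 2:5)
    expect_identical(ph$volume$samples[, i, , ], ph$volume$samples[, 1, , ])
})

test_that("phantom generation is deterministic given the seed", {
  cfg <- phantom_config(meta = small_meta(NB = 3L, X = 16L, Z = 80L),
                        retina_px = 30, cs_px = 20, ilm_coef = c(c0 = 16),
                        seed = 21)
  ph1 <- generate_phantom(cfg)
  ph2 <- generate_phantom(cfg)
  expect_identical(ph1$volume$samples, ph2$volume$samples)
  expect_identical(ph1$truth$d_cs, ph2$truth$d_cs)
})

test_that("a linear bulk step of lambda/(8n) per frame yields -pi/2 phase differences", {
  meta <- small_meta(NB = 3L, X = 32L, Z = 80L)
  step <- meta$lambda_c / (8 * meta$n_refr)          # quarter-wavelength path
  cfg <- phantom_config(meta = meta,
                        retina_px = 30, cs_px = 20, ilm_coef = c(c0 = 16),
                        cs_pulse = list(f0 = 4, amplitudes = 0),
                        bulk = list(type = "linear",
                                    rate = step / meta$tau_B, jitter_sd = 0),
                        noise_floor = 0.02, seed = 13)
  ph <- generate_phantom(cfg)
  s1 <- ph$volume$samples[2, 1, , ]
  s2 <- ph$volume$samples[2, 2, , ]
  bright <- Mod(s1) > 0.5
  measured <- Arg(sum(s1[bright] * Conj(s2[bright])))
  expect_lt(abs(measured - (-pi / 2)), 0.05)
})

test_that("speckle amplitude within a tissue class is Rayleigh distributed", {
  cfg <- phantom_config(meta = small_meta(NB = 8L, X = 64L, Z = 96L),
                        cs_pulse = list(f0 = 4, amplitudes = 0),
                        bulk = list(type = "sinusoid", amplitude = 0,
                                    freq = 0.5, jitter_sd = 0),
                        noise_floor = 0, seed = 17)
  ph <- generate_phantom(cfg)
  # retina occupies [z_I, z_R) with unit reflectivity scale
  zi <- ph$truth$z_I[1, 1]; zr <- ph$truth$z_R[1, 1]
  amps <- Mod(ph$volume$samples[, 1, , (zi + 1):(zr - 1)])
  expect_gte(length(amps), 1e4)
  # Rayleigh(sigma) == Weibull(shape 2, scale sigma*sqrt(2)), sigma = 1 here
  ks <- suppressWarnings(ks.test(as.vector(amps), pweibull,
                                 shape = 2, scale = sqrt(2)))
  expect_gt(ks$p.value, 0.01)
})

test_that("injected phase increments match 4*pi*n*delta_d/lambda at high SNR", {
  cfg <- pulsing_config(seed = 23, noise_floor = 0)
  ph <- generate_phantom(cfg)
  meta <- ph$volume$meta
  k_phase <- 4 * pi * meta$n_refr / meta$lambda_c
  errs <- c()
  for (b in c(1, 20, 40)) {
    zr <- ph$truth$z_R[1, b]
    s1 <- ph$volume$samples[b, 1, , (zr + 2):(zr + 20)]
    s2 <- ph$volume$samples[b, 2, , (zr + 2):(zr + 20)]
    k <- (b - 1) * meta$MB + 1
    d_step <- ph$truth$d_cs[k + 1] - ph$truth$d_cs[k]
    expected <- -k_phase * d_step * cos(ph$truth$alpha[, b])  # arg(S1 * S2*)
    measured <- Arg(rowSums(s1 * Conj(s2)))
    errs <- c(errs, measured - expected)
  }
  expect_lt(sqrt(mean(((errs + pi) %% (2 * pi) - pi)^2)), 0.05)
})

test_that("flow voxel intensity correlation matches the configured level", {
  cfg <- phantom_config(meta = small_meta(NB = 32L, X = 64L, Z = 96L),
                        cs_pulse = list(f0 = 4, amplitudes = 0),
                        bulk = list(type = "sinusoid", amplitude = 0,
                                    freq = 0.5, jitter_sd = 0),
                        vessels = list(list(plexus = "cs", x0 = 32,
                                            radius_px = 4, level = 0.5)),
                        noise_floor = 0, seed = 31)
  ph <- generate_phantom(cfg)
  rho <- 1 - 0.5
  i1 <- c(); i2 <- c()
  for (b in seq_len(32)) {
    fm <- ph$truth$flow_mask[, , b]
    for (i in 1:4) {
      s <- ph$volume$samples[b, i, , ][fm]
      s2 <- ph$volume$samples[b, i + 1, , ][fm]
      i1 <- c(i1, Mod(s)^2); i2 <- c(i2, Mod(s2)^2)
    }
  }
  # consecutive-repetition intensity correlation of circular Gaussian speckle
  # with complex correlation rho is rho^2
  expect_gt(length(i1), 5000)
  expect_lt(abs(cor(i1, i2) - rho^2), 0.05)
})

test_that("preset catalog covers the study regimes", {
  presets <- phantom_presets(seed = 2)
  expect_gte(length(presets), 5)
  expect_true(all(c("flat_quiet", "pulsing_65mmhg_like", "tilted",
                    "bulk_heavy", "with_vessels") %in% names(presets)))
  # tilted preset has a non-constant incidence angle
  tilt <- presets$tilted
  a <- surface_alpha_for_test(tilt)
  expect_gt(diff(range(a)), 0.01)
  # pulsing preset peak-to-peak displacement ~300 nm
  pp <- waveform_pp_for_test(presets$pulsing_65mmhg_like$cs_pulse)
  expect_equal(pp, 300e-9, tolerance = 0.02)
})
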