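# Phase differencing, phasor bulk correction, velocity conversion and
# outlier handling — unit oracles plus phantom ground truth.

test_that("phase difference of identical frames is zero; a global factor e^{j pi/3} gives -pi/3", {
  meta <- small_meta(NB = 2L, X = 8L, Z = 16L, MB = 2L)
  set.seed(4)
  base <- array(complex(real = rnorm(2 * 8 * 16), imaginary = rnorm(2 * 8 * 16)),
                dim = c(2, 1, 8, 16))
  s <- array(complex(real = 0, imaginary = 0), dim = c(2, 2, 8, 16))
  s[, 1, , ] <- base
  s[, 2, , ] <- base            # identical
  vol <- complex_volume(s, meta)
  f <- phase_difference(vol, 1, 1, threshold = 0)
  expect_true(all(abs(f$dphi) < 1e-12))
  s[, 2, , ] <- base * exp(1i * pi / 3)
  vol <- complex_volume(s, meta)
  f <- phase_difference(vol, 1, 1, threshold = 0)
  expect_equal(unname(f$dphi[1, 1]), -pi / 3, tolerance = 1e-12)
  expect_true(all(abs(f$dphi - (-pi / 3)) < 1e-12))
  expect_error(phase_difference(vol, 1, 2), "out of range")
})

test_that("threshold_mask implements absolute and noise-quantile contracts", {
  amp <- matrix(c(1, 2, 3, 4), 1, 4)
  m <- threshold_mask(amp, "absolute", 2.5)
  expect_equal(as.vector(m), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(threshold_mask(matrix(0.1, 2, 2), "absolute", 5), "no valid")
})

test_that("reflectivity mask agrees with the true tissue mask (Jaccard >= 0.9)", {
  ph <- phantom_flat_quiet()
  b <- 5
  A <- Mod(ph$volume$samples[b, , , ])
  amp <- apply(A, c(2, 3), mean)
  mask <- threshold_mask(amp)
  zi <- ph$truth$z_I[1, b]; zr <- ph$truth$z_R[1, b]
  cs_hi <- zr + ph$truth$config$rpe_px - 1 + ph$truth$config$cs_px
  tissue <- matrix(FALSE, nrow(amp), ncol(amp))
  tissue[, zi:cs_hi] <- TRUE
  jaccard <- sum(mask & tissue) / sum(mask | tissue)
  expect_gte(jaccard, 0.9)
})

test_that("bulk phase is the complex-sum argument (wrap-robust two-phasor oracle)", {
  meta <- small_meta(NB = 1L, X = 2L, Z = 4L, MB = 2L)
  # hand-built differential frame: one A-scan with uniform 0.3 rad, one with
  # two equal-amplitude phasors at +2.9 and -2.9 rad
  dS <- matrix(complex(real = 0, imaginary = 0), 2, 4)
  dS[1, ] <- exp(1i * 0.3)
  dS[2, 1] <- exp(1i * 2.9); dS[2, 2] <- exp(-1i * 2.9)
  frame <- structure(list(dS = dS, dphi = Arg(dS),
                          mask = matrix(TRUE, 2, 4), amp = Mod(dS),
                          b = 1, i = 1, meta = meta),
                     class = "phase_diff_frame")
  layers <- layer_model(matrix(1, 2, 1), matrix(4, 2, 1), meta)
  bp <- bulk_phase(frame, layers)
  expect_equal(bp$dphi_bulk[1], 0.3, tolerance = 1e-12)
  # complex sum 2*cos(2.9) is a negative real: argument pi, not 0
  expect_equal(bp$dphi_bulk[2], pi, tolerance = 1e-12)
})

test_that("bulk phase tracks the injected drift within 0.05 rad circular RMS", {
  cfg <- phantom_config(meta = small_meta(NB = 32L),
                        cs_pulse = list(f0 = 3.8, amplitudes = 0),
                        bulk = list(type = "sinusoid", amplitude = 1.5e-6,
                                    freq = 0.5, jitter_sd = 0.05),
                        seed = 37)
  ph <- generate_phantom(cfg)
  meta <- ph$volume$meta
  layers <- layer_model(ph$truth$z_I, ph$truth$z_R, meta)
  k_phase <- 4 * pi * meta$n_refr / meta$lambda_c
  thr <- octpulse:::volume_threshold(ph$volume)
  errs <- c()
  for (b in seq(1, 32, by = 4)) {
    for (i in 1:4) {
      fr <- phase_difference(ph$volume, b, i, threshold = thr)
      bp <- bulk_phase(fr, layers)
      k <- (b - 1) * 5 + i
      expected <- -k_phase * (ph$truth$d_bulk[k + 1] - ph$truth$d_bulk[k])
      errs <- c(errs, bp$dphi_bulk - expected)
    }
  }
  expect_lt(sqrt(mean(((errs + pi) %% (2 * pi) - pi)^2)), 0.05)
})

test_that("chorioscleral phase: injected step recovered, bulk-invariant, zero-pulse unbiased", {
  meta <- small_meta(NB = 1L, X = 16L, Z = 60L, MB = 2L)
  set.seed(6)
  make_frame <- function(cs_step, bulk_step) {
    s1 <- matrix(complex(real = rnorm(16 * 60), imaginary = rnorm(16 * 60)),
                 16, 60)
    phase <- matrix(bulk_step, 16, 60)
    phase[, 41:60] <- phase[, 41:60] + cs_step
    s2 <- s1 * exp(1i * phase)
    dS <- s1 * Conj(s2)    # measured dphi = -(injected step)
    structure(list(dS = dS, dphi = Arg(dS), mask = matrix(TRUE, 16, 60),
                   amp = Mod(dS), b = 1, i = 1, meta = meta),
              class = "phase_diff_frame")
  }
  layers <- layer_model(matrix(10, 16, 1), matrix(40, 16, 1), meta)
  # CS step +0.5 rad, no bulk: measured relative phase is -0.5
  f1 <- make_frame(0.5, 0)
  r1 <- relative_cs_phase(f1, bulk_phase(f1, layers), layers)
  expect_lt(abs(Arg(mean(exp(1i * r1$dphi_rcs))) - (-0.5)), 0.05)
  # same CS step with bulk +1.0 everywhere: identical answer (bulk cancels)
  f2 <- make_frame(0.5, 1.0)
  r2 <- relative_cs_phase(f2, bulk_phase(f2, layers), layers)
  expect_equal(r2$dphi_rcs, r1$dphi_rcs, tolerance = 1e-10)
  # zero CS pulse with bulk present: bias below 0.02 rad
  f3 <- make_frame(0, 0.7)
  r3 <- relative_cs_phase(f3, bulk_phase(f3, layers), layers)
  expect_lt(abs(Arg(mean(exp(1i * r3$dphi_rcs)))), 0.02)
})

test_that("phase-to-velocity evaluates the conversion exactly and linearly", {
  meta <- acquisition_meta()
  expect_equal(phase_to_velocity(0, meta), 0)
  expect_equal(phase_to_velocity(pi, meta) * 1e6, 20.33, tolerance = 1e-3)
  expect_equal(phase_to_velocity(pi / 2, meta) * 1e6, 10.17, tolerance = 1e-3)
  a <- 0.37
  expect_equal(phase_to_velocity(a * 1.5, meta),
               1.5 * phase_to_velocity(a, meta))
})

test_that("angle correction divides by cos(alpha) and flags beyond the cap", {
  expect_equal(angle_correct(5e-6, 0), 5e-6)
  expect_equal(angle_correct(5e-6, pi / 3, cap = pi / 2.9), 1e-5,
               tolerance = 1e-10)
  expect_true(is.na(angle_correct(5e-6, pi / 3)))  # default cap is 60 deg
})

test_that("retinal slab is self-consistent after bulk correction", {
  pp <- pulsing_processed()
  thr <- pp$field$threshold
  ph <- pp$ph; layers <- pp$layers
  args <- c()
  for (b in c(3, 17, 31)) {
    fr <- phase_difference(ph$volume, b, 2, threshold = thr)
    bp <- bulk_phase(fr, layers)
    Z <- ph$volume$meta$n_depth; X <- ph$volume$meta$n_ascans
    zg <- matrix(rep(seq_len(Z), each = X), X, Z)
    slab <- zg >= matrix(layers$z_I[, b], X, Z) &
      zg <= matrix(layers$z_R[, b], X, Z)
    w <- rowSums(fr$dS * (fr$mask & slab)) * exp(-1i * bp$dphi_bulk)
    args <- c(args, Arg(w))
  }
  expect_lt(max(abs(args)), 0.02)
})

test_that("velocities stay inside the unambiguous range (wrapping, not clipping)", {
  pp <- pulsing_processed()
  vmax <- pp$field$meta$lambda_c / (4 * pp$field$meta$n_refr *
                                      pp$field$meta$tau_B)
  expect_true(all(abs(pp$field$v_rcs) <= vmax / cos(pp$layers$alpha_cap),
                  na.rm = TRUE))
  expect_true(all(abs(pp$field$v) <= vmax + 1e-12, na.rm = TRUE))
})

test_that("end-to-end velocity recovery tracks ground truth with R^2 >= 0.9", {
  pp <- pulsing_processed()
  fit <- lm(pp$series$v ~ pp$gt$v)
  expect_gte(summary(fit)$r.squared, 0.9)
  # sign convention: positive velocity = motion toward the beam source
  expect_gt(coef(fit)[2], 0.9)
  expect_lt(coef(fit)[2], 1.1)
})

test_that("clean_series excludes decorrelated frames and interpolates them", {
  make_field <- function(circ_var, v) {
    n <- length(circ_var)
    structure(list(
      v = matrix(v, 3, n, byrow = TRUE),
      v_rcs = matrix(v, 3, n, byrow = TRUE),
      valid = matrix(TRUE, 3, n),
      interpolated = matrix(FALSE, 3, n),
      frame_stats = tibble::tibble(frame = 1:n, b = 1:n, i = 1,
                                   time = (1:n) * 7.65e-3,
                                   circ_var = circ_var,
                                   valid_frac = 1, excluded = FALSE),
      meta = small_meta(), alpha = NULL, threshold = 0),
      class = "velocity_field")
  }
  # no frame above the limit: untouched
  f <- make_field(rep(0.1, 6), c(1, 2, 3, 4, 5, 6) * 1e-6)
  out <- clean_series(f)
  expect_identical(out$v_rcs, f$v_rcs)
  expect_false(any(out$interpolated))
  # middle frame corrupted: replaced by the neighbour average
  f <- make_field(c(0.1, 0.1, 0.9, 0.1, 0.1), c(1, 2, 9, 4, 5) * 1e-6)
  out <- clean_series(f)
  expect_equal(out$v_rcs[1, 3], 3e-6, tolerance = 1e-12)
  expect_true(all(out$interpolated[, 3]))
  expect_true(out$frame_stats$excluded[3])
  # corrupted first frame: nearest-valid copy
  f <- make_field(c(0.9, 0.1, 0.1), c(9, 2, 3) * 1e-6)
  out <- clean_series(f)
  expect_equal(out$v_rcs[1, 1], 2e-6, tolerance = 1e-12)
  # more than half the frames corrupted: unusable
  f <- make_field(c(0.9, 0.9, 0.9, 0.1), rep(1e-6, 4))
  expect_error(clean_series(f), "unusable")
})
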