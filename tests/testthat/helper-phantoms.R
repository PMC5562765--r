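# Shared phantom fixtures, generated once per test run and cached.

.phantom_cache <- new.env(parent = emptyenv())

small_meta <- function(NB = 64L, X = 64L, Z = 96L, MB = 5L, ...) {
  acquisition_meta(NB = NB, MB = MB, n_ascans = X, n_depth = Z, ...)
}

# standard pulsing fixture: 300 nm peak-to-peak at 3.8 Hz, 64 x 5 x 64 x 96
pulsing_config <- function(seed = 42, ...) {
  phantom_config(meta = small_meta(),
                 cs_pulse = scale_pulse_pp(300e-9),
                 seed = seed, ...)
}

scale_pulse_pp <- function(pp, f0 = 3.8) {
  # two-harmonic waveform rescaled to an exact peak-to-peak displacement
  spec <- list(f0 = f0, amplitudes = c(135e-9, 25e-9), phases = c(0, pi / 3))
  tt <- seq(0, 1 / f0, length.out = 4096)
  cur <- max(cardiac_waveform(tt, spec)) - min(cardiac_waveform(tt, spec))
  spec$amplitudes <- spec$amplitudes * pp / cur
  spec
}

cached_phantom <- function(name, maker) {
  if (!exists(name, envir = .phantom_cache))
    assign(name, maker(), envir = .phantom_cache)
  get(name, envir = .phantom_cache)
}

phantom_pulsing <- function() {
  cached_phantom("pulsing", function() generate_phantom(pulsing_config()))
}

phantom_flat_quiet <- function() {
  cached_phantom("flat_quiet", function() {
    generate_phantom(phantom_config(
      meta = small_meta(),
      cs_pulse = list(f0 = 3.8, amplitudes = 0),
      bulk = list(type = "sinusoid", amplitude = 0, freq = 0.5,
                  jitter_sd = 0),
      seed = 11))
  })
}

# pulsing phantom processed through segmentation + velocity + series
pulsing_processed <- function() {
  cached_phantom("pulsing_processed", function() {
    ph <- phantom_pulsing()
    layers <- fit_surface_normals(segment_layers(ph$volume))
    field <- clean_series(compute_velocity_field(ph$volume, layers))
    list(ph = ph, layers = layers, field = field,
         series = frame_mean_velocity(field),
         gt = gt_velocity_series(ph$truth))
  })
}

true_pp <- function(ph) max(ph$truth$d_cs) - min(ph$truth$d_cs)

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

surface_alpha_for_test <- function(cfg) {
  z_I <- octpulse:::eval_ilm(cfg$ilm_coef, cfg$meta$n_ascans, cfg$meta$NB)
  octpulse:::surface_alpha(z_I + cfg$retina_px, cfg$meta)
}

waveform_pp_for_test <- function(spec) octpulse:::waveform_pp(spec)

# half-amplitude variant of the pulsing fixture, fully processed
pulsing_half_processed <- function() {
  cached_phantom("pulsing_half_processed", function() {
    cfg <- pulsing_config(seed = 42)
    cfg$cs_pulse$amplitudes <- cfg$cs_pulse$amplitudes / 2
    ph <- generate_phantom(cfg)
    layers <- fit_surface_normals(segment_layers(ph$volume))
    field <- clean_series(compute_velocity_field(ph$volume, layers))
    list(ph = ph, layers = layers, field = field,
         series = frame_mean_velocity(field))
  })
}

# static phantom with one wide SCP vessel, one narrow DCP vessel and two CS
# vessels (64 x 5 x 64 x 96)
vessel_config <- function(level = 1, retinal_level = level, seed = 55) {
  phantom_config(
    meta = small_meta(),
    cs_pulse = list(f0 = 4, amplitudes = 0),
    bulk = list(type = "sinusoid", amplitude = 0, freq = 0.5, jitter_sd = 0),
    vessels = list(
      list(plexus = "scp", x0 = 19, radius_px = 5, level = retinal_level),
      list(plexus = "dcp", x0 = 44, radius_px = 2, level = retinal_level),
      list(plexus = "cs", x0 = 30, radius_px = 4, level = level),
      list(plexus = "cs", x0 = 54, radius_px = 4, level = level)),
    seed = seed)
}

vessel_phantom <- function() {
  cached_phantom("vessels", function() generate_phantom(vessel_config()))
}
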