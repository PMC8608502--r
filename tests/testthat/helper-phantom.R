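# Shared phantom fixtures. Generating the default 64 x 128 x 128 phantom
# takes a few seconds, so commonly reused ones are cached per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

default_phantom <- function(seed = 1) {
  cached(paste0("default_", seed), generate_phantom(phantom_spec(), seed))
}

# phantom with 10 isolated nodules (the end-to-end study condition:
# contrast >= 300 HU over -850 HU lung, diameters 6-16 mm, noise sd 20)
nodule_phantom <- function(seed = 1) {
  cached(paste0("nodule_", seed), {
    spec <- phantom_spec(nodules = sample_nodules(phantom_spec(), 10, seed = 42))
    generate_phantom(spec, seed)
  })
}

# segmented + repaired lung mask for a phantom
segmented_mask <- function(ph) {
  thr <- optimal_threshold(ph$volume)
  repair_contour(fill_cavities(
    extract_lung_mask(ph$volume, thr, min_volume_ml = 50)), 5)
}

# tiny grid for fast structural tests
small_spec <- function(...) {
  phantom_spec(grid_shape = c(24L, 48L, 48L), spacing_mm = c(2, 1.5, 1.5),
               body_semi_axes_mm = c(22, 30, 33),
               lung_semi_axes_mm = c(15, 18, 12),
               lung_offset_x_mm = 16, vessel_count = 2L, ...)
}
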