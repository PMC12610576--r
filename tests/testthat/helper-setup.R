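# Shared fixtures.  Heavy objects are memoised so several test files can
# reuse one computation within the session.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

# Small geometry for fast unit tests (no inserts fit on 10 cm).
small_geom <- function() beam_geometry(detector_cm = 10)

# Mid-size geometry that fits the full insert layout (30 x 30 cm, 300 px).
mid_geom <- function() beam_geometry(detector_cm = 30)

test_spectrum <- function(mgy = 1)
  memo(paste0("spec", mgy),
       normalize_to_kerma(generate_spectrum(120, 4), mgy))

# Noise-free mid-size forward model shared by dual-energy/evaluation tests:
# expected LE/HE maps of the standard phantom (no scatter) plus the open-beam
# reference, at 0.05 mGy.
mid_forward <- function() memo("mid_forward", {
  g <- mid_geom()
  s <- normalize_to_kerma(generate_spectrum(120, 4), 0.05)
  det <- detector_model()
  ph <- build_phantom("standard", g)
  primary <- project_primary(ph, s, g)
  ref <- apply_detector(project_primary(reference_phantom(60, g), s, g),
                        detector = det, sample = FALSE)
  list(geometry = g, spectrum = s, detector = det, phantom = ph,
       primary = primary,
       expected = apply_detector(primary, detector = det, sample = FALSE),
       reference = ref)
})

# One full reference-configuration experiment (all three phantom sizes),
# shared by the acceptance criteria.
acceptance_experiment <- function() memo("acceptance_experiment", {
  run_experiment(run_config(seed = 20260922))
})

# Synthetic frame set with a known constant scatter level and zero primary,
# noise-free: every shadow sample must recover exactly `scatter_level`.
constant_scatter_frames <- function(geometry, scatter_level = 100,
                                    n_positions = 25) {
  rod <- blocker_positions(n_positions, geometry)
  n <- geometry$n_pixels
  frames <- lapply(seq_len(n_positions), function(i)
    pcdexr:::new_binned_image(
      matrix(scatter_level / n_positions, n, n),
      matrix(scatter_level / (2 * n_positions), n, n),
      kerma_mgy = 1 / n_positions))
  structure(list(frames = frames, rod = rod,
                 truth = NULL, detector = detector_model(),
                 geometry = geometry, n_frames = n_positions),
            class = "frame_set")
}
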