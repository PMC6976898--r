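# Small scene/source constructors shared across tests. Problem sizes are kept
# tiny: the physics checks here are about correctness, not precision.

small_scene <- function(pitch = 0.3, side = 12, skin = 0,
                        bulk = tissue_spec("fibrous", 700)) {
  build_layered_scene(scene_config(side_length = side, voxel_pitch = pitch,
                                   skin_thickness = skin, bulk = bulk))
}

# homogeneous scene with hand-set optical properties
custom_scene <- function(mu_a, mu_s, g = 0.9, n = 1.4, pitch = 0.3,
                         side = 12) {
  sc <- small_scene(pitch = pitch, side = side)
  sc$palette$mu_a <- mu_a
  sc$palette$mu_s <- mu_s
  sc$palette$g <- g
  sc$palette$n <- n
  sc
}

narrow_beam <- function(n_photons = 1e5, seed = 1, theta = 0, D = 1) {
  make_source(D = D, theta = theta, n_photons = n_photons, seed = seed,
              length_mm = 4, width_mm = 0.6)
}
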