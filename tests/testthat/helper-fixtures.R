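# shared small fixtures, built in code

small_bank <- function(seed = 1) {
  default_shape_bank(n_per_taxon = 2, seed = seed, resolution = 16)
}

small_bathymetry <- function() {
  generate_bathymetry(list(
    fore_reef_length = 80, crest_width = 10, back_reef_width = 20,
    sand_width = 60, flat_depth = 1.5, lagoon_depth = 2.5,
    offshore_depth = 12
  ))
}

# tiny flume for fast solver-based tests: short profile, mild waves
flume_bathymetry <- function(depth = 5, length = 80) {
  generate_bathymetry(list(
    offshore_depth = depth,
    segments = data.frame(length = length, end_z = -depth,
                          label = "reef_flat")
  ))
}
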