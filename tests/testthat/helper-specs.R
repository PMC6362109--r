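# Small phantom specs and random volumes reused across tests.

small_spec <- function(grid = c(48, 48, 48),
                       tumors = list(tumor_spec(c(28, 20, 20), 5)),
                       noise_sigma = 0, rng_seed = 7, ...) {
  phantom_spec(grid_shape = grid, tumors = tumors, noise_sigma = noise_sigma,
               rng_seed = rng_seed, ...)
}

rand_volume <- function(d = c(5, 5, 5), seed = 1, maxval = 100) {
  set.seed(seed)
  vox_volume(array(sample(0:maxval, prod(d), replace = TRUE), dim = d),
             voxel_size_um = 13)
}

label_array <- function(labels) array(as.integer(labels), dim = dim(labels))
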