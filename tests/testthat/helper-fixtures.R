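# Shared fixtures, built in code at test time.

fixture_paradigm <- function(n_blocks = 2L) make_paradigm(n_blocks)

fixture_slab <- function(nz = 2L)
  make_ribbon(c(20L, 16L, nz), voxel_size = c(0.8, 0.8, 0.8), thickness = 2)

fixture_annulus <- function(inner = 4, outer = 6, voxel = 0.8, nz = 2L) {
  n <- ceiling((outer + 2 * voxel) / voxel)
  make_ribbon(c(n, n, nz), voxel_size = c(voxel, voxel, 0.8),
              geometry = "annulus", inner = inner, outer = outer)
}

# a "delta-like" response basis: unit response sustained over one block,
# zero outside (so superposition over onsets reproduces the boxcar)
fixture_boxcar_response <- function(block_s = 26.6) {
  structure(list(time_grid = c(0, block_s - 1e-6), amplitude = c(1, 1),
                 age_group = "none", block_s = block_s,
                 shape_params = list()),
            class = "response_model")
}
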