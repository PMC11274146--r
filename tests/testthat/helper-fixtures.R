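# Shared fixtures, built once per test run.  The tiny phantom keeps
# per-operation costs in milliseconds; the coarse phantom is the desk-scale
# stand-in used for surrogate accuracy and statistics studies.
.fixtures <- new.env(parent = emptyenv())

tiny_phantom <- function() {
  if (is.null(.fixtures$tiny)) {
    .fixtures$tiny <- build_head_phantom(
      grid_n = 15, voxel_size = 5, radii = c(12, 18, 24, 28, 33),
      eye_centers = rbind(c(8, 20, 0), c(-8, 20, 0)), eye_radius = 5
    )
  }
  .fixtures$tiny
}

coarse_phantom <- function() {
  if (is.null(.fixtures$coarse)) {
    .fixtures$coarse <- build_head_phantom(grid_n = 25, voxel_size = 3.2)
  }
  .fixtures$coarse
}

default_space <- function() {
  if (is.null(.fixtures$space)) .fixtures$space <- head_tissue_space()
  .fixtures$space
}

# Relative coordinates s_k = (x_k - nominal_k) / (0.2 nominal_k) in [-1, 1],
# handy for writing polynomial test models on the head-tissue box.
rel_coords <- function(x, space = default_space()) {
  ref <- reference_point(space)
  (x - ref) / (0.2 * ref)
}
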