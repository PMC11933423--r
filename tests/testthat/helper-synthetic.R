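# Shared synthetic fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

.cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small grid: 12x14x12 at 6 mm, ellipsoidal mask (~500 voxels)
small_grid <- function() .cached("small_grid",
  default_grid(c(12L, 14L, 12L), voxel_mm = 6))

small_model <- function() .cached("small_model",
  planted_network_model(grid = small_grid(), seed = 42L))

small_connectome <- function() .cached("small_connectome",
  generate_connectome(small_model(), n_subjects = 8, n_timepoints = 80,
                      seed = 2L))

# jitter 0: foci on voxel centers, so 6 mm seeds always rasterize on the
# coarse 6 mm test lattice
small_coords <- function() .cached("small_coords",
  sample_study_coordinates(small_model(), n_studies = 5, jitter_mm = 0,
                           seed = 3L))

small_networks <- function() .cached("small_networks",
  run_study_networks(small_coords(), small_connectome()))

# wrap explicit per-subject matrices as a connectome (oracle inputs)
fake_connectome <- function(grid, matrices) {
  structure(list(grid = grid, subjects = matrices,
                 n_timepoints = ncol(matrices[[1]])),
            class = "connectome")
}

# all-TRUE-mask grid with identity-scaled affine, handy for exact geometry
box_grid <- function(shape = c(5L, 5L, 5L), voxel_mm = 1, origin = NULL) {
  affine <- diag(c(rep(voxel_mm, 3), 1))
  if (!is.null(origin)) affine[1:3, 4] <- origin
  volume_grid(shape, affine)
}
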