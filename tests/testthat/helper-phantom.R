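# Shared phantom fixtures. Tests run the standard thorax geometry on a
# coarsened raster (same millimeter anatomy, 128 x 128 x 25 voxels) so the
# whole pipeline stays fast; the acceptance tests use the full 512 x 512 x
# 100 raster.

small_phantom_spec <- function(seed = 3, ...) {
  phantom_spec(rows = 128L, cols = 128L, n_planes = 25L,
               in_plane_spacing = c(3.0468, 3.0468),
               plane_separation = 8.8, slice_thickness = 8.8,
               seed = seed, ...)
}

# strip geometry and disk radius scaled by the same factor 4 as the raster
small_config <- function(...) {
  pipeline_config(preprocess = preprocess_config(disk_radius = 3),
                  strips = strip_spec(19, 25, 5, 29, 31), ...)
}

# one shared small phantom + segmentation, computed once per test run
.fixture_env <- new.env(parent = emptyenv())

small_case <- function() {
  if (is.null(.fixture_env$case)) {
    ph <- generate_phantom(small_phantom_spec())
    res <- lung_segment(ph$volume, small_config())
    .fixture_env$case <- list(phantom = ph, result = res)
  }
  .fixture_env$case
}
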