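# Shared fixtures: reference parameter sets and memoised meshes.

# classic route, the set used for the relative-diffusion / reaction-strength
# figures (c1, c_minus1, c2) = (0.05, 0.04, 0.45)
classic_params <- function(...) {
  model_params(c1 = 0.05, c_minus1 = 0.04, c2 = 0.45, c_max = 3, V0 = 6,
               gamma = 25, d = 10, ...)
}

# classic route, the time-evolution fixture (c_minus1 = 0.02)
classic_fixture_params <- function(...) {
  model_params(c1 = 0.05, c_minus1 = 0.02, c2 = 0.45, c_max = 3, V0 = 6,
               gamma = 25, d = 10, ...)
}

# non-classic route (c1, c_minus1, c2) = (0.05, 0.03, 0.15)
nonclassic_params <- function(...) {
  model_params(c1 = 0.05, c_minus1 = 0.03, c2 = 0.15, c_max = 3, V0 = 6,
               gamma = 25, d = 10, ...)
}

# meshes are expensive to assemble; build each level once per test run
.mesh_cache <- new.env(parent = emptyenv())
cached_mesh <- function(level) {
  key <- as.character(level)
  if (is.null(.mesh_cache[[key]])) {
    .mesh_cache[[key]] <- build_icosphere(level)
  }
  .mesh_cache[[key]]
}

# random strictly positive parameter set for property sweeps
random_params <- function() {
  model_params(c1 = runif(1, 0.001, 2), c_minus1 = runif(1, 0.001, 2),
               c2 = runif(1, 0.01, 2), c_max = runif(1, 0.5, 5),
               V0 = runif(1, 1, 10), gamma = runif(1, 1, 100),
               d = runif(1, 1, 50))
}

# degree-3 zonal spherical harmonic on mesh vertices (Legendre P3)
zonal_harmonic3 <- function(mesh) {
  z <- mesh$vertices[, 3]
  (5 * z^3 - 3 * z) / 2
}
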