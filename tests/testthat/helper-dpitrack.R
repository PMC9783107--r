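# shared fixtures: default parameter sets and a small tracked run
mat0 <- material_parameters()
fluid0 <- fluid_properties()

# spatially uniform custom field (R-query only)
uniform_field <- function(u) {
  flow_field(function(p) matrix(rep(u, each = nrow(p)), ncol = 3),
             kind = "custom")
}

# plane Couette shear u_x = G * z
couette_field <- function(G) {
  flow_field(function(p) cbind(G * p[, 3], 0, 0), kind = "custom")
}

small_run <- function(n = 80, seed = 1, ...) {
  run_simulation(simulation_config(n_particles = n, seed = seed, ...))
}
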