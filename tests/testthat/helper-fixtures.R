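# shared fixtures: small meshes and fast parameter profiles

tri_canonical <- chemomech:::tri_canonical
tri_angles_cpp <- chemomech:::tri_angles_cpp
points_in_polygon_cpp <- chemomech:::points_in_polygon_cpp

tiny_mesh <- function(n_membrane = 12L, n_interior = 8L, seed = 7L,
                      diameter = 6) {
  build_disk_mesh(diameter = diameter, n_membrane = n_membrane,
                  n_interior = n_interior, seed = seed)
}

# a square membrane with one interior node, hand-built (for closed-form
# mechanics checks)
square_mesh <- function(half = 1) {
  mesh <- list(membrane = rbind(c(half, -half), c(half, half),
                                c(-half, half), c(-half, -half)),
               interior = matrix(c(0.3, 0.1), 1),
               n_membrane = 4L, n_interior = 1L, diameter = 2 * half,
               seed = 0L, rest_spacing = 2 * half)
  class(mesh) <- "cell_mesh"
  mesh$triangles <- tri_canonical(rbind(c(1L, 2L, 5L), c(2L, 3L, 5L),
                                        c(3L, 4L, 5L), c(4L, 1L, 5L)))
  mesh$tri_keys_v <- chemomech:::tri_keys(mesh$triangles, 5L)
  mesh$ref_angles <- tri_angles_cpp(mesh$triangles,
                                    rbind(mesh$membrane, mesh$interior))
  mesh
}

# small, fast simulation configuration (coarse mesh, short horizon)
fast_config <- function(t_end = 30, master_seed = 1L, ...) {
  sim_config(t_end = t_end,
             mesh = list(diameter = 10, n_membrane = 24L, n_interior = 60L),
             master_seed = master_seed, ...)
}
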