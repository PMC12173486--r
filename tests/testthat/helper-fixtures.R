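# coarse mesh used where element count does not matter: 6 slices,
# 2x2 cores, 16/12/24 in-plane elements -> 96/72/144 hexes
small_mesh_config <- function(twist_deg = 0, ...) {
  mesh_config(n_slices = 6,
              butterfly_density = list(n_core = 2,
                                       n_radial = c(LG = 3, MG = 2, S = 2)),
              twist_deg = twist_deg, ...)
}

table1_params <- function() material_params()

# uniform load case at a given nominal stress (Pa) on a mesh
uniform_case <- function(mesh, sigma) {
  areas <- distal_areas(mesh)
  partition_cohort_forces(sigma * sum(areas) * 1e-6, areas, ratio = 1)
}

# deterministic text nodal-displacement log in the reader's grammar
write_displacement_log <- function(path, times_ms, u_mm, node_ids,
                                   data_name = "uy") {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(times_ms)) {
    writeLines(sprintf("*Step = %d", k), con)
    writeLines(sprintf("*Time = %.6f", times_ms[k]), con)
    writeLines(sprintf("*Data = %s", data_name), con)
    writeLines(sprintf("%d %.12g", node_ids, u_mm[, k]), con)
  }
  invisible(path)
}
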