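# natural coordinates of the hex8 corners (bottom quad CCW, then top)
.hex_corners <- cbind(
  xi   = c(-1,  1,  1, -1, -1,  1,  1, -1),
  eta  = c(-1, -1,  1,  1, -1, -1,  1,  1),
  zeta = c(-1, -1, -1, -1,  1,  1,  1,  1))

# trilinear Jacobian determinant of every hex at a set of natural points
.hex_detJ <- function(mesh, pts) {
  h <- mesh$hexes
  M <- nrow(h)
  out <- matrix(NA_real_, M, nrow(pts))
  X <- lapply(1:3, function(a) matrix(mesh$nodes[h, a], ncol = 8))
  for (p in seq_len(nrow(pts))) {
    g <- pts[p, ]
    dN <- cbind(
      .hex_corners[, 1] * (1 + .hex_corners[, 2] * g[2]) * (1 + .hex_corners[, 3] * g[3]),
      .hex_corners[, 2] * (1 + .hex_corners[, 1] * g[1]) * (1 + .hex_corners[, 3] * g[3]),
      .hex_corners[, 3] * (1 + .hex_corners[, 1] * g[1]) * (1 + .hex_corners[, 2] * g[2])) / 8
    J <- array(0, c(M, 3, 3))
    for (a in 1:3) for (b in 1:3) J[, a, b] <- X[[a]] %*% dN[, b]
    out[, p] <-
      J[, 1, 1] * (J[, 2, 2] * J[, 3, 3] - J[, 2, 3] * J[, 3, 2]) -
      J[, 1, 2] * (J[, 2, 1] * J[, 3, 3] - J[, 2, 3] * J[, 3, 1]) +
      J[, 1, 3] * (J[, 2, 1] * J[, 3, 2] - J[, 2, 2] * J[, 3, 1])
  }
  out
}

#' Hexahedral element Jacobian determinants
#'
#' Evaluates the trilinear Jacobian determinant of every element at its
#' eight corners (the standard inversion check: all corner determinants
#' must be positive for a non-inverted hex).
#'
#' @param mesh a `tendon_mesh`.
#' @return an M x 8 matrix of determinants (mm^3 per natural volume).
#' @export
hex_jacobians <- function(mesh) {
  stopifnot(inherits(mesh, "tendon_mesh"))
  .hex_detJ(mesh, .hex_corners)
}

#' Per-slice in-plane cross-sectional areas
#'
#' Shoelace areas of the in-plane element faces at every slice, from the
#' actual (possibly twisted) node coordinates, summed per subtendon.
#'
#' @param mesh a `tendon_mesh`.
#' @return `(n_slices + 1) x 3` matrix (mm^2), columns LG, MG, S.
#' @export
slice_areas <- function(mesh) {
  stopifnot(inherits(mesh, "tendon_mesh"))
  tpl <- mesh$template
  Tn <- nrow(tpl$nodes)
  ns <- mesh$config$n_slices
  labs <- c("LG", "MG", "S")
  out <- matrix(0, ns + 1, 3, dimnames = list(NULL, labs))
  for (s in 0:ns) {
    q <- tpl$quads + s * Tn
    a <- .quad_signed_area(mesh$nodes[, c("x", "y")], q)
    out[s + 1, ] <- vapply(labs, function(l) sum(a[tpl$quad_label == l]), 0)
  }
  out
}

#' Distal cross-sectional areas per subtendon
#'
#' Areas of the three subtendon sectors at the distal end (slice 0) of
#' the undeformed mesh, in mm^2.  These are the areas used to partition
#' cohort forces into a-priori axial stresses.
#'
#' @param mesh a `tendon_mesh`.
#' @return named numeric vector (LG, MG, S), mm^2.
#' @export
distal_areas <- function(mesh) {
  stopifnot(inherits(mesh, "tendon_mesh"))
  ax <- mesh$semiaxes[1, ]
  mesh$template$areas * ax[["a"]] * ax[["b"]]
}

#' Total mesh volume
#'
#' Two measures are provided.  `"prismatic"` integrates the per-slice
#' in-plane polygon areas along the axis (trapezoidal rule); because
#' in-plane rotation is isometric this measure is exactly invariant
#' under helical twist.  `"tet"` integrates the trilinear element
#' Jacobian (2x2x2 Gauss); it measures the faceted solid, which changes
#' at second order in the inter-slice twist increment.
#'
#' @param mesh a `tendon_mesh`.
#' @param method `"prismatic"` (default) or `"tet"`.
#' @return volume in mm^3.
#' @export
mesh_volume <- function(mesh, method = c("prismatic", "tet")) {
  method <- match.arg(method)
  if (method == "prismatic") {
    A <- rowSums(slice_areas(mesh))
    dz <- mesh$config$length / mesh$config$n_slices
    sum((A[-1] + A[-length(A)]) / 2) * dz
  } else {
    g <- 1 / sqrt(3)
    sum(.hex_detJ(mesh, .hex_corners * g))
  }
}

#' Export a tendon mesh as legacy ASCII VTK
#'
#' Writes an unstructured-grid legacy VTK file (hexahedral cells) with
#' per-cell subtendon labels (integer: LG = 1, MG = 2, S = 3) and fibre
#' direction vectors, readable by ParaView and meshio.
#'
#' @param mesh a `tendon_mesh` (with fibre directions assigned).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vtk_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tendon_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$hexes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "tendonwave three-subtendon hex mesh (mm)",
               "ASCII", "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1], mesh$nodes[, 2],
                     mesh$nodes[, 3]), con)
  writeLines(sprintf("CELLS %d %d", m, 9 * m), con)
  h0 <- mesh$hexes - 1L
  writeLines(paste(8L, h0[, 1], h0[, 2], h0[, 3], h0[, 4],
                   h0[, 5], h0[, 6], h0[, 7], h0[, 8]), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep.int(12L, m)), con)
  writeLines(sprintf("CELL_DATA %d", m), con)
  writeLines(c("SCALARS subtendon int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$label, c("LG", "MG", "S"))), con)
  if (!is.null(mesh$fibre)) {
    writeLines("VECTORS fibre double", con)
    writeLines(sprintf("%.9g %.9g %.9g", mesh$fibre[, 1], mesh$fibre[, 2],
                       mesh$fibre[, 3]), con)
  }
  invisible(path)
}
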