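#' Configuration of the three-subtendon tendon mesh
#'
#' Describes the tapered elliptical free-tendon geometry and its butterfly
#' hex discretisation.  The cross-section is an ellipse, linearly tapered
#' from the distal end (`distal_width` x `distal_thickness`) to the
#' proximal end, partitioned into three angular sectors -- lateral
#' gastrocnemius (LG), medial gastrocnemius (MG) and soleus (S) -- whose
#' areas match `csa_fractions`.  Sectors are defined in a scaled-circle
#' parametric domain, where angular span is exactly proportional to area.
#'
#' The default in-plane density (`butterfly_density`) is chosen by
#' construction so that the per-subtendon element counts are exactly
#' 22140 (LG), 13500 (MG) and 16200 (S): with 45 axial slices, a 6 x 6
#' butterfly core per wedge and annulus radial divisions of 38/22/12,
#' each wedge contributes `n_core^2 + 2 n_core n_radial` in-plane
#' elements (the soleus sector, spanning more than 180 degrees, is split
#' into two conforming wedges).
#'
#' @param distal_width,distal_thickness distal ellipse axes, mm
#'   (defaults 22.04 x 6.42).
#' @param proximal_width,proximal_thickness proximal ellipse axes, mm
#'   (defaults 17.83 x 5.76).
#' @param length free tendon length, mm (default 60; representative free
#'   Achilles length, not a measured input).
#' @param twist_deg helical twist between proximal (fixed, 0 deg) and
#'   distal cross-sections, degrees in \[0, 180\].
#' @param n_slices number of axial element layers.
#' @param butterfly_density list with `n_core` (core divisions per wedge)
#'   and `n_radial` (named vector, annulus radial divisions per subtendon
#'   wedge).
#' @param csa_fractions named per-subtendon cross-sectional area
#'   fractions, summing to 1.  Defaults S = 0.52, MG = 0.26, LG = 0.22.
#' @param sector_start_deg angle (degrees, parametric circle domain) at
#'   which the LG sector starts; sectors follow in the order LG, MG, S
#'   counter-clockwise.
#' @param r_core radius (fraction of the boundary) of the butterfly core.
#' @param max_wedge_deg maximum angular span of one wedge; wider sectors
#'   are split into equal conforming sub-wedges to keep the bilinear core
#'   convex.
#' @return A `mesh_config` list.
#' @export
mesh_config <- function(distal_width = 22.04, distal_thickness = 6.42,
                        proximal_width = 17.83, proximal_thickness = 5.76,
                        length = 60, twist_deg = 0, n_slices = 45,
                        butterfly_density = list(
                          n_core = 6,
                          n_radial = c(LG = 38, MG = 22, S = 12)),
                        csa_fractions = c(LG = 0.22, MG = 0.26, S = 0.52),
                        sector_start_deg = 0, r_core = 0.35,
                        max_wedge_deg = 100) {
  dims <- c(distal_width, distal_thickness, proximal_width,
            proximal_thickness, length)
  if (any(!is.finite(dims)) || any(dims <= 0))
    stop("degenerate geometry: all dimensions must be positive and finite")
  if (!is.finite(twist_deg) || twist_deg < 0 || twist_deg > 180)
    stop("'twist_deg' must lie in [0, 180]")
  if (n_slices < 1) stop("'n_slices' must be >= 1")
  labs <- c("LG", "MG", "S")
  if (!all(labs %in% names(csa_fractions)))
    stop("'csa_fractions' must be named with LG, MG, S")
  csa_fractions <- csa_fractions[labs]
  if (abs(sum(csa_fractions) - 1) > 1e-9)
    stop("'csa_fractions' must sum to 1")
  if (any(csa_fractions <= 0)) stop("'csa_fractions' must be positive")
  if (!all(labs %in% names(butterfly_density$n_radial)))
    stop("'butterfly_density$n_radial' must be named with LG, MG, S")
  if (butterfly_density$n_core < 1 || any(butterfly_density$n_radial < 1))
    stop("butterfly density parameters must be >= 1")
  if (r_core <= 0 || r_core >= 1) stop("'r_core' must lie in (0, 1)")
  structure(list(
    distal_width = distal_width, distal_thickness = distal_thickness,
    proximal_width = proximal_width, proximal_thickness = proximal_thickness,
    length = length, twist_deg = twist_deg, n_slices = n_slices,
    butterfly_density = butterfly_density,
    csa_fractions = csa_fractions, sector_start_deg = sector_start_deg,
    r_core = r_core, max_wedge_deg = max_wedge_deg),
    class = "mesh_config")
}

# --- in-plane butterfly template (unit-circle parametric domain) -----------

# one wedge: bilinear core quad (apex at origin) + transfinite annulus block
.build_wedge <- function(t1, t2, n_c, n_r, r_core) {
  tm <- (t1 + t2) / 2
  e <- function(a) c(cos(a), sin(a))
  A <- r_core * e(t1); B <- r_core * e(t2); M <- r_core * e(tm)
  # core: bilinear map of [0,1]^2, xi -> A edge, eta -> B edge
  g <- seq(0, 1, length.out = n_c + 1)
  xi <- rep(g, times = n_c + 1)
  eta <- rep(g, each = n_c + 1)
  core <- cbind(xi * (1 - eta) * A[1] + xi * eta * M[1] + (1 - xi) * eta * B[1],
                xi * (1 - eta) * A[2] + xi * eta * M[2] + (1 - xi) * eta * B[2])
  cid <- function(i, j) i + j * (n_c + 1) + 1L      # i = xi, j = eta, 0-based
  ii <- rep(0:(n_c - 1), times = n_c)
  jj <- rep(0:(n_c - 1), each = n_c)
  core_q <- cbind(cid(ii, jj), cid(ii + 1L, jj),
                  cid(ii + 1L, jj + 1L), cid(ii, jj + 1L))
  # annulus: inner polyline = core boundary A -> M -> B (2 n_c segments)
  jline <- 0:(2L * n_c)
  pin <- t(vapply(jline, function(j) {
    if (j <= n_c) { x <- 1; y <- j / n_c } else { x <- 1 - (j - n_c) / n_c; y <- 1 }
    c(x * (1 - y) * A[1] + x * y * M[1] + (1 - x) * y * B[1],
      x * (1 - y) * A[2] + x * y * M[2] + (1 - x) * y * B[2])
  }, numeric(2)))
  th <- t1 + (t2 - t1) * jline / (2 * n_c)
  pout <- cbind(cos(th), sin(th))
  ann <- do.call(rbind, lapply(0:n_r, function(i) {
    w <- i / n_r
    pin + w * (pout - pin)
  }))
  aid <- function(i, j) length(g)^2 + j + i * (2L * n_c + 1L) + 1L
  ii <- rep(0:(n_r - 1), each = 2L * n_c)
  jj <- rep(0:(2L * n_c - 1L), times = n_r)
  ann_q <- cbind(aid(ii, jj), aid(ii, jj + 1L),
                 aid(ii + 1L, jj + 1L), aid(ii + 1L, jj))
  list(nodes = rbind(core, ann), quads = rbind(core_q, ann_q))
}

.quad_signed_area <- function(nodes, quads) {
  x <- matrix(nodes[quads, 1], ncol = 4)
  y <- matrix(nodes[quads, 2], ncol = 4)
  0.5 * ((x[, 1] * y[, 2] - x[, 2] * y[, 1]) +
         (x[, 2] * y[, 3] - x[, 3] * y[, 2]) +
         (x[, 3] * y[, 4] - x[, 4] * y[, 3]) +
         (x[, 4] * y[, 1] - x[, 1] * y[, 4]))
}

# sector template for one subtendon label, deduplicated across its wedges
.build_sector <- function(t1, t2, k, n_c, n_r, r_core) {
  bounds <- seq(t1, t2, length.out = k + 1)
  nodes <- NULL; quads <- NULL
  for (w in seq_len(k)) {
    wd <- .build_wedge(bounds[w], bounds[w + 1], n_c, n_r, r_core)
    quads <- rbind(quads, wd$quads + if (is.null(nodes)) 0L else nrow(nodes))
    nodes <- rbind(nodes, wd$nodes)
  }
  key <- paste(round(nodes[, 1], 9), round(nodes[, 2], 9))
  keep <- !duplicated(key)
  map <- match(key, key[keep])
  nodes <- nodes[keep, , drop = FALSE]
  quads <- matrix(map[quads], ncol = 4)
  # enforce counter-clockwise quads
  a <- .quad_signed_area(nodes, quads)
  if (any(a < 0)) quads[a < 0, ] <- quads[a < 0, c(4, 3, 2, 1)]
  list(nodes = nodes, quads = quads)
}

.build_template <- function(config) {
  labs <- c("LG", "MG", "S")
  frac <- config$csa_fractions
  start <- config$sector_start_deg * pi / 180
  spans <- 2 * pi * as.numeric(frac)
  bounds <- start + cumsum(c(0, spans))       # LG | MG | S boundaries
  n_c <- config$butterfly_density$n_core
  nodes <- NULL; quads <- NULL
  node_label <- character(0); quad_label <- character(0)
  centroids <- matrix(NA_real_, 3, 2, dimnames = list(labs, c("u", "v")))
  areas <- setNames(numeric(3), labs)
  for (i in seq_along(labs)) {
    k <- max(1L, ceiling(spans[i] * 180 / pi / config$max_wedge_deg))
    sec <- .build_sector(bounds[i], bounds[i + 1], k, n_c,
                         config$butterfly_density$n_radial[[labs[i]]],
                         config$r_core)
    quads <- rbind(quads, sec$quads + length(node_label))
    nodes <- rbind(nodes, sec$nodes)
    node_label <- c(node_label, rep(labs[i], nrow(sec$nodes)))
    quad_label <- c(quad_label, rep(labs[i], nrow(sec$quads)))
    qa <- .quad_signed_area(sec$nodes, sec$quads)
    cx <- rowMeans(matrix(sec$nodes[sec$quads, 1], ncol = 4))
    cy <- rowMeans(matrix(sec$nodes[sec$quads, 2], ncol = 4))
    areas[labs[i]] <- sum(qa)
    centroids[labs[i], ] <- c(sum(qa * cx), sum(qa * cy)) / sum(qa)
  }
  list(nodes = nodes, quads = quads, node_label = node_label,
       quad_label = quad_label, areas = areas, centroids = centroids,
       interface_angles = c("LG-MG" = bounds[2], "MG-S" = bounds[3],
                            "S-LG" = bounds[1]))
}

# per-slice ellipse semi-axes (mm): linear taper, distal slice 0 at z = 0
.slice_semiaxes <- function(config) {
  t <- seq(0, 1, length.out = config$n_slices + 1)
  cbind(a = ((1 - t) * config$distal_width + t * config$proximal_width) / 2,
        b = ((1 - t) * config$distal_thickness + t * config$proximal_thickness) / 2)
}

#' Generate the untwisted three-subtendon butterfly hex mesh
#'
#' Extrudes the in-plane butterfly template through `n_slices` axial
#' layers with a linear taper.  Coordinates: x = width (medial--lateral),
#' y = thickness (anterior--posterior), z = long axis with the distal end
#' at z = 0.  Subtendons are separate bodies (no shared nodes across
#' labels), mirroring the contact-coupled full-fidelity model.
#'
#' @param config a [mesh_config()].
#' @return A `tendon_mesh`: list with `nodes` (N x 3, mm), `hexes`
#'   (M x 8, 1-based, standard hex8 ordering), `label` (per element),
#'   `fibre` (per-element unit vectors, filled by
#'   [assign_fiber_directions()]), `node_slice`, `node_label`,
#'   `elem_layer`, the template and taper metadata, and `twist_deg`.
#' @examples
#' m <- generate_butterfly_mesh(mesh_config(n_slices = 3,
#'   butterfly_density = list(n_core = 2, n_radial = c(LG = 2, MG = 2, S = 2))))
#' table(m$label)
#' @export
generate_butterfly_mesh <- function(config = mesh_config()) {
  stopifnot(inherits(config, "mesh_config"))
  tpl <- .build_template(config)
  ns <- config$n_slices
  ax <- .slice_semiaxes(config)
  Tn <- nrow(tpl$nodes)
  z <- rep(seq(0, config$length, length.out = ns + 1), each = Tn)
  u <- rep.int(tpl$nodes[, 1], ns + 1)
  v <- rep.int(tpl$nodes[, 2], ns + 1)
  sl <- rep(0:ns, each = Tn)
  nodes <- cbind(x = u * ax[sl + 1, "a"], y = v * ax[sl + 1, "b"], z = z)
  Q <- nrow(tpl$quads)
  lay <- rep(0:(ns - 1), each = Q)
  bot <- tpl$quads[rep(seq_len(Q), ns), , drop = FALSE] + lay * Tn
  hexes <- cbind(bot, bot + Tn)
  structure(list(
    nodes = nodes, hexes = hexes,
    label = rep.int(tpl$quad_label, ns),
    fibre = NULL,
    node_slice = sl, node_label = rep.int(tpl$node_label, ns + 1),
    elem_layer = lay,
    template = tpl, semiaxes = ax, config = config, twist_deg = 0),
    class = "tendon_mesh")
}

#' @export
print.tendon_mesh <- function(x, ...) {
  cat(sprintf("Three-subtendon tendon mesh: %d nodes, %d hex8 elements\n",
              nrow(x$nodes), nrow(x$hexes)))
  print(table(x$label))
  cat(sprintf("length %.2f mm, %d slices, helical twist %.1f deg\n",
              x$config$length, x$config$n_slices, x$twist_deg))
  invisible(x)
}

# twist rotation angle (radians) per node, proximal end fixed
.twist_angle <- function(z, length, twist_deg) {
  twist_deg * pi / 180 * (length - z) / length
}

#' Apply helical twist by in-plane nodal rotation
#'
#' Rotates every node about the composite cross-section centre (the z
#' axis) by `f * twist_deg`, where `f` is the node's axial fraction
#' measured from the proximal end (proximal fixed at 0 deg, distal fully
#' rotated).  The rotation is in-plane and isometric: per-slice node
#' radii and cross-sectional areas are preserved.
#'
#' @param mesh an untwisted `tendon_mesh`.
#' @param twist_deg twist angle, degrees in \[0, 360).
#' @return The twisted mesh (fibre directions, if any, are invalidated
#'   and must be re-assigned).
#' @export
apply_helical_twist <- function(mesh, twist_deg) {
  stopifnot(inherits(mesh, "tendon_mesh"))
  if (!is.finite(twist_deg) || twist_deg < 0 || twist_deg >= 360)
    stop("'twist_deg' must lie in [0, 360)")
  if (mesh$twist_deg != 0)
    stop("mesh is already twisted; start from an untwisted mesh")
  phi <- .twist_angle(mesh$nodes[, "z"], mesh$config$length, twist_deg)
  x <- mesh$nodes[, "x"]; y <- mesh$nodes[, "y"]
  mesh$nodes[, "x"] <- x * cos(phi) - y * sin(phi)
  mesh$nodes[, "y"] <- x * sin(phi) + y * cos(phi)
  mesh$twist_deg <- twist_deg
  mesh$fibre <- NULL
  mesh
}

#' Assign helically wound per-element fibre directions
#'
#' The fibre direction of each element is the unit vector along its
#' rotated axial edges (the mean of the four edges connecting matching
#' in-plane nodes of adjacent slices).  With no twist all fibres are
#' (0, 0, 1); under twist the fibres follow helices whose pitch angle
#' grows with in-plane radius.
#'
#' @param mesh a (possibly twisted) `tendon_mesh`.
#' @return The mesh with an `fibre` matrix (M x 3 unit vectors).
#' @export
assign_fiber_directions <- function(mesh) {
  stopifnot(inherits(mesh, "tendon_mesh"))
  h <- mesh$hexes
  vec <- matrix(0, nrow(h), 3)
  for (k in 1:4) {
    vec <- vec + (mesh$nodes[h[, k + 4], ] - mesh$nodes[h[, k], ])
  }
  nrm <- sqrt(rowSums(vec^2))
  mesh$fibre <- vec / nrm
  colnames(mesh$fibre) <- c("x", "y", "z")
  mesh
}

#' Build a twisted tendon mesh with fibre directions in one call
#'
#' Convenience wrapper: [generate_butterfly_mesh()], then
#' [apply_helical_twist()] with `config$twist_deg`, then
#' [assign_fiber_directions()].
#'
#' @param config a [mesh_config()].
#' @return a `tendon_mesh`.
#' @export
tendon_mesh <- function(config = mesh_config()) {
  mesh <- generate_butterfly_mesh(config)
  if (config$twist_deg != 0)
    mesh <- apply_helical_twist(mesh, config$twist_deg)
  assign_fiber_directions(mesh)
}

#' Geometric prestretch of a helical material line
#'
#' Arc-length ratio of a helix at radius `r` with total twist
#' `twist_rad` over an axial length `length`, relative to the straight
#' axis: `sqrt(1 + (r twist_rad / length)^2)`.  Quantifies the
#' twist-induced non-uniformity of fibre stretch across the
#' cross-section.
#'
#' @param r in-plane radius (mm), >= 0.
#' @param twist_rad total twist, radians.
#' @param length axial length (mm), > 0.
#' @return stretch factor >= 1 (vectorised).
#' @export
fibre_prestretch <- function(r, twist_rad, length) {
  if (any(length <= 0)) stop("'length' must be > 0")
  if (any(r < 0)) stop("'r' must be >= 0")
  sqrt(1 + (r * twist_rad / length)^2)
}

#' Per-subtendon centroid line
#'
#' For each axial slice, finds the mesh node of the given subtendon
#' nearest to the subtendon's in-plane area centroid (which follows the
#' helix under twist), ordered distal to proximal.  Ties are broken by
#' lowest node index.
#'
#' @param mesh a `tendon_mesh`.
#' @param label one of "LG", "MG", "S".
#' @return list with `node_ids`, `coords` (mm), `arc` (cumulative arc
#'   length along the path, mm) and `length` (total path length, mm).
#' @export
centroid_line <- function(mesh, label) {
  stopifnot(inherits(mesh, "tendon_mesh"))
  if (!label %in% mesh$node_label)
    stop("no nodes carry subtendon label '", label, "'")
  ns <- mesh$config$n_slices
  ctr_uv <- mesh$template$centroids[label, ]
  ids <- integer(ns + 1)
  for (s in 0:ns) {
    ax <- mesh$semiaxes[s + 1, ]
    z_s <- mesh$config$length * s / ns
    phi <- .twist_angle(z_s, mesh$config$length, mesh$twist_deg)
    cx <- ctr_uv[1] * ax["a"]; cy <- ctr_uv[2] * ax["b"]
    ctr <- c(cx * cos(phi) - cy * sin(phi), cx * sin(phi) + cy * cos(phi))
    cand <- which(mesh$node_slice == s & mesh$node_label == label)
    d2 <- (mesh$nodes[cand, "x"] - ctr[1])^2 + (mesh$nodes[cand, "y"] - ctr[2])^2
    ids[s + 1] <- cand[which.min(d2)]   # candidates ascend in id: ties -> lowest
  }
  coords <- mesh$nodes[ids, , drop = FALSE]
  seg <- sqrt(rowSums((coords[-1, , drop = FALSE] -
                       coords[-nrow(coords), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  list(node_ids = ids, coords = coords, arc = arc, length = sum(seg))
}

#' Per-slice inter-subtendon contact boundary lengths
#'
#' The three subtendon sectors share pairwise internal boundaries along
#' radial interface lines of the cross-section.  For each slice this
#' returns the in-plane length (mm) of the shared boundary for each pair
#' -- the geometric weight used by the reduced-order contact coupling.
#' In-plane rotation (twist) preserves these lengths; taper scales them.
#'
#' @param mesh a `tendon_mesh`.
#' @return matrix `(n_slices + 1) x 3` with columns `LG-MG`, `MG-S`,
#'   `S-LG`; attribute `angles` holds the parametric interface angles.
#' @export
contact_adjacency <- function(mesh) {
  stopifnot(inherits(mesh, "tendon_mesh"))
  ang <- mesh$template$interface_angles
  ax <- mesh$semiaxes
  out <- sapply(ang, function(th)
    sqrt((ax[, "a"] * cos(th))^2 + (ax[, "b"] * sin(th))^2))
  dimnames(out) <- list(NULL, names(ang))
  attr(out, "angles") <- ang
  out
}
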