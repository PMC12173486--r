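#' Spatiotemporal displacement map
#'
#' Container for transverse displacement sampled over position along a
#' subtendon centroid path (rows, uniform spacing `dx`) and time
#' (columns, uniform spacing `dt`).  All quantities in SI units (m, s).
#'
#' @param u numeric matrix, rows = positions (distal first), columns =
#'   time samples.
#' @param dx position spacing, m (> 0).
#' @param dt time spacing, s (> 0).
#' @param meta optional named list of provenance metadata (subtendon,
#'   twist, stresses, coupling coefficient, ...).
#' @return a `spatiotemporal_map`.
#' @export
spatiotemporal_map <- function(u, dx, dt, meta = list()) {
  u <- as.matrix(u)
  if (!is.numeric(u) || any(!is.finite(u)))
    stop("'u' must be a finite numeric matrix")
  if (!is.finite(dx) || dx <= 0 || !is.finite(dt) || dt <= 0)
    stop("'dx' and 'dt' must be positive")
  structure(list(u = u, dx = dx, dt = dt, meta = meta),
            class = "spatiotemporal_map")
}

#' @export
print.spatiotemporal_map <- function(x, ...) {
  cat(sprintf("Spatiotemporal map: %d positions (dx = %.3g mm) x %d times (dt = %.3g us)\n",
              nrow(x$u), x$dx * 1e3, ncol(x$u), x$dt * 1e6))
  invisible(x)
}

#' Write / read a spatiotemporal map as CSV with a metadata header
#'
#' Plain-text container: `#` comment lines carry `dx`, `dt` and any
#' scalar metadata; the body is the position x time displacement matrix.
#' External solver or ultrafast-ultrasound exports in the same layout
#' can be read back for analysis.
#'
#' @param map a [spatiotemporal_map()].
#' @param path file path.
#' @return `write_map_csv()` returns `path` invisibly;
#'   `read_map_csv()` a `spatiotemporal_map`.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "spatiotemporal_map"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# dx %.17g", map$dx), con)
  writeLines(sprintf("# dt %.17g", map$dt), con)
  for (nm in names(map$meta)) {
    v <- map$meta[[nm]]
    if (length(v) == 1 && (is.numeric(v) || is.character(v)))
      writeLines(sprintf("# %s %s", nm, format(v, digits = 17)), con)
  }
  utils::write.table(map$u, con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- lapply(strsplit(sub("^#\\s*", "", hdr), "\\s+"), function(x)
    c(x[1], paste(x[-1], collapse = " ")))
  meta <- stats::setNames(lapply(kv, function(x) {
    num <- suppressWarnings(as.numeric(x[2]))
    if (is.na(num)) x[2] else num
  }), vapply(kv, `[`, "", 1))
  u <- as.matrix(utils::read.csv(text = lines[!grepl("^#", lines)],
                                 header = FALSE))
  dimnames(u) <- NULL
  if (is.null(meta$dx) || is.null(meta$dt))
    stop("map CSV lacks dx/dt header lines")
  spatiotemporal_map(u, meta$dx, meta$dt,
                     meta[setdiff(names(meta), c("dx", "dt"))])
}

#' Half-sine impulsive excitation
#'
#' The distal plane-wave excitation: a half-sine transverse displacement
#' pulse, `u(t) = A sin(pi t / T)` for `0 <= t <= T`, zero otherwise.
#' Defaults: amplitude 20 um, half period 250 us.
#'
#' @param amplitude pulse amplitude, m (> 0).
#' @param half_period pulse half period, s (> 0).
#' @param direction transverse excitation axis (`"y"`, the
#'   anterior-posterior axis where tensiometer taps are delivered, or
#'   `"x"`).
#' @return an `excitation_spec`.
#' @export
excitation_spec <- function(amplitude = 20e-6, half_period = 250e-6,
                            direction = c("y", "x")) {
  if (amplitude <= 0 || half_period <= 0)
    stop("'amplitude' and 'half_period' must be > 0")
  structure(list(amplitude = amplitude, half_period = half_period,
                 direction = match.arg(direction)),
            class = "excitation_spec")
}

#' @rdname excitation_spec
#' @param t time, s (vectorised, >= 0).
#' @param spec an `excitation_spec`.
#' @return `half_sine_excitation()`: displacement in m.
#' @export
half_sine_excitation <- function(t, spec = excitation_spec()) {
  if (any(t < 0)) stop("'t' must be >= 0")
  ifelse(t <= spec$half_period,
         spec$amplitude * sin(pi * t / spec$half_period), 0)
}

#' Reduced-order assembly of three coupled tensioned beams
#'
#' Desk-scale stand-in for the 3-D dynamic finite element solve: each
#' subtendon is a tensioned shear beam along its centroid path with
#' linear density `rho A` and tension `sigma A + k' mu A`; frictionless
#' inter-subtendon contact is reduced to a distributed transverse
#' coupling `kappa_sj(z) = coeff * mu * L_shared(z) / d_sj(z)` (N m^-2),
#' where `L_shared` is the shared sector boundary length and `d_sj` the
#' in-plane centroid distance.  `coeff = 0` is the free-sliding limit,
#' large `coeff` the bonded limit.  Helical twist enters only through
#' the centroid-path geometry and the taper-scaled adjacency weights.
#'
#' The nominal a-priori axial stress (distal-area based) is applied
#' uniformly along each beam, so the closed-form tensioned-beam speed is
#' the exact decoupled solution.
#'
#' @param mesh a `tendon_mesh`.
#' @param params a [material_params()].
#' @param kprime shear correction factor (default 1).
#' @param coupling_coeff dimensionless contact-coupling coefficient
#'   (default 0.1).
#' @return a `beam_assembly`; apply loads with [set_assembly_loads()].
#' @export
beam_assembly <- function(mesh, params, kprime = 1, coupling_coeff = 0.1) {
  stopifnot(inherits(mesh, "tendon_mesh"), inherits(params, "material_params"))
  if (coupling_coeff < 0) stop("'coupling_coeff' must be >= 0")
  labs <- c("LG", "MG", "S")
  paths <- lapply(stats::setNames(labs, labs),
                  function(l) centroid_line(mesh, l))
  ns <- mesh$config$n_slices
  areas <- distal_areas(mesh) * 1e-6                      # m^2
  dx <- vapply(paths, function(p) p$length, 0) * 1e-3 / ns  # m
  adj <- contact_adjacency(mesh) * 1e-3                   # m, (ns+1) x 3
  # in-plane centroid distances per slice and pair (twist-invariant)
  ctr <- mesh$template$centroids
  ax <- mesh$semiaxes
  pairdist <- function(l1, l2)
    sqrt((ax[, "a"] * (ctr[l1, 1] - ctr[l2, 1]))^2 +
         (ax[, "b"] * (ctr[l1, 2] - ctr[l2, 2]))^2) * 1e-3
  dmat <- cbind(`LG-MG` = pairdist("LG", "MG"),
                `MG-S` = pairdist("MG", "S"),
                `S-LG` = pairdist("S", "LG"))
  kappa <- coupling_coeff * params$mu * adj / dmat        # N m^-2 per slice
  structure(list(labels = labs, paths = paths, n_nodes = ns + 1,
                 dx = dx, areas = areas, rhoA = params$rho * areas,
                 kappa = kappa, mu = params$mu, rho = params$rho,
                 kprime = kprime, coupling_coeff = coupling_coeff,
                 tension = NULL, stress = NULL),
            class = "beam_assembly")
}

#' Apply a load case to a beam assembly
#'
#' Sets per-subtendon tensions `T_s = sigma_s A_s + k' mu A_s` from the
#' load case stresses.
#'
#' @param assembly a [beam_assembly()].
#' @param case a [partition_cohort_forces()] load case, or a named
#'   stress vector (Pa).
#' @return the assembly with `tension` (N) and `stress` (Pa) filled.
#' @export
set_assembly_loads <- function(assembly, case) {
  stopifnot(inherits(assembly, "beam_assembly"))
  stress <- if (inherits(case, "load_case")) case$stress else case
  if (!all(assembly$labels %in% names(stress)))
    stop("stresses must be named with LG, MG, S")
  stress <- stress[assembly$labels]
  if (any(stress + assembly$kprime * assembly$mu < 0))
    stop("negative effective tension: sigma + k'mu must be >= 0")
  assembly$stress <- stress
  assembly$tension <- (stress + assembly$kprime * assembly$mu) * assembly$areas
  assembly
}

#' Simulate transient shear waves on the coupled beam assembly
#'
#' Explicit central-difference integration of
#' `rhoA u_tt = T u_xx - sum_j kappa_sj (u_s - u_j)` on the three
#' centroid-path beams, with the distal node displacement-driven by the
#' half-sine excitation (all subtendons excited in phase, mirroring the
#' whole-cross-section plane excitation) and the proximal node free
#' (reflective -- deliberately, so the directional filter is exercised).
#' Zero initial conditions.  The internal step is half the explicit
#' stability bound (CFL and coupling); output is resampled at `dt_out`.
#'
#' The internal spatial grid is refined by an integer factor `refine`
#' (default 4) relative to the output map grid (`dx` = path length /
#' `n_slices`): the half-sine onset has a velocity step whose lattice
#' dispersion ringing would otherwise widen the pulse noticeably at the
#' mesh-inherited spacing.  Output maps are sampled back on the
#' mesh-inherited grid.
#'
#' @param assembly a loaded [beam_assembly()] (see
#'   [set_assembly_loads()]).
#' @param excitation an [excitation_spec()].
#' @param duration simulated window, s (default 1 ms).
#' @param dt_out output cadence, s (default 10 us).
#' @param dt optional internal step override; rejected (with the
#'   computed bound) if it violates stability.
#' @param refine integer internal spatial refinement factor (>= 1).
#' @param proximal_bc `"free"` (reflective Neumann end, the default --
#'   reflections are then removed by [directional_filter()]) or
#'   `"absorbing"` (first-order characteristic outflow, for
#'   filter-validation studies).
#' @param return_energy if `TRUE`, attach the discrete energy trace
#'   (J, at output times) as attribute `energy`.
#' @return named list of [spatiotemporal_map()]s (LG, MG, S), each with
#'   provenance metadata.
#' @export
simulate_coupled_beams <- function(assembly, excitation = excitation_spec(),
                                   duration = 1e-3, dt_out = 1e-5,
                                   dt = NULL, refine = 4,
                                   proximal_bc = c("free", "absorbing"),
                                   return_energy = FALSE) {
  stopifnot(inherits(assembly, "beam_assembly"))
  proximal_bc <- match.arg(proximal_bc)
  if (is.null(assembly$tension))
    stop("assembly has no loads; call set_assembly_loads() first")
  refine <- as.integer(refine)
  if (refine < 1) stop("'refine' must be >= 1")
  n0 <- assembly$n_nodes
  n <- (n0 - 1L) * refine + 1L
  dx0 <- assembly$dx
  assembly$dx <- assembly$dx / refine
  # resample the per-slice coupling onto the refined grid
  if (refine > 1) {
    f0 <- seq(0, 1, length.out = n0)
    f1 <- seq(0, 1, length.out = n)
    assembly$kappa <- apply(assembly$kappa, 2, function(k)
      stats::approx(f0, k, xout = f1)$y)
  }
  assembly$n_nodes <- n
  c_beam <- sqrt(assembly$tension / assembly$rhoA)
  dt_cfl <- min(assembly$dx) / max(c_beam)
  # coupling restoring-rate bound: omega_max^2 ~ 2 kappa_tot / rhoA
  pair_idx <- list(LG = c("LG-MG", "S-LG"), MG = c("LG-MG", "MG-S"),
                   S = c("MG-S", "S-LG"))
  krow <- vapply(assembly$labels, function(l)
    max(rowSums(assembly$kappa[, pair_idx[[l]], drop = FALSE])), 0)
  dt_coup <- if (max(krow) > 0)
    sqrt(2 * min(assembly$rhoA) / max(krow)) else Inf
  bound <- min(dt_cfl, dt_coup)
  if (is.null(dt)) {
    n_sub <- ceiling(dt_out / (0.5 * bound))
    dt <- dt_out / n_sub
  } else {
    if (dt > bound)
      stop(sprintf("unstable time step %.3g s: explicit bound is %.3g s",
                   dt, bound))
    n_sub <- max(1, round(dt_out / dt))
    dt <- dt_out / n_sub
  }
  n_out <- round(duration / dt_out) + 1
  labs <- assembly$labels
  u_prev <- matrix(0, n, 3, dimnames = list(NULL, labs))
  u_cur <- u_prev
  u_cur[1, ] <- half_sine_excitation(dt * 0, excitation)  # zero ICs
  keep <- seq(1L, n, by = refine)
  out <- lapply(labs, function(l) matrix(0, n0, n_out))
  names(out) <- labs
  energy <- numeric(n_out)
  Tn <- assembly$tension; rA <- assembly$rhoA; dx <- assembly$dx
  kap <- assembly$kappa
  idx_in <- 2:(n - 1)
  store <- function(k, u_cur, u_prev) {
    for (l in labs) out[[l]][, k] <<- u_cur[keep, l]
    if (return_energy) {
      # conserved staggered (leapfrog) energy: KE at the half step,
      # PE as the symmetric bilinear form of consecutive steps
      v <- (u_cur - u_prev) / dt
      wq <- c(0.5, rep(1, n - 2), 0.5)        # trapezoid: half-cells at ends
      ke <- sum(vapply(seq_along(labs), function(s)
        0.5 * rA[s] * dx[s] * sum(wq * v[, s]^2), 0))
      pe <- sum(vapply(seq_along(labs), function(s) {
        du1 <- diff(u_cur[, s]) / dx[s]
        du0 <- diff(u_prev[, s]) / dx[s]
        0.5 * Tn[s] * dx[s] * sum(du1 * du0)
      }, 0))
      pc <- 0
      for (pr in list(c(1, 2, "LG-MG"), c(2, 3, "MG-S"), c(3, 1, "S-LG"))) {
        s1 <- as.integer(pr[1]); s2 <- as.integer(pr[2])
        dxm <- (dx[s1] + dx[s2]) / 2
        d1 <- u_cur[, s1] - u_cur[, s2]
        d0 <- u_prev[, s1] - u_prev[, s2]
        pc <- pc + 0.5 * dxm * sum(wq * kap[, pr[3]] * d1 * d0)
      }
      energy[k] <<- ke + pe + pc
    }
  }
  store(1, u_cur, u_prev)
  t_cur <- 0
  for (k in 2:n_out) {
    for (sub in seq_len(n_sub)) {
      lap <- u_cur            # reuse shape
      for (s in 1:3) {
        us <- u_cur[, s]
        lap[idx_in, s] <- (us[idx_in - 1] - 2 * us[idx_in] + us[idx_in + 1]) / dx[s]^2
        lap[n, s] <- 2 * (us[n - 1] - us[n]) / dx[s]^2   # free (Neumann) end
        lap[1, s] <- 0
      }
      if (proximal_bc == "absorbing") lap[n, ] <- 0
      cf <- cbind(
        kap[, "LG-MG"] * (u_cur[, 1] - u_cur[, 2]) +
          kap[, "S-LG"] * (u_cur[, 1] - u_cur[, 3]),
        kap[, "LG-MG"] * (u_cur[, 2] - u_cur[, 1]) +
          kap[, "MG-S"] * (u_cur[, 2] - u_cur[, 3]),
        kap[, "MG-S"] * (u_cur[, 3] - u_cur[, 2]) +
          kap[, "S-LG"] * (u_cur[, 3] - u_cur[, 1]))
      acc <- sweep(lap, 2, Tn, `*`) - cf
      acc <- sweep(acc, 2, rA, `/`)
      u_next <- 2 * u_cur - u_prev + dt^2 * acc
      if (proximal_bc == "absorbing")
        u_next[n, ] <- u_cur[n, ] -
          (c_beam * dt / dx) * (u_cur[n, ] - u_cur[n - 1, ])
      t_cur <- t_cur + dt
      u_next[1, ] <- half_sine_excitation(t_cur, excitation)
      u_prev <- u_cur
      u_cur <- u_next
    }
    store(k, u_cur, u_prev)
  }
  maps <- lapply(labs, function(l) {
    spatiotemporal_map(out[[l]], dx = dx0[[l]], dt = dt_out, meta = list(
      subtendon = l, stress = unname(assembly$stress[l]),
      kprime = assembly$kprime, mu = assembly$mu, rho = assembly$rho,
      coupling_coeff = assembly$coupling_coeff, refine = refine,
      proximal_bc = proximal_bc,
      path_length = assembly$paths[[l]]$length * 1e-3))
  })
  names(maps) <- labs
  if (return_energy) attr(maps, "energy") <- energy
  attr(maps, "dt_internal") <- dt
  attr(maps, "stability_bound") <- bound
  maps
}
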