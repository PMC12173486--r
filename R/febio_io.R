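#' @noRd
.feb_version <- "4.0"

# deterministic boundary-edge list (template, in-plane) for one label
.template_boundary_edges <- function(tpl, label) {
  q <- tpl$quads[tpl$quad_label == label, , drop = FALSE]
  e <- rbind(q[, c(1, 2)], q[, c(2, 3)], q[, c(3, 4)], q[, c(4, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  tab <- table(key)
  bnd <- e[key %in% names(tab)[tab == 1], , drop = FALSE]
  bnd[order(pmin(bnd[, 1], bnd[, 2]), pmax(bnd[, 1], bnd[, 2])), ,
      drop = FALSE]
}

#' Write a full-fidelity FEBio XML model file
#'
#' Emits a self-contained `.feb` input file (FEBio 4.0 format) for one
#' load case: the three-subtendon hex mesh with per-element helical
#' fibre vectors, the uncoupled transversely isotropic Mooney--Rivlin
#' material, penalty-enforced frictionless sliding-elastic contact
#' between subtendon lateral surfaces, a static proximal-traction
#' preload step and a dynamic step with the half-sine transverse
#' displacement prescribed across the whole distal cross-section
#' (1 ms at 10 us output).  Units are mm / N / MPa / ms (density in
#' g mm^-3), stated in a header comment.  Output is deterministic:
#' identical inputs give byte-identical files.
#'
#' @param mesh a `tendon_mesh` with fibre directions assigned.
#' @param params a [material_params()].
#' @param case a [partition_cohort_forces()] load case.
#' @param excitation an [excitation_spec()].
#' @param path output file path.
#' @param penalty contact penalty factor (not printed in any reference;
#'   exposed as configuration and echoed into the file).
#' @param duration,dt_out dynamic step window and output cadence, s.
#' @return `path`, invisibly.
#' @export
write_feb <- function(mesh, params, case, excitation = excitation_spec(),
                      path, penalty = 100, duration = 1e-3, dt_out = 1e-5) {
  stopifnot(inherits(mesh, "tendon_mesh"), inherits(params, "material_params"),
            inherits(case, "load_case"))
  if (is.null(mesh$fibre))
    stop("mesh has no fibre directions; call assign_fiber_directions()")
  labs <- c("LG", "MG", "S")
  tpl <- mesh$template
  Tn <- nrow(tpl$nodes)
  ns <- mesh$config$n_slices
  dof <- excitation$direction
  num <- function(x) sprintf("%.9g", x)
  L <- character(0)
  add <- function(...) L <<- c(L, ...)
  add('<?xml version="1.0" encoding="ISO-8859-1"?>',
      "<!-- tendonwave model file; units: mm / N / MPa / ms (density g mm^-3) -->",
      sprintf('<febio_spec version="%s">', .feb_version),
      '  <Module type="solid"/>')
  # materials: one per subtendon body, identical constants
  add("  <Material>")
  for (i in seq_along(labs)) {
    add(sprintf('    <material id="%d" name="%s" type="trans iso Mooney-Rivlin">',
                i, labs[i]),
        sprintf("      <density>%s</density>", num(params$rho * 1e-6)),
        sprintf("      <c1>%s</c1>", num(params$C1 / 1e6)),
        sprintf("      <c2>%s</c2>", num(params$C2 / 1e6)),
        sprintf("      <c3>%s</c3>", num(params$C3 / 1e6)),
        sprintf("      <c4>%s</c4>", num(params$C4)),
        sprintf("      <c5>%s</c5>", num(params$C5 / 1e6)),
        sprintf("      <lam_max>%s</lam_max>", num(params$lambda_star)),
        sprintf("      <k>%s</k>", num(params$K / 1e6)),
        '      <fiber type="user"/>',
        "    </material>")
  }
  add("  </Material>")
  # mesh
  add("  <Mesh>", '    <Nodes name="tendon">')
  add(sprintf('      <node id="%d">%s,%s,%s</node>', seq_len(nrow(mesh$nodes)),
              num(mesh$nodes[, 1]), num(mesh$nodes[, 2]), num(mesh$nodes[, 3])))
  add("    </Nodes>")
  eid <- seq_len(nrow(mesh$hexes))
  for (l in labs) {
    sel <- mesh$label == l
    h <- mesh$hexes[sel, , drop = FALSE]
    add(sprintf('    <Elements type="hex8" name="%s">', l))
    add(sprintf('      <elem id="%d">%s</elem>', eid[sel],
                paste(h[, 1], h[, 2], h[, 3], h[, 4], h[, 5], h[, 6],
                      h[, 7], h[, 8], sep = ",")))
    add("    </Elements>")
  }
  # node sets: distal (all), proximal + centroid line per label
  dist <- which(mesh$node_slice == 0)
  add(sprintf('    <NodeSet name="Distal">%s</NodeSet>',
              paste(dist, collapse = ",")))
  for (l in labs) {
    cl <- centroid_line(mesh, l)
    add(sprintf('    <NodeSet name="Centroid%s">%s</NodeSet>', l,
                paste(cl$node_ids, collapse = ",")))
  }
  # surfaces: proximal end faces (traction) and lateral faces (contact)
  for (l in labs) {
    q <- tpl$quads[tpl$quad_label == l, , drop = FALSE] + ns * Tn
    add(sprintf('    <Surface name="Proximal%s">', l))
    add(sprintf('      <quad4 id="%d">%s</quad4>', seq_len(nrow(q)),
                paste(q[, 1], q[, 2], q[, 3], q[, 4], sep = ",")))
    add("    </Surface>")
    bnd <- .template_boundary_edges(tpl, l)
    n_b <- nrow(bnd)
    fe <- do.call(rbind, lapply(0:(ns - 1), function(s)
      cbind(bnd[, 1] + s * Tn, bnd[, 2] + s * Tn,
            bnd[, 2] + (s + 1) * Tn, bnd[, 1] + (s + 1) * Tn)))
    add(sprintf('    <Surface name="Lateral%s">', l))
    add(sprintf('      <quad4 id="%d">%s</quad4>', seq_len(nrow(fe)),
                paste(fe[, 1], fe[, 2], fe[, 3], fe[, 4], sep = ",")))
    add("    </Surface>")
  }
  pairs <- rbind(c("LG", "MG"), c("MG", "S"), c("S", "LG"))
  for (p in seq_len(nrow(pairs)))
    add(sprintf('    <SurfacePair name="%s_%s"><primary>Lateral%s</primary><secondary>Lateral%s</secondary></SurfacePair>',
                pairs[p, 1], pairs[p, 2], pairs[p, 1], pairs[p, 2]))
  add("  </Mesh>")
  add("  <MeshDomains>")
  for (l in labs)
    add(sprintf('    <SolidDomain name="%s" mat="%s"/>', l, l))
  add("  </MeshDomains>")
  # per-element fibre vectors
  add("  <MeshData>")
  for (l in labs) {
    sel <- which(mesh$label == l)
    add(sprintf('    <ElementData type="fiber" elem_set="%s">', l))
    add(sprintf('      <e lid="%d">%s,%s,%s</e>', seq_along(sel),
                num(mesh$fibre[sel, 1]), num(mesh$fibre[sel, 2]),
                num(mesh$fibre[sel, 3])))
    add("    </ElementData>")
  }
  add("  </MeshData>")
  # contact
  add("  <Contact>")
  for (p in seq_len(nrow(pairs)))
    add(sprintf('    <contact type="sliding-elastic" surface_pair="%s_%s">',
                pairs[p, 1], pairs[p, 2]),
        "      <laugon>PENALTY</laugon>",
        sprintf("      <penalty>%s</penalty>", num(penalty)),
        "      <fric_coeff>0</fric_coeff>",
        "      <two_pass>1</two_pass>",
        "    </contact>")
  add("  </Contact>")
  # boundary: distal end fixed in-plane during preload, driven in step 2
  add("  <Boundary>",
      '    <bc name="FixDistal" type="zero displacement" node_set="Distal">',
      "      <x_dof>1</x_dof><y_dof>1</y_dof><z_dof>1</z_dof>",
      "    </bc>",
      "  </Boundary>")
  # load controllers: 1 = half-sine drive (ms), 2 = static ramp
  thalf_ms <- excitation$half_period * 1e3
  tp <- seq(0, thalf_ms, length.out = 26)
  pts <- sprintf("        <pt>%s,%s</pt>", num(tp),
                 num(sin(pi * tp / thalf_ms)))
  add("  <LoadData>",
      '    <load_controller id="1" type="loadcurve">',
      "      <interpolate>LINEAR</interpolate>",
      "      <extend>CONSTANT</extend>",
      "      <points>", pts,
      sprintf("        <pt>%s,0</pt>", num(thalf_ms * 1.0001)),
      sprintf("        <pt>%s,0</pt>", num(duration * 1e3)),
      "      </points>",
      "    </load_controller>",
      '    <load_controller id="2" type="loadcurve">',
      "      <interpolate>LINEAR</interpolate>",
      "      <extend>CONSTANT</extend>",
      "      <points>", "        <pt>0,0</pt>", "        <pt>1,1</pt>",
      "      </points>",
      "    </load_controller>",
      "  </LoadData>")
  # step 1: static preload via proximal tractions (MPa)
  add("  <Step>", '    <step id="1" name="Preload">',
      "      <Control>",
      "        <analysis>STATIC</analysis>",
      "        <time_steps>10</time_steps>",
      "        <step_size>0.1</step_size>",
      "      </Control>",
      "      <Loads>")
  for (l in labs)
    add(sprintf('        <surface_load name="Pull%s" type="traction" surface="Proximal%s">', l, l),
        '          <scale lc="2">1</scale>',
        sprintf("          <traction>0,0,%s</traction>",
                num(case$stress[[l]] / 1e6)),
        "        </surface_load>")
  add("      </Loads>", "    </step>")
  # step 2: dynamic wave propagation, distal transverse drive
  add('    <step id="2" name="Wave">',
      "      <Control>",
      "        <analysis>DYNAMIC</analysis>",
      sprintf("        <time_steps>%d</time_steps>", round(duration / dt_out)),
      sprintf("        <step_size>%s</step_size>", num(dt_out * 1e3)),
      "      </Control>",
      "      <Boundary>",
      sprintf('        <bc name="Excite" type="prescribed displacement" node_set="Distal">'),
      sprintf("          <dof>%s</dof>", dof),
      sprintf('          <value lc="1">%s</value>', num(excitation$amplitude * 1e3)),
      "          <relative>1</relative>",
      "        </bc>",
      "      </Boundary>", "    </step>", "  </Step>")
  # output: transverse displacement along each centroid line
  add("  <Output>",
      '    <logfile file="wave.log">')
  for (l in labs)
    add(sprintf('      <node_data data="u%s" name="centroid_%s" node_set="Centroid%s" delim=" "/>',
                dof, l, l))
  add("    </logfile>", "  </Output>", "</febio_spec>")
  writeLines(L, path)
  invisible(path)
}

#' Read mesh geometry back from a FEBio XML file
#'
#' Parses the `Nodes` and `Elements` sections of a `.feb` file written
#' by [write_feb()] (round-trip check and external-model ingestion).
#'
#' @param path `.feb` file path.
#' @return list with `nodes` (N x 3, mm), `hexes` (M x 8) and `label`
#'   (per element, from the Elements block names).
#' @export
read_feb_mesh <- function(path) {
  doc <- xml2::read_xml(path)
  nd <- xml2::xml_find_all(doc, ".//Mesh/Nodes/node")
  ids <- as.integer(xml2::xml_attr(nd, "id"))
  xyz <- do.call(rbind, lapply(strsplit(xml2::xml_text(nd), ","), as.numeric))
  nodes <- matrix(NA_real_, max(ids), 3)
  nodes[ids, ] <- xyz
  colnames(nodes) <- c("x", "y", "z")
  blocks <- xml2::xml_find_all(doc, ".//Mesh/Elements")
  hex <- NULL; label <- character(0); eids <- integer(0)
  for (b in blocks) {
    el <- xml2::xml_find_all(b, "./elem")
    conn <- do.call(rbind, lapply(strsplit(xml2::xml_text(el), ","), as.integer))
    hex <- rbind(hex, conn)
    eids <- c(eids, as.integer(xml2::xml_attr(el, "id")))
    label <- c(label, rep(xml2::xml_attr(b, "name"), length(el)))
  }
  ord <- order(eids)
  list(nodes = nodes, hexes = hex[ord, , drop = FALSE], label = label[ord])
}

#' Read per-node displacement time series from a solver text log
#'
#' Parses plain-text nodal data logs with the block grammar
#' `*Step = <n>`, `*Time = <t>`, `*Data = <name>`, followed by
#' `<node id> <value>` rows -- the text export consumed by the
#' wave-speed pipeline.  Times must be uniformly spaced and every
#' requested node present in every block.
#'
#' @param path log file path.
#' @param node_ids nodes to extract (default: all nodes of the first
#'   block, in file order).
#' @param time_unit seconds per log time unit (default `1e-3`: solver
#'   logs in ms).
#' @return list with `u` (nodes x times, m if the log is in mm -- see
#'   `length_unit`), `times` (s), `dt` (s), `node_ids`, `data_name`.
#' @param length_unit metres per log displacement unit (default `1e-3`).
#' @export
read_node_displacements <- function(path, node_ids = NULL,
                                    time_unit = 1e-3, length_unit = 1e-3) {
  lines <- readLines(path)
  step_i <- grep("^\\*Step", lines)
  if (!length(step_i)) stop("no '*Step' blocks found in ", path)
  bounds <- c(step_i, length(lines) + 1)
  times <- numeric(0); series <- list(); data_name <- NA_character_
  for (b in seq_along(step_i)) {
    blk <- lines[bounds[b]:(bounds[b + 1] - 1)]
    tline <- grep("^\\*Time", blk, value = TRUE)
    if (!length(tline))
      stop("block starting at line ", step_i[b], " lacks a '*Time' record")
    times <- c(times, as.numeric(sub(".*=\\s*", "", tline[1])))
    dline <- grep("^\\*Data", blk, value = TRUE)
    if (length(dline)) data_name <- sub(".*=\\s*", "", dline[1])
    rows <- blk[!grepl("^\\*", blk) & nzchar(trimws(blk))]
    parts <- strsplit(trimws(rows), "\\s+")
    ids <- vapply(parts, function(p) as.integer(p[1]), 0L)
    vals <- vapply(parts, function(p) as.numeric(p[2]), 0)
    if (anyDuplicated(ids))
      stop("duplicate node record in step block ", b)
    series[[b]] <- stats::setNames(vals, ids)
  }
  if (is.null(node_ids)) node_ids <- as.integer(names(series[[1]]))
  u <- matrix(NA_real_, length(node_ids), length(series))
  for (b in seq_along(series)) {
    miss <- setdiff(as.character(node_ids), names(series[[b]]))
    if (length(miss))
      stop("step block ", b, " (time ", times[b], ") is missing node(s) ",
           paste(miss, collapse = ", "))
    u[, b] <- series[[b]][as.character(node_ids)]
  }
  dts <- diff(times)
  if (length(dts) && (max(dts) - min(dts)) > 1e-6 * max(abs(dts)))
    stop("non-uniform output cadence: steps at ",
         paste(utils::head(signif(times, 6), 8), collapse = ", "), " ...")
  list(u = u * length_unit, times = times * time_unit,
       dt = if (length(dts)) stats::median(dts) * time_unit else NA_real_,
       node_ids = node_ids, data_name = data_name)
}
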