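test_that("feb writer emits a deterministic, well-formed model document", {
  m <- tendon_mesh(small_mesh_config(twist_deg = 30))
  p <- table1_params()
  lc <- uniform_case(m, 10e6)
  f1 <- tempfile(fileext = ".feb"); f2 <- tempfile(fileext = ".feb")
  write_feb(m, p, lc, excitation_spec(), f1)
  write_feb(m, p, lc, excitation_spec(), f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  doc <- xml2::read_xml(f1)
  expect_identical(xml2::xml_attr(doc, "version"), "4.0")
  mats <- xml2::xml_find_all(doc, ".//Material/material")
  expect_length(mats, 3)
  expect_identical(unique(xml2::xml_attr(mats, "type")),
                   "trans iso Mooney-Rivlin")
  # density in g/mm^3, moduli in MPa (mm/N/MPa convention)
  expect_equal(as.numeric(xml2::xml_text(
    xml2::xml_find_first(doc, ".//material[@name='LG']/density"))), 1.5e-3)
  expect_equal(as.numeric(xml2::xml_text(
    xml2::xml_find_first(doc, ".//material[@name='LG']/c5"))), 350)
  # one element block and one fibre block per subtendon, matching counts
  for (l in c("LG", "MG", "S")) {
    n_el <- sum(m$label == l)
    expect_length(xml2::xml_find_all(doc, sprintf(
      ".//Mesh/Elements[@name='%s']/elem", l)), n_el)
    expect_length(xml2::xml_find_all(doc, sprintf(
      ".//MeshData/ElementData[@elem_set='%s']/e", l)), n_el)
  }
  # three sliding-elastic contact pairs with the echoed penalty
  ct <- xml2::xml_find_all(doc, ".//Contact/contact")
  expect_length(ct, 3)
  expect_identical(unique(xml2::xml_attr(ct, "type")), "sliding-elastic")
  expect_equal(as.numeric(xml2::xml_text(
    xml2::xml_find_first(doc, ".//Contact/contact/penalty"))), 100)
  # static preload step then dynamic half-sine step at 10 us cadence
  expect_identical(xml2::xml_text(xml2::xml_find_first(
    doc, ".//step[@name='Preload']/Control/analysis")), "STATIC")
  expect_identical(xml2::xml_text(xml2::xml_find_first(
    doc, ".//step[@name='Wave']/Control/analysis")), "DYNAMIC")
  expect_equal(as.numeric(xml2::xml_text(xml2::xml_find_first(
    doc, ".//step[@name='Wave']/Control/step_size"))), 0.01)  # ms
})

test_that("written mesh round-trips through the reader", {
  m <- tendon_mesh(small_mesh_config(twist_deg = 75))
  f <- tempfile(fileext = ".feb")
  write_feb(m, table1_params(), uniform_case(m, 5e6), excitation_spec(), f)
  back <- read_feb_mesh(f)
  expect_equal(back$nodes, unname(m$nodes), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_identical(unname(back$hexes), unname(m$hexes))
  expect_identical(back$label, m$label)
})

test_that("default-resolution export carries the printed element set sizes", {
  m <- tendon_mesh(mesh_config())
  f <- tempfile(fileext = ".feb")
  write_feb(m, table1_params(), uniform_case(m, 5e6), excitation_spec(), f)
  lines <- readLines(f)
  for (l in c(LG = 22140, MG = 13500, S = 16200)[1]) {
    # block bounded by the Elements open/close tags
    i0 <- grep('<Elements type="hex8" name="LG">', lines, fixed = TRUE)
    i1 <- grep("</Elements>", lines)
    expect_identical(sum(grepl("<elem id=", lines[i0:i1[i1 > i0][1]],
                               fixed = TRUE)), 22140L)
  }
  unlink(f)
})

test_that("nodal displacement logs round-trip and reject broken records", {
  f <- tempfile(fileext = ".log")
  times <- seq(0.01, 0.1, by = 0.01)          # ms
  ids <- c(4L, 9L, 17L)
  u <- matrix(sin(seq_len(30)), 3, 10)        # mm
  write_displacement_log(f, times, u, ids)
  out <- read_node_displacements(f)
  expect_equal(out$u, u * 1e-3, tolerance = 1e-12)
  expect_equal(out$times, times * 1e-3)
  expect_equal(out$dt, 1e-5)                  # 10 us cadence
  expect_identical(out$node_ids, ids)
  expect_identical(out$data_name, "uy")
  # subset extraction preserves order
  sub <- read_node_displacements(f, node_ids = c(17L, 4L))
  expect_equal(sub$u[1, ], u[3, ] * 1e-3)
  # missing node in one block is named
  lines <- readLines(f)
  drop <- grep("^9 ", lines)[4]
  writeLines(lines[-drop], f)
  expect_error(read_node_displacements(f), "missing node.*9")
  # non-uniform cadence rejected
  f2 <- tempfile(fileext = ".log")
  write_displacement_log(f2, c(0.01, 0.02, 0.05), u[, 1:3], ids)
  expect_error(read_node_displacements(f2), "cadence")
})

test_that("simulated centroid histories survive a log round-trip to the estimator", {
  m <- tendon_mesh(mesh_config())
  a <- beam_assembly(m, table1_params(), coupling_coeff = 0)
  maps <- simulate_coupled_beams(set_assembly_loads(a, uniform_case(m, 8e6)))
  u <- maps$S$u
  f <- tempfile(fileext = ".log")
  ids <- seq_len(nrow(u))
  write_displacement_log(f, (0:(ncol(u) - 1)) * 1e-2, u * 1e3, ids)
  back <- read_node_displacements(f, ids)
  map2 <- assemble_map(back$u, (ids - 1) * maps$S$dx, back$dt)
  est <- measure_wave_speed(map2)
  expect_equal(est$speed, measure_wave_speed(maps$S)$speed, tolerance = 1e-6)
})
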