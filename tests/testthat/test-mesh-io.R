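test_that("surface_mesh enforces its invariants", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  m <- surface_mesh(v, matrix(c(1L, 2L, 3L), 1))
  expect_equal(n_vertices(m), 3L)
  expect_equal(n_faces(m), 1L)
  expect_error(surface_mesh(v, matrix(c(1L, 2L, 4L), 1)), "out of range")
  expect_error(surface_mesh(v, matrix(c(1L, 1L, 2L), 1)), "repeat")
  expect_error(surface_mesh(v, matrix(c(1L, 2L, 3L), 1), scalar = 1:2),
               "one value per vertex")
  expect_error(surface_mesh(rbind(c(0, 0, NA)), matrix(integer(0), 0, 3)),
               "non-finite")
})

test_that("a single-triangle ASCII STL parses to 3 vertices and 1 face", {
  p <- withr::local_tempfile(fileext = ".stl")
  writeLines(c(
    "solid t", " facet normal 0 0 1", "  outer loop",
    "   vertex 0 0 0", "   vertex 1 0 0", "   vertex 0 1 0",
    "  endloop", " endfacet", "endsolid t"), p)
  m <- read_surface(p)
  expect_equal(n_vertices(m), 3L)
  expect_equal(n_faces(m), 1L)
})

test_that("binary STL of a unit cube welds 12 facets to 8 unique vertices", {
  p <- withr::local_tempfile(fileext = ".stl")
  write_surface(unit_cube(), p, binary = TRUE)
  m <- read_surface(p)
  expect_equal(n_faces(m), 12L)
  expect_equal(n_vertices(m), 8L)
})

test_that("every format round-trips the synthetic foot surface", {
  s <- small_template()$surface
  for (fmt in c("stl", "ply", "obj")) {
    p <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_surface(s, p)
    expect_mesh_equal(read_surface(p), s, tol = 1e-6)
  }
  # binary STL stores float32: tolerance scales with the coordinate magnitude
  p <- withr::local_tempfile(fileext = ".stl")
  write_surface(s, p, binary = TRUE)
  expect_mesh_equal(read_surface(p), s, tol = 300 * 2^-23)
})

test_that("PLY carries the per-vertex scalar channel and STL refuses it", {
  s <- small_template()$surface
  s$scalar <- seq_len(n_vertices(s)) * 0.25
  p <- withr::local_tempfile(fileext = ".ply")
  write_surface(s, p, include_scalar = TRUE)
  m <- read_surface(p)
  expect_lt(max(abs(m$scalar - s$scalar)), 1e-4)
  expect_error(write_surface(s, withr::local_tempfile(fileext = ".stl"),
                             include_scalar = TRUE), "PLY")
})

test_that("writing an empty mesh errors", {
  empty <- surface_mesh(matrix(numeric(0), 0, 3), matrix(integer(0), 0, 3))
  expect_error(write_surface(empty, tempfile(fileext = ".stl")), "empty")
})

test_that("OBJ polygon faces are fan-triangulated around the first vertex", {
  p <- withr::local_tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), p)
  expect_message(m <- read_surface(p), "fan-triangulated")
  expect_equal(n_faces(m), 2L)
  expect_equal(m$faces, rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)))
})

test_that("landmark files round-trip exactly and reject invalid content", {
  lms <- landmark_set(FOOT_LANDMARKS_16,
                      points = matrix(seq_len(48) * 1.5, ncol = 3))
  for (ext in c(".csv", ".json")) {
    p <- withr::local_tempfile(fileext = ext)
    write_landmarks(lms, p)
    got <- read_landmarks(p)
    expect_identical(got$name, lms$name)
    expect_equal(landmark_points(got), landmark_points(lms), tolerance = 1e-12)
  }
  expect_error(landmark_set(c("hallux tip", "hallux tip"),
                            points = matrix(1:6, 2)), "Duplicate")
  expect_error(landmark_set("a", NA_real_, 1, 2), "finite")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,x,y,z", '"hallux tip",1,2,3', '"hallux tip",4,5,6'), p)
  expect_error(read_landmarks(p), "Duplicate")
})

test_that("trimming clips faces at the plane and never grows the surface", {
  s <- small_template()$surface
  a0 <- mesh_area(s)
  zmin <- min(s$vertices[, 3])
  tr <- trim_surface(s, c(0, 0, 1), zmin + 30)
  expect_lte(max(tr$vertices[, 3]), zmin + 30 + 1e-9)
  expect_lte(mesh_area(tr), a0 + 1e-9)
  # kept vertices are either originals in the half-space or lie on the plane
  d <- tr$vertices[, 3] - (zmin + 30)
  key_orig <- apply(round(s$vertices, 9), 1, paste, collapse = ",")
  key_new <- apply(round(tr$vertices, 9), 1, paste, collapse = ",")
  on_plane <- abs(d) <= 1e-9
  expect_true(all(on_plane | key_new %in% key_orig))
})

test_that("the 65-mm scan trim bounds the height above the plantar point", {
  s <- small_template()$surface
  zmin <- min(s$vertices[, 3])
  tr <- trim_surface(s, c(0, 0, 1), zmin + 65)
  expect_lte(max(tr$vertices[, 3]) - zmin, 65 + 1e-9)
})

test_that("a plane that misses the mesh is a no-op with a notice", {
  s <- small_template()$surface
  expect_message(tr <- trim_surface(s, c(0, 0, 1), max(s$vertices[, 3]) + 10),
                 "unchanged")
  expect_identical(tr$vertices, s$vertices)
  expect_error(trim_surface(s, c(0, 0, 1), min(s$vertices[, 3]) - 10),
               "entire mesh")
})

test_that("welding merges coincident vertices", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0),
             c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  m <- surface_mesh(v, rbind(c(1L, 2L, 3L), c(4L, 6L, 5L)))
  w <- weld_vertices(m)
  expect_equal(n_vertices(w), 4L)
  expect_equal(n_faces(w), 2L)
})
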