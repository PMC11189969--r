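test_that("block volume meshes have valid connectivity and sizes", {
  hx <- make_block_volume(2, 3, 1, size = 5, type = "hex")
  expect_equal(nrow(hx$hex8), 6L)
  expect_equal(nrow(hx$nodes), 3 * 4 * 2)
  tt <- make_block_volume(2, 3, 1, size = 5, type = "tet")
  expect_equal(nrow(tt$tet4), 36L)
  rep_ <- mesh_size_report(tt)
  expect_equal(rep_$n_tet4, 36L)
  expect_gte(rep_$median_edge_mm, 5)
  expect_lte(rep_$median_edge_mm, 5 * sqrt(3))
  expect_equal(mesh_size_report(hx)$median_edge_mm, 5)
  expect_error(volume_mesh(hx$nodes, tet4 = matrix(c(1L, 2L, 3L, 999L), 1)),
               "out of range")
})

test_that("the skin layer shares the bulk surface nodes and its thickness", {
  s <- flat_square(side = 10, n = 5)  # 50 triangles... build one with 100
  s2 <- flat_square(side = 10, n = 10)
  skin <- make_skin_layer(s2, 2)
  expect_equal(nrow(skin$tri3), n_faces(s2))
  expect_equal(nrow(skin$nodes), n_vertices(s2))  # no new nodes
  expect_equal(attr(skin, "thickness"), 2)
  expect_error(make_skin_layer(s, 0), "positive")
  expect_error(make_skin_layer(s, -2), "positive")
  nonman <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                               c(0, -1, 0)),
                         rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 2L, 5L)))
  expect_error(make_skin_layer(nonman, 2), "non-manifold")
})

test_that("the model spec carries the stated load fractions exactly", {
  spec <- suppressMessages(build_model_spec(fe_bundle(), body_weight = 700))
  expect_identical(spec$loads$plate_vertical, 350)
  expect_identical(spec$loads$achilles, 175)
  expect_identical(spec$friction, 0.6)
  expect_equal(spec$mesh_targets[["merged_bone"]], 3)
  expect_equal(spec$mesh_targets[["bulk_soft_tissue"]], 5)
  g <- glance(spec)
  expect_equal(g$plate_load_n + g$achilles_load_n, 700 * 0.75)
})

test_that("overrides are applied last and recorded", {
  spec <- suppressMessages(build_model_spec(fe_bundle(), 600,
                                            overrides = list(friction = 0.5)))
  expect_identical(spec$friction, 0.5)
  expect_match(spec$overrides_applied, "friction=0.5", all = FALSE)
})

test_that("missing parts and invalid weights are rejected by name", {
  geom <- fe_bundle()
  expect_error(build_model_spec(geom[c("merged_bone", "ground_plate")], 700),
               "bulk_soft_tissue")
  expect_error(build_model_spec(geom[setdiff(names(geom), "skin")], 700),
               "skin")
  expect_error(build_model_spec(geom, -10), "positive")
})

test_that("deck writing is byte-deterministic and round-trips its inventory", {
  spec <- suppressMessages(build_model_spec(fe_bundle(), body_weight = 700))
  p1 <- withr::local_tempfile(fileext = ".inp")
  p2 <- withr::local_tempfile(fileext = ".inp")
  write_inp(spec, p1)
  write_inp(spec, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  sm <- read_inp_summary(p1)
  expect_equal(sm$n_nodes, sum(vapply(spec$parts, function(p) nrow(p$nodes),
                                      integer(1))))
  expect_equal(sort(sm$elements$elset),
               sort(toupper(names(spec$parts))))
  expect_equal(sm$elements$n[match("MERGED_BONE", sm$elements$elset)],
               nrow(spec$parts$merged_bone$tet4))
  expect_equal(sm$elements$type[match("SKIN", sm$elements$elset)], "M3D3")
  expect_equal(sm$elements$type[match("GROUND_PLATE", sm$elements$elset)], "C3D8")
  expect_identical(sm$friction, 0.6)
  expect_equal(sort(sm$materials$model),
               sort(c("elastic", "elastic", "polynomial_n2", "ogden_n1")))
  expect_equal(sm$sections$thickness[sm$sections$kind == "membrane"], 2)
  # CLOAD lines carry the exact half/quarter body-weight split
  expect_equal(sum(sm$cloads$magnitude), 350 + 175)
  expect_equal(sm$cloads$magnitude[sm$cloads$nset == "ACHILLES_ATTACHMENT"], 175)
})

test_that("a minimal one-tet deck parses back", {
  one <- volume_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                     tet4 = matrix(1:4, 1))
  p <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("*HEADING", "minimal", "*NODE",
               "1, 0, 0, 0", "2, 1, 0, 0", "3, 0, 1, 0", "4, 0, 0, 1",
               "*ELEMENT, TYPE=C3D4, ELSET=ONE",
               "1, 1, 2, 3, 4"), p)
  sm <- read_inp_summary(p)
  expect_equal(sm$n_nodes, 4L)
  expect_equal(sm$elements$n, 1L)
  expect_equal(sm$elements$type, "C3D4")
  expect_equal(n_elements(one), 1L)
})

test_that("unknown keywords are skipped with a warning, bad connectivity errors", {
  p <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("*HEADING", "x", "*NODE", "1, 0, 0, 0", "2, 1, 0, 0",
               "3, 0, 1, 0", "4, 0, 0, 1",
               "*ELEMENT, TYPE=C3D4, ELSET=A", "1, 1, 2, 3, 4",
               "*STRANGEKEYWORD, OPT=1", "whatever"), p)
  expect_warning(sm <- read_inp_summary(p), "STRANGEKEYWORD")
  expect_equal(sm$elements$n, 1L)
  p2 <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("*HEADING", "x", "*NODE", "1, 0, 0, 0",
               "*ELEMENT, TYPE=C3D4, ELSET=A", "1, 1, 2, 3"), p2)
  expect_error(read_inp_summary(p2), "malformed")
})

test_that("the convergence ladder encodes the halving sweep", {
  lad <- convergence_ladder(c(20, 10, 5, 2.5, 1.25))
  expect_equal(nrow(lad), 5L)
  expect_equal(lad$element_size_mm, c(20, 10, 5, 2.5, 1.25))
  expect_equal(lad$element_size_mm[-5] / lad$element_size_mm[-1], rep(2, 4))
  expect_match(attr(lad, "acceptance_rule"), "5%")
  expect_equal(nrow(convergence_ladder(5)), 1L)
  expect_error(convergence_ladder(c(5, 10)), "decreasing")
  expect_error(convergence_ladder(c(5, -1)), "positive")
})
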