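test_that("identity targets give an identity morph", {
  tpl <- small_template()
  res <- morph_rbfpt(tpl$surface, tpl$bone, tpl$landmarks, tpl$landmarks)
  expect_lt(max(abs(res$morphed_surface$vertices - tpl$surface$vertices)), 1e-8)
  expect_lt(max(abs(res$morphed_bone$vertices - tpl$bone$vertices)), 1e-8)
  expect_identical(res$morphed_surface$faces, tpl$surface$faces)
})

test_that("an exactly-affine target reproduces the affine image of the template", {
  tpl <- small_template()
  M0 <- rbind(cbind(diag(c(1.08, 1.02, 0.95)), c(5, 2, -3)), c(0, 0, 0, 1))
  aff <- footmorph:::new_affine(M0)
  tgt_lms <- apply_affine(aff, tpl$landmarks)
  res <- morph_rbfpt(tpl$surface, tpl$bone, tpl$landmarks, tgt_lms)
  expect_lt(max(abs(res$morphed_surface$vertices -
                      apply_affine(aff, tpl$surface)$vertices)), 1e-6)
  expect_lt(max(abs(res$morphed_bone$vertices -
                      apply_affine(aff, tpl$bone)$vertices)), 1e-6)
})

test_that("landmarks land exactly on their targets after RBFPT", {
  tpl <- bench_template()
  tgt <- bench_target()
  res <- morph_rbfpt(tpl$surface, tpl$bone, tpl$landmarks, tgt$target_landmarks)
  expect_lt(res$provenance$stage_residuals$rbfpt, 1e-6)
})

test_that("correspondence sampling is seeded, exhaustive-capable and bounded", {
  tpl <- small_template()
  s <- tpl$surface
  a <- sample_correspondences(s, s, 20, seed = 5)
  b <- sample_correspondences(s, s, 20, seed = 5)
  expect_identical(a, b)
  c_ <- sample_correspondences(s, s, 20, seed = 6)
  expect_false(identical(a$index, c_$index))
  # identical surfaces pair each vertex with itself at zero separation
  expect_lt(max(sqrt(rowSums((a$sources - a$targets)^2))), 1e-12)
  all_v <- sample_correspondences(s, s, n_vertices(s), seed = 1)
  expect_equal(nrow(all_v$sources), n_vertices(s))
  expect_error(sample_correspondences(s, s, n_vertices(s) + 1, seed = 1),
               "only")
  expect_error(sample_correspondences(s, s, 3, seed = 1), "at least 4")
})

test_that("RBFST is the identity when the target equals the scaled surface", {
  tpl <- small_template()
  res <- morph_rbfpt(tpl$surface, tpl$bone, tpl$landmarks, tpl$landmarks)
  res2 <- morph_rbfst(res, res$morphed_surface, n_sample_points = 50, seed = 3)
  expect_lt(max(abs(res2$morphed_surface$vertices -
                      res$morphed_surface$vertices)), 1e-8)
})

test_that("the pipeline dispatches methods and is bit-reproducible", {
  tpl <- bench_template()
  tgt <- bench_target()
  cfg1 <- morph_config("RBFPT", rbf_kernel("THI"))
  r1 <- run_pipeline(cfg1, tpl$surface, tpl$bone, tgt$target_surface,
                     tpl$landmarks, tgt$target_landmarks)
  expect_length(r1$rbf_stages, 1L)
  cfg2 <- morph_config("RBFPT+RBFST", rbf_kernel("THI"),
                       n_sample_points = 200, seed = 9)
  r2a <- run_pipeline(cfg2, tpl$surface, tpl$bone, tgt$target_surface,
                      tpl$landmarks, tgt$target_landmarks)
  r2b <- run_pipeline(cfg2, tpl$surface, tpl$bone, tgt$target_surface,
                      tpl$landmarks, tgt$target_landmarks)
  expect_identical(r2a$morphed_surface, r2b$morphed_surface)
  expect_identical(r2a$morphed_bone, r2b$morphed_bone)
  expect_length(r2a$rbf_stages, 2L)
  expect_identical(r2a$morphed_surface$faces, tpl$surface$faces)
  expect_error(morph_config("nope"), "arg")
})

test_that("every variant beats the affine-only registration on the benchmark", {
  tpl <- bench_template()
  tgt <- bench_target()
  aff <- fit_affine(tpl$landmarks, tgt$target_landmarks)
  e_aff <- error_stats(error_map(apply_affine(aff, tpl$surface),
                                 tgt$target_surface))$mean_abs
  for (fam in c("THI", "MUL", "TRI")) {
    cfg <- morph_config("RBFPT+RBFST", rbf_kernel(fam),
                        n_sample_points = 300, seed = 7)
    res <- run_pipeline(cfg, tpl$surface, tpl$bone, tgt$target_surface,
                        tpl$landmarks, tgt$target_landmarks)
    e <- error_stats(error_map(res$morphed_surface, tgt$target_surface))$mean_abs
    expect_true(is.finite(e))
    expect_lte(e, e_aff)
  }
})

test_that("RBFST reduces the RBFPT surface error on the benchmark", {
  tpl <- bench_template()
  tgt <- bench_target()
  pt <- morph_rbfpt(tpl$surface, tpl$bone, tpl$landmarks, tgt$target_landmarks)
  e_pt <- error_stats(error_map(pt$morphed_surface, tgt$target_surface))$mean_abs
  st <- morph_rbfst(pt, tgt$target_surface, n_sample_points = 500, seed = 7)
  e_st <- error_stats(error_map(st$morphed_surface, tgt$target_surface))$mean_abs
  expect_lte(e_st, e_pt)
})

test_that("morph provenance serialises the run configuration", {
  tpl <- small_template()
  res <- morph_rbfpt(tpl$surface, tpl$bone, tpl$landmarks, tpl$landmarks)
  p <- withr::local_tempfile(fileext = ".json")
  write_morph_provenance(res, p)
  got <- jsonlite::fromJSON(p)
  expect_equal(got$stages, c("affine", "RBFPT"))
  expect_equal(got$kernel, "THI")
  expect_lt(got$stage_residuals_mm$rbfpt, 1e-6)
  g <- glance(res)
  expect_equal(g$n_rbf_stages, 1L)
})
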