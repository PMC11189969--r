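test_that("kernel families evaluate to their closed forms", {
  expect_equal(kernel_eval(rbf_kernel("TRI"), 2), 8)
  expect_equal(kernel_eval(rbf_kernel("THI"), 1), 0)
  expect_equal(kernel_eval(rbf_kernel("THI"), 0), 0)  # continuity limit
  expect_equal(kernel_eval(rbf_kernel("THI"), exp(1)), exp(2))
  expect_equal(kernel_eval(rbf_kernel("MUL"), 0), sqrt(0.2))
  expect_equal(kernel_eval(rbf_kernel("MUL", beta = 1), 2), sqrt(5))
  expect_error(kernel_eval(rbf_kernel("TRI"), -1), "nonnegative")
  expect_error(rbf_kernel("MUL", beta = 0), "beta")
})

test_that("the legacy multiquadric sign errors on imaginary arguments", {
  k <- rbf_kernel("MUL", beta = 0.2, legacy_sign = TRUE)
  expect_equal(kernel_eval(k, 2), sqrt(4 - 0.2))
  expect_error(kernel_eval(k, 0.1), "imaginary")
})

test_that("fit_affine recovers an exact affine map and rejects degeneracy", {
  set.seed(11)
  src <- landmark_set(FOOT_LANDMARKS_16, points = matrix(rnorm(48, sd = 50), ncol = 3))
  # identity case
  ident <- fit_affine(src, src)
  expect_equal(ident$M, diag(4), tolerance = 1e-9)
  # known-matrix recovery
  M0 <- rbind(cbind(matrix(c(1.2, 0.1, 0, -0.05, 0.9, 0.2, 0, 0.1, 1.1), 3, 3),
                    c(5, -3, 7)), c(0, 0, 0, 1))
  tgt <- apply_affine(footmorph:::new_affine(M0), src)
  fit <- fit_affine(src, tgt)
  expect_equal(fit$M, M0, tolerance = 1e-9)
  # exactly four non-degenerate pairs interpolate exactly
  s4 <- landmark_set(letters[1:4], points = rbind(c(0, 0, 0), c(10, 0, 0),
                                                  c(0, 10, 0), c(0, 0, 10)))
  t4 <- apply_affine(footmorph:::new_affine(M0), s4)
  f4 <- fit_affine(s4, t4)
  expect_lt(max(abs(landmark_points(apply_affine(f4, s4)) - landmark_points(t4))),
            1e-8)
  # coplanar sources are rank-deficient
  flat <- landmark_set(letters[1:5], points = cbind(rnorm(5), rnorm(5), 0))
  expect_error(fit_affine(flat, flat), "rank")
  expect_error(fit_affine(s4, landmark_set(c("w", "x", "y", "z"),
                                           points = landmark_points(t4))),
               "correspond", ignore.case = TRUE)
  # collinear targets make the fitted linear block singular
  expect_error(fit_affine(s4, landmark_set(letters[1:4],
                                           points = matrix(0:11, 4))),
               "singular")
})

test_that("RBF interpolation is exact at the sources for all kernels", {
  set.seed(21)
  src <- matrix(runif(48, -100, 100), ncol = 3)
  tgt <- src + matrix(rnorm(48, sd = 5), ncol = 3)
  for (fam in c("THI", "MUL", "TRI")) {
    t <- fit_rbf(src, tgt, rbf_kernel(fam))
    expect_lt(max(sqrt(rowSums((apply_rbf(t, src) - tgt)^2))), 1e-6)
  }
})

test_that("zero displacement gives zero coefficients and the identity map", {
  set.seed(22)
  src <- matrix(runif(30, -50, 50), ncol = 3)
  t <- fit_rbf(src, src, rbf_kernel("THI"))
  expect_lt(max(abs(t$coefficients)), 1e-10)
  probe <- matrix(runif(30, -60, 60), ncol = 3)
  expect_equal(apply_rbf(t, probe), probe, tolerance = 1e-8)
})

test_that("the affine tail absorbs exactly-affine correspondences", {
  set.seed(23)
  src <- matrix(runif(48, -100, 100), ncol = 3)
  M0 <- rbind(cbind(diag(c(1.1, 0.95, 1.05)), c(3, -2, 8)), c(0, 0, 0, 1))
  tgt <- apply_affine(footmorph:::new_affine(M0), src)
  for (fam in c("THI", "MUL", "TRI")) {
    t <- fit_rbf(src, tgt, rbf_kernel(fam), with_affine_tail = TRUE)
    expect_lt(sqrt(sum(t$coefficients^2)), 1e-8)
  }
})

test_that("coefficients satisfy the moment side-conditions with a tail", {
  set.seed(24)
  src <- matrix(runif(60, -80, 80), ncol = 3)
  tgt <- src + matrix(rnorm(60, sd = 3), ncol = 3)
  t <- fit_rbf(src, tgt, rbf_kernel("THI"))
  scale <- max(abs(t$coefficients)) * max(abs(src)) + 1e-300
  expect_lt(max(abs(colSums(t$coefficients))) / scale, 1e-8)
  expect_lt(max(abs(t(t$coefficients) %*% src)) / scale, 1e-8)
})

test_that("duplicate source points are rejected", {
  src <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0, 0, 5))
  expect_error(fit_rbf(src, src, rbf_kernel("THI")), "Duplicate")
})

test_that("a pure translation maps midpoints exactly", {
  set.seed(25)
  src <- matrix(runif(24, -50, 50), ncol = 3)
  shift <- c(3, -7, 11)
  t <- fit_rbf(src, sweep(src, 2, shift, "+"), rbf_kernel("TRI"))
  mid <- (src[1, ] + src[2, ]) / 2
  expect_equal(drop(apply_rbf(t, matrix(mid, 1))), mid + shift,
               tolerance = 1e-8)
})

test_that("RBF interpolation is exact on 16-landmark fixtures", {
  tpl <- bench_template()
  tgt <- bench_target()
  src <- landmark_points(tpl$landmarks)
  dst <- landmark_points(tgt$target_landmarks)
  for (fam in c("THI", "MUL", "TRI")) {
    t <- fit_rbf(src, dst, rbf_kernel(fam))
    expect_lt(max(sqrt(rowSums((apply_rbf(t, src) - dst)^2))), 1e-6)
  }
})
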