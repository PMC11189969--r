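# Landmark-driven registration primitives: least-squares affine fit and
# radial-basis-function (RBF) interpolation of 3D displacement fields.
#
# The RBF interpolant maps a free point x through
#   f_i(x) = sum_j c_ij * Phi(||x - x_j||)  (+ optional affine tail),  i = 1..3
# where x_j are source points with known images. Three kernel families are
# supported: multiquadric (MUL), thin-plate (THI, r^2 log r) and triharmonic
# (TRI, r^3).

#' RBF kernel specification
#'
#' @param family `"MUL"` (multiquadric), `"THI"` (thin-plate, r^2 log r) or
#'   `"TRI"` (triharmonic, r^3).
#' @param beta shape parameter of the multiquadric, added under the square
#'   root as a squared-mm offset: Phi(r) = sqrt(r^2 + beta). Default 0.2.
#'   Ignored for THI/TRI.
#' @param legacy_sign evaluate the multiquadric as sqrt(r^2 - beta) instead.
#'   This form is imaginary for r < sqrt(beta) (including r = 0) and
#'   evaluation then errors; it exists only for comparison with software that
#'   prints the kernel this way. Default `FALSE`.
#' @return An object of class `rbf_kernel`.
#' @export
rbf_kernel <- function(family = c("THI", "MUL", "TRI"), beta = 0.2,
                       legacy_sign = FALSE) {
  family <- toupper(family)
  family <- match.arg(family)
  if (family == "MUL" && (!is.finite(beta) || beta <= 0)) {
    abort("Multiquadric shape parameter `beta` must be > 0.")
  }
  structure(list(family = family, beta = beta, legacy_sign = isTRUE(legacy_sign)),
            class = "rbf_kernel")
}

#' @export
print.rbf_kernel <- function(x, ...) {
  extra <- if (x$family == "MUL") sprintf(" (beta = %g)", x$beta) else ""
  cat(sprintf("<rbf_kernel> %s%s\n", x$family, extra))
  invisible(x)
}

#' Evaluate an RBF kernel at radii r
#'
#' TRI returns r^3; THI returns r^2 log(r) with Phi(0) = 0 by continuity;
#' MUL returns sqrt(r^2 + beta).
#'
#' @param kernel an [rbf_kernel()].
#' @param r nonnegative radii (mm); vectorised.
#' @return Numeric vector of kernel values.
#' @export
kernel_eval <- function(kernel, r) {
  if (any(r < 0)) abort("Kernel radii must be nonnegative.")
  switch(kernel$family,
    TRI = r^3,
    THI = ifelse(r == 0, 0, r^2 * log(r)),
    MUL = {
      if (kernel$legacy_sign) {
        arg <- r^2 - kernel$beta
        if (any(arg < 0)) {
          abort(sprintf(
            "Multiquadric with legacy sign is imaginary for r < sqrt(beta) = %g.",
            sqrt(kernel$beta)))
        }
        sqrt(arg)
      } else {
        sqrt(r^2 + kernel$beta)
      }
    }
  )
}

pairwise_dist <- function(a, b) {
  # rows of a vs rows of b -> |a_i - b_j|
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Fit a least-squares affine transform between corresponding landmark sets
#'
#' Finds the 4x4 homogeneous matrix M minimising sum_k ||M P_k - P'_k||^2
#' over the landmark pairs. With exactly four non-degenerate pairs the fit is
#' exact.
#'
#' @param source,target corresponding `landmark_set`s (same names, same
#'   order) or plain n-by-3 matrices; n >= 4 and sources must span 3D.
#' @return An object of class `affine_transform` with element `M` (4x4).
#' @export
fit_affine <- function(source, target) {
  P <- if (is.matrix(source)) source else landmark_points(source)
  Q <- if (is.matrix(target)) target else landmark_points(target)
  if (!is.matrix(source) && !is.matrix(target) &&
      !landmarks_correspond(source, target)) {
    abort("Landmark sets do not correspond (name sequences differ).")
  }
  n <- nrow(P)
  if (n < 4 || nrow(Q) != n) abort("Need at least 4 corresponding landmark pairs.")
  A <- cbind(P, 1)
  qrA <- qr(A)
  if (qrA$rank < 4) {
    abort(sprintf(
      "Source landmarks are rank-deficient (rank %d of 4): coplanar or collinear; the affine fit is underdetermined.",
      qrA$rank))
  }
  X <- qr.coef(qrA, Q)            # 4 x 3, rows = (a b c | t)
  M <- rbind(cbind(t(X[1:3, , drop = FALSE]), X[4, ]), c(0, 0, 0, 1))
  new_affine(M)
}

new_affine <- function(M) {
  M <- unname(as.matrix(M))
  stopifnot(all(dim(M) == c(4, 4)))
  if (max(abs(M[4, ] - c(0, 0, 0, 1))) > 1e-12) {
    abort("Affine matrix bottom row must be (0, 0, 0, 1).")
  }
  if (abs(det(M[1:3, 1:3])) <= 1e-12) {
    abort("Affine linear block is singular.")
  }
  structure(list(M = M), class = "affine_transform")
}

#' Identity affine transform
#' @return An `affine_transform` with M = I.
#' @export
affine_identity <- function() new_affine(diag(4))

#' Apply an affine transform to points
#'
#' @param t an `affine_transform`.
#' @param points n-by-3 matrix, `surface_mesh` or `landmark_set`; the same
#'   type is returned.
#' @return Transformed points/mesh/landmarks.
#' @export
apply_affine <- function(t, points) {
  apply_pointmap(points, function(p) {
    sweep(p %*% t(t$M[1:3, 1:3]), 2, t$M[1:3, 4], "+")
  })
}

# Apply a coordinate map fn(matrix)->matrix to matrix / mesh / landmark_set.
apply_pointmap <- function(points, fn) {
  if (inherits(points, "surface_mesh")) {
    out <- points
    out$vertices <- fn(points$vertices)
    return(out)
  }
  if (inherits(points, "landmark_set")) {
    p <- fn(landmark_points(points))
    return(landmark_set(points$name, points = p))
  }
  fn(as.matrix(points))
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(round(x$M, 6))
  invisible(x)
}

#' Fit an RBF interpolant mapping source points to target points
#'
#' Solves the dense interpolation system so that [apply_rbf()] maps every
#' source exactly (to numerical precision) onto its target. By default the
#' interpolant is augmented with a full affine tail under the usual moment
#' side-conditions (sum_j c_j = 0, sum_j c_j x_j^T = 0), which makes the
#' thin-plate system well-posed and lets exactly-affine correspondences be
#' absorbed with zero RBF coefficients. Without the tail a small Tikhonov
#' ridge (`lambda` times the mean absolute kernel value) stabilises the
#' system.
#'
#' @param sources,targets corresponding n-by-3 point matrices (mm), n >= 4,
#'   sources pairwise distinct.
#' @param kernel an [rbf_kernel()].
#' @param with_affine_tail include the affine polynomial tail (default TRUE).
#' @param lambda ridge factor used only when `with_affine_tail = FALSE`.
#' @return An object of class `rbf_transform` with elements `kernel`,
#'   `sources`, `coefficients` (n x 3) and `affine_tail` (4 x 3 or NULL,
#'   rows = constant, x, y, z).
#' @export
fit_rbf <- function(sources, targets, kernel = rbf_kernel("THI"),
                    with_affine_tail = TRUE, lambda = 1e-10) {
  sources <- as.matrix(sources); targets <- as.matrix(targets)
  n <- nrow(sources)
  if (n < 4 || nrow(targets) != n) {
    abort("Need >= 4 corresponding source/target points of equal count.")
  }
  D <- pairwise_dist(sources, sources)
  mind <- min(D[upper.tri(D)])
  if (mind < 1e-9) {
    abort("Duplicate source points (minimum pairwise distance < 1e-9 mm); the RBF system is singular.")
  }
  K <- kernel_eval(kernel, D)
  if (with_affine_tail) {
    P <- cbind(1, sources)                     # n x 4
    A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
    rhs <- rbind(targets, matrix(0, 4, 3))
  } else {
    A <- K + diag(lambda * mean(abs(K)), n)
    rhs <- targets
  }
  # The raw condition number is dominated by the scale gap between kernel
  # values (~mm^3 for TRI) and the unit constraint rows; the partial-pivot LU
  # still solves these systems accurately, so gate on the achieved
  # interpolation residual rather than on rcond.
  sol <- tryCatch(solve(A, rhs, tol = 0), error = function(e) {
    abort(sprintf("RBF system numerically singular (reciprocal condition number %.3g).",
                  rcond(A)))
  })
  fitted <- K %*% sol[seq_len(n), , drop = FALSE]
  if (with_affine_tail) fitted <- fitted + P %*% sol[n + 1:4, , drop = FALSE]
  resid <- max(sqrt(rowSums((fitted - targets)^2)))
  if (!is.finite(resid) || resid > 1e-6) {
    abort(sprintf(
      "RBF system numerically singular: source residual %.3g mm (reciprocal condition number %.3g).",
      resid, rcond(A)))
  }
  structure(list(
    kernel = kernel,
    sources = sources,
    coefficients = sol[seq_len(n), , drop = FALSE],
    affine_tail = if (with_affine_tail) sol[n + 1:4, , drop = FALSE] else NULL
  ), class = "rbf_transform")
}

#' Evaluate an RBF transform at points
#'
#' @param t an `rbf_transform` from [fit_rbf()].
#' @param points n-by-3 matrix, `surface_mesh` or `landmark_set`.
#' @return Mapped points, same type as the input.
#' @export
apply_rbf <- function(t, points) {
  apply_pointmap(points, function(p) {
    K <- kernel_eval(t$kernel, pairwise_dist(p, t$sources))
    out <- K %*% t$coefficients
    if (!is.null(t$affine_tail)) out <- out + cbind(1, p) %*% t$affine_tail
    out
  })
}

#' @export
print.rbf_transform <- function(x, ...) {
  cat(sprintf("<rbf_transform> %s kernel, %d centres, affine tail: %s\n",
              x$kernel$family, nrow(x$sources),
              if (is.null(x$affine_tail)) "no" else "yes"))
  invisible(x)
}

# Residuals of the interpolation at its own sources; used for provenance.
rbf_source_residual <- function(t, targets) {
  mapped <- apply_rbf(t, t$sources)
  max(sqrt(rowSums((mapped - targets)^2)))
}

#' @export
tidy.rbf_transform <- function(x, ...) {
  tibble::tibble(
    centre = seq_len(nrow(x$sources)),
    x = x$sources[, 1], y = x$sources[, 2], z = x$sources[, 3],
    cx = x$coefficients[, 1], cy = x$coefficients[, 2], cz = x$coefficients[, 3]
  )
}

#' @export
glance.rbf_transform <- function(x, ...) {
  tibble::tibble(
    kernel = x$kernel$family,
    beta = if (x$kernel$family == "MUL") x$kernel$beta else NA_real_,
    n_centres = nrow(x$sources),
    affine_tail = !is.null(x$affine_tail),
    coefficient_norm = sqrt(sum(x$coefficients^2))
  )
}
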