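# Customised foot scaling pipeline: affine registration on landmarks, then
# landmark-based RBF morphing (RBFPT), optionally followed by a second RBF
# stage fitted on sampled surface correspondences (RBFST).

#' Morphing configuration
#'
#' @param method `"RBFPT"` (landmark stage only) or `"RBFPT+RBFST"` (add a
#'   surface-correspondence stage).
#' @param kernel an [rbf_kernel()]; used for every RBF stage.
#' @param n_sample_points number of surface correspondences for RBFST
#'   (default 1000).
#' @param seed integer seed controlling the correspondence sampling; fixed
#'   seed gives a bit-reproducible run.
#' @param keep_landmarks_in_rbfst also pin the landmark pairs in the RBFST
#'   system so anatomical landmarks never drift (default TRUE).
#' @return A `morph_config` list.
#' @export
morph_config <- function(method = c("RBFPT+RBFST", "RBFPT"),
                         kernel = rbf_kernel("THI"),
                         n_sample_points = 1000L, seed = 1L,
                         keep_landmarks_in_rbfst = TRUE) {
  method <- toupper(method)
  method <- match.arg(method)
  if (n_sample_points < 4) abort("`n_sample_points` must be >= 4.")
  structure(list(method = method, kernel = kernel,
                 n_sample_points = as.integer(n_sample_points),
                 seed = as.integer(seed),
                 keep_landmarks_in_rbfst = isTRUE(keep_landmarks_in_rbfst)),
            class = "morph_config")
}

new_morph_result <- function(surface, bone, affine, rbf_stages, provenance) {
  structure(list(morphed_surface = surface, morphed_bone = bone,
                 affine = affine, rbf_stages = rbf_stages,
                 provenance = provenance),
            class = "morph_result")
}

#' @export
print.morph_result <- function(x, ...) {
  cat(sprintf("<morph_result> %s; %d RBF stage(s)\n",
              paste(x$provenance$stages, collapse = " -> "),
              length(x$rbf_stages)))
  res <- x$provenance$stage_residuals
  if (length(res)) {
    cat(sprintf("  max source residuals (mm): %s\n",
                paste(sprintf("%.2e", unlist(res)), collapse = ", ")))
  }
  invisible(x)
}

#' Landmark-based morphing (affine + point-based RBF)
#'
#' Pipeline: fit the least-squares affine transform on the landmark pairs,
#' apply it to the template surface, bone and landmarks, then fit an RBF
#' interpolant from the affine-transformed source landmarks to the target
#' landmarks and apply it to surface and bone. Source landmarks land exactly
#' on their targets; mesh topology is untouched.
#'
#' @param template_surface,template_bone template `surface_mesh`es.
#' @param src_lms,tgt_lms corresponding `landmark_set`s on the template and
#'   target.
#' @param kernel an [rbf_kernel()].
#' @return A `morph_result` with `morphed_surface`, `morphed_bone`, `affine`,
#'   `rbf_stages` (one stage) and `provenance`.
#' @export
morph_rbfpt <- function(template_surface, template_bone, src_lms, tgt_lms,
                        kernel = rbf_kernel("THI")) {
  if (!landmarks_correspond(src_lms, tgt_lms)) {
    abort("Template and target landmark sets do not correspond.")
  }
  aff <- fit_affine(src_lms, tgt_lms)
  surf_a <- apply_affine(aff, template_surface)
  bone_a <- apply_affine(aff, template_bone)
  lms_a <- apply_affine(aff, src_lms)
  rbf <- fit_rbf(landmark_points(lms_a), landmark_points(tgt_lms), kernel)
  surface <- apply_rbf(rbf, surf_a)
  bone <- apply_rbf(rbf, bone_a)
  resid <- rbf_source_residual(rbf, landmark_points(tgt_lms))
  new_morph_result(surface, bone, aff, list(rbfpt = rbf), list(
    stages = c("affine", "RBFPT"),
    kernel = kernel,
    landmark_names = src_lms$name,
    stage_residuals = list(rbfpt = resid)
  ))
}

#' Sample surface correspondences for the RBFST stage
#'
#' Draws `n` vertices of the scaled surface uniformly at random without
#' replacement (seeded) and pairs each with its closest point on the target
#' surface (point-to-surface correspondence; closest-point ties resolve to
#' the lowest triangle index).
#'
#' @param scaled_surface,target_surface `surface_mesh`es.
#' @param n number of correspondences (4 <= n <= vertex count).
#' @param seed integer seed.
#' @param method `"random"` (uniform over vertices) or `"farthest"` (greedy
#'   farthest-point stratification started from the seeded first pick).
#' @return List with `sources` and `targets`, two n-by-3 matrices.
#' @export
sample_correspondences <- function(scaled_surface, target_surface, n,
                                   seed = 1L, method = c("random", "farthest")) {
  method <- match.arg(method)
  nv <- n_vertices(scaled_surface)
  if (n < 4) abort("Need at least 4 correspondences.")
  if (n > nv) abort(sprintf("Requested %d correspondences but the surface has only %d vertices.", n, nv))
  idx <- withr_seed(seed, {
    if (method == "random" || n == nv) {
      sort(sample.int(nv, n))
    } else {
      farthest_point_sample(scaled_surface$vertices, n)
    }
  })
  src <- scaled_surface$vertices[idx, , drop = FALSE]
  cp <- cpp_closest_point(src, target_surface$vertices, target_surface$faces)
  list(sources = src, targets = cp$closest, index = idx)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

farthest_point_sample <- function(v, n) {
  nv <- nrow(v)
  sel <- integer(n)
  sel[1] <- sample.int(nv, 1)
  d <- sqrt(rowSums(sweep(v, 2, v[sel[1], ])^2))
  for (k in 2:n) {
    sel[k] <- which.max(d)
    d <- pmin(d, sqrt(rowSums(sweep(v, 2, v[sel[k], ])^2)))
  }
  sort(sel)
}

#' Surface-correspondence morphing stage (RBFST)
#'
#' Refines an RBFPT result by fitting a second RBF on sampled closest-point
#' correspondences between the scaled and the target surface (plus the
#' landmark pairs when `keep_landmarks`), and applying it to the morphed
#' surface and bone. Sampled vertices that coincide with a landmark source
#' (within 1e-3 mm — landmarks ride on mesh vertices, so a sampled vertex can
#' be a landmark) are dropped to keep the system nonsingular.
#'
#' @param rbfpt_result a `morph_result` from [morph_rbfpt()] against the same
#'   target.
#' @param target_surface the target `surface_mesh`.
#' @param kernel an [rbf_kernel()].
#' @param n_sample_points number of sampled correspondences.
#' @param seed integer seed for the sampling.
#' @param keep_landmarks pin the landmark pairs too (default TRUE).
#' @return A `morph_result` with two RBF stages.
#' @export
morph_rbfst <- function(rbfpt_result, target_surface,
                        kernel = rbf_kernel("THI"), n_sample_points = 1000L,
                        seed = 1L, keep_landmarks = TRUE) {
  scaled <- rbfpt_result$morphed_surface
  corr <- sample_correspondences(scaled, target_surface, n_sample_points, seed)
  src <- corr$sources
  tgt <- corr$targets
  if (keep_landmarks) {
    lm_tgt <- apply_rbf(rbfpt_result$rbf_stages$rbfpt,
                        rbfpt_result$rbf_stages$rbfpt$sources)
    keep <- rep(TRUE, nrow(src))
    if (nrow(lm_tgt)) {
      d <- pairwise_dist(src, lm_tgt)
      keep <- apply(d, 1, min) > 1e-3
    }
    src <- rbind(src[keep, , drop = FALSE], lm_tgt)
    tgt <- rbind(tgt[keep, , drop = FALSE], lm_tgt)
  }
  rbf <- fit_rbf(src, tgt, kernel)
  surface <- apply_rbf(rbf, scaled)
  bone <- apply_rbf(rbf, rbfpt_result$morphed_bone)
  prov <- rbfpt_result$provenance
  prov$stages <- c(prov$stages, "RBFST")
  prov$n_sample_points <- n_sample_points
  prov$seed <- seed
  prov$keep_landmarks <- keep_landmarks
  prov$stage_residuals$rbfst <- rbf_source_residual(rbf, tgt)
  new_morph_result(surface, bone,
                   rbfpt_result$affine,
                   c(rbfpt_result$rbf_stages, list(rbfst = rbf)),
                   prov)
}

#' Run a full morphing pipeline
#'
#' Dispatches among the customised-scaling variants: RBFPT alone, or
#' RBFPT followed by RBFST with a thin-plate, multiquadric or triharmonic
#' kernel. Provenance (stages, kernel, seed, sample count, per-stage source
#' residuals) is recorded on the result.
#'
#' @param config a [morph_config()].
#' @param template_surface,template_bone template `surface_mesh`es.
#' @param target_surface the target `surface_mesh` (needed for RBFST).
#' @param src_lms,tgt_lms corresponding `landmark_set`s.
#' @return A `morph_result`.
#' @export
run_pipeline <- function(config, template_surface, template_bone,
                         target_surface, src_lms, tgt_lms) {
  if (!inherits(config, "morph_config")) abort("`config` must be a morph_config().")
  res <- morph_rbfpt(template_surface, template_bone, src_lms, tgt_lms,
                     kernel = config$kernel)
  if (config$method == "RBFPT+RBFST") {
    res <- morph_rbfst(res, target_surface, kernel = config$kernel,
                       n_sample_points = config$n_sample_points,
                       seed = config$seed,
                       keep_landmarks = config$keep_landmarks_in_rbfst)
  }
  res$provenance$config <- config
  res
}

#' @export
glance.morph_result <- function(x, ...) {
  tibble::tibble(
    method = paste(x$provenance$stages, collapse = "+"),
    kernel = x$provenance$kernel$family,
    n_rbf_stages = length(x$rbf_stages),
    n_sample_points = x$provenance$n_sample_points %||% NA_integer_,
    seed = x$provenance$seed %||% NA_integer_,
    max_stage_residual_mm = max(unlist(x$provenance$stage_residuals))
  )
}

#' @export
tidy.morph_result <- function(x, ...) {
  tibble::tibble(
    stage = names(x$rbf_stages),
    kernel = vapply(x$rbf_stages, function(s) s$kernel$family, character(1)),
    n_centres = vapply(x$rbf_stages, function(s) nrow(s$sources), integer(1)),
    source_residual_mm = unlist(x$provenance$stage_residuals)[names(x$rbf_stages)]
  )
}

#' Write a morph provenance sidecar
#'
#' Serialises the configuration, seed, kernel and per-stage residuals of a
#' morph result as JSON next to the exported geometry.
#'
#' @param result a `morph_result`.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_morph_provenance <- function(result, path) {
  p <- result$provenance
  out <- list(
    stages = p$stages,
    kernel = p$kernel$family,
    beta = if (p$kernel$family == "MUL") p$kernel$beta else NULL,
    n_sample_points = p$n_sample_points,
    seed = p$seed,
    keep_landmarks = p$keep_landmarks,
    stage_residuals_mm = p$stage_residuals,
    landmark_names = p$landmark_names
  )
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
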