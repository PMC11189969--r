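# Synthetic fixtures: a parametric foot-like closed surface with an embedded
# bone core and 16 named landmarks, smooth invertible ground-truth
# deformation fields, and two-lobed plantar pressure maps. Everything is
# deterministic under its seed, so the full morphing benchmark is hermetic.

#' Fixture specification for the synthetic foot template
#'
#' @param length overall foot length in mm (default 250, an adult foot).
#' @param width overall width in mm.
#' @param height overall height in mm.
#' @param bone_scale inward scale factor of the bone core about the surface
#'   centroid (default 0.6).
#' @param n_rings longitudinal resolution (cross-section rings).
#' @param n_around circumferential resolution (vertices per ring).
#' @param bumpiness amplitude (mm) of seeded smooth random surface bumps
#'   that break the fixture's symmetry.
#' @param seed integer seed; a fixed seed gives a bit-identical fixture.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(length = 250, width = 90, height = 80,
                         bone_scale = 0.6, n_rings = 48, n_around = 36,
                         bumpiness = 1.5, seed = 42L) {
  if (length <= 0 || width <= 0 || height <= 0 || bone_scale <= 0) {
    abort("Fixture dimensions and bone scale must be positive.")
  }
  structure(list(length = length, width = width, height = height,
                 bone_scale = bone_scale, n_rings = as.integer(n_rings),
                 n_around = as.integer(n_around), bumpiness = bumpiness,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

gaussian01 <- function(t, c, s) exp(-((t - c) / s)^2)

# Parametric foot map: t in (0,1) heel -> toe, u in [0, 2pi) around the
# cross-section. Returns xyz in mm. Plantar side is flattened (z exponent),
# the heel tapers as a half-ellipsoid, the forefoot widens as a flat wedge
# and the toes carry a bulge.
foot_param <- function(t, u, spec) {
  L <- spec$length; W <- spec$width; H <- spec$height
  s <- sin(pi * t)^0.7
  w <- (W / 2) * s * (1 + 0.30 * gaussian01(t, 0.72, 0.15) +
                        0.10 * gaussian01(t, 0.93, 0.06))
  h <- (H / 2) * s * (0.45 + 0.55 * gaussian01(t, 0.20, 0.25) +
                        0.15 * gaussian01(t, 0.90, 0.08))
  y <- L * (1 - cos(pi * t)) / 2
  x <- w * cos(u)
  z <- h * ((1 + sin(u)) / 2)^1.6 * 2
  cbind(x, y, z)
}

#' Generate the synthetic foot template
#'
#' Builds a closed foot-like triangle surface (tapered half-ellipsoid heel,
#' flattened forefoot wedge, toe bulge), an inward-scaled bone core, and the
#' 16 canonical landmarks placed at fixed parametric stations and snapped to
#' the nearest surface vertex (stable across resolutions). A seeded set of
#' smooth Gaussian bumps breaks the left-right symmetry.
#'
#' @param spec a [fixture_spec()].
#' @return List with `surface` and `bone` ([surface_mesh()]s) and
#'   `landmarks` (a `landmark_set` of the 16 canonical names).
#' @export
make_template <- function(spec = fixture_spec()) {
  nr <- spec$n_rings; na <- spec$n_around
  tt <- seq_len(nr) / (nr + 1)
  uu <- 2 * pi * (seq_len(na) - 1) / na
  grid <- expand.grid(u = uu, t = tt)              # ring-major, u fastest
  v <- foot_param(grid$t, grid$u, spec)
  # seeded smooth bumps (radial in x/z, zero near poles via the sin profile)
  bumps <- withr_seed(spec$seed, {
    k <- 6
    list(tc = runif(k, 0.1, 0.9), uc = runif(k, 0, 2 * pi),
         amp = runif(k, -1, 1) * spec$bumpiness, st = runif(k, 0.08, 0.2),
         su = runif(k, 0.5, 1.2))
  })
  if (spec$bumpiness > 0) {
    disp <- numeric(nrow(v))
    for (k in seq_along(bumps$tc)) {
      du <- abs((grid$u - bumps$uc[k] + pi) %% (2 * pi) - pi)
      disp <- disp + bumps$amp[k] * sin(pi * grid$t) *
        gaussian01(grid$t, bumps$tc[k], bumps$st[k]) *
        exp(-(du / bumps$su[k])^2)
    }
    rad <- cbind(v[, 1], 0, v[, 3] - spec$height / 2)
    rl <- sqrt(rowSums(rad^2)); rl[rl < 1e-9] <- 1
    v <- v + disp / rl * rad
    v[, 3] <- pmax(v[, 3], 0)                      # keep the sole planar-ish
  }
  heel_pole <- c(0, 0, mean(v[grid$t == tt[1], 3]))
  toe_pole <- c(0, spec$length, mean(v[grid$t == tt[nr], 3]))
  verts <- rbind(heel_pole, v, toe_pole)
  ring_id <- function(r, j) 1L + (r - 1L) * na + (j - 1L) %% na + 1L
  faces <- list()
  faces[[1]] <- cbind(1L, ring_id(1, 2:(na + 1)), ring_id(1, 1:na))
  for (r in seq_len(nr - 1)) {
    a <- ring_id(r, 1:na); b <- ring_id(r, 2:(na + 1))
    c_ <- ring_id(r + 1, 1:na); d <- ring_id(r + 1, 2:(na + 1))
    faces[[r + 1]] <- rbind(cbind(a, b, d), cbind(a, d, c_))
  }
  toe_id <- nrow(verts)
  faces[[nr + 1]] <- cbind(toe_id, ring_id(nr, 1:na), ring_id(nr, 2:(na + 1)))
  ff <- do.call(rbind, faces)[, c(1, 3, 2)]        # outward orientation
  surface <- surface_mesh(verts, ff)
  ctr <- colMeans(surface$vertices)
  bone <- surface
  bone$vertices <- sweep(surface$vertices, 2, ctr) * spec$bone_scale
  bone$vertices <- sweep(bone$vertices, 2, ctr, "+")
  stations <- landmark_stations()
  lm_param <- foot_param(stations$t, stations$u, spec)
  # snap to the nearest vertex for index-stable landmarks
  vid <- vapply(seq_len(nrow(lm_param)), function(i) {
    which.min(colSums((t(surface$vertices) - lm_param[i, ])^2))
  }, integer(1))
  if (anyDuplicated(vid)) {
    abort("Mesh resolution too coarse: landmark stations snap to shared vertices.")
  }
  landmarks <- landmark_set(stations$name, points = surface$vertices[vid, ])
  attr(landmarks, "vertex_index") <- vid
  list(surface = surface, bone = bone, landmarks = landmarks)
}

# Parametric stations (t along the foot, u around the ring) of the 16
# canonical landmarks. u = pi/2 dorsal, 3pi/2 plantar, ~pi medial, ~0 lateral
# (right foot convention).
landmark_stations <- function() {
  tibble::tibble(
    name = FOOT_LANDMARKS_16,
    t = c(0.03, 0.10, 0.10, 0.10, 0.07, 0.17, 0.17, 0.38, 0.36, 0.45,
          0.68, 0.50, 0.70, 0.95, 0.96, 0.93),
    u = c(0.95, 1.50, 1.15, 1.85, 0.50, 0.80, 0.20, 1.10, 0.62, 1.92,
          1.30, 0.55, 1.50, 1.20, 0.50, 1.82) * pi
  )
}

#' Smooth ground-truth deformation field
#'
#' An affine component followed by Gaussian radial bumps: each bump displaces
#' points by `disp * exp(-|p - centre|^2 / (2 radius^2))`. Bump magnitudes
#' must stay below `radius / 2`, which keeps the field smoothly invertible
#' (the displacement gradient stays well under 1).
#'
#' @param affine an `affine_transform` (default identity).
#' @param bumps list of bumps, each `list(centre =, radius =, disp =)` in mm.
#' @return A `deformation_field` object.
#' @export
deformation_field <- function(affine = affine_identity(), bumps = list()) {
  for (b in bumps) {
    if (sqrt(sum(b$disp^2)) >= b$radius / 2) {
      abort(sprintf(
        "Bump magnitude %.3g mm violates the invertibility bound radius/2 = %.3g mm.",
        sqrt(sum(b$disp^2)), b$radius / 2))
    }
  }
  structure(list(affine = affine, bumps = bumps), class = "deformation_field")
}

apply_field <- function(field, points) {
  apply_pointmap(points, function(p) {
    out <- sweep(p %*% t(field$affine$M[1:3, 1:3]), 2, field$affine$M[1:3, 4], "+")
    for (b in field$bumps) {
      r2 <- rowSums(sweep(out, 2, as.numeric(b$centre))^2)
      w <- exp(-r2 / (2 * b$radius^2))
      out <- out + outer(w, as.numeric(b$disp))
    }
    out
  })
}

#' Deform a template with a ground-truth field
#'
#' Applies the field to every vertex of the surface and bone, returning the
#' deformed geometry together with the true per-vertex displacements for
#' recovery scoring. Target landmarks are the field images of the template
#' landmarks (they ride on surface vertices).
#'
#' @param template list from [make_template()].
#' @param field a [deformation_field()].
#' @return List `target_surface`, `target_bone`, `target_landmarks`,
#'   `true_displacement` (n-by-3, surface vertices).
#' @export
deform <- function(template, field) {
  tgt <- apply_field(field, template$surface)
  list(
    target_surface = tgt,
    target_bone = apply_field(field, template$bone),
    target_landmarks = apply_field(field, template$landmarks),
    true_displacement = tgt$vertices - template$surface$vertices
  )
}

#' Two-lobed synthetic plantar pressure map
#'
#' A heel lobe and a forefoot lobe of Gaussian pressure on a uniform grid,
#' plus seeded uniform noise of at most `noise` times the larger peak. The
#' global maximum equals the larger stated peak up to that noise.
#'
#' @param length footprint length in mm (default 250).
#' @param width footprint width in mm.
#' @param peak_heel,peak_forefoot lobe peak pressures in kPa (> 0).
#' @param spacing grid spacing in mm.
#' @param noise noise amplitude as a fraction of the larger peak (<= 0.02).
#' @param seed integer seed.
#' @return A [pressure_map()].
#' @export
make_pressure_map <- function(length = 250, width = 100, peak_heel = 121,
                              peak_forefoot = 107, spacing = 5, noise = 0.02,
                              seed = 1L) {
  if (peak_heel <= 0 || peak_forefoot <= 0) abort("Peaks must be positive (kPa).")
  if (noise < 0 || noise > 0.02) abort("`noise` must lie in [0, 0.02].")
  gx <- seq(-width / 2, width / 2, by = spacing)
  gy <- seq(0, length, by = spacing)
  df <- expand.grid(x = gx, y = gy)
  # lobe centres snap to the grid so the stated peaks are attained exactly
  snap <- function(v) spacing * round(v / spacing)
  heel_c <- c(0, snap(0.14 * length))
  fore_c <- c(snap(-0.06 * width), snap(0.72 * length))
  lobe <- function(cx, cy, sx, sy, peak) {
    peak * exp(-((df$x - cx)^2 / (2 * sx^2) + (df$y - cy)^2 / (2 * sy^2)))
  }
  p <- pmax(lobe(heel_c[1], heel_c[2], 0.18 * width, 0.09 * length, peak_heel),
            lobe(fore_c[1], fore_c[2], 0.30 * width, 0.08 * length, peak_forefoot))
  if (noise > 0) {
    eps <- withr_seed(seed, runif(nrow(df), 0, noise * max(peak_heel, peak_forefoot)))
    p <- p + eps
  }
  p[p < 0.02 * max(peak_heel, peak_forefoot)] <- 0   # trim the far tails
  pressure_map(tibble::tibble(x = df$x, y = df$y, pressure = p),
               heel = c(0, 0), toe_direction = c(0, 1))
}
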