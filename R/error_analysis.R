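# Signed surface-to-surface distance analysis. The magnitude of each value is
# the exact Euclidean distance to the closest point on the reference
# triangulation; the sign comes from the angle-weighted pseudo-normal at the
# closest feature (negative = inside / behind the reference orientation),
# which is well defined even for open (trimmed) surfaces.

#' Signed distance from points to a reference surface
#'
#' @param points n-by-3 matrix of query points (mm), or a `surface_mesh`
#'   whose vertices are queried.
#' @param reference a [surface_mesh()] with outward-oriented faces.
#' @return Numeric vector of signed distances in mm (negative inside).
#' @export
signed_distance <- function(points, reference) {
  if (inherits(points, "surface_mesh")) points <- points$vertices
  points <- as.matrix(points)
  if (any(!is.finite(points))) abort("Query points must be finite.")
  validate_surface_mesh(reference)
  if (n_faces(reference) == 0 || mesh_area(reference) <= 0) {
    abort("Reference surface is degenerate (no faces or zero total area).")
  }
  cp <- cpp_closest_point(points, reference$vertices, reference$faces)
  normal_at_closest(cp, reference, points)
}

# Resolve the pseudo-normal at each closest feature and apply the sign.
normal_at_closest <- function(cp, reference, points) {
  fn <- face_normals(reference)
  vn <- vertex_pseudo_normals(reference)
  en <- edge_pseudo_normals(reference)
  f <- reference$faces
  n <- matrix(0, nrow(points), 3)
  feat <- cp$feature
  tri <- cp$tri
  face_rows <- feat == 0L
  if (any(face_rows)) n[face_rows, ] <- fn[tri[face_rows], , drop = FALSE]
  vert_rows <- feat %in% 1:3
  if (any(vert_rows)) {
    vid <- f[cbind(tri[vert_rows], feat[vert_rows])]
    n[vert_rows, ] <- vn[vid, , drop = FALSE]
  }
  edge_rows <- feat %in% 4:6
  if (any(edge_rows)) {
    k1 <- c(1L, 2L, 3L)[feat[edge_rows] - 3L]
    k2 <- c(2L, 3L, 1L)[feat[edge_rows] - 3L]
    i <- f[cbind(tri[edge_rows], k1)]
    j <- f[cbind(tri[edge_rows], k2)]
    key <- paste(pmin(i, j), pmax(i, j), sep = "_")
    n[edge_rows, ] <- en[key, , drop = FALSE]
  }
  offset <- points - cp$closest
  s <- rowSums(offset * n)
  ifelse(cp$dist == 0, 0, ifelse(s < 0, -cp$dist, cp$dist))
}

#' Per-vertex geometric error map between a scaled and a target surface
#'
#' Evaluates the signed distance of every vertex of `scaled` against `target`
#' as the reference surface and stores it in the scalar channel. Negative
#' values mean the scaled surface lies inside the target.
#'
#' @param scaled the evaluated (morphed/scaled) `surface_mesh`.
#' @param target the reference `surface_mesh` (e.g. the scanned foot).
#' @return `scaled` with class `error_map` prepended and the signed distance
#'   (mm) in `$scalar`.
#' @export
error_map <- function(scaled, target) {
  d <- signed_distance(scaled$vertices, target)
  out <- scaled
  out$scalar <- d
  class(out) <- unique(c("error_map", class(out)))
  out
}

#' Positive/negative error summary of an error map
#'
#' Means are taken over the strictly positive and strictly negative values
#' separately (zeros belong to neither), matching how geometric morphing
#' errors are conventionally reported; `max_positive` / `max_negative` are
#' the extreme values.
#'
#' @param map an `error_map` (or any `surface_mesh` with a scalar channel),
#'   or a bare numeric vector of signed distances.
#' @return A one-row tibble of class `error_stats`: `mean_positive`,
#'   `mean_negative`, `max_positive`, `max_negative`, `mean_abs`,
#'   `n_positive`, `n_negative`, `n_zero` (mm).
#' @export
error_stats <- function(map) {
  v <- if (is.numeric(map)) map else map$scalar
  if (is.null(v) || length(v) == 0) abort("Error map is empty (no scalar values).")
  if (any(!is.finite(v))) abort("Error map contains non-finite values.")
  pos <- v[v > 0]; neg <- v[v < 0]
  out <- tibble::tibble(
    mean_positive = if (length(pos)) mean(pos) else 0,
    mean_negative = if (length(neg)) mean(neg) else 0,
    max_positive = if (length(pos)) max(pos) else 0,
    max_negative = if (length(neg)) min(neg) else 0,
    mean_abs = mean(abs(v)),
    n_positive = length(pos),
    n_negative = length(neg),
    n_zero = sum(v == 0)
  )
  class(out) <- c("error_stats", class(out))
  out
}

#' @export
tidy.error_map <- function(x, ...) {
  tibble::tibble(
    vertex = seq_len(n_vertices(x)),
    x = x$vertices[, 1], y = x$vertices[, 2], z = x$vertices[, 3],
    signed_distance = x$scalar
  )
}

#' @export
glance.error_map <- function(x, ...) {
  tibble::as_tibble(error_stats(x))
}

#' Plot an error map
#'
#' Projects the mesh vertices onto a coordinate plane and colours them by
#' signed distance, a quick visual analogue of rendered 3D error maps.
#'
#' @param object an `error_map`.
#' @param plane `"xy"`, `"xz"` or `"yz"` projection plane.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.error_map <- function(object, plane = c("xy", "xz", "yz"), ...) {
  plane <- match.arg(plane)
  ax <- strsplit(plane, "")[[1]]
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]],
                                   colour = .data$signed_distance)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_gradient2(low = "#2166ac", mid = "grey90",
                                    high = "#b2182b", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "signed\ndistance (mm)",
                  x = paste0(ax[1], " (mm)"), y = paste0(ax[2], " (mm)"),
                  title = "Geometric error map") +
    ggplot2::theme_minimal()
}
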