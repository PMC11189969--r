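# Triangle surface mesh container. Coordinates are millimetres in a
# right-handed frame with +z superior (vertical) and +y anterior (toes).

#' Create a triangle surface mesh
#'
#' The basic geometry carrier of the package: a vertex matrix in millimetres
#' and a face matrix of vertex-index triples. An optional per-vertex scalar
#' channel carries quantities such as signed-distance error maps.
#'
#' @param vertices numeric matrix (or data frame) with 3 columns, one row per
#'   vertex, in mm.
#' @param faces integer matrix with 3 columns of 1-based vertex indices.
#' @param scalar optional numeric vector, one value per vertex (mm for error
#'   maps).
#' @return An object of class `surface_mesh` with elements `vertices`,
#'   `faces` and (optionally) `scalar`.
#' @examples
#' tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                     matrix(c(1L, 2L, 3L), nrow = 1))
#' n_vertices(tri)
#' @export
surface_mesh <- function(vertices, faces, scalar = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) {
    abort("`vertices` must have exactly 3 columns (x, y, z in mm).")
  }
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) {
    abort("`faces` must have exactly 3 columns of vertex indices.")
  }
  dimnames(vertices) <- NULL
  dimnames(faces) <- NULL
  m <- structure(list(vertices = vertices, faces = faces),
                 class = "surface_mesh")
  if (!is.null(scalar)) m$scalar <- as.double(scalar)
  validate_surface_mesh(m)
  m
}

validate_surface_mesh <- function(m) {
  nv <- nrow(m$vertices)
  if (nv > 0 && any(!is.finite(m$vertices))) {
    abort("Mesh vertices contain non-finite coordinates.")
  }
  if (nrow(m$faces) > 0) {
    if (any(m$faces < 1L) || any(m$faces > nv)) {
      abort(sprintf("Face indices out of range [1, %d].", nv))
    }
    degen <- m$faces[, 1] == m$faces[, 2] | m$faces[, 2] == m$faces[, 3] |
      m$faces[, 1] == m$faces[, 3]
    if (any(degen)) {
      abort(sprintf("%d face(s) repeat a vertex index.", sum(degen)))
    }
  }
  if (!is.null(m$scalar) && length(m$scalar) != nv) {
    abort("Per-vertex scalar channel must have exactly one value per vertex.")
  }
  invisible(m)
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces%s\n",
              n_vertices(x), n_faces(x),
              if (is.null(x$scalar)) "" else ", per-vertex scalar"))
  if (n_vertices(x) > 0) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] mm\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

#' @rdname surface_mesh
#' @param m,x a `surface_mesh`.
#' @export
n_vertices <- function(m) nrow(m$vertices)

#' @rdname surface_mesh
#' @export
n_faces <- function(m) nrow(m$faces)

#' Total surface area of a mesh (mm^2)
#' @param m a `surface_mesh`.
#' @return Scalar area in mm^2.
#' @export
mesh_area <- function(m) {
  if (n_faces(m) == 0) return(0)
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  b <- m$vertices[m$faces[, 2], , drop = FALSE]
  c_ <- m$vertices[m$faces[, 3], , drop = FALSE]
  cr <- row_cross(b - a, c_ - a)
  sum(sqrt(rowSums(cr^2))) / 2
}

row_cross <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

# Unit face normals; zero-area faces get a zero normal.
face_normals <- function(m) {
  a <- m$vertices[m$faces[, 1], , drop = FALSE]
  cr <- row_cross(m$vertices[m$faces[, 2], , drop = FALSE] - a,
                  m$vertices[m$faces[, 3], , drop = FALSE] - a)
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  cr / len
}

# Angle-weighted vertex pseudo-normals (Baerentzen-Aanaes), used for the sign
# of point-to-surface distances on open surfaces.
vertex_pseudo_normals <- function(m) {
  fn <- face_normals(m)
  vn <- matrix(0, n_vertices(m), 3)
  v <- m$vertices
  f <- m$faces
  for (k in 1:3) {
    i0 <- f[, k]
    i1 <- f[, if (k == 3) 1 else k + 1]
    i2 <- f[, if (k == 1) 3 else k - 1]
    e1 <- v[i1, , drop = FALSE] - v[i0, , drop = FALSE]
    e2 <- v[i2, , drop = FALSE] - v[i0, , drop = FALSE]
    n1 <- sqrt(rowSums(e1^2)); n2 <- sqrt(rowSums(e2^2))
    cosang <- pmin(1, pmax(-1, rowSums(e1 * e2) / pmax(n1 * n2, 1e-300)))
    ang <- acos(cosang)
    w <- fn * ang
    for (ax in 1:3) {
      vn[, ax] <- vn[, ax] + unname(tapply_add(i0, w[, ax], n_vertices(m)))
    }
  }
  len <- sqrt(rowSums(vn^2))
  len[len == 0] <- 1
  vn / len
}

tapply_add <- function(idx, val, n) {
  out <- numeric(n)
  agg <- rowsum(val, idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# Edge pseudo-normals: named list keyed "i_j" (i < j), sum of adjacent face
# normals (unnormalised direction is fine for sign tests).
edge_pseudo_normals <- function(m) {
  fn <- face_normals(m)
  f <- m$faces
  keys <- character(0)
  e_i <- c(pmin(f[, 1], f[, 2]), pmin(f[, 2], f[, 3]), pmin(f[, 3], f[, 1]))
  e_j <- c(pmax(f[, 1], f[, 2]), pmax(f[, 2], f[, 3]), pmax(f[, 3], f[, 1]))
  keys <- paste(e_i, e_j, sep = "_")
  fidx <- rep(seq_len(nrow(f)), 3)
  en <- rowsum(fn[fidx, , drop = FALSE], keys)
  en
}

#' Weld duplicate vertices
#'
#' Merges vertices closer than `tol` (by coordinate rounding) and remaps
#' faces; used when reading STL files, which store independent triangles.
#'
#' @param m a `surface_mesh`.
#' @param tol welding tolerance in mm.
#' @return A `surface_mesh` with duplicates merged.
#' @export
weld_vertices <- function(m, tol = 1e-6) {
  if (n_vertices(m) == 0) return(m)
  key <- apply(round(m$vertices / tol), 1, paste, collapse = "_")
  first <- !duplicated(key)
  new_id <- match(key, key[first])
  keep <- m$vertices[first, , drop = FALSE]
  faces <- matrix(new_id[m$faces], ncol = 3)
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  surface_mesh(keep, faces[!degen, , drop = FALSE],
               scalar = if (is.null(m$scalar)) NULL else m$scalar[first])
}

#' @export
tidy.surface_mesh <- function(x, ...) {
  out <- tibble::tibble(
    vertex = seq_len(n_vertices(x)),
    x = x$vertices[, 1], y = x$vertices[, 2], z = x$vertices[, 3]
  )
  if (!is.null(x$scalar)) out$scalar <- x$scalar
  out
}

#' @export
glance.surface_mesh <- function(x, ...) {
  bb <- if (n_vertices(x)) apply(x$vertices, 2, range) else matrix(NA_real_, 2, 3)
  tibble::tibble(
    n_vertices = n_vertices(x), n_faces = n_faces(x),
    area_mm2 = mesh_area(x),
    bbox_diag_mm = sqrt(sum((bb[2, ] - bb[1, ])^2))
  )
}
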