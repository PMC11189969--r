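# Surface mesh file I/O: STL (ASCII + binary), PLY (ASCII, with optional
# per-vertex "quality" scalar) and OBJ. All coordinates in mm.

format_from_path <- function(path, format = NULL) {
  if (!is.null(format)) return(tolower(format))
  tolower(tools::file_ext(path))
}

#' Read a triangle surface mesh
#'
#' Supports STL (ASCII and binary; triangle soup is welded), PLY (ASCII,
#' reads a per-vertex float `quality` property into the scalar channel) and
#' OBJ (quad/polygon faces are fan-triangulated around their first vertex,
#' with a notice).
#'
#' @param path file path.
#' @param format `"stl"`, `"ply"` or `"obj"`; inferred from the extension
#'   when `NULL`.
#' @return A [surface_mesh()].
#' @export
read_surface <- function(path, format = NULL) {
  if (!file.exists(path)) abort(sprintf("Cannot read mesh: '%s' does not exist.", path))
  fmt <- format_from_path(path, format)
  switch(fmt,
    stl = read_stl(path),
    ply = read_ply(path),
    obj = read_obj(path),
    abort(sprintf("Unsupported mesh format '%s' (use STL, PLY or OBJ).", fmt))
  )
}

#' Write a triangle surface mesh
#'
#' @param mesh a [surface_mesh()].
#' @param path output file path.
#' @param format `"stl"`, `"ply"` or `"obj"`; inferred from the extension
#'   when `NULL`. STL can be written `binary = TRUE`.
#' @param include_scalar write the per-vertex scalar channel (PLY only,
#'   as a float `quality` property).
#' @param binary write binary STL instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path, format = NULL, include_scalar = FALSE,
                          binary = FALSE) {
  validate_surface_mesh(mesh)
  if (n_vertices(mesh) == 0 || n_faces(mesh) == 0) {
    abort("Refusing to write an empty mesh (no vertices or no faces).")
  }
  fmt <- format_from_path(path, format)
  if (include_scalar) {
    if (is.null(mesh$scalar)) abort("`include_scalar = TRUE` but the mesh has no scalar channel.")
    if (fmt != "ply") {
      abort(sprintf("Format '%s' cannot carry a per-vertex scalar; write PLY instead.", fmt))
    }
  }
  switch(fmt,
    stl = if (binary) write_stl_binary(mesh, path) else write_stl_ascii(mesh, path),
    ply = write_ply(mesh, path, include_scalar = include_scalar),
    obj = write_obj(mesh, path),
    abort(sprintf("Unsupported mesh format '%s' (use STL, PLY or OBJ).", fmt))
  )
  invisible(path)
}

# ---- STL ----

is_binary_stl <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  head <- readBin(con, "raw", 84)
  if (length(head) < 84) return(FALSE)
  ntri <- readBin(head[81:84], "integer", 1, size = 4, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  isTRUE(file.size(path) == expected)
}

read_stl <- function(path) {
  if (is_binary_stl(path)) read_stl_binary(path) else read_stl_ascii(path)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) == 0 || length(vl) %% 3 != 0) {
    abort(sprintf("'%s' is not a valid ASCII STL (vertex count %d not a multiple of 3).",
                  path, length(vl)))
  }
  coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  if (any(!is.finite(coords))) abort(sprintf("Non-finite vertex coordinate in '%s'.", path))
  ntri <- nrow(coords) / 3
  soup <- surface_mesh(coords, matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE))
  weld_vertices(soup)
}

read_stl_binary <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- readBin(con, "raw", 50 * ntri)
  idx <- rep(seq_len(ntri) - 1L, each = 36) * 50L +
    rep(12L + seq_len(36), ntri)  # skip 12-byte normal, take 36 vertex bytes
  vbytes <- rec[idx]
  coords <- readBin(vbytes, "numeric", n = 9 * ntri, size = 4, endian = "little")
  coords <- matrix(coords, ncol = 3, byrow = TRUE)
  soup <- surface_mesh(coords, matrix(seq_len(3 * ntri), ncol = 3, byrow = TRUE))
  weld_vertices(soup)
}

fmt_num <- function(x) formatC(x, format = "g", digits = 9)

write_stl_ascii <- function(mesh, path) {
  fn <- face_normals(mesh)
  f <- mesh$faces
  v <- mesh$vertices
  con <- file(path, "w"); on.exit(close(con))
  writeLines("solid footmorph", con)
  tri_txt <- vapply(seq_len(nrow(f)), function(i) {
    p <- v[f[i, ], , drop = FALSE]
    paste0(
      " facet normal ", paste(fmt_num(fn[i, ]), collapse = " "), "\n",
      "  outer loop\n",
      paste(vapply(1:3, function(k) {
        paste0("   vertex ", paste(fmt_num(p[k, ]), collapse = " "))
      }, character(1)), collapse = "\n"), "\n",
      "  endloop\n endfacet")
  }, character(1))
  writeLines(tri_txt, con)
  writeLines("endsolid footmorph", con)
}

write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(as.raw(rep(0L, 80)), con)
  writeBin(as.integer(n_faces(mesh)), con, size = 4, endian = "little")
  fn <- face_normals(mesh)
  v <- mesh$vertices
  f <- mesh$faces
  for (i in seq_len(nrow(f))) {
    writeBin(as.numeric(c(fn[i, ], t(v[f[i, ], ]))), con, size = 4,
             endian = "little")
    writeBin(as.raw(c(0, 0)), con)
  }
}

# ---- PLY (ASCII) ----

write_ply <- function(mesh, path, include_scalar = FALSE) {
  con <- file(path, "w"); on.exit(close(con))
  nv <- n_vertices(mesh); nf <- n_faces(mesh)
  hdr <- c("ply", "format ascii 1.0", "comment footmorph",
           sprintf("element vertex %d", nv),
           "property float x", "property float y", "property float z")
  if (include_scalar) hdr <- c(hdr, "property float quality")
  hdr <- c(hdr, sprintf("element face %d", nf),
           "property list uchar int vertex_indices", "end_header")
  writeLines(hdr, con)
  vm <- mesh$vertices
  if (include_scalar) vm <- cbind(vm, mesh$scalar)
  writeLines(apply(vm, 1, function(r) paste(fmt_num(r), collapse = " ")), con)
  writeLines(paste("3", mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                   mesh$faces[, 3] - 1L), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply") {
    abort(sprintf("'%s' is not a PLY file.", path))
  }
  endh <- match("end_header", trimws(lines))
  if (is.na(endh)) abort(sprintf("PLY '%s': no end_header.", path))
  hdr <- trimws(lines[seq_len(endh)])
  if (!any(grepl("^format ascii", hdr))) {
    abort(sprintf("PLY '%s': only ASCII PLY is supported.", path))
  }
  nv <- nf <- 0L
  vprops <- character(0)
  cur <- ""
  for (h in hdr) {
    tok <- strsplit(h, "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      if (cur == "vertex") nv <- as.integer(tok[3])
      if (cur == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && cur == "vertex" && tok[2] != "list") {
      vprops <- c(vprops, tok[3])
    }
  }
  body <- lines[(endh + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  vrows <- body[seq_len(nv)]
  vmat <- do.call(rbind, lapply(strsplit(trimws(vrows), "\\s+"), as.numeric))
  colnames(vmat) <- vprops[seq_len(ncol(vmat))]
  frows <- body[nv + seq_len(nf)]
  faces <- do.call(rbind, lapply(strsplit(trimws(frows), "\\s+"), function(x) {
    n <- as.integer(x[1])
    if (n != 3L) abort("PLY faces must be triangles.")
    as.integer(x[2:4]) + 1L
  }))
  scalar <- if ("quality" %in% colnames(vmat)) vmat[, "quality"] else NULL
  surface_mesh(vmat[, c("x", "y", "z"), drop = FALSE], faces, scalar = scalar)
}

# ---- OBJ ----

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(r) {
    paste("v", paste(fmt_num(r), collapse = " "))
  }), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0) abort(sprintf("OBJ '%s': no vertices.", path))
  verts <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(x) as.numeric(x[2:4])))
  polys <- lapply(strsplit(fl, "\\s+"), function(x) {
    as.integer(vapply(strsplit(x[-1], "/"), `[`, character(1), 1))
  })
  n_gt3 <- sum(lengths(polys) > 3)
  if (n_gt3 > 0) {
    inform(sprintf("OBJ '%s': fan-triangulated %d polygon face(s).", path, n_gt3))
  }
  faces <- do.call(rbind, lapply(polys, function(p) {
    if (length(p) < 3) abort(sprintf("OBJ '%s': face with fewer than 3 vertices.", path))
    # deterministic fan anchored at the first vertex
    cbind(p[1], p[seq(2, length(p) - 1)], p[seq(3, length(p))])
  }))
  surface_mesh(verts, faces)
}

# ---- Trimming ----

#' Trim a surface mesh with a half-space
#'
#' Keeps the part of the mesh on the side `dot(v, plane_normal) <= plane_offset`;
#' faces crossing the plane are clipped, creating new vertices exactly on the
#' plane. Used to reproduce scan preprocessing such as removing everything more
#' than 65 mm above the lowest plantar point (`plane_normal = c(0, 0, 1)`,
#' `plane_offset = min(z) + 65`).
#'
#' @param mesh a [surface_mesh()].
#' @param plane_normal length-3 vector (normalised internally); points toward
#'   the discarded half-space.
#' @param plane_offset signed distance of the plane from the origin along the
#'   normal, in mm.
#' @return A clipped `surface_mesh`. If the whole mesh is already on the kept
#'   side, the input is returned unchanged with a notice.
#' @export
trim_surface <- function(mesh, plane_normal, plane_offset) {
  validate_surface_mesh(mesh)
  n <- as.numeric(plane_normal)
  nl <- sqrt(sum(n^2))
  if (!is.finite(nl) || nl == 0) abort("`plane_normal` must be a nonzero vector.")
  n <- n / nl
  d <- drop(mesh$vertices %*% n) - plane_offset  # > 0 means discard side
  tol <- 1e-9
  if (all(d <= tol)) {
    inform("Trim plane does not cut the mesh; returning it unchanged.")
    return(mesh)
  }
  if (all(d >= -tol)) {
    abort("Trim plane removes the entire mesh.")
  }
  keep_v <- d <= tol
  v <- mesh$vertices
  sc <- mesh$scalar
  new_pts <- list()
  new_sc <- numeric(0)
  edge_cache <- new.env(parent = emptyenv())
  nv0 <- nrow(v)
  clip_edge <- function(i, j) {
    key <- if (i < j) paste0(i, "_", j) else paste0(j, "_", i)
    hit <- edge_cache[[key]]
    if (!is.null(hit)) return(hit)
    t_ <- d[i] / (d[i] - d[j])
    p <- v[i, ] + t_ * (v[j, ] - v[i, ])
    new_pts[[length(new_pts) + 1L]] <<- p
    if (!is.null(sc)) new_sc[length(new_sc) + 1L] <<- sc[i] + t_ * (sc[j] - sc[i])
    id <- nv0 + length(new_pts)
    edge_cache[[key]] <- id
    id
  }
  out_faces <- vector("list", nrow(mesh$faces))
  for (fi in seq_len(nrow(mesh$faces))) {
    tri <- mesh$faces[fi, ]
    inside <- d[tri] <= tol
    ni <- sum(inside)
    if (ni == 0L) next
    if (ni == 3L) { out_faces[[fi]] <- matrix(tri, 1); next }
    # rotate so pattern starts at the first kept vertex
    ord <- tri
    ins <- inside
    while (!ins[1]) { ord <- ord[c(2, 3, 1)]; ins <- ins[c(2, 3, 1)] }
    if (ni == 1L) {
      a <- ord[1]; b <- ord[2]; c_ <- ord[3]
      ab <- clip_edge(a, b); ac <- clip_edge(a, c_)
      out_faces[[fi]] <- matrix(c(a, ab, ac), 1)
    } else {
      # two kept: rotate so the two kept vertices are first
      while (!(ins[1] && ins[2])) { ord <- ord[c(2, 3, 1)]; ins <- ins[c(2, 3, 1)] }
      a <- ord[1]; b <- ord[2]; c_ <- ord[3]
      bc <- clip_edge(b, c_); ac <- clip_edge(a, c_)
      out_faces[[fi]] <- rbind(c(a, b, bc), c(a, bc, ac))
    }
  }
  faces <- do.call(rbind, out_faces)
  allv <- rbind(v, do.call(rbind, new_pts))
  if (!is.null(sc)) sc <- c(sc, new_sc)
  used <- sort(unique(as.integer(faces)))
  remap <- integer(nrow(allv)); remap[used] <- seq_along(used)
  surface_mesh(allv[used, , drop = FALSE],
               matrix(remap[faces], ncol = 3),
               scalar = if (is.null(sc)) NULL else sc[used])
}
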