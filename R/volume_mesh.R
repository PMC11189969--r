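# Volume mesh container for FE preprocessing: tet4 / hex8 solids and tri3
# membrane elements over one node block. Tet generation from morphed
# surfaces is delegated to external meshers; this type carries their output
# (or the structured blocks below) into the deck writer.

#' Create a volume mesh
#'
#' @param nodes n-by-3 node coordinate matrix (mm).
#' @param tet4 optional m-by-4 integer connectivity (1-based).
#' @param hex8 optional m-by-8 integer connectivity.
#' @param tri3 optional m-by-3 integer connectivity (membrane faces).
#' @param node_sets named list of integer node-id vectors.
#' @return An object of class `volume_mesh`.
#' @export
volume_mesh <- function(nodes, tet4 = NULL, hex8 = NULL, tri3 = NULL,
                        node_sets = list()) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  if (ncol(nodes) != 3) abort("`nodes` must have 3 columns.")
  check_conn <- function(conn, width, what) {
    if (is.null(conn)) return(NULL)
    conn <- as.matrix(conn)
    storage.mode(conn) <- "integer"
    if (ncol(conn) != width) abort(sprintf("`%s` must have %d columns.", what, width))
    if (nrow(conn) > 0 && (any(conn < 1) || any(conn > nrow(nodes)))) {
      abort(sprintf("`%s` connectivity indices out of range.", what))
    }
    conn
  }
  ns <- lapply(node_sets, as.integer)
  if (length(ns) && any(unlist(ns) < 1 | unlist(ns) > nrow(nodes))) {
    abort("Node-set ids out of range.")
  }
  structure(list(nodes = nodes,
                 tet4 = check_conn(tet4, 4, "tet4"),
                 hex8 = check_conn(hex8, 8, "hex8"),
                 tri3 = check_conn(tri3, 3, "tri3"),
                 node_sets = ns),
            class = "volume_mesh")
}

n_elements <- function(vm) {
  sum(vapply(vm[c("tet4", "hex8", "tri3")],
             function(x) if (is.null(x)) 0L else nrow(x), integer(1)))
}

#' @export
print.volume_mesh <- function(x, ...) {
  cat(sprintf("<volume_mesh> %d nodes; tet4 %d, hex8 %d, tri3 %d\n",
              nrow(x$nodes),
              if (is.null(x$tet4)) 0L else nrow(x$tet4),
              if (is.null(x$hex8)) 0L else nrow(x$hex8),
              if (is.null(x$tri3)) 0L else nrow(x$tri3)))
  invisible(x)
}

#' Structured block volume mesh
#'
#' Builds a rectangular block of `nx * ny * nz` cells as hex8 elements, or
#' as tet4 elements via the deterministic 6-tet splitting of each cell.
#' Useful for ground plates and hermetic test fixtures.
#'
#' @param nx,ny,nz cell counts per axis (>= 1).
#' @param size length-3 cell size in mm (or scalar).
#' @param origin length-3 corner coordinate (mm).
#' @param type `"hex"` or `"tet"`.
#' @return A [volume_mesh()].
#' @export
make_block_volume <- function(nx = 2, ny = 2, nz = 1, size = 5,
                              origin = c(0, 0, 0), type = c("hex", "tet")) {
  type <- match.arg(type)
  size <- rep_len(as.numeric(size), 3)
  nid <- function(i, j, k) {
    (k * (ny + 1) + j) * (nx + 1) + i + 1L  # 0-based i,j,k -> 1-based id
  }
  grid <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  ord <- order(grid$k, grid$j, grid$i)
  grid <- grid[ord, ]
  nodes <- cbind(origin[1] + grid$i * size[1],
                 origin[2] + grid$j * size[2],
                 origin[3] + grid$k * size[3])
  cells <- expand.grid(i = 0:(nx - 1), j = 0:(ny - 1), k = 0:(nz - 1))
  hex <- t(apply(cells, 1, function(c_) {
    i <- c_[1]; j <- c_[2]; k <- c_[3]
    c(nid(i, j, k), nid(i + 1, j, k), nid(i + 1, j + 1, k), nid(i, j + 1, k),
      nid(i, j, k + 1), nid(i + 1, j, k + 1), nid(i + 1, j + 1, k + 1),
      nid(i, j + 1, k + 1))
  }))
  if (type == "hex") return(volume_mesh(nodes, hex8 = hex))
  # 6-tet split of each hexahedron (corner-consistent, deterministic)
  split6 <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  tets <- do.call(rbind, lapply(seq_len(nrow(hex)), function(e) {
    matrix(hex[e, ][t(split6)], ncol = 4, byrow = TRUE)
  }))
  volume_mesh(nodes, tet4 = tets)
}

#' Mesh size report
#'
#' Element counts, median edge length and tet aspect-ratio range (longest
#' edge over shortest altitude-proxy: longest/shortest edge) of a volume
#' mesh, for checking external meshes against per-part target sizes.
#'
#' @param vm a [volume_mesh()].
#' @return One-row tibble: `n_tet4`, `n_hex8`, `n_tri3`,
#'   `median_edge_mm`, `tet_aspect_min`, `tet_aspect_max`.
#' @export
mesh_size_report <- function(vm) {
  edges <- NULL
  add_edges <- function(conn, pairs) {
    if (is.null(conn) || nrow(conn) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(p) {
      cbind(conn[, pairs[p, 1]], conn[, pairs[p, 2]])
    }))
  }
  tet_pairs <- t(utils::combn(4, 2))
  hex_pairs <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1), c(5, 6), c(6, 7),
                     c(7, 8), c(8, 5), c(1, 5), c(2, 6), c(3, 7), c(4, 8))
  tri_pairs <- rbind(c(1, 2), c(2, 3), c(3, 1))
  edges <- rbind(add_edges(vm$tet4, tet_pairs),
                 add_edges(vm$hex8, hex_pairs),
                 add_edges(vm$tri3, tri_pairs))
  elen <- if (is.null(edges)) numeric(0) else {
    sqrt(rowSums((vm$nodes[edges[, 1], , drop = FALSE] -
                    vm$nodes[edges[, 2], , drop = FALSE])^2))
  }
  aspect <- c(NA_real_, NA_real_)
  if (!is.null(vm$tet4) && nrow(vm$tet4) > 0) {
    ar <- vapply(seq_len(nrow(vm$tet4)), function(e) {
      p <- vm$nodes[vm$tet4[e, ], , drop = FALSE]
      el <- sqrt(rowSums((p[tet_pairs[, 1], , drop = FALSE] -
                            p[tet_pairs[, 2], , drop = FALSE])^2))
      max(el) / min(el)
    }, numeric(1))
    aspect <- range(ar)
  }
  tibble::tibble(
    n_tet4 = if (is.null(vm$tet4)) 0L else nrow(vm$tet4),
    n_hex8 = if (is.null(vm$hex8)) 0L else nrow(vm$hex8),
    n_tri3 = if (is.null(vm$tri3)) 0L else nrow(vm$tri3),
    median_edge_mm = if (length(elen)) stats::median(elen) else NA_real_,
    tet_aspect_min = aspect[1], tet_aspect_max = aspect[2]
  )
}
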