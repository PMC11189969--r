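# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# Small, fast template for I/O and geometry tests.
small_template <- function() {
  cached("small_template", make_template(fixture_spec(n_rings = 16, n_around = 12)))
}

# Full-resolution template + benchmark deformation for morphing tests.
bench_template <- function() {
  cached("bench_template", make_template())
}

bench_target <- function() {
  cached("bench_target", deform(bench_template(), benchmark_field()))
}

# Closed unit cube: 8 vertices, 12 outward-oriented triangles.
unit_cube <- function() {
  v <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  f <- rbind(c(1, 3, 2), c(2, 3, 4), c(5, 6, 7), c(6, 8, 7),
             c(1, 2, 5), c(2, 6, 5), c(3, 7, 4), c(4, 7, 8),
             c(1, 5, 3), c(3, 5, 7), c(2, 4, 6), c(4, 8, 6))
  surface_mesh(v, f)
}

# Flat triangulated square in the z = 0 plane, normals +z, side `side`,
# n x n cells.
flat_square <- function(side = 10, n = 5) {
  g <- seq(0, side, length.out = n + 1)
  grid <- expand.grid(x = g, y = g)
  id <- function(i, j) (j - 1L) * (n + 1L) + i
  f <- do.call(rbind, lapply(seq_len(n), function(j) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(c(id(i, j), id(i + 1, j), id(i + 1, j + 1)),
            c(id(i, j), id(i + 1, j + 1), id(i, j + 1)))
    }))
  }))
  surface_mesh(cbind(grid$x, grid$y, 0), f)
}

# Pure-R brute-force unsigned point-to-mesh distance: the independent oracle
# for the compiled closest-point query. Loops over every triangle.
brute_force_distance <- function(points, mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  pt_tri <- function(p, a, b, c) {
    # closest point on triangle by direct projection + edge/vertex clamping
    ab <- b - a; ac <- c - a; ap <- p - a
    d1 <- sum(ab * ap); d2 <- sum(ac * ap)
    if (d1 <= 0 && d2 <= 0) return(sum((p - a)^2))
    bp <- p - b
    d3 <- sum(ab * bp); d4 <- sum(ac * bp)
    if (d3 >= 0 && d4 <= d3) return(sum((p - b)^2))
    vc <- d1 * d4 - d3 * d2
    if (vc <= 0 && d1 >= 0 && d3 <= 0) {
      t <- d1 / (d1 - d3)
      return(sum((p - (a + t * ab))^2))
    }
    cp <- p - c
    d5 <- sum(ab * cp); d6 <- sum(ac * cp)
    if (d6 >= 0 && d5 <= d6) return(sum((p - c)^2))
    vb <- d5 * d2 - d1 * d6
    if (vb <= 0 && d2 >= 0 && d6 <= 0) {
      t <- d2 / (d2 - d6)
      return(sum((p - (a + t * ac))^2))
    }
    va <- d3 * d6 - d5 * d4
    if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
      t <- (d4 - d3) / ((d4 - d3) + (d5 - d6))
      return(sum((p - (b + t * (c - b)))^2))
    }
    den <- va + vb + vc
    q <- a + ab * (vb / den) + ac * (vc / den)
    sum((p - q)^2)
  }
  apply(as.matrix(points), 1, function(p) {
    sqrt(min(vapply(seq_len(nrow(f)), function(k) {
      pt_tri(p, v[f[k, 1], ], v[f[k, 2], ], v[f[k, 3], ])
    }, numeric(1))))
  })
}

# Tiny four-part FE geometry bundle for deck tests.
fe_bundle <- function() {
  cached("fe_bundle", {
    tpl <- small_template()
    list(
      merged_bone = make_block_volume(2, 3, 1, size = 10, type = "tet"),
      bulk_soft_tissue = make_block_volume(3, 4, 2, size = 12,
                                           origin = c(-5, -5, -2), type = "tet"),
      skin = make_skin_layer(tpl$surface, 2),
      ground_plate = make_block_volume(4, 4, 1, size = 20,
                                       origin = c(-20, -20, -25), type = "hex")
    )
  })
}

expect_mesh_equal <- function(a, b, tol = 1e-6) {
  expect_equal(n_faces(a), n_faces(b))
  expect_equal(n_vertices(a), n_vertices(b))
  # vertex order may differ (welding); compare sorted coordinate multisets
  expect_lt(max(abs(apply(a$vertices, 2, sort) - apply(b$vertices, 2, sort))), tol)
}
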