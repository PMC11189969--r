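# FE model assembly and Abaqus-INP-dialect deck writing. The contract ends
# at a valid, deterministic input deck: solving, contact resolution and
# result extraction are external.

PART_NAMES <- c("merged_bone", "bulk_soft_tissue", "skin", "ground_plate")

#' Build a skin membrane layer over a bulk surface
#'
#' Creates one 3-node membrane (M3D3-style) element per triangle of the bulk
#' outer surface, sharing the surface nodes (no new nodes, no geometric
#' offset) and carrying the thickness as a section property.
#'
#' @param bulk_surface a [surface_mesh()] — the outer surface of the bulk
#'   soft tissue part. Must be manifold (every edge in at most 2 faces).
#' @param thickness membrane thickness in mm (> 0); default 2.
#' @return A [volume_mesh()] of tri3 elements with attribute `thickness`.
#' @export
make_skin_layer <- function(bulk_surface, thickness = 2) {
  validate_surface_mesh(bulk_surface)
  if (!is.finite(thickness) || thickness <= 0) {
    abort("Membrane thickness must be positive (mm).")
  }
  f <- bulk_surface$faces
  ekey <- paste(pmin(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])),
                pmax(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1])),
                sep = "_")
  if (any(table(ekey) > 2)) {
    abort("Bulk surface is non-manifold (an edge is shared by > 2 faces).")
  }
  vm <- volume_mesh(bulk_surface$vertices, tri3 = f)
  attr(vm, "thickness") <- thickness
  vm
}

default_materials <- function() {
  list(merged_bone = linear_elastic(),
       bulk_soft_tissue = polynomial_n2(),
       skin = ogden_n1(),
       ground_plate = linear_elastic(youngs_modulus = 17000, poissons_ratio = 0.1))
}

#' Assemble the finite-element model specification
#'
#' Populates the model with the standard balanced-standing configuration:
#' linear-elastic merged bone (C3D4), polynomial hyperelastic bulk soft
#' tissue (C3D4), 2-mm Ogden skin membrane (M3D3), linear-elastic ground
#' plate (C3D8); foot-plate friction coefficient 0.6; a vertical plate force
#' of half the body weight and an Achilles tendon force of a quarter of the
#' body weight; the plate fixed in all but the vertical direction and the
#' proximal tibia/fibula/skin sections fully fixed. Target element sizes are
#' 3 mm for bone and 5 mm for soft tissue and plate. `overrides` are applied
#' last and recorded in the provenance.
#'
#' @param geometry named list of parts: `merged_bone` (tet4 [volume_mesh()]),
#'   `bulk_soft_tissue` (tet4), `skin` (tri3 membrane layer, e.g. from
#'   [make_skin_layer()]), `ground_plate` (hex8).
#' @param body_weight body weight in N (> 0).
#' @param node_sets named list of lists `list(part =, nodes =)` defining
#'   `achilles_attachment`, `proximal_tibia_fibula`, `proximal_skin` and
#'   `plate_load`. Missing sets are derived geometrically (posterior-superior
#'   bone nodes; top 5% of bone/skin nodes; all plate nodes) with a notice.
#' @param overrides named list; recognised keys `friction`, `materials`
#'   (partial named list), `mesh_targets` (named numeric, mm).
#' @return An object of class `fe_model_spec`.
#' @export
build_model_spec <- function(geometry, body_weight, node_sets = NULL,
                             overrides = list()) {
  missing_parts <- setdiff(PART_NAMES, names(geometry))
  if (length(missing_parts)) {
    abort(sprintf("Missing geometry part(s): %s.", paste(missing_parts, collapse = ", ")))
  }
  for (p in PART_NAMES) {
    if (!inherits(geometry[[p]], "volume_mesh")) {
      abort(sprintf("Part '%s' must be a volume_mesh.", p))
    }
  }
  if (!is.numeric(body_weight) || !is.finite(body_weight) || body_weight <= 0) {
    abort("`body_weight` must be a positive force in N.")
  }
  if (is.null(geometry$skin$tri3) || nrow(geometry$skin$tri3) == 0) {
    abort("Part 'skin' must carry tri3 membrane elements (see make_skin_layer()).")
  }
  node_sets <- node_sets %||% list()
  auto <- character(0)
  topband <- function(vm, frac = 0.05) {
    z <- vm$nodes[, 3]
    which(z >= max(z) - frac * (max(z) - min(z) + 1e-12))
  }
  if (is.null(node_sets$achilles_attachment)) {
    bn <- geometry$merged_bone$nodes
    score <- bn[, 3] - bn[, 2]                 # superior and posterior
    node_sets$achilles_attachment <- list(
      part = "merged_bone", nodes = order(score, decreasing = TRUE)[1:min(4, nrow(bn))])
    auto <- c(auto, "achilles_attachment")
  }
  if (is.null(node_sets$proximal_tibia_fibula)) {
    node_sets$proximal_tibia_fibula <- list(part = "merged_bone",
                                            nodes = topband(geometry$merged_bone))
    auto <- c(auto, "proximal_tibia_fibula")
  }
  if (is.null(node_sets$proximal_skin)) {
    node_sets$proximal_skin <- list(part = "skin", nodes = topband(geometry$skin))
    auto <- c(auto, "proximal_skin")
  }
  if (is.null(node_sets$plate_load)) {
    node_sets$plate_load <- list(part = "ground_plate",
                                 nodes = seq_len(nrow(geometry$ground_plate$nodes)))
    auto <- c(auto, "plate_load")
  }
  if (length(auto)) {
    inform(sprintf("Derived node set(s) geometrically: %s.", paste(auto, collapse = ", ")))
  }
  spec <- list(
    parts = geometry[PART_NAMES],
    materials = default_materials(),
    skin_thickness = attr(geometry$skin, "thickness") %||% 2,
    friction = 0.6,
    body_weight = body_weight,
    loads = list(plate_vertical = body_weight / 2,
                 achilles = body_weight / 4),
    node_sets = node_sets,
    mesh_targets = c(merged_bone = 3, bulk_soft_tissue = 5, ground_plate = 5),
    overrides_applied = character(0)
  )
  if (!is.null(overrides$friction)) {
    spec$friction <- overrides$friction
    spec$overrides_applied <- c(spec$overrides_applied,
                                sprintf("friction=%g", overrides$friction))
  }
  if (!is.null(overrides$materials)) {
    for (nm in names(overrides$materials)) {
      spec$materials[[nm]] <- overrides$materials[[nm]]
      spec$overrides_applied <- c(spec$overrides_applied, sprintf("material:%s", nm))
    }
  }
  if (!is.null(overrides$mesh_targets)) {
    spec$mesh_targets[names(overrides$mesh_targets)] <- overrides$mesh_targets
    spec$overrides_applied <- c(spec$overrides_applied, "mesh_targets")
  }
  structure(spec, class = "fe_model_spec")
}

#' @export
print.fe_model_spec <- function(x, ...) {
  cat("<fe_model_spec>\n")
  for (p in names(x$parts)) {
    cat(sprintf("  %-17s %6d nodes, %6d elements\n", p,
                nrow(x$parts[[p]]$nodes), n_elements(x$parts[[p]])))
  }
  cat(sprintf("  friction %.2f; plate load %.4g N; Achilles %.4g N\n",
              x$friction, x$loads$plate_vertical, x$loads$achilles))
  if (length(x$overrides_applied)) {
    cat("  overrides:", paste(x$overrides_applied, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
glance.fe_model_spec <- function(x, ...) {
  tibble::tibble(
    n_parts = length(x$parts),
    n_nodes = sum(vapply(x$parts, function(p) nrow(p$nodes), integer(1))),
    n_elements = sum(vapply(x$parts, n_elements, integer(1))),
    friction = x$friction,
    body_weight_n = x$body_weight,
    plate_load_n = x$loads$plate_vertical,
    achilles_load_n = x$loads$achilles
  )
}

deck_num <- function(x) formatC(x, format = "g", digits = 10)

material_cards <- function(name, mat, ogden_note = FALSE) {
  if (inherits(mat, "linear_elastic")) {
    c(sprintf("*MATERIAL, NAME=%s", name),
      "*ELASTIC",
      paste0(deck_num(mat$youngs_modulus), ", ", deck_num(mat$poissons_ratio)))
  } else if (inherits(mat, "polynomial_n2")) {
    c(sprintf("*MATERIAL, NAME=%s", name),
      "*HYPERELASTIC, N=2, POLYNOMIAL",
      paste(deck_num(c(mat$C10, mat$C01, mat$C20, mat$C11, mat$C02,
                       mat$D1, mat$D2)), collapse = ", "))
  } else if (inherits(mat, "ogden_n1")) {
    # printed normalisation U = 2 mu / alpha^2 (...); Abaqus' Ogden card takes
    # (mu_abq, alpha, D) with U = 2 mu_abq / alpha^2 (...), so mu maps through
    # unchanged and D = 0 marks incompressible.
    c(sprintf("*MATERIAL, NAME=%s", name),
      "*HYPERELASTIC, OGDEN, N=1",
      paste(deck_num(c(mat$mu, mat$alpha, 0)), collapse = ", "))
  } else {
    abort(sprintf("Unknown material class for '%s'.", name))
  }
}

#' Write a solver-ready input deck
#'
#' Serialises an [build_model_spec()] result to an Abaqus-INP-dialect text
#' deck: `*NODE`, `*ELEMENT` (`C3D4`/`C3D8`/`M3D3`), solid and membrane
#' sections, material cards, `*SURFACE INTERACTION`/`*FRICTION`, `*NSET`,
#' `*BOUNDARY` and `*CLOAD`. Output is byte-deterministic for a fixed spec.
#'
#' @param spec an `fe_model_spec`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_inp <- function(spec, path) {
  if (!inherits(spec, "fe_model_spec")) abort("`spec` must be an fe_model_spec.")
  lines <- c("*HEADING", "footmorph balanced-standing foot model deck")
  offset <- 0L
  offsets <- integer(0)
  node_lines <- "*NODE"
  for (p in names(spec$parts)) {
    nd <- spec$parts[[p]]$nodes
    offsets[p] <- offset
    ids <- offset + seq_len(nrow(nd))
    node_lines <- c(node_lines,
                    paste0(ids, ", ", deck_num(nd[, 1]), ", ",
                           deck_num(nd[, 2]), ", ", deck_num(nd[, 3])))
    offset <- offset + nrow(nd)
  }
  lines <- c(lines, node_lines)
  elem_id <- 0L
  etype_of <- c(merged_bone = "C3D4", bulk_soft_tissue = "C3D4",
                skin = "M3D3", ground_plate = "C3D8")
  for (p in names(spec$parts)) {
    vm <- spec$parts[[p]]
    conn <- switch(etype_of[[p]], C3D4 = vm$tet4, C3D8 = vm$hex8, M3D3 = vm$tri3)
    if (is.null(conn) || nrow(conn) == 0) {
      abort(sprintf("Part '%s' has no %s elements.", p, etype_of[[p]]))
    }
    lines <- c(lines, sprintf("*ELEMENT, TYPE=%s, ELSET=%s",
                              etype_of[[p]], toupper(p)))
    ids <- elem_id + seq_len(nrow(conn))
    lines <- c(lines, paste0(ids, ", ",
                             apply(conn + offsets[p], 1, paste, collapse = ", ")))
    elem_id <- elem_id + nrow(conn)
  }
  for (p in c("merged_bone", "bulk_soft_tissue", "ground_plate")) {
    lines <- c(lines, sprintf("*SOLID SECTION, ELSET=%s, MATERIAL=%s",
                              toupper(p), toupper(p)))
  }
  lines <- c(lines,
             sprintf("*MEMBRANE SECTION, ELSET=SKIN, MATERIAL=SKIN"),
             deck_num(spec$skin_thickness))
  for (p in names(spec$materials)) {
    lines <- c(lines, material_cards(toupper(p), spec$materials[[p]]))
  }
  lines <- c(lines,
             "*SURFACE INTERACTION, NAME=FOOT_PLATE",
             "*FRICTION",
             paste0(deck_num(spec$friction), ","))
  for (s in names(spec$node_sets)) {
    ns <- spec$node_sets[[s]]
    ids <- sort(offsets[ns$part] + as.integer(ns$nodes))
    chunks <- split(ids, ceiling(seq_along(ids) / 12))
    lines <- c(lines, sprintf("*NSET, NSET=%s", toupper(s)),
               vapply(chunks, function(ch) paste(ch, collapse = ", "), character(1)))
  }
  plate_ids <- sort(offsets["ground_plate"] +
                      seq_len(nrow(spec$parts$ground_plate$nodes)))
  chunks <- split(plate_ids, ceiling(seq_along(plate_ids) / 12))
  lines <- c(lines, "*NSET, NSET=PLATE_ALL",
             vapply(chunks, function(ch) paste(ch, collapse = ", "), character(1)))
  lines <- c(lines, "*BOUNDARY",
             "PLATE_ALL, 1, 2",                       # fixed except vertical
             "PROXIMAL_TIBIA_FIBULA, 1, 3",
             "PROXIMAL_SKIN, 1, 3")
  lines <- c(lines,
             "*STEP",
             "*STATIC",
             "*CLOAD",
             paste0("PLATE_LOAD, 3, ", deck_num(spec$loads$plate_vertical)),
             paste0("ACHILLES_ATTACHMENT, 3, ", deck_num(spec$loads$achilles)),
             "*END STEP")
  con <- file(path, "wb")   # binary mode: byte-identical output on any platform
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Summarise an input deck
#'
#' Re-reads a deck in the package's own dialect subset and recovers the
#' node/element/part inventory, section and material names, friction, and
#' load lines. Unknown keywords are skipped with a warning.
#'
#' @param path deck path.
#' @return List with `n_nodes`, `elements` (tibble: elset, type, n),
#'   `sections` (tibble), `materials` (tibble: name, model), `friction`,
#'   `cloads` (tibble: nset, dof, magnitude), `node_sets` (tibble: nset, n).
#' @export
read_inp_summary <- function(path) {
  if (!file.exists(path)) abort(sprintf("No deck at '%s'.", path))
  lines <- readLines(path, warn = FALSE)
  is_kw <- startsWith(lines, "*")
  kw_at <- which(is_kw)
  known <- c("*HEADING", "*NODE", "*ELEMENT", "*SOLID SECTION",
             "*MEMBRANE SECTION", "*MATERIAL", "*ELASTIC", "*HYPERELASTIC",
             "*SURFACE INTERACTION", "*FRICTION", "*NSET", "*BOUNDARY",
             "*STEP", "*STATIC", "*CLOAD", "*END STEP")
  n_nodes <- 0L
  elements <- list(); sections <- list(); materials <- list()
  cloads <- list(); nsets <- list()
  friction <- NA_real_
  cur_mat <- NULL
  kwname <- function(l) toupper(trimws(strsplit(l, ",")[[1]][1]))
  kwopt <- function(l, key) {
    m <- regmatches(l, regexec(paste0(key, "\\s*=\\s*([^,]+)"), toupper(l)))[[1]]
    if (length(m) == 2) trimws(m[2]) else NA_character_
  }
  for (ki in seq_along(kw_at)) {
    i <- kw_at[ki]
    l <- lines[i]
    kn <- kwname(l)
    body_end <- if (ki < length(kw_at)) kw_at[ki + 1] - 1L else length(lines)
    body <- if (body_end > i) lines[(i + 1):body_end] else character(0)
    body <- body[nzchar(trimws(body))]
    if (!(kn %in% known)) {
      warn(sprintf("Deck '%s': unknown keyword '%s' skipped.", basename(path), kn))
      next
    }
    if (kn == "*NODE") {
      n_nodes <- n_nodes + length(body)
    } else if (kn == "*ELEMENT") {
      conn <- strsplit(body, ",")
      widths <- lengths(conn) - 1L
      type <- kwopt(l, "TYPE")
      want <- c(C3D4 = 4L, C3D8 = 8L, M3D3 = 3L)[type]
      if (!is.na(want) && any(widths != want)) {
        abort(sprintf("Deck '%s': malformed %s connectivity.", basename(path), type))
      }
      elements[[length(elements) + 1]] <- tibble::tibble(
        elset = kwopt(l, "ELSET"), type = type, n = length(body))
    } else if (kn %in% c("*SOLID SECTION", "*MEMBRANE SECTION")) {
      sections[[length(sections) + 1]] <- tibble::tibble(
        elset = kwopt(l, "ELSET"), material = kwopt(l, "MATERIAL"),
        kind = if (kn == "*SOLID SECTION") "solid" else "membrane",
        thickness = if (kn == "*MEMBRANE SECTION" && length(body))
          as.numeric(body[1]) else NA_real_)
    } else if (kn == "*MATERIAL") {
      cur_mat <- kwopt(l, "NAME")
    } else if (kn %in% c("*ELASTIC", "*HYPERELASTIC")) {
      model <- if (kn == "*ELASTIC") "elastic" else {
        if (grepl("OGDEN", toupper(l))) "ogden_n1" else "polynomial_n2"
      }
      materials[[length(materials) + 1]] <- tibble::tibble(
        name = cur_mat, model = model)
    } else if (kn == "*FRICTION") {
      friction <- as.numeric(strsplit(body[1], ",")[[1]][1])
    } else if (kn == "*NSET") {
      ids <- as.integer(unlist(strsplit(body, ",")))
      nsets[[length(nsets) + 1]] <- tibble::tibble(
        nset = kwopt(l, "NSET"), n = length(ids[!is.na(ids)]))
    } else if (kn == "*CLOAD") {
      cl <- strsplit(body, ",")
      cloads[[length(cloads) + 1]] <- tibble::tibble(
        nset = trimws(vapply(cl, `[`, character(1), 1)),
        dof = as.integer(vapply(cl, `[`, character(1), 2)),
        magnitude = as.numeric(vapply(cl, `[`, character(1), 3)))
    }
  }
  list(
    n_nodes = n_nodes,
    elements = dplyr::bind_rows(elements),
    sections = dplyr::bind_rows(sections),
    materials = dplyr::bind_rows(materials),
    friction = friction,
    node_sets = dplyr::bind_rows(nsets),
    cloads = dplyr::bind_rows(cloads)
  )
}

#' Mesh convergence ladder
#'
#' Emits one mesh-target specification per element size for an external
#' solver sweep (sizes must be strictly decreasing, conventionally halving,
#' e.g. 20, 10, 5, 2.5, 1.25 mm). The acceptance rule — peak plantar
#' pressure deviating by less than 5% between consecutive refinements — is
#' recorded as metadata, not evaluated here.
#'
#' @param target_sizes positive, strictly decreasing element sizes (mm).
#' @return Tibble with `level`, `element_size_mm` and a `bone_size_mm` /
#'   `soft_tissue_size_mm` pair scaled by the standard 3:5 ratio; attribute
#'   `acceptance_rule`.
#' @export
convergence_ladder <- function(target_sizes) {
  if (any(!is.finite(target_sizes)) || any(target_sizes <= 0)) {
    abort("Element sizes must be positive.")
  }
  if (length(target_sizes) > 1 && any(diff(target_sizes) >= 0)) {
    abort("Element sizes must be strictly decreasing.")
  }
  out <- tibble::tibble(
    level = seq_along(target_sizes),
    element_size_mm = as.numeric(target_sizes),
    bone_size_mm = as.numeric(target_sizes) * 3 / 5,
    soft_tissue_size_mm = as.numeric(target_sizes)
  )
  attr(out, "acceptance_rule") <-
    "peak plantar pressure deviation < 5% between consecutive refinements"
  out
}
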