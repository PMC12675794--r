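#' Triangle mesh
#'
#' A minimal indexed triangle mesh in millimetres: an `n x 3` vertex matrix,
#' an `m x 3` integer face matrix (1-based vertex indices, counter-clockwise
#' winding seen from outside), and an optional per-face integer layer label
#' (`0` = outer cortical, `1` = inner cortical, `2` = fracture surface).
#'
#' @param vertices numeric matrix `n x 3` of vertex positions (mm).
#' @param faces integer matrix `m x 3` of vertex indices.
#' @param labels optional integer vector of length `m` with per-face layer
#'   labels; defaults to `0` for every face.
#' @return An object of class `trimesh`.
#' @export
trimesh <- function(vertices, faces, labels = NULL) {
  vertices <- matrix(as.numeric(vertices), ncol = 3)
  faces <- matrix(as.integer(faces), ncol = 3)
  if (nrow(vertices) == 0L || nrow(faces) == 0L)
    stop("empty mesh: need at least one vertex and one face")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face index out of range")
  if (any(faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
            faces[, 1] == faces[, 3]))
    stop("face repeats a vertex")
  labels <- if (is.null(labels)) integer(nrow(faces)) else as.integer(labels)
  if (length(labels) != nrow(faces))
    stop("labels must have one entry per face")
  structure(list(vertices = vertices, faces = faces, labels = labels),
            class = "trimesh")
}

#' @export
print.trimesh <- function(x, ...) {
  cat(sprintf("trimesh: %d vertices, %d faces", nrow(x$vertices),
              nrow(x$faces)))
  tab <- table(x$labels)
  if (length(tab) > 1L || !identical(names(tab), "0")) {
    nm <- c(`0` = "outer", `1` = "inner", `2` = "fracture")
    lab <- paste(sprintf("%s=%d", nm[names(tab)], as.integer(tab)),
                 collapse = ", ")
    cat(" (", lab, ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

# Undirected edge table: one row per (face, local edge) with canonical
# vertex order. Local edge j of a face joins face[, j] and face[, j %% 3 + 1].
mesh_edge_table <- function(mesh) {
  f <- mesh$faces
  m <- nrow(f)
  va <- c(f[, 1], f[, 2], f[, 3])
  vb <- c(f[, 2], f[, 3], f[, 1])
  data.frame(face = rep.int(seq_len(m), 3L),
             edge = rep(1:3, each = m),
             v1 = pmin(va, vb), v2 = pmax(va, vb))
}

edge_key <- function(v1, v2) paste(pmin(v1, v2), pmax(v1, v2))

#' Per-face areas and normals
#'
#' @param mesh a [trimesh].
#' @return `face_areas`: numeric vector of triangle areas (mm^2);
#'   `face_normals`: `m x 3` matrix of unit normals (zero rows for degenerate
#'   faces).
#' @export
face_areas <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- cross3_rows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                    v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  0.5 * sqrt(rowSums(cr^2))
}

#' @rdname face_areas
#' @export
face_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  cr <- cross3_rows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                    v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  len <- sqrt(rowSums(cr^2))
  len[len == 0] <- 1
  cr / len
}

#' Signed volume of a closed mesh
#'
#' Sum of signed tetrahedron volumes against the origin; exact for watertight,
#' consistently oriented meshes and invariant under rigid motion.
#'
#' @param mesh a [trimesh].
#' @return volume in mm^3 (positive for outward-oriented meshes).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  sum(rowSums(a * cross3_rows(b, c3))) / 6
}

#' Mesh diagnostics
#'
#' Reports watertightness (every undirected edge bounds exactly two faces),
#' orientability (the two incident faces traverse each shared edge in opposite
#' directions), the number of degenerate faces (area below `tol`), and the
#' number of non-manifold edges (face degree != 2).
#'
#' @param mesh a [trimesh].
#' @param tol area threshold (mm^2) below which a face counts as degenerate.
#' @return An object of class `mesh_quality_report` with fields `watertight`,
#'   `orientable`, `n_degenerate`, `n_nonmanifold_edges`.
#' @export
validate_mesh <- function(mesh, tol = 1e-10) {
  et <- mesh_edge_table(mesh)
  key <- paste(et$v1, et$v2)
  deg <- table(key)
  nonman <- sum(deg != 2L)
  watertight <- nonman == 0L
  # Orientability: per undirected edge seen twice, the directed traversals
  # must be opposite. Count directed duplicates.
  f <- mesh$faces
  va <- c(f[, 1], f[, 2], f[, 3])
  vb <- c(f[, 2], f[, 3], f[, 1])
  dirkey <- paste(va, vb)
  orientable <- watertight && !anyDuplicated(dirkey)
  rep <- structure(list(watertight = watertight,
                        orientable = orientable,
                        n_degenerate = sum(face_areas(mesh) < tol),
                        n_nonmanifold_edges = as.integer(nonman)),
                   class = "mesh_quality_report")
  rep
}

#' @export
print.mesh_quality_report <- function(x, ...) {
  cat(sprintf(paste0("mesh quality: watertight=%s orientable=%s ",
                     "degenerate=%d nonmanifold_edges=%d\n"),
              x$watertight, x$orientable, x$n_degenerate,
              x$n_nonmanifold_edges))
  invisible(x)
}

#' Long axis of an elongated mesh
#'
#' First principal direction of the vertex cloud, with origin at the vertex
#' centroid. The sign is chosen so the axis has a non-negative +Z component
#' (ties broken toward +Y, then +X). Errors on nearly isotropic clouds.
#'
#' @param mesh a [trimesh].
#' @param min_spread_ratio minimum ratio between the two leading principal
#'   extents for the axis to be considered well defined.
#' @return list with `axis` (unit 3-vector) and `origin` (centroid).
#' @export
compute_long_axis <- function(mesh, min_spread_ratio = 1.2) {
  v <- mesh$vertices
  if (nrow(v) < 4L) stop("need at least 4 vertices")
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  eg <- eigen(crossprod(vc) / nrow(vc), symmetric = TRUE)
  sd1 <- sqrt(eg$values[1])
  sd2 <- sqrt(max(eg$values[2], 0))
  if (sd2 <= 0 || sd1 / sd2 < min_spread_ratio)
    stop(sprintf(
      "degenerate vertex cloud: principal spread ratio %.3f < %.2f",
      if (sd2 > 0) sd1 / sd2 else Inf, min_spread_ratio))
  ax <- eg$vectors[, 1]
  s <- sign(ax[3])
  if (s == 0) s <- sign(ax[2])
  if (s == 0) s <- sign(ax[1])
  if (s < 0) ax <- -ax
  list(axis = unit(ax), origin = ctr)
}

# Axial coordinate of points relative to an axis frame.
axial_coord <- function(points, axis, origin) {
  sweep(points, 2, origin) %*% axis
}

# Axial height of points measured from the LOW end of the model, so heights
# live in [0, length]. All user-facing "fracture height" arguments use this
# convention.
axial_height <- function(model, points) {
  h <- as.vector(axial_coord(points, model$axis, model$origin))
  h0 <- min(as.vector(axial_coord(model$mesh$vertices, model$axis,
                                  model$origin)))
  h - h0
}

#' Generalized bone radius
#'
#' Mean distance to the bone axis of outer-cortical vertices whose axial
#' coordinate lies within `height +/- band`. Stands in for the local bone
#' thickness when fitting the projection cylinder and when scaling height-map
#' statistics between bones.
#'
#' @param model a [cortical_bone] model.
#' @param height axial position (mm, measured from the low end of the bone
#'   along the axis, so heights lie in `[0, length]`).
#' @param band half-width of the axial averaging band (mm).
#' @return mean radius in mm.
#' @export
generalized_radius <- function(model, height, band = 2) {
  stopifnot(inherits(model, "cortical_bone"), band > 0)
  mesh <- model$mesh
  outer_faces <- mesh$faces[mesh$labels == 0L, , drop = FALSE]
  vid <- sort(unique(as.vector(outer_faces)))
  pts <- mesh$vertices[vid, , drop = FALSE]
  h <- axial_height(model, pts)
  sel <- h >= height - band & h <= height + band
  if (!any(sel))
    stop(sprintf("no outer-layer vertices in band %.2f +/- %.2f mm",
                 height, band))
  pc <- sweep(pts[sel, , drop = FALSE], 2, model$origin)
  radial <- pc - outer(as.vector(pc %*% model$axis), model$axis)
  mean(sqrt(rowSums(radial^2)))
}

#' Two-layer cortical bone model
#'
#' Wraps a labeled [trimesh] (outer/inner cortical surfaces) together with its
#' long axis, origin and length. Constructed by [generate_long_bone()] or from
#' an imported mesh via [as_cortical_bone()].
#'
#' @param mesh labeled [trimesh].
#' @param axis unit 3-vector, the bone long axis.
#' @param origin 3-vector, reference point on the axis (vertex centroid).
#' @param length bone length along the axis (mm).
#' @return An object of class `cortical_bone`.
#' @export
cortical_bone <- function(mesh, axis, origin, length) {
  stopifnot(inherits(mesh, "trimesh"))
  structure(list(mesh = mesh, axis = unit(axis), origin = as.numeric(origin),
                 length = as.numeric(length)),
            class = "cortical_bone")
}

#' @rdname cortical_bone
#' @param min_spread_ratio passed to [compute_long_axis()].
#' @export
as_cortical_bone <- function(mesh, min_spread_ratio = 1.2) {
  ax <- compute_long_axis(mesh, min_spread_ratio)
  h <- as.vector(axial_coord(mesh$vertices, ax$axis, ax$origin))
  cortical_bone(mesh, ax$axis, ax$origin, diff(range(h)))
}

#' @export
print.cortical_bone <- function(x, ...) {
  cat(sprintf("cortical_bone: length %.1f mm, axis (%.3f, %.3f, %.3f)\n",
              x$length, x$axis[1], x$axis[2], x$axis[3]))
  print(x$mesh)
  invisible(x)
}

# Apply a rigid (or affine) transform to a mesh; used by tests and the
# synthetic generator.
transform_mesh <- function(mesh, rotation = diag(3), translation = c(0, 0, 0),
                           scale = 1) {
  v <- mesh$vertices %*% t(rotation) * scale
  v <- sweep(v, 2, translation, `+`)
  trimesh(v, mesh$faces, mesh$labels)
}
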