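#' Simulate a fracture on a cortical bone model
#'
#' Runs the full fragmentation pipeline: fit the projection cylinder, unwrap
#' both cortical layers, place the 2D pattern, compute cut points, embed the
#' fracture lines with the chosen cutting strategy, identify fragments,
#' close every fragment across the cortical thickness with a constrained
#' triangulation of each fracture interface (optionally perturbed), and
#' assemble watertight fragment meshes. Each interface wall is triangulated
#' once and attached to its two fragments with opposite orientations, so the
#' fragment volumes sum exactly to the intact shell volume for every
#' strategy and perturbation.
#'
#' @param model a [cortical_bone].
#' @param pattern a [fracture_pattern].
#' @param fracture_height axial fracture position (mm from the low end);
#'   defaults to mid-shaft.
#' @param band_halfwidth projection band half-width (mm); must cover the
#'   pattern's longitudinal extent.
#' @param strategy a [cut_strategy].
#' @param perturbation a [perturbation_config].
#' @param aspect_limit maximum pattern/bone circumference ratio
#'   ([place_pattern()]).
#' @param longitudinal_scale optional scaling of the pattern's v axis.
#' @return An object of class `fractured_bone`: `fragments` (list of
#'   watertight labeled [trimesh]), `volumes`, `n_fragments`, the cut model,
#'   fracture edges, interface bookkeeping and the run configuration.
#' @export
fracture_bone <- function(model, pattern, fracture_height = NULL,
                          band_halfwidth = NULL,
                          strategy = cut_strategy("hybrid", 0.10),
                          perturbation = perturbation_config("none"),
                          aspect_limit = 2, longitudinal_scale = 1) {
  stopifnot(inherits(model, "cortical_bone"),
            inherits(pattern, "fracture_pattern"))
  fracture_height <- fracture_height %||% (model$length / 2)
  if (is.null(band_halfwidth)) {
    vext <- diff(range(unlist(lapply(c(pattern$lines_outer,
                                       pattern$lines_inner),
                                     function(l) l[, 2]))))
    band_halfwidth <- max(12, vext / 2 * longitudinal_scale + 6)
  }
  cyl <- fit_projection_cylinder(model, fracture_height, band_halfwidth)
  uo <- unwrap_band(model, cyl, "outer")
  ui <- unwrap_band(model, cyl, "inner")
  pl <- place_pattern(pattern, cyl, fracture_height, aspect_limit,
                      longitudinal_scale)
  co <- compute_cut_points(uo, pl)
  ci <- compute_cut_points(ui, pl)
  emb <- embed_cuts(model, list(co, ci), strategy)
  cmesh <- emb$model$mesh
  labeling <- identify_fragments(cmesh, emb$fracture_edges)
  solid_of_comp <- group_solids(cmesh, labeling, cyl, pl)
  solid_of_face <- solid_of_comp[labeling$face_fragment]
  n_solids <- max(solid_of_comp)

  # Adjacency of cut-mesh faces to fracture edges (for wall-side lookup).
  et <- mesh_edge_table(cmesh)
  et$key <- paste(et$v1, et$v2)

  verts <- cmesh$vertices
  lines_present <- sort(unique(emb$fracture_edges$line))
  walls <- list()
  for (li in lines_present) {
    contours <- extract_fracture_contours(cmesh, emb$fracture_edges, li)
    zone <- triangulate_fracture_zone(
      verts, contours, perturbation,
      seed = child_seed(perturbation$seed, li))
    verts <- zone$verts
    # The two solids this interface separates, read off the outer loop.
    fo <- emb$fracture_edges[emb$fracture_edges$line == li &
                               emb$fracture_edges$layer == "outer", ]
    adj <- et$face[et$key %in% paste(fo$v1, fo$v2)]
    sids <- sort(unique(solid_of_face[adj]))
    if (length(sids) != 2L)
      stop("fracture interface ", li, " borders ", length(sids),
           " fragments; expected 2")
    walls[[length(walls) + 1L]] <-
      list(line = li, faces = zone$faces, solids = sids)
  }

  # Directed edges of each wall, for orientation-consistent attachment.
  fragments <- vector("list", n_solids)
  volumes <- numeric(n_solids)
  for (s in seq_len(n_solids)) {
    shell_faces <- cmesh$faces[solid_of_face == s, , drop = FALSE]
    shell_labels <- cmesh$labels[solid_of_face == s]
    shell_dir <- paste(c(shell_faces[, 1], shell_faces[, 2],
                         shell_faces[, 3]),
                       c(shell_faces[, 2], shell_faces[, 3],
                         shell_faces[, 1]))
    all_faces <- shell_faces
    all_labels <- shell_labels
    for (w in walls) {
      if (!s %in% w$solids) next
      wf <- w$faces
      wall_dir <- paste(c(wf[, 1], wf[, 2], wf[, 3]),
                        c(wf[, 2], wf[, 3], wf[, 1]))
      # A closed orientable mesh traverses each shared edge twice in
      # opposite directions; flip the wall if it repeats a shell direction.
      if (any(wall_dir %in% shell_dir))
        wf <- wf[, c(1, 3, 2), drop = FALSE]
      all_faces <- rbind(all_faces, wf)
      all_labels <- c(all_labels, rep(2L, nrow(wf)))
    }
    vid <- sort(unique(as.vector(all_faces)))
    remap <- match(all_faces, vid)
    frag <- trimesh(verts[vid, , drop = FALSE],
                    matrix(remap, ncol = 3), all_labels)
    fragments[[s]] <- frag
    volumes[s] <- mesh_volume(frag)
  }

  structure(list(fragments = fragments, volumes = volumes,
                 n_fragments = n_solids,
                 cut_model = emb$model,
                 fracture_edges = emb$fracture_edges,
                 labeling = labeling,
                 solid_of_face = solid_of_face,
                 interfaces = walls,
                 cylinder = cyl, placed = pl,
                 strategy = strategy, perturbation = perturbation,
                 fracture_height = fracture_height),
            class = "fractured_bone")
}

# Group surface components into solid fragments: a detached region (wedge,
# comminuted) appears as separate outer- and inner-layer surface patches
# that belong to one solid. Each component votes for the planar region of
# the placed pattern its band faces project into; components sharing a
# region share a solid.
group_solids <- function(cmesh, labeling, cyl, placed) {
  lines_uv <- lapply(placed$outer, function(l)
    cbind(l[, 1] / cyl$circumference, l[, 2]))
  rr <- region_raster(lines_uv, pad = 10)
  cen <- (cmesh$vertices[cmesh$faces[, 1], , drop = FALSE] +
            cmesh$vertices[cmesh$faces[, 2], , drop = FALSE] +
            cmesh$vertices[cmesh$faces[, 3], , drop = FALSE]) / 3
  cc <- cyl_coords(cen, cyl)
  in_raster <- cc[, "h"] > rr$v_lo & cc[, "h"] < rr$v_hi &
    cmesh$labels != 2L
  region <- rep(0L, nrow(cmesh$faces))
  region[in_raster] <- rr$lookup(cc[in_raster, "theta"] / (2 * pi),
                                 cc[in_raster, "h"])
  comp <- labeling$face_fragment
  solid_key <- vapply(seq_len(labeling$n_fragments), function(k) {
    reg <- region[comp == k]
    reg <- reg[reg > 0L]
    if (!length(reg)) return(-k)  # isolated component: its own solid
    as.integer(names(which.max(table(reg))))
  }, numeric(1))
  as.integer(factor(solid_key))
}

#' @export
print.fractured_bone <- function(x, ...) {
  cat(sprintf("fractured_bone: %d fragments (%s strategy, %s perturbation)\n",
              x$n_fragments, x$strategy$mode, x$perturbation$method))
  for (i in seq_along(x$fragments))
    cat(sprintf("  fragment %d: %5d faces, volume %10.2f mm^3\n", i,
                nrow(x$fragments[[i]]$faces), x$volumes[i]))
  invisible(x)
}

#' @export
summary.fractured_bone <- function(object, ...) {
  wt <- vapply(object$fragments,
               function(f) validate_mesh(f)$watertight, logical(1))
  q <- unlist(lapply(object$fragments, mesh_face_quality))
  out <- list(n_fragments = object$n_fragments,
              volumes = object$volumes,
              total_volume = sum(object$volumes),
              intact_volume = mesh_volume(object$cut_model$mesh),
              all_watertight = all(wt),
              mean_q = mean(q[is.finite(q)]),
              max_q = max(q[is.finite(q)]))
  class(out) <- "summary.fractured_bone"
  out
}

#' @export
print.summary.fractured_bone <- function(x, ...) {
  cat(sprintf(
    paste0("fracture summary: %d fragments, all watertight: %s\n",
           "  volume sum %0.4f vs intact %0.4f mm^3 (rel err %.2e)\n",
           "  triangle quality: mean q %.4f, max q %.2f\n"),
    x$n_fragments, x$all_watertight, x$total_volume, x$intact_volume,
    abs(x$total_volume - x$intact_volume) / x$intact_volume,
    x$mean_q, x$max_q))
  invisible(x)
}
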