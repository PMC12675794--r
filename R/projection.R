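#' Fit the projection cylinder
#'
#' Encloses the target band of the bone in a cylinder whose axis is the bone
#' long axis and whose radius is the generalized radius at the fracture
#' height — the frame in which the mesh band is unwrapped and the 2D pattern
#' placed.
#'
#' @param model a [cortical_bone].
#' @param fracture_height axial position of the fracture (mm from the low
#'   end of the bone).
#' @param band_halfwidth half-width of the working band (mm); the band must
#'   lie inside the shaft, clear of the end caps.
#' @param radius_band half-width of the averaging band for
#'   [generalized_radius()]; by default adapted to the mesh's axial
#'   resolution (at least one vertex ring always falls in the band).
#' @return An object of class `projection_cylinder` with the axis frame
#'   (`axis`, `basis`, `origin`, `h0`), `radius`, `circumference` and `band`
#'   (`[v_min, v_max]` in bone heights).
#' @export
fit_projection_cylinder <- function(model, fracture_height,
                                    band_halfwidth = 15,
                                    radius_band = NULL) {
  stopifnot(inherits(model, "cortical_bone"), band_halfwidth > 0)
  band <- c(fracture_height - band_halfwidth,
            fracture_height + band_halfwidth)
  eps <- 1e-9
  if (band[1] <= eps || band[2] >= model$length - eps)
    stop(sprintf(
      "band [%.1f, %.1f] mm touches the bone ends (length %.1f mm)",
      band[1], band[2], model$length))
  if (is.null(radius_band)) {
    h <- sort(unique(round(axial_height(model, model$mesh$vertices), 6)))
    gap <- if (length(h) > 1L) stats::median(diff(h)) else 2
    radius_band <- max(2, 0.75 * gap)
  }
  radius <- generalized_radius(model, fracture_height, radius_band)
  h_all <- as.vector(axial_coord(model$mesh$vertices, model$axis,
                                 model$origin))
  structure(list(axis = model$axis, basis = axis_basis(model$axis),
                 origin = model$origin, h0 = min(h_all),
                 radius = radius, circumference = 2 * pi * radius,
                 band = band, fracture_height = fracture_height),
            class = "projection_cylinder")
}

#' @export
print.projection_cylinder <- function(x, ...) {
  cat(sprintf(
    "projection_cylinder: radius %.2f mm, band [%.1f, %.1f] mm\n",
    x$radius, x$band[1], x$band[2]))
  invisible(x)
}

# (theta, height) cylindrical coordinates of points in the cylinder frame.
cyl_coords <- function(points, cylinder) {
  pc <- sweep(points, 2, cylinder$origin)
  e1 <- cylinder$basis[, 1]
  e2 <- cylinder$basis[, 2]
  theta <- atan2(pc %*% e2, pc %*% e1) %% (2 * pi)
  h <- pc %*% cylinder$axis - cylinder$h0
  cbind(theta = as.vector(theta), h = as.vector(h))
}

#' Unwrap a mesh band to 2D
#'
#' Maps the faces of one cortical layer inside the cylinder band to the
#' plane: `x = theta * radius` (arc length), `y = axial height`. Faces
#' crossing the seam `theta = 0` get their small-angle vertices shifted by
#' one circumference so every 2D triangle is seam-free; the downstream
#' cut-point deduplication removes the resulting duplicates. Both layers are
#' unwrapped in the same (outer-radius) frame so they share a coordinate
#' system.
#'
#' @param model a [cortical_bone].
#' @param cylinder a [fit_projection_cylinder()] result.
#' @param layer `"outer"` or `"inner"`.
#' @return An object of class `unwrapped_band`: per-face 2D triangle
#'   coordinates (`x`, `y`: `m x 3`), global face ids and vertex ids.
#' @export
unwrap_band <- function(model, cylinder, layer = c("outer", "inner")) {
  layer <- match.arg(layer)
  lab <- if (layer == "outer") 0L else 1L
  mesh <- model$mesh
  cc <- cyl_coords(mesh$vertices, cylinder)
  in_band <- cc[, "h"] >= cylinder$band[1] & cc[, "h"] <= cylinder$band[2]
  fsel <- which(mesh$labels == lab &
                  in_band[mesh$faces[, 1]] &
                  in_band[mesh$faces[, 2]] &
                  in_band[mesh$faces[, 3]])
  if (length(fsel) == 0L)
    stop("no ", layer, "-layer faces inside the projection band")
  f <- mesh$faces[fsel, , drop = FALSE]
  th <- matrix(cc[f, "theta"], ncol = 3)
  # Seam fix: a face spanning the theta = 0 meridian mixes angles near 0 and
  # near 2*pi; shift the small ones up by a full turn.
  spread <- apply(th, 1, function(t) max(t) - min(t))
  cross_seam <- spread > pi
  if (any(cross_seam)) {
    tcs <- th[cross_seam, , drop = FALSE]
    tcs[tcs < pi] <- tcs[tcs < pi] + 2 * pi
    th[cross_seam, ] <- tcs
    if (any(apply(th[cross_seam, , drop = FALSE], 1,
                  function(t) max(t) - min(t)) > pi))
      stop("face spans more than pi in angle; mesh too coarse to unwrap")
  }
  structure(list(layer = layer, face_ids = fsel, faces = f,
                 x = th * cylinder$radius,
                 y = matrix(cc[f, "h"], ncol = 3),
                 vertices = mesh$vertices,
                 cylinder = cylinder),
            class = "unwrapped_band")
}

# Map unwrapped 2D points back onto the cylinder surface (test support and
# debug rendering; cut points themselves are mapped through mesh edges).
rewrap_points <- function(xy, cylinder) {
  theta <- xy[, 1] / cylinder$radius
  h <- xy[, 2] + cylinder$h0
  p <- cbind(cylinder$radius * cos(theta), cylinder$radius * sin(theta), h)
  sweep(p %*% t(cylinder$basis), 2, cylinder$origin, `+`)
}

#' Place a pattern in the unwrapped frame
#'
#' Applies the transform T: `u` is scaled by the circumference (arc length)
#' and `v` is translated so the pattern's longitudinal midpoint sits at the
#' fracture height. If the pattern records the circumference it was designed
#' or extracted at, the implied transverse distortion is checked against
#' `aspect_limit`; placement fails (scale-infeasible) when the pattern would
#' have to stretch beyond it — the situation that makes large-bone patterns
#' inapplicable to much thinner bones.
#'
#' @param pattern a [fracture_pattern].
#' @param cylinder a [projection_cylinder].
#' @param fracture_height target axial position (mm); defaults to the
#'   cylinder's fracture height.
#' @param aspect_limit maximum allowed ratio between the target and source
#'   circumference.
#' @param longitudinal_scale optional scale applied to `v` (default 1).
#' @return An object of class `placed_pattern`: per layer, polylines in mm
#'   `(x, y)` with unrolled x (seam-free), plus closure flags.
#' @export
place_pattern <- function(pattern, cylinder, fracture_height = NULL,
                          aspect_limit = 2, longitudinal_scale = 1) {
  stopifnot(inherits(pattern, "fracture_pattern"),
            inherits(cylinder, "projection_cylinder"))
  fracture_height <- fracture_height %||% cylinder$fracture_height
  cf <- cylinder$circumference
  c0 <- pattern$meta$design_circumference
  if (!is.null(c0)) {
    ratio <- max(cf, c0) / min(cf, c0)
    if (ratio > aspect_limit)
      stop(sprintf(
        paste0("scale-infeasible: circumference ratio %.2f exceeds aspect ",
               "limit %.2f (pattern designed at %.1f mm, bone %.1f mm)"),
        ratio, aspect_limit, c0, cf))
  }
  all_v <- unlist(lapply(pattern$lines_outer, function(l) l[, 2]))
  v_shift <- fracture_height - longitudinal_scale * mean(range(all_v))
  xform <- function(lines) lapply(lines, function(l) {
    xy <- cbind(x = unroll_u(l) * cf,
                y = l[, 2] * longitudinal_scale + v_shift)
    attr(xy, "closed") <- is_closed_line(l)
    xy
  })
  placed <- structure(list(outer = xform(pattern$lines_outer),
                           inner = xform(pattern$lines_inner),
                           cylinder = cylinder,
                           fracture_type = pattern$fracture_type),
                      class = "placed_pattern")
  yr <- range(unlist(lapply(placed$outer, function(l) l[, 2])),
              unlist(lapply(placed$inner, function(l) l[, 2])))
  if (yr[1] < cylinder$band[1] || yr[2] > cylinder$band[2])
    stop(sprintf(
      "placed pattern extent [%.1f, %.1f] mm exceeds band [%.1f, %.1f] mm",
      yr[1], yr[2], cylinder$band[1], cylinder$band[2]))
  placed
}

#' Cut points of a placed pattern on an unwrapped band
#'
#' Intersects every pattern segment with the triangle edges of the unwrapped
#' band. Each crossing of an undirected mesh edge yields exactly one cut
#' point (deduplicated across the two faces sharing the edge and across seam
#' duplicates); crossings within `snap_tolerance` of an edge endpoint are
#' flagged `on_vertex` and merged per vertex. Cut points are ordered along
#' each polyline and consecutive points sharing a face are recorded as
#' face-crossing pairs (the unit the cutting strategies operate on).
#'
#' @param unwrapped an [unwrap_band()] result.
#' @param placed a [place_pattern()] result.
#' @param snap_tolerance fraction of edge length below which a crossing is
#'   flagged as a vertex hit (flag only; snapping itself is the cutting
#'   strategy's decision).
#' @return An object of class `cut_points`: data frame `points` (edge vertex
#'   ids `v1 < v2`, parameter `t` along `v1 -> v2`, 3D position, layer, line
#'   and order index, `on_vertex`) and integer matrix `pairs` (rows: point
#'   index a, point index b, shared face id).
#' @export
compute_cut_points <- function(unwrapped, placed, snap_tolerance = 0) {
  stopifnot(inherits(unwrapped, "unwrapped_band"),
            inherits(placed, "placed_pattern"))
  cf <- unwrapped$cylinder$circumference
  lines <- placed[[unwrapped$layer]]
  mesh_faces <- unwrapped$faces
  m <- nrow(mesh_faces)
  # Edge soup: 3 edges per face, canonical vertex order v1 < v2.
  e_face <- rep(seq_len(m), 3L)
  e_a <- c(mesh_faces[, 1], mesh_faces[, 2], mesh_faces[, 3])
  e_b <- c(mesh_faces[, 2], mesh_faces[, 3], mesh_faces[, 1])
  ax <- c(unwrapped$x[, 1], unwrapped$x[, 2], unwrapped$x[, 3])
  ay <- c(unwrapped$y[, 1], unwrapped$y[, 2], unwrapped$y[, 3])
  bx <- c(unwrapped$x[, 2], unwrapped$x[, 3], unwrapped$x[, 1])
  by <- c(unwrapped$y[, 2], unwrapped$y[, 3], unwrapped$y[, 1])
  flip <- e_a > e_b
  v1 <- ifelse(flip, e_b, e_a)
  v2 <- ifelse(flip, e_a, e_b)
  x1 <- ifelse(flip, bx, ax); y1 <- ifelse(flip, by, ay)
  x2 <- ifelse(flip, ax, bx); y2 <- ifelse(flip, ay, by)

  pts <- list()
  eps <- 1e-12
  yr_faces <- range(unwrapped$y)
  for (li in seq_along(lines)) {
    l <- lines[[li]]
    overlaps <- max(l[, 2]) >= yr_faces[1] && min(l[, 2]) <= yr_faces[2]
    exceeds <- min(l[, 2]) < yr_faces[1] - eps ||
      max(l[, 2]) > yr_faces[2] + eps
    if (overlaps && exceeds)
      stop(sprintf(
        paste0("pattern line %d spans [%.1f, %.1f] mm but the unwrapped ",
               "%s band only covers [%.1f, %.1f] mm; widen the band or ",
               "refine the mesh axially"),
        li, min(l[, 2]), max(l[, 2]), unwrapped$layer, yr_faces[1],
        yr_faces[2]))
    closed <- isTRUE(attr(l, "closed"))
    if (!closed) {
      # Open lines must traverse the band: endpoints outside, else error.
      yr <- unwrapped$cylinder$band
      ends_in <- l[c(1, nrow(l)), 2] > yr[1] & l[c(1, nrow(l)), 2] < yr[2]
      xr <- range(c(x1, x2))
      ends_in <- ends_in & l[c(1, nrow(l)), 1] > xr[1] &
        l[c(1, nrow(l)), 1] < xr[2]
      if (any(ends_in))
        stop("open fracture line ends inside the band; ",
             "lines must traverse the band or close")
    }
    for (k in seq_len(nrow(l) - 1L)) {
      for (shift in c(-cf, 0, cf)) {
        px <- l[k, 1] + shift;  py <- l[k, 2]
        qx <- l[k + 1, 1] + shift; qy <- l[k + 1, 2]
        if (max(px, qx) < min(x1, x2) - eps ||
              min(px, qx) > max(x1, x2) + eps) next
        rx <- qx - px; ry <- qy - py
        sx <- x2 - x1; sy <- y2 - y1
        denom <- rx * sy - ry * sx
        d1 <- (x1 - px) * ry - (y1 - py) * rx  # edge endpoint 1 vs segment
        d2 <- (x2 - px) * ry - (y2 - py) * rx
        d3 <- (px - x1) * sy - (py - y1) * sx  # segment endpoints vs edge
        d4 <- (qx - x1) * sy - (qy - y1) * sx
        hit <- which(d1 * d2 <= 0 & d3 * d4 <= 0 & abs(denom) > eps)
        if (!length(hit)) next
        t_seg <- ((x1[hit] - px) * sy[hit] - (y1[hit] - py) * sx[hit]) /
          denom[hit]
        t_edge <- ((x1[hit] - px) * ry - (y1[hit] - py) * rx) / denom[hit]
        ok <- t_seg >= -1e-9 & t_seg <= 1 + 1e-9 &
          t_edge >= -1e-9 & t_edge <= 1 + 1e-9
        if (!any(ok)) next
        hit <- hit[ok]; t_seg <- t_seg[ok]; t_edge <- t_edge[ok]
        pts[[length(pts) + 1L]] <- data.frame(
          line = li, seg = k, t_seg = pmin(pmax(t_seg, 0), 1),
          v1 = v1[hit], v2 = v2[hit],
          t = pmin(pmax(t_edge, 0), 1),
          face = unwrapped$face_ids[e_face[hit]])
      }
    }
  }
  if (!length(pts))
    return(structure(list(points = NULL, pairs = NULL,
                          layer = unwrapped$layer),
                     class = "cut_points"))
  df <- do.call(rbind, pts)
  # Dedup: same undirected edge hit from both incident faces / seam copies.
  df <- df[order(df$line, df$seg, df$t_seg), ]
  key <- paste(df$line, df$v1, df$v2, round(df$t, 7))
  facemap <- tapply(df$face, key, function(x) sort(unique(x)),
                    simplify = FALSE)
  df <- df[!duplicated(key), ]
  df$key <- key[!duplicated(key)]
  # Vertex hits: merge all cuts snapping to the same vertex on one segment
  # neighborhood into a single cut point.
  df$on_vertex <- pmin(df$t, 1 - df$t) <= snap_tolerance + 1e-12
  vtx <- ifelse(df$t < 0.5, df$v1, df$v2)
  vkey <- paste(df$line, ifelse(df$on_vertex, paste0("v", vtx), df$key))
  keep <- !duplicated(vkey)
  merged_faces <- tapply(seq_len(nrow(df)), vkey, function(i)
    sort(unique(unlist(facemap[df$key[i]]))), simplify = FALSE)
  df <- df[keep, ]
  df$cand_faces <- merged_faces[vkey[keep]]
  df <- df[order(df$line, df$seg, df$t_seg), ]
  rownames(df) <- NULL
  df$id <- seq_len(nrow(df))
  df$layer <- unwrapped$layer

  # 3D positions through the mesh edge (exactly on the source surface).
  vm <- unwrapped$vertices
  p3 <- (1 - df$t) * vm[df$v1, , drop = FALSE] +
    df$t * vm[df$v2, , drop = FALSE]
  df$px <- p3[, 1]; df$py <- p3[, 2]; df$pz <- p3[, 3]

  # Pair consecutive cut points sharing a face (face-crossing pairs).
  pairs <- list()
  for (li in seq_along(lines)) {
    idx <- df$id[df$line == li]
    if (length(idx) < 2L) next
    closed <- isTRUE(attr(lines[[li]], "closed"))
    seqs <- cbind(idx[-length(idx)], idx[-1])
    if (closed) seqs <- rbind(seqs, c(idx[length(idx)], idx[1]))
    for (r in seq_len(nrow(seqs))) {
      ra <- which(df$id == seqs[r, 1])
      rb <- which(df$id == seqs[r, 2])
      fa <- df$cand_faces[[ra]]
      fb <- df$cand_faces[[rb]]
      common <- intersect(fa, fb)
      if (length(common)) {
        pairs[[length(pairs) + 1L]] <- c(seqs[r, 1], seqs[r, 2],
                                         common[1])
        next
      }
      # Near-tangent crossing missed between two edges that share a
      # vertex: route the fracture path through that vertex with two
      # degenerate-safe sub-pairs.
      shared <- intersect(c(df$v1[ra], df$v2[ra]),
                          c(df$v1[rb], df$v2[rb]))
      if (!length(shared))
        stop("consecutive cut points share no face; ",
             "refine the mesh or simplify the pattern")
      w <- shared[1]
      n_old <- nrow(df)
      vrow <- df[ra, ]
      vrow$t <- if (df$v1[ra] == w) 0 else 1
      vrow$on_vertex <- TRUE
      vrow$id <- max(df$id) + 1L
      vrow$cand_faces <- list(sort(unique(c(fa, fb))))
      p3w <- vm[w, ]
      vrow$px <- p3w[1]; vrow$py <- p3w[2]; vrow$pz <- p3w[3]
      df <- rbind(df, vrow)
      pairs[[length(pairs) + 1L]] <- c(seqs[r, 1], vrow$id, fa[1])
      pairs[[length(pairs) + 1L]] <- c(vrow$id, seqs[r, 2], fb[1])
    }
  }
  pairs <- if (length(pairs)) do.call(rbind, pairs) else NULL
  structure(list(points = df, pairs = pairs, layer = unwrapped$layer),
            class = "cut_points")
}

#' @export
print.cut_points <- function(x, ...) {
  n <- if (is.null(x$points)) 0L else nrow(x$points)
  np <- if (is.null(x$pairs)) 0L else nrow(x$pairs)
  cat(sprintf("cut_points (%s layer): %d points, %d face pairs\n",
              x$layer, n, np))
  invisible(x)
}
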