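#' Triangle quality: circumradius-to-inradius ratio
#'
#' For a triangle with inradius `r` and circumradius `R`, the quality ratio
#' is `q = R / (2 r)`: `q = 1` exactly for equilateral triangles (Euler's
#' inequality `R >= 2r`), growing without bound as the triangle degenerates.
#' Values near 1 are ideal; an acceptable practical band is about
#' `[1, 1.3]`.
#'
#' @param p0,p1,p2 3D points (mm).
#' @return An object of class `triangle_quality` with fields `r`, `R`, `q`.
#' @export
triangle_quality <- function(p0, p1, p2) {
  a <- vnorm(p1 - p2)
  b <- vnorm(p0 - p2)
  c3 <- vnorm(p0 - p1)
  area <- 0.5 * vnorm(cross3(p1 - p0, p2 - p0))
  if (area < 1e-10 * max(a, b, c3)^2 || area == 0)
    stop("degenerate (collinear) triangle")
  s <- (a + b + c3) / 2
  r <- area / s
  R <- a * b * c3 / (4 * area)
  structure(list(r = r, R = R, q = R / (2 * r)),
            class = "triangle_quality")
}

#' @export
print.triangle_quality <- function(x, ...) {
  cat(sprintf("triangle quality: q = %.4f (r = %.4g, R = %.4g)\n",
              x$q, x$r, x$R))
  invisible(x)
}

#' @rdname triangle_quality
#' @param p0s,p1s,p2s `n x 3` matrices of triangle corners.
#' @return [triangle_qualities()] returns the numeric vector of q ratios
#'   (`Inf` for degenerate triangles).
#' @export
triangle_qualities <- function(p0s, p1s, p2s) {
  a <- sqrt(rowSums((p1s - p2s)^2))
  b <- sqrt(rowSums((p0s - p2s)^2))
  c3 <- sqrt(rowSums((p0s - p1s)^2))
  area <- 0.5 * sqrt(rowSums(cross3_rows(p1s - p0s, p2s - p0s)^2))
  s <- (a + b + c3) / 2
  q <- (a * b * c3 / (4 * area)) / (2 * area / s)
  q[!is.finite(q) | area <= 0] <- Inf
  q
}

# Vectorized q over faces of a mesh (Inf for degenerate faces).
mesh_face_quality <- function(mesh, faces = NULL) {
  f <- if (is.null(faces)) mesh$faces else faces
  v <- mesh$vertices
  a <- sqrt(rowSums((v[f[, 2], , drop = FALSE] -
                       v[f[, 3], , drop = FALSE])^2))
  b <- sqrt(rowSums((v[f[, 1], , drop = FALSE] -
                       v[f[, 3], , drop = FALSE])^2))
  c3 <- sqrt(rowSums((v[f[, 1], , drop = FALSE] -
                        v[f[, 2], , drop = FALSE])^2))
  cr <- cross3_rows(v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE],
                    v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE])
  area <- 0.5 * sqrt(rowSums(cr^2))
  s <- (a + b + c3) / 2
  q <- (a * b * c3 / (4 * area)) / (2 * area / s)
  q[!is.finite(q) | area <= 0] <- Inf
  q
}

#' Cutting strategy
#'
#' How cut points are embedded into the mesh: `"approximation"` snaps every
#' cut point to the nearest endpoint of its edge (topology preserved),
#' `"subdivision"` inserts every cut point as a new vertex, and `"hybrid"`
#' snaps a cut point only when its parametric distance to an endpoint is at
#' most `threshold` (fraction of the edge), subdividing otherwise. The limit
#' cases coincide: `hybrid(0)` is subdivision and `hybrid(0.5)` is
#' approximation; the named modes are aliases for those thresholds. The
#' default hybrid threshold is 0.10.
#'
#' @param mode `"approximation"`, `"subdivision"` or `"hybrid"`.
#' @param threshold snapping band as a fraction of edge length, in
#'   `[0, 0.5]`; used only by `"hybrid"`.
#' @return An object of class `cut_strategy`.
#' @export
cut_strategy <- function(mode = c("hybrid", "approximation", "subdivision"),
                         threshold = 0.10) {
  mode <- match.arg(mode)
  if (mode == "hybrid") {
    if (threshold < 0 || threshold > 0.5)
      stop("hybrid threshold must be in [0, 0.5]")
  } else {
    threshold <- if (mode == "approximation") 0.5 else 0
  }
  structure(list(mode = mode, threshold = threshold),
            class = "cut_strategy")
}

# Best triangulation of a small convex polygon chain (vertices in order):
# dynamic programme minimizing total q (equivalently mean q, since any
# triangulation of an n-gon has n - 2 triangles). Returns index triples.
best_polygon_triangulation <- function(pos) {
  n <- nrow(pos)
  if (n < 3L) return(NULL)
  qmemo <- array(NA_real_, c(n, n, n))
  qual <- function(i, k, j) {
    if (is.na(qmemo[i, k, j])) {
      q <- tryCatch(triangle_quality(pos[i, ], pos[k, ], pos[j, ])$q,
                    error = function(e) Inf)
      qmemo[i, k, j] <<- if (is.finite(q)) q else 1e6  # penalize slivers
    }
    qmemo[i, k, j]
  }
  best <- function(i, j) {
    if (j - i < 2L) return(list(score = 0, tris = NULL))
    out <- list(score = Inf, tris = NULL)
    for (k in (i + 1L):(j - 1L)) {
      l <- best(i, k)
      r <- best(k, j)
      sc <- l$score + r$score + qual(i, k, j)
      if (sc < out$score)
        out <- list(score = sc, tris = rbind(l$tris, c(i, k, j), r$tris))
    }
    out
  }
  best(1L, n)$tris
}

#' Embed cut points into the mesh
#'
#' Applies a [cut_strategy] to the cut points of all layers, producing a
#' mesh in which the fracture line is realized as a connected set of edges:
#' snapped cut points reuse existing vertices; subdivided ones insert a new
#' vertex on their edge, and affected faces are re-triangulated choosing the
#' candidate split with the best (lowest) mean quality ratio q. Surface area
#' is conserved exactly (all strategies re-triangulate the same polygons).
#'
#' @param model a [cortical_bone].
#' @param cuts a list of [compute_cut_points()] results (one per layer).
#' @param strategy a [cut_strategy].
#' @return A list of class `embedded_cuts`: `model` (mesh with cuts
#'   embedded), `fracture_edges` (data frame `v1`, `v2`, `line`, `layer`)
#'   and `n_subdivided` / `n_snapped` counts.
#' @export
embed_cuts <- function(model, cuts, strategy = cut_strategy("hybrid", 0.10)) {
  stopifnot(inherits(model, "cortical_bone"),
            inherits(strategy, "cut_strategy"))
  mesh <- model$mesh
  pts_list <- list()
  pairs_list <- list()
  off <- 0L
  for (cp in cuts) {
    if (is.null(cp$points)) next
    df <- cp$points
    df$gid <- df$id + off
    pr <- cp$pairs
    if (!is.null(pr)) {
      pr[, 1:2] <- pr[, 1:2] + off
      pairs_list[[length(pairs_list) + 1L]] <- pr
    }
    pts_list[[length(pts_list) + 1L]] <- df
    off <- off + nrow(df)
  }
  if (!length(pts_list)) stop("no cut points to embed")
  pts <- do.call(rbind, pts_list)
  pairs <- do.call(rbind, pairs_list)

  thr <- strategy$threshold
  d_end <- pmin(pts$t, 1 - pts$t)
  snap <- d_end <= thr + 1e-12

  verts <- mesh$vertices
  target <- integer(nrow(pts))
  # Per-edge processing: order cuts along the edge, merge coincident ones,
  # veto snaps that would merge cuts from different lines onto one vertex.
  ekey <- paste(pts$v1, pts$v2)
  for (k in unique(ekey)) {
    idx <- which(ekey == k)
    idx <- idx[order(pts$t[idx])]
    used_vertex <- integer(0)
    used_line <- integer(0)
    for (i in idx) {
      if (snap[i]) {
        tv <- if (pts$t[i] < 0.5) pts$v1[i] else pts$v2[i]
        clash <- tv %in% used_vertex &&
          any(used_line[used_vertex == tv] != pts$line[i])
        if (clash && d_end[i] > 1e-9) {
          snap[i] <- FALSE  # another line already owns this vertex
        } else {
          target[i] <- tv
          used_vertex <- c(used_vertex, tv)
          used_line <- c(used_line, pts$line[i])
          next
        }
      }
      # Subdivide: merge with an already-processed coincident cut here.
      prev <- idx[idx != i & !snap[idx] & target[idx] > nrow(mesh$vertices)]
      hit <- prev[abs(pts$t[prev] - pts$t[i]) < 1e-9]
      if (length(hit)) {
        target[i] <- target[hit[1]]
      } else {
        verts <- rbind(verts,
                       (1 - pts$t[i]) * mesh$vertices[pts$v1[i], ] +
                         pts$t[i] * mesh$vertices[pts$v2[i], ])
        target[i] <- nrow(verts)
      }
    }
  }

  # Splits per undirected edge (subdivided cuts only).
  sub <- which(!snap)
  split_by_edge <- split(data.frame(t = pts$t[sub], vid = target[sub]),
                         ekey[sub])

  # Crossing-pair bookkeeping: chords per face (a face may carry several
  # chords when the fracture line touches one of its edges at a corner).
  face_chords <- list()
  if (!is.null(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      fid <- as.character(pairs[r, 3])
      face_chords[[fid]] <- c(face_chords[[fid]],
                              list(c(pairs[r, 1], pairs[r, 2])))
    }
  }
  gid_row <- match(seq_len(off), pts$gid)
  pt_line <- pts$line
  pt_layer <- pts$layer

  # Faces needing a rebuild: those with a crossing pair and any face
  # adjacent to a split edge (splits propagate to both incident faces).
  et <- mesh_edge_table(mesh)
  et_key <- paste(et$v1, et$v2)
  split_faces <- unique(et$face[et_key %in% names(split_by_edge)])
  faces_to_fix <- sort(unique(c(as.integer(names(face_chords)),
                                split_faces)))

  new_faces <- list()
  new_labels <- list()
  frac_edges <- list()
  keep <- rep(TRUE, nrow(mesh$faces))

  for (fid in faces_to_fix) {
    fv <- mesh$faces[fid, ]
    # Polygon: corners with split vertices inserted along each directed edge.
    poly <- integer(0)
    for (j in 1:3) {
      a <- fv[j]
      b <- fv[j %% 3 + 1]
      poly <- c(poly, a)
      k <- paste(min(a, b), max(a, b))
      sp <- split_by_edge[[k]]
      if (!is.null(sp)) {
        ord <- if (a < b) order(sp$t) else order(-sp$t)
        poly <- c(poly, sp$vid[ord])
      }
    }
    # Resolve chords to target vertices and flag fracture edges.
    chords <- list()
    for (pr in face_chords[[as.character(fid)]]) {
      ia <- gid_row[pr[1]]
      ib <- gid_row[pr[2]]
      va <- target[ia]
      vb <- target[ib]
      if (va == vb) next  # collapsed pair: path passes through a vertex
      frac_edges[[length(frac_edges) + 1L]] <-
        data.frame(v1 = min(va, vb), v2 = max(va, vb),
                   line = pt_line[ia], layer = pt_layer[ia])
      chords[[length(chords) + 1L]] <- c(va, vb)
    }
    if (length(poly) == 3L) {
      # Pure snapping: geometry unchanged, chords lie on existing edges.
      keep[fid] <- TRUE
      next
    }
    keep[fid] <- FALSE
    lab <- mesh$labels[fid]
    # Split the face polygon along each chord, then triangulate each piece
    # choosing the candidate triangulation with the lowest mean q.
    pieces <- list(poly)
    for (ch in chords) {
      placed <- FALSE
      for (pi in seq_along(pieces)) {
        pp <- pieces[[pi]]
        ia_p <- match(ch[1], pp)
        ib_p <- match(ch[2], pp)
        if (is.na(ia_p) || is.na(ib_p)) next
        placed <- TRUE
        lo <- min(ia_p, ib_p)
        hi <- max(ia_p, ib_p)
        if ((hi - lo == 1L) || (lo == 1L && hi == length(pp))) break
        pieces[[pi]] <- pp[lo:hi]
        pieces[[length(pieces) + 1L]] <- pp[c(hi:length(pp), 1:lo)]
        break
      }
      if (!placed)
        stop("fracture chords cross inside face ", fid,
             ": refine the mesh or simplify the pattern")
    }
    for (pp in pieces) {
      tris <- best_polygon_triangulation(verts[pp, , drop = FALSE])
      if (is.null(tris)) next
      for (r in seq_len(nrow(tris))) {
        new_faces[[length(new_faces) + 1L]] <- pp[tris[r, ]]
        new_labels[[length(new_labels) + 1L]] <- lab
      }
    }
  }

  fmat <- rbind(mesh$faces[keep, , drop = FALSE],
                do.call(rbind, new_faces))
  labs <- c(mesh$labels[keep], unlist(new_labels))
  out_mesh <- trimesh(verts, fmat, labs)
  fe <- if (length(frac_edges)) do.call(rbind, frac_edges) else
    data.frame(v1 = integer(), v2 = integer(), line = integer(),
               layer = character())
  if (nrow(fe)) {
    # Mod-2 reduction per line and layer: an edge traversed twice is an
    # out-and-back sliver collapsed by snapping and bounds no region.
    k <- paste(fe$v1, fe$v2, fe$line, fe$layer)
    mult <- table(k)
    fe <- fe[!duplicated(k) & (mult[k] %% 2L == 1L), , drop = FALSE]
    rownames(fe) <- NULL
  }
  # The embedded fracture line must chain into a closed cycle per line and
  # layer (degenerate collapsed pairs pass through shared vertices).
  for (li in unique(fe$line)) for (ly in unique(fe$layer)) {
    sub_e <- fe[fe$line == li & fe$layer == ly, ]
    if (nrow(sub_e) == 0L) next
    deg <- table(c(sub_e$v1, sub_e$v2))
    if (any(deg != 2L) && nrow(sub_e) > 2L)
      warning(sprintf(
        "fracture line %d (%s layer) does not close cleanly (%d odd-degree vertices)",
        li, ly, sum(deg != 2L)))
  }
  out <- model
  out$mesh <- out_mesh
  structure(list(model = out, fracture_edges = fe,
                 n_snapped = sum(snap), n_subdivided = sum(!snap),
                 strategy = strategy),
            class = "embedded_cuts")
}

#' @export
print.embedded_cuts <- function(x, ...) {
  cat(sprintf(
    "embedded_cuts (%s, threshold %.2f): %d snapped, %d subdivided, %d fracture edges\n",
    x$strategy$mode, x$strategy$threshold, x$n_snapped, x$n_subdivided,
    nrow(x$fracture_edges)))
  invisible(x)
}

#' Identify bone fragments
#'
#' Labels every face of the cut mesh by connected region: region growing
#' over face adjacency that never crosses a fracture edge (the seeded
#' flood-fill view of fragment identification; the result is independent of
#' seed choice by construction of connected components).
#'
#' @param mesh a [trimesh] with embedded fracture edges.
#' @param fracture_edges data frame with columns `v1`, `v2` (as produced by
#'   [embed_cuts()]).
#' @return An object of class `fragment_labeling`: integer `face_fragment`
#'   (per-face fragment id) and `n_fragments`.
#' @export
identify_fragments <- function(mesh, fracture_edges) {
  et <- mesh_edge_table(mesh)
  key <- paste(et$v1, et$v2)
  frac_keys <- if (nrow(fracture_edges))
    unique(paste(pmin(fracture_edges$v1, fracture_edges$v2),
                 pmax(fracture_edges$v1, fracture_edges$v2)))
  else character()
  open_edge <- !(key %in% frac_keys)
  sp <- split(et$face[open_edge], key[open_edge])
  sp <- sp[lengths(sp) == 2L]
  m <- nrow(mesh$faces)
  if (length(sp)) {
    el <- do.call(rbind, sp)
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, m - igraph::vcount(g)))
    comp <- igraph::components(g)$membership[seq_len(m)]
  } else comp <- seq_len(m)
  comp <- as.integer(factor(comp))
  structure(list(face_fragment = comp,
                 n_fragments = max(comp)),
            class = "fragment_labeling")
}

#' @export
print.fragment_labeling <- function(x, ...) {
  cat(sprintf("fragment_labeling: %d fragments (%s faces)\n",
              x$n_fragments,
              paste(tabulate(x$face_fragment), collapse = ", ")))
  invisible(x)
}
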