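#' Extract fracture contours of one fracture interface
#'
#' Chains the embedded fracture edges of one pattern line into closed,
#' ordered vertex loops, one per cortical layer. The two loops bound the
#' annular fracture wall across the cortical thickness; their orientations
#' are made consistent (same winding about the loop normal).
#'
#' @param mesh the cut [trimesh] (from [embed_cuts()]).
#' @param fracture_edges data frame from [embed_cuts()].
#' @param line pattern line id.
#' @return An object of class `fracture_contours`: integer vertex-id vectors
#'   `outer` and `inner` (ordered, first vertex not repeated), plus `line`.
#' @export
extract_fracture_contours <- function(mesh, fracture_edges, line = 1L) {
  chain_loop <- function(ed, what) {
    if (nrow(ed) == 0L)
      stop(what, " layer has no fracture edges for line ", line)
    nb <- split(c(ed$v2, ed$v1), c(ed$v1, ed$v2))
    deg <- lengths(nb)
    if (any(deg != 2L))
      stop(sprintf(
        "fracture contour (%s layer, line %d) does not close: %d vertices of degree != 2",
        what, line, sum(deg != 2L)))
    start <- ed$v1[1]
    loop <- c(start, nb[[as.character(start)]][1])
    repeat {
      cur <- loop[length(loop)]
      prev <- loop[length(loop) - 1L]
      nxt <- setdiff(nb[[as.character(cur)]], prev)
      if (length(nxt) != 1L)
        stop("ambiguous fracture contour at vertex ", cur)
      if (nxt == start) break
      loop <- c(loop, nxt)
      if (length(loop) > 2L * nrow(ed))
        stop("fracture contour (", what, " layer) failed to close")
    }
    loop
  }
  fo <- fracture_edges[fracture_edges$line == line &
                         fracture_edges$layer == "outer", , drop = FALSE]
  fi <- fracture_edges[fracture_edges$line == line &
                         fracture_edges$layer == "inner", , drop = FALSE]
  lo <- chain_loop(fo, "outer")
  li <- chain_loop(fi, "inner")
  # Consistent winding: flip the inner loop if its normal opposes the
  # outer loop's.
  if (sum(newell_normal(mesh$vertices[lo, , drop = FALSE]) *
            newell_normal(mesh$vertices[li, , drop = FALSE])) < 0)
    li <- rev(li)
  structure(list(outer = lo, inner = li, line = line),
            class = "fracture_contours")
}

# Newell's method: area-weighted polygon normal (robust for non-planar
# closed polylines).
newell_normal <- function(p) {
  q <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  c(sum((p[, 2] - q[, 2]) * (p[, 3] + q[, 3])),
    sum((p[, 3] - q[, 3]) * (p[, 1] + q[, 1])),
    sum((p[, 1] - q[, 1]) * (p[, 2] + q[, 2])))
}

# Normalized arc-length fractions of loop points (fraction 0 at point 1).
loop_fractions <- function(p) {
  seg <- sqrt(rowSums((rbind(p[-1, , drop = FALSE],
                             p[1, , drop = FALSE]) - p)^2))
  cs <- cumsum(c(0, seg))
  cs[-length(cs)] / cs[length(cs)]
}

# Point on a closed polyline at arc fraction f.
loop_point_at <- function(p, f) {
  fr <- loop_fractions(p)
  n <- nrow(p)
  f <- f %% 1
  i <- findInterval(f, fr)
  i[i < 1L] <- 1L
  nxt <- ifelse(i == n, 1L, i + 1L)
  f_hi <- ifelse(i == n, 1, fr[pmin(i + 1L, n)])
  w <- (f - fr[i]) / pmax(f_hi - fr[i], .Machine$double.eps)
  (1 - w) * p[i, , drop = FALSE] + w * p[nxt, , drop = FALSE]
}

# Arc-length zipper between two closed loops of vertex ids (same winding):
# marches both loops by arc fraction, emitting a consistent triangle strip.
# Loop A is traversed forward, loop B appears reversed on the boundary, as
# an annulus requires.
ribbon_triangulate <- function(verts, loopA, loopB) {
  pa <- verts[loopA, , drop = FALSE]
  pb <- verts[loopB, , drop = FALSE]
  # Align loop B's start with loop A's.
  j0 <- which.min(colSums((t(pb) - pa[1, ])^2))
  loopB <- c(loopB[j0:length(loopB)], loopB[seq_len(j0 - 1L)])
  pb <- verts[loopB, , drop = FALSE]
  fa <- c(loop_fractions(pa), 1)
  fb <- c(loop_fractions(pb), 1)
  na <- length(loopA)
  nb <- length(loopB)
  ia <- 1L
  jb <- 1L
  tris <- matrix(0L, nrow = na + nb, ncol = 3L)
  k <- 0L
  wrapA <- function(i) loopA[(i - 1L) %% na + 1L]
  wrapB <- function(j) loopB[(j - 1L) %% nb + 1L]
  while (ia <= na || jb <= nb) {
    adv_a <- jb > nb || (ia <= na && fa[ia + 1L] <= fb[jb + 1L])
    k <- k + 1L
    if (adv_a) {
      tris[k, ] <- c(wrapA(ia), wrapA(ia + 1L), wrapB(jb))
      ia <- ia + 1L
    } else {
      tris[k, ] <- c(wrapA(ia), wrapB(jb + 1L), wrapB(jb))
      jb <- jb + 1L
    }
  }
  tris[seq_len(k), , drop = FALSE]
}

# Constrained Lawson flips: improve the triangulation toward the (locally)
# Delaunay / max-min-angle optimum without touching constraint edges.
lawson_flip <- function(verts, faces, constrained_keys, vclass = NULL,
                        max_sweeps = 15) {
  min_angle <- function(a, b, c3) {
    e1 <- vnorm(b - c3); e2 <- vnorm(a - c3); e3 <- vnorm(a - b)
    s <- sort(c(e1, e2, e3))
    if (s[1] <= 0) return(0)
    # smallest angle opposite the shortest side
    cosv <- (s[2]^2 + s[3]^2 - s[1]^2) / (2 * s[2] * s[3])
    acos(pmin(pmax(cosv, -1), 1))
  }
  for (sweep in seq_len(max_sweeps)) {
    m <- nrow(faces)
    va <- c(faces[, 1], faces[, 2], faces[, 3])
    vb <- c(faces[, 2], faces[, 3], faces[, 1])
    key <- paste(pmin(va, vb), pmax(va, vb))
    key_set <- new.env(parent = emptyenv())
    for (kk in key) assign(kk, TRUE, envir = key_set)
    fidx <- rep(seq_len(m), 3L)
    byk <- split(seq_along(key), key)
    flipped <- FALSE
    used <- logical(m)
    for (kk in names(byk)) {
      occ <- byk[[kk]]
      if (length(occ) != 2L || kk %in% constrained_keys) next
      f1 <- fidx[occ[1]]
      f2 <- fidx[occ[2]]
      if (used[f1] || used[f2]) next
      u <- va[occ[1]]; v <- vb[occ[1]]  # directed in f1
      p <- setdiff(faces[f1, ], c(u, v))
      q <- setdiff(faces[f2, ], c(u, v))
      if (length(p) != 1L || length(q) != 1L || p == q) next
      # Never create a diagonal joining two vertices of the same contour
      # loop: it could coincide with a shell edge (or fold the wall flat).
      if (!is.null(vclass) && vclass[p] == vclass[q] && vclass[p] != 0L)
        next
      dk <- paste(min(p, q), max(p, q))
      if (exists(dk, envir = key_set)) next  # diagonal already present
      cur <- min(min_angle(verts[u, ], verts[v, ], verts[p, ]),
                 min_angle(verts[u, ], verts[v, ], verts[q, ]))
      new <- min(min_angle(verts[p, ], verts[u, ], verts[q, ]),
                 min_angle(verts[q, ], verts[v, ], verts[p, ]))
      if (new > cur + 1e-10) {
        faces[f1, ] <- c(p, u, q)
        faces[f2, ] <- c(q, v, p)
        used[f1] <- used[f2] <- TRUE
        assign(dk, TRUE, envir = key_set)
        flipped <- TRUE
      }
    }
    if (!flipped) break
  }
  faces
}

#' Perturbation configuration for the fracture surface
#'
#' Two roughness models: `"pre_triangulation"` displaces the interior
#' (mid-thickness) fracture-zone vertices along the local wall normal before
#' the wall is triangulated; `"post_triangulation"` refines the triangulated
#' wall by fanning each triangle from its centroid displaced along the face
#' normal. Displacements are drawn uniformly from `[-tau, tau]` (signed,
#' symmetric; set `one_sided = TRUE` for `[0, tau]`). `tau` is typically
#' 0.1–1.0 mm. `"none"` leaves the wall flat.
#'
#' @param method `"none"`, `"pre_triangulation"` or `"post_triangulation"`.
#' @param tau maximum displacement magnitude (mm), in `[0, 1]`.
#' @param seed root RNG seed; each fracture interface derives a child seed
#'   from it, so results do not depend on interface order.
#' @param one_sided draw from `[0, tau]` instead of `[-tau, tau]`.
#' @return An object of class `perturbation_config`.
#' @export
perturbation_config <- function(method = c("none", "pre_triangulation",
                                           "post_triangulation"),
                                tau = 0.3, seed = 1, one_sided = FALSE) {
  method <- match.arg(method)
  if (tau < 0 || tau > 1)
    stop("tau must be in [0, 1] mm")
  structure(list(method = method, tau = tau, seed = as.integer(seed),
                 one_sided = one_sided),
            class = "perturbation_config")
}

draw_displacements <- function(n, config) {
  if (config$method == "none" || config$tau == 0) return(numeric(n))
  if (config$one_sided) stats::runif(n, 0, config$tau)
  else stats::runif(n, -config$tau, config$tau)
}

#' Triangulate the fracture zone of one interface
#'
#' Builds the annular fracture wall between the outer and inner contour
#' loops: an intermediate mid-thickness ring of new vertices is inserted,
#' the two ribbons (outer-mid, mid-inner) are triangulated by an arc-length
#' zipper, and constrained Lawson (max-min-angle, i.e. locally Delaunay)
#' edge flips improve the interior. The contour loops are constraint edges
#' and appear unchanged on the wall boundary; nothing inside the inner loop
#' (the medullary canal) is ever meshed. With
#' `method = "pre_triangulation"` the mid-ring vertices are displaced along
#' the wall normal before triangulation (bounded by `tau`, with halving
#' retries if a displacement degenerates a wall triangle); with
#' `"post_triangulation"` the finished wall is refined by displaced-centroid
#' fans (triangle count exactly triples, boundary untouched).
#'
#' @param verts vertex matrix of the cut mesh (new mid-ring / centroid
#'   vertices are appended).
#' @param contours a [fracture_contours].
#' @param config a [perturbation_config].
#' @param seed interface seed (already derived from the root seed).
#' @return list with `verts` (extended matrix), `faces` (wall triangles,
#'   global ids), `boundary_keys` (edge keys of the contour loops).
#' @export
triangulate_fracture_zone <- function(verts, contours,
                                      config = perturbation_config("none"),
                                      seed = 1) {
  lo <- contours$outer
  li <- contours$inner
  po <- verts[lo, , drop = FALSE]
  # Align the inner loop's start (arbitrary from chaining) with the outer
  # loop's, so mid-ring averaging pairs radially corresponding points.
  pi_ <- verts[li, , drop = FALSE]
  j0 <- which.min(colSums((t(pi_) - po[1, ])^2))
  li <- c(li[j0:length(li)], li[seq_len(j0 - 1L)])
  pi_ <- verts[li, , drop = FALSE]
  n_m <- max(length(lo), length(li))
  fr <- (seq_len(n_m) - 1) / n_m
  so <- loop_point_at(po, fr)
  si <- loop_point_at(pi_, fr)
  mid <- (so + si) / 2

  if (config$method == "pre_triangulation" && config$tau > 0) {
    disp <- with_seed(seed, draw_displacements(n_m, config))
    nxt <- c(2:n_m, 1)
    prv <- c(n_m, seq_len(n_m - 1))
    tangent <- mid[nxt, , drop = FALSE] - mid[prv, , drop = FALSE]
    across <- si - so
    nrm <- cross3_rows(tangent, across)
    len <- sqrt(rowSums(nrm^2))
    len[len == 0] <- 1
    nrm <- nrm / len
    thick <- sqrt(rowSums(across^2))
    for (try in 0:5) {
      cand <- mid + disp * nrm
      # degenerate-wall guard: displaced point must stay clear of both
      # contours relative to the local thickness
      bad <- sqrt(rowSums((cand - so)^2)) < 0.1 * thick |
        sqrt(rowSums((cand - si)^2)) < 0.1 * thick
      if (!any(bad)) break
      if (try == 5)
        stop("perturbation keeps degenerating the fracture wall; ",
             "reduce tau")
      disp[bad] <- disp[bad] / 2
    }
    mid <- mid + disp * nrm
  }

  mid_ids <- nrow(verts) + seq_len(n_m)
  verts <- rbind(verts, mid)
  t1 <- ribbon_triangulate(verts, lo, mid_ids)
  t2 <- ribbon_triangulate(verts, mid_ids, li)
  faces <- rbind(t1, t2)
  bk <- function(loop) {
    nx <- c(loop[-1], loop[1])
    paste(pmin(loop, nx), pmax(loop, nx))
  }
  boundary <- c(bk(lo), bk(li))
  vclass <- integer(nrow(verts))  # 0 = interior (flippable-to)
  vclass[lo] <- 1L
  vclass[li] <- 2L
  faces <- lawson_flip(verts, faces, boundary, vclass)

  if (config$method == "post_triangulation") {
    res <- perturb_fracture_surface(verts, faces, config, seed)
    verts <- res$verts
    faces <- res$faces
  }
  list(verts = verts, faces = faces, boundary_keys = boundary,
       mid_ids = mid_ids)
}

#' Centroid-fan refinement of a fracture wall (post-triangulation method)
#'
#' Replaces each wall triangle by three triangles fanning from its centroid
#' displaced along the face normal by a seeded uniform draw bounded by
#' `tau`. The boundary loops are untouched and the triangle count exactly
#' triples.
#'
#' @param verts vertex matrix (centroids appended).
#' @param faces wall triangles.
#' @param config a [perturbation_config].
#' @param seed interface seed.
#' @return list with updated `verts` and `faces`.
#' @export
perturb_fracture_surface <- function(verts, faces, config, seed = 1) {
  m <- nrow(faces)
  a <- verts[faces[, 1], , drop = FALSE]
  b <- verts[faces[, 2], , drop = FALSE]
  c3 <- verts[faces[, 3], , drop = FALSE]
  cen <- (a + b + c3) / 3
  nrm <- cross3_rows(b - a, c3 - a)
  len <- sqrt(rowSums(nrm^2))
  len[len == 0] <- 1
  nrm <- nrm / len
  disp <- with_seed(seed, draw_displacements(m, config))
  cen <- cen + disp * nrm
  cen_ids <- nrow(verts) + seq_len(m)
  verts <- rbind(verts, cen)
  newf <- matrix(0L, nrow = 3L * m, ncol = 3L)
  newf[seq(1, 3 * m, by = 3), ] <- cbind(faces[, 1], faces[, 2], cen_ids)
  newf[seq(2, 3 * m, by = 3), ] <- cbind(faces[, 2], faces[, 3], cen_ids)
  newf[seq(3, 3 * m, by = 3), ] <- cbind(faces[, 3], faces[, 1], cen_ids)
  list(verts = verts, faces = newf)
}
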