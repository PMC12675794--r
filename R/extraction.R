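#' Detect the fracture zone on a fragment mesh
#'
#' Locates fracture points on a fractured fragment without any labeling:
#' the fragment's oriented bounding box (principal-axis box) is discretized
#' into a grid over the cross-section, the grid is swept parallel to the
#' long axis, and in each occupied column the extremal surface vertices
#' along the sweep direction are marked as candidates, split into outer- and
#' inner-cortical candidates by radial distance relative to the local
#' mid-thickness. An end whose candidate relief (max minus min axial
#' position across columns) stays below `min_relief` is a flat machined end
#' (shaft end or cap), not a fracture; if neither end shows relief the
#' result is empty with a warning.
#'
#' A perfectly flat unperturbed transverse fracture is geometrically
#' indistinguishable from a cap and falls below the relief threshold by
#' design; pass `end` explicitly for that case.
#'
#' @param fragment a [trimesh].
#' @param grid_n grid columns across the bounding-box cross-section.
#' @param min_relief minimum axial relief (mm) for an end to count as a
#'   fracture zone.
#' @param end `"auto"`, `"+"` or `"-"`: which end of the long axis carries
#'   the fracture.
#' @return An object of class `fracture_zone`: `points` (n x 3, mm),
#'   `layer` (`"outer"`/`"inner"`), `axis`, `origin`, `radius` (estimated
#'   outer radius), `empty` flag.
#' @export
detect_fracture_zone <- function(fragment, grid_n = 20, min_relief = 0.1,
                                 end = c("auto", "+", "-")) {
  stopifnot(inherits(fragment, "trimesh"))
  end <- match.arg(end)
  v <- fragment$vertices
  ctr <- colMeans(v)
  vc <- sweep(v, 2, ctr)
  # Tube axis from area-weighted face normals: wall normals span the
  # cross-section plane, so the axis is the least-represented direction.
  # (Vertex PCA tilts on fragments with slanted fracture ends.)
  nrm <- face_normals(fragment)
  ar <- face_areas(fragment)
  M <- crossprod(nrm * sqrt(ar))
  eg <- eigen(M, symmetric = TRUE)
  ax <- eg$vectors[, 3]
  if (ax[which.max(abs(ax))] < 0) ax <- -ax  # deterministic sign
  B <- axis_basis(ax)
  c1 <- as.vector(vc %*% B[, 3])
  c2 <- as.vector(vc %*% B[, 1])
  c3 <- as.vector(vc %*% B[, 2])
  # Recenter the cross-section by an algebraic (Kasa) circle fit: the
  # vertex centroid sits off-axis on fragments with slanted ends.
  A <- cbind(2 * c2, 2 * c3, 1)
  sol <- qr.solve(A, c2^2 + c3^2)
  c2 <- c2 - sol[1]
  c3 <- c3 - sol[2]
  ctr <- ctr + sol[1] * B[, 1] + sol[2] * B[, 2]
  r <- sqrt(c2^2 + c3^2)
  r_hi <- stats::quantile(r, 0.95)
  r_lo <- stats::quantile(r, 0.05)
  mid <- (r_hi + r_lo) / 2
  band <- ifelse(r >= (mid + r_hi) / 2, "outer",
                 ifelse(r <= (mid + r_lo) / 2, "inner", NA))
  cell <- function(x, lo, hi)
    pmin(pmax(floor((x - lo) / (hi - lo) * grid_n), 0), grid_n - 1L)
  col_id <- cell(c2, min(c2), max(c2) + 1e-9) * grid_n +
    cell(c3, min(c3), max(c3) + 1e-9)

  pick_end <- function(sgn) {
    sel <- which(!is.na(band))
    key <- paste(col_id[sel], band[sel])
    ext <- tapply(seq_along(sel), key, function(i) {
      ii <- sel[i]
      ii[which.max(sgn * c1[ii])]
    })
    idx <- as.integer(ext)
    # Local angular consistency: a column extreme sitting far behind the
    # extremes of neighbouring angles is a shaft vertex picked up by a grid
    # column that straddles a cell boundary, not a fracture point. On a
    # machined flat end this filter strips the stragglers and the relief
    # collapses to ~0, which is how flat ends are rejected.
    keep_tol <- 0.25 * diff(stats::quantile(c1[idx], c(0.1, 0.9))) + 1.0
    th_all <- atan2(c3[idx], c2[idx])
    keep <- rep(TRUE, length(idx))
    for (bn in c("outer", "inner")) {
      bi <- which(band[idx] == bn)
      if (length(bi) < 5L) next
      for (i in bi) {
        nbr <- bi[abs(((th_all[bi] - th_all[i] + pi) %% (2 * pi)) - pi) <=
                    0.15]
        if (sgn * c1[idx[i]] < max(sgn * c1[idx[nbr]]) - keep_tol)
          keep[i] <- FALSE
      }
    }
    idx <- idx[keep]
    # robust relief: lone stragglers must not make a flat end look rough
    relief <- if (length(idx) > 4L)
      diff(stats::quantile(c1[idx], c(0.05, 0.95))) else 0
    list(idx = idx, relief = relief, sgn = sgn)
  }
  cand <- switch(end,
                 "+" = pick_end(1),
                 "-" = pick_end(-1),
                 auto = {
                   a <- pick_end(1)
                   b <- pick_end(-1)
                   if (a$relief >= b$relief) a else b
                 })
  if (cand$relief < min_relief) {
    warning(sprintf(
      "no fracture zone detected (relief %.3f mm below %.3f mm)",
      cand$relief, min_relief))
    return(structure(list(points = matrix(numeric(), ncol = 3),
                          layer = character(), axis = ax, origin = ctr,
                          radius = as.numeric(r_hi), empty = TRUE),
                     class = "fracture_zone"))
  }
  idx <- cand$idx
  structure(list(points = v[idx, , drop = FALSE],
                 layer = unname(band[idx]),
                 axis = ax, origin = ctr, radius = as.numeric(r_hi),
                 empty = FALSE),
            class = "fracture_zone")
}

#' @export
print.fracture_zone <- function(x, ...) {
  if (x$empty) cat("fracture_zone: empty (no fracture detected)\n")
  else cat(sprintf(
    "fracture_zone: %d points (%d outer, %d inner), est. radius %.2f mm\n",
    nrow(x$points), sum(x$layer == "outer"), sum(x$layer == "inner"),
    x$radius))
  invisible(x)
}

# Douglas-Peucker simplification of an open polyline (2D).
douglas_peucker <- function(p, tol) {
  n <- nrow(p)
  if (n <= 2L) return(p)
  a <- p[1, ]
  b <- p[n, ]
  ab <- b - a
  len <- sqrt(sum(ab^2))
  d <- if (len < 1e-12) sqrt(rowSums(sweep(p, 2, a)^2)) else
    abs((p[, 1] - a[1]) * ab[2] - (p[, 2] - a[2]) * ab[1]) / len
  k <- which.max(d)
  if (d[k] <= tol) return(p[c(1, n), , drop = FALSE])
  rbind(douglas_peucker(p[1:k, , drop = FALSE], tol)[-k, , drop = FALSE],
        douglas_peucker(p[k:n, , drop = FALSE], tol))
}

#' Convert detected fracture-zone points to a 2D pattern
#'
#' Maps the 3D fracture points of each layer through a cylindrical unwrap to
#' `(u, v)` coordinates, chains them into a polyline by nearest-neighbour
#' continuation (with wrap-aware distances), simplifies the chain with a
#' Douglas-Peucker pass, and closes the loop when the endpoints meet. When a
#' [projection_cylinder] is supplied (self-validation against a known bone)
#' its frame is used, making the extracted pattern directly comparable with
#' the pattern that generated the fracture; otherwise the zone's own
#' principal frame defines an arbitrary reference meridian.
#'
#' @param zone a [detect_fracture_zone()] result.
#' @param cylinder optional [projection_cylinder] defining the unwrap frame.
#' @param simplify_tol Douglas-Peucker tolerance (mm); `0` keeps every
#'   point.
#' @param max_jump_factor chaining sanity bound: a nearest-neighbour step
#'   longer than this multiple of the median step aborts with an ambiguity
#'   error.
#' @return A [fracture_pattern] with `source = "extracted"`.
#' @export
extract_pattern <- function(zone, cylinder = NULL, simplify_tol = 0.3,
                            max_jump_factor = 8) {
  stopifnot(inherits(zone, "fracture_zone"))
  if (zone$empty || !any(zone$layer == "outer"))
    stop("fracture zone is empty on the outer layer")
  if (!is.null(cylinder)) {
    cc <- cyl_coords(zone$points, cylinder)
    u <- cc[, "theta"] / (2 * pi)
    vv <- cc[, "h"]
    cf <- cylinder$circumference
  } else {
    B <- axis_basis(zone$axis)
    pc <- sweep(zone$points, 2, zone$origin)
    u <- (atan2(pc %*% B[, 2], pc %*% B[, 1]) %% (2 * pi)) / (2 * pi)
    vv <- as.vector(pc %*% zone$axis)
    cf <- 2 * pi * zone$radius
  }

  chain_layer <- function(sel) {
    uu <- u[sel]
    w <- vv[sel]
    n <- length(uu)
    if (n < 3L) return(NULL)
    ord <- integer(n)
    used <- logical(n)
    ord[1] <- which.min(uu)
    used[ord[1]] <- TRUE
    dists <- numeric(n - 1L)
    for (k in 2:n) {
      cur <- ord[k - 1L]
      du <- wrap_du(uu[cur], uu) * cf
      dv <- w - w[cur]
      d <- du^2 + dv^2
      d[used] <- Inf
      ord[k] <- which.min(d)
      dists[k - 1L] <- sqrt(d[ord[k]])
      used[ord[k]] <- TRUE
    }
    med <- stats::median(dists)
    bad <- which(dists > max_jump_factor * pmax(med, 1e-6))
    if (length(bad)) {
      # Nearest-neighbour chaining consumes the true curve first; a long
      # jump near the end of the chain marks leftover stragglers, which
      # are trimmed. An early jump is a genuine branching ambiguity.
      if (bad[1] < 0.85 * n)
        stop(sprintf(
          "ambiguous fracture-point chaining: step %d jumps %.2f mm (median %.2f mm)",
          bad[1], dists[bad[1]], med))
      ord <- ord[seq_len(bad[1])]
      n <- length(ord)
    }
    # unroll u along the chain, simplify in mm coordinates
    uo <- uu[ord]
    uc <- cumsum(c(uo[1], wrap_du(uo[-n], uo[-1])))
    xy <- cbind(uc * cf, w[ord])
    if (simplify_tol > 0) xy <- douglas_peucker(xy, simplify_tol)
    line <- cbind(u = (xy[, 1] / cf) %% 1, v = xy[, 2])
    # close the loop when the chain returns near its start
    gap <- sqrt((wrap_du(line[nrow(line), 1], line[1, 1]) * cf)^2 +
                  (line[nrow(line), 2] - line[1, 2])^2)
    if (gap < 3 * max(med, simplify_tol))
      line <- rbind(line, line[1, ])
    line
  }
  lo <- chain_layer(zone$layer == "outer")
  li <- chain_layer(zone$layer == "inner")
  if (is.null(lo)) stop("too few outer-layer fracture points to chain")
  # Crude class from the longitudinal extent of a single extracted line:
  # near-constant height reads as transverse, otherwise oblique.
  vext <- diff(range(lo[, 2]))
  fracture_pattern(list(lo),
                   if (is.null(li)) NULL else list(li),
                   fracture_type = if (vext < 0.05 * cf) "transverse"
                                   else "oblique",
                   source = "extracted",
                   meta = list(design_circumference = cf,
                               extracted_radius = zone$radius))
}
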