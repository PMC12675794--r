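# Cylinder fitting, unwrapping, pattern placement, cut points.

test_that("projection cylinder inherits the tube's radius and axis", {
  tube <- tube_model()
  cyl <- fit_projection_cylinder(tube, 50, 15)
  expect_equal(cyl$radius, 10, tolerance = 1e-9)
  expect_equal(abs(sum(cyl$axis * c(0, 0, 1))), 1, tolerance = 1e-9)
  expect_equal(cyl$band, c(35, 65))

  # frustum: radius equals the band-mean outer radius (brute force)
  fr <- generate_long_bone(bone_spec(
    length = 100, outer_radius = cbind(c(0, 100), c(5, 15)),
    thickness = 1.5, n_theta = 48, n_z = 40))
  cylf <- fit_projection_cylinder(fr, 50, 10, radius_band = 4)
  expect_equal(cylf$radius, generalized_radius(fr, 50, 4),
               tolerance = 1e-12)

  expect_error(fit_projection_cylinder(tube, 98, 15), "touches")
})

test_that("unwrap maps arc length exactly and inverts on an exact cylinder", {
  tube <- tube_model(n_theta = 64, n_z = 32)
  cyl <- fit_projection_cylinder(tube, 50, 15)
  ub <- unwrap_band(tube, cyl, "outer")
  # a vertex at angle pi/2 on a radius-10 cylinder unwraps to x = 5*pi
  sel <- which(abs(ub$x - pi / 2 * 10) < 1e-9)
  expect_gt(length(sel), 0)
  # rewrap every unwrapped corner: max 3D error < 1e-9 mm
  xy <- cbind(as.vector(ub$x), as.vector(ub$y))
  p3 <- cortifrac:::rewrap_points(xy, cyl)
  orig <- tube$mesh$vertices[as.vector(ub$faces), , drop = FALSE]
  expect_lt(max(abs(p3 - orig)), 1e-9)
})

test_that("unwrapped area equals the lateral band area within discretization", {
  tube <- tube_model(n_theta = 64, n_z = 32)
  cyl <- fit_projection_cylinder(tube, 50, 15)
  ub <- unwrap_band(tube, cyl, "outer")
  tri_area_2d <- function(x, y)
    abs((x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
          (x[, 3] - x[, 1]) * (y[, 2] - y[, 1])) / 2
  a2d <- sum(tri_area_2d(ub$x, ub$y))
  a3d <- sum(face_areas(tube$mesh)[ub$face_ids])
  # chordal 3D area vs unrolled arc-length area: small flattening factor
  expect_equal(a2d, a3d, tolerance = 2e-3)
  # seam-crossing faces unwrap with consistent (non-overlapping) x ranges
  expect_true(all(apply(ub$x, 1, function(r) max(r) - min(r)) <
                    cyl$circumference / 2))
})

test_that("pattern placement scales u by arc length and checks feasibility", {
  tube <- tube_model()
  cyl <- fit_projection_cylinder(tube, 50, 15)
  p <- generate_parametric_pattern("transverse", list(v0 = 50))
  pl <- place_pattern(p, cyl)
  l <- pl$outer[[1]]
  # u = 0.5 maps to x = half circumference = 10*pi
  k <- which.min(abs(p$lines_outer[[1]][, 1] - 0.5))
  expect_equal(unname(l[k, 1]), 10 * pi, tolerance = 1e-9)
  expect_equal(mean(range(l[, 2])), 50)

  # aspect feasibility mirrors the large-to-small bone case
  mk <- function(r)
    generate_parametric_pattern("transverse", list(v0 = 50),
                                design_circumference = 2 * pi * r)
  cyl_f <- structure(cyl, class = class(cyl))
  cyl_f$radius <- 13.08
  cyl_f$circumference <- 2 * pi * 13.08
  expect_silent(place_pattern(mk(9.23), cyl_f))        # ratio 1.42
  cyl_r <- cyl
  cyl_r$radius <- 2
  cyl_r$circumference <- 2 * pi * 2
  expect_error(place_pattern(mk(9.23), cyl_r), "scale-infeasible")

  # longitudinal extent beyond the band errors
  tall <- generate_parametric_pattern("spiral", list(v0 = 30, pitch = 60))
  expect_error(place_pattern(tall, cyl), "exceeds band")
})

test_that("cut points on a unit-square fixture match brute-force intersections", {
  # square (0,0)-(1,1) split along the diagonal (1)-(3); segment y = 0.5
  # from x = -0.1 to 1.1 must cross left edge, diagonal, right edge.
  verts <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  faces <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  ub <- structure(list(
    layer = "outer", face_ids = 1:2, faces = faces,
    x = rbind(verts[faces[1, ], 1], verts[faces[2, ], 1]),
    y = rbind(verts[faces[1, ], 2], verts[faces[2, ], 2]),
    vertices = verts,
    cylinder = list(circumference = 1000, band = c(-10, 10))),
    class = "unwrapped_band")
  seg <- cbind(x = c(-0.1, 1.1), y = c(0.5, 0.5))
  attr(seg, "closed") <- FALSE
  pl <- structure(list(outer = list(seg), inner = list()),
                  class = "placed_pattern")
  cp <- compute_cut_points(ub, pl)
  expect_equal(nrow(cp$points), 3L)
  # brute force over the 5 undirected edges
  edges <- rbind(c(1, 2), c(2, 3), c(1, 3), c(3, 4), c(1, 4))
  hits <- apply(edges, 1, function(e) {
    a <- verts[e[1], 1:2]
    b <- verts[e[2], 1:2]
    # crossing y = 0.5 within x in [-0.1, 1.1]
    if ((a[2] - 0.5) * (b[2] - 0.5) > 0) return(NA_real_)
    if (a[2] == b[2]) return(NA_real_)
    t <- (0.5 - a[2]) / (b[2] - a[2])
    a[1] + t * (b[1] - a[1])
  })
  expect_equal(sum(!is.na(hits)), 3L)
  expect_setequal(round(sort(cp$points$t), 6), c(0.5, 0.5, 0.5))
  # one cut point per undirected edge: edges hit are (1,4), (1,3), (2,3)
  expect_setequal(paste(cp$points$v1, cp$points$v2), c("1 4", "1 3", "2 3"))
  # and both crossing pairs are recorded with their shared faces
  expect_equal(nrow(cp$pairs), 2L)

  # a segment entirely outside all triangles yields no cut points
  seg2 <- cbind(x = c(-0.1, 1.1), y = c(5, 5))
  attr(seg2, "closed") <- FALSE
  pl2 <- structure(list(outer = list(seg2), inner = list()),
                   class = "placed_pattern")
  expect_null(compute_cut_points(ub, pl2)$points)
})

test_that("a segment through a shared vertex yields one flagged cut point", {
  # square fanned around its centre vertex (5); the line y = 1 passes
  # exactly through that shared vertex.
  verts <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 2, 0), c(0, 2, 0),
                 c(1, 1, 0))
  faces <- rbind(c(1L, 2L, 5L), c(2L, 3L, 5L), c(3L, 4L, 5L),
                 c(4L, 1L, 5L))
  ub <- structure(list(
    layer = "outer", face_ids = 1:4, faces = faces,
    x = t(apply(faces, 1, function(f) verts[f, 1])),
    y = t(apply(faces, 1, function(f) verts[f, 2])),
    vertices = verts,
    cylinder = list(circumference = 1000, band = c(-10, 10))),
    class = "unwrapped_band")
  seg <- cbind(x = c(-0.5, 2.5), y = c(1, 1))
  attr(seg, "closed") <- FALSE
  pl <- structure(list(outer = list(seg), inner = list()),
                  class = "placed_pattern")
  cp <- compute_cut_points(ub, pl, snap_tolerance = 0.1)
  # left edge, centre vertex (merged to ONE cut point), right edge
  expect_equal(nrow(cp$points), 3L)
  expect_equal(sum(cp$points$on_vertex), 1L)
  ctr <- cp$points[cp$points$on_vertex, ]
  tv <- if (ctr$t < 0.5) ctr$v1 else ctr$v2
  expect_equal(tv, 5L)
})

test_that("cut-point 3D positions lie on the mesh and transverse cuts are planar", {
  tube <- tube_model()
  cyl <- fit_projection_cylinder(tube, 50, 15)
  ub <- unwrap_band(tube, cyl, "outer")
  p <- generate_parametric_pattern("transverse", list(v0 = 51.3))
  pl <- place_pattern(p, cyl, fracture_height = 51.3)
  cp <- compute_cut_points(ub, pl)
  pos <- cbind(cp$points$px, cp$points$py, cp$points$pz)
  # on the edge between its two vertices (distance to segment ~ 0)
  a <- tube$mesh$vertices[cp$points$v1, , drop = FALSE]
  b <- tube$mesh$vertices[cp$points$v2, , drop = FALSE]
  interp <- a + cp$points$t * (b - a)
  expect_lt(max(abs(pos - interp)), 1e-9)
  # transverse pattern at height h: all cut points in the plane z = h
  expect_lt(max(abs(pos[, 3] - 51.3)), 1e-9)
  # closed pattern: even number of crossings
  expect_equal(nrow(cp$points) %% 2L, 0L)
})
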